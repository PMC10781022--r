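#' Estimate local heritability from summary statistics
#'
#' Computes a local (per-locus) SNP heritability estimate of the HESS form
#' \deqn{\hat h^2 = (N \hat\beta^T R^+ \hat\beta - p) / (N - p)}
#' with \eqn{\hat\beta = z/\sqrt{N}} in standardized units and \eqn{R^+} the
#' pseudo-inverse of the LD matrix restricted to eigenvalues at least
#' `eig_threshold` times the largest one (p = number retained). The estimate
#' is clipped to `[1e-6, 0.9]` to keep the derived precisions finite.
#'
#' @param locus A [locus_data()] object.
#' @param eig_threshold Relative eigenvalue truncation threshold in (0, 1].
#'
#' @return The clipped local heritability estimate (scalar).
#' @export
estimate_local_h2 <- function(locus, eig_threshold = 1e-3) {
  stopifnot(inherits(locus, "locus_data"),
            eig_threshold > 0, eig_threshold <= 1)
  z <- locus$z
  n <- locus$n
  eig <- eigen(locus$ld, symmetric = TRUE)
  lam_max <- eig$values[1]
  if (!is.finite(lam_max) || lam_max <= 0) {
    abort("degenerate LD matrix: no positive eigenvalues")
  }
  keep <- eig$values >= eig_threshold * lam_max
  if (!any(keep)) {
    abort("degenerate LD matrix: all eigenvalues below the truncation threshold")
  }
  p <- sum(keep)
  v <- eig$vectors[, keep, drop = FALSE]
  proj <- drop(crossprod(v, z))
  quad <- sum(proj^2 / eig$values[keep]) # z' R+ z = N beta' R+ beta
  h2 <- (quad - p) / (n - p)
  if (h2 < 1e-6) {
    inform(sprintf("estimated local h2 = %.3g floored at 1e-6", h2))
  }
  min(max(h2, 1e-6), 0.9)
}

#' Derive model precisions from local heritability
#'
#' With the trait standardized to unit variance, the residual precision is
#' `tau_y = 1/(1 - h2)` and the effect-size precision is `tau_beta = K/h2`
#' under the default strategy where each of the K effect groups carries
#' prior variance `h2/K`. The alternative strategy `"full"` gives every
#' effect the whole local heritability as prior variance (`tau_beta = 1/h2`).
#'
#' @param h2_local Local heritability in `[1e-6, 0.9]`.
#' @param K Maximum number of effect groups (>= 1).
#' @param split Either `"per_effect"` (default, prior variance `h2/K` per
#'   effect) or `"full"` (prior variance `h2` per effect).
#'
#' @return A `hyperparameters` list with elements `h2_local`, `tau_beta`,
#'   `tau_y` and `k_max`.
#' @export
derive_precisions <- function(h2_local, K, split = c("per_effect", "full")) {
  split <- match.arg(split)
  stopifnot(h2_local >= 1e-6, h2_local <= 0.9, K >= 1)
  tau_beta <- if (split == "per_effect") K / h2_local else 1 / h2_local
  structure(
    list(
      h2_local = h2_local,
      tau_beta = tau_beta,
      tau_y = 1 / (1 - h2_local),
      k_max = as.integer(K)
    ),
    class = "hyperparameters"
  )
}
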