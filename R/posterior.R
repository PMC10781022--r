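# Posterior summaries: PIPs, attainable coverage and credible sets.

#' Posterior inclusion probabilities from effect-group posteriors
#'
#' Combines per-group selection probabilities into variant-level PIPs as
#' `PIP_g = 1 - prod_k (1 - gamma_kg)`.
#'
#' @param gamma K x G matrix of selection probabilities (rows on the
#'   simplex), or a `vi_state` from [fit_vi()].
#'
#' @return Numeric vector of length G with entries in `[0, 1]`.
#' @export
compute_pip <- function(gamma) {
  if (inherits(gamma, "vi_state")) gamma <- gamma$gamma
  stopifnot(is.matrix(gamma))
  1 - apply(1 - gamma, 2, prod)
}

#' Attainable coverage of one effect group
#'
#' The posterior mass an effect group can concentrate on a single
#' LD-coherent signal: the sum of its selection probabilities over variants
#' whose squared correlation with the group's top variant is at least
#' `r2_min`. Diffuse groups (posterior spread across uncorrelated variants)
#' score low and are filtered before credible sets are reported.
#'
#' @param gamma_k Selection probabilities of one group (length G, simplex).
#' @param ld G x G LD matrix.
#' @param r2_min Minimum squared correlation with the lead variant
#'   (default 0.25).
#'
#' @return Scalar attainable coverage in `[0, 1]`.
#' @export
attainable_coverage <- function(gamma_k, ld, r2_min = 0.25) {
  lead <- which.max(gamma_k)
  sum(gamma_k[ld[, lead]^2 >= r2_min])
}

#' Build rho-level credible sets from effect-group posteriors
#'
#' For each effect group whose attainable coverage is at least `rho`, the
#' smallest prefix of variants (sorted by selection probability descending,
#' ties broken by |z| descending then variant index) with cumulative
#' probability >= `rho` forms a credible set. Groups that converged on the
#' same lead variant as an already-reported set are dropped, keeping the set
#' with the higher attainable coverage. A warning is raised when two
#' reported sets have leads in strong LD (r^2 > 0.8).
#'
#' @param gamma K x G matrix of selection probabilities or a `vi_state`.
#' @param ld G x G LD matrix.
#' @param rho Nominal coverage level in (0, 1), default 0.95.
#' @param r2_min Attainable-coverage LD threshold (default 0.25).
#' @param z Optional per-variant z-scores used for tie-breaking.
#'
#' @return A tibble with one row per set: `set_id`, `group_index`, `rho`,
#'   `attainable`, `lead`, `size`, and list-columns `members` (variant
#'   indices) and `member_probs`.
#' @export
build_credible_sets <- function(gamma, ld, rho = 0.95, r2_min = 0.25,
                                z = NULL) {
  if (inherits(gamma, "vi_state")) gamma <- gamma$gamma
  stopifnot(rho > 0, rho < 1)
  g <- ncol(gamma)
  if (is.null(z)) z <- rep(0, g)
  cand <- purrr::map(seq_len(nrow(gamma)), function(k) {
    gk <- gamma[k, ]
    att <- attainable_coverage(gk, ld, r2_min)
    if (att < rho) return(NULL)
    ord <- order(-gk, -abs(z), seq_len(g))
    size <- which(cumsum(gk[ord]) >= rho - 1e-12)[1]
    member_idx <- ord[seq_len(size)]
    member_probs <- gk[member_idx]
    tibble::tibble(
      group_index = k, rho = rho, attainable = att,
      lead = member_idx[1], size = size,
      members = list(member_idx), member_probs = list(member_probs)
    )
  })
  sets <- dplyr::bind_rows(cand)
  if (nrow(sets) == 0) {
    return(tibble::tibble(
      set_id = integer(0), group_index = integer(0), rho = numeric(0),
      attainable = numeric(0), lead = integer(0), size = integer(0),
      members = list(), member_probs = list()
    ))
  }
  # Deduplicate groups sharing a lead variant, keep the most concentrated.
  sets <- sets |>
    dplyr::arrange(.data$lead, dplyr::desc(.data$attainable)) |>
    dplyr::distinct(.data$lead, .keep_all = TRUE) |>
    dplyr::arrange(.data$group_index) |>
    dplyr::mutate(set_id = dplyr::row_number(), .before = 1)
  if (nrow(sets) > 1) {
    leads <- sets$lead
    r2 <- ld[leads, leads, drop = FALSE]^2
    if (max(r2[upper.tri(r2)]) > 0.8) {
      warn("credible sets with distinct leads in strong LD (r^2 > 0.8) were reported separately")
    }
  }
  sets
}
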