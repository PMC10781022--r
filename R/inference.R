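# Paired mean-field variational inference for the sum-of-single-effects
# model on GWAS summary statistics.
#
# Each of K effect groups k has a sparse indicator s_k ~ Multinomial(1, pi)
# selecting one variant and an effect size beta_k ~ N(0, 1/tau_beta); the
# trait is y ~ N(X S beta, I/tau_y). Substituting the summary-statistic
# sufficient statistics X'X = N R and X'y = z sqrt(N) gives coordinate
# updates that never invert the LD matrix, so rank-deficient R is fine.

# Initialize the variational state: uniform gamma, zero means.
vi_init <- function(g, k, priors, hyper, z, n) {
  tau_star <- n * hyper$tau_y + hyper$tau_beta
  list(
    gamma = matrix(1 / g, nrow = k, ncol = g),
    mu = matrix(0, nrow = k, ncol = g),
    s2 = 1 / tau_star,
    tau_star = tau_star,
    priors = priors,
    hyper = hyper,
    b = z * sqrt(n),
    n = n
  )
}

#' Update one effect group's variational posterior
#'
#' Performs the exact coordinate-ascent update for effect group `k` holding
#' the other groups fixed: the residual score removes the other groups'
#' expected contributions through the LD matrix, the conditional effect
#' posterior is Gaussian with precision `N tau_y + tau_beta`, and the
#' selection probabilities are the softmax of the per-variant log evidence
#' plus log prior.
#'
#' @param state Variational state as produced by [fit_vi()] internals.
#' @param locus A [locus_data()] object.
#' @param k Effect-group index to update (1..K).
#'
#' @return The updated state (only group `k` changes).
#' @export
update_effect_group <- function(state, locus, k) {
  stopifnot(k >= 1, k <= nrow(state$gamma))
  eff <- state$gamma * state$mu            # K x G expected effects
  other <- colSums(eff[-k, , drop = FALSE])
  r_k <- state$b - state$n * drop(locus$ld %*% other)
  tau_star <- state$tau_star
  mu_k <- state$hyper$tau_y * r_k / tau_star
  u <- log(state$priors) + 0.5 * log(state$hyper$tau_beta / tau_star) +
    0.5 * mu_k^2 * tau_star
  if (any(!is.finite(u))) {
    bad <- which(!is.finite(u))[1]
    abort(sprintf("non-finite selection score at variant %d (group %d)",
                  bad, k))
  }
  u <- u - max(u)
  w <- exp(u)
  state$gamma[k, ] <- w / sum(w)
  state$mu[k, ] <- mu_k
  state
}

#' Evidence lower bound of the variational state
#'
#' Assembles the ELBO from summary-statistic sufficient statistics: the
#' expected Gaussian log-likelihood (using `y'y = N` for a standardized
#' trait), minus the categorical KL of each group's selection probabilities
#' against the prior and the Gaussian KL of each conditional effect against
#' `N(0, 1/tau_beta)`.
#'
#' @inheritParams update_effect_group
#' @return The ELBO in nats (scalar).
#' @export
compute_elbo <- function(state, locus) {
  n <- state$n
  tau_y <- state$hyper$tau_y
  tau_b <- state$hyper$tau_beta
  gamma <- state$gamma
  mu <- state$mu
  s2 <- state$s2
  eff <- gamma * mu                         # K x G, E[s_k beta_k]
  bsum <- colSums(eff)
  # E[(X S beta)' (X S beta)]: cross terms use first moments, the diagonal
  # (same-group) term uses E[(s b)^2] per variant with X'X diag = N.
  quad_cross <- n * (drop(crossprod(bsum, locus$ld %*% bsum)) -
                       sum(vapply(seq_len(nrow(gamma)), function(k) {
                         drop(crossprod(eff[k, ], locus$ld %*% eff[k, ]))
                       }, numeric(1))))
  quad_diag <- n * sum(gamma * (mu^2 + s2))
  fit_term <- sum(bsum * state$b)
  ell <- 0.5 * n * log(tau_y / (2 * pi)) -
    0.5 * tau_y * (n - 2 * fit_term + quad_cross + quad_diag)
  kl_cat <- sum(gamma * (log(pmax(gamma, 1e-300)) -
                           rep(log(state$priors), each = nrow(gamma))))
  kl_gauss <- sum(gamma * 0.5 * (tau_b * (mu^2 + s2) - 1 - log(tau_b * s2)))
  ell - kl_cat - kl_gauss
}

#' Fit the sum-of-single-effects model by coordinate-ascent VI
#'
#' Sweeps the K effect groups in fixed order, updating each with
#' [update_effect_group()], until the ELBO gain per sweep falls below `tol`
#' or the maximum absolute PIP change falls below `pip_tol`, or `max_iter`
#' sweeps are reached. Inference is deterministic.
#'
#' @param locus A [locus_data()] object.
#' @param priors Prior inclusion probabilities (length G, summing to 1);
#'   `NULL` for a flat prior.
#' @param hyper A `hyperparameters` object from [derive_precisions()].
#' @param K Number of effect groups.
#' @param tol ELBO convergence tolerance in nats per sweep.
#' @param pip_tol Secondary criterion: max absolute PIP change per sweep.
#' @param max_iter Maximum number of sweeps.
#' @param track_updates If `TRUE`, record the ELBO after every single group
#'   update (K entries per sweep) instead of once per sweep.
#'
#' @return A `vi_state` list with `gamma` and `mu` (K x G matrices), `s2`,
#'   `elbo_trace`, `converged`, `n_iter`, `priors` and `hyper`.
#' @export
fit_vi <- function(locus, priors = NULL, hyper, K = 10, tol = 1e-2,
                   pip_tol = 1e-4, max_iter = 100, track_updates = FALSE) {
  g <- length(locus$z)
  stopifnot(K >= 1, max_iter >= 1)
  if (is.null(priors)) priors <- rep(1 / g, g)
  if (abs(sum(priors) - 1) > 1e-8 || any(priors < 0)) {
    abort("priors must be non-negative and sum to 1")
  }
  priors <- pmax(priors, 1e-300)
  state <- vi_init(g, K, priors, hyper, locus$z, locus$n)
  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    pip_prev <- compute_pip(state$gamma)
    for (k in seq_len(K)) {
      state <- update_effect_group(state, locus, k)
      if (track_updates) {
        elbo_trace <- c(elbo_trace, compute_elbo(state, locus))
      }
    }
    elbo <- compute_elbo(state, locus)
    if (!track_updates) elbo_trace <- c(elbo_trace, elbo)
    dpip <- max(abs(compute_pip(state$gamma) - pip_prev))
    if ((elbo - elbo_prev) < tol || dpip < pip_tol) {
      converged <- TRUE
      elbo_prev <- elbo
      break
    }
    elbo_prev <- elbo
  }
  if (!converged) {
    warn(sprintf("VI did not converge after %d sweeps (last ELBO gain %.3g)",
                 it, elbo - if (length(elbo_trace) > 1)
                   elbo_trace[length(elbo_trace) - 1] else -Inf))
  }
  structure(
    list(
      gamma = state$gamma, mu = state$mu, s2 = state$s2,
      priors = priors, hyper = hyper, elbo = elbo_prev,
      elbo_trace = elbo_trace, converged = converged, n_iter = it
    ),
    class = "vi_state"
  )
}
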