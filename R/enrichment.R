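# Functionally-informed priors: softmax prior construction, G-test
# annotation screening and joint enrichment-weight estimation from PIPs.

#' Softmax prior inclusion probabilities from annotation weights
#'
#' `pi_g = exp(A_g' w) / sum_g' exp(A_g'' w)`, computed with max-subtraction.
#' With no annotations or all-zero weights the prior is uniform.
#'
#' @param anno G x M binary annotation matrix (or `NULL`).
#' @param w Enrichment weights, length M.
#'
#' @return Prior inclusion probabilities, length G, summing to 1.
#' @export
softmax_prior <- function(anno, w) {
  if (is.null(anno) || length(w) == 0) {
    abort("softmax_prior needs an annotation matrix and weights; use a flat prior directly")
  }
  a <- as.matrix(anno)
  stopifnot(ncol(a) == length(w))
  s <- drop(a %*% w)
  s <- s - max(s)
  e <- exp(s)
  e / sum(e)
}

#' Convert a log-scale enrichment weight to fold enrichment
#'
#' The fold enrichment is `exp(w)`; the 95% confidence bounds are
#' `exp(w +/- 1.96 se)`.
#'
#' @param w Enrichment weight (log scale).
#' @param se Standard error of `w` (>= 0).
#'
#' @return A tibble with columns `fold`, `fold_ci_low`, `fold_ci_high`.
#' @export
#' @examples
#' weight_to_fold(log(4), 0.1)
weight_to_fold <- function(w, se = 0) {
  stopifnot(all(se >= 0))
  tibble::tibble(
    fold = exp(w),
    fold_ci_low = exp(w - 1.96 * se),
    fold_ci_high = exp(w + 1.96 * se)
  )
}

#' G-test for enrichment of causal signal in one annotation
#'
#' Likelihood-ratio goodness-of-fit test comparing the observed PIP-weighted
#' causal mass inside and outside a binary annotation to its expectation
#' under no enrichment: `G = 2 sum_c O_c log(O_c / E_c)` over the annotated
#' and unannotated classes, referred to a chi-square with 1 degree of
#' freedom. Terms with zero observed mass contribute 0.
#'
#' @param anno_col Binary vector (length G).
#' @param pip PIP vector (length G), with positive total mass.
#'
#' @return A list with `g_stat` and `p_value`.
#' @export
g_test <- function(anno_col, pip) {
  stopifnot(length(anno_col) == length(pip))
  g <- length(pip)
  total <- sum(pip)
  if (total <= 0) {
    warn("G-test: total PIP mass is zero; returning p = 1")
    return(list(g_stat = 0, p_value = 1))
  }
  n1 <- sum(anno_col)
  if (n1 == 0 || n1 == g) {
    warn("G-test undefined for an all-0 or all-1 annotation; returning p = 1")
    return(list(g_stat = 0, p_value = 1))
  }
  o1 <- sum(pip[anno_col == 1])
  o0 <- total - o1
  e1 <- total * n1 / g
  e0 <- total - e1
  term <- function(o, e) if (o > 0) o * log(o / e) else 0
  g_stat <- 2 * (term(o1, e1) + term(o0, e0))
  g_stat <- max(g_stat, 0)
  list(g_stat = g_stat, p_value = pchisq(g_stat, df = 1, lower.tail = FALSE))
}

#' Jointly estimate annotation enrichment weights from PIPs
#'
#' Maximizes the PIP-weighted softmax cross-entropy
#' `Q(w) = sum_g pip_g log pi_g(w)` jointly over all M annotations by
#' Newton ascent (the objective is concave). Standard errors come from the
#' inverse observed information at the maximum; each annotation also gets a
#' marginal [g_test()].
#'
#' @param anno G x M binary annotation matrix with column names.
#' @param pip PIP vector of length G with positive total mass.
#' @param p_threshold G-test screening threshold (default 1e-5).
#' @param w_cap Absolute cap on weights for separated annotations
#'   (default 10).
#' @param grad_tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#'
#' @return An `enrichment_model`: a tibble with one row per annotation and
#'   columns `annotation`, `weight`, `se`, `ci_low`, `ci_high`, `g_stat`,
#'   `p_value`, `selected`.
#' @export
estimate_weights <- function(anno, pip, p_threshold = 1e-5, w_cap = 10,
                             grad_tol = 1e-6, max_iter = 100) {
  a <- as.matrix(anno)
  g <- nrow(a)
  m <- ncol(a)
  stopifnot(length(pip) == g, m >= 1)
  total <- sum(pip)
  if (total <= 0) abort("estimate_weights requires positive total PIP mass")
  labels <- colnames(a) %||% paste0("anno", seq_len(m))

  w <- rep(0, m)
  apip <- drop(crossprod(a, pip)) # sum_g pip_g A_g, fixed
  capped <- FALSE
  for (it in seq_len(max_iter)) {
    pri <- softmax_prior(a, w)
    ea <- drop(crossprod(a, pri))
    grad <- apip - total * ea
    hess <- -total * (crossprod(a * pri, a) - tcrossprod(ea))
    if (sqrt(sum(grad^2)) < grad_tol) break
    step <- tryCatch(solve(hess, grad),
                     error = function(e) -grad / (total + 1))
    w_new <- w - step
    # Backtrack if the (concave) objective did not improve.
    q <- function(wv) sum(pip * log(softmax_prior(a, wv)))
    q0 <- q(w)
    shrink <- 1
    while (q(w_new) < q0 && shrink > 1e-8) {
      shrink <- shrink / 2
      w_new <- w - shrink * step
    }
    w <- w_new
    if (any(abs(w) > w_cap)) {
      w <- pmin(pmax(w, -w_cap), w_cap)
      capped <- TRUE
    }
  }
  pri <- softmax_prior(a, w)
  ea <- drop(crossprod(a, pri))
  info <- total * (crossprod(a * pri, a) - tcrossprod(ea))
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(Inf, m))
  if (capped || any(!is.finite(se))) {
    warn("separated annotation(s): weight capped and/or standard error infinite")
    se[!is.finite(se)] <- Inf
  }
  tests <- purrr::map(seq_len(m), function(j) g_test(a[, j], pip))
  w <- unname(w)
  se <- unname(se)
  out <- tibble::tibble(
    annotation = labels,
    weight = w,
    se = se,
    ci_low = w - 1.96 * se,
    ci_high = w + 1.96 * se,
    g_stat = purrr::map_dbl(tests, "g_stat"),
    p_value = purrr::map_dbl(tests, "p_value"),
    selected = purrr::map_dbl(tests, "p_value") < p_threshold
  )
  class(out) <- c("enrichment_model", class(out))
  out
}
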