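# Evaluation metrics: AUPRC, credible-set coverage/power/size, PIP
# calibration and prior informativeness.

#' Area under the precision-recall curve
#'
#' Ranks variants by PIP (descending) against true causal status, groups
#' tied scores, and integrates precision over recall by the trapezoidal
#' rule. The curve is anchored at recall 0 with the precision of the
#' top-scoring tie group.
#'
#' @param pip Numeric score vector.
#' @param truth Binary vector (1 = causal) of the same length, with at least
#'   one positive.
#' @return Scalar AUPRC in `[0, 1]`.
#' @export
auprc <- function(pip, truth) {
  stopifnot(length(pip) == length(truth))
  truth <- as.numeric(truth)
  if (sum(truth) == 0) abort("AUPRC undefined: no true causal variants")
  ord <- order(pip, decreasing = TRUE)
  s <- pip[ord]
  t <- truth[ord]
  # cumulative counts at the end of each tie group
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(t)[last]
  npred <- last
  recall <- tp / sum(truth)
  precision <- tp / npred
  r <- c(0, recall)
  p <- c(precision[1], precision)
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}

#' Coverage, power and size of credible sets
#'
#' @param sets Credible-set tibble from [build_credible_sets()] (needs the
#'   `members` list-column).
#' @param truth Binary vector over variants (1 = causal).
#' @return A one-row tibble: `coverage` (fraction of sets containing a true
#'   causal variant; `NA` when no sets were reported), `power` (fraction of
#'   causal variants captured by any set), `mean_size` and `n_sets`.
#' @export
set_metrics <- function(sets, truth) {
  causal <- which(as.numeric(truth) == 1)
  if (is.null(sets) || nrow(sets) == 0) {
    return(tibble::tibble(coverage = NA_real_, power = 0,
                          mean_size = NA_real_, n_sets = 0L))
  }
  hit <- purrr::map_lgl(sets$members, function(m) any(m %in% causal))
  captured <- unique(unlist(sets$members))
  tibble::tibble(
    coverage = mean(hit),
    power = if (length(causal) > 0) {
      sum(causal %in% captured) / length(causal)
    } else NA_real_,
    mean_size = mean(purrr::map_int(sets$members, length)),
    n_sets = nrow(sets)
  )
}

#' PIP calibration table
#'
#' Groups variants into equal-width PIP bins on `[0, 1]` and compares the
#' mean PIP (expected precision) with the observed fraction of causal
#' variants (actual precision) per bin. Empty bins are omitted.
#'
#' @param pip PIP vector.
#' @param truth Binary vector (1 = causal).
#' @param bins Number of equal-width bins (default 5).
#' @return A tibble with `bin`, `expected` (mean PIP), `observed`
#'   (fraction causal) and `count`.
#' @export
calibration <- function(pip, truth, bins = 5) {
  stopifnot(length(pip) == length(truth), bins >= 1)
  truth <- as.numeric(truth)
  idx <- pmin(pmax(ceiling(pip * bins), 1), bins)
  tibble::tibble(bin = idx, pip = pip, truth = truth) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      expected = mean(.data$pip),
      observed = mean(.data$truth),
      count = dplyr::n(),
      .groups = "drop"
    )
}

#' Prior informativeness (log relative ratio)
#'
#' The log of the ratio between the largest and smallest prior inclusion
#' probabilities; 0 for a flat prior.
#'
#' @param priors Positive prior inclusion probabilities.
#' @return Scalar `log(max/min)`.
#' @export
log_rr <- function(priors) {
  stopifnot(all(priors > 0))
  log(max(priors) / min(priors))
}

#' Evaluate a fine-mapping fit against simulated truth
#'
#' @param fit A `finemap_fit`.
#' @param truth Binary causal-status vector or integer causal indices.
#' @param bins Calibration bins.
#' @return A list with `summary` (one-row tibble: AUPRC, coverage, power,
#'   mean size, n_sets, logRR) and `calibration` (tibble).
#' @export
evaluate_fit <- function(fit, truth, bins = 5) {
  stopifnot(inherits(fit, "finemap_fit"))
  g <- length(fit$pip)
  if (!all(truth %in% c(0, 1)) || length(truth) != g) {
    idx <- as.integer(truth)
    truth <- rep(0, g)
    truth[idx] <- 1
  }
  sm <- set_metrics(fit$sets, truth)
  list(
    summary = tibble::tibble(
      auprc = auprc(fit$pip, truth),
      coverage = sm$coverage,
      power = sm$power,
      mean_size = sm$mean_size,
      n_sets = sm$n_sets,
      log_rr = log_rr(fit$priors)
    ),
    calibration = calibration(fit$pip, truth, bins)
  )
}
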