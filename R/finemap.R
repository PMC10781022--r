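#' Fine-map a locus from GWAS summary statistics
#'
#' Fits the sum-of-single-effects model by variational inference and
#' summarizes the posterior into PIPs and attainable-coverage-filtered
#' credible sets. When a binary annotation matrix is supplied, a two-pass
#' workflow is used: pass 1 fits with a flat prior, annotation enrichment
#' weights are estimated jointly from the pass-1 PIPs and screened with a
#' G-test, and (if any annotation is selected) pass 2 re-fits with the
#' functionally-informed softmax prior.
#'
#' @param sumstats Data frame of summary statistics (see [read_sumstats()])
#'   or a ready-made [locus_data()] object.
#' @param ld G x G LD matrix (ignored when `sumstats` is a `locus_data`).
#' @param n GWAS sample size; defaults to the median per-variant `n`.
#' @param anno Optional G x M binary annotation matrix.
#' @param K Maximum number of effect groups (default 10).
#' @param rho Credible-set level (default 0.95).
#' @param r2_min LD threshold for attainable coverage (default 0.25).
#' @param p_threshold G-test screening threshold for annotations
#'   (default 1e-5).
#' @param anno_mode `"screened"` (default) uses only annotations passing the
#'   G-test; `"all"` uses every annotation unscreened; `"none"` ignores
#'   `anno` beyond reporting enrichment.
#' @param eig_threshold Relative eigenvalue truncation for the local
#'   heritability estimator.
#' @param h2 Optional fixed local heritability, bypassing estimation.
#' @param tol,max_iter VI convergence controls (see [fit_vi()]).
#'
#' @return A `finemap_fit` object. Use [tidy()] for per-variant,
#'   credible-set and enrichment tables, [glance()] for a one-row fit
#'   summary, and [autoplot()] to plot PIPs.
#' @export
finemap <- function(sumstats, ld = NULL, n = NULL, anno = NULL, K = 10,
                    rho = 0.95, r2_min = 0.25, p_threshold = 1e-5,
                    anno_mode = c("screened", "all", "none"),
                    eig_threshold = 1e-3, h2 = NULL, tol = 1e-2,
                    max_iter = 100) {
  anno_mode <- match.arg(anno_mode)
  locus <- if (inherits(sumstats, "locus_data")) {
    sumstats
  } else {
    if (is.null(ld)) abort("an LD matrix is required")
    locus_data(sumstats, ld, n = n)
  }
  g <- length(locus$z)
  if (!is.null(anno)) anno <- validate_annotations(anno, g)

  if (is.null(h2)) h2 <- estimate_local_h2(locus, eig_threshold)
  hyper <- derive_precisions(h2, K)

  pass1 <- fit_vi(locus, priors = NULL, hyper = hyper, K = K, tol = tol,
                  max_iter = max_iter)
  pip1 <- compute_pip(pass1)

  enrichment <- NULL
  fit <- pass1
  pip <- pip1
  informed <- FALSE
  if (!is.null(anno)) {
    enrichment <- estimate_weights(anno, pip1, p_threshold = p_threshold)
    use <- switch(anno_mode,
      screened = which(enrichment$selected),
      all = seq_len(ncol(anno)),
      none = integer(0)
    )
    if (length(use) > 0) {
      # Re-estimate weights jointly on the retained annotations so the
      # informed prior reflects the sparser model.
      sub <- if (length(use) < ncol(anno)) {
        estimate_weights(anno[, use, drop = FALSE], pip1,
                         p_threshold = p_threshold)
      } else {
        enrichment
      }
      priors <- softmax_prior(anno[, use, drop = FALSE], sub$weight)
      fit <- fit_vi(locus, priors = priors, hyper = hyper, K = K,
                    tol = tol, max_iter = max_iter)
      pip <- compute_pip(fit)
      informed <- TRUE
    }
  }
  sets <- build_credible_sets(fit, locus$ld, rho = rho, r2_min = r2_min,
                              z = locus$z)
  structure(
    list(
      variants = locus$variants,
      pip = pip,
      pip_flat = pip1,
      sets = sets,
      enrichment = enrichment,
      fit = fit,
      pass1 = if (informed) pass1 else NULL,
      informed_prior = informed,
      priors = fit$priors,
      hyper = hyper,
      params = list(K = K, rho = rho, r2_min = r2_min,
                    p_threshold = p_threshold, anno_mode = anno_mode),
      locus = locus
    ),
    class = "finemap_fit"
  )
}

#' @export
print.finemap_fit <- function(x, ...) {
  cat(sprintf(
    "<finemap_fit> %d variants, K = %d, h2_local = %.3g, %s prior\n",
    length(x$pip), x$params$K, x$hyper$h2_local,
    if (x$informed_prior) "functionally-informed" else "flat"
  ))
  cat(sprintf("  %d credible set(s) at rho = %.2f; ELBO = %.2f (%d sweeps%s)\n",
              nrow(x$sets), x$params$rho, x$fit$elbo, x$fit$n_iter,
              if (x$fit$converged) "" else ", not converged"))
  invisible(x)
}

#' Tidy a fine-mapping fit
#'
#' @param x A `finemap_fit`.
#' @param type `"variants"` (default): one row per variant with `pip`, the
#'   best effect-group index and its selection probability, and credible-set
#'   membership; `"sets"`: one row per credible-set member; `"enrichment"`:
#'   the annotation enrichment table.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy finemap_fit
#' @export
tidy.finemap_fit <- function(x, type = c("variants", "sets", "enrichment"),
                             ...) {
  type <- match.arg(type)
  if (type == "variants") {
    gamma <- x$fit$gamma
    best <- apply(gamma, 2, which.max)
    best_prob <- gamma[cbind(best, seq_len(ncol(gamma)))]
    cs <- rep(NA_integer_, length(x$pip))
    for (i in seq_len(nrow(x$sets))) cs[x$sets$members[[i]]] <- x$sets$set_id[i]
    out <- x$variants |>
      dplyr::mutate(
        pip = x$pip,
        best_group = as.integer(best),
        best_group_prob = best_prob,
        cs = cs
      )
    return(out)
  }
  if (type == "sets") {
    if (nrow(x$sets) == 0) {
      return(tibble::tibble(
        set_id = integer(0), group_index = integer(0), rho = numeric(0),
        attainable = numeric(0), size = integer(0), lead_id = character(0),
        id = character(0), member_prob = numeric(0)
      ))
    }
    x$sets |>
      dplyr::mutate(lead_id = x$variants$id[.data$lead]) |>
      tidyr::unnest_longer(c("members", "member_probs")) |>
      dplyr::mutate(id = x$variants$id[.data$members],
                    member_prob = .data$member_probs) |>
      dplyr::select("set_id", "group_index", "rho", "attainable", "size",
                    "lead_id", "id", "member_prob")
  } else {
    if (is.null(x$enrichment)) {
      abort("this fit has no enrichment model (no annotations supplied)")
    }
    tibble::as_tibble(x$enrichment)
  }
}

#' One-row summary of a fine-mapping fit
#'
#' @param x A `finemap_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the locus size, sample size, model
#'   hyperparameters, ELBO, iteration count, convergence flag, number of
#'   credible sets and the prior log relative ratio.
#' @method glance finemap_fit
#' @export
glance.finemap_fit <- function(x, ...) {
  tibble::tibble(
    g = length(x$pip),
    n = x$locus$n,
    K = x$params$K,
    h2_local = x$hyper$h2_local,
    tau_beta = x$hyper$tau_beta,
    tau_y = x$hyper$tau_y,
    elbo = x$fit$elbo,
    n_iter = x$fit$n_iter,
    converged = x$fit$converged,
    n_sets = nrow(x$sets),
    informed_prior = x$informed_prior,
    log_rr = log_rr(x$priors)
  )
}

#' Fine-map several loci with a shared, pooled enrichment model
#'
#' Runs the two-pass functionally-informed workflow across a collection of
#' loci that share the same annotation columns: pass 1 fits every locus with
#' a flat prior, PIPs and annotation rows are pooled across loci to estimate
#' one joint enrichment model (and G-test screen), and every locus is then
#' re-fitted with the shared informed prior. This mirrors genome-wide usage
#' where per-locus causal mass is too small to estimate enrichment.
#'
#' @param loci List of [locus_data()] objects.
#' @param annos List of G_i x M annotation matrices (same columns), or a
#'   single matrix if `length(loci) == 1`; `NULL` disables annotations.
#' @param pool_idx Optional list of integer vectors (one per locus) naming
#'   the variants whose PIPs and annotation rows enter the pooled enrichment
#'   estimation (e.g. genome-scan core regions); default all.
#' @inheritParams finemap
#'
#' @return A list with `fits` (list of `finemap_fit`), `enrichment` (pooled
#'   `enrichment_model` or `NULL`) and `informed_prior` (logical).
#' @export
finemap_loci <- function(loci, annos = NULL, K = 10, rho = 0.95,
                         r2_min = 0.25, p_threshold = 1e-5,
                         anno_mode = c("screened", "all", "none"),
                         eig_threshold = 1e-3, tol = 1e-2, max_iter = 100,
                         pool_idx = NULL) {
  anno_mode <- match.arg(anno_mode)
  stopifnot(is.list(loci), length(loci) > 0)
  if (!is.null(annos) && is.matrix(annos)) annos <- list(annos)
  pass1 <- purrr::map(loci, function(lc) {
    finemap(lc, K = K, rho = rho, r2_min = r2_min, anno_mode = "none",
            eig_threshold = eig_threshold, tol = tol, max_iter = max_iter)
  })
  if (is.null(annos) || anno_mode == "none") {
    return(list(fits = pass1, enrichment = NULL, informed_prior = FALSE))
  }
  stopifnot(length(annos) == length(loci))
  if (is.null(pool_idx)) {
    pool_idx <- purrr::map(loci, function(lc) seq_along(lc$z))
  }
  pooled_pip <- unlist(purrr::map2(pass1, pool_idx,
                                   function(f, ix) f$pip[ix]))
  pooled_anno <- do.call(rbind, purrr::map2(annos, pool_idx,
                                            function(a, ix) {
                                              a[ix, , drop = FALSE]
                                            }))
  enrichment <- estimate_weights(pooled_anno, pooled_pip,
                                 p_threshold = p_threshold)
  use <- switch(anno_mode,
    screened = which(enrichment$selected),
    all = seq_len(ncol(pooled_anno))
  )
  if (length(use) == 0) {
    fits <- purrr::map(pass1, function(f) { f$enrichment <- enrichment; f })
    return(list(fits = fits, enrichment = enrichment,
                informed_prior = FALSE))
  }
  sub <- if (length(use) < ncol(pooled_anno)) {
    estimate_weights(pooled_anno[, use, drop = FALSE], pooled_pip,
                     p_threshold = p_threshold)
  } else {
    enrichment
  }
  fits <- purrr::pmap(list(loci, annos, pass1), function(lc, an, f) {
    # Locus-level prior: softmax of the shared weights over this locus.
    priors <- softmax_prior(an[, use, drop = FALSE], sub$weight)
    fit2 <- fit_vi(lc, priors = priors, hyper = f$hyper, K = K, tol = tol,
                   max_iter = max_iter)
    f$pass1 <- f$fit
    f$fit <- fit2
    f$pip_flat <- f$pip
    f$pip <- compute_pip(fit2)
    f$priors <- priors
    f$informed_prior <- TRUE
    f$enrichment <- enrichment
    f$sets <- build_credible_sets(fit2, lc$ld, rho = rho, r2_min = r2_min,
                                  z = lc$z)
    f
  })
  list(fits = fits, enrichment = enrichment, informed_prior = TRUE)
}
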