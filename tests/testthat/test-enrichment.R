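test_that("softmax priors normalize, flatten at w = 0 and shift-invariantly", {
  a <- cbind(c(1, 1, 0, 0), c(0, 1, 0, 1))
  expect_equal(softmax_prior(a, c(0, 0)), rep(0.25, 4))

  p <- softmax_prior(cbind(c(1, 0)), log(4))
  expect_equal(p, c(0.8, 0.2))

  set.seed(4)
  for (i in 1:10) {
    w <- rnorm(2)
    p1 <- softmax_prior(a, w)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    # adding a constant to the weights of an all-ones annotation is a shift
    p2 <- softmax_prior(cbind(a, 1), c(w, 3.7))
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("a single annotation weight sets the annotated:unannotated prior ratio", {
  a <- cbind(c(rep(1, 10), rep(0, 30)))
  p <- softmax_prior(a, 3.19)
  ratio <- p[1] / p[40]
  expect_equal(signif(ratio, 3), 24.3)
})

test_that("weights convert to fold enrichments with exponentiated CIs", {
  ft <- weight_to_fold(3.19, se = (3.50 - 3.19) / 1.96)
  expect_equal(signif(ft$fold, 3), 24.3)
  expect_equal(signif(ft$fold_ci_low, 3), 17.8)
  expect_equal(signif(ft$fold_ci_high, 3), 33.1)
  expect_equal(weight_to_fold(0)$fold, 1)
  expect_equal(weight_to_fold(1.42)$fold, exp(1.42), tolerance = 1e-12)
  expect_equal(signif(weight_to_fold(1.42)$fold, 3), 4.14)
})

test_that("the G-test matches hand-evaluated soft-count likelihood ratios", {
  # total PIP mass 5, annotation prevalence 20%, observed mass 4 inside
  g <- 100
  anno <- c(rep(1, 20), rep(0, 80))
  pip <- numeric(g)
  pip[1:20] <- 4 / 20
  pip[21:100] <- 1 / 80
  gt <- g_test(anno, pip)
  expect_equal(gt$g_stat, 2 * (4 * log(4) + 1 * log(1 / 4)), tolerance = 1e-12)
  expect_equal(gt$p_value, pchisq(2 * 3 * log(4), 1, lower.tail = FALSE))
  expect_lt(gt$p_value, 0.004)

  # observed mass proportional to prevalence: no signal
  pip_null <- rep(0.05, g)
  gt0 <- g_test(anno, pip_null)
  expect_equal(gt0$g_stat, 0, tolerance = 1e-12)
  expect_equal(gt0$p_value, 1)

  expect_warning(res <- g_test(anno, rep(0, g)), "zero")
  expect_equal(res$p_value, 1)
  expect_warning(g_test(rep(1, g), pip), "all-0 or all-1")
})

test_that("joint weight estimation matches the single-annotation closed form", {
  set.seed(9)
  for (i in 1:5) {
    g <- 200
    anno <- cbind(x = as.numeric(runif(g) < 0.25))
    n1 <- sum(anno); n0 <- g - n1
    pip <- runif(g, 0, 0.3)
    em <- suppressWarnings(estimate_weights(anno, pip))
    o1 <- sum(pip[anno == 1]); o0 <- sum(pip[anno == 0])
    expect_equal(em$weight, log((o1 / n1) / (o0 / n0)), tolerance = 1e-5)
  }
})

test_that("uniform PIPs give near-zero weights for every annotation", {
  set.seed(10)
  g <- 300
  anno <- vapply(1:4, function(j) as.numeric(runif(g) < 0.2), numeric(g))
  colnames(anno) <- paste0("a", 1:4)
  em <- estimate_weights(anno, rep(0.1, g))
  expect_true(all(abs(em$weight) < 1e-5))
  expect_true(all(em$p_value == 1 | em$g_stat < 1e-8))
})

test_that("a perfectly separating annotation is capped with a warning", {
  g <- 50
  anno <- cbind(sep = c(rep(1, 5), rep(0, 45)))
  pip <- c(rep(0.9, 5), rep(0, 45))
  expect_warning(em <- estimate_weights(anno, pip), "separated")
  expect_equal(abs(em$weight), 10)
})

test_that("weight CIs are symmetric on the log scale and bracket the estimate", {
  set.seed(12)
  g <- 400
  anno <- cbind(a = as.numeric(runif(g) < 0.3), b = as.numeric(runif(g) < 0.15))
  pip <- runif(g) * (1 + anno[, 1])
  em <- estimate_weights(anno, pip)
  expect_true(all(em$ci_low <= em$weight & em$weight <= em$ci_high))
  expect_equal(em$weight - em$ci_low, em$ci_high - em$weight,
               tolerance = 1e-10)
})

test_that("the two-pass locus workflow only engages selected annotations", {
  # strong single signal; an annotation that contains all the causal mass
  # but the per-locus G-test cannot reach p < 1e-5 from one signal
  g <- 100
  ld <- ar1(g, 0.5)
  z <- ld[, 50] * 9
  loc <- quick_locus(z, ld, n = 5e4)
  anno <- cbind(hit = as.numeric(seq_len(g) %in% 45:55),
                null = rep(c(1, 0), g / 2))
  fit <- finemap(loc, anno = anno, K = 2)
  expect_false(fit$informed_prior)
  expect_equal(log_rr(fit$priors), 0) # flat prior => max/min ratio 1
  expect_equal(fit$pip, fit$pip_flat)
  # unscreened mode uses every annotation
  fit_all <- finemap(loc, anno = anno, K = 2, anno_mode = "all")
  expect_true(fit_all$informed_prior)
  expect_gt(log_rr(fit_all$priors), 0)
})
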