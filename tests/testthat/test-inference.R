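test_that("a single-variant locus gets the whole simplex", {
  loc <- quick_locus(2.5, matrix(1, 1, 1), n = 1e4)
  fit <- fit_vi(loc, hyper = derive_precisions(0.01, 1), K = 1)
  expect_equal(drop(fit$gamma), 1)
})

test_that("K = 1 fits equal the exact single-causal enumeration posterior", {
  hyper <- derive_precisions(0.01, 1)
  loc <- quick_locus(c(5, 0, 0), diag(3), n = 1e4)
  fit <- fit_vi(loc, hyper = hyper, K = 1)
  oracle <- enumerate_single_effect(loc$z, loc$n, hyper$tau_beta,
                                    hyper$tau_y)
  expect_equal(drop(fit$gamma), oracle, tolerance = 1e-6)
  expect_gt(fit$gamma[1, 1], 0.9)

  # random loci with correlated LD and non-flat priors, G <= 20
  for (seed in 1:5) {
    set.seed(seed)
    g <- sample(5:20, 1)
    ld <- ar1(g, runif(1, 0, 0.9))
    z <- drop(chol(ld) %*% rnorm(g)) + sample(c(0, 4), g, replace = TRUE,
                                              prob = c(0.9, 0.1))
    loc <- quick_locus(z, ld, n = 2e4)
    pri <- runif(g); pri <- pri / sum(pri)
    hyper <- derive_precisions(0.005, 1)
    fit <- fit_vi(loc, priors = pri, hyper = hyper, K = 1)
    oracle <- enumerate_single_effect(z, loc$n, hyper$tau_beta,
                                      hyper$tau_y, priors = pri)
    expect_equal(drop(fit$gamma), oracle, tolerance = 1e-6)
  }
})

test_that("perfectly correlated variants with equal z split the posterior", {
  ld <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  loc <- quick_locus(c(5, 5, 0), ld, n = 1e4)
  fit <- fit_vi(loc, hyper = derive_precisions(0.01, 1), K = 1)
  expect_equal(fit$gamma[1, 1], fit$gamma[1, 2], tolerance = 1e-12)
  expect_equal(fit$gamma[1, 1] + fit$gamma[1, 2], 1, tolerance = 1e-5)
})

test_that("the ELBO never decreases across coordinate updates", {
  set.seed(21)
  for (i in 1:5) {
    g <- 30
    ld <- ar1(g, 0.85)
    z <- drop(chol(ld) %*% rnorm(g))
    z[sample(g, 2)] <- c(7, -5)
    loc <- quick_locus(z, ld, n = 3e4)
    fit <- fit_vi(loc, hyper = derive_precisions(0.01, 5), K = 5,
                  track_updates = TRUE)
    expect_true(all(diff(fit$elbo_trace) >= -1e-7))
  }
})

test_that("the ELBO matches a hand computation on a one-variant null locus", {
  loc <- quick_locus(0, matrix(1, 1, 1), n = 100)
  for (tau_y in c(1, 2)) {
    hyper <- list(tau_beta = 50, tau_y = tau_y)
    st <- finemapvi:::vi_init(1, 1, priors = 1, hyper = hyper, z = 0,
                              n = 100)
    # gamma = prior: categorical KL is 0; mu = 0: only the data term and
    # the Gaussian KL of N(0, s2) against N(0, 1/tau_beta) remain.
    s2 <- 1 / (100 * tau_y + 50)
    by_hand <- 0.5 * 100 * log(tau_y / (2 * pi)) -
      0.5 * tau_y * (100 + 100 * s2) -
      0.5 * (50 * s2 - 1 - log(50 * s2))
    expect_equal(compute_elbo(st, loc), by_hand, tolerance = 1e-12)
  }
})

test_that("an unneeded second effect group stays diffuse", {
  # z is exactly the LD-propagated expectation of one causal variant, so
  # the residual after the first group is null everywhere
  g <- 150
  ld <- ar1(g, 0.8)
  z <- ld[, 25] * 9
  loc <- quick_locus(z, ld, n = 5e4)
  f1 <- fit_vi(loc, hyper = derive_precisions(0.002, 1), K = 1)
  f2 <- fit_vi(loc, hyper = derive_precisions(0.002, 2), K = 2)
  expect_lt(max(abs(compute_pip(f2) - compute_pip(f1))), 0.01)
  expect_lt(max(f2$gamma[2, ]), 5 / g)
})

test_that("independent causal variants land in separate effect groups", {
  set.seed(8)
  g <- 40
  ld <- matrix(0, g, g)
  ld[1:20, 1:20] <- ar1(20, 0.9)
  ld[21:40, 21:40] <- ar1(20, 0.9)
  cfg_z <- rep(0, g); cfg_z[c(10, 30)] <- c(8, 7.5)
  z <- drop(chol(ld) %*% rnorm(g)) + cfg_z
  loc <- quick_locus(z, ld, n = 5e4)
  fit <- fit_vi(loc, hyper = derive_precisions(0.003, 5), K = 5)
  top <- apply(fit$gamma, 1, which.max)
  conc <- apply(fit$gamma, 1, max)
  hits <- top[conc > 0.9]
  expect_true(any(abs(hits - 10) <= 1))
  expect_true(any(abs(hits - 30) <= 1))
})

test_that("a null locus keeps near-uniform posteriors and reports no sets", {
  loc <- quick_locus(rep(0, 100), diag(100), n = 1e4)
  fit <- fit_vi(loc, hyper = derive_precisions(0.001, 3), K = 3)
  expect_lt(max(compute_pip(fit)), 2 * 3 / 100)
  sets <- build_credible_sets(fit, loc$ld)
  expect_equal(nrow(sets), 0)
})

test_that("rank-deficient LD (duplicated variants) runs to completion", {
  g <- 12
  base <- ar1(6, 0.5)
  ld <- base[rep(1:6, each = 2), rep(1:6, each = 2)]
  diag(ld) <- 1
  ld <- (ld + t(ld)) / 2
  z <- rep(c(4, 4, 0, 0, 0, 0), each = 2)
  loc <- quick_locus(z, ld, n = 1e4)
  expect_silent(fit <- fit_vi(loc, hyper = derive_precisions(0.01, 2),
                              K = 2))
  expect_true(all(is.finite(compute_pip(fit))))
})

test_that("fits are equivariant under variant permutation", {
  set.seed(31)
  g <- 25
  ld <- ar1(g, 0.7)
  z <- drop(chol(ld) %*% rnorm(g)); z[7] <- 6
  loc <- quick_locus(z, ld, n = 2e4)
  hyper <- derive_precisions(0.004, 3)
  fit <- fit_vi(loc, hyper = hyper, K = 3)
  perm <- sample(g)
  loc_p <- quick_locus(z[perm], ld[perm, perm], n = 2e4)
  fit_p <- fit_vi(loc_p, hyper = hyper, K = 3)
  expect_equal(compute_pip(fit_p), compute_pip(fit)[perm],
               tolerance = 1e-8)
})
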