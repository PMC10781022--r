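test_that("genotype simulation is reproducible and respects ld_decay", {
  cfg <- sim_config(g = 20, n = 500, k_causal = 2, h2 = 0.01, seed = 99)
  g1 <- simulate_genotypes(cfg, theoretical_ld = FALSE)
  g2 <- simulate_genotypes(cfg, theoretical_ld = FALSE)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_true(all(g1$genotypes %in% 0:2))

  cfg0 <- sim_config(g = 30, n = 10000, k_causal = 1, ld_decay = 0,
                     seed = 5)
  gen0 <- simulate_genotypes(cfg0, theoretical_ld = FALSE)
  emp <- cor(gen0$genotypes)
  adj <- emp[cbind(1:29, 2:30)]
  expect_lt(max(abs(adj)), 0.05)
})

test_that("empirical LD converges to the theoretical thresholded-Gaussian LD", {
  cfg <- sim_config(g = 25, n = 10000, k_causal = 1, ld_decay = 0.95,
                    seed = 17)
  gen <- simulate_genotypes(cfg)
  emp <- cor(gen$genotypes)
  expect_lt(max(abs(emp - gen$ld_true)), 0.05)
  # adjacent correlations positive and decaying with distance on average
  adj <- emp[cbind(1:24, 2:25)]
  lag5 <- emp[cbind(1:20, 6:25)]
  # thresholding attenuates the latent 0.95, most strongly for mismatched MAFs
  expect_true(all(adj > 0.1))
  expect_gt(mean(adj), 0.5)
  expect_lt(mean(lag5), mean(adj))
})

test_that("independent LD blocks are uncorrelated across the boundary", {
  cfg <- sim_config(g = 20, n = 8000, k_causal = 1, ld_decay = 0.9,
                    n_blocks = 2, seed = 23)
  gen <- simulate_genotypes(cfg)
  expect_equal(gen$ld_true[10, 11], 0)
  emp <- cor(gen$genotypes)
  expect_lt(abs(emp[10, 11]), 0.05)
})

test_that("causal assignment follows annotation log-odds", {
  g <- 20
  anno <- cbind(a = rep(c(1, 0), each = g / 2))

  cfg0 <- sim_config(g = g, n = 100, k_causal = 1, w_intensity = 0,
                     m_anno = 1, enriched_idx = 1, seed = 1)
  set.seed(42)
  draws0 <- replicate(10000, assign_causal(cfg0, anno))
  tab <- tabulate(draws0, g)
  expect_gt(chisq.test(tab)$p.value, 0.01)

  cfg2 <- sim_config(g = g, n = 100, k_causal = 1, w_intensity = 2,
                     m_anno = 1, enriched_idx = 1, seed = 1)
  set.seed(43)
  draws2 <- replicate(10000, assign_causal(cfg2, anno))
  ratio <- sum(draws2 <= g / 2) / sum(draws2 > g / 2)
  expect_lt(abs(ratio - exp(2)) / exp(2), 0.1)

  cfg_all <- sim_config(g = g, n = 100, k_causal = g, w_intensity = 1,
                        m_anno = 1, enriched_idx = 1, seed = 1)
  expect_equal(assign_causal(cfg_all, anno), seq_len(g))
})

test_that("trait simulation hits the target heritability exactly", {
  cfg <- sim_config(g = 50, n = 5000, k_causal = 3, h2 = 0.3, seed = 7)
  gen <- simulate_genotypes(cfg, theoretical_ld = FALSE)
  tr <- simulate_trait(gen$genotypes, c(10, 25, 40), h2 = 0.3, seed = 8)
  xs <- scale(gen$genotypes[, c(10, 25, 40)])
  gc <- drop(xs %*% tr$true_beta)
  expect_equal(var(gc) / var(tr$trait), 0.3, tolerance = 1e-6)
  expect_equal(mean(tr$trait), 0, tolerance = 1e-10)
  expect_equal(var(tr$trait), 1, tolerance = 1e-6)

  tr0 <- simulate_trait(gen$genotypes, c(1, 2), h2 = 0, seed = 9)
  expect_equal(tr0$true_beta, c(0, 0))

  # h2 = 0.5 with one causal variant: trait-dosage r^2 near 0.5
  cfg1 <- sim_config(g = 5, n = 10000, k_causal = 1, h2 = 0.5, seed = 11)
  gen1 <- simulate_genotypes(cfg1, theoretical_ld = FALSE)
  tr1 <- simulate_trait(gen1$genotypes, 3, h2 = 0.5, seed = 12)
  expect_equal(cor(tr1$trait, gen1$genotypes[, 3])^2, 0.5,
               tolerance = 0.02)
})

test_that("GWAS z-scores behave under the null and the noncentrality formula", {
  set.seed(33)
  cfg <- sim_config(g = 100, n = 2000, k_causal = 1, h2 = 0, ld_decay = 0,
                    seed = 31)
  gen <- simulate_genotypes(cfg, theoretical_ld = FALSE)
  tr <- simulate_trait(gen$genotypes, 1, h2 = 0)
  loc <- run_gwas(gen$genotypes, tr$trait)
  expect_equal(mean(loc$z^2), 1, tolerance = 0.35)

  # causal variant: E[z^2] = N h2 + 1, averaged over a few replicates
  z2 <- vapply(1:5, function(i) {
    cfgc <- sim_config(g = 5, n = 5e4, k_causal = 1, h2 = 0.01,
                       ld_decay = 0, seed = 300 + i)
    genc <- simulate_genotypes(cfgc, theoretical_ld = FALSE)
    trc <- simulate_trait(genc$genotypes, 3, h2 = 0.01)
    locc <- run_gwas(genc$genotypes, trc$trait)
    locc$z[3]^2
  }, numeric(1))
  expect_lt(abs(mean(z2) - 501), 3 * sd(z2) / sqrt(5) + 10)

  # permuting the trait destroys the association
  genp <- simulate_genotypes(sim_config(g = 5, n = 5e4, k_causal = 1,
                                        h2 = 0.01, seed = 311),
                             theoretical_ld = FALSE)
  trp <- simulate_trait(genp$genotypes, 3, h2 = 0.01)
  locp <- run_gwas(genp$genotypes, sample(trp$trait))
  expect_lt(max(abs(locp$z)), 5)
})

test_that("whole-locus simulation is seed-reproducible and annotation-aware", {
  cfg <- sim_config(g = 60, n = 2000, k_causal = 5, w_intensity = 2,
                    seed = 77)
  s1 <- simulate_locus(cfg, keep_genotypes = FALSE)
  s2 <- simulate_locus(cfg, keep_genotypes = FALSE)
  expect_identical(s1$locus$z, s2$locus$z)
  expect_identical(s1$causal_idx, s2$causal_idx)
  expect_equal(length(s1$causal_idx), 5)
  expect_equal(dim(s1$anno), c(60, 10))
  expect_equal(s1$w_sim, c(rep(2, 5), rep(0, 5)))

  # W = 0: causal status independent of annotations over replicates
  # (paired per-replicate difference, Monte-Carlo 3-SE bound)
  d <- vapply(1:100, function(i) {
    cfg0 <- sim_config(g = 60, n = 100, k_causal = 5, w_intensity = 0,
                       seed = 4000 + i)
    set.seed(cfg0$seed)
    anno <- simulate_annotations(cfg0)
    ci <- assign_causal(cfg0, anno)
    mean(anno[ci, 1]) - mean(anno[, 1])
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.01)
})

test_that("simulated loci round-trip through the file formats", {
  cfg <- sim_config(g = 25, n = 1500, k_causal = 2, seed = 55)
  sim <- simulate_locus(cfg, keep_genotypes = FALSE)
  prefix <- file.path(withr::local_tempdir(), "sim")
  files <- write_simulated_locus(sim, prefix)
  ss <- read_sumstats(files["ss"])
  expect_equal(ss$z, sim$locus$z, tolerance = 1e-5)
  ld <- read_ld(files["ld"], expected_g = 25)
  expect_equal(ld, sim$locus$ld, tolerance = 1e-5)
  anno <- read_annotations(files["anno"], ids = ss$id)
  expect_equal(unname(anno), unname(sim$anno))
})
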