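# Shared fixtures and independent oracles used across the test files.

# AR(1) correlation matrix rho^|i-j|
ar1 <- function(g, rho) rho^abs(outer(seq_len(g), seq_len(g), "-"))

# Minimal locus from a z vector and LD matrix.
quick_locus <- function(z, ld, n = 1e4) {
  g <- length(z)
  locus_data(
    tibble::tibble(
      id = paste0("v", seq_len(g)), chrom = "1", pos = seq_len(g) * 1000L,
      allele_effect = "A", allele_other = "G", z = z, n = n
    ),
    ld, n = n
  )
}

# Independent oracle for the single-effect model: enumerate the G
# single-causal configurations and integrate the summary-statistic
# likelihood against the effect prior numerically (no reuse of the
# variational update algebra).
enumerate_single_effect <- function(z, n, tau_beta, tau_y,
                                    priors = NULL) {
  g <- length(z)
  if (is.null(priors)) priors <- rep(1 / g, g)
  b <- z * sqrt(n)
  log_marg <- vapply(seq_len(g), function(j) {
    # peak of the integrand exponent, subtracted for numerical stability
    c0 <- 0.5 * (tau_y * b[j])^2 / (n * tau_y + tau_beta)
    val <- stats::integrate(
      function(beta) {
        exp(tau_y * (beta * b[j] - 0.5 * beta^2 * n) - c0) *
          stats::dnorm(beta, 0, 1 / sqrt(tau_beta))
      },
      lower = -Inf, upper = Inf, rel.tol = 1e-12
    )$value
    log(val) + c0
  }, numeric(1))
  u <- log(priors) + log_marg
  u <- u - max(u)
  exp(u) / sum(exp(u))
}

# Brute-force precision-recall enumeration: one point per distinct score
# threshold, trapezoidal area anchored at recall 0.
brute_auprc <- function(score, truth) {
  th <- sort(unique(score), decreasing = TRUE)
  pr <- t(vapply(th, function(t0) {
    pred <- score >= t0
    c(sum(truth[pred]) / sum(truth), sum(truth[pred]) / sum(pred))
  }, numeric(2)))
  r <- c(0, pr[, 1])
  p <- c(pr[1, 2], pr[, 2])
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}

# Summary-statistics fixture file writer.
write_ss_fixture <- function(path, df) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Build a synthetic chromosome and slice per-window loci the way the CLI
# manifest would.
make_chromosome <- function(g = 250, len = 5e6, seed = 101, k_causal = 4,
                            w_intensity = 0, h2 = 0.002, n = 8000) {
  cfg <- sim_config(g = g, n = n, k_causal = k_causal,
                    w_intensity = w_intensity, h2 = h2, ld_decay = 0.9,
                    pos_spacing = floor(len / g), seed = seed)
  sim <- simulate_locus(cfg, keep_genotypes = FALSE)
  windows <- make_windows(len)
  loci <- lapply(seq_len(nrow(windows)), function(i) {
    keep <- which(sim$locus$variants$pos >= windows$start[i] &
                    sim$locus$variants$pos <= windows$end[i])
    locus_data(sim$locus$variants[keep, ],
               sim$locus$ld[keep, keep, drop = FALSE], n = n)
  })
  annos <- lapply(seq_len(nrow(windows)), function(i) {
    keep <- which(sim$locus$variants$pos >= windows$start[i] &
                    sim$locus$variants$pos <= windows$end[i])
    sim$anno[keep, , drop = FALSE]
  })
  list(sim = sim, windows = windows, loci = loci, annos = annos)
}
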