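# Synthetic-data generator: LD-structured genotypes, annotation-driven
# causal sampling, a continuous trait with fixed heritability, and
# per-variant univariate GWAS summary statistics. Replaces real biobank
# genotypes with a parametric latent-Gaussian model so the whole method is
# testable offline.

#' Simulation configuration
#'
#' @param g Number of variants per locus.
#' @param n Number of individuals.
#' @param k_causal Number of causal variants K.
#' @param w_intensity Enrichment log-odds W used when sampling causal
#'   variants (annotated variants are `exp(W)` times more likely causal).
#' @param h2 Trait heritability contributed by the locus; defaults to
#'   `k_causal * 1e-4` (the per-locus design value).
#' @param ld_decay AR(1) correlation of the latent haplotype Gaussian
#'   between adjacent variants, in `[0, 1)`.
#' @param n_blocks Number of independent LD blocks the variants are split
#'   into (AR(1) within blocks, independence across).
#' @param maf_range Minor-allele-frequency interval, inside `(0, 0.5]`.
#' @param m_anno Number of binary annotations.
#' @param enriched_idx Indices of the truly enriched annotations.
#' @param prevalence Range the per-annotation prevalences are drawn from.
#' @param pos_start,pos_spacing Base-pair position of the first variant and
#'   spacing between consecutive variants.
#' @param seed Integer seed; every simulation operation is reproducible
#'   from it.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(g = 1000, n = 25000, k_causal = 5, w_intensity = 2,
                       h2 = k_causal * 1e-4, ld_decay = 0.9, n_blocks = 1,
                       maf_range = c(0.05, 0.5), m_anno = 10,
                       enriched_idx = 1:5, prevalence = c(0.1, 0.3),
                       pos_start = 1, pos_spacing = 1000, seed = 1) {
  stopifnot(h2 >= 0, h2 < 1, k_causal >= 1, k_causal <= g,
            ld_decay >= 0, ld_decay < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(
    list(g = g, n = n, k_causal = k_causal, w_intensity = w_intensity,
         h2 = h2, ld_decay = ld_decay, n_blocks = n_blocks,
         maf_range = maf_range, m_anno = m_anno,
         enriched_idx = enriched_idx, prevalence = prevalence,
         pos_start = pos_start, pos_spacing = pos_spacing, seed = seed),
    class = "sim_config"
  )
}

# One haplotype matrix: latent AR(1) Gaussian thresholded at qnorm(maf).
sim_haplotypes <- function(n, g, ld_decay, thresholds, blocks) {
  lat <- matrix(0, n, g)
  s <- sqrt(1 - ld_decay^2)
  lat[, 1] <- rnorm(n)
  if (g > 1) {
    for (j in 2:g) {
      lat[, j] <- if (blocks[j] != blocks[j - 1]) {
        rnorm(n)
      } else {
        ld_decay * lat[, j - 1] + s * rnorm(n)
      }
    }
  }
  # hap = 1 when the latent value falls below the MAF quantile
  sweep(lat, 2, thresholds, `<`) * 1
}

#' Simulate LD-structured genotype dosages
#'
#' Each of two haplotypes per individual is a latent multivariate normal
#' with AR(1) correlation `ld_decay^|i-j|` (within LD blocks), thresholded
#' at the per-variant minor-allele-frequency quantile; dosages are the sum
#' of the two haplotypes. MAFs are drawn uniformly from `cfg$maf_range`.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed (default `cfg$seed`); pass `NULL` to use the current RNG
#'   state.
#' @param theoretical_ld If `TRUE`, also return the theoretical dosage
#'   correlation matrix (bivariate-normal orthant probabilities for each
#'   variant pair; zero beyond latent correlation 1e-4).
#'
#' @return A list with `genotypes` (n x g matrix of 0/1/2), `maf`, and
#'   `ld_true` (matrix or `NULL`).
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed, theoretical_ld = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  g <- cfg$g
  maf <- runif(g, cfg$maf_range[1], cfg$maf_range[2])
  thr <- qnorm(maf)
  blocks <- sort(rep_len(seq_len(cfg$n_blocks), g))
  geno <- sim_haplotypes(cfg$n, g, cfg$ld_decay, thr, blocks) +
    sim_haplotypes(cfg$n, g, cfg$ld_decay, thr, blocks)
  ld_true <- if (theoretical_ld) {
    theoretical_dosage_ld(maf, cfg$ld_decay, blocks)
  }
  list(genotypes = geno, maf = maf, ld_true = ld_true)
}

# Correlation between thresholded-Gaussian indicators: the latent AR(1)
# correlation attenuates through the binormal orthant probability.
theoretical_dosage_ld <- function(maf, ld_decay, blocks) {
  g <- length(maf)
  thr <- qnorm(maf)
  ld <- diag(g)
  if (ld_decay == 0 || g == 1) return(ld)
  max_lag <- min(g - 1, ceiling(log(1e-4) / log(ld_decay)))
  for (d in seq_len(max_lag)) {
    rho <- ld_decay^d
    for (i in seq_len(g - d)) {
      j <- i + d
      if (blocks[i] != blocks[j]) next
      p11 <- mvtnorm::pmvnorm(
        upper = c(thr[i], thr[j]),
        corr = matrix(c(1, rho, rho, 1), 2)
      )[1]
      r <- (p11 - maf[i] * maf[j]) /
        sqrt(maf[i] * (1 - maf[i]) * maf[j] * (1 - maf[j]))
      ld[i, j] <- ld[j, i] <- r
    }
  }
  ld
}

#' Simulate binary annotations
#'
#' Each annotation is a union of contiguous variant segments (segment length
#' geometric with mean `block`), placed at random starts until the
#' annotation covers a prevalence drawn from `cfg$prevalence`. Segment
#' structure emulates region-based functional annotations (conserved
#' elements, open chromatin, histone-mark peaks), whose carriers cluster in
#' the genome instead of scattering independently; overlap between
#' annotations arises at random.
#'
#' @inheritParams simulate_genotypes
#' @param block Mean segment length in variants (default 10).
#' @return A g x m 0/1 matrix with columns `anno1..annoM`.
#' @export
simulate_annotations <- function(cfg, seed = NULL, block = 10) {
  if (!is.null(seed)) set.seed(seed)
  g <- cfg$g
  prev <- runif(cfg$m_anno, cfg$prevalence[1], cfg$prevalence[2])
  a <- vapply(prev, function(p) {
    col <- numeric(g)
    target <- ceiling(p * g)
    while (sum(col) < target) {
      len <- 1 + stats::rgeom(1, 1 / block)
      start <- sample.int(g, 1)
      col[start:min(start + len - 1, g)] <- 1
    }
    col
  }, numeric(g))
  colnames(a) <- paste0("anno", seq_len(cfg$m_anno))
  a
}

#' Sample causal variants with annotation-dependent odds
#'
#' Samples `cfg$k_causal` distinct variants with probability proportional to
#' `exp(A_g' w_sim)` where `w_sim` equals `cfg$w_intensity` for the enriched
#' annotations and 0 elsewhere. `w_intensity = 0` reduces to uniform
#' sampling.
#'
#' @inheritParams simulate_genotypes
#' @param anno g x m binary annotation matrix.
#' @return Integer vector of causal variant indices.
#' @export
assign_causal <- function(cfg, anno, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w_sim <- rep(0, ncol(anno))
  w_sim[cfg$enriched_idx] <- cfg$w_intensity
  p <- exp(drop(as.matrix(anno) %*% w_sim))
  sort(sample.int(cfg$g, cfg$k_causal, prob = p))
}

#' Simulate a continuous trait with fixed heritability
#'
#' Causal effects are drawn standard normal on standardized dosages and
#' rescaled so the genetic component has sample variance exactly `h2`; the
#' Gaussian noise is residualized against the genetic component and scaled
#' to sample variance exactly `1 - h2`, so the realized heritability equals
#' `h2` by construction and the trait has mean 0 and variance 1.
#'
#' @param genotypes n x g dosage matrix.
#' @param causal_idx Indices of causal variants.
#' @param h2 Target heritability in `[0, 1)`.
#' @param seed Optional seed.
#' @return A list with `trait` (length n) and `true_beta` (effects of the
#'   causal variants on the standardized-dosage scale).
#' @export
simulate_trait <- function(genotypes, causal_idx, h2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(h2 >= 0, h2 < 1)
  n <- nrow(genotypes)
  k <- length(causal_idx)
  noise <- rnorm(n)
  if (h2 == 0) {
    trait <- noise - mean(noise)
    trait <- trait / sd(trait)
    return(list(trait = trait, true_beta = rep(0, k)))
  }
  xs <- scale(genotypes[, causal_idx, drop = FALSE])
  if (anyNA(xs)) abort("monomorphic causal variant; re-simulate genotypes")
  beta <- rnorm(k)
  gc <- drop(xs %*% beta)
  gc <- gc - mean(gc)
  fac <- sqrt(h2) / sd(gc)
  gc <- gc * fac
  beta <- beta * fac
  # exact variance split: strip the noise's sample correlation with gc
  noise <- noise - mean(noise)
  noise <- noise - gc * sum(noise * gc) / sum(gc^2)
  noise <- noise * sqrt(1 - h2) / sd(noise)
  list(trait = gc + noise, true_beta = beta)
}

#' Univariate GWAS on simulated genotypes
#'
#' Per-variant simple linear regression of the trait on each dosage column,
#' returning z-scores and the in-sample LD matrix as a [locus_data()]
#' object. Monomorphic variants get z = 0 with a warning and zero LD with
#' every other variant.
#'
#' @param genotypes n x g dosage matrix.
#' @param trait Standardized trait vector (length n).
#' @param variants Optional variant metadata tibble; synthesized when
#'   missing.
#' @return A [locus_data()] object with in-sample LD.
#' @export
run_gwas <- function(genotypes, trait, variants = NULL) {
  n <- nrow(genotypes)
  g <- ncol(genotypes)
  sds <- apply(genotypes, 2, sd)
  mono <- sds == 0
  if (any(mono)) {
    warn(sprintf("%d monomorphic variant(s); z set to 0", sum(mono)))
  }
  y <- (trait - mean(trait)) / sd(trait)
  xc <- sweep(genotypes, 2, colMeans(genotypes))
  xc[, mono] <- 0
  sds[mono] <- 1
  xs <- sweep(xc, 2, sds * sqrt(n - 1), `/`) # unit-norm columns
  r <- drop(crossprod(xs, y)) / sqrt(n - 1)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- r * sqrt((n - 2) / (1 - r^2))
  z[mono] <- 0
  ld <- crossprod(xs)
  ld[mono, ] <- 0
  ld[, mono] <- 0
  diag(ld) <- 1
  if (is.null(variants)) {
    variants <- tibble::tibble(
      id = paste0("v", seq_len(g)), chrom = "1", pos = seq_len(g),
      allele_effect = "A", allele_other = "G", z = z, n = n
    )
  } else {
    variants$z <- z
    variants$n <- n
  }
  locus_data(variants, ld, n = n)
}

#' Simulate a complete fine-mapping locus
#'
#' Chains [simulate_genotypes()] -> [simulate_annotations()] ->
#' [assign_causal()] -> [simulate_trait()] -> [run_gwas()]; fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param keep_genotypes Keep the dosage matrix in the result (default
#'   `TRUE`; disable to save memory in large sweeps).
#' @return A `simulated_locus` list: `locus` ([locus_data()]), `anno`,
#'   `causal_idx`, `true_beta`, `w_sim`, `maf`, `trait` and optionally
#'   `genotypes`.
#' @export
simulate_locus <- function(cfg, keep_genotypes = TRUE) {
  set.seed(cfg$seed)
  gen <- simulate_genotypes(cfg, seed = NULL, theoretical_ld = FALSE)
  anno <- simulate_annotations(cfg)
  causal_idx <- assign_causal(cfg, anno)
  tr <- simulate_trait(gen$genotypes, causal_idx, cfg$h2)
  variants <- tibble::tibble(
    id = paste0("v", seq_len(cfg$g)), chrom = "1",
    pos = as.integer(cfg$pos_start + (seq_len(cfg$g) - 1) * cfg$pos_spacing),
    allele_effect = "A", allele_other = "G",
    z = 0, n = cfg$n
  )
  locus <- run_gwas(gen$genotypes, tr$trait, variants)
  w_sim <- rep(0, cfg$m_anno)
  w_sim[cfg$enriched_idx] <- cfg$w_intensity
  structure(
    list(
      locus = locus, anno = anno, causal_idx = causal_idx,
      true_beta = tr$true_beta, w_sim = w_sim, maf = gen$maf,
      trait = tr$trait,
      genotypes = if (keep_genotypes) gen$genotypes
    ),
    class = "simulated_locus"
  )
}

#' Write a simulated locus in the formats the fine-mapping reader accepts
#'
#' Writes `<prefix>.ss.tsv` (summary statistics), `<prefix>.ld.tsv`,
#' `<prefix>.anno.tsv` and `<prefix>.truth.tsv` (causal indices, ids, true
#' effects and the simulated enrichment weights as a header comment).
#'
#' @param sim A `simulated_locus`.
#' @param prefix Output path prefix.
#' @return Invisibly, the files written.
#' @export
write_simulated_locus <- function(sim, prefix) {
  ss <- sim$locus$variants |>
    dplyr::transmute(
      SNP = .data$id, CHR = .data$chrom, POS = .data$pos,
      A1 = .data$allele_effect, A2 = .data$allele_other,
      Z = signif(sim$locus$z, 6), N = sim$locus$n
    )
  files <- c(
    ss = paste0(prefix, ".ss.tsv"),
    ld = paste0(prefix, ".ld.tsv"),
    anno = paste0(prefix, ".anno.tsv"),
    truth = paste0(prefix, ".truth.tsv")
  )
  utils::write.table(as.data.frame(ss), files["ss"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_ld(sim$locus$ld, files["ld"])
  anno_df <- data.frame(SNP = ss$SNP, sim$anno, check.names = FALSE)
  utils::write.table(anno_df, files["anno"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- data.frame(
    SNP = ss$SNP[sim$causal_idx],
    index = sim$causal_idx,
    true_beta = signif(sim$true_beta, 6)
  )
  con <- file(files["truth"], "w")
  writeLines(paste0("# w_sim\t", paste(signif(sim$w_sim, 6), collapse = "\t")),
             con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(files)
}
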