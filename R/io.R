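#' Read GWAS summary statistics
#'
#' Reads a tab- or whitespace-separated summary-statistics file with a
#' header. Either a z-score column or beta + SE columns must be present;
#' when z is absent it is computed as beta/SE. Row order is preserved.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping the canonical names
#'   `id`, `chrom`, `pos`, `allele_effect`, `allele_other`, `beta`, `se`,
#'   `z`, `n` to the column names used in the file. Defaults cover the
#'   common SNP/CHR/POS/A1/A2/BETA/SE/N (or Z) layout.
#' @param n Optional locus-level sample size used when the file has no N
#'   column.
#'
#' @return A tibble with columns `id`, `chrom`, `pos`, `allele_effect`,
#'   `allele_other`, `z` and `n`, one row per variant in file order.
#' @export
read_sumstats <- function(path, column_map = NULL, n = NULL) {
  default_map <- c(
    id = "SNP", chrom = "CHR", pos = "POS",
    allele_effect = "A1", allele_other = "A2",
    beta = "BETA", se = "SE", z = "Z", n = "N"
  )
  map <- default_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  get_col <- function(key) {
    if (map[[key]] %in% names(raw)) raw[[map[[key]]]] else NULL
  }
  for (key in c("id", "chrom", "pos", "allele_effect", "allele_other")) {
    if (is.null(get_col(key))) {
      abort(sprintf("summary-statistics file is missing column '%s' (%s)",
                    map[[key]], key))
    }
  }
  z <- get_col("z")
  if (is.null(z)) {
    beta <- get_col("beta")
    se <- get_col("se")
    if (is.null(beta) || is.null(se)) {
      abort(sprintf(
        "file must contain either a '%s' column or both '%s' and '%s'",
        map[["z"]], map[["beta"]], map[["se"]]
      ))
    }
    beta <- parse_numeric(beta, map[["beta"]])
    se <- parse_numeric(se, map[["se"]])
    z <- beta / se
  } else {
    z <- parse_numeric(z, map[["z"]])
  }
  n_col <- get_col("n")
  if (is.null(n_col)) {
    if (is.null(n)) {
      abort(sprintf(
        "file has no '%s' column; supply the sample size via `n`", map[["n"]]
      ))
    }
    n_col <- rep(n, nrow(raw))
  } else {
    n_col <- parse_numeric(n_col, map[["n"]])
  }
  tibble::tibble(
    id = as.character(get_col("id")),
    chrom = as.character(get_col("chrom")),
    pos = as.integer(get_col("pos")),
    allele_effect = toupper(as.character(get_col("allele_effect"))),
    allele_other = toupper(as.character(get_col("allele_other"))),
    z = as.numeric(z),
    n = as.numeric(n_col)
  )
}

# Coerce a column to numeric, reporting 1-based data-row line numbers of
# malformed entries.
parse_numeric <- function(x, colname) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad) > 0) {
    abort(sprintf(
      "non-numeric value(s) in column '%s' at data row(s) %s",
      colname, paste(head(bad, 5), collapse = ", ")
    ))
  }
  out
}

#' Read an LD matrix from a whitespace-delimited text file
#'
#' @param path Path to a square numeric matrix (no header, no row names).
#' @param expected_g Expected number of variants; dimension mismatches are
#'   an error.
#'
#' @return A validated, symmetrized G x G correlation matrix.
#' @export
read_ld <- function(path, expected_g = NULL) {
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  split <- strsplit(trimws(rows), "[[:space:],]+")
  lens <- lengths(split)
  if (length(unique(lens)) != 1 || lens[1] != length(rows)) {
    abort(sprintf(
      "LD file is not a square matrix: %d rows, row lengths %s",
      length(rows), paste(unique(lens), collapse = "/")
    ))
  }
  m <- matrix(as.numeric(unlist(split)), nrow = length(rows), byrow = TRUE)
  if (anyNA(m)) abort("LD file contains non-numeric entries")
  validate_ld(m, expected_g = expected_g)
}

#' Read a binary annotation matrix
#'
#' First column is the variant ID, remaining columns are 0/1 annotation
#' indicators named in the header.
#'
#' @param path Path to the annotation TSV.
#' @param ids Optional character vector of variant IDs; when given, rows are
#'   reordered to match and missing variants are an error.
#'
#' @return A numeric 0/1 matrix with variant IDs as row names and annotation
#'   labels as column names.
#' @export
read_annotations <- function(path, ids = NULL) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  rn <- as.character(raw[[1]])
  a <- as.matrix(raw[, -1, drop = FALSE])
  rownames(a) <- rn
  if (!is.null(ids)) {
    miss <- setdiff(ids, rn)
    if (length(miss) > 0) {
      abort(sprintf("annotation file is missing %d variant(s), e.g. %s",
                    length(miss), miss[1]))
    }
    a <- a[ids, , drop = FALSE]
  }
  validate_annotations(a, nrow(a))
}

#' Harmonize summary-statistic alleles against an LD reference panel
#'
#' Aligns a summary-statistics table to the variant order and allele coding
#' of a reference panel. Swapped effect/other alleles flip the z sign;
#' strand-ambiguous variants (A/T, C/G) and variants absent from the
#' reference are dropped and logged.
#'
#' @param sumstats Tibble as returned by [read_sumstats()].
#' @param reference Data frame of reference variants with columns `id`,
#'   `allele_effect`, `allele_other` (and optionally `chrom`, `pos`).
#'
#' @return A tibble in reference order with harmonized alleles and flipped z
#'   where needed. The attribute `"dropped"` holds a tibble of removed
#'   variants and the reason (`ambiguous`, `unmatched`, `allele_mismatch`).
#' @export
match_alleles <- function(sumstats, reference) {
  stopifnot(is.data.frame(sumstats), is.data.frame(reference))
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- function(a1, a2) {
    nchar(a1) == 1 & nchar(a2) == 1 & !is.na(flip[a1]) & flip[a1] == a2
  }
  ss <- tibble::as_tibble(sumstats)
  drop_log <- list()

  amb <- ambiguous(ss$allele_effect, ss$allele_other)
  if (any(amb)) {
    drop_log$ambiguous <- dplyr::mutate(ss[amb, ], reason = "ambiguous")
    ss <- ss[!amb, ]
  }
  idx <- match(reference$id, ss$id)
  unmatched_ss <- ss[!ss$id %in% reference$id, ]
  if (nrow(unmatched_ss) > 0) {
    drop_log$unmatched <- dplyr::mutate(unmatched_ss, reason = "unmatched")
  }
  keep <- !is.na(idx)
  out <- ss[idx[keep], ]
  ref <- reference[keep, ]
  if (nrow(out) == 0) {
    abort("no overlap between summary statistics and the reference panel")
  }
  same <- out$allele_effect == ref$allele_effect &
    out$allele_other == ref$allele_other
  swapped <- out$allele_effect == ref$allele_other &
    out$allele_other == ref$allele_effect
  mism <- !(same | swapped)
  if (any(mism)) {
    drop_log$allele_mismatch <-
      dplyr::mutate(out[mism, ], reason = "allele_mismatch")
  }
  out$z[swapped] <- -out$z[swapped]
  out$allele_effect <- ref$allele_effect
  out$allele_other <- ref$allele_other
  out <- out[!mism, ]
  dropped <- dplyr::bind_rows(drop_log)
  if (nrow(dropped) > 0) {
    inform(sprintf("match_alleles: dropped %d variant(s) (%s)",
                   nrow(dropped),
                   paste(unique(dropped$reason), collapse = ", ")))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Write fine-mapping results to TSV files
#'
#' Writes up to three files: `<prefix>.pip.tsv` (per-variant PIP, best
#' effect-group index and its selection probability), `<prefix>.cs.tsv`
#' (credible-set members) and, when the fit used annotations,
#' `<prefix>.enrichment.tsv`. Values are written with 6 significant digits.
#'
#' @param result A `finemap_fit` object from [finemap()].
#' @param prefix Output path prefix.
#'
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(result, prefix) {
  stopifnot(inherits(result, "finemap_fit"))
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) signif(col, 6) else col
    })
    df
  }
  files <- character(0)
  pip_path <- paste0(prefix, ".pip.tsv")
  utils::write.table(fmt(as.data.frame(tidy(result))), pip_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, pip_path)

  cs_path <- paste0(prefix, ".cs.tsv")
  cs <- as.data.frame(tidy(result, "sets"))
  utils::write.table(fmt(cs), cs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, cs_path)

  if (!is.null(result$enrichment)) {
    en_path <- paste0(prefix, ".enrichment.tsv")
    utils::write.table(fmt(as.data.frame(tidy(result, "enrichment"))),
                       en_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, en_path)
  }
  invisible(files)
}

#' Write an LD matrix as whitespace-delimited text
#'
#' @param ld Square matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ld <- function(ld, path) {
  utils::write.table(signif(ld, 6), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
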