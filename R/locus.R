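#' Assemble a fine-mapping locus
#'
#' Bundles per-variant GWAS summary statistics with a matched LD matrix into
#' the unit of fine-mapping. The summary statistics come first as a data
#' frame (one row per variant, in LD-matrix order) so loci can be built at
#' the end of a pipe.
#'
#' @param sumstats Data frame with columns `id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`, `z` and optionally `n`
#'   (as returned by [read_sumstats()]).
#' @param ld Square numeric matrix of Pearson correlations between variant
#'   genotypes, rows/columns in the same order as `sumstats`.
#' @param n GWAS sample size (individuals). Defaults to the median of the
#'   per-variant `n` column when present; one locus-level value is used
#'   because the precision updates need a single N.
#'
#' @return An object of class `locus_data`: a list with elements
#'   `variants` (tibble), `z` (numeric vector), `n` (scalar) and `ld`
#'   (matrix).
#' @export
#' @examples
#' ss <- tibble::tibble(
#'   id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'   allele_effect = c("A", "C"), allele_other = c("G", "T"),
#'   z = c(3.2, 1.1), n = 10000
#' )
#' loc <- locus_data(ss, diag(2))
locus_data <- function(sumstats, ld, n = NULL) {
  stopifnot(is.data.frame(sumstats))
  req <- c("id", "z")
  miss <- setdiff(req, names(sumstats))
  if (length(miss) > 0) {
    abort(paste0("sumstats is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (is.null(n)) {
    if (!"n" %in% names(sumstats)) {
      abort("no `n` column in sumstats and no locus-level `n` supplied")
    }
    n <- stats::median(sumstats$n)
  }
  ld <- validate_ld(as.matrix(ld), expected_g = nrow(sumstats))
  z <- as.numeric(sumstats$z)
  if (anyNA(z)) abort("z contains missing values")
  if (n < 2) abort("sample size n must be >= 2")
  structure(
    list(
      variants = tibble::as_tibble(sumstats),
      z = z,
      n = as.numeric(n),
      ld = ld
    ),
    class = "locus_data"
  )
}

#' @export
print.locus_data <- function(x, ...) {
  cat(sprintf(
    "<locus_data> %d variants, n = %s, max |z| = %.2f\n",
    length(x$z), format(x$n), max(abs(x$z))
  ))
  invisible(x)
}

# Validate an LD matrix against the locus invariants: square, symmetric
# within tol, unit diagonal, |r| <= 1. Small asymmetries are averaged out.
validate_ld <- function(ld, expected_g = NULL, sym_tol = 1e-8,
                        diag_tol = 1e-6) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    abort("LD matrix must be square")
  }
  if (!is.null(expected_g) && nrow(ld) != expected_g) {
    abort(sprintf(
      "LD matrix dimension %d does not match the %d variants expected",
      nrow(ld), expected_g
    ))
  }
  asym <- max(abs(ld - t(ld)))
  if (asym > sym_tol) {
    abort(sprintf("LD matrix is asymmetric (max |R - t(R)| = %.3g)", asym))
  }
  ld <- (ld + t(ld)) / 2
  dev <- max(abs(diag(ld) - 1))
  if (dev > diag_tol) {
    abort(sprintf("LD diagonal deviates from 1 by up to %.3g", dev))
  }
  if (max(abs(ld)) > 1 + 1e-6) {
    abort("LD matrix has entries with |r| > 1")
  }
  ld
}

# Validate a binary annotation matrix against a locus (G rows, M columns).
validate_annotations <- function(anno, g) {
  a <- as.matrix(anno)
  if (is.null(colnames(a))) {
    colnames(a) <- paste0("anno", seq_len(ncol(a)))
  }
  if (nrow(a) != g) {
    abort(sprintf("annotation matrix has %d rows but locus has %d variants",
                  nrow(a), g))
  }
  if (!all(a %in% c(0, 1))) abort("annotation entries must be 0/1")
  storage.mode(a) <- "double"
  a
}
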