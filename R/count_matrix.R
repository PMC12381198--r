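#' Construct a gene-by-sample count matrix
#'
#' Container for raw integer counts with gene and sample identifiers and
#' per-sample library sizes (column sums).
#'
#' @param counts Numeric matrix of non-negative finite counts.
#' @param genes,samples Identifier vectors; default to the dimnames.
#' @return An object of class `count_matrix`: list with `counts` (matrix with
#'   dimnames), `genes`, `samples`, `lib_size`.
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         samples = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(genes) || is.null(samples)) {
    stop("gene and sample identifiers are required")
  }
  genes <- as.character(genes); samples <- as.character(samples)
  if (length(genes) != nrow(counts) || length(samples) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene ID(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at gene ", genes[bad[1]], ", sample ",
         samples[bad[2]])
  }
  dimnames(counts) <- list(genes, samples)
  structure(list(counts = counts, genes = genes, samples = samples,
                 lib_size = colSums(counts)),
            class = "count_matrix")
}

#' @export
#' @method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, median library %.3g\n",
              length(x$genes), length(x$samples),
              stats::median(x$lib_size)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV format: header row of sample IDs, first column gene IDs. MTX format:
#' MatrixMarket triplet file with `genes.tsv` and `samples.tsv` sidecars
#' (one ID per line) in the same directory unless given explicitly.
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @param genes_path,samples_path Sidecar paths for MTX input.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) != 1) {
      stop("ragged TSV: row(s) ",
           paste(which(nf != nf[1]), collapse = ", "),
           " have a different number of fields")
    }
    d <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE)
    genes <- as.character(d[[1]])
    m <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    count_matrix(m, genes = genes, samples = colnames(d)[-1])
  } else {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(samples_path)) {
      samples_path <- file.path(dirname(path), "samples.tsv")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    samples <- readLines(samples_path)
    count_matrix(m, genes = genes, samples = samples)
  }
}

#' Write a count matrix to TSV or MatrixMarket files
#'
#' @param m A [count_matrix].
#' @param path Output path (`.tsv`, or `.mtx` with `genes.tsv`/`samples.tsv`
#'   sidecars written next to it).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("auto", "tsv", "mtx")) {
  stopifnot(inherits(m, "count_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    d <- data.frame(gene = m$genes, m$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    writeLines(m$genes, file.path(dirname(path), "genes.tsv"))
    writeLines(m$samples, file.path(dirname(path), "samples.tsv"))
  }
  invisible(path)
}

#' Counts per million
#'
#' `cpm = count / (lib_size * factor) * 1e6`. Factors default to 1 (raw
#' library-size CPM, the convention used for the expression filter);
#' TMM-adjusted CPM is obtained by passing [tmm_factors()] output.
#'
#' @param m A [count_matrix].
#' @param factors Optional per-sample positive normalization factors, named
#'   by sample or in sample order.
#' @return Numeric matrix of CPM values with the same dimnames.
#' @export
compute_cpm <- function(m, factors = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (any(m$lib_size <= 0)) {
    stop("zero library size for sample(s): ",
         paste(m$samples[m$lib_size <= 0], collapse = ", "))
  }
  if (is.null(factors)) factors <- rep(1, length(m$samples))
  if (!is.null(names(factors))) factors <- factors[m$samples]
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("normalization factors must be positive and finite")
  }
  t(t(m$counts) / (m$lib_size * factors)) * 1e6
}

#' Expression filter
#'
#' Retains genes with at least one sample at CPM > 1 (strict) and cumulative
#' CPM > 1 across all samples, computed on raw library sizes. Optionally the
#' CPM criterion is evaluated on a subset of samples (e.g. the reference
#' genotype only) while all samples are retained in the output.
#'
#' @param m A [count_matrix].
#' @param use_samples Optional character vector of sample IDs on which to
#'   evaluate the filter (default: all samples).
#' @return A [count_matrix] restricted to the retained genes, in the original
#'   gene order.
#' @export
filter_expressed <- function(m, use_samples = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  cpm <- compute_cpm(m)
  if (!is.null(use_samples)) {
    missing <- setdiff(use_samples, m$samples)
    if (length(missing) > 0) {
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
    }
    cpm <- cpm[, use_samples, drop = FALSE]
  }
  keep <- rowSums(cpm > 1) >= 1 & rowSums(cpm) > 1
  count_matrix(m$counts[keep, , drop = FALSE])
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors computed against a reference sample: after
#' library-size division, log ratios (M) are trimmed by 30 percent on each
#' side and log intensities (A) by 5 percent; the factor is the
#' inverse-asymptotic-variance weighted mean of the surviving M values.
#' Genes with a zero count in either the sample or the reference are
#' excluded. Factors are normalized to geometric mean 1.
#'
#' @param m A [count_matrix] with at least two samples.
#' @param ref Reference sample ID, or `NULL` to pick the sample whose
#'   upper-quartile count fraction is closest to the mean upper quartile.
#' @param trim_m,trim_a Trim fractions for M and A (defaults 0.3 and 0.05).
#' @return Named per-sample factor vector with geometric mean 1.
#' @export
tmm_factors <- function(m, ref = NULL, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  if (length(m$samples) < 2) stop("need at least 2 samples")
  y <- m$counts
  lib <- m$lib_size
  if (is.null(ref)) {
    uq <- apply(y, 2, function(v) stats::quantile(v[v > 0], 0.75)) / lib
    ref <- m$samples[which.min(abs(uq - mean(uq)))]
  }
  if (!ref %in% m$samples) stop("unknown reference sample: ", ref)
  yr <- y[, ref]
  nr <- lib[ref]
  f <- vapply(m$samples, function(s) {
    if (s == ref) return(1)
    ys <- y[, s]; ns <- lib[s]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) {
      stop("sample ", s, " shares no nonzero genes with the reference")
    }
    ys <- ys[ok]; yrk <- yr[ok]
    M <- log2((ys / ns) / (yrk / nr))
    A <- 0.5 * log2((ys / ns) * (yrk / nr))
    w <- 1 / ((ns - ys) / (ns * ys) + (nr - yrk) / (nr * yrk))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- m$samples
  f
}

#' Center (and optionally standardize) gene expression rows
#'
#' Subtracts each gene's mean across all samples, the "scaling" used before
#' correlation and community-trace analysis. With `unit_variance = TRUE`
#' rows are additionally divided by their standard deviation; constant rows
#' are left at zero with a warning.
#'
#' @param cpm Numeric matrix (genes x samples), e.g. from [compute_cpm()].
#' @param unit_variance Also scale rows to unit SD (default FALSE).
#' @return Matrix of the same shape with row means 0.
#' @export
center_genes <- function(cpm, unit_variance = FALSE) {
  x <- as.matrix(cpm)
  out <- x - rowMeans(x)
  if (unit_variance) {
    s <- apply(x, 1, stats::sd)
    const <- s == 0 | !is.finite(s)
    if (any(const)) {
      warning(sum(const), " constant row(s) left at zero")
      s[const] <- 1
    }
    out <- out / s
  }
  out
}
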