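# Negative-binomial differential expression engine.
#
# The model for gene g in sample j is y_gj ~ NB(mu_gj, phi_g) with
# log mu_gj = eta_g(group_j) + offset_j, offset_j = log(lib_size_j * factor_j).
# Group means are fitted by Fisher-scoring on eta; contrasts are tested by a
# likelihood-ratio test against chi-square with 1 df. Dispersions are
# estimated by Cox-Reid adjusted profile likelihood with empirical-Bayes
# shrinkage of gene-wise values toward the common value.

.PHI_FLOOR <- 1e-8

# Fit per-gene intercepts eta for one group of columns.
# y: genes x samples matrix; offset: length ncol(y); phi: length nrow(y).
# Returns list(eta, mu, info) where info = sum_j mu/(1+phi*mu) (Fisher info).
.nb_fit_group <- function(y, offset, phi, maxit = 50L, tol = 1e-10) {
  O <- exp(offset)
  phi <- pmax(rep_len(phi, nrow(y)), 0)
  eta <- log(pmax(rowSums(y) / sum(O), 1e-8))
  for (it in seq_len(maxit)) {
    mu <- exp(eta) %o% O
    denom <- 1 + phi * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- ifelse(info > 0, score / pmax(info, 1e-12), 0)
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  eta <- pmax(eta, -30)
  mu <- exp(eta) %o% O
  list(eta = eta, mu = mu, info = rowSums(mu / (1 + phi * mu)))
}

# Row-wise NB log-likelihood at fitted means (phi floored toward Poisson).
.nb_loglik_rows <- function(y, mu, phi) {
  phi <- pmax(rep_len(phi, nrow(y)), .PHI_FLOOR)
  size <- 1 / phi
  rowSums(stats::dnbinom(y, size = size, mu = pmax(mu, 1e-12), log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood per gene for a one-way group
# layout at a single dispersion value phi. The CR adjustment for the
# group-means design is 0.5 * sum over groups of log(sum_j mu/(1+phi*mu)).
.apl_per_gene <- function(y, offset, group, phi) {
  group <- as.factor(group)
  ll <- numeric(nrow(y))
  cr <- numeric(nrow(y))
  for (g in levels(group)) {
    cols <- which(group == g)
    fit <- .nb_fit_group(y[, cols, drop = FALSE], offset[cols], phi)
    ll <- ll + .nb_loglik_rows(y[, cols, drop = FALSE], fit$mu, phi)
    cr <- cr + 0.5 * log(pmax(fit$info, 1e-12))
  }
  ll - cr
}

#' Estimate negative-binomial dispersions
#'
#' Common dispersion is the maximizer of the Cox-Reid adjusted profile
#' likelihood (APL) summed over genes, located on a log-spaced grid and
#' refined by golden-section search. Gene-wise dispersions are shrunk toward
#' the common value by maximizing, per gene, the weighted likelihood
#' APL_g(phi) + prior_n * mean_g APL(phi) with prior_n = prior_df / residual
#' df, the usual empirical-Bayes compromise between a noisy per-gene profile
#' and the stable common profile.
#'
#' @param m A [count_matrix], or a bare counts matrix.
#' @param groups Per-sample grouping vector defining the cell means.
#' @param factors Optional per-sample normalization factors (default 1).
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @param grid_range Dispersion grid endpoints (default `c(1e-6, 4)`).
#' @param grid_length Number of log-spaced grid points (default 25).
#' @return List with `common` (scalar), `tagwise` (per-gene vector, named by
#'   gene), `prior_df`, and `grid` (the grid searched). With a single sample
#'   per group throughout, the gene-wise component is undefined (residual df
#'   0) and `tagwise` equals `common` with a warning.
#' @export
estimate_dispersion <- function(m, groups, factors = NULL, prior_df = 10,
                                grid_range = c(1e-6, 4), grid_length = 25L) {
  y <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (all(y == 0)) stop("all counts are zero; dispersion is undefined")
  groups <- as.factor(groups)
  if (length(groups) != ncol(y)) stop("'groups' must have one entry per sample")
  lib <- colSums(y)
  if (is.null(factors)) factors <- rep(1, ncol(y))
  offset <- log(lib * factors)
  keep <- rowSums(y) > 0
  yk <- y[keep, , drop = FALSE]

  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_length))
  apl <- matrix(NA_real_, nrow(yk), grid_length)
  for (i in seq_len(grid_length)) {
    apl[, i] <- .apl_per_gene(yk, offset, groups, grid[i])
  }
  mean_apl <- colMeans(apl)

  # golden-section refinement of the common dispersion on the log scale
  i0 <- which.max(mean_apl)
  lo <- log(grid[max(1, i0 - 1)])
  hi <- log(grid[min(grid_length, i0 + 1)])
  f <- function(lphi) mean(.apl_per_gene(yk, offset, groups, exp(lphi)))
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  for (it in seq_len(20L)) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
    if (hi - lo < 1e-4) break
  }
  common <- exp((lo + hi) / 2)

  df_resid <- ncol(y) - nlevels(groups)
  tagwise <- rep(common, nrow(y))
  if (df_resid <= 0) {
    warning("single sample per group: gene-wise dispersion undefined, ",
            "returning common dispersion only")
  } else {
    prior_n <- prior_df / df_resid
    wl <- apl + matrix(prior_n * mean_apl, nrow(yk), grid_length, byrow = TRUE)
    best <- max.col(wl, ties.method = "first")
    tagwise_k <- grid[best]
    # quadratic interpolation on log(phi) around the grid maximum
    interior <- best > 1 & best < grid_length
    if (any(interior)) {
      ii <- which(interior)
      b <- best[ii]
      lg <- log(grid)
      x0 <- lg[b - 1]; x1i <- lg[b]; x2i <- lg[b + 1]
      y0 <- wl[cbind(ii, b - 1)]; y1 <- wl[cbind(ii, b)]
      y2 <- wl[cbind(ii, b + 1)]
      denom <- (y0 - 2 * y1 + y2)
      shift <- ifelse(abs(denom) > 1e-12,
                      0.5 * (y0 - y2) / denom * (x2i - x0) / 2, 0)
      shift <- pmin(pmax(shift, -(x1i - x0)), x2i - x1i)
      tagwise_k[ii] <- exp(x1i + shift)
    }
    tagwise[keep] <- tagwise_k
  }
  names(tagwise) <- rownames(y)
  list(common = common, tagwise = tagwise, prior_df = prior_df, grid = grid)
}

#' Define a mutant-versus-reference contrast at one timepoint
#'
#' @param mutant,reference Genotype labels (must differ).
#' @param temperature Temperature in degrees C.
#' @param timepoint ZT timepoint in hours.
#' @return An object of class `de_contrast`.
#' @export
de_contrast <- function(mutant, reference, temperature, timepoint) {
  if (identical(mutant, reference)) stop("'mutant' and 'reference' must differ")
  structure(list(mutant = mutant, reference = reference,
                 temperature = temperature, timepoint = timepoint),
            class = "de_contrast")
}

#' @export
#' @method print de_contrast
print.de_contrast <- function(x, ...) {
  cat(sprintf("contrast: %s vs %s at %g C, ZT%g\n",
              x$mutant, x$reference, x$temperature, x$timepoint))
  invisible(x)
}

#' Test one mutant-versus-reference contrast at one timepoint
#'
#' Negative-binomial likelihood-ratio test of equal group means with offsets
#' `log(lib_size * factor)`. The log2 fold change uses moderated group-average
#' CPM with a prior count of 0.5, which keeps estimates finite when one side
#' is all zero.
#'
#' @param m A [count_matrix].
#' @param contrast A [de_contrast].
#' @param design Sample metadata data.frame with columns `sample_id`,
#'   `genotype`, `temperature_C`, `zt_h`, `replicate` (see
#'   [generate_design()]).
#' @param factors Optional per-sample normalization factors named by sample
#'   (default 1).
#' @param dispersion Per-gene dispersions (e.g. `estimate_dispersion()$tagwise`),
#'   or a scalar.
#' @return An object of class `de_result`: data.frame with columns `gene`,
#'   `log2fc` (mutant over reference), `p_value`, `q_value` (BH-adjusted),
#'   `mean_cpm`, carrying the contrast as an attribute.
#' @export
test_contrast <- function(m, contrast, design, factors = NULL,
                          dispersion = 0.05) {
  stopifnot(inherits(m, "count_matrix"), inherits(contrast, "de_contrast"))
  sel <- design$temperature_C == contrast$temperature &
    design$zt_h == contrast$timepoint
  id_ref <- design$sample_id[sel & design$genotype == contrast$reference]
  id_mut <- design$sample_id[sel & design$genotype == contrast$mutant]
  id_ref <- intersect(id_ref, m$samples)
  id_mut <- intersect(id_mut, m$samples)
  if (length(id_ref) == 0 || length(id_mut) == 0) {
    stop("empty group for contrast ", contrast$mutant, " vs ",
         contrast$reference, " at ", contrast$temperature, " C, ZT",
         contrast$timepoint)
  }
  if (length(id_ref) < 2 || length(id_mut) < 2) {
    warning("fewer than 2 replicates on one side of the contrast; ",
            "test proceeds but power is reduced")
  }
  if (is.null(factors)) {
    factors <- stats::setNames(rep(1, length(m$samples)), m$samples)
  }
  cols <- c(id_ref, id_mut)
  y <- m$counts[, cols, drop = FALSE]
  offset <- log(m$lib_size[cols] * factors[cols])
  phi <- rep_len(dispersion, nrow(y))
  if (!is.null(names(dispersion)) && !is.null(m$genes)) {
    phi <- dispersion[m$genes]
    if (anyNA(phi)) stop("dispersion vector is missing genes")
  }

  iR <- seq_along(id_ref)
  iM <- length(id_ref) + seq_along(id_mut)
  fitR <- .nb_fit_group(y[, iR, drop = FALSE], offset[iR], phi)
  fitM <- .nb_fit_group(y[, iM, drop = FALSE], offset[iM], phi)
  fit0 <- .nb_fit_group(y, offset, phi)
  ll1 <- .nb_loglik_rows(y[, iR, drop = FALSE], fitR$mu, phi) +
    .nb_loglik_rows(y[, iM, drop = FALSE], fitM$mu, phi)
  ll0 <- .nb_loglik_rows(y, fit0$mu, phi)
  lr <- pmax(2 * (ll1 - ll0), 0)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)

  cpm <- t(t(y) / exp(offset)) * 1e6
  cpm_ref <- rowMeans(cpm[, iR, drop = FALSE])
  cpm_mut <- rowMeans(cpm[, iM, drop = FALSE])
  log2fc <- log2((cpm_mut + 0.5) / (cpm_ref + 0.5))

  out <- data.frame(gene = m$genes, log2fc = log2fc, p_value = p,
                    q_value = bh_adjust(p), mean_cpm = rowMeans(cpm),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "n_ref") <- length(id_ref)
  attr(out, "n_mut") <- length(id_mut)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment. Input order is preserved.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is called up-regulated when `q_value < fdr` and
#' `log2fc >= min_abs_log2fc`, down-regulated when `q_value < fdr` and
#' `log2fc <= -min_abs_log2fc` (strict FDR inequality; configurable).
#'
#' @param r A `de_result`.
#' @param fdr FDR threshold in (0, 1\] (default 0.05).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 0.25).
#' @param strict Use `q < fdr` (default) rather than `q <= fdr`.
#' @return An object of class `deg_set`: list with character vectors `up` and
#'   `down` (disjoint), the `contrast`, and the thresholds used.
#' @export
call_degs <- function(r, fdr = 0.05, min_abs_log2fc = 0.25, strict = TRUE) {
  stopifnot(fdr > 0, fdr <= 1, min_abs_log2fc >= 0)
  pass <- if (strict) r$q_value < fdr else r$q_value <= fdr
  up <- r$gene[pass & r$log2fc >= min_abs_log2fc]
  down <- r$gene[pass & r$log2fc <= -min_abs_log2fc]
  structure(list(up = up, down = down, contrast = attr(r, "contrast"),
                 fdr = fdr, min_abs_log2fc = min_abs_log2fc),
            class = "deg_set")
}

#' @export
#' @method print deg_set
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set: %d up, %d down (FDR < %g, |log2FC| >= %g)\n",
              length(x$up), length(x$down), x$fdr, x$min_abs_log2fc))
  invisible(x)
}

#' Collapse per-timepoint DEG sets across the day
#'
#' Unions the up- and down-regulated sets of one genotype across timepoints.
#' A gene up-regulated at one ZT and down-regulated at another appears in
#' both unions; such genes are reported with a warning.
#'
#' @param sets List of `deg_set` objects sharing mutant, reference and
#'   temperature.
#' @param check_temperature Require a shared temperature (default TRUE); set
#'   FALSE to additionally collapse across temperatures.
#' @return List with `up`, `down` (character unions), `both` (genes in both
#'   unions), and the shared `mutant`.
#' @export
collapse_degs <- function(sets, check_temperature = TRUE) {
  stopifnot(length(sets) >= 1)
  muts <- vapply(sets, function(s) s$contrast$mutant, character(1))
  if (length(unique(muts)) != 1) {
    stop("cannot collapse DEG sets from different mutant genotypes: ",
         paste(unique(muts), collapse = ", "))
  }
  if (check_temperature) {
    temps <- vapply(sets, function(s) s$contrast$temperature, numeric(1))
    if (length(unique(temps)) != 1) {
      stop("cannot collapse DEG sets across temperatures ",
           "(set check_temperature = FALSE to allow)")
    }
  }
  up <- sort(unique(unlist(lapply(sets, `[[`, "up"))))
  down <- sort(unique(unlist(lapply(sets, `[[`, "down"))))
  both <- intersect(up, down)
  if (length(both) > 0) {
    warning(length(both), " gene(s) up at one ZT and down at another; ",
            "present in both unions")
  }
  list(up = up, down = down, both = both, mutant = muts[1])
}
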