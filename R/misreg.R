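# Community-level time-course traces and genotype x time misregulation
# heatmaps.
#
# The observational unit is the per-sample community score (the mean of the
# member genes' scaled values in that sample): member genes are co-expressed
# by construction, so gene-level observations would inflate the degrees of
# freedom. A gene-level mode is available for comparison.

.community_scores <- function(scaled, members, cols, unit = "sample") {
  x <- scaled[members, cols, drop = FALSE]
  if (unit == "sample") {
    data.frame(sample_id = cols, score = colMeans(x),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(sample_id = rep(cols, each = length(members)),
               score = as.vector(x), stringsAsFactors = FALSE)
  }
}

#' Community time-course traces
#'
#' For each (community, genotype, temperature, timepoint): the mean over
#' replicates of the per-sample community score, with a t-distribution 95
#' percent confidence half-width over replicates.
#'
#' @param scaled Centered expression matrix (genes x samples), e.g. from
#'   [center_genes()].
#' @param partition A `community_partition` (typically after
#'   [filter_min_size()]).
#' @param design Sample metadata (see [generate_design()]).
#' @return An object of class `community_traces`: data.frame with columns
#'   `community`, `genotype`, `temperature_C`, `zt_h`, `mean`,
#'   `ci_halfwidth`, `n`.
#' @export
community_traces <- function(scaled, partition, design) {
  stopifnot(inherits(partition, "community_partition"))
  design <- design[design$sample_id %in% colnames(scaled), , drop = FALSE]
  out <- list()
  for (ci in seq_along(partition$communities)) {
    members <- intersect(partition$communities[[ci]], rownames(scaled))
    if (length(members) == 0) {
      stop("community ", ci, " has no member genes in the matrix")
    }
    sc <- .community_scores(scaled, members, design$sample_id)
    sc <- merge(sc, design, by = "sample_id")
    agg <- stats::aggregate(score ~ genotype + temperature_C + zt_h, sc,
                            function(v) c(mean = mean(v), sd = stats::sd(v),
                                          n = length(v)))
    m <- agg$score
    n <- m[, "n"]
    hw <- ifelse(n > 1, stats::qt(0.975, pmax(n - 1, 1)) * m[, "sd"] / sqrt(n),
                 NA_real_)
    hw[is.finite(hw) & m[, "sd"] == 0] <- 0
    out[[ci]] <- data.frame(community = ci, genotype = agg$genotype,
                            temperature_C = agg$temperature_C,
                            zt_h = agg$zt_h, mean = m[, "mean"],
                            ci_halfwidth = hw, n = n,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$community, res$genotype, res$temperature_C,
                   res$zt_h), ]
  rownames(res) <- NULL
  class(res) <- c("community_traces", "data.frame")
  res
}

#' Genotype-by-time misregulation heatmap
#'
#' For each community, temperature, and mutant: a two-way ANOVA (genotype in
#' \{reference, mutant\} crossed with timepoint) is fitted on the per-sample
#' community scores, with Type-II sums of squares under unbalance; Tukey HSD
#' is applied over all genotype-by-time cell means using the full-model
#' residual mean square, and the reported cell p-value is the Tukey-adjusted
#' p for mutant versus reference within that timepoint.
#'
#' @param scaled Centered expression matrix (genes x samples).
#' @param partition A `community_partition`.
#' @param design Sample metadata.
#' @param reference_genotype Reference (wild-type-like) genotype label.
#' @param mutants Mutant genotypes (default: all non-reference genotypes in
#'   the design).
#' @param anova_unit `"sample"` (per-sample community means; default) or
#'   `"gene"` (per-gene observations).
#' @param bh_adjust_cells Additionally BH-adjust p across all heatmap cells
#'   (default FALSE; the raw Tukey-adjusted p is the conventional display).
#' @return An object of class `misreg_heatmap`: data.frame with columns
#'   `community`, `mutant`, `temperature_C`, `zt_h`, `p`.
#' @export
misregulation_heatmap <- function(scaled, partition, design,
                                  reference_genotype,
                                  mutants = NULL,
                                  anova_unit = c("sample", "gene"),
                                  bh_adjust_cells = FALSE) {
  stopifnot(inherits(partition, "community_partition"))
  anova_unit <- match.arg(anova_unit)
  design <- design[design$sample_id %in% colnames(scaled), , drop = FALSE]
  if (!reference_genotype %in% design$genotype) {
    stop("reference genotype ", reference_genotype, " not in design")
  }
  if (is.null(mutants)) {
    mutants <- setdiff(unique(design$genotype), reference_genotype)
  }
  out <- list()
  for (ci in seq_along(partition$communities)) {
    members <- intersect(partition$communities[[ci]], rownames(scaled))
    if (length(members) == 0) {
      stop("community ", ci, " has no member genes in the matrix")
    }
    for (temp in unique(design$temperature_C)) {
      for (mut in mutants) {
        d <- design[design$temperature_C == temp &
                      design$genotype %in% c(reference_genotype, mut), ,
                    drop = FALSE]
        sc <- .community_scores(scaled, members, d$sample_id, anova_unit)
        sc <- merge(sc, d, by = "sample_id")
        sc$genotype <- factor(sc$genotype,
                              levels = c(reference_genotype, mut))
        sc$zt <- factor(sc$zt_h)
        cell_n <- table(sc$genotype, sc$zt)
        if (any(cell_n == 0)) {
          bad <- which(cell_n == 0, arr.ind = TRUE)[1, ]
          stop("no observations for cell (", rownames(cell_n)[bad[1]], ", ZT",
               colnames(cell_n)[bad[2]], ") at ", temp, " C")
        }
        fit <- if (nlevels(droplevels(sc$zt)) > 1) {
          stats::lm(score ~ genotype * zt, data = sc)
        } else {
          stats::lm(score ~ genotype, data = sc)  # single-timepoint design
        }
        df_res <- fit$df.residual
        if (df_res < 1) stop("no residual degrees of freedom; add replicates")
        mse <- sum(fit$residuals^2) / df_res
        means <- tapply(sc$score, list(sc$genotype, sc$zt), mean)
        ns <- as.matrix(cell_n)
        k <- length(means)
        zts <- sort(unique(sc$zt_h))
        cm <- as.vector(means)
        cn <- as.vector(ns)
        names(cm) <- paste(rep(rownames(means), times = ncol(means)),
                           rep(colnames(means), each = nrow(means)),
                           sep = ".")
        th <- tukey_hsd(cm, cn, mse, df_res)
        p_cells <- vapply(zts, function(z) {
          th$p[paste(reference_genotype, z, sep = "."),
               paste(mut, z, sep = ".")]
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          community = ci, mutant = mut, temperature_C = temp, zt_h = zts,
          p = p_cells, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (bh_adjust_cells) res$p <- bh_adjust(res$p)
  res <- res[order(res$community, res$mutant, -res$temperature_C,
                   res$zt_h), ]
  rownames(res) <- NULL
  class(res) <- c("misreg_heatmap", "data.frame")
  attr(res, "reference") <- reference_genotype
  attr(res, "anova_unit") <- anova_unit
  res
}

#' Reshape a misregulation heatmap to wide matrix form
#'
#' Rows are (community, mutant), columns (temperature, ZT), matching the
#' usual heatmap display.
#'
#' @param h A `misreg_heatmap`.
#' @return Numeric matrix of p-values.
#' @export
heatmap_matrix <- function(h) {
  stopifnot(inherits(h, "misreg_heatmap"))
  rows <- unique(paste(h$community, h$mutant, sep = "|"))
  cols <- unique(paste(h$temperature_C, h$zt_h, sep = "|"))
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(paste(h$community, h$mutant, sep = "|"),
          paste(h$temperature_C, h$zt_h, sep = "|"))] <- h$p
  m
}
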