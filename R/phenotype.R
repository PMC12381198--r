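# Flowering-phenotype statistics: total leaf number (TLN) group comparisons
# with compact letters, leaves-per-day, the leaf-number-ratio temperature
# sensitivity index, and ddCq relative expression.

#' Leaves per day
#'
#' LPD = total leaf number / days post-germination, the leaf generation
#' rate.
#'
#' @param table Phenotype data.frame with columns `total_leaf_number` and
#'   `days_post_germination` (> 0), and optionally `plant_id` used to name
#'   the result.
#' @return Numeric vector of per-plant LPD values.
#' @export
leaves_per_day <- function(table) {
  stopifnot(all(c("total_leaf_number", "days_post_germination") %in%
                  names(table)))
  if (any(table$days_post_germination <= 0)) {
    stop("days_post_germination must be > 0")
  }
  out <- table$total_leaf_number / table$days_post_germination
  if (!is.null(table$plant_id)) names(out) <- table$plant_id
  out
}

#' Leaf number ratio between two populations
#'
#' A between-population index of the TLN difference at cool versus warm
#' temperature: each index point is a ratio of leaf numbers between the two
#' populations, not a single plant. The default "all-pairs" construction is
#' the multiset of TLN_cool(i)/TLN_warm(j) over all cross-population pairs;
#' "bootstrap-means" draws B resampled mean ratios instead.
#'
#' @param pop_cool,pop_warm Numeric TLN vectors (> 0) for the cool and warm
#'   populations.
#' @param mode `"all-pairs"` (default) or `"bootstrap-means"`.
#' @param B Number of bootstrap draws for `"bootstrap-means"` (default 1000).
#' @param seed Seed for the bootstrap mode.
#' @return Numeric vector of index values (length |cool| x |warm| for
#'   all-pairs) with attributes `mode`, `median` and `iqr`.
#' @export
leaf_number_ratio <- function(pop_cool, pop_warm,
                              mode = c("all-pairs", "bootstrap-means"),
                              B = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (length(pop_cool) == 0 || length(pop_warm) == 0) {
    stop("both populations must be nonempty")
  }
  if (any(pop_cool <= 0) || any(pop_warm <= 0)) {
    stop("leaf numbers must be positive")
  }
  vals <- if (mode == "all-pairs") {
    as.vector(outer(pop_cool, pop_warm, "/"))
  } else {
    set.seed(seed)
    replicate(B, mean(sample(pop_cool, replace = TRUE)) /
                mean(sample(pop_warm, replace = TRUE)))
  }
  attr(vals, "mode") <- mode
  attr(vals, "median") <- stats::median(vals)
  attr(vals, "iqr") <- stats::IQR(vals)
  vals
}

#' Flowering-time group comparisons with compact letters
#'
#' Within each temperature stratum: one-way ANOVA on TLN across genotypes,
#' Tukey HSD over the genotype means, and a compact letter display (groups
#' sharing a letter are not significantly different at `alpha`). The
#' two-way mode crosses genotype with the `light` column instead (genotype x
#' light within temperature), lettering the genotype-by-light cells.
#'
#' @param table Phenotype data.frame (see [simulate_phenotypes()]).
#' @param by_temperature Stratify by `temperature_C` (default TRUE).
#' @param mode `"one-way"` (genotype; default) or `"two-way"` (genotype x
#'   light).
#' @param alpha Significance level for the letters (default 0.05).
#' @return An object of class `flowering_groups`: named list per stratum,
#'   each with `anova`, `tukey` and `letters`.
#' @export
flowering_groups <- function(table, by_temperature = TRUE,
                             mode = c("one-way", "two-way"), alpha = 0.05) {
  mode <- match.arg(mode)
  strata <- if (by_temperature) {
    split(table, table$temperature_C)
  } else {
    list(all = table)
  }
  out <- lapply(strata, function(d) {
    if (length(unique(d$genotype)) < 2) {
      stop("stratum with a single genotype; need >= 2 for comparison")
    }
    if (mode == "one-way") {
      a <- one_way_anova(d$total_leaf_number, d$genotype)
      cell <- factor(d$genotype, levels = sort(unique(d$genotype)))
    } else {
      if (is.null(d$light)) stop("two-way mode requires a 'light' column")
      a <- two_way_anova(d$total_leaf_number, d$genotype, d$light)
      cell <- factor(paste(d$genotype, d$light, sep = "."))
    }
    mse <- a$ms[a$term == "Residuals"]
    df_res <- a$df[a$term == "Residuals"]
    means <- tapply(d$total_leaf_number, cell, mean)
    ns <- as.numeric(table(cell))
    th <- tukey_hsd(means, ns, mse, df_res)
    list(anova = a, tukey = th, letters = compact_letters(th$p, alpha))
  })
  structure(out, class = "flowering_groups")
}

#' @export
#' @method print flowering_groups
print.flowering_groups <- function(x, ...) {
  for (s in names(x)) {
    cat("stratum ", s, ": ",
        paste(names(x[[s]]$letters), x[[s]]$letters, sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Relative expression by the ddCq method
#'
#' Per sample: dCq = target Cq - internal-control Cq; ddCq = dCq minus the
#' mean dCq of the calibrator condition; relative abundance = 2^(-ddCq), so
#' the calibrator averages 1 and each cycle below the calibrator doubles the
#' abundance.
#'
#' @param cq Data.frame with columns `sample_id`, `condition`, `cq_target`,
#'   `cq_control` (all Cq finite).
#' @param calibrator_condition Condition used as the calibrator.
#' @return The input with added columns `dcq`, `ddcq`,
#'   `relative_abundance`.
#' @export
ddcq <- function(cq, calibrator_condition) {
  stopifnot(all(c("condition", "cq_target", "cq_control") %in% names(cq)))
  if (any(!is.finite(cq$cq_target)) || any(!is.finite(cq$cq_control))) {
    stop("missing or non-finite Cq value(s)")
  }
  if (!calibrator_condition %in% cq$condition) {
    stop("calibrator condition ", calibrator_condition, " not present")
  }
  cq$dcq <- cq$cq_target - cq$cq_control
  cal <- mean(cq$dcq[cq$condition == calibrator_condition])
  cq$ddcq <- cq$dcq - cal
  cq$relative_abundance <- 2^(-cq$ddcq)
  cq
}
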