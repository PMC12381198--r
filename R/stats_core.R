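#' One-way analysis of variance
#'
#' Standard one-way decomposition of `values` by a grouping factor, returning
#' the ANOVA table used throughout the phenotype and misregulation stages.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor). Every level must have at
#'   least one observation.
#' @return A data.frame with one row per term (`groups`, `Residuals`) and
#'   columns `term`, `df`, `ss`, `ms`, `f`, `p`. When the residual variance is
#'   exactly zero the F statistic is undefined; `p` is reported as 1 with a
#'   warning if the group means are also all equal, and as 0 otherwise.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups)) {
    stop("'values' and 'groups' must have the same length")
  }
  tab <- table(groups)
  if (any(tab == 0)) {
    stop("group(s) with zero observations: ",
         paste(names(tab)[tab == 0], collapse = ", "))
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  fit <- stats::lm(values ~ groups)
  # degenerate (constant-response) fits are handled explicitly below
  a <- suppressWarnings(stats::anova(fit))
  out <- data.frame(
    term = c("groups", "Residuals"),
    df = a$Df, ss = a$`Sum Sq`, ms = a$`Mean Sq`,
    f = c(a$`F value`[1], NA_real_),
    p = c(a$`Pr(>F)`[1], NA_real_),
    stringsAsFactors = FALSE
  )
  scale <- .Machine$double.eps * (sum(values^2) + 1) * length(values)
  if (sum(out$ss) <= scale) {
    # constant response: no variance to partition
    warning("zero residual variance and equal group means; p set to 1")
    out$f[1] <- NA_real_
    out$p[1] <- 1
  } else if (out$ms[2] == 0 || !is.finite(out$f[1])) {
    out$p[1] <- if (out$ss[1] <= scale) 1 else 0
  }
  out
}

#' Two-way analysis of variance with Type-II sums of squares
#'
#' Crossed two-factor ANOVA including the interaction term. Sums of squares
#' are Type II (each main effect adjusted for the other, the interaction
#' adjusted for both), computed by nested model comparison, so the table is
#' well defined for the unbalanced designs that arise after sample drops.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Crossed factors (coerced to factor).
#' @return A data.frame with rows `A`, `B`, `A:B`, `Residuals` and columns
#'   `term`, `df`, `ss`, `ms`, `f`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- as.factor(factor_a)
  b <- as.factor(factor_b)
  if (length(values) != length(a) || length(values) != length(b)) {
    stop("'values' and both factors must have the same length")
  }
  ta <- table(a); tb <- table(b)
  if (any(ta == 0) || any(tb == 0)) stop("factor level(s) with zero observations")
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("both factors need >= 2 levels")
  rss <- function(form) sum(stats::lm(form)$residuals^2)
  rss_a  <- rss(values ~ a)
  rss_b  <- rss(values ~ b)
  rss_ab <- rss(values ~ a + b)
  fit_full <- stats::lm(values ~ a * b)
  rss_full <- sum(fit_full$residuals^2)
  df_a  <- nlevels(a) - 1L
  df_b  <- nlevels(b) - 1L
  df_ab <- sum(!is.na(stats::coef(fit_full))) - (1L + df_a + df_b)
  df_res <- fit_full$df.residual
  if (df_res < 1) stop("residual degrees of freedom < 1; add replication")
  ss <- c(A = rss_b - rss_ab, B = rss_a - rss_ab,
          `A:B` = rss_ab - rss_full, Residuals = rss_full)
  ss <- pmax(ss, 0)
  df <- c(df_a, df_b, df_ab, df_res)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA_real_)
  p <- c(stats::pf(f[1:3], df[1:3], df_res, lower.tail = FALSE), NA_real_)
  data.frame(term = c("A", "B", "A:B", "Residuals"),
             df = df, ss = unname(ss), ms = unname(ms), f = unname(f),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Tukey HSD pairwise comparisons from cell summaries
#'
#' Tukey (honestly significant difference) adjusted p-values for all pairwise
#' differences among `k` cell means, using the studentized range distribution
#' with `k` means and the supplied residual degrees of freedom. Unequal cell
#' sizes are handled by the Tukey-Kramer standard error.
#'
#' @param cell_means Named numeric vector of cell means (k >= 2).
#' @param cell_ns Cell sizes, recycled to `length(cell_means)`.
#' @param mse Residual mean square from the ANOVA fit (> 0).
#' @param df_resid Residual degrees of freedom (>= 1).
#' @return An object of class `tukey_hsd`: list with symmetric matrices `p`
#'   (adjusted p-values, diagonal 1), `q` (observed studentized range
#'   statistics) and `diff` (mean differences), plus `df` and `k`.
#' @export
tukey_hsd <- function(cell_means, cell_ns, mse, df_resid) {
  k <- length(cell_means)
  if (k < 2) stop("need at least 2 cell means")
  if (!is.finite(mse) || mse <= 0) stop("'mse' must be > 0")
  if (df_resid < 1) stop("'df_resid' must be >= 1")
  cell_ns <- rep_len(cell_ns, k)
  nm <- names(cell_means)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  dmat <- outer(cell_means, cell_means, "-")
  se <- sqrt(mse / 2 * outer(1 / cell_ns, 1 / cell_ns, "+"))
  q <- abs(dmat) / se
  p <- stats::ptukey(q, nmeans = k, df = df_resid, lower.tail = FALSE)
  diag(p) <- 1
  diag(q) <- 0
  dimnames(p) <- dimnames(q) <- dimnames(dmat) <- list(nm, nm)
  structure(list(p = p, q = q, diff = dmat, df = df_resid, k = k),
            class = "tukey_hsd")
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns letters to groups such that two groups share a letter if and only
#' if they are not significantly different, using the insert-and-absorb
#' algorithm. Processing order is fixed by the row order of `pairwise_p`, so
#' the display is deterministic.
#'
#' @param pairwise_p Symmetric matrix of pairwise p-values with group names as
#'   dimnames (e.g. `tukey_hsd(...)$p`).
#' @param alpha Significance threshold (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pairwise_p, alpha = 0.05) {
  if (inherits(pairwise_p, "tukey_hsd")) pairwise_p <- pairwise_p$p
  p <- as.matrix(pairwise_p)
  if (nrow(p) != ncol(p) || max(abs(p - t(p)), na.rm = TRUE) > 1e-12) {
    stop("'pairwise_p' must be a symmetric matrix")
  }
  k <- nrow(p)
  nm <- rownames(p)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  # columns of 'cols' are candidate letters: logical membership vectors
  cols <- matrix(TRUE, nrow = k, ncol = 1)
  sig <- which(upper.tri(p) & p < alpha, arr.ind = TRUE)
  if (nrow(sig) > 0) {
    ord <- order(sig[, 1], sig[, 2])
    sig <- sig[ord, , drop = FALSE]
    for (s in seq_len(nrow(sig))) {
      i <- sig[s, 1]; j <- sig[s, 2]
      repeat {
        hit <- which(cols[i, ] & cols[j, ])
        if (length(hit) == 0) break
        h <- hit[1]
        c1 <- cols[, h]; c1[i] <- FALSE
        c2 <- cols[, h]; c2[j] <- FALSE
        cols <- cbind(cols[, -h, drop = FALSE], c1, c2)
        # absorb: drop subset columns; among duplicates keep the first
        keep <- rep(TRUE, ncol(cols))
        for (x in seq_len(ncol(cols))) {
          for (y in seq_len(ncol(cols))) {
            if (x != y && keep[x] && keep[y] &&
                all(cols[, x] <= cols[, y]) &&
                (any(cols[, x] < cols[, y]) || x > y)) {
              keep[x] <- FALSE
            }
          }
        }
        cols <- cols[, keep, drop = FALSE]
      }
    }
  }
  first_member <- apply(cols, 2, function(v) which(v)[1])
  cols <- cols[, order(first_member), drop = FALSE]
  letters_used <- rep(letters, length.out = ncol(cols))
  out <- vapply(seq_len(k), function(i) {
    paste(letters_used[cols[i, ]], collapse = "")
  }, character(1))
  names(out) <- nm
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric with `n_setA` "marked" elements in a
#' universe of `N_universe`, drawing `n_setB` elements. This is the one-sided
#' enrichment p-value used for all gene-set overlap tests; the observed
#' overlap is included in the tail. Evaluation is delegated to
#' `stats::phyper`, which works in log space internally and is exact for
#' large universes.
#'
#' @param k_overlap Observed overlap (0 <= k <= min(n_setA, n_setB)).
#' @param n_setA,n_setB Sizes of the two sets.
#' @param N_universe Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k_overlap, n_setA, n_setB, N_universe) {
  if (any(c(k_overlap, n_setA, n_setB, N_universe) < 0)) {
    stop("all arguments must be non-negative")
  }
  if (n_setA > N_universe || n_setB > N_universe) {
    stop("set sizes cannot exceed the universe size")
  }
  if (k_overlap > min(n_setA, n_setB)) {
    stop("'k_overlap' cannot exceed min(n_setA, n_setB)")
  }
  stats::phyper(k_overlap - 1, n_setA, N_universe - n_setA, n_setB,
                lower.tail = FALSE)
}
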