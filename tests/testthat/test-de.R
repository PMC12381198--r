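test_that("BH adjustment matches the step-up oracle and hand examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DEG calling applies the FDR and fold-change thresholds", {
  r <- data.frame(gene = c("a", "b", "c", "d"),
                  log2fc = c(0.3, 0.2, 2, -0.3),
                  p_value = c(0.001, 0.001, 0.01, 0.001),
                  q_value = c(0.04, 0.04, 0.06, 0.04))
  attr(r, "contrast") <- de_contrast("mut", "ref", 15, 8)
  class(r) <- c("de_result", "data.frame")
  d <- call_degs(r)
  expect_identical(d$up, "a")          # q 0.04, lfc 0.3
  expect_identical(d$down, "d")
  expect_false("b" %in% c(d$up, d$down))  # below |0.25|
  expect_false("c" %in% c(d$up, d$down))  # fails FDR
  # boundary: strict vs inclusive FDR
  r$q_value <- 0.05
  expect_length(call_degs(r)$up, 0)
  expect_setequal(call_degs(r, strict = FALSE)$up, c("a", "c"))
})

test_that("collapsing DEG sets unions per direction and flags conflicts", {
  mk <- function(up, down, zt, mut = "mutA") {
    structure(list(up = up, down = down,
                   contrast = de_contrast(mut, "ref", 15, zt),
                   fdr = 0.05, min_abs_log2fc = 0.25), class = "deg_set")
  }
  out <- collapse_degs(list(mk(c("a", "b", "c"), "x", 4),
                            mk(c("d", "e", "f", "g"), "y", 8)))
  expect_length(out$up, 7)
  expect_length(out$down, 2)
  same <- collapse_degs(list(mk(c("a", "b"), "x", 4), mk(c("a", "b"), "x", 8)))
  expect_equal(same$up, c("a", "b"))
  expect_warning(
    both <- collapse_degs(list(mk("g1", character(0), 4),
                               mk(character(0), "g1", 16))),
    "both unions")
  expect_identical(both$both, "g1")
  expect_error(collapse_degs(list(mk("a", "b", 4),
                                  mk("a", "b", 4, mut = "mutB"))),
               "different mutant")
})

test_that("dispersion estimation recovers known simulation regimes", {
  groups <- rep(c("A", "B"), each = 3)
  set.seed(5)
  pois <- nb_two_group(2000, phi = 0)
  d0 <- estimate_dispersion(pois$counts, groups)
  expect_lt(d0$common, 0.01)
  nb <- nb_two_group(2000, phi = 0.2)
  d2 <- estimate_dispersion(nb$counts, groups)
  expect_gt(d2$common, 0.15)
  expect_lt(d2$common, 0.25)
  # single sample per group: only the common component is defined
  y1 <- nb$counts[, c(1, 4)]
  expect_warning(d1 <- estimate_dispersion(y1, c("A", "B")), "common")
  expect_true(all(d1$tagwise == d1$common))
  expect_error(estimate_dispersion(matrix(0, 5, 4), rep(1:2, 2)), "all counts")
})

test_that("the contrast test is calibrated, recovers effects, and is symmetric", {
  set.seed(6)
  design <- two_group_design()
  # null calibration at 5,000 genes (acceptance repeats this at 20,000 x 3 seeds)
  null <- nb_two_group(5000, phi = 0.1)
  m <- count_matrix(null$counts)
  disp <- estimate_dispersion(null$counts, design$genotype)
  r <- test_contrast(m, de_contrast("mut", "ref", 15, 0), design,
                     dispersion = disp$tagwise)
  expect_gt(mean(r$p_value < 0.05), 0.03)
  expect_lt(mean(r$p_value < 0.05), 0.07)
  expect_gt(stats::ks.test(r$p_value, "punif")$p.value, 0.001)

  # planted |log2FC| = 1 at mu = 200: mean estimate over the DE genes within
  # +/- 0.1 (mostly-null fixture so library sizes stay comparable)
  eff <- nb_two_group(2000, mu_meanlog = log(200), mu_sdlog = 0, phi = 0.05,
                      lfc = 1, n_de = 200)
  me <- count_matrix(eff$counts)
  re <- test_contrast(me, de_contrast("mut", "ref", 15, 0), design,
                      dispersion = 0.05)
  de_idx <- eff$true_lfc != 0
  expect_lt(abs(mean(re$log2fc[de_idx] - eff$true_lfc[de_idx])), 0.1)

  # swapping contrast sides negates log2FC and preserves p exactly
  swap_design <- design
  swap_design$genotype <- rev(design$genotype)
  rs <- test_contrast(m, de_contrast("mut", "ref", 15, 0), swap_design,
                      dispersion = disp$tagwise)
  expect_equal(rs$log2fc, -r$log2fc, tolerance = 1e-8)
  expect_equal(rs$p_value, r$p_value, tolerance = 1e-6)
})

test_that("degenerate contrasts stay finite and error when ill-posed", {
  design <- two_group_design()
  y <- rbind(gzero = c(500, 480, 510, 0, 0, 0),
             filler = c(1000, 1000, 1000, 1500, 1500, 1500))
  colnames(y) <- design$sample_id
  m <- count_matrix(y)
  r <- test_contrast(m, de_contrast("mut", "ref", 15, 0), design,
                     dispersion = 0.05)
  g <- r[r$gene == "gzero", ]
  expect_true(is.finite(g$log2fc))
  expect_lt(g$log2fc, -3)
  expect_lt(g$p_value, 1e-6)
  expect_error(test_contrast(m, de_contrast("mut", "ref", 20, 0), design,
                             dispersion = 0.05), "empty group")
  one_rep <- design[-(1:2), ]
  expect_warning(test_contrast(count_matrix(y[, -(1:2)]),
                               de_contrast("mut", "ref", 15, 0), one_rep,
                               dispersion = 0.05), "fewer than 2")
})

test_that("dispersion and LRT agree with edgeR on a shared fixture", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  design <- two_group_design()
  fix <- nb_two_group(800, phi = 0.1, lfc = 1, n_de = 80)
  grp <- factor(design$genotype, levels = c("ref", "mut"))
  dge <- edgeR::DGEList(fix$counts, group = grp)
  dge <- edgeR::calcNormFactors(dge, method = "none")
  dge <- edgeR::estimateDisp(dge, model.matrix(~grp))
  mine <- estimate_dispersion(fix$counts, design$genotype)
  expect_lt(abs(log(mine$common / dge$common.dispersion)), 0.35)
  fit <- edgeR::glmFit(dge, model.matrix(~grp))
  lrt <- edgeR::glmLRT(fit)
  r <- test_contrast(count_matrix(fix$counts),
                     de_contrast("mut", "ref", 15, 0), design,
                     dispersion = mine$tagwise)
  # strong rank agreement between the two implementations
  expect_gt(cor(-log10(r$p_value), -log10(lrt$table$PValue),
                method = "spearman"), 0.95)
  expect_gt(cor(r$log2fc, lrt$table$logFC), 0.98)
})
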