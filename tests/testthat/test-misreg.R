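# A small hand-built scaled matrix with a known community structure:
# two genotypes x 7 ZT x 3 replicates, 12 genes in two communities.
make_misreg_fixture <- function(shift = 0, shift_zt = 8, sd = 0.2,
                                seed = 1, genotypes = c("ref", "mut")) {
  set.seed(seed)
  design <- expand.grid(replicate = 1:3, zt_h = seq(0, 24, 4),
                        genotype = genotypes, temperature_C = 15,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_ZT%g_r%d", design$genotype, design$zt_h,
                              design$replicate)
  genes <- sprintf("g%02d", 1:12)
  x <- matrix(rnorm(12 * nrow(design), sd = sd), 12, nrow(design),
              dimnames = list(genes, design$sample_id))
  prof <- sin(2 * pi * design$zt_h / 24)
  x[1:6, ] <- x[1:6, ] + matrix(prof, 6, nrow(design), byrow = TRUE)
  x[7:12, ] <- x[7:12, ] - matrix(prof, 6, nrow(design), byrow = TRUE)
  hit <- design$genotype == "mut" & design$zt_h %in% shift_zt
  x[1:6, hit] <- x[1:6, hit] + shift
  part <- structure(list(communities = list(genes[1:6], genes[7:12]),
                         membership = stats::setNames(rep(1:2, each = 6),
                                                      genes),
                         modularity = 0.4, min_size = 4),
                    class = "community_partition")
  list(x = x, design = design, partition = part)
}

test_that("community traces are replicate means with t confidence bands", {
  fx <- make_misreg_fixture(seed = 2)
  # single-gene community: trace equals that gene's replicate means
  single <- structure(list(communities = list("g01"),
                           membership = c(g01 = 1L), modularity = 0,
                           min_size = 1), class = "community_partition")
  tr <- community_traces(fx$x, single, fx$design)
  ref0 <- fx$design$sample_id[fx$design$genotype == "ref" &
                                fx$design$zt_h == 0]
  expect_equal(tr$mean[tr$genotype == "ref" & tr$zt_h == 0],
               mean(fx$x["g01", ref0]))
  v <- fx$x["g01", ref0]
  expect_equal(tr$ci_halfwidth[tr$genotype == "ref" & tr$zt_h == 0],
               qt(0.975, 2) * sd(v) / sqrt(3))
  # all-zero community: flat zero trace with zero bands
  xz <- fx$x; xz["g01", ] <- 0
  trz <- community_traces(xz, single, fx$design)
  expect_true(all(trz$mean == 0))
  expect_true(all(trz$ci_halfwidth == 0))
  bad <- structure(list(communities = list("nope"), membership = c(nope = 1L),
                        modularity = 0, min_size = 1),
                   class = "community_partition")
  expect_error(community_traces(fx$x, bad, fx$design), "no member genes")
})

test_that("a planted one-timepoint shift is detected at that cell only", {
  hits <- 0; elsewhere <- numeric(0)
  for (s in 1:5) {
    fx <- make_misreg_fixture(shift = 1, shift_zt = 8, seed = s)
    h <- misregulation_heatmap(fx$x, fx$partition, fx$design, "ref")
    cell <- h$p[h$community == 1 & h$zt_h == 8]
    if (cell < 0.05) hits <- hits + 1
    elsewhere <- c(elsewhere, h$p[!(h$community == 1 & h$zt_h == 8)])
  }
  expect_equal(hits, 5)
  expect_gt(median(elsewhere), 0.2)
})

test_that("null heatmap p-values are conservative, never anti-conservative", {
  ps <- numeric(0)
  for (s in 1:3) {
    fx <- make_misreg_fixture(shift = 0, seed = 10 + s)
    h <- misregulation_heatmap(fx$x, fx$partition, fx$design, "ref")
    ps <- c(ps, h$p)
  }
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("the heatmap is invariant to gene and sample order and to row offsets", {
  fx <- make_misreg_fixture(shift = 1, seed = 4)
  h1 <- misregulation_heatmap(fx$x, fx$partition, fx$design, "ref")
  perm <- sample(nrow(fx$x))
  h2 <- misregulation_heatmap(fx$x[perm, ], fx$partition, fx$design, "ref")
  expect_equal(h1$p, h2$p)
  sperm <- sample(ncol(fx$x))
  h3 <- misregulation_heatmap(fx$x[, sperm], fx$partition,
                              fx$design[match(colnames(fx$x)[sperm],
                                              fx$design$sample_id), ], "ref")
  expect_equal(h1$p, h3$p)
  # adding a constant to one community's genes is absorbed by re-centering
  x4 <- fx$x
  x4[1:6, ] <- x4[1:6, ] + 7
  h4 <- misregulation_heatmap(center_genes(x4), fx$partition, fx$design,
                              "ref")
  expect_equal(h1$p, h4$p, tolerance = 1e-9)
})

test_that("two-cell designs reduce to the pooled t-test via q = sqrt(2)|t|", {
  set.seed(20)
  design <- data.frame(sample_id = sprintf("s%d", 1:8),
                       genotype = rep(c("ref", "mut"), each = 4),
                       temperature_C = 15, zt_h = 0, replicate = rep(1:4, 2))
  x <- matrix(rnorm(8 * 5), 5, 8,
              dimnames = list(sprintf("g%d", 1:5), design$sample_id))
  x[1:5, design$genotype == "mut"] <- x[1:5, design$genotype == "mut"] + 1
  part <- structure(list(communities = list(sprintf("g%d", 1:5)),
                         membership = stats::setNames(rep(1L, 5),
                                                      sprintf("g%d", 1:5)),
                         modularity = 0, min_size = 4),
                    class = "community_partition")
  h <- misregulation_heatmap(x, part, design, "ref")
  score <- colMeans(x)
  tt <- t.test(score[design$genotype == "mut"],
               score[design$genotype == "ref"], var.equal = TRUE)
  expect_equal(h$p, tt$p.value, tolerance = 1e-6)
})

test_that("heatmap errors name missing cells and supports the gene unit", {
  fx <- make_misreg_fixture(seed = 5)
  drop <- fx$design$sample_id[fx$design$genotype == "mut" &
                                fx$design$zt_h == 12]
  d2 <- fx$design[!fx$design$sample_id %in% drop, ]
  expect_error(misregulation_heatmap(fx$x[, d2$sample_id], fx$partition, d2,
                                     "ref"), "ZT12")
  hg <- misregulation_heatmap(fx$x, fx$partition, fx$design, "ref",
                              anova_unit = "gene")
  expect_equal(nrow(hg), nrow(misregulation_heatmap(fx$x, fx$partition,
                                                    fx$design, "ref")))
})
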