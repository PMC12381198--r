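test_that("design has one row per factor combination, minus explicit drops", {
  spec <- sim_spec(n_genes = 120, communities = list(), seed = 1)
  expect_equal(nrow(generate_design(spec, drop = NULL)), 4 * 2 * 7 * 3)
  d <- generate_design(spec)  # default drop: one wild-type sample
  expect_equal(nrow(d), 167)
  expect_false("Col0_T15_ZT12_r1" %in% d$sample_id)
  # completeness: every remaining combination appears exactly n_reps times
  tab <- table(d$genotype, d$temperature_C, d$zt_h)
  expect_equal(sum(tab == 3), length(tab) - 1)
  expect_equal(sum(tab == 2), 1)

  tiny <- sim_spec(n_genes = 10, genotypes = "A", temperatures = 20,
                   timepoints = 0, n_reps = 2, communities = list(),
                   drop_sample = NULL, seed = 1)
  expect_equal(nrow(generate_design(tiny)), 2)
  expect_error(sim_spec(genotypes = character(0)), "nonempty")
  expect_error(generate_design(spec, drop = "nope"), "not in design")
})

test_that("spec validation enforces the documented invariants", {
  expect_error(sim_spec(n_reps = 1), "n_reps")
  expect_error(sim_spec(dispersion = -0.1), "dispersion")
  expect_error(sim_spec(timepoints = c(0, 4, 4)), "strictly increasing")
  dup <- list(community_truth(c("g00001", "g00002")),
              community_truth(c("g00002", "g00003")))
  expect_error(sim_spec(communities = dup), "disjoint")
  expect_error(
    sim_spec(communities = list(
      community_truth("g00001", base_profile = c(0, 1)))),
    "base_profile")
  expect_error(community_truth("g1", shift = Inf), "finite")
})

test_that("simulated counts are seed-deterministic and follow NB moments", {
  spec <- small_sim_spec(seed = 42)
  d <- generate_design(spec)
  s1 <- simulate_counts(d, spec)
  s2 <- simulate_counts(d, spec)
  expect_identical(s1$counts$counts, s2$counts$counts)

  # NB variance: mu = 100, phi = 0.1 -> var = mu + phi mu^2 = 1100
  nrep <- 10000
  # 10 equal-abundance genes at library size 1000 -> per-gene mean 100
  rep_spec <- sim_spec(n_genes = 10, genotypes = "A", temperatures = 20,
                       timepoints = 0, n_reps = nrep, library_size_mean = 1000,
                       dispersion = 0.1, communities = list(),
                       cpm_sdlog = 0, cpm_meanlog = log(100),
                       libsize_sdlog = 0, drop_sample = NULL, seed = 9)
  rd <- generate_design(rep_spec)
  y <- simulate_counts(rd, rep_spec)$counts$counts
  v <- apply(y, 1, var)
  mu_hat <- rowMeans(y)
  target <- 100 + 0.1 * 100^2
  mc_se <- target * sqrt(2 / nrep) * sqrt(1 + 2 * 0.1)  # approx SE of NB variance
  expect_true(all(abs(v - target) < 6 * mc_se))
  expect_true(all(abs(mu_hat - 100) < 5))

  # phi = 0 -> Poisson: variance ~ mean
  pois_spec <- sim_spec(n_genes = 10, genotypes = "A", temperatures = 20,
                        timepoints = 0, n_reps = nrep,
                        library_size_mean = 1000, dispersion = 0,
                        communities = list(), cpm_sdlog = 0,
                        cpm_meanlog = log(100), libsize_sdlog = 0,
                        drop_sample = NULL, seed = 10)
  yp <- simulate_counts(generate_design(pois_spec), pois_spec)$counts$counts
  expect_true(all(abs(apply(yp, 1, var) / rowMeans(yp) - 1) < 0.1))
})

test_that("no planted shift means near-zero empirical log2 fold changes", {
  spec <- sim_spec(n_genes = 300, communities = list(
    community_truth(sprintf("g%05d", 1:10), phase = 0,
                    base_cpm = 200, shift = 0)), seed = 5)
  d <- generate_design(spec)
  sim <- simulate_counts(d, spec)
  cpm <- compute_cpm(sim$counts)
  ref <- d$sample_id[d$genotype == "Col0"]
  mut <- d$sample_id[d$genotype == "mutA"]
  lfc <- log2((rowMeans(cpm[, mut]) + 0.5) / (rowMeans(cpm[, ref]) + 0.5))
  keep <- rowMeans(cpm) > 5
  expect_lt(abs(mean(lfc[keep])), 0.05)
  expect_equal(nrow(sim$truth$planted_log2fc), 0)
})

test_that("promoter simulation plants exact motif counts on clean background", {
  genes <- sprintf("p%03d", 1:60)
  plan <- rbind(
    data.frame(gene_id = genes[1:20], motif = "CGCG", count = 2L),
    data.frame(gene_id = genes[21:35], motif = "CGTG", count = 3L),
    data.frame(gene_id = genes[21:35], motif = "CGCG", count = 1L))
  pr <- simulate_promoters(genes, plan, window = 1000, seed = 11)
  sc <- motif_scan(pr$sequences, both_strands = TRUE)
  for (i in seq_len(nrow(pr$planted))) {
    expect_identical(unname(sc[pr$planted$gene_id[i], pr$planted$motif[i]]),
                     pr$planted$count[i])
  }
  # empty plan on rejection-sampled background: zero everywhere
  pr0 <- simulate_promoters(genes[1:10], NULL, window = 500, seed = 3)
  expect_true(all(motif_scan(pr0$sequences, window = 500) == 0))
  # determinism
  pr2 <- simulate_promoters(genes, plan, window = 1000, seed = 11)
  expect_identical(pr$sequences, pr2$sequences)
  # capacity and window errors
  expect_error(simulate_promoters("x", data.frame(
    gene_id = "x", motif = "CGCG", count = 200L), window = 100), "capacity")
  expect_error(simulate_promoters("x", NULL, window = 2), "motif length")
})

test_that("binding simulation matches its null and extreme regimes", {
  genes <- sprintf("g%05d", 1:400)
  target <- genes[1:30]
  # odds -> infinity much faster than background -> 0: the enriched TF binds
  # exactly the target set while controls bind nothing
  bt <- simulate_binding_table(genes, n_tfs = 5, enriched_tf = "TF001",
                               target_set = target, enrichment_odds = 1e12,
                               background_rate = 1e-6, seed = 2)
  expect_setequal(bt$bound$TF001, target)
  expect_true(all(lengths(bt$bound[-1]) == 0))
  expect_equal(overlap_test(target, bt$bound$TF001, genes)$k, length(target))
  # null (odds = 1): enrichment of the named TF is rarely significant
  hits <- vapply(1:40, function(s) {
    b <- simulate_binding_table(genes, n_tfs = 6, target_set = target,
                                enrichment_odds = 1, background_rate = 0.2,
                                seed = s)
    binding_enrichment(target, b, tf = "TF001")$table$p[
      binding_enrichment(target, b, tf = "TF001")$table$tf == "TF001"] < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.25)
  expect_error(simulate_binding_table(genes, n_tfs = 1), "n_tfs")
  expect_error(simulate_binding_table(genes, target_set = "absent"),
               "outside the universe")
})

test_that("phenotype and Cq simulators enforce their preconditions", {
  gm <- data.frame(genotype = c("A", "B"), temperature_C = 15,
                   mean_tln = c(45, 60))
  expect_error(simulate_phenotypes(gm, sd = 0), "positive")
  expect_error(simulate_phenotypes(gm, n = 1), "n >= 2")
  ph <- simulate_phenotypes(gm, sd = 2, n = 30, seed = 4)
  expect_true(all(ph$total_leaf_number >= 1))
  expect_true(all(ph$days_post_germination > 0))
  # clearly separated means earn distinct letters
  fg <- flowering_groups(ph)
  expect_equal(length(unique(fg[["15"]]$letters)), 2)
  cq <- simulate_cq(data.frame(condition = c("cal", "high"),
                               log2_expression = c(0, 2)), seed = 6)
  expect_true(all(is.finite(cq$cq_target)))
})
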