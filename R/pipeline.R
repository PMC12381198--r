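# End-to-end pipeline: simulate -> filter/normalize -> per-timepoint DE ->
# collapse -> co-expression graph -> communities -> traces + misregulation
# heatmap -> enrichment -> phenotype indices.

#' Pipeline configuration
#'
#' Collects every tunable threshold with its conventional default (FDR 0.05,
#' |log2FC| >= 0.25, PCC > 0.9, community size >= 4, alpha 0.05) and the
#' mode flags. Unknown arguments are rejected.
#'
#' @param fdr DEG FDR threshold in (0, 1].
#' @param min_abs_log2fc Minimum absolute log2 fold change (>= 0).
#' @param pcc_threshold Co-expression edge threshold in (-1, 1).
#' @param min_community_size Minimum community size (>= 1).
#' @param alpha Significance level for phenotype letters.
#' @param signed_pcc Signed correlation threshold (TRUE) or absolute (FALSE).
#' @param unit_variance Also standardize rows when centering.
#' @param both_strands Scan promoter motifs on both strands.
#' @param lnr_mode Leaf-number-ratio construction (`"all-pairs"` or
#'   `"bootstrap-means"`).
#' @param anova_unit Observational unit for the misregulation ANOVA
#'   (`"sample"` or `"gene"`).
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @param filter_samples Evaluate the expression filter on the
#'   `"reference"` genotype's samples (default, matching the original
#'   reference-only filter) or on `"all"` samples.
#' @param seed Root seed for every stochastic stage.
#' @param sim A [sim_spec()] describing the synthetic experiment (default:
#'   `sim_spec(seed = seed)`).
#' @param out_dir Optional directory for TSV/JSON artifacts.
#' @param ... Unknown keys; any use is an error.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr = 0.05, min_abs_log2fc = 0.25,
                            pcc_threshold = 0.9, min_community_size = 4,
                            alpha = 0.05, signed_pcc = TRUE,
                            unit_variance = FALSE, both_strands = TRUE,
                            lnr_mode = "all-pairs", anova_unit = "sample",
                            prior_df = 10,
                            filter_samples = c("reference", "all"),
                            seed = 1, sim = NULL, out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  if (fdr <= 0 || fdr > 1) stop("'fdr' must be in (0, 1]")
  if (min_abs_log2fc < 0) stop("'min_abs_log2fc' must be >= 0")
  if (pcc_threshold <= -1 || pcc_threshold >= 1) {
    stop("'pcc_threshold' must be in (-1, 1)")
  }
  if (min_community_size < 1) stop("'min_community_size' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  lnr_mode <- match.arg(lnr_mode, c("all-pairs", "bootstrap-means"))
  anova_unit <- match.arg(anova_unit, c("sample", "gene"))
  filter_samples <- match.arg(filter_samples)
  if (is.null(sim)) sim <- sim_spec(seed = seed)
  stopifnot(inherits(sim, "sim_spec"))
  structure(list(fdr = fdr, min_abs_log2fc = min_abs_log2fc,
                 pcc_threshold = pcc_threshold,
                 min_community_size = min_community_size, alpha = alpha,
                 signed_pcc = signed_pcc, unit_variance = unit_variance,
                 both_strands = both_strands, lnr_mode = lnr_mode,
                 anova_unit = anova_unit, prior_df = prior_df,
                 filter_samples = filter_samples, seed = seed, sim = sim,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.stage_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
}

# default promoter motif plan over the planted communities
.default_motif_plan <- function(spec) {
  cm <- spec$communities
  plan <- list()
  add <- function(genes, motif, count) {
    data.frame(gene_id = genes, motif = motif, count = count,
               stringsAsFactors = FALSE)
  }
  if (length(cm) >= 1) plan[[1]] <- add(cm[[1]]$genes, "CGCG", 2L)
  if (length(cm) >= 2) {
    plan[[2]] <- add(cm[[2]]$genes, "CGCG", 1L)
    plan[[3]] <- add(cm[[2]]$genes, "CGTG", 2L)
  }
  if (length(cm) >= 3) plan[[4]] <- add(cm[[3]]$genes, "CGTG", 1L)
  do.call(rbind, plan)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> expression filter -> TMM/CPM -> dispersion -> DE per
#' (mutant, temperature, timepoint) -> DEG calling and collapse -> centered
#' co-expression graph -> Girvan-Newman communities -> community traces and
#' misregulation heatmap -> binding/motif enrichment -> phenotype indices.
#' Output is deterministic given the configuration and seed; artifacts are
#' written as TSV/JSON when `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages (default FALSE).
#' @return An object of class `ztnet_pipeline`: list with the per-stage
#'   results (`design`, `counts`, `truth`, `filtered`, `factors`, `cpm`,
#'   `dispersion`, `de`, `degs`, `collapsed`, `deg_universe`, `scaled`,
#'   `graph`, `dendrogram`, `partition`, `traces`, `heatmap`, `binding`,
#'   `motifs`, `phenotype`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- if (quiet) function(...) invisible(NULL) else .stage_msg
  spec <- config$sim
  reference <- spec$genotypes[1]
  mutants <- setdiff(spec$genotypes, reference)

  say("simulate: design + counts (seed ", config$seed, ")")
  design <- generate_design(spec)
  sim <- simulate_counts(design, spec)

  say("preprocess: expression filter + TMM + CPM")
  use <- if (config$filter_samples == "reference") {
    intersect(design$sample_id[design$genotype == reference],
              sim$counts$samples)
  } else NULL
  filtered <- filter_expressed(sim$counts, use_samples = use)
  factors <- tmm_factors(filtered)
  cpm <- compute_cpm(filtered, factors)

  say("de: dispersion estimation over ", nrow(filtered$counts), " genes")
  groups <- interaction(design$genotype, design$temperature_C, design$zt_h,
                        drop = TRUE)
  disp <- estimate_dispersion(filtered, groups, factors = factors,
                              prior_df = config$prior_df)

  say("de: ", length(mutants) * length(spec$temperatures) *
        length(spec$timepoints), " contrasts")
  de <- list()
  degs <- list()
  for (mut in mutants) {
    for (temp in spec$temperatures) {
      for (zt in spec$timepoints) {
        key <- sprintf("%s_T%g_ZT%g", mut, temp, zt)
        r <- suppressWarnings(
          test_contrast(filtered, de_contrast(mut, reference, temp, zt),
                        design, factors, disp$tagwise))
        de[[key]] <- r
        degs[[key]] <- call_degs(r, fdr = config$fdr,
                                 min_abs_log2fc = config$min_abs_log2fc)
      }
    }
  }

  say("collapse: DEG unions per mutant and temperature")
  collapsed <- list()
  for (mut in mutants) {
    for (temp in spec$temperatures) {
      key <- sprintf("%s_T%g", mut, temp)
      sets <- degs[sprintf("%s_T%g_ZT%g", mut, temp, spec$timepoints)]
      collapsed[[key]] <- suppressWarnings(collapse_degs(sets))
    }
  }
  deg_universe <- sort(unique(unlist(lapply(collapsed,
                                            function(cc) c(cc$up, cc$down)))))

  say("network: PCC graph over ", length(deg_universe), " DEGs")
  scaled <- center_genes(cpm, unit_variance = config$unit_variance)
  graph_genes <- intersect(deg_universe, rownames(scaled))
  pcc <- pcc_matrix(scaled, graph_genes)
  graph <- build_graph(pcc, threshold = config$pcc_threshold,
                       absolute = !config$signed_pcc)

  say("communities: Girvan-Newman on ", length(graph$nodes), " nodes, ",
      nrow(graph$edges), " edges")
  dendrogram <- girvan_newman(graph)
  partition <- filter_min_size(cut_max_modularity(dendrogram),
                               config$min_community_size)

  say("misreg: traces + heatmap over ", length(partition$communities),
      " communities")
  traces <- community_traces(scaled, partition, design)
  heatmap <- misregulation_heatmap(scaled, partition, design, reference,
                                   anova_unit = config$anova_unit)

  say("enrich: binding panel + promoter motifs")
  planted_genes <- sim$truth$community_membership$gene
  bt <- simulate_binding_table(filtered$genes, n_tfs = 76,
                               enriched_tf = "TF001",
                               target_set = intersect(planted_genes,
                                                      filtered$genes),
                               enrichment_odds = 10, seed = config$seed)
  binding <- binding_enrichment(intersect(deg_universe, filtered$genes), bt,
                                tf = "TF001")
  plan <- .default_motif_plan(spec)
  prom_genes <- sort(union(deg_universe, planted_genes))
  plan <- plan[plan$gene_id %in% prom_genes, , drop = FALSE]
  prom <- simulate_promoters(prom_genes, plan, seed = config$seed)
  scanned <- motif_scan(prom$sequences, both_strands = config$both_strands)
  planted_tab <- prom$planted
  planted_tab$scanned <- scanned[cbind(planted_tab$gene_id,
                                       planted_tab$motif)]
  motifs <- list(planted = planted_tab,
                 exact_match = all(planted_tab$scanned == planted_tab$count))

  say("phenotype: flowering indices")
  warm <- max(spec$temperatures)
  cool <- min(spec$temperatures)
  gm <- expand.grid(genotype = spec$genotypes,
                    temperature_C = c(warm, cool),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gm$mean_tln <- ifelse(gm$temperature_C == warm, 15,
                        ifelse(gm$genotype == reference, 22, 27))
  pheno <- simulate_phenotypes(gm, sd = 2, n = 30, seed = config$seed)
  groups_fl <- flowering_groups(pheno, alpha = config$alpha)
  lpd <- leaves_per_day(pheno)
  lnr <- lapply(stats::setNames(spec$genotypes, spec$genotypes),
                function(gt) {
    leaf_number_ratio(
      pheno$total_leaf_number[pheno$genotype == gt &
                                pheno$temperature_C == cool],
      pheno$total_leaf_number[pheno$genotype == gt &
                                pheno$temperature_C == warm],
      mode = config$lnr_mode, seed = config$seed)
  })
  cqsim <- simulate_cq(data.frame(
    condition = c("calibrator", "cool_mutant"),
    log2_expression = c(0, 2), stringsAsFactors = FALSE), seed = config$seed)
  cq <- ddcq(cqsim, "calibrator")

  manifest <- list(
    package = "ztnet",
    seed = config$seed,
    stages = list(
      samples = nrow(design),
      genes_simulated = spec$n_genes,
      genes_expressed = length(filtered$genes),
      contrasts = length(de),
      deg_universe = length(deg_universe),
      graph_nodes = length(graph$nodes),
      graph_edges = nrow(graph$edges),
      communities = length(partition$communities),
      heatmap_cells = nrow(heatmap)
    ),
    thresholds = config[c("fdr", "min_abs_log2fc", "pcc_threshold",
                          "min_community_size", "alpha")]
  )

  result <- structure(list(
    config = config, design = design, counts = sim$counts,
    truth = sim$truth, filtered = filtered, factors = factors, cpm = cpm,
    dispersion = disp, de = de, degs = degs, collapsed = collapsed,
    deg_universe = deg_universe, scaled = scaled, graph = graph,
    dendrogram = dendrogram, partition = partition, traces = traces,
    heatmap = heatmap, binding = binding, motifs = motifs,
    phenotype = list(table = pheno, groups = groups_fl, lpd = lpd,
                     lnr = lnr, cq = cq),
    manifest = manifest), class = "ztnet_pipeline")

  if (!is.null(config$out_dir)) {
    say("write: artifacts to ", config$out_dir)
    write_pipeline(result, config$out_dir)
  }
  result
}

#' @export
#' @method print ztnet_pipeline
print.ztnet_pipeline <- function(x, ...) {
  s <- x$manifest$stages
  cat("ztnet pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  %d samples, %d/%d genes expressed, %d contrasts\n",
              s$samples, s$genes_expressed, s$genes_simulated, s$contrasts))
  cat(sprintf("  DEG universe %d -> graph %d nodes / %d edges -> %d communities\n",
              s$deg_universe, s$graph_nodes, s$graph_edges, s$communities))
  invisible(x)
}

#' Write pipeline artifacts as TSV/JSON
#'
#' Deterministic text serializations of the main stage outputs plus a run
#' manifest, so a rerun with the same configuration and seed is
#' byte-identical.
#'
#' @param x A `ztnet_pipeline`.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline <- function(x, dir) {
  stopifnot(inherits(x, "ztnet_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(x$design, "design.tsv")
  wt(data.frame(sample_id = names(x$factors), factor = unname(x$factors)),
     "tmm_factors.tsv")
  deg_rows <- do.call(rbind, lapply(names(x$degs), function(k) {
    d <- x$degs[[k]]
    if (length(d$up) + length(d$down) == 0) return(NULL)
    data.frame(contrast = k,
               gene = c(d$up, d$down),
               direction = rep(c("up", "down"),
                               c(length(d$up), length(d$down))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(deg_rows)) {
    deg_rows <- data.frame(contrast = character(0), gene = character(0),
                           direction = character(0))
  }
  wt(deg_rows, "degs.tsv")
  wt(data.frame(gene = x$deg_universe), "deg_universe.tsv")
  write_graph_edges(x$graph, file.path(dir, "graph_edges.tsv"))
  write_partition(x$partition, file.path(dir, "communities.tsv"))
  wt(as.data.frame(x$traces), "community_traces.tsv")
  wt(as.data.frame(x$heatmap), "misregulation_heatmap.tsv")
  wt(x$binding$table, "binding_enrichment.tsv")
  wt(x$motifs$planted, "motif_counts.tsv")
  wt(x$phenotype$table, "phenotypes.tsv")
  wt(x$phenotype$cq, "ddcq.tsv")
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
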