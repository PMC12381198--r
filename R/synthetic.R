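# Synthetic-data generator.
#
# Emulates the study design: 4 genotypes (wild-type reference + two single
# mutants + the double) x 2 temperatures x 7 ZT timepoints x 3 replicates,
# negative-binomial counts over ~19,000 expressed genes, planted co-expressed
# communities with sinusoidal diel profiles and genotype/temperature-specific
# log2 shifts, and one dropped sample mirroring the unbalanced design.

# deterministic child seeds so artifacts can be regenerated independently
.child_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 100003) * 20011 + k * 7919) %% 2147483629L
}

#' Define a planted co-expressed community
#'
#' Member genes share a sinusoidal diel log2 profile (common phase within the
#' community) and a common misregulation pattern: a log2 `shift` applied at
#' the `shift_zt` timepoints in the (genotype, temperature) combinations
#' listed in `misregulated_in`.
#'
#' @param genes Character vector of member gene IDs.
#' @param phase Peak time of the sinusoid (ZT hours).
#' @param amplitude Sinusoid amplitude in log2 units (default 2).
#' @param base_cpm Baseline CPM per member gene (recycled; default 150).
#' @param misregulated_in Data.frame with columns `genotype`,
#'   `temperature_C` listing the conditions carrying the shift.
#' @param shift_zt ZT timepoints (hours) at which the shift applies.
#' @param shift Log2 offset (finite; default 0).
#' @param base_profile Optional explicit per-timepoint log2 profile
#'   (overrides the sinusoid; length must match the spec timepoints).
#' @return An object of class `community_truth`.
#' @export
community_truth <- function(genes, phase = 0, amplitude = 2, base_cpm = 150,
                            misregulated_in = NULL, shift_zt = numeric(0),
                            shift = 0, base_profile = NULL) {
  if (length(genes) == 0) stop("community needs at least one gene")
  if (!is.finite(shift)) stop("'shift' must be finite")
  if (is.null(misregulated_in)) {
    misregulated_in <- data.frame(genotype = character(0),
                                  temperature_C = numeric(0))
  }
  structure(list(genes = as.character(genes), phase = phase,
                 amplitude = amplitude,
                 base_cpm = rep_len(base_cpm, length(genes)),
                 misregulated_in = misregulated_in,
                 shift_zt = shift_zt, shift = shift,
                 base_profile = base_profile),
            class = "community_truth")
}

#' Default planted communities
#'
#' Five communities of 20 genes with evenly spaced diel phases (distinct
#' phases keep between-community correlation well below the network
#' threshold while the shared within-community profile keeps within-community
#' PCC above it). Two communities are shifted by +1 log2 unit at ZT8-16 in
#' all mutants at 15 degrees C; the other three carry three- to four-timepoint shifts
#' in other (temperature, ZT) windows so that every community is
#' differentially expressed somewhere and enters the DEG universe. Shift
#' windows sit around each community's expression peak (the sinusoid peaks
#' at phase + 6 h), so planted effects occur at well-measured expression
#' levels rather than at the diel trough.
#'
#' @param mutants Mutant genotype labels (default `c("mutA","mutB","mutAB")`).
#' @return List of five `community_truth` objects.
#' @export
default_communities <- function(mutants = c("mutA", "mutB", "mutAB")) {
  gene_block <- function(k) sprintf("g%05d", (k - 1) * 20 + 1:20)
  base <- exp(seq(log(60), log(350), length.out = 20))
  mis <- function(temp) data.frame(genotype = mutants,
                                   temperature_C = rep(temp, length(mutants)))
  list(
    community_truth(gene_block(1), phase = 0, base_cpm = base,
                    misregulated_in = mis(15), shift_zt = c(8, 12, 16),
                    shift = 1),
    community_truth(gene_block(2), phase = 4.8, base_cpm = base,
                    misregulated_in = mis(15), shift_zt = c(8, 12, 16),
                    shift = 1),
    community_truth(gene_block(3), phase = 9.6, base_cpm = base,
                    misregulated_in = mis(20), shift_zt = c(8, 12, 16, 20),
                    shift = 1),
    community_truth(gene_block(4), phase = 14.4, base_cpm = base,
                    misregulated_in = mis(20), shift_zt = c(12, 16, 20, 24),
                    shift = -1),
    community_truth(gene_block(5), phase = 19.2, base_cpm = base,
                    misregulated_in = mis(15), shift_zt = c(0, 4, 20, 24),
                    shift = -1)
  )
}

#' Simulation specification
#'
#' Collects the experimental design and distributional parameters of the
#' synthetic data. The defaults reproduce the study conditions: 4 genotypes
#' x 2 temperatures x ZT 0,4,...,24 x 3 replicates, ~19,000 expressed genes,
#' NB dispersion 0.025 (biological CV ~0.16, appropriate for pooled
#' seedlings of an isogenic inbred line), and one dropped sample (the wild-type 15 C ZT12 replicate 1).
#'
#' @param n_genes Number of genes (default 19000).
#' @param genotypes Genotype labels; the first is the wild-type reference.
#' @param temperatures Temperatures in degrees C (default `c(20, 15)`).
#' @param timepoints Strictly increasing ZT hours (default `seq(0, 24, 4)`).
#' @param n_reps Replicates per cell (>= 2; default 3).
#' @param library_size_mean Mean sequencing depth in reads (default 1e7).
#' @param dispersion NB dispersion phi >= 0, scalar or per-gene (default 0.025).
#' @param communities List of [community_truth()] objects with disjoint gene
#'   sets (default [default_communities()]).
#' @param drop_sample Sample ID(s) to omit from the design, or `NULL`
#'   (default: the wild-type, lower-temperature, ZT12, replicate-1 sample).
#' @param cpm_meanlog,cpm_sdlog Log-normal parameters of the background gene
#'   baseline CPM, chosen to span the CPM > 1 expression-filter boundary.
#' @param libsize_sdlog Log-normal spread of per-sample library sizes.
#' @param seed Root seed; per-artifact child seeds are derived from it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 19000,
                     genotypes = c("Col0", "mutA", "mutB", "mutAB"),
                     temperatures = c(20, 15),
                     timepoints = seq(0, 24, by = 4),
                     n_reps = 3,
                     library_size_mean = 1e7,
                     dispersion = 0.025,
                     communities = default_communities(),
                     drop_sample = sprintf("%s_T%g_ZT12_r1", genotypes[1],
                                           min(temperatures)),
                     cpm_meanlog = log(5), cpm_sdlog = 1.8,
                     libsize_sdlog = 0.1,
                     seed = 1) {
  if (length(genotypes) == 0 || length(temperatures) == 0 ||
      length(timepoints) == 0) {
    stop("genotypes, temperatures and timepoints must be nonempty")
  }
  if (n_reps < 2) stop("'n_reps' must be >= 2")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (any(diff(timepoints) <= 0)) {
    stop("'timepoints' must be strictly increasing")
  }
  all_genes <- unlist(lapply(communities, `[[`, "genes"))
  if (anyDuplicated(all_genes)) stop("community gene sets must be disjoint")
  ids <- sprintf("g%05d", seq_len(n_genes))
  if (!all(all_genes %in% ids)) {
    stop("community genes must be among the simulated gene IDs g00001..")
  }
  for (co in communities) {
    if (!is.null(co$base_profile) &&
        length(co$base_profile) != length(timepoints)) {
      stop("community base_profile length must equal the number of timepoints")
    }
  }
  structure(list(n_genes = n_genes, genotypes = genotypes,
                 temperatures = temperatures, timepoints = timepoints,
                 n_reps = n_reps, library_size_mean = library_size_mean,
                 dispersion = dispersion, communities = communities,
                 drop_sample = drop_sample, cpm_meanlog = cpm_meanlog,
                 cpm_sdlog = cpm_sdlog, libsize_sdlog = libsize_sdlog,
                 seed = seed, gene_ids = ids),
            class = "sim_spec")
}

#' Generate the sample design table
#'
#' One row per genotype x temperature x timepoint x replicate, minus any
#' explicitly dropped samples (by default one, mirroring the unbalanced
#' design all downstream statistics must tolerate).
#'
#' @param spec A [sim_spec()].
#' @param drop Sample ID(s) to drop (default `spec$drop_sample`); `NULL`
#'   keeps the full factorial design.
#' @return Data.frame with columns `sample_id`, `genotype`, `temperature_C`,
#'   `zt_h`, `replicate`.
#' @export
generate_design <- function(spec, drop = spec$drop_sample) {
  stopifnot(inherits(spec, "sim_spec"))
  d <- expand.grid(replicate = seq_len(spec$n_reps),
                   zt_h = spec$timepoints,
                   temperature_C = spec$temperatures,
                   genotype = spec$genotypes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("genotype", "temperature_C", "zt_h", "replicate")]
  d$sample_id <- sprintf("%s_T%g_ZT%g_r%d", d$genotype, d$temperature_C,
                         d$zt_h, d$replicate)
  d <- d[, c("sample_id", "genotype", "temperature_C", "zt_h", "replicate")]
  rownames(d) <- NULL
  if (!is.null(drop) && length(drop) > 0) {
    unknown <- setdiff(drop, d$sample_id)
    if (length(unknown) > 0) {
      stop("drop sample(s) not in design: ", paste(unknown, collapse = ", "))
    }
    d <- d[!d$sample_id %in% drop, , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

#' Simulate negative-binomial counts with planted communities
#'
#' Per-gene baseline CPM is log-normal (spanning the expression-filter
#' boundary); community genes override it with their configured baselines and
#' add a sinusoidal diel log2 profile plus the planted condition-specific
#' shifts. Relative abundances are renormalized per sample, multiplied by a
#' log-normal library size, and counts drawn NB(mu, phi) (Poisson when
#' phi = 0).
#'
#' @param design Output of [generate_design()].
#' @param spec A [sim_spec()].
#' @return List with `counts` (a [count_matrix]) and `truth` (list:
#'   `community_membership` data.frame, `planted_log2fc` data.frame of all
#'   nonzero planted shifts per (gene, genotype, temperature, ZT),
#'   `base_cpm`, and the `design`).
#' @export
simulate_counts <- function(design, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (any(spec$dispersion < 0)) stop("dispersion must be >= 0")
  set.seed(.child_seed(spec$seed, 1L))
  G <- spec$n_genes
  S <- nrow(design)
  ids <- spec$gene_ids

  base_cpm <- exp(stats::rnorm(G, spec$cpm_meanlog, spec$cpm_sdlog))
  names(base_cpm) <- ids
  for (co in spec$communities) base_cpm[co$genes] <- co$base_cpm

  # log2 offsets: diel profile + planted shifts
  offs <- matrix(0, G, S, dimnames = list(ids, design$sample_id))
  shift_rows <- list()
  for (ci in seq_along(spec$communities)) {
    co <- spec$communities[[ci]]
    prof <- if (is.null(co$base_profile)) {
      co$amplitude * sin(2 * pi * (design$zt_h - co$phase) / 24)
    } else {
      co$base_profile[match(design$zt_h, spec$timepoints)]
    }
    offs[co$genes, ] <- matrix(prof, length(co$genes), S, byrow = TRUE)
    if (nrow(co$misregulated_in) > 0 && co$shift != 0) {
      hit <- rep(FALSE, S)
      for (r in seq_len(nrow(co$misregulated_in))) {
        hit <- hit | (design$genotype == co$misregulated_in$genotype[r] &
                        design$temperature_C ==
                          co$misregulated_in$temperature_C[r] &
                        design$zt_h %in% co$shift_zt)
        shift_rows[[length(shift_rows) + 1L]] <- data.frame(
          gene = rep(co$genes, each = length(co$shift_zt)),
          genotype = co$misregulated_in$genotype[r],
          temperature_C = co$misregulated_in$temperature_C[r],
          zt_h = rep(co$shift_zt, length(co$genes)),
          log2fc = co$shift, community = ci,
          stringsAsFactors = FALSE)
      }
      offs[co$genes, hit] <- offs[co$genes, hit] + co$shift
    }
  }

  W <- base_cpm * 2^offs
  W <- t(t(W) / colSums(W))
  lib <- round(stats::rlnorm(S, log(spec$library_size_mean) -
                               spec$libsize_sdlog^2 / 2, spec$libsize_sdlog))
  mu <- t(t(W) * lib)
  phi <- rep_len(spec$dispersion, G)
  counts <- matrix(0, G, S, dimnames = list(ids, design$sample_id))
  pois <- phi == 0
  if (any(pois)) {
    counts[pois, ] <- stats::rpois(sum(pois) * S, lambda = mu[pois, ])
  }
  if (any(!pois)) {
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * S,
                                      mu = mu[!pois, ],
                                      size = rep(1 / phi[!pois], S))
  }

  membership <- do.call(rbind, lapply(seq_along(spec$communities), function(ci) {
    data.frame(gene = spec$communities[[ci]]$genes, community = ci,
               stringsAsFactors = FALSE)
  }))
  planted <- if (length(shift_rows) > 0) {
    do.call(rbind, shift_rows)
  } else {
    data.frame(gene = character(0), genotype = character(0),
               temperature_C = numeric(0), zt_h = numeric(0),
               log2fc = numeric(0), community = integer(0))
  }
  list(counts = count_matrix(counts),
       truth = list(community_membership = membership,
                    planted_log2fc = planted,
                    base_cpm = base_cpm,
                    design = design))
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# overlapping match start positions of a literal motif
.motif_starts <- function(seq, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Simulate promoter sequences with planted motif counts
#'
#' Background sequence is generated CG-dinucleotide-free (a Markov draw that
#' never emits G after C), which by construction contains none of the scanned
#' motifs; planned motifs are then planted with a 2-bp spacer and any
#' occurrence accidentally created at a junction is repaired by mutating a
#' background base, so the scan of each sequence returns exactly the planted
#' counts on either strand.
#'
#' @param gene_ids Character vector of gene IDs (one promoter each).
#' @param motif_plan Data.frame with columns `gene_id`, `motif`, `count`, or
#'   `NULL` for motif-free backgrounds.
#' @param window Promoter length in bp (the 1 kb upstream of the TSS by
#'   default), >= the motif length.
#' @param seed Seed for the background draw.
#' @param motifs Motifs guaranteed absent from background even if not in the
#'   plan (default `c("CGCG", "CGTG")`).
#' @return List with `sequences` (named character vector, 5'->3' on the gene
#'   strand, TSS at the right end) and `planted` (data.frame `gene_id`,
#'   `motif`, `count` over all genes and scanned motifs).
#' @export
simulate_promoters <- function(gene_ids, motif_plan = NULL, window = 1000,
                               seed = 1, motifs = c("CGCG", "CGTG")) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs")
  if (is.null(motif_plan) || nrow(motif_plan) == 0) {
    motif_plan <- data.frame(gene_id = character(0), motif = character(0),
                             count = integer(0), stringsAsFactors = FALSE)
  }
  bad <- setdiff(motif_plan$gene_id, gene_ids)
  if (length(bad) > 0) stop("plan gene(s) not in gene_ids: ",
                            paste(bad, collapse = ", "))
  scan_motifs <- sort(unique(c(motifs, motif_plan$motif)))
  if (window < max(nchar(scan_motifs))) {
    stop("'window' must be at least the motif length")
  }
  cap <- tapply((nchar(motif_plan$motif) + 2) * motif_plan$count,
                motif_plan$gene_id, sum)
  if (any(cap > window)) {
    stop("planted motifs exceed window capacity for gene(s): ",
         paste(names(cap)[cap > window], collapse = ", "))
  }

  set.seed(.child_seed(seed, 2L))
  n <- length(gene_ids)
  mat <- matrix("A", n, window)
  prev <- rep("A", n)
  for (j in seq_len(window)) {
    r <- stats::runif(n)
    isC <- prev == "C"
    ch <- character(n)
    if (any(!isC)) ch[!isC] <- c("A", "C", "G", "T")[1L + floor(r[!isC] * 4)]
    if (any(isC)) ch[isC] <- c("A", "C", "T")[1L + floor(r[isC] * 3)]
    mat[, j] <- ch
    prev <- ch
  }
  seqs <- do.call(paste0, lapply(seq_len(window), function(j) mat[, j]))
  names(seqs) <- gene_ids

  forbidden <- sort(unique(c(scan_motifs, .revcomp(scan_motifs))))
  planted_pos <- stats::setNames(vector("list", n), gene_ids)
  for (g in unique(motif_plan$gene_id)) {
    rows <- motif_plan[motif_plan$gene_id == g & motif_plan$count > 0, ]
    s <- seqs[[g]]
    pos <- 1L
    spans <- data.frame(motif = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(rows))) {
      mo <- rows$motif[r]
      for (cc in seq_len(rows$count[r])) {
        substr(s, pos, pos + nchar(mo) - 1L) <- mo
        spans <- rbind(spans, data.frame(motif = mo, start = pos,
                                         end = pos + nchar(mo) - 1L,
                                         stringsAsFactors = FALSE))
        pos <- pos + nchar(mo) + 2L
      }
    }
    seqs[[g]] <- s
    planted_pos[[g]] <- spans
  }

  # repair junction-created occurrences without touching planted spans
  for (g in gene_ids) {
    spans <- planted_pos[[g]]
    in_planted <- rep(FALSE, window)
    if (!is.null(spans) && nrow(spans) > 0) {
      for (r in seq_len(nrow(spans))) {
        in_planted[spans$start[r]:spans$end[r]] <- TRUE
      }
    }
    for (iter in seq_len(50L)) {
      s <- seqs[[g]]
      dirty <- FALSE
      for (f in forbidden) {
        starts <- .motif_starts(s, f)
        if (!is.null(spans) && nrow(spans) > 0) {
          ok <- spans$start[spans$motif == f]
          starts <- setdiff(starts, ok)
        }
        for (st in starts) {
          span <- st:(st + nchar(f) - 1L)
          fixable <- span[!in_planted[span]]
          if (length(fixable) == 0) next
          j <- fixable[length(fixable)]
          lo <- max(1L, st - 4L)
          hi <- min(window, st + nchar(f) + 3L)
          ctx_hits <- function(sq) {
            out <- character(0)
            for (ff in forbidden) {
              stv <- .motif_starts(substr(sq, lo, hi), ff)
              if (length(stv) > 0) {
                out <- c(out, paste0(ff, ":", lo - 1L + stv))
              }
            }
            out
          }
          before <- ctx_hits(s)
          target <- paste0(f, ":", st)
          for (repl in c("A", "T", "C", "G")) {
            if (substr(s, j, j) == repl) next
            s2 <- s
            substr(s2, j, j) <- repl
            after <- ctx_hits(s2)
            # accept if the target occurrence is gone and nothing new appears
            if (!target %in% after &&
                length(setdiff(after, before)) == 0) {
              s <- s2
              break
            }
          }
          dirty <- TRUE
        }
      }
      seqs[[g]] <- s
      if (!dirty) break
    }
  }

  planted <- expand.grid(gene_id = gene_ids, motif = scan_motifs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  planted$count <- 0L
  if (nrow(motif_plan) > 0) {
    key <- paste(planted$gene_id, planted$motif)
    pk <- paste(motif_plan$gene_id, motif_plan$motif)
    hit <- match(key, pk)
    planted$count[!is.na(hit)] <- as.integer(motif_plan$count[hit[!is.na(hit)]])
  }
  # verify: the scan must return exactly the planted counts
  for (i in seq_len(nrow(planted))) {
    got <- length(.motif_starts(seqs[[planted$gene_id[i]]], planted$motif[i]))
    if (got != planted$count[i]) {
      stop("internal error: planted count mismatch for ",
           planted$gene_id[i], "/", planted$motif[i], " (planted ",
           planted$count[i], ", scanned ", got, ")")
    }
  }
  list(sequences = seqs, planted = planted[order(planted$gene_id,
                                                 planted$motif), ])
}

#' Write promoter sequences as FASTA
#'
#' @param sequences Named character vector (record ID = gene ID).
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' TF-to-gene binding table
#'
#' @param bound Named list mapping TF IDs to character vectors of bound
#'   genes (each a subset of `universe`).
#' @param universe Character vector of all genes.
#' @return An object of class `binding_table`.
#' @export
binding_table <- function(bound, universe) {
  universe <- as.character(universe)
  for (tf in names(bound)) {
    out <- setdiff(bound[[tf]], universe)
    if (length(out) > 0) {
      stop("TF ", tf, " binds gene(s) outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  structure(list(bound = bound, universe = universe), class = "binding_table")
}

#' Simulate a TF binding-event table
#'
#' Bernoulli binding per (TF, gene) at `background_rate`; one named TF binds
#' the target set with `enrichment_odds`-fold elevated odds, emulating a
#' specifically enriched factor among a panel of controls.
#'
#' @param gene_ids Universe of genes.
#' @param n_tfs Number of TFs (>= 2; default 76, one enriched + 75 controls).
#' @param enriched_tf ID of the enriched TF (default `"TF001"`).
#' @param target_set Genes bound with elevated odds (subset of `gene_ids`).
#' @param enrichment_odds Odds multiplier for the enriched TF on targets
#'   (default 10; 1 = null).
#' @param background_rate Background binding probability (default 0.05).
#' @param seed Seed.
#' @return A [binding_table()].
#' @export
simulate_binding_table <- function(gene_ids, n_tfs = 76,
                                   enriched_tf = "TF001",
                                   target_set = character(0),
                                   enrichment_odds = 10,
                                   background_rate = 0.05, seed = 1) {
  if (n_tfs < 2) stop("'n_tfs' must be >= 2")
  gene_ids <- as.character(gene_ids)
  out <- setdiff(target_set, gene_ids)
  if (length(out) > 0) {
    stop("target gene(s) outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  }
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  if (!enriched_tf %in% tfs) stop("'enriched_tf' must be one of ", tfs[1],
                                  "..", tfs[n_tfs])
  set.seed(.child_seed(seed, 3L))
  odds_bg <- background_rate / (1 - background_rate)
  p_enr <- enrichment_odds * odds_bg / (1 + enrichment_odds * odds_bg)
  bound <- lapply(tfs, function(tf) {
    p <- rep(background_rate, length(gene_ids))
    if (tf == enriched_tf) p[gene_ids %in% target_set] <- p_enr
    gene_ids[stats::runif(length(gene_ids)) < p]
  })
  names(bound) <- tfs
  binding_table(bound, gene_ids)
}

#' Simulate a flowering phenotype table
#'
#' Total leaf number (TLN) is drawn around the group mean and rounded to a
#' positive integer; days post-germination are co-generated from a
#' temperature-dependent leaf-generation rate so that leaves-per-day behaves
#' realistically (cooler plants produce leaves more slowly).
#'
#' @param group_means Data.frame with columns `genotype`, `temperature_C`,
#'   `mean_tln` and optionally `light` (defaults to `"WL"`).
#' @param sd TLN standard deviation (> 0; default 2).
#' @param n Plants per group (>= 2; scalar or per-group).
#' @param seed Seed.
#' @return Data.frame with columns `plant_id`, `genotype`, `temperature_C`,
#'   `light`, `total_leaf_number`, `days_post_germination`.
#' @export
simulate_phenotypes <- function(group_means, sd = 2, n = 12, seed = 1) {
  if (any(sd <= 0)) stop("'sd' must be positive")
  n <- rep_len(n, nrow(group_means))
  if (any(n < 2)) stop("need n >= 2 plants per group")
  if (is.null(group_means$light)) group_means$light <- "WL"
  set.seed(.child_seed(seed, 4L))
  rows <- lapply(seq_len(nrow(group_means)), function(i) {
    tln <- pmax(1, round(stats::rnorm(n[i], group_means$mean_tln[i], sd)))
    lpd <- stats::rlnorm(n[i], log(0.03 * group_means$temperature_C[i]), 0.08)
    data.frame(
      plant_id = sprintf("%s_T%g_%s_p%02d", group_means$genotype[i],
                         group_means$temperature_C[i], group_means$light[i],
                         seq_len(n[i])),
      genotype = group_means$genotype[i],
      temperature_C = group_means$temperature_C[i],
      light = group_means$light[i],
      total_leaf_number = tln,
      days_post_germination = tln / lpd,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Cq table
#'
#' Fixed-efficiency (doubling per cycle) model: the target Cq tracks the
#' internal-control Cq plus a constant offset minus the condition's true
#' log2 expression, with Gaussian cycle noise.
#'
#' @param effects Data.frame with columns `condition`, `log2_expression`
#'   (true log2 abundance relative to the calibrator, which should have 0).
#' @param n_reps Replicates per condition (default 3).
#' @param noise_sd Cq noise SD in cycles (default 0.1).
#' @param control_mean Mean Cq of the internal control (default 20).
#' @param delta0 Baseline target-minus-control Cq offset (default 8).
#' @param seed Seed.
#' @return Data.frame with columns `sample_id`, `condition`, `cq_target`,
#'   `cq_control`.
#' @export
simulate_cq <- function(effects, n_reps = 3, noise_sd = 0.1,
                        control_mean = 20, delta0 = 8, seed = 1) {
  stopifnot(all(c("condition", "log2_expression") %in% names(effects)))
  set.seed(.child_seed(seed, 5L))
  rows <- lapply(seq_len(nrow(effects)), function(i) {
    ctrl <- stats::rnorm(n_reps, control_mean, noise_sd)
    tgt <- ctrl + delta0 - effects$log2_expression[i] +
      stats::rnorm(n_reps, 0, noise_sd)
    data.frame(sample_id = sprintf("%s_r%d", effects$condition[i],
                                   seq_len(n_reps)),
               condition = effects$condition[i],
               cq_target = tgt, cq_control = ctrl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
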