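# Gene-set overlap, binding enrichment and promoter motif counting.

#' Hypergeometric overlap test between two gene sets
#'
#' @param setA,setB Character vectors, both subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return List with `k` (observed overlap), `expected` (|A||B|/N), `p`
#'   (upper-tail hypergeometric probability including the observed overlap),
#'   and the set sizes.
#' @export
overlap_test <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  outA <- setdiff(setA, universe)
  outB <- setdiff(setB, universe)
  if (length(outA) > 0 || length(outB) > 0) {
    stop("element(s) outside the universe: ",
         paste(utils::head(c(outA, outB), 10), collapse = ", "))
  }
  k <- length(intersect(setA, setB))
  N <- length(universe)
  list(k = k, expected = length(setA) * length(setB) / N,
       p = hypergeom_tail(k, length(setA), length(setB), N),
       n_a = length(setA), n_b = length(setB), n_universe = N)
}

#' Binding-event enrichment across a TF panel
#'
#' Hypergeometric overlap between a DEG list and each TF's bound genes, with
#' BH adjustment across TFs, and the specificity rank (by p-value) of a
#' named TF among the panel — the check that no control factor shows a
#' similar enrichment.
#'
#' @param deg_list Character vector of genes (subset of the binding
#'   universe).
#' @param binding A [binding_table()].
#' @param tf TF whose specificity rank to report, or `NULL`.
#' @return List with `table` (data.frame `tf`, `n_bound`, `k`, `expected`,
#'   `p`, `q`, sorted by p), `tf`, and `rank` (1 = most enriched;
#'   minimum rank under ties).
#' @export
binding_enrichment <- function(deg_list, binding, tf = NULL) {
  stopifnot(inherits(binding, "binding_table"))
  if (!is.null(tf) && !tf %in% names(binding$bound)) {
    stop("TF ", tf, " not in the binding table")
  }
  res <- lapply(names(binding$bound), function(t) {
    ot <- overlap_test(deg_list, binding$bound[[t]], binding$universe)
    data.frame(tf = t, n_bound = ot$n_b, k = ot$k, expected = ot$expected,
               p = ot$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- bh_adjust(tab$p)
  rk <- rank(tab$p, ties.method = "min")
  names(rk) <- tab$tf
  tab <- tab[order(tab$p, tab$tf), ]
  rownames(tab) <- NULL
  list(table = tab, tf = tf,
       rank = if (is.null(tf)) NA_integer_ else unname(rk[tf]))
}

#' Count motif occurrences in promoter windows
#'
#' Counts occurrences of each motif within the `window` bases adjacent to
#' the TSS (promoter records are written 5'->3' on the gene strand with the
#' TSS at the right end, so the window is the right-hand portion of each
#' sequence). Overlapping occurrences are counted by default (CGCGCG
#' contains CGCG twice). With `both_strands`, occurrences of the motif's
#' reverse complement are also counted (as the union of match positions, so
#' the self-reverse-complementary CGCG is not double-counted while CGTG
#' additionally picks up CACG sites). N never matches.
#'
#' @param promoters Named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file (record ID =
#'   gene ID).
#' @param motifs Motifs to count (default `c("CGCG", "CGTG")`).
#' @param window Scan window in bp relative to the TSS (default 1000). If a
#'   sequence is shorter, the available span is scanned with a warning.
#' @param both_strands Also count on the reverse strand (default TRUE).
#' @param overlapping Count overlapping occurrences (default TRUE).
#' @return Integer matrix, genes x motifs.
#' @export
motif_scan <- function(promoters, motifs = c("CGCG", "CGTG"), window = 1000,
                       both_strands = TRUE, overlapping = TRUE) {
  if (is.character(promoters) && length(promoters) == 1 &&
      is.null(names(promoters)) && file.exists(promoters)) {
    x <- Biostrings::readDNAStringSet(promoters)
    promoters <- stats::setNames(as.character(x), names(x))
  } else if (inherits(promoters, "DNAStringSet")) {
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  }
  if (is.null(names(promoters))) stop("promoter sequences must be named")
  seqs <- toupper(promoters)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character in sequence ", names(seqs)[i], " at position ",
         bad[i])
  }
  lens <- nchar(seqs)
  if (any(lens < window)) {
    warning(sum(lens < window), " sequence(s) shorter than the ", window,
            "-bp window; scanning the available span")
  }
  sub <- substr(seqs, pmax(1L, lens - window + 1L), lens)
  counts <- matrix(0L, length(seqs), length(motifs),
                   dimnames = list(names(seqs), motifs))
  for (mo in motifs) {
    rc <- .revcomp(mo)
    for (i in seq_along(sub)) {
      if (overlapping) {
        st <- .motif_starts(sub[i], mo)
        if (both_strands && rc != mo) {
          st <- union(st, .motif_starts(sub[i], rc))
        }
        counts[i, mo] <- length(st)
      } else {
        hits <- gregexpr(mo, sub[i], fixed = TRUE)[[1]]
        n <- if (hits[1] == -1) 0L else length(hits)
        if (both_strands && rc != mo) {
          hits2 <- gregexpr(rc, sub[i], fixed = TRUE)[[1]]
          n <- n + if (hits2[1] == -1) 0L else length(hits2)
        }
        counts[i, mo] <- n
      }
    }
  }
  counts
}

#' Gene-set over-representation analysis
#'
#' One-sided Fisher exact enrichment (equivalently the hypergeometric upper
#' tail) of a gene list against each annotation term, with fold enrichment
#' and BH adjustment across terms.
#'
#' @param gene_list Character vector (subset of `universe`).
#' @param annotations Named list mapping term IDs to gene sets.
#' @param universe Character vector of all genes; term sets are intersected
#'   with it.
#' @param q_cutoff Threshold for the `significant` flag (default 0.05).
#' @return Data.frame with columns `term`, `n_term`, `k`, `fold_enrichment`,
#'   `p`, `q`, `significant`, sorted by q then p.
#' @export
gene_set_ora <- function(gene_list, annotations, universe, q_cutoff = 0.05) {
  if (length(annotations) == 0) stop("'annotations' is empty")
  universe <- unique(as.character(universe))
  gene_list <- unique(as.character(gene_list))
  out <- setdiff(gene_list, universe)
  if (length(out) > 0) {
    stop("gene(s) outside the universe: ",
         paste(utils::head(out, 10), collapse = ", "))
  }
  if (length(gene_list) == 0) stop("gene list is empty within the universe")
  N <- length(universe)
  nl <- length(gene_list)
  rows <- lapply(names(annotations), function(tm) {
    term <- intersect(unique(as.character(annotations[[tm]])), universe)
    k <- length(intersect(gene_list, term))
    nt <- length(term)
    fe <- if (nt == 0) NA_real_ else (k / nl) / (nt / N)
    p <- if (nt == 0) 1 else hypergeom_tail(k, nl, nt, N)
    data.frame(term = tm, n_term = nt, k = k, fold_enrichment = fe, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  tab$significant <- tab$q < q_cutoff
  tab <- tab[order(tab$q, tab$p, tab$term), ]
  rownames(tab) <- NULL
  tab
}
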