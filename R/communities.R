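# Girvan-Newman community detection.
#
# Edge betweenness is computed with Brandes' BFS accumulation (shortest
# paths are unweighted; correlation weights are annotation only). The
# Girvan-Newman loop removes the highest-betweenness edge, recomputing
# betweenness after every removal (restricted to the affected component),
# records a partition whenever a component splits, and scores each recorded
# partition by Newman-Girvan modularity against the ORIGINAL graph.

# integer index view of a coex_graph
.graph_index <- function(g) {
  nodes <- g$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  list(nodes = nodes, n = length(nodes),
       ea = unname(idx[g$edges$a]), eb = unname(idx[g$edges$b]),
       m = nrow(g$edges))
}

# adjacency + incident-edge-id lists for the active edges
.adjacency <- function(n, ea, eb, active) {
  act <- which(active)
  src <- c(ea[act], eb[act])
  dst <- c(eb[act], ea[act])
  eidv <- c(act, act)
  f <- factor(src, levels = seq_len(n))
  list(adj = split(dst, f), eid = split(eidv, f))
}

# Brandes edge-betweenness accumulation over the given sources.
# Returns per-edge sums over ordered source pairs; caller halves it.
.brandes <- function(adj, eid, n, m, sources) {
  ebv <- numeric(m)
  for (s in sources) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv1 <- dist[v] + 1L
      nb <- adj[[v]]
      for (w in nb) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (qi in tail:1) {
      w <- queue[qi]
      nb <- adj[[w]]
      ne <- eid[[w]]
      dw <- dist[w]
      coef <- (1 + delta[w]) / sigma[w]
      for (i in seq_along(nb)) {
        v <- nb[i]
        if (dist[v] == dw - 1L) {
          contrib <- sigma[v] * coef
          e <- ne[i]
          ebv[e] <- ebv[e] + contrib
          delta[v] <- delta[v] + contrib
        }
      }
    }
  }
  ebv
}

# connected-component membership among active edges
.components <- function(n, ea, eb, active) {
  ad <- .adjacency(n, ea, eb, active)$adj
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    comp[s] <- cid
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- ad[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Edge betweenness centrality
#'
#' For every edge, the sum over unordered node pairs of the fraction of
#' shortest paths between the pair that pass through the edge (unweighted
#' BFS shortest paths; Brandes accumulation).
#'
#' @param g A `coex_graph`.
#' @return `g$edges` with an additional `betweenness` column (empty
#'   data.frame for an edgeless graph).
#' @export
edge_betweenness <- function(g) {
  stopifnot(inherits(g, "coex_graph"))
  gi <- .graph_index(g)
  out <- g$edges
  if (gi$m == 0) {
    out$betweenness <- numeric(0)
    return(out)
  }
  ad <- .adjacency(gi$n, gi$ea, gi$eb, rep(TRUE, gi$m))
  out$betweenness <- .brandes(ad$adj, ad$eid, gi$n, gi$m,
                              seq_len(gi$n)) / 2
  out
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over communities of \[l_c/m - (d_c/(2m))^2\], where l_c is the
#' number of edges inside community c, d_c the total degree of its nodes and
#' m the number of edges, all taken from `g`. Q of the all-in-one partition
#' is 0 by construction; an edgeless graph has Q = 0.
#'
#' @param g A `coex_graph`.
#' @param membership Integer community labels named by node, covering
#'   `g$nodes`.
#' @return Modularity in \[-0.5, 1\].
#' @export
modularity_q <- function(g, membership) {
  stopifnot(inherits(g, "coex_graph"))
  m <- nrow(g$edges)
  if (m == 0) return(0)
  memb <- membership[g$nodes]
  if (anyNA(memb)) stop("'membership' must cover all graph nodes")
  ca <- memb[g$edges$a]
  cb <- memb[g$edges$b]
  l_c <- table(factor(ca[ca == cb], levels = unique(memb)))
  deg <- table(factor(c(g$edges$a, g$edges$b), levels = g$nodes))
  d_c <- tapply(as.numeric(deg), memb[names(deg)], sum)
  sum(as.numeric(l_c) / m) - sum((d_c / (2 * m))^2)
}

#' Girvan-Newman edge-removal dendrogram
#'
#' Iteratively removes the edge with the highest betweenness (recomputing
#' betweenness after every removal; ties broken toward the lexicographically
#' smallest (a, b) edge), recording a partition each time a component
#' splits. Modularity of every recorded partition is evaluated against the
#' original graph. Components are processed independently: only the
#' component containing the removed edge has its betweenness recomputed.
#'
#' @param g A `coex_graph`.
#' @return An object of class `gn_dendrogram`: list with `graph`, `removals`
#'   (data.frame `order`, `a`, `b`, `betweenness`), `partitions` (list of
#'   named integer membership vectors, refining over the sequence down to
#'   all singletons) and `modularity` (one Q per partition).
#' @export
girvan_newman <- function(g) {
  stopifnot(inherits(g, "coex_graph"))
  gi <- .graph_index(g)
  n <- gi$n; m <- gi$m
  active <- rep(TRUE, m)
  comp <- .components(n, gi$ea, gi$eb, active)
  partitions <- list(stats::setNames(comp, gi$nodes))
  modularity <- modularity_q(g, partitions[[1]])
  removals <- data.frame(order = integer(0), a = character(0),
                         b = character(0), betweenness = numeric(0),
                         stringsAsFactors = FALSE)
  if (m == 0) {
    return(structure(list(graph = g, removals = removals,
                          partitions = partitions, modularity = modularity),
                     class = "gn_dendrogram"))
  }
  eb_val <- rep(NA_real_, m)
  dirty <- unique(comp)
  next_cid <- max(comp)
  step <- 0L
  while (any(active)) {
    if (length(dirty) > 0) {
      for (cid in dirty) {
        cnodes <- which(comp == cid)
        if (length(cnodes) < 2) next
        ce <- which(active & comp[gi$ea] == cid)
        if (length(ce) == 0) next
        act_c <- rep(FALSE, m)
        act_c[ce] <- TRUE
        ad <- .adjacency(n, gi$ea, gi$eb, act_c)
        ebv <- .brandes(ad$adj, ad$eid, n, m, cnodes) / 2
        eb_val[ce] <- ebv[ce]
      }
      dirty <- integer(0)
    }
    act_idx <- which(active)
    vals <- eb_val[act_idx]
    mx <- max(vals)
    cand <- act_idx[vals >= mx - 1e-9 * max(1, abs(mx))]
    e <- cand[1]  # edges are pre-sorted lexicographically by (a, b)
    step <- step + 1L
    removals <- rbind(removals, data.frame(
      order = step, a = g$edges$a[e], b = g$edges$b[e],
      betweenness = eb_val[e], stringsAsFactors = FALSE))
    active[e] <- FALSE
    eb_val[e] <- NA_real_
    cid <- comp[gi$ea[e]]
    # did the removal split the component?
    cnodes <- which(comp == cid)
    act_c <- active & comp[gi$ea] == cid
    ad <- .adjacency(n, gi$ea, gi$eb, act_c)$adj
    reached <- rep(FALSE, n)
    start <- gi$ea[e]
    reached[start] <- TRUE
    queue <- start
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- ad[[v]]
      new <- nb[!reached[nb]]
      reached[new] <- TRUE
      queue <- c(queue, new)
    }
    if (!reached[gi$eb[e]]) {
      next_cid <- next_cid + 1L
      moved <- cnodes[reached[cnodes]]
      comp[moved] <- next_cid
      partitions[[length(partitions) + 1L]] <- stats::setNames(comp, gi$nodes)
      modularity <- c(modularity,
                      modularity_q(g, partitions[[length(partitions)]]))
      dirty <- c(cid, next_cid)
    } else {
      dirty <- cid
    }
  }
  structure(list(graph = g, removals = removals, partitions = partitions,
                 modularity = modularity),
            class = "gn_dendrogram")
}

#' @export
#' @method print gn_dendrogram
print.gn_dendrogram <- function(x, ...) {
  cat(sprintf("gn_dendrogram: %d removals, %d recorded partitions, max Q = %.4f\n",
              nrow(x$removals), length(x$partitions), max(x$modularity)))
  invisible(x)
}

#' Cut a Girvan-Newman dendrogram at maximum modularity
#'
#' Returns the recorded partition with the highest modularity; ties are
#' broken toward fewer communities (the earlier, coarser partition).
#'
#' @param d A `gn_dendrogram`.
#' @return An object of class `community_partition`: list with `communities`
#'   (list of gene-ID vectors, indexed by decreasing size), `membership`
#'   (named integer vector over all graph nodes), `modularity`, and
#'   `min_size` (NA until [filter_min_size()] is applied).
#' @export
cut_max_modularity <- function(d) {
  stopifnot(inherits(d, "gn_dendrogram"))
  if (length(d$partitions) == 0) stop("empty dendrogram")
  q <- d$modularity
  best <- max(q)
  cand <- which(q >= best - 1e-12)
  ncomm <- vapply(d$partitions[cand], function(p) length(unique(p)),
                  integer(1))
  pick <- cand[which.min(ncomm)]
  memb <- d$partitions[[pick]]
  comms <- split(names(memb), memb)
  sizes <- lengths(comms)
  first <- vapply(comms, function(v) min(v), character(1))
  ord <- order(-sizes, first)
  comms <- lapply(comms[ord], sort)
  names(comms) <- NULL
  memb_new <- integer(length(memb))
  names(memb_new) <- names(memb)
  for (i in seq_along(comms)) memb_new[comms[[i]]] <- i
  structure(list(communities = comms, membership = memb_new,
                 modularity = q[pick], min_size = NA_integer_),
            class = "community_partition")
}

#' @export
#' @method print community_partition
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities (sizes %s), Q = %.4f\n",
              length(x$communities),
              paste(utils::head(lengths(x$communities), 10), collapse = ","),
              x$modularity))
  invisible(x)
}

#' Drop communities below a minimum size
#'
#' Communities smaller than `min_size` are removed from the working set
#' (the full partition is retained in `$full_communities`); the survivors
#' are renumbered by decreasing size.
#'
#' @param p A `community_partition`.
#' @param min_size Minimum community size (default 4).
#' @return A `community_partition` whose `communities` all have at least
#'   `min_size` members; `membership` covers only their genes.
#' @export
filter_min_size <- function(p, min_size = 4) {
  stopifnot(inherits(p, "community_partition"), min_size >= 1)
  full <- if (is.null(p$full_communities)) p$communities else p$full_communities
  keep <- full[lengths(full) >= min_size]
  if (length(keep) == 0) {
    warning("no community has at least ", min_size, " members")
  }
  memb <- integer(0)
  for (i in seq_along(keep)) {
    memb[keep[[i]]] <- i
  }
  structure(list(communities = keep, membership = memb,
                 modularity = p$modularity, min_size = min_size,
                 full_communities = full),
            class = "community_partition")
}

#' Write a partition as a two-column TSV (gene, community_id)
#'
#' @param p A `community_partition`.
#' @param path Output path.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "community_partition"))
  d <- data.frame(gene = names(p$membership),
                  community_id = unname(p$membership))
  d <- d[order(d$community_id, d$gene), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Girvan-Newman dendrogram as JSON
#'
#' Records the edge-removal order, the split points and the modularity
#' sequence.
#'
#' @param d A `gn_dendrogram`.
#' @param path Output path.
#' @export
write_dendrogram_json <- function(d, path) {
  stopifnot(inherits(d, "gn_dendrogram"))
  obj <- list(removals = d$removals,
              n_partitions = length(d$partitions),
              modularity = d$modularity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
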