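# Independent oracles used across the suite.

# Brute-force edge betweenness: enumerate all shortest paths between every
# unordered node pair by backward recursion over BFS distance layers.
brute_edge_betweenness <- function(g) {
  n <- length(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes)
  m <- nrow(g$edges)
  res <- numeric(m)
  if (m == 0 || n < 2) return(res)
  A <- matrix(FALSE, n, n)
  ekey <- new.env()
  for (e in seq_len(m)) {
    i <- idx[g$edges$a[e]]; j <- idx[g$edges$b[e]]
    A[i, j] <- A[j, i] <- TRUE
    assign(paste(min(i, j), max(i, j)), e, envir = ekey)
  }
  for (s in 1:(n - 1)) {
    dist <- rep(Inf, n); dist[s] <- 0; q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in which(A[v, ])) {
        if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; q <- c(q, w) }
      }
    }
    for (t in (s + 1):n) {
      if (!is.finite(dist[t])) next
      paths <- list()
      rec <- function(v, acc) {
        if (v == s) { paths[[length(paths) + 1]] <<- c(s, rev(acc)); return() }
        for (u in which(A[v, ])) {
          if (dist[u] == dist[v] - 1) rec(u, c(acc, v))
        }
      }
      rec(t, integer(0))
      np <- length(paths)
      for (pp in paths) {
        for (k in seq_len(length(pp) - 1)) {
          e <- get(paste(min(pp[k], pp[k + 1]), max(pp[k], pp[k + 1])),
                   envir = ekey)
          res[e] <- res[e] + 1 / np
        }
      }
    }
  }
  res
}

# random simple graph on n nodes with edge probability p (may be disconnected)
random_graph <- function(n, p) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  sel <- stats::runif(nrow(pairs)) < p
  coex_graph(data.frame(a = pairs[sel, 1], b = pairs[sel, 2],
                        stringsAsFactors = FALSE), nodes = nodes)
}

# stochastic block graph: `k` blocks of `size` nodes
sbm_graph <- function(k = 4, size = 10, p_in = 0.9, p_out = 0.02) {
  nodes <- sprintf("b%d_n%02d", rep(seq_len(k), each = size),
                   rep(seq_len(size), k))
  block <- rep(seq_len(k), each = size)
  pairs <- t(utils::combn(seq_along(nodes), 2))
  pp <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], p_in, p_out)
  sel <- stats::runif(nrow(pairs)) < pp
  list(graph = coex_graph(data.frame(a = nodes[pairs[sel, 1]],
                                     b = nodes[pairs[sel, 2]],
                                     stringsAsFactors = FALSE),
                          nodes = nodes),
       membership = stats::setNames(block, nodes))
}

# Adjusted Rand Index between two labelings over the same names
ari <- function(a, b) {
  b <- b[names(a)]
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# BH step-up oracle: q_i = min over j >= rank(i) of m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# closed-form hypergeometric upper tail by direct enumeration with choose()
hyper_tail_oracle <- function(k, nA, nB, N) {
  js <- k:min(nA, nB)
  sum(choose(nA, js) * choose(N - nA, nB - js)) / choose(N, nB)
}

# NB two-group count fixture: rows 1..n_de carry the planted log2fc
nb_two_group <- function(n_genes, n_per_group = 3, mu_meanlog = log(150),
                         mu_sdlog = 1, phi = 0.1, lfc = 0, n_de = 0) {
  mu <- exp(stats::rnorm(n_genes, mu_meanlog, mu_sdlog))
  fc <- rep(1, n_genes)
  if (n_de > 0) {
    sgn <- rep(c(1, -1), length.out = n_de)
    fc[seq_len(n_de)] <- 2^(sgn * lfc)
  }
  muA <- matrix(mu, n_genes, n_per_group)
  muB <- matrix(mu * fc, n_genes, n_per_group)
  draw <- function(m) {
    if (phi == 0) matrix(stats::rpois(length(m), m), nrow(m), ncol(m))
    else matrix(stats::rnbinom(length(m), mu = m, size = 1 / phi),
                nrow(m), ncol(m))
  }
  y <- cbind(draw(muA), draw(muB))
  rownames(y) <- sprintf("g%05d", seq_len(n_genes))
  colnames(y) <- sprintf("s%d", seq_len(2 * n_per_group))
  list(counts = y, mu = mu, true_lfc = log2(fc))
}

two_group_design <- function(n_per_group = 3) {
  data.frame(
    sample_id = sprintf("s%d", seq_len(2 * n_per_group)),
    genotype = rep(c("ref", "mut"), each = n_per_group),
    temperature_C = 15, zt_h = 0,
    replicate = rep(seq_len(n_per_group), 2),
    stringsAsFactors = FALSE)
}

# tiny simulation spec used by pipeline-level tests
small_sim_spec <- function(seed, n_genes = 400) {
  base <- exp(seq(log(80), log(300), length.out = 10))
  comms <- list(
    community_truth(sprintf("g%05d", 1:10), phase = 0, base_cpm = base,
                    misregulated_in = data.frame(
                      genotype = c("mutA", "mutB", "mutAB"),
                      temperature_C = 15),
                    shift_zt = c(8, 12, 16), shift = 1),
    community_truth(sprintf("g%05d", 11:20), phase = 12, base_cpm = base,
                    misregulated_in = data.frame(
                      genotype = c("mutA", "mutB", "mutAB"),
                      temperature_C = 20),
                    shift_zt = c(12, 16, 20), shift = -1))
  sim_spec(n_genes = n_genes, communities = comms, seed = seed)
}
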