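triangle <- coex_graph(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")))
bridge <- coex_graph(data.frame(a = c("A", "A", "B", "D", "D", "E", "C"),
                                b = c("B", "C", "C", "E", "F", "F", "D")))

test_that("edge betweenness matches closed forms on canonical graphs", {
  expect_equal(edge_betweenness(triangle)$betweenness, rep(1, 3))
  path <- coex_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(edge_betweenness(path)$betweenness, c(2, 2))
  star <- coex_graph(data.frame(a = rep("H", 3), b = c("L1", "L2", "L3")))
  expect_equal(edge_betweenness(star)$betweenness, rep(3, 3))
  eb <- edge_betweenness(bridge)
  expect_equal(eb$betweenness[eb$a == "C" & eb$b == "D"], 9)
  empty <- coex_graph(NULL, nodes = c("x", "y"))
  expect_equal(nrow(edge_betweenness(empty)), 0)
})

test_that("edge betweenness equals the brute-force oracle on random graphs", {
  set.seed(16)
  for (i in 1:40) {
    g <- random_graph(sample(4:12, 1), runif(1, 0.2, 0.7))
    if (nrow(g$edges) == 0) next
    got <- edge_betweenness(g)$betweenness
    expect_equal(got, brute_edge_betweenness(g), tolerance = 1e-9)
    # sum over edges = sum of pairwise distances over connected pairs
    n <- length(g$nodes)
    idx <- stats::setNames(seq_len(n), g$nodes)
    A <- matrix(FALSE, n, n)
    A[cbind(idx[g$edges$a], idx[g$edges$b])] <- TRUE
    A <- A | t(A)
    dsum <- 0
    for (s in seq_len(n)) {
      dist <- rep(Inf, n); dist[s] <- 0; q <- s
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in which(A[v, ])) {
          if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; q <- c(q, w) }
        }
      }
      dsum <- dsum + sum(dist[is.finite(dist)])
    }
    expect_equal(sum(got), dsum / 2, tolerance = 1e-9)
  }
})

test_that("edge betweenness agrees with igraph", {
  skip_if_not_installed("igraph")
  set.seed(17)
  g <- random_graph(15, 0.3)
  ig <- igraph::graph_from_data_frame(g$edges[, c("a", "b")],
                                      directed = FALSE,
                                      vertices = g$nodes)
  expect_equal(edge_betweenness(g)$betweenness,
               igraph::edge_betweenness(ig, weights = NA), tolerance = 1e-9)
})

test_that("Girvan-Newman removes the bridge first and cuts at the triangles", {
  d <- girvan_newman(bridge)
  expect_equal(d$removals$a[1], "C")
  expect_equal(d$removals$b[1], "D")
  expect_equal(d$removals$betweenness[1], 9)
  p <- cut_max_modularity(d)
  expect_equal(length(p$communities), 2)
  expect_setequal(p$communities[[1]], c("A", "B", "C"))
  expect_setequal(p$communities[[2]], c("D", "E", "F"))
  expect_equal(p$modularity, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-12)
  # partitions strictly refine down to singletons
  ks <- vapply(d$partitions, function(m) length(unique(m)), integer(1))
  expect_true(all(diff(ks) > 0))
  expect_equal(ks[length(ks)], 6)
})

test_that("maximum-modularity cut handles cliques, components and ties", {
  k5 <- coex_graph(as.data.frame(t(utils::combn(paste0("n", 1:5), 2)),
                                 col.names = c("a", "b")) |>
                     stats::setNames(c("a", "b")))
  p5 <- cut_max_modularity(girvan_newman(k5))
  expect_equal(length(p5$communities), 1)   # all splits have negative Q
  expect_equal(p5$modularity, 0)
  k4 <- function(pre) {
    e <- t(utils::combn(paste0(pre, 1:4), 2))
    data.frame(a = e[, 1], b = e[, 2])
  }
  two <- coex_graph(rbind(k4("a"), k4("b")))
  p2 <- cut_max_modularity(girvan_newman(two))
  expect_equal(length(p2$communities), 2)   # components are already optimal
  edgeless <- girvan_newman(coex_graph(NULL, nodes = c("x", "y", "z")))
  expect_equal(length(edgeless$partitions), 1)
  pe <- cut_max_modularity(edgeless)
  expect_equal(length(pe$communities), 3)
  expect_equal(pe$modularity, 0)
})

test_that("modularity of the trivial partition is zero on any graph", {
  set.seed(18)
  for (i in 1:10) {
    g <- random_graph(sample(5:12, 1), runif(1, 0.2, 0.8))
    memb <- stats::setNames(rep(1L, length(g$nodes)), g$nodes)
    expect_equal(modularity_q(g, memb), 0, tolerance = 1e-12)
  }
})

test_that("minimum-size filtering keeps the full partition on the side", {
  sizes <- c(10, 4, 3, 1)
  comms <- lapply(seq_along(sizes), function(i) {
    sprintf("c%d_%02d", i, seq_len(sizes[i]))
  })
  memb <- stats::setNames(rep(seq_along(sizes), sizes), unlist(comms))
  p <- structure(list(communities = comms, membership = memb,
                      modularity = 0.5, min_size = NA_integer_),
                 class = "community_partition")
  f <- filter_min_size(p)
  expect_equal(lengths(f$communities), c(10, 4))
  expect_equal(length(f$full_communities), 4)
  expect_identical(filter_min_size(p, 1)$communities, p$communities)
  expect_warning(f0 <- filter_min_size(p, 99), "no community")
  expect_length(f0$communities, 0)
})

test_that("planted stochastic blocks are recovered exactly in most seeds", {
  ok <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    sb <- sbm_graph()
    p <- cut_max_modularity(girvan_newman(sb$graph))
    if (isTRUE(all.equal(ari(p$membership, sb$membership), 1))) ok <- ok + 1L
  }
  expect_gte(ok, 4)
})

test_that("dendrogram JSON and partition TSV serializations are readable", {
  td <- withr::local_tempdir()
  d <- girvan_newman(bridge)
  write_dendrogram_json(d, file.path(td, "d.json"))
  back <- jsonlite::read_json(file.path(td, "d.json"), simplifyVector = TRUE)
  expect_equal(nrow(back$removals), nrow(d$removals))
  expect_equal(back$modularity, d$modularity, tolerance = 1e-9)
  p <- cut_max_modularity(d)
  write_partition(p, file.path(td, "p.tsv"))
  tab <- read.delim(file.path(td, "p.tsv"))
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$community_id)), 1:2)
})
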