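# topological node properties against brute-force oracles

net_from_edges <- function(nodes, from, to) {
  metabolic_network(nodes = nodes,
                    edges = data.frame(from = from, to = to,
                                       stringsAsFactors = FALSE))
}

path3 <- function() net_from_edges(c("K1", "K2", "K3"),
                                   c("K1", "K2"), c("K2", "K3"))

test_that("degree counts edges at the node; isolated nodes score 0", {
  net <- net_from_edges(c("K1", "K2", "K3", "K4"), c("K1", "K2"),
                        c("K2", "K3"))
  expect_identical(node_degree(net),
                   c(K1 = 1L, K2 = 2L, K3 = 1L, K4 = 0L))
})

test_that("self-loops count twice toward degree", {
  net <- net_from_edges(c("K1", "K2"), c("K1", "K1"), c("K1", "K2"))
  expect_identical(node_degree(net)[["K1"]], 3L)
})

test_that("betweenness of a 2-node graph is zero everywhere", {
  net <- net_from_edges(c("K1", "K2"), "K1", "K2")
  expect_equal(unname(betweenness_centrality(net)), c(0, 0))
})

test_that("the middle of a directed path mediates exactly one pair", {
  b <- betweenness_centrality(path3())
  expect_equal(b, c(K1 = 0, K2 = 1, K3 = 0))
  bn <- betweenness_centrality(path3(), normalized = TRUE)
  expect_equal(bn[["K2"]], 1 / 2)  # (n-1)(n-2) = 2 ordered pairs
})

test_that("clustering is 1 on a triangle and 0 at a star center", {
  tri <- net_from_edges(c("K1", "K2", "K3"),
                        c("K1", "K2", "K3"), c("K2", "K3", "K1"))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  star <- net_from_edges(c("C", "A", "B", "D"),
                         c("C", "C", "C"), c("A", "B", "D"))
  expect_equal(clustering_coefficient(star)[["C"]], 0)
})

test_that("pagerank is 1 on a singleton and uniform on a cycle", {
  one <- net_from_edges("K1", character(), character())
  expect_equal(pagerank(one), c(K1 = 1))
  cyc <- net_from_edges(c("K1", "K2", "K3"),
                        c("K1", "K2", "K3"), c("K2", "K3", "K1"))
  expect_equal(unname(pagerank(cyc)), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("pagerank of a 2-node chain matches the closed-form solve", {
  net <- net_from_edges(c("K1", "K2"), "K1", "K2")
  # x1 = 0.15/2 + 0.85 * x2/2 ; x2 = 0.15/2 + 0.85 * (x1 + x2/2)
  A <- matrix(c(1, -0.85 / 2, -0.85, 1 - 0.85 / 2), 2, 2, byrow = TRUE)
  x <- solve(A, rep(0.15 / 2, 2))
  x <- x / sum(x)
  expect_equal(unname(pagerank(net)), x, tolerance = 1e-8)
})

test_that("all four metrics match brute-force oracles on random digraphs", {
  set.seed(64)
  for (rep in 1:30) {
    net <- random_digraph(sample(3:10, 1), p = stats::runif(1, 0.1, 0.5))
    expect_identical(node_degree(net), orc_degree(net$nodes, net$edges))
    expect_equal(betweenness_centrality(net),
                 orc_betweenness(net$nodes, net$edges), tolerance = 1e-9)
    expect_equal(clustering_coefficient(net),
                 orc_clustering(net$nodes, net$edges), tolerance = 1e-9)
    pr <- pagerank(net)
    expect_equal(pr, orc_pagerank(net$nodes, net$edges), tolerance = 1e-8)
    expect_equal(sum(pr), 1, tolerance = 1e-6)
    cc <- clustering_coefficient(net)
    expect_true(all(cc >= 0 & cc <= 1))
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(65)
  net <- random_digraph(8, p = 0.3)
  perm <- sample(net$nodes)
  names(perm) <- net$nodes
  net2 <- metabolic_network(
    nodes = unname(perm[net$nodes]),
    edges = data.frame(from = unname(perm[net$edges$from]),
                       to = unname(perm[net$edges$to]),
                       stringsAsFactors = FALSE)
  )
  for (metric in list(node_degree, betweenness_centrality,
                      clustering_coefficient, pagerank)) {
    a <- metric(net)
    b <- metric(net2)
    expect_equal(unname(a[net$nodes]), unname(b[perm[net$nodes]]),
                 tolerance = 1e-9)
  }
})

test_that("pagerank raises a numeric error when iteration is capped too low", {
  set.seed(66)
  net <- random_digraph(8, p = 0.3)
  expect_error(pagerank(net, tol = 1e-14, max_iter = 2L),
               class = "konet_numeric_error")
})

with_abundance <- function(net, abund) {
  metabolic_network(
    nodes = net$nodes, edges = net$edges,
    node_attributes = data.frame(abundance = abund, row.names = net$nodes),
    kind = "ssn"
  )
}

test_that("analyze_topology attaches metrics and reports correlations", {
  set.seed(67)
  net <- random_digraph(9, p = 0.35)
  deg <- node_degree(net)
  # abundance proportional to degree forces a perfect rank correlation
  ssn <- with_abundance(net, (deg + 1) / sum(deg + 1))
  res <- analyze_topology(ssn)
  expect_setequal(
    names(res$network$node_attributes),
    c("abundance", "degree", "betweenness", "betweenness_normalized",
      "clustering", "pagerank")
  )
  row <- res$correlations[res$correlations$metric == "degree", ]
  expect_equal(row$spearman_rho, 1, tolerance = 1e-9)
  expect_equal(row$pearson_r, 1, tolerance = 1e-9)
})

test_that("constant abundance flags the correlation as undefined", {
  cyc <- net_from_edges(c("K1", "K2", "K3"),
                        c("K1", "K2", "K3"), c("K2", "K3", "K1"))
  res <- analyze_topology(with_abundance(cyc, rep(1 / 3, 3)))
  expect_true(all(grepl("zero variance", res$correlations$note)))
  expect_true(all(is.na(res$correlations$pearson_r)))
  expect_equal(res$table$pagerank, rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("an empty SSN yields an empty result", {
  empty <- metabolic_network(kind = "ssn")
  empty$node_attributes$abundance <- numeric(0)
  res <- analyze_topology(empty)
  expect_identical(nrow(res$table), 0L)
})

test_that("fewer than 3 nodes computes metrics but no correlations", {
  net <- net_from_edges(c("K1", "K2"), "K1", "K2")
  res <- analyze_topology(with_abundance(net, c(0.7, 0.3)))
  expect_true(all(grepl("fewer than 3", res$correlations$note)))
  expect_identical(res$table$degree, c(1L, 1L))
})
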