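#' Node degree
#'
#' Total degree (in + out) of every node in the directed network;
#' self-loops, when present, count twice.
#'
#' @param net a [metabolic_network()].
#' @return Named integer vector over nodes.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (n_nodes(net) == 0L) return(stats::setNames(integer(0), character(0)))
  g <- as_igraph(net)
  d <- igraph::degree(g, mode = "all", loops = TRUE)
  stats::setNames(as.integer(d[net$nodes]), net$nodes)
}

#' Shortest-path betweenness centrality
#'
#' The fraction of shortest paths between ordered node pairs that pass
#' through each node, on the directed graph: endpoints are excluded and
#' multiple shortest paths between a pair contribute fractionally. With
#' `normalized = TRUE` the raw value is divided by `(n-1)(n-2)`, the number
#' of ordered pairs a node can mediate.
#'
#' @param net a [metabolic_network()].
#' @param normalized divide by `(n-1)(n-2)`?
#' @return Named numeric vector over nodes.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "metabolic_network"))
  if (n_nodes(net) == 0L) return(stats::setNames(numeric(0), character(0)))
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = TRUE)
  b <- as.numeric(b[net$nodes])
  n <- n_nodes(net)
  if (normalized) {
    b <- if (n > 2) b / ((n - 1) * (n - 2)) else rep(0, n)
  }
  stats::setNames(b, net$nodes)
}

#' Local clustering coefficient
#'
#' Computed on the undirected projection of the network (edge direction,
#' multiplicity and self-loops dropped): the number of triangles through a
#' node divided by `k(k-1)/2` for undirected neighbor count `k`; nodes with
#' fewer than two neighbors score 0.
#'
#' @param net a [metabolic_network()].
#' @return Named numeric vector over nodes, values in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  if (n_nodes(net) == 0L) return(stats::setNames(numeric(0), character(0)))
  g <- as_igraph(net)
  u <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  cc <- igraph::transitivity(u, type = "local", isolates = "zero")
  cc <- stats::setNames(cc, igraph::V(u)$name)
  cc[is.na(cc)] <- 0
  stats::setNames(as.numeric(cc[net$nodes]), net$nodes)
}

#' PageRank by power iteration
#'
#' Stationary distribution of the damped random walk on the directed graph:
#' with probability `damping` the walker follows a uniformly chosen outgoing
#' edge, otherwise it teleports uniformly; mass on dangling nodes (out-degree
#' 0) is redistributed uniformly. Iteration stops when the L1 change drops
#' below `tol`; values sum to 1.
#'
#' @param net a nonempty [metabolic_network()].
#' @param damping damping factor, conventionally 0.85.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeding it raises a numeric error.
#' @return Named numeric vector over nodes, summing to 1.
#' @export
pagerank <- function(net, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(net, "metabolic_network"),
            damping >= 0, damping < 1, tol > 0, max_iter >= 1)
  n <- n_nodes(net)
  if (n == 0L) validation_error("pagerank requires a nonempty network")
  fi <- match(net$edges$from, net$nodes)
  ti <- match(net$edges$to, net$nodes)
  outdeg <- tabulate(fi, nbins = n)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    contrib <- numeric(n)
    if (length(fi)) {
      w <- x[fi] / outdeg[fi]
      agg <- rowsum(w, ti)
      contrib[as.integer(rownames(agg))] <- agg[, 1]
    }
    dangling <- sum(x[outdeg == 0])
    x_new <- (1 - damping) / n + damping * (contrib + dangling / n)
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new / sum(x_new)
      return(stats::setNames(x, net$nodes))
    }
    x <- x_new
  }
  numeric_error(sprintf(
    "pagerank did not converge within %d iterations (tol %g)", max_iter, tol
  ))
}

#' Topological analysis of a state-specific network
#'
#' Computes the four node properties (degree, betweenness centrality, local
#' clustering coefficient, PageRank), writes them back onto the network as
#' node attributes, and reports Pearson and Spearman correlations (with
#' two-sided p-values) between node abundance and each property. With fewer
#' than 3 nodes, or a zero-variance vector, the affected correlations are
#' reported as `NA` with a note; the metrics themselves are still computed.
#'
#' @param ssn a [metabolic_network()] whose nodes carry an `abundance`
#'   attribute (as produced by [construct_ssn()]).
#' @return A `topology_result`: list with `table` (one row per node:
#'   abundance, degree, betweenness, betweenness_normalized, clustering,
#'   pagerank), `correlations` (per metric: Pearson/Spearman estimates and
#'   p-values, plus a note), and `network` (the annotated SSN).
#' @export
analyze_topology <- function(ssn) {
  stopifnot(inherits(ssn, "metabolic_network"))
  if (!"abundance" %in% names(ssn$node_attributes)) {
    validation_error("analyze_topology needs an 'abundance' node attribute (is this an SSN?)")
  }
  nodes <- ssn$nodes
  if (length(nodes) == 0L) {
    empty <- data.frame(node = character(), abundance = numeric(),
                        degree = integer(), betweenness = numeric(),
                        betweenness_normalized = numeric(),
                        clustering = numeric(), pagerank = numeric())
    return(structure(list(table = empty, correlations = empty_corr(),
                          network = ssn), class = "topology_result"))
  }
  abund <- ssn$node_attributes[nodes, "abundance"]
  deg <- node_degree(ssn)
  btw <- betweenness_centrality(ssn, normalized = FALSE)
  btw_n <- betweenness_centrality(ssn, normalized = TRUE)
  cc <- clustering_coefficient(ssn)
  pr <- pagerank(ssn)
  tab <- data.frame(
    node = nodes, abundance = abund, degree = as.integer(deg[nodes]),
    betweenness = btw[nodes], betweenness_normalized = btw_n[nodes],
    clustering = cc[nodes], pagerank = pr[nodes],
    row.names = NULL, stringsAsFactors = FALSE
  )
  ssn$node_attributes$degree <- as.integer(deg[nodes])
  ssn$node_attributes$betweenness <- as.numeric(btw[nodes])
  ssn$node_attributes$betweenness_normalized <- as.numeric(btw_n[nodes])
  ssn$node_attributes$clustering <- as.numeric(cc[nodes])
  ssn$node_attributes$pagerank <- as.numeric(pr[nodes])
  metrics <- c("degree", "betweenness", "clustering", "pagerank")
  corr <- do.call(rbind, lapply(metrics, function(m_) {
    corr_row(m_, abund, tab[[m_]])
  }))
  structure(list(table = tab, correlations = corr, network = ssn),
            class = "topology_result")
}

empty_corr <- function() {
  data.frame(metric = character(), pearson_r = numeric(),
             pearson_p = numeric(), spearman_rho = numeric(),
             spearman_p = numeric(), note = character(),
             stringsAsFactors = FALSE)
}

corr_row <- function(metric, abund, value) {
  note <- ""
  if (length(abund) < 3L) {
    note <- "fewer than 3 nodes; correlation undefined"
  } else if (stats::sd(abund) == 0 || stats::sd(value) == 0) {
    note <- "zero variance; correlation undefined"
  }
  if (nzchar(note)) {
    return(data.frame(metric = metric, pearson_r = NA_real_,
                      pearson_p = NA_real_, spearman_rho = NA_real_,
                      spearman_p = NA_real_, note = note,
                      stringsAsFactors = FALSE))
  }
  pe <- stats::cor.test(abund, value, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(abund, value, method = "spearman", exact = FALSE)
  )
  data.frame(metric = metric,
             pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
             spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
             note = "", stringsAsFactors = FALSE)
}

#' @export
print.topology_result <- function(x, ...) {
  cat(sprintf("<topology_result> %d nodes\n", nrow(x$table)))
  if (nrow(x$correlations)) {
    cat("abundance vs topology:\n")
    print(x$correlations, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Scatter plots of abundance against each topological property
#'
#' @param x a `topology_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.topology_result <- function(x, ...) {
  tab <- x$table
  if (!nrow(tab)) {
    warning("empty topology result; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m_ in c("degree", "betweenness", "clustering", "pagerank")) {
    graphics::plot(tab[[m_]], tab$abundance, xlab = m_,
                   ylab = "relative abundance", ...)
  }
  invisible(x)
}
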