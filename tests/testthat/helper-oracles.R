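# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition (exhaustive enumeration, direct linear
# algebra) and share no code with the implementation they check.

# -- edge rule ---------------------------------------------------------------

# effective product/substrate sets restated from the reaction semantics
orc_eff <- function(rt, i, side) {
  if (rt$reversible[[i]]) {
    union(rt$substrate_ids[[i]], rt$product_ids[[i]])
  } else if (side == "prod") {
    rt$product_ids[[i]]
  } else {
    rt$substrate_ids[[i]]
  }
}

# enumerate every (r1, r2, ko_a, ko_b, compound) combination
orc_edges <- function(rt, exclude = character(), loops = FALSE) {
  from <- character()
  to <- character()
  nr <- nrow(rt)
  if (nr) {
    for (i in seq_len(nr)) {
      prods <- setdiff(orc_eff(rt, i, "prod"), exclude)
      for (j in seq_len(nr)) {
        subs <- setdiff(orc_eff(rt, j, "sub"), exclude)
        if (!length(intersect(prods, subs))) next
        for (a in rt$ko_ids[[i]]) {
          for (b in rt$ko_ids[[j]]) {
            if (a == b && !loops) next
            from <- c(from, a)
            to <- c(to, b)
          }
        }
      }
    }
  }
  out <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sorted_edges <- function(edges) {
  out <- edges[order(edges$from, edges$to), c("from", "to"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- graph metrics -----------------------------------------------------------

adj_list <- function(nodes, edges) {
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) out[[nd]] <- edges$to[edges$from == nd]
  out
}

bfs_dist <- function(adj, s) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1]
    q <- q[-1]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        q <- c(q, w)
      }
    }
  }
  d
}

# all shortest s->t paths by depth-first extension along the BFS distances
all_shortest_paths <- function(adj, d, s, t) {
  if (is.infinite(d[t])) return(list())
  paths <- list()
  extend <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (d[w] == d[v] + 1) extend(c(path, w))
    }
  }
  extend(s)
  paths
}

orc_betweenness <- function(nodes, edges) {
  adj <- adj_list(nodes, edges)
  b <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    d <- bfs_dist(adj, s)
    for (t in nodes) {
      if (s == t) next
      paths <- all_shortest_paths(adj, d, s, t)
      if (!length(paths)) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        b[inner] <- b[inner] + 1 / length(paths)
      }
    }
  }
  b
}

orc_degree <- function(nodes, edges) {
  tal <- table(factor(c(edges$from, edges$to), levels = nodes))
  stats::setNames(as.integer(tal), nodes)
}

orc_clustering <- function(nodes, edges) {
  und <- unique(data.frame(
    a = pmin(edges$from, edges$to), b = pmax(edges$from, edges$to),
    stringsAsFactors = FALSE
  ))
  und <- und[und$a != und$b, , drop = FALSE]
  linked <- function(x, y) {
    any(und$a == pmin(x, y) & und$b == pmax(x, y))
  }
  vapply(nodes, function(v) {
    nb <- union(und$b[und$a == v], und$a[und$b == v])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (linked(nb[i], nb[j])) tri <- tri + 1
      }
    }
    tri / (k * (k - 1) / 2)
  }, 0)
}

# stationarity system solved directly: x = (1-d)/n + d * T x
orc_pagerank <- function(nodes, edges, damping = 0.85) {
  n <- length(nodes)
  Tm <- matrix(0, n, n, dimnames = list(nodes, nodes))
  outdeg <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(nrow(edges))) {
    outdeg[edges$from[i]] <- outdeg[edges$from[i]] + 1
  }
  for (i in seq_len(nrow(edges))) {
    Tm[edges$to[i], edges$from[i]] <-
      Tm[edges$to[i], edges$from[i]] + 1 / outdeg[edges$from[i]]
  }
  Tm[, outdeg == 0] <- 1 / n
  x <- solve(diag(n) - damping * Tm, rep((1 - damping) / n, n))
  stats::setNames(x / sum(x), nodes)
}

empty_rec <- function() {
  out <- data.frame(read_id = character(), subject_id = character(),
                    e_value = numeric(), stringsAsFactors = FALSE)
  out$ko_ids <- list()
  out
}

# -- random generators -------------------------------------------------------

random_digraph <- function(n, p = 0.25, loops = FALSE) {
  nodes <- sprintf("K%05d", seq_len(n))
  g <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  if (!loops) g <- g[g$from != g$to, ]
  g <- g[stats::runif(nrow(g)) < p, , drop = FALSE]
  rownames(g) <- NULL
  metabolic_network(nodes = nodes, edges = g, kind = "reference")
}

random_reaction_table <- function(max_reactions = 30, max_kos = 15,
                                  max_compounds = 10) {
  nr <- sample(1:max_reactions, 1)
  nk <- sample(2:max_kos, 1)
  nc <- sample(2:max_compounds, 1)
  kos <- sprintf("K%05d", seq_len(nk))
  cmps <- sprintf("C%05d", seq_len(nc))
  ko_l <- replicate(nr, sample(kos, sample(1:2, 1)), simplify = FALSE)
  sub_l <- vector("list", nr)
  prod_l <- vector("list", nr)
  for (i in seq_len(nr)) {
    ns <- min(sample(1:2, 1), nc - 1)
    np <- min(sample(1:2, 1), nc - ns)
    both <- sample(cmps, ns + np)
    sub_l[[i]] <- both[seq_len(ns)]
    prod_l[[i]] <- both[-seq_len(ns)]
  }
  reaction_table(sprintf("R%05d", seq_len(nr)),
                 stats::runif(nr) < 0.3, ko_l, sub_l, prod_l)
}

random_profile <- function(sample_id = "s1", n_reads = 30, n_kos = 8) {
  kos <- sprintf("K%05d", seq_len(n_kos))
  evals <- c(1e-30, 1e-20, 1e-10)  # coarse grid so ties happen often
  rows <- list()
  for (r in seq_len(n_reads)) {
    nh <- sample(1:3, 1)
    rows[[r]] <- data.frame(
      read_id = sprintf("r%04d", r),
      subject_id = sprintf("sub%04d_%d", r, seq_len(nh)),
      e_value = sample(evals, nh, replace = TRUE),
      stringsAsFactors = FALSE
    )
    rows[[r]]$ko_ids <- replicate(nh, sample(kos, sample(1:2, 1)),
                                  simplify = FALSE)
  }
  annotation_profile(sample_id, do.call(rbind, rows))
}

random_abundance_table <- function(n_samples = 3, n_kos = 5,
                                   states = NULL) {
  counts <- matrix(stats::rpois(n_samples * n_kos, 8) +
                     stats::runif(n_samples * n_kos),
                   nrow = n_samples,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   sprintf("K%05d", seq_len(n_kos))))
  abundance_table(counts, state_labels = states)
}
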