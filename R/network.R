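#' Metabolic network objects
#'
#' A `metabolic_network` is a simple directed graph over KO identifiers.
#' A directed edge A -> B means that some product metabolite of a reaction
#' catalyzed by enzyme A is a substrate metabolite of a reaction catalyzed by
#' enzyme B. Each edge keeps an evidence list of the `(compound,
#' from_reaction, to_reaction)` triples that created it; parallel evidence is
#' collapsed onto one edge. `kind` tags the network as `"reference"`,
#' `"ssn"` (state-specific network) or `"differential"`.
#'
#' @param nodes character vector of KO ids.
#' @param edges `data.frame` with character columns `from`, `to`.
#' @param evidence list (one element per edge row) of `data.frame`s with
#'   columns `compound`, `from_reaction`, `to_reaction`; may be `NULL` for
#'   derived networks.
#' @param node_attributes `data.frame` keyed by `rownames` = node ids.
#' @param kind one of `"reference"`, `"ssn"`, `"differential"`.
#' @return A `metabolic_network` object.
#' @export
metabolic_network <- function(nodes = character(), edges = empty_edges(),
                              evidence = NULL,
                              node_attributes = NULL, kind = "reference") {
  kind <- match.arg(kind, c("reference", "ssn", "differential"))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) validation_error("duplicate node ids")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges <- edges[, c("from", "to")]
  if (nrow(edges)) {
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
      validation_error("duplicate directed edges")
    }
    miss <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(miss)) {
      validation_error(sprintf(
        "edge endpoint(s) not in node set: %s", paste(miss, collapse = ", ")
      ))
    }
  }
  if (is.null(node_attributes)) {
    node_attributes <- data.frame(row.names = nodes)
  } else {
    stopifnot(identical(sort(rownames(node_attributes)), sort(nodes)))
    node_attributes <- node_attributes[nodes, , drop = FALSE]
  }
  if (!is.null(evidence)) stopifnot(length(evidence) == nrow(edges))
  structure(
    list(
      nodes = nodes, edges = edges, evidence = evidence,
      node_attributes = node_attributes, kind = kind
    ),
    class = "metabolic_network"
  )
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
}

#' @rdname metabolic_network
#' @param net a `metabolic_network`.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname metabolic_network
#' @export
n_edges <- function(net) nrow(net$edges)

# substrate/product sets as seen by the edge rule: a reversible reaction can
# run either way, so both sides act as substrates and as products
effective_products <- function(reactions, i) {
  if (reactions$reversible[[i]]) {
    union(reactions$substrate_ids[[i]], reactions$product_ids[[i]])
  } else {
    reactions$product_ids[[i]]
  }
}

effective_substrates <- function(reactions, i) {
  if (reactions$reversible[[i]]) {
    union(reactions$substrate_ids[[i]], reactions$product_ids[[i]])
  } else {
    reactions$substrate_ids[[i]]
  }
}

#' Construct the enzyme-level reference metabolic network
#'
#' Builds the directed KO graph from a reaction table: nodes are all KOs
#' catalyzing any reaction, and a directed edge A -> B exists iff some
#' compound (outside `exclude_compounds`) is an effective product of a
#' reaction catalyzed by A and an effective substrate of a reaction catalyzed
#' by B. For reversible reactions both sides count as substrates and as
#' products. Every `(compound, from_reaction, to_reaction)` triple supporting
#' an edge is retained as edge evidence.
#'
#' Currency metabolites (ATP, water, common cofactors) are not excluded by
#' default; pass their compound ids in `exclude_compounds` to avoid the
#' near-complete graphs they induce. Self-loops (A -> A) are dropped unless
#' `allow_self_loops = TRUE`.
#'
#' @param reactions a [reaction_table()].
#' @param exclude_compounds character vector of compound ids to ignore when
#'   matching products to substrates.
#' @param allow_self_loops keep edges whose two endpoints are the same KO?
#' @return A [metabolic_network()] with `kind = "reference"`.
#' @examples
#' rt <- reaction_table(
#'   c("R1", "R2"), c(FALSE, FALSE),
#'   ko_ids = list("K00001", "K00002"),
#'   substrate_ids = list("C00001", "C00002"),
#'   product_ids = list("C00002", "C00003")
#' )
#' net <- construct_metabolic_network(rt)
#' net$edges  # K00001 -> K00002 via C00002
#' @export
construct_metabolic_network <- function(reactions,
                                        exclude_compounds = character(),
                                        allow_self_loops = FALSE) {
  stopifnot(inherits(reactions, "reaction_table"))
  nodes <- sort(unique(unlist(reactions$ko_ids)))
  if (nrow(reactions) == 0L) {
    return(metabolic_network(kind = "reference"))
  }
  # index: compound -> (ko, reaction) producer/consumer pairs
  producers <- list()
  consumers <- list()
  add_pairs <- function(index, compounds, kos, rid) {
    for (c_ in compounds) {
      index[[c_]] <- rbind(
        index[[c_]],
        data.frame(ko = kos, reaction = rid, stringsAsFactors = FALSE)
      )
    }
    index
  }
  for (i in seq_len(nrow(reactions))) {
    rid <- reactions$reaction_id[[i]]
    kos <- reactions$ko_ids[[i]]
    prods <- setdiff(effective_products(reactions, i), exclude_compounds)
    subs <- setdiff(effective_substrates(reactions, i), exclude_compounds)
    producers <- add_pairs(producers, prods, kos, rid)
    consumers <- add_pairs(consumers, subs, kos, rid)
  }
  triples <- list()
  for (c_ in intersect(names(producers), names(consumers))) {
    p <- producers[[c_]]
    s <- consumers[[c_]]
    g <- expand.grid(pi = seq_len(nrow(p)), si = seq_len(nrow(s)))
    triples[[c_]] <- data.frame(
      from = p$ko[g$pi], to = s$ko[g$si],
      compound = c_,
      from_reaction = p$reaction[g$pi], to_reaction = s$reaction[g$si],
      stringsAsFactors = FALSE
    )
  }
  tr <- if (length(triples)) do.call(rbind, triples) else
    data.frame(from = character(), to = character(), compound = character(),
               from_reaction = character(), to_reaction = character())
  if (!allow_self_loops) tr <- tr[tr$from != tr$to, , drop = FALSE]
  if (nrow(tr) == 0L) {
    return(metabolic_network(nodes = nodes, kind = "reference"))
  }
  key <- paste(tr$from, tr$to, sep = "\r")
  ord <- order(tr$from, tr$to, tr$compound, tr$from_reaction, tr$to_reaction)
  tr <- tr[ord, ]
  key <- key[ord]
  first <- !duplicated(key)
  edges <- tr[first, c("from", "to")]
  rownames(edges) <- NULL
  evidence <- lapply(split(tr[, c("compound", "from_reaction", "to_reaction")],
                           factor(key, levels = key[first])),
                     function(d) {
                       d <- unique(d)
                       rownames(d) <- NULL
                       d
                     })
  names(evidence) <- NULL
  metabolic_network(nodes = nodes, edges = edges, evidence = evidence,
                    kind = "reference")
}

#' Convert a metabolic network to an igraph graph
#'
#' Node attributes become vertex attributes; edge evidence is flattened to a
#' character attribute of `compound:from_reaction>to_reaction` tokens joined
#' by `"|"`.
#'
#' @param net a [metabolic_network()].
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  vdf <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  if (ncol(net$node_attributes)) {
    vdf <- cbind(vdf, net$node_attributes)
  }
  edf <- net$edges
  if (!is.null(net$evidence) && nrow(edf)) {
    edf$evidence <- vapply(net$evidence, function(d) {
      paste(sprintf("%s:%s>%s", d$compound, d$from_reaction, d$to_reaction),
            collapse = "|")
    }, "")
  }
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network kind=%s> %d nodes, %d directed edges\n",
    x$kind, n_nodes(x), n_edges(x)
  ))
  if (ncol(x$node_attributes)) {
    cat("  node attributes:", paste(names(x$node_attributes), collapse = ", "),
        "\n")
  }
  invisible(x)
}
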