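#' Export a metabolic network to GraphML
#'
#' Node attributes are written as GraphML node data; edge evidence is
#' flattened to a string attribute (see [as_igraph()]). The file re-imports
#' with [read_graphml()] to an attribute-equal network.
#'
#' @param net a [metabolic_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::graph_attr(g, "kind") <- net$kind
  if (!is.null(net$sample_id)) {
    igraph::graph_attr(g, "sample_id") <- net$sample_id
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a metabolic network from GraphML
#'
#' Inverse of [write_graphml()]: rebuilds nodes, directed edges, node
#' attributes, and the edge evidence list (when present).
#'
#' @param path a GraphML file written by [write_graphml()] (any directed
#'   GraphML graph with named nodes is accepted).
#' @return A [metabolic_network()].
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  node_attributes <- data.frame(row.names = nodes)
  for (a in vattrs) node_attributes[[a]] <- igraph::vertex_attr(g, a)
  evidence <- NULL
  if ("evidence" %in% igraph::edge_attr_names(g)) {
    evidence <- lapply(igraph::E(g)$evidence, parse_evidence)
  }
  kind <- igraph::graph_attr(g, "kind") %||% "reference"
  net <- metabolic_network(nodes = nodes, edges = edges, evidence = evidence,
                           node_attributes = node_attributes, kind = kind)
  sid <- igraph::graph_attr(g, "sample_id")
  if (!is.null(sid)) net$sample_id <- sid
  net
}

parse_evidence <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(compound = character(), from_reaction = character(),
                      to_reaction = character(), stringsAsFactors = FALSE))
  }
  toks <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], "[:>]")
  data.frame(
    compound = vapply(toks, `[`, "", 1),
    from_reaction = vapply(toks, `[`, "", 2),
    to_reaction = vapply(toks, `[`, "", 3),
    stringsAsFactors = FALSE
  )
}

#' Export a metabolic network as Cytoscape.js JSON
#'
#' Writes `{"elements": {"nodes": [...], "edges": [...]}}` with node
#' attributes under each node's `data` and the flattened evidence string
#' under each edge's `data`.
#'
#' @param net a [metabolic_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytoscape_json <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  nodes <- lapply(net$nodes, function(nd) {
    data <- c(list(id = nd),
              as.list(net$node_attributes[nd, , drop = FALSE]))
    list(data = data)
  })
  ev <- if (!is.null(net$evidence)) {
    vapply(net$evidence, function(d) {
      paste(sprintf("%s:%s>%s", d$compound, d$from_reaction, d$to_reaction),
            collapse = "|")
    }, "")
  } else rep(NA_character_, n_edges(net))
  edges <- lapply(seq_len(n_edges(net)), function(i) {
    data <- list(source = net$edges$from[i], target = net$edges$to[i])
    if (!is.na(ev[i])) data$evidence <- ev[i]
    list(data = data)
  })
  obj <- list(elements = list(nodes = nodes, edges = edges),
              data = list(kind = net$kind))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a topology result as TSV
#'
#' One row per node with abundance and all computed metrics.
#'
#' @param result a `topology_result` from [analyze_topology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_tsv <- function(result, path) {
  stopifnot(inherits(result, "topology_result"))
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a differential result as TSV
#'
#' One row per KO with the score, direction call, and the method's raw
#' intermediate columns.
#'
#' @param result a `differential_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_tsv <- function(result, path) {
  stopifnot(inherits(result, "differential_result"))
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
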