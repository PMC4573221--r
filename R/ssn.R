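#' Construct a state-specific network (SSN)
#'
#' Induces the subgraph of the reference metabolic network on the KOs
#' detected in one sample: nodes are reference KOs whose relative abundance
#' in the sample exceeds `min_abundance` (default 0, i.e. any KO identified
#' at all), and edges are exactly the reference edges with both endpoints
#' retained. Each node carries its relative abundance (attribute
#' `abundance`) and raw count (attribute `count`). KOs observed in the
#' sample but absent from the reference are not added; their ids are
#' reported via a message and kept in the `unmatched_kos` field.
#'
#' @param table an [abundance_table()].
#' @param sample_id which sample to induce the network for.
#' @param reference a [metabolic_network()] with `kind = "reference"`.
#' @param min_abundance relative-abundance threshold; a node is kept when
#'   its relative abundance is strictly greater than this value.
#' @return A [metabolic_network()] with `kind = "ssn"`, plus fields
#'   `sample_id` and `unmatched_kos`.
#' @export
construct_ssn <- function(table, sample_id, reference, min_abundance = 0) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(reference, "metabolic_network"))
  if (!identical(reference$kind, "reference")) {
    validation_error("'reference' must be a network of kind 'reference'")
  }
  if (!is_string(sample_id) || !(sample_id %in% table$sample_ids)) {
    lookup_error(sprintf("unknown sample_id '%s'", sample_id))
  }
  stopifnot(is.numeric(min_abundance), min_abundance >= 0)
  rel <- table$relative[sample_id, ]
  present <- table$ko_ids[rel > min_abundance]
  nodes <- intersect(reference$nodes, present)
  unmatched <- setdiff(present, reference$nodes)
  if (length(unmatched)) {
    message(sprintf(
      "sample %s: %d KO(s) not in the reference network: %s",
      sample_id, length(unmatched),
      paste(utils::head(unmatched, 5), collapse = ", ")
    ))
  }
  keep <- reference$edges$from %in% nodes & reference$edges$to %in% nodes
  edges <- reference$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  evidence <- if (!is.null(reference$evidence)) reference$evidence[keep]
  attrs <- data.frame(
    abundance = as.numeric(rel[nodes]),
    count = as.numeric(table$counts[sample_id, nodes]),
    row.names = nodes
  )
  net <- metabolic_network(nodes = nodes, edges = edges, evidence = evidence,
                           node_attributes = attrs, kind = "ssn")
  net$sample_id <- sample_id
  net$unmatched_kos <- unmatched
  net
}
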