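# Differential abundance scoring between two biological states.
# All three methods operate on the relative-abundance matrix of an
# abundance_table and return a differential_result.

state_samples <- function(table, state) {
  if (is.null(table$state_labels)) {
    validation_error("abundance table carries no state labels")
  }
  s <- table$sample_ids[table$state_labels == state]
  if (length(s) == 0L) {
    validation_error(sprintf("state '%s' has no samples", state))
  }
  s
}

new_differential_result <- function(method, df, threshold, state1, state2) {
  # direction is 'unchanged' exactly when the score does not exceed the
  # threshold; otherwise the method's sign decides enriched/depleted
  sgn <- df$sign
  sgn[is.na(sgn)] <- 0
  df$direction <- ifelse(
    !is.na(df$score) & df$score > threshold & sgn != 0,
    ifelse(sgn > 0, "enriched", "depleted"),
    "unchanged"
  )
  df$sign <- NULL
  rownames(df) <- NULL
  structure(
    list(method = method, table = df, threshold_used = threshold,
         state1 = state1, state2 = state2),
    class = "differential_result"
  )
}

#' Odds-ratio differential abundance score
#'
#' For each KO `k`, the odds ratio contrasts `k`'s abundance odds between
#' the two states:
#' `OR_k = [sum_{s in state1} A_sk / sum_{s in state1} sum_{i != k} A_si] /
#'         [sum_{s in state2} A_sk / sum_{s in state2} sum_{i != k} A_si]`
#' over relative abundances `A_sk`, with `pseudocount` added to each of the
#' four sums. The score is `|log2(OR_k)|`; a KO is enriched in `state1` when
#' `OR_k > 1`. With `pseudocount = 0`, KOs absent from one state get an
#' infinite score and are flagged; a state with zero total abundance raises
#' a numeric error.
#'
#' @param table an [abundance_table()] with state labels.
#' @param state1,state2 the two state labels to contrast.
#' @param pseudocount nonnegative value stabilizing zero sums (relative
#'   abundance scale). Default `1e-6`.
#' @param threshold scores at or below this are called `unchanged`.
#'   Default 0.
#' @return A `differential_result` with per-KO columns `or`, `log2_or`,
#'   `score`, `direction`.
#' @export
score_or <- function(table, state1, state2, pseudocount = 1e-6,
                     threshold = 0) {
  stopifnot(inherits(table, "abundance_table"), pseudocount >= 0)
  s1 <- state_samples(table, state1)
  s2 <- state_samples(table, state2)
  A <- table$relative
  num1 <- colSums(A[s1, , drop = FALSE])
  num2 <- colSums(A[s2, , drop = FALSE])
  den1 <- sum(num1) - num1  # sum over samples of sum over other KOs
  den2 <- sum(num2) - num2
  if (pseudocount == 0 && (sum(num1) == 0 || sum(num2) == 0)) {
    numeric_error("a state has zero total abundance and pseudocount is 0")
  }
  or <- ((num1 + pseudocount) / (den1 + pseudocount)) /
    ((num2 + pseudocount) / (den2 + pseudocount))
  log2_or <- log2(or)
  score <- abs(log2_or)
  if (any(!is.finite(score))) {
    warning(sprintf(
      "%d KO(s) have infinite OR score (absent from one state, pseudocount 0)",
      sum(!is.finite(score))
    ), call. = FALSE)
  }
  df <- data.frame(ko = table$ko_ids, or = unname(or),
                   log2_or = unname(log2_or), score = unname(score),
                   sign = unname(sign(log2_or)), stringsAsFactors = FALSE)
  new_differential_result("OR", df, threshold, state1, state2)
}

# within-sample abundance ranks: 1 = most abundant; ties (including the
# zero-abundance block) get the average rank
sample_ranks <- function(A) {
  t(apply(A, 1, function(x) rank(-x, ties.method = "average")))
}

#' Mean-rank differential abundance score
#'
#' KO abundances are ranked within each sample from most abundant (rank 1)
#' downward, ties averaged. The score is the absolute difference between a
#' KO's mean rank over `state1` samples and over `state2` samples; a KO is
#' enriched in `state1` when its mean rank there is smaller.
#'
#' @inheritParams score_or
#' @return A `differential_result` with per-KO columns `mean_rank_state1`,
#'   `mean_rank_state2`, `score`, `direction`.
#' @export
score_rank <- function(table, state1, state2, threshold = 0) {
  stopifnot(inherits(table, "abundance_table"))
  s1 <- state_samples(table, state1)
  s2 <- state_samples(table, state2)
  R <- sample_ranks(table$relative)
  mr1 <- colMeans(R[s1, , drop = FALSE])
  mr2 <- colMeans(R[s2, , drop = FALSE])
  df <- data.frame(ko = table$ko_ids,
                   mean_rank_state1 = unname(mr1),
                   mean_rank_state2 = unname(mr2),
                   score = unname(abs(mr1 - mr2)),
                   sign = unname(sign(mr2 - mr1)),  # smaller rank = enriched
                   stringsAsFactors = FALSE)
  new_differential_result("RANK", df, threshold, state1, state2)
}

# base-2 Shannon entropy with 0*log0 = 0
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

jsd2_bernoulli <- function(p, q) {
  P <- c(p, 1 - p)
  Q <- c(q, 1 - q)
  entropy2((P + Q) / 2) - (entropy2(P) + entropy2(Q)) / 2
}

#' Jensen-Shannon divergence differential abundance score
#'
#' Each KO's mean relative abundance over the samples of a state is read as
#' the parameter of a Bernoulli distribution ("fraction of enzymatic reads
#' that are this KO"); the score is the base-2 Jensen-Shannon divergence
#' between the two states' Bernoulli distributions, bounded in `[0, 1]`.
#' A KO is enriched in `state1` when its mean relative abundance is larger
#' there.
#'
#' @inheritParams score_or
#' @return A `differential_result` with per-KO columns `p_state1`,
#'   `p_state2`, `score`, `direction`.
#' @export
score_jsd <- function(table, state1, state2, threshold = 0) {
  stopifnot(inherits(table, "abundance_table"))
  s1 <- state_samples(table, state1)
  s2 <- state_samples(table, state2)
  p <- colMeans(table$relative[s1, , drop = FALSE])
  q <- colMeans(table$relative[s2, , drop = FALSE])
  score <- vapply(seq_along(p), function(i) jsd2_bernoulli(p[i], q[i]), 0)
  df <- data.frame(ko = table$ko_ids, p_state1 = unname(p),
                   p_state2 = unname(q), score = score,
                   sign = unname(sign(p - q)), stringsAsFactors = FALSE)
  new_differential_result("JSD", df, threshold, state1, state2)
}

#' Differential network analysis between two states
#'
#' Takes state-specific networks of samples from two biological states,
#' merges them into one community-level network (union of nodes and edges),
#' scores every KO's differential abundance with the chosen method, and
#' colors nodes by call: enriched in `state1` = red (`#FF0000`), depleted =
#' green (`#00AA00`), unchanged = neutral gray (`#CCCCCC`).
#'
#' @param ssns list of SSNs from [construct_ssn()]; every SSN's sample must
#'   carry a state label in `table`, and both states need at least one SSN.
#' @param table the [abundance_table()] the SSNs were induced from (with
#'   state labels).
#' @param state1,state2 state labels to contrast; default: the two distinct
#'   states of the provided SSNs, in label order of appearance.
#' @param method `"or"`, `"rank"` or `"jsd"`.
#' @param threshold absolute score above which a KO is called
#'   enriched/depleted; default `NULL` uses the 0.9 quantile of the nonzero
#'   scores.
#' @param pseudocount passed to [score_or()].
#' @param quantile quantile defining the default threshold.
#' @return A `differential_analysis`: list with `network` (a
#'   [metabolic_network()] of `kind = "differential"` whose nodes carry
#'   `score`, `direction`, `color`) and `result` (the
#'   `differential_result`).
#' @export
differential_analyze <- function(ssns, table, state1 = NULL, state2 = NULL,
                                 method = c("or", "rank", "jsd"),
                                 threshold = NULL, pseudocount = 1e-6,
                                 quantile = 0.9) {
  method <- match.arg(method)
  stopifnot(is.list(ssns), length(ssns) >= 1L,
            all(vapply(ssns, inherits, TRUE, "metabolic_network")),
            inherits(table, "abundance_table"))
  if (any(vapply(ssns, function(s) !identical(s$kind, "ssn"), TRUE))) {
    validation_error("every element of 'ssns' must be of kind 'ssn'")
  }
  samples <- vapply(ssns, function(s) s$sample_id %||% NA_character_, "")
  if (anyNA(samples)) validation_error("every SSN must carry a sample_id")
  if (is.null(table$state_labels)) {
    validation_error("abundance table carries no state labels")
  }
  states <- unname(table$state_labels[samples])
  if (is.null(state1) || is.null(state2)) {
    u <- unique(states)
    if (length(u) != 2L) {
      validation_error("SSNs must span exactly two states (or pass state1/state2)")
    }
    state1 <- state1 %||% u[1]
    state2 <- state2 %||% u[2]
  }
  for (st in c(state1, state2)) {
    if (!any(states == st)) {
      validation_error(sprintf("state '%s' has no SSN", st))
    }
  }
  use <- states %in% c(state1, state2)
  ssns <- ssns[use]
  samples <- samples[use]
  # restrict scoring to the samples the SSNs came from
  sub <- abundance_table(
    table$counts[samples, , drop = FALSE],
    state_labels = table$state_labels[samples]
  )
  res <- switch(method,
    or = score_or(sub, state1, state2, pseudocount = pseudocount),
    rank = score_rank(sub, state1, state2),
    jsd = score_jsd(sub, state1, state2)
  )
  scores <- stats::setNames(res$table$score, res$table$ko)
  finite_nz <- scores[is.finite(scores) & scores > 0]
  thr <- threshold %||%
    (if (length(finite_nz)) unname(stats::quantile(finite_nz, quantile)) else 0)
  # re-call directions under the final threshold
  sgn <- direction_sign(res)
  res$table$direction <- ifelse(
    res$table$score <= thr | sgn == 0, "unchanged",
    ifelse(sgn > 0, "enriched", "depleted")
  )
  res$threshold_used <- thr
  # union network over all SSNs
  nodes <- sort(unique(unlist(lapply(ssns, function(s) s$nodes))))
  all_edges <- unique(do.call(rbind, c(
    list(empty_edges()), lapply(ssns, function(s) s$edges)
  )))
  rownames(all_edges) <- NULL
  dir_ <- stats::setNames(res$table$direction, res$table$ko)[nodes]
  dir_[is.na(dir_)] <- "unchanged"
  attrs <- data.frame(
    score = as.numeric(scores[nodes]),
    direction = unname(dir_),
    color = unname(c(enriched = "#FF0000", depleted = "#00AA00",
                     unchanged = "#CCCCCC")[dir_]),
    row.names = nodes, stringsAsFactors = FALSE
  )
  attrs$score[is.na(attrs$score)] <- 0
  net <- metabolic_network(nodes = nodes, edges = all_edges,
                           node_attributes = attrs, kind = "differential")
  structure(list(network = net, result = res),
            class = "differential_analysis")
}

# per-KO enrichment sign recoverable from each method's raw columns
direction_sign <- function(res) {
  with(res$table, switch(res$method,
    OR = sign(log2_or),
    RANK = sign(mean_rank_state2 - mean_rank_state1),
    JSD = sign(p_state1 - p_state2)
  ))
}

#' @export
print.differential_result <- function(x, ...) {
  tab <- table(factor(x$table$direction,
                      c("enriched", "depleted", "unchanged")))
  cat(sprintf(
    "<differential_result method=%s> %s vs %s, %d KOs (threshold %.4g): %d enriched, %d depleted, %d unchanged\n",
    x$method, x$state1, x$state2, nrow(x$table), x$threshold_used,
    tab[["enriched"]], tab[["depleted"]], tab[["unchanged"]]
  ))
  top <- utils::head(x$table[order(-x$table$score), ], 5)
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.differential_analysis <- function(x, ...) {
  print(x$result)
  print(x$network)
  invisible(x)
}
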