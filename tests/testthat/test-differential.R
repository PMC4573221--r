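# differential abundance scoring: OR, RANK, JSD and the colored network

tab2 <- function(m, states) {
  abundance_table(m, state_labels = states)
}

two_state_tab <- function(row1, row2) {
  m <- rbind(a1 = row1, b1 = row2)
  colnames(m) <- sprintf("K%d", seq_along(row1))
  tab2(m, c(a1 = "A", b1 = "B"))
}

test_that("identical states give OR = 1 and all-unchanged calls", {
  m <- rbind(a1 = c(2, 1, 1), a2 = c(2, 1, 1),
             b1 = c(2, 1, 1), b2 = c(2, 1, 1))
  colnames(m) <- c("K1", "K2", "K3")
  tab <- tab2(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  res <- score_or(tab, "A", "B", pseudocount = 0)
  expect_equal(res$table$or, rep(1, 3))
  expect_equal(res$table$score, rep(0, 3))
  expect_true(all(res$table$direction == "unchanged"))
})

test_that("the two-KO hand example gives OR = 4 and score 2", {
  tab <- two_state_tab(c(2, 1), c(1, 2))
  res <- score_or(tab, "A", "B", pseudocount = 0)
  k1 <- res$table[res$table$ko == "K1", ]
  expect_equal(k1$or, 4)
  expect_equal(k1$score, 2)
  expect_identical(k1$direction, "enriched")
  expect_identical(res$table$direction[res$table$ko == "K2"], "depleted")
})

test_that("swapping state labels inverts OR, keeps scores, flips directions", {
  set.seed(21)
  for (rep in 1:8) {
    states <- stats::setNames(rep(c("A", "B"), each = 3), sprintf("s%02d", 1:6))
    tab <- random_abundance_table(6, 7, states = states)
    fwd <- score_or(tab, "A", "B")
    rev_ <- score_or(tab, "B", "A")
    expect_equal(rev_$table$or, 1 / fwd$table$or, tolerance = 1e-9)
    expect_equal(rev_$table$score, fwd$table$score, tolerance = 1e-9)
    flip <- c(enriched = "depleted", depleted = "enriched",
              unchanged = "unchanged")
    expect_identical(rev_$table$direction,
                     unname(flip[fwd$table$direction]))
  }
})

test_that("zero-in-state KOs: pseudocount keeps OR finite, zero flags infinity", {
  m <- rbind(a1 = c(4, 0), b1 = c(2, 2))
  colnames(m) <- c("K1", "K2")
  tab <- tab2(m, c(a1 = "A", b1 = "B"))
  expect_warning(res0 <- score_or(tab, "A", "B", pseudocount = 0), "infinite")
  expect_true(is.infinite(res0$table$score[res0$table$ko == "K2"]))
  res <- score_or(tab, "A", "B", pseudocount = 1e-6)
  expect_true(all(is.finite(res$table$score)))
  expect_identical(res$table$direction[res$table$ko == "K2"], "depleted")
})

test_that("a state of all-zero abundance with pseudocount 0 is a numeric error", {
  m <- rbind(a1 = c(0, 0), b1 = c(1, 1))
  colnames(m) <- c("K1", "K2")
  tab <- suppressWarnings(tab2(m, c(a1 = "A", b1 = "B")))
  expect_error(score_or(tab, "A", "B", pseudocount = 0),
               class = "konet_numeric_error")
})

test_that("rank reversal between two samples scores 1 for both KOs", {
  tab <- two_state_tab(c(2, 1), c(1, 2))
  res <- score_rank(tab, "A", "B")
  expect_equal(res$table$score, c(1, 1))
  expect_identical(res$table$direction, c("enriched", "depleted"))
  expect_equal(res$table$mean_rank_state1, c(1, 2))
})

test_that("full within-sample ties give every KO the average rank and score 0", {
  m <- rbind(a1 = c(1, 1, 1), b1 = c(2, 2, 2))
  colnames(m) <- c("K1", "K2", "K3")
  tab <- tab2(m, c(a1 = "A", b1 = "B"))
  res <- score_rank(tab, "A", "B")
  expect_equal(res$table$mean_rank_state1, rep(2, 3))  # (m+1)/2
  expect_equal(res$table$score, rep(0, 3))
})

test_that("rank scores are invariant under strictly monotone transforms", {
  set.seed(22)
  states <- stats::setNames(rep(c("A", "B"), each = 2), sprintf("s%02d", 1:4))
  tab <- random_abundance_table(4, 6, states = states)
  res1 <- score_rank(tab, "A", "B")
  warped <- abundance_table(exp(3 * tab$counts), state_labels = states)
  res2 <- score_rank(warped, "A", "B")
  expect_equal(res1$table$score, res2$table$score)
})

test_that("JSD matches hand-computed values and its bounds", {
  tab <- two_state_tab(c(1, 1), c(1, 1))
  expect_equal(score_jsd(tab, "A", "B")$table$score, c(0, 0))
  # disjoint support: p = 1 vs q = 0 reaches the base-2 bound of 1
  m <- rbind(a1 = c(1, 0), b1 = c(0, 1))
  colnames(m) <- c("K1", "K2")
  disjoint <- tab2(m, c(a1 = "A", b1 = "B"))
  expect_equal(score_jsd(disjoint, "A", "B")$table$score, c(1, 1))
  # p = 0.5, q = 1: H(0.75, 0.25) - 1/2
  m2 <- rbind(a1 = c(1, 1), b1 = c(1, 0))
  colnames(m2) <- c("K1", "K2")
  half <- tab2(m2, c(a1 = "A", b1 = "B"))
  res <- score_jsd(half, "A", "B")
  expect_equal(res$table$score[1], 0.311278, tolerance = 1e-6)
  expect_identical(res$table$direction[1], "depleted")
})

test_that("JSD is symmetric, bounded in [0,1], and 0 iff p = q", {
  set.seed(23)
  states <- stats::setNames(rep(c("A", "B"), each = 3), sprintf("s%02d", 1:6))
  for (rep in 1:8) {
    tab <- random_abundance_table(6, 6, states = states)
    ab <- score_jsd(tab, "A", "B")$table
    ba <- score_jsd(tab, "B", "A")$table
    expect_equal(ab$score, ba$score, tolerance = 1e-12)
    expect_true(all(ab$score >= 0 & ab$score <= 1))
    expect_identical(ab$score == 0, ab$p_state1 == ab$p_state2)
  }
})

make_ssns <- function(tab, ref) {
  lapply(tab$sample_ids, function(s) {
    suppressMessages(construct_ssn(tab, s, ref))
  })
}

test_that("differential_analyze unions SSNs and colors the planted KO red", {
  ref <- metabolic_network(
    nodes = c("K1", "K2", "K3"),
    edges = data.frame(from = c("K1", "K2"), to = c("K2", "K3"),
                       stringsAsFactors = FALSE)
  )
  m <- rbind(a1 = c(K1 = 8, K2 = 1, K3 = 1), a2 = c(9, 1, 1),
             b1 = c(K1 = 0, K2 = 1, K3 = 1), b2 = c(0, 1, 1))
  colnames(m) <- c("K1", "K2", "K3")
  tab <- tab2(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  da <- differential_analyze(make_ssns(tab, ref), tab, "A", "B",
                             method = "or")
  # union of a K1->K2 SSN and K2->K3 SSNs: 3 nodes, 2 edges
  expect_identical(n_nodes(da$network), 3L)
  expect_identical(n_edges(da$network), 2L)
  attrs <- da$network$node_attributes
  expect_identical(attrs["K1", "direction"], "enriched")
  expect_identical(attrs["K1", "color"], "#FF0000")
  expect_true(all(attrs[c("K2", "K3"), "color"] == "#CCCCCC"))
})

test_that("identical SSNs in both states give an all-neutral network", {
  ref <- metabolic_network(
    nodes = c("K1", "K2"),
    edges = data.frame(from = "K1", to = "K2", stringsAsFactors = FALSE)
  )
  m <- rbind(a1 = c(K1 = 2, K2 = 2), b1 = c(2, 2))
  colnames(m) <- c("K1", "K2")
  tab <- tab2(m, c(a1 = "A", b1 = "B"))
  da <- differential_analyze(make_ssns(tab, ref), tab, "A", "B",
                             method = "or")
  expect_true(all(da$network$node_attributes$direction == "unchanged"))
  expect_true(all(da$network$node_attributes$color == "#CCCCCC"))
})

test_that("a state without an SSN is a validation error", {
  ref <- metabolic_network(
    nodes = c("K1", "K2"),
    edges = data.frame(from = "K1", to = "K2", stringsAsFactors = FALSE)
  )
  m <- rbind(a1 = c(K1 = 2, K2 = 2), b1 = c(2, 2))
  colnames(m) <- c("K1", "K2")
  tab <- tab2(m, c(a1 = "A", b1 = "B"))
  ssns <- make_ssns(tab, ref)
  expect_error(
    differential_analyze(ssns[1], tab, "A", "B", method = "or"),
    class = "konet_validation_error"
  )
})

test_that("the default threshold is the 0.9 quantile of nonzero scores", {
  set.seed(24)
  states <- stats::setNames(rep(c("A", "B"), each = 3), sprintf("s%02d", 1:6))
  tab <- random_abundance_table(6, 10, states = states)
  ref <- metabolic_network(nodes = tab$ko_ids)
  da <- differential_analyze(make_ssns(tab, ref), tab, "A", "B",
                             method = "or")
  sc <- da$result$table$score
  expect_equal(da$result$threshold_used,
               unname(stats::quantile(sc[sc > 0], 0.9)))
  called <- da$result$table$direction != "unchanged"
  expect_identical(called, sc > da$result$threshold_used)
})
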