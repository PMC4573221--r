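#' Configuration for the synthetic-data generator
#'
#' Bundles all parameters of the synthetic metagenome emulator: the size of
#' the reference reaction table, the sampling design (two states), the
#' annotation quirks that exercise even-split counting (multi-KO reference
#' sequences and tied best hits), and an optional planted differential
#' effect whose ground truth is returned alongside the data.
#'
#' @param n_kos number of KO identifiers.
#' @param n_compounds number of compound identifiers (>= 2).
#' @param n_reactions number of reactions in the reference table.
#' @param reversible_fraction probability that a reaction is reversible.
#' @param n_samples_per_state samples simulated per state.
#' @param n_reads reads per sample.
#' @param multi_ko_fraction fraction of reads hitting a reference sequence
#'   annotated with two KOs.
#' @param tie_fraction fraction of reads with two tied best hits (plus one
#'   worse decoy hit).
#' @param planted_ko KO id carrying the planted effect; `NULL` picks the KO
#'   of median baseline weight once the baseline is drawn.
#' @param planted_log2_fold log2 fold change of the planted KO's relative
#'   abundance in state1 versus state2 (0 = null model).
#' @param seed integer seed driving every random draw.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_kos = 50, n_compounds = 30, n_reactions = 40,
                              reversible_fraction = 0.2,
                              n_samples_per_state = 20, n_reads = 10000,
                              multi_ko_fraction = 0.1, tie_fraction = 0.1,
                              planted_ko = NULL, planted_log2_fold = 0,
                              seed = 1) {
  cfg <- list(
    n_kos = n_kos, n_compounds = n_compounds, n_reactions = n_reactions,
    reversible_fraction = reversible_fraction,
    n_samples_per_state = n_samples_per_state, n_reads = n_reads,
    multi_ko_fraction = multi_ko_fraction, tie_fraction = tie_fraction,
    planted_ko = planted_ko, planted_log2_fold = planted_log2_fold,
    seed = seed
  )
  for (f in c("n_kos", "n_compounds", "n_samples_per_state", "n_reads")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1) {
      validation_error(sprintf("%s must be a positive integer", f))
    }
  }
  if (!is_count(cfg$n_reactions)) {
    validation_error("n_reactions must be a nonnegative integer")
  }
  for (f in c("reversible_fraction", "multi_ko_fraction", "tie_fraction")) {
    if (!is_fraction(cfg[[f]])) {
      validation_error(sprintf("%s must be in [0, 1]", f))
    }
  }
  if (cfg$multi_ko_fraction + cfg$tie_fraction > 1) {
    validation_error("multi_ko_fraction + tie_fraction must not exceed 1")
  }
  if (!is.null(cfg$planted_ko) && !is_string(cfg$planted_ko)) {
    validation_error("planted_ko must be NULL or a single KO id")
  }
  stopifnot(is.numeric(cfg$planted_log2_fold), length(cfg$planted_log2_fold) == 1L,
            is.numeric(cfg$seed), length(cfg$seed) == 1L)
  for (f in c("n_kos", "n_compounds", "n_reactions", "n_samples_per_state",
              "n_reads", "seed")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  structure(cfg, class = "simulation_config")
}

sim_ko_ids <- function(cfg) sprintf("K%05d", seq_len(cfg$n_kos))
sim_compound_ids <- function(cfg) sprintf("C%05d", seq_len(cfg$n_compounds))

#' Generate a synthetic reference reaction table with its true edge set
#'
#' Draws `n_reactions` reactions over the configured KO and compound pools
#' (1-2 catalyzing KOs, 1-2 substrates and 1-2 products per reaction,
#' substrates and products disjoint within a reaction) and returns both the
#' reaction table and the network edge set obtained by exhaustive
#' enumeration over all ordered KO pairs and reaction pairs — an oracle
#' independent of [construct_metabolic_network()]'s compound-indexed
#' algorithm, for use in tests.
#'
#' @param config a [simulation_config()].
#' @return List with `reactions` (a [reaction_table()]) and `oracle_edges`
#'   (`data.frame` with columns `from`, `to`, sorted).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_compounds < 2) {
    validation_error("n_compounds must be at least 2 to form a reaction")
  }
  kos <- sim_ko_ids(config)
  cmps <- sim_compound_ids(config)
  n <- config$n_reactions
  if (n == 0L) {
    rt <- reaction_table(character(), logical(), list(), list(), list())
    return(list(reactions = rt, oracle_edges = empty_edges()))
  }
  with_seed(config$seed + 101L, {
    sub_l <- vector("list", n)
    prod_l <- vector("list", n)
    ko_l <- vector("list", n)
    rev_ <- stats::runif(n) < config$reversible_fraction
    for (i in seq_len(n)) {
      # cycle the first catalyst through the KO pool so that (given enough
      # reactions) every simulated enzyme participates in metabolism, as in
      # real reference data where the KO universe derives from reactions
      first <- kos[(i - 1L) %% config$n_kos + 1L]
      ko_l[[i]] <- unique(c(first, if (stats::runif(1) < 0.5) sample(kos, 1)))
      n_sub <- min(sample(1:2, 1), config$n_compounds - 1L)
      n_prod <- min(sample(1:2, 1), config$n_compounds - n_sub)
      both <- sample(cmps, n_sub + n_prod)
      sub_l[[i]] <- both[seq_len(n_sub)]
      prod_l[[i]] <- both[-seq_len(n_sub)]
    }
    rt <- reaction_table(sprintf("R%05d", seq_len(n)), rev_, ko_l, sub_l,
                         prod_l)
    list(reactions = rt, oracle_edges = brute_force_edges(rt))
  })
}

#' Exhaustive edge enumeration over a reaction table
#'
#' Tests every ordered KO pair (A, B) against every reaction pair for a
#' shared effective product/substrate compound — the O(KO^2 x reactions^2)
#' definition of the network edge rule, kept separate from the constructor
#' so the two can check each other.
#'
#' @param reactions a [reaction_table()].
#' @param exclude_compounds compound ids ignored by the edge rule.
#' @param allow_self_loops keep A -> A edges?
#' @return `data.frame` with columns `from`, `to`, sorted by (`from`, `to`).
#' @export
brute_force_edges <- function(reactions, exclude_compounds = character(),
                              allow_self_loops = FALSE) {
  stopifnot(inherits(reactions, "reaction_table"))
  kos <- sort(unique(unlist(reactions$ko_ids)))
  nr <- nrow(reactions)
  prods <- lapply(seq_len(nr), function(i)
    setdiff(effective_products(reactions, i), exclude_compounds))
  subs <- lapply(seq_len(nr), function(i)
    setdiff(effective_substrates(reactions, i), exclude_compounds))
  from <- character()
  to <- character()
  for (a in kos) {
    ra <- which(vapply(reactions$ko_ids, function(k) a %in% k, TRUE))
    for (b in kos) {
      if (a == b && !allow_self_loops) next
      rb <- which(vapply(reactions$ko_ids, function(k) b %in% k, TRUE))
      hit <- FALSE
      for (i in ra) {
        for (j in rb) {
          if (length(intersect(prods[[i]], subs[[j]]))) {
            hit <- TRUE
            break
          }
        }
        if (hit) break
      }
      if (hit) {
        from <- c(from, a)
        to <- c(to, b)
      }
    }
  }
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Generate synthetic annotation profiles with known ground truth
#'
#' Simulates two states of samples. Each state has a KO probability vector:
#' a baseline drawn once from exponential weights, with the planted KO's
#' probability scaled by `2^planted_log2_fold` in state1 and the vector
#' renormalized. Every read picks its KO from the state's multinomial; a
#' `multi_ko_fraction` of reads hit a reference sequence carrying a second
#' KO, and a `tie_fraction` of reads have two best hits with identical
#' e-values (plus a worse decoy hit that best-hit filtering must discard).
#' Partner KOs are drawn from the same state distribution, so even-split
#' counting is unbiased and the returned probability vectors are the exact
#' expected relative abundances.
#'
#' @param config a [simulation_config()].
#' @return List with `profiles` (list of [annotation_profile()]),
#'   `state_labels` (named character), and `truth` (list: `p_state1`,
#'   `p_state2`, `planted_ko`, `planted_log2_fold`).
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  kos <- sim_ko_ids(config)
  base_w <- with_seed(config$seed + 211L, stats::rexp(config$n_kos))
  planted <- config$planted_ko
  if (is.null(planted)) {
    planted <- kos[order(base_w)[ceiling(config$n_kos / 2)]]
  } else if (!(planted %in% kos)) {
    validation_error(sprintf("planted_ko '%s' is not among the simulated KOs",
                             planted))
  }
  p2 <- base_w / sum(base_w)
  w1 <- base_w
  w1[kos == planted] <- w1[kos == planted] * 2^config$planted_log2_fold
  p1 <- w1 / sum(w1)
  names(p1) <- names(p2) <- kos
  ns <- config$n_samples_per_state
  sample_ids <- c(sprintf("state1_s%02d", seq_len(ns)),
                  sprintf("state2_s%02d", seq_len(ns)))
  states <- stats::setNames(rep(c("state1", "state2"), each = ns), sample_ids)
  probs <- list(state1 = p1, state2 = p2)
  profiles <- vector("list", length(sample_ids))
  for (i in seq_along(sample_ids)) {
    profiles[[i]] <- with_seed(
      config$seed + 1000L + 7919L * i,
      simulate_profile(sample_ids[i], probs[[states[[i]]]], config)
    )
  }
  list(profiles = profiles, state_labels = states,
       truth = list(p_state1 = p1, p_state2 = p2, planted_ko = planted,
                    planted_log2_fold = config$planted_log2_fold))
}

# one sample's annotation records under the current RNG stream
simulate_profile <- function(sample_id, p, config) {
  n <- config$n_reads
  nk <- config$n_kos
  ko <- sample.int(nk, n, replace = TRUE, prob = p)
  partner <- sample.int(nk, n, replace = TRUE, prob = p)
  u <- stats::runif(n)
  type <- ifelse(u < config$tie_fraction, "tie",
                 ifelse(u < config$tie_fraction + config$multi_ko_fraction,
                        "multi", "single"))
  # a tied pair needs two distinct subjects; a self-pair degenerates to a
  # plain single-subject read (same split weight either way)
  type[type == "tie" & partner == ko] <- "single"
  # e-values exact under the writer's %.3e formatting, so file round trips
  # and in-memory analysis see identical numbers
  e <- as.numeric(sprintf("%.3e", 10^-stats::runif(n, 5, 50)))
  read_id <- sprintf("r%06d", seq_len(n))
  ko_id <- function(i) sprintf("K%05d", i)
  subj <- character(n)
  kol <- vector("list", n)
  is_single <- type == "single"
  is_multi <- type == "multi"
  is_tie <- type == "tie"
  subj[is_single | is_tie] <- sprintf("S%05d", ko[is_single | is_tie])
  subj[is_multi] <- sprintf("M%05d.%05d", pmin(ko[is_multi], partner[is_multi]),
                            pmax(ko[is_multi], partner[is_multi]))
  kol[is_single | is_tie] <- lapply(ko[is_single | is_tie], ko_id)
  kol[is_multi] <- mapply(function(a, b) unique(ko_id(c(a, b))),
                          ko[is_multi], partner[is_multi], SIMPLIFY = FALSE)
  rec <- data.frame(read_id = read_id, subject_id = subj, e_value = e,
                    stringsAsFactors = FALSE)
  rec$ko_ids <- kol
  if (any(is_tie)) {
    # second tied best hit with the identical e-value, plus a worse decoy
    tie2 <- data.frame(read_id = read_id[is_tie],
                       subject_id = sprintf("S%05d", partner[is_tie]),
                       e_value = e[is_tie], stringsAsFactors = FALSE)
    tie2$ko_ids <- lapply(partner[is_tie], ko_id)
    decoy_ko <- sample.int(nk, sum(is_tie), replace = TRUE)
    decoy <- data.frame(read_id = read_id[is_tie],
                        subject_id = sprintf("X%05d", decoy_ko),
                        e_value = as.numeric(sprintf("%.3e", e[is_tie] * 1e3)),
                        stringsAsFactors = FALSE)
    decoy$ko_ids <- lapply(decoy_ko, ko_id)
    rec <- rbind(rec, tie2, decoy)
    rec <- rec[order(rec$read_id, rec$subject_id), ]
  }
  annotation_profile(sample_id, rec)
}

#' Write a complete synthetic fixture directory
#'
#' Materializes a simulated study on disk: the reaction table
#' (`reactions.tsv`), one annotation profile per sample
#' (`<sample_id>.tsv`), the sample-to-state map (`labels.tsv`), and a
#' ground-truth sidecar (`truth.json`) holding the per-state KO probability
#' vectors, the planted effect, the oracle edge list, and the configuration.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
simulate_fixture <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config)
  write_reaction_table(ref$reactions, file.path(dir, "reactions.tsv"))
  gen <- generate_profiles(config)
  for (p in gen$profiles) {
    write_annotation_profile(p, file.path(dir, paste0(p$sample_id, ".tsv")))
  }
  labels <- data.frame(sample_id = names(gen$state_labels),
                       state = unname(gen$state_labels))
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    p_state1 = as.list(gen$truth$p_state1),
    p_state2 = as.list(gen$truth$p_state2),
    planted_ko = gen$truth$planted_ko,
    planted_log2_fold = gen$truth$planted_log2_fold,
    oracle_edges = ref$oracle_edges,
    config = unclass(config)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
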