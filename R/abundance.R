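#' Estimate per-KO enzymatic gene abundance for one sample
#'
#' Turns an annotation profile into KO counts by even-split counting: every
#' read contributes total weight 1. Among a read's hits only those at the
#' read's best (minimum) e-value are kept — ties at the best e-value are kept
#' together (compared with relative tolerance 1e-9 to absorb decimal
#' rounding). The unique KO ids across the kept hits are pooled and each
#' receives an equal `1/n` share. A read whose KO-annotated hits are all
#' worse than its best hit set contributes nothing.
#'
#' @param profile an [annotation_profile()].
#' @return Named numeric vector of (possibly fractional) counts per KO id.
#' @examples
#' rec <- data.frame(read_id = "r1", subject_id = "s1", e_value = 1e-30)
#' rec$ko_ids <- list(c("K00001", "K00002"))
#' estimate_abundance(annotation_profile("a", rec))  # 0.5 each
#' @export
estimate_abundance <- function(profile) {
  stopifnot(inherits(profile, "annotation_profile"))
  rec <- profile$records
  if (nrow(rec) == 0L) return(stats::setNames(numeric(0), character(0)))
  f <- factor(rec$read_id)
  best <- tapply(rec$e_value, f, min)
  keep <- rec$e_value <= best[as.integer(f)] * (1 + 1e-9)
  kept <- rec[keep, , drop = FALSE]
  pooled <- lapply(split(kept$ko_ids, factor(kept$read_id)),
                   function(l) unique(unlist(l, use.names = FALSE)))
  n_per_read <- lengths(pooled)
  kos <- unlist(pooled, use.names = FALSE)
  w <- rep(1 / n_per_read, n_per_read)
  counts <- tapply(w, kos, sum)
  stats::setNames(as.numeric(counts), names(counts))
}

#' Build a samples-by-KOs abundance table
#'
#' Runs [estimate_abundance()] on each profile and assembles the counts over
#' the union of all observed KOs (absent KOs get 0). Relative abundances are
#' each sample's counts divided by the sample's total count of enzymatic-gene
#' reads, so nonzero rows sum to 1 — the normalization that makes samples of
#' different sequencing depth comparable. Samples with no KO-annotated reads
#' keep an all-zero row and trigger a warning.
#'
#' @param profiles list of [annotation_profile()] objects with unique
#'   sample ids.
#' @param state_labels optional named character vector mapping every
#'   sample id to a biological state label.
#' @return An `abundance_table`: list with `sample_ids`, `ko_ids`, matrices
#'   `counts` and `relative` (samples x KOs), and `state_labels`.
#' @export
build_abundance_table <- function(profiles, state_labels = NULL) {
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, TRUE, "annotation_profile")))
  sample_ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(sample_ids)) {
    validation_error(sprintf(
      "duplicate sample_id: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  per_sample <- lapply(profiles, estimate_abundance)
  ko_ids <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0, nrow = length(sample_ids), ncol = length(ko_ids),
                   dimnames = list(sample_ids, ko_ids))
  for (i in seq_along(per_sample)) {
    v <- per_sample[[i]]
    if (length(v)) counts[i, names(v)] <- v
  }
  abundance_table(counts, state_labels = state_labels)
}

#' Construct an abundance table from a counts matrix
#'
#' Lower-level constructor used by [build_abundance_table()] and
#' [read_biom()]: validates the counts matrix, recomputes relative
#' abundances by row normalization, and attaches state labels.
#'
#' @param counts numeric samples x KOs matrix with dimnames.
#' @param state_labels optional named character vector covering all samples.
#' @return An `abundance_table`.
#' @export
abundance_table <- function(counts, state_labels = NULL) {
  stopifnot(is.matrix(counts), is.numeric(counts),
            nrow(counts) == 0L || !is.null(rownames(counts)),
            ncol(counts) == 0L || !is.null(colnames(counts)))
  if (any(counts < 0)) validation_error("counts must be nonnegative")
  sample_ids <- rownames(counts) %||% character()
  if (anyDuplicated(sample_ids)) validation_error("duplicate sample_id")
  totals <- rowSums(counts)
  zero <- totals == 0
  if (any(zero) && nrow(counts)) {
    warning(sprintf(
      "sample(s) with no enzymatic-gene reads: %s",
      paste(sample_ids[zero], collapse = ", ")
    ), call. = FALSE)
  }
  relative <- counts
  nz <- which(!zero)
  relative[nz, ] <- counts[nz, , drop = FALSE] / totals[nz]
  if (!is.null(state_labels)) {
    state_labels <- state_labels[sample_ids]
    if (anyNA(state_labels) || anyNA(names(state_labels))) {
      validation_error("state_labels must cover every sample_id")
    }
  }
  structure(
    list(sample_ids = sample_ids, ko_ids = colnames(counts) %||% character(),
         counts = counts, relative = relative, state_labels = state_labels),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "<abundance_table> %d samples x %d KOs\n",
    length(x$sample_ids), length(x$ko_ids)
  ))
  if (!is.null(x$state_labels)) {
    tab <- table(x$state_labels)
    cat("  states:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.abundance_table <- function(object, ...) {
  tot <- rowSums(object$counts)
  cat(sprintf(
    "<abundance_table> %d samples x %d KOs; reads/sample: min %.1f, median %.1f, max %.1f\n",
    length(object$sample_ids), length(object$ko_ids),
    if (length(tot)) min(tot) else NA, if (length(tot)) stats::median(tot) else NA,
    if (length(tot)) max(tot) else NA
  ))
  invisible(object)
}
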