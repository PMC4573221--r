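#' Annotation profiles
#'
#' An annotation profile holds the functional annotation of one metagenomic
#' sample: one record per read-to-reference-sequence hit, with the alignment
#' e-value and the KO identifiers annotating the reference sequence. Rows
#' whose KO field is empty (hits to non-enzymatic references) are dropped at
#' read time and counted in `n_dropped`.
#'
#' The on-disk dialect is tab-separated UTF-8 with header
#' `read_id  subject_id  e_value  ko_ids`; `ko_ids` is semicolon-separated
#' and may be empty; `e_value` is a nonnegative (scientific-notation) float.
#'
#' @param sample_id sample identifier (nonempty string).
#' @param records `data.frame` with columns `read_id`, `subject_id`,
#'   `e_value` (numeric) and list column `ko_ids`.
#' @param n_dropped number of KO-less rows dropped when reading.
#' @return An `annotation_profile` object.
#' @export
annotation_profile <- function(sample_id, records, n_dropped = 0L) {
  if (!is_string(sample_id) || !nzchar(sample_id)) {
    validation_error("sample_id must be a nonempty string")
  }
  stopifnot(is.data.frame(records),
            all(c("read_id", "subject_id", "e_value", "ko_ids") %in%
                  names(records)))
  records <- records[, c("read_id", "subject_id", "e_value", "ko_ids")]
  if (nrow(records)) {
    if (any(records$e_value < 0)) validation_error("e_value must be >= 0")
    if (any(lengths(records$ko_ids) == 0L)) {
      validation_error("records must carry at least one KO id")
    }
    key <- paste(records$read_id, records$subject_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- records[duplicated(key), ][1, ]
      validation_error(sprintf(
        "duplicate (read_id, subject_id) pair: (%s, %s)",
        d$read_id, d$subject_id
      ))
    }
    # a subject annotated twice with the same KO is one annotation
    records$ko_ids <- lapply(records$ko_ids, unique)
  }
  rownames(records) <- NULL
  structure(
    list(sample_id = sample_id, records = records,
         n_dropped = as.integer(n_dropped)),
    class = "annotation_profile"
  )
}

annotation_header <- c("read_id", "subject_id", "e_value", "ko_ids")

empty_records <- function() {
  out <- data.frame(read_id = character(), subject_id = character(),
                    e_value = numeric(), stringsAsFactors = FALSE)
  out$ko_ids <- list()
  out
}

#' Read a per-sample KO annotation profile
#'
#' Parses the tab-separated annotation dialect (see [annotation_profile()]).
#' Rows with an empty KO field are filtered out and counted; a message
#' reports the count. Unparseable e-values raise a parse error naming the
#' line; duplicate `(read_id, subject_id)` pairs raise a validation error.
#'
#' @param path path to an annotation profile file.
#' @param sample_id sample identifier to attach.
#' @param max_e_value optional e-value cutoff; hits with a larger e-value are
#'   discarded before any downstream counting. Default `NULL` keeps all hits.
#' @return An [annotation_profile()].
#' @export
read_annotation_profile <- function(path, sample_id, max_e_value = NULL) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) parse_error(sprintf("%s: empty file, header expected", path))
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, annotation_header)) {
    parse_error(sprintf(
      "%s: line 1: bad header, expected '%s'",
      path, paste(annotation_header, collapse = "\\t")
    ))
  }
  body <- lines[-1]
  body_no <- which(nzchar(body)) + 1L
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(annotation_profile(sample_id, empty_records(), n_dropped = 0L))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  # a trailing empty ko_ids field is dropped by strsplit; restore it
  fields <- lapply(fields, function(f) if (length(f) == 3L) c(f, "") else f)
  ncol_ok <- lengths(fields) == 4L
  if (any(!ncol_ok)) {
    i <- which(!ncol_ok)[1]
    parse_error(sprintf(
      "%s: line %d: expected 4 tab-separated columns, got %d",
      path, body_no[i], lengths(fields)[i]
    ))
  }
  m <- do.call(rbind, fields)
  ev <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(ev)) {
    i <- which(is.na(ev))[1]
    parse_error(sprintf(
      "%s: line %d: unparseable e_value '%s'", path, body_no[i], m[i, 3]
    ))
  }
  if (any(ev < 0)) {
    i <- which(ev < 0)[1]
    parse_error(sprintf(
      "%s: line %d: negative e_value %g", path, body_no[i], ev[i]
    ))
  }
  kos <- split_ids(m[, 4])
  keep <- lengths(kos) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf(
      "%s: dropped %d row(s) without KO annotation", path, n_dropped
    ))
  }
  rec <- data.frame(read_id = m[keep, 1], subject_id = m[keep, 2],
                    e_value = ev[keep], stringsAsFactors = FALSE)
  rec$ko_ids <- kos[keep]
  if (!is.null(max_e_value)) {
    rec <- rec[rec$e_value <= max_e_value, , drop = FALSE]
  }
  annotation_profile(sample_id, rec, n_dropped = n_dropped)
}

#' Write an annotation profile
#'
#' Inverse of [read_annotation_profile()]; e-values are written in
#' scientific notation with three significant decimals, so records with
#' equal e-values serialize to identical strings and tie detection survives
#' the round trip.
#'
#' @param profile an [annotation_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_profile <- function(profile, path) {
  stopifnot(inherits(profile, "annotation_profile"))
  rec <- profile$records
  lines <- c(
    paste(annotation_header, collapse = "\t"),
    if (nrow(rec)) paste(
      rec$read_id, rec$subject_id,
      sprintf("%.3e", rec$e_value),
      join_ids(rec$ko_ids),
      sep = "\t"
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.annotation_profile <- function(x, ...) {
  cat(sprintf(
    "<annotation_profile '%s'> %d records over %d reads, %d KOs (%d KO-less rows dropped)\n",
    x$sample_id, nrow(x$records), length(unique(x$records$read_id)),
    length(unique(unlist(x$records$ko_ids))), x$n_dropped
  ))
  invisible(x)
}
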