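#' Write an abundance table as a BIOM 1.0 JSON file
#'
#' Serializes the table with observations (rows) = KOs and columns =
#' samples, `matrix_type = "sparse"` over the counts matrix. Each
#' observation's relative abundances across samples are stored as
#' per-observation metadata (`relative_abundance`), and each sample's state
#' label (when present) as column metadata (`state`).
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_biom()]
#' @export
write_biom <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  counts <- t(table$counts)  # observations x samples
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    list(id = rownames(counts)[i],
         metadata = list(relative_abundance = unname(table$relative[, i])))
  })
  cols <- lapply(seq_len(ncol(counts)), function(j) {
    sid <- colnames(counts)[j]
    md <- if (!is.null(table$state_labels)) {
      list(state = unname(table$state_labels[[sid]]))
    } else NULL
    list(id = sid, metadata = md)
  })
  nz <- which(counts != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(nz)), function(k) {
    c(nz[k, 1] - 1, nz[k, 2] - 1, counts[nz[k, 1], nz[k, 2]])
  })
  obj <- list(
    id = NULL,
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = paste0("konet ", utils::packageVersion("konet")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    rows = rows,
    columns = cols,
    matrix_type = "sparse",
    matrix_element_type = "float",
    shape = c(nrow(counts), ncol(counts)),
    data = data
  )
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) konet_stop(
                    sprintf("cannot write %s: %s", path, conditionMessage(e)),
                    "konet_io_error"))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  invisible(path)
}

biom_field <- function(obj, name) {
  if (is.null(obj[[name]])) {
    format_error(sprintf("not a BIOM 1.0 file: missing field '%s'", name))
  }
  obj[[name]]
}

#' Read a BIOM 1.0 JSON file into an abundance table
#'
#' Accepts both sparse and dense matrix encodings. Relative abundances are
#' recomputed from the counts; sample state labels are recovered from column
#' metadata field `state` when every column carries one.
#'
#' @param path path to a BIOM 1.0 JSON file.
#' @return An [abundance_table()].
#' @export
read_biom <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) format_error(
      sprintf("not a BIOM JSON file (%s): %s", path, conditionMessage(e))
    )
  )
  shape <- unlist(biom_field(obj, "shape"))
  if (length(shape) != 2L || any(shape < 0)) {
    format_error("not a BIOM 1.0 file: field 'shape' must be two nonnegative integers")
  }
  rows <- biom_field(obj, "rows")
  cols <- biom_field(obj, "columns")
  mtype <- biom_field(obj, "matrix_type")
  if (length(rows) != shape[1] || length(cols) != shape[2]) {
    format_error("not a BIOM 1.0 file: 'shape' disagrees with rows/columns")
  }
  ko_ids <- vapply(rows, function(r) as.character(biom_field(r, "id")), "")
  sample_ids <- vapply(cols, function(c_) as.character(biom_field(c_, "id")), "")
  m <- matrix(0, nrow = shape[1], ncol = shape[2])
  data <- obj$data %||% list()
  if (identical(mtype, "sparse")) {
    for (trip in data) {
      trip <- unlist(trip)
      if (length(trip) != 3L) {
        format_error("not a BIOM 1.0 file: sparse 'data' entries must be [row, col, value]")
      }
      m[trip[1] + 1, trip[2] + 1] <- trip[3]
    }
  } else if (identical(mtype, "dense")) {
    if (length(data) != shape[1]) {
      format_error("not a BIOM 1.0 file: dense 'data' must have one row per observation")
    }
    for (i in seq_along(data)) m[i, ] <- unlist(data[[i]])
  } else {
    format_error(sprintf(
      "not a BIOM 1.0 file: unknown matrix_type '%s'", mtype
    ))
  }
  counts <- t(m)
  rownames(counts) <- sample_ids
  colnames(counts) <- ko_ids
  states <- vapply(cols, function(c_) {
    s <- c_$metadata$state
    if (is.null(s)) NA_character_ else as.character(s)
  }, "")
  state_labels <- if (length(states) && !anyNA(states)) {
    stats::setNames(states, sample_ids)
  } else NULL
  abundance_table(counts, state_labels = state_labels)
}
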