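#' Reaction tables
#'
#' A reaction table describes directed enzymatic transformations: each row is
#' one reaction with the KEGG Orthology (KO) identifiers of the catalyzing
#' enzymes, its substrate compound ids and its product compound ids, plus a
#' reversibility flag. It is the reference data from which the enzyme-level
#' metabolic network is constructed.
#'
#' The on-disk dialect is tab-separated UTF-8 with header
#' `reaction_id  direction  ko_ids  substrate_ids  product_ids`;
#' `direction` is `"=>"` (irreversible) or `"<=>"` (reversible) and
#' multi-valued fields are semicolon-separated.
#'
#' @param reaction_id character vector of unique reaction identifiers.
#' @param reversible logical vector, `TRUE` for reversible reactions.
#' @param ko_ids,substrate_ids,product_ids lists of character vectors, one
#'   element per reaction; each must be nonempty.
#' @return A `reaction_table`: a `data.frame` with columns `reaction_id`,
#'   `reversible` and list columns `ko_ids`, `substrate_ids`, `product_ids`.
#' @examples
#' rt <- reaction_table(
#'   reaction_id = c("R1", "R2"),
#'   reversible = c(FALSE, TRUE),
#'   ko_ids = list("K00001", c("K00002", "K00003")),
#'   substrate_ids = list("C00001", "C00002"),
#'   product_ids = list("C00002", "C00003")
#' )
#' @export
reaction_table <- function(reaction_id, reversible, ko_ids, substrate_ids,
                           product_ids) {
  n <- length(reaction_id)
  stopifnot(
    is.character(reaction_id), is.logical(reversible),
    length(reversible) == n, length(ko_ids) == n,
    length(substrate_ids) == n, length(product_ids) == n
  )
  if (anyDuplicated(reaction_id)) {
    validation_error(sprintf(
      "duplicate reaction_id: %s",
      paste(unique(reaction_id[duplicated(reaction_id)]), collapse = ", ")
    ))
  }
  chk <- function(lst, what) {
    bad <- which(!vapply(lst, function(v) is.character(v) && length(v) > 0, TRUE))
    if (length(bad)) {
      validation_error(sprintf(
        "reaction %s has empty %s", reaction_id[bad[1]], what
      ))
    }
    lapply(lst, unique)
  }
  out <- data.frame(
    reaction_id = reaction_id, reversible = reversible,
    stringsAsFactors = FALSE
  )
  out$ko_ids <- chk(ko_ids, "ko_ids")
  out$substrate_ids <- chk(substrate_ids, "substrate_ids")
  out$product_ids <- chk(product_ids, "product_ids")
  class(out) <- c("reaction_table", "data.frame")
  out
}

reaction_header <- c("reaction_id", "direction", "ko_ids",
                     "substrate_ids", "product_ids")

#' Read a reaction table
#'
#' Parses the tab-separated reaction dialect (see [reaction_table()] for the
#' layout). Rows with the wrong number of columns, an unknown direction
#' token, or an empty KO/substrate/product field raise a parse error naming
#' the offending line; duplicated reaction ids raise a validation error.
#'
#' @param path path to a reaction table file.
#' @return A [reaction_table()].
#' @seealso [write_reaction_table()], [construct_metabolic_network()]
#' @export
read_reaction_table <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) parse_error(sprintf("%s: empty file, header expected", path))
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, reaction_header)) {
    parse_error(sprintf(
      "%s: line 1: bad header, expected '%s'",
      path, paste(reaction_header, collapse = "\\t")
    ))
  }
  body <- lines[-1]
  body_no <- which(nzchar(body)) + 1L  # file line numbers
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(reaction_table(character(), logical(), list(), list(), list()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == 5L
  if (any(!ncol_ok)) {
    i <- which(!ncol_ok)[1]
    parse_error(sprintf(
      "%s: line %d: expected 5 tab-separated columns, got %d",
      path, body_no[i], lengths(fields)[i]
    ))
  }
  m <- do.call(rbind, fields)
  dir_ok <- m[, 2] %in% c("=>", "<=>")
  if (any(!dir_ok)) {
    i <- which(!dir_ok)[1]
    parse_error(sprintf(
      "%s: line %d: direction must be '=>' or '<=>', got '%s'",
      path, body_no[i], m[i, 2]
    ))
  }
  kos <- split_ids(m[, 3])
  subs <- split_ids(m[, 4])
  prods <- split_ids(m[, 5])
  for (col in list(list(kos, "KO"), list(subs, "substrate"), list(prods, "product"))) {
    empty <- which(lengths(col[[1]]) == 0L)
    if (length(empty)) {
      parse_error(sprintf(
        "%s: line %d: empty %s field", path, body_no[empty[1]], col[[2]]
      ))
    }
  }
  reaction_table(
    reaction_id = m[, 1],
    reversible = m[, 2] == "<=>",
    ko_ids = kos, substrate_ids = subs, product_ids = prods
  )
}

#' Write a reaction table
#'
#' Inverse of [read_reaction_table()]; emits the tab-separated dialect.
#'
#' @param reactions a [reaction_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(reactions, path) {
  stopifnot(inherits(reactions, "reaction_table"))
  lines <- c(
    paste(reaction_header, collapse = "\t"),
    if (nrow(reactions)) paste(
      reactions$reaction_id,
      ifelse(reactions$reversible, "<=>", "=>"),
      join_ids(reactions$ko_ids),
      join_ids(reactions$substrate_ids),
      join_ids(reactions$product_ids),
      sep = "\t"
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.reaction_table <- function(x, ...) {
  cat(sprintf(
    "<reaction_table> %d reactions (%d reversible), %d KOs, %d compounds\n",
    nrow(x), sum(x$reversible), length(unique(unlist(x$ko_ids))),
    length(unique(c(unlist(x$substrate_ids), unlist(x$product_ids))))
  ))
  invisible(x)
}
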