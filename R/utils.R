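# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers (and the CLI) can distinguish bad input
# (parse/validation/lookup/format) from programming errors
konet_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "konet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

parse_error <- function(msg) konet_stop(msg, "konet_parse_error")
validation_error <- function(msg) konet_stop(msg, "konet_validation_error")
format_error <- function(msg) konet_stop(msg, "konet_format_error")
lookup_error <- function(msg) konet_stop(msg, "konet_lookup_error")
numeric_error <- function(msg) konet_stop(msg, "konet_numeric_error")
usage_error <- function(msg) konet_stop(msg, "konet_usage_error")

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# split a semicolon-separated multi-valued field, dropping empty tokens
split_ids <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_ids <- function(x) vapply(x, paste, "", collapse = ";")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
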