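`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

tsp_config_error <- function(msg) {
  stop(errorCondition(msg, class = c("tsp_config_error", "tsp_error")))
}

tsp_state_error <- function(msg) {
  stop(errorCondition(msg, class = c("tsp_state_error", "tsp_error")))
}

ttsd_parse_error <- function(msg, line = NA_integer_) {
  if (!is.na(line)) msg <- sprintf("line %d: %s", line, msg)
  stop(errorCondition(msg, class = c("ttsd_parse_error", "tsp_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Research IDs become the first underscore-delimited field of archive
# filenames, so they may not contain underscores, path separators or spaces.
check_research_id <- function(research_id) {
  if (!is.character(research_id) || length(research_id) != 1L ||
      is.na(research_id) || !nzchar(research_id)) {
    tsp_config_error("research_id must be a non-empty string")
  }
  if (grepl("[_/\\\\[:space:]]", research_id)) {
    tsp_config_error(
      "research_id must not contain underscores, path separators or whitespace")
  }
  invisible(research_id)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         format(x, scientific = FALSE, trim = TRUE, digits = 15))
}
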