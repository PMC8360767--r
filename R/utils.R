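# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.oscivm_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oscivm_error", "error", "condition")))
}

abort_config <- function(msg) .oscivm_abort(msg, "oscivm_config_error")
abort_input <- function(msg) .oscivm_abort(msg, "oscivm_input_error")
abort_singular <- function(msg) .oscivm_abort(msg, "oscivm_singular_error")
abort_io <- function(msg) .oscivm_abort(msg, "oscivm_io_error")

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.is_prob <- function(x) .is_number(x) && x >= 0 && x <= 1

#' Stable hash of a (nested) configuration list
#'
#' Flattens the configuration to `name=value` pairs and returns the MD5 of the
#' canonical string. Used to stamp every output artifact so that runs can be
#' matched to the exact configuration that produced them.
#'
#' @param cfg A list of scalar/vector fields (nesting allowed).
#' @return A length-1 character MD5 digest.
#' @export
config_hash <- function(cfg) {
  flat <- unlist(cfg, use.names = TRUE)
  flat <- flat[order(names(flat))]
  s <- paste(names(flat),
             vapply(flat, function(v) format(v, digits = 15L), character(1)),
             sep = "=", collapse = ";")
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

# Truncated-normal sampler (lower bound only), by rejection; sd > 0 assumed.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(2L * n, 16L), mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

# jsonlite writer with the conventions used for every JSON artifact.
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
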