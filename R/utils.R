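#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

dielop_version <- function() {
  as.character(utils::packageVersion("dieloperon"))
}

#' Signal a usage/configuration error (CLI exit code 2)
#' @noRd
abort_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("dielop_usage_error", "error")))
}

md5_of_string <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  con <- file(f, "wb")
  writeBin(charToRaw(x), con)
  close(con)
  unname(tools::md5sum(f))
}

#' Stable hash of a flat configuration list
#' @noRd
config_hash <- function(config) {
  if (is.null(config) || !length(config)) return("none")
  # output locations do not affect the analysis; excluding them keeps
  # reruns into different directories byte-identical
  config <- config[setdiff(names(config), c("out", "out_dir"))]
  if (!length(config)) return("none")
  keys <- sort(names(config))
  vals <- vapply(config[keys], function(v) {
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE), collapse = ",")
  }, character(1))
  md5_of_string(paste0(keys, "=", vals, collapse = "\n"))
}

#' Header comment lines stamped into every output file
#'
#' Carries tool version, seed and a hash of the effective configuration; no
#' timestamps, so identical runs are byte-identical.
#' @noRd
output_header <- function(seed = NA, config = NULL) {
  c(sprintf("# tool=dieloperon %s", dielop_version()),
    sprintf("# seed=%s", as.character(seed)),
    sprintf("# config_hash=%s", config_hash(config)))
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Derive a stage seed from the run seed (kept under 2^31)
#' @noRd
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (.Machine$integer.max - 1L)) + 1L
}

log_msg <- function(...) {
  message("[dieloperon] ", ...)
}
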