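#' @importFrom utils read.delim write.table packageVersion
#' @importFrom stats sd qt setNames
NULL

rs_version <- function() as.character(utils::packageVersion("riboshift"))

# Short md5 of an R object, for provenance headers on written tables.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f)
  unname(tools::md5sum(f))
}

# Standard '#' header lines carried by every writer.
rs_header <- function(seed = NULL, config = NULL) {
  lines <- sprintf("# riboshift %s", rs_version())
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %s", format(seed)))
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config: %s", config_hash(config)))
  }
  lines
}

write_tsv <- function(df, path, header = rs_header(), row_names = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, row_names = NULL) {
  read.delim(path, comment.char = "#", sep = "\t",
             stringsAsFactors = FALSE, row.names = row_names,
             check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
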