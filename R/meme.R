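#' Write a motif model in MEME minimal motif text format
#'
#' Version header, alphabet, background frequencies and the
#' letter-probability matrix, readable by standard motif tools and by
#' \code{\link{read_meme_motif}}.
#'
#' @param model \code{motif_model}
#' @param path output file
#' @param name motif name in the file
#' @param nsites effective site count recorded in the header (default the
#'   expected occurrence count gamma * n_seq)
#' @return invisibly, \code{path}
#' @export
write_meme_motif <- function(model, path, name = "motif_1",
                             nsites = NULL) {
  stopifnot(inherits(model, "motif_model"))
  nsites <- nsites %||% max(1L, round(model$gamma * model$n_seq))
  bg <- model$background
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       model$width, nsites)), con)
  for (j in seq_len(model$width))
    writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                       model$pwm["A", j], model$pwm["C", j],
                       model$pwm["G", j], model$pwm["T", j]), con)
  invisible(path)
}

#' Read a motif model from MEME minimal motif text format
#'
#' @param path MEME minimal format file
#' @return \code{motif_model} (loglik fields NA; the file does not carry
#'   them)
#' @export
read_meme_motif <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME minimal motif file: ", path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1L] + 1L]), "\\s+")[[1L]]
    bg <- setNames(as.numeric(tok[c(2, 4, 6, 8)]), tok[c(1, 3, 5, 7)])
    bg <- bg[DNA_BASES]
  }
  ml <- grep("^letter-probability matrix", lines)
  if (!length(ml)) stop("no letter-probability matrix in ", path)
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[ml[1L]]))
  rows <- lines[(ml[1L] + 1L):(ml[1L] + w)]
  pwm <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4L)))
  pwm <- t(pwm)
  rownames(pwm) <- DNA_BASES
  pwm <- sweep(pwm, 2L, colSums(pwm), "/")
  model <- list(width = w, pwm = pwm, consensus = pwm_consensus(pwm),
                background = bg / sum(bg), gamma = NA_real_,
                loglik = NA_real_, loglik_background = NA_real_,
                loglik_trace = numeric(0L), n_seq = NA_integer_)
  class(model) <- "motif_model"
  model
}
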