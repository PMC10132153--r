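#' Transcript models: sequence plus 5'UTR/CDS/3'UTR annotation
#'
#' A transcript set is a data.frame with one row per transcript and columns
#' \code{id}, \code{seq} (DNA alphabet, U mapped to T at ingest),
#' \code{utr5_length}, \code{cds_length}, \code{utr3_length}. Region lengths
#' must sum to the sequence length. All coordinates used by the package are
#' 1-based inclusive on the transcript.
#'
#' @param id character vector of unique transcript ids
#' @param seq character vector of nucleotide sequences over A/C/G/T (U is
#'   accepted and mapped to T; IUPAC ambiguity codes are rejected)
#' @param utr5_length,cds_length,utr3_length nonnegative integer region
#'   lengths summing to \code{nchar(seq)}
#' @return data.frame of class \code{transcript_set}
#' @export
transcript_set <- function(id, seq, utr5_length, cds_length, utr3_length) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate transcript id: ",
                              id[duplicated(id)][1L])
  seq <- toupper(chartr("u", "t", seq))
  seq <- chartr("U", "T", seq)
  bad <- grepl("[^ACGT]", seq)
  if (any(bad))
    stop("sequence of '", id[bad][1L],
         "' contains characters outside A/C/G/T/U (ambiguity codes are not supported)")
  u5 <- as.integer(utr5_length); cd <- as.integer(cds_length)
  u3 <- as.integer(utr3_length)
  if (any(u5 < 0 | cd < 0 | u3 < 0)) stop("region lengths must be nonnegative")
  mism <- which(u5 + cd + u3 != nchar(seq))
  if (length(mism))
    stop("region lengths of '", id[mism[1L]],
         "' do not sum to the sequence length")
  structure(data.frame(id = id, seq = seq, utr5_length = u5,
                       cds_length = cd, utr3_length = u3,
                       stringsAsFactors = FALSE),
            class = c("transcript_set", "data.frame"))
}

#' Read transcripts from FASTA plus a region-annotation table
#'
#' The annotation table is tab-delimited with columns id, utr5_length,
#' cds_length, utr3_length ('#' comments ignored). Region lengths are
#' validated against the sequence lengths; RNA-alphabet input is accepted
#' with U mapped to T.
#'
#' @param fasta_path FASTA file of transcript sequences
#' @param annotation_path region-annotation table
#' @return \code{transcript_set}
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ann <- read_tsv(annotation_path)
  need <- c("id", "utr5_length", "cds_length", "utr3_length")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  ids <- sub("\\s.*$", "", names(seqs))
  m <- match(ids, ann$id)
  if (anyNA(m)) stop("no annotation for transcript '", ids[is.na(m)][1L], "'")
  ann <- ann[m, , drop = FALSE]
  transcript_set(ids, as.character(seqs), ann$utr5_length,
                 ann$cds_length, ann$utr3_length)
}

#' Write transcripts as FASTA plus region-annotation table
#'
#' @param tx transcript_set
#' @param fasta_path,annotation_path output files
#' @param seed,config optional provenance for the annotation header
#' @return invisibly, \code{fasta_path}
#' @export
write_transcripts <- function(tx, fasta_path, annotation_path, seed = NULL,
                              config = NULL) {
  stopifnot(inherits(tx, "transcript_set"))
  ss <- Biostrings::DNAStringSet(setNames(tx$seq, tx$id))
  Biostrings::writeXStringSet(ss, fasta_path)
  write_tsv(tx[, c("id", "utr5_length", "cds_length", "utr3_length")],
            annotation_path, header = rs_header(seed = seed, config = config))
  invisible(fasta_path)
}

tx_row <- function(tx, id) {
  i <- match(id, tx$id)
  if (is.na(i)) stop("unknown transcript id: ", id)
  tx[i, , drop = FALSE]
}

# Region of a 1-based inclusive interval on one transcript.
region_of <- function(utr5_length, cds_length, utr3_length, start, end) {
  u5 <- utr5_length; ce <- utr5_length + cds_length
  len <- u5 + cds_length + utr3_length
  if (start < 1L || end > len || start > end) stop("interval outside transcript")
  if (end <= u5) "utr5"
  else if (start > u5 && end <= ce) "cds"
  else if (start > ce) "utr3"
  else "spanning"
}

#' Convert between transcript-global and region-local coordinates
#'
#' Both conventions are 1-based inclusive. A CDS-local position p maps to
#' global position p + utr5_length.
#'
#' @param tx transcript_set
#' @param id transcript id
#' @param pos position to convert
#' @param region for \code{local_to_global}, which region \code{pos} is
#'   local to (\code{utr5}, \code{cds} or \code{utr3})
#' @return converted position; \code{global_to_local} returns a list with
#'   elements \code{region} and \code{pos}
#' @export
global_to_local <- function(tx, id, pos) {
  r <- tx_row(tx, id)
  len <- nchar(r$seq)
  if (pos < 1L || pos > len) stop("position outside transcript")
  u5 <- r$utr5_length; ce <- r$utr5_length + r$cds_length
  if (pos <= u5) list(region = "utr5", pos = pos)
  else if (pos <= ce) list(region = "cds", pos = pos - u5)
  else list(region = "utr3", pos = pos - ce)
}

#' @rdname global_to_local
#' @export
local_to_global <- function(tx, id, region, pos) {
  r <- tx_row(tx, id)
  off <- switch(region,
                utr5 = 0L,
                cds = r$utr5_length,
                utr3 = r$utr5_length + r$cds_length,
                stop("unknown region: ", region))
  rl <- switch(region, utr5 = r$utr5_length, cds = r$cds_length,
               utr3 = r$utr3_length)
  if (pos < 1L || pos > rl) stop("position outside region ", region)
  off + pos
}
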