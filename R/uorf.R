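STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find upstream open reading frames in a transcript 5'UTR
#'
#' Every occurrence of an active start codon whose first base lies in the
#' 5'UTR opens a candidate uORF. The frame is extended codon by codon from
#' the start until the first in-frame stop (TAA/TAG/TGA) inside the
#' transcript. Candidates are classified \code{contained} (stop ends
#' before the CDS), \code{overlapping} (stop ends at or after the CDS
#' start) or \code{no_stop}. In \code{atg_only} mode only ATG starts are
#' active; \code{atg_plus_alternatives} adds \code{alt_codons}
#' (default CTG/GTG/TTG, recorded in the output). All start codons are
#' reported independently (nested uORFs are not suppressed).
#'
#' @param tx \code{transcript_set}
#' @param ids transcripts to scan (default all)
#' @param mode \code{"atg_only"} or \code{"atg_plus_alternatives"}
#' @param min_length_nt minimum number of nucleotides between the start
#'   and stop codons (0 = a bare start-stop pair qualifies); not applied
#'   to \code{no_stop} records
#' @param alt_codons alternative initiation codons for the second mode
#' @return data.frame: transcript, start, end (last base of the stop
#'   codon; NA for no_stop), start_codon, frame (of the uORF start
#'   relative to the annotated CDS frame, 0..2), n_codons (codons between
#'   start and stop), classification; the mode and codon set are attached
#'   as attributes
#' @export
find_uorfs <- function(tx, ids = NULL,
                       mode = c("atg_only", "atg_plus_alternatives"),
                       min_length_nt = 0L,
                       alt_codons = c("CTG", "GTG", "TTG")) {
  stopifnot(inherits(tx, "transcript_set"))
  mode <- match.arg(mode)
  starts_active <- if (mode == "atg_only") "ATG"
                   else unique(c("ATG", toupper(alt_codons)))
  ids <- ids %||% tx$id
  rows <- list()
  for (id in ids) {
    r <- tx_row(tx, id)
    u5 <- r$utr5_length
    if (u5 < 3L) next
    s <- r$seq
    len <- nchar(s)
    for (p in seq_len(u5)) {
      if (p + 2L > len) break
      codon <- substr(s, p, p + 2L)
      if (!(codon %in% starts_active)) next
      q <- p + 3L
      end <- NA_integer_
      n_codons <- 0L
      while (q + 2L <= len) {
        cd <- substr(s, q, q + 2L)
        if (cd %in% STOP_CODONS) { end <- q + 2L; break }
        n_codons <- n_codons + 1L
        q <- q + 3L
      }
      cls <- if (is.na(end)) "no_stop"
             else if (end <= u5) "contained" else "overlapping"
      if (!is.na(end) && 3L * n_codons < min_length_nt) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = id, start = p, end = end, start_codon = codon,
        frame = (p - u5 - 1L) %% 3L, n_codons = n_codons,
        classification = cls, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(transcript = character(0), start = integer(0),
                         end = integer(0), start_codon = character(0),
                         frame = integer(0), n_codons = integer(0),
                         classification = character(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "start_codons") <- starts_active
  out
}

#' Per-group uORF prevalence with a homogeneity test
#'
#' Fraction of transcripts carrying at least one uORF, per regulation
#' group, with a test of homogeneity of those fractions across groups:
#' Pearson chi-square when all expected cell counts are >= 5, otherwise
#' Fisher's exact test (the method used is recorded). Groups with no
#' transcripts are reported with n = 0 and excluded from the test.
#'
#' @param tx \code{transcript_set}
#' @param groups data.frame with columns \code{feature}, \code{group}
#' @inheritParams find_uorfs
#' @return list with \code{table} (group, n, n_with_uorf, frac), \code{p_value},
#'   \code{method}, \code{mode}
#' @export
uorf_prevalence_by_group <- function(tx, groups,
                                     mode = c("atg_only",
                                              "atg_plus_alternatives"),
                                     min_length_nt = 0L,
                                     alt_codons = c("CTG", "GTG", "TTG")) {
  mode <- match.arg(mode)
  recs <- find_uorfs(tx, ids = intersect(groups$feature, tx$id),
                     mode = mode, min_length_nt = min_length_nt,
                     alt_codons = alt_codons)
  with_uorf <- unique(recs$transcript)
  gids <- sort(unique(groups$group))
  tab <- do.call(rbind, lapply(gids, function(g) {
    gf <- intersect(groups$feature[groups$group == g], tx$id)
    data.frame(group = g, n = length(gf),
               n_with_uorf = sum(gf %in% with_uorf),
               frac = if (length(gf)) mean(gf %in% with_uorf) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  use <- tab$n > 0L
  if (!any(use)) stop("all groups are empty")
  m <- cbind(tab$n_with_uorf[use], tab$n[use] - tab$n_with_uorf[use])
  expected_ok <- {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    all(e >= 5)
  }
  if (nrow(m) < 2L) {
    p <- NA_real_; method <- "none"
  } else if (expected_ok) {
    p <- suppressWarnings(chisq.test(m)$p.value)
    method <- "pearson_chisq"
  } else {
    p <- fisher.test(m, simulate.p.value = nrow(m) > 6L, B = 2000L)$p.value
    method <- "fisher_exact"
  }
  list(table = tab, p_value = p, method = method, mode = mode,
       start_codons = attr(recs, "start_codons"))
}
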