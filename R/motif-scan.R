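#' Integer-rescaled log-odds score matrix of a motif model
#'
#' Scores are log2(pwm/background) per cell, multiplied by
#' \code{precision} and rounded to integers. All scanning and p-value
#' machinery in the package works on this common integer scale, so the
#' dynamic-programming p-values are exact for the scores the scanner
#' reports (reported scores are integer/precision, in bits).
#'
#' @param model \code{motif_model}
#' @param precision integer scale factor (default 1000, i.e. milli-bits)
#' @return 4 x W integer matrix
#' @export
integer_score_matrix <- function(model, precision = 1000L) {
  if (any(model$background <= 0))
    stop("degenerate background: zero frequency")
  sm <- log2(model$pwm / model$background)
  storage.mode(sm) <- "double"
  round(sm * precision)
}

#' Exact p-value of a PWM score under the background model
#'
#' Dynamic programming over the per-column integer score distributions:
#' the distribution of the total score of a background-generated W-mer is
#' built column by column, and the p-value is the probability of a score
#' greater than or equal to the query. Exact (up to the integer rescaling
#' shared with the scanner) for any width; enumeration over all 4^W words
#' gives the identical value.
#'
#' @param model \code{motif_model}
#' @param score query score in bits (as reported by the scanner), or
#'   \code{-Inf} for p = 1
#' @param background optional override of the model background
#' @param precision integer scale factor, matching the scanner
#' @return tail probability in [0, 1]
#' @export
exact_score_pvalue <- function(model, score, background = NULL,
                               precision = 1000L) {
  dist <- score_distribution(model, background = background,
                             precision = precision)
  if (identical(score, -Inf)) return(1.0)
  thr <- round(score * precision)
  sum(dist$prob[dist$score_int >= thr])
}

#' Exact distribution of background W-mer scores
#'
#' @inheritParams exact_score_pvalue
#' @return data.frame with \code{score_int} (integer score) and
#'   \code{prob}, plus the offset range as attributes
#' @export
score_distribution <- function(model, background = NULL,
                               precision = 1000L) {
  bg <- background %||% model$background
  if (any(bg <= 0)) stop("degenerate background: zero frequency")
  bg <- bg / sum(bg)
  sm <- integer_score_matrix(model, precision)
  W <- ncol(sm)
  lo <- sum(apply(sm, 2L, min)); hi <- sum(apply(sm, 2L, max))
  span <- hi - lo + 1
  if (span > 5e7)
    stop("score range too wide for exact DP; use a coarser precision")
  probs <- numeric(span)   # index = score - lo + 1, built incrementally
  # start: before any column, score 0 with probability 1 at offset -lo
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(W)) {
    col <- sm[, j]
    new_lo <- cur_lo + min(col)
    new_len <- length(cur) + (max(col) - min(col))
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- col[b] - min(col)
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg[b] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  keep <- cur > 0
  data.frame(score_int = (cur_lo + seq_along(cur) - 1L)[keep],
             prob = cur[keep])
}

# Integer window scores of a sequence under a model's score matrix.
window_scores_int <- function(v, sm) {
  W <- ncol(sm)
  mi <- length(v) - W + 1L
  if (mi < 1L) return(integer(0L))
  sc <- numeric(mi)
  for (k in seq_len(W))
    sc <- sc + sm[cbind(v[k:(k + mi - 1L)], k)]
  sc
}

#' Scan a transcript with a motif model (log-odds PWM scan)
#'
#' Scores every sense-strand window, attaches the exact background
#' p-value of each score, keeps windows with p <= \code{p_threshold}, and
#' resolves overlaps greedily by ascending p-value (ties to the leftmost
#' start). Hits are labeled with the transcript region they fall in
#' (\code{spanning} if they cross a region boundary); \code{local_start}
#' gives the 1-based start within that region.
#'
#' @param model \code{motif_model}
#' @param tx \code{transcript_set}
#' @param ids transcripts to scan (default all)
#' @param p_threshold per-window p-value cutoff (default 1e-4)
#' @param precision integer score scale shared with
#'   \code{\link{exact_score_pvalue}}
#' @return data.frame of hits: transcript, start, end, region,
#'   local_start, score (bits), p_value
#' @export
log_odds_scan <- function(model, tx, ids = NULL, p_threshold = 1e-4,
                          precision = 1000L) {
  stopifnot(inherits(model, "motif_model"), inherits(tx, "transcript_set"))
  ids <- ids %||% tx$id
  sm <- integer_score_matrix(model, precision)
  W <- ncol(sm)
  dist <- score_distribution(model, precision = precision)
  # tail p for every achievable integer score, queried by lookup
  ord <- order(dist$score_int)
  si <- dist$score_int[ord]
  tailp <- rev(cumsum(rev(dist$prob[ord])))
  pval_of <- function(s) {
    i <- findInterval(s, si)            # largest si <= s (0 if none)
    j <- ifelse(i >= 1L & si[pmax(i, 1L)] == s, i, i + 1L)
    ifelse(j > length(si), 0, tailp[pmax(j, 1L)])
  }
  hits <- list()
  for (id in ids) {
    r <- tx_row(tx, id)
    if (nchar(r$seq) < W) stop("transcript '", id,
                               "' is shorter than the motif width")
    v <- seq_to_int(r$seq)
    sc <- window_scores_int(v, sm)
    p <- pval_of(sc)
    cand <- which(p <= p_threshold)
    if (!length(cand)) next
    cand <- cand[order(p[cand], cand)]
    taken <- integer(0L)
    sel <- integer(0L)
    for (j in cand) {
      if (any(abs(j - taken) < W)) next
      taken <- c(taken, j); sel <- c(sel, j)
    }
    sel <- sort(sel)
    reg <- vapply(sel, function(j)
      region_of(r$utr5_length, r$cds_length, r$utr3_length, j,
                j + W - 1L), character(1L))
    lstart <- vapply(seq_along(sel), function(k) {
      if (reg[k] == "spanning") NA_integer_
      else global_to_local(tx, id, sel[k])$pos
    }, integer(1L))
    hits[[id]] <- data.frame(transcript = id, start = sel,
                             end = sel + W - 1L, region = reg,
                             local_start = lstart,
                             score = sc[sel] / precision,
                             p_value = p[sel], stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), region = character(0),
                      local_start = integer(0), score = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Exact-substring motif search on transcripts
#'
#' Finds verbatim occurrences of a nucleotide string, with region labels
#' and region-local coordinates; the companion of the PWM scan for printed
#' motif instances.
#'
#' @param pattern nucleotide string (U accepted, mapped to T)
#' @param tx \code{transcript_set}
#' @param ids transcripts to search (default all)
#' @return data.frame: transcript, start, end, region, local_start,
#'   local_end
#' @export
exact_substring_scan <- function(pattern, tx, ids = NULL) {
  stopifnot(inherits(tx, "transcript_set"))
  pattern <- toupper(chartr("Uu", "Tt", pattern))
  w <- nchar(pattern)
  ids <- ids %||% tx$id
  rows <- list()
  for (id in ids) {
    r <- tx_row(tx, id)
    st <- gregexpr(pattern, r$seq, fixed = TRUE)[[1L]]
    if (st[1L] == -1L) next
    for (s in as.integer(st)) {
      reg <- region_of(r$utr5_length, r$cds_length, r$utr3_length, s,
                       s + w - 1L)
      ls <- if (reg == "spanning") NA_integer_
            else global_to_local(tx, id, s)$pos
      rows[[length(rows) + 1L]] <-
        data.frame(transcript = id, start = s, end = s + w - 1L,
                   region = reg, local_start = ls,
                   local_end = if (is.na(ls)) NA_integer_ else ls + w - 1L,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), region = character(0),
                      local_start = integer(0), local_end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group motif occurrence and hit-region breakdown
#'
#' For each regulation group: the fraction of transcripts with at least
#' one motif hit, and among hits the fractions falling in the 5'UTR, CDS,
#' 3'UTR or spanning a boundary. The motif may be a fitted
#' \code{motif_model} (PWM scan at \code{p_threshold}) or a consensus
#' string (exact substring search).
#'
#' @param motif \code{motif_model} or character consensus
#' @param tx \code{transcript_set}
#' @param groups data.frame with columns \code{feature} and \code{group}
#' @param p_threshold PWM scan cutoff (ignored for exact search)
#' @return data.frame, one row per group: group, n, n_with_hit,
#'   frac_with_hit, n_hits, frac_utr5, frac_cds, frac_utr3, frac_spanning
#' @export
region_occurrence_table <- function(motif, tx, groups,
                                    p_threshold = 1e-4) {
  stopifnot(is.data.frame(groups), all(c("feature", "group") %in%
                                       names(groups)))
  ids <- intersect(groups$feature, tx$id)
  hits <- if (inherits(motif, "motif_model"))
    log_odds_scan(motif, tx, ids = ids, p_threshold = p_threshold)
  else exact_substring_scan(motif, tx, ids = ids)
  out <- list()
  for (g in sort(unique(groups$group))) {
    gf <- intersect(groups$feature[groups$group == g], tx$id)
    n <- length(gf)
    h <- hits[hits$transcript %in% gf, , drop = FALSE]
    nh <- nrow(h)
    out[[length(out) + 1L]] <- data.frame(
      group = g, n = n, n_with_hit = length(unique(h$transcript)),
      frac_with_hit = if (n == 0L) NA_real_
                      else length(unique(h$transcript)) / n,
      n_hits = nh,
      frac_utr5 = if (nh == 0L) NA_real_ else mean(h$region == "utr5"),
      frac_cds = if (nh == 0L) NA_real_ else mean(h$region == "cds"),
      frac_utr3 = if (nh == 0L) NA_real_ else mean(h$region == "utr3"),
      frac_spanning = if (nh == 0L) NA_real_
                      else mean(h$region == "spanning"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
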