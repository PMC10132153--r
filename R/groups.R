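#' The 27-group regulation taxonomy
#'
#' Genes are classified by the triple (protein call, total-mRNA call,
#' monosome/polysome shift call). Each axis has three levels ordered
#' up / stable / down (for the shift axis: m_to_p / stable / p_to_m), and
#' the group id is
#' \deqn{g = 9p + 3r + s + 1}
#' with p, r, s the 0-based protein, RNA and shift indices. Group 4 is
#' protein up, mRNA stable, M-to-P shift; group 14 is stable on all three
#' axes; groups 19-27 are all protein down. A feature with \code{other} on
#' any axis is unassigned.
#'
#' @name regulation_groups
NULL

.protein_levels <- c(up = 0L, stable = 1L, down = 2L)
.shift_levels <- c(m_to_p = 0L, stable = 1L, p_to_m = 2L)

#' Assign 27-group ids from the three per-feature calls
#'
#' @param protein_call,rna_call character vectors over
#'   \{up, stable, down, other\}
#' @param shift_call character vector over \{m_to_p, stable, p_to_m, other\}
#' @return integer vector of group ids 1..27, \code{NA} where any call is
#'   \code{other}
#' @export
assign_group <- function(protein_call, rna_call, shift_call) {
  chk <- function(x, vocab, what) {
    bad <- setdiff(unique(x), c(names(vocab), "other"))
    if (length(bad)) stop("unknown ", what, " call token: ", bad[1L])
  }
  chk(protein_call, .protein_levels, "protein")
  chk(rna_call, .protein_levels, "RNA")
  chk(shift_call, .shift_levels, "shift")
  p <- .protein_levels[protein_call]
  r <- .protein_levels[rna_call]
  s <- .shift_levels[shift_call]
  unname(9L * p + 3L * r + s + 1L)
}

#' Decode a group id back into its (protein, RNA, shift) triple
#'
#' @param group_id integer vector in 1..27
#' @return data.frame with columns group, protein_call, rna_call, shift_call
#' @export
group_triple <- function(group_id) {
  group_id <- as.integer(group_id)
  if (any(is.na(group_id) | group_id < 1L | group_id > 27L))
    stop("group ids must lie in 1..27")
  g0 <- group_id - 1L
  data.frame(group = group_id,
             protein_call = names(.protein_levels)[g0 %/% 9L + 1L],
             rna_call = names(.protein_levels)[(g0 %/% 3L) %% 3L + 1L],
             shift_call = names(.shift_levels)[g0 %% 3L + 1L],
             stringsAsFactors = FALSE)
}

#' Groups whose protein and RNA directions disagree
#'
#' The ids whose protein index differs from the RNA index under the group
#' numbering: the features where the treatment effect on the protein does
#' not match its effect on the mRNA.
#'
#' @return integer vector of the 18 mismatch group ids
#' @export
mismatch_groups <- function() {
  tr <- group_triple(1:27)
  tr$group[tr$protein_call != tr$rna_call]
}

#' Combine the three call layers into regulation-group records
#'
#' Joins protein direction calls, total-RNA direction calls and shift
#' records by feature id (union of the three; a feature absent from a layer
#' is unassigned with the reason recorded) and assigns each feature its
#' group. Features with \code{other} on any axis are excluded from grouping.
#'
#' @param protein_calls,rna_calls data.frames from \code{\link{call_layer}}
#' @param shift_records data.frame from \code{\link{shift_layer}}
#' @return list with \code{records} (feature, three calls, group, reason)
#'   and \code{summary} (counts per group 1..27, plus unassigned reasons)
#' @export
classify_dataset <- function(protein_calls, rna_calls, shift_records) {
  feats <- union(union(protein_calls$feature, rna_calls$feature),
                 shift_records$feature)
  if (length(intersect(intersect(protein_calls$feature, rna_calls$feature),
                       shift_records$feature)) == 0L)
    stop("no features shared by the three call layers")
  pc <- protein_calls$call[match(feats, protein_calls$feature)]
  rc <- rna_calls$call[match(feats, rna_calls$feature)]
  sc <- shift_records$call[match(feats, shift_records$feature)]
  reason <- character(length(feats))
  reason[is.na(pc)] <- "missing_protein_call"
  reason[is.na(rc)] <- "missing_rna_call"
  reason[is.na(sc)] <- "missing_shift_call"
  complete <- reason == ""
  other_axis <- complete & (pc == "other" | rc == "other" | sc == "other")
  reason[other_axis] <- "other_on_an_axis"
  group <- rep(NA_integer_, length(feats))
  ok <- complete & !other_axis
  if (any(ok)) group[ok] <- assign_group(pc[ok], rc[ok], sc[ok])
  records <- data.frame(feature = feats, protein_call = pc, rna_call = rc,
                        shift_call = sc, group = group, reason = reason,
                        stringsAsFactors = FALSE)
  counts <- table(factor(records$group, levels = 1:27))
  summary <- data.frame(group = c(1:27, NA_integer_),
                        n = c(as.integer(counts), sum(is.na(group))),
                        stringsAsFactors = FALSE)
  reasons <- table(records$reason[records$reason != ""])
  list(records = records, summary = summary,
       unassigned_reasons = as.data.frame(reasons,
                                          stringsAsFactors = FALSE))
}

#' Correlation of PM-ratio change with protein change
#'
#' For a set of features (typically one regulation group), correlates
#' log X (the treated/control ratio of mean PM ratios) with the log protein
#' fold change. Rank-based (Spearman) by default, robust to the ratio
#' scale; Pearson on the logs is available.
#'
#' @param shift_records data.frame from \code{\link{shift_layer}}
#' @param protein_calls data.frame from \code{\link{call_layer}}
#' @param features optional feature ids to restrict to (e.g. one group)
#' @param method \code{"spearman"} (default) or \code{"pearson"}
#' @return list with estimate, p_value, n and method; if either vector is
#'   constant the correlation is undefined and returned as \code{NA} with
#'   \code{degenerate = TRUE}
#' @export
correlate_shift_protein <- function(shift_records, protein_calls,
                                    features = NULL,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  feats <- intersect(shift_records$feature, protein_calls$feature)
  if (!is.null(features)) feats <- intersect(feats, features)
  X <- shift_records$X[match(feats, shift_records$feature)]
  ratio <- protein_calls$ratio[match(feats, protein_calls$feature)]
  ok <- !is.na(X) & !is.na(ratio) & X > 0 & ratio > 0
  x <- log(X[ok]); y <- log(ratio[ok])
  n <- sum(ok)
  if (n < 3L) stop("insufficient features with defined X and protein ratio (need >= 3)")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_, n = n,
                method = method, degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = method, degenerate = FALSE)
}
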