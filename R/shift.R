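#' Per-sample polysome/monosome ratios
#'
#' Elementwise (polysome + pseudocount) / (monosome + pseudocount) for
#' sample-aligned replicate vectors. The pseudocount (default 0.5,
#' symmetric) keeps ratios finite for sparse features while preserving
#' ordering; with strictly positive counts the ratios converge to the
#' pseudocount-free values as the pseudocount goes to 0.
#'
#' @param monosome,polysome nonnegative numeric vectors, aligned by sample
#' @param pseudocount nonnegative value added to both fractions
#' @return numeric vector of PM ratios
#' @export
pm_ratio <- function(monosome, polysome, pseudocount = 0.5) {
  if (length(monosome) != length(polysome))
    stop("monosome and polysome vectors must be sample-aligned")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  den <- monosome + pseudocount
  if (any(den == 0)) {
    bad <- which(den == 0)[1L]
    nm <- names(monosome)[bad] %||% as.character(bad)
    stop("zero monosome denominator with zero pseudocount in sample ", nm)
  }
  (polysome + pseudocount) / den
}

#' Monosome/polysome shift verdict for one feature
#'
#' Compares PM ratios between conditions with a two-tailed t-test. For
#' significant features the X statistic (mean treated PM ratio divided by
#' mean control PM ratio) decides the direction: X > 1 is a monosome-to-
#' polysome shift (\code{m_to_p}), X < 1 the reverse (\code{p_to_m}).
#' Non-significant features are \code{stable} when the treated PM-ratio CI
#' is contained in the expanded control band, else \code{other}.
#'
#' @param pm_control,pm_treated PM-ratio vectors (length >= 2)
#' @param alpha significance level
#' @param params \code{\link{equivalence_params}}
#' @param paired paired t-test across matched units
#' @param feature feature id recorded in the result
#' @return one-row data.frame with feature, n per condition, p_value,
#'   significant, X, ci bounds and call
#' @export
shift_call <- function(pm_control, pm_treated, alpha = 0.05,
                       params = equivalence_params(), paired = FALSE,
                       feature = NA_character_) {
  pm_control <- as.numeric(pm_control); pm_treated <- as.numeric(pm_treated)
  if (length(pm_control) < 2L || length(pm_treated) < 2L)
    stop("insufficient replicates: need >= 2 PM ratios per condition")
  mc <- mean(pm_control)
  if (mc <= 0) stop("undefined X: control PM ratios are all zero")
  p <- two_tailed_p(pm_control, pm_treated, paired = paired)
  X <- mean(pm_treated) / mc
  cic <- mean_ci(pm_control, params$ci_level)
  cit <- mean_ci(pm_treated, params$ci_level)
  sig <- p < alpha
  call <- if (sig) {
    if (X > 1) "m_to_p" else if (X < 1) "p_to_m" else "other"
  } else if (equivalence_contained(cic, cit, params)) "stable" else "other"
  data.frame(feature = feature, n_control = length(pm_control),
             n_treated = length(pm_treated), p_value = p, significant = sig,
             X = X, ci_control_low = cic[1L], ci_control_high = cic[2L],
             ci_treated_low = cit[1L], ci_treated_high = cit[2L],
             call = call, stringsAsFactors = FALSE)
}

#' Shift verdicts for all features of a monosome/polysome table pair
#'
#' PM ratios are computed per sample (within-sample ratios, so sequencing
#' depth largely cancels) and then tested across samples. Samples of the
#' two fraction tables are matched by (condition, unit); a metadata mismatch
#' is an error. Features present in only one fraction are excluded and
#' reported in the \code{excluded} attribute. The significance gate is raw
#' p (default) or Benjamini-Hochberg across features.
#'
#' @param monosome,polysome abundance_table objects for the two fractions
#' @param alpha significance level (or q for the bh gate)
#' @param params \code{\link{equivalence_params}}
#' @param pseudocount see \code{\link{pm_ratio}}
#' @param gate \code{"raw"} or \code{"bh"}
#' @param paired paired t-test across matched units
#' @param scale_columns divide each column by its total (per-fraction
#'   column scaling for unequal fraction depths; off by default)
#' @return data.frame of shift records with per-sample PM ratios in the
#'   \code{pm} attribute and excluded feature ids in \code{excluded}
#' @export
shift_layer <- function(monosome, polysome, alpha = 0.05,
                        params = equivalence_params(), pseudocount = 0.5,
                        gate = c("raw", "bh"), paired = FALSE,
                        scale_columns = FALSE) {
  stopifnot(inherits(monosome, "abundance_table"),
            inherits(polysome, "abundance_table"))
  gate <- match.arg(gate)
  mm <- monosome$metadata; pm <- polysome$metadata
  key_m <- paste(mm$condition, mm$unit, sep = ":")
  key_p <- paste(pm$condition, pm$unit, sep = ":")
  if (anyDuplicated(key_m) || anyDuplicated(key_p))
    stop("duplicate (condition, unit) sample in a fraction table")
  if (!setequal(key_m, key_p))
    stop("sample metadata mismatch between monosome and polysome tables")
  ord <- match(key_m, key_p)
  mvals <- monosome$values
  pvals <- polysome$values[, ord, drop = FALSE]
  if (scale_columns) {
    mvals <- sweep(mvals, 2L, colSums(mvals, na.rm = TRUE), "/")
    pvals <- sweep(pvals, 2L, colSums(pvals, na.rm = TRUE), "/")
  }
  common <- intersect(rownames(mvals), rownames(pvals))
  excluded <- setdiff(union(rownames(mvals), rownames(pvals)), common)
  if (length(common) == 0L) stop("no features shared by the two fractions")
  ctrl <- mm$condition == "control"; trt <- mm$condition == "treated"
  ctrl_ord <- order(mm$unit[ctrl]); trt_ord <- order(mm$unit[trt])
  rows <- vector("list", length(common))
  pm_mat <- matrix(NA_real_, length(common), ncol(mvals),
                   dimnames = list(common, colnames(monosome$values)))
  for (i in seq_along(common)) {
    f <- common[i]
    r <- pm_ratio(mvals[f, ], pvals[f, ], pseudocount)
    pm_mat[i, ] <- r
    rows[[i]] <- shift_call(r[ctrl][ctrl_ord], r[trt][trt_ord],
                            alpha = alpha, params = params, paired = paired,
                            feature = f)
  }
  out <- do.call(rbind, rows)
  out$q_flag <- bh_flags(out$p_value, q = alpha)
  out$gate <- gate
  if (gate == "bh") {
    # re-finalize the verdicts under the BH gate
    for (i in seq_len(nrow(out))) {
      sig <- out$q_flag[i]
      out$significant[i] <- sig
      out$call[i] <- if (sig) {
        if (out$X[i] > 1) "m_to_p" else if (out$X[i] < 1) "p_to_m" else "other"
      } else if (equivalence_contained(
                   c(out$ci_control_low[i], out$ci_control_high[i]),
                   c(out$ci_treated_low[i], out$ci_treated_high[i]),
                   params)) "stable" else "other"
    }
  }
  out$pseudocount <- pseudocount
  attr(out, "pm") <- pm_mat
  attr(out, "excluded") <- excluded
  out
}
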