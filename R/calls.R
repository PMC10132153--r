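#' Parameters of the confidence-interval containment equivalence rule
#'
#' A non-significant feature is called \emph{stable} when the treated-group
#' 95\% CI of the mean lies completely within the control CI expanded to
#' \code{lower_factor} (default 70\%) of its low end and \code{upper_factor}
#' (default 130\%) of its high end. Negative control lower bounds are
#' clamped to 0 before the factor is applied (abundances are nonnegative;
#' without clamping the band would invert for negative lows).
#'
#' @param ci_level two-sided confidence level for the per-condition CIs
#' @param upper_factor multiplier on the high end of the control CI
#' @param lower_factor multiplier on the low end of the control CI
#' @param clamp_nonnegative clamp the control low end at 0 first
#' @return list of class \code{equivalence_params}
#' @export
equivalence_params <- function(ci_level = 0.95, upper_factor = 1.30,
                               lower_factor = 0.70,
                               clamp_nonnegative = TRUE) {
  if (!(ci_level > 0 && ci_level < 1)) stop("invalid field 'ci_level'")
  if (!(lower_factor > 0 && lower_factor <= 1)) stop("invalid field 'lower_factor'")
  if (upper_factor < 1) stop("invalid field 'upper_factor'")
  structure(list(ci_level = ci_level, upper_factor = upper_factor,
                 lower_factor = lower_factor,
                 clamp_nonnegative = isTRUE(clamp_nonnegative)),
            class = "equivalence_params")
}

#' Two-sided t-based confidence interval of a mean
#'
#' mean +/- t((1+level)/2, n-1) * sd/sqrt(n).
#'
#' @param values numeric replicate values (length >= 2, finite)
#' @param level confidence level in (0,1)
#' @return numeric c(low, high)
#' @export
mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("insufficient replicates: need >= 2 values for a CI")
  if (any(!is.finite(values))) stop("values must be finite")
  m <- mean(values)
  half <- qt((1 + level) / 2, df = n - 1L) * sd(values) / sqrt(n)
  c(m - half, m + half)
}

#' Equivalence by containment of the treated CI in the expanded control band
#'
#' @param ci_control,ci_treated numeric c(low, high), low <= high
#' @param params \code{\link{equivalence_params}}
#' @return logical: is \code{ci_treated} completely inside the band
#'   [lower_factor * max(control low, 0), upper_factor * control high]?
#' @export
equivalence_contained <- function(ci_control, ci_treated,
                                  params = equivalence_params()) {
  stopifnot(length(ci_control) == 2L, length(ci_treated) == 2L)
  if (ci_control[1L] > ci_control[2L] || ci_treated[1L] > ci_treated[2L])
    stop("malformed interval: low > high")
  lo <- ci_control[1L]
  if (params$clamp_nonnegative) lo <- max(lo, 0)
  band <- c(params$lower_factor * lo, params$upper_factor * ci_control[2L])
  ci_treated[1L] >= band[1L] && ci_treated[2L] <= band[2L]
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up FDR control at level \code{q}, via \code{stats::p.adjust}.
#'
#' @param p_values numeric vector in [0,1]
#' @param q target false-discovery rate
#' @return logical vector of rejections (empty input gives empty output)
#' @export
bh_flags <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(logical(0L))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH") <= q
}

# Two-tailed t-test p-value with the package's zero-variance convention:
# both groups constant and equal -> p = 1 (no evidence of change); both
# constant but unequal -> p = 0.
two_tailed_p <- function(control, treated, paired = FALSE,
                         var_equal = TRUE) {
  if (paired && length(control) != length(treated))
    stop("paired test needs equal-length vectors")
  degenerate <- if (paired) sd(treated - control) == 0
                else sd(control) == 0 && sd(treated) == 0
  if (degenerate) {
    return(if (isTRUE(all.equal(mean(control), mean(treated)))) 1 else 0)
  }
  stats::t.test(treated, control, paired = paired,
                var.equal = var_equal)$p.value
}

finalize_call <- function(significant, ratio, ci_control, ci_treated,
                          params) {
  if (significant) {
    if (ratio > 1) "up" else if (ratio < 1) "down" else "other"
  } else if (equivalence_contained(ci_control, ci_treated, params)) {
    "stable"
  } else {
    "other"
  }
}

#' Direction call for one feature from control and treated replicates
#'
#' Computes a two-tailed t-test p-value, the treated/control ratio of means
#' (a linear fold change), the per-condition CIs of the mean, and the
#' verdict: \code{up}/\code{down} when significant (by ratio direction),
#' \code{stable} when non-significant and the treated CI is contained in the
#' expanded control band, \code{other} otherwise.
#'
#' @param control,treated numeric replicate vectors (length >= 2)
#' @param alpha significance level for the raw-p gate
#' @param params \code{\link{equivalence_params}}
#' @param paired paired t-test across matched units (default unpaired)
#' @param var_equal pooled-variance t-test (default); \code{FALSE} for Welch
#' @param feature feature id recorded in the result
#' @return one-row data.frame with feature, n_control, n_treated, p_value,
#'   significant, ratio, ci bounds and call
#' @export
call_feature <- function(control, treated, alpha = 0.05,
                         params = equivalence_params(), paired = FALSE,
                         var_equal = TRUE, feature = NA_character_) {
  control <- as.numeric(control); treated <- as.numeric(treated)
  if (length(control) < 2L || length(treated) < 2L)
    stop("insufficient replicates: need >= 2 values per condition")
  if (anyNA(control) || anyNA(treated))
    stop("missing replicate values; drop or impute before calling")
  mc <- mean(control)
  if (mc <= 0) stop("undefined ratio: control mean is not positive")
  p <- two_tailed_p(control, treated, paired = paired, var_equal = var_equal)
  ratio <- mean(treated) / mc
  cic <- mean_ci(control, params$ci_level)
  cit <- mean_ci(treated, params$ci_level)
  sig <- p < alpha
  call <- finalize_call(sig, ratio, cic, cit, params)
  data.frame(feature = feature, n_control = length(control),
             n_treated = length(treated), p_value = p, significant = sig,
             ratio = ratio, ci_control_low = cic[1L],
             ci_control_high = cic[2L], ci_treated_low = cit[1L],
             ci_treated_high = cit[2L], call = call,
             stringsAsFactors = FALSE)
}

#' Direction calls for every feature of one layer
#'
#' Runs \code{\link{call_feature}} per feature of the requested layer.
#' Features failing preconditions (fewer than 2 non-missing replicates in a
#' condition, or a nonpositive control mean) are emitted with
#' \code{call = "other"} and the reason recorded. The significance gate is
#' either the raw p-value (\code{gate = "raw"}, p < alpha) or
#' Benjamini-Hochberg across the layer (\code{gate = "bh"}, at q = alpha);
#' the gate used is recorded per row, and the BH flag is reported either
#' way.
#'
#' @param x abundance_table containing the layer
#' @param layer layer label to analyse
#' @param alpha significance level (raw gate) or FDR level q (bh gate)
#' @param params \code{\link{equivalence_params}}
#' @param gate \code{"raw"} or \code{"bh"}
#' @param paired,var_equal t-test flavor, as in \code{\link{call_feature}}
#' @return data.frame of direction calls, one row per feature, with columns
#'   feature, layer, n_control, n_treated, p_value, q_flag, significant,
#'   gate, ratio, ci bounds, call, reason
#' @export
call_layer <- function(x, layer, alpha = 0.05,
                       params = equivalence_params(),
                       gate = c("raw", "bh"), paired = FALSE,
                       var_equal = TRUE) {
  stopifnot(inherits(x, "abundance_table"))
  gate <- match.arg(gate)
  md <- x$metadata
  sel <- md$layer == layer
  if (!any(sel)) stop("layer '", layer, "' absent from the table")
  for (cond in c("control", "treated"))
    if (!any(sel & md$condition == cond))
      stop("layer '", layer, "' has no ", cond, " samples")
  sub <- subset_samples(x, layer = layer)
  feats <- rownames(sub$values)
  n <- length(feats)
  out <- data.frame(feature = feats, layer = layer,
                    n_control = NA_integer_, n_treated = NA_integer_,
                    p_value = NA_real_, q_flag = NA, significant = NA,
                    gate = gate, ratio = NA_real_,
                    ci_control_low = NA_real_, ci_control_high = NA_real_,
                    ci_treated_low = NA_real_, ci_treated_high = NA_real_,
                    call = "other", reason = "", stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  ctrl_cols <- sub$metadata$condition == "control"
  trt_cols <- sub$metadata$condition == "treated"
  ctrl_units <- order(sub$metadata$unit[ctrl_cols])
  trt_units <- order(sub$metadata$unit[trt_cols])
  cvals <- sub$values[, ctrl_cols, drop = FALSE][, ctrl_units, drop = FALSE]
  tvals <- sub$values[, trt_cols, drop = FALSE][, trt_units, drop = FALSE]
  for (i in seq_len(n)) {
    cv <- cvals[i, ]; tv <- tvals[i, ]
    if (paired) {
      ok <- !is.na(cv) & !is.na(tv)
      cv <- cv[ok]; tv <- tv[ok]
    } else {
      cv <- cv[!is.na(cv)]; tv <- tv[!is.na(tv)]
    }
    out$n_control[i] <- length(cv); out$n_treated[i] <- length(tv)
    if (length(cv) < 2L || length(tv) < 2L) {
      out$reason[i] <- "insufficient_replicates"
      next
    }
    if (mean(cv) <= 0) {
      out$reason[i] <- "zero_control_mean"
      next
    }
    p <- two_tailed_p(cv, tv, paired = paired, var_equal = var_equal)
    cic <- mean_ci(cv, params$ci_level)
    cit <- mean_ci(tv, params$ci_level)
    out$p_value[i] <- p
    out$ratio[i] <- mean(tv) / mean(cv)
    out$ci_control_low[i] <- cic[1L]; out$ci_control_high[i] <- cic[2L]
    out$ci_treated_low[i] <- cit[1L]; out$ci_treated_high[i] <- cit[2L]
  }
  tested <- !is.na(out$p_value)
  out$q_flag[tested] <- bh_flags(out$p_value[tested], q = alpha)
  out$significant[tested] <- if (gate == "bh") out$q_flag[tested]
                             else out$p_value[tested] < alpha
  for (i in which(tested)) {
    out$call[i] <- finalize_call(
      out$significant[i], out$ratio[i],
      c(out$ci_control_low[i], out$ci_control_high[i]),
      c(out$ci_treated_low[i], out$ci_treated_high[i]), params)
  }
  out
}
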