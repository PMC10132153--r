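#' Run configuration for a full classification run
#'
#' Bundles and validates the tunable parameters of the pipeline; echoed
#' into reports and written table headers.
#'
#' @param alpha per-test significance level
#' @param q FDR level for the BH gate
#' @param params \code{\link{equivalence_params}}
#' @param pseudocount PM-ratio pseudocount
#' @param w_min,w_max motif discovery width range
#' @param scan_p PWM scan p-value threshold
#' @param uorf_mode uORF start-codon mode
#' @param paired paired t-tests across units
#' @param seed RNG seed
#' @return list of class \code{run_config}
#' @export
run_config <- function(alpha = 0.05, q = 0.05,
                       params = equivalence_params(), pseudocount = 0.5,
                       w_min = 10L, w_max = 25L, scan_p = 1e-4,
                       uorf_mode = c("atg_only", "atg_plus_alternatives"),
                       paired = FALSE, seed = 1L) {
  uorf_mode <- match.arg(uorf_mode)
  fail <- function(f) stop("invalid configuration field '", f, "'")
  if (!(alpha > 0 && alpha < 1)) fail("alpha")
  if (!(q > 0 && q < 1)) fail("q")
  if (pseudocount < 0) fail("pseudocount")
  if (!(w_min >= 2 && w_min <= w_max)) fail("w_min")
  if (!(scan_p > 0 && scan_p <= 1)) fail("scan_p")
  structure(list(alpha = alpha, q = q, params = params,
                 pseudocount = pseudocount, w_min = as.integer(w_min),
                 w_max = as.integer(w_max), scan_p = scan_p,
                 uorf_mode = uorf_mode, paired = isTRUE(paired),
                 seed = as.integer(seed)),
            class = "run_config")
}

fmt_dist <- function(calls, vocab) {
  tab <- table(factor(calls, levels = vocab))
  paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = "  ")
}

#' Plain-text summary report of a classification run
#'
#' Assembles the per-layer call distributions, the shift distribution, the
#' group-size table (one row per group 1..27 plus unassigned) and the
#' motif/uORF summaries into a character vector of report lines; sections
#' whose inputs are absent are marked so. Rerunning with identical inputs
#' and config yields an identical report.
#'
#' @param protein_calls,rna_calls outputs of \code{\link{call_layer}}
#'   (either may be NULL)
#' @param shifts output of \code{\link{shift_layer}} (or NULL)
#' @param classification output of \code{\link{classify_dataset}} (or NULL)
#' @param motif_table output of \code{\link{region_occurrence_table}}
#' @param uorf_summary output of \code{\link{uorf_prevalence_by_group}}
#' @param config \code{\link{run_config}} echoed at the top
#' @return character vector of report lines
#' @export
run_report <- function(protein_calls = NULL, rna_calls = NULL,
                       shifts = NULL, classification = NULL,
                       motif_table = NULL, uorf_summary = NULL,
                       config = NULL) {
  if (is.null(protein_calls) && is.null(rna_calls) && is.null(shifts) &&
      is.null(classification) && is.null(motif_table) &&
      is.null(uorf_summary))
    stop("at least one stage output is required")
  L <- c(sprintf("riboshift %s run report", rs_version()))
  if (!is.null(config)) {
    L <- c(L, sprintf("seed: %d", config$seed),
           sprintf("config: %s", config_hash(config)),
           sprintf("alpha=%g q=%g pseudocount=%g widths=[%d,%d] scan_p=%g uorf=%s paired=%s",
                   config$alpha, config$q, config$pseudocount,
                   config$w_min, config$w_max, config$scan_p,
                   config$uorf_mode, config$paired))
  }
  dircalls <- c("up", "stable", "down", "other")
  L <- c(L, "", "[direction calls]")
  L <- c(L, if (is.null(protein_calls)) "protein: absent"
         else sprintf("protein: %s", fmt_dist(protein_calls$call, dircalls)))
  L <- c(L, if (is.null(rna_calls)) "total RNA: absent"
         else sprintf("total RNA: %s", fmt_dist(rna_calls$call, dircalls)))
  L <- c(L, "", "[monosome/polysome shift]")
  L <- c(L, if (is.null(shifts)) "shift: absent"
         else sprintf("shift: %s",
                      fmt_dist(shifts$call,
                               c("m_to_p", "stable", "p_to_m", "other"))))
  L <- c(L, "", "[regulation groups]")
  if (is.null(classification)) {
    L <- c(L, "groups: absent")
  } else {
    s <- classification$summary
    for (i in seq_len(nrow(s)))
      L <- c(L, sprintf("group %s\t%d",
                        ifelse(is.na(s$group[i]), "unassigned",
                               as.character(s$group[i])), s$n[i]))
  }
  L <- c(L, "", "[motif occurrence]")
  if (is.null(motif_table)) {
    L <- c(L, "motifs: absent")
  } else {
    for (i in seq_len(nrow(motif_table)))
      L <- c(L, sprintf("group %s\tn=%d\tfrac_with_hit=%s",
                        as.character(motif_table$group[i]),
                        motif_table$n[i],
                        format(motif_table$frac_with_hit[i], digits = 4)))
  }
  L <- c(L, "", "[uORFs]")
  if (is.null(uorf_summary)) {
    L <- c(L, "uORFs: absent")
  } else {
    L <- c(L, sprintf("mode: %s (starts %s); homogeneity %s p=%s",
                      uorf_summary$mode,
                      paste(uorf_summary$start_codons, collapse = ","),
                      uorf_summary$method,
                      format(uorf_summary$p_value, digits = 4)))
    for (i in seq_len(nrow(uorf_summary$table)))
      L <- c(L, sprintf("group %s\tn=%d\tfrac_uorf=%s",
                        as.character(uorf_summary$table$group[i]),
                        uorf_summary$table$n[i],
                        format(uorf_summary$table$frac[i], digits = 4)))
  }
  L
}

#' The published group-4 consensus motif
#'
#' The 20-nucleotide GA-rich consensus of the motif shared by group-4
#' mRNAs (protein up, total mRNA stable, monosome-to-polysome shift),
#' used as the default planted motif in simulations and as the bait
#' sequence in RNA pull-down work.
#'
#' @return character scalar, width 20
#' @export
group4_motif <- function() "GGAGGAGGAGGAGGAGGAGG"
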