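#' @importFrom stats rlnorm rnorm rnbinom runif p.adjust t.test cor.test
#'   chisq.test fisher.test
NULL

DNA_BASES <- c("A", "C", "G", "T")

seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains characters outside A/C/G/T")
  v
}

#' Zero-order background frequencies of a sequence set
#'
#' @param sequences character vector of A/C/G/T sequences
#' @param pseudocount added per base before normalising
#' @return named numeric vector of length 4 summing to 1
#' @export
background_frequencies <- function(sequences, pseudocount = 1) {
  counts <- rep(pseudocount, 4L)
  names(counts) <- DNA_BASES
  for (s in sequences) {
    t <- tabulate(seq_to_int(s), nbins = 4L)
    counts <- counts + t
  }
  counts / sum(counts)
}

#' Consensus string of a position probability matrix
#'
#' Per-column argmax; ties broken alphabetically.
#'
#' @param pwm 4 x W matrix with rownames A/C/G/T
#' @return character string of length W
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
}

# PWM initialised from a seed word: weight on the seed base, remainder
# spread uniformly.
pwm_from_word <- function(word_int, weight = 0.7) {
  W <- length(word_int)
  pwm <- matrix((1 - weight) / 3, 4L, W, dimnames = list(DNA_BASES, NULL))
  pwm[cbind(word_int, seq_len(W))] <- weight
  pwm
}

# One EM fit from a given initial PWM; returns model with loglik trace.
# The M-step uses a small pseudocount, so the raw likelihood can dip by a
# hair once converged; the loop stops and reverts to the previous
# parameters on any decrease, keeping the recorded trace non-decreasing.
zoops_em_one <- function(ints, W, background, pwm, gamma, max_iter, tol,
                         pseudocount) {
  n <- length(ints)
  logbg <- log(background)
  logPbg <- vapply(ints, function(v) sum(logbg[v]), numeric(1L))
  m <- lengths(ints) - W + 1L
  trace <- numeric(0L)
  loglik_old <- -Inf
  pwm_prev <- pwm; gamma_prev <- gamma
  for (iter in seq_len(max_iter)) {
    logratio <- log(pwm) - logbg   # 4 x W, recycled by column
    counts <- matrix(pseudocount, 4L, W, dimnames = list(DNA_BASES, NULL))
    zsum <- 0
    loglik <- 0
    for (i in seq_len(n)) {
      v <- ints[[i]]
      mi <- m[i]
      llr <- numeric(mi)
      for (k in seq_len(W))
        llr <- llr + logratio[cbind(v[k:(k + mi - 1L)], k)]
      top <- max(0, llr)     # log-sum-exp guard
      a0 <- (1 - gamma) * exp(-top)
      aj <- (gamma / mi) * exp(llr - top)
      denom <- a0 + sum(aj)
      loglik <- loglik + log(denom) + top + logPbg[i]
      z <- aj / denom
      zsum <- zsum + sum(z)
      for (k in seq_len(W)) {
        b <- v[k:(k + mi - 1L)]
        counts[, k] <- counts[, k] +
          vapply(1:4, function(bb) sum(z[b == bb]), numeric(1L))
      }
    }
    if (loglik < loglik_old) {
      pwm <- pwm_prev; gamma <- gamma_prev
      break
    }
    trace <- c(trace, loglik)
    pwm_prev <- pwm; gamma_prev <- gamma
    pwm <- sweep(counts, 2L, colSums(counts), "/")
    gamma <- min(max(zsum / n, 1e-6), 1 - 1e-6)
    if (is.finite(loglik_old) && abs(loglik - loglik_old) < tol) break
    loglik_old <- loglik
  }
  list(pwm = pwm, gamma = gamma, loglik = trace[length(trace)],
       loglik_trace = trace, loglik_background = sum(logPbg))
}

#' ZOOPS expectation-maximization motif discovery at one width
#'
#' Fits the zero-or-one-occurrence-per-sequence mixture model: each
#' sequence contains, with prior probability gamma, one motif occurrence at
#' a uniformly chosen position, and background elsewhere. The E-step
#' computes per-sequence posteriors over (no occurrence, occurrence at each
#' window); the M-step re-estimates the position probability matrix from
#' expected aligned counts (pseudocount 0.01 per cell) and gamma from the
#' expected occurrence count. Starts are seeded from the highest-rarity
#' (lowest background probability) distinct data W-mers plus random PWMs;
#' the best start by final log-likelihood is returned. The observed-data
#' log-likelihood is non-decreasing across iterations; the full trace is
#' kept in the model.
#'
#' @param sequences character vector of A/C/G/T sequences, all of length
#'   >= W
#' @param W motif width; must lie in [10, 25] unless
#'   \code{check_width = FALSE}
#' @param background named base-frequency vector; default estimated from
#'   the input
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change)
#' @param seed RNG seed used for candidate sampling and the random starts
#'   (determinism)
#' @param n_starts number of screened data-seeded starts run to
#'   convergence; 2 random starts are added
#' @param n_candidates number of data W-mers screened by a single EM
#'   iteration before the best \code{n_starts} are refined
#' @param pseudocount per-cell M-step pseudocount
#' @param check_width enforce the 10..25 width range
#' @return list of class \code{motif_model}: width, pwm, consensus,
#'   background, gamma, loglik, loglik_background, loglik_trace, n_seq
#' @export
zoops_em <- function(sequences, W, background = NULL, max_iter = 200L,
                     tol = 1e-6, seed = 1L, n_starts = 5L,
                     n_candidates = 100L, pseudocount = 0.01,
                     check_width = TRUE) {
  if (length(sequences) == 0L) stop("empty sequence set")
  if (check_width && (W < 10L || W > 25L))
    stop("motif width must lie in [10, 25] (set check_width = FALSE to override)")
  short <- which(nchar(sequences) < W)
  if (length(short)) {
    nm <- names(sequences)[short[1L]] %||% as.character(short[1L])
    stop("sequence ", nm, " is shorter than the motif width ", W)
  }
  set.seed(seed)
  ints <- lapply(sequences, seq_to_int)
  if (is.null(background)) background <- background_frequencies(sequences)
  if (any(background <= 0)) stop("degenerate background: zero frequency")
  background <- background / sum(background)

  # candidate starts: data W-mers sampled across sequences, screened by
  # one EM iteration; the n_starts best by screened likelihood are run to
  # convergence, plus 2 random-PWM starts
  windows <- do.call(rbind, lapply(seq_along(ints), function(i) {
    mi <- length(ints[[i]]) - W + 1L
    cbind(i, seq_len(mi))
  }))
  n_cand <- min(n_candidates, nrow(windows))
  pick <- if (n_cand < nrow(windows))
    windows[sample.int(nrow(windows), n_cand), , drop = FALSE]
  else windows
  cand <- unique(t(apply(pick, 1L, function(w)
    ints[[w[1L]]][w[2L]:(w[2L] + W - 1L)])))
  screened <- vapply(seq_len(nrow(cand)), function(r) {
    zoops_em_one(ints, W, background, pwm_from_word(cand[r, ]),
                 gamma = 0.5, max_iter = 1L, tol = tol,
                 pseudocount = pseudocount)$loglik
  }, numeric(1L))
  top <- order(-screened)[seq_len(min(n_starts, nrow(cand)))]
  starts <- lapply(top, function(r) pwm_from_word(cand[r, ]))
  for (r in 1:2) {  # random starts
    rnd <- matrix(runif(4L * W, 0.5, 1.5), 4L, W,
                  dimnames = list(DNA_BASES, NULL))
    starts <- c(starts, list(sweep(rnd, 2L, colSums(rnd), "/")))
  }
  best <- NULL
  for (pwm0 in starts) {
    fit <- zoops_em_one(ints, W, background, pwm0, gamma = 0.5,
                        max_iter = max_iter, tol = tol,
                        pseudocount = pseudocount)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  model <- list(width = W, pwm = best$pwm,
                consensus = pwm_consensus(best$pwm),
                background = background, gamma = best$gamma,
                loglik = best$loglik,
                loglik_background = best$loglik_background,
                loglik_trace = best$loglik_trace,
                n_seq = length(sequences))
  class(model) <- "motif_model"
  model
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: width %d, consensus %s, gamma %.3f, logLik %.2f\n",
              x$width, x$consensus, x$gamma, x$loglik))
  invisible(x)
}

#' Motif discovery over a range of widths
#'
#' Runs \code{\link{zoops_em}} at every width in [W_min, W_max] and selects
#' the overall best model by a penalized log-likelihood ratio against the
#' background-only model: LLR - (3W + 1)/2 * log(n), with n the number of
#' sequences (each contributes at most one occurrence) and 3W + 1 the
#' parameter count of a width-W model (a BIC-type penalty, so widening the
#' motif must buy more than chance-level likelihood).
#'
#' @inheritParams zoops_em
#' @param W_min,W_max inclusive width range (default 10..25)
#' @return list with \code{best} (motif_model), \code{by_width}
#'   (data.frame width/consensus/loglik/score) and \code{models}
#' @export
discover <- function(sequences, W_min = 10L, W_max = 25L,
                     background = NULL, max_iter = 200L, tol = 1e-6,
                     seed = 1L, n_starts = 5L, n_candidates = 100L) {
  if (length(sequences) == 0L) stop("empty sequence set")
  if (W_min > W_max) stop("W_min must not exceed W_max")
  widths <- seq.int(W_min, W_max)
  models <- vector("list", length(widths))
  score <- numeric(length(widths))
  for (i in seq_along(widths)) {
    Wi <- widths[i]
    models[[i]] <- zoops_em(sequences, Wi, background = background,
                            max_iter = max_iter, tol = tol,
                            seed = seed + i, n_starts = n_starts,
                            n_candidates = n_candidates,
                            check_width = FALSE)
    llr <- models[[i]]$loglik - models[[i]]$loglik_background
    score[i] <- llr - (3 * Wi + 1) / 2 * log(length(sequences))
  }
  by_width <- data.frame(
    width = widths,
    consensus = vapply(models, `[[`, character(1L), "consensus"),
    gamma = vapply(models, `[[`, numeric(1L), "gamma"),
    loglik = vapply(models, `[[`, numeric(1L), "loglik"),
    score = score, stringsAsFactors = FALSE)
  list(best = models[[which.max(score)]], by_width = by_width,
       models = models)
}
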