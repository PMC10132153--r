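# Fixtures shared across tests; everything is generated in code.

# n replicate values with an exact mean and sd (n = 4 base pattern)
values_with <- function(mean, sd, n = 4L) {
  z <- seq(-1.5, 1.5, length.out = n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# random background sequences with one exact copy of `motif` planted in each
planted_sequences <- function(n = 20L, len = 100L,
                              motif = group4_motif(), seed = 42L) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  w <- nchar(motif)
  vapply(seq_len(n), function(i) {
    s <- paste(sample(nt, len, replace = TRUE), collapse = "")
    pos <- sample.int(len - w + 1L, 1L)
    paste0(substr(s, 1L, pos - 1L), motif, substr(s, pos + w, len))
  }, character(1L))
}

# small random motif model for scan/p-value tests
random_model <- function(W, seed = 1L, uniform_bg = FALSE) {
  set.seed(seed)
  pwm <- matrix(stats::runif(4L * W, 0.05, 1), 4L, W,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- sweep(pwm, 2L, colSums(pwm), "/")
  bg <- if (uniform_bg) rep(0.25, 4L) else {
    b <- stats::runif(4L, 0.1, 1); b / sum(b)
  }
  names(bg) <- c("A", "C", "G", "T")
  structure(list(width = W, pwm = pwm, consensus = pwm_consensus(pwm),
                 background = bg, gamma = 0.5, loglik = NA_real_,
                 loglik_background = NA_real_,
                 loglik_trace = numeric(0L), n_seq = 1L),
            class = "motif_model")
}

# brute-force tail probability by enumerating all 4^W words on the same
# integer score scale as the scanner
enumerated_pvalue <- function(model, score_int) {
  sm <- integer_score_matrix(model)
  W <- ncol(sm)
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- rowSums(matrix(sm[cbind(as.vector(words),
                                rep(seq_len(W), each = nrow(words)))],
                       nrow(words)))
  pr <- apply(words, 1L, function(w) prod(model$background[w]))
  vapply(score_int, function(s) sum(pr[sc >= s]), numeric(1L))
}

# independent uORF finder: brute-force triplet enumeration on the raw
# sequence string, written against the same definition as find_uorfs but
# with none of its code
brute_uorfs <- function(seq, utr5_len, mode = "atg_only",
                        alt_codons = c("CTG", "GTG", "TTG")) {
  starts <- if (mode == "atg_only") "ATG" else c("ATG", alt_codons)
  stops <- c("TAA", "TAG", "TGA")
  len <- nchar(seq)
  out <- list()
  p <- 0L
  while (p < utr5_len) {
    p <- p + 1L
    if (p + 2L > len) break
    if (!substr(seq, p, p + 2L) %in% starts) next
    q <- p + 3L
    end <- NA_integer_
    while (q + 2L <= len) {
      if (substr(seq, q, q + 2L) %in% stops) { end <- q + 2L; break }
      q <- q + 3L
    }
    out[[length(out) + 1L]] <- data.frame(
      start = p, end = end,
      classification = if (is.na(end)) "no_stop"
                       else if (end <= utr5_len) "contained"
                       else "overlapping")
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(0), end = integer(0),
                  classification = character(0))
}
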