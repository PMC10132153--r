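#' Configuration of the synthetic multi-omic dataset generator
#'
#' Describes a paired design of \code{n_units} cell lines measured under
#' two conditions (control/treated) in five layers (protein, total, free,
#' monosome, polysome RNA), with per-feature lognormal baselines and
#' multiplicative condition effects organised by intended regulation group.
#'
#' @param n_units number of paired units (cell lines); one replicate column
#'   per unit per condition per layer
#' @param features_per_group named integer vector mapping group ids (1..27)
#'   to feature counts, e.g. \code{c("4" = 200, "14" = 200)}
#' @param baseline_log_mean,baseline_log_sd log-scale mean and sd of the
#'   per-feature lognormal baseline abundance
#' @param effect_up,effect_down fold changes applied on the protein/RNA
#'   axes for up/down templates (must bracket 1)
#' @param replicate_cv coefficient of variation of the multiplicative
#'   replicate noise
#' @param unit_cv coefficient of variation of the per-unit multiplier
#'   (shared across conditions, so paired tests benefit from it)
#' @param polysome_fraction_base control-condition polysome allocation
#'   theta (fraction of ribosome-bound mRNA in polysomes)
#' @param polysome_fraction_m_to_p treated-condition allocation for
#'   m_to_p-template features
#' @param polysome_fraction_p_to_m treated-condition allocation for
#'   p_to_m-template features
#' @param theta_logit_sd per-feature jitter (sd on the logit scale) of the
#'   shifted allocation, giving shifted features a spread of X values;
#'   jittered values are kept on the template's side of the base allocation
#' @param fractionation_efficiency fraction of the total-RNA signal
#'   recovered in the monosome + polysome fractions; the remainder feeds
#'   the free layer
#' @param couple_protein_to_shift when \code{TRUE}, shifted features get a
#'   protein fold change equal to their realized allocation odds ratio
#'   raised to \code{coupling_exponent} (instead of the template fold)
#' @param coupling_exponent exponent of the coupling above
#' @param library_size expected column sum per layer; \code{NA} (default)
#'   leaves baselines unscaled
#' @param noise_model \code{"lognormal"} (default) for all layers, or
#'   \code{"negbin"} for integer counts on the RNA layers
#' @param nb_size negative-binomial size (inverse dispersion) for the
#'   negbin mode
#' @param utr5_length,cds_length,utr3_length region lengths of the
#'   generated transcripts (cds divisible by 3)
#' @param utr5_start_free scrub start codons (ATG/CTG/GTG/TTG) from the
#'   generated 5'UTRs so planted uORFs are the only ones present
#' @param seed integer seed; identical configs give bit-identical output
#' @return list of class \code{sim_config}
#' @export
sim_config <- function(n_units = 4L,
                       features_per_group = c("4" = 200L, "14" = 200L),
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1,
                       effect_up = 2.0,
                       effect_down = 0.5,
                       replicate_cv = 0.1,
                       unit_cv = 0.05,
                       polysome_fraction_base = 0.5,
                       polysome_fraction_m_to_p = 0.8,
                       polysome_fraction_p_to_m = 0.2,
                       theta_logit_sd = 0.25,
                       fractionation_efficiency = 0.7,
                       couple_protein_to_shift = FALSE,
                       coupling_exponent = 0.5,
                       library_size = NA_real_,
                       noise_model = c("lognormal", "negbin"),
                       nb_size = 100,
                       utr5_length = 99L,
                       cds_length = 300L,
                       utr3_length = 150L,
                       utr5_start_free = FALSE,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  fail <- function(field) stop("invalid configuration field '", field, "'")
  if (!(is.numeric(n_units) && n_units >= 2)) fail("n_units")
  g <- suppressWarnings(as.integer(names(features_per_group)))
  if (length(features_per_group) == 0L || anyNA(g) ||
      any(g < 1L | g > 27L) || any(features_per_group < 1))
    fail("features_per_group")
  if (!(effect_up > 1)) fail("effect_up")
  if (!(effect_down > 0 && effect_down < 1)) fail("effect_down")
  if (!(replicate_cv > 0)) fail("replicate_cv")
  if (unit_cv < 0) fail("unit_cv")
  for (f in c("polysome_fraction_base", "polysome_fraction_m_to_p",
              "polysome_fraction_p_to_m", "fractionation_efficiency")) {
    v <- get(f)
    if (!(v > 0 && v < 1)) fail(f)
  }
  if (!(polysome_fraction_m_to_p > polysome_fraction_base))
    fail("polysome_fraction_m_to_p")
  if (!(polysome_fraction_p_to_m < polysome_fraction_base))
    fail("polysome_fraction_p_to_m")
  if (theta_logit_sd < 0) fail("theta_logit_sd")
  if (!is.na(library_size) && library_size <= 0) fail("library_size")
  if (cds_length %% 3L != 0L) fail("cds_length")
  if (utr5_length < 0L || utr3_length < 0L) fail("utr5_length")
  if (!(is.numeric(seed) && length(seed) == 1L && is.finite(seed)))
    fail("seed")
  cfg <- list(n_units = as.integer(n_units),
              features_per_group = setNames(as.integer(features_per_group),
                                            names(features_per_group)),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              effect_up = effect_up, effect_down = effect_down,
              replicate_cv = replicate_cv, unit_cv = unit_cv,
              polysome_fraction_base = polysome_fraction_base,
              polysome_fraction_m_to_p = polysome_fraction_m_to_p,
              polysome_fraction_p_to_m = polysome_fraction_p_to_m,
              theta_logit_sd = theta_logit_sd,
              fractionation_efficiency = fractionation_efficiency,
              couple_protein_to_shift = isTRUE(couple_protein_to_shift),
              coupling_exponent = coupling_exponent,
              library_size = library_size, noise_model = noise_model,
              nb_size = nb_size,
              utr5_length = as.integer(utr5_length),
              cds_length = as.integer(cds_length),
              utr3_length = as.integer(utr3_length),
              utr5_start_free = isTRUE(utr5_start_free),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# multiplicative lognormal noise with mean 1 and the given cv
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

effect_of <- function(call, effect_up, effect_down) {
  c(up = effect_up, stable = 1, down = effect_down)[call]
}

#' Generate a matched multi-layer synthetic dataset with known truth
#'
#' For each feature of intended group g with template triple (protein, RNA,
#' shift): the total-RNA layer carries the RNA fold change; monosome and
#' polysome expectations split the ribosome-bound signal
#' (total x fractionation efficiency) by the polysome allocation theta,
#' which moves from the base value to the shifted value for shift-template
#' features; the protein layer carries the protein fold change (or, when
#' coupled, a fold change tied to the realized allocation odds ratio). The
#' free layer carries no condition effect. Replicate noise is
#' multiplicative lognormal (optionally negative-binomial counts for RNA
#' layers).
#'
#' @param config \code{\link{sim_config}}
#' @return list with \code{tables} (named abundance_table list: protein,
#'   total, free, monosome, polysome), \code{transcripts}
#'   (\code{\link{transcript_set}}), \code{truth} (per-feature intended
#'   group, template calls, allocations, realized effects, planting flags)
#'   and \code{config}
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  groups <- rep(as.integer(names(cfg$features_per_group)),
                cfg$features_per_group)
  n <- length(groups)
  feats <- sprintf("feat_%04d", seq_len(n))
  tmpl <- group_triple(groups)
  baseline <- rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
  if (!is.na(cfg$library_size))
    baseline <- baseline * cfg$library_size / sum(baseline)

  rna_eff <- effect_of(tmpl$rna_call, cfg$effect_up, cfg$effect_down)
  theta_c <- rep(cfg$polysome_fraction_base, n)
  theta_t <- theta_c
  is_mp <- tmpl$shift_call == "m_to_p"
  is_pm <- tmpl$shift_call == "p_to_m"
  jitter <- rnorm(n, 0, cfg$theta_logit_sd)
  up_t <- inv_logit(logit(cfg$polysome_fraction_m_to_p) + jitter)
  dn_t <- inv_logit(logit(cfg$polysome_fraction_p_to_m) + jitter)
  # keep jittered allocations on the template's side of the base value
  gap <- 0.02
  up_t <- pmax(up_t, cfg$polysome_fraction_base + gap)
  dn_t <- pmin(dn_t, cfg$polysome_fraction_base - gap)
  theta_t[is_mp] <- up_t[is_mp]
  theta_t[is_pm] <- dn_t[is_pm]

  odds_ratio <- (theta_t / (1 - theta_t)) / (theta_c / (1 - theta_c))
  prot_eff <- effect_of(tmpl$protein_call, cfg$effect_up, cfg$effect_down)
  if (cfg$couple_protein_to_shift) {
    shifted <- is_mp | is_pm
    prot_eff[shifted] <- odds_ratio[shifted]^cfg$coupling_exponent
  }

  phi <- cfg$fractionation_efficiency
  expected <- function(layer, cond) {
    fac <- if (cond == "control") rep(1, n) else switch(layer,
      protein = prot_eff, total = rna_eff, free = rep(1, n),
      monosome = rna_eff, polysome = rna_eff)
    theta <- if (cond == "control") theta_c else theta_t
    base <- baseline * fac
    switch(layer,
           protein = base,
           total = base,
           free = baseline * (1 - phi),
           monosome = base * phi * (1 - theta),
           polysome = base * phi * theta)
  }

  units <- sprintf("u%d", seq_len(cfg$n_units))
  unit_mult <- matrix(rlnorm_cv(n * cfg$n_units, cfg$unit_cv), n,
                      cfg$n_units)
  layers <- c("protein", "total", "free", "monosome", "polysome")
  tables <- list()
  for (layer in layers) {
    cols <- list()
    md <- list()
    for (cond in c("control", "treated")) {
      mu <- expected(layer, cond)
      for (ui in seq_len(cfg$n_units)) {
        m <- mu * unit_mult[, ui]
        v <- if (cfg$noise_model == "negbin" && layer != "protein")
          rnbinom(n, size = cfg$nb_size, mu = m)
        else m * rlnorm_cv(n, cfg$replicate_cv)
        sid <- paste(layer, substr(cond, 1, 4), units[ui], sep = "_")
        cols[[sid]] <- v
        md[[sid]] <- data.frame(sample = sid, layer = layer,
                                condition = cond, unit = units[ui],
                                stringsAsFactors = FALSE)
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- feats
    tables[[layer]] <- abundance_table(values, do.call(rbind, md))
  }

  tx <- random_transcripts(feats, cfg$utr5_length, cfg$cds_length,
                           cfg$utr3_length,
                           utr5_start_free = cfg$utr5_start_free %||% FALSE)

  truth <- data.frame(feature = feats, group = groups,
                      protein_template = tmpl$protein_call,
                      rna_template = tmpl$rna_call,
                      shift_template = tmpl$shift_call,
                      protein_effect = unname(prot_eff),
                      rna_effect = unname(rna_eff),
                      theta_control = theta_c, theta_treated = theta_t,
                      motif_planted = FALSE, motif_start = NA_integer_,
                      motif_region = NA_character_, uorf_planted = FALSE,
                      uorf_start = NA_integer_, seed = cfg$seed,
                      stringsAsFactors = FALSE)
  list(tables = tables, transcripts = tx, truth = truth, config = cfg)
}

#' Random transcript sequences with fixed region structure
#'
#' Uniform A/C/G/T sequences; the CDS is framed by an ATG and a TAA stop at
#' its ends with internal in-frame stops recoded, so the annotation is
#' self-consistent. With \code{utr5_start_free} the 5'UTR is scrubbed of
#' ATG/CTG/GTG/TTG trinucleotides so that only planted uORFs exist.
#'
#' @param ids transcript ids
#' @param utr5_length,cds_length,utr3_length region lengths (cds divisible
#'   by 3)
#' @param utr5_start_free scrub potential start codons from the 5'UTR
#' @return \code{\link{transcript_set}}
#' @export
random_transcripts <- function(ids, utr5_length = 99L, cds_length = 300L,
                               utr3_length = 150L,
                               utr5_start_free = FALSE) {
  stopifnot(cds_length %% 3L == 0L, cds_length >= 6L)
  nt <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  mk <- function(len) paste(sample(nt, len, replace = TRUE), collapse = "")
  seqs <- vapply(ids, function(id) {
    u5 <- mk(utr5_length)
    if (utr5_start_free && utr5_length > 0L) {
      # removing TG dinucleotides removes ATG/CTG/GTG/TTG (and TGA stops)
      u5 <- gsub("TG", "TC", u5, fixed = TRUE)
      u5 <- gsub("TG", "TC", u5, fixed = TRUE)
    }
    n_int <- cds_length / 3L - 2L
    codons <- replicate(n_int, mk(3L))
    codons[codons %in% stops] <- "GGC"
    cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    paste0(u5, cds, mk(utr3_length))
  }, character(1L))
  transcript_set(ids, unname(seqs), utr5_length, cds_length, utr3_length)
}

#' Plant a motif into a region of target transcripts
#'
#' Overwrites the motif verbatim at a random position fully inside the
#' named region of each selected target. With \code{rate < 1} exactly
#' \code{round(rate * length(target_features))} targets are selected
#' (deterministically given the RNG state).
#'
#' @param tx transcript_set
#' @param motif nucleotide string (A/C/G/T/U)
#' @param target_features transcript ids eligible for planting
#' @param region \code{"utr5"}, \code{"cds"} or \code{"utr3"}
#' @param rate planting rate over the targets
#' @return \code{tx} with the motif written into the selected targets; the
#'   placements (feature, global start/end, region) are in the
#'   \code{placements} attribute
#' @export
plant_motif <- function(tx, motif, target_features, region = "cds",
                        rate = 1) {
  stopifnot(inherits(tx, "transcript_set"))
  motif <- toupper(chartr("Uu", "Tt", motif))
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T/U")
  w <- nchar(motif)
  miss <- setdiff(target_features, tx$id)
  if (length(miss)) stop("unknown transcript id: ", miss[1L])
  k <- round(rate * length(target_features))
  chosen <- if (k < length(target_features))
    sample(target_features, k) else target_features
  placements <- data.frame(feature = character(0), start = integer(0),
                           end = integer(0), region = character(0),
                           stringsAsFactors = FALSE)
  for (id in chosen) {
    i <- match(id, tx$id)
    rl <- switch(region, utr5 = tx$utr5_length[i], cds = tx$cds_length[i],
                 utr3 = tx$utr3_length[i], stop("unknown region: ", region))
    if (rl < w)
      stop("region ", region, " of transcript '", id,
           "' is shorter than the motif")
    local_start <- if (rl == w) 1L else sample.int(rl - w + 1L, 1L)
    gstart <- local_to_global(tx, id, region, local_start)
    s <- tx$seq[i]
    tx$seq[i] <- paste0(substr(s, 1L, gstart - 1L), motif,
                        substr(s, gstart + w, nchar(s)))
    placements <- rbind(placements,
                        data.frame(feature = id, start = gstart,
                                   end = gstart + w - 1L, region = region,
                                   stringsAsFactors = FALSE))
  }
  attr(tx, "placements") <- placements
  tx
}

#' Plant a short uORF into the 5'UTR of target transcripts
#'
#' Writes a contained uORF (ATG + \code{n_codons} sense codons + TAA) at a
#' random position in the 5'UTR of each selected target.
#'
#' @param tx transcript_set
#' @param target_features transcript ids eligible
#' @param rate planting rate over the targets (exact count, as in
#'   \code{\link{plant_motif}})
#' @param n_codons number of internal codons between start and stop
#' @return \code{tx} with planted uORFs; placements in the
#'   \code{placements} attribute
#' @export
plant_uorf <- function(tx, target_features, rate = 1, n_codons = 2L) {
  body <- paste(rep("GCC", n_codons), collapse = "")
  plant_motif(tx, paste0("ATG", body, "TAA"), target_features,
              region = "utr5", rate = rate)
}
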