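# Synthetic-data generators. Each generator is a pure function of
# (config, seed) and emits both the observable table and the planted
# truth, so every downstream classifier has an exact recovery oracle.
# Noise is lognormal throughout: occupancy, PBM intensity and abundance
# are strictly positive, right-skewed assay readouts.

#' Synthetic-data configuration
#'
#' Bundles the knobs of all generators. Component lists are merged over
#' the defaults, so `synth_config(occupancy = list(sigma = 0.3))` changes
#' one field only.
#'
#' Defaults encode the statistical structure the analysis stages assume:
#' a gene-class mix of ~30% TATA-box (split T5/A5), 30% TATA-like, 40%
#' other; SAGA (Spt20p) occupancy planted high with class-ordered
#' probabilities averaging ~0.5 (T5 > A5 > TATA-like > other) and TFIID
#' (Taf1p) planted high at 0.5 independent of class; ~2-fold planted
#' occupancy shifts over lognormal noise (sdlog 0.15); PBM intensity
#' means ordered T5 > A5 > TATA-like > other; an inverse mean-CV law
#' `cv = k / sqrt(mean)` with class-dependent DM offsets (log10 units);
#' TBP turnover confined to \[0.008, 0.051\] a.u. with the TATA-box mean
#' above the TATA-like mean; and size-confounded cytometry events on an
#' 18-bit ADC scale.
#'
#' @param n_genes Number of genes (default 2000).
#' @param class_mix Named proportions over `TATA-box-T5`, `TATA-box-A5`,
#'   `TATA-like`, `other` (normalised to sum to 1).
#' @param promoter_length Promoter length in bp (default 200).
#' @param background_gc Background G+C fraction (default 0.7; a GC-rich
#'   background keeps spurious TATA-like windows rare).
#' @param occupancy,pbm,noise,cytometry,turnover Component overrides
#'   (lists merged over the defaults; see the function source for
#'   fields).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         class_mix = c(`TATA-box-T5` = 0.15,
                                       `TATA-box-A5` = 0.15,
                                       `TATA-like` = 0.30,
                                       other = 0.40),
                         promoter_length = 200,
                         background_gc = 0.70,
                         occupancy = list(),
                         pbm = list(),
                         noise = list(),
                         cytometry = list(),
                         turnover = list()) {
  check_scalar(n_genes, "n_genes", 0, Inf)
  check_scalar(promoter_length, "promoter_length", 20, Inf)
  check_scalar(background_gc, "background_gc", 0, 1)
  if (is.null(names(class_mix)) || any(class_mix < 0) || sum(class_mix) <= 0) {
    abort("`class_mix` must be named non-negative proportions.")
  }
  class_mix <- class_mix / sum(class_mix)

  occupancy <- modifyList(list(
    spt20_high_prob = c(`TATA-box-T5` = 0.85, `TATA-box-A5` = 0.70,
                        `TATA-like` = 0.45, other = 0.35),
    taf1_high_prob = 0.5,
    fold_change = 2,
    sigma = 0.15,
    base_level = 100,
    tbp_shift = c(`TATA-box-T5` = 0.5, `TATA-box-A5` = 0.35,
                  `TATA-like` = 0.1, other = 0),
    missing_rate = 0.02
  ), occupancy)
  pbm <- modifyList(list(
    n_like_motifs = 40, n_other_motifs = 60, replicates = 16,
    mean_intensity = c(T5 = 4000, A5 = 2500, `TATA-like` = 1200,
                       other = 500),
    motif_sigma = 0.1, sigma = 0.2
  ), pbm)
  noise <- modifyList(list(
    k = 30, sigma = 0.05,
    dm_offsets = c(`TATA-box-T5` = 0.12, `TATA-box-A5` = 0.09,
                   `TATA-like` = 0.03, other = 0),
    mean_meanlog = log(1000), mean_sdlog = 1
  ), noise)
  cytometry <- modifyList(list(
    n_events = 20000, n_replicates = 2, true_cv = 0.3,
    size_meanlog = log(5e4), size_sdlog = 0.25,
    ssc_scale = 0.6, channel_sigma = 0.05, confound = 1,
    gfp_mean = 500
  ), cytometry)
  turnover <- modifyList(list(
    range = c(0.008, 0.051),
    shape = list(`TATA-box` = c(4, 2), `TATA-like` = c(2, 4),
                 other = c(2.5, 3.5))
  ), turnover)
  if (occupancy$sigma < 0 || pbm$sigma < 0 || noise$sigma < 0) {
    abort("noise sigmas must be non-negative.")
  }
  structure(
    list(n_genes = as.integer(n_genes), class_mix = class_mix,
         promoter_length = as.integer(promoter_length),
         background_gc = background_gc, occupancy = occupancy,
         pbm = pbm, noise = noise, cytometry = cytometry,
         turnover = turnover),
    class = "synth_config"
  )
}

# All concrete instantiations of an IUPAC pattern.
expand_iupac <- function(pattern) {
  pat <- check_pattern(pattern)
  grid <- expand.grid(lapply(pat, function(p) IUPAC_SETS[[p]]),
                      stringsAsFactors = FALSE)
  apply(grid, 1, paste0, collapse = "")
}

# Mutate exactly k positions of a motif to bases disallowed by the
# pattern at those positions, guaranteeing exactly k mismatches.
mutate_motif <- function(motif, k, pat) {
  pos <- sample(length(pat), k)
  for (p in pos) {
    choices <- setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[pat[p]]])
    substr(motif, p, p) <- sample(choices, 1)
  }
  motif
}

# One random background promoter with the motif planted at `offset`.
plant_promoter <- function(motif, offset, len, base_probs) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = base_probs), collapse = "")
  substr(s, offset + 1L, offset + nchar(motif)) <- motif
  s
}

#' Generate synthetic promoters with planted TBS motifs
#'
#' Draws a TBS class for each gene from the configured mix and plants one
#' 8-mer of that class into a random GC-rich background: an exact
#' consensus instantiation with the chosen position-5 base for the
#' TATA-box subsets, a 1-2 mismatch variant for TATA-like, a 3-5 mismatch
#' variant for other. Promoters are rejection-resampled until no
#' non-planted window beats the planted one (fewer mismatches, an equal
#' count at an earlier offset, or a class-flipping hit for an "other"
#' gene), so the planted class, subset and offset are recoverable
#' exactly by [scan_promoter()].
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param pattern IUPAC consensus used for planting and validation.
#' @return A tibble with `gene_id`, `class` (planted 4-level label),
#'   `tbs_class`, `subset`, `offset` (0-based), `motif`, `sequence`.
#' @export
gen_promoters <- function(config = synth_config(), seed = 1L,
                          pattern = "TATAWAWR") {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes
  empty <- tibble(gene_id = character(), class = character(),
                  tbs_class = factor(levels = c("TATA-box", "TATA-like", "other")),
                  subset = factor(levels = c("T5", "A5", "none")),
                  offset = integer(), motif = character(),
                  sequence = character())
  if (n == 0L) return(empty)
  set.seed(seed)
  pat <- check_pattern(pattern)
  k <- length(pat)
  len <- config$promoter_length
  gc <- config$background_gc
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  consensus <- expand_iupac(pattern)
  t5 <- consensus[substr(consensus, 5, 5) == "T"]
  a5 <- consensus[substr(consensus, 5, 5) == "A"]

  cls <- sample(names(config$class_mix), n, replace = TRUE,
                prob = config$class_mix)
  gen_motif <- function(class) {
    switch(
      class,
      `TATA-box-T5` = sample(t5, 1),
      `TATA-box-A5` = sample(a5, 1),
      `TATA-like` = mutate_motif(sample(consensus, 1), sample(1:2, 1), pat),
      other = mutate_motif(sample(consensus, 1), sample(3:5, 1), pat)
    )
  }
  motifs <- vapply(cls, gen_motif, character(1), USE.NAMES = FALSE)
  offsets <- sample(0:(len - k), n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    plant_promoter(motifs[i], offsets[i], len, base_probs)
  }, character(1))

  # rejection: regenerate promoters where a non-planted window would
  # change the scan result — a strictly better window, an equal window at
  # an earlier offset (the scanner's tie-break), or a window good enough
  # to lift an "other" gene into the TATA-like class. Windows overlapping
  # the plant are allowed to be merely similar (the consensus overlaps a
  # shifted copy of itself), only never better-or-leftmost-equal.
  planted_mm <- mismatches_impl(motifs, pat)
  spurious <- function(idx) {
    w <- tbs_windows(seqs[idx], k)
    w$mm <- mismatches_impl(w$window, pat)
    p_off <- offsets[idx][w$gene]
    p_mm <- planted_mm[idx][w$gene]
    other <- w$offset != p_off
    bad_rows <- other & (
      (p_mm >= 3L & w$mm <= 2L) |
        (p_mm <= 2L & (w$mm < p_mm |
                         (w$mm == p_mm & w$offset < p_off))))
    idx[sort(unique(w$gene[bad_rows]))]
  }
  bad <- spurious(seq_len(n))
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > 200L) abort("promoter rejection sampling failed to converge.")
    # redraw motif (same class), offset and background: some motif draws
    # are structurally shadowed by their own shifted frame
    motifs[bad] <- vapply(cls[bad], gen_motif, character(1),
                          USE.NAMES = FALSE)
    planted_mm[bad] <- mismatches_impl(motifs[bad], pat)
    offsets[bad] <- sample(0:(len - k), length(bad), replace = TRUE)
    for (i in bad) {
      seqs[i] <- plant_promoter(motifs[i], offsets[i], len, base_probs)
    }
    bad <- spurious(bad)
  }

  truth_cls <- classify_tbs(motifs, pattern = pattern)
  tibble(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    class = cls,
    tbs_class = truth_cls$tbs_class,
    subset = truth_cls$subset,
    offset = offsets,
    motif = motifs,
    sequence = seqs
  )
}

#' Generate synthetic ChIP occupancies with planted regulation classes
#'
#' Plants per-gene TFIID- and SAGA-regulation flags (SAGA probability
#' ordered by TBS class, TFIID at 0.5 independent of class, so each split
#' is close to 50/50) and draws lognormal occupancies with a ~2-fold
#' shift for regulated genes. Mot1p tracks the realised Spt20p and TBP
#' draws; TBP is elevated at TATA-box promoters. A small fraction of
#' Taf1p/Spt20p values is set missing.
#'
#' @param config A [synth_config()].
#' @param truth Promoter truth table from [gen_promoters()].
#' @param seed Integer seed.
#' @return A list: `occupancy` (tibble `gene_id`, `TBP`, `Mot1p`,
#'   `Taf1p`, `Spt20p`) and `truth` (planted `tfiid_regulated`,
#'   `saga_regulated`, `coactivator_class`).
#' @export
gen_occupancy <- function(config = synth_config(), truth, seed = 1L) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(truth))
  oc <- config$occupancy
  n <- nrow(truth)
  set.seed(seed)
  base <- log(oc$base_level)
  shift <- log(oc$fold_change)

  p_saga <- unname(oc$spt20_high_prob[truth$class])
  saga_reg <- stats::runif(n) < p_saga
  tfiid_reg <- stats::runif(n) < oc$taf1_high_prob

  spt20 <- stats::rlnorm(n, base + saga_reg * shift, oc$sigma)
  taf1 <- stats::rlnorm(n, base + tfiid_reg * shift, oc$sigma)
  tbp <- stats::rlnorm(n, base + unname(oc$tbp_shift[truth$class]) * shift,
                       oc$sigma)
  mot1 <- exp(base + 0.4 * (log(spt20) - base) + 0.4 * (log(tbp) - base) +
                stats::rnorm(n, 0, oc$sigma))

  if (oc$missing_rate > 0) {
    taf1[stats::runif(n) < oc$missing_rate] <- NA_real_
    spt20[stats::runif(n) < oc$missing_rate] <- NA_real_
  }
  list(
    occupancy = tibble(gene_id = truth$gene_id, TBP = tbp, Mot1p = mot1,
                       Taf1p = taf1, Spt20p = spt20),
    truth = tibble(
      gene_id = truth$gene_id,
      tfiid_regulated = tfiid_reg,
      saga_regulated = saga_reg,
      coactivator_class = factor(
        paste0(ifelse(tfiid_reg, "+", "-"), "/",
               ifelse(saga_reg, "+", "-")),
        levels = c("+/+", "+/-", "-/+", "-/-"))
    )
  )
}

#' Generate synthetic PBM probe intensities
#'
#' Builds a motif panel (all consensus 8-mers split T5/A5, a sample of
#' 1-2 mismatch TATA-like variants, and random >= 3 mismatch "other"
#' 8-mers) and draws replicate probe intensities per motif around
#' class-ordered lognormal means (T5 > A5 > TATA-like > other).
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param pattern IUPAC consensus.
#' @return A probe tibble: `probe_id`, `motif`, `intensity`.
#' @export
gen_pbm <- function(config = synth_config(), seed = 1L,
                    pattern = "TATAWAWR") {
  stopifnot(inherits(config, "synth_config"))
  pb <- config$pbm
  set.seed(seed)
  pat <- check_pattern(pattern)

  consensus <- expand_iupac(pattern)
  t5 <- consensus[substr(consensus, 5, 5) == "T"]
  a5 <- consensus[substr(consensus, 5, 5) == "A"]
  like <- unique(vapply(seq_len(pb$n_like_motifs * 4), function(i) {
    mutate_motif(sample(consensus, 1), sample(1:2, 1), pat)
  }, character(1)))
  like <- like[seq_len(min(length(like), pb$n_like_motifs))]
  other <- unique(vapply(seq_len(pb$n_other_motifs * 4), function(i) {
    mutate_motif(sample(consensus, 1), sample(3:6, 1), pat)
  }, character(1)))
  other <- other[seq_len(min(length(other), pb$n_other_motifs))]

  motifs <- c(t5, a5, like, other)
  means <- c(rep(pb$mean_intensity[["T5"]], length(t5)),
             rep(pb$mean_intensity[["A5"]], length(a5)),
             rep(pb$mean_intensity[["TATA-like"]], length(like)),
             rep(pb$mean_intensity[["other"]], length(other)))
  motif_meanlog <- log(means) + stats::rnorm(length(motifs), 0,
                                             pb$motif_sigma)
  reps <- max(1L, as.integer(pb$replicates))
  tibble(
    probe_id = sprintf("probe_%05d", seq_len(length(motifs) * reps)),
    motif = rep(motifs, each = reps),
    intensity = stats::rlnorm(length(motifs) * reps,
                              rep(motif_meanlog, each = reps), pb$sigma)
  )
}

#' Generate a synthetic noise (mean/CV) table
#'
#' Lognormal mean abundances with an exact inverse mean-CV backbone
#' `cv = k / sqrt(mean)`, modulated by class-dependent DM offsets and
#' residual lognormal noise (both in log10 units). With zero offsets and
#' zero residual sigma the DM of every gene is identically zero.
#'
#' @param config A [synth_config()].
#' @param truth Promoter truth table from [gen_promoters()].
#' @param seed Integer seed.
#' @return A tibble: `gene_id`, `class`, `mean`, `cv`.
#' @export
gen_noise_table <- function(config = synth_config(), truth, seed = 1L) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(truth))
  ns <- config$noise
  n <- nrow(truth)
  if (n == 0L) {
    return(tibble(gene_id = character(), class = character(),
                  mean = numeric(), cv = numeric()))
  }
  set.seed(seed)
  m <- stats::rlnorm(n, ns$mean_meanlog, ns$mean_sdlog)
  off <- unname(ns$dm_offsets[truth$class])
  eps <- stats::rnorm(n, 0, ns$sigma)
  tibble(gene_id = truth$gene_id, class = truth$class, mean = m,
         cv = (ns$k / sqrt(m)) * 10^(off + eps))
}

#' Generate synthetic cytometry events
#'
#' Per event, a lognormal cell size drives both scatter channels (with
#' independent multiplicative channel noise, clipped at the 18-bit ADC
#' ceiling) and, through the configurable confound exponent, the raw GFP
#' signal: `gfp = (size / median size)^confound * g`, where `g` is
#' lognormal expression with the requested CV. With confound 0 the raw
#' CV already equals the expression CV.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param true_cv Expression CV to emulate (default from the config).
#' @return An event tibble: `fsc_a`, `ssc_a`, `gfp`, `sample_id`,
#'   `replicate_id`.
#' @export
gen_cytometry <- function(config = synth_config(), seed = 1L,
                          true_cv = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cy <- config$cytometry
  if (is.null(true_cv)) true_cv <- cy$true_cv
  check_scalar(true_cv, "true_cv", 0, Inf)
  set.seed(seed)
  sg <- sqrt(log(1 + true_cv^2))
  out <- purrr::map(seq_len(cy$n_replicates), function(r) {
    n <- cy$n_events
    s <- stats::rlnorm(n, cy$size_meanlog, cy$size_sdlog)
    fsc <- pmin(s * exp(stats::rnorm(n, 0, cy$channel_sigma)), ADC_LIMIT)
    ssc <- pmin(cy$ssc_scale * s * exp(stats::rnorm(n, 0, cy$channel_sigma)),
                ADC_LIMIT)
    g <- stats::rlnorm(n, log(cy$gfp_mean) - sg^2 / 2, sg)
    tibble(fsc_a = fsc, ssc_a = ssc,
           gfp = (s / exp(cy$size_meanlog))^cy$confound * g,
           sample_id = "synthetic", replicate_id = r)
  })
  dplyr::bind_rows(out)
}

#' Generate synthetic TBP turnover values
#'
#' Scaled-beta draws confined to the configured range (default the
#' 0.008-0.051 a.u. span of measured promoter turnover), with shapes per
#' TBS class placing the TATA-box mean above the TATA-like mean.
#'
#' @param config A [synth_config()].
#' @param truth Promoter truth table from [gen_promoters()].
#' @param seed Integer seed.
#' @return A tibble: `gene_id`, `tbs_class`, `turnover`.
#' @export
gen_turnover <- function(config = synth_config(), truth, seed = 1L) {
  stopifnot(inherits(config, "synth_config"), is.data.frame(truth))
  tv <- config$turnover
  n <- nrow(truth)
  set.seed(seed)
  shp <- tv$shape[as.character(truth$tbs_class)]
  a <- vapply(shp, `[`, numeric(1), 1)
  b <- vapply(shp, `[`, numeric(1), 2)
  lo <- tv$range[1]; hi <- tv$range[2]
  tibble(gene_id = truth$gene_id, tbs_class = truth$tbs_class,
         turnover = lo + (hi - lo) * stats::rbeta(n, a, b))
}
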