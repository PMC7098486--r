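#' Default TMT plex designs
#'
#' `tmt_design_11()` mirrors the genotype x treatment x time layout of the
#' depolarization experiments (WT and S65A-Parkin iNeurons, untreated or
#' depolarized 2 or 6 h, duplicate cultures; one S65A 2 h channel to fill
#' 11). `tmt_design_10()` mirrors the USP30 time-course layout (WT and
#' USP30-null, 0-4 h, one channel each).
#'
#' @return A tibble with columns `channel`, `genotype`, `treatment`
#'   (`"UT"` or `"AO"`), `timepoint_h`, `replicate`.
#' @export
tmt_design_11 <- function() {
  tibble::tibble(
    channel = c("126", "127N", "127C", "128N", "128C", "129N",
                "129C", "130N", "130C", "131N", "131C"),
    genotype = c(rep("WT", 6), rep("S65A", 5)),
    treatment = c("UT", "UT", "AO", "AO", "AO", "AO",
                  "UT", "UT", "AO", "AO", "AO"),
    timepoint_h = c(0, 0, 2, 2, 6, 6, 0, 0, 2, 6, 6),
    replicate = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 1, 2)
  )
}

#' @rdname tmt_design_11
#' @export
tmt_design_10 <- function() {
  tibble::tibble(
    channel = c("126", "127N", "127C", "128N", "128C",
                "129N", "129C", "130N", "130C", "131N"),
    genotype = rep(c("WT", "USP30KO"), each = 5),
    treatment = rep(c("UT", "AO", "AO", "AO", "AO"), 2),
    timepoint_h = rep(0:4, 2),
    replicate = 1
  )
}

#' Effect and noise model for simulated TMT experiments
#'
#' The stated world of the simulator: a fraction of features ("planted"
#' Parkin targets) gains a log2 effect in depolarized channels, drawn
#' uniformly from `log2_effect_range` at 6 h (the bulk of real hits spans
#' roughly 2- to 8-fold); 2 h channels carry `effect_2h_scale` of the 6 h
#' log2 effect (most sites are already elevated at 2 h); S65A channels are
#' attenuated by `s65a_attenuation` (the ~2-fold reduced signature of the
#' phospho-dead UBL). Measurement noise is multiplicative log-normal with
#' `sigma_log2` per channel (typical TMT-MS3 replicate precision);
#' configurable fractions of PSMs violate each quality filter.
#'
#' @param n_elevated Number of planted elevated features.
#' @param log2_effect_range Range of planted 6 h log2 effects (>= 1).
#' @param effect_2h_scale Scale of the 2 h log2 effect relative to 6 h.
#' @param s65a_attenuation Multiplier in [0, 1] on log2 effects in S65A
#'   channels.
#' @param sigma_log2 Log2-scale channel noise sd (> 0 unless exactly 0 for
#'   noise-free runs).
#' @param psm_rate Poisson rate; each feature gets 1 + Pois(rate) PSMs.
#' @param frac_low_isolation,frac_low_sn,frac_no_ms3,frac_unlocalized
#'   Fractions of PSMs planted to violate, respectively, the isolation
#'   specificity >= 0.7 filter, the summed S/N >= 150 filter, the has-MS3
#'   requirement, and AScore site localization (< 13).
#' @param base_meanlog,base_sdlog Log-normal parameters of per-PSM base
#'   channel S/N.
#' @return A list of class `ub_effect_model`.
#' @export
effect_model <- function(n_elevated = 134, log2_effect_range = c(1, 3),
                         effect_2h_scale = 0.75, s65a_attenuation = 0.5,
                         sigma_log2 = 0.2, psm_rate = 2,
                         frac_low_isolation = 0.05, frac_low_sn = 0.05,
                         frac_no_ms3 = 0.02, frac_unlocalized = 0.03,
                         base_meanlog = log(100), base_sdlog = 1) {
  stopifnot(s65a_attenuation >= 0, s65a_attenuation <= 1, sigma_log2 >= 0,
            all(log2_effect_range >= 0))
  structure(as.list(environment()), class = "ub_effect_model")
}

#' Simulate a multiplexed TMT PSM table with known ground truth
#'
#' Emits PSM-level rows for a proteome layer (null effects, used for
#' site-to-protein normalization) and a diGLY layer with planted elevated
#' sites, each with the quality attributes the downstream filters act on
#' (isolation specificity, summed reporter S/N, has-MS3 flag, AScore).
#' Planted effects multiply channel means before noise.
#'
#' @param design A plex design tibble (see [tmt_design_11()]).
#' @param effects An [effect_model()].
#' @param n_features Number of diGLY features (sites).
#' @param n_proteins Number of proteins in the proteome layer; sites map
#'   onto these (planted sites are concentrated on a subset, echoing the
#'   134-sites-in-83-proteins structure).
#' @param n_phospho Number of phospho-layer features; exactly one (the
#'   pS65-Ub peptide analogue) is planted with a > 4-fold effect, echoing
#'   the single depolarization-responsive phosphopeptide. Set 0 to skip
#'   the layer.
#' @param seed Integer seed; the run is reproducible from (arguments, seed).
#' @return A list with `psms` (PSM tibble; channel columns are named by
#'   `design$channel`) and `ground_truth` (list with per-feature effect
#'   table and per-rule violation counts).
#' @export
simulate_tmt_experiment <- function(design = tmt_design_11(),
                                    effects = effect_model(),
                                    n_features = 2400,
                                    n_proteins = max(100L, round(n_features / 3)),
                                    n_phospho = 0L,
                                    seed = 1L) {
  stopifnot(inherits(effects, "ub_effect_model"), n_features >= 1)
  set.seed(seed)
  ch <- design$channel
  stopifnot(!anyDuplicated(ch))

  n_elev <- min(effects$n_elevated, n_features)
  planted <- sort(sample.int(n_features, n_elev))
  effect6 <- numeric(n_features)
  effect6[planted] <- stats::runif(n_elev, effects$log2_effect_range[1],
                                   effects$log2_effect_range[2])
  ## planted sites cluster on fewer proteins (~1.6 sites/protein)
  n_hit_prot <- max(1L, round(n_elev / 1.6))
  hit_prot <- sample.int(n_proteins, min(n_hit_prot, n_proteins))
  protein_of <- sample.int(n_proteins, n_features, replace = TRUE)
  protein_of[planted] <- sample(hit_prot, n_elev, replace = TRUE)

  ## per-channel log2 effect multiplier for a given feature
  channel_log2 <- function(e6) {
    eff <- numeric(length(ch))
    depol <- design$treatment != "UT"
    eff[depol & design$timepoint_h >= 6] <- e6
    eff[depol & design$timepoint_h < 6] <- e6 * effects$effect_2h_scale
    eff[design$genotype != "WT"] <- eff[design$genotype != "WT"] *
      effects$s65a_attenuation
    eff
  }

  gen_layer <- function(layer_name, n_feat, feat_protein, feat_effect6, rate) {
    n_psm <- 1L + stats::rpois(n_feat, rate)
    feat <- rep(seq_len(n_feat), n_psm)
    total <- length(feat)
    base <- stats::rlnorm(total, effects$base_meanlog, effects$base_sdlog)
    eff_mat <- t(vapply(feat_effect6[feat], channel_log2,
                        numeric(length(ch))))
    noise <- if (effects$sigma_log2 > 0) {
      matrix(stats::rnorm(total * length(ch), 0, effects$sigma_log2),
             total, length(ch))
    } else matrix(0, total, length(ch))
    sn <- base * 2^(eff_mat + noise)

    low_iso <- stats::runif(total) < effects$frac_low_isolation
    low_sn <- stats::runif(total) < effects$frac_low_sn
    no_ms3 <- stats::runif(total) < effects$frac_no_ms3
    unloc <- stats::runif(total) < effects$frac_unlocalized
    iso <- ifelse(low_iso, stats::runif(total, 0.30, 0.699),
                  stats::runif(total, 0.75, 1))
    ## scale whole S/N vectors of low-S/N violators below the threshold
    rs <- rowSums(sn)
    target <- stats::runif(total, 20, 149)
    scale <- ifelse(low_sn, target / rs, pmax(1, 160 / rs))
    sn <- sn * scale
    ascore <- ifelse(unloc, stats::runif(total, 0, 12.9),
                     stats::runif(total, 13, 100))
    if (layer_name == "proteome") ascore <- NA_real_

    psms <- tibble::tibble(
      layer = layer_name,
      psm_id = sprintf("%s_%05d", layer_name, seq_len(total)),
      protein = sprintf("P%04d", feat_protein[feat]),
      site = if (layer_name == "proteome") NA_integer_ else rep(seq_len(n_feat), n_psm),
      mod_type = switch(layer_name, proteome = NA_character_,
                        diGLY = "diGLY", phospho = "phospho"),
      ascore = ascore,
      isolation_specificity = iso,
      summed_sn = rowSums(sn),
      has_ms3 = !no_ms3
    )
    psms <- dplyr::bind_cols(psms, tibble::as_tibble(
      stats::setNames(as.data.frame(sn), ch)))
    list(psms = psms,
         violations = tibble::tibble(
           rule = c("isolation_specificity", "summed_sn", "no_ms3"),
           n_planted = c(sum(low_iso), sum(low_sn), sum(no_ms3))),
         n_psm = n_psm)
  }

  digly <- gen_layer("diGLY", n_features, protein_of, effect6,
                     effects$psm_rate)
  prote <- gen_layer("proteome", n_proteins, seq_len(n_proteins),
                     numeric(n_proteins), effects$psm_rate * 3)

  truth <- tibble::tibble(
    layer = "diGLY",
    feature = seq_len(n_features),
    protein = sprintf("P%04d", protein_of),
    site = seq_len(n_features),
    planted = seq_len(n_features) %in% planted,
    log2_effect_6h = effect6,
    n_psms = digly$n_psm
  )
  psms <- dplyr::bind_rows(digly$psms, prote$psms)
  violations <- dplyr::bind_rows(
    dplyr::mutate(digly$violations, layer = "diGLY"),
    dplyr::mutate(prote$violations, layer = "proteome"))

  if (n_phospho > 0) {
    effp <- numeric(n_phospho)
    effp[1] <- 2.5  # the pS65-Ub analogue, log2 ratio > 2
    prot_p <- sample.int(n_proteins, n_phospho, replace = TRUE)
    phos <- gen_layer("phospho", n_phospho, prot_p, effp, effects$psm_rate)
    psms <- dplyr::bind_rows(psms, phos$psms)
    violations <- dplyr::bind_rows(
      violations, dplyr::mutate(phos$violations, layer = "phospho"))
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      layer = "phospho", feature = seq_len(n_phospho),
      protein = sprintf("P%04d", prot_p), site = seq_len(n_phospho),
      planted = seq_len(n_phospho) == 1, log2_effect_6h = effp,
      n_psms = phos$n_psm))
  }
  list(
    psms = psms,
    ground_truth = list(
      features = truth,
      violations = violations,
      design = design, seed = seed, effects = effects)
  )
}
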