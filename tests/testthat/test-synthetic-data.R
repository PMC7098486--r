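test_that("proteoform mixtures validate fractions", {
  expect_error(proteoform_mixture(0, FALSE, 0.9), "sum to 1")
  expect_error(proteoform_mixture(c(0, 1), c(FALSE, FALSE), c(1.2, -0.2)),
               ">= 0")
  for (mix in list(ub_mixture_hela_1h(), ub_mixture_ineuron_6h())) {
    expect_equal(sum(mix$fraction), 1, tolerance = 1e-9)
    expect_true(all(mix$fraction >= 0))
  }
})

test_that("noise-free spectra conserve total rendered intensity per scan", {
  p <- spectrum_sim_params(noise = 0, n_scans = 4, total_abundance = 5e5)
  sim <- simulate_intact_spectra(proteoform_mixture(0, FALSE, 1), p, seed = 3)
  expect_length(sim$spectra, 4)
  for (s in seq_len(4)) {
    sp <- sim$spectra[[s]]
    area <- sum((sp$intensity[-1] + sp$intensity[-nrow(sp)]) / 2 * diff(sp$mz))
    expect_equal(area, 5e5 * sim$ground_truth$elution_weights[s],
                 tolerance = 1e-6)
  }
  expect_length(sim$ground_truth$warnings, 0)
})

test_that("spectrum generation is reproducible from (params, seed)", {
  p <- spectrum_sim_params(noise = 0.02, n_scans = 2)
  mix <- proteoform_mixture(c(0, 0), c(FALSE, TRUE), c(0.8, 0.2))
  a <- simulate_intact_spectra(mix, p, seed = 11)
  b <- simulate_intact_spectra(mix, p, seed = 11)
  c <- simulate_intact_spectra(mix, p, seed = 12)
  expect_identical(a$spectra[[1]]$intensity, b$spectra[[1]]$intensity)
  expect_false(identical(a$spectra[[1]]$intensity, c$spectra[[1]]$intensity))
})

test_that("a species drifting outside the window is flagged in ground truth", {
  p <- spectrum_sim_params(mz_range = c(625, 700), noise = 0, n_scans = 1)
  sim <- simulate_intact_spectra(proteoform_mixture(3, TRUE, 1), p, seed = 1)
  expect_gt(length(sim$ground_truth$warnings), 0)
})

test_that("peak-list TSV round trip preserves spectra", {
  p <- spectrum_sim_params(noise = 0, n_scans = 2)
  sim <- simulate_intact_spectra(proteoform_mixture(0, TRUE, 1), p, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_peaklists(sim$spectra, dir)
  back <- read_peaklists(paths)
  expect_equal(back[[2]]$intensity, sim$spectra[[2]]$intensity,
               tolerance = 1e-12)
})

test_that("TMT generator plants effects, violations and is reproducible", {
  sim <- simulate_tmt_experiment(n_features = 400, n_phospho = 50, seed = 9)
  truth <- sim$ground_truth$features
  digly_truth <- truth[truth$layer == "diGLY", ]
  expect_identical(sum(digly_truth$planted), 134L)
  expect_true(all(digly_truth$log2_effect_6h[digly_truth$planted] >= 1))
  expect_true(all(digly_truth$log2_effect_6h[!digly_truth$planted] == 0))
  expect_identical(sum(truth$planted[truth$layer == "phospho"]), 1L)

  # planted filter violations equal the audit counts of filter_psms
  kept <- filter_psms(sim$psms)
  audit <- attr(kept, "audit")
  v <- sim$ground_truth$violations
  for (rule in c("isolation_specificity", "summed_sn", "no_ms3")) {
    expect_identical(audit$n_excluded[audit$rule == rule],
                     sum(v$n_planted[v$rule == rule]), label = rule)
  }
  sim2 <- simulate_tmt_experiment(n_features = 400, n_phospho = 50, seed = 9)
  expect_identical(sim$psms, sim2$psms)
})

test_that("zero-noise, zero-effect TMT data gives exactly flat ratios", {
  eff <- effect_model(n_elevated = 0, sigma_log2 = 0, frac_low_isolation = 0,
                      frac_low_sn = 0, frac_no_ms3 = 0, frac_unlocalized = 0)
  sim <- simulate_tmt_experiment(effects = eff, n_features = 50, seed = 2)
  site <- rollup(filter_psms(sim$psms[sim$psms$layer == "diGLY", ]), "site")
  ch <- attr(site, "channels")
  m <- as.matrix(site[ch])
  ratios <- log2(m / m[, 1])
  expect_equal(max(abs(ratios)), 0, tolerance = 1e-12)
})

test_that("flux blot generator recovers trivial and planted ratios", {
  cond <- tibble::tibble(genotype = "WT", timepoint_h = 0, true_ratio = 1)
  sim <- simulate_flux_blots(cond, n_replicates = 2, cv = 0, background = 0)
  expect_equal(keima_ratio(sim$bands)$keima_ratio, c(1, 1))
  img <- simulate_flux_images(n_somata = 2, n_puncta = 0, seed = 1)
  expect_identical(red_only_signal(img[[1]]$red, img[[1]]$green), 0)
})

test_that("noise-free PRM areas invert exactly through prm_abundance", {
  prot <- tibble::tibble(protein = c("A", "B"),
                         true_fmol_per_ug = c(3.7, 0.41),
                         n_peptides = c(3L, 2L))
  sim <- simulate_prm_areas(prot, spike_fmol = 25, input_ug = 2, cv = 0,
                            seed = 4)
  ab <- prm_abundance(sim$areas)
  expect_equal(ab$fmol_per_ug[match(c("A", "B"), ab$protein)],
               c(3.7, 0.41), tolerance = 1e-12)
})
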