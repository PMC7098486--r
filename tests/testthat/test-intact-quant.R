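# shared noise-free fixtures (built once per file; 1 scan keeps it fast)
one_scan <- function(mix, seed = 1) {
  simulate_intact_spectra(mix, spectrum_sim_params(noise = 0, n_scans = 1),
                          seed = seed)$spectra[[1]]
}
ub_params <- deconv_params(mass_range = c(8000, 9200))

test_that("pick_peaks finds nothing in empty or flat spectra", {
  flat <- tibble::tibble(mz = seq(600, 610, 0.01), intensity = 0)
  expect_identical(nrow(pick_peaks(flat)), 0L)
  empty <- tibble::tibble(mz = numeric(), intensity = numeric())
  expect_identical(nrow(pick_peaks(empty)), 0L)
})

test_that("pick_peaks centroids a rendered Gaussian to sub-bin accuracy", {
  sp <- render_gaussians(700.1234, area = 50, sigma = 0.01)
  pk <- pick_peaks(sp)
  expect_identical(nrow(pk), 1L)
  step <- sp$mz[2] - sp$mz[1]
  expect_lt(abs(pk$mz - 700.1234), step / 2)
  expect_equal(pk$area, 50, tolerance = 1e-3)

  # two resolved isotopologues spaced ~1.0033/z
  z <- 12
  sp2 <- render_gaussians(c(700, 700 + 1.0033548 / z), area = c(40, 30),
                          sigma = c(0.008, 0.008))
  pk2 <- pick_peaks(sp2)
  expect_identical(nrow(pk2), 2L)
  expect_equal(diff(pk2$mz), 1.0033548 / z, tolerance = 1e-4)
})

test_that("deisotope recovers each single proteoform at high mass accuracy", {
  for (case in list(c(0, FALSE), c(3, TRUE))) {
    mix <- proteoform_mixture(case[1], as.logical(case[2]), 1)
    sp <- one_scan(mix)
    species <- deisotope(pick_peaks(sp), ub_params)
    expect_identical(nrow(species), 1L)
    expect_lt(abs(species$mass - mix$mass), 0.01)
    expect_identical(length(strsplit(species$charges, ",")[[1]]), 4L)
  }
  expect_identical(nrow(deisotope(pick_peaks(
    tibble::tibble(mz = numeric(), intensity = numeric())), ub_params)), 0L)
})

test_that("a 50/50 phospho pair deconvolves to equal areas", {
  mix <- proteoform_mixture(c(1, 1), c(FALSE, TRUE), c(0.5, 0.5))
  species <- deisotope(pick_peaks(one_scan(mix)), ub_params)
  expect_identical(nrow(species), 2L)
  expect_equal(diff(species$mass), 79.966, tolerance = 0.02)
  expect_equal(species$area[1] / species$area[2], 1, tolerance = 0.01)
})

test_that("XIC integration matches species across scans and sums areas", {
  # one scan: XIC area equals that scan's area
  s1 <- tibble::tibble(mass = 8445.6, area = 100, charges = "12",
                       n_peaks = 10L)
  attr(s1, "unassigned_area") <- 0
  xic <- integrate_xic(list(s1), deconv_params())
  expect_equal(xic$area, 100)

  # species absent from middle scans still merges into one entry
  s2 <- tibble::tibble(mass = numeric(), area = numeric(),
                       charges = character(), n_peaks = integer())
  attr(s2, "unassigned_area") <- 0
  s3 <- tibble::tibble(mass = 8445.8, area = 40, charges = "11",
                       n_peaks = 8L)
  attr(s3, "unassigned_area") <- 0
  xic2 <- integrate_xic(list(s1, s2, s3), deconv_params())
  expect_identical(nrow(xic2), 1L)
  expect_equal(xic2$area, 140)
  expect_identical(xic2$n_scans, 2L)
})

test_that("multi-scan deconvolution conserves generator totals", {
  mix <- proteoform_mixture(c(0, 0), c(FALSE, TRUE), c(0.7, 0.3))
  sim <- simulate_intact_spectra(mix, spectrum_sim_params(noise = 0,
                                                          n_scans = 5),
                                 seed = 2)
  per_scan <- lapply(sim$spectra,
                     function(s) deisotope(pick_peaks(s), ub_params))
  xic <- integrate_xic(per_scan, ub_params)
  expect_identical(nrow(xic), 2L)
  expect_equal(sum(xic$area), 1e6, tolerance = 1e-3)
  expect_equal(xic$area / sum(xic$area), c(0.7, 0.3), tolerance = 5e-3)
})

test_that("quantify_proteoforms assigns, conserves and guards overlaps", {
  sp <- tibble::tibble(mass = 8445.60, area = 10, charges = "12",
                       n_peaks = 5L)
  attr(sp, "unassigned_area") <- 0
  q <- quantify_proteoforms(sp)
  expect_equal(q$fraction[q$n_branches == 0 & !q$phospho], 1)
  expect_equal(sum(q$fraction) + attr(q, "unassigned_fraction"), 1,
               tolerance = 1e-9)

  # species outside tolerance goes to the unassigned pool
  far <- tibble::tibble(mass = 8500, area = 5, charges = "12", n_peaks = 5L)
  attr(far, "unassigned_area") <- 0
  q2 <- quantify_proteoforms(far)
  expect_equal(attr(q2, "unassigned_fraction"), 1)

  cand <- tibble::tibble(proteoform = c("a", "b"), mass = c(8445, 8445.6))
  expect_error(quantify_proteoforms(sp, cand, tolerance = 0.5), "overlap")
})

test_that("recovered fraction is monotone in the true fraction (noise-free)", {
  fr <- c(0.05, 0.15)
  rec <- vapply(fr, function(f) {
    mix <- proteoform_mixture(c(0, 1), c(FALSE, TRUE), c(1 - f, f))
    sim <- simulate_intact_spectra(mix, spectrum_sim_params(noise = 0,
                                                            n_scans = 1),
                                   seed = 7)
    q <- quantify_ub_proteoforms(sim$spectra)
    q$fraction[q$n_branches == 1 & q$phospho]
  }, 0)
  expect_true(all(diff(rec) > 0))
  expect_equal(rec, fr, tolerance = 0.005)
})
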