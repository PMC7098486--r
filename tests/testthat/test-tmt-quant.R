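make_psms <- function(iso, sn, ms3 = TRUE, layer = "diGLY",
                      protein = "P1", site = 1L, ascore = 50,
                      channels = c(100, 200, 300)) {
  n <- max(length(iso), length(sn))
  tibble::tibble(
    layer = layer, psm_id = sprintf("p%d", seq_len(n)),
    protein = rep_len(protein, n), site = rep_len(site, n),
    mod_type = layer, ascore = rep_len(ascore, n),
    isolation_specificity = rep_len(iso, n),
    summed_sn = rep_len(sn, n), has_ms3 = rep_len(ms3, n),
    `126` = channels[1], `127N` = channels[2], `127C` = channels[3]
  )
}

test_that("PSM filters use the stated boundary semantics", {
  # exclusion is 'less than' the thresholds, so the boundaries are kept
  p <- make_psms(iso = c(0.69, 1.0, 0.7, 0.71), sn = c(1000, 150, 149.9, 151))
  kept <- filter_psms(p)
  expect_identical(kept$psm_id, c("p2", "p4"))
  audit <- attr(kept, "audit")
  expect_identical(audit$n_excluded[audit$rule == "isolation_specificity"], 1L)
  expect_identical(audit$n_excluded[audit$rule == "summed_sn"], 1L)

  # no-MS3 PSMs are excluded regardless of other attributes
  p2 <- make_psms(iso = 1, sn = 1000, ms3 = FALSE)
  expect_identical(nrow(filter_psms(p2)), 0L)

  # idempotence
  expect_identical(filter_psms(kept)$psm_id, kept$psm_id)
})

test_that("reporter centroids match within 0.003 Da, nearest wins", {
  ref <- tmt_reporter_table(11)
  expect_identical(nrow(ref), 11L)
  expect_identical(nrow(tmt_reporter_table(10)), 10L)

  m0 <- ref$reporter_mz[1]
  exact <- match_reporter_centroids(tibble::tibble(mz = m0, sn = 42), ref)
  expect_equal(exact$sn[1], 42)

  # two centroids at +0.002 and -0.0025: the nearer one is chosen
  two <- match_reporter_centroids(
    tibble::tibble(mz = c(m0 + 0.002, m0 - 0.0025), sn = c(7, 9)), ref)
  expect_equal(two$sn[1], 7)

  # nearest at 0.004 Da: outside tolerance, channel reads 0
  far <- match_reporter_centroids(tibble::tibble(mz = m0 + 0.004, sn = 5), ref)
  expect_equal(far$sn[1], 0)
})

test_that("rollup sums matching PSMs and keys sites by modification type", {
  p <- dplyr::bind_rows(
    make_psms(iso = 1, sn = 1000, channels = c(10, 20, 30)),
    make_psms(iso = 1, sn = 1000, channels = c(1, 2, 3)))
  site <- rollup(p, "site")
  expect_identical(nrow(site), 1L)
  expect_equal(unlist(site[c("126", "127N", "127C")]),
               c(`126` = 11, `127N` = 22, `127C` = 33))

  # diGLY and phospho layers never merge
  q <- dplyr::bind_rows(p, make_psms(iso = 1, sn = 1000, layer = "phospho"))
  expect_identical(nrow(rollup(q, "site")), 2L)

  # unlocalized PSMs (AScore < 13) do not contribute to site rows
  r <- dplyr::bind_rows(p, make_psms(iso = 1, sn = 1000, ascore = 12.9,
                                     channels = c(1000, 1000, 1000)))
  expect_equal(rollup(r, "site")$`126`, 11)

  # linearity: rollup of concatenated sets equals sum of separate rollups
  a <- make_psms(iso = 1, sn = 1000, channels = c(5, 6, 7))
  both <- rollup(dplyr::bind_rows(p, a), "site")
  expect_equal(both$`126`, rollup(p, "site")$`126` + rollup(a, "site")$`126`)
})

test_that("shared peptides resolve to the most-quantified protein", {
  p <- dplyr::bind_rows(
    make_psms(iso = 1, sn = 1000, protein = "PB"),
    make_psms(iso = 1, sn = 1000, protein = "PB"),
    make_psms(iso = 1, sn = 1000, protein = "PA"),
    make_psms(iso = 1, sn = 1000, protein = "PA;PB"))
  prot <- rollup(p, "protein")
  expect_identical(sort(prot$protein), c("PA", "PB"))
  expect_equal(prot$`126`[prot$protein == "PB"], 300)  # 2 unique + shared
  # with no unique evidence the alphabetical candidate wins
  q <- make_psms(iso = 1, sn = 1000, protein = "PZ;PC")
  expect_identical(rollup(q, "protein")$protein, "PC")
})

test_that("equal-loading normalization equalizes column sums", {
  set.seed(1)
  mat <- tibble::tibble(protein = sprintf("P%d", 1:40),
                        `126` = stats::rlnorm(40, 5, 1),
                        `127N` = stats::rlnorm(40, 6, 1),
                        `127C` = stats::rlnorm(40, 4, 1))
  norm <- normalize_equal_loading(mat, channels = c("126", "127N", "127C"))
  sums <- colSums(as.matrix(norm[c("126", "127N", "127C")]))
  expect_lt(diff(range(sums)) / mean(sums), 1e-6)

  # already-equal columns unchanged
  eq <- tibble::tibble(protein = "P1", `126` = 5, `127N` = 5, `127C` = 5)
  expect_equal(normalize_equal_loading(eq, c("126", "127N", "127C"))$`126`, 5)

  # normalization is one scalar per channel, so each feature's
  # cross-channel pattern survives up to that scalar
  scal <- as.matrix(norm[c("126", "127N", "127C")]) /
    as.matrix(mat[c("126", "127N", "127C")])
  expect_lt(max(apply(scal, 2, function(x) diff(range(x)))), 1e-9)
})

test_that("site-to-protein normalization inverts protein drift exactly", {
  ch <- c("126", "127N", "127C")
  # protein halves in the third channel; the site is constant
  prot <- tibble::tibble(protein = "P1", `126` = 100, `127N` = 100,
                         `127C` = 50)
  site <- tibble::tibble(protein = c("P1", "P2"), site = c(4L, 9L),
                         mod_type = "diGLY",
                         `126` = 10, `127N` = 10, `127C` = 10)
  out <- normalize_site_to_protein(site, prot, channels = ch)
  # relative protein profile is (1.2, 1.2, 0.6): site doubles where the
  # protein halved, modulo the mean-centering constant
  v <- unlist(out[1, ch])
  expect_equal(v[["127C"]] / v[["126"]], 2, tolerance = 1e-12)
  expect_true(out$normalized[1])
  # site without protein passes through, flagged
  expect_false(out$normalized[2])
  expect_equal(unlist(out[2, ch]), c(`126` = 10, `127N` = 10, `127C` = 10))

  # zero protein channel gives a missing site value
  prot0 <- tibble::tibble(protein = "P1", `126` = 100, `127N` = 0,
                          `127C` = 100)
  out0 <- normalize_site_to_protein(site[1, ], prot0, channels = ch)
  expect_true(is.na(out0$`127N`[1]))

  # a flat protein leaves the site unchanged
  flat <- tibble::tibble(protein = "P1", `126` = 7, `127N` = 7, `127C` = 7)
  outf <- normalize_site_to_protein(site[1, ], flat, channels = ch)
  expect_equal(unlist(outf[1, ch]), c(`126` = 10, `127N` = 10, `127C` = 10))
})

test_that("relative_to_untreated divides by per-genotype untreated means", {
  d <- tibble::tibble(channel = c("126", "127N", "127C", "128N"),
                      genotype = c("WT", "WT", "WT", "KO"),
                      treatment = c("UT", "UT", "AO", "AO"),
                      timepoint_h = c(0, 0, 4, 4))
  mat <- tibble::tibble(feature = "f1", `126` = 10, `127N` = 14,
                        `127C` = 24, `128N` = 8)
  expect_error(relative_to_untreated(mat, d,
                                     channels = c("126", "127N", "127C", "128N")),
               "no untreated")
  d_ok <- d[1:3, ]
  out <- relative_to_untreated(mat[c("feature", "126", "127N", "127C")], d_ok,
                               channels = c("126", "127N", "127C"))
  # untreated mean is 12: UT channels average to 1, the 2x effect reads 2.0
  expect_equal(mean(unlist(out[1, c("126", "127N")])), 1, tolerance = 1e-12)
  expect_equal(out$`127C`[1], 2, tolerance = 1e-12)
})
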