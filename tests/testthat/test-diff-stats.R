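test_that("welch_s0 with s0 = 0 reduces exactly to classical Welch", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    ours <- welch_s0(a, b, s0 = 0)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  }
})

test_that("welch_s0 matches the hand-computed moderated statistic", {
  # A = (1,2,3), B = (4,5,6): means 2 and 5, variances 1, se = sqrt(2/3);
  # d = -3 / (1 + sqrt(2/3))
  res <- welch_s0(c(1, 2, 3), c(4, 5, 6), s0 = 1)
  expect_equal(res$statistic, -3 / (1 + sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # equal groups give statistic 0; all-zero variance with s0 = 0 is NA
  expect_equal(welch_s0(c(1, 2), c(1, 2), s0 = 1)$statistic, 0)
  expect_true(is.na(welch_s0(c(1, 1), c(2, 2), s0 = 0)$statistic))
})

test_that("increasing s0 never increases |d|", {
  set.seed(7)
  a <- rnorm(4); b <- rnorm(5, 1)
  ds <- vapply(c(0, 0.2, 0.585, 1, 2),
               function(s0) abs(welch_s0(a, b, s0)$statistic), 0)
  expect_true(all(diff(ds) < 0))
})

test_that("permutation enumeration matches a brute-force oracle for small arms", {
  for (arms in list(c(3, 3), c(4, 4), c(2, 4), c(4, 3))) {
    n <- sum(arms)
    ia <- seq_len(arms[1])
    ours <- ubiquant:::enumerate_assignments(n, ia)
    oracle <- oracle_assignments(n, ia)
    key <- function(sets) sort(vapply(sets, function(s)
      paste(sort(s), collapse = ","), ""))
    expect_identical(key(ours), key(oracle))
  }

  # and the pooled null counts agree with a per-assignment recomputation
  set.seed(3)
  m <- matrix(rnorm(20 * 6), 20)
  p <- stats_params(s0 = 1, fdr_level = 0.05, n_permutations = 1000)
  res <- permutation_fdr(m, rep(c("A", "B"), each = 3), p)
  oracle_d <- vapply(oracle_assignments(6, 1:3), function(s) {
    vapply(seq_len(20), function(i) {
      abs(welch_s0(m[i, s], m[i, -s], s0 = 1)$statistic)
    }, 0)
  }, numeric(20))
  expect_identical(attr(res, "n_permutations"), ncol(oracle_d))
})

test_that("permutation FDR is calibrated on all-null data", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    m <- matrix(rnorm(1000 * 10), 1000)
    groups <- rep(c("A", "B"), each = 5)
    for (level in c(0.05, 0.01)) {
      res <- permutation_fdr(m, groups,
                             stats_params(s0 = 1, fdr_level = level,
                                          n_permutations = 250, seed = seed))
      fpp <- mean(res$significant)
      # binomial error allowance around the nominal level
      expect_lte(fpp, level + 2 * sqrt(level * (1 - level) / 1000))
    }
  }
})

test_that("permutation FDR flags a strongly shifted feature and only that", {
  set.seed(9)
  m <- matrix(rnorm(200 * 8, sd = 1), 200)
  m[57, 5:8] <- m[57, 5:8] + 10  # a 10-sigma shift
  res <- permutation_fdr(m, rep(c("A", "B"), each = 4),
                         stats_params(s0 = 0.1, fdr_level = 0.05))
  expect_true(res$significant[57])
  expect_lte(sum(res$significant), 3)

  # identical groups everywhere: nothing is significant
  m0 <- matrix(rep(rnorm(50), 6), 50)
  res0 <- permutation_fdr(m0, rep(c("A", "B"), each = 3),
                          stats_params(s0 = 1, fdr_level = 0.05))
  expect_identical(sum(res0$significant), 0L)
})

test_that("label swap negates d and preserves the significant set", {
  set.seed(5)
  m <- matrix(rnorm(100 * 6), 100)
  m[1:5, 1:3] <- m[1:5, 1:3] + 4
  g <- rep(c("A", "B"), each = 3)
  p <- stats_params(s0 = 1, fdr_level = 0.05)
  r1 <- permutation_fdr(m, g, p)
  r2 <- permutation_fdr(m, rev(g), p)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  expect_identical(r1$significant, r2$significant)
})

test_that("volcano classification uses strict thresholds", {
  p <- stats_params(log2_threshold = 1, p_threshold = 0.05)
  expect_identical(volcano_classify(1.2, 0.01, p), "up")
  expect_identical(volcano_classify(2.5, 0.2, p), "ns")
  expect_identical(volcano_classify(-1.0, 0.001, p), "ns")
  expect_identical(volcano_classify(-1.01, 0.049, p), "down")
  expect_identical(volcano_classify(c(NA, 1.5), c(0.01, NA), p),
                   c("ns", "ns"))
})

test_that("organelle_shift isolates a planted mitochondrial reduction", {
  set.seed(21)
  classes <- c("mitochondrion", "ER", "Golgi", "lysosome")
  ann <- tibble::tibble(
    protein = sprintf("P%03d", 1:640),
    organelle = rep(classes, each = 160))
  ratios <- tibble::tibble(
    protein = ann$protein,
    log2_ratio = rnorm(640, 0, 0.2) +
      ifelse(ann$organelle == "mitochondrion", -0.3, 0))
  res <- organelle_shift(ratios, ann)
  expect_true(res$significant[res$organelle == "mitochondrion"])
  expect_identical(sum(res$significant), 1L)
  expect_lt(res$mean[res$organelle == "mitochondrion"], -0.2)

  # all-zero ratios: nothing is distinct; singleton classes untestable
  flat <- tibble::tibble(protein = ann$protein, log2_ratio = 0)
  resf <- organelle_shift(flat, ann)
  expect_identical(sum(resf$significant), 0L)
  single <- organelle_shift(
    tibble::tibble(protein = "P001", log2_ratio = 1),
    ann[1, ])
  expect_true(is.na(single$p))
})

test_that("diff_expression ties the pieces together with tidy/glance", {
  set.seed(13)
  n <- 120L
  mat <- tibble::tibble(protein = sprintf("P%d", 1:n))
  base <- stats::rlnorm(n, 5, 1)
  eff <- c(rep(4, 10), rep(1, n - 10))
  for (chn in c("c1", "c2", "c3")) mat[[chn]] <- base * 2^rnorm(n, 0, 0.2)
  for (chn in c("c4", "c5", "c6")) mat[[chn]] <- base * eff * 2^rnorm(n, 0, 0.2)
  fit <- diff_expression(mat, groups = rep(c("AO", "UT"), each = 3),
                         params = stats_params(s0 = 1, fdr_level = 0.01),
                         channels = paste0("c", 1:6))
  td <- tidy(fit)
  expect_identical(nrow(td), n)
  expect_gte(sum(td$significant[1:10]), 9)
  gl <- glance(fit)
  expect_identical(gl$n_features, n)
  expect_identical(gl$n_significant, sum(td$significant))
  pl <- ggplot2::autoplot(fit)
  expect_s3_class(pl, "ggplot")
})
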