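#' Parameters for differential-abundance statistics
#'
#' @param s0 Fudge constant added to the Welch denominator (Tusher-style);
#'   de-emphasizes low-variance features. Conventional settings here: 1
#'   for phospho/diGLY volcanoes, 0.585 for genotype contrasts.
#' @param fdr_level Permutation-FDR level in (0, 1).
#' @param n_permutations Number of label permutations (exhaustive
#'   enumeration is used whenever at most 1,000 distinct permutations
#'   exist).
#' @param seed Seed for permutation sampling.
#' @param log2_threshold,p_threshold Volcano classification thresholds
#'   (strict inequalities).
#' @return A list of class `ub_stats_params`.
#' @export
stats_params <- function(s0 = 1, fdr_level = 0.01, n_permutations = 250,
                         seed = 1L, log2_threshold = 1, p_threshold = 0.05) {
  stopifnot(s0 >= 0, fdr_level > 0, fdr_level < 1, n_permutations >= 1)
  structure(list(s0 = s0, fdr_level = fdr_level,
                 n_permutations = n_permutations, seed = seed,
                 log2_threshold = log2_threshold, p_threshold = p_threshold),
            class = "ub_stats_params")
}

#' Welch's t test with an S0 fudge constant
#'
#' The moderated statistic is d = (meanA - meanB) / (s0 + sqrt(varA/nA +
#' varB/nB)). The p value is computed from the unmodified Welch statistic
#' and its Welch-Satterthwaite degrees of freedom (two-sided), so with
#' s0 = 0 the result is the classical Welch test; s0 only moderates the
#' statistic used for permutation-FDR ranking.
#'
#' @param a,b Numeric vectors (log2 scale), each of length >= 2 after
#'   removing missing values.
#' @param s0 Fudge constant >= 0.
#' @return A tibble with `estimate` (meanA - meanB), `statistic` (the
#'   moderated d), `t` (unmodified Welch statistic), `df`, `p`. If both
#'   variances are zero and s0 = 0 the statistic is undefined and is
#'   reported as `NA`.
#' @export
welch_s0 <- function(a, b, s0 = 1) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se <- sqrt(va + vb)
  est <- mean(a) - mean(b)
  if (se == 0 && s0 == 0) {
    return(tibble::tibble(estimate = est, statistic = NA_real_,
                          t = NA_real_, df = NA_real_, p = NA_real_))
  }
  d <- est / (s0 + se)
  if (se > 0) {
    df <- (va + vb)^2 /
      (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    t <- est / se
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    t <- if (est == 0) 0 else sign(est) * Inf
    df <- NA_real_
    p <- if (est == 0) 1 else 0
  }
  tibble::tibble(estimate = est, statistic = d, t = t, df = df, p = p)
}

## vectorized moderated d over matrix rows for one column split
row_mean_var <- function(x) {
  n <- rowSums(!is.na(x))
  s1 <- rowSums(x, na.rm = TRUE)
  s2 <- rowSums(x^2, na.rm = TRUE)
  m <- s1 / n
  v <- pmax(s2 - s1^2 / n, 0) / (n - 1)
  list(n = n, mean = m, var = v)
}

welch_d_matrix <- function(mat, ia, ib, s0) {
  a <- row_mean_var(mat[, ia, drop = FALSE])
  b <- row_mean_var(mat[, ib, drop = FALSE])
  d <- (a$mean - b$mean) / (s0 + sqrt(a$var / a$n + b$var / b$n))
  d[a$n < 2 | b$n < 2] <- NA
  d
}

## distinct two-group label assignments as a list of group-A index sets;
## identity excluded; complements deduplicated when arms are equal
enumerate_assignments <- function(n, ia) {
  nA <- length(ia)
  sets <- utils::combn(n, nA, simplify = FALSE)
  ident <- purrr::map_lgl(sets, ~ setequal(.x, ia))
  sets <- sets[!ident]
  if (nA == n - nA) {
    keyed <- purrr::map_chr(sets, function(s) {
      s2 <- if (min(s) > min(setdiff(seq_len(n), s))) setdiff(seq_len(n), s) else s
      paste(s2, collapse = ",")
    })
    sets <- sets[!duplicated(keyed)]
    sets <- sets[!purrr::map_lgl(sets, ~ setequal(.x, setdiff(seq_len(n), ia)))]
  }
  sets
}

#' SAM-style permutation-based FDR control
#'
#' Computes the moderated Welch statistic d per feature for the observed
#' two-group labeling, builds a null |d| distribution from label
#' permutations (all distinct permutations when at most
#' min(n_permutations, 1000) exist, otherwise a seeded random sample),
#' and for each candidate cut-off estimates FDR as the median permuted
#' count of features beyond the cut-off divided by the observed count.
#' The significant set is the largest set with estimated FDR at or below
#' `fdr_level`.
#'
#' @param mat Numeric matrix (features x samples) of log2 values, or a
#'   wide tibble with channel columns.
#' @param groups Two-level vector (or factor) over the columns of `mat`;
#'   `NA` columns are ignored.
#' @param params A [stats_params()] object.
#' @param channels When `mat` is a tibble, the channel columns.
#' @return A tibble with `feature`, `estimate` (mean log2 difference),
#'   `statistic`, `p`, `significant`, plus attributes `cutoff`,
#'   `est_fdr`, `n_permutations`.
#' @export
permutation_fdr <- function(mat, groups, params = stats_params(),
                            channels = NULL) {
  if (is.data.frame(mat)) {
    channels <- quant_channels(mat, channels)
    feature <- seq_len(nrow(mat))
    m <- as.matrix(mat[channels])
  } else {
    m <- as.matrix(mat)
    feature <- rownames(m) %||% seq_len(nrow(m))
  }
  use <- !is.na(groups)
  m <- m[, use, drop = FALSE]
  g <- factor(groups[use])
  if (nlevels(g) != 2) rlang::abort("exactly two groups required")
  ia <- which(g == levels(g)[1])
  ib <- which(g == levels(g)[2])

  sets <- enumerate_assignments(ncol(m), ia)
  if (length(sets) < 2) {
    rlang::abort("fewer than 2 distinct label permutations exist")
  }
  if (length(sets) > min(params$n_permutations, 1000)) {
    set.seed(params$seed)
    sets <- sets[sample.int(length(sets), params$n_permutations)]
  }

  d_obs <- welch_d_matrix(m, ia, ib, params$s0)
  est <- rowMeans(m[, ia, drop = FALSE], na.rm = TRUE) -
    rowMeans(m[, ib, drop = FALSE], na.rm = TRUE)
  d_null <- vapply(sets, function(s) {
    abs(welch_d_matrix(m, s, setdiff(seq_len(ncol(m)), s), params$s0))
  }, numeric(nrow(m)))

  ok <- !is.na(d_obs)
  cuts <- sort(abs(d_obs[ok]), decreasing = TRUE)
  n_obs <- seq_along(cuts)
  med_null <- vapply(cuts, function(ct) {
    stats::median(colSums(d_null >= ct, na.rm = TRUE))
  }, 0)
  fdr_hat <- med_null / n_obs
  k <- which(fdr_hat <= params$fdr_level)
  cutoff <- if (length(k)) cuts[max(k)] else Inf
  sig <- !is.na(d_obs) & abs(d_obs) >= cutoff

  out <- tibble::tibble(feature = feature, estimate = est,
                        statistic = d_obs, significant = sig)
  attr(out, "cutoff") <- cutoff
  attr(out, "est_fdr") <- if (length(k)) fdr_hat[max(k)] else NA_real_
  attr(out, "n_permutations") <- length(sets)
  out
}

#' Volcano-style classification of features
#'
#' `"up"` when log2 ratio > threshold and p < p-threshold, `"down"` when
#' log2 ratio < -threshold and p < p-threshold, otherwise `"ns"`. The
#' inequalities are strict (a log2 ratio of exactly -1 is `"ns"`).
#'
#' @param log2_ratio,p Numeric vectors.
#' @param params A [stats_params()] (uses `log2_threshold`, `p_threshold`).
#' @return Character vector in `c("up", "down", "ns")`.
#' @export
volcano_classify <- function(log2_ratio, p, params = stats_params()) {
  out <- rep("ns", length(log2_ratio))
  sigp <- !is.na(p) & p < params$p_threshold
  out[sigp & !is.na(log2_ratio) & log2_ratio > params$log2_threshold] <- "up"
  out[sigp & !is.na(log2_ratio) & log2_ratio < -params$log2_threshold] <- "down"
  out
}

#' Per-organelle distribution shift of protein abundance ratios
#'
#' Summarizes per-protein log2 ratios by organelle class (mean, SEM) and
#' tests each class mean against zero with a two-sided one-sample t test,
#' Benjamini-Hochberg corrected across classes. Classes with fewer than
#' two proteins cannot be tested and get `NA` p values.
#'
#' @param ratios Tibble with `protein` and `log2_ratio`.
#' @param annotation Tibble mapping `protein` to one `organelle` class.
#' @return A tibble per class: `organelle`, `n`, `mean`, `sem`, `p`,
#'   `p_adj`, `significant` (p_adj < 0.05).
#' @export
organelle_shift <- function(ratios, annotation) {
  joined <- dplyr::inner_join(ratios, annotation, by = "protein")
  out <- joined |>
    dplyr::group_by(.data$organelle) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$log2_ratio),
      sem = stats::sd(.data$log2_ratio) / sqrt(dplyr::n()),
      p = if (dplyr::n() >= 2 && stats::sd(.data$log2_ratio) > 0) {
        stats::t.test(.data$log2_ratio, mu = 0)$p.value
      } else NA_real_,
      .groups = "drop")
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Two-group differential abundance with permutation FDR and volcano calls
#'
#' The figure-legend procedure end to end: per-feature mean log2 ratio and
#' moderated Welch statistic, classical Welch p value, SAM-style
#' permutation-FDR significance, and volcano category.
#'
#' @param mat Wide quantification tibble or numeric matrix of positive
#'   intensities (log2 is taken internally; set `log2 = FALSE` if the
#'   input is already log scale).
#' @param groups Two-level assignment over columns/channels (NA = unused).
#' @param params A [stats_params()].
#' @param channels Channel columns when `mat` is a tibble.
#' @param log2 Log2-transform the values first?
#' @return An object of class `ub_diff`: the underlying tibble carries
#'   `feature`, `log2_ratio`, `statistic`, `p`, `significant`,
#'   `category`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
diff_expression <- function(mat, groups, params = stats_params(),
                            channels = NULL, log2 = TRUE) {
  if (is.data.frame(mat)) {
    channels <- quant_channels(mat, channels)
    m <- as.matrix(mat[channels])
    keys <- mat[setdiff(names(mat), channels)]
  } else {
    m <- as.matrix(mat)
    keys <- tibble::tibble(.rows = nrow(m))
  }
  if (log2) {
    m[m <= 0] <- NA
    m <- base::log2(m)
  }
  pf <- permutation_fdr(m, groups, params)
  use <- !is.na(groups)
  g <- factor(groups[use])
  ia <- which(g == levels(g)[1]); ib <- which(g == levels(g)[2])
  mm <- m[, use, drop = FALSE]
  welch <- purrr::map(seq_len(nrow(mm)), function(i) {
    a <- mm[i, ia]; b <- mm[i, ib]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
      return(tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                            t = NA_real_, df = NA_real_, p = NA_real_))
    }
    welch_s0(a, b, params$s0)
  }) |> dplyr::bind_rows()
  res <- dplyr::bind_cols(keys, tibble::tibble(
    feature = pf$feature,
    log2_ratio = welch$estimate,
    statistic = welch$statistic,
    p = welch$p,
    significant = pf$significant,
    category = volcano_classify(welch$estimate, welch$p, params)
  ))
  structure(list(result = res, params = params,
                 cutoff = attr(pf, "cutoff"),
                 n_permutations = attr(pf, "n_permutations"),
                 groups = levels(g)),
            class = "ub_diff")
}

#' @export
print.ub_diff <- function(x, ...) {
  cat(sprintf(
    "Two-group differential abundance (%s vs %s): %d features, %d significant at permutation FDR %.2g (s0 = %g, %d permutations)\n",
    x$groups[1], x$groups[2], nrow(x$result), sum(x$result$significant),
    x$params$fdr_level, x$params$s0, x$n_permutations))
  print(x$result, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-abundance fit
#'
#' @param x An `ub_diff` object.
#' @param ... Unused.
#' @return The per-feature result tibble.
#' @export
tidy.ub_diff <- function(x, ...) x$result

#' One-row summary of a differential-abundance fit
#'
#' @param x An `ub_diff` object.
#' @param ... Unused.
#' @return A tibble with feature counts, the |d| cutoff, and parameters.
#' @export
glance.ub_diff <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$result),
    n_significant = sum(x$result$significant),
    n_up = sum(x$result$category == "up"),
    n_down = sum(x$result$category == "down"),
    cutoff = x$cutoff,
    s0 = x$params$s0,
    fdr_level = x$params$fdr_level,
    n_permutations = x$n_permutations
  )
}
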