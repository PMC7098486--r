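# Independent oracles used to freeze expected values. These deliberately
# avoid the package's computational paths (repeated-squaring convolution,
# composition tables): the isotope oracle expands one atom at a time with
# explicit loops; the mass oracle sums published residue monoisotopic
# masses.

# atom-by-atom polynomial expansion of the aggregated isotope distribution
brute_force_isotope <- function(formula, n_peaks = 15) {
  iso <- list(
    H = list(mass = c(1.00782503207, 2.0141017778),
             ab = c(0.999885, 0.000115)),
    C = list(mass = c(12.0, 13.0033548378), ab = c(0.9893, 0.0107)),
    N = list(mass = c(14.0030740048, 15.0001088982), ab = c(0.99636, 0.00364)),
    O = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
             ab = c(0.99757, 0.00038, 0.00205)),
    S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
             ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
    P = list(mass = 30.97376163, ab = 1)
  )
  m <- gregexpr("[A-Z][a-z]?\\d*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?\\d*", formula))[[1]]
  atoms <- character()
  for (tk in toks) {
    sym <- gsub("\\d", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (n == "") 1L else as.integer(n)
    atoms <- c(atoms, rep(sym, n))
  }
  w <- 1; wm <- 0  # abundance and abundance*mass by nucleon offset
  for (a in atoms) {
    el <- iso[[a]]
    off <- round(el$mass - el$mass[1])
    len <- length(w) + max(off)
    w2 <- numeric(len); wm2 <- numeric(len)
    for (i in seq_along(w)) {
      for (j in seq_along(el$mass)) {
        k <- i + off[j]
        w2[k] <- w2[k] + w[i] * el$ab[j]
        wm2[k] <- wm2[k] + wm[i] * el$ab[j] + w[i] * el$ab[j] * el$mass[j]
      }
    }
    w <- w2; wm <- wm2
  }
  keep <- seq_len(min(n_peaks, length(w)))
  w <- w[keep]; wm <- wm[keep]
  ok <- w > 0
  data.frame(mass = wm[ok] / w[ok], abundance = w[ok] / sum(w[ok]))
}

# published residue monoisotopic masses (5 decimals) + water
RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

oracle_peptide_mass <- function(seq) {
  sum(RESIDUE_MONO[strsplit(seq, "")[[1]]]) + 18.010565
}

# exhaustive two-group label assignments (group-A index sets), identity
# excluded, complements deduplicated for equal arms; independent of the
# package's enumerator
oracle_assignments <- function(n, ia) {
  sets <- utils::combn(n, length(ia), simplify = FALSE)
  out <- list()
  seen <- character()
  for (s in sets) {
    if (setequal(s, ia)) next
    if (length(ia) * 2 == n) {
      comp <- setdiff(seq_len(n), s)
      if (setequal(comp, ia)) next
      key <- paste(sort(if (min(s) < min(comp)) s else comp), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    out[[length(out) + 1]] <- s
  }
  out
}

# small synthetic profile spectrum: Gaussians of given areas at given m/z
render_gaussians <- function(mz0, area, sigma, range = NULL, step = NULL) {
  if (is.null(range)) range <- c(min(mz0) - 1, max(mz0) + 1)
  if (is.null(step)) step <- min(sigma) / 6
  grid <- seq(range[1], range[2], by = step)
  y <- numeric(length(grid))
  for (k in seq_along(mz0)) {
    y <- y + area[k] / (sigma[k] * sqrt(2 * pi)) *
      exp(-(grid - mz0[k])^2 / (2 * sigma[k]^2))
  }
  tibble::tibble(mz = grid, intensity = y)
}
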