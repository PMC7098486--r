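#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## IUPAC monoisotopic masses / natural abundances; heavy-label tokens
## ("13C", "15N", "2H") carry abundance 1 so labeled reagents (TMT) work.
ISOTOPE_TABLE <- list(
  H = list(mass = c(1.00782503207, 2.0141017778),
           abundance = c(0.999885, 0.000115)),
  C = list(mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  N = list(mass = c(14.0030740048, 15.0001088982),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(mass = 30.97376163, abundance = 1),
  `13C` = list(mass = 13.0033548378, abundance = 1),
  `15N` = list(mass = 15.0001088982, abundance = 1),
  `2H`  = list(mass = 2.0141017778, abundance = 1)
)

#' Physical constants used throughout
#'
#' `proton_mass()` returns the mass of a proton in Da (1.007276 Da, the
#' convention of vendor deconvolution software reporting MH+ masses);
#' `isotopologue_spacing()` the average spacing between successive
#' isotopologue peaks (the 13C-12C mass difference, ~1.0034 Da).
#'
#' @return A single numeric value in Da.
#' @export
proton_mass <- function() 1.007276466622

#' @rdname proton_mass
#' @export
isotopologue_spacing <- function() 1.0033548378

#' Parse or construct an elemental composition
#'
#' An elemental composition is a named integer vector mapping element (or
#' isotope-label, e.g. `"13C"`) symbols to non-negative counts. A formula
#' string such as `"C4H6N2O2"` is parsed left to right; isotope labels are
#' written with a leading mass number in parentheses-free Hill-ish style,
#' e.g. `"(13C)4"`.
#'
#' @param x A formula string, a named numeric vector, or a list of counts.
#' @return A named integer vector of class `ub_composition`.
#' @examples
#' composition("C4H6N2O2")   # the GlyGly remnant
#' composition(c(H = 2, O = 1))
#' @export
composition <- function(x) {
  if (inherits(x, "ub_composition")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    counts <- parse_formula(x)
  } else {
    counts <- unlist(x)
    if (is.null(names(counts)) || any(names(counts) == "")) {
      rlang::abort("composition counts must be named by element symbol")
    }
  }
  validate_composition(counts)
}

parse_formula <- function(formula) {
  tokens <- stringr::str_match_all(
    formula, "\\((\\d+[A-Z][a-z]?)\\)(\\d*)|([A-Z][a-z]?)(\\d*)")[[1]]
  consumed <- sum(nchar(tokens[, 1]))
  if (consumed != nchar(formula)) {
    rlang::abort(sprintf("cannot parse formula '%s'", formula))
  }
  sym <- ifelse(is.na(tokens[, 2]), tokens[, 4], tokens[, 2])
  n <- ifelse(is.na(tokens[, 2]), tokens[, 5], tokens[, 3])
  n <- as.integer(ifelse(n == "", "1", n))
  tapply(n, factor(sym, levels = unique(sym)), sum)
}

validate_composition <- function(counts) {
  counts <- counts[counts != 0]
  unknown <- setdiff(names(counts), names(ISOTOPE_TABLE))
  if (length(unknown)) {
    rlang::abort(sprintf("unknown element symbol(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (any(counts < 0)) rlang::abort("element counts must be >= 0")
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "ub_composition")
}

#' Combine elemental compositions
#'
#' Element-wise addition of compositions; multiples are allowed via `times`.
#' Subtraction is deliberately not provided: compositions never go negative.
#'
#' @param ... Compositions (or objects coercible by [composition()]).
#' @param times Integer multipliers recycled across `...`.
#' @return A `ub_composition`.
#' @export
composition_sum <- function(..., times = 1L) {
  comps <- purrr::map(list(...), composition)
  times <- rep_len(times, length(comps))
  all_el <- unique(unlist(purrr::map(comps, names)))
  counts <- purrr::reduce(purrr::map2(comps, times, function(cc, k) {
    v <- stats::setNames(rep(0L, length(all_el)), all_el)
    v[names(cc)] <- cc * k
    v
  }), `+`)
  validate_composition(counts)
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums the lightest-isotope masses (IUPAC values) over all atoms.
#'
#' @param comp Composition (anything accepted by [composition()]).
#' @return Monoisotopic mass in Da. The empty composition has mass 0.
#' @examples
#' monoisotopic_mass("C4H6N2O2")  # 114.0429, the diGLY remnant
#' @export
monoisotopic_mass <- function(comp) {
  comp <- composition(comp)
  if (!length(comp)) return(0)
  sum(purrr::map_dbl(names(comp), ~ ISOTOPE_TABLE[[.x]]$mass[1]) * comp)
}

#' Aggregated isotopologue distribution of a composition
#'
#' Convolves per-element isotope distributions (computed by repeated
#' squaring of each element's single-atom distribution) and aggregates
#' isotopologues by nucleon-number offset from the monoisotopic peak, so
#' successive peaks are spaced ~1.0034 Da apart. Peak masses are
#' abundance-weighted centroids of the isotopologues sharing an offset.
#'
#' @param comp Composition.
#' @param n_peaks Number of leading isotopologue peaks to return (>= 1).
#' @return A tibble with columns `mass` (Da, strictly increasing) and
#'   `abundance` (non-negative, renormalized to sum to 1).
#' @export
isotope_distribution <- function(comp, n_peaks = 10L) {
  stopifnot(n_peaks >= 1)
  comp <- composition(comp)
  if (!length(comp)) {
    return(tibble::tibble(mass = 0, abundance = 1)[seq_len(min(1, n_peaks)), ])
  }
  dist <- purrr::reduce(
    purrr::map2(names(comp), as.integer(comp), element_power_dist),
    convolve_dist)
  keep <- seq_len(min(n_peaks, length(dist$w)))
  w <- dist$w[keep]
  m <- dist$m[keep] / ifelse(w > 0, w, 1)
  ok <- w > 0
  tibble::tibble(mass = m[ok], abundance = w[ok] / sum(w[ok]))
}

## distribution of n atoms of one element, by repeated squaring;
## representation: w[k+1] = P(offset k), m[k+1] = sum over isotopologues of
## P * mass (i.e. abundance-weighted mass, unnormalized)
element_power_dist <- function(element, n) {
  iso <- ISOTOPE_TABLE[[element]]
  offset <- round(iso$mass - iso$mass[1])
  len <- max(offset) + 1
  base <- list(w = numeric(len), m = numeric(len))
  base$w[offset + 1] <- iso$abundance
  base$m[offset + 1] <- iso$abundance * iso$mass
  acc <- NULL
  while (n > 0) {
    if (n %% 2 == 1) acc <- if (is.null(acc)) base else convolve_dist(acc, base)
    n <- n %/% 2
    if (n > 0) base <- convolve_dist(base, base)
  }
  acc
}

## direct (non-FFT) convolution: exact to double precision even in the
## far tail, where FFT round-off would corrupt centroid masses
conv_direct <- function(a, b) {
  n <- length(a) + length(b) - 1
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

convolve_dist <- function(a, b, prune = 1e-14, max_len = 120L) {
  w <- conv_direct(a$w, b$w)
  ## E[mass] bookkeeping: mass of a sum is additive, so
  ## m_out = conv(a$m, b$w) + conv(a$w, b$m)
  m <- conv_direct(a$m, b$w) + conv_direct(a$w, b$m)
  keep <- seq_len(min(length(w), max_len))
  w <- w[keep]; m <- m[keep]
  ## drop negligible trailing mass to keep convolutions short
  last <- max(which(w > prune * max(w)), 1)
  list(w = w[seq_len(last)], m = m[seq_len(last)])
}

#' Averagine model composition for a target mass
#'
#' Scales the averagine average-residue unit (C4.9384 H7.7583 N1.3577
#' O1.4773 S0.0417) to a target monoisotopic mass, rounds element counts,
#' and adjusts the hydrogen count so the monoisotopic mass lands within
#' 0.5 Da of the target. With `sulfur_free = TRUE` (the vendor "averagine
#' no sulfur" setting used for Ub work) the sulfur count is forced to zero
#' before rebalancing.
#'
#' @param target_mass Target neutral monoisotopic mass (Da, > 0).
#' @param sulfur_free Drop sulfur from the model unit? Default `TRUE`.
#' @return A `ub_composition`.
#' @export
averagine_composition <- function(target_mass, sulfur_free = TRUE) {
  stopifnot(target_mass > 0)
  unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
  if (sulfur_free) unit <- unit[names(unit) != "S"]
  unit_mass <- sum(purrr::imap_dbl(unit, ~ .x * ISOTOPE_TABLE[[.y]]$mass[1]))
  counts <- pmax(round(unit * target_mass / unit_mass), 0)
  counts["H"] <- max(counts["H"] +
    round((target_mass - sum(purrr::imap_dbl(
      counts, ~ .x * ISOTOPE_TABLE[[.y]]$mass[1]))) /
      ISOTOPE_TABLE$H$mass[1]), 0)
  validate_composition(counts)
}

#' m/z of a protonated ion, and its inverse
#'
#' `mz_for_charge()` computes (M + z * m_proton) / z for a neutral mass M;
#' `neutral_mass()` inverts it.
#'
#' @param neutral_mass,mz Neutral mass (Da) / observed m/z.
#' @param z Positive integer charge.
#' @return m/z (or neutral mass) in Da.
#' @export
mz_for_charge <- function(neutral_mass, z) {
  stopifnot(all(z >= 1), all(z == round(z)))
  (neutral_mass + z * proton_mass()) / z
}

#' @rdname mz_for_charge
#' @export
neutral_mass <- function(mz, z) {
  stopifnot(all(z >= 1), all(z == round(z)))
  mz * z - z * proton_mass()
}

#' Localization-score threshold for a confidence level
#'
#' AScore-style probability scores are -10 log10 of the complementary
#' probability; 95% confidence corresponds to the conventional threshold
#' of 13 used to call a site localized.
#'
#' @param confidence Probability in (0, 1).
#' @return Score (not rounded; round to the nearest integer for the
#'   conventional thresholds).
#' @examples
#' round(ascore_threshold(0.95))  # 13
#' @export
ascore_threshold <- function(confidence) {
  stopifnot(all(confidence > 0), all(confidence < 1))
  -10 * log10(1 - confidence)
}
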