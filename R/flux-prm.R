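#' Processed/unprocessed reporter ratio from immunoblot bands
#'
#' The mitophagic-flux readout: (processed - background) /
#' (post-import - background). The ratio is invariant to uniform
#' intensity scaling of both bands.
#'
#' @param bands Tibble with `processed`, `post_import` and (optionally)
#'   `background` columns, e.g. from [simulate_flux_blots()].
#' @return The tibble with a `keima_ratio` column appended.
#' @export
keima_ratio <- function(bands) {
  bg <- bands$background %||% 0
  if (any(bands$post_import - bg <= 0)) {
    rlang::abort("post-import band must exceed background")
  }
  dplyr::mutate(bands,
                keima_ratio = (.data$processed - bg) / (.data$post_import - bg))
}

#' Red-only signal of a two-channel soma image
#'
#' The imaging flux equation: the red channel is subtracted by the green
#' channel (clipped at zero), positive pixels form a binary mask, and the
#' per-soma value is area x percent area x 0.01 x mean intensity of the
#' masked pixels in the subtracted image. An empty mask gives 0.
#'
#' @param red,green Numeric matrices of identical shape.
#' @param threshold Subtracted-intensity threshold above which a pixel
#'   enters the mask (default 0, i.e. any positive pixel).
#' @return A single numeric value.
#' @export
red_only_signal <- function(red, green, threshold = 0) {
  stopifnot(identical(dim(red), dim(green)))
  sub <- pmax(red - green, 0)
  mask <- sub > threshold
  area <- sum(mask)
  if (area == 0) return(0)
  percent_area <- 100 * area / length(sub)
  area * percent_area * 0.01 * mean(sub[mask])
}

#' Red-only signals for a cohort of somata, normalized to untreated
#'
#' Applies [red_only_signal()] per soma and, when a `condition` label is
#' provided, divides every value by the mean of the untreated condition.
#'
#' @param somata List of somata (as from [simulate_flux_images()]), each
#'   with `red` and `green` matrices.
#' @param condition Optional per-soma condition labels.
#' @param untreated Label of the untreated condition.
#' @param threshold Passed to [red_only_signal()].
#' @return Tibble with `soma`, `condition`, `value` and (when normalized)
#'   `relative_value`.
#' @export
flux_image_signal <- function(somata, condition = NULL, untreated = "UT",
                              threshold = 0) {
  out <- tibble::tibble(
    soma = purrr::map_int(somata, ~ as.integer(.x$soma %||% NA_integer_)),
    value = purrr::map_dbl(somata, ~ red_only_signal(.x$red, .x$green,
                                                     threshold))
  )
  if (!is.null(condition)) {
    out$condition <- rep_len(condition, nrow(out))
    ref <- mean(out$value[out$condition == untreated])
    if (!is.finite(ref) || ref == 0) {
      rlang::abort("untreated condition has no usable somata")
    }
    out$relative_value <- out$value / ref
  }
  out
}

#' Exclude low-expressing somata
#'
#' Somata whose mean dual-channel (red + green) intensity is below 30%
#' of the cohort mean are excluded (removes low-level expressing cells).
#'
#' @param somata List of somata with `red` and `green` matrices.
#' @param min_fraction Exclusion threshold relative to the cohort mean.
#' @return The retained somata; attribute `excluded` holds the indices
#'   removed.
#' @export
expression_filter <- function(somata, min_fraction = 0.3) {
  stopifnot(length(somata) >= 1)
  expr <- purrr::map_dbl(somata, ~ mean((.x$red + .x$green) / 2))
  keep <- expr >= min_fraction * mean(expr)
  out <- somata[keep]
  attr(out, "excluded") <- which(!keep)
  out
}

#' Absolute protein abundance from PRM heavy-reference peptides
#'
#' Per peptide, endogenous fmol = spike fmol x (light area / heavy area);
#' the protein value is the mean across its peptides divided by the
#' mitochondrial input, with SEM across peptides.
#'
#' @param areas Tibble with `protein`, `peptide`, `spike_fmol`,
#'   `light_area`, `heavy_area`, `input_ug`.
#' @return Tibble per protein: `protein`, `n_peptides`, `fmol_per_ug`,
#'   `sem`.
#' @export
prm_abundance <- function(areas) {
  if (any(areas$heavy_area <= 0)) {
    rlang::abort("heavy reference areas must be positive")
  }
  areas |>
    dplyr::mutate(fmol = .data$spike_fmol * .data$light_area /
                    .data$heavy_area / .data$input_ug) |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      fmol_per_ug = mean(.data$fmol),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$fmol) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop")
}

#' Molar stoichiometry between two quantified proteins
#'
#' Ratio of absolute abundances with first-order error propagation from
#' the peptide-level SEMs.
#'
#' @param abundance Tibble from [prm_abundance()].
#' @param numerator,denominator Protein names.
#' @return Tibble with `numerator`, `denominator`, `ratio`, `se`.
#' @export
prm_stoichiometry <- function(abundance, numerator, denominator) {
  get <- function(p) {
    i <- match(p, abundance$protein)
    if (is.na(i)) rlang::abort(sprintf("protein '%s' not quantified", p))
    abundance[i, ]
  }
  purrr::map_dfr(denominator, function(den) {
    a <- get(numerator); b <- get(den)
    if (b$fmol_per_ug <= 0) rlang::abort("denominator abundance must be > 0")
    ratio <- a$fmol_per_ug / b$fmol_per_ug
    se <- sqrt((a$sem %|na|% 0 / b$fmol_per_ug)^2 +
                 (ratio * (b$sem %|na|% 0) / b$fmol_per_ug)^2)
    tibble::tibble(numerator = numerator, denominator = den,
                   ratio = ratio, se = se)
  })
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a
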