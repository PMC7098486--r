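#' Simulate mitophagic-flux reporter immunoblot intensities
#'
#' Band intensities for a lysosome-resistant processed reporter fragment
#' and the post-import (unprocessed) form, drawn around configurable true
#' processed/unprocessed ratios with multiplicative log-normal noise and
#' a constant lane background.
#'
#' @param conditions Tibble with `genotype`, `timepoint_h` and
#'   `true_ratio` (true processed/unprocessed ratio per condition).
#'   Default: the WT basal-to-depolarized trajectory rising from 0.3
#'   to 0.5 over 4-12 h.
#' @param n_replicates Replicates per condition (default 3).
#' @param unprocessed Mean post-import band intensity (arbitrary units).
#' @param background Constant background intensity per lane.
#' @param cv Log-normal coefficient of variation of band intensities
#'   (0 = noise-free).
#' @param seed Integer seed.
#' @return A list with `bands` (tibble: sample, genotype, timepoint_h,
#'   replicate, post_import, processed, background) and `ground_truth`
#'   (the conditions table).
#' @export
simulate_flux_blots <- function(conditions = flux_trajectory_wt(),
                                n_replicates = 3, unprocessed = 1000,
                                background = 50, cv = 0.08, seed = 1L) {
  stopifnot(all(c("genotype", "timepoint_h", "true_ratio") %in%
                  names(conditions)))
  set.seed(seed)
  grid <- tidyr::expand_grid(conditions,
                             replicate = seq_len(n_replicates))
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(n) if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  n <- nrow(grid)
  post <- unprocessed * noise(n)
  proc <- unprocessed * grid$true_ratio * noise(n)
  bands <- tibble::tibble(
    sample = sprintf("%s_%gh_r%d", grid$genotype, grid$timepoint_h,
                     grid$replicate),
    genotype = grid$genotype, timepoint_h = grid$timepoint_h,
    replicate = grid$replicate,
    post_import = post + background,
    processed = proc + background,
    background = background
  )
  list(bands = bands, ground_truth = conditions)
}

#' @rdname simulate_flux_blots
#' @export
flux_trajectory_wt <- function() {
  tibble::tibble(genotype = "WT",
                 timepoint_h = c(0, 4, 8, 12),
                 true_ratio = c(0.30, 0.38, 0.45, 0.50))
}

#' Simulate two-channel soma images for a red-only flux reporter
#'
#' Each soma is a square field with dual-channel (red + green) cytoplasmic
#' signal plus `n_puncta` circular red-only puncta (lysosomally delivered
#' reporter) of given radius and intensity. Expression level scales both
#' channels; low-expression somata can be planted to exercise the 30%
#' expression filter.
#'
#' @param n_somata Number of somata.
#' @param dim Image side length in pixels.
#' @param n_puncta Red-only puncta per soma (recycled).
#' @param punctum_radius,punctum_intensity Punctum geometry and intensity
#'   above the red background.
#' @param soma_intensity Dual-channel soma intensity.
#' @param expression Per-soma expression scaling (recycled; values < 0.3
#'   of the cohort mean should be excluded by [expression_filter()]).
#' @param noise_sd Additive Gaussian pixel noise sd.
#' @param seed Integer seed.
#' @return A list of somata, each a list with `soma` id, `red`, `green`
#'   matrices and `ground_truth` (n_puncta, punctum pixel area, true
#'   red-only value by the area x percent-area x 0.01 x mean-intensity
#'   equation).
#' @export
simulate_flux_images <- function(n_somata = 6, dim = 64, n_puncta = 3,
                                 punctum_radius = 3, punctum_intensity = 200,
                                 soma_intensity = 500, expression = 1,
                                 noise_sd = 0, seed = 1L) {
  set.seed(seed)
  n_puncta <- rep_len(n_puncta, n_somata)
  expression <- rep_len(expression, n_somata)
  coords <- expand.grid(x = seq_len(dim), y = seq_len(dim))
  purrr::map(seq_len(n_somata), function(i) {
    base <- soma_intensity * expression[i]
    red <- matrix(base, dim, dim)
    green <- matrix(base, dim, dim)
    mask <- matrix(FALSE, dim, dim)
    if (n_puncta[i] > 0) {
      cx <- stats::runif(n_puncta[i], punctum_radius + 2, dim - punctum_radius - 2)
      cy <- stats::runif(n_puncta[i], punctum_radius + 2, dim - punctum_radius - 2)
      for (k in seq_len(n_puncta[i])) {
        inside <- (coords$x - cx[k])^2 + (coords$y - cy[k])^2 <= punctum_radius^2
        red[cbind(coords$x[inside], coords$y[inside])] <-
          base + punctum_intensity * expression[i]
        mask[cbind(coords$x[inside], coords$y[inside])] <- TRUE
      }
    }
    if (noise_sd > 0) {
      red <- pmax(red + stats::rnorm(dim^2, 0, noise_sd), 0)
      green <- pmax(green + stats::rnorm(dim^2, 0, noise_sd), 0)
    }
    area <- sum(mask)
    truth_value <- area * (100 * area / dim^2) * 0.01 *
      (punctum_intensity * expression[i])
    list(soma = i, red = red, green = green,
         ground_truth = list(n_puncta = n_puncta[i], punctum_area = area,
                             red_only_value = truth_value,
                             expression = expression[i]))
  })
}

#' Simulate PRM light/heavy chromatographic peak areas
#'
#' Heavy-reference (AQUA) peptides are spiked at a known fmol amount; the
#' light (endogenous) area relates to the heavy area by the true
#' endogenous fmol divided by the spike. Multiplicative log-normal noise
#' is applied per peptide.
#'
#' @param proteins Tibble with `protein`, `true_fmol_per_ug` and
#'   `n_peptides`. Default: the outer-membrane translocon receptors and
#'   their deubiquitylase at ~0.3 stoichiometry (2, 6 and 2 peptides).
#' @param spike_fmol Heavy spike per peptide (fmol, > 0).
#' @param input_ug Mitochondrial input (micrograms).
#' @param cv Log-normal CV of the light/heavy ratio (0 = noise-free).
#' @param seed Integer seed.
#' @return A list with `areas` (tibble: protein, peptide, spike_fmol,
#'   light_area, heavy_area, input_ug) and `ground_truth` (the protein
#'   table).
#' @export
simulate_prm_areas <- function(proteins = prm_reference_proteins(),
                               spike_fmol = 10, input_ug = 1, cv = 0.05,
                               seed = 1L) {
  stopifnot(spike_fmol > 0, all(proteins$n_peptides >= 1))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  rows <- tidyr::uncount(proteins, .data$n_peptides, .remove = FALSE)
  rows <- dplyr::group_by(rows, .data$protein)
  rows <- dplyr::mutate(rows, peptide = sprintf("%s_pep%d", .data$protein,
                                                dplyr::row_number()))
  rows <- dplyr::ungroup(rows)
  n <- nrow(rows)
  heavy <- stats::rlnorm(n, log(1e6), 0.3)
  ratio_noise <- if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  light <- heavy * (rows$true_fmol_per_ug * input_ug / spike_fmol) * ratio_noise
  list(
    areas = tibble::tibble(protein = rows$protein, peptide = rows$peptide,
                           spike_fmol = spike_fmol, light_area = light,
                           heavy_area = heavy, input_ug = input_ug),
    ground_truth = proteins
  )
}

#' @rdname simulate_prm_areas
#' @export
prm_reference_proteins <- function() {
  tibble::tibble(
    protein = c("TOMM20", "TOMM70", "USP30"),
    true_fmol_per_ug = c(2.0, 2.0, 0.6),
    n_peptides = c(2L, 6L, 2L)
  )
}
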