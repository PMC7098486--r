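#' Define a Ub^dGG proteoform mixture
#'
#' @param n_branches,phospho,fraction Parallel vectors defining each
#'   species and its relative molar fraction. Fractions must be
#'   non-negative and sum to 1 (within 1e-9).
#' @return A tibble with proteoform identity, neutral monoisotopic `mass`
#'   and `fraction`.
#' @export
proteoform_mixture <- function(n_branches, phospho, fraction) {
  stopifnot(length(n_branches) == length(phospho),
            length(phospho) == length(fraction))
  if (any(fraction < 0)) rlang::abort("fractions must be >= 0")
  if (abs(sum(fraction) - 1) > 1e-9) rlang::abort("fractions must sum to 1")
  out <- ub_proteoform(n_branches, phospho)
  out$fraction <- fraction
  out
}

#' Published proteoform compositions used for round-trip validation
#'
#' `ub_mixture_hela_1h()`: the HeLa + inducible-Parkin system 1 h after
#' depolarization, where 12% of Ub^dGG is phosphorylated and unbranched and
#' 1.42% / 0.05% carry one / two diGLY branches with phosphorylation.
#' `ub_mixture_ineuron_6h()`: WT-Parkin iNeurons 6 h after depolarization
#' (5.5% and 0.27% phosphorylated with zero / one branch). The non-phospho
#' complement is not reported as percentages; it is apportioned with the
#' same ~10-fold decay per added branch observed in the phospho series
#' (see the methods vignette).
#'
#' @return A proteoform mixture tibble (see [proteoform_mixture()]).
#' @export
ub_mixture_hela_1h <- function() {
  proteoform_mixture(
    n_branches = c(0, 1, 2, 3, 0, 1, 2),
    phospho    = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    fraction   = c(0.7653, 0.0900, 0.0090, 0.0010, 0.1200, 0.0142, 0.0005)
  )
}

#' @rdname ub_mixture_hela_1h
#' @export
ub_mixture_ineuron_6h <- function() {
  proteoform_mixture(
    n_branches = c(0, 1, 2, 3, 0, 1, 2),
    phospho    = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    fraction   = c(0.8482, 0.0850, 0.0080, 0.0010, 0.0550, 0.0027, 0.0001)
  )
}

#' Simulation parameters for intact-mass profile spectra
#'
#' Defaults mirror the acquisition used for Ub-clipping intact MS:
#' 625-925 m/z window, resolving power 60,000 at 200 Th (scaling as
#' 1/sqrt(m/z)), charge envelope centered at z = 12 (truncated to the
#' charge states of Ub^dGG-sized species observable inside the window,
#' never above z = 17), 5 scans across a Gaussian elution peak.
#'
#' @param mz_range Acquisition window (m/z), low < high.
#' @param resolving_power,resolving_mz Resolving power at `resolving_mz`.
#' @param charge_mean,charge_sd,charge_range Discretized-Gaussian charge
#'   envelope; `charge_range` is clipped at 17.
#' @param n_scans,elution_sd Number of chromatographic scans and Gaussian
#'   elution-peak sd in scan units.
#' @param total_abundance Total ion abundance (area units) of the mixture.
#' @param noise Additive Gaussian noise sd as a fraction of the tallest
#'   profile point (0 = noise-free).
#' @param grid_step Profile grid spacing (m/z); default = minimum peak
#'   FWHM / 6.
#' @return A list of class `ub_sim_params`.
#' @export
spectrum_sim_params <- function(mz_range = c(625, 925),
                                resolving_power = 60000,
                                resolving_mz = 200,
                                charge_mean = 12,
                                charge_sd = 1,
                                charge_range = c(10, 13),
                                n_scans = 5,
                                elution_sd = 1.2,
                                total_abundance = 1e6,
                                noise = 0.01,
                                grid_step = NULL) {
  stopifnot(mz_range[1] < mz_range[2], resolving_power > 0,
            charge_range[1] >= 1, charge_range[2] >= charge_range[1])
  charge_range[2] <- min(charge_range[2], 17L)
  if (is.null(grid_step)) {
    r_low <- resolving_power * sqrt(resolving_mz / mz_range[1])
    grid_step <- (mz_range[1] / r_low) / 6
  }
  structure(list(mz_range = mz_range, resolving_power = resolving_power,
                 resolving_mz = resolving_mz, charge_mean = charge_mean,
                 charge_sd = charge_sd, charge_range = charge_range,
                 n_scans = n_scans, elution_sd = elution_sd,
                 total_abundance = total_abundance, noise = noise,
                 grid_step = grid_step),
            class = "ub_sim_params")
}

resolving_at <- function(params, mz) {
  params$resolving_power * sqrt(params$resolving_mz / mz)
}

peak_sigma <- function(params, mz) {
  (mz / resolving_at(params, mz)) / (2 * sqrt(2 * log(2)))
}

#' Simulate profile-mode intact-mass spectra of a proteoform mixture
#'
#' Each scan is the sum, over proteoforms and charge states, of isotopic
#' clusters rendered as Gaussian profiles at the stated resolving power,
#' scaled by mixture fraction x charge-envelope weight x Gaussian elution
#' weight, plus optional additive noise. Envelopes use each proteoform's
#' exact elemental composition (the deconvolution side deliberately uses
#' averagine, keeping the round trip honest).
#'
#' @param mixture A [proteoform_mixture()] tibble.
#' @param params A [spectrum_sim_params()] object.
#' @param seed Integer seed for the noise draws.
#' @return A list with `spectra` (list of tibbles `mz`, `intensity`, one
#'   per scan, with scan index as attribute) and `ground_truth` (species
#'   table with true fractions, theoretical masses, rendered areas, charge
#'   and elution weights, plus any out-of-window warnings).
#' @export
simulate_intact_spectra <- function(mixture, params = spectrum_sim_params(),
                                    seed = 1L) {
  stopifnot(inherits(params, "ub_sim_params"))
  set.seed(seed)
  zs <- seq(params$charge_range[1], params$charge_range[2])
  wz <- stats::dnorm(zs, params$charge_mean, params$charge_sd)
  wz <- wz / sum(wz)
  scans <- seq_len(params$n_scans)
  we <- stats::dnorm(scans, (params$n_scans + 1) / 2, params$elution_sd)
  we <- we / sum(we)

  grid <- seq(params$mz_range[1], params$mz_range[2], by = params$grid_step)
  warnings <- character()

  species <- purrr::pmap(
    mixture[c("n_branches", "phospho", "fraction", "mass")],
    function(n_branches, phospho, fraction, mass) {
      if (fraction <= 0) return(NULL)
      dist <- isotope_distribution(
        ub_proteoform_composition(n_branches, phospho), n_peaks = 60L)
      dist <- dist[dist$abundance > 1e-12, ]
      dist$abundance <- dist$abundance / sum(dist$abundance)
      list(mass = mass, fraction = fraction, dist = dist)
    })
  species <- purrr::compact(species)

  render_scan <- function(scan) {
    y <- numeric(length(grid))
    for (sp in species) {
      for (iz in seq_along(zs)) {
        z <- zs[iz]
        mzs <- mz_for_charge(sp$mass + (sp$dist$mass - sp$dist$mass[1]), z)
        inside <- mzs >= params$mz_range[1] & mzs <= params$mz_range[2]
        if (!all(inside)) {
          warnings <<- union(warnings, sprintf(
            "species mass %.2f (z=%d) partially outside the m/z window",
            sp$mass, z))
        }
        areas <- params$total_abundance * sp$fraction * wz[iz] * we[scan] *
          sp$dist$abundance
        for (k in which(inside)) {
          s <- peak_sigma(params, mzs[k])
          lo <- max(1L, ceiling((mzs[k] - 6 * s - grid[1]) / params$grid_step) + 1L)
          hi <- min(length(grid),
                    floor((mzs[k] + 6 * s - grid[1]) / params$grid_step) + 1L)
          if (lo > hi) next
          idx <- lo:hi
          y[idx] <- y[idx] +
            areas[k] / (s * sqrt(2 * pi)) * exp(-(grid[idx] - mzs[k])^2 / (2 * s^2))
        }
      }
    }
    y
  }

  clean <- purrr::map(scans, render_scan)
  peak_max <- max(purrr::map_dbl(clean, max), 0)
  spectra <- purrr::map2(clean, scans, function(y, scan) {
    if (params$noise > 0 && peak_max > 0) {
      y <- pmax(y + stats::rnorm(length(y), 0, params$noise * peak_max), 0)
    }
    out <- tibble::tibble(mz = grid, intensity = y)
    attr(out, "scan") <- scan
    attr(out, "params") <- params
    out
  })

  truth <- mixture
  truth$rendered_area <- params$total_abundance * truth$fraction
  list(spectra = spectra,
       ground_truth = list(species = truth, charge_states = zs,
                           charge_weights = wz, elution_weights = we,
                           seed = seed, warnings = warnings))
}

#' Write simulated spectra as plain two-column peak lists
#'
#' One TSV per scan (`scan_001.tsv`, ...), columns `mz` and `intensity`.
#'
#' @param spectra List of spectrum tibbles from [simulate_intact_spectra()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_peaklists <- function(spectra, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(spectra, function(sp, i) {
    path <- file.path(dir, sprintf("scan_%03d.tsv", i))
    readr::write_tsv(sp, path)
    path
  })
  invisible(paths)
}

#' Read plain two-column peak lists back as spectra
#'
#' @param paths TSV files with columns `mz` and `intensity`.
#' @return A list of spectrum tibbles ordered as given.
#' @export
read_peaklists <- function(paths) {
  purrr::imap(paths, function(p, i) {
    out <- readr::read_tsv(p, show_col_types = FALSE)
    stopifnot(all(c("mz", "intensity") %in% names(out)))
    attr(out, "scan") <- i
    out
  })
}
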