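#' Deconvolution parameters
#'
#' Defaults follow the vendor settings used for Ub-clipping intact MS:
#' S/N threshold 3, fit factor 80%, remainder 25%, sulfur-free averagine,
#' max charge 17, neutral-mass search range 189-2000 Da (override to
#' c(8000, 9200) for Ub^dGG work), 0.5 Da proteoform assignment tolerance.
#'
#' @param sn_threshold Peak-picking S/N threshold (x noise floor).
#' @param fit_factor Minimum normalized dot product between observed and
#'   theoretical isotopologue vectors to accept a cluster (0, 1].
#' @param remainder Residual fraction of a centroid's original intensity
#'   above which it is re-queued after cluster subtraction, [0, 1).
#' @param sulfur_free Use sulfur-free averagine? Default `TRUE`.
#' @param max_charge Highest charge state considered.
#' @param mass_range Neutral monoisotopic mass search range (Da).
#' @param tolerance Mass tolerance for proteoform assignment and
#'   cross-scan XIC matching (Da); the vendor "500 mmu" setting.
#' @param merge_tol Neutral-mass tolerance for merging one species across
#'   charge states within a scan (Da).
#' @return A list of class `ub_deconv_params`.
#' @export
deconv_params <- function(sn_threshold = 3, fit_factor = 0.80,
                          remainder = 0.25, sulfur_free = TRUE,
                          max_charge = 17, mass_range = c(189, 2000),
                          tolerance = 0.5, merge_tol = 0.25) {
  stopifnot(fit_factor > 0, fit_factor <= 1, remainder >= 0, remainder < 1,
            tolerance > 0, max_charge >= 1, mass_range[1] < mass_range[2])
  structure(list(sn_threshold = sn_threshold, fit_factor = fit_factor,
                 remainder = remainder, sulfur_free = sulfur_free,
                 max_charge = as.integer(max_charge),
                 mass_range = mass_range, tolerance = tolerance,
                 merge_tol = merge_tol),
            class = "ub_deconv_params")
}

#' Pick centroids from a profile spectrum
#'
#' Local maxima with intensity at least `sn_threshold` times the noise
#' floor (median absolute deviation of the intensity trace, with a small
#' relative floor so noise-free spectra are handled). Apex m/z is refined
#' by a log-parabola through the three points around the maximum (exact
#' for Gaussian profiles); centroid area is the trapezoidal integral
#' between the bracketing local minima.
#'
#' @param spectrum Tibble with `mz` (strictly increasing) and `intensity`
#'   (>= 0) columns.
#' @param sn_threshold S/N threshold; default 3.
#' @return A tibble with `mz`, `height`, `area`, ordered by m/z. Empty
#'   for empty or featureless spectra.
#' @export
pick_peaks <- function(spectrum, sn_threshold = 3) {
  mz <- spectrum$mz
  y <- spectrum$intensity
  stopifnot(length(mz) == length(y))
  empty <- tibble::tibble(mz = numeric(), height = numeric(), area = numeric())
  if (length(y) < 3 || max(y) <= 0) return(empty)
  noise_floor <- max(stats::mad(y), 1e-9 * max(y))
  thr <- sn_threshold * noise_floor
  core <- 2:(length(y) - 1)
  is_max <- y[core] > y[core - 1] & y[core] >= y[core + 1] & y[core] >= thr
  apex <- core[is_max]
  if (!length(apex)) return(empty)
  ## bracketing minima (incl. endpoints) delimit each peak's support
  is_min <- c(TRUE, y[core] <= y[core - 1] & y[core] < y[core + 1], TRUE)
  mins <- which(is_min)
  left <- mins[findInterval(apex - 1L, mins)]
  right <- mins[findInterval(apex, mins) + 1L]
  right[is.na(right)] <- length(y)

  step <- mz[2] - mz[1]
  refine <- function(i) {
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    if (y1 <= 0 || y3 <= 0) return(mz[i])
    l1 <- log(y1); l2 <- log(y2); l3 <- log(y3)
    den <- l1 - 2 * l2 + l3
    if (den >= 0) return(mz[i])
    mz[i] + 0.5 * (l1 - l3) / den * step
  }
  area_of <- function(l, r) {
    idx <- l:r
    sum((y[idx[-1]] + y[idx[-length(idx)]]) / 2 * diff(mz[idx]))
  }
  tibble::tibble(
    mz = vapply(apex, refine, 0),
    height = y[apex],
    area = purrr::map2_dbl(left, right, area_of)
  )
}

## averagine isotope envelope cached by rounded mass (shape varies slowly
## with mass, so 1 Da granularity is ample)
averagine_cache <- new.env(parent = emptyenv())

averagine_envelope <- function(mass, sulfur_free = TRUE) {
  key <- sprintf("%d_%d", round(mass), sulfur_free)
  hit <- averagine_cache[[key]]
  if (!is.null(hit)) return(hit)
  dist <- isotope_distribution(
    averagine_composition(round(mass), sulfur_free), n_peaks = 60L)
  dist <- dist[dist$abundance > 1e-5, ]
  dist$abundance <- dist$abundance / sum(dist$abundance)
  out <- list(offset = dist$mass - dist$mass[1], abundance = dist$abundance)
  averagine_cache[[key]] <- out
  out
}

#' Deisotope and charge-deconvolve a centroid list
#'
#' Greedy highest-intensity-first clustering. For each seed centroid,
#' every candidate charge z <= max charge and every plausible isotopologue
#' index of the seed within the envelope are scored by the normalized dot
#' product between observed centroid areas (gathered at the predicted
#' isotopologue positions) and the sulfur-free averagine envelope at the
#' implied neutral mass. The best-scoring hypothesis is accepted when the
#' fit reaches `fit_factor`; the fitted cluster is subtracted, and member
#' centroids retaining more than `remainder` of their original area are
#' re-queued. Species are then merged across charge states (descending
#' summed intensity, ties to lower charge) when neutral masses agree
#' within `merge_tol`. The reported mass is the monoisotopic neutral mass
#' (abundance-weighted over matched isotopologues).
#'
#' @param centroids Tibble from [pick_peaks()].
#' @param params A [deconv_params()] object.
#' @return A tibble with `mass`, `area`, `charges` (comma-separated),
#'   `n_peaks`; attribute `unassigned_area` carries the summed area of
#'   centroids no hypothesis explained.
#' @export
deisotope <- function(centroids, params = deconv_params()) {
  out_empty <- tibble::tibble(mass = numeric(), area = numeric(),
                              charges = character(), n_peaks = integer())
  attr(out_empty, "unassigned_area") <- 0
  if (!nrow(centroids)) return(out_empty)

  mzv <- centroids$mz
  area <- centroids$area
  orig <- centroids$area
  active <- rep(TRUE, length(mzv))
  tried <- rep(FALSE, length(mzv))
  hits <- list()

  spacing <- isotopologue_spacing()
  while (any(active & !tried & area > 0)) {
    seed <- which(active & !tried)[which.max(area[active & !tried])]
    best <- NULL
    for (z in seq_len(params$max_charge)) {
      base_mass <- neutral_mass(mzv[seed], z)
      env0 <- averagine_envelope(base_mass, params$sulfur_free)
      j_max <- length(env0$offset) - 1L
      match_tol <- min(0.02, 0.3 * spacing / z)
      for (j in 0:j_max) {
        mono <- base_mass - j * spacing
        if (mono < params$mass_range[1] || mono > params$mass_range[2]) next
        env <- averagine_envelope(mono, params$sulfur_free)
        pred <- mz_for_charge(mono + env$offset, z)
        idx <- vapply(pred, function(p) {
          cand <- which(active & abs(mzv - p) <= match_tol)
          if (!length(cand)) return(NA_integer_)
          cand[which.min(abs(mzv[cand] - p))]
        }, 1L)
        if (!(seed %in% idx)) next
        obs <- ifelse(is.na(idx), 0, area[ifelse(is.na(idx), 1L, idx)])
        n_matched <- sum(!is.na(idx) & obs > 0)
        if (n_matched < 2) next
        fit <- sum(obs * env$abundance) /
          sqrt(sum(obs^2) * sum(env$abundance^2))
        if (is.null(best) || fit > best$fit) {
          best <- list(fit = fit, z = z, mono = mono, env = env,
                       idx = idx, obs = obs)
        }
      }
    }
    if (is.null(best) || best$fit < params$fit_factor) {
      tried[seed] <- TRUE
      next
    }
    alpha <- sum(best$obs * best$env$abundance) / sum(best$env$abundance^2)
    matched <- !is.na(best$idx) & best$obs > 0
    ii <- best$idx[matched]
    w <- best$obs[matched]
    mono_est <- sum(w * (neutral_mass(mzv[ii], best$z) -
                           best$env$offset[matched])) / sum(w)
    fitted <- alpha * best$env$abundance
    ## cluster area: observed areas where peaks matched (exact trapezoids)
    ## plus the fitted envelope tail for unmatched positions, so totals
    ## are conserved despite averagine/true envelope shape mismatch
    consumed_area <- sum(pmin(fitted[matched], area[ii]))
    cluster_area <- consumed_area + alpha * sum(best$env$abundance[!matched])
    area[ii] <- area[ii] - pmin(fitted[matched], area[ii])
    consumed <- area[ii] <= params$remainder * orig[ii]
    active[ii[consumed]] <- FALSE
    cluster_area <- cluster_area + sum(area[ii][consumed])
    area[ii[consumed]] <- 0
    tried[ii[!consumed]] <- FALSE  # re-queue residuals
    hits[[length(hits) + 1]] <- tibble::tibble(
      mass = mono_est, z = best$z,
      area = cluster_area, n_peaks = sum(matched))
  }
  unassigned <- sum(area[active])
  if (!length(hits)) {
    attr(out_empty, "unassigned_area") <- unassigned
    return(out_empty)
  }
  sp <- dplyr::arrange(dplyr::bind_rows(hits),
                       dplyr::desc(.data$area), .data$z)
  groups <- list()
  for (i in seq_len(nrow(sp))) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (abs(sp$mass[i] - groups[[g]]$mass) <= params$merge_tol) {
        gr <- groups[[g]]
        tot <- gr$area + sp$area[i]
        gr$mass <- (gr$mass * gr$area + sp$mass[i] * sp$area[i]) / tot
        gr$area <- tot
        gr$charges <- union(gr$charges, sp$z[i])
        gr$n_peaks <- gr$n_peaks + sp$n_peaks[i]
        groups[[g]] <- gr
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- list(mass = sp$mass[i],
                                           area = sp$area[i],
                                           charges = sp$z[i],
                                           n_peaks = sp$n_peaks[i])
    }
  }
  out <- tibble::tibble(
    mass = purrr::map_dbl(groups, "mass"),
    area = purrr::map_dbl(groups, "area"),
    charges = purrr::map_chr(groups, ~ paste(sort(.x$charges), collapse = ",")),
    n_peaks = purrr::map_int(groups, ~ as.integer(.x$n_peaks))
  )
  out <- dplyr::arrange(out, .data$mass)
  attr(out, "unassigned_area") <- unassigned
  out
}

#' Integrate species across scans (extracted-ion-chromatogram area)
#'
#' Matches deconvolved species across scans within the mass tolerance and
#' sums per-scan areas into one chromatographic area per species. A
#' species may be absent from intermediate scans and still forms a single
#' merged entry.
#'
#' @param species_by_scan List (one element per scan) of [deisotope()]
#'   outputs.
#' @param params A [deconv_params()] object; `tolerance` is the
#'   cross-scan matching tolerance.
#' @return A tibble with `mass` (area-weighted), `area` (summed),
#'   `n_scans`; attribute `unassigned_area` sums across scans.
#' @export
integrate_xic <- function(species_by_scan, params = deconv_params()) {
  stopifnot(length(species_by_scan) >= 1)
  unassigned <- sum(purrr::map_dbl(
    species_by_scan, ~ attr(.x, "unassigned_area") %||% 0))
  all_sp <- dplyr::bind_rows(
    purrr::imap(species_by_scan, ~ dplyr::mutate(.x, scan = .y)))
  if (!nrow(all_sp)) {
    out <- tibble::tibble(mass = numeric(), area = numeric(),
                          n_scans = integer())
    attr(out, "unassigned_area") <- unassigned
    return(out)
  }
  all_sp <- dplyr::arrange(all_sp, dplyr::desc(.data$area))
  groups <- list()
  for (i in seq_len(nrow(all_sp))) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (abs(all_sp$mass[i] - groups[[g]]$mass) <= params$tolerance) {
        gr <- groups[[g]]
        tot <- gr$area + all_sp$area[i]
        gr$mass <- (gr$mass * gr$area + all_sp$mass[i] * all_sp$area[i]) / tot
        gr$area <- tot
        gr$scans <- union(gr$scans, all_sp$scan[i])
        groups[[g]] <- gr
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1]] <- list(mass = all_sp$mass[i],
                                           area = all_sp$area[i],
                                           scans = all_sp$scan[i])
    }
  }
  out <- tibble::tibble(
    mass = purrr::map_dbl(groups, "mass"),
    area = purrr::map_dbl(groups, "area"),
    n_scans = purrr::map_int(groups, ~ length(.x$scans))
  )
  out <- dplyr::arrange(out, .data$mass)
  attr(out, "unassigned_area") <- unassigned
  out
}

#' Assign deconvolved species to candidate proteoforms and quantify
#'
#' Each species is assigned to the nearest candidate within `tolerance`
#' (candidate masses must be pairwise separated by more than twice the
#' tolerance, so ties cannot occur); fractions are assigned areas over
#' total deconvolved + unassigned area, so assigned plus unassigned
#' fractions sum to 1.
#'
#' @param species Tibble from [integrate_xic()] (or [deisotope()]).
#' @param candidates Candidate proteoforms with a `mass` column; default
#'   [ub_proteoform_candidates()].
#' @param tolerance Assignment tolerance in Da (default 0.5).
#' @return The candidate tibble with `area` and `fraction` columns;
#'   attribute `unassigned_fraction`.
#' @export
quantify_proteoforms <- function(species,
                                 candidates = ub_proteoform_candidates(),
                                 tolerance = 0.5) {
  stopifnot(tolerance > 0, nrow(candidates) >= 1)
  if (nrow(candidates) > 1) {
    sep <- min(diff(sort(candidates$mass)))
    if (sep <= 2 * tolerance) {
      rlang::abort("candidate masses overlap: pairwise separation must exceed twice the tolerance")
    }
  }
  areas <- numeric(nrow(candidates))
  unassigned <- attr(species, "unassigned_area") %||% 0
  for (i in seq_len(nrow(species))) {
    d <- abs(candidates$mass - species$mass[i])
    j <- which.min(d)
    if (d[j] <= tolerance) {
      areas[j] <- areas[j] + species$area[i]
    } else {
      unassigned <- unassigned + species$area[i]
    }
  }
  total <- sum(areas) + unassigned
  out <- candidates
  out$area <- areas
  out$fraction <- if (total > 0) areas / total else 0 * areas
  attr(out, "unassigned_fraction") <- if (total > 0) unassigned / total else 0
  out
}

#' Full intact-mass quantification of Ub^dGG proteoforms
#'
#' Runs peak picking, deisotoping and XIC integration on a set of profile
#' scans, then targeted assignment against the eight Ub^dGG candidates.
#' The neutral-mass search range is widened to cover Ub^dGG species.
#'
#' @param spectra List of profile-spectrum tibbles.
#' @param params A [deconv_params()]; the default here overrides the
#'   vendor 189-2000 Da range with c(8000, 9200).
#' @param candidates Candidate proteoform tibble.
#' @return As [quantify_proteoforms()], plus a `percent` column.
#' @export
quantify_ub_proteoforms <- function(spectra,
                                    params = deconv_params(mass_range = c(8000, 9200)),
                                    candidates = ub_proteoform_candidates()) {
  per_scan <- purrr::map(spectra, function(sp) {
    deisotope(pick_peaks(sp, params$sn_threshold), params)
  })
  xic <- integrate_xic(per_scan, params)
  out <- quantify_proteoforms(xic, candidates, params$tolerance)
  out$percent <- 100 * out$fraction
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
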