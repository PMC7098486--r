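#' TMT reporter-ion reference masses
#'
#' @param plex 10 or 11.
#' @return Tibble with `channel` and `reporter_mz` for the requested plex.
#' @export
tmt_reporter_table <- function(plex = 11) {
  stopifnot(plex %in% c(10, 11))
  path <- system.file("extdata", "tmt_reporter_ions.tsv",
                      package = "ubiquant", mustWork = TRUE)
  tbl <- readr::read_tsv(path, col_types = "cdc")
  tbl <- tbl[purrr::map_lgl(strsplit(tbl$plex, ","),
                            ~ as.character(plex) %in% .x), ]
  tbl[c("channel", "reporter_mz")]
}

#' Match MS3 centroids to TMT reporter reference masses
#'
#' For each channel, the closest centroid within the integration tolerance
#' (0.003 Da) supplies the S/N value; channels with no centroid inside the
#' tolerance get 0.
#'
#' @param peaks Tibble with `mz` and `sn` columns (one MS3 peak list).
#' @param reference Tibble of reference masses (see [tmt_reporter_table()]).
#' @param tolerance Integration tolerance in Da.
#' @return Tibble with `channel` and `sn`.
#' @export
match_reporter_centroids <- function(peaks, reference = tmt_reporter_table(11),
                                     tolerance = 0.003) {
  sn <- purrr::map_dbl(reference$reporter_mz, function(m) {
    if (!nrow(peaks)) return(0)
    d <- abs(peaks$mz - m)
    i <- which.min(d)
    if (d[i] <= tolerance) peaks$sn[i] else 0
  })
  tibble::tibble(channel = reference$channel, sn = sn)
}

#' Filter PSMs on the standard quantification quality rules
#'
#' Retains PSMs with isolation specificity >= 0.7 AND summed reporter
#' S/N >= 150 AND an MS3 spectrum (the exclusions are stated as "less
#' than", so the boundaries are retained). The per-rule exclusion counts
#' (non-exclusive: a PSM may violate several rules) are attached as the
#' `"audit"` attribute.
#'
#' @param psms PSM tibble with `isolation_specificity`, `summed_sn`,
#'   `has_ms3` columns.
#' @param min_isolation,min_sn Retention thresholds.
#' @return The retained rows, with an `audit` attribute tibble
#'   (`rule`, `n_excluded`) including an `"any"` row and `n_retained`.
#' @export
filter_psms <- function(psms, min_isolation = 0.7, min_sn = 150) {
  bad_iso <- psms$isolation_specificity < min_isolation
  bad_sn <- psms$summed_sn < min_sn
  bad_ms3 <- !psms$has_ms3
  keep <- !(bad_iso | bad_sn | bad_ms3)
  out <- psms[keep, ]
  attr(out, "audit") <- tibble::tibble(
    rule = c("isolation_specificity", "summed_sn", "no_ms3", "any"),
    n_excluded = c(sum(bad_iso), sum(bad_sn), sum(bad_ms3), sum(!keep)),
    n_retained = sum(keep)
  )
  out
}

#' Roll PSMs up to protein- or site-level quantification matrices
#'
#' Features are quantified by summing reporter S/N across all matching
#' PSMs. Site-level keys are (protein, site, modification type) so diGLY
#' and phospho layers never merge, and only localized PSMs (AScore >= 13,
#' i.e. 95% localization confidence) contribute to site rows.
#'
#' PSMs whose peptide maps to several proteins (a `;`-separated `protein`
#' field) are resolved by a simple parsimony rule before aggregation: the
#' protein with the most uniquely assigned PSMs in the table wins, ties
#' broken alphabetically.
#'
#' @param psms Filtered PSM tibble.
#' @param level `"protein"` or `"site"`.
#' @param channels Channel column names; defaults to the TMT channel
#'   labels present in `psms`.
#' @param min_ascore Localization threshold for site-level rollup.
#' @return A wide tibble (feature key columns then channel columns) with
#'   attribute `channels`.
#' @export
rollup <- function(psms, level = c("protein", "site"), channels = NULL,
                   min_ascore = 13) {
  level <- match.arg(level)
  channels <- channels %||% intersect(tmt_channel_names(), names(psms))
  if (!length(channels)) rlang::abort("no channel columns found")
  shared <- grepl(";", psms$protein)
  if (any(shared)) {
    counts <- table(psms$protein[!shared])
    psms$protein[shared] <- vapply(strsplit(psms$protein[shared], ";"),
                                   function(cands) {
      cands <- sort(cands)
      n <- vapply(cands, function(p) {
        if (p %in% names(counts)) counts[[p]] else 0L
      }, 0L)
      cands[which.max(n)]
    }, "")
  }
  keys <- if (level == "protein") "protein" else c("protein", "site", "mod_type")
  if (level == "site") {
    psms <- psms[!is.na(psms$ascore) & psms$ascore >= min_ascore, ]
  }
  out <- psms |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(channels),
                                   ~ sum(.x, na.rm = TRUE)),
                     n_psms = dplyr::n(), .groups = "drop")
  structure(out, channels = channels, layer = level)
}

tmt_channel_names <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N",
    "129C", "130N", "130C", "131N", "131C")
}

quant_channels <- function(mat, channels = NULL) {
  channels %||% attr(mat, "channels") %||%
    intersect(tmt_channel_names(), names(mat))
}

#' Equal-loading normalization of a quantification matrix
#'
#' Each reporter channel is summed across all quantified features and
#' scaled so every column sum equals the mean original column sum
#' (equal protein loading of all samples). Missing values are excluded
#' from the sums.
#'
#' @param mat Wide quantification tibble (see [rollup()]).
#' @param channels Channel column names.
#' @return The matrix with scaled channel columns (attribute
#'   `normalization = "equal_loading"`).
#' @export
normalize_equal_loading <- function(mat, channels = NULL) {
  channels <- quant_channels(mat, channels)
  stopifnot(nrow(mat) >= 1)
  sums <- purrr::map_dbl(mat[channels], ~ sum(.x, na.rm = TRUE))
  if (any(sums == 0)) rlang::abort("channel with zero total signal")
  scale <- mean(sums) / sums
  mat[channels] <- purrr::map2(mat[channels], scale, `*`)
  structure(mat, channels = channels, normalization = "equal_loading")
}

#' Normalize site abundances against total protein abundance
#'
#' Each site row is divided channel-wise by its protein's relative
#' abundance profile (protein channel values over their mean) when the
#' protein is quantified in the protein matrix; sites whose protein is
#' absent pass through unchanged and are flagged `normalized = FALSE`.
#' Channels where the protein value is 0 become `NA`.
#'
#' @param site_mat,protein_mat Column-aligned wide tibbles.
#' @param channels Channel column names.
#' @return `site_mat` with adjusted channel values and a `normalized`
#'   flag column.
#' @export
normalize_site_to_protein <- function(site_mat, protein_mat, channels = NULL) {
  channels <- quant_channels(site_mat, channels)
  stopifnot(all(channels %in% names(protein_mat)))
  pmat <- as.matrix(protein_mat[channels])
  rownames(pmat) <- protein_mat$protein
  smat <- as.matrix(site_mat[channels])
  idx <- match(site_mat$protein, protein_mat$protein)
  normalized <- !is.na(idx)
  for (i in which(normalized)) {
    prof <- pmat[idx[i], ]
    prof[prof == 0] <- NA
    smat[i, ] <- smat[i, ] / (prof / mean(prof, na.rm = TRUE))
  }
  out <- site_mat
  out[channels] <- tibble::as_tibble(as.data.frame(smat))
  out$normalized <- normalized
  structure(out, channels = channels,
            normalization = "site_to_protein")
}

#' Express channels relative to the untreated mean, per genotype
#'
#' Each channel value is divided by the feature's mean over the untreated
#' channels of the same genotype (time courses are normalized to
#' untreated separately for each genotype).
#'
#' @param mat Wide quantification tibble.
#' @param design Plex design with `channel`, `genotype`, `treatment`.
#' @param channels Channel column names.
#' @return The matrix of ratios (untreated channels average to 1).
#' @export
relative_to_untreated <- function(mat, design, channels = NULL) {
  channels <- quant_channels(mat, channels)
  stopifnot(all(channels %in% design$channel))
  d <- design[match(channels, design$channel), ]
  vals <- as.matrix(mat[channels])
  out_vals <- vals
  for (g in unique(d$genotype)) {
    gcols <- which(d$genotype == g)
    ut <- which(d$genotype == g & d$treatment == "UT")
    if (!length(ut)) {
      rlang::abort(sprintf("genotype '%s' has no untreated channels", g))
    }
    ref <- rowMeans(vals[, ut, drop = FALSE], na.rm = TRUE)
    out_vals[, gcols] <- vals[, gcols, drop = FALSE] / ref
  }
  out <- mat
  out[channels] <- tibble::as_tibble(as.data.frame(out_vals))
  structure(out, channels = channels, normalization = "relative_to_untreated")
}
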