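#' Configuration for an end-to-end pipeline run
#'
#' @param stages Character subset of `c("intact", "tmt", "flux", "prm")`.
#' @param out_dir Output directory for intermediate tables (TSV) and
#'   ground truth (JSON); `NULL` writes nothing.
#' @param seed Global seed; recorded in the report and used to derive
#'   per-stage seeds.
#' @param intact_mixture,intact_sim,deconv Proteoform mixture and
#'   parameters for the intact-mass stage.
#' @param tmt_design,tmt_effects,tmt_n_features,tmt_stats TMT stage
#'   configuration; the stats contrast compares depolarized 6 h against
#'   untreated within the `tmt_genotype` genotype.
#' @param tmt_genotype Genotype used for the differential contrast.
#' @param flux_conditions,prm_proteins Flux and PRM stage configuration.
#' @return A list of class `ub_run_config`.
#' @export
run_config <- function(stages = c("intact", "tmt", "flux", "prm"),
                       out_dir = NULL, seed = 1L,
                       intact_mixture = ub_mixture_hela_1h(),
                       intact_sim = spectrum_sim_params(noise = 0),
                       deconv = deconv_params(mass_range = c(8000, 9200)),
                       tmt_design = tmt_design_11(),
                       tmt_effects = effect_model(),
                       tmt_n_features = 2400,
                       tmt_stats = stats_params(s0 = 1, fdr_level = 0.01),
                       tmt_genotype = "WT",
                       flux_conditions = flux_trajectory_wt(),
                       prm_proteins = prm_reference_proteins()) {
  stages <- match.arg(stages, c("intact", "tmt", "flux", "prm"),
                      several.ok = TRUE)
  structure(as.list(environment()), class = "ub_run_config")
}

stage_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 101L) %% 2147483647L

#' Run the simulate -> quantify -> test pipeline
#'
#' Executes the selected stages in dependency order, writing intermediate
#' tables when an output directory is configured. Identical (config,
#' seed) pairs give identical outputs. A stage failure halts the run
#' with an error naming the stage.
#'
#' @param config A [run_config()].
#' @return A list of class `ub_run_report`: per-stage summaries, the
#'   seed, and a config hash.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "ub_run_config"))
  out <- list()
  dir <- config$out_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(tbl, name) {
    if (!is.null(dir)) readr::write_tsv(tbl, file.path(dir, paste0(name, ".tsv")))
    tbl
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  if ("intact" %in% config$stages) {
    out$intact <- run_stage("intact", function() {
      sim <- simulate_intact_spectra(config$intact_mixture,
                                     config$intact_sim,
                                     seed = stage_seed(config$seed, 1L))
      if (!is.null(dir)) write_peaklists(sim$spectra, file.path(dir, "spectra"))
      quant <- quantify_ub_proteoforms(sim$spectra, config$deconv)
      emit(quant, "proteoform_fractions")
      truth <- config$intact_mixture
      list(quant = quant, truth = truth,
           unassigned_fraction = attr(quant, "unassigned_fraction"),
           warnings = sim$ground_truth$warnings)
    })
  }
  if ("tmt" %in% config$stages) {
    out$tmt <- run_stage("tmt", function() {
      sim <- simulate_tmt_experiment(config$tmt_design, config$tmt_effects,
                                     config$tmt_n_features,
                                     seed = stage_seed(config$seed, 2L))
      emit(sim$psms, "psms")
      kept <- filter_psms(sim$psms)
      ## equal loading is estimated on the proteome layer (planted diGLY
      ## effects would bias the site matrix's own column sums); sites are
      ## then normalized against protein relative profiles
      prot <- normalize_equal_loading(
        rollup(kept[kept$layer == "proteome", ], "protein"))
      site <- rollup(kept[kept$layer == "diGLY", ], "site")
      site_n <- normalize_site_to_protein(site, prot)
      emit(site_n, "digly_sites_normalized")
      d <- config$tmt_design
      groups <- ifelse(d$genotype == config$tmt_genotype &
                         d$treatment != "UT" & d$timepoint_h >= 6, "AO6",
                       ifelse(d$genotype == config$tmt_genotype &
                                d$treatment == "UT", "UT", NA))
      fit <- diff_expression(site_n, groups, config$tmt_stats)
      emit(tidy(fit), "digly_diff")
      list(fit = fit, audit = attr(kept, "audit"),
           truth = sim$ground_truth$features)
    })
  }
  if ("flux" %in% config$stages) {
    out$flux <- run_stage("flux", function() {
      sim <- simulate_flux_blots(config$flux_conditions,
                                 seed = stage_seed(config$seed, 3L))
      ratios <- keima_ratio(sim$bands)
      emit(ratios, "keima_ratios")
      list(ratios = ratios, truth = sim$ground_truth)
    })
  }
  if ("prm" %in% config$stages) {
    out$prm <- run_stage("prm", function() {
      sim <- simulate_prm_areas(config$prm_proteins,
                                seed = stage_seed(config$seed, 4L))
      emit(sim$areas, "prm_areas")
      ab <- prm_abundance(sim$areas)
      emit(ab, "prm_abundance")
      stoich <- prm_stoichiometry(ab, "USP30", c("TOMM20", "TOMM70"))
      emit(stoich, "prm_stoichiometry")
      list(abundance = ab, stoichiometry = stoich, truth = sim$ground_truth)
    })
  }
  report <- list(stages = out, seed = config$seed,
                 config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]))
  class(report) <- "ub_run_report"
  if (!is.null(dir)) {
    jsonlite::write_json(list(seed = config$seed,
                              config_hash = report$config_hash,
                              stages = names(out)),
                         file.path(dir, "run_report.json"),
                         auto_unbox = TRUE)
  }
  report
}

#' Check a pipeline report against a table of acceptance targets
#'
#' @param report A `ub_run_report`.
#' @param targets Tibble (or TSV path) with columns `id`, `value_fn`
#'   (name of a quantity understood by [report_value()]), `expected`,
#'   `tolerance`.
#' @return Tibble with `id`, `computed`, `expected`, `tolerance`, `pass`;
#'   attribute `all_pass`. An empty target table passes trivially.
#' @export
check_acceptance <- function(report, targets) {
  if (is.character(targets)) {
    targets <- readr::read_tsv(targets, show_col_types = FALSE)
  }
  if (!nrow(targets)) {
    out <- tibble::tibble(id = character(), computed = numeric(),
                          expected = numeric(), tolerance = numeric(),
                          pass = logical())
    attr(out, "all_pass") <- TRUE
    return(out)
  }
  computed <- purrr::map_dbl(targets$value_fn, report_value, report = report)
  out <- tibble::tibble(id = targets$id, computed = computed,
                        expected = targets$expected,
                        tolerance = targets$tolerance,
                        pass = abs(computed - targets$expected) <=
                          targets$tolerance)
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Extract a named quantity from a pipeline report
#'
#' Supported quantities: `"percent_<proteoform>"` (recovered percentage,
#' e.g. `"percent_0xGG+pS65"`), `"tmt_recovery"`, `"tmt_fdp"`,
#' `"stoichiometry_<A>_<B>"`, `"keima_ratio_<t>h"` (mean at time t).
#'
#' @param report A `ub_run_report`.
#' @param what Quantity name.
#' @return A single numeric value.
#' @export
report_value <- function(report, what) {
  if (grepl("^percent_", what)) {
    q <- report$stages$intact$quant
    i <- match(sub("^percent_", "", what), q$proteoform)
    if (is.na(i)) rlang::abort(sprintf("unknown proteoform in '%s'", what))
    return(q$percent[i])
  }
  if (what %in% c("tmt_recovery", "tmt_fdp")) {
    fit <- tidy(report$stages$tmt$fit)
    truth <- report$stages$tmt$truth
    called <- fit[fit$significant & !is.na(fit$log2_ratio) &
                    fit$log2_ratio > 0, ]
    key <- paste(called$protein, called$site)
    planted <- truth[truth$planted, ]
    hits <- sum(paste(planted$protein, planted$site) %in% key)
    if (what == "tmt_recovery") return(hits / nrow(planted))
    if (!nrow(called)) return(0)
    return(1 - sum(key %in% paste(planted$protein, planted$site)) / nrow(called))
  }
  if (grepl("^stoichiometry_", what)) {
    parts <- strsplit(sub("^stoichiometry_", "", what), "_")[[1]]
    st <- report$stages$prm$stoichiometry
    i <- which(st$numerator == parts[1] & st$denominator == parts[2])
    if (!length(i)) rlang::abort(sprintf("no stoichiometry for '%s'", what))
    return(st$ratio[i])
  }
  if (grepl("^keima_ratio_", what)) {
    t <- as.numeric(sub("h$", "", sub("^keima_ratio_", "", what)))
    r <- report$stages$flux$ratios
    return(mean(r$keima_ratio[r$timepoint_h == t]))
  }
  rlang::abort(sprintf("unknown report quantity '%s'", what))
}
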