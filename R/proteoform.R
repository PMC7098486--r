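## Residue elemental compositions (residue = amino acid minus water).
RESIDUE_COMPOSITION <- list(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Read protein sequences from a FASTA file
#'
#' Thin reader for uncompressed amino-acid FASTA returning a tidy tibble.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` (full header line, `>` stripped)
#'   and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) rlang::abort("no FASTA headers found")
  grp <- cumsum(hdr)
  tibble::tibble(
    name = sub("^>", "", lines[hdr]),
    sequence = vapply(split(lines[!hdr], grp[!hdr]),
                      function(x) paste(toupper(x), collapse = ""), "")
  )
}

#' The bundled human ubiquitin sequence
#'
#' `ub_sequence()` returns the 76-residue human Ub monomer (UniProt P0CG48
#' numbering, 1-based); `ub_dgg_sequence()` the clipped form left by
#' LbPro*-type proteases that cut after R74, removing the C-terminal
#' Gly-Gly (residues 1-74).
#'
#' @return A single character string.
#' @export
ub_sequence <- function() {
  path <- system.file("extdata", "ubiquitin_P0CG48.fasta",
                      package = "ubiquant", mustWork = TRUE)
  read_fasta(path)$sequence[[1]]
}

#' @rdname ub_sequence
#' @export
ub_dgg_sequence <- function() substr(ub_sequence(), 1, 74)

#' Elemental composition of an unmodified peptide
#'
#' Sums residue compositions and adds one water for the termini.
#'
#' @param sequence One-letter amino-acid string.
#' @return A `ub_composition`.
#' @export
peptide_composition <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, names(RESIDUE_COMPOSITION))
  if (length(unknown)) {
    rlang::abort(sprintf("unknown residue(s): %s",
                         paste(unique(unknown), collapse = ", ")))
  }
  tab <- table(factor(aa, levels = names(RESIDUE_COMPOSITION)))
  args <- c(purrr::map(names(tab)[tab > 0], ~ RESIDUE_COMPOSITION[[.x]]),
            list("H2O"))
  do.call(composition_sum,
          c(args, list(times = c(as.integer(tab[tab > 0]), 1L))))
}

#' The bundled post-translational modification table
#'
#' Deltas are stored at full precision (monoisotopic); the `printed_delta`
#' column carries the conventional rounded values used in reports. When a
#' modification has an elemental composition its monoisotopic mass agrees
#' with `delta_da` to better than 0.001 Da (checked on load).
#'
#' @return A tibble with columns `name`, `delta_da`, `composition`,
#'   `residues`, `printed_delta`.
#' @export
modification_table <- function() {
  path <- system.file("extdata", "modifications.tsv",
                      package = "ubiquant", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  ok <- purrr::map2_lgl(tbl$composition, tbl$delta_da, function(f, d) {
    if (is.na(f) || f == "") return(TRUE)
    abs(monoisotopic_mass(f) - d) < 0.001
  })
  if (!all(ok)) rlang::abort("modification composition/delta mismatch")
  tbl
}

modification_delta <- function(name) {
  tbl <- modification_table()
  i <- match(name, tbl$name)
  if (is.na(i)) rlang::abort(sprintf("unknown modification '%s'", name))
  tbl$delta_da[i]
}

#' Construct Ub^dGG proteoforms
#'
#' A Ub^dGG proteoform is the clipped ubiquitin monomer (residues 1-74)
#' carrying `n_branches` diGLY remnants (0-3, on the seven Ub lysines) and
#' optionally phosphorylation of S65. Its neutral monoisotopic mass is
#' mass(Ub^dGG) + n * delta(GlyGly) + phospho * delta(HPO3). Branch lysine
#' positions are not modeled: intact mass cannot resolve them, so proteoform
#' identity is (branch count, phospho state) only.
#'
#' @param n_branches Integer vector, diGLY branch count (0-3 quantified;
#'   at most 7 lysines exist).
#' @param phospho Logical vector, S65 phosphorylated?
#' @return A tibble with `proteoform` (label like `"1xGG+pS65"`),
#'   `n_branches`, `phospho` and `mass` (neutral monoisotopic, Da).
#' @export
ub_proteoform <- function(n_branches = 0L, phospho = FALSE) {
  stopifnot(all(n_branches >= 0), all(n_branches <= 7))
  if (any(n_branches > 3)) {
    rlang::warn("branch counts > 3 are outside the quantified range")
  }
  base <- monoisotopic_mass(peptide_composition(ub_dgg_sequence()))
  tibble::tibble(
    proteoform = paste0(n_branches, "xGG",
                        ifelse(phospho, "+pS65", "")),
    n_branches = as.integer(n_branches),
    phospho = as.logical(phospho),
    mass = base + n_branches * modification_delta("GlyGly") +
      phospho * modification_delta("Phospho")
  )
}

#' The eight quantified Ub^dGG candidate proteoforms
#'
#' The targeted-quantification candidate list: branch counts 0-3 crossed
#' with +/- pS65. Candidate masses are pairwise separated by > 34 Da, far
#' above the default 0.5 Da assignment tolerance.
#'
#' @return A tibble as from [ub_proteoform()], 8 rows.
#' @export
ub_proteoform_candidates <- function() {
  grid <- tidyr::expand_grid(n_branches = 0:3, phospho = c(FALSE, TRUE))
  ub_proteoform(grid$n_branches, grid$phospho)
}

#' Elemental composition of a Ub^dGG proteoform
#'
#' @param n_branches,phospho Scalars as in [ub_proteoform()].
#' @return A `ub_composition` (used to render exact isotope envelopes in
#'   the simulator; deconvolution deliberately uses averagine instead).
#' @export
ub_proteoform_composition <- function(n_branches = 0L, phospho = FALSE) {
  comp <- peptide_composition(ub_dgg_sequence())
  if (n_branches > 0) {
    comp <- composition_sum(comp, "C4H6N2O2", times = c(1L, as.integer(n_branches)))
  }
  if (phospho) comp <- composition_sum(comp, "HPO3")
  comp
}
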