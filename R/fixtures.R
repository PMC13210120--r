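# Packaged reference tables: experimental/calculated chemical shifts and
# fractional-intensity / effective-distance columns for three
# paracetamol-based structures (monoclinic paracetamol, its HCl monohydrate
# salt, and its oxalic-acid cocrystal), transcribed from the published
# tables at printed precision. These are measurement/report fixtures, not
# synthetic data: the underlying coordinate files are not shipped.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "dqcryst")
  if (p == "") stop("fixture not found: ", name)
  p
}

#' Packaged chemical-shift comparison table
#'
#' Per-site experimental 1H/13C shifts and the values calculated from the
#' structure model before ("xrd") and after ("dft") geometry optimization.
#' Sites whose MAS peaks overlap completely carry the shared peak-maximum
#' shift and are flagged in `overlap`.
#'
#' @param structure optional filter: "Para", "ParaHCl" or "ParaOA".
#' @param species optional filter: "1H" or "13C".
#' @return data.frame with columns `structure`, `site`, `species`,
#'   `overlap`, `delta_nmr`, `delta_dft`, `delta_xrd` (ppm).
#' @export
shift_table_fixture <- function(structure = NULL, species = NULL) {
  tab <- utils::read.delim(fixture_path("shift_table.tsv"),
                           stringsAsFactors = FALSE)
  if (!is.null(structure)) tab <- tab[tab$structure %in% structure, ]
  if (!is.null(species)) tab <- tab[tab$species %in% species, ]
  rownames(tab) <- NULL
  tab
}

#' Packaged fractional-intensity / effective-distance table
#'
#' Per site-group pair: experimental fractional 2Q-1Q intensity `f_nmr`,
#' the model fractions `f_dft`/`f_xrd`, and effective distances (pm) of
#' each model with its NMR-referenced counterpart and deviation. The row
#' flagged `excluded` was omitted from normalization in the distance
#' analysis (its fractions are reported on the retained scale).
#'
#' @param structure optional filter: "Para", "ParaHCl" or "ParaOA".
#' @param retained_only drop excluded rows?
#' @return data.frame; distances NA on the excluded row.
#' @export
distance_table_fixture <- function(structure = NULL, retained_only = FALSE) {
  tab <- utils::read.delim(fixture_path("distance_table.tsv"),
                           stringsAsFactors = FALSE)
  if (!is.null(structure)) tab <- tab[tab$structure %in% structure, ]
  if (retained_only) tab <- tab[!tab$excluded, ]
  rownames(tab) <- NULL
  tab
}

#' Re-emit the packaged fixtures to a directory
#'
#' Convenience for CLI users who want editable copies of the packaged
#' tables next to their own data.
#'
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
emit_fixtures <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c(file.path(dir, "shift_table.tsv"),
           file.path(dir, "distance_table.tsv"))
  file.copy(fixture_path("shift_table.tsv"), out[1], overwrite = TRUE)
  file.copy(fixture_path("distance_table.tsv"), out[2], overwrite = TRUE)
  invisible(out)
}
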