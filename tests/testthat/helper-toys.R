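# Shared toy systems built in code (no stored fixtures).

# methyl triangle plus an amide-like proton 215 pm from the nearest methyl H
toy_methyl_amide <- function(d_ext_pm = 215) {
  made <- make_methyl_structure()
  s <- made$structure
  cellA <- s$cell$a
  ext <- data.frame(label = "Hn", element = "H",
                    fx = s$sites$fx[1] - (d_ext_pm / 100) / cellA,
                    fy = s$sites$fy[1], fz = s$sites$fz[1], occupancy = 1)
  s2 <- crystal_structure(s$cell, rbind(s$sites, ext))
  g <- made$groups
  g[[1]]$shift <- 1.07
  g <- c(g, list(proton_site_group("Hn", "Hn", shift = 9.0)))
  list(structure = s2, groups = g)
}

# n single-proton groups scattered in a cubic cell, shifts spaced 1.5 ppm
toy_network <- function(n = 6, seed = 42, cell_A = 12) {
  tc <- make_toy_crystal("random_cell", params = list(n = n, cell_A = cell_A),
                         seed = seed)
  for (i in seq_along(tc$groups)) tc$groups[[i]]$shift <- 1 + 1.5 * (i - 1)
  tc
}

group_ids_public <- function(groups) vapply(groups, function(g) g$group_id, "")

is_p1_public <- function(s) length(s$symmetry_ops) == 1

runif_seeded <- function(n, lo, hi, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::runif(n, lo, hi)
}

# minimal CIF text helper
write_min_cif <- function(path, extra_ops = character(0),
                          sites = "H1 H 0.0 0.0 0.0 1.0", a = 10) {
  lines <- c(
    "data_test",
    sprintf("_cell_length_a %s", a), sprintf("_cell_length_b %s", a),
    sprintf("_cell_length_c %s", a),
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    sprintf("'%s'", extra_ops),
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "_atom_site_occupancy", sites)
  writeLines(lines, path)
  path
}
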