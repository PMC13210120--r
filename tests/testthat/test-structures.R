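test_that("unit cell validates its invariants", {
  expect_error(unit_cell(-1, 5, 5), "positive")
  expect_error(unit_cell(5, 5, 5, alpha = 200), "angles")
  cell <- unit_cell(10, 10, 10)
  expect_equal(cell_volume(cell), 1000)
  # triclinic volume against the closed form
  tc <- unit_cell(5, 6, 7, 80, 95, 110)
  ca <- cos(80 * pi / 180); cb <- cos(95 * pi / 180); cg <- cos(110 * pi / 180)
  expect_equal(cell_volume(tc),
               5 * 6 * 7 * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
})

test_that("minimal P1 CIF parses to one site and one operator", {
  p <- write_min_cif(tempfile(fileext = ".cif"))
  s <- read_cif(p)
  expect_equal(nrow(s$sites), 1)
  expect_length(s$symmetry_ops, 1)
  expect_equal(s$sites$element, "H")
})

test_that("inversion operator yields two P1 positions", {
  p <- write_min_cif(tempfile(fileext = ".cif"), extra_ops = "-x,-y,-z",
                     sites = "H1 H 0.1 0.1 0.1 1.0")
  s <- read_cif(p)
  expect_length(s$symmetry_ops, 2)
  p1 <- expand_to_p1(s)
  expect_equal(nrow(p1$sites), 2)
  expect_true(is_p1_public(p1))
})

test_that("CIF round-trip preserves fractional coordinates to 1e-6", {
  made <- make_methyl_structure()
  p <- tempfile(fileext = ".cif")
  write_cif(made$structure, p)
  back <- read_cif(p)
  expect_equal(as.matrix(back$sites[, c("fx", "fy", "fz")]),
               as.matrix(made$structure$sites[, c("fx", "fy", "fz")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  # alternative symmetry tag dialect is accepted too
  txt <- readLines(p)
  txt <- sub("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz",
             txt)
  writeLines(txt, p)
  expect_equal(nrow(read_cif(p)$sites), 3)
})

test_that("CIF errors: missing cell, unknown element; zero H warns", {
  p <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
               "H1 H 0 0 0"), p)
  expect_error(read_cif(p), "cell")
  write_min_cif(p, sites = "Q1 Qq 0.0 0.0 0.0 1.0")
  expect_error(read_cif(p), "element")
  write_min_cif(p, sites = "C1 C 0.0 0.0 0.0 1.0")
  expect_warning(read_cif(p), "no hydrogen")
})

test_that("P1 expansion: idempotence, orbit sizes, special positions", {
  made <- make_methyl_structure()
  expect_identical(expand_to_p1(made$structure), made$structure)

  # 222-type point group: general position -> 4 copies
  ops <- c("-x,-y,z", "-x,y,-z", "x,-y,-z")
  p <- write_min_cif(tempfile(fileext = ".cif"), extra_ops = ops,
                     sites = "H1 H 0.11 0.17 0.23 1.0")
  expect_equal(nrow(expand_to_p1(read_cif(p))$sites), 4)

  # site on the z axis fixed by 2 of the 4 operators -> orbit of 2
  p <- write_min_cif(tempfile(fileext = ".cif"), extra_ops = ops,
                     sites = "H1 H 0.0 0.0 0.23 1.0")
  expect_equal(nrow(expand_to_p1(read_cif(p))$sites), 2)
})

test_that("expansion detects element collisions", {
  p <- write_min_cif(tempfile(fileext = ".cif"), extra_ops = "-x,-y,-z",
                     sites = c("H1 H 0.1 0.0 0.0 1.0",
                               "C1 C 0.9 0.0 0.0 1.0"))
  expect_error(expand_to_p1(read_cif(p)), "consistency")
})

test_that("isolated pair and periodic self-pair distances are exact", {
  cell <- unit_cell(50, 50, 50)
  sites <- data.frame(label = c("Ha", "Hb"), element = "H",
                      fx = c(0.5, 0.5 + 3 / 5000 * 100), fy = 0.5, fz = 0.5,
                      occupancy = 1)
  s <- crystal_structure(cell, sites)
  g <- list(proton_site_group("A", "Ha"), proton_site_group("B", "Hb"))
  pd <- enumerate_pair_distances(s, g, 1000)
  expect_equal(pd[["A:B"]]$distances, 300)
  expect_length(pd[["A:A"]]$distances, 0)

  # one H in a 400 pm cubic cell: first shells of the primitive lattice
  s1 <- crystal_structure(unit_cell(4, 4, 4),
                          data.frame(label = "H1", element = "H", fx = 0,
                                     fy = 0, fz = 0, occupancy = 1))
  pd1 <- enumerate_pair_distances(s1, list(proton_site_group("H1", "H1")),
                                  1000)[[1]]
  counts <- table(round(pd1$distances, 1))
  expect_equal(unname(counts[c("400", "565.7", "692.8", "800", "894.4")]),
               c(6L, 12L, 8L, 6L, 24L), ignore_attr = TRUE)
  # equals the brute-force supercell oracle
  expect_equal(sort(pd1$distances),
               brute_force_pair_distances(s1, list(proton_site_group("H1", "H1")),
                                          1000)[[1]])
})

test_that("methyl triangle gives exactly the requested multiset", {
  made <- make_methyl_structure(176, 178, 179)
  pd <- enumerate_pair_distances(made$structure, made$groups, 1000)[[1]]
  expect_equal(sort(pd$distances), c(176, 178, 179), tolerance = 1e-8)
})

test_that("distance properties: symmetry, translation invariance, cutoff monotonicity, oracle", {
  for (seed in 1:5) {
    tc <- toy_network(n = 4, seed = seed)
    pd <- enumerate_pair_distances(tc$structure, tc$groups, 1000)
    bf <- brute_force_pair_distances(tc$structure, tc$groups, 1000)
    for (id in names(pd))
      expect_equal(sort(pd[[id]]$distances), bf[[id]], tolerance = 1e-9)

    # translation invariance
    s2 <- tc$structure
    s2$sites[, c("fx", "fy", "fz")] <-
      s2$sites[, c("fx", "fy", "fz")] + rep(c(0.13, 0.41, 0.77), each = nrow(s2$sites))
    pd2 <- enumerate_pair_distances(s2, tc$groups, 1000)
    for (id in names(pd))
      expect_equal(sort(pd2[[id]]$distances), sort(pd[[id]]$distances),
                   tolerance = 1e-9)

    # enlarging the cutoff never removes a distance
    pd_small <- enumerate_pair_distances(tc$structure, tc$groups, 700)
    for (id in names(pd_small)) {
      tab_small <- sort(pd_small[[id]]$distances)
      tab_large <- sort(pd[[id]]$distances)
      expect_true(all(tab_small %in% round(tab_large, 10) |
                        vapply(tab_small, function(d)
                          any(abs(tab_large - d) < 1e-9), TRUE)))
    }
  }
  # group order does not matter
  tc <- toy_network(n = 3, seed = 9)
  pd_ab <- enumerate_pair_distances(tc$structure, tc$groups, 1000)
  pd_ba <- enumerate_pair_distances(tc$structure, rev(tc$groups), 1000)
  ids <- group_ids_public(tc$groups)
  key <- paste(ids[1], ids[2], sep = ":")
  key_rev <- paste(ids[2], ids[1], sep = ":")
  got <- if (!is.null(pd_ba[[key]])) pd_ba[[key]] else pd_ba[[key_rev]]
  expect_equal(sort(pd_ab[[key]]$distances), sort(got$distances),
               tolerance = 1e-9)
})

test_that("sub-cutoff cells trigger an enlarged image search", {
  # 300 pm cell, cutoff 1000 pm: neighbours out to 3 cells must appear
  s <- crystal_structure(unit_cell(3, 30, 30),
                         data.frame(label = "H1", element = "H", fx = 0,
                                    fy = 0.5, fz = 0.5, occupancy = 1))
  pd <- enumerate_pair_distances(s, list(proton_site_group("H1", "H1")),
                                 1000)[[1]]
  expect_equal(sort(pd$distances), c(300, 300, 600, 600, 900, 900))
})

test_that("group resolution errors are caught", {
  made <- make_methyl_structure()
  expect_error(
    enumerate_pair_distances(made$structure,
                             list(proton_site_group("X", "nope")), 1000),
    "unresolvable")
  expect_error(
    enumerate_pair_distances(made$structure, made$groups, 100),
    ">= 200")
})
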