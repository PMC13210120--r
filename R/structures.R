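# Crystal-structure container, minimal CIF 1.1 I/O, and symmetry expansion.
#
# All Cartesian work is done in Angstrom internally; user-facing distances
# are reported in pm, matching the conventions of solid-state NMR tables.

ELEMENTS <- c(
  "H", "D", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
  "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb",
  "Sr", "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba"
)

#' Unit cell
#'
#' Construct a triclinic unit cell from lengths (Angstrom) and angles
#' (degrees). Lengths must be positive and angles in (0, 180) with a
#' positive cell volume.
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return An object of class `unit_cell`.
#' @export
#' @examples
#' unit_cell(10, 10, 10)
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell"
  )
  if (cell_volume(cell) <= 0) stop("cell volume must be positive")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4f b=%.4f c=%.4f A  alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Fractional-to-Cartesian matrix of a unit cell
#'
#' Returns the 3x3 matrix `M` such that `M %*% frac` gives Cartesian
#' coordinates in Angstrom (standard crystallographic convention with `a`
#' along x and `b` in the xy plane).
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg
  ), nrow = 3, byrow = TRUE)
}

#' Unit-cell volume in cubic Angstrom
#' @param cell a [unit_cell()].
#' @export
cell_volume <- function(cell) det(cell_matrix(cell))

identity_op <- function() list(R = diag(3), t = c(0, 0, 0))

op_is_identity <- function(op) {
  all(abs(op$R - diag(3)) < 1e-9) && all(abs(op$t %% 1) < 1e-9)
}

#' Parse a symmetry operator in xyz notation
#'
#' Converts strings such as `"1/2+x, -y, z"` into an affine operator acting
#' on fractional coordinates, represented as `list(R = <3x3>, t = <3>)`.
#'
#' @param s operator string with three comma-separated components.
#' @return list with rotation matrix `R` and translation `t`.
#' @export
parse_symop <- function(s) {
  comps <- strsplit(s, ",")[[1]]
  if (length(comps) != 3) stop("symmetry operator must have 3 components: ", s)
  if (!grepl("^[-+0-9xyzXYZ/\\. ]+$", gsub(",", "", s)))
    stop("malformed symmetry operator: ", s)
  evalc <- function(expr, x, y, z) {
    env <- list2env(list(x = x, y = y, z = z, X = x, Y = y, Z = z))
    eval(parse(text = expr), envir = env)
  }
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    e <- comps[i]
    t[i] <- evalc(e, 0, 0, 0)
    R[i, 1] <- evalc(e, 1, 0, 0) - t[i]
    R[i, 2] <- evalc(e, 0, 1, 0) - t[i]
    R[i, 3] <- evalc(e, 0, 0, 1) - t[i]
  }
  list(R = R, t = t)
}

format_symop <- function(op) {
  comp <- function(i) {
    terms <- character(0)
    for (j in 1:3) {
      co <- op$R[i, j]
      if (abs(co) < 1e-9) next
      v <- c("x", "y", "z")[j]
      pre <- if (co < 0) "-" else if (length(terms)) "+" else ""
      mag <- if (abs(abs(co) - 1) < 1e-9) "" else paste0(abs(co), "*")
      terms <- c(terms, paste0(pre, mag, v))
    }
    tr <- op$t[i]
    if (abs(tr) > 1e-9) {
      fr <- paste0(if (tr < 0) "-" else "+", abs(round(tr, 6)))
      terms <- c(terms, fr)
    }
    if (!length(terms)) "0" else paste(terms, collapse = "")
  }
  paste(vapply(1:3, comp, ""), collapse = ",")
}

#' Crystal structure
#'
#' A unit cell, a set of symmetry operators in fractional space, and a table
#' of atomic sites. The identity operator is always present.
#'
#' @param cell a [unit_cell()].
#' @param sites data.frame with columns `label`, `element`, `fx`, `fy`, `fz`
#'   and optionally `occupancy` (defaults to 1).
#' @param symmetry_ops list of operators as returned by [parse_symop()];
#'   defaults to the identity alone (P1).
#' @return object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, sites, symmetry_ops = list(identity_op())) {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(sites))
  need <- c("label", "element", "fx", "fy", "fz")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  if (is.null(sites$occupancy)) sites$occupancy <- 1
  if (any(!is.finite(as.matrix(sites[, c("fx", "fy", "fz")]))))
    stop("fractional coordinates must be finite")
  if (any(sites$occupancy <= 0 | sites$occupancy > 1))
    stop("occupancy must lie in (0, 1]")
  bad <- setdiff(unique(sites$element), ELEMENTS)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (!any(vapply(symmetry_ops, op_is_identity, logical(1))))
    symmetry_ops <- c(list(identity_op()), symmetry_ops)
  if (any(sites$occupancy < 1))
    warning("partial occupancy present; pair sums ignore occupancy")
  structure(
    list(cell = cell, sites = sites, symmetry_ops = symmetry_ops),
    class = "crystal_structure"
  )
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %d site(s), %d symmetry op(s)\n",
              nrow(x$sites), length(x$symmetry_ops)))
  print(x$cell)
  nH <- sum(x$sites$element == "H")
  cat(sprintf("  H sites: %d of %d atoms\n", nH, nrow(x$sites)))
  invisible(x)
}

is_p1 <- function(s) length(s$symmetry_ops) == 1 &&
  op_is_identity(s$symmetry_ops[[1]])

strip_su <- function(x) as.numeric(sub("\\(.*\\)", "", x))

cif_tokens <- function(line) {
  # split on whitespace, respecting single/double quotes
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Read a crystal structure from CIF
#'
#' Supports the CIF 1.1 subset needed for validation work: cell parameters,
#' symmetry operators in xyz notation (both `_symmetry_equiv_pos_as_xyz` and
#' `_space_group_symop_operation_xyz` dialects), and the `_atom_site_` loop.
#' Hydrogen atoms present in the file are preserved verbatim; no hydrogens
#' are added or repositioned.
#'
#' @param path path to a CIF file.
#' @return a [crystal_structure()].
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]

  getval <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    strip_su(cif_tokens(hit[1])[2])
  }
  a <- getval("_cell_length_a"); b <- getval("_cell_length_b")
  cc <- getval("_cell_length_c")
  al <- getval("_cell_angle_alpha"); be <- getval("_cell_angle_beta")
  ga <- getval("_cell_angle_gamma")
  if (any(is.na(c(a, b, cc))))
    stop("CIF format error: missing _cell_length_* block")
  if (is.na(al)) al <- 90; if (is.na(be)) be <- 90; if (is.na(ga)) ga <- 90
  cell <- unit_cell(a, b, cc, al, be, ga)

  # walk loops
  ops <- list()
  sites <- NULL
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1
      headers <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        headers <- c(headers, cif_tokens(lines[j])[1])
        j <- j + 1
      }
      body <- character(0)
      while (j <= n && !grepl("^\\s*(loop_|_|data_)", lines[j]) &&
             !grepl("^\\s*$", lines[j])) {
        body <- c(body, lines[j])
        j <- j + 1
      }
      symcol <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                     headers)
      if (length(symcol)) {
        for (ln in body) {
          toks <- cif_tokens(ln)
          # operator may be the only (quoted) token or follow an id column
          op_str <- toks[min(symcol, length(toks))]
          if (length(toks) > length(headers)) {
            # unquoted operator split by spaces: rejoin everything after ids
            op_str <- paste(toks[symcol:length(toks)], collapse = "")
          }
          ops <- c(ops, list(parse_symop(op_str)))
        }
      } else if (any(grepl("^_atom_site_label$", headers))) {
        rows <- lapply(body, cif_tokens)
        rows <- rows[vapply(rows, length, 1L) == length(headers)]
        tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tab) <- headers
        el <- if ("_atom_site_type_symbol" %in% headers) {
          gsub("[0-9+-]+$", "", tab[["_atom_site_type_symbol"]])
        } else {
          # derive from label: leading element symbol
          m2 <- regmatches(tab[["_atom_site_label"]],
                           regexpr("^[A-Z][a-z]?", tab[["_atom_site_label"]]))
          ifelse(m2 %in% ELEMENTS, m2, substr(m2, 1, 1))
        }
        occ <- if ("_atom_site_occupancy" %in% headers)
          strip_su(tab[["_atom_site_occupancy"]]) else 1
        sites <- data.frame(
          label = tab[["_atom_site_label"]],
          element = el,
          fx = strip_su(tab[["_atom_site_fract_x"]]),
          fy = strip_su(tab[["_atom_site_fract_y"]]),
          fz = strip_su(tab[["_atom_site_fract_z"]]),
          occupancy = occ,
          stringsAsFactors = FALSE
        )
      }
      i <- j
    } else i <- i + 1
  }
  if (is.null(sites) || !nrow(sites))
    stop("CIF format error: no atom sites found")
  if (!length(ops)) ops <- list(identity_op())
  s <- crystal_structure(cell, sites, ops)
  if (!any(sites$element == "H"))
    warning("structure contains no hydrogen atoms")
  s
}

#' Write a crystal structure to CIF
#'
#' Emits the same CIF 1.1 subset that [read_cif()] consumes. Symmetry
#' operators are written in xyz notation.
#'
#' @param s a [crystal_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(s, path) {
  stopifnot(inherits(s, "crystal_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_dqcryst")
  w("_cell_length_a    %.6f", s$cell$a)
  w("_cell_length_b    %.6f", s$cell$b)
  w("_cell_length_c    %.6f", s$cell$c)
  w("_cell_angle_alpha %.6f", s$cell$alpha)
  w("_cell_angle_beta  %.6f", s$cell$beta)
  w("_cell_angle_gamma %.6f", s$cell$gamma)
  w("loop_")
  w("_symmetry_equiv_pos_as_xyz")
  for (op in s$symmetry_ops) w("'%s'", format_symop(op))
  w("loop_")
  w("_atom_site_label")
  w("_atom_site_type_symbol")
  w("_atom_site_fract_x")
  w("_atom_site_fract_y")
  w("_atom_site_fract_z")
  w("_atom_site_occupancy")
  for (i in seq_len(nrow(s$sites))) {
    r <- s$sites[i, ]
    w("%s %s %.8f %.8f %.8f %.4f", r$label, r$element, r$fx, r$fy, r$fz,
      r$occupancy)
  }
  invisible(path)
}

wrap_frac <- function(f) f - floor(f)

#' Expand a structure to P1
#'
#' Applies every symmetry operator to every site, wraps positions into
#' `[0, 1)`, and merges duplicate images closer than `tol_pm` (minimum-image
#' Cartesian distance). Copies generated from one crystallographic site keep
#' its label. Idempotent on P1 input.
#'
#' @param s a [crystal_structure()].
#' @param tol_pm merge tolerance for coincident images, in pm. Default 10 pm
#'   (typical special-position noise in deposited CIFs).
#' @return a P1 [crystal_structure()] whose only operator is the identity.
#' @export
expand_to_p1 <- function(s, tol_pm = 10) {
  stopifnot(inherits(s, "crystal_structure"))
  if (is_p1(s)) return(s)
  M <- cell_matrix(s$cell)
  tol_A <- tol_pm / 100
  out <- list()
  for (i in seq_len(nrow(s$sites))) {
    site <- s$sites[i, ]
    f0 <- c(site$fx, site$fy, site$fz)
    for (op in s$symmetry_ops) {
      f <- wrap_frac(as.numeric(op$R %*% f0 + op$t))
      dup <- FALSE
      for (prev in out) {
        df <- f - prev$f
        df <- df - round(df)          # minimum image
        if (sqrt(sum((M %*% df)^2)) < tol_A) {
          if (prev$element != site$element)
            stop("symmetry consistency error: operator maps ", site$label,
                 " onto a ", prev$element, " position")
          dup <- TRUE
          break
        }
      }
      if (!dup)
        out <- c(out, list(list(label = site$label, element = site$element,
                                f = f, occupancy = site$occupancy)))
    }
  }
  sites <- data.frame(
    label = vapply(out, `[[`, "", "label"),
    element = vapply(out, `[[`, "", "element"),
    fx = vapply(out, function(p) p$f[1], 0),
    fy = vapply(out, function(p) p$f[2], 0),
    fz = vapply(out, function(p) p$f[3], 0),
    occupancy = vapply(out, `[[`, 0, "occupancy"),
    stringsAsFactors = FALSE
  )
  suppressWarnings(crystal_structure(s$cell, sites))
}
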