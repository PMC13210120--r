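# Dipolar couplings, squared effective couplings with motional scaling,
# multiplicities, effective distances, and model fractional couplings.

#' Physical constants for 1H-1H dipolar couplings
#'
#' CODATA values of the vacuum permeability, reduced Planck constant and 1H
#' magnetogyric ratio, together with the derived dipolar prefactor
#' `K_HH = -mu0 * hbar * gammaH^2 / (8 * pi^2)` in Hz m^3. `K_HH` is
#' negative; its magnitude at r = 200 pm gives a coupling of about
#' -1.50e4 Hz.
#'
#' @return list with `mu0`, `hbar`, `gammaH`, `K_HH`.
#' @export
#' @examples
#' hh_constants()$K_HH
hh_constants <- function() {
  mu0 <- 1.25663706212e-6     # N A^-2
  hbar <- 1.054571817e-34     # J s
  gammaH <- 2.6752218744e8    # rad s^-1 T^-1
  list(mu0 = mu0, hbar = hbar, gammaH = gammaH,
       K_HH = -mu0 * hbar * gammaH^2 / (8 * pi^2))
}

#' Dipolar coupling constant of a proton pair
#'
#' `b = K_HH / r^3` with `r` the internuclear distance. The negative sign of
#' `K_HH` is preserved; only `b^2` enters intensity analysis, so the sign is
#' informational.
#'
#' @param r_pm internuclear distance(s) in pm; must be positive.
#' @return coupling(s) in Hz (negative).
#' @export
#' @examples
#' dipolar_coupling(200)   # about -1.5e4 Hz
dipolar_coupling <- function(r_pm) {
  if (any(!is.finite(r_pm)) || any(r_pm <= 0))
    stop("distance must be positive and finite")
  hh_constants()$K_HH / (r_pm * 1e-12)^3
}

#' Squared effective dipolar coupling of a site-group pair
#'
#' Sums `b^2` over every enumerated proton pair of the family. For an
#' equivalent pair (j = k) under rapid methyl three-site jumps
#' (`fast_3site`), each intra-group coupling is scaled by -1/2 before
#' squaring, i.e. every term picks up a factor 1/4. Couplings between a
#' methyl group and an external site are unchanged by the jump motion, so
#' no scaling is applied for j != k.
#'
#' @param pair a `site_pair_distances` object.
#' @param motion_j,motion_k motion models; default to those recorded on the
#'   pair (taken from the groups at enumeration time).
#' @return squared effective coupling in Hz^2, with attribute
#'   `motion_applied` recording the scaling used.
#' @export
effective_coupling_squared <- function(pair,
                                       motion_j = pair$motion_j,
                                       motion_k = pair$motion_k) {
  stopifnot(inherits(pair, "site_pair_distances"))
  if (!length(pair$distances))
    stop("pair ", pair_id(pair$j, pair$k), " has no distances within cutoff")
  scale <- 1
  if (pair$equivalent && motion_j == "fast_3site") {
    if (pair$n_j != 3)
      stop("fast_3site motion requires a 3-member group (", pair$j, ")")
    scale <- 0.25                        # (-1/2)^2 on every intra-group term
  }
  b2 <- sum(dipolar_coupling(pair$distances)^2) * scale
  attr(b2, "motion_applied") <- if (scale != 1) "fast_3site x1/4" else "static"
  b2
}

#' Multiplicity of the set of largest couplings
#'
#' Number of near-degenerate shortest distances in a pair family: distances
#' within a relative tolerance of the minimum. The default 10% tolerance
#' makes the three near-equal intra-methyl distances of a CH3 group count
#' as multiplicity 3.
#'
#' @param pair a `site_pair_distances` object or a numeric distance vector
#'   (pm).
#' @param rel_tol relative tolerance on the minimum distance; default 0.10.
#' @return integer count >= 1.
#' @export
multiplicity <- function(pair, rel_tol = 0.10) {
  d <- if (inherits(pair, "site_pair_distances")) pair$distances else pair
  if (!length(d)) stop("no distances")
  if (rel_tol <= 0) stop("rel_tol must be positive")
  sum(d <= min(d) * (1 + rel_tol))
}

#' Effective interatomic distance of a pair family
#'
#' The r^-6-weighted aggregate distance
#' `r_eff = (M * K_HH^2 / b_eff^2)^(1/6)`, equivalently
#' `(M / sum(r^-6))^(1/6)` when computed from distances directly. Dominated
#' by the shortest contacts; equals the single distance when the family has
#' one pair and M = 1.
#'
#' @param b_eff_sq squared effective coupling in Hz^2 (ignored when
#'   `distances` is given).
#' @param M multiplicity of the set of largest couplings.
#' @param distances optional distance vector in pm; when supplied the
#'   aggregate is computed as `(M / sum(r^-6))^(1/6)` with no unit
#'   round-trip.
#' @return effective distance in pm.
#' @export
#' @examples
#' effective_distance(M = 3, distances = c(176, 178, 179))  # ~177.6 pm
effective_distance <- function(b_eff_sq = NULL, M, distances = NULL) {
  if (M < 1) stop("multiplicity must be >= 1")
  if (!is.null(distances)) {
    if (any(distances <= 0)) stop("distances must be positive")
    return((M / sum(distances^-6))^(1 / 6))
  }
  if (is.null(b_eff_sq) || !is.finite(b_eff_sq) || b_eff_sq <= 0)
    stop("undefined effective distance: b_eff_sq must be positive")
  K <- hh_constants()$K_HH
  (M * K^2 / b_eff_sq)^(1 / 6) * 1e12
}

#' Per-pair coupling table of a structure model
#'
#' Runs distance enumeration and aggregates each site-group pair into its
#' squared effective coupling, multiplicity, and effective distance — the
#' model side of a fractional-intensity analysis.
#'
#' @param s a [crystal_structure()] (expanded to P1 if needed).
#' @param groups list of [proton_site_group()] (their `motion` fields drive
#'   the methyl scaling).
#' @param cutoff_pm distance cutoff in pm, default 1000.
#' @param mult_tol relative tolerance defining the multiplicity, default
#'   0.10.
#' @param pairs optional precomputed result of [enumerate_pair_distances()].
#' @return data.frame of class `pair_coupling_table` with one row per
#'   site-group pair having at least one contact: `pair`, `j`, `k`,
#'   `b_eff_sq` (Hz^2), `M`, `r_eff_pm`, `r_min_pm`, `n_terms`,
#'   `motion_applied`.
#' @export
pair_coupling_table <- function(s, groups, cutoff_pm = 1000, mult_tol = 0.10,
                                pairs = NULL) {
  if (is.null(pairs))
    pairs <- enumerate_pair_distances(s, groups, cutoff_pm = cutoff_pm)
  rows <- lapply(pairs, function(p) {
    if (!length(p$distances)) return(NULL)
    b2 <- effective_coupling_squared(p)
    M <- multiplicity(p, rel_tol = mult_tol)
    data.frame(
      pair = pair_id(p$j, p$k), j = p$j, k = p$k,
      b_eff_sq = as.numeric(b2), M = M,
      r_eff_pm = effective_distance(M = M, distances = p$distances),
      r_min_pm = min(p$distances), n_terms = length(p$distances),
      motion_applied = attr(b2, "motion_applied"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(tab) <- NULL
  attr(tab, "cutoff_pm") <- cutoff_pm
  attr(tab, "mult_tol") <- mult_tol
  class(tab) <- c("pair_coupling_table", class(tab))
  tab
}

#' Convergence diagnostic for the distance cutoff
#'
#' Reports the relative change of every `b_eff_sq` when the cutoff is
#' reduced (default from 1000 pm to 800 pm), as a quick check that the
#' r^-6 sums are converged at the working cutoff.
#'
#' @param s structure; @param groups site groups.
#' @param cutoff_pm working cutoff; @param reduced_pm reduced cutoff.
#' @inheritParams pair_coupling_table
#' @return data.frame with `pair`, `b_eff_sq`, `b_eff_sq_reduced`,
#'   `rel_change`.
#' @export
cutoff_convergence <- function(s, groups, cutoff_pm = 1000, reduced_pm = 800,
                               mult_tol = 0.10) {
  full <- pair_coupling_table(s, groups, cutoff_pm, mult_tol)
  red <- pair_coupling_table(s, groups, reduced_pm, mult_tol)
  m <- match(full$pair, red$pair)
  b2r <- red$b_eff_sq[m]
  b2r[is.na(b2r)] <- 0
  data.frame(pair = full$pair, b_eff_sq = full$b_eff_sq,
             b_eff_sq_reduced = b2r,
             rel_change = (full$b_eff_sq - b2r) / full$b_eff_sq,
             stringsAsFactors = FALSE)
}

#' Fraction set container
#'
#' Internal constructor shared by the model ([model_fractions()]) and
#' experimental ([nmr_fractions()]) sides: retained fractions are
#' normalized to unity; excluded entries are reported relative to the
#' retained total but omitted from the normalizing denominator.
#'
#' @param ids pair/group identifiers.
#' @param weights non-negative weights (b_eff_sq or integrated intensity).
#' @param excluded character vector of excluded ids.
#' @param provenance one of "NMR", "XRD", "DFT", "model".
#' @return data.frame of class `fraction_set` with columns `id`, `f`,
#'   `excluded`, plus attributes `total` (retained weight sum) and
#'   `provenance`.
#' @export
fraction_set <- function(ids, weights, excluded = character(0),
                         provenance = "model") {
  stopifnot(length(ids) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  ex <- ids %in% excluded
  if (all(ex)) stop("all groups excluded; nothing to normalize")
  tot <- sum(weights[!ex])
  if (tot <= 0) stop("retained total is zero")
  out <- data.frame(id = ids, f = weights / tot, excluded = ex,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- tot
  attr(out, "provenance") <- provenance
  class(out) <- c("fraction_set", class(out))
  out
}

retained <- function(fs) fs[!fs$excluded, , drop = FALSE]

apply_grouping <- function(ids, weights, grouping) {
  # grouping: named list merged_id -> character vector of original ids
  if (is.null(grouping) || !length(grouping)) return(list(ids = ids, w = weights))
  flat <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(flat)) stop("grouping assigns an id twice")
  unknown <- setdiff(flat, ids)
  if (length(unknown))
    stop("grouping references unknown id(s): ", paste(unknown, collapse = ", "))
  keep <- !(ids %in% flat)
  out_ids <- ids[keep]; out_w <- weights[keep]
  for (nm in names(grouping)) {
    out_ids <- c(out_ids, nm)
    out_w <- c(out_w, sum(weights[ids %in% grouping[[nm]]]))
  }
  list(ids = out_ids, w = out_w)
}

#' Model fractional couplings of a structure
#'
#' Converts a [pair_coupling_table()] into fractions
#' `f = b_eff_sq / b_eff_sq(tot)`, where the total runs over all retained
#' pair groups. Pairs whose 2D NMR peaks overlap experimentally may be
#' merged via `grouping` (their `b_eff_sq` values are summed before
#' normalization, matching how overlapped intensities are integrated
#' together). Excluded groups are reported on the retained scale but do not
#' enter the denominator.
#'
#' @param tab a [pair_coupling_table()].
#' @param grouping named list: merged id -> character vector of pair ids.
#' @param exclude ids (after merging) to exclude from normalization.
#' @param provenance label, e.g. "XRD" or "DFT".
#' @return a [fraction_set()] with attribute `total` = retained
#'   `b_eff_sq(tot)` in Hz^2.
#' @export
model_fractions <- function(tab, grouping = NULL, exclude = character(0),
                            provenance = "model") {
  stopifnot(inherits(tab, "pair_coupling_table"))
  g <- apply_grouping(tab$pair, tab$b_eff_sq, grouping)
  fraction_set(g$ids, g$w, excluded = exclude, provenance = provenance)
}

#' @export
print.fraction_set <- function(x, ...) {
  cat(sprintf("<fraction_set> %s: %d group(s), %d excluded; retained sum = %.6f\n",
              attr(x, "provenance"), nrow(x), sum(x$excluded),
              sum(x$f[!x$excluded])))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Export a coupling table or fraction set as TSV
#'
#' @param x a `pair_coupling_table` or `fraction_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
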