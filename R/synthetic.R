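# Synthetic-data generators: toy crystal structures with known pair
# geometry, noisy fractional-intensity sets, and synthetic shieldings.
# Every generator is deterministic under a fixed seed, and toy crystals
# ship with a ground-truth coupling table computed by the brute-force
# supercell oracle rather than the production pipeline.

pm2A <- function(x) x / 100

#' Synthetic methyl-triangle structure
#'
#' A P1 structure holding exactly three H atoms whose pairwise distances
#' equal the requested values (to machine precision), centred in a cell
#' large enough that no periodic image lies within the default 1000 pm
#' cutoff. The three protons form one equivalent site group, mirroring a
#' methyl group.
#'
#' @param d12,d13,d23 target distances in pm (must satisfy the triangle
#'   inequality); defaults are the near-equal intra-methyl distances of a
#'   DFT-refined paracetamol methyl group.
#' @param cell_A cubic cell edge in Angstrom (default 30).
#' @return list with `structure` (a P1 [crystal_structure()]) and `groups`
#'   (a single fast-capable 3-member group labelled `"CH3"`).
#' @export
make_methyl_structure <- function(d12 = 176, d13 = 178, d23 = 179,
                                  cell_A = 30) {
  d <- c(d12, d13, d23)
  if (any(d < 150)) stop("target distances must be >= 150 pm")
  if (d12 + d13 <= d23 || d12 + d23 <= d13 || d13 + d23 <= d12)
    stop("geometry error: triangle inequality violated")
  a12 <- pm2A(d12); a13 <- pm2A(d13); a23 <- pm2A(d23)
  x <- (a12^2 + a13^2 - a23^2) / (2 * a12)
  y2 <- a13^2 - x^2
  if (y2 <= 0) stop("geometry error: degenerate triangle")
  xyz <- rbind(c(0, 0, 0), c(a12, 0, 0), c(x, sqrt(y2), 0))
  cell <- unit_cell(cell_A, cell_A, cell_A)
  frac <- sweep(xyz %*% t(solve(cell_matrix(cell))), 2, 0.5, "+")
  sites <- data.frame(label = c("H1m", "H2m", "H3m"), element = "H",
                      fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                      occupancy = 1, stringsAsFactors = FALSE)
  list(structure = crystal_structure(cell, sites),
       groups = list(proton_site_group("CH3", c("H1m", "H2m", "H3m"))))
}

#' Toy crystal generator with ground truth
#'
#' Builds a small synthetic structure per motif and returns it together
#' with its exact pair-coupling table computed by the independent
#' brute-force supercell oracle ([brute_force_pair_distances()]), enabling
#' cross-checks of the production pipeline.
#'
#' Motifs:
#' * `methyl_triangle`: three H forming a triangle (see
#'   [make_methyl_structure()]); `params$d` = three distances (pm).
#' * `hbond_pair`: two inequivalent H separated by `params$sep_pm`
#'   (default 233 pm, a carboxylic-to-phenolic H-bond contact).
#' * `lattice_chain`: one H repeating along `a` with period
#'   `params$spacing_pm` (default 400 pm), a genuinely periodic self pair.
#' * `random_cell`: `params$n` H sites (default 4) scattered in a cubic
#'   cell with a 150 pm minimum separation.
#'
#' @param motif one of the motifs above.
#' @param params named list of motif parameters.
#' @param seed integer seed (used by `random_cell`).
#' @param cutoff_pm cutoff for the ground-truth table (default 1000).
#' @param mult_tol multiplicity tolerance for the ground truth.
#' @return list with `structure`, `groups`, and `truth` — a data.frame
#'   `pair`, `b_eff_sq`, `M`, `r_eff_pm`, `n_terms` computed from the
#'   oracle distances.
#' @export
make_toy_crystal <- function(motif = c("methyl_triangle", "hbond_pair",
                                       "lattice_chain", "random_cell"),
                             params = list(), seed = 1L,
                             cutoff_pm = 1000, mult_tol = 0.10) {
  motif <- match.arg(motif)
  if (motif == "methyl_triangle") {
    d <- params$d %||% c(176, 178, 179)
    made <- make_methyl_structure(d[1], d[2], d[3])
    s <- made$structure; groups <- made$groups
  } else if (motif == "hbond_pair") {
    sep <- params$sep_pm %||% 233
    if (sep < 150) stop("separation must be >= 150 pm")
    cell <- unit_cell(30, 30, 30)
    sites <- data.frame(
      label = c("HD", "HA"), element = "H",
      fx = c(0.5, 0.5 + pm2A(sep) / 30), fy = 0.5, fz = 0.5,
      occupancy = 1, stringsAsFactors = FALSE)
    s <- crystal_structure(cell, sites)
    groups <- list(proton_site_group("HD", "HD"),
                   proton_site_group("HA", "HA"))
  } else if (motif == "lattice_chain") {
    sp <- params$spacing_pm %||% 400
    if (sp < 150) stop("spacing must be >= 150 pm")
    cell <- unit_cell(pm2A(sp), 30, 30)
    sites <- data.frame(label = "Hc", element = "H", fx = 0, fy = 0.5,
                        fz = 0.5, occupancy = 1, stringsAsFactors = FALSE)
    s <- crystal_structure(cell, sites)
    groups <- list(proton_site_group("Hc", "Hc"))
  } else {
    n <- params$n %||% 4L
    edge <- params$cell_A %||% 12
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    cell <- unit_cell(edge, edge, edge)
    M <- cell_matrix(cell)
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pts) < n) {
      cand <- stats::runif(3)
      ok <- TRUE
      if (nrow(pts)) {
        for (i in seq_len(nrow(pts))) {
          df <- cand - pts[i, ]; df <- df - round(df)
          if (sqrt(sum((M %*% df)^2)) < 1.5) { ok <- FALSE; break }
        }
      }
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1
      if (tries > 10000) stop("infeasible geometry: cannot place sites")
    }
    sites <- data.frame(label = paste0("Hr", seq_len(n)), element = "H",
                        fx = pts[, 1], fy = pts[, 2], fz = pts[, 3],
                        occupancy = 1, stringsAsFactors = FALSE)
    s <- crystal_structure(cell, sites)
    groups <- lapply(sites$label, function(l) proton_site_group(l, l))
  }
  truth <- oracle_coupling_table(s, groups, cutoff_pm, mult_tol)
  list(structure = s, groups = groups, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_coupling_table <- function(s, groups, cutoff_pm, mult_tol = 0.10) {
  dist <- brute_force_pair_distances(s, groups, cutoff_pm)
  rows <- lapply(names(dist), function(id) {
    d <- dist[[id]]
    if (!length(d)) return(NULL)
    b2 <- sum((hh_constants()$K_HH / (d * 1e-12)^3)^2)
    M <- sum(d <= min(d) * (1 + mult_tol))
    data.frame(pair = id, b_eff_sq = b2, M = M,
               r_eff_pm = (M / sum(d^-6))^(1 / 6),
               n_terms = length(d), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(tab) <- NULL
  tab
}

#' Noise specification for fractional intensities
#'
#' @param model `"multiplicative_gaussian"` (each fraction multiplied by
#'   `1 + N(0, scale)`, negatives resampled) or `"dirichlet"` (resampled
#'   from a Dirichlet centred on the input with concentration `1/scale`).
#' @param scale noise scale (>= 0; 0 means identity).
#' @param seed integer seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("multiplicative_gaussian", "dirichlet"),
                       scale = 0.05, seed = 1L) {
  model <- match.arg(model)
  if (scale < 0) stop("scale must be >= 0")
  structure(list(model = model, scale = scale, seed = seed),
            class = "noise_spec")
}

#' Perturb a fraction set with integration-like noise
#'
#' Applies the noise model to the retained fractions and renormalizes so
#' the output is again a simplex point; excluded entries are perturbed and
#' reported on the new retained scale. Deterministic under the given
#' seed. Resampling of would-be-negative multiplicative draws is counted
#' in attribute `n_resampled` (with a warning).
#'
#' @param f a [fraction_set()].
#' @param noise a [noise_spec()].
#' @return perturbed [fraction_set()].
#' @export
perturb_fractions <- function(f, noise = noise_spec()) {
  stopifnot(inherits(f, "fraction_set"), inherits(noise, "noise_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  w <- f$f
  n_res <- 0L
  if (noise$scale > 0) {
    if (noise$model == "multiplicative_gaussian") {
      for (i in seq_along(w)) {
        repeat {
          fac <- 1 + stats::rnorm(1, 0, noise$scale)
          if (fac > 0) break
          n_res <- n_res + 1L
        }
        w[i] <- w[i] * fac
      }
      if (n_res > 0)
        warning(n_res, " negative multiplicative draw(s) resampled")
    } else {
      conc <- 1 / noise$scale
      w <- vapply(w, function(fi) stats::rgamma(1, shape = fi * conc), 0)
      if (all(w == 0)) w <- f$f   # pathological scale; fall back
    }
  }
  out <- fraction_set(f$id, w, excluded = f$id[f$excluded],
                      provenance = attr(f, "provenance"))
  attr(out, "n_resampled") <- n_res
  out
}

#' Synthetic shielding tensors
#'
#' Emulates computed isotropic shieldings via
#' `sigma_iso = sigma_ref - delta_true + N(0, noise_sd)`, optionally
#' emitting three principal values whose mean equals `sigma_iso` exactly.
#'
#' @param delta_true true shifts in ppm (optionally named by site).
#' @param sigma_ref reference shielding in ppm.
#' @param noise_sd Gaussian noise sd in ppm (>= 0).
#' @param seed integer seed.
#' @param principal emit three principal values per site?
#' @param species species label stored with the table.
#' @return data.frame `site`, `species`, `sigma_iso` and, when requested,
#'   `sigma_xx`, `sigma_yy`, `sigma_zz`.
#' @export
synth_shieldings <- function(delta_true, sigma_ref, noise_sd = 0, seed = 1L,
                             principal = FALSE, species = "1H") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(delta_true)
  iso <- sigma_ref - delta_true +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  out <- data.frame(
    site = if (is.null(names(delta_true))) paste0("S", seq_len(n))
           else names(delta_true),
    species = species, sigma_iso = iso, stringsAsFactors = FALSE)
  if (principal) {
    span <- stats::runif(n, 1, 10)        # arbitrary anisotropy, mean-exact
    out$sigma_xx <- iso - span
    out$sigma_yy <- iso
    out$sigma_zz <- iso + span
  }
  out
}
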