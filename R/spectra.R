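# Linear-regime 2Q-1Q 1H correlation spectrum simulation and rectangular
# peak integration.
#
# The simulator is linear by construction: each site-pair contributes a
# total 2D volume proportional to kappa^2 * b_eff^2, the short-excitation
# proportionality that underpins the fractional-intensity analysis. The
# "peak volumes should stay below ~1/3 of the maximum seen at longer
# excitation" criterion is an experimental validity condition, not a
# simulated dynamic.

#' Spectrum simulation configuration
#'
#' @param kappa recoupling scaling factor of the effective 2Q Hamiltonian,
#'   dimensionless in (0, 1]; cancels in all fractional quantities.
#' @param tau_exc 2QC excitation interval in microseconds (recorded in the
#'   config echo; the linear simulator does not propagate spin dynamics).
#'   Default 16.67 us, one rotor period at 60 kHz MAS.
#' @param lw_1q,lw_2q Gaussian standard deviations of the peaks along the
#'   1Q and 2Q dimensions, in ppm.
#' @param n_1q,n_2q grid points per dimension (default 512).
#' @param pad padding of the axis ranges beyond the outermost peaks, in
#'   multiples of the linewidth (default 5).
#' @return object of class `spectrum_config`.
#' @export
spectrum_config <- function(kappa = 0.5, tau_exc = 16.67,
                            lw_1q = 0.15, lw_2q = 0.25,
                            n_1q = 512, n_2q = 512, pad = 5) {
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  if (tau_exc <= 0) stop("tau_exc must be positive")
  if (lw_1q <= 0 || lw_2q <= 0) stop("linewidths must be positive")
  structure(list(kappa = kappa, tau_exc = tau_exc, lw_1q = lw_1q,
                 lw_2q = lw_2q, n_1q = n_1q, n_2q = n_2q, pad = pad),
            class = "spectrum_config")
}

peak_list <- function(groups, couplings, cfg) {
  shifts <- stats::setNames(vapply(groups, `[[`, 0, "shift"),
                            group_ids(groups))
  if (any(is.na(shifts[unique(c(couplings$j, couplings$k))])))
    stop("every group entering the simulation needs a chemical shift")
  rows <- list()
  for (i in seq_len(nrow(couplings))) {
    j <- couplings$j[i]; k <- couplings$k[i]
    vol <- cfg$kappa^2 * couplings$b_eff_sq[i]
    d2q <- shifts[j] + shifts[k]
    if (j == k) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = couplings$pair[i], d2q = d2q, d1q = shifts[j], vol = vol)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        pair = couplings$pair[i], d2q = d2q, d1q = shifts[j], vol = vol / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = couplings$pair[i], d2q = d2q, d1q = shifts[k], vol = vol / 2)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a 2Q-1Q correlation spectrum in the linear regime
#'
#' Places 2D Gaussian peaks per site-group pair: a j != k pair gives two
#' cross peaks at `{dj + dk, dj}` and `{dj + dk, dk}`, each carrying half
#' the pair volume; an equivalent pair gives a single autocorrelation peak
#' at `{2 dj, dj}` with the full volume. Volumes are
#' `kappa^2 * b_eff_sq` in arbitrary units.
#'
#' @param groups list of [proton_site_group()] with shifts set (ppm).
#' @param couplings a [pair_coupling_table()].
#' @param cfg a [spectrum_config()].
#' @return object of class `spectrum_2d`: `axis_1q`, `axis_2q` (ppm grids),
#'   `intensity` matrix (rows = 2Q, cols = 1Q) and the peak list.
#' @export
simulate_2q1q <- function(groups, couplings, cfg = spectrum_config()) {
  pk <- peak_list(groups, couplings, cfg)
  r1 <- range(pk$d1q) + c(-1, 1) * cfg$pad * cfg$lw_1q
  r2 <- range(pk$d2q) + c(-1, 1) * cfg$pad * cfg$lw_2q
  axis_1q <- seq(r1[1], r1[2], length.out = cfg$n_1q)
  axis_2q <- seq(r2[1], r2[2], length.out = cfg$n_2q)
  I <- matrix(0, nrow = cfg$n_2q, ncol = cfg$n_1q)
  for (i in seq_len(nrow(pk))) {
    g1 <- stats::dnorm(axis_1q, pk$d1q[i], cfg$lw_1q)
    g2 <- stats::dnorm(axis_2q, pk$d2q[i], cfg$lw_2q)
    I <- I + pk$vol[i] * outer(g2, g1)
  }
  structure(list(axis_1q = axis_1q, axis_2q = axis_2q, intensity = I,
                 peaks = pk, config = cfg),
            class = "spectrum_2d")
}

#' @export
print.spectrum_2d <- function(x, ...) {
  cat(sprintf("<spectrum_2d> %d x %d grid, 1Q [%.2f, %.2f] ppm, 2Q [%.2f, %.2f] ppm, %d peak(s)\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$axis_1q), max(x$axis_1q), min(x$axis_2q), max(x$axis_2q),
              nrow(x$peaks)))
  invisible(x)
}

#' Nominal integration rectangles from peak positions
#'
#' Builds one rectangle per 2D peak, `half_lw` linewidths wide in each
#' dimension, and collects the rectangles of each site-group pair under the
#' pair id (so summing a cross pair's two rectangles recovers its full
#' volume). Overlapping pairs can be merged downstream via the grouping map.
#'
#' @param groups,couplings,cfg as in [simulate_2q1q()].
#' @param half_lw half-width in linewidth multiples (default 4).
#' @return named list: pair id -> data.frame with `lo_1q`, `hi_1q`,
#'   `lo_2q`, `hi_2q` (one row per peak).
#' @export
auto_regions <- function(groups, couplings, cfg = spectrum_config(),
                         half_lw = 4) {
  pk <- peak_list(groups, couplings, cfg)
  out <- list()
  for (i in seq_len(nrow(pk))) {
    r <- data.frame(lo_1q = pk$d1q[i] - half_lw * cfg$lw_1q,
                    hi_1q = pk$d1q[i] + half_lw * cfg$lw_1q,
                    lo_2q = pk$d2q[i] - half_lw * cfg$lw_2q,
                    hi_2q = pk$d2q[i] + half_lw * cfg$lw_2q)
    out[[pk$pair[i]]] <- rbind(out[[pk$pair[i]]], r)
  }
  out
}

riemann <- function(spec, lo1, hi1, lo2, hi2) {
  dx <- diff(spec$axis_1q[1:2]); dy <- diff(spec$axis_2q[1:2])
  c1 <- which(spec$axis_1q >= lo1 & spec$axis_1q <= hi1)
  c2 <- which(spec$axis_2q >= lo2 & spec$axis_2q <= hi2)
  if (!length(c1) || !length(c2)) stop("empty integration rectangle")
  sum(spec$intensity[c2, c1]) * dx * dy
}

#' Integrate rectangular regions of a 2D spectrum
#'
#' Each region is integrated by a Riemann sum times the grid-cell area, in
#' several jittered replicates emulating independent manual integrations;
#' the reported intensity is the replicate mean. Rectangles of one group
#' are summed (a cross pair's two peaks belong to one group).
#'
#' @param spec a `spectrum_2d`.
#' @param regions named list of rectangle data.frames (see
#'   [auto_regions()]).
#' @param n_replicates replicate integrations per region set (default 3).
#' @param jitter fractional jitter of each rectangle's bounds (default
#'   0.10 of its width); replicates are seeded for reproducibility.
#' @param seed integer seed for the jitter.
#' @return object of class `peak_intensities`: data.frame `id`, `I`,
#'   `I_sd`, `n_rect`, with attribute `I_tot` and the replicate matrix.
#' @export
integrate_rectangles <- function(spec, regions, n_replicates = 3,
                                 jitter = 0.10, seed = 1L) {
  stopifnot(inherits(spec, "spectrum_2d"))
  # warn on overlapping rectangles of different groups (double counting)
  allr <- do.call(rbind, lapply(names(regions), function(nm)
    cbind(regions[[nm]], id = nm)))
  if (nrow(allr) > 1) {
    for (i in 1:(nrow(allr) - 1)) for (j in (i + 1):nrow(allr)) {
      if (allr$id[i] != allr$id[j] &&
          allr$lo_1q[i] < allr$hi_1q[j] && allr$hi_1q[i] > allr$lo_1q[j] &&
          allr$lo_2q[i] < allr$hi_2q[j] && allr$hi_2q[i] > allr$lo_2q[j]) {
        warning("integration rectangles of ", allr$id[i], " and ",
                allr$id[j], " overlap; intensities may double-count")
      }
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- names(regions)
  reps <- matrix(NA_real_, nrow = length(ids), ncol = n_replicates,
                 dimnames = list(ids, NULL))
  for (g in seq_along(ids)) {
    rects <- regions[[g]]
    for (r in seq_len(n_replicates)) {
      tot <- 0
      for (i in seq_len(nrow(rects))) {
        w1 <- rects$hi_1q[i] - rects$lo_1q[i]
        w2 <- rects$hi_2q[i] - rects$lo_2q[i]
        if (w1 <= 0 || w2 <= 0) stop("empty integration rectangle")
        jit <- if (r == 1) c(0, 0, 0, 0) else
          stats::runif(4, -jitter, jitter) * c(w1, w1, w2, w2)
        tot <- tot + riemann(spec,
                             rects$lo_1q[i] + jit[1], rects$hi_1q[i] + jit[2],
                             rects$lo_2q[i] + jit[3], rects$hi_2q[i] + jit[4])
      }
      reps[g, r] <- tot
    }
  }
  I <- rowMeans(reps)
  out <- data.frame(id = ids, I = I,
                    I_sd = apply(reps, 1, stats::sd),
                    n_rect = vapply(regions, nrow, 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "I_tot") <- sum(I)
  attr(out, "replicates") <- reps
  class(out) <- c("peak_intensities", class(out))
  out
}

# save/restore RNG state so seeded integrations do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Experimental fractional intensities from integrated volumes
#'
#' `f = I / sum(retained I)`, with optional merging of overlapped groups
#' (intensities summed before normalization) and exclusion with
#' renormalization: excluded groups are reported on the retained scale but
#' left out of the normalizing sum.
#'
#' @param intens a `peak_intensities` (or data.frame with `id`, `I`).
#' @param grouping named list: merged id -> ids to sum.
#' @param exclude ids (after merging) excluded from normalization.
#' @return a [fraction_set()] with provenance `"NMR"` and attribute `total`
#'   = retained I_tot.
#' @export
nmr_fractions <- function(intens, grouping = NULL, exclude = character(0)) {
  g <- apply_grouping(intens$id, intens$I, grouping)
  fraction_set(g$ids, g$w, excluded = exclude, provenance = "NMR")
}

#' Export a 2D spectrum as a delimited matrix
#'
#' Writes a TSV whose first row holds the 1Q axis and whose first column
#' holds the 2Q axis.
#'
#' @param spec a `spectrum_2d`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  m <- cbind(spec$axis_2q, spec$intensity)
  colnames(m) <- c("d2q_ppm", sprintf("%.5f", spec$axis_1q))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
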