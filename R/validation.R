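# Model-versus-experiment comparison: R^2 statistic, NMR-referenced
# effective distances, per-pair distance deviations and rmsd, and the
# end-to-end validation pipeline.

align_fractions <- function(f_model, f_nmr) {
  rm_ <- retained(f_model); rn <- retained(f_nmr)
  if (!setequal(rm_$id, rn$id))
    stop("retained pair-group ids differ between model and NMR sets: ",
         paste(union(setdiff(rm_$id, rn$id), setdiff(rn$id, rm_$id)),
               collapse = ", "))
  m <- match(rn$id, rm_$id)
  list(id = rn$id, model = rm_$f[m], nmr = rn$f)
}

#' R-squared agreement of model and experimental fractions
#'
#' `R^2 = 1 - sum((f_model - f_nmr)^2) / (N * Var{f_nmr})` with the
#' population variance, so the denominator is the total sum of squares
#' `sum((f_nmr - mean)^2)`. Computed over the retained pair groups common
#' to both sets.
#'
#' @param f_model,f_nmr [fraction_set()] objects with matching retained
#'   ids (at least 2).
#' @return R^2 (<= 1; can be negative for very poor models).
#' @export
r_squared <- function(f_model, f_nmr) {
  al <- align_fractions(f_model, f_nmr)
  if (length(al$id) < 2) stop("R^2 needs at least 2 retained pair groups")
  tss <- sum((al$nmr - mean(al$nmr))^2)
  if (tss <= 0) stop("undefined statistic: zero variance in f_nmr")
  1 - sum((al$model - al$nmr)^2) / tss
}

#' NMR-referenced effective distances
#'
#' Converts experimental fractions into effective distances against a
#' reference structure: `b_eff_sq(NMR) = f_nmr * b_eff_sq(tot, reference)`
#' inserted into the effective-distance formula with the reference
#' multiplicity. These values are biased to the chosen reference structure
#' and serve only to express deviations in pm; they should not be read as
#' absolute distances.
#'
#' @param f_nmr a [fraction_set()] (provenance NMR).
#' @param reference a [fraction_set()] from [model_fractions()] on the
#'   reference structure (its `total` attribute supplies `b_eff_sq(tot)`).
#' @param coupling_table the reference [pair_coupling_table()] supplying
#'   per-pair multiplicities; merged groups use the multiplicity of their
#'   dominant (largest `b_eff_sq`) member.
#' @param grouping the same merge map used to build the fraction sets.
#' @return data.frame `id`, `b_eff_sq_nmr`, `M`, `r_eff_nmr_pm` (Inf
#'   sentinel where `f_nmr` = 0, with a warning).
#' @export
nmr_effective_distances <- function(f_nmr, reference, coupling_table,
                                    grouping = NULL) {
  b_tot <- attr(reference, "total")
  Mmap <- merged_multiplicities(coupling_table, grouping)
  rn <- retained(f_nmr)
  M <- Mmap[rn$id]
  if (any(is.na(M)))
    stop("no multiplicity for id(s): ",
         paste(rn$id[is.na(M)], collapse = ", "))
  b2 <- rn$f * b_tot
  r <- numeric(length(b2))
  for (i in seq_along(b2)) {
    if (b2[i] <= 0) {
      warning("f_nmr = 0 for ", rn$id[i],
              "; infinite-distance sentinel, excluded from rmsd")
      r[i] <- Inf
    } else r[i] <- effective_distance(b_eff_sq = b2[i], M = M[i])
  }
  data.frame(id = rn$id, b_eff_sq_nmr = b2, M = M, r_eff_nmr_pm = r,
             stringsAsFactors = FALSE)
}

merged_multiplicities <- function(coupling_table, grouping = NULL) {
  ids <- coupling_table$pair
  M <- coupling_table$M
  b2 <- coupling_table$b_eff_sq
  out <- stats::setNames(M, ids)
  if (!is.null(grouping)) {
    for (nm in names(grouping)) {
      memb <- grouping[[nm]]
      sel <- ids %in% memb
      if (!any(sel)) stop("grouping id ", nm, " matches no pairs")
      out <- out[!(names(out) %in% memb)]
      out[nm] <- M[sel][which.max(b2[sel])]
    }
  }
  out
}

#' Per-pair distance deviations and rmsd
#'
#' `Delta = r_model - r_nmr` per pair, and the root mean square deviation
#' over the retained set (population mean). Non-finite entries (the
#' infinite-distance sentinel of a zero fraction) are excluded from the
#' rmsd but kept in the table.
#'
#' @param r_model,r_nmr numeric vectors in pm, or data.frames with `id` and
#'   a distance column (`r_eff_pm` / `r_eff_nmr_pm`); ids must match.
#' @param ids optional ids when plain vectors are given.
#' @return list with `table` (id, r_model, r_nmr, delta) and `rmsd_pm`.
#' @export
distance_deviations <- function(r_model, r_nmr, ids = NULL) {
  if (is.data.frame(r_model)) {
    ids <- r_model$id
    rmv <- r_model[[intersect(c("r_eff_pm", "r_model"), names(r_model))[1]]]
  } else rmv <- r_model
  if (is.data.frame(r_nmr)) {
    if (!is.null(ids) && !identical(as.character(ids), as.character(r_nmr$id))) {
      m <- match(ids, r_nmr$id)
      if (any(is.na(m))) stop("mismatched pair ids between distance sets")
      r_nmr <- r_nmr[m, , drop = FALSE]
    }
    rnv <- r_nmr[[intersect(c("r_eff_nmr_pm", "r_eff_pm", "r_nmr"),
                            names(r_nmr))[1]]]
  } else rnv <- r_nmr
  if (length(rmv) != length(rnv)) stop("mismatched distance vectors")
  delta <- rmv - rnv
  ok <- is.finite(delta)
  list(table = data.frame(id = if (is.null(ids)) seq_along(delta) else ids,
                          r_model_pm = rmv, r_nmr_pm = rnv, delta_pm = delta,
                          stringsAsFactors = FALSE),
       rmsd_pm = sqrt(mean(delta[ok]^2)))
}

#' Full structure validation against experimental fractional intensities
#'
#' Runs the whole model pipeline — distance enumeration, effective
#' couplings, model fractions — and scores the structure against an
#' experimental fraction set: R^2, NMR-referenced effective distances,
#' per-pair deviations and rmsd.
#'
#' @param s a [crystal_structure()].
#' @param groups list of [proton_site_group()].
#' @param f_nmr experimental [fraction_set()] (ids must match pair ids
#'   after merging).
#' @param grouping merge map applied to the model pairs (must mirror the
#'   merging used when integrating the experiment).
#' @param exclude ids excluded from normalization on both sides.
#' @param cutoff_pm,mult_tol as in [pair_coupling_table()].
#' @param alpha_label provenance label for the model ("XRD"/"DFT"/other).
#' @return object of class `validation_report`.
#' @export
validate_structure <- function(s, groups, f_nmr, grouping = NULL,
                               exclude = character(0), cutoff_pm = 1000,
                               mult_tol = 0.10, alpha_label = "model") {
  tab <- pair_coupling_table(s, groups, cutoff_pm = cutoff_pm,
                             mult_tol = mult_tol)
  fm <- model_fractions(tab, grouping = grouping, exclude = exclude,
                        provenance = alpha_label)
  R2 <- r_squared(fm, f_nmr)
  nd <- nmr_effective_distances(f_nmr, fm, tab, grouping = grouping)
  rm_ <- retained(fm)
  rmod <- merged_r_eff(tab, grouping)[rm_$id]
  m <- match(nd$id, names(rmod))
  dev <- distance_deviations(as.numeric(rmod[m]), nd$r_eff_nmr_pm,
                             ids = nd$id)
  structure(list(
    R2 = R2,
    N_pairs = nrow(retained(f_nmr)),
    variance = stats::var(retained(f_nmr)$f) *
      (nrow(retained(f_nmr)) - 1) / nrow(retained(f_nmr)),
    fractions = merge_fraction_frames(fm, f_nmr),
    distances = dev$table,
    rmsd_delta_r_pm = dev$rmsd_pm,
    config = list(cutoff_pm = cutoff_pm, mult_tol = mult_tol,
                  grouping = grouping, exclude = exclude,
                  motion = stats::setNames(
                    vapply(groups, `[[`, "", "motion"), group_ids(groups)),
                  alpha_label = alpha_label)
  ), class = "validation_report")
}

merged_r_eff <- function(tab, grouping = NULL) {
  # effective distance per (possibly merged) group: merged groups aggregate
  # b_eff_sq and take the dominant member's multiplicity
  ids <- tab$pair
  out <- stats::setNames(tab$r_eff_pm, ids)
  if (!is.null(grouping)) {
    for (nm in names(grouping)) {
      memb <- grouping[[nm]]
      sel <- ids %in% memb
      b2 <- sum(tab$b_eff_sq[sel])
      M <- tab$M[sel][which.max(tab$b_eff_sq[sel])]
      out <- out[!(names(out) %in% memb)]
      out[nm] <- effective_distance(b_eff_sq = b2, M = M)
    }
  }
  out
}

merge_fraction_frames <- function(fm, fn) {
  m <- match(fm$id, fn$id)
  data.frame(id = fm$id, f_model = fm$f, f_nmr = fn$f[m],
             excluded = fm$excluded, stringsAsFactors = FALSE)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  model: %s | pairs: %d | cutoff: %g pm | mult_tol: %g\n",
              x$config$alpha_label, x$N_pairs, x$config$cutoff_pm,
              x$config$mult_tol))
  cat(sprintf("  R^2 = %.3f | rmsd(Delta r_eff) = %.1f pm\n",
              x$R2, x$rmsd_delta_r_pm))
  tab <- x$distances
  tab$r_model_pm <- round(tab$r_model_pm)
  tab$r_nmr_pm <- round(tab$r_nmr_pm)
  tab$delta_pm <- round(tab$delta_pm)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Full precision is retained in the JSON export; the printed report
#' rounds distances to integer pm and statistics to 3 decimals.
#'
#' @param x a `validation_report`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
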