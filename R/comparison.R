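# Wild-type vs. mutant deltas, convergence reports across independent runs,
# RDC uniform scaling and secondary chemical-shift differencing.

#' Helicity difference report between two variants
#'
#' Per-residue helicity delta `b - a` with propagated uncertainty
#' `sqrt(ua^2 + ub^2)`, window summaries over configured residue windows
#' (defaults: the three transient helices of p53-TAD), and a significance
#' flag: a window is "modulated" when the absolute window-mean delta
#' exceeds `n_sigma` times the combined window uncertainty.  Profile
#' uncertainties follow the independent-run convention of
#' [pool_profiles()]; no multiple-testing correction is applied across the
#' (three) windows.
#'
#' @param a,b `helicity_profile` objects over identical residues (`a` the
#'   reference, e.g. wild type; `b` the variant).
#' @param windows List of inclusive residue windows, default
#'   `list(c(18, 27), c(40, 44), c(48, 52))`.
#' @param n_sigma Flag threshold multiplier (default 1: flag when the
#'   delta exceeds the combined uncertainty itself).
#' @return Object of class `"delta_helicity"`: list with `resno`, `delta`,
#'   `uncertainty`, and `windows`, a data frame with columns `first`,
#'   `last`, `delta`, `uncertainty`, `flagged`.
#' @export
delta_helicity <- function(a, b,
                           windows = list(c(18, 27), c(40, 44), c(48, 52)),
                           n_sigma = 1) {
  check_same_residues(a, b)
  ua <- ifelse(is.na(a$uncertainty), 0, a$uncertainty)
  ub <- ifelse(is.na(b$uncertainty), 0, b$uncertainty)
  delta <- b$fraction - a$fraction
  unc <- sqrt(ua^2 + ub^2)
  wtab <- do.call(rbind, lapply(windows, function(w) {
    sel <- a$resno >= w[1] & a$resno <= w[2]
    if (!any(sel)) stop("window [", w[1], ", ", w[2], "] selects no residues")
    wd <- mean(delta[sel])
    wu <- sqrt(mean(ua[sel])^2 + mean(ub[sel])^2)
    data.frame(first = w[1], last = w[2], delta = wd, uncertainty = wu,
               flagged = abs(wd) > n_sigma * wu)
  }))
  structure(list(resno = a$resno, delta = delta, uncertainty = unc,
                 windows = wtab, labels = c(a = a$backend, b = b$backend)),
            class = "delta_helicity")
}

#' @export
print.delta_helicity <- function(x, ...) {
  cat("Helicity delta report (variant - reference):\n")
  w <- x$windows
  for (k in seq_len(nrow(w)))
    cat(sprintf("  residues %d-%d: delta %+.3f (uncertainty %.3f)%s\n",
                w$first[k], w$last[k], w$delta[k], w$uncertainty[k],
                if (w$flagged[k]) "  [modulated]" else ""))
  invisible(x)
}

#' Convergence diagnostics between two independent runs
#'
#' The agreement pattern used to judge whether two independently started
#' simulations (e.g. folding and control runs) sample the same ensemble:
#' RMSD of the per-residue helicity profiles, Pearson correlation and RMSD
#' of the long-range contact maps, and the histogram overlap of selected
#' inter-residue distance distributions.
#'
#' @param run1,run2 `ensemble` objects over the same topology.
#' @param backend Helix-assignment backend (default `"ca-torsion"`).
#' @param contact_mode Contact-map distance mode (default `"CA"` suits
#'   C-alpha-trace ensembles; use `"min-heavy-atom"` for full ensembles).
#' @param pairs Optional list of residue pairs `c(i, j)` whose distance
#'   distributions are compared by histogram overlap (1 = identical).
#' @return Object of class `"convergence_report"`: list with
#'   `profile_rmsd`, `map_correlation`, `map_rmsd`, `distance_overlap`.
#' @export
convergence_report <- function(run1, run2, backend = "ca-torsion",
                               contact_mode = "CA", pairs = NULL) {
  if (!same_topology(run1, run2))
    stop("runs have different topologies")
  p1 <- helicity_profile(assign_helix(run1, backend), run1$weights,
                         backend = backend)
  p2 <- helicity_profile(assign_helix(run2, backend), run2$weights,
                         backend = backend)
  m1 <- contact_map(run1, mode = contact_mode)
  m2 <- contact_map(run2, mode = contact_mode)
  overlap <- NULL
  if (!is.null(pairs)) {
    overlap <- vapply(pairs, function(pr) {
      d1 <- distance_distribution(run1, pr[1], pr[2])
      d2 <- distance_distribution(run2, pr[1], pr[2])
      nb <- max(length(d1$frequency), length(d2$frequency))
      f1 <- c(d1$frequency, rep(0, nb - length(d1$frequency)))
      f2 <- c(d2$frequency, rep(0, nb - length(d2$frequency)))
      sum(pmin(f1, f2))
    }, numeric(1))
    names(overlap) <- vapply(pairs, function(pr)
      paste0(pr[1], "-", pr[2]), character(1))
  }
  structure(list(profile_rmsd = profile_rmsd(p1, p2),
                 map_correlation = map_correlation(m1, m2),
                 map_rmsd = map_rmsd(m1, m2),
                 distance_overlap = overlap,
                 profiles = list(p1, p2)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence report (run 1 vs run 2):\n")
  cat(sprintf("  helicity profile RMSD: %.4f\n", x$profile_rmsd))
  cat(sprintf("  contact map correlation: %.3f, RMSD: %.4f\n",
              x$map_correlation, x$map_rmsd))
  if (!is.null(x$distance_overlap))
    cat("  distance-distribution overlap:",
        paste(sprintf("%s: %.3f", names(x$distance_overlap),
                      x$distance_overlap), collapse = ", "), "\n")
  invisible(x)
}

#' Uniform scaling of a back-calculated RDC profile
#'
#' Residual dipolar couplings predicted from an ensemble are compared to
#' experiment after one global scale factor.  Returns the least-squares
#' scalar `s` minimizing `sum((s * predicted - experimental)^2)`, i.e.
#' `s = sum(pred * exp) / sum(pred^2)`, the scaled profile and the Pearson
#' correlation.
#'
#' @param predicted,experimental Numeric vectors over the same residues
#'   (NA pairs are dropped).
#' @return List with `scale`, `scaled` (the scaled predicted profile, NA
#'   preserved) and `r` (Pearson correlation on the overlap).
#' @export
rdc_scale_fit <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("predicted and experimental profiles differ in length")
  keep <- !is.na(predicted) & !is.na(experimental)
  p <- predicted[keep]; e <- experimental[keep]
  if (length(p) < 2L) stop("need at least 2 overlapping residues")
  if (all(p == 0)) stop("predicted profile is identically zero")
  s <- sum(p * e) / sum(p * p)
  r <- if (stats::sd(p) == 0 || stats::sd(e) == 0) NA_real_ else
    stats::cor(p, e)
  list(scale = s, scaled = s * predicted, r = r)
}

#' Secondary chemical shifts against a random-coil reference
#'
#' `delta_delta = observed - reference(residue type)`, the standard
#' secondary-shift computation: for Halpha shifts, negative values are the
#' helical signature.  The random-coil reference (e.g. database coil
#' statistics) is supplied by the user as a per-residue-type table.
#'
#' @param observed Data frame with columns `resno`, `aa` (one-letter
#'   residue type) and `shift` (ppm; `NA` allowed and propagated).
#' @param reference Data frame with columns `aa` and `shift`: the coil
#'   reference value per residue type.
#' @return Data frame with columns `resno`, `aa`, `delta`: the secondary
#'   shift per residue.
#' @export
secondary_shift <- function(observed, reference) {
  stopifnot(all(c("resno", "aa", "shift") %in% names(observed)),
            all(c("aa", "shift") %in% names(reference)))
  idx <- match(observed$aa, reference$aa)
  if (anyNA(idx))
    stop("no coil reference for residue type(s): ",
         paste(unique(observed$aa[is.na(idx)]), collapse = ", "))
  data.frame(resno = observed$resno, aa = observed$aa,
             delta = observed$shift - reference$shift[idx])
}
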