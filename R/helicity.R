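# Per-residue helicity: assignment, profiles, substate histograms and
# profile-level convergence metrics.

# alpha-basin windows (degrees); see the methods vignette for rationale
PHI_WINDOW <- c(-100, -30)
PSI_WINDOW <- c(-67, -7)
CA_TORSION_WINDOW <- c(30, 70)
MIN_HELIX_RUN <- 3L

in_window <- function(x, w) !is.na(x) & x > w[1] & x < w[2]

# relabel helical runs shorter than MIN_HELIX_RUN as coil, frame-wise
relabel_short_runs <- function(states, min_run = MIN_HELIX_RUN) {
  t(apply(states, 1L, function(row) {
    r <- rle(row)
    r$values[r$values == 1L & r$lengths < min_run] <- 0L
    inverse.rle(r)
  }))
}

#' Assign per-residue helical states
#'
#' Flags each residue of each frame as helical (1) or coil (0).  Two
#' backends are available: `"phi-psi"` flags residues with backbone dihedrals
#' in the alpha basin (phi in (-100, -30), psi in (-67, -7) degrees;
#' requires N, CA and C atoms), and `"ca-torsion"` flags residues whose
#' C-alpha virtual torsion over atoms i..i+3 lies in (30, 70) degrees,
#' attributing each in-window torsion to its two interior residues i+1 and
#' i+2.  In both backends a residue counts as helical only when it belongs
#' to a run of at least 3 consecutive flagged residues; chain-terminal
#' residues with undefined dihedrals are coil.
#'
#' @param ens An `ensemble`.
#' @param backend `"ca-torsion"` (default, works on C-alpha traces) or
#'   `"phi-psi"`.
#' @return Integer matrix, `n_frames` x `n_residues`, of 0/1 states with
#'   residue numbers as column names.
#' @export
assign_helix <- function(ens, backend = c("ca-torsion", "phi-psi")) {
  backend <- match.arg(backend)
  n <- n_residues(ens)
  flagged <- matrix(0L, n_frames(ens), n)
  if (backend == "ca-torsion") {
    ca <- select_atoms(ens, "CA")
    if (n_residues(ca) < 4L)
      stop("ca-torsion backend needs CA atoms for >= 4 consecutive residues")
    tor <- ca_virtual_torsions(ca)            # frames x (n - 3)
    hit <- in_window(tor, CA_TORSION_WINDOW)
    for (j in seq_len(ncol(hit))) {
      flagged[, j + 1L] <- flagged[, j + 1L] | hit[, j]
      flagged[, j + 2L] <- flagged[, j + 2L] | hit[, j]
    }
  } else {
    need <- c("N", "CA", "C")
    have <- ens$topology$atoms$elety
    for (i in seq_len(n)) {
      at_i <- have[ens$topology$atoms$res_index == i]
      if (!all(need %in% at_i))
        stop("phi-psi backend: residue ", ens$topology$resno[i],
             " lacks one of N, CA, C")
    }
    pp <- backbone_phi_psi(select_atoms(ens, "backbone"))
    flagged[] <- in_window(pp$phi, PHI_WINDOW) &
      in_window(pp$psi, PSI_WINDOW)
  }
  states <- relabel_short_runs(flagged + 0L)
  colnames(states) <- ens$topology$resno
  states
}

#' Per-residue helicity profile
#'
#' The weighted column mean of a binary helical-state matrix: the fraction
#' of the ensemble in which each residue is helical.
#'
#' @param states 0/1 matrix (frames x residues) from [assign_helix()] or the
#'   synthetic generator, with residue numbers as column names.
#' @param weights Frame weights (default uniform); renormalized to sum 1.
#' @param uncertainty Optional per-residue uncertainty to attach (see
#'   [pool_profiles()] for the two-run convention).
#' @param backend Assignment backend recorded as metadata.
#' @return Object of class `"helicity_profile"`: list with `resno`,
#'   `fraction`, `uncertainty`, `n_frames`, `backend`.
#' @export
helicity_profile <- function(states, weights = NULL, uncertainty = NULL,
                             backend = "ca-torsion") {
  states <- as.matrix(states)
  w <- if (is.null(weights)) rep(1 / nrow(states), nrow(states)) else
    normalize_weights(weights, nrow(states))
  fraction <- as.numeric(crossprod(states, w))
  resno <- if (!is.null(colnames(states))) as.integer(colnames(states)) else
    seq_len(ncol(states))
  if (is.null(uncertainty)) uncertainty <- rep(NA_real_, length(fraction))
  structure(list(resno = resno, fraction = fraction,
                 uncertainty = uncertainty, n_frames = nrow(states),
                 backend = backend),
            class = "helicity_profile")
}

#' @export
print.helicity_profile <- function(x, ...) {
  cat("Helicity profile over residues", x$resno[1], "-",
      x$resno[length(x$resno)], "(", x$n_frames, "frames,", x$backend,
      "backend )\n")
  cat(sprintf("  mean helicity %.3f, max %.3f at residue %d\n",
              mean(x$fraction), max(x$fraction),
              x$resno[which.max(x$fraction)]))
  invisible(x)
}

#' @export
plot.helicity_profile <- function(x, ...) {
  graphics::plot(x$resno, x$fraction, type = "h", lwd = 2,
                 xlab = "residue", ylab = "helical fraction",
                 ylim = c(0, max(0.2, max(x$fraction)) * 1.1), ...)
  if (!all(is.na(x$uncertainty)))
    graphics::arrows(x$resno, pmax(0, x$fraction - x$uncertainty),
                     x$resno, x$fraction + x$uncertainty,
                     angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Average two independent-run profiles, with run-difference uncertainty
#'
#' The convergence convention for paired independent simulations (e.g.
#' folding and control runs started from contrasting structures): the
#' reported fraction is the mean of the two runs and the per-residue
#' uncertainty is the absolute difference between them.
#'
#' @param a,b `helicity_profile` objects over the same residues.
#' @return A `helicity_profile` with `uncertainty = |a - b|`.
#' @export
pool_profiles <- function(a, b) {
  check_same_residues(a, b)
  structure(list(resno = a$resno,
                 fraction = (a$fraction + b$fraction) / 2,
                 uncertainty = abs(a$fraction - b$fraction),
                 n_frames = a$n_frames + b$n_frames,
                 backend = a$backend),
            class = "helicity_profile")
}

check_same_residues <- function(a, b) {
  if (!identical(a$resno, b$resno))
    stop("profiles cover different residue ranges")
  invisible(TRUE)
}

#' Mean helicity over an inclusive residue window
#'
#' @param profile A `helicity_profile`.
#' @param first,last Inclusive author residue numbers, e.g. 18 and 27 for
#'   the major transient helix of p53-TAD.
#' @return Unweighted mean of the per-residue fractions over the window.
#' @export
region_mean_helicity <- function(profile, first, last) {
  sel <- profile$resno >= first & profile$resno <= last
  if (!any(sel)) stop("residue window [", first, ", ", last,
                      "] is empty for this profile")
  mean(profile$fraction[sel])
}

#' Root-mean-square difference between two helicity profiles
#'
#' The profile-level convergence metric: sqrt of the mean over residues of
#' squared fraction differences.
#'
#' @param a,b `helicity_profile` objects over identical residues.
#' @return Nonnegative RMSD of the two profiles.
#' @export
profile_rmsd <- function(a, b) {
  check_same_residues(a, b)
  sqrt(mean((a$fraction - b$fraction)^2))
}

#' Helical-substate histogram
#'
#' Each maximal helical run of length >= 3 in a frame contributes that
#' frame's weight to the cell (run start residue, run end residue).  Cell
#' values are weighted per-frame frequencies; their sum equals the mean
#' number of helical segments per frame and may exceed 1.
#'
#' @param states 0/1 state matrix with residue-number column names.
#' @param weights Frame weights (default uniform).
#' @return Object of class `"substate_histogram"`: list with `resno` and
#'   `matrix` (start x end, residue-number dimnames).
#' @export
substate_histogram <- function(states, weights = NULL) {
  states <- as.matrix(states)
  w <- if (is.null(weights)) rep(1 / nrow(states), nrow(states)) else
    normalize_weights(weights, nrow(states))
  resno <- if (!is.null(colnames(states))) as.integer(colnames(states)) else
    seq_len(ncol(states))
  n <- length(resno)
  h <- matrix(0, n, n, dimnames = list(start = resno, end = resno))
  for (f in seq_len(nrow(states))) {
    r <- rle(states[f, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg <- which(r$values == 1L & r$lengths >= MIN_HELIX_RUN)
    for (s in seg) h[starts[s], ends[s]] <- h[starts[s], ends[s]] + w[f]
  }
  structure(list(resno = resno, matrix = h), class = "substate_histogram")
}

#' @export
print.substate_histogram <- function(x, ...) {
  tot <- sum(x$matrix)
  cat("Helical-substate histogram:", sum(x$matrix > 0), "occupied cells,",
      sprintf("%.3f segments/frame\n", tot))
  invisible(x)
}

#' @export
plot.substate_histogram <- function(x, levels = c(0.001, 0.002, 0.004,
                                                  0.008, 0.012, 0.024,
                                                  0.048), ...) {
  graphics::contour(x$resno, x$resno, x$matrix, levels = levels,
                    xlab = "segment start residue",
                    ylab = "segment end residue", ...)
  invisible(x)
}
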