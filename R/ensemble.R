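# Ensemble container: a topology plus frames x (3 * n_atoms) coordinates.
# Coordinates follow the bio3d "xyz" layout (x1, y1, z1, x2, ...), in Angstrom.

#' Construct a conformational ensemble
#'
#' @param topology A `topology` describing the atoms of every frame.
#' @param xyz Numeric matrix, `n_frames` rows by `3 * n_atoms` columns in
#'   bio3d order (x1, y1, z1, x2, ...), coordinates in Angstrom.
#' @param weights Optional nonnegative frame weights; renormalized to sum 1.
#'   Default uniform.
#' @param label Free-text label (e.g. `"wt-folding"`).
#' @return An object of class `"ensemble"`.
#' @export
ensemble <- function(topology, xyz, weights = NULL, label = "") {
  validate_topology(topology)
  xyz <- as.matrix(xyz)
  n_atoms <- nrow(topology$atoms)
  if (ncol(xyz) != 3L * n_atoms)
    stop("xyz has ", ncol(xyz), " columns; topology implies ",
         3L * n_atoms)
  if (nrow(xyz) < 1L)
    stop("an ensemble needs at least one frame")
  if (anyNA(xyz) || any(!is.finite(xyz)))
    stop("ensemble coordinates contain NA or non-finite values")
  if (is.null(weights)) weights <- rep(1 / nrow(xyz), nrow(xyz))
  weights <- normalize_weights(weights, nrow(xyz))
  structure(list(topology = topology, xyz = unname(xyz),
                 weights = weights, label = label),
            class = "ensemble")
}

normalize_weights <- function(w, n) {
  if (length(w) != n) stop("weights length must equal frame count")
  if (any(w < 0)) stop("frame weights must be nonnegative")
  s <- sum(w)
  if (s <= 0) stop("frame weights must not all be zero")
  w / s
}

#' Number of frames in an ensemble
#' @param ens An `ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Coordinates of one frame as an atoms x 3 matrix
#' @param ens An `ensemble`.
#' @param i Frame index (1-based).
#' @return `n_atoms` x 3 numeric matrix.
#' @export
frame_coords <- function(ens, i) {
  stopifnot(i >= 1L, i <= n_frames(ens))
  matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' @export
print.ensemble <- function(x, ...) {
  cat("Ensemble", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ":", n_frames(x), "frames x", nrow(x$topology$atoms), "atoms (",
      n_residues(x), "residues )\n")
  if (!isTRUE(all.equal(x$weights, rep(1 / n_frames(x), n_frames(x)))))
    cat("  non-uniform frame weights\n")
  invisible(x)
}

#' @export
summary.ensemble <- function(object, ...) {
  rg <- radius_of_gyration(object)
  cat("Ensemble summary:", n_frames(object), "frames,",
      n_residues(object), "residues\n")
  cat(sprintf("  radius of gyration: %.2f A (weighted mean), sd %.2f A\n",
              rg$mean, stats::sd(rg$per_frame)))
  invisible(rg)
}

#' Select atoms of an ensemble
#'
#' Restricts an ensemble (and its topology) to an atom subset.  Hydrogens are
#' identified by element and excluded from `"heavy"` selections.
#'
#' @param ens An `ensemble`.
#' @param mode One of `"CA"`, `"backbone"` (N, CA, C), `"heavy"`, `"all"`.
#' @param residues Inclusive author residue-number range `c(first, last)`, or
#'   `NULL` (default) for all residues.
#' @return A new `ensemble` holding only the selected atoms.
#' @export
select_atoms <- function(ens, mode = c("CA", "backbone", "heavy", "all"),
                         residues = NULL) {
  mode <- match.arg(mode)
  top <- ens$topology
  keep <- switch(mode,
    CA = top$atoms$elety == "CA",
    backbone = top$atoms$elety %in% c("N", "CA", "C"),
    heavy = top$atoms$element != "H",
    all = rep(TRUE, nrow(top$atoms)))
  if (!is.null(residues)) {
    ridx <- which(top$resno >= residues[1] & top$resno <= residues[2])
    if (length(ridx) == 0L) stop("residue range selects no residues")
    keep <- keep & top$atoms$res_index %in% ridx
  }
  if (!any(keep)) stop("atom selection is empty")
  if (mode == "CA") {
    ridx_kept <- if (is.null(residues)) seq_len(n_residues(ens)) else
      which(top$resno >= residues[1] & top$resno <= residues[2])
    have <- top$atoms$res_index[keep]
    missing <- setdiff(ridx_kept, have)
    if (length(missing) > 0L)
      stop("missing CA atom for residue(s) ",
           paste(top$resno[missing], collapse = ", "))
  }
  res_kept <- sort(unique(top$atoms$res_index[keep]))
  new_top <- top
  new_top$resno <- top$resno[res_kept]
  new_top$resid <- top$resid[res_kept]
  new_top$atoms <- top$atoms[keep, , drop = FALSE]
  new_top$atoms$res_index <- match(new_top$atoms$res_index, res_kept)
  rownames(new_top$atoms) <- NULL
  cols <- as.vector(rbind(3L * which(keep) - 2L,
                          3L * which(keep) - 1L,
                          3L * which(keep)))
  ensemble(new_top, ens$xyz[, cols, drop = FALSE],
           weights = ens$weights, label = ens$label)
}

#' Subsample frames of an ensemble
#'
#' Keeps frames `first, first + stride, first + 2 * stride, ...` up to `last`
#' (1-based, inclusive), renormalizing frame weights.  The typical use is the
#' production-segment convention of replica-exchange studies: keep the last
#' 4000 snapshots of a run before clustering or map calculations.
#'
#' @param ens An `ensemble`.
#' @param stride Positive integer step between kept frames (default 1).
#' @param first,last Inclusive 1-based frame bounds (defaults: whole run).
#' @return The subsampled `ensemble`.
#' @examples
#' \dontrun{
#' last4000 <- subset_frames(run, first = n_frames(run) - 3999)
#' }
#' @export
subset_frames <- function(ens, stride = 1L, first = 1L, last = n_frames(ens)) {
  stride <- as.integer(stride); first <- as.integer(first)
  last <- as.integer(last)
  if (stride < 1L) stop("stride must be a positive integer")
  if (first < 1L || last > n_frames(ens) || first > last)
    stop("frame range [", first, ", ", last, "] invalid for ",
         n_frames(ens), " frames")
  idx <- seq.int(first, last, by = stride)
  if (length(idx) == 0L) stop("frame subset is empty")
  ensemble(ens$topology, ens$xyz[idx, , drop = FALSE],
           weights = ens$weights[idx], label = ens$label)
}

# shared check used by profile/map comparison functions
same_topology <- function(a, b) {
  identical(a$topology$resno, b$topology$resno) &&
    identical(a$topology$resid, b$topology$resid) &&
    identical(a$topology$atoms$elety, b$topology$atoms$elety)
}
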