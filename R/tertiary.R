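# Long-range structure: contact probability maps, map convergence metrics,
# inter-residue distance distributions, radius of gyration.

#' Residue-residue contact probability map
#'
#' Entry (i, j) is the weighted fraction of frames in which the residues are
#' in contact.  In `"min-heavy-atom"` mode two residues are in contact when
#' their minimal heavy-atom distance is no greater than the cutoff
#' (boundary inclusive; default 4.2 Angstrom).  In `"CA"` mode the C-alpha
#' distance is used (default cutoff 8 Angstrom, an artifact convention for
#' C-alpha-trace ensembles).  Pairs closer in sequence than
#' `min_sequence_separation` are masked `NA` so the map reports long-range
#' structure only.
#'
#' @param ens An `ensemble`.
#' @param cutoff Contact cutoff in Angstrom; default 4.2 for
#'   `"min-heavy-atom"`, 8 for `"CA"`.
#' @param mode `"min-heavy-atom"` or `"CA"`.
#' @param min_sep Minimum sequence separation |i - j| for an entry to be
#'   defined (default 4).
#' @return Object of class `"contact_map"`: list with `resno`, `matrix`
#'   (symmetric, masked below `min_sep`), `cutoff`, `mode`, `min_sep`,
#'   `n_frames`.
#' @export
contact_map <- function(ens, cutoff = NULL,
                        mode = c("min-heavy-atom", "CA"), min_sep = 4L) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "CA") 8 else 4.2
  n <- n_residues(ens)
  w <- ens$weights
  acc <- matrix(0, n, n)
  if (mode == "CA") {
    ca <- select_atoms(ens, "CA")
    if (n_residues(ca) != n)
      stop("CA contact mode requires a CA atom for every residue")
    for (f in seq_len(n_frames(ca))) {
      d <- as.matrix(stats::dist(frame_coords(ca, f)))
      acc <- acc + w[f] * (d <= cutoff)
    }
  } else {
    heavy <- select_atoms(ens, "heavy")
    extra <- setdiff(heavy$topology$atoms$elety, "CA")
    if (length(extra) == 0L)
      stop("min-heavy-atom mode requires heavy atoms beyond CA; ",
           "use mode = \"CA\" for C-alpha traces")
    ri <- heavy$topology$atoms$res_index
    for (f in seq_len(n_frames(heavy))) {
      d <- as.matrix(stats::dist(frame_coords(heavy, f)))
      contact <- d <= cutoff
      # residue-block minimum distance reduces to block-wise any() on contacts
      per_res <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (any(contact[ri == i, ri == j])) {
          per_res[i, j] <- 1
          per_res[j, i] <- 1
        }
      }
      acc <- acc + w[f] * per_res
    }
  }
  diag(acc) <- 0
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  acc[sep < min_sep] <- NA_real_
  structure(list(resno = ens$topology$resno, matrix = acc, cutoff = cutoff,
                 mode = mode, min_sep = as.integer(min_sep),
                 n_frames = n_frames(ens)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  ut <- x$matrix[upper.tri(x$matrix)]
  ut <- ut[!is.na(ut)]
  cat("Contact map (", x$mode, ", cutoff ", x$cutoff, " A, |i-j| >= ",
      x$min_sep, "): ", length(x$resno), " residues, ", x$n_frames,
      " frames\n", sep = "")
  cat(sprintf("  %d pairs with probability >= 0.06 (max %.3f)\n",
              sum(ut >= 0.06), max(ut)))
  invisible(x)
}

#' @export
plot.contact_map <- function(x, levels = seq(0.06, 0.98, by = 0.04), ...) {
  m <- x$matrix
  m[is.na(m)] <- 0
  graphics::contour(x$resno, x$resno, m, levels = levels,
                    xlab = "residue", ylab = "residue", ...)
  invisible(x)
}

check_compatible_maps <- function(a, b) {
  if (!identical(dim(a$matrix), dim(b$matrix)) ||
      !identical(a$resno, b$resno))
    stop("contact maps cover different residues")
  if (a$mode != b$mode || a$cutoff != b$cutoff || a$min_sep != b$min_sep)
    stop("contact maps were computed with different cutoff/mode/mask")
  invisible(TRUE)
}

map_upper_entries <- function(m) {
  v <- m$matrix[upper.tri(m$matrix)]
  v[!is.na(v)]
}

#' Pearson correlation of two contact maps
#'
#' Computed over the unmasked upper-triangle entries, the standard
#' convergence statistic for comparing maps from independent runs.
#'
#' @param a,b `contact_map` objects with identical residues, cutoff, mode
#'   and mask.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
map_correlation <- function(a, b) {
  check_compatible_maps(a, b)
  x <- map_upper_entries(a); y <- map_upper_entries(b)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("contact map has zero variance; correlation undefined")
  stats::cor(x, y)
}

#' Root-mean-square difference of two contact maps
#'
#' @inheritParams map_correlation
#' @return Nonnegative RMSD over unmasked upper-triangle entries.
#' @export
map_rmsd <- function(a, b) {
  check_compatible_maps(a, b)
  sqrt(mean((map_upper_entries(a) - map_upper_entries(b))^2))
}

#' Distribution of an inter-residue C-alpha distance
#'
#' Weighted histogram of the per-frame CA-CA distance between two residues,
#' plus its weighted mean and standard deviation.  `end-to-end` distance is
#' the special case of the first versus last residue.
#'
#' @param ens An `ensemble`.
#' @param i,j Author residue numbers (must differ), or `"end-to-end"` for
#'   `i` to select the terminal pair.
#' @param bin_width Histogram bin width in Angstrom (default 1).
#' @return Object of class `"distance_distribution"`: list with `pair`,
#'   `breaks`, `frequency` (sums to 1), `mean`, `sd`, `distances`.
#' @export
distance_distribution <- function(ens, i, j = NULL, bin_width = 1) {
  if (identical(i, "end-to-end")) {
    i <- ens$topology$resno[1]
    j <- ens$topology$resno[n_residues(ens)]
    pair_label <- "end-to-end"
  } else {
    pair_label <- paste0(i, "-", j)
  }
  if (i == j) stop("distance distribution needs two distinct residues")
  ca <- select_atoms(ens, "CA")
  ii <- res_index_of(ca$topology, i)
  jj <- res_index_of(ca$topology, j)
  di <- ca$xyz[, c(3L * ii - 2L, 3L * ii - 1L, 3L * ii), drop = FALSE] -
    ca$xyz[, c(3L * jj - 2L, 3L * jj - 1L, 3L * jj), drop = FALSE]
  r <- sqrt(rowSums(di * di))
  w <- ca$weights
  breaks <- seq(0, max(r) + bin_width, by = bin_width)
  bin <- findInterval(r, breaks, rightmost.closed = TRUE)
  freq <- as.numeric(tapply(w, factor(bin, levels = seq_len(length(breaks) - 1L)),
                            sum))
  freq[is.na(freq)] <- 0
  m <- sum(w * r)
  structure(list(pair = pair_label, breaks = breaks, frequency = freq,
                 mean = m, sd = sqrt(sum(w * (r - m)^2)), distances = r),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("Distance distribution %s: mean %.2f A, sd %.2f A\n",
              x$pair, x$mean, x$sd))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::plot(mids, x$frequency, type = "l",
                 xlab = "distance (A)", ylab = "frequency",
                 main = x$pair, ...)
  invisible(x)
}

#' Radius of gyration per frame
#'
#' Mass-uniform radius of gyration: the root-mean-square distance of the
#' selected atoms to their centroid, per frame, plus the weighted ensemble
#' mean.
#'
#' @param ens An `ensemble`.
#' @param mode Atom selection (default `"CA"`).
#' @return List with `per_frame` (Angstrom) and `mean`.
#' @export
radius_of_gyration <- function(ens, mode = "CA") {
  sel <- select_atoms(ens, mode)
  nf <- n_frames(sel)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- frame_coords(sel, f)
    cen <- colMeans(x)
    out[f] <- sqrt(mean(rowSums((x - rep(cen, each = nrow(x)))^2)))
  }
  list(per_frame = out, mean = sum(sel$weights * out))
}
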