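# Fixed-radius conformational clustering on superposed C-alpha RMSD.
#
# Algorithm (the package's contract, an order-deterministic approximation of
# the kclust-style fixed-radius schemes used with MMTSB's enscluster):
#   1. Leader pass in frame order: assign each frame to the nearest existing
#      centroid with RMSD <= radius, else found a new cluster with the frame
#      as centroid.
#   2. `refine_passes` rounds of: re-pick each centroid as the member
#      minimizing the maximum RMSD to the other members (minimax member);
#      re-assign every frame to its nearest centroid, founding a new cluster
#      only when a frame exceeds the radius to all existing centroids.
# Ties (equidistant centroids) break toward the lower cluster id.

#' Superposed RMSD between two conformations
#'
#' Least-squares optimal superposition (proper rotation + translation,
#' Kabsch algorithm) followed by the root-mean-square deviation, in Angstrom.
#'
#' @param a,b Numeric `n x 3` coordinate matrices with the same `n >= 3`.
#' @return RMSD in Angstrom after optimal superposition.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' superposed_rmsd(x, x + 5)  # rigid translation: ~0
#' @export
superposed_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 3L) stop("need at least 3 atoms for superposition")
  cpp_kabsch_rmsd(a, b)
}

#' Fixed-radius clustering of an ensemble
#'
#' Partitions frames so every member lies within `radius` Angstrom
#' (superposed C-alpha RMSD) of its cluster centroid frame.  Deterministic
#' given the frame order.  Ensembles are conventionally subsampled to their
#' last 4000 production frames before clustering (see [subset_frames()]).
#'
#' @param ens An `ensemble`; clustering runs on its CA atoms.
#' @param radius Cluster radius in Angstrom (default 5, the conventional
#'   cutoff for a ~60-residue disordered chain).
#' @param refine_passes Rounds of centroid refinement after the leader pass
#'   (default 3).
#' @return An object of class `"cluster_set"`: list with `radius`,
#'   `assignment` (cluster id per frame, dense ids `1..k` sorted by
#'   descending population), `centroid_frames` (frame index per cluster),
#'   `sizes`, `fractions` and `n_frames`.
#' @export
fixed_radius_cluster <- function(ens, radius = 5, refine_passes = 3L) {
  if (radius <= 0) stop("radius must be positive")
  ca <- select_atoms(ens, "CA")
  flat <- ca$xyz
  nf <- nrow(flat)
  natoms <- ncol(flat) / 3L
  coords <- function(i) matrix(flat[i, ], ncol = 3L, byrow = TRUE)

  # 1. leader pass
  centroids <- 1L
  assignment <- integer(nf)
  assignment[1L] <- 1L
  if (nf > 1L) {
    for (i in 2:nf) {
      d <- cpp_rmsd_one_to_many(coords(i), flat[centroids, , drop = FALSE])
      best <- which.min(d)
      if (d[best] <= radius) {
        assignment[i] <- best
      } else {
        centroids <- c(centroids, i)
        assignment[i] <- length(centroids)
      }
    }
  }

  # 2. refinement passes
  for (pass in seq_len(refine_passes)) {
    for (k in seq_along(centroids)) {
      members <- which(assignment == k)
      if (length(members) > 2L) {
        mx <- cpp_rmsd_minimax(flat[members, , drop = FALSE], natoms)
        centroids[k] <- members[which.min(mx)]
      } else if (length(members) > 0L) {
        centroids[k] <- members[1L]
      }
    }
    for (i in seq_len(nf)) {
      d <- cpp_rmsd_one_to_many(coords(i), flat[centroids, , drop = FALSE])
      best <- which.min(d)
      if (d[best] <= radius) {
        assignment[i] <- best
      } else {
        centroids <- c(centroids, i)
        assignment[i] <- length(centroids)
      }
    }
    # drop clusters emptied by re-assignment, keeping ids dense
    occupied <- sort(unique(assignment))
    if (length(occupied) < length(centroids)) {
      centroids <- centroids[occupied]
      assignment <- match(assignment, occupied)
    }
  }

  # order clusters by descending population (stable: earlier id wins ties)
  sizes <- tabulate(assignment, nbins = length(centroids))
  ord <- order(-sizes, seq_along(sizes))
  rank <- match(seq_along(sizes), ord)
  structure(list(radius = radius,
                 assignment = rank[assignment],
                 centroid_frames = centroids[ord],
                 sizes = sizes[ord],
                 fractions = sizes[ord] / nf,
                 n_frames = nf),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Fixed-radius clustering:", length(x$sizes), "clusters of",
      x$n_frames, "frames at", x$radius, "A CA RMSD\n")
  k <- min(4L, length(x$sizes))
  cat(sprintf("  top %d populations: %s\n", k,
              paste(sprintf("%.1f%%", 100 * x$fractions[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Cluster-size band summary
#'
#' Totals the ensemble population held in clusters whose member count falls
#' in each size band, the presentation used for cluster inventories of
#' disordered ensembles (e.g. bands <10, 10-19, ..., 40-49 members).
#'
#' @param cs A `cluster_set`.
#' @param bands List of inclusive `c(lo, hi)` member-count bands; use `Inf`
#'   for an open upper bound.  Bands must not overlap.
#' @param top_k How many top-cluster centroid frame indices to report.
#' @return A list with `table` (data frame: band, n_clusters, percent of
#'   frames) and `top_centroid_frames`.
#' @export
cluster_summary <- function(cs, bands = list(c(1, 9), c(10, 19), c(20, 29),
                                             c(30, 39), c(40, 49),
                                             c(50, Inf)),
                            top_k = 4L) {
  b <- do.call(rbind, lapply(bands, function(x) as.numeric(x[1:2])))
  if (any(b[, 1] > b[, 2])) stop("band lo > hi")
  ord <- order(b[, 1])
  if (nrow(b) > 1L && any(b[ord, 1][-1] <= b[ord, 2][-nrow(b)]))
    stop("size bands overlap")
  percent <- n_cl <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    in_band <- cs$sizes >= b[i, 1] & cs$sizes <= b[i, 2]
    n_cl[i] <- sum(in_band)
    percent[i] <- 100 * sum(cs$sizes[in_band]) / cs$n_frames
  }
  list(table = data.frame(
         band = sprintf("%g-%g", b[, 1], b[, 2]),
         n_clusters = n_cl, percent = percent,
         stringsAsFactors = FALSE),
       top_centroid_frames =
         cs$centroid_frames[seq_len(min(top_k, length(cs$sizes)))])
}
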