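# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: different formulas, different algorithms.

# --- closed-form expected helicity after the >=3-run relabeling -------------
# For independent Bernoulli sites, P(position k helical after relabeling)
# = sum over runs [a, b] containing k with length >= 3 of
#   P(exactly that run) = prod(p[a:b]) * (1 - p[a-1]) * (1 - p[b+1]),
# with boundary factors 1 at the chain ends.
oracle_run_helicity <- function(p) {
  n <- length(p)
  out <- numeric(n)
  pad <- c(0, p, 0)
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (b - a + 1 < 3) next
      pr <- prod(p[a:b]) * (1 - pad[a]) * (1 - pad[b + 2])
      if (pr > 0) out[a:b] <- out[a:b] + pr
    }
  }
  out
}

# --- brute-force contact map ------------------------------------------------
oracle_contact_map <- function(ens, cutoff, mode, min_sep) {
  top <- ens$topology
  n <- length(top$resno)
  out <- matrix(0, n, n)
  heavy <- top$atoms$element != "H"
  for (f in seq_len(nrow(ens$xyz))) {
    x <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (mode == "CA") {
          ai <- which(top$atoms$res_index == i & top$atoms$elety == "CA")
          aj <- which(top$atoms$res_index == j & top$atoms$elety == "CA")
        } else {
          ai <- which(top$atoms$res_index == i & heavy)
          aj <- which(top$atoms$res_index == j & heavy)
        }
        dmin <- Inf
        for (a in ai) for (b in aj) {
          d <- sqrt(sum((x[a, ] - x[b, ])^2))
          if (d < dmin) dmin <- d
        }
        if (dmin <= cutoff) {
          out[i, j] <- out[i, j] + ens$weights[f]
          out[j, i] <- out[j, i] + ens$weights[f]
        }
      }
    }
  }
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  out[sep < min_sep] <- NA_real_
  diag(out) <- NA_real_
  out
}

# --- quaternion (Horn) superposition RMSD -----------------------------------
# Independent of the SVD-based Kabsch path in the package.
oracle_superposed_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  M <- t(a) %*% b
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lambda) / nrow(a)
  sqrt(max(msd, 0))
}

# --- PRE scalar oracle ------------------------------------------------------
# Written as a direct transcription of the intensity-ratio equation with
# explicit unit handling, kept separate from the package implementation.
oracle_pre_ratio <- function(r_angstrom,
                             K = 1.23e-32,     # cm^6 s^-2
                             tau_c = 3.3e-9,   # s
                             nu_H = 600e6,     # Hz
                             R2 = 16,          # s^-1
                             t = 9.8e-3,       # s
                             angular = TRUE) {
  r_cm <- r_angstrom * 1e-8
  omega <- if (angular) 2 * pi * nu_H else nu_H
  sdens <- 4 * tau_c + 3 * tau_c / (1 + (omega * tau_c)^2)
  R2sp <- K * sdens / r_cm^6
  (R2 * exp(-R2sp * t)) / (R2 + R2sp)
}

# --- independent fixed-radius clusterer (leader + minimax refinement) -------
oracle_cluster <- function(frames, radius, refine_passes = 3) {
  # frames: list of n x 3 matrices
  nf <- length(frames)
  rmsd <- function(i, j) oracle_superposed_rmsd(frames[[i]], frames[[j]])
  centroids <- 1L
  assign <- integer(nf)
  assign[1] <- 1L
  for (f in seq_len(nf)[-1]) {
    d <- vapply(centroids, function(cc) rmsd(f, cc), numeric(1))
    if (min(d) <= radius) assign[f] <- which.min(d)
    else { centroids <- c(centroids, f); assign[f] <- length(centroids) }
  }
  for (p in seq_len(refine_passes)) {
    for (k in seq_along(centroids)) {
      mem <- which(assign == k)
      if (length(mem) > 2) {
        mx <- vapply(mem, function(i)
          max(vapply(setdiff(mem, i), function(j) rmsd(i, j),
                     numeric(1))), numeric(1))
        centroids[k] <- mem[which.min(mx)]
      } else if (length(mem) > 0) centroids[k] <- mem[1]
    }
    for (f in seq_len(nf)) {
      d <- vapply(centroids, function(cc) rmsd(f, cc), numeric(1))
      if (min(d) <= radius) assign[f] <- which.min(d)
      else { centroids <- c(centroids, f); assign[f] <- length(centroids) }
    }
    occ <- sort(unique(assign))
    centroids <- centroids[occ]
    assign <- match(assign, occ)
  }
  sizes <- tabulate(assign, length(centroids))
  ord <- order(-sizes, seq_along(sizes))
  list(assign = match(assign, ord), sizes = sizes[ord])
}

# --- shared fixtures --------------------------------------------------------

make_heavy_top <- function(n) {
  # tiny residues with CA + CB heavy atoms + one hydrogen
  top <- topology(strrep("A", n))
  top$atoms <- data.frame(
    elety = rep(c("CA", "CB", "HA"), n),
    res_index = rep(seq_len(n), each = 3),
    element = rep(c("C", "C", "H"), n),
    stringsAsFactors = FALSE)
  top
}

random_heavy_ens <- function(n_res, n_frames, spread = 6) {
  top <- make_heavy_top(n_res)
  frames <- lapply(seq_len(n_frames), function(f) {
    base <- matrix(rnorm(n_res * 3, sd = spread), n_res, 3)
    coords <- matrix(NA_real_, 3 * n_res, 3)
    for (r in seq_len(n_res)) {
      coords[3 * r - 2, ] <- base[r, ]
      coords[3 * r - 1, ] <- base[r, ] + rnorm(3, sd = 1)
      coords[3 * r, ] <- base[r, ] + rnorm(3, sd = 1)
    }
    coords
  })
  w <- runif(n_frames); w <- w / sum(w)
  make_ens(frames, top, weights = w)
}

# --- geometric fixtures -----------------------------------------------------
# Ideal alpha-helix C-alpha trace from the cylindrical parametrization
# (radius 2.30 A, rise 1.50 A/residue, 100 deg/residue): an independent
# construction route from the internal-coordinate builder.
ideal_helix_ca <- function(n) {
  t <- (seq_len(n) - 1) * 100 * pi / 180
  # clockwise viewed down +z while rising: right-handed helix
  cbind(2.30 * cos(t), -2.30 * sin(t), 1.50 * (seq_len(n) - 1))
}

# Fully extended C-alpha trace (all atoms on a line, 3.8 A apart).
extended_ca <- function(n) cbind(3.8 * (seq_len(n) - 1), 0, 0)

# Ideal backbone (N-CA-C) helix / extended chain built with an independent
# little NeRF of its own.
tiny_place <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- (C - B) / sqrt(sum((C - B)^2))
  nv <- pracma_cross(B - A, bc); nv <- nv / sqrt(sum(nv^2))
  mv <- pracma_cross(nv, bc)
  C - r * cos(th) * bc + r * sin(th) * cos(ta) * mv - r * sin(th) * sin(ta) * nv
}
pracma_cross <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

backbone_chain_ca_ens <- function(n, phi, psi) {
  # returns flattened frame (1 x 9n) of an N-CA-C chain with constant
  # phi/psi, built independently of the package growers
  atoms <- matrix(NA_real_, 3 * n, 3)
  atoms[1, ] <- c(0, 0, 0)
  atoms[2, ] <- c(1.458, 0, 0)
  th <- 111 * pi / 180
  atoms[3, ] <- c(1.458 - 1.525 * cos(th), 1.525 * sin(th), 0)
  bl <- c(N = 1.329, CA = 1.458, C = 1.525)
  ba <- c(N = 116.2, CA = 121.7, C = 111.0)
  for (a in 4:(3 * n)) {
    res <- (a - 1) %/% 3 + 1
    kind <- c("N", "CA", "C")[(a - 1) %% 3 + 1]
    tau <- switch(kind, N = psi, CA = 180, C = phi)
    atoms[a, ] <- tiny_place(atoms[a - 3, ], atoms[a - 2, ], atoms[a - 1, ],
                             bl[kind], ba[kind], tau)
  }
  atoms
}

# Build an ensemble object directly from a list of per-frame atom matrices.
make_ens <- function(coord_list, top, weights = NULL) {
  xyz <- do.call(rbind, lapply(coord_list, function(x)
    as.vector(t(x))))
  ensemble(top, xyz, weights = weights)
}

# Random rigid transform of an n x 3 matrix.
rigid_transform <- function(x) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  x %*% t(R) + matrix(rnorm(3, sd = 10), nrow(x), 3, byrow = TRUE)
}

# Planted-partition ensemble: K well-separated reference conformations with
# per-frame Gaussian jitter.
planted_ensemble <- function(sizes, jitter_sd = 0.2, n_res = 20) {
  half <- n_res %/% 2
  lshape <- rbind(cbind(3.8 * (seq_len(half) - 1), 0, 0),
                  cbind(3.8 * (half - 1),
                        3.8 * seq_len(n_res - half), 0))
  refs <- list(ideal_helix_ca(n_res), extended_ca(n_res), lshape)
  refs <- refs[seq_along(sizes)]
  top <- topology(strrep("A", n_res))
  frames <- list()
  labels <- integer(0)
  for (k in seq_along(sizes)) {
    for (r in seq_len(sizes[k])) {
      frames[[length(frames) + 1L]] <-
        refs[[k]] + matrix(rnorm(3 * n_res, sd = jitter_sd), n_res, 3)
      labels <- c(labels, k)
    }
  }
  ord <- sample(seq_along(frames))   # interleave the conformers
  list(ens = make_ens(frames[ord], top), labels = labels[ord])
}
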