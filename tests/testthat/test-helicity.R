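test_that("canonical geometries are assigned helix / coil by both backends", {
  n <- 12
  # ideal alpha helix CA trace (cylindrical construction, independent route)
  ens_h <- make_ens(list(ideal_helix_ca(n)), topology(strrep("A", n)))
  st <- assign_helix(ens_h, "ca-torsion")
  expect_true(all(st[1, 2:(n - 1)] == 1L))   # interior residues helical
  expect_true(all(st[1, c(1, n)] == 0L))     # terminal dihedrals undefined

  # fully extended chain: all coil (torsion undefined on a line is NaN ->
  # coil); use a slightly kinked extended chain to keep torsions defined
  ext <- backbone_chain_ca_ens(n, 180, 180)
  top_bb <- topology(strrep("A", n), backbone_mode = "N-CA-C")
  ens_e <- make_ens(list(ext), top_bb)
  expect_true(all(assign_helix(ens_e, "phi-psi") == 0L))

  # ideal helical backbone phi = -62, psi = -41
  hel <- backbone_chain_ca_ens(n, -62, -41)
  ens_hb <- make_ens(list(hel), top_bb)
  st_bb <- assign_helix(ens_hb, "phi-psi")
  expect_true(all(st_bb[1, 2:(n - 1)] == 1L))
  expect_true(all(st_bb[1, c(1, n)] == 0L))
  # and its CA trace is helical under the ca-torsion backend too
  st_ca <- assign_helix(select_atoms(ens_hb, "CA"), "ca-torsion")
  expect_true(all(st_ca[1, 3:(n - 2)] == 1L))
})

test_that("runs shorter than 3 residues are relabeled coil", {
  # H,H,C,H,H pattern around a coil gap: all relabeled coil
  states <- matrix(c(1L, 1L, 0L, 1L, 1L), 1)
  expect_true(all(idpens:::relabel_short_runs(states) == 0L))
  states2 <- matrix(c(0L, 1L, 1L, 1L, 0L, 1L, 1L, 0L), 1)
  expect_equal(as.integer(idpens:::relabel_short_runs(states2)),
               c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
})

test_that("helicity profiles are weighted column means", {
  st <- rbind(c(1L, 1L, 1L, 0L), c(0L, 1L, 1L, 1L))
  colnames(st) <- 5:8
  prof <- helicity_profile(st)
  expect_equal(prof$fraction, c(0.5, 1, 1, 0.5))
  expect_equal(prof$resno, 5:8)

  # all mass on one frame reproduces that frame's binary row
  prof1 <- helicity_profile(st, weights = c(1, 0))
  expect_equal(prof1$fraction, as.numeric(st[1, ]))

  allh <- helicity_profile(matrix(1L, 3, 4))
  expect_equal(allh$fraction, rep(1, 4))
})

test_that("region means average the window and validate the range", {
  p <- structure(list(resno = 18:19, fraction = c(0.2, 0.0),
                      uncertainty = c(NA_real_, NA_real_), n_frames = 10,
                      backend = "ca-torsion"), class = "helicity_profile")
  expect_equal(region_mean_helicity(p, 18, 19), 0.10)
  expect_equal(region_mean_helicity(p, 18, 18), 0.20)
  expect_error(region_mean_helicity(p, 30, 40), "empty")
})

test_that("profile RMSD is a metric and matches constant offsets", {
  set.seed(1)
  mk <- function(f) structure(
    list(resno = 1:20, fraction = f, uncertainty = rep(NA_real_, 20),
         n_frames = 1, backend = "ca-torsion"), class = "helicity_profile")
  a <- mk(runif(20, 0, 0.3)); b <- mk(runif(20, 0, 0.3))
  c3 <- mk(runif(20, 0, 0.3))
  expect_equal(profile_rmsd(a, a), 0)
  expect_equal(profile_rmsd(a, b), profile_rmsd(b, a))
  expect_lte(profile_rmsd(a, c3),
             profile_rmsd(a, b) + profile_rmsd(b, c3))
  off <- mk(a$fraction + 0.014)
  expect_equal(profile_rmsd(a, off), 0.014)
  shifted <- mk(runif(20, 0, 0.3)); shifted$resno <- 2:21
  expect_error(profile_rmsd(a, shifted), "residue")
})

test_that("two independent draws agree within the binomial bound", {
  s1 <- wt_like_spec(n_frames = 4000, seed = 21)
  s2 <- wt_like_spec(n_frames = 4000, seed = 22)
  p1 <- helicity_profile(sample_states(s1))
  p2 <- helicity_profile(sample_states(s2))
  pbar <- (p1$fraction + p2$fraction) / 2
  bound <- 3 * sqrt(mean(2 * pbar * (1 - pbar) / 4000))
  expect_lt(profile_rmsd(p1, p2), bound)
})

test_that("substate histogram counts maximal runs per frame", {
  st <- matrix(0L, 1, 61); colnames(st) <- 1:61
  st[1, 18:27] <- 1L
  h <- substate_histogram(st)
  expect_equal(h$matrix[18, 27], 1)
  expect_equal(sum(h$matrix), 1)

  # two disjoint runs in one frame: two cells, total mass 2
  st2 <- matrix(0L, 1, 61); colnames(st2) <- 1:61
  st2[1, c(18:27, 40:44)] <- 1L
  h2 <- substate_histogram(st2)
  expect_equal(h2$matrix[18, 27], 1)
  expect_equal(h2$matrix[40, 44], 1)
  expect_equal(sum(h2$matrix), 2)
})

test_that("substate cell sum equals mean segments per frame", {
  spec <- wt_like_spec(n_frames = 500, seed = 17)
  st <- sample_states(spec)
  h <- substate_histogram(st)
  # independent run-length-encoding count of segments per frame
  segs <- apply(st, 1, function(row) {
    r <- rle(row)
    sum(r$values == 1L & r$lengths >= 3)
  })
  expect_equal(sum(h$matrix), mean(segs))
  # mass concentrates in the rectangles of the two propensity blocks
  inside <- sum(h$matrix[18:27, 18:27]) + sum(h$matrix[40:44, 40:44]) +
    sum(h$matrix[48:52, 48:52])
  expect_equal(sum(h$matrix), inside)
})

test_that("pooled two-run profiles carry the run-difference uncertainty", {
  s1 <- wt_like_spec(n_frames = 800, seed = 31)
  s2 <- wt_like_spec(n_frames = 800, seed = 32)
  p1 <- helicity_profile(sample_states(s1))
  p2 <- helicity_profile(sample_states(s2))
  pool <- pool_profiles(p1, p2)
  expect_equal(pool$fraction, (p1$fraction + p2$fraction) / 2)
  expect_equal(pool$uncertainty, abs(p1$fraction - p2$fraction))
})

test_that("assignment preconditions produce named hard errors", {
  ens <- make_ens(list(ideal_helix_ca(10)), topology(strrep("A", 10)))
  expect_error(assign_helix(ens, "phi-psi"), "lacks one of N, CA, C")
  small <- make_ens(list(ideal_helix_ca(3)), topology("AAA"))
  expect_error(assign_helix(small, "ca-torsion"), ">= 4")
})
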