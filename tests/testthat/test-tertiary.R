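test_that("contact boundary is inclusive: distance == cutoff counts", {
  top <- topology("AAAAAAAA")
  x <- extended_ca(8)
  x[8, ] <- x[1, ] + c(4.2, 0, 0)   # exactly at the 4.2 A cutoff... via CA
  ens <- make_ens(list(x), top)
  cm <- contact_map(ens, cutoff = 4.2, mode = "CA", min_sep = 4)
  expect_equal(cm$matrix[1, 8], 1)
  just_over <- x; just_over[8, 1] <- just_over[8, 1] + 1e-9
  cm2 <- contact_map(make_ens(list(just_over), top), cutoff = 4.2,
                     mode = "CA", min_sep = 4)
  expect_equal(cm2$matrix[1, 8], 0)
})

test_that("contact maps equal the brute-force oracle on random toys", {
  set.seed(101)
  for (trial in 1:8) {
    n_res <- sample(4:8, 1)
    nf <- sample(5:20, 1)
    ens <- random_heavy_ens(n_res, nf)
    for (mode in c("CA", "min-heavy-atom")) {
      cutoff <- if (mode == "CA") 8 else 4.2
      cm <- contact_map(ens, cutoff = cutoff, mode = mode, min_sep = 2)
      ref <- oracle_contact_map(ens, cutoff, mode, 2)
      expect_equal(cm$matrix[upper.tri(cm$matrix)],
                   ref[upper.tri(ref)], tolerance = 1e-12)
    }
  }
})

test_that("fully extended chains have empty long-range maps", {
  ens <- make_ens(list(extended_ca(12)), topology(strrep("A", 12)))
  cm <- contact_map(ens, mode = "CA", min_sep = 4)
  expect_true(all(cm$matrix[!is.na(cm$matrix)] == 0))
})

test_that("contact probability is nondecreasing in the cutoff", {
  set.seed(7)
  ens <- random_heavy_ens(6, 30)
  cuts <- c(4, 6, 8, 10, 14)
  maps <- lapply(cuts, function(cc)
    contact_map(ens, cutoff = cc, mode = "CA", min_sep = 2)$matrix)
  for (k in seq_along(cuts)[-1]) {
    d <- maps[[k]] - maps[[k - 1]]
    expect_true(all(d[!is.na(d)] >= 0))
  }
})

test_that("map comparison statistics behave as metrics with hard errors", {
  set.seed(3)
  ens <- random_heavy_ens(8, 40)
  a <- contact_map(ens, mode = "CA", min_sep = 2)
  expect_equal(map_correlation(a, a), 1)
  expect_equal(map_rmsd(a, a), 0)
  b <- a
  b$matrix <- 1 - a$matrix
  expect_equal(map_correlation(a, b), -1)
  off <- a
  off$matrix <- a$matrix + 0.016
  expect_equal(map_rmsd(a, off), 0.016)
  # incompatible maps refuse to compare
  other <- contact_map(ens, cutoff = 10, mode = "CA", min_sep = 2)
  expect_error(map_correlation(a, other), "different cutoff")
  flat <- a
  flat$matrix[] <- 0.5
  expect_error(map_correlation(a, flat), "zero variance")
})

test_that("two independent biased draws give near-identical contact maps", {
  spec <- calibrate_contact_strengths(
    wt_like_spec(n_frames = 2000, seed = 41, contacts = TRUE))
  specB <- spec
  specB$seed <- 42L
  mA <- contact_map(generate_ensemble(spec)$ensemble, mode = "CA")
  mB <- contact_map(generate_ensemble(specB)$ensemble, mode = "CA")
  expect_gt(map_correlation(mA, mB), 0.9)
  ut <- upper.tri(mA$matrix)
  pbar <- (mA$matrix[ut] + mB$matrix[ut]) / 2
  pbar <- pbar[!is.na(pbar)]
  expect_lt(map_rmsd(mA, mB), 3 * sqrt(mean(2 * pbar * (1 - pbar) / 2000)))
})

test_that("distance distributions match brute-force moments", {
  set.seed(11)
  ens <- random_heavy_ens(10, 50)
  dd <- distance_distribution(ens, 2, 9, bin_width = 0.5)
  # brute-force weighted mean over frames
  ref <- 0
  for (f in 1:50) {
    x <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    ref <- ref + ens$weights[f] *
      sqrt(sum((x[3 * 2 - 2, ] - x[3 * 9 - 2, ])^2))
  }
  expect_equal(dd$mean, ref, tolerance = 1e-9)
  expect_equal(sum(dd$frequency), 1, tolerance = 1e-12)
  expect_true(all(diff(dd$breaks) > 0))
  expect_error(distance_distribution(ens, 3, 3), "distinct")
})

test_that("rigid ensembles concentrate in a single distance bin", {
  base <- ideal_helix_ca(15)
  frames <- lapply(1:10, function(i) base + matrix(i * 5, 15, 3))
  ens <- make_ens(frames, topology(strrep("A", 15)))
  dd <- distance_distribution(ens, 1, 15, bin_width = 1)
  expect_equal(sum(dd$frequency > 0), 1L)
  expect_equal(dd$sd, 0, tolerance = 1e-9)
})

test_that("helical i,i+3 distances cluster near the one-turn separation", {
  spec <- synthetic_spec(helix_propensity = list("18-27" = 1),
                         n_frames = 100, seed = 19)
  ens <- generate_ensemble(spec)$ensemble
  dd <- distance_distribution(ens, 21, 24)
  # ideal alpha-helix CA i,i+3 distance is ~5 A
  expect_lt(abs(dd$mean - 5), 0.8)
})

test_that("radius of gyration matches closed forms and brute force", {
  top2 <- topology("AA")
  two <- make_ens(list(rbind(c(0, 0, 0), c(2, 0, 0))), top2)
  expect_equal(radius_of_gyration(two)$mean, 1.0)
  coincident <- make_ens(list(rbind(c(1, 1, 1), c(1, 1, 1))), top2)
  expect_equal(radius_of_gyration(coincident)$mean, 0)
  set.seed(13)
  ens <- random_heavy_ens(7, 5)
  rg <- radius_of_gyration(ens, mode = "all")
  x <- matrix(ens$xyz[3, ], ncol = 3, byrow = TRUE)
  cen <- colMeans(x)
  ref <- sqrt(mean(colSums((t(x) - cen)^2)))
  expect_equal(rg$per_frame[3], ref, tolerance = 1e-9)
})

test_that("min-heavy-atom mode refuses C-alpha traces", {
  ens <- make_ens(list(extended_ca(8)), topology(strrep("A", 8)))
  expect_error(contact_map(ens, mode = "min-heavy-atom"), "heavy atoms")
})
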