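test_that("degenerate propensities give all-coil / segment-only helicity", {
  spec0 <- synthetic_spec(helix_propensity = 0, n_frames = 20, seed = 1)
  expect_true(all(sample_states(spec0) == 0L))

  spec1 <- synthetic_spec(helix_propensity = list("18-27" = 1),
                          n_frames = 20, seed = 1)
  st <- sample_states(spec1)
  expect_true(all(st[, 18:27] == 1L))
  expect_true(all(st[, -(18:27)] == 0L))
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- wt_like_spec(n_frames = 60, seed = 7)
  g1 <- generate_ensemble(spec)
  g2 <- generate_ensemble(spec)
  expect_identical(g1$ensemble$xyz, g2$ensemble$xyz)
  expect_identical(g1$ground_truth$states, g2$ground_truth$states)

  g3 <- generate_ensemble(wt_like_spec(n_frames = 60, seed = 8))
  expect_false(identical(g1$ensemble$xyz, g3$ensemble$xyz))
})

test_that("a single-frame spec yields a consistent ground truth", {
  spec <- synthetic_spec(helix_propensity = list("18-27" = 0.5),
                         n_frames = 1, seed = 3)
  gen <- generate_ensemble(spec)
  expect_equal(n_frames(gen$ensemble), 1L)
  expect_equal(gen$ground_truth$helicity,
               colMeans(gen$ground_truth$states))
})

test_that("sampled helicity matches the exact run-rule expectation", {
  # 10-site segment at propensity 0.10, no cooperativity: compare the
  # realized mean helicity against the closed-form run-probability oracle
  spec <- synthetic_spec(helix_propensity = list("18-27" = 0.10),
                         n_frames = 4000, seed = 11)
  st <- sample_states(spec)
  p_full <- spec$helix_propensity
  expected <- oracle_run_helicity(p_full)
  got <- colMeans(st)
  seg <- 18:27
  se <- sqrt(mean(expected[seg] * (1 - expected[seg])) / 4000)
  expect_lt(abs(mean(got[seg]) - mean(expected[seg])), 3 * se)
  # and the package's own enumeration agrees with the closed form
  expect_equal(expected_helicity_exact(p_full), expected, tolerance = 1e-12)
})

test_that("cooperativity lengthens runs at matched enumeration expectation", {
  p <- numeric(20); p[6:15] <- 0.2
  sim <- synthetic_spec(topology(strrep("A", 20)),
                        helix_propensity = p, cooperativity = 1.5,
                        n_frames = 6000, seed = 5)
  st <- sample_states(sim)
  exp_c <- expected_helicity_exact(p, cooperativity = 1.5)
  se <- sqrt(mean(exp_c[6:15] * (1 - exp_c[6:15])) / 6000)
  expect_lt(abs(mean(colMeans(st)[6:15]) - mean(exp_c[6:15])), 3 * se)
  # cooperative sampling carries more helicity than independent sampling
  exp_0 <- expected_helicity_exact(p, cooperativity = 0)
  expect_gt(mean(exp_c[6:15]), mean(exp_0[6:15]))
})

test_that("propensity calibration inverts the run-rule expectation", {
  p <- propensity_for_helicity(0.10, 10)
  expect_equal(mean(oracle_run_helicity(rep(p, 10))), 0.10,
               tolerance = 1e-6)
  expect_gt(p, 0.10)  # the run rule erodes raw propensity
})

test_that("all-helical state places residues on ideal helix geometry", {
  spec <- synthetic_spec(topology(strrep("A", 20)), helix_propensity = 1,
                         n_frames = 3, seed = 2, torsion_jitter = 0)
  ens <- build_coordinates(sample_states(spec), spec)
  x <- frame_coords(ens, 1)
  e2e <- sqrt(sum((x[20, ] - x[1, ])^2))
  expect_lt(abs(e2e - 1.5 * 19) / (1.5 * 19), 0.15)  # ~1.5 A rise/residue
  # i,i+1 virtual bonds all 3.8 A
  bonds <- sqrt(rowSums((x[-1, ] - x[-20, ])^2))
  expect_equal(bonds, rep(3.8, 19), tolerance = 1e-6)
})

test_that("excluded volume holds in every accepted frame", {
  spec <- synthetic_spec(helix_propensity = 0, n_frames = 100, seed = 6,
                         excluded_volume_radius = 4.0)
  ens <- build_coordinates(sample_states(spec), spec)
  for (f in c(1, 50, 100)) {
    x <- frame_coords(ens, f)
    d <- as.matrix(dist(x))
    sep <- abs(outer(1:61, 1:61, "-"))
    expect_gte(min(d[sep >= 3]), 4.0)
  }
})

test_that("calibrated contact bias realizes its target frequency", {
  spec <- synthetic_spec(
    helix_propensity = 0,
    contact_biases = data.frame(i = 10, j = 50, target = 0.15),
    n_frames = 4000, seed = 5)
  expect_error(build_coordinates(sample_states(spec), spec), "calibrate")
  spec <- calibrate_contact_strengths(spec)
  gen <- generate_ensemble(spec)
  expect_lt(abs(gen$ground_truth$contact_frequencies - 0.15), 0.05)
})

test_that("realized contact frequency increases with bias strength", {
  base <- synthetic_spec(
    helix_propensity = 0,
    contact_biases = data.frame(i = 20, j = 30, target = 0.2,
                                strength = 0),
    n_frames = 800, seed = 9)
  freqs <- vapply(c(0, 1.5, 3), function(s) {
    sp <- base
    sp$contact_biases$strength <- s
    generate_ensemble(sp)$ground_truth$contact_frequencies
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
})

test_that("wild-type-like preset is helical only in its three segments", {
  gen <- generate_ensemble(wt_like_spec(n_frames = 800, seed = 12))
  h <- gen$ground_truth$helicity
  inside <- c(18:27, 40:44, 48:52)
  expect_true(all(h[inside] > 0))
  expect_true(all(h[-inside] == 0))
})

test_that("ground truth equals the ca-torsion assignment on built frames", {
  # zero torsion jitter: exact by construction
  spec <- wt_like_spec(n_frames = 150, seed = 13)
  spec$torsion_jitter <- 0
  gen <- generate_ensemble(spec)
  st <- assign_helix(gen$ensemble, "ca-torsion")
  expect_identical(unname(st), unname(gen$ground_truth$states))
  # default jitter: helical torsions stay inside the detection window,
  # coil torsions are excluded from it, so agreement remains exact
  spec2 <- wt_like_spec(n_frames = 150, seed = 14)
  gen2 <- generate_ensemble(spec2)
  st2 <- assign_helix(gen2$ensemble, "ca-torsion")
  expect_identical(unname(st2), unname(gen2$ground_truth$states))
})

test_that("impossible constraints trip the rejection-rate guard", {
  # an 11 A exclusion radius exceeds the largest i,i+3 separation the
  # coil geometry can reach, so growth must stall on every frame
  spec <- synthetic_spec(helix_propensity = 0, n_frames = 50, seed = 1,
                         excluded_volume_radius = 11)
  expect_error(generate_ensemble(spec), "rejection rate")
})
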