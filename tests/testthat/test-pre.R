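test_that("intensity ratio has the correct limits and monotonicity", {
  expect_equal(pre_ratio(1e6), 1, tolerance = 1e-6)
  expect_lt(pre_ratio(1), 1e-6)
  # below ~3.6 A the exponential underflows to an exact double 0, so the
  # strictly-increasing check runs over the representable range
  grid <- seq(4, 120, length.out = 1000)
  expect_true(all(diff(pre_ratio(grid)) > 0))
  expect_error(pre_ratio(-2), "positive")
})

test_that("intensity ratio matches the independent scalar oracle", {
  set.seed(23)
  r <- runif(50, 5, 80)
  expect_equal(pre_ratio(r), oracle_pre_ratio(r), tolerance = 1e-10)
  # linear-frequency convention is exposed and also matches
  lin <- pre_parameters(omega_convention = "linear")
  expect_equal(pre_ratio(r, lin), oracle_pre_ratio(r, angular = FALSE),
               tolerance = 1e-10)
})

test_that("the spectral-density bracket is dominated by its 4*tau_c term", {
  p <- pre_parameters()
  omega <- 2 * pi * p$larmor_frequency
  second <- 3 * p$tau_c / (1 + omega^2 * p$tau_c^2)
  expect_lt(second, 0.01 * (4 * p$tau_c))
  expect_equal(idpens:::pre_tau_bracket(p), 4 * p$tau_c + second)
})

test_that("effective distances average as r^-6 and obey the power mean", {
  # two frames at 10 and 20 A between residues 1 and 5
  top <- topology("AAAAA")
  f1 <- extended_ca(5); f1[5, ] <- c(10, 0, 0)
  f2 <- extended_ca(5); f2[5, ] <- c(20, 0, 0)
  ens <- make_ens(list(f1, f2), top)
  r6 <- effective_distance(ens, 1, 5, mode = "r6")
  expect_equal(r6, (0.5 * 10^-6 + 0.5 * 20^-6)^(-1 / 6), tolerance = 1e-12)
  expect_equal(effective_distance(ens, 1, 5, mode = "arithmetic"), 15)
  expect_lte(r6, 15)

  single <- make_ens(list(f1), top)
  expect_equal(effective_distance(single, 1, 5, "r6"),
               effective_distance(single, 1, 5, "arithmetic"))
  expect_error(effective_distance(ens, 1, 1), "equals the label site")
})

test_that("r6 averaging never predicts weaker broadening than arithmetic", {
  spec <- wt_like_spec(n_frames = 100, seed = 25)
  ens <- generate_ensemble(spec)$ensemble
  for (target in c(10, 30, 55)) {
    r6 <- effective_distance(ens, "E28C", target, "r6")
    ar <- effective_distance(ens, "E28C", target, "arithmetic")
    expect_lte(r6, ar + 1e-12)
  }
})

test_that("profiles over a rigid structure equal the per-residue oracle", {
  x <- ideal_helix_ca(20)
  ens <- make_ens(list(x), topology(strrep("A", 20)))
  prof <- pre_profile(ens, 1, mode = "r6")
  for (k in 2:20) {
    r <- sqrt(sum((x[k, ] - x[1, ])^2))
    expect_equal(prof$ratio[k], oracle_pre_ratio(r), tolerance = 1e-10)
  }
  expect_equal(prof$ratio[1], 0)   # label site reported as 0
})

test_that("extended chains give ratios increasing away from the label", {
  ens <- make_ens(list(extended_ca(30)), topology(strrep("A", 30)))
  prof <- pre_profile(ens, 1)
  expect_true(all(diff(prof$ratio[-1]) > 0))
})

test_that("a biased long-range contact dips the profile at its partner", {
  base <- synthetic_spec(helix_propensity = 0, n_frames = 1500, seed = 27)
  biased <- synthetic_spec(
    helix_propensity = 0,
    contact_biases = data.frame(i = 10, j = 50, target = 0.12),
    n_frames = 1500, seed = 27)
  biased <- calibrate_contact_strengths(biased)
  e0 <- generate_ensemble(base)$ensemble
  e1 <- generate_ensemble(biased)$ensemble
  site <- spin_label_site(10, e0$topology)
  p0 <- pre_profile(e0, site)
  p1 <- pre_profile(e1, site)
  expect_lt(p1$ratio[50], p0$ratio[50] - 0.05)
})

test_that("spin-label site parsing validates the wild-type residue", {
  top <- p53_tad_fixture()
  s <- spin_label_site("E28C", top)
  expect_equal(s$resno, 28L)
  expect_error(spin_label_site("A28C", top), "has E at residue 28")
  expect_error(spin_label_site("E28G", top), "end in C")
  panel <- pre_profile_panel(
    generate_ensemble(wt_like_spec(n_frames = 30, seed = 2))$ensemble)
  expect_named(panel, c("D7C", "E28C", "A39C", "D61C"))
})

test_that("profile correlation handles agreement, inversion and errors", {
  ens <- generate_ensemble(wt_like_spec(n_frames = 50, seed = 3))$ensemble
  prof <- pre_profile(ens, "E28C")
  tab <- data.frame(resno = prof$resno, ratio = prof$ratio)
  expect_equal(profile_correlation(prof, tab), 1)
  inv <- data.frame(resno = prof$resno, ratio = 1 - prof$ratio)
  expect_equal(profile_correlation(prof, inv), -1)
  few <- tab[1:2, ]
  expect_error(profile_correlation(prof, few), "fewer than 3")
})

test_that("correlation with a noisy copy matches the attenuation model", {
  set.seed(29)
  ens <- generate_ensemble(wt_like_spec(n_frames = 400, seed = 33))$ensemble
  prof <- pre_profile(ens, "E28C")
  keep <- prof$resno != prof$site$resno
  sd_sig <- sd(prof$ratio[keep])
  sigma <- 0.05
  expected_r <- sd_sig / sqrt(sd_sig^2 + sigma^2)
  rs <- replicate(40, {
    noisy <- data.frame(resno = prof$resno,
                        ratio = prof$ratio + rnorm(61, sd = sigma))
    profile_correlation(prof, noisy)
  })
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - expected_r), 3 * se + 0.02)
})
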