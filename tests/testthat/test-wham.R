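# WHAM reconstruction, binding free energy extraction, equilibration split,
# overlap diagnostics.

test_that("a single window on a flat landscape yields a flat PMF", {
  pot <- potential_spec("flat", domain = c(0.5, 1.5))
  uw <- gen_umbrella_windows(pot, centers = 1.0, k = 1000,
                             n_per_window = 2e4, seed = 1)
  pmf <- bayesian_bootstrap_errors(uw, n_boot = 50, seed = 2)
  # within the well-sampled core (+-1.5 sd of the bias) G is flat within 2 sigma
  core <- dplyr::filter(pmf$profile, abs(x - 1.0) < 1.5 * sqrt(kB * 310 / 1000))
  expect_gt(nrow(core), 5)
  expect_true(all(abs(core$G - mean(core$G)) <= pmax(2 * core$sigma, 0.05)))
})

test_that("WHAM reduces to direct histogram unbiasing for a single window", {
  pot <- potential_spec("harmonic", domain = c(0.6, 1.4), kappa = 300, center = 1)
  uw <- gen_umbrella_windows(pot, centers = 1.0, k = 800,
                             n_per_window = 1e4, seed = 3)
  pmf <- wham(uw, bin_width = 0.01)
  # independent unbiasing on the same bins: G = -kT ln(h) - U_bias, shifted
  kT <- kB * 310
  s <- uw$samples[[1]]
  edges <- seq(min(s), max(s) + 0.01 * 1e-9, by = 0.01)
  if (max(edges) < max(s)) edges <- c(edges, max(edges) + 0.01)
  h <- tabulate(findInterval(s, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), length(edges) - 1)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  occ <- h > 0
  Gd <- -kT * log(h[occ] / sum(h)) - 0.5 * 800 * (ctr[occ] - 1)^2
  manual <- tibble::tibble(x = ctr[occ], G_direct = Gd)
  joined <- dplyr::inner_join(pmf$profile, manual, by = "x")
  expect_gt(nrow(joined), 20)
  # both profiles determined up to an additive constant on the shared bins
  expect_lt(max(abs((joined$G - joined$G[1]) -
                      (joined$G_direct - joined$G_direct[1]))), 1e-8)
})

test_that("WHAM recovers a harmonic PMF from five standard windows", {
  kappa <- 500
  pot <- potential_spec("harmonic", domain = c(0.6, 1.4), kappa = kappa,
                        center = 1.0)
  uw <- gen_umbrella_windows(pot, centers = seq(0.8, 1.2, 0.1), k = 1000,
                             n_per_window = 2e4, temperature = 310, seed = 5)
  pmf <- wham(uw)
  ctr <- dplyr::filter(pmf$profile, x >= 0.8, x <= 1.2)
  ref <- 0.5 * kappa * (ctr$x - 1)^2
  # align additive offsets before comparing shapes
  rms <- sqrt(mean(((ctr$G - mean(ctr$G)) - (ref - mean(ref)))^2))
  expect_lt(rms, 0.5)
})

test_that("window free-energy offsets are invariant under reordering", {
  pot <- potential_spec("double_well", domain = c(0.5, 1.5),
                        center1 = 0.8, center2 = 1.2, depth1 = 10,
                        depth2 = 5, barrier = 3, width = 0.08)
  uw <- gen_umbrella_windows(pot, centers = seq(0.7, 1.3, 0.1), k = 1000,
                             n_per_window = 5000, seed = 6)
  pmf1 <- wham(uw)
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  uw2 <- uw[perm, ]
  class(uw2) <- class(uw)
  pmf2 <- wham(uw2)
  f1 <- pmf1$f; f2 <- pmf2$f[order(perm)]
  expect_lt(max(abs((f1 - f1[1]) - (f2 - f2[1]))), 1e-5)
  expect_equal(pmf1$dg_binding, pmf2$dg_binding, tolerance = 1e-6)
})

test_that("binding free energy is minus the span of the profile", {
  expect_equal(binding_dg(c(0, 10, 57)), -57)
  expect_equal(binding_dg(c(0, 0, 0)), 0)
  # double-well synthetic profile with wells 0 and 12, barrier 20
  x <- seq(0, 1, 0.01)
  G <- 20 * exp(-(x - 0.5)^2 / 0.005)
  G[x < 0.25] <- 0; G[x > 0.75] <- 12
  expect_equal(binding_dg(G), -20)
})

test_that("profile minimum is exactly zero after convergence", {
  pot <- potential_spec("flat", domain = c(0.8, 1.2))
  uw <- gen_umbrella_windows(pot, centers = c(0.95, 1.05), k = 1000,
                             n_per_window = 4000, seed = 7)
  pmf <- wham(uw)
  expect_identical(min(pmf$profile$G), 0)
})

test_that("equilibration split discards early samples with the 10/50 ns default ratio", {
  pot <- potential_spec("flat", domain = c(0.5, 1.5))
  uw <- gen_umbrella_windows(pot, centers = 1, k = 1000, n_per_window = 5000,
                             seed = 8, dt = 10)   # 10 ps spacing -> 50 ns total
  trimmed <- equilibration_split(uw, discard_time = 1e4, total_time = 5e4)
  expect_equal(length(trimmed$samples[[1]]) / 5000, 0.8)
  same <- equilibration_split(uw, discard_time = 0)
  expect_identical(same$samples, uw$samples)
  expect_error(equilibration_split(uw, discard_time = 6e4, total_time = 5e4),
               "smaller")
  expect_error(equilibration_split(uw, discard_time = 5e4 + 1), "no samples")
})

test_that("overlap diagnostics flag distant windows and accept standard spacing", {
  pot <- potential_spec("flat", domain = c(0.2, 2.4))
  near <- gen_umbrella_windows(pot, centers = c(1.0, 1.1), k = 1000,
                               n_per_window = 5000, seed = 9)
  ov <- overlap_report(near)
  expect_gt(ov$adjacent$overlap, 0.05)
  expect_false(ov$adjacent$flagged)

  selfov <- overlap_report(
    gen_umbrella_windows(pot, centers = c(1.0, 1.0), k = 1000,
                         n_per_window = 5000, seed = 10))
  expect_gt(selfov$adjacent$overlap, 0.9)

  far <- gen_umbrella_windows(pot, centers = c(0.7, 1.7), k = 1000,
                              n_per_window = 5000, seed = 11)
  expect_true(overlap_report(far)$adjacent$flagged)
  expect_error(wham(far), "gap")
})

test_that("pmf tidiers and plot expose the profile", {
  pot <- potential_spec("flat", domain = c(0.8, 1.2))
  uw <- gen_umbrella_windows(pot, centers = 1, k = 1000, n_per_window = 2000,
                             seed = 12)
  pmf <- wham(uw)
  expect_named(generics::tidy(pmf), c("x", "G", "sigma"))
  expect_equal(generics::glance(pmf)$dg_binding, pmf$dg_binding)
  expect_s3_class(ggplot2::autoplot(pmf), "ggplot")
})
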