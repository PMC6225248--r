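# Structural statistics: superposed RMSD, RMSD-cutoff clustering, hydrogen
# bonds, salt bridges, COM separation, sheet registry.

test_that("superposed RMSD is zero under rigid-body motion and symmetric", {
  a <- random_conformer(4, seed = 1)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)

  # rotate 90 degrees about z and translate (1, 2, 3) nm
  b <- a
  x <- a$x; y <- a$y
  b$x <- -y + 1; b$y <- x + 2; b$z <- a$z + 3
  expect_equal(kabsch_rmsd(a, b), 0, tolerance = 1e-10)

  c2 <- a; c2$x <- c2$x + stats::rnorm(nrow(a), 0, 0.1)
  expect_equal(kabsch_rmsd(a, c2), kabsch_rmsd(c2, a), tolerance = 1e-12)
  expect_error(kabsch_rmsd(a, b, sel(atoms = "ZZ")), "empty")
})

test_that("superposed RMSD agrees with an independent rotation-grid search", {
  # 4 atoms, one displaced: closed-form Kabsch vs brute-force minimisation
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  Q <- P; Q[4, ] <- Q[4, ] + c(0.3, -0.2, 0.1)
  mk <- function(M) conformer(tibble::tibble(
    atom = c("N", "CA", "C", "O"), resname = "ALA", resid = 1,
    x = M[, 1], y = M[, 2], z = M[, 3]))
  impl <- kabsch_rmsd(mk(P), mk(Q))
  oracle <- grid_rmsd_oracle(P, Q)
  expect_lt(abs(impl - oracle), 1e-4)
})

test_that("clustering partitions frames and finds constructed groups", {
  sh <- gen_beta_sheet_pair(6, "antiparallel")
  base <- combine_conformers(sh$strand_A, sh$strand_B)

  # N identical frames -> one cluster with full population
  same <- conformer_ensemble(rep(list(base), 5))
  one <- cluster_rmsd_cutoff(same, 0.25, selection = NULL)
  expect_equal(nrow(one$clusters), 1)
  expect_equal(one$clusters$population, 1.0)

  # two groups: within-group RMSD << cutoff, between-group >> cutoff
  frames <- c(noisy_ensemble(base, 6, noise = 0.01, seed = 1),
              noisy_ensemble(base, 4, noise = 0.01, seed = 50, scramble = TRUE))
  ens <- conformer_ensemble(frames)
  m <- rmsd_matrix(ens, selection = NULL)
  expect_lt(max(m[1:6, 1:6]), 0.25)
  expect_gt(min(m[1:6, 7:10]), 0.25)

  ca <- cluster_rmsd_cutoff(ens, 0.25, selection = NULL)
  expect_equal(nrow(ca$clusters), 2)
  expect_equal(ca$clusters$n, c(6L, 4L))
  expect_equal(sum(ca$clusters$population), 1, tolerance = 1e-9)
  expect_setequal(cluster_frames(ca, 1), 1:6)

  # determinism: repeated runs give identical assignments
  expect_identical(ca$assignment,
                   cluster_rmsd_cutoff(ens, 0.25, selection = NULL)$assignment)
  # every frame assigned exactly once
  expect_equal(sort(ca$assignment$frame), 1:10)
})

test_that("hydrogen-bond counting honours both geometric cutoffs and directions", {
  # constructed N-H...O: N...O 0.29 nm, angle 0 -> counted
  mk <- function(no_dist, angle_deg) {
    th <- angle_deg * pi / 180
    conformer(tibble::tibble(
      atom = c("N", "H", "O"),
      resname = c("ALA", "ALA", "ALA"), resid = c(1, 1, 1),
      chain = c("A", "A", "B"),
      x = c(0, 0.1 * cos(th), no_dist),
      y = c(0, 0.1 * sin(th), 0),
      z = 0))
  }
  expect_equal(hbond_count(mk(0.29, 0), sel(chain = "A"),
                           sel(chain = "B"))$n_hbonds, 1L)
  expect_equal(hbond_count(mk(0.40, 0), sel(chain = "A"),
                           sel(chain = "B"))$n_hbonds, 0L)
  expect_equal(hbond_count(mk(0.29, 45), sel(chain = "A"),
                           sel(chain = "B"))$n_hbonds, 0L)

  # mean over a 3-frame ensemble with counts 2, 3, 4
  shn <- lapply(c(2, 3, 4), function(k) {
    sh <- gen_beta_sheet_pair(4, "antiparallel", registry = 13 + k)
    combine_conformers(sh$strand_A, sh$strand_B)
  })
  counts <- vapply(shn, function(cc)
    nrow(pairing_from_hbonds(cc)), integer(1))
  expect_equal(counts, c(2L, 3L, 4L))
  ens3 <- conformer_ensemble(shn)
  hb3 <- hbond_count(ens3, sel(chain = "A"), sel(chain = "B"))
  expect_equal(hb3$n_hbonds, 2L * counts)       # two directed bonds per pair
  expect_equal(attr(hb3, "mean"), mean(2 * counts))

  # monotone in both cutoffs
  sh <- gen_beta_sheet_pair(5, "antiparallel", rmsd_noise = 0.04, seed = 8)
  cc <- combine_conformers(sh$strand_A, sh$strand_B)
  n1 <- hbond_count(cc, sel(chain = "A"), sel(chain = "B"),
                    d_cut = 0.30, angle_cut = 20)$n_hbonds
  n2 <- hbond_count(cc, sel(chain = "A"), sel(chain = "B"),
                    d_cut = 0.35, angle_cut = 30)$n_hbonds
  n3 <- hbond_count(cc, sel(chain = "A"), sel(chain = "B"),
                    d_cut = 0.45, angle_cut = 60)$n_hbonds
  expect_true(n1 <= n2 && n2 <= n3)
})

test_that("salt bridges flip exactly at the 1 nm threshold with minimum semantics", {
  mk <- function(xs) conformer(tibble::tibble(
    atom = c("NZ", rep("OE1", length(xs))),
    resname = c("LYS", rep("GLU", length(xs))),
    resid = c(1, rep(2, length(xs))),
    chain = c("A", rep("B", length(xs))),
    x = c(0, xs), y = 0, z = 0))
  pair <- list(kq = list(sel(chain = "A"), sel(chain = "B")))
  expect_true(salt_bridge_series(mk(0.3), pair)$exists)
  expect_false(salt_bridge_series(mk(1.2), pair)$exists)
  expect_false(salt_bridge_series(mk(1.0), pair)$exists)   # strictly < 1 nm
  expect_true(salt_bridge_series(mk(0.9999), pair)$exists)
  # min over atoms: 0.9 and 1.4 -> 0.9, exists
  two <- salt_bridge_series(mk(c(0.9, 1.4)), pair)
  expect_equal(two$min_distance, 0.9)
  expect_true(two$exists)
})

test_that("COM separation is the mass-weighted centroid distance", {
  mk <- function(df) {
    if (!"y" %in% names(df)) df$y <- 0
    conformer(tibble::tibble(
      atom = "CA", resname = "ALA", resid = seq_len(nrow(df)),
      chain = df$chain, x = df$x, y = df$y, z = 0, element = "C",
      backbone = TRUE, mass = df$m))
  }
  a <- mk(tibble::tibble(chain = c("A", "B"), x = c(0, 3), y = c(0, 4), m = 1))
  expect_equal(com_separation(a, sel(chain = "A"), sel(chain = "B")), 5)
  expect_equal(com_separation(a, sel(chain = "A"), sel(chain = "A")), 0)
  # unequal masses: m = 1 at x = 0 and m = 3 at x = 4 -> centroid 3; |10 - 3| = 7
  b <- mk(tibble::tibble(chain = c("A", "A", "B"), x = c(0, 4, 10), m = c(1, 3, 2)))
  expect_equal(com_separation(b, sel(chain = "A"), sel(chain = "B")), 7)
})

test_that("sheet registry is the invariant i + j, with parallel not applicable", {
  r <- sheet_registry(tibble::tibble(i = c(16, 17, 18), j = c(7, 6, 5)),
                      "antiparallel")
  expect_identical(r$registry, 23L)
  p <- sheet_registry(tibble::tibble(i = c(16, 17), j = c(7, 6)), "parallel")
  expect_true(is.na(p$registry))
  expect_equal(nrow(p$pairing), 2)
  expect_error(sheet_registry(tibble::tibble(i = c(16, 17), j = c(7, 7)),
                              "antiparallel"), "inconsistent")
  expect_error(sheet_registry(tibble::tibble(i = integer(0), j = integer(0)),
                              "antiparallel"), "non-empty")
})

test_that("tidiers summarise clustering results", {
  sh <- gen_beta_sheet_pair(5, "antiparallel")
  base <- combine_conformers(sh$strand_A, sh$strand_B)
  ens <- conformer_ensemble(noisy_ensemble(base, 4, seed = 2))
  ca <- cluster_rmsd_cutoff(ens, 0.3, selection = NULL)
  expect_named(generics::tidy(ca), c("cluster", "n", "population", "center_frame"))
  g <- generics::glance(ca)
  expect_equal(g$n_frames, 4)
  expect_s3_class(ggplot2::autoplot(ca), "ggplot")
})
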