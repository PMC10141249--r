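test_that("frozen projection zeroes frozen blocks and preserves free ones", {
  ch <- gen_coupled_oscillator(3, masses = c(2, 3, 4),
                               springs = c(0.2, 0.3), frozen = 3)
  P <- project_frozen(ch$hessian, ch$structure)
  expect_equal(unclass(P)[7:9, ], matrix(0, 3, 9), ignore_attr = TRUE)
  expect_equal(unclass(P)[, 7:9], matrix(0, 9, 3), ignore_attr = TRUE)
  expect_equal(unclass(P)[1:6, 1:6], unclass(ch$hessian)[1:6, 1:6],
               ignore_attr = TRUE)

  # f = 0 is the identity
  free <- gen_coupled_oscillator(3, masses = c(2, 3, 4),
                                 springs = c(0.2, 0.3))
  expect_equal(unclass(project_frozen(free$hessian, free$structure)),
               unclass(free$hessian), ignore_attr = TRUE)

  expect_error(xyz_structure(c("H", "H"), cbind(0, 0, 0:1),
                             frozen = c(1, 2)), "all atoms frozen")
})

test_that("diatomic stretch matches the closed-form frequency and KED", {
  # nu = (1/2 pi c) sqrt(k / mu), constants written out independently
  Eh <- 4.3597447222071e-18; a0 <- 5.29177210903e-11
  u <- 1.66053906660e-27; c_cm <- 2.99792458e10
  k <- 0.37; m <- c(1.008, 1.008)
  osc <- diatomic(m[1], m[2], k)
  ms <- normal_modes(osc$hessian, osc$structure)
  mu <- prod(m) / sum(m)
  nu_ref <- sqrt(k * Eh / (a0^2 * mu * u)) / (2 * pi * c_cm)
  expect_equal(length(ms$freq), 1)
  expect_equal(ms$freq, nu_ref, tolerance = 1e-6)
  expect_equal(ms$ked[, 1], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("heteronuclear diatomic KED follows m_j / (m_i + m_j)", {
  ms <- normal_modes(diatomic(1, 3)$hessian, diatomic(1, 3)$structure)
  expect_equal(ms$ked[, 1], c(0.75, 0.25), tolerance = 1e-10)
  set.seed(42)
  for (i in 1:100) {
    m <- runif(2, 0.5, 200)
    osc <- diatomic(m[1], m[2], runif(1, 0.05, 1))
    ked <- normal_modes(osc$hessian, osc$structure)$ked[, 1]
    expect_equal(ked, c(m[2], m[1]) / sum(m), tolerance = 1e-10)
  }
})

test_that("mode counting follows the 3n-3f / 3n-3f-1 cluster convention", {
  # minimum: n = 10, f = 8 -> 6 free DOF, all real (3n - 24)
  n <- 10
  set.seed(7)
  fix <- gen_coupled_oscillator(n, frozen = 3:10, seed = 7)
  # couple the two free atoms in all three directions so no zero modes
  # survive among the free DOF
  H <- unclass(fix$hessian)
  blk <- matrix(rnorm(36), 6, 6); blk <- crossprod(blk) * 0.05
  H[1:6, 1:6] <- blk
  Hp <- project_frozen(cart_hessian(H), fix$structure)
  ms <- normal_modes(Hp, fix$structure)
  expect_equal(length(ms$freq), 3 * n - 24)
  expect_true(all(ms$freq > 0))

  # transition state: one negative eigenvalue -> 3n - 25 real modes + 1
  V <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  Hts <- V %*% diag(c(-0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) %*% t(V)
  H2 <- matrix(0, 30, 30); H2[1:6, 1:6] <- (Hts + t(Hts)) / 2
  Hp2 <- project_frozen(cart_hessian(H2), fix$structure)
  ts <- normal_modes(Hp2, fix$structure, expect_ts = TRUE)
  expect_equal(sum(ts$freq < 0), 1)
  expect_equal(sum(ts$freq > 0), 3 * n - 25)
  expect_true(is_ts(ts))
  expect_error(normal_modes(Hp, fix$structure, expect_ts = TRUE),
               "exactly one imaginary")
})

test_that("frozen-atom displacements are identically zero in every mode", {
  fix <- gen_random_hessian(6, seed = 3, frozen = c(5, 6))
  Hp <- project_frozen(fix$hessian, fix$structure)
  ms <- normal_modes(Hp, fix$structure)
  frozen_rows <- 13:18
  expect_identical(ms$displacements[frozen_rows, ],
                   matrix(0, 6, ncol(ms$displacements)))
  expect_true(all(ms$ked[5:6, ] == 0))
})

test_that("unprojected Hessians with frozen atoms are rejected", {
  fix <- gen_random_hessian(4, seed = 9, frozen = 4)
  expect_error(normal_modes(fix$hessian, fix$structure),
               "frozen-projected")
})

test_that("KED equals a brute-force oracle on random small systems", {
  for (s in 1:20) {
    n <- sample(2:5, 1)
    fix <- gen_random_hessian(n, seed = s)
    ms <- normal_modes(fix$hessian, fix$structure)
    ora <- ked_oracle(fix$hessian, fix$structure)
    expect_equal(ms$freq, ora$freq, tolerance = 1e-8)
    expect_equal(ms$ked, ora$ked, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("KED columns sum to one and lie in [0,1] across random seeds", {
  for (s in 1:25) {
    fix <- gen_coupled_oscillator(sample(3:8, 1), seed = s)
    ms <- normal_modes(fix$hessian, fix$structure)
    expect_equal(colSums(ms$ked), rep(1, ncol(ms$ked)), tolerance = 1e-8)
    expect_true(all(ms$ked >= 0 & ms$ked <= 1))
  }
})

test_that("KED is invariant to displacement normalization", {
  fix <- gen_random_hessian(4, seed = 12)
  ms <- normal_modes(fix$hessian, fix$structure)
  scaled <- ms
  scaled$displacements <- ms$displacements * 7.3
  expect_equal(compute_ked(scaled)$ked, ms$ked, tolerance = 1e-12)
})

test_that("Eckart projection removes six DOF from a free nonlinear molecule", {
  set.seed(21)
  st <- xyz_structure(c("O", "H", "H"),
                      rbind(c(0, 0, 0.12), c(0, 0.76, -0.48),
                            c(0, -0.76, -0.48)))
  fix <- gen_random_hessian(3, seed = 21)
  H <- cart_hessian(unclass(fix$hessian) + diag(0.5, 9))  # make stiff
  ms <- normal_modes(H, st, project_trans_rot = TRUE)
  expect_equal(length(ms$freq), 3 * 3 - 6)
})

test_that("fragment KED is normalized, additive, and warns on degeneracy", {
  fix <- gen_random_hessian(6, seed = 31)
  ms <- normal_modes(fix$hessian, fix$structure)
  j <- length(ms$freq)
  expect_equal(fragment_ked(ms, 1:6, j), 1.0, tolerance = 1e-12)
  fF <- fragment_ked(ms, 1:2, j)
  fG <- fragment_ked(ms, 3:4, j)
  expect_equal(fragment_ked(ms, 1:4, j), fF + fG, tolerance = 1e-12)
  expect_error(fragment_ked(ms, integer(0), j), "empty fragment")

  # two equal frequencies flag the degenerate subspace
  st <- fix$structure
  dm <- mode_set(c(500, 500.001), ms$displacements[, 1:2], st)
  expect_warning(fragment_ked(dm, 1:2, 1), "degenerate")
})

test_that("zero-displacement support and thermal aggregation behave", {
  fix <- gen_random_hessian(10, seed = 5)
  frag <- fragment("CH3", 1:4, n = 10)
  ts <- gen_ts_mode(fix$structure, frag, 0.88, seed = 6)
  # off-fragment share
  expect_equal(sum(ts$ked[5:10, 1]), 0.12, tolerance = 1e-9)
  # Eq-3-style aggregation with user weights
  w <- rep(0, length(ts$freq)); w[1] <- 2.5
  Ti <- atom_kinetic_energy(ts, w)
  expect_equal(sum(Ti), 2.5, tolerance = 1e-9)
  expect_equal(sum(Ti[1:4]), 2.5 * 0.88, tolerance = 1e-9)
  expect_error(atom_kinetic_energy(ts, w[-1]), "one kinetic energy per mode")
})

test_that("precomputed modes can be read back from a delimited table", {
  fix <- gen_coupled_oscillator(3, masses = c(1, 2, 3),
                                springs = c(0.2, 0.4))
  ms <- normal_modes(fix$hessian, fix$structure)
  hdr <- paste(c("freq_cm1", paste0("d", 1:9)), collapse = "\t")
  rows <- sapply(seq_along(ms$freq), function(j)
    paste(c(ms$freq[j], ms$displacements[, j]), collapse = "\t"))
  p <- write_text_fixture(c(hdr, rows))
  ms2 <- read_modes(p, fix$structure)
  expect_equal(ms2$freq, ms$freq, tolerance = 1e-6)
  expect_equal(ms2$ked, ms$ked, tolerance = 1e-8)
})
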