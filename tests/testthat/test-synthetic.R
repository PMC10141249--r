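test_that("coupled-oscillator chains have closed-form spectra", {
  # two equal masses, one spring: single mode, KED split evenly
  osc <- gen_coupled_oscillator(2, masses = c(1, 1), springs = 1)
  ms <- normal_modes(osc$hessian, osc$structure)
  expect_length(ms$freq, 1)
  expect_equal(ms$ked[, 1], c(0.5, 0.5))

  # uniform free 3-chain: two stretches in ratio 1 : sqrt(3)
  ch <- gen_coupled_oscillator(3, masses = rep(2, 3),
                               springs = rep(0.2, 2))
  ms3 <- normal_modes(ch$hessian, ch$structure)
  expect_length(ms3$freq, 2)
  expect_equal(ms3$freq[2] / ms3$freq[1], sqrt(3), tolerance = 1e-8)

  # freezing the end atom removes three Cartesian DOF
  frz <- gen_coupled_oscillator(3, masses = rep(2, 3),
                                springs = rep(0.2, 2), frozen = 3)
  expect_equal(dof_counts(ch$structure)[["free_dof"]] -
               dof_counts(frz$structure)[["free_dof"]], 3L)

  expect_error(gen_coupled_oscillator(3, masses = c(1, 2),
                                      springs = c(0.1, 0.1)),
               "inconsistent")
  expect_error(gen_coupled_oscillator(2, masses = c(1, 1), springs = -1),
               "positive")
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_coupled_oscillator(5, seed = 31),
                   gen_coupled_oscillator(5, seed = 31))
  expect_identical(gen_random_hessian(4, seed = 8),
                   gen_random_hessian(4, seed = 8))
  st <- gen_random_hessian(6, seed = 1)$structure
  expect_identical(gen_ts_mode(st, 1:3, 0.7, seed = 5),
                   gen_ts_mode(st, 1:3, 0.7, seed = 5))
  expect_identical(gen_charge_response(10, slope_truth = 1.1, seed = 3,
                                       noise_sd = 0.01),
                   gen_charge_response(10, slope_truth = 1.1, seed = 3,
                                       noise_sd = 0.01))
  expect_identical(gen_model_series(seed = 7), gen_model_series(seed = 7))
})

test_that("generated Hessians are symmetric and responses are valid inputs", {
  for (s in 1:10) {
    h1 <- gen_coupled_oscillator(4, seed = s)$hessian
    h2 <- gen_random_hessian(4, seed = s)$hessian
    expect_identical(unclass(h1), t(unclass(h1)))
    expect_identical(unclass(h2), t(unclass(h2)))
    cr <- gen_charge_response(8, slope_truth = 1.2, noise_sd = 0.01,
                              seed = s)
    expect_silent(polarization_curve(cr))
  }
})

test_that("constructed TS modes hit the fragment share exactly", {
  st <- gen_random_hessian(10, seed = 2)$structure
  frag <- fragment("CH3", 1:4, n = 10)
  ts <- gen_ts_mode(st, frag, 0.88, seed = 9)
  expect_equal(fragment_ked(ts, frag), 0.88, tolerance = 1e-9)
  expect_equal(sum(ts$freq < 0), 1)
  # KED columns of the constructed set remain normalized
  expect_equal(colSums(ts$ked), rep(1, ncol(ts$ked)), tolerance = 1e-9)

  # share 1 on the full unfrozen set: off-fragment KED identically 0
  full <- gen_ts_mode(st, 1:10, 1.0, seed = 9)
  expect_equal(fragment_ked(full, 1:10), 1.0, tolerance = 1e-12)

  expect_error(gen_ts_mode(st, 1:10, 0.9, seed = 1), "infeasible")
  expect_error(gen_ts_mode(st, 1:3, 1.5, seed = 1), "\\(0, 1\\]")

  # frozen atoms never carry amplitude
  stf <- gen_random_hessian(8, seed = 3, frozen = 7:8)$structure
  tsf <- gen_ts_mode(stf, 1:3, 0.85, seed = 4)
  expect_true(all(tsf$ked[7:8, ] == 0))
  expect_error(gen_ts_mode(stf, 7:8, 0.5, seed = 1), "no unfrozen")
})

test_that("noise-free preset responses reproduce their slopes exactly", {
  crE <- gen_charge_response(25, preset = "E", noise_sd = 0, seed = 1)
  expect_equal(polarization_slope(polarization_curve(crE))$m, 1.02,
               tolerance = 1e-10)
  cr0 <- gen_charge_response(10, slope_truth = 0, noise_sd = 0.005,
                             seed = 6)
  m0 <- polarization_slope(polarization_curve(cr0))$m
  expect_lt(abs(m0), 0.1)  # pure noise level
  expect_error(gen_charge_response(5, slope_truth = 1,
                                   grid = numeric(0)), "empty")
  expect_error(gen_charge_response(5, preset = "Z"), "unknown preset")
})

test_that("the default model series carries the documented trends", {
  series <- gen_model_series(seed = 42)
  en <- series$energetics
  # barrier ordering E < D < C < A < B
  expect_identical(en$model[order(en$dG_act)], c("E", "D", "C", "A", "B"))
  # late TS window respected and barrier above driving force
  expect_true(all(en$dG_act - en$dG0 > 0 & en$dG_act - en$dG0 < 5))
  expect_true(all(en$dG_act >= 0))
  # potentials increase along B < A < C < D < E (maturation ordering)
  pots <- series$potentials
  expect_identical(pots$model[order(pots$E0)], c("B", "A", "C", "D", "E"))
  # Ni-S leg most negative (strongest bond) for E, least for B
  expect_identical(series$legs$model[which.min(series$legs$NiS)], "E")
  expect_identical(series$legs$model[which.max(series$legs$NiS)], "B")
  # cleavage leg independent of the cofactor
  expect_equal(diff(range(series$legs$cleavage)), 0, tolerance = 1e-12)
  # step 3 exergonic throughout, least so for E
  expect_true(all(series$legs$total_step3 < 0))
  expect_identical(series$legs$model[which.max(series$legs$total_step3)],
                   "E")
})

test_that("series leg correlations reproduce the specified slopes", {
  series <- gen_model_series(seed = 13)
  out <- leg_correlations(series_cycles(series), series$potentials$E0)
  expect_equal(out$slope[out$quantity == "NiS"], 2.8, tolerance = 1e-9)
  expect_equal(out$slope[out$quantity == "ET"], -1.8, tolerance = 1e-9)
  expect_equal(out$slope[out$quantity == "E0"], -1.8, tolerance = 1e-9)
  expect_equal(attr(out, "slope_ratio"), 2.8 / 1.8, tolerance = 1e-9)
})
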