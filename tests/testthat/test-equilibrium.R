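params_ref <- energy_params(g_rG4 = 23, g_bind = 9.2, g_backfold = 0.8)

test_that("binding-mode enumeration reproduces the hand-counted modes", {
  st <- enumerate_states(params_ref)
  expect_true(all(c("unbound", "folded") %in% st$label))
  # two proteins with 2+2 contacts: single placement {12}{34}
  expect_equal(st$multiplicity[st$label == "2^22"], 1L)
  # two proteins with 3+1 contacts: {123}{4} and {1}{234}
  expect_equal(st$multiplicity[st$label == "2^31"], 2L)
  expect_equal(st$n_backfolds[st$label == "2^22"], 2L)
  expect_equal(st$n_backfolds[st$label == "2^31"], 2L)
  # single site: unbound, folded and one singly-bound mode only
  st1 <- enumerate_states(energy_params(5, 5, 0, n_sites = 1))
  expect_setequal(st1$label, c("unbound", "folded", "1^1"))
  # no backfolding: only singly-contacted proteins, up to 4
  stq1 <- enumerate_states(energy_params(5, 5, 0, max_qrrm = 1))
  bound <- stq1[stq1$m > 0, ]
  expect_true(all(bound$n_backfolds == 0))
  expect_equal(max(bound$m), 4L)
  # helper state appears when g_rG4_bind is set
  sth <- enumerate_states(energy_params(5, 5, 0, g_rG4_bind = 2))
  expect_true("1^F" %in% sth$label)
})

test_that("partition function equals the brute-force configuration sum", {
  grid <- expand.grid(
    g_rG4 = c(-3, 5, 23), g_bind = c(2, 9.2), g_backfold = c(0, 0.8, 5),
    n = c(1L, 2L, 4L), q = c(1L, 3L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- energy_params(g$g_rG4, g$g_bind, g$g_backfold,
                       n_sites = g$n, max_qrrm = g$q)
    for (c in c(1e-8, 1e-5, 1e-2)) {
      oracle <- brute_force_partition(c, g$g_rG4, g$g_bind, g$g_backfold,
                                      n = g$n, q = g$q)
      expect_equal(bound_fraction(p, c), oracle$bound, tolerance = 1e-10)
    }
  }
})

test_that("single-site model is exactly the Langmuir isotherm", {
  # with folding switched off (large negative g_rG4) and one site the
  # model must collapse to c / (c + K_d)
  g_bind <- 9.2
  p <- energy_params(g_rG4 = -200, g_bind = g_bind, g_backfold = 0,
                     n_sites = 1)
  kd <- exp(-g_bind / (1.987e-3 * 298))
  cs <- 10^seq(-10, -2, length.out = 41)
  expect_equal(bound_fraction(p, cs), cs / (cs + kd), tolerance = 1e-12)
  expect_equal(transition_concentration(p), kd, tolerance = 1e-8)
})

test_that("bound fraction is a proper, monotone saturation curve", {
  for (p in list(params_ref,
                 energy_params(10, 5, 2),
                 energy_params(30, 12, 0, max_qrrm = 1))) {
    cs <- 10^seq(-12, 2, length.out = 101)
    bf <- bound_fraction(p, cs)
    expect_true(all(bf >= 0 & bf <= 1))
    expect_true(all(diff(bf) >= -1e-12))
    expect_equal(bound_fraction(p, 0), 0)
    sp <- state_probabilities(p, 1e-6)
    expect_equal(sum(sp$probability), 1, tolerance = 1e-12)
  }
  expect_error(bound_fraction(params_ref, -1), "non-negative")
})

test_that("no-backfolding limit yields fourth-order cooperativity", {
  p <- energy_params(g_rG4 = 30, g_bind = 15, g_backfold = 0, max_qrrm = 1)
  expect_equal(model_hill(p, n_grid = 1001L), 4, tolerance = 0.01)
})

test_that("zero backfolding penalty yields second-order cooperativity", {
  p <- energy_params(g_rG4 = 30, g_bind = 9.2, g_backfold = 0)
  expect_equal(model_hill(p, n_grid = 1001L), 2, tolerance = 0.05)
})

test_that("model Hill coefficient matches a brute-force EC lookup", {
  p <- energy_params(23, 9.2, 0.8)
  K <- transition_concentration(p)
  oracle <- brute_force_hill(function(c) bound_fraction(p, c),
                             K * 1e-3, K * 1e3)
  expect_equal(model_hill(p, n_grid = 2001L), oracle, tolerance = 1e-3)
})

test_that("binding energy from Kd reproduces the thermodynamic identity", {
  expect_equal(binding_energy_from_kd(1), 0)
  rt <- 1.987e-3 * 298
  expect_equal(binding_energy_from_kd(exp(-1)), rt, tolerance = 1e-12)
  expect_equal(binding_energy_from_kd(0.2e-6), 9.2, tolerance = 0.1)
})

test_that("transition concentration is monotone in the backfolding penalty", {
  Ks <- vapply(c(0, 1, 2, 4, 8), function(gb) {
    transition_concentration(energy_params(23, 9.2, gb))
  }, numeric(1))
  expect_true(all(diff(Ks) >= 0))
})

test_that("backfold-penalty inversion round-trips and is monotone", {
  for (gb_true in c(-0.5, 0.8, 3)) {
    K <- transition_concentration(energy_params(23, 9.2, gb_true))
    gb_hat <- invert_backfold_penalty(23, 9.2, K)
    expect_equal(gb_hat, gb_true, tolerance = 1e-6)
  }
  g_lo <- invert_backfold_penalty(23, 9.2, 1e-6)
  g_hi <- invert_backfold_penalty(23, 9.2, 1e-4)
  expect_true(g_hi > g_lo)  # weaker apparent binding needs a larger penalty
  expect_error(invert_backfold_penalty(23, 9.2, 1e-29), "no root")
})

test_that("double-backfolding states dominate the bound ensemble at K", {
  K <- transition_concentration(params_ref)
  sp <- state_probabilities(params_ref, K)
  bound <- sp[sp$m > 0, ]
  double <- sum(bound$probability[bound$label %in% c("2^22", "2^31")])
  expect_gt(double / sum(bound$probability), 0.5)
  top <- bound$label[order(-bound$probability)][1:2]
  expect_setequal(top, c("2^22", "2^31"))
})

test_that("reduced double-backfolding model tracks the full model", {
  p <- energy_params(23, 9.2, 0)
  K <- transition_concentration(p)
  cs <- 10^seq(log10(K) - 3, log10(K) + 3, length.out = 201)
  expect_lt(max(abs(reduced_double_backfold(p, cs) - bound_fraction(p, cs))),
            0.05)
  expect_equal(reduced_double_backfold(p, 1e6), 1, tolerance = 1e-6)
  # a large penalty suppresses the double-backfolding states and drives
  # the full model toward four singly-bound proteins (n_H -> 4)
  p_hi <- energy_params(23, 9.2, 12)
  expect_gt(model_hill(p_hi, n_grid = 1001L), 3.5)
})

test_that("a weak helper state leaves cooperativity untouched", {
  # baseline tuned so that K = 3e-6 mol/l
  gb <- invert_backfold_penalty(23, 9.2, 3e-6)
  base <- energy_params(23, 9.2, gb)
  nh0 <- model_hill(base, n_grid = 1001L)
  eff <- helper_state_effect(base, c(-50, 2, 3.5), n_grid = 1001L)
  expect_true(all(abs(eff$n_H - nh0) < 0.1))
})

test_that("strong folded-rG4 binding collapses cooperativity", {
  gb <- invert_backfold_penalty(23, 9.2, 3e-6)
  base <- energy_params(23, 9.2, gb)
  eff <- helper_state_effect(base, 9.2, n_grid = 1001L)
  expect_lt(eff$n_H, 1.3)
})
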