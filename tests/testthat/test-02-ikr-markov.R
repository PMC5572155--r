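bind_example <- function(Ku = 1e-3, Vhalf = -1) {
  ikr_binding_params(list(Kmax = 1e6, Ku = Ku, n = 0.9,
                          halfmax = 4.157e6, Vhalf = Vhalf))
}

test_that("generator matrix columns sum to zero and drug-free case has no binding", {
  Q <- markov_transition_rates(-20, drug_conc = 50, binding = bind_example())
  expect_lt(max(abs(colSums(Q))), 1e-12)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))

  Q0 <- markov_transition_rates(-20, drug_conc = 0)
  # no flux into any bound state without drug
  expect_equal(Q0["ob", "o"], 0)
  expect_equal(Q0["ib", "i"], 0)
  # drug-free 4x4 wing identical with and without a binding parameter set
  Q0b <- markov_transition_rates(-20, drug_conc = 0,
                                 binding = bind_example())
  free <- c("c", "o", "i", "ci")
  expect_equal(Q0[free, free], Q0b[free, free])
})

test_that("stationary occupancy matches long-time ODE relaxation", {
  # voltages where the chain mixes on a tractable timescale (at deep
  # diastolic potentials the opening rate is ~1e-7/ms and equilibration
  # exceeds any practical relaxation horizon)
  for (v in c(-20, 0, 30)) {
    ss <- markov_stationary(v, drug_conc = 50, binding = bind_example())
    rx <- markov_relax(c(c = 1, o = 0, i = 0, ci = 0, ob = 0, ib = 0,
                         cb = 0),
                       V = v, t_end = 5e6, drug_conc = 50,
                       binding = bind_example())
    expect_equal(sum(ss), 1, tolerance = 1e-12)
    expect_lt(max(abs(ss - rx)), 1e-8)
  }
})

test_that("ikr_current trivial cases and linearity in the scaler", {
  occ <- c(c = 0.2, o = 0, i = 0.3, ci = 0.5, ob = 0, ib = 0, cb = 0)
  expect_equal(ikr_current(occ, V = -40, E_K = -88), 0)
  occ2 <- c(c = 0.2, o = 0.3, i = 0, ci = 0.5, ob = 0, ib = 0, cb = 0)
  expect_equal(ikr_current(occ2, V = -88, E_K = -88), 0)
  i1 <- ikr_current(occ2, V = 0, E_K = -88, s_IKr = 1)
  i2 <- ikr_current(occ2, V = 0, E_K = -88, s_IKr = 1.013)
  expect_equal(i2, 1.013 * i1)
  expect_gt(i1, 0)   # outward-positive above E_K
})

test_that("corrupt occupancies raise a state-corruption error", {
  bad <- c(c = 0.5, o = 0.5, i = 0.5, ci = 0, ob = 0, ib = 0, cb = 0)
  expect_error(ikr_current(bad, 0, -88), "sum to 1")
  neg <- c(c = 1.2, o = -0.2, i = 0, ci = 0, ob = 0, ib = 0, cb = 0)
  expect_error(ikr_current(neg, 0, -88), "corrupt")
})

test_that("occupancy conservation holds along a paced trajectory (< 1e-6)", {
  res <- ctrl2000()
  s <- res$beats[[2]]$end_state
  expect_lt(abs(sum(s[cipaord:::.markov_idx]) - 1), 1e-6)
  # and under drug
  drugged <- apply_drug(ord_params(), drug_panel()$dofetilide, 25)
  b <- record_beat(res$state, drugged, pacing_protocol(cl = 2000))
  expect_lt(abs(sum(b$end_state[cipaord:::.markov_idx]) - 1), 1e-6)
})

test_that("trapped parameterization holds its bound occupancy through a diastolic hold", {
  # bind at plateau voltage, then hold at rest
  loaded <- markov_relax(c(c = 1, o = 0, i = 0, ci = 0, ob = 0, ib = 0,
                           cb = 0),
                         V = 0, t_end = 2e4, drug_conc = 50,
                         binding = bind_example(Ku = 1e-3))
  trapped <- bind_example(Ku = 1e-10)   # unbinding -> 0
  held <- markov_relax(loaded, V = -88, t_end = 1e4, drug_conc = 0,
                       binding = trapped)
  bound0 <- sum(loaded[c("ob", "ib", "cb")])
  bound1 <- sum(held[c("ob", "ib", "cb")])
  expect_gt(bound0, 0.1)
  expect_equal(bound1, bound0, tolerance = 1e-6)

  # whereas a fast-unbinding, untrapped drug (permissive escape midpoint)
  # loses its block during the same hold
  fast <- bind_example(Ku = 1e-2, Vhalf = -90)
  held_fast <- markov_relax(loaded, V = -88, t_end = 1e4, drug_conc = 0,
                            binding = fast)
  expect_lt(sum(held_fast[c("ob", "ib", "cb")]), 0.01 * bound0)
})

test_that("at zero drug all bound occupancy decays away", {
  loaded <- markov_relax(c(c = 0.5, o = 0, i = 0, ci = 0, ob = 0.25,
                           ib = 0.25, cb = 0),
                         V = -10, t_end = 1e6, drug_conc = 0,
                         binding = bind_example(Ku = 1e-3))
  expect_lt(sum(loaded[c("ob", "ib", "cb")]), 1e-6)
})

test_that("fast-unbinding drug yields less paced steady-state block than a trapped drug of identical equilibrium affinity", {
  mk <- function(Ku, Vhalf) list(Kmax = 1e6, Ku = Ku, n = 0.9,
                                 halfmax = 4.157e6, Vhalf = Vhalf)
  run <- function(Ku, Vhalf) {
    p <- ord_params(drug_conc = 10, binding = mk(Ku, Vhalf))
    pace_to_steady_state(ctrl2000()$state, p,
                         pacing_protocol(cl = 2000, n_beats = 300))
  }
  # identical equilibrium affinity (same Kmax/halfmax, hence same Kb/Ku)
  slow <- run(1e-5, -1)     # trapped: no diastolic escape
  fast <- run(5e-3, -90)    # unbinds freely at the resting potential
  bound <- function(res) sum(res$state[c("kr_ob", "kr_ib", "kr_cb")])
  # the trapped drug retains its block through diastole (states sampled at
  # end-diastole), the fast drug re-equilibrates within every beat
  expect_gt(bound(slow), bound(fast))
  expect_gt(bound(slow), 2 * bound(fast))
})

test_that("washout: removing drug and pacing returns qNet to control within 1%", {
  # load a fast-unbinding drug, then wash out
  drugged <- apply_drug(ord_params(), drug_panel()$quinidine, 5)
  loaded <- pace_to_steady_state(ctrl2000()$state, drugged,
                                 pacing_protocol(cl = 2000, n_beats = 200))
  washed <- pace_to_steady_state(loaded$state, ord_params(),
                                 pacing_protocol(cl = 2000,
                                                 n_beats = 1000))
  q_ctrl <- qnet(ctrl_beat2000())
  q_wash <- qnet(washed$beats[[2]])
  expect_lt(abs(q_wash - q_ctrl) / abs(q_ctrl), 0.01)
})
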