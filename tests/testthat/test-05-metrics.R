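## a small synthetic beat record with known geometry, for closed-form checks
synthetic_beat <- function() {
  tt <- seq(0, 1000, by = 1)
  V <- rep(-85, length(tt))
  # 1-ms linear upstroke to +35, plateau, linear repolarization 250-400 ms
  V[tt >= 2 & tt < 3] <- -85 + 120 * (tt[tt >= 2 & tt < 3] - 2)
  V[tt >= 3 & tt <= 250] <- 35
  ramp <- tt > 250 & tt <= 400
  V[ramp] <- 35 - 120 * (tt[ramp] - 250) / 150
  cur <- matrix(0, length(tt), 16,
                dimnames = list(NULL, cipaord:::.current_names))
  cur[, "IKr"] <- 0.5      # constant outward
  cur[, "INaL"] <- -0.2    # constant inward
  ca <- 1e-4 + 4e-4 * exp(-(tt - 30)^2 / 2000) * (tt > 5)
  structure(list(time = tt, V = V, Cai = ca, currents = cur, cl = 1000,
                 end_state = NULL), class = "beat_record")
}

test_that("APD measures a known triangle-wave beat correctly", {
  b <- synthetic_beat()
  # amplitude 120, APD90 crossing at V = 35 - 0.9*120 = -73 ->
  # t = 250 + 150*(108/120) = 385; upstroke max-slope point at t = 2
  expect_equal(apd(b, 0.9), 383, tolerance = 0.01)
  expect_equal(apd(b, 0.5), 250 + 150 * (60 / 120) - 2, tolerance = 0.01)
  # a beat truncated mid-plateau never repolarizes to the APD90 level
  keep <- b$time <= 240
  b_cut <- structure(list(time = b$time[keep], V = b$V[keep],
                          Cai = b$Cai[keep],
                          currents = b$currents[keep, , drop = FALSE],
                          cl = 1000, end_state = NULL),
                     class = "beat_record")
  expect_true(is.na(apd(b_cut, 0.9)))
})

test_that("charges integrate exactly on constant currents and add up", {
  b <- synthetic_beat()
  expect_equal(per_current_charge(b, "IKr"), 0.5 * 1000 / 1000)
  expect_equal(per_current_charge(b, "INaL"), -0.2)
  expect_equal(qnet(b), 0.3)   # only IKr + INaL are nonzero
})

test_that("qNet equals the sum of its six per-current charges (additivity < 1e-4)", {
  b <- ctrl_beat2000()
  parts <- sum(vapply(c("ICaL", "INaL", "IKr", "IKs", "IK1", "Ito"),
                      function(cc) per_current_charge(b, cc), 0))
  expect_lt(abs(qnet(b) - parts), 1e-4)
})

test_that("cqInward is 1 against itself and requires matching cycle lengths", {
  b <- ctrl_beat2000()
  expect_equal(cq_inward(b, b), 1)
  b2 <- b
  b2$cl <- 1000
  expect_error(cq_inward(b2, b), "cycle length")
})

test_that("metric panel carries every candidate metric and a validity flag", {
  pan <- metric_panel(ctrl_beat2000(), ctrl_beat2000(),
                      prev_beat = ctrl2000()$beats[[1]])
  need <- c("resting_Vm", "dVdt_max", "peak_Vm", "APD50", "APD90",
            "APDtri", "diastolic_Ca", "peak_Ca", "CaD50", "CaD90",
            "Catri", "qNet", "qKr", "qNaL", "qCaL", "qKs", "qK1", "qto",
            "cqInward", "ead", "alternans", "valid")
  expect_true(all(need %in% names(pan)))
  expect_true(pan$valid)
  expect_gt(pan$APDtri, 0)
  expect_gt(pan$peak_Ca, pan$diastolic_Ca)
  expect_lt(pan$qNaL, 0)   # inward charges are negative
  expect_lt(pan$qCaL, 0)
  expect_gt(pan$qKr, 0)
})

test_that("qNet is grid-stable: halving the coarse grid changes it < 1e-3", {
  st <- ctrl2000()$state
  b1 <- record_beat(st, ord_params(), pacing_protocol(cl = 2000))
  t2 <- sort(unique(c(seq(0, 20, by = 0.01), seq(20, 2000, by = 0.5), 0.5)))
  out <- cipaord:::.integrate_beat(st, ord_params(), 2000, 0.5, -80, t2)
  b2 <- structure(list(time = out[, "time"], V = out[, "V"],
                       Cai = out[, "cai"],
                       currents = out[, cipaord:::.current_names],
                       cl = 2000, end_state = NULL),
                  class = "beat_record")
  expect_lt(abs(qnet(b1) - qnet(b2)), 1e-3)
})

test_that("invalid-dose substitution replaces flagged rows by the last valid dose", {
  tab <- data.frame(drug = c("control", "x", "x", "x"),
                    conc_multiple = c(0, 1, 2, 3), cl = 2000,
                    qNet = c(0.06, 0.05, 0.02, -0.1),
                    APD90 = c(300, 320, 380, 900),
                    ead = c(FALSE, FALSE, FALSE, TRUE),
                    alternans = FALSE,
                    valid = c(TRUE, TRUE, TRUE, FALSE))
  out <- substitute_invalid_doses(tab)
  expect_equal(out$qNet[4], 0.02)
  expect_equal(out$APD90[4], 380)
  expect_true(out$substituted[4])
  expect_false(any(out$substituted[1:3]))
})
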