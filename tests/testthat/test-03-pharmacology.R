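test_that("Hill block fraction: half-max, zero dose, monotonicity, errors", {
  expect_equal(hill_block_fraction(10, 10, 1), 0.5)
  expect_equal(hill_block_fraction(10, 10, 0.7), 0.5)   # any Hill coefficient
  expect_equal(hill_block_fraction(0, 10, 1), 0)
  d <- hill_block_fraction(c(1, 10, 100, 1000), 10, 1)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 0 & d < 1))
  expect_error(hill_block_fraction(1, 0, 1), "> 0")
  expect_error(hill_block_fraction(1, 10, -1), "> 0")
  expect_error(hill_block_fraction(-1, 10, 1), ">= 0")
})

test_that("safety margin arithmetic and the dofetilide fixture value", {
  expect_equal(safety_margin(4.87, 2), 2.435)
  d <- drug_panel()$dofetilide
  expect_equal(safety_margin(d$ikr_ic50_nM, d$cmax), 2.435)
  expect_error(safety_margin(0, 2), "> 0")
})

test_that("fixture panel loads 12 drugs with the expected structure", {
  panel <- drug_panel()
  expect_length(panel, 12)
  risks <- vapply(panel, `[[`, 0, "risk_category")
  expect_equal(sum(risks == 3), 4)
  expect_equal(sum(risks == 2), 4)
  expect_equal(sum(risks == 1), 4)
  expect_true(all(vapply(panel, function(d) !is.null(d$binding), TRUE)))
})

test_that("mexiletine fixture reproduces its calibration block fractions at 10 uM", {
  m <- drug_panel()$mexiletine
  conc <- 10000  # nM
  h <- m$hill
  bNaL <- hill_block_fraction(conc, h$ic50_nM[h$channel == "INaL"],
                              h$hill[h$channel == "INaL"])
  bCaL <- hill_block_fraction(conc, h$ic50_nM[h$channel == "ICaL"],
                              h$hill[h$channel == "ICaL"])
  bKr <- hill_block_fraction(conc, m$ikr_ic50_nM, 1)
  expect_equal(bNaL, 0.54, tolerance = 1e-3)
  expect_equal(bCaL, 0.20, tolerance = 1e-3)
  expect_equal(bKr, 0.09, tolerance = 1e-2)
})

test_that("apply_drug at zero dose is the identity", {
  p0 <- ord_params()
  p <- apply_drug(p0, drug_panel()$quinidine, 0)
  expect_equal(p$block, p0$block)
  expect_equal(p$drug_conc, 0)
  expect_equal(unclass(p$scaling), unclass(p0$scaling))
  # and the simulated beat is bitwise the control beat
  b0 <- record_beat(ctrl2000()$state, p0, pacing_protocol(cl = 2000))
  b1 <- record_beat(ctrl2000()$state, p, pacing_protocol(cl = 2000))
  expect_identical(b0$V, b1$V)
})

test_that("apply_drug is stateless and composes block multiplicatively", {
  q <- drug_panel()$quinidine
  a <- apply_drug(ord_params(), q, 10)
  b <- apply_drug(ord_params(), q, 10)
  expect_equal(a, b)
  # drug binding never touches the IKr conductance scaler
  expect_equal(a$scaling[["IKr"]], ord_params()$scaling[["IKr"]])
  expect_gt(a$drug_conc, 0)
  # pre-existing block composes: 1-(1-b1)(1-b2)
  pre <- ord_params(block = c(INaL = 0.5))
  c1 <- apply_drug(pre, q, 10)
  bq <- hill_block_fraction(10 * q$cmax,
                            q$hill$ic50_nM[q$hill$channel == "INaL"],
                            q$hill$hill[q$hill$channel == "INaL"])
  expect_equal(c1$block[["INaL"]], 1 - 0.5 * (1 - bq))
})

test_that("static-IC50 variant reduces the IKr scaler and disables binding", {
  d <- drug_panel()$dofetilide
  p <- apply_drug_static_ikr(ord_params(), d, 1)
  expect_equal(p$drug_conc, 0)
  expect_null(p$binding)
  b <- hill_block_fraction(d$cmax, d$ikr_ic50_nM, 1)
  expect_equal(p$scaling[["IKr"]], 1.013 * (1 - b))
})

test_that("drug tables round-trip through CSV", {
  ext <- system.file("extdata", package = "cipaord")
  panel <- read_drug_table(file.path(ext, "fixture_drug_hill.csv"),
                           file.path(ext, "fixture_drug_ikr_binding.csv"),
                           file.path(ext, "fixture_drug_risk.csv"))
  expect_equal(sort(names(panel)), sort(names(drug_panel())))
  q <- panel$quinidine
  expect_equal(q$cmax, 3237)
  expect_s3_class(q$binding, "ikr_binding_params")
  # malformed CSV errors
  bad <- tempfile(fileext = ".csv")
  writeLines("drug,channel\nfoo,INa", bad)
  expect_error(read_drug_table(bad, file.path(
    ext, "fixture_drug_ikr_binding.csv")), "columns")
})

test_that("block conditions apply fixed fractions, IKr via the scaler", {
  p <- apply_block_condition(ord_params(), c(IKr = 0.70))
  expect_equal(p$scaling[["IKr"]], 1.013 * 0.30)
  p2 <- apply_block_condition(ord_params(),
                              c(INaL = 0.54, IKr = 0.09, ICaL = 0.20))
  expect_equal(p2$block[["INaL"]], 0.54)
  expect_equal(p2$block[["ICaL"]], 0.20)
  expect_equal(p2$scaling[["IKr"]], 1.013 * 0.91)
  expect_error(apply_block_condition(ord_params(), c(IKr = 1.2)), "0, 1")
  conds <- calibration_block_conditions()
  expect_setequal(names(conds), c("control", "e4031", "hmr1556",
                                  "nisoldipine", "bacl2", "mexiletine"))
})
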