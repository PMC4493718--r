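test_that("thresholds evaluate the printed crowding formulas", {
  p <- default_params
  th <- thresholds(p)
  # u_G = phi/(2 a_ox + a_glyc), v_G = phi/(2 a_LDH + a_glyc)
  expect_equal(th$u_G, 0.4 / (2 * 0.2 + 3e-3), tolerance = 1e-12)
  expect_equal(th$u_G, 0.9926, tolerance = 1e-4)
  expect_equal(th$v_G, 0.4 / (2 * 4.6e-4 + 3e-3), tolerance = 1e-12)
  expect_equal(th$v_G, 102.04, tolerance = 1e-4)
  expect_true(th$u_G < th$v_G)
  expect_true(0 < th$u_G0 && th$u_G1 == th$u_G + th$u_G0 && th$u_G1 < th$u_G2)
  # yield-38 identity: f_atp_min = 38 gives u_G0 = 1 exactly
  th38 <- thresholds(minimal_params(f_atp_min = 38))
  expect_identical(th38$u_G0, 1)
})

test_that("parameters round trip through a JSON file", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a_glyc = 4e-3, f_atp_min = 2), f,
                       auto_unbox = TRUE)
  p <- read_minimal_params(f)
  expect_equal(p$a_glyc, 4e-3)
  expect_equal(p$f_atp_min, 2)
  expect_equal(p$a_ox, 0.2)  # untouched default
  jsonlite::write_json(list(nonsense = 1), f, auto_unbox = TRUE)
  expect_error(read_minimal_params(f), "unknown parameter fields")
})

test_that("parameter validation rejects bad inputs", {
  expect_error(minimal_params(a_glyc = -1), "positive")
  expect_error(minimal_params(phi_atp = 0), "0, 1")
  expect_error(minimal_params(a_ldh = 0.5), "ordered")
  expect_error(single_cell_optimum(default_params, -1), "non-negative")
})

test_that("single-cell optimum is piecewise with full yield below u_G", {
  p <- default_params
  th <- default_th
  # below the crowding onset: fully oxidative, f_ATP = 38 U_G
  for (ug in c(0, 0.1, 0.5, th$u_G)) {
    cf <- single_cell_optimum(p, ug)
    expect_equal(cf$f_glyc, ug)
    expect_equal(cf$f_ox, 2 * ug)
    expect_equal(cf$f_ldh, 0)
    expect_equal(cf$f_atp, 38 * ug, tolerance = 1e-12)
  }
  expect_equal(single_cell_optimum(p, 0.5)$f_atp, 19)
  # overflow regime: crowding saturated, lactate secreted
  for (ug in c(th$u_G * 1.01, 10, 50, th$v_G)) {
    cf <- single_cell_optimum(p, ug)
    expect_gt(cf$f_ldh, 0)
    expect_lt(abs(crowding_slack(cf, p)), 1e-8)
  }
  # at full fermentation: no oxidation left, f_ATP = 2 v_G
  cf <- single_cell_optimum(p, th$v_G)
  expect_equal(cf$f_ox, 0, tolerance = 1e-9)
  expect_equal(cf$f_ldh, 2 * th$v_G, tolerance = 1e-9)
  expect_equal(cf$f_atp, 2 * th$v_G, tolerance = 1e-9)
  expect_equal(cf$f_atp, 204.1, tolerance = 1e-4)
  # beyond v_G the intake is capped and flagged
  cf2 <- single_cell_optimum(p, th$v_G * 2)
  expect_true(attr(cf2, "capped"))
  expect_equal(cf2$U_G_in, th$v_G)
})

test_that("mass balance, ATP accounting and crowding hold for all states", {
  p <- default_params
  th <- default_th
  grid <- c(seq(0, th$v_G, length.out = 41), th$u_G, th$v_G)
  for (ug in grid) {
    cf <- single_cell_optimum(p, ug)
    expect_equal(cf$f_ox + cf$f_ldh, 2 * cf$f_glyc, tolerance = 1e-10)
    expect_equal(cf$f_atp, 2 * cf$f_glyc + 18 * cf$f_ox, tolerance = 1e-10)
    expect_equal(cf$U_G_in, cf$f_glyc)
    slack <- crowding_slack(cf, p)
    expect_gte(slack, -1e-10)
    if (ug > th$u_G + 1e-9) expect_lt(abs(slack), 1e-8)
    if (ug < th$u_G - 1e-9) expect_gt(slack, 1e-8)
  }
})

test_that("single-cell optimum is continuous at both thresholds", {
  p <- default_params
  th <- default_th
  for (t0 in c(th$u_G, th$v_G)) {
    lo <- single_cell_optimum(p, t0 - 1e-10)
    hi <- single_cell_optimum(p, t0 + 1e-10)
    for (fld in c("f_glyc", "f_ox", "f_ldh", "f_atp"))
      expect_lt(abs(lo[[fld]] - hi[[fld]]), 1e-7)
  }
})

test_that("two-cell solution has the four-regime structure", {
  p <- default_params
  th <- default_th
  expect_error(two_cell_solution(p, 1.9 * th$u_G0), "starvation")

  # glucose-shared: acceptor gets exactly u_G0, both fully oxidative
  s <- two_cell_solution(p, (2 * th$u_G0 + th$u_G1) / 2)
  expect_identical(s$regime, "glucose-shared")
  expect_equal(s$acceptor_min$U_G_in, th$u_G0)
  expect_equal(s$acceptor_min$f_ldh, 0)
  expect_equal(s$donor$f_ldh, 0)
  expect_equal(s$acceptor_min$f_atp, p$f_atp_min, tolerance = 1e-12)
  expect_identical(s$acceptor_min, s$acceptor_max)
  expect_equal(s$delta_U_G, 0)

  # lactate-subsidized: acceptor imports lactate, held at survival ATP
  ug_mid <- (th$u_G1 + th$u_G2) / 2
  s2 <- two_cell_solution(p, ug_mid)
  expect_identical(s2$regime, "lactate-subsidized")
  expect_lt(s2$acceptor_min$f_ldh, 0)
  expect_gt(s2$donor$f_ldh, 0)
  expect_equal(s2$acceptor_min$f_ldh, -s2$donor$f_ldh, tolerance = 1e-10)
  expect_equal(s2$acceptor_min$f_atp, p$f_atp_min, tolerance = 1e-10)
  expect_true(s2$delta_U_G > 0 && s2$delta_U_G < th$u_G0)
  # donor overflow line: f_LDH,don = (38/18) delta
  expect_equal(s2$donor$f_ldh, 38 / 18 * s2$delta_U_G, tolerance = 1e-10)

  # full sequestration: acceptor gets no glucose (U_G below v_G), imports
  s3 <- two_cell_solution(p, th$u_G2 * 1.5)
  expect_identical(s3$regime, "full-sequestration")
  expect_equal(s3$acceptor_min$U_G_in, 0, tolerance = 1e-9)
  expect_lt(s3$acceptor_min$f_ldh, 0)
  expect_equal(s3$delta_U_G, th$u_G0)
  rng <- attr(s3$acceptor_min, "range")
  expect_true(rng["hi", "f_atp"] > rng["lo", "f_atp"])
  expect_equal(rng["lo", "f_atp"], p$f_atp_min, tolerance = 1e-9)

  # shared-glucose bookkeeping holds everywhere
  for (s_i in list(s, s2, s3))
    expect_lte(s_i$donor$U_G_in + s_i$acceptor_min$U_G_in, s_i$U_G + 1e-9)
})

test_that("two-cell solution is continuous at u_G1 and u_G2", {
  p <- default_params
  th <- default_th
  for (t0 in c(th$u_G1, th$u_G2)) {
    lo <- two_cell_solution(p, t0 - 1e-10)
    hi <- two_cell_solution(p, t0 + 1e-10)
    for (fld in c("f_glyc", "f_ox", "f_ldh", "f_atp")) {
      expect_lt(abs(lo$donor[[fld]] - hi$donor[[fld]]), 1e-7)
      expect_lt(abs(lo$acceptor_min[[fld]] - hi$acceptor_min[[fld]]), 1e-7)
    }
  }
})

test_that("donor monotonicity and acceptor glucose decrease with supply", {
  p <- default_params
  th <- default_th
  grid <- seq(2 * th$u_G0, 2.5 * th$v_G, length.out = 200)
  sols <- lapply(grid, two_cell_solution, params = p)
  don_atp <- vapply(sols, function(s) s$donor$f_atp, 0)
  don_ldh <- vapply(sols, function(s) s$donor$f_ldh, 0)
  expect_true(all(diff(don_atp) >= -1e-9))
  expect_true(all(diff(don_ldh) >= -1e-9))
  band <- grid >= th$u_G1 & grid <= th$u_G2
  acc_in <- vapply(sols[band], function(s) s$acceptor_min$U_G_in, 0)
  expect_true(all(diff(acc_in) <= 1e-9))
})

test_that("analytic solution agrees with the LP oracle across all regimes", {
  p <- default_params
  th <- default_th
  grid <- sort(c(
    seq(2 * th$u_G0, th$u_G1, length.out = 30),
    seq(th$u_G1 + 1e-9, th$u_G2, length.out = 30),
    seq(th$u_G2 * 1.001, th$v_G, length.out = 30),
    seq(th$v_G * 1.02, 2.6 * th$v_G, length.out = 30)))
  worst <- 0
  for (ug in grid) {
    a <- two_cell_solution(p, ug)
    o <- lp_oracle(p, ug)
    expect_identical(a$regime, o$regime)
    dev <- mixed_dev(unlist(a$donor), unlist(o$donor))
    ra <- attr(a$acceptor_min, "range")
    if (is.null(ra)) {
      acc <- unlist(a$acceptor_min[c("f_glyc", "f_ox", "f_ldh", "U_G_in",
                                     "f_atp")])
      ra <- rbind(lo = acc, hi = acc)
    }
    dev <- max(dev, mixed_dev(ra, attr(o$acceptor_min, "range")))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-6)
})

test_that("LP oracle boundary and far-excess cases", {
  p <- default_params
  th <- default_th
  # at the survival boundary both cells sit exactly at f_atp_min
  o <- lp_oracle(p, 2 * th$u_G0)
  expect_equal(o$donor$f_atp, p$f_atp_min, tolerance = 1e-9)
  expect_equal(o$acceptor_min$f_atp, p$f_atp_min, tolerance = 1e-9)
  expect_error(lp_oracle(p, th$u_G0), "starvation")
  # glucose far beyond both cells' capacity: acceptor ATP ceiling equals its
  # own crowding-limited single-cell maximum
  o2 <- lp_oracle(p, th$u_G2 + 2.2 * th$v_G)
  own_max <- single_cell_optimum(p, th$v_G)$f_atp
  acc_hi <- attr(o2$acceptor_min, "range")["hi", "f_atp"]
  expect_gte(acc_hi, own_max - 1e-6)  # lactate can only help
})
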