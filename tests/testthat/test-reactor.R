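test_that("derivatives reproduce the mass balances mode by mode", {
  p <- lineB_params()
  opt <- lineB_optics()
  # batch, c_X = 1: dc_X/dt equals the specific growth rate
  sch <- batch_schedule()
  st <- reactor_state(c_X = 1, c_N = 500, c_P = 0, V = 5)
  d <- derivatives(st, p, opt, sch)
  r <- effective_rates(500, 1, 0, p, opt)
  expect_equal(unname(d["dc_X"]), r$r_X)
  expect_equal(unname(d["dV"]), 0)

  # semi-continuous D = 0.4 with growth switched off: pure washout
  p0 <- kinetic_params(0, 4.41, 15.29, 7.042)
  sch_d <- operation_schedule("semi_continuous_rate", t_end = 11,
                              initial = reactor_state(0.1, 500, 0, 5),
                              dilution = list(start_day = 0, rate = 0.4,
                                              c_N_f = 500))
  d <- derivatives(st, p0, opt, sch_d, time = 1)
  expect_equal(unname(d["dc_X"]), -0.4)
  expect_equal(unname(d["dV"]), 0)

  # fed-batch 0.2 L/d into 4 L: D = 0.05 d^-1 on all balances, dV/dt = 0.2
  sch_f <- operation_schedule("fed_batch", t_end = 12,
                              initial = reactor_state(0.1, 500, 0, 4),
                              feed = list(start_day = 0, rate = 0.2,
                                          c_N_f = 2500))
  st4 <- reactor_state(c_X = 1, c_N = 100, c_P = 2, V = 4)
  d <- derivatives(st4, p0, opt, sch_f, time = 1)
  expect_equal(unname(d["dc_X"]), -0.05 * 1)
  expect_equal(unname(d["dc_N"]), 0.05 * (2500 - 100))
  expect_equal(unname(d["dc_P"]), -0.05 * 2)
  expect_equal(unname(d["dV"]), 0.2)
})

test_that("batch trajectories obey the yield conservation law", {
  p <- lineB_params()
  opt <- lineB_optics()
  tr <- simulate_reactor(p, opt, batch_schedule(t_end = 10),
                         output_times = seq(0, 10, by = 0.5))
  lhs <- tr$biomass_gDW_per_L - tr$biomass_gDW_per_L[1]
  rhs <- p$y_X_N * (tr$nitrate_mg_per_L[1] - tr$nitrate_mg_per_L) / 1000
  expect_equal(lhs, rhs, tolerance = 1e-7)
})

test_that("saturating light and nitrate give exponential growth", {
  # k_I = 0 (light never limits), c_N0 >> k_N: c_X ~ c_X0 exp(r_X_max t)
  p <- kinetic_params(0.699, 4.41, 0, 7.042)
  opt <- lineB_optics()
  sch <- operation_schedule("batch", t_end = 1,
                            initial = reactor_state(0.1, 5000, 0, 5))
  tr <- simulate_reactor(p, opt, sch, output_times = seq(0, 1, by = 0.25))
  expected <- 0.1 * exp(0.699 * tr$time_d)
  expect_equal(tr$biomass_gDW_per_L, expected, tolerance = 0.01)
})

test_that("dilution faster than growth washes the culture out", {
  p <- lineB_params()  # r_X_max = 0.699 < D = 1.0
  opt <- lineB_optics()
  sch <- operation_schedule("semi_continuous_rate", t_end = 10,
                            initial = reactor_state(0.1, 500, 0, 5),
                            dilution = list(start_day = 2, rate = 1.0,
                                            c_N_f = 500))
  tr <- simulate_reactor(p, opt, sch, output_times = seq(2, 10, by = 1))
  expect_true(all(diff(tr$biomass_gDW_per_L) < 0))
  expect_lt(tr$biomass_gDW_per_L[nrow(tr)], tr$biomass_gDW_per_L[1] / 10)
})

test_that("line-B batch kinetics deplete nitrate and stop growth", {
  p <- lineB_params()
  opt <- lineB_optics()
  tr <- simulate_reactor(p, opt, batch_schedule(t_end = 10),
                         output_times = 0:10)
  final <- tr[nrow(tr), ]
  expect_lt(final$nitrate_mg_per_L, 5)
  expect_lt(final$growth_rate_per_d, 1e-3)
  expect_identical(final$limiting_regime, "nitrate")
  # growth ceased when nitrate ran out: biomass at its ceiling
  ceiling <- 0.1 + p$y_X_N * 500 / 1000
  expect_equal(final$biomass_gDW_per_L, ceiling, tolerance = 1e-3)
})

test_that("exchange events mix, conserve volume and fill the harvest ledger", {
  st <- reactor_state(c_X = 2, c_N = 10, c_P = 1, V = 5)
  ex <- apply_exchange_event(st, fraction = 0.4, fresh_nitrate = 500)
  expect_equal(ex$state$c_X, 1.2)
  expect_equal(ex$state$c_N, 10 * 0.6 + 500 * 0.4)
  expect_equal(ex$state$V, 5)
  expect_equal(ex$harvested_biomass, 0.4 * 5 * 2)

  # mixing arithmetic from the module contract
  st2 <- reactor_state(c_X = 1, c_N = 10, c_P = 0, V = 5)
  expect_equal(apply_exchange_event(st2, 0.2, 500)$state$c_N, 108)

  # two successive half-exchanges with product-free medium quarter c_P
  st3 <- reactor_state(c_X = 1, c_N = 100, c_P = 2, V = 5)
  once <- apply_exchange_event(st3, 0.5, 0)$state
  twice <- apply_exchange_event(once, 0.5, 0)$state
  expect_equal(twice$c_P, 0.5)

  expect_error(apply_exchange_event(st, 0, 500), "fraction")
  expect_error(apply_exchange_event(st, 1, 500), "fraction")
})

test_that("discrete daily exchanges reproduce the event arithmetic in-run", {
  p <- lineB_params()
  opt <- lineB_optics()
  ev <- data.frame(day = 6:8, fraction = 0.4, c_N_fresh = 500)
  sch <- operation_schedule("semi_continuous_events", t_end = 9,
                            initial = reactor_state(0.1, 500, 0, 5),
                            exchange_events = ev)
  tr <- simulate_reactor(p, opt, sch, output_times = seq(0, 9, by = 0.5))
  # trajectory reports the pre-exchange state at event times; the ledger
  # advances by fraction * V * c_X at each event
  led <- tr$harvested_biomass_g
  expect_equal(led[tr$time_d < 6], rep(0, sum(tr$time_d < 6)))
  pre6 <- tr[tr$time_d == 6, ]
  post <- tr[tr$time_d == 6.5, ]
  expect_equal(post$harvested_biomass_g,
               0.4 * 5 * pre6$biomass_gDW_per_L, tolerance = 1e-6)
  # and volume never changes
  expect_equal(tr$volume_L, rep(5, nrow(tr)))
})

test_that("fed-batch volume bookkeeping is exact", {
  p <- lineB_params()
  opt <- lineB_optics()
  sch <- operation_schedule("fed_batch", t_end = 12,
                            initial = reactor_state(0.1, 500, 0, 4),
                            feed = list(start_day = 7, rate = 0.2,
                                        c_N_f = 2500))
  tr <- simulate_reactor(p, opt, sch, output_times = 0:12)
  expect_equal(tr$volume_L, 4 + pmax(tr$time_d - 7, 0) * 0.2,
               tolerance = 1e-10)
})

test_that("product never degrades when k_pd = 0 and never turns negative", {
  p <- kinetic_params(0.699, 4.41, 15.29, 7.042, r_p_max = 0.327,
                      k_p = 1.010, k_pd = 0)
  opt <- lineB_optics()
  tr <- simulate_reactor(p, opt, batch_schedule(t_end = 10),
                         output_times = seq(0, 10, by = 0.5))
  expect_true(all(diff(tr$product_mg_per_L) >= -1e-10))
  expect_true(all(as.matrix(tr[, 2:5]) >= 0))
})

test_that("halving the integration tolerances leaves trajectories unchanged", {
  p <- lineB_params()
  opt <- lineB_optics()
  sch <- batch_schedule(t_end = 9)
  t1 <- simulate_reactor(p, opt, sch, output_times = 0:9,
                         rtol = 1e-8, atol = 1e-10)
  t2 <- simulate_reactor(p, opt, sch, output_times = 0:9,
                         rtol = 5e-9, atol = 5e-11)
  for (col in c("biomass_gDW_per_L", "nitrate_mg_per_L", "product_mg_per_L")) {
    expect_equal(t1[[col]], t2[[col]], tolerance = 1e-6)
  }
})

test_that("compiled and pure-R right-hand sides integrate to the same run", {
  p <- lineB_params()
  opt <- lineB_optics()
  sch <- batch_schedule(t_end = 4)
  tc <- simulate_reactor(p, opt, sch, output_times = 0:4, engine = "compiled")
  tr <- simulate_reactor(p, opt, sch, output_times = 0:4, engine = "R")
  expect_equal(tc$biomass_gDW_per_L, tr$biomass_gDW_per_L, tolerance = 1e-4)
  expect_equal(tc$nitrate_mg_per_L, tr$nitrate_mg_per_L, tolerance = 1e-4)
  expect_equal(tc$product_mg_per_L, tr$product_mg_per_L, tolerance = 1e-4)
})

test_that("a light step in the schedule changes growth when it happens", {
  p <- lineB_params()
  opt_step <- optical_geometry(0.049, 8.75,
                               data.frame(from_day = c(0, 2),
                                          I0 = c(160, 350)))
  sch <- batch_schedule(t_end = 4)
  tr_step <- simulate_reactor(p, opt_step, sch, output_times = 0:4)
  tr_const <- simulate_reactor(p, lineB_optics(), sch, output_times = 0:4)
  # dimmer start -> less biomass early; schedules coincide later in force
  expect_lt(tr_step$biomass_gDW_per_L[3], tr_const$biomass_gDW_per_L[3])
  expect_equal(light_at(opt_step, 1), 160)
  expect_equal(light_at(opt_step, 2.5), 350)
})

test_that("trajectory export writes the documented CSV layout", {
  p <- lineB_params()
  tr <- simulate_reactor(p, lineB_optics(), batch_schedule(t_end = 2),
                         output_times = 0:2)
  path <- tempfile(fileext = ".csv")
  export_trajectory(tr, path, comments = "config_md5: abc")
  lines <- readLines(path)
  expect_true(any(grepl("^# config_md5: abc", lines)))
  df <- utils::read.csv(path, comment.char = "#")
  expect_identical(names(df),
                   c("time_d", "biomass_gDW_per_L", "nitrate_mg_per_L",
                     "product_mg_per_L", "volume_L", "growth_rate_per_d",
                     "limiting_regime"))
  expect_equal(nrow(df), 3L)
})
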