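# Lung-function metrics: unit behaviour on synthetic traces and
# physiological orderings across the disease scenarios.

test_that("tidal volume is zero for a constant-volume trace", {
  h <- synthetic_history(rep(0.5, 101L), rep(0, 101L))
  expect_equal(tidal_volume(h), 0)
})

test_that("compliance recovers the slope of a linear spring exactly", {
  p <- seq(0, 244, length.out = 101L)
  C <- 3.1e-4
  h <- synthetic_history(0.5 + C * p, -p)
  expect_equal(compliance(h), C, tolerance = 1e-10)
  h0 <- synthetic_history(rep(0.5, 11L), rep(0, 11L))
  expect_error(compliance(h0), class = "acinusim_degenerate_input")
})

test_that("a sinusoidal volume trace gives PIF equal to PEF", {
  tt <- seq(0, 4, by = 0.01)
  V <- 0.5 + 0.05 * (1 - cos(pi / 2 * tt)) / 2
  h <- synthetic_history(V, -244 * (0.5 - 0.5 * cos(pi / 2 * tt)))
  pf <- peak_flows(h)
  expect_equal(unname(pf["PIF"]), unname(pf["PEF"]), tolerance = 0.02)
  lp <- loops(h)
  # loops close over a full cycle
  expect_equal(lp$fv$volume[1], utils::tail(lp$fv$volume, 1),
               tolerance = 0.01 * 0.05)
})

test_that("resistance halves when flow doubles at fixed pressure drop", {
  tt <- seq(0, 4, by = 0.01)
  V <- 0.5 + 0.05 * (1 - cos(pi / 2 * tt)) / 2
  h1 <- synthetic_history(V, -244 * (0.5 - 0.5 * cos(pi / 2 * tt)))
  h2 <- h1
  h2$df$flow <- 2 * h1$df$flow           # doubled flow, same p_drop trace
  expect_equal(acinus_resistance(h2), acinus_resistance(h1) / 2,
               tolerance = 0.05)
})

test_that("comparing identical reports yields zero percent differences", {
  r <- scenario_report("healthy")
  r2 <- r; r2$scenario <- "NSIP"
  r3 <- r; r3$scenario <- "IPF"
  tab <- compare_scenarios(list(r, r2, r3))
  expect_true(all(abs(tab$pct_nsip_vs_healthy) < 1e-12))
  expect_true(all(abs(tab$pct_nsip_vs_ipf) < 1e-12))
})

test_that("reported flow equals the numerical dV/dt of the volume trace", {
  h <- scenario_history("healthy")
  df <- h$df
  n <- nrow(df)
  dv <- (df$volume[3:n] - df$volume[1:(n - 2)]) / (df$time[3:n] - df$time[1:(n - 2)])
  err <- max(abs(df$flow[2:(n - 1)] - dv)) / max(abs(dv))
  expect_lt(err, 0.01)
})

test_that("fibrosis stiffens the acinus and raises its resistance", {
  rh <- scenario_report("healthy")
  rn <- scenario_report("nsip")
  ri <- scenario_report("ipf")
  expect_gt(rh$tidal_volume, rn$tidal_volume)
  expect_gt(rh$tidal_volume, ri$tidal_volume)
  expect_gt(rh$compliance, rn$compliance)
  expect_gt(rh$compliance, ri$compliance)
  # both fibrotic patterns impede flow relative to healthy
  expect_gt(rn$resistance, rh$resistance)
  expect_gt(ri$resistance, rh$resistance)
  expect_gt(rh$max_pressure_drop, rn$max_pressure_drop)
  expect_gt(rh$max_pressure_drop, ri$max_pressure_drop)
  # healthy flow and shear dominate the diseased models
  expect_gt(rh$pif, rn$pif)
  expect_gt(rh$max_wss, rn$max_wss)
  expect_gt(rh$max_wss, ri$max_wss)
  # secondary septa carry higher peak stress than primary septa (healthy)
  expect_gt(rh$peak_stress_secondary, rh$peak_stress_primary)
})

test_that("loops close and stay within the physical volume band", {
  h <- scenario_history("healthy")
  lp <- loops(h)
  tv <- tidal_volume(h)
  expect_lt(abs(lp$pv$volume[1] - utils::tail(lp$pv$volume, 1)), 0.01 * tv)
  expect_true(all(lp$pv$volume >= h$V0 - 0.01 * tv))
  expect_true(all(lp$pv$volume <= h$V0 + tv * 1.01))
})

test_that("mismatched configurations are refused in comparisons", {
  r1 <- scenario_report("healthy")
  r2 <- r1; r2$dt <- 0.02; r2$scenario <- "NSIP"
  expect_error(compare_scenarios(list(r1, r2)),
               class = "acinusim_invalid_parameter")
})
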