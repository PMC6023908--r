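test_that("schedule construction validates its inputs", {
  expect_s3_class(injection_schedule(), "injection_schedule")
  expect_error(injection_schedule(numeric(0)), "non-empty")
  expect_error(injection_schedule(c(10, -1)), "positive")
  expect_error(injection_schedule(10, cell_ul = 5), "cell volume")
})

test_that("overflow dilution matches hand values and an iterative mass balance", {
  one <- injection_schedule(10, exclude_first = FALSE)
  conc <- concentrations_after_injections(one)
  expect_equal(conc$lipid_M, 0.01 * 10 / 1456.5, tolerance = 1e-12)
  expect_equal(conc$solute_M, 1e-5 * (1 - 10 / 1456.5), tolerance = 1e-12)

  sched <- injection_schedule()  # 2 uL + 28 x 10 uL
  conc <- concentrations_after_injections(sched)
  orc <- oracle_concentrations(sched$injection_ul, sched$cell_ul,
                               sched$syringe_lipid_M, sched$cell_solute_M)
  expect_equal(conc$lipid_M, unname(orc[, "lipid_M"]), tolerance = 1e-12)
  expect_equal(conc$solute_M, unname(orc[, "solute_M"]), tolerance = 1e-12)
  # lipid accumulates, solute dilutes
  expect_true(all(diff(conc$lipid_M) > 0))
  expect_true(all(diff(conc$solute_M) < 0))
  # no-dilution variant holds the solute constant
  conc0 <- concentrations_after_injections(sched, dilute_solute = FALSE)
  expect_equal(unique(conc0$solute_M), sched$cell_solute_M)
})

test_that("thermogram integration recovers pulse areas on and off a baseline", {
  sched <- injection_schedule(rep(10, 3), exclude_first = FALSE)
  t <- seq(0, 4 * 600, by = 1)

  # constant zero heat flow: all heats zero
  flat <- data.frame(time_s = t, heat_flow_ucal_per_s = 0)
  h <- integrate_thermogram(flat, sched)
  expect_equal(h$heat_ucal, rep(0, 3))

  # exponential pulses with closed-form area A * tau = -12 ucal each
  tau <- 30; area <- -12
  hf <- numeric(length(t))
  for (i in 1:3) {
    on_t <- t >= i * 600
    hf[on_t] <- hf[on_t] + area / tau * exp(-(t[on_t] - i * 600) / tau)
  }
  pulses <- data.frame(time_s = t, heat_flow_ucal_per_s = hf)
  h <- integrate_thermogram(pulses, sched)
  expect_equal(h$heat_ucal, rep(area, 3), tolerance = 0.01)

  # the same pulses atop a constant 0.5 ucal/s offset: baseline removed
  offset <- pulses
  offset$heat_flow_ucal_per_s <- offset$heat_flow_ucal_per_s + 0.5
  h2 <- integrate_thermogram(offset, sched)
  expect_equal(h2$heat_ucal, rep(area, 3), tolerance = 0.01)

  # cumulative heat is the running sum of per-injection heats
  expect_equal(h$cumulative_ucal, cumsum(h$heat_ucal))
})

test_that("integration rejects truncated or disordered thermograms", {
  sched <- injection_schedule(rep(10, 3), exclude_first = FALSE)
  short <- data.frame(time_s = seq(0, 1500), heat_flow_ucal_per_s = 0)
  expect_error(integrate_thermogram(short, sched), "injection 2")
  bad <- data.frame(time_s = c(0, 2, 1, 3), heat_flow_ucal_per_s = 0)
  expect_error(integrate_thermogram(bad, sched), "increasing")
})

test_that("partition model evaluation matches limits and a hand value", {
  V <- 1.4565e-3
  expect_equal(eval_partition_model(0, -5000, V, 1e-5, 1e-3), 0)
  # saturation plateau at large K
  sat <- eval_partition_model(1e12, -5000, V, 1e-5, 1e-3)
  expect_equal(sat, -5000 * V * 1e-5, tolerance = 1e-6)
  # K * C_L = 1 gives exactly half the plateau
  expect_equal(eval_partition_model(1000, -5000, V, 1e-5, 1e-3),
               -3.64125e-5, tolerance = 1e-10)
  expect_error(eval_partition_model(-1, -5000, V, 1e-5, 1e-3),
               "non-negative")
})

test_that("predicted heat scales linearly in dH and C_A, monotonically in C_L", {
  V <- 1.4565e-3
  base <- eval_partition_model(500, -4000, V, 1e-5, 5e-4)
  expect_equal(eval_partition_model(500, -8000, V, 1e-5, 5e-4), 2 * base)
  expect_equal(eval_partition_model(500, -4000, V, 3e-5, 5e-4), 3 * base)
  cl <- seq(1e-5, 5e-3, length.out = 40)
  heats <- abs(eval_partition_model(500, -4000, V, 1e-5, cl))
  expect_true(all(diff(heats) > 0))
})

test_that("noiseless generate-fit round trip recovers K and dH across the range", {
  set.seed(11)
  draws <- cbind(K = exp(runif(8, log(10), log(1e5))),
                 dH = -exp(runif(8, log(100), log(1e4))))
  for (r in seq_len(nrow(draws))) {
    g <- gen_itc(K = draws[r, "K"], dH = draws[r, "dH"])
    fit <- fit_partition(injection_heats(g$truth$heat_ucal, g$schedule))
    expect_true(fit$converged)
    expect_lt(abs(fit$K - draws[r, "K"]) / draws[r, "K"], 1e-3)
    expect_lt(abs(fit$dH - draws[r, "dH"]) / abs(draws[r, "dH"]), 1e-3)
  }
  # through the full thermogram rendering and integration path
  g <- gen_itc(K = 800, dH = -4000)
  fit <- fit_partition(integrate_thermogram(g$thermogram, g$schedule))
  expect_lt(abs(fit$K - 800) / 800, 1e-3)
  expect_lt(abs(fit$dH + 4000) / 4000, 1e-3)
})

test_that("degenerate heats are flagged non-identifiable without an exception", {
  sched <- injection_schedule()
  fit <- fit_partition(injection_heats(rep(0, 29), sched))
  expect_false(fit$converged)
  expect_true(is.na(fit$K))
  expect_match(fit$message, "identifiable")
})

test_that("fit_partition honours the accessible-lipid option", {
  g <- gen_itc(K = 800, dH = -4000)
  h <- injection_heats(g$truth$heat_ucal, g$schedule)
  full <- fit_partition(h)
  half <- fit_partition(h, accessible_lipid_fraction = 0.5)
  # halving the accessible lipid doubles the apparent K
  expect_equal(half$K, 2 * full$K, tolerance = 1e-3)
})
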