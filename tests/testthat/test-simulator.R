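test_that("identical configuration and seed give bit-identical trajectories", {
  net <- make_model5(0.005, 0.8)
  a <- simulate(net, 5000, seed = 42)
  b <- simulate(net, 5000, seed = 42)
  expect_identical(a$I, b$I)
  expect_identical(a$J, b$J)
  expect_identical(a$event, b$event)
})

test_that("compiled and R engines consume the RNG identically", {
  nets <- list(make_model3(0.005, 0.5), make_model5(0.005, 0.8),
               make_follicle_model(0.05, 0.5, h = 0.3))
  for (net in nets) {
    a <- simulate(net, 2000, seed = 11, engine = "native",
                  stop_on_extinction = FALSE)
    b <- simulate(net, 2000, seed = 11, engine = "r",
                  stop_on_extinction = FALSE)
    expect_identical(a$I, b$I)
    expect_identical(a$J, b$J)
    expect_identical(a$event, b$event)
  }
  # also with injuries, which add one uniform per update
  inj <- injury_config(0.01, 0.1)
  a <- simulate(nets[[2]], 2000, seed = 5, injury = inj)
  b <- simulate(nets[[2]], 2000, seed = 5, injury = inj, engine = "r")
  expect_identical(a$J, b$J)
  expect_identical(a$event, b$event)
})

test_that("replaying the event log reproduces the stored counts", {
  net <- make_model5(0.005, 0.6)
  inj <- injury_config(0.005, 0.2)
  traj <- simulate(net, 4000, seed = 9, injury = inj)
  init <- as.integer(attr(traj, "init"))
  I <- init[1]; J <- init[2]
  recI <- integer(nrow(traj)); recJ <- integer(nrow(traj))
  for (r in seq_len(nrow(traj))) {
    switch(traj$event[r],
      diff = { I <- I - 1L; J <- J + 2L },
      prolif = { I <- I + 1L },
      asym = { J <- J + 1L },
      death = { J <- J - 1L },
      influx = { I <- I + 1L },
      injury = { J <- J - as.integer(floor(0.2 * J + 0.5)) },
      none = NULL)
    recI[r] <- I; recJ[r] <- J
  }
  expect_identical(recI, traj$I)
  expect_identical(recJ, traj$J)
})

test_that("event repertoire follows the division-symmetry weights", {
  # S = 1: no asymmetric divisions
  full <- simulate(make_model5(0.005, 1), 5000, seed = 3)
  expect_false("asym" %in% full$event)
  # S = 0: only asymmetric divisions and deaths
  asym <- simulate(network_all_asymmetric(), 5000, seed = 3,
                   init = c(50, 50), stop_on_extinction = FALSE)
  expect_true(all(asym$event %in% c("asym", "death", "none")))
  expect_true("asym" %in% asym$event)
})

test_that("populations never go negative and extinction is reported", {
  traj <- simulate(network_death_heavy(), 5000, seed = 8, init = c(5, 3),
                   stop_on_extinction = FALSE)
  expect_gte(min(traj$J), 0)
  expect_gte(min(traj$I), 0)
  dead <- simulate(network_death_heavy(), 5000, seed = 8, init = c(1, 3))
  expect_true(attr(dead, "status") %in% c("extinct", "completed"))
  # a rate-free network freezes immediately and says so
  frozen <- control_network(L = function(x, y) 0, P = function(x, y) 0.5,
                            D = function(x, y) 0, S = function(x, y) 1,
                            epsilon = 0.01)
  tr <- simulate(frozen, 10, seed = 1, init = c(5, 5))
  expect_identical(attr(tr, "status"), "frozen")
})

test_that("moment estimates agree between streaming and trajectory paths", {
  net <- make_model3(0.005, 0.5)
  traj <- simulate(net, 20000, seed = 21, burn_in = 500)
  m1 <- estimate_moments(traj, burn_in = 500)
  m2 <- simulate(net, 20000, seed = 21, burn_in = 500, keep = "moments")
  expect_equal(m1$mean_I, m2$mean_I, tolerance = 1e-10)
  expect_equal(m1$var_J, m2$var_J, tolerance = 1e-8)
  expect_equal(m1$rel_sd_J, m2$rel_sd_J, tolerance = 1e-8)
  expect_equal(m1$cv_J, sqrt(m1$var_J) / m1$mean_J)
  # degenerate cases
  const <- structure(data.frame(step = 1:10, I = 5L, J = 7L,
                                event = "none"),
                     status = "completed",
                     class = c("trajectory", "data.frame"))
  m0 <- estimate_moments(const)
  expect_equal(m0$var_I, 0)
  expect_equal(m0$var_J, 0)
  expect_error(estimate_moments(traj, burn_in = nrow(traj)), "burn_in")
})

test_that("micro-injury events occur at the configured rate", {
  inj <- injury_config(0.01, 0.1)
  traj <- simulate(make_model5(0.005, 0.8), 5000, seed = 13, injury = inj)
  n_inj <- sum(traj$event == "injury")
  expect_gt(n_inj, 0)
  # binomial(5000, 0.01): mean 50, sd ~ 7; allow 4 sd
  expect_lt(abs(n_inj - 50), 4 * sqrt(5000 * 0.01 * 0.99))
  # injuries remove differentiated cells
  at <- which(traj$event == "injury")[1]
  prevJ <- if (at == 1) attr(traj, "init")[2] else traj$J[at - 1]
  expect_equal(traj$J[at], prevJ - floor(0.1 * prevJ + 0.5))
})

test_that("simulated moments track the linear-noise predictions", {
  # short replicate check; the full grid lives in the acceptance suite.
  # The stationary mean of the nonlinear process sits an O(1)-cell
  # second-order correction away from (i0, j0), so means are compared at a
  # few-percent tolerance while variances use the 20% theory band.
  for (setup in list(list(net = make_model5(0.005, 0.8), S = 0.8),
                     list(net = make_model3(0.005, 0.5), S = 0.5))) {
    eq <- solve_mixed(setup$net)
    ct <- evaluate_controls(setup$net, c(eq$x0, eq$y0))
    lna <- lna_moments(eq, ct, setup$S)
    ms <- lapply(1:5, function(r) {
      simulate(setup$net, 2e5, seed = 700 + r, keep = "moments")
    })
    mean_I <- mean(vapply(ms, `[[`, 1, "mean_I"))
    mean_J <- mean(vapply(ms, `[[`, 1, "mean_J"))
    var_I <- mean(vapply(ms, `[[`, 1, "var_I"))
    expect_lt(abs(mean_I - eq$i0) / eq$i0, 0.05)
    expect_lt(abs(mean_J - eq$j0) / eq$j0, 0.05)
    expect_lt(abs(var_I - lna$var_I) / lna$var_I, 0.2)
  }
})

test_that("fluctuations shrink as the control strength grows", {
  vars <- sapply(c(0.005, 0.02, 0.05), function(eps) {
    m <- simulate(make_model5(eps, 0.8), 1e5, seed = 31, keep = "moments")
    c(m$mean_I, m$var_I, m$var_J)
  })
  expect_true(all(diff(vars[1, ]) < 0))
  expect_true(all(diff(vars[2, ]) < 0))
  expect_true(all(diff(vars[3, ]) < 0))
})

test_that("exact event-time scheme yields a continuous clock and no idle draws", {
  net <- make_follicle_model(0.05, 0.5, h = 0.3)
  traj <- simulate(net, 2000, seed = 17, scheme = "exact",
                   stop_on_extinction = FALSE)
  expect_true("time" %in% names(traj))
  expect_true(all(diff(traj$time) > 0))
  expect_false("none" %in% traj$event)
})

test_that("symmetry sweeps tabulate replicates with derived seeds", {
  net <- make_model5(0.01, 0.5)
  sw <- sweep_symmetry(net, S_values = c(0.4, 0.8), replicates = 2,
                       steps = 3000, seed = 100)
  expect_equal(nrow(sw), 4)
  expect_equal(sw$seed, c(100, 101, 102, 103))
  # a single cell reproduces a direct moments run with the derived seed
  one <- sweep_symmetry(net, S_values = 0.8, replicates = 1, steps = 3000,
                        seed = 55)
  direct <- simulate(sclineage:::set_symmetry(net, 0.8), 3000, seed = 55,
                     keep = "moments")
  expect_equal(one$mean_J, direct$mean_J, tolerance = 1e-12)
  expect_equal(one$var_I, direct$var_I, tolerance = 1e-10)
  ag <- aggregate_sweep(sw)
  expect_equal(nrow(ag), 2)
  expect_equal(ag$replicates, c(2, 2))
})

test_that("equilibrium initial states are the rounded-up expected values", {
  net <- make_model5(0.005, 0.8)
  eq <- solve_mixed(net)
  traj <- simulate(net, 10, seed = 1)
  expect_equal(attr(traj, "init"), c(ceiling(eq$i0), ceiling(eq$j0)))
  # with an exogenous source the starting point is the influx-aware
  # mean-field attractor, which exceeds the closed-system value of J
  fol <- make_follicle_model(0.05, 0.3, h = 0.3, influx = TRUE)
  closed_eq <- solve_mixed(make_follicle_model(0.05, 0.3, h = 0.3,
                                               influx = FALSE))
  trf <- simulate(fol, 10, seed = 1, stop_on_extinction = FALSE)
  expect_gt(attr(trf, "init")[2], ceiling(closed_eq$j0))
})

test_that("invalid simulator configurations are rejected", {
  net <- make_model5(0.01, 0.5)
  expect_error(simulate(net, 0, seed = 1), "steps")
  expect_error(simulate(net, 100, seed = 1, init = c(0, 5)), "stem-cell")
  expect_error(simulate(net, 100, seed = 1, init = c(-1, 5)), "init")
  expect_error(simulate(net, 100, seed = 1, injury = list(a = 1)),
               "injury_config")
  expect_error(injury_config(1.5), "\\[0, 1\\]")
  expect_error(sweep_symmetry(net, c(0, 0.5), 1, 100, 1), "S_values")
  expect_error(simulate(network_all_asymmetric(), 100, seed = 1,
                        init = c(10, 10), engine = "native"),
               "presets")
})
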