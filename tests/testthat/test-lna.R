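analysis_for <- function(net, S_star) {
  eq <- solve_mixed(net)
  ct <- evaluate_controls(net, c(eq$x0, eq$y0))
  lna_moments(eq, ct, S_star)
}

test_that("variances at the preset equilibria match the closed forms", {
  # frozen values derived by substituting the printed control derivatives
  # into Var = K/(4 B Delta)
  r5 <- analysis_for(make_model5(0.005, 1), 1)
  expect_equal(r5$var_I, 78.7037, tolerance = 1e-5)
  expect_equal(r5$var_J, 3055.5556, tolerance = 1e-5)
  expect_equal(r5$mean_I, 40.5465, tolerance = 1e-4)
  expect_equal(r5$mean_J, 693.1472, tolerance = 1e-4)
  expect_true(r5$stable)

  r3 <- analysis_for(make_model3(0.005, 0.5), 0.5)
  expect_equal(r3$var_I, 115.8949, tolerance = 1e-5)
  expect_equal(r3$var_J, 127.6256, tolerance = 1e-5)
  expect_true(r3$stable)
})

test_that("Var[I] of the SC-driven preset is independent of the symmetry", {
  net <- make_model5(0.005, 0.5)
  eq <- solve_mixed(net)
  ct <- evaluate_controls(net, c(eq$x0, eq$y0))
  vals <- sapply(seq(0.1, 1, by = 0.1),
                 function(S) lna_moments(eq, ct, S)$var_I)
  expect_lt(max(abs(vals / vals[1] - 1)), 1e-12)
})

test_that("closed-form variances equal the brute-force moment-system solve", {
  set.seed(202)
  for (k in 1:50) {
    cs <- random_stable_controls(L_star = runif(1, 0.2, 0.9))
    eq <- structure(list(kind = "mixed", i0 = 10, j0 = 10,
                         L_star = cs$L_star, S_star = cs$S_star),
                    class = "equilibrium")
    lna <- lna_moments(eq, cs$controls, cs$S_star)
    # the oracle carries random first-derivative terms of L, S and D;
    # they must cancel through X10 = X01 = 0
    orc <- lna_oracle(cs$controls, cs$L_star, cs$S_star,
                      lx = runif(1, -1, 1), ly = runif(1, -1, 1),
                      sx = runif(1, -1, 1), sy = runif(1, -1, 1),
                      dx = runif(1, -1, 1), dy = runif(1, -1, 1))
    expect_lt(abs(orc$X10), 1e-6)
    expect_lt(abs(orc$X01), 1e-6)
    expect_equal(lna$var_I, orc$var_I, tolerance = 1e-10)
    expect_equal(lna$var_J, orc$var_J, tolerance = 1e-10)
  }
})

test_that("K_x and K_y are positive and variances positive when stable", {
  set.seed(303)
  for (k in 1:50) {
    cs <- random_stable_controls()
    eq <- structure(list(kind = "mixed", i0 = 1, j0 = 1,
                         L_star = cs$L_star, S_star = cs$S_star),
                    class = "equilibrium")
    lna <- lna_moments(eq, cs$controls, cs$S_star)
    expect_gt(lna$K_x, 0)
    expect_gt(lna$K_y, 0)
    expect_gt(lna$var_I, 0)
    expect_gt(lna$var_J, 0)
  }
})

test_that("critical symmetry and stability verdicts follow the B threshold", {
  eps <- 0.005
  m5 <- make_model5(eps, 0.5)
  eq5 <- solve_mixed(m5)
  ct5 <- evaluate_controls(m5, c(eq5$x0, eq5$y0))
  st5 <- stability(ct5, eq5$L_star, 0.5)
  expect_equal(st5$S_c, 0)
  for (S in c(0.05, 0.5, 1)) {
    expect_true(stability(ct5, eq5$L_star, S)$stable)
  }

  m3 <- make_model3(eps, 0.5)
  eq3 <- solve_mixed(m3)
  ct3 <- evaluate_controls(m3, c(eq3$x0, eq3$y0))
  st3 <- stability(ct3, eq3$L_star, 0.5)
  # p_x < p_y here, so the stable side is S* < S_c; S_c > 1 covers (0, 1]
  expect_equal(st3$S_c, 1.442695, tolerance = 1e-6)
  for (S in c(0.05, 0.5, 1)) {
    expect_true(stability(ct3, eq3$L_star, S)$stable)
  }

  # p_x = p_y: B does not depend on S*; S_c degenerates to a signed infinity
  expect_identical(stability(make_controls(1, -0.2, 0.3, 0.3), 0.5, 0.5)$S_c,
                   -Inf)
  expect_identical(stability(make_controls(1, 0.2, 0.3, 0.3), 0.5, 0.5)$S_c,
                   Inf)
  expect_true(is.nan(stability(make_controls(1, 0, 0.3, 0.3), 0.5, 0.5)$S_c))
  # Delta <= 0 is unstable no matter the symmetry
  for (S in c(0.1, 0.5, 1)) {
    expect_false(stability(make_controls(-1, 0, 0, 1), 0.5, S)$stable)
  }
})

test_that("sensitivity closed forms match finite differences of the moments", {
  set.seed(404)
  for (k in 1:50) {
    cs <- random_stable_controls(S_star = runif(1, 0.2, 0.9))
    eq <- structure(list(kind = "mixed", i0 = 1, j0 = 1,
                         L_star = cs$L_star, S_star = cs$S_star),
                    class = "equilibrium")
    sens <- variance_sensitivity(cs$controls, cs$L_star, cs$S_star)
    h <- 1e-4
    up <- lna_moments(eq, cs$controls, cs$S_star + h)
    dn <- lna_moments(eq, cs$controls, cs$S_star - h)
    fd_I <- (up$var_I - dn$var_I) / (2 * h)
    fd_J <- (up$var_J - dn$var_J) / (2 * h)
    scale_I <- max(abs(fd_I), abs(up$var_I))
    scale_J <- max(abs(fd_J), abs(up$var_J))
    expect_lt(abs(sens$dvarI_dS - fd_I) / scale_I, 1e-6)
    expect_lt(abs(sens$dvarJ_dS - fd_J) / scale_J, 1e-6)
  }
})

test_that("variances are monotone in the symmetric fraction", {
  set.seed(505)
  for (k in 1:50) {
    cs <- random_stable_controls(S_star = 0.5)
    ss <- seq(0.1, 1, by = 0.1)
    ok <- sapply(ss, function(S) stability(cs$controls, cs$L_star, S)$stable)
    ss <- ss[ok]
    eq <- structure(list(kind = "mixed", i0 = 1, j0 = 1,
                         L_star = cs$L_star, S_star = 0.5),
                    class = "equilibrium")
    vi <- sapply(ss, function(S) lna_moments(eq, cs$controls, S)$var_I)
    vj <- sapply(ss, function(S) lna_moments(eq, cs$controls, S)$var_J)
    expect_true(all(diff(vi) >= -1e-12 * abs(vi[-1])) ||
                all(diff(vi) <= 1e-12 * abs(vi[-1])))
    expect_true(all(diff(vj) >= -1e-12 * abs(vj[-1])) ||
                all(diff(vj) <= 1e-12 * abs(vj[-1])))
  }
})

test_that("degenerate and invalid inputs are rejected", {
  eq <- structure(list(kind = "mixed", i0 = 1, j0 = 1, L_star = 0.5,
                       S_star = 0.5), class = "equilibrium")
  expect_error(lna_moments(eq, make_controls(0, 0, 0, 0), 0.5),
               "non-hyperbolic")
  expect_error(variance_sensitivity(make_controls(0, 0, 0, 0), 0.5, 0.5),
               "non-hyperbolic")
  eq_a <- structure(list(kind = "purely_asymmetric", L_star = 0.5,
                         S_star = 0), class = "equilibrium")
  expect_error(lna_moments(eq_a, make_controls(1, 0, 0, 1), 0.5), "mixed")
  expect_error(lna_moments(eq, make_controls(1, 0, 0, 1), 0), "S_star")
  expect_error(lna_moments(eq, make_controls(1, 0, 0, 1), 1.2), "S_star")
})

test_that("analyze_network assembles a consistent report", {
  an <- analyze_network(make_model5(0.005, 0.5))
  expect_equal(an$classification$label, "#5")
  expect_equal(an$lna$S_c, 0)
  expect_equal(an$sensitivity$dvarI_dS, 0)
  expect_lt(an$sensitivity$dvarJ_dS, 0)
  rep <- report_from_analysis(an)
  expect_equal(rep$varI, an$lna$var_I)
  expect_equal(rep$class_label, "#5")
})
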