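# Recalculation rules and the observed-conditional-power calculus.

test_that("observed conditional power matches direct evaluation and its
           stated monotonicities", {
  d <- main_design()
  # direct evaluation of the definition
  direct <- 1 - pnorm((sqrt(2) * d$q_final - 1.0 - 0.2 * sqrt(150 / 2)) /
                        sqrt(1 - 0.04 / 4))
  expect_equal(observed_conditional_power(1.0, 0.2, 150, d), direct,
               tolerance = 1e-12)
  expect_equal(round(direct, 3), 0.363)
  # lam_hat = 0: independent of n2
  expect_equal(observed_conditional_power(0.5, 0, 10, d),
               observed_conditional_power(0.5, 0, 150, d))
  # limits and monotonicity
  expect_gt(observed_conditional_power(1, 0.3, 1e8, d), 1 - 1e-6)
  cp_z <- observed_conditional_power(seq(0, 2, 0.1), 0.2, 100, d)
  expect_true(all(diff(cp_z) > 0))
  cp_n <- observed_conditional_power(1, 0.2, seq(10, 150, 10), d)
  expect_true(all(diff(cp_n) > 0))
  cp_l <- observed_conditional_power(1, seq(0.05, 0.5, 0.05), 100, d)
  expect_true(all(diff(cp_l) > 0))
  # degenerate observed effect: 0/1 step
  expect_equal(observed_conditional_power(0, 2, 50, d), 1)
  expect_equal(observed_conditional_power(0, -2, 50, d), 0)
})

test_that("stage-2 inversion is the exact inverse of the conditional power", {
  d <- main_design()
  n2 <- invert_cp_for_n2(1.0, 0.2, 0.8, d)
  expect_equal(n2, 425.72, tolerance = 1e-3)
  # round trip to 1e-9 over random interim states
  set.seed(31)
  z1 <- runif(200, d$q_futility, d$q_efficacy)
  lh <- runif(200, 0.01, 0.6)
  tcp <- runif(200, 0.05, 0.95)
  n2 <- invert_cp_for_n2(z1, lh, tcp, d)
  interior <- n2 > 0
  expect_equal(observed_conditional_power(z1[interior], lh[interior],
                                          n2[interior], d),
               tcp[interior], tolerance = 1e-9)
  # huge interim statistic: bracket non-positive -> 0
  expect_equal(invert_cp_for_n2(50, 0.5, 0.2, d), 0)
  # non-positive observed effect signals unattainable
  expect_true(is.na(invert_cp_for_n2(1, 0, 0.8, d)))
  expect_true(is.na(invert_cp_for_n2(1, -0.1, 0.8, d)))
})

test_that("classic group sequential rule is constant at the initial stage-2
           size", {
  d <- main_design()
  r <- rule_spec("classicGS")
  z1 <- seq(0, 2.1, by = 0.1)
  res <- rule_classic_gs(z1, d, r)
  expect_true(all(res$n2 == 50L))
  expect_true(all(!res$stopped))
  res_ap <- rule_classic_gs(1, apsac_design(), r)
  expect_identical(res_ap$n2, 90L)
})

test_that("OCP rule: clamping, unattainable targets, and monotone
           non-increase in z1 on the interior", {
  d <- main_design()
  r <- rule_spec("OCP")
  # published-style clamp: required 425.7 exceeds 150
  expect_identical(rule_ocp(1.0, 0.2, d, r)$n2, 150L)
  # unattainable (lam_hat <= 0) -> maximum
  expect_identical(rule_ocp(1.0, 0, d, r)$n2, 150L)
  expect_identical(rule_ocp(0.5, -0.2, d, r)$n2, 150L)
  # very favourable interim -> floor clamp at 1
  expect_identical(rule_ocp(2.17, 0.43, d, r)$n2,
                   max(1L, rule_ocp(2.17, 0.43, d, r)$n2))
  # non-increasing in z1 where interior (lam_hat fixed, large enough)
  z1 <- seq(1.2, 2.1, by = 0.05)
  n2 <- rule_ocp(z1, rep(0.42, length(z1)), d, r)$n2
  interior <- n2 < 150L & n2 > 1L
  expect_true(all(diff(n2[interior]) <= 0))
})

test_that("restricted OCP stops exactly when even the maximal stage-2 size
           is futile", {
  d <- main_design()
  r <- rule_spec("restrOCP")
  low <- rule_restricted_ocp(0.1, 0.02, d, r)
  expect_true(low$stopped)
  expect_identical(low$n2, 0L)
  high <- rule_restricted_ocp(2.0, 0.4, d, r)
  expect_false(high$stopped)
  expect_identical(high$n2, rule_ocp(2.0, 0.4, d, r)$n2)
  # threshold is strict: continue when CP at the maximum equals the bound
  # (verified by locating the boundary z1 for a fixed lam_hat)
  lam_hat <- 0.2
  f <- function(z) observed_conditional_power(z, lam_hat, 150, d) - 0.6
  z_star <- uniroot(f, c(0, 2.17), tol = 1e-12)$root
  expect_false(rule_restricted_ocp(z_star + 1e-9, lam_hat, d, r)$stopped)
  expect_true(rule_restricted_ocp(z_star - 1e-6, lam_hat, d, r)$stopped)
})

test_that("promising zone rule keeps the group-sequential size outside the
           promising zone and applies OCP inside it", {
  d <- main_design()
  r <- rule_spec("promising")
  # unfavourable: conditional power at n_GS far below 0.36
  expect_identical(rule_promising_zone(0.1, 0.02, d, r)$n2, 50L)
  # favourable: conditional power at n_GS above 0.8
  expect_identical(rule_promising_zone(2.1, 0.42, d, r)$n2, 50L)
  # promising: matches OCP
  cp_gs <- observed_conditional_power(1.6, 0.32, 50, d)
  expect_true(cp_gs > 0.36 && cp_gs < 0.8)
  expect_identical(rule_promising_zone(1.6, 0.32, d, r)$n2,
                   rule_ocp(1.6, 0.32, d, r)$n2)
  # coincides with classicGS outside / OCP inside across a sweep
  z1 <- seq(0, 2.1, by = 0.02)
  lh <- z1 / sqrt(25)
  prom <- rule_promising_zone(z1, lh, d, r)$n2
  cp_gs <- observed_conditional_power(z1, lh, 50, d)
  inside <- cp_gs >= 0.36 & cp_gs <= 0.8
  expect_identical(prom[!inside], rule_classic_gs(z1[!inside], d, r)$n2)
  expect_identical(prom[inside], rule_ocp(z1[inside], lh[inside], d, r)$n2)
})

test_that("optimization rule equals an independent exhaustive scan and
           responds correctly to the trade-off extremes", {
  d <- main_design()
  r <- rule_spec("optfunc", gamma = 0.005 / 4)
  set.seed(77)
  z1 <- runif(40, 0, 2.17)
  lh <- z1 / sqrt(25)
  got <- rule_optfunc(z1, lh, d, r)$n2
  # independent oracle: direct maximization of the written-out objective
  oracle <- vapply(seq_along(z1), function(i) {
    best <- -Inf; arg <- NA_integer_
    for (m in 50:150) {
      f <- observed_conditional_power(z1[i], lh[i], m, d) - r$gamma * (m - 50)
      if (f > best + 1e-15) { best <- f; arg <- m }
    }
    arg
  }, integer(1))
  expect_identical(got, oracle)
  # enormous cost: never move beyond the initially planned size
  r_big <- rule_spec("optfunc", gamma = 10)
  expect_true(all(rule_optfunc(z1, lh, d, r_big)$n2 == 50L))
  # vanishing cost with positive observed effect: conditional power is
  # monotone, so the maximum is taken
  r_tiny <- rule_spec("optfunc", gamma = 1e-12)
  expect_true(all(rule_optfunc(z1[lh > 0], lh[lh > 0], d, r_tiny)$n2 == 150L))
})

test_that("every rule returns stage-2 sizes in [0, n_max - n1], zero only
           for restricted-OCP stops", {
  d <- main_design()
  set.seed(55)
  z1 <- runif(100, d$q_futility, d$q_efficacy)
  lh <- z1 / sqrt(d$n1 / 2)
  for (r in all_rules()) {
    res <- recalc_n2(z1, lh, d, r)
    expect_true(all(res$n2 >= 0 & res$n2 <= 150))
    expect_true(all(res$n2[!res$stopped] >= 1))
    expect_true(all(res$n2[res$stopped] == 0))
    if (r$kind != "restrOCP") expect_false(any(res$stopped))
  }
})
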