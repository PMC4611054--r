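test_that("time-course simulation honours trivial limits", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  ts <- c(0, 30, 60, 120)
  # no substrate: nothing ever happens
  tr <- simulate_time_course(m9, p, 0, ts)
  expect_true(all(observable_product(tr) == 0))
  expect_true(all(abs(as.matrix(tr[-1]) -
                        rep(as.numeric(tr[1, -1]), each = nrow(tr))) < 1e-12))
  # no catalysis: no product, all peptide in substrate-containing species
  p0 <- p; p0[["kp"]] <- 0
  tr <- simulate_time_course(m9, p0, 200, ts)
  expect_true(all(observable_product(tr, p0) < 1e-9))
  s_species <- tr$Sout + tr$G1Sout + tr$S + tr$G2S + tr$EregS +
    p0[["h"]] * tr$IS
  expect_true(all(abs(s_species - 200) < 1e-6 * 200))
})

test_that("adaptive integration matches a fixed-step oracle", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  p[c("kp", "KaS")] <- c(600, 0.5)   # keep the fast hydrolysis scale
                                     # resolvable by the explicit oracle
  tr <- simulate_time_course(m9, p, 320, c(0, 60))
  y_oracle <- rk4_integrate(m9, p, 320, 60, dt = 0.005)
  prod_oracle <- y_oracle[["Pout"]] + y_oracle[["G1Pout"]] + y_oracle[["P"]] +
    y_oracle[["G2P"]] + y_oracle[["EregP"]] + p[["h"]] * y_oracle[["IP"]]
  prod_adaptive <- utils::tail(observable_product(tr), 1)
  expect_lt(abs(prod_adaptive - prod_oracle) / prod_oracle, 1e-3)
})

test_that("conservation holds along trajectories at solver tolerances", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  tr <- simulate_time_course(m9, p, 480, seq(0, 360, 30))
  expect_lt(conservation_drift(tr), 1e-6)
  expect_true(all(as.matrix(tr[-1]) > -1e-9))
})

test_that("solver tolerance refinement leaves the observable unchanged", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  ts <- seq(0, 240, 30)
  a <- observable_product(simulate_time_course(m9, p, 320, ts))
  b <- observable_product(simulate_time_course(
    m9, p, 320, ts, solver_opts = list(rtol = 1e-9, atol = 1e-11)))
  expect_lt(max(abs(a - b) / pmax(b, 1e-12)), 1e-4)
})

test_that("total product equals cumulative hydrolysis", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  ts <- seq(0, 120, 1)
  tr <- simulate_time_course(m9, p, 320, ts)
  prod <- observable_product(tr)
  expect_equal(prod[1], 0)
  expect_true(all(diff(prod) >= -1e-12))   # vhydr >= 0 implies monotone
  # trapezoidal integral of the hydrolysis flux reproduces the observable
  vh <- vapply(seq_len(nrow(tr)), function(i)
    rate_hydrolysis(tr$S[i], tr$P[i], p)$vhydr, numeric(1))
  integ <- c(0, cumsum(diff(ts) * (utils::head(vh, -1) + utils::tail(vh, -1)) / 2))
  expect_lt(max(abs(integ - prod)) / max(prod), 5e-3)
  # outer-product observable is a lower bound
  expect_true(all(observable_product(tr, where = "outer") <= prod + 1e-12))
})

test_that("reaction velocity estimation matches closed-form least squares", {
  # exactly linear series returns its slope; constant series returns zero
  t <- c(15, 30, 45, 60)
  expect_equal(reaction_velocity(t, 5 + 0.3 * t)$initial, 0.3)
  expect_equal(reaction_velocity(t, rep(2, 4))$initial, 0)
  # noisy series against the normal-equations oracle
  set.seed(11)
  y <- 1 + 0.25 * t + rnorm(4, 0, 0.4)
  xb <- mean(t); yb <- mean(y)
  slope_oracle <- sum((t - xb) * (y - yb)) / sum((t - xb)^2)
  expect_equal(reaction_velocity(t, y)$initial, slope_oracle,
               tolerance = 1e-10)
  # centred finite differences
  rv <- reaction_velocity(c(0, 10, 20, 30), c(0, 1, 4, 9),
                          window = c(0, 10, 20, 30))
  expect_equal(rv$running$velocity, c((4 - 0) / 20, (9 - 1) / 20))
  expect_error(reaction_velocity(t, 5 + 0.3 * t, window = c(99)), "window")
})

test_that("dose-response is monotone without regulation, peaked with it", {
  m9 <- build_model("M9")
  doses <- c(20, 40, 80, 160, 320, 480, 640)
  # MM limit: monotone non-decreasing
  dr <- dose_response(m9, mm_limit_params(kp = 0.01, KaS = 100, E0 = 0.1),
                      doses, 60, check_conservation = FALSE)
  expect_true(all(diff(dr$product) >= -1e-9))
  # active external inhibitory site with h = 2: interior maximum
  p <- fixture_parameters("Z-LLE-MCA", "mouse")
  expect_gt(p[["Yinh"]], 0); expect_gte(p[["h"]], 2)
  dr <- dose_response(m9, p, doses, 240, check_conservation = FALSE)
  peak <- which.max(dr$product)
  expect_gt(peak, 1); expect_lt(peak, nrow(dr))
  # grid-search confirmation of non-monotonicity on a finer grid
  fine <- dose_response(m9, p, seq(20, 640, length.out = 20), 240,
                        check_conservation = FALSE)
  expect_true(any(diff(fine$product) < 0) && any(diff(fine$product) > 0))
  # t_end = 0 gives all zeros
  expect_true(all(dose_response(m9, p, doses, 0)$product == 0))
  expect_error(dose_response(m9, p, numeric(0), 60), "empty")
})

test_that("open-gate mutant scales transport and boosts product", {
  m9 <- build_model("M9")
  p <- fixture_parameters("Suc-LLVY-MCA", "mouse")
  ts <- c(0, 30, 60)
  wt <- simulate_time_course(m9, p, 200, ts, check_conservation = FALSE)
  mu1 <- simulate_open_gate_mutant(m9, p, 200, ts, factor = 1,
                                   check_conservation = FALSE)
  expect_equal(as.matrix(mu1[-1]), as.matrix(wt[-1]), tolerance = 1e-10)
  mu10 <- simulate_open_gate_mutant(m9, p, 200, ts, check_conservation = FALSE)
  expect_gt(utils::tail(observable_product(mu10, p), 1),
            utils::tail(observable_product(wt, p), 1))
  expect_error(simulate_open_gate_mutant(build_model("M1"), p, 200, ts),
               "compartmental")
  expect_error(simulate_open_gate_mutant(m9, p, 200, ts, factor = 0), "> 0")
})

test_that("Rpt stimulation is unity at factor one and decays on the
           fast-transport fixture", {
  m9 <- build_model("M9")
  p <- fixture_parameters("Z-LLE-MCA", "mouse")
  ts <- seq(15, 240, 15)
  r1 <- simulate_with_rpt(m9, p, 200, ts, rpt_factor = 1,
                          check_conservation = FALSE)
  expect_true(all(abs(r1$fold_stimulation - 1) < 1e-9))
  r5 <- simulate_with_rpt(m9, p, 200, ts, rpt_factor = 5,
                          check_conservation = FALSE)
  expect_true(all(r5$fold_stimulation > 1))
  expect_true(all(diff(r5$fold_stimulation) < 0))
  expect_error(simulate_with_rpt(m9, p, 200, ts, rpt_factor = 0), "> 0")
  # zero baseline product reported as undefined, not infinite
  p0 <- p; p0[["kp"]] <- 0
  r0 <- simulate_with_rpt(m9, p0, 200, c(30, 60), check_conservation = FALSE)
  expect_true(all(is.na(r0$fold_stimulation)))
})

test_that("co-substrate digestion reduces and splits correctly", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  ts <- c(15, 30, 60, 120)
  # species A absent: B follows its single-substrate trajectory
  co <- simulate_cosubstrate(m9, p, p, 0, 240, ts)
  single <- simulate_time_course(m9, p, 240, c(0, ts),
                                 check_conservation = FALSE)
  cp <- cosubstrate_products(co)
  pb <- cp$product_B[match(ts, cp$time)]
  ps <- observable_product(single, p)[match(ts, single$time)]
  expect_lt(max(abs(pb - ps) / pmax(ps, 1e-12)), 1e-6)
  expect_true(all(abs(cp$product_A) < 1e-12))
  # identical parameters, S0/2 + S0/2 equals the single run at S0
  # (linear binding: na = ni = h = 1)
  plin <- p; plin[c("na", "ni", "h")] <- 1
  co2 <- simulate_cosubstrate(m9, plin, plin, 120, 120, ts)
  cp2 <- cosubstrate_products(co2)
  tot2 <- rowSums(cp2[match(ts, cp2$time), c("product_A", "product_B")])
  single2 <- simulate_time_course(m9, plin, 240, c(0, ts),
                                  check_conservation = FALSE)
  ps2 <- observable_product(single2, plin)[match(ts, single2$time)]
  expect_lt(max(abs(tot2 - ps2) / pmax(ps2, 1e-12)), 1e-5)
  expect_error(simulate_cosubstrate(build_model("M2"), p, p, 1, 1, ts),
               "compartmental")
})

test_that("pre-incubation and enhancer occupancy speed up the co-substrate", {
  m9 <- build_model("M9")
  pA <- fixture_parameters("Suc-LLVY-MCA", "mouse")
  pB <- fixture_parameters("Bz-VGR-MCA", "mouse")
  ts <- c(15, 30, 60)
  # with species A pre-loading the enhancer, B starts faster than alone
  co_pre <- simulate_cosubstrate(m9, pA, pB, 200, 200, ts,
                                 pre_incubation_min = 120)
  co_flat <- simulate_cosubstrate(m9, pA, pB, 200, 200, ts,
                                  pre_incubation_min = 0)
  bp <- function(co) {
    cp <- cosubstrate_products(co)
    cp$product_B[match(ts, cp$time)]
  }
  expect_gt(bp(co_pre)[1], bp(co_flat)[1])
  # and exceeds its single-substrate product at matching times
  alone <- simulate_time_course(m9, pB, 200, c(0, ts),
                                check_conservation = FALSE)
  pb_alone <- observable_product(alone, pB)[match(ts, alone$time)]
  expect_gt(bp(co_pre)[3], pb_alone[3])
})
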