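test_that("sensitivity fold-changes behave under the identity factor and
           identify the transport-limited regime", {
  m9 <- build_model("M9")
  p <- fixture_parameters("Suc-LLVY-MCA", "mouse")   # vin-limited regime
  s1 <- rate_limiting_analysis(m9, p, S0 = 320, t_end = 60, factor = 1)
  expect_true(all(abs(s1$fold_change - 1) < 1e-8))
  expect_equal(attr(s1, "factor"), 1)

  s2 <- rate_limiting_analysis(m9, p, S0 = 320, t_end = 60, factor = 2)
  sm <- summary(s2)
  gate <- sm$mean_fold[sm$reaction_class == "gate_size"]
  hyd <- sm$mean_fold[sm$reaction_class == "hydrolysis"]
  expect_gt(gate, hyd)   # transport, not catalysis, limits this substrate
  # purely productive scalings never decrease product formation
  for (cl in c("influx", "hydrolysis"))
    expect_gte(s2$fold_change[s2$reaction_class == cl], 1 - 1e-8)
  expect_error(rate_limiting_analysis(m9, p, classes = "warp"), "unknown")
  expect_error(rate_limiting_analysis(m9, p, factor = -1), "> 0")
  expect_error(rate_limiting_analysis(build_model("M2"), p), "compartmental")
})

test_that("the hydrolysis-limited substrate is flagged as such", {
  m9 <- build_model("M9")
  p <- fixture_parameters("Z-LLE-MCA", "mouse")
  sm <- summary(rate_limiting_analysis(m9, p, S0 = 320, t_end = 60,
                                       factor = 2))
  hyd <- sm$mean_fold[sm$reaction_class == "hydrolysis"]
  expect_gt(hyd, sm$mean_fold[sm$reaction_class == "influx"])
})

test_that("posterior sensitivity is invariant to particle order", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  set.seed(9)
  n <- 12
  particles <- data.frame(model = 1L,
                          vin = rlnorm(n, log(4), 0.3),
                          kp = rlnorm(n, log(6000), 0.3),
                          weight = {
                            w <- runif(n); w / sum(w)
                          }, distance = 0)
  post <- structure(list(particles = particles), class = "proteodyn_abc")
  post_rev <- structure(list(particles = particles[rev(seq_len(n)), ]),
                        class = "proteodyn_abc")
  s_a <- summary(rate_limiting_analysis(m9, post, S0 = 160, t_end = 30,
                                        base_params = p,
                                        classes = c("influx", "hydrolysis")))
  s_b <- summary(rate_limiting_analysis(m9, post_rev, S0 = 160, t_end = 30,
                                        base_params = p,
                                        classes = c("influx", "hydrolysis")))
  expect_equal(s_a, s_b, tolerance = 1e-10)
})

test_that("both gate-affinity scaling conventions are available", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  a <- scale_reaction_class(p, "gate_affinity", 2, "kon")
  b <- scale_reaction_class(p, "gate_affinity", 2, "koff")
  expect_equal(a[["kon"]], 2 * p[["kon"]])
  expect_equal(b[["koff"]], p[["koff"]] / 2)
})

test_that("chamber occupancy stays within capacity and reports filling", {
  m9 <- build_model("M9")
  p <- fixture_parameters("Z-LLE-MCA", "mouse")   # fast-filling fixture
  tr <- simulate_time_course(m9, p, 320, seq(0, 240, 15),
                             check_conservation = FALSE)
  rep <- chamber_occupancy(tr)
  expect_equal(rep$molecules_inside[1], 0)
  expect_true(is.na(rep$product_fraction[1]))   # empty chamber: undefined
  expect_true(all(rep$molecules_inside <= p[["C"]] + 1e-6))
  expect_true(is.finite(attr(rep, "time_to_fill")))
  # fast-hydrolysis substrate: the chamber content is predominantly product
  pf <- fixture_parameters("Suc-LLVY-MCA", "mouse")
  trf <- simulate_time_course(m9, pf, 320, seq(0, 240, 15),
                              check_conservation = FALSE)
  repf <- chamber_occupancy(trf)
  expect_gt(utils::tail(repf$product_fraction, 1), 0.9)
  m1tr <- simulate_time_course(build_model("M1"),
                               parameter_set(vmax = 0.1, KM = 50), 100,
                               c(0, 30))
  expect_error(chamber_occupancy(m1tr), "compartmental")
})

test_that("capacity ratios track inverse molecular volumes", {
  C_est <- c("Suc-LLVY-MCA" = 200, "Z-LLE-MCA" = 249, "Bz-VGR-MCA" = 293)
  vols <- c("Suc-LLVY-MCA" = 936, "Z-LLE-MCA" = 741, "Bz-VGR-MCA" = 606)
  tab <- capacity_consistency(C_est, vols)
  expect_equal(nrow(tab), 3)
  r <- function(pair) tab[tab$pair == pair, ]
  expect_equal(r("Z-LLE-MCA:Suc-LLVY-MCA")$capacity_ratio, 1.245)
  expect_equal(r("Z-LLE-MCA:Suc-LLVY-MCA")$capacity_ratio_2dp, 1.24)
  expect_equal(r("Bz-VGR-MCA:Suc-LLVY-MCA")$capacity_ratio, 1.465)
  expect_equal(r("Bz-VGR-MCA:Suc-LLVY-MCA")$capacity_ratio_2dp, 1.46)
  expect_true(all(tab$agreement > 0 & tab$agreement <= 1))
  # equal capacities: all ratios one
  eq <- capacity_consistency(c(a = 100, b = 100), c(a = 1, b = 1))
  expect_equal(eq$capacity_ratio, 1)
  expect_error(capacity_consistency(c(a = 1, b = 2), c(a = 0, b = 1)), "> 0")
  expect_error(capacity_consistency(c(a = 1), c(a = 1)), "two")
})
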