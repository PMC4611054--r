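test_that("build_model returns consistent definitions and rejects bad ids", {
  m1 <- build_model("M1")
  expect_false(m1$compartmentalised)
  expect_setequal(m1$species, c("Sout", "Pout"))
  expect_setequal(m1$parameters, c("vmax", "KM", "E0"))

  m9 <- build_model("M9")
  expect_true(m9$compartmentalised)
  expect_identical(m9$enhancer_location, "inside")
  expect_identical(m9$inhibitor_location, "outside")
  expect_length(m9$species, 16)

  # M5-M9 share the transport skeleton and differ only in regulation
  skeleton <- c("kon", "koff", "vin", "vout", "tau", "C")
  for (id in paste0("M", 5:9))
    expect_true(all(skeleton %in% build_model(id)$parameters), label = id)
  expect_identical(build_model("M8")$inhibitor_location, "inside")
  expect_identical(build_model("M6")$enhancer_location, "outside")
  # feedback variants
  expect_identical(build_model("M3")$feedback, "binding")
  expect_identical(build_model("M4")$feedback, "hydrolysis")

  expect_error(build_model("M0"), "valid ids")
  expect_error(build_model("nonsense"), "M1")

  # every model's species/parameter lists are mutually consistent: the rate
  # evaluation runs on the model's own state and parameter subset
  for (id in MODEL_IDS) {
    m <- build_model(id)
    p <- parameter_set()
    y <- initial_state(m, 100, p)
    expect_length(ode_rhs(m, y, p), length(m$species))
  }
})

test_that("parameter invariants are enforced", {
  expect_error(parameter_set(C = 0.5), "C")
  expect_error(parameter_set(beta = 0), "beta")
  expect_error(parameter_set(beta = 1.2), "beta")
  expect_error(parameter_set(na = 0.5), "na")
  expect_error(parameter_set(alpha = 0), "alpha")
  expect_error(parameter_set(kon = -1), ">= 0")
  expect_error(parameter_set(bogus = 1), "unknown")
  # enzyme concentration from assay description
  expect_equal(enzyme_concentration_uM(0.125, 100, 700),
               0.125 / 7e5 / 100 * 1e6)
})

test_that("two-site-modifier hydrolysis law matches a term-by-term oracle", {
  p <- parameter_set(kp = 1, E0 = 1, KaS = 100, KiS = 200, KaP = 300,
                     KiP = 400, na = 1, ni = 1, alpha = 0.5, beta = 0.2)
  S <- 50; P <- 10
  # independent oracle: enumerate the nine partition states and the three
  # catalytically productive ones explicitly
  states <- c(free = 1,
              S_cat = S / 100, S_inh = S / 200,
              P_cat = P / 300, P_inh = P / 400,
              SS = S^2 / (0.5 * 100 * 200), PP = P^2 / (0.5 * 300 * 400),
              SP = S * 10 / (0.5 * 100 * 400), PS = S * P / (0.5 * 200 * 300))
  x_oracle <- sum(states)
  v_oracle <- (states[["S_cat"]] + 0.2 * states[["SS"]] +
                 0.2 * states[["SP"]]) / x_oracle
  r <- rate_hydrolysis(S, P, p)
  expect_equal(r$x, x_oracle, tolerance = 1e-12)
  expect_equal(r$vhydr, v_oracle, tolerance = 1e-12)
  expect_gte(r$x, 1)

  # S = 0 gives zero flux whatever the product level
  expect_equal(rate_hydrolysis(0, 123, p)$vhydr, 0)
  # empty modifier site and na = 1 reduce to Michaelis-Menten
  pmm <- parameter_set(kp = 2, E0 = 3, KaS = 100, KaP = 1e12, KiS = 1e12,
                       KiP = 1e12, na = 1, ni = 1)
  expect_equal(rate_hydrolysis(50, 40, pmm)$vhydr, 2 * 3 * 50 / (100 + 50),
               tolerance = 1e-8)
  # active-site copy number as the leading factor
  expect_equal(rate_hydrolysis(50, 0, pmm, lead_factor = "copies")$vhydr,
               2 * rate_hydrolysis(50, 0, pmm)$vhydr)
  expect_error(rate_hydrolysis(NaN, 0, pmm), "finite")
  p0 <- pmm; p0[["KaS"]] <- 0
  expect_error(rate_hydrolysis(1, 1, p0), "non-zero")
})

test_that("regulated transport rates follow capacity and regulation", {
  p <- parameter_set(vin = 7, vout = 3, Xenh = 4, Yinh = 2, C = 100, E0 = 1)
  # chamber exactly at capacity: influx shuts off
  st <- c(S = 60, P = 40, EregS = 0, EregP = 0, IS = 0, IP = 0)
  expect_equal(rate_transport(st, p, "in"), 0)
  # empty chamber far from capacity: tanh saturates at 1
  st <- c(S = 0, P = 0, EregS = 0, EregP = 0, IS = 0, IP = 0)
  expect_equal(rate_transport(st, p, "in"), 7, tolerance = 1e-10)
  # occupied enhancer multiplies the rate: EregS/E0 = 0.5, Xenh = 4 -> x3
  st <- c(S = 0, P = 0, EregS = 0.5, EregP = 0, IS = 0, IP = 0)
  expect_equal(rate_transport(st, p, "in"), 3 * 7, tolerance = 1e-10)
  expect_equal(rate_transport(st, p, "out"), 3 * 3)
  # efflux carries no capacity term
  st <- c(S = 60, P = 40, EregS = 0, EregP = 0, IS = 0, IP = 0)
  expect_equal(rate_transport(st, p, "out"), 3)
  # inhibition divides
  st <- c(S = 0, P = 0, EregS = 0, EregP = 0, IS = 0.5, IP = 0.5)
  expect_equal(rate_transport(st, p, "in"), 7 / 3, tolerance = 1e-10)
  # over-capacity is clamped, not reversed
  st <- c(S = 200, P = 0, EregS = 0, EregP = 0, IS = 0, IP = 0)
  expect_equal(rate_transport(st, p, "in"), 0)
  p0 <- p; p0[["E0"]] <- 0
  expect_error(rate_transport(c(S = 0, P = 0, EregS = 0.1, EregP = 0,
                                IS = 0, IP = 0), p0, "in"), "E0")
})

test_that("ode_rhs conserves sites and peptide moiety for every model", {
  set.seed(42)
  for (id in MODEL_IDS) {
    m <- build_model(id)
    for (rep in 1:5) {
      p <- random_params()
      y <- random_state(m, p)
      d <- ode_rhs(m, y, p)
      # peptide-moiety derivative sums to zero
      g <- function(n) if (n %in% names(d)) d[[n]] else 0
      pep <- g("Sout") + g("Pout") + g("G1Sout") + g("G1Pout") + g("S") +
        g("P") + g("G2S") + g("G2P") + g("EregS") + g("EregP") +
        p[["h"]] * (g("IS") + g("IP"))
      expect_lt(abs(pep), 1e-10 * max(abs(d), 1))
      for (site in list(c("G1", "G1Sout", "G1Pout"), c("G2", "G2S", "G2P"),
                        c("Ereg", "EregS", "EregP"), c("Ifree", "IS", "IP")))
        if (all(site %in% names(d)))
          expect_lt(abs(sum(d[site])), 1e-12 * max(abs(d), 1))
    }
    # all-zero peptide state is a fixed point
    p <- random_params()
    y0 <- initial_state(m, 0, p)
    expect_true(all(abs(ode_rhs(m, y0, p)) < 1e-14))
  }
  m9 <- build_model("M9")
  p <- test_params_m9()
  expect_error(ode_rhs(m9, initial_state(m9, 10, p) - 1, p), "negative")
})

test_that("M9 derivatives match an independent line-by-line evaluation", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  set.seed(7)
  y <- random_state(m9, p)
  d <- ode_rhs(m9, y, p)
  # hand-coded evaluation of the printed system, written out term by term
  tin <- p[["vin"]] *
    (1 + p[["Xenh"]] * (y[["EregS"]] + y[["EregP"]]) / p[["E0"]]) /
    (1 + p[["Yinh"]] * (y[["IS"]] + y[["IP"]]) / p[["I0"]]) *
    tanh(max(0, p[["E0"]] * p[["C"]] - y[["S"]] - y[["P"]]))
  tout <- p[["vout"]] *
    (1 + p[["Xenh"]] * (y[["EregS"]] + y[["EregP"]]) / p[["E0"]]) /
    (1 + p[["Yinh"]] * (y[["IS"]] + y[["IP"]]) / p[["I0"]])
  vh <- rate_hydrolysis(y[["S"]], y[["P"]], p)$vhydr
  expect_equal(d[["Sout"]],
               -y[["Sout"]] * y[["G1"]] * p[["kon"]] +
                 y[["G1Sout"]] * p[["koff"]] + y[["G2S"]] * tout -
                 p[["h"]] * y[["Sout"]]^p[["h"]] * y[["Ifree"]] * p[["Ion"]] +
                 p[["h"]] * y[["IS"]] * p[["Ioff"]], tolerance = 1e-12)
  expect_equal(d[["G1Sout"]],
               y[["Sout"]] * y[["G1"]] * p[["kon"]] -
                 y[["G1Sout"]] * (p[["koff"]] + tin), tolerance = 1e-12)
  expect_equal(d[["S"]],
               y[["G1Sout"]] * tin -
                 p[["tau"]] * y[["S"]] * y[["G2"]] / p[["E0"]] - vh -
                 p[["Ron"]] * y[["S"]] * y[["Ereg"]] / p[["E0"]] +
                 p[["Roff"]] * y[["EregS"]], tolerance = 1e-12)
  expect_equal(d[["P"]],
               y[["G1Pout"]] * tin -
                 p[["tau"]] * y[["P"]] * y[["G2"]] / p[["E0"]] + vh -
                 p[["Ron"]] * y[["P"]] * y[["Ereg"]] / p[["E0"]] +
                 p[["Roff"]] * y[["EregP"]], tolerance = 1e-12)
  expect_equal(d[["G2S"]],
               p[["tau"]] * y[["G2"]] * y[["S"]] / p[["E0"]] -
                 y[["G2S"]] * tout, tolerance = 1e-12)
  expect_equal(d[["EregS"]],
               p[["Ron"]] * y[["Ereg"]] * y[["S"]] / p[["E0"]] -
                 p[["Roff"]] * y[["EregS"]], tolerance = 1e-12)
  expect_equal(d[["IS"]],
               y[["Sout"]]^p[["h"]] * y[["Ifree"]] * p[["Ion"]] -
                 p[["Ioff"]] * y[["IS"]], tolerance = 1e-12)
})

test_that("initial_state places the dose outside and satisfies totals", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  y <- initial_state(m9, 480, p)
  tot <- conserved_totals(m9, y, p)
  expect_equal(tot[["peptide"]], 480)
  expect_equal(tot[["G1_sites"]], p[["G1_tot"]])
  expect_equal(tot[["G2_sites"]], p[["G2_tot"]])
  expect_equal(tot[["Ereg_sites"]], p[["Ereg_tot"]])
  expect_equal(tot[["I_sites"]], p[["I0"]])
  y20 <- initial_state(m9, 20, p)
  expect_equal(conserved_totals(m9, y20, p)[["peptide"]], 20)
  expect_error(initial_state(m9, -1, p), "non-negative")
})

test_that("compiled and reference derivatives agree along trajectories", {
  ts <- seq(0, 120, 15)
  for (id in c("M1", "M2", "M3", "M4", "M5", "M6", "M7", "M8", "M9")) {
    m <- build_model(id)
    p <- if (m$compartmentalised) test_params_m9() else
      parameter_set(kp = 100, KaS = 50, KaP = 80, KiS = 150, KiP = 150,
                    na = 1, ni = 1, alpha = 0.7, beta = 0.5,
                    eps_fb = 2, K_fb = 5, vmax = 0.05, KM = 120)
    tr_c <- simulate_time_course(m, p, 300, ts)
    tr_r <- simulate_time_course(m, p, 300, ts, engine = "R")
    expect_lt(max(abs(as.matrix(tr_c[-1]) -
                        as.matrix(tr_r[colnames(tr_c)][-1]))),
              1e-7, label = id)
  }
})

test_that("the free-diffusion transport variant exchanges without gates", {
  m5d <- build_model("M5", diffusion_transport = TRUE)
  expect_true(m5d$diffusion_transport)
  p <- test_params_m9()
  tr <- simulate_time_course(m5d, p, 100, c(0, 30, 60))
  expect_true(all(tr$G1Sout == 0))           # gate sites unused
  expect_gt(utils::tail(observable_product(tr, p), 1), 0)
  # gate variant uses them
  tr2 <- simulate_time_course(build_model("M5"), p, 100, c(0, 30, 60))
  expect_gt(max(tr2$G1Sout), 0)
})
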