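test_that("the fragment roster is consistent and lengths conserved", {
  fs <- fragment_set(len_A = 8, len_B = 7, len_C = 8)
  expect_length(fs$lengths, 6)   # six-species roster
  expect_equal(fs$lengths[["S"]],
               fs$lengths[["A"]] + fs$lengths[["B"]] + fs$lengths[["C"]])
  expect_equal(fs$lengths[["BC"]], 15)
  expect_equal(fs$lengths[["AB"]], 15)
  expect_error(fragment_set(len_A = -1), "> 0")
  expect_error(fragment_set(transport = list(A = c(kon = 1))), "'S'")

  pm <- build_polypeptide_model(fs)
  expect_length(pm$species, 26)
  tr <- simulate_polypeptide(pm, 50, seq(0, 120, 10))
  res <- poly_residue_total(tr)
  expect_lt(max(abs(res - res[1])) / res[1], 1e-6)
})

test_that("compiled and reference polypeptide derivatives agree", {
  fs <- fragment_set()
  pm <- build_polypeptide_model(fs)
  a <- simulate_polypeptide(pm, 40, seq(0, 120, 20))
  b <- simulate_polypeptide(pm, 40, seq(0, 120, 20), engine = "R")
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-8)
})

test_that("symmetric sites share usage equally; silencing one site gives
           single-cleavage behaviour", {
  fs <- fragment_set()     # identical transport for every fragment
  tr <- simulate_polypeptide(build_polypeptide_model(fs), 50, seq(0, 180, 15))
  u <- cleavage_site_usage(tr)
  expect_true(all(abs(u$rel_site1[-1] - 0.5) < 1e-9))
  expect_true(all(diff(u$cum_site1) >= 0))   # cumulative counts non-decreasing

  fs0 <- fragment_set(active_site = utils::modifyList(
    fs$active_site, list(site_rates = c(1, 0))))
  tr0 <- simulate_polypeptide(build_polypeptide_model(fs0), 50,
                              seq(0, 180, 15))
  u0 <- cleavage_site_usage(tr0)
  expect_true(all(u0$flux_site2 == 0))
  expect_true(all(u0$rel_site1[-1] == 1))
  # no AB or C fragments are ever produced without site 2
  expect_true(all(abs(tr0$in_AB) < 1e-12) && all(abs(tr0$in_C) < 1e-12))
})

test_that("usage classification follows the slope sign rule", {
  t <- seq(10, 100, 10)
  mk <- function(n1, n2) {
    u <- data.frame(time = t, flux_site1 = 1, flux_site2 = 1,
                    cum_site1 = t, cum_site2 = t,
                    rel_site1 = 0.5, rel_site2 = 0.5,
                    norm_site1 = n1, norm_site2 = n2)
    class(u) <- c("proteodyn_usage", "data.frame")
    u
  }
  expect_equal(classify_usage_behavior(mk(rep(1, 10), rep(1, 10))), "flat")
  expect_equal(classify_usage_behavior(mk(seq(1, 2, length = 10),
                                          seq(1, 0.4, length = 10))),
               "divergent")
  expect_equal(classify_usage_behavior(mk(seq(1, 2, length = 10),
                                          seq(1, 1.8, length = 10))),
               "both_increase")
  expect_equal(classify_usage_behavior(mk(seq(1, 0.5, length = 10),
                                          seq(1, 0.6, length = 10))),
               "both_decrease")
  expect_error(classify_usage_behavior(mk(1, 1)[1:2, ]), "3")
  # hand-rule oracle on simulated fixtures: labels match an independent
  # slope evaluation
  set.seed(4)
  fs <- fragment_set()
  pri <- default_poly_prior(fs, orders = 3)
  z <- sample_prior(pri, 6)
  for (i in 1:6) {
    th <- prior_untransform(pri, stats::setNames(z[i, ], colnames(z)))
    fsi <- fs
    for (nm in names(th)) {
      parts <- strsplit(nm, "_")[[1]]
      fsi$transport[[parts[2]]][[parts[1]]] <- th[[nm]]
    }
    u <- cleavage_site_usage(simulate_polypeptide(
      build_polypeptide_model(fsi), 50, seq(10, 240, 10)))
    keep <- stats::complete.cases(u[, c("norm_site1", "norm_site2")]) &
      u$time > 0
    uu <- u[keep, ]
    sl <- function(v) {
      s <- stats::coef(stats::lm(v ~ uu$time))[2] * diff(range(uu$time))
      ifelse(abs(s / max(abs(mean(v)), 1e-300)) < 0.05, 0, sign(s))
    }
    s1 <- sl(uu$norm_site1); s2 <- sl(uu$norm_site2)
    want <- if (s1 == 0 && s2 == 0) "flat" else if (s1 * s2 < 0) "divergent"
      else if (max(s1, s2) > 0) "both_increase" else "both_decrease"
    expect_equal(classify_usage_behavior(u), want)
  }
})

test_that("behaviour search is reproducible and a near-degenerate
           symmetric prior only yields flat", {
  fs <- fragment_set()
  a <- search_behaviors(fs, n_samples = 40, seed = 12)
  b <- search_behaviors(fs, n_samples = 40, seed = 12)
  expect_identical(a$labels, b$labels)
  # essentially-point-mass prior at the symmetric defaults
  tiny <- default_poly_prior(fs, orders = 1e-6)
  d <- search_behaviors(fs, prior = tiny, n_samples = 10, seed = 3)
  expect_true(all(d$labels == d$labels[1]))
  expect_length(d$exemplars, 1)
})

test_that("usage drifts over time even with product re-entry disabled", {
  fs <- fragment_set()
  # retain the site-2-cleavable fragment, flush its counterpart
  fs$transport$BC[c("tau", "vout")] <- c(0.02, 0.05)
  fs$transport$AB[c("tau", "vout")] <- c(30, 10)
  tr <- simulate_polypeptide(build_polypeptide_model(fs), 50,
                             seq(10, 240, 10), product_reentry = FALSE)
  u <- cleavage_site_usage(tr)
  # relative usage changes although no product can re-enter
  expect_gt(max(u$rel_site2, na.rm = TRUE) - min(u$rel_site2[-1],
                                                 na.rm = TRUE), 0.01)
  expect_false(classify_usage_behavior(u) == "flat")
})

test_that("mean fragment length tracks digestion state", {
  fs <- fragment_set(len_A = 8, len_B = 7, len_C = 8)
  pm <- build_polypeptide_model(fs)
  tr <- simulate_polypeptide(pm, 50, c(0, seq(10, 360, 10)))
  ml <- mean_fragment_length(tr)
  expect_true(is.na(ml[1]))                      # no products yet
  # single-cleavage products only (early): mean is the weighted mean of
  # A/BC/AB/C lengths, hence between 8 and 15
  expect_true(all(ml[-1] > 8 - 1e-9 & ml[-1] < 15 + 1e-9))
  # secondary cleavage pushes the mean down over time
  expect_lt(utils::tail(ml, 1), max(ml, na.rm = TRUE) + 1e-12)
  n <- length(ml)
  expect_lte(ml[n], ml[round(n / 2)])
})
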