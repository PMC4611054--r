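test_that("the dataset distance is a normalised RMS over design cells", {
  obs <- data.frame(concentration_uM = c(100, 100, 200, 200),
                    time_min = c(30, 60, 30, 60),
                    product_nM = c(2, 4, 5, 10))
  expect_equal(abc_distance(obs, obs), 0)
  zero <- obs; zero$product_nM <- 0
  expect_equal(abc_distance(zero, zero), 0)
  # hand-computed oracle for a 2x2 design: cells normalised by their
  # series maxima (4 and 10)
  sim <- obs; sim$product_nM <- c(3, 4, 5, 8)
  oracle <- sqrt(mean(c((3 - 2) / 4, 0, 0, (8 - 10) / 10)^2))
  expect_equal(abc_distance(sim, obs), oracle, tolerance = 1e-12)
  # row order must not matter
  expect_equal(abc_distance(sim[c(3, 1, 4, 2), ], obs), oracle)
  bad <- obs[-2, ]
  expect_error(abc_distance(bad, obs), "mismatch")
})

test_that("ABC-SMC is reproducible with monotone epsilon schedules", {
  dfn <- function(m, th) abs(th[["mu"]] - 2) + stats::runif(1, 0, 0.1)
  pri <- prior_set(mu = prior("uniform", -10, 10))
  f1 <- abc_smc(dfn, pri, 80, seed = 5, max_populations = 5)
  f2 <- abc_smc(dfn, pri, 80, seed = 5, max_populations = 5)
  expect_identical(f1$particles, f2$particles)
  expect_identical(f1$epsilons, f2$epsilons)
  expect_true(all(diff(f1$epsilons[-1]) < 0))
  expect_true(all(f1$acceptance_rates > 0 & f1$acceptance_rates <= 1))
  expect_equal(sum(f1$particles$weight), 1, tolerance = 1e-12)
  # noise-free self-consistency: final distances below final epsilon
  expect_true(all(f1$particles$distance <= f1$epsilons[length(f1$epsilons)]))
})

test_that("ABC-SMC recovers the analytic posterior of the Gaussian toy", {
  set.seed(31)
  sigma <- 1; n <- 25
  obs <- rnorm(n, 1.2, sigma)
  pri <- prior_set(mu = prior("uniform", -5, 5))
  dfn <- function(m, th) abs(mean(rnorm(n, th[["mu"]], sigma)) - mean(obs))
  fit <- abc_smc(dfn, pri, 300, seed = 8, max_populations = 5,
                 eps_floor = 0.05)
  est <- abc_mcse(fit$particles$mu, fit$particles$weight)
  # flat prior on a wide interval: analytic posterior mean is the sample
  # mean (truncation negligible)
  expect_lt(abs(est$mean - mean(obs)), 3 * est$mcse)
})

test_that("model selection is symmetric for identical models", {
  m9 <- build_model("M9")
  p <- test_params_m9()
  dat <- generate_assay_dataset(m9, p, small_design(times = c(30, 120)),
                                noise_sd = 0.05, seed = 21)
  pri <- default_priors(m9, p, orders = 2, free = c("vin", "kp"))
  sel <- abc_smc_model_select(list(m9, m9), dat, list(pri, pri),
                              list(p, p), n_particles = 60, seed = 4,
                              max_populations = 3)
  final <- sel$final_probs
  expect_equal(unname(final[1] + final[2]), 1, tolerance = 1e-12)
  expect_lt(abs(final[1] - 0.5), 0.2)   # within Monte-Carlo error
  expect_equal(dim(sel$model_probs)[2], 2)
})

test_that("the iterative ladder has the expected comparison structure", {
  m1 <- build_model("M1")
  p <- parameter_set(vmax = 0.05, KM = 150, E0 = 0.0018)
  dat <- generate_assay_dataset(m1, p, small_design(times = c(30, 90)),
                                noise_sd = 0.05, seed = 33)
  base <- test_params_m9()
  base[c("vmax", "KM")] <- c(0.05, 150)
  res <- iterative_selection_scheme(dat, base, n_particles = 25, seed = 2,
                                    max_populations = 2)
  # 1 joint four-model comparison + 5 pairwise + 1 final re-test
  expect_length(res$history, 7)
  expect_equal(ncol(res$history[[1]]$model_probs), 4)
  for (k in 2:6) expect_equal(ncol(res$history[[k]]$model_probs), 2)
  expect_equal(ncol(res$history[[7]]$model_probs), 9)
  expect_true(res$winner %in% MODEL_IDS)
})

test_that("posterior comparison flags exactly the parameter that differs", {
  # two synthetic posteriors: equal in vin/KaS, kp differing three-fold
  mk_post <- function(kp_centre, seed) {
    set.seed(seed)
    n <- 400
    particles <- data.frame(
      model = 1L,
      vin = rlnorm(n, log(4), 0.15),
      kp = rlnorm(n, log(kp_centre), 0.15),
      KaS = rlnorm(n, log(0.05), 0.15),
      weight = rep(1 / n, n), distance = 0)
    structure(list(particles = particles, epsilons = 1,
                   acceptance_rates = 1, seed = seed),
              class = "proteodyn_abc")
  }
  a <- mk_post(2000, 1)
  b <- mk_post(6000, 2)
  cmp <- posterior_compare(a, b)
  expect_true(cmp$flagged[cmp$parameter == "kp"])
  expect_false(any(cmp$flagged[cmp$parameter != "kp"]))
  # identical posteriors: full overlap, nothing flagged
  cmp_same <- posterior_compare(a, a)
  expect_true(all(cmp_same$overlap == 1))
  expect_false(any(cmp_same$flagged))
  # disjoint marginals: overlap zero and flagged
  c2 <- mk_post(2000 * 1e3, 3)
  cmp_far <- posterior_compare(a, c2)
  expect_equal(cmp_far$overlap[cmp_far$parameter == "kp"], 0)
  expect_true(cmp_far$flagged[cmp_far$parameter == "kp"])
  # mismatched parameterisations are rejected
  bad <- mk_post(2000, 4)
  bad$particles$extra <- 1
  expect_error(posterior_compare(a, bad), "parameterisation")
})

test_that("weighted quantiles interpolate the weighted CDF", {
  x <- c(1, 2, 3, 4)
  w <- c(1, 1, 1, 1)
  expect_equal(weighted_quantile(x, w, 0.5), 2.5)
  # all weight on one value collapses every quantile onto it
  expect_equal(weighted_quantile(x, c(0, 1, 0, 0), c(0.1, 0.9)), c(2, 2))
})
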