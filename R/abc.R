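# Generic ABC-SMC engine (sequential populations of weighted particles,
# adaptive epsilon, component-wise uniform perturbation kernel). Model
# selection runs the same engine with the model indicator sampled jointly
# with the parameters; the indicator is not perturbed between populations,
# so a model's probability can only shrink through repeated rejection.

#' Likelihood-free sequential Monte Carlo sampler
#'
#' Core ABC-SMC engine used by [abc_smc_fit()] and
#' [abc_smc_model_select()]. Population 1 draws from the prior and accepts
#' every particle with a finite distance; each subsequent population
#' shrinks the acceptance threshold to the `eps_quantile` quantile of the
#' previous population's distances, resamples particles by weight,
#' perturbs them with a component-wise uniform kernel whose half-width is
#' `kernel_shrink` times the previous population's range per component
#' (log10 space for log-uniform parameters), and reweights by the
#' standard prior-over-kernel importance ratio. Runs are bit-reproducible
#' from `seed`.
#'
#' @param distance_fn `function(model_index, theta)` returning a
#'   non-negative scalar distance (or `Inf`/`NA` for failed simulations);
#'   `theta` is a named vector on the natural parameter scale.
#' @param priors a single [prior_set()] or, for model selection, a list of
#'   one prior set per model.
#' @param n_particles particles per population, `>= 50` for production
#'   runs (smaller values are allowed for smoke tests).
#' @param n_init prior draws scouted in population 1 (default
#'   `n_particles`). When larger, the first population simulates `n_init`
#'   prior draws and keeps the `n_particles` with the smallest distances,
#'   so later populations start from the best-supported prior regions —
#'   plain rejection ABC with an adaptive first threshold.
#' @param seed integer seed.
#' @param n_models number of models compared (1 for plain fitting).
#' @param model_prior prior model probabilities, default uniform.
#' @param max_populations maximum number of SMC populations.
#' @param eps_quantile adaptive threshold quantile; default 0.3.
#' @param eps_floor stop once epsilon falls to or below this value.
#' @param kernel perturbation kernel: `"mvnorm"` (default) perturbs with a
#'   multivariate normal whose covariance is `kernel_scale` times the
#'   weighted covariance of the previous population (per model), which
#'   follows correlated posterior ridges; `"uniform"` is the
#'   component-wise uniform kernel with half-width `kernel_shrink` times
#'   the previous population's component range.
#' @param kernel_scale covariance multiplier of the `"mvnorm"` kernel;
#'   default 1.
#' @param kernel_shrink kernel half-width as a fraction of the previous
#'   population's component range (uniform kernel only); default 0.5.
#' @param max_draws_per_pop cap on proposal draws per population before the
#'   sampler stops early with a warning (vanishing acceptance rate).
#' @param verbose print per-population progress.
#' @return an object of class `proteodyn_abc` with elements `particles`
#'   (data.frame: `model`, parameter columns, `weight`, `distance`),
#'   `epsilons`, `acceptance_rates`, `model_probs` (populations x models),
#'   `priors`, `seed`, `n_particles`.
#' @export
abc_smc <- function(distance_fn, priors, n_particles, seed = 1,
                    n_init = n_particles, n_models = 1, model_prior = NULL,
                    max_populations = 8, eps_quantile = 0.3, eps_floor = 0,
                    kernel = c("mvnorm", "uniform"), kernel_scale = 1,
                    kernel_shrink = 0.5, max_draws_per_pop = 2e6,
                    verbose = FALSE) {
  kernel <- match.arg(kernel)
  set.seed(as.integer(seed))
  prior_list <- if (n_models == 1 && inherits(priors, "proteodyn_priors"))
    list(priors) else priors
  if (length(prior_list) != n_models) stop("need one prior set per model")
  model_prior <- model_prior %||% rep(1 / n_models, n_models)
  if (length(model_prior) != n_models || any(model_prior <= 0))
    stop("malformed model prior")
  model_prior <- model_prior / sum(model_prior)

  par_names <- lapply(prior_list, names)
  epsilons <- numeric(0)
  acc_rates <- numeric(0)
  model_probs <- NULL
  pop <- NULL          # list: model (int), z (list of vectors), dist, weight

  for (t in seq_len(max_populations)) {
    t_pop <- proc.time()[3]
    eps <- if (t == 1) Inf else {
      q <- stats::quantile(pop$dist, eps_quantile, names = FALSE)
      min(q, epsilons[length(epsilons)] * 0.999)  # strictly decreasing
    }
    # per-model perturbation kernels from the previous population
    if (t > 1) {
      kernels <- lapply(seq_len(n_models), function(m) {
        idx <- which(pop$model == m)
        if (!length(idx)) return(NULL)
        zz <- do.call(rbind, pop$z[idx])
        ww <- pop$weight[idx] / sum(pop$weight[idx])
        if (kernel == "uniform") {
          wd <- pmax(kernel_shrink *
                       (apply(zz, 2, max) - apply(zz, 2, min)), 1e-8)
          list(type = "uniform", w = wd)
        } else {
          d <- ncol(zz)
          mu <- colSums(zz * ww)
          zc <- sweep(zz, 2, mu)
          S <- kernel_scale * crossprod(zc * ww, zc)
          S <- S + diag(d) * (1e-12 + 1e-6 * mean(diag(S)))
          U <- chol(S)
          list(type = "mvnorm", U = U,
               logconst = -sum(log(diag(U))) - d / 2 * log(2 * pi))
        }
      })
      perturb <- function(z, k) {
        if (k$type == "uniform")
          z + stats::runif(length(z), -1, 1) * k$w
        else
          z + drop(stats::rnorm(length(z)) %*% k$U)
      }
      kdens <- function(z, zz_rows, k) {
        # kernel density of z around each previous particle (vectorised)
        if (k$type == "uniform") {
          vapply(zz_rows, function(zj) {
            dz <- abs(z - zj)
            if (all(dz <= k$w)) prod(1 / (2 * k$w)) else 0
          }, numeric(1))
        } else {
          V <- matrix(vapply(zz_rows, function(zj) z - zj,
                             numeric(length(z))),
                      nrow = length(z))
          Y <- forwardsolve(t(k$U), V)
          exp(-0.5 * colSums(matrix(Y, nrow = length(z))^2) + k$logconst)
        }
      }
    }
    n_target <- if (t == 1) max(n_init, n_particles) else n_particles
    new_model <- integer(n_target)
    new_z <- vector("list", n_target)
    new_dist <- numeric(n_target)
    new_wraw <- numeric(n_target)
    accepted <- 0L
    draws <- 0L
    if (t > 1) cumw <- cumsum(pop$weight)
    while (accepted < n_target) {
      draws <- draws + 1L
      if (draws > max_draws_per_pop) break
      if (t == 1) {
        m <- sample.int(n_models, 1, prob = model_prior)
        z <- drop(sample_prior(prior_list[[m]], 1))
      } else {
        i <- min(findInterval(stats::runif(1), cumw) + 1L, length(pop$model))
        m <- pop$model[i]
        if (is.null(kernels[[m]])) next
        z <- perturb(pop$z[[i]], kernels[[m]])
        if (prior_density(prior_list[[m]], z) == 0) next
      }
      names(z) <- par_names[[m]]
      theta <- prior_untransform(prior_list[[m]], z)
      d <- tryCatch(distance_fn(m, theta), error = function(e) Inf)
      if (!is.finite(d) || d > eps) next
      accepted <- accepted + 1L
      new_model[accepted] <- m
      new_z[[accepted]] <- z
      new_dist[accepted] <- d
      if (t == 1) {
        new_wraw[accepted] <- 1
      } else {
        idx <- which(pop$model == m)
        kd <- kdens(z, pop$z[idx], kernels[[m]])
        denom <- sum(pop$weight[idx] * kd)
        num <- model_prior[m] * prior_density(prior_list[[m]], z)
        new_wraw[accepted] <- if (denom > 0) num / denom else 0
      }
    }
    if (accepted < n_target) {
      warning("ABC-SMC stopped early in population ", t,
              ": acceptance rate fell below ",
              signif(n_particles / max_draws_per_pop, 2))
      break
    }
    if (t == 1 && n_target > n_particles) {
      # keep the best-scoring scouts as the working population
      keep <- order(new_dist)[seq_len(n_particles)]
      new_model <- new_model[keep]
      new_z <- new_z[keep]
      new_dist <- new_dist[keep]
      new_wraw <- new_wraw[keep]
      eps <- max(new_dist)
    }
    wsum <- sum(new_wraw)
    if (wsum == 0) {
      warning("degenerate population (all weights zero); stopping")
      break
    }
    weight <- new_wraw / wsum
    ess <- 1 / sum(weight^2)
    if (ess < 1.5 && t > 1)
      warning("degenerate population (effective sample size ~1)")
    pop <- list(model = new_model, z = new_z, dist = new_dist,
                weight = weight)
    epsilons <- c(epsilons, eps)
    acc_rates <- c(acc_rates, accepted / draws)
    mp <- vapply(seq_len(n_models), function(m)
      sum(weight[new_model == m]), numeric(1))
    model_probs <- rbind(model_probs, mp)
    if (verbose)
      message(sprintf("population %d: eps=%.4g acc=%.3g draws=%d models=[%s] (%.1fs)",
                      t, eps, accepted / draws, draws,
                      paste(signif(mp, 3), collapse = " "),
                      proc.time()[3] - t_pop))
    if (ess < 1.5 && t > 1) break
    if (n_models > 1 && any(mp >= 1)) break
    if (eps <= eps_floor) break
  }

  # assemble particle table on the natural scale
  all_names <- unique(unlist(par_names))
  tab <- as.data.frame(matrix(NA_real_, length(pop$model), length(all_names),
                              dimnames = list(NULL, all_names)))
  for (i in seq_along(pop$model)) {
    th <- prior_untransform(prior_list[[pop$model[i]]], pop$z[[i]])
    tab[i, names(th)] <- th
  }
  out <- list(particles = cbind(data.frame(model = pop$model), tab,
                                data.frame(weight = pop$weight,
                                           distance = pop$dist)),
              epsilons = epsilons, acceptance_rates = acc_rates,
              model_probs = {
                rownames(model_probs) <- NULL
                colnames(model_probs) <- paste0("model_", seq_len(n_models))
                model_probs
              },
              priors = prior_list, seed = seed, n_particles = n_particles)
  class(out) <- "proteodyn_abc"
  out
}

#' @export
print.proteodyn_abc <- function(x, ...) {
  cat("ABC-SMC result: ", nrow(x$particles), " particles, ",
      length(x$epsilons), " populations\n", sep = "")
  cat("epsilon schedule:", signif(x$epsilons, 4), "\n")
  cat("acceptance rates:", signif(x$acceptance_rates, 3), "\n")
  if (ncol(x$model_probs) > 1) {
    cat("final model probabilities:\n")
    print(signif(x$model_probs[nrow(x$model_probs), ], 3))
  }
  invisible(x)
}

#' Weighted quantiles of posterior particles
#'
#' @param x numeric values.
#' @param w weights (summing to anything positive).
#' @param probs quantile levels.
#' @return numeric vector of quantiles (linear interpolation of the
#'   weighted empirical CDF).
#' @export
weighted_quantile <- function(x, w, probs) {
  ok <- is.finite(x) & is.finite(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(rep(NA_real_, length(probs)))
  if (length(x) == 1) return(rep(x, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Monte-Carlo standard error of a weighted posterior mean
#'
#' Weighted standard deviation over the square root of the effective
#' sample size, inflated by sqrt(2): after resampling, SMC particles
#' share ancestors, so the weight-based effective sample size
#' overestimates the number of independent draws and the plain estimator
#' is anti-conservative.
#'
#' @param x particle values.
#' @param w particle weights.
#' @return list with `mean`, `mcse` and `ess`.
#' @export
abc_mcse <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  ess <- 1 / sum(w^2)
  list(mean = m, mcse = sqrt(2 * sum(w * (x - m)^2) / ess), ess = ess)
}
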