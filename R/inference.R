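#' Distance between a simulated and an observed assay dataset
#'
#' Root-mean-square difference of product concentrations over every
#' (concentration, time) design cell, each cell normalised by the maximum
#' observed product of its concentration series (so all series contribute
#' on a comparable scale). Both inputs are cell tables
#' (`concentration_uM`, `time_min`, `product_nM`); replicate datasets
#' should be reduced with [dataset_cell_means()] first.
#'
#' @param simulated,observed cell tables with matching designs.
#' @return non-negative scalar.
#' @export
abc_distance <- function(simulated, observed) {
  key <- function(d) paste(d$concentration_uM, d$time_min)
  ks <- key(simulated); ko <- key(observed)
  if (length(ks) != length(ko) || !setequal(ks, ko)) {
    missing <- union(setdiff(ko, ks), setdiff(ks, ko))
    stop("design mismatch between simulated and observed datasets; ",
         "unmatched cells: ", paste(utils::head(missing, 5), collapse = "; "))
  }
  sim <- simulated[match(ko, ks), , drop = FALSE]
  norm <- stats::ave(observed$product_nM, observed$concentration_uM,
                     FUN = function(v) max(abs(v)))
  norm[norm == 0] <- 1
  sqrt(mean(((sim$product_nM - observed$product_nM) / norm)^2))
}

# distance closure for ODE models against a dataset's cell means; the
# solver runs at relaxed tolerances with a low step budget so implausible
# (stiff) prior corners fail fast instead of burning the simulation budget
make_dataset_distance <- function(models, dataset, base_params_list,
                                  lead_factor = "hill",
                                  solver_opts = list(rtol = 1e-6,
                                                     atol = 1e-9,
                                                     maxsteps = 5000)) {
  obs <- dataset_cell_means(dataset)
  conc <- unique(obs$concentration_uM)
  times <- sort(unique(obs$time_min))
  norm <- stats::ave(obs$product_nM, obs$concentration_uM,
                     FUN = function(v) max(abs(v)))
  norm[norm == 0] <- 1
  function(m, theta) {
    params <- base_params_list[[m]]
    params[names(theta)] <- theta
    sim <- suppressWarnings(
      simulate_design(models[[m]], params,
                      list(concentrations_uM = conc, times_min = times),
                      solver_opts = solver_opts, lead_factor = lead_factor))
    key_o <- paste(obs$concentration_uM, obs$time_min)
    key_s <- paste(sim$concentration_uM, sim$time_min)
    sim <- sim[match(key_o, key_s), , drop = FALSE]
    sqrt(mean(((sim$product_nM - obs$product_nM) / norm)^2))
  }
}

#' Fit one model to a time-course dataset with ABC-SMC
#'
#' The fitting target is the mean over replicates per design cell; the
#' distance is [abc_distance()]'s normalised RMS. Parameters without a
#' prior stay fixed at `base_params`.
#'
#' @param model a `proteodyn_model`.
#' @param dataset a `proteodyn_dataset` covering at least two
#'   concentration series.
#' @param priors a [prior_set()]; see [default_priors()].
#' @param base_params [parameter_set()] supplying every fixed parameter
#'   (including `E0`).
#' @param n_particles particles per population (>= 50 recommended).
#' @param seed integer seed; runs are bit-reproducible.
#' @param ... passed to [abc_smc()] (`max_populations`, `eps_quantile`,
#'   `eps_floor`, ...).
#' @return a `proteodyn_abc` posterior.
#' @export
abc_smc_fit <- function(model, dataset, priors, base_params, n_particles,
                        seed = 1, ...) {
  if (length(unique(dataset$concentration_uM)) < 2)
    stop("dataset must cover at least two initial concentrations")
  bad <- setdiff(names(priors), model$parameters)
  if (length(bad))
    stop("priors refer to parameters absent from ", model$model_id, ": ",
         paste(bad, collapse = ", "))
  dist_fn <- make_dataset_distance(list(model), dataset, list(base_params))
  abc_smc(dist_fn, priors, n_particles, seed = seed, n_models = 1, ...)
}

#' Bayesian model selection by joint ABC-SMC
#'
#' Samples a model indicator jointly with that model's parameters; the
#' per-population model probability is the weighted fraction of accepted
#' particles per model. Terminates when one model reaches probability 1 or
#' after `max_populations`.
#'
#' @param models list of `proteodyn_model`s (>= 2).
#' @param dataset a `proteodyn_dataset`.
#' @param priors_list one [prior_set()] per model.
#' @param base_params_list one [parameter_set()] per model.
#' @param n_particles particles per population.
#' @param seed integer seed.
#' @param model_prior prior model probabilities; default uniform (0.5 for a
#'   pairwise comparison, 0.25 for a four-model comparison).
#' @param ... passed to [abc_smc()].
#' @return a `proteodyn_model_selection`: fields `result` (the
#'   `proteodyn_abc`), `model_probs` (populations x models, named by model
#'   id), `winner` (model id or `NA` if unresolved).
#' @export
abc_smc_model_select <- function(models, dataset, priors_list,
                                 base_params_list, n_particles, seed = 1,
                                 model_prior = NULL, ...) {
  if (length(models) < 2) stop("need at least two models to compare")
  stopifnot(length(priors_list) == length(models),
            length(base_params_list) == length(models))
  dist_fn <- make_dataset_distance(models, dataset, base_params_list)
  fit <- abc_smc(dist_fn, priors_list, n_particles, seed = seed,
                 n_models = length(models), model_prior = model_prior, ...)
  probs <- fit$model_probs
  colnames(probs) <- vapply(models, `[[`, "", "model_id")
  final <- probs[nrow(probs), ]
  winner <- colnames(probs)[which.max(final)]
  out <- list(result = fit, model_probs = probs, winner = winner,
              final_probs = final,
              model_prior = model_prior %||% rep(1 / length(models),
                                                 length(models)))
  class(out) <- "proteodyn_model_selection"
  out
}

#' @export
print.proteodyn_model_selection <- function(x, ...) {
  cat("model selection over", ncol(x$model_probs), "models;",
      nrow(x$model_probs), "populations\n")
  print(round(x$model_probs, 3))
  cat("winner:", x$winner, "\n")
  invisible(x)
}

#' Iterative model-selection ladder
#'
#' Stage 1 compares the four non-compartmental models jointly (prior 1/4
#' each). The stage-1 winner is then compared pairwise (prior 1/2 each)
#' against the compartmental models in order of increasing complexity,
#' each comparison's winner advancing to the next. Finally the surviving
#' model is re-tested jointly against all other models.
#'
#' @param dataset a `proteodyn_dataset`.
#' @param base_params [parameter_set()] of fixed parameters shared by all
#'   candidates (`E0` etc.).
#' @param n_particles particles per population.
#' @param seed integer seed (each comparison uses a sub-seed derived from
#'   it, so the whole history is reproducible).
#' @param prior_orders width of the default priors (orders of magnitude).
#' @param ... passed to [abc_smc()].
#' @return list with `winner` (model id) and `history` (list of
#'   `proteodyn_model_selection`, one per comparison, in order).
#' @export
iterative_selection_scheme <- function(dataset, base_params, n_particles,
                                       seed = 1, prior_orders = 4, ...) {
  mk <- function(ids) lapply(ids, build_model)
  setup <- function(models) {
    list(priors = lapply(models, default_priors, base_params = base_params,
                         orders = prior_orders),
         base = lapply(models, function(m) base_params))
  }
  history <- list()
  # stage 1: the four non-compartmental models, prior 1/4 each
  ids1 <- paste0("M", 1:4)
  s <- setup(mk(ids1))
  sel <- abc_smc_model_select(mk(ids1), dataset, s$priors, s$base,
                              n_particles, seed = seed, ...)
  history <- c(history, list(sel))
  winner <- sel$winner
  # pairwise ladder against M5..M9 in order of increasing complexity
  for (k in 5:9) {
    ids <- c(winner, paste0("M", k))
    s <- setup(mk(ids))
    sel <- abc_smc_model_select(mk(ids), dataset, s$priors, s$base,
                                n_particles, seed = seed + k, ...)
    history <- c(history, list(sel))
    winner <- sel$winner
  }
  # final re-test of the survivor against all other models
  ids <- c(winner, setdiff(MODEL_IDS, winner))
  s <- setup(mk(ids))
  sel <- abc_smc_model_select(mk(ids), dataset, s$priors, s$base,
                              n_particles, seed = seed + 100, ...)
  history <- c(history, list(sel))
  list(winner = sel$winner, history = history)
}

#' Compare two posteriors parameter by parameter
#'
#' For every shared inferred parameter, reports weighted marginal
#' summaries (median and the central `level` interval) for both
#' posteriors plus an interval-overlap score: the length of the
#' intersection of the two credible intervals divided by the length of
#' the shorter one (1 for nested/identical marginals, 0 for disjoint).
#' Parameters with overlap below `threshold` are flagged as showing
#' evidence for a difference; overlap above it is read as "no evidence
#' for differences".
#'
#' @param posterior_A,posterior_B `proteodyn_abc` objects over the same
#'   parameterisation.
#' @param level central credible-interval mass; default 0.9 (5-95%).
#' @param threshold overlap below which a parameter is flagged; default
#'   0.05.
#' @return data.frame: `parameter`, `median_A`, `lo_A`, `hi_A`,
#'   `median_B`, `lo_B`, `hi_B`, `overlap`, `flagged`.
#' @export
posterior_compare <- function(posterior_A, posterior_B, level = 0.9,
                              threshold = 0.05) {
  pars_of <- function(p) setdiff(colnames(p$particles),
                                 c("model", "weight", "distance"))
  pa <- pars_of(posterior_A); pb <- pars_of(posterior_B)
  if (!setequal(pa, pb))
    stop("posteriors have different parameterisations: ",
         paste(union(setdiff(pa, pb), setdiff(pb, pa)), collapse = ", "))
  lo_p <- (1 - level) / 2; hi_p <- 1 - lo_p
  rows <- lapply(sort(pa), function(nm) {
    qa <- weighted_quantile(posterior_A$particles[[nm]],
                            posterior_A$particles$weight,
                            c(lo_p, 0.5, hi_p))
    qb <- weighted_quantile(posterior_B$particles[[nm]],
                            posterior_B$particles$weight,
                            c(lo_p, 0.5, hi_p))
    inter <- max(0, min(qa[3], qb[3]) - max(qa[1], qb[1]))
    shorter <- max(min(qa[3] - qa[1], qb[3] - qb[1]), .Machine$double.eps)
    ov <- min(1, inter / shorter)
    data.frame(parameter = nm, median_A = qa[2], lo_A = qa[1], hi_A = qa[3],
               median_B = qb[2], lo_B = qb[1], hi_B = qb[3],
               overlap = ov, flagged = ov < threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
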