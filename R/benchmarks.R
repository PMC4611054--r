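# Scaled-down recovery experiments. These are the package's built-in
# self-calibration studies: they generate synthetic data under known
# conditions, run the full inference machinery, and report how well the
# truth is recovered. The tests and the reproduction script both call
# them, so the settings live in one place.

#' Six-concentration assay design used by the recovery experiments
#'
#' Six initial concentrations from 20 to 640 uM sampled at seven times up
#' to 360 min with duplicate replicates -- the human-design layout at a
#' time resolution chosen to keep the desk-scale ABC runs affordable.
#'
#' @param concentrations_uM,times_min overrides.
#' @return design list as in [default_designs()].
#' @export
recovery_design <- function(concentrations_uM = c(20, 40, 80, 160, 320, 640),
                            times_min = c(15, 30, 60, 120, 180, 270, 360)) {
  list(substrate = "Suc-LLVY-MCA", isoform = "mouse",
       concentrations_uM = concentrations_uM, times_min = times_min,
       replicates = 2, enzyme_ug = 0.125, volume_ul = 100)
}

#' M9 parameter-recovery experiment
#'
#' Generates a noisy synthetic dataset from the full compartmental model
#' M9, fits M9 to it with ABC-SMC, and summarises the marginal posteriors
#' against the generating truth. The generating parameters are the
#' Suc-LLVY-MCA fixture with the efflux reduced to `vout = 0.1` so the
#' chamber approaches its capacity within the experiment: a container's
#' size is only measurable when it fills, so the recovery study runs in
#' the capacity-limited regime where the time of the velocity bend
#' identifies `C`. The free parameters are the transport rates (`vin`,
#' `vout`, `tau`), the chamber capacity `C`, the enhancement factor
#' `Xenh` and the active-site parameters (`kp`, `KaS`, `beta`);
#' binding/unbinding rate pairs of the gate and regulatory sites are
#' fixed -- the observable constrains their occupancies, not the
#' individual rates.
#'
#' @param seed integer seed (data noise and sampler).
#' @param n_particles particles per population; default 200.
#' @param noise_sd measurement noise; default 0.05.
#' @param max_populations,eps_floor,n_init sampler settings (defaults
#'   calibrated so the run finishes in minutes on one CPU while reaching
#'   the noise floor of the distance).
#' @return list with `truth`, `posterior` (`proteodyn_abc`) and `summary`
#'   (data.frame: parameter, truth, q05, median, q95, in_interval,
#'   rel_err_median).
#' @export
recovery_experiment_m9 <- function(seed = 1, n_particles = 200,
                                   noise_sd = 0.05, max_populations = 14,
                                   eps_floor = 0.03, n_init = 3000, ...) {
  m9 <- build_model("M9")
  truth <- fixture_parameters("Suc-LLVY-MCA", "mouse")
  truth[["vout"]] <- 0.1       # capacity-limited regime (see above)
  design <- recovery_design()
  dat <- generate_assay_dataset(m9, truth, design, noise_sd = noise_sd,
                                seed = seed + 1000L)
  truth[["E0"]] <- enzyme_concentration_uM(design$enzyme_ug,
                                           design$volume_ul)
  truth[c("G1_tot", "G2_tot", "Ereg_tot", "I0")] <- truth[["E0"]]
  free <- c("vin", "vout", "tau", "C", "Xenh", "kp", "KaS", "beta")
  priors <- default_priors(m9, truth, free = free)
  fit <- abc_smc_fit(m9, dat, priors, truth, n_particles = n_particles,
                     seed = seed, n_init = n_init, kernel_scale = 0.5,
                     max_populations = max_populations,
                     eps_floor = eps_floor, ...)
  summ <- do.call(rbind, lapply(free, function(nm) {
    q <- weighted_quantile(fit$particles[[nm]], fit$particles$weight,
                           c(0.05, 0.5, 0.95))
    data.frame(parameter = nm, truth = truth[[nm]], q05 = q[1],
               median = q[2], q95 = q[3],
               in_interval = truth[[nm]] >= q[1] & truth[[nm]] <= q[3],
               rel_err_median = abs(q[2] - truth[[nm]]) / truth[[nm]])
  }))
  list(truth = truth, posterior = fit, summary = summ)
}

#' Stage-1 model-selection recovery (non-compartmental models)
#'
#' Simulates Michaelis-Menten (M1) data on a three-concentration design
#' and runs the joint comparison of M1-M4 at prior probability 1/4 each.
#' The expected outcome is M1: the richer rate laws gain no support from
#' MM kinetics.
#'
#' @param seed integer seed.
#' @param n_particles particles per population; default 120.
#' @param max_populations default 6.
#' @return a `proteodyn_model_selection`.
#' @export
selection_experiment_stage1 <- function(seed = 1, n_particles = 120,
                                        max_populations = 6, ...) {
  design <- recovery_design(concentrations_uM = c(80, 240, 480),
                            times_min = c(30, 60, 120, 240, 360))
  m1 <- build_model("M1")
  p1 <- parameter_set(vmax = 0.05, KM = 150)
  dat <- generate_assay_dataset(m1, p1, design, noise_sd = 0.05,
                                seed = seed + 2000L)
  base <- parameter_set(kp = 30, KaS = 150, KaP = 100, KiS = 200,
                        KiP = 200, vmax = 0.05, KM = 150, alpha = 1,
                        beta = 0.5)
  base[["E0"]] <- enzyme_concentration_uM(design$enzyme_ug)
  models <- lapply(paste0("M", 1:4), build_model)
  abc_smc_model_select(models, dat,
                       lapply(models, default_priors, base_params = base),
                       lapply(models, function(m) base),
                       n_particles = n_particles, seed = seed,
                       n_init = 4 * n_particles,
                       max_populations = max_populations, ...)
}

#' Pairwise selection of M9 against M5 under strong regulation
#'
#' Simulates data from M9 with a strong internal enhancer and strong
#' external inhibition (`Xenh = 10`, `Yinh = 12`), then compares M9
#' against the regulation-free transport model M5 pairwise (prior 1/2
#' each). M5 can reproduce neither the accelerating velocity nor the
#' substrate inhibition, so its probability should collapse.
#'
#' @param seed integer seed.
#' @param n_particles particles per population; default 120.
#' @param max_populations default 8.
#' @return a `proteodyn_model_selection`.
#' @export
selection_experiment_m9_vs_m5 <- function(seed = 1, n_particles = 150,
                                          max_populations = 12, ...) {
  design <- recovery_design(concentrations_uM = c(80, 240, 480),
                            times_min = c(30, 60, 120, 240, 360))
  m9 <- build_model("M9"); m5 <- build_model("M5")
  truth <- fixture_parameters("Suc-LLVY-MCA", "mouse")
  truth[c("Yinh", "Ion")] <- c(12, 3e-7)
  dat <- generate_assay_dataset(m9, truth, design, noise_sd = 0.05,
                                seed = seed + 3000L)
  base <- truth
  base[["E0"]] <- enzyme_concentration_uM(design$enzyme_ug)
  # symmetric convention for both candidates: transport, capacity,
  # regulation strength and active-site parameters free; gate association
  # fixed along with the other per-site kinetics
  free9 <- c("vin", "vout", "tau", "C", "Xenh", "Yinh", "kp", "KaS", "beta")
  free5 <- c("vin", "vout", "tau", "C", "kp", "KaS", "beta")
  abc_smc_model_select(list(m9, m5), dat,
                       list(default_priors(m9, base, free = free9),
                            default_priors(m5, base, free = free5)),
                       list(base, base),
                       n_particles = n_particles, seed = seed,
                       n_init = 8 * n_particles, kernel_scale = 0.5,
                       max_populations = max_populations, ...)
}
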