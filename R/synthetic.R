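#' Substrate and isoform identifiers known to the fixture generator
#' @export
SUBSTRATES <- c("Suc-LLVY-MCA", "Bz-VGR-MCA", "Z-LLE-MCA")

#' @rdname SUBSTRATES
#' @export
ISOFORMS <- c("mouse", "human-s", "human-i")

#' Assay designs shipped with the package
#'
#' Named list of fluorogenic-assay designs mirroring the experimental
#' protocols the package emulates: mouse digestions of 80-480 uM
#' Suc-LLVY-MCA and 160-640 uM Z-LLE-MCA, human standard-/immuno-proteasome
#' digestions of all three substrates at six initial concentrations from
#' 20 to 640 uM, a short initial-velocity design sampled at 15/30/45/60 min,
#' and a long kinetics design out to 360 min.
#'
#' Each design is a list with fields `substrate`, `isoform`,
#' `concentrations_uM`, `times_min`, `replicates`, `enzyme_ug`,
#' `volume_ul`.
#'
#' @return named list of designs.
#' @export
#' @examples
#' length(default_designs()$human_llvy$concentrations_uM) # six-point design
default_designs <- function() {
  times_long <- seq(15, 360, by = 15)
  base <- function(substrate, isoform, conc, times, enzyme_ug) {
    list(substrate = substrate, isoform = isoform,
         concentrations_uM = conc, times_min = times, replicates = 2,
         enzyme_ug = enzyme_ug, volume_ul = 100)
  }
  human_conc <- c(20, 40, 80, 160, 320, 640)
  designs <- list(
    mouse_llvy = base("Suc-LLVY-MCA", "mouse",
                      c(80, 160, 240, 320, 400, 480), times_long, 0.125),
    mouse_lle = base("Z-LLE-MCA", "mouse",
                     c(160, 240, 320, 480, 640), times_long, 0.125),
    human_llvy = base("Suc-LLVY-MCA", "human-s", human_conc, times_long, 0.5),
    human_vgr = base("Bz-VGR-MCA", "human-s", human_conc, times_long, 0.5),
    human_lle = base("Z-LLE-MCA", "human-s", human_conc, times_long, 0.5),
    velocity = base("Suc-LLVY-MCA", "mouse", c(20, 40, 80, 160, 320, 480, 640),
                    c(15, 30, 45, 60), 0.125),
    long_kinetics = base("Suc-LLVY-MCA", "mouse", 480,
                         seq(15, 360, by = 5), 0.125)
  )
  for (d in designs) stopifnot(all(d$concentrations_uM > 0), d$replicates >= 1)
  designs
}

#' Fixture kinetic parameters per substrate and proteasome isoform
#'
#' Documented, order-of-magnitude-plausible parameter sets used by the
#' tests, the synthetic-data generator and the demo analyses. They are
#' fixtures chosen to reproduce the qualitative kinetic regimes of each
#' substrate class -- they are not estimates from experimental data:
#'
#' * `Suc-LLVY-MCA`: transport-limited hydrolysis with a strong internal
#'   transport enhancer, so the reaction velocity grows over the first
#'   90-120 min as the chamber fills.
#' * `Z-LLE-MCA`: fast transport, strong external inhibitory site
#'   (`h = 2`) and heavy substrate/product inhibition at the active site
#'   (small `beta`), giving substrate inhibition (an interior maximum in
#'   the dose-response).
#' * `Bz-VGR-MCA`: intermediate, enhancer-driven but without substrate
#'   inhibition in the assayed range.
#'
#' Chamber capacities are in the hundreds of molecules, the physically
#' plausible scale for short peptides, and differ between substrates
#' (inversely with molecular volume). The human immuno-isoform differs
#' from the standard isoform in transport parameters (gate affinity,
#' influx/efflux, enhancer affinity) and in active-site parameters for the
#' chymotryptic- and caspase-like substrates, not for Bz-VGR-MCA.
#'
#' @param substrate one of `"Suc-LLVY-MCA"`, `"Bz-VGR-MCA"`, `"Z-LLE-MCA"`.
#' @param isoform one of `"mouse"`, `"human-s"`, `"human-i"`.
#' @return a [parameter_set()] for model M9.
#' @export
fixture_parameters <- function(substrate = SUBSTRATES,
                               isoform = ISOFORMS) {
  substrate <- match.arg(substrate)
  isoform <- match.arg(isoform)
  E0 <- enzyme_concentration_uM(if (isoform == "mouse") 0.125 else 0.5)
  base <- switch(
    substrate,
    "Suc-LLVY-MCA" = list(
      kon = 0.02, koff = 10, vin = 4, vout = 0.2, tau = 5, C = 200,
      Ron = 3e-4, Roff = 0.004, Xenh = 10,
      Ion = 2e-8, Ioff = 0.05, h = 2, Yinh = 1.5,
      kp = 6000, KaS = 0.05, KaP = 0.15, KiS = 2, KiP = 2,
      na = 1, ni = 1, alpha = 0.8, beta = 0.6),
    "Bz-VGR-MCA" = list(
      kon = 0.012, koff = 10, vin = 3, vout = 0.25, tau = 5, C = 290,
      Ron = 2.5e-4, Roff = 0.004, Xenh = 6,
      Ion = 1e-8, Ioff = 0.05, h = 2, Yinh = 1,
      kp = 4000, KaS = 0.08, KaP = 0.2, KiS = 3, KiP = 3,
      na = 1, ni = 1, alpha = 0.8, beta = 0.7),
    "Z-LLE-MCA" = list(
      kon = 0.05, koff = 8, vin = 60, vout = 1, tau = 10, C = 250,
      Ron = 0.004, Roff = 0.04, Xenh = 3,
      Ion = 3e-7, Ioff = 0.04, h = 2, Yinh = 12,
      kp = 10, KaS = 0.05, KaP = 0.05, KiS = 0.3, KiP = 0.15,
      na = 1, ni = 1, alpha = 0.6, beta = 0.05))
  if (isoform == "human-i") {
    # immuno-isoform: altered gate affinity, faster influx/efflux for the
    # chymotryptic/tryptic substrates, slower for the caspase-like one,
    # higher enhancer affinity throughout; beta5i/beta1i active-site shifts
    scale <- if (substrate == "Z-LLE-MCA") 0.7 else 1.6
    base$vin <- base$vin * scale
    base$vout <- base$vout * scale
    base$koff <- base$koff * if (substrate == "Bz-VGR-MCA") 1.5 else 0.6
    base$Roff <- base$Roff * 0.5
    if (substrate == "Suc-LLVY-MCA") {
      base$KaS <- base$KaS * 0.5
      base$kp <- base$kp * 1.5
    }
    if (substrate == "Z-LLE-MCA") base$KaS <- base$KaS * 2
  }
  do.call(parameter_set, c(base, list(E0 = E0)))
}

#' Generate a synthetic fluorogenic-assay dataset
#'
#' Simulates the given design with the given model/parameters and applies
#' per-cell measurement noise independently per replicate: multiplicative
#' log-normal with log-scale standard deviation `noise_sd` (fluorescence
#' errors scale with signal), or additive Gaussian with standard deviation
#' `noise_sd` (in nM) as an option. Negative additive draws are clamped at
#' zero. The generating model, parameters, seed and design are recorded as
#' provenance.
#'
#' @param model a `proteodyn_model`.
#' @param params a [parameter_set()]. `E0` is taken from the design's
#'   enzyme amount, not from `params`, so the dataset is internally
#'   consistent with its design.
#' @param design one entry of [default_designs()] (or a list with the same
#'   fields).
#' @param noise_sd noise magnitude, `>= 0`; default 0.05.
#' @param seed integer seed; the dataset is bit-reproducible given the seed.
#' @param noise_model `"lognormal"` (default) or `"additive"`.
#' @return data.frame of class `proteodyn_dataset` with columns
#'   `substrate`, `concentration_uM`, `time_min`, `replicate`,
#'   `product_nM`, and attribute `provenance`.
#' @export
generate_assay_dataset <- function(model, params, design, noise_sd = 0.05,
                                   seed = 1,
                                   noise_model = c("lognormal", "additive")) {
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  params[["E0"]] <- enzyme_concentration_uM(design$enzyme_ug, design$volume_ul)
  params[c("G1_tot", "G2_tot", "Ereg_tot", "I0")] <- params[["E0"]]
  clean <- simulate_design(model, params, design)
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(design$replicates), function(r) {
    noisy <- switch(noise_model,
      lognormal = clean$product_nM * exp(stats::rnorm(nrow(clean), 0, noise_sd)),
      additive = pmax(0, clean$product_nM + stats::rnorm(nrow(clean), 0, noise_sd)))
    data.frame(substrate = design$substrate,
               concentration_uM = clean$concentration_uM,
               time_min = clean$time_min, replicate = r,
               product_nM = noisy)
  }))
  rownames(rows) <- NULL
  attr(rows, "provenance") <- list(model_id = model$model_id,
                                   params = unclass(params), seed = seed,
                                   noise_sd = noise_sd,
                                   noise_model = noise_model,
                                   design = design)
  class(rows) <- c("proteodyn_dataset", "data.frame")
  rows
}

# noiseless simulation of a design: one row per (concentration, time)
simulate_design <- function(model, params, design, ...) {
  do.call(rbind, lapply(design$concentrations_uM, function(s0) {
    traj <- simulate_time_course(model, params, s0, design$times_min,
                                 check_conservation = FALSE, ...)
    data.frame(concentration_uM = s0, time_min = traj$time,
               product_nM = 1000 * observable_product(traj, params))
  }))
}

#' Mean-over-replicates fitting target of a dataset
#'
#' @param dataset a `proteodyn_dataset` (or data.frame with the same
#'   columns).
#' @return data.frame `concentration_uM`, `time_min`, `product_nM` with the
#'   replicate mean per design cell.
#' @export
dataset_cell_means <- function(dataset) {
  agg <- stats::aggregate(product_nM ~ concentration_uM + time_min,
                          data = dataset, FUN = mean)
  agg[order(agg$concentration_uM, agg$time_min), , drop = FALSE]
}
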