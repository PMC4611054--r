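# Two-cleavage-site polypeptide extension. A hypothetical substrate S with
# cleavage sites 1 and 2 yields the fragment roster
#   S --site1--> A + BC      S --site2--> AB + C
#   BC --site2--> B + C      AB --site1--> A + B
# Every species is transported with its own gate/transport parameters but
# all share the gate sites, the chamber capacity and a simplified common
# active-site law (two-site-modifier denominator with species-summed
# occupancies).

POLY_FRAGMENTS <- c("S", "A", "BC", "AB", "B", "C")
POLY_CLEAVABLE <- c(S = TRUE, A = FALSE, BC = TRUE, AB = TRUE,
                    B = FALSE, C = FALSE)
POLY_TRANSPORT_PARS <- c("kon", "koff", "vin", "vout", "tau")

#' Fragment roster of a two-cleavage-site polypeptide
#'
#' @param len_A,len_B,len_C residue lengths of the three terminal
#'   fragments; the full substrate has `len_A + len_B + len_C` residues
#'   (default 8 + 7 + 8 = 23, sites after positions 8 and 15).
#' @param transport named list of per-fragment transport parameters; each
#'   entry a numeric vector with names `kon`, `koff`, `vin`, `vout`,
#'   `tau`. Fragments not listed inherit the `"S"` entry (which must be
#'   present).
#' @param active_site shared active-site parameters: `kp`, `KaS`, `KiS`,
#'   `KiP`, `na`, `ni`, `alpha`, `beta` and `site_rates` (length-2
#'   relative catalytic rates of sites 1 and 2).
#' @param E0 proteasome concentration (uM).
#' @param C shared chamber capacity (molecules per proteasome).
#' @param G1_tot,G2_tot gate-site totals; default `E0`.
#' @return a `proteodyn_fragment_set`.
#' @export
fragment_set <- function(len_A = 8, len_B = 7, len_C = 8,
                         transport = list(S = c(kon = 0.02, koff = 5,
                                                vin = 4, vout = 0.3,
                                                tau = 3)),
                         active_site = list(kp = 200, KaS = 10,
                                            KiS = 1, KiP = 0.005,
                                            na = 1, ni = 1, alpha = 1,
                                            beta = 0.3,
                                            site_rates = c(1, 1)),
                         E0 = 0.0018, C = 150, G1_tot = E0, G2_tot = E0) {
  if (any(c(len_A, len_B, len_C) <= 0)) stop("fragment lengths must be > 0")
  lengths <- c(S = len_A + len_B + len_C, A = len_A, BC = len_B + len_C,
               AB = len_A + len_B, B = len_B, C = len_C)
  if (lengths[["S"]] != lengths[["A"]] + lengths[["B"]] + lengths[["C"]])
    stop("inconsistent fragment lengths")
  if (is.null(transport$S)) stop("transport must define the 'S' entry")
  tr <- lapply(POLY_FRAGMENTS, function(f) {
    v <- transport[[f]] %||% transport$S
    if (!all(POLY_TRANSPORT_PARS %in% names(v)))
      stop("transport entry for ", f, " must name ",
           paste(POLY_TRANSPORT_PARS, collapse = ", "))
    v[POLY_TRANSPORT_PARS]
  })
  names(tr) <- POLY_FRAGMENTS
  need <- c("kp", "KaS", "KiS", "KiP", "na", "ni", "alpha", "beta",
            "site_rates")
  miss <- setdiff(need, names(active_site))
  if (length(miss))
    stop("active_site missing: ", paste(miss, collapse = ", "))
  if (length(active_site$site_rates) != 2 || any(active_site$site_rates < 0))
    stop("site_rates must be two non-negative relative rates")
  structure(list(lengths = lengths, transport = tr,
                 active_site = active_site, E0 = E0, C = C,
                 G1_tot = G1_tot, G2_tot = G2_tot),
            class = "proteodyn_fragment_set")
}

#' Build the polypeptide digestion model
#'
#' @param fs a [fragment_set()].
#' @return a `proteodyn_poly_model` with the state layout (`out_*`,
#'   `g1_*`, `in_*`, `g2_*` per fragment plus free `G1`, `G2`).
#' @export
build_polypeptide_model <- function(fs) {
  if (!inherits(fs, "proteodyn_fragment_set")) stop("not a fragment set")
  species <- c(paste0("out_", POLY_FRAGMENTS), paste0("g1_", POLY_FRAGMENTS),
               paste0("in_", POLY_FRAGMENTS), paste0("g2_", POLY_FRAGMENTS),
               "G1", "G2")
  structure(list(fragment_set = fs, species = species),
            class = "proteodyn_poly_model")
}

pack_poly_params <- function(fs) {
  tr <- unlist(fs$transport, use.names = FALSE)
  a <- fs$active_site
  c(tr, fs$E0, fs$C, a$kp * a$site_rates[1], a$kp * a$site_rates[2],
    a$KaS, a$KiS, a$KiP, a$na, a$ni, a$alpha, a$beta)
}

# simplified shared active-site law: per-fragment-per-site cleavage fluxes
poly_cleavage_flux <- function(inner, fs) {
  a <- fs$active_site
  X <- pmax(inner, 0)
  occ_a <- ifelse(POLY_CLEAVABLE, X^a$na / a$KaS, 0)
  occ_i <- ifelse(POLY_CLEAVABLE, X^a$ni / a$KiS, X^a$ni / a$KiP)
  asum <- sum(occ_a); bsum <- sum(occ_i)
  x <- 1 + asum + bsum + asum * bsum / a$alpha
  mod <- (1 + a$beta * bsum / a$alpha) / x
  kp1 <- a$kp * a$site_rates[1]; kp2 <- a$kp * a$site_rates[2]
  list(vS1 = a$na * kp1 * fs$E0 * occ_a[["S"]] * mod,
       vS2 = a$na * kp2 * fs$E0 * occ_a[["S"]] * mod,
       vBC2 = a$na * kp2 * fs$E0 * occ_a[["BC"]] * mod,
       vAB1 = a$na * kp1 * fs$E0 * occ_a[["AB"]] * mod,
       x = x)
}

# reference R right-hand side (mirrors the compiled version)
poly_rhs_R <- function(y, fs) {
  y <- pmax(y, 0)
  d <- numeric(26)
  E0 <- fs$E0
  G1 <- y[25]; G2 <- y[26]
  inner <- stats::setNames(y[13:18], POLY_FRAGMENTS)
  cap <- tanh(max(0, E0 * fs$C - sum(inner)))
  fl <- poly_cleavage_flux(inner, fs)
  for (i in seq_along(POLY_FRAGMENTS)) {
    tp <- fs$transport[[i]]
    b <- tp[["kon"]] * y[i] * G1
    u <- tp[["koff"]] * y[6 + i]
    inn <- tp[["vin"]] * cap * y[6 + i]
    trn <- tp[["tau"]] * y[12 + i] * G2 / E0
    out <- tp[["vout"]] * y[18 + i]
    d[i] <- d[i] - b + u + out
    d[6 + i] <- b - u - inn
    d[12 + i] <- d[12 + i] + inn - trn
    d[18 + i] <- trn - out
    d[25] <- d[25] - b + u + inn
    d[26] <- d[26] - trn + out
  }
  d[12 + 1] <- d[12 + 1] - fl$vS1 - fl$vS2
  d[12 + 2] <- d[12 + 2] + fl$vS1 + fl$vAB1
  d[12 + 3] <- d[12 + 3] + fl$vS1 - fl$vBC2
  d[12 + 4] <- d[12 + 4] + fl$vS2 - fl$vAB1
  d[12 + 5] <- d[12 + 5] + fl$vBC2 + fl$vAB1
  d[12 + 6] <- d[12 + 6] + fl$vS2 + fl$vBC2
  d
}

#' Simulate a polypeptide digestion
#'
#' @param poly_model from [build_polypeptide_model()].
#' @param S0 initial full-substrate concentration (uM).
#' @param times sampling times (min).
#' @param product_reentry if `FALSE`, product fragments cannot re-bind the
#'   outer gate (their `kon` is set to zero), switching product re-entry
#'   off.
#' @param solver_opts list with `rtol`, `atol`, `maxsteps`.
#' @param engine `"compiled"` (default) or `"R"` (reference).
#' @return `proteodyn_poly_trajectory` data.frame (`time` + species).
#' @export
simulate_polypeptide <- function(poly_model, S0, times,
                                 product_reentry = TRUE,
                                 solver_opts = list(),
                                 engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  if (!inherits(poly_model, "proteodyn_poly_model")) stop("not a poly model")
  fs <- poly_model$fragment_set
  if (!product_reentry)
    for (f in setdiff(POLY_FRAGMENTS, "S")) fs$transport[[f]][["kon"]] <- 0
  if (S0 < 0) stop("S0 must be >= 0")
  times <- sort(unique(c(0, as.numeric(times))))
  y0 <- stats::setNames(numeric(26), poly_model$species)
  y0["out_S"] <- S0
  y0["G1"] <- fs$G1_tot; y0["G2"] <- fs$G2_tot
  rtol <- solver_opts$rtol %||% 1e-8
  atol <- solver_opts$atol %||% 1e-10
  maxsteps <- solver_opts$maxsteps %||% 50000
  raw <- if (engine == "compiled") {
    deSolve::lsoda(y0, times, func = "proteodyn_deriv_poly",
                   parms = pack_poly_params(fs), dllname = "proteodyn",
                   initfunc = "proteodyn_init_poly",
                   rtol = rtol, atol = atol, maxsteps = maxsteps)
  } else {
    deSolve::lsoda(y0, times, function(t, y, p) list(poly_rhs_R(y, fs)),
                   NULL, rtol = rtol, atol = atol, maxsteps = maxsteps)
  }
  out <- as.data.frame(check_solution(raw, times, "polypeptide"))
  attr(out, "fragment_set") <- fs
  class(out) <- c("proteodyn_poly_trajectory", "data.frame")
  out
}

#' Total residues across all species of a polypeptide trajectory
#'
#' Residue conservation diagnostic: constant along any valid trajectory.
#'
#' @param trajectory a `proteodyn_poly_trajectory`.
#' @return numeric vector (residue concentration, uM of residues) per time
#'   point.
#' @export
poly_residue_total <- function(trajectory) {
  fs <- attr(trajectory, "fragment_set")
  tot <- 0
  for (i in seq_along(POLY_FRAGMENTS)) {
    f <- POLY_FRAGMENTS[i]
    n_f <- trajectory[[paste0("out_", f)]] + trajectory[[paste0("g1_", f)]] +
      trajectory[[paste0("in_", f)]] + trajectory[[paste0("g2_", f)]]
    tot <- tot + fs$lengths[[f]] * n_f
  }
  tot
}

#' Cleavage-site usage along a polypeptide trajectory
#'
#' Per-site instantaneous cleavage flux (summed over every species
#' cleavable at that site), cumulative cleavage counts (trapezoidal
#' integral), the relative usage (each site's share of total cleavage) and
#' a per-site normalised usage (instantaneous flux relative to its value
#' at the first positive-flux time point) -- the model analogue of the
#' experimental site-specific cleavage strength.
#'
#' @param trajectory a `proteodyn_poly_trajectory`.
#' @return `proteodyn_usage`: data.frame `time`, `flux_site1`,
#'   `flux_site2`, `cum_site1`, `cum_site2`, `rel_site1`, `rel_site2`,
#'   `norm_site1`, `norm_site2`.
#' @export
cleavage_site_usage <- function(trajectory) {
  fs <- attr(trajectory, "fragment_set")
  n <- nrow(trajectory)
  f1 <- numeric(n); f2 <- numeric(n)
  for (i in seq_len(n)) {
    inner <- stats::setNames(as.numeric(
      trajectory[i, paste0("in_", POLY_FRAGMENTS)]), POLY_FRAGMENTS)
    fl <- poly_cleavage_flux(inner, fs)
    f1[i] <- fl$vS1 + fl$vAB1
    f2[i] <- fl$vS2 + fl$vBC2
  }
  tt <- trajectory$time
  cum <- function(f) c(0, cumsum(diff(tt) * (utils::head(f, -1) +
                                               utils::tail(f, -1)) / 2))
  c1 <- cum(f1); c2 <- cum(f2)
  tot <- c1 + c2
  rel1 <- ifelse(tot > 0, c1 / tot, NA_real_)
  ref_i <- which(f1 + f2 > 0)[1]
  out <- data.frame(time = tt, flux_site1 = f1, flux_site2 = f2,
                    cum_site1 = c1, cum_site2 = c2,
                    rel_site1 = rel1, rel_site2 = 1 - rel1,
                    norm_site1 = if (is.na(ref_i) || f1[ref_i] == 0)
                      NA_real_ else f1 / f1[ref_i],
                    norm_site2 = if (is.na(ref_i) || f2[ref_i] == 0)
                      NA_real_ else f2 / f2[ref_i])
  class(out) <- c("proteodyn_usage", "data.frame")
  out
}

#' Classify the temporal behaviour of cleavage-site usage
#'
#' Fits a least-squares slope to each site's normalised usage over time
#' and labels the pattern: `flat` (both total changes within the dead
#' band), `both_decrease`, `both_increase`, or `divergent` (opposite
#' signs). The normalised per-site measure is used (not the share of
#' total, which is constrained to sum to 1).
#'
#' @param usage a `proteodyn_usage` with at least 3 time points.
#' @param dead_band total relative change below which a trend counts as
#'   flat; default 0.05.
#' @param measure `"normalized"` (default) or `"share"`.
#' @return character label.
#' @export
classify_usage_behavior <- function(usage, dead_band = 0.05,
                                    measure = c("normalized", "share")) {
  measure <- match.arg(measure)
  cols <- if (measure == "normalized") c("norm_site1", "norm_site2") else
    c("rel_site1", "rel_site2")
  keep <- stats::complete.cases(usage[, cols]) & usage$time > 0
  u <- usage[keep, , drop = FALSE]
  if (nrow(u) < 3) stop("need usage at >= 3 time points")
  trend <- function(v) {
    fit <- stats::lm.fit(cbind(1, u$time), v)
    delta <- fit$coefficients[2] * (max(u$time) - min(u$time))
    scale <- max(abs(mean(v)), .Machine$double.eps)
    ifelse(abs(delta / scale) < dead_band, 0, sign(delta))
  }
  s1 <- trend(u[[cols[1]]]); s2 <- trend(u[[cols[2]]])
  if (s1 == 0 && s2 == 0) return("flat")
  if (s1 * s2 < 0) return("divergent")
  if (max(s1, s2) > 0) "both_increase" else "both_decrease"
}

#' Default prior over polypeptide transport parameters
#'
#' Log-uniform, two orders of magnitude around the fragment set's own
#' transport values, independently for every fragment and transport
#' parameter (names `kon_S`, ..., `tau_C`).
#'
#' @param fs a [fragment_set()].
#' @param orders width in orders of magnitude; default 2.
#' @return a [prior_set()].
#' @export
default_poly_prior <- function(fs, orders = 2) {
  half <- 10^(orders / 2)
  ps <- list()
  for (f in POLY_FRAGMENTS) for (pn in POLY_TRANSPORT_PARS) {
    v <- fs$transport[[f]][[pn]]
    ps[[paste(pn, f, sep = "_")]] <- prior("loguniform", v / half, v * half)
  }
  prior_set(ps)
}

#' Search transport-parameter space for cleavage-site-usage behaviours
#'
#' Samples transport parameters from the prior, simulates the polypeptide
#' digestion, classifies each run with [classify_usage_behavior()] and
#' returns one exemplar parameter draw per attained label plus the label
#' frequency table. Runs are reproducible from `seed`.
#'
#' @param fs a [fragment_set()] providing everything not sampled.
#' @param prior a [prior_set()] over species-suffixed transport parameters
#'   (default [default_poly_prior()]).
#' @param n_samples number of prior draws.
#' @param seed integer seed.
#' @param S0 substrate dose (uM); default 50.
#' @param times sampling grid (min); default `seq(10, 240, by = 10)`.
#' @param dead_band passed to the classifier.
#' @param product_reentry passed to [simulate_polypeptide()].
#' @return list with `frequencies` (named counts incl. failed runs as
#'   `error`), `exemplars` (named list label -> parameter draw), `labels`
#'   (per-draw labels).
#' @export
search_behaviors <- function(fs, prior = default_poly_prior(fs),
                             n_samples = 1000, seed = 1, S0 = 50,
                             times = seq(10, 240, by = 10),
                             dead_band = 0.05, product_reentry = TRUE) {
  set.seed(as.integer(seed))
  z <- sample_prior(prior, n_samples)
  labels <- character(n_samples)
  exemplars <- list()
  for (i in seq_len(n_samples)) {
    theta <- prior_untransform(prior, stats::setNames(z[i, ], colnames(z)))
    fsi <- fs
    for (nm in names(theta)) {
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      fsi$transport[[parts[2]]][[parts[1]]] <- theta[[nm]]
    }
    lab <- tryCatch({
      traj <- simulate_polypeptide(build_polypeptide_model(fsi), S0, times,
                                   product_reentry = product_reentry,
                                   solver_opts = list(rtol = 1e-6,
                                                      atol = 1e-9))
      classify_usage_behavior(cleavage_site_usage(traj),
                              dead_band = dead_band)
    }, error = function(e) "error")
    labels[i] <- lab
    if (lab != "error" && is.null(exemplars[[lab]]))
      exemplars[[lab]] <- theta
  }
  list(frequencies = table(labels), exemplars = exemplars, labels = labels)
}

#' Mean residue length of the digestion products
#'
#' Abundance-weighted mean residue length over all product species
#' (excluding the intact substrate), per time point; `NA` before any
#' product exists.
#'
#' @param trajectory a `proteodyn_poly_trajectory`.
#' @return numeric vector per time point.
#' @export
mean_fragment_length <- function(trajectory) {
  fs <- attr(trajectory, "fragment_set")
  prods <- setdiff(POLY_FRAGMENTS, "S")
  num <- 0; den <- 0
  for (f in prods) {
    n_f <- trajectory[[paste0("out_", f)]] + trajectory[[paste0("g1_", f)]] +
      trajectory[[paste0("in_", f)]] + trajectory[[paste0("g2_", f)]]
    num <- num + fs$lengths[[f]] * n_f
    den <- den + n_f
  }
  ifelse(den > 0, num / den, NA_real_)
}
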