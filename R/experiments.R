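#' Simulate a digestion time course
#'
#' Integrates a model from [initial_state()] over the requested time grid
#' with a stiff-capable adaptive integrator (deSolve's `lsoda`). By default
#' the derivatives are evaluated in compiled code; `engine = "R"` uses the
#' reference [ode_rhs()] instead (the two are interchangeable and tested
#' against each other).
#'
#' @param model a `proteodyn_model` from [build_model()].
#' @param params a [parameter_set()].
#' @param S0 initial substrate concentration (uM).
#' @param times sampling times (min), strictly increasing; 0 is prepended
#'   if absent.
#' @param solver_opts list of solver options: `rtol` (default 1e-8), `atol`
#'   (default 1e-10), `maxsteps` (default 50000).
#' @param engine `"compiled"` or `"R"`.
#' @param lead_factor,n_copies passed to the hydrolysis law, see
#'   [rate_hydrolysis()].
#' @param check_conservation if `TRUE` (default) error when any conserved
#'   total drifts by more than `1e-6` relative.
#' @param state0 optional full starting state (named over
#'   `model$species`), overriding [initial_state()]; used e.g. to continue
#'   a digestion or to probe conservation from arbitrary valid states.
#' @return a `proteodyn_trajectory`: data.frame with column `time` and one
#'   column per model species, with the model, parameters and hydrolysis
#'   options attached as attributes.
#' @export
simulate_time_course <- function(model, params, S0, times,
                                 solver_opts = list(),
                                 engine = c("compiled", "R"),
                                 lead_factor = "hill", n_copies = 2,
                                 check_conservation = TRUE, state0 = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "proteodyn_model"))
  validate_params(params)
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop("negative sampling times")
  drop_t0 <- FALSE
  if (length(times) == 0) stop("empty time grid")
  if (times[1] > 0) { times <- c(0, times); drop_t0 <- TRUE }
  rtol <- solver_opts$rtol %||% 1e-8
  atol <- solver_opts$atol %||% 1e-10
  maxsteps <- solver_opts$maxsteps %||% 50000

  y0 <- if (is.null(state0)) initial_state(model, S0, params) else {
    stopifnot(length(state0) == length(model$species))
    stats::setNames(as.numeric(state0), model$species)
  }
  if (length(times) == 1) {            # t = 0 only
    out <- matrix(y0, nrow = 1, dimnames = list(NULL, names(y0)))
    sol <- cbind(time = 0, out)
  } else if (engine == "compiled") {
    y0f <- expand_state(model, y0)
    raw <- deSolve::lsoda(y0f, times, func = "proteodyn_deriv_single",
                          parms = pack_params(model, params, lead_factor,
                                              n_copies),
                          dllname = "proteodyn",
                          initfunc = "proteodyn_init_single",
                          rtol = rtol, atol = atol, maxsteps = maxsteps)
    sol <- check_solution(raw, times, model$model_id)
    sol <- sol[, c("time", model$species), drop = FALSE]
  } else {
    rhs <- function(t, y, parms) {
      list(unname(ode_rhs(model, stats::setNames(y, model$species), params,
                          lead_factor, n_copies, neg_tol = Inf)))
    }
    raw <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = maxsteps)
    sol <- check_solution(raw, times, model$model_id)
  }
  traj <- as.data.frame(sol)
  if (drop_t0) traj <- traj[traj$time > 0, , drop = FALSE]
  rownames(traj) <- NULL
  attr(traj, "model") <- model
  attr(traj, "params") <- params
  attr(traj, "lead_factor") <- lead_factor
  attr(traj, "n_copies") <- n_copies
  class(traj) <- c("proteodyn_trajectory", "data.frame")
  if (check_conservation) assert_conserved(traj, tol = 1e-6)
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_solution <- function(raw, times, model_id) {
  diagn <- attr(raw, "istate")
  if (nrow(raw) < length(times) || any(!is.finite(raw)))
    stop("integration failure for model ", model_id,
         " (istate = ", if (!is.null(diagn)) diagn[1] else NA,
         "): returned ", nrow(raw), "/", length(times), " time points")
  raw
}

#' Worst relative drift of the conserved totals along a trajectory
#'
#' Evaluates [conserved_totals()] at every sampled time point and returns
#' the largest relative deviation from the initial totals -- the
#' package's conservation diagnostic (expected ~1e-8 at default solver
#' tolerances).
#'
#' @param traj a `proteodyn_trajectory`.
#' @return non-negative scalar.
#' @export
conservation_drift <- function(traj) {
  model <- attr(traj, "model")
  params <- attr(traj, "params")
  sp <- intersect(model$species, colnames(traj))
  tot0 <- conserved_totals(model, stats::setNames(as.numeric(traj[1, sp]), sp),
                           params)
  drift <- vapply(seq_len(nrow(traj)), function(i) {
    tot <- conserved_totals(model, stats::setNames(as.numeric(traj[i, sp]), sp),
                            params)
    max(abs(tot - tot0) / pmax(abs(tot0), 1e-12))
  }, numeric(1))
  max(drift)
}

assert_conserved <- function(traj, tol = 1e-6) {
  d <- conservation_drift(traj)
  if (is.na(d) || d > tol)
    stop("conservation breach: relative drift ", signif(d, 3),
         " exceeds tolerance ", tol)
  invisible(d)
}

#' Total product observable of a trajectory
#'
#' The fluorogenic readout detects the released fluorophore wherever the
#' cleaved peptide resides, so the default observable is the total product
#' moiety `Pout + G1Pout + P + G2P + EregP + h * IP` -- identically the
#' cumulative hydrolysis. `where = "outer"` restricts to free outer
#' product.
#'
#' @param trajectory a `proteodyn_trajectory`.
#' @param params parameter set (defaults to the one attached to the
#'   trajectory); needed for the inhibitor stoichiometry `h`.
#' @param where `"total"` (default) or `"outer"`.
#' @return numeric vector of product concentration (uM) per time point.
#' @export
observable_product <- function(trajectory, params = NULL,
                               where = c("total", "outer")) {
  where <- match.arg(where)
  params <- params %||% attr(trajectory, "params")
  if (where == "outer") return(trajectory$Pout)
  g <- function(n) if (n %in% colnames(trajectory)) trajectory[[n]] else 0
  g("Pout") + g("G1Pout") + g("P") + g("G2P") + g("EregP") +
    params[["h"]] * g("IP")
}

#' Reaction velocity from a product time series
#'
#' The initial velocity is the least-squares slope of product concentration
#' over the measurement window (default the 15/30/45/60 min samples); the
#' running velocity is the centred finite difference of the series.
#'
#' @param time sampling times (min).
#' @param product product concentrations (same length).
#' @param window times to use for the initial-velocity regression; default
#'   `c(15, 30, 45, 60)`. Only times present in `time` are used.
#' @return list with `initial` (slope, conc/min) and `running` (data.frame
#'   `time`, `velocity` from centred differences).
#' @export
reaction_velocity <- function(time, product, window = c(15, 30, 45, 60)) {
  if (length(time) != length(product)) stop("length mismatch")
  sel <- time %in% window
  if (sum(sel) < 2)
    stop("need at least 2 points inside the regression window")
  fit <- stats::lm.fit(cbind(1, time[sel]), product[sel])
  n <- length(time)
  if (n >= 3) {
    mid <- 2:(n - 1)
    vel <- (product[mid + 1] - product[mid - 1]) / (time[mid + 1] - time[mid - 1])
    running <- data.frame(time = time[mid], velocity = vel)
  } else running <- data.frame(time = numeric(0), velocity = numeric(0))
  list(initial = unname(fit$coefficients[2]), running = running)
}

#' Dose-response: product at a fixed end time across initial doses
#'
#' One simulation per initial substrate concentration; returns total
#' product at `t_end`. With the external inhibitory site active the curve
#' develops an interior maximum (substrate inhibition); in the
#' Michaelis-Menten limit it is monotone non-decreasing.
#'
#' @param model,params model definition and parameters.
#' @param S0_list initial concentrations (uM), non-empty.
#' @param t_end end time (min).
#' @param ... passed to [simulate_time_course()].
#' @return data.frame with columns `S0` and `product`.
#' @export
dose_response <- function(model, params, S0_list, t_end, ...) {
  if (!length(S0_list)) stop("empty S0 list")
  product <- vapply(S0_list, function(s0) {
    if (t_end == 0) return(0)
    traj <- simulate_time_course(model, params, s0, c(0, t_end), ...)
    utils::tail(observable_product(traj), 1)
  }, numeric(1))
  data.frame(S0 = as.numeric(S0_list), product = product)
}

#' Simulate an open-gate (deltaN-alpha3-like) mutant
#'
#' The constitutively open gate is emulated by scaling both transport
#' rates `vin` and `vout` by a common factor (default 10).
#'
#' @param model,params,S0,times as in [simulate_time_course()].
#' @param factor fold-increase of `vin` and `vout`; default 10.
#' @param ... passed to [simulate_time_course()].
#' @return a `proteodyn_trajectory`.
#' @export
simulate_open_gate_mutant <- function(model, params, S0, times, factor = 10,
                                      ...) {
  if (!model$compartmentalised)
    stop("open-gate mutant is defined only for compartmental models (M5-M9)")
  if (factor <= 0) stop("factor must be > 0")
  params[["vin"]] <- params[["vin"]] * factor
  params[["vout"]] <- params[["vout"]] * factor
  simulate_time_course(model, params, S0, times, ...)
}

#' Fold stimulation of hydrolysis by gate-opening Rpt peptides
#'
#' Rpt peptides are modelled as a constant multiplication of the influx
#' rate `vin`. The fold stimulation at each sampled time is the ratio of
#' total product with and without the perturbation; times where the
#' baseline product is zero are reported as `NA` (undefined), not
#' infinity.
#'
#' @param model,params,S0,times as in [simulate_time_course()].
#' @param rpt_factor multiplication of `vin`, > 0; default 5.
#' @param ... passed to [simulate_time_course()].
#' @return data.frame `time`, `product_with`, `product_without`,
#'   `fold_stimulation`.
#' @export
simulate_with_rpt <- function(model, params, S0, times, rpt_factor = 5, ...) {
  if (rpt_factor <= 0) stop("rpt_factor must be > 0")
  base <- simulate_time_course(model, params, S0, times, ...)
  pstim <- params
  pstim[["vin"]] <- pstim[["vin"]] * rpt_factor
  stim <- simulate_time_course(model, pstim, S0, times, ...)
  p0 <- observable_product(base)
  p1 <- observable_product(stim)
  fold <- ifelse(p0 > 0, p1 / p0, NA_real_)
  data.frame(time = base$time, product_with = p1, product_without = p0,
             fold_stimulation = fold)
}
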