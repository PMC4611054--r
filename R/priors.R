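#' Prior distributions for ABC-SMC
#'
#' A `PriorSet` is a named list, one entry per free parameter, each entry a
#' list with `dist` (`"loguniform"` or `"uniform"`) and bounds `min`,
#' `max`. Log-uniform parameters are handled on the log10 scale
#' throughout the sampler (sampling, perturbation and kernel densities).
#'
#' @param ... named entries, each created by [prior()].
#' @return a `proteodyn_priors` list.
#' @export
#' @examples
#' prior_set(vin = prior("loguniform", 0.1, 1000),
#'           C = prior("uniform", 10, 1000))
prior_set <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && is.list(ps[[1]]) && is.null(ps[[1]]$dist))
    ps <- ps[[1]]
  if (is.null(names(ps)) || any(!nzchar(names(ps))))
    stop("every prior must be named after its parameter")
  for (nm in names(ps)) {
    p <- ps[[nm]]
    if (!is.list(p) || is.null(p$dist)) stop("malformed prior for ", nm)
    if (!is.finite(p$min) || !is.finite(p$max) || p$min >= p$max)
      stop("prior bounds for ", nm, " must be finite with min < max")
    if (p$dist == "loguniform" && p$min <= 0)
      stop("log-uniform prior for ", nm, " needs positive bounds")
  }
  structure(ps, class = "proteodyn_priors")
}

#' @rdname prior_set
#' @param dist `"loguniform"` or `"uniform"`.
#' @param min,max bounds (natural scale).
#' @export
prior <- function(dist = c("loguniform", "uniform"), min, max) {
  list(dist = match.arg(dist), min = min, max = max)
}

# transform to/from the internal (sampling) scale
prior_transform <- function(priors, theta) {
  vapply(names(priors), function(nm) {
    if (priors[[nm]]$dist == "loguniform") log10(theta[[nm]]) else theta[[nm]]
  }, numeric(1))
}

prior_untransform <- function(priors, z) {
  vapply(names(priors), function(nm) {
    if (priors[[nm]]$dist == "loguniform") 10^z[[nm]] else z[[nm]]
  }, numeric(1))
}

# bounds on the internal scale
prior_bounds <- function(priors) {
  lo <- vapply(priors, function(p)
    if (p$dist == "loguniform") log10(p$min) else p$min, numeric(1))
  hi <- vapply(priors, function(p)
    if (p$dist == "loguniform") log10(p$max) else p$max, numeric(1))
  cbind(lo = lo, hi = hi)
}

# n draws on the internal scale (matrix n x n_par)
sample_prior <- function(priors, n) {
  b <- prior_bounds(priors)
  m <- vapply(seq_along(priors), function(j)
    stats::runif(n, b[j, 1], b[j, 2]), numeric(n))
  matrix(m, nrow = n, dimnames = list(NULL, names(priors)))
}

# density on the internal scale (uniform in every case)
prior_density <- function(priors, z) {
  b <- prior_bounds(priors)
  inside <- all(z >= b[, 1] & z <= b[, 2])
  if (!inside) return(0)
  prod(1 / (b[, 2] - b[, 1]))
}

#' Default priors for a model's free parameters
#'
#' Log-uniform over `orders` orders of magnitude centred (in log space) on
#' the supplied base values for the rate and affinity parameters of the
#' model, with the chamber capacity `C` uniform on `[10, 1000]` molecules.
#' `beta` is clipped at its upper invariant bound of 1. Hill coefficients,
#' the inhibitor stoichiometry `h`, the modifier interaction `alpha` and
#' the known enzyme/site concentrations stay fixed at their base values
#' and are not inferred.
#'
#' @param model a `proteodyn_model`.
#' @param base_params [parameter_set()] around which priors are centred.
#' @param orders total width in orders of magnitude; default 4.
#' @param free optional character vector restricting which parameters get
#'   priors.
#' @return a `proteodyn_priors`.
#' @export
default_priors <- function(model, base_params, orders = 4, free = NULL) {
  # one rate per binding equilibrium: the product observable constrains
  # site occupancies and transport fluxes, not the individual on/off rates,
  # so koff and the regulatory-site kinetics stay fixed while the site
  # strengths (Xenh, Yinh) are inferred
  cand <- switch(model$model_id,
    M1 = c("vmax", "KM"),
    M2 = c("kp", "KaS", "KaP", "KiS", "KiP", "beta"),
    M3 = ,
    M4 = c("kp", "KaS", "KaP", "KiS", "KiP", "beta", "eps_fb", "K_fb"),
    M5 = c("kon", "vin", "vout", "tau", "C", "kp", "KaS", "beta"),
    M6 = ,
    M7 = c("kon", "vin", "vout", "tau", "C", "Xenh", "kp", "KaS", "beta"),
    M8 = ,
    M9 = c("kon", "vin", "vout", "tau", "C", "Xenh", "Yinh",
           "kp", "KaS", "beta"))
  if (!is.null(free)) cand <- intersect(cand, free)
  half <- 10^(orders / 2)
  ps <- lapply(cand, function(nm) {
    if (nm == "C") return(prior("uniform", 10, 1000))
    if (nm == "eps_fb") return(prior("loguniform", 1e-2, 1e2))
    v <- base_params[[nm]]
    if (v <= 0) v <- 1e-6
    up <- if (nm == "beta") min(1, v * half) else v * half
    prior("loguniform", v / half, up)
  })
  names(ps) <- cand
  prior_set(ps)
}
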