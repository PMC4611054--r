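#' Two-site-modifier hydrolysis rate
#'
#' Rate law for peptide-bond hydrolysis at the proteasome active sites with
#' both a catalytic and a modifier (inhibitory) binding site, each
#' accessible to substrate and product with Hill cooperativity. The
#' partition denominator is
#' \deqn{x = 1 + S^{na}/KaS + S^{ni}/KiS + P^{na}/KaP + P^{ni}/KiP +
#'   S^{na+ni}/(\alpha KaS KiS) + P^{na+ni}/(\alpha KaP KiP) +
#'   S^{na} P^{ni}/(\alpha KaS KiP) + S^{ni} P^{na}/(\alpha KiS KaP)}
#' and the flux
#' \deqn{v_{hydr} = n_a k_p E_0 \frac{S^{na}}{KaS}
#'   \left(1 + \beta S^{ni}/(\alpha KiS) + \beta P^{ni}/(\alpha KiP)\right)/x.}
#' With the modifier site empty (`KiS, KiP, KaP` effectively infinite) and
#' `na = 1` this reduces to Michaelis-Menten kinetics with
#' `vmax = kp * E0`, `KM = KaS`.
#'
#' @param S,P substrate and product concentrations at the active site (uM).
#' @param params a [parameter_set()].
#' @param lead_factor leading multiplicity in the flux: `"hill"` uses the
#'   Hill coefficient `na` (the law as printed), `"copies"` uses the number
#'   of active-site copies `n_copies`.
#' @param n_copies active-site copies per proteasome, used when
#'   `lead_factor = "copies"`; default 2.
#' @return list with `vhydr` (uM/min) and the partition denominator `x`.
#' @export
rate_hydrolysis <- function(S, P, params, lead_factor = c("hill", "copies"),
                            n_copies = 2) {
  lead_factor <- match.arg(lead_factor)
  if (!all(is.finite(c(S, P)))) stop("non-finite substrate/product input")
  if (any(S < 0) || any(P < 0)) stop("concentrations must be >= 0")
  KaS <- params[["KaS"]]; KaP <- params[["KaP"]]
  KiS <- params[["KiS"]]; KiP <- params[["KiP"]]
  if (any(c(KaS, KaP, KiS, KiP) == 0))
    stop("affinity constants must be non-zero")
  na <- params[["na"]]; ni <- params[["ni"]]
  a <- params[["alpha"]]; b <- params[["beta"]]
  x <- 1 + S^na / KaS + S^ni / KiS + P^na / KaP + P^ni / KiP +
    S^(na + ni) / (a * KaS * KiS) + P^(na + ni) / (a * KaP * KiP) +
    S^na * P^ni / (a * KaS * KiP) + S^ni * P^na / (a * KiS * KaP)
  lead <- if (lead_factor == "hill") na else n_copies
  vhydr <- lead * params[["kp"]] * params[["E0"]] * (S^na / KaS) *
    (1 + b * S^ni / (a * KiS) + b * P^ni / (a * KiP)) / x
  list(vhydr = vhydr, x = x)
}

#' Regulated capacity-limited transport rate
#'
#' Effective first-order transport rates through the proteasome gate.
#' Occupied enhancer sites multiply both rates by
#' `1 + Xenh * (EregS + EregP) / E0`; occupied inhibitory sites divide both
#' by `1 + Yinh * (IS + IP) / I0`. Influx additionally carries the
#' capacity term `tanh(max(0, E0 * C - S - P))`, the heuristic saturation
#' that shuts the gate as the chamber load `S + P` approaches the capacity
#' `E0 * C`; efflux carries no capacity term. The `tanh` argument is
#' treated as dimensionless with an implicit scale of 1 uM and clamped at
#' zero so an over-full chamber cannot drive reverse flux. For a model
#' without an enhancer (inhibitor) the corresponding factor is identically
#' one because the bound-site species are identically zero.
#'
#' @param state named state vector (needs `S`, `P` and, if present,
#'   `EregS`, `EregP`, `IS`, `IP`).
#' @param params a [parameter_set()].
#' @param direction `"in"` or `"out"`.
#' @return transport rate (per-min).
#' @export
rate_transport <- function(state, params, direction = c("in", "out")) {
  direction <- match.arg(direction)
  g <- function(n) if (n %in% names(state)) state[[n]] else 0
  ereg_occ <- g("EregS") + g("EregP")
  inh_occ <- g("IS") + g("IP")
  if (ereg_occ > 0 && params[["E0"]] == 0)
    stop("E0 = 0 with an active enhancer site")
  if (inh_occ > 0 && params[["I0"]] == 0)
    stop("I0 = 0 with an active inhibitory site")
  enh <- if (ereg_occ > 0) 1 + params[["Xenh"]] * ereg_occ / params[["E0"]] else 1
  inh <- if (inh_occ > 0) 1 + params[["Yinh"]] * inh_occ / params[["I0"]] else 1
  if (direction == "in") {
    cap <- tanh(max(0, params[["E0"]] * params[["C"]] - g("S") - g("P")))
    params[["vin"]] * enh / inh * cap
  } else {
    params[["vout"]] * enh / inh
  }
}
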