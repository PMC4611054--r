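#' Kinetic parameters of the proteasome model family
#'
#' A `ParameterSet` is a named numeric vector holding every kinetic constant
#' any member of the model family can consume. Units follow the package's
#' canonical convention: concentrations in uM, time in minutes.
#'
#' Fields:
#' \describe{
#'   \item{kon, koff}{substrate/product association to and dissociation from
#'     the outer gate site G1 (per-uM per-min, per-min).}
#'   \item{vin, vout}{influx through the gate into the chamber and efflux
#'     from the inner gate site (per-min).}
#'   \item{tau}{translocation of inner peptide onto the inner gate site G2
#'     (per-min, scaled by 1/E0 in the rate law).}
#'   \item{C}{chamber capacity: maximal number of peptide molecules per
#'     proteasome (dimensionless count, >= 1).}
#'   \item{Ron, Roff, Xenh}{binding/unbinding at the transport-enhancing
#'     regulatory site and the enhancement factor.}
#'   \item{Ion, Ioff, h, Yinh}{binding/unbinding at the transport-inhibiting
#'     regulatory site, its peptide stoichiometry (Hill exponent) and the
#'     inhibition factor.}
#'   \item{kp}{peptide-bond hydrolysis rate constant (per-min).}
#'   \item{KaS, KaP, KiS, KiP}{active-site and inhibitory-site affinity
#'     constants for substrate and product (uM^na / uM^ni).}
#'   \item{na, ni}{Hill coefficients for active/inhibitory binding (>= 1).}
#'   \item{alpha, beta}{two-site-modifier interaction factor (> 0) and
#'     catalysis-modulation factor (0 < beta <= 1).}
#'   \item{vmax, KM}{Michaelis-Menten parameters (model M1 only).}
#'   \item{eps_fb, K_fb}{strength and half-saturation of the product
#'     feedback on binding (M3) or hydrolysis (M4).}
#'   \item{E0}{proteasome concentration (uM).}
#'   \item{I0}{total external (or internal, model M8) inhibitory sites (uM).}
#'   \item{G1_tot, G2_tot, Ereg_tot}{total outer gate, inner gate and
#'     enhancer sites (uM); default one effective site per proteasome.}
#' }
#'
#' @param ... named numeric overrides of the defaults returned by
#'   [param_template()].
#' @return a named numeric vector of class `proteodyn_params`.
#' @export
#' @examples
#' p <- parameter_set(kp = 50, C = 200)
#' p[["C"]]
parameter_set <- function(...) {
  p <- param_template()
  over <- c(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- as.numeric(over)
  }
  # site totals default to E0 (one effective site of each class per
  # proteasome) unless explicitly set
  defaulted <- setdiff(c("G1_tot", "G2_tot", "Ereg_tot", "I0"), names(over))
  p[defaulted] <- p[["E0"]]
  class(p) <- "proteodyn_params"
  validate_params(p)
  p
}

#' @rdname parameter_set
#' @export
param_template <- function() {
  c(kon = 0.01, koff = 1, vin = 10, vout = 10, tau = 10, C = 200,
    Ron = 1, Roff = 10, Xenh = 0, Ion = 1e-6, Ioff = 0.1, h = 2, Yinh = 0,
    kp = 50, KaS = 1, KaP = 1, KiS = 1e12, KiP = 1e12,
    na = 1, ni = 1, alpha = 1, beta = 1,
    vmax = 0.1, KM = 100, eps_fb = 0, K_fb = 10,
    E0 = 0.0018, I0 = 0.0018, G1_tot = 0.0018, G2_tot = 0.0018,
    Ereg_tot = 0.0018)
}

#' Validate a ParameterSet
#'
#' Checks the invariants all models share: non-negativity, `C >= 1`,
#' `na, ni, h >= 1`, `alpha > 0` and `0 < beta <= 1` (a modifier-bound
#' enzyme is at most as active as the free one).
#'
#' @param p named numeric vector as from [parameter_set()].
#' @return `p`, invisibly, or an error describing the violated invariant.
#' @export
validate_params <- function(p) {
  need <- names(param_template())
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(p[setdiff(need, c("KiS", "KiP", "KaP"))])))
    stop("parameters must be finite (affinity constants may be large but finite)")
  if (any(p < 0)) stop("all parameters must be >= 0")
  if (p[["C"]] < 1) stop("capacity C must be >= 1 molecule")
  if (any(p[c("na", "ni", "h")] < 1)) stop("na, ni and h must be >= 1")
  if (p[["alpha"]] <= 0) stop("alpha must be > 0")
  if (p[["beta"]] <= 0 || p[["beta"]] > 1) stop("beta must be in (0, 1]")
  invisible(p)
}

#' Proteasome concentration from enzyme mass
#'
#' Converts an enzyme amount in ug and a reaction volume in ul into a molar
#' concentration, the package's canonical way of setting `E0` from an assay
#' description such as "0.125 ug 20S proteasome in 100 ul".
#'
#' @param amount_ug enzyme amount (ug).
#' @param volume_ul reaction volume (ul); default 100.
#' @param molar_mass_kda molar mass (kDa); default 700 for the 20S particle.
#' @return concentration in uM.
#' @export
#' @examples
#' enzyme_concentration_uM(0.125) # ~0.0018 uM
enzyme_concentration_uM <- function(amount_ug, volume_ul = 100,
                                    molar_mass_kda = 700) {
  if (amount_ug < 0 || volume_ul <= 0 || molar_mass_kda <= 0)
    stop("amounts, volumes and molar masses must be positive")
  # ug / (kDa * 1000 g/mol) = umol; / (ul * 1e-6 L) = M -> * 1e6 = uM
  (amount_ug / (molar_mass_kda * 1000)) / volume_ul * 1e6
}
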