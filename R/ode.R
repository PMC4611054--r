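#' Time derivative of a model state
#'
#' Reference implementation of the ordinary differential equations of every
#' model in the family. Signs are fixed by the conservation laws: each
#' binding-site total (G1, G2, enhancer, inhibitor) and the peptide-moiety
#' total have exactly zero time derivative, hydrolysis converts inner
#' substrate to inner product one-to-one, inhibitor binding consumes `h`
#' peptide molecules per site, and all inner binding/unbinding steps carry
#' the `1/E0` normalisation (e.g. `tau * S * G2 / E0`,
#' `Ron * S * Ereg / E0`).
#'
#' Slightly negative entries (integrator probing) are clamped to zero for
#' rate evaluation; entries below `-neg_tol` raise an error.
#'
#' This R implementation is the package's documented reference; simulation
#' runs through an equivalent compiled version (see
#' [simulate_time_course()]), and the two are held equal by the test suite.
#'
#' @param model a `proteodyn_model`.
#' @param state named state vector over `model$species`.
#' @param params a [parameter_set()].
#' @param lead_factor,n_copies passed to [rate_hydrolysis()].
#' @param neg_tol tolerance below zero before a state is rejected.
#' @return named derivative vector over `model$species`.
#' @export
ode_rhs <- function(model, state, params, lead_factor = "hill", n_copies = 2,
                    neg_tol = 1e-6) {
  if (!inherits(model, "proteodyn_model")) stop("not a model definition")
  if (length(state) != length(model$species))
    stop("state has ", length(state), " entries; model ", model$model_id,
         " has ", length(model$species), " species")
  if (any(state < -neg_tol))
    stop("negative state entries beyond tolerance: ",
         paste(model$species[state < -neg_tol], collapse = ", "))
  y <- stats::setNames(pmax(as.numeric(state), 0), model$species)
  d <- stats::setNames(numeric(length(y)), model$species)
  E0 <- params[["E0"]]

  if (!model$compartmentalised) {
    Sout <- y[["Sout"]]; Pout <- y[["Pout"]]
    if (model$model_id == "M1") {
      v <- params[["vmax"]] * Sout / (params[["KM"]] + Sout)
    } else {
      p2 <- params
      fb <- 1 + params[["eps_fb"]] * Pout / (params[["K_fb"]] + Pout)
      if (model$feedback == "binding") p2[["KaS"]] <- params[["KaS"]] / fb
      kp_eff <- if (model$feedback == "hydrolysis") params[["kp"]] * fb else
        params[["kp"]]
      p2[["kp"]] <- kp_eff
      v <- rate_hydrolysis(Sout, Pout, p2, lead_factor, n_copies)$vhydr
    }
    d["Sout"] <- -v
    d["Pout"] <- v
    return(d)
  }

  g <- function(n) if (n %in% names(y)) y[[n]] else 0
  Sout <- g("Sout"); Pout <- g("Pout")
  S <- g("S"); P <- g("P")

  tin <- rate_transport(y, params, "in")
  tout <- rate_transport(y, params, "out")
  vh <- rate_hydrolysis(S, P, params, lead_factor, n_copies)$vhydr

  if (model$diffusion_transport) {
    cap <- tanh(max(0, E0 * params[["C"]] - S - P))
    inS <- params[["vin"]] * cap * Sout; inP <- params[["vin"]] * cap * Pout
    outS <- params[["vout"]] * S;        outP <- params[["vout"]] * P
    d["Sout"] <- -inS + outS
    d["Pout"] <- -inP + outP
    d["S"] <- inS - outS - vh
    d["P"] <- inP - outP + vh
    return(d)
  }

  kon <- params[["kon"]]; koff <- params[["koff"]]; tau <- params[["tau"]]
  # outer gate binding and influx
  bS <- kon * Sout * g("G1"); bP <- kon * Pout * g("G1")
  uS <- koff * g("G1Sout");   uP <- koff * g("G1Pout")
  inS <- tin * g("G1Sout");   inP <- tin * g("G1Pout")
  # inner translocation onto G2 and efflux
  trS <- tau * S * g("G2") / E0; trP <- tau * P * g("G2") / E0
  outS <- tout * g("G2S");       outP <- tout * g("G2P")

  d["Sout"] <- -bS + uS + outS
  d["Pout"] <- -bP + uP + outP
  d["G1"] <- -(bS + bP) + (uS + uP) + (inS + inP)
  d["G1Sout"] <- bS - uS - inS
  d["G1Pout"] <- bP - uP - inP
  d["S"] <- inS - trS - vh
  d["P"] <- inP - trP + vh
  d["G2"] <- -(trS + trP) + (outS + outP)
  d["G2S"] <- trS - outS
  d["G2P"] <- trP - outP

  if (model$enhancer_location != "none") {
    Ron <- params[["Ron"]]; Roff <- params[["Roff"]]
    if (model$enhancer_location == "inside") { eS <- S; eP <- P } else {
      eS <- Sout; eP <- Pout
    }
    ebS <- Ron * eS * g("Ereg") / E0; ebP <- Ron * eP * g("Ereg") / E0
    euS <- Roff * g("EregS");         euP <- Roff * g("EregP")
    d["Ereg"] <- -(ebS + ebP) + (euS + euP)
    d["EregS"] <- ebS - euS
    d["EregP"] <- ebP - euP
    tgt <- if (model$enhancer_location == "inside") c("S", "P") else
      c("Sout", "Pout")
    d[tgt[1]] <- d[tgt[1]] - ebS + euS
    d[tgt[2]] <- d[tgt[2]] - ebP + euP
  }

  if (model$inhibitor_location != "none") {
    Ion <- params[["Ion"]]; Ioff <- params[["Ioff"]]; h <- params[["h"]]
    if (model$inhibitor_location == "outside") { iS <- Sout; iP <- Pout } else {
      iS <- S; iP <- P
    }
    ibS <- Ion * iS^h * g("Ifree"); ibP <- Ion * iP^h * g("Ifree")
    iuS <- Ioff * g("IS");          iuP <- Ioff * g("IP")
    d["Ifree"] <- -(ibS + ibP) + (iuS + iuP)
    d["IS"] <- ibS - iuS
    d["IP"] <- ibP - iuP
    tgt <- if (model$inhibitor_location == "outside") c("Sout", "Pout") else
      c("S", "P")
    d[tgt[1]] <- d[tgt[1]] - h * ibS + h * iuS
    d[tgt[2]] <- d[tgt[2]] - h * ibP + h * iuP
  }

  d
}

# Pack a model + parameter set into the flat numeric vector consumed by the
# compiled derivative functions (layout mirrored in src/proteodyn_rhs.c).
pack_params <- function(model, params, lead_factor = "hill", n_copies = 2) {
  cls <- switch(model$model_id, M1 = 1, M2 = 2, M3 = 3, M4 = 4, 5)
  enh <- match(model$enhancer_location, c("none", "outside", "inside")) - 1
  inh <- match(model$inhibitor_location, c("none", "inside", "outside")) - 1
  lead <- if (identical(lead_factor, "hill")) params[["na"]] else n_copies
  c(cls, enh, inh, as.numeric(model$diffusion_transport), lead,
    params[c("kon", "koff", "vin", "vout", "tau", "C", "Ron", "Roff", "Xenh",
             "Ion", "Ioff", "h", "Yinh", "kp", "KaS", "KaP", "KiS", "KiP",
             "na", "ni", "alpha", "beta", "vmax", "KM", "eps_fb", "K_fb",
             "E0", "I0", "G1_tot", "G2_tot", "Ereg_tot")])
}

# Expand a model-specific state to the full 16-species layout used by the
# compiled code.
expand_state <- function(model, state) {
  y <- stats::setNames(numeric(length(SPECIES_ALL)), SPECIES_ALL)
  y[model$species] <- as.numeric(state)
  y
}
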