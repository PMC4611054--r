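# The nine-model family. M1-M4 are non-compartmental rate laws acting on
# outer substrate/product only; M5-M9 share the gated-transport skeleton
# (outer gate site G1, capacity-limited influx, inner gate site G2, efflux)
# and differ only in the placement of the regulatory sites.

#' Model identifiers of the family
#'
#' `MODEL_IDS` lists the nine model ids (`"M1"`..`"M9"`); `SPECIES_ALL`
#' is the full compartmental state layout (16 species, the M9 state).
#'
#' @export
MODEL_IDS <- paste0("M", 1:9)

#' @rdname MODEL_IDS
#' @export

SPECIES_ALL <- c("Sout", "Pout", "G1", "G1Sout", "G1Pout",
                 "S", "P", "G2", "G2S", "G2P",
                 "Ereg", "EregS", "EregP", "Ifree", "IS", "IP")

.model_table <- list(
  M1 = list(compartmentalised = FALSE, enhancer_location = "none",
            inhibitor_location = "none", feedback = "none",
            species = c("Sout", "Pout"),
            parameters = c("vmax", "KM", "E0")),
  M2 = list(compartmentalised = FALSE, enhancer_location = "none",
            inhibitor_location = "none", feedback = "none",
            species = c("Sout", "Pout"),
            parameters = c("kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "E0")),
  M3 = list(compartmentalised = FALSE, enhancer_location = "none",
            inhibitor_location = "none", feedback = "binding",
            species = c("Sout", "Pout"),
            parameters = c("kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "eps_fb", "K_fb", "E0")),
  M4 = list(compartmentalised = FALSE, enhancer_location = "none",
            inhibitor_location = "none", feedback = "hydrolysis",
            species = c("Sout", "Pout"),
            parameters = c("kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "eps_fb", "K_fb", "E0")),
  M5 = list(compartmentalised = TRUE, enhancer_location = "none",
            inhibitor_location = "none", feedback = "none",
            species = SPECIES_ALL[1:10],
            parameters = c("kon", "koff", "vin", "vout", "tau", "C",
                           "kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "E0", "G1_tot", "G2_tot")),
  M6 = list(compartmentalised = TRUE, enhancer_location = "outside",
            inhibitor_location = "none", feedback = "none",
            species = SPECIES_ALL[1:13],
            parameters = c("kon", "koff", "vin", "vout", "tau", "C",
                           "Ron", "Roff", "Xenh",
                           "kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "E0", "G1_tot", "G2_tot",
                           "Ereg_tot")),
  M7 = list(compartmentalised = TRUE, enhancer_location = "inside",
            inhibitor_location = "none", feedback = "none",
            species = SPECIES_ALL[1:13],
            parameters = c("kon", "koff", "vin", "vout", "tau", "C",
                           "Ron", "Roff", "Xenh",
                           "kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "E0", "G1_tot", "G2_tot",
                           "Ereg_tot")),
  M8 = list(compartmentalised = TRUE, enhancer_location = "inside",
            inhibitor_location = "inside", feedback = "none",
            species = SPECIES_ALL,
            parameters = c("kon", "koff", "vin", "vout", "tau", "C",
                           "Ron", "Roff", "Xenh", "Ion", "Ioff", "h", "Yinh",
                           "kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "E0", "I0", "G1_tot", "G2_tot",
                           "Ereg_tot")),
  M9 = list(compartmentalised = TRUE, enhancer_location = "inside",
            inhibitor_location = "outside", feedback = "none",
            species = SPECIES_ALL,
            parameters = c("kon", "koff", "vin", "vout", "tau", "C",
                           "Ron", "Roff", "Xenh", "Ion", "Ioff", "h", "Yinh",
                           "kp", "KaS", "KaP", "KiS", "KiP", "na", "ni",
                           "alpha", "beta", "E0", "I0", "G1_tot", "G2_tot",
                           "Ereg_tot"))
)

#' Build a model definition
#'
#' Returns the self-consistent definition of one member of the nine-model
#' family: M1 Michaelis-Menten; M2 two-site-modifier rate law with substrate
#' and product inhibition (intermediate complexes in quasi-steady state);
#' M3/M4 two-site-modifier law with saturating positive product feedback on
#' active-site binding / on the hydrolysis rate; M5 compartmentalised gated
#' transport without regulation; M6/M7 with a transport-enhancing site on
#' the outer surface / inside the chamber; M8 enhancer inside plus a
#' transport-inhibiting site inside; M9 (the selected model) enhancer inside
#' the chamber plus inhibiting site on the outer surface.
#'
#' @param model_id one of `"M1"` ... `"M9"`.
#' @param diffusion_transport if `TRUE` (only meaningful for compartmental
#'   models) gate binding is replaced by symmetric first-order exchange
#'   between outside and chamber, the free-diffusion transport variant.
#' @return a list of class `proteodyn_model` with fields `model_id`,
#'   `compartmentalised`, `enhancer_location`, `inhibitor_location`,
#'   `feedback`, `species`, `parameters`, `diffusion_transport`.
#' @export
#' @examples
#' build_model("M1")$species
#' build_model("M9")$enhancer_location
build_model <- function(model_id, diffusion_transport = FALSE) {
  if (length(model_id) != 1 || !model_id %in% MODEL_IDS)
    stop("unknown model id '", paste(model_id, collapse = ","),
         "'; valid ids are ", paste(MODEL_IDS, collapse = ", "))
  def <- .model_table[[model_id]]
  def$model_id <- model_id
  def$diffusion_transport <- isTRUE(diffusion_transport) && def$compartmentalised
  class(def) <- "proteodyn_model"
  def
}

#' @export
print.proteodyn_model <- function(x, ...) {
  cat("proteasome kinetic model ", x$model_id,
      if (x$compartmentalised) " (compartmentalised)" else " (non-compartmental)",
      "\n  enhancer: ", x$enhancer_location,
      "; inhibitor: ", x$inhibitor_location,
      "; feedback: ", x$feedback, "\n  species (", length(x$species), "): ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Initial state for a simulated digestion
#'
#' All free sites start unoccupied at their totals, the full substrate dose
#' sits outside the proteasome, and every other species is zero.
#'
#' @param model a `proteodyn_model` from [build_model()].
#' @param S0 initial substrate concentration (uM), `>= 0`.
#' @param params a [parameter_set()].
#' @return named numeric state vector over `model$species`.
#' @export
initial_state <- function(model, S0, params) {
  if (!inherits(model, "proteodyn_model")) stop("not a model definition")
  if (!is.finite(S0) || S0 < 0) stop("S0 must be a non-negative concentration")
  y <- stats::setNames(numeric(length(model$species)), model$species)
  y["Sout"] <- S0
  if ("G1" %in% model$species) y["G1"] <- params[["G1_tot"]]
  if ("G2" %in% model$species) y["G2"] <- params[["G2_tot"]]
  if ("Ereg" %in% model$species) y["Ereg"] <- params[["Ereg_tot"]]
  if ("Ifree" %in% model$species) y["Ifree"] <- params[["I0"]]
  y
}

#' Conserved totals of a model state
#'
#' Returns the site totals and the peptide-moiety total that any valid
#' trajectory of the model must keep constant: each binding-site class is
#' conserved, and every peptide molecule is accounted for whether free,
#' gate-bound, regulator-bound (h molecules per occupied inhibitory site)
#' or hydrolysed.
#'
#' @param model a `proteodyn_model`.
#' @param state named state vector over `model$species`.
#' @param params a [parameter_set()].
#' @return named numeric vector of the applicable totals (always includes
#'   `peptide`; sites only for the species the model carries).
#' @export
conserved_totals <- function(model, state, params) {
  sp <- model$species
  g <- function(n) if (n %in% sp) state[[n]] else 0
  tot <- c(peptide = g("Sout") + g("Pout") + g("G1Sout") + g("G1Pout") +
             g("S") + g("P") + g("G2S") + g("G2P") + g("EregS") + g("EregP") +
             params[["h"]] * (g("IS") + g("IP")))
  if ("G1" %in% sp) tot["G1_sites"] <- g("G1") + g("G1Sout") + g("G1Pout")
  if ("G2" %in% sp) tot["G2_sites"] <- g("G2") + g("G2S") + g("G2P")
  if ("Ereg" %in% sp) tot["Ereg_sites"] <- g("Ereg") + g("EregS") + g("EregP")
  if ("Ifree" %in% sp) tot["I_sites"] <- g("Ifree") + g("IS") + g("IP")
  tot
}
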