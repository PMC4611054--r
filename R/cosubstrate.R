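# Two fluorogenic peptide species digested together: both share the gate
# sites, the chamber capacity (volume-weighted through their capacities),
# the enhancer and inhibitor sites and the active sites (competitive via a
# joint partition denominator: the free-enzyme state is counted once and
# every species contributes its own occupancy terms).

COSUB_SPECIES <- c(outer = "Sout", outerP = "Pout", g1s = "G1S", g1p = "G1P",
                   inS = "S", inP = "P", g2s = "G2S", g2p = "G2P",
                   es = "EregS", ep = "EregP", is = "IS", ip = "IP")

cosub_state_names <- function() {
  c(paste0(COSUB_SPECIES, "_A"), paste0(COSUB_SPECIES, "_B"),
    "G1", "G2", "Ereg", "Ifree")
}

# numerator and own partition terms of the two-site-modifier law
tsm_parts <- function(S, P, params, lead_factor = "hill", n_copies = 2) {
  KaS <- params[["KaS"]]; KaP <- params[["KaP"]]
  KiS <- params[["KiS"]]; KiP <- params[["KiP"]]
  na <- params[["na"]]; ni <- params[["ni"]]
  a <- params[["alpha"]]; b <- params[["beta"]]
  terms <- S^na / KaS + S^ni / KiS + P^na / KaP + P^ni / KiP +
    S^(na + ni) / (a * KaS * KiS) + P^(na + ni) / (a * KaP * KiP) +
    S^na * P^ni / (a * KaS * KiP) + S^ni * P^na / (a * KiS * KaP)
  lead <- if (identical(lead_factor, "hill")) na else n_copies
  num <- lead * params[["kp"]] * params[["E0"]] * (S^na / KaS) *
    (1 + b * S^ni / (a * KiS) + b * P^ni / (a * KiP))
  list(num = num, terms = terms)
}

cosub_rhs <- function(t, y, ctx) {
  y <- pmax(y, 0)
  pA <- ctx$params_A; pB <- ctx$params_B; model <- ctx$model
  E0 <- pA[["E0"]]; I0 <- pA[["I0"]]
  gA <- function(n) y[[paste0(n, "_A")]]
  gB <- function(n) y[[paste0(n, "_B")]]
  d <- stats::setNames(numeric(length(y)), names(y))

  enh <- 1 + (pA[["Xenh"]] * (gA("EregS") + gA("EregP")) +
                pB[["Xenh"]] * (gB("EregS") + gB("EregP"))) / E0
  inh <- 1 + (pA[["Yinh"]] * (gA("IS") + gA("IP")) +
                pB[["Yinh"]] * (gB("IS") + gB("IP"))) / I0

  loadA <- gA("S") + gA("P"); loadB <- gB("S") + gB("P")
  CA <- pA[["C"]]; CB <- pB[["C"]]

  hA <- tsm_parts(gA("S"), gA("P"), pA, ctx$lead_factor, ctx$n_copies)
  hB <- tsm_parts(gB("S"), gB("P"), pB, ctx$lead_factor, ctx$n_copies)
  xj <- 1 + hA$terms + hB$terms
  vhA <- hA$num / xj
  vhB <- hB$num / xj

  for (side in c("A", "B")) {
    p <- if (side == "A") pA else pB
    gg <- if (side == "A") gA else gB
    vh <- if (side == "A") vhA else vhB
    Cown <- if (side == "A") CA else CB
    Coth <- if (side == "A") CB else CA
    lown <- if (side == "A") loadA else loadB
    loth <- if (side == "A") loadB else loadA
    cap <- tanh(max(0, E0 * Cown - (lown + (Cown / Coth) * loth)))
    tin <- p[["vin"]] * enh / inh * cap
    tout <- p[["vout"]] * enh / inh
    nm <- function(n) paste0(n, "_", side)

    bS <- p[["kon"]] * gg("Sout") * y[["G1"]]
    bP <- p[["kon"]] * gg("Pout") * y[["G1"]]
    uS <- p[["koff"]] * gg("G1S"); uP <- p[["koff"]] * gg("G1P")
    inS <- tin * gg("G1S"); inP <- tin * gg("G1P")
    trS <- p[["tau"]] * gg("S") * y[["G2"]] / E0
    trP <- p[["tau"]] * gg("P") * y[["G2"]] / E0
    outS <- tout * gg("G2S"); outP <- tout * gg("G2P")

    d[nm("Sout")] <- -bS + uS + outS
    d[nm("Pout")] <- -bP + uP + outP
    d[nm("G1S")] <- bS - uS - inS
    d[nm("G1P")] <- bP - uP - inP
    d[nm("S")] <- inS - trS - vh
    d[nm("P")] <- inP - trP + vh
    d[nm("G2S")] <- trS - outS
    d[nm("G2P")] <- trP - outP
    d["G1"] <- d[["G1"]] - (bS + bP) + (uS + uP) + (inS + inP)
    d["G2"] <- d[["G2"]] - (trS + trP) + (outS + outP)

    if (model$enhancer_location != "none") {
      eS <- if (model$enhancer_location == "inside") gg("S") else gg("Sout")
      eP <- if (model$enhancer_location == "inside") gg("P") else gg("Pout")
      ebS <- p[["Ron"]] * eS * y[["Ereg"]] / E0
      ebP <- p[["Ron"]] * eP * y[["Ereg"]] / E0
      euS <- p[["Roff"]] * gg("EregS"); euP <- p[["Roff"]] * gg("EregP")
      d[nm("EregS")] <- ebS - euS
      d[nm("EregP")] <- ebP - euP
      d["Ereg"] <- d[["Ereg"]] - (ebS + ebP) + (euS + euP)
      tgt <- if (model$enhancer_location == "inside") c("S", "P") else
        c("Sout", "Pout")
      d[nm(tgt[1])] <- d[[nm(tgt[1])]] - ebS + euS
      d[nm(tgt[2])] <- d[[nm(tgt[2])]] - ebP + euP
    }
    if (model$inhibitor_location != "none") {
      hh <- p[["h"]]
      iS <- if (model$inhibitor_location == "outside") gg("Sout") else gg("S")
      iP <- if (model$inhibitor_location == "outside") gg("Pout") else gg("P")
      ibS <- p[["Ion"]] * iS^hh * y[["Ifree"]]
      ibP <- p[["Ion"]] * iP^hh * y[["Ifree"]]
      iuS <- p[["Ioff"]] * gg("IS"); iuP <- p[["Ioff"]] * gg("IP")
      d[nm("IS")] <- ibS - iuS
      d[nm("IP")] <- ibP - iuP
      d["Ifree"] <- d[["Ifree"]] - (ibS + ibP) + (iuS + iuP)
      tgt <- if (model$inhibitor_location == "outside") c("Sout", "Pout") else
        c("S", "P")
      d[nm(tgt[1])] <- d[[nm(tgt[1])]] - hh * ibS + hh * iuS
      d[nm(tgt[2])] <- d[[nm(tgt[2])]] - hh * ibP + hh * iuP
    }
  }
  list(unname(d))
}

#' Simulate a co-substrate digestion
#'
#' Two peptide species digested by the same proteasome pool. They share
#' the gate sites, the chamber capacity (the influx saturation of each
#' species sees the volume-weighted inner load
#' `S_A + P_A + (C_A / C_B) (S_B + P_B)`), the regulatory sites and the
#' active sites (joint partition denominator, i.e. competition). An
#' optional pre-incubation phase digests species A alone before species B
#' is added at time zero.
#'
#' @param model compartmental `proteodyn_model`; the regulatory topology is
#'   shared by both species.
#' @param params_A,params_B per-species [parameter_set()]s; `E0`, `I0` and
#'   the site totals of `params_A` define the shared pools.
#' @param S0_A,S0_B initial concentrations (uM).
#' @param times sampling times (min) counted from the addition of species B.
#' @param pre_incubation_min duration of the A-only phase; default 0.
#' @param solver_opts,lead_factor,n_copies as in [simulate_time_course()].
#' @return data.frame of class `proteodyn_cosub_trajectory`: `time` plus a
#'   column per species/state (suffix `_A`/`_B`) and the shared free sites.
#' @export
simulate_cosubstrate <- function(model, params_A, params_B, S0_A, S0_B,
                                 times, pre_incubation_min = 0,
                                 solver_opts = list(), lead_factor = "hill",
                                 n_copies = 2) {
  if (!model$compartmentalised)
    stop("co-substrate digestion requires a compartmental model (M5-M9)")
  validate_params(params_A); validate_params(params_B)
  ctx <- list(model = model, params_A = params_A, params_B = params_B,
              lead_factor = lead_factor, n_copies = n_copies)
  rtol <- solver_opts$rtol %||% 1e-8
  atol <- solver_opts$atol %||% 1e-10

  y <- stats::setNames(numeric(length(cosub_state_names())),
                       cosub_state_names())
  y["G1"] <- params_A[["G1_tot"]]
  y["G2"] <- params_A[["G2_tot"]]
  y["Ereg"] <- if (model$enhancer_location != "none")
    params_A[["Ereg_tot"]] else 0
  y["Ifree"] <- if (model$inhibitor_location != "none") params_A[["I0"]] else 0
  y["Sout_A"] <- S0_A

  if (pre_incubation_min > 0) {
    pre <- deSolve::lsoda(y, c(0, pre_incubation_min), cosub_rhs, ctx,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    y <- stats::setNames(as.numeric(pre[nrow(pre), -1]), names(y))
  }
  y["Sout_B"] <- y[["Sout_B"]] + S0_B

  times <- sort(unique(c(0, as.numeric(times))))
  raw <- deSolve::lsoda(y, times, cosub_rhs, ctx,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  out <- as.data.frame(check_solution(raw, times, model$model_id))
  attr(out, "model") <- model
  attr(out, "params_A") <- params_A
  attr(out, "params_B") <- params_B
  class(out) <- c("proteodyn_cosub_trajectory", "data.frame")
  out
}

#' Per-species product observables of a co-substrate trajectory
#'
#' @param trajectory result of [simulate_cosubstrate()].
#' @return data.frame `time`, `product_A`, `product_B` (total product
#'   moiety per species).
#' @export
cosubstrate_products <- function(trajectory) {
  pA <- attr(trajectory, "params_A"); pB <- attr(trajectory, "params_B")
  tot <- function(side, p) {
    g <- function(n) trajectory[[paste0(n, "_", side)]]
    g("Pout") + g("G1P") + g("P") + g("G2P") + g("EregP") + p[["h"]] * g("IP")
  }
  data.frame(time = trajectory$time, product_A = tot("A", pA),
             product_B = tot("B", pB))
}
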