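# Shared helpers for the test suite. Everything is generated in code; no
# stored fixtures.

# a mid-scale M9 parameter set with every mechanism active
test_params_m9 <- function() {
  parameter_set(kon = 0.02, koff = 10, vin = 4, vout = 0.2, tau = 5,
                C = 200, Ron = 3e-4, Roff = 0.004, Xenh = 10,
                Ion = 2e-8, Ioff = 0.05, h = 2, Yinh = 1.5,
                kp = 6000, KaS = 0.05, KaP = 0.15, KiS = 2, KiP = 2,
                na = 1, ni = 1, alpha = 0.8, beta = 0.6)
}

# random parameter set drawn log-uniformly from plausible ranges
random_params <- function() {
  lu <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  parameter_set(kon = lu(1e-3, 0.1), koff = lu(0.1, 50), vin = lu(0.1, 50),
                vout = lu(0.01, 10), tau = lu(0.1, 50), C = lu(10, 500),
                Ron = lu(1e-4, 1), Roff = lu(1e-3, 1), Xenh = lu(0.1, 20),
                Ion = lu(1e-9, 1e-5), Ioff = lu(1e-3, 1), h = sample(1:3, 1),
                Yinh = lu(0.1, 20), kp = lu(10, 1e4), KaS = lu(0.01, 10),
                KaP = lu(0.01, 10), KiS = lu(0.05, 50), KiP = lu(0.05, 50),
                na = stats::runif(1, 1, 2), ni = stats::runif(1, 1, 2),
                alpha = lu(0.1, 5), beta = stats::runif(1, 0.05, 1),
                vmax = lu(0.01, 1), KM = lu(10, 500),
                eps_fb = lu(0.01, 10), K_fb = lu(1, 100))
}

# random non-trivial state respecting the model's conservation totals
random_state <- function(model, params, S0 = 300) {
  y <- initial_state(model, S0, params)
  frac <- function(n) { x <- stats::runif(n); x / sum(x) }
  if (all(c("Sout", "Pout") %in% model$species)) {
    sp <- stats::runif(1, 0.2, 0.8)
    y["Pout"] <- y[["Sout"]] * (1 - sp)
    y["Sout"] <- y[["Sout"]] * sp
  }
  if ("G1" %in% model$species) {
    f <- frac(3) * params[["G1_tot"]]
    y[c("G1", "G1Sout", "G1Pout")] <- f
    y["Sout"] <- max(0, y[["Sout"]] - f[2])
    y["Pout"] <- max(0, y[["Pout"]] - f[3])
  }
  if ("G2" %in% model$species) {
    f <- frac(3) * params[["G2_tot"]]
    y[c("G2", "G2S", "G2P")] <- f
    y["S"] <- 0.3 * params[["E0"]] * params[["C"]] * stats::runif(1)
    y["P"] <- 0.3 * params[["E0"]] * params[["C"]] * stats::runif(1)
  }
  if ("Ereg" %in% model$species) {
    f <- frac(3) * params[["Ereg_tot"]]
    y[c("Ereg", "EregS", "EregP")] <- f
  }
  if ("Ifree" %in% model$species) {
    f <- frac(3) * params[["I0"]]
    y[c("Ifree", "IS", "IP")] <- f
  }
  y
}

# M9 parameters in the Michaelis-Menten limit: regulation off, modifier
# site empty, transport fast and balanced (tau = kon * E0) so the inner
# substrate concentration tracks the outer one. Because the two pools
# then hold equal amounts, the observable kinetics are Michaelis-Menten
# with an effective KM of 2 * KaS.
mm_limit_params <- function(kp = 1, KaS = 100, E0 = 1) {
  parameter_set(kp = kp, KaS = KaS, E0 = E0,
                KaP = 1e12, KiS = 1e12, KiP = 1e12, na = 1, ni = 1,
                alpha = 1, beta = 1, Xenh = 0, Yinh = 0,
                Ron = 0, Roff = 1, Ion = 0, Ioff = 1, h = 1,
                kon = 1e3, koff = 1, tau = 1e3 * E0, vin = 1e7, vout = 1e7,
                C = 1e7, vmax = kp * E0, KM = 2 * KaS,
                G1_tot = E0, G2_tot = E0, Ereg_tot = E0, I0 = E0)
}

# small assay design for fast inference tests
small_design <- function(conc = c(80, 240, 480), times = c(30, 60, 120, 240)) {
  list(substrate = "Suc-LLVY-MCA", isoform = "mouse",
       concentrations_uM = conc, times_min = times, replicates = 2,
       enzyme_ug = 0.125, volume_ul = 100)
}

# independent fourth-order fixed-step integrator over the reference RHS
rk4_integrate <- function(model, params, S0, t_end, dt = 0.01) {
  y <- initial_state(model, S0, params)
  f <- function(y) unname(ode_rhs(model, y, params, neg_tol = Inf))
  nm <- names(y)
  steps <- ceiling(t_end / dt)
  dt <- t_end / steps
  for (i in seq_len(steps)) {
    k1 <- f(y)
    k2 <- f(stats::setNames(y + dt / 2 * k1, nm))
    k3 <- f(stats::setNames(y + dt / 2 * k2, nm))
    k4 <- f(stats::setNames(y + dt * k3, nm))
    y <- stats::setNames(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), nm)
  }
  y
}
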