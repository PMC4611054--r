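REACTION_CLASSES <- c("gate_affinity", "influx", "hydrolysis",
                      "translocation", "efflux", "gate_size")

# scale the parameters of one reaction class by `factor`
scale_reaction_class <- function(params, class,
                                 factor, gate_affinity_mode = c("kon", "koff")) {
  gate_affinity_mode <- match.arg(gate_affinity_mode)
  if (!class %in% REACTION_CLASSES)
    stop("unknown reaction class '", class, "'; valid classes: ",
         paste(REACTION_CLASSES, collapse = ", "))
  switch(class,
    gate_affinity = {
      if (gate_affinity_mode == "kon") params[["kon"]] <- params[["kon"]] * factor
      else params[["koff"]] <- params[["koff"]] / factor
      params
    },
    influx = { params[["vin"]] <- params[["vin"]] * factor; params },
    hydrolysis = { params[["kp"]] <- params[["kp"]] * factor; params },
    translocation = { params[["tau"]] <- params[["tau"]] * factor; params },
    efflux = { params[["vout"]] <- params[["vout"]] * factor; params },
    gate_size = {
      params[["vin"]] <- params[["vin"]] * factor
      params[["vout"]] <- params[["vout"]] * factor
      params
    })
}

#' Rate-limiting-step (sensitivity) analysis
#'
#' For each reaction class, re-simulates the digestion with that class's
#' parameters scaled by `factor` and reports the fold-change of total
#' product at `t_end` relative to the unperturbed run. The class with the
#' largest fold-change is the rate-limiting step. Classes: `gate_affinity`
#' (`kon` up, or `koff` down via `gate_affinity_mode`), `influx` (`vin`),
#' `hydrolysis` (`kp`), `translocation` (`tau`), `efflux` (`vout`) and
#' `gate_size` (`vin` and `vout` jointly).
#'
#' Given a posterior, the analysis runs per particle and the result holds
#' the weighted fold-change distribution per class (so it is invariant to
#' particle order).
#'
#' @param model compartmental `proteodyn_model`.
#' @param params_or_posterior a [parameter_set()] or a `proteodyn_abc`
#'   posterior (particles supply the free parameters on top of
#'   `base_params`).
#' @param S0 substrate concentration (uM); the canonical probe uses 320.
#' @param t_end measurement time (min); the canonical probe uses 60.
#' @param factor perturbation factor > 0; default 2.
#' @param base_params needed when a posterior is supplied.
#' @param classes reaction classes to probe; default all six.
#' @param gate_affinity_mode `"kon"` (default) or `"koff"`.
#' @param max_particles cap on posterior particles evaluated (weighted
#'   subsample without replacement is not used; the heaviest particles are
#'   taken to keep the probe deterministic).
#' @return `proteodyn_sensitivity`: data.frame `reaction_class`,
#'   `particle`, `weight`, `fold_change`, with `S0`, `t_end`, `factor`
#'   attributes; `summary(x)` gives weighted means/medians per class.
#' @export
rate_limiting_analysis <- function(model, params_or_posterior, S0 = 320,
                                   t_end = 60, factor = 2,
                                   base_params = NULL,
                                   classes = REACTION_CLASSES,
                                   gate_affinity_mode = "kon",
                                   max_particles = 50) {
  if (factor <= 0) stop("factor must be > 0")
  bad <- setdiff(classes, REACTION_CLASSES)
  if (length(bad))
    stop("unknown reaction class '", bad[1], "'; valid classes: ",
         paste(REACTION_CLASSES, collapse = ", "))
  if (!model$compartmentalised)
    stop("rate-limiting analysis applies to compartmental models")

  particle_params <- if (inherits(params_or_posterior, "proteodyn_abc")) {
    if (is.null(base_params))
      stop("base_params needed when analysing a posterior")
    pt <- params_or_posterior$particles
    pt <- pt[order(-pt$weight), , drop = FALSE]
    pt <- utils::head(pt, max_particles)
    pars <- setdiff(colnames(pt), c("model", "weight", "distance"))
    lapply(seq_len(nrow(pt)), function(i) {
      p <- base_params
      vals <- unlist(pt[i, pars])
      vals <- vals[is.finite(vals)]
      p[names(vals)] <- vals
      list(params = p, weight = pt$weight[i])
    })
  } else {
    list(list(params = params_or_posterior, weight = 1))
  }

  rows <- do.call(rbind, lapply(seq_along(particle_params), function(i) {
    p <- particle_params[[i]]$params
    base <- product_at(model, p, S0, t_end)
    do.call(rbind, lapply(classes, function(cl) {
      pp <- scale_reaction_class(p, cl, factor, gate_affinity_mode)
      data.frame(reaction_class = cl, particle = i,
                 weight = particle_params[[i]]$weight,
                 fold_change = product_at(model, pp, S0, t_end) / base)
    }))
  }))
  rownames(rows) <- NULL
  attr(rows, "S0") <- S0
  attr(rows, "t_end") <- t_end
  attr(rows, "factor") <- factor
  class(rows) <- c("proteodyn_sensitivity", "data.frame")
  rows
}

product_at <- function(model, params, S0, t_end) {
  traj <- simulate_time_course(model, params, S0, c(0, t_end),
                               check_conservation = FALSE)
  utils::tail(observable_product(traj, params), 1)
}

#' @export
summary.proteodyn_sensitivity <- function(object, ...) {
  cls <- unique(object$reaction_class)
  out <- do.call(rbind, lapply(cls, function(cl) {
    d <- object[object$reaction_class == cl, ]
    w <- d$weight / sum(d$weight)
    data.frame(reaction_class = cl,
               mean_fold = sum(w * d$fold_change),
               median_fold = weighted_quantile(d$fold_change, w, 0.5))
  }))
  out[order(-out$mean_fold), ]
}

#' Chamber occupancy diagnostics
#'
#' Reports, along a compartmental trajectory, the number of peptide
#' molecules inside the chambers per proteasome
#' (`(S + P + G2S + G2P + EregS + EregP) / E0`), the product fraction of
#' that inner load, and a time-to-fill summary (first time the occupancy
#' reaches `fill_fraction` of its final value).
#'
#' @param trajectory a `proteodyn_trajectory` of a compartmental model.
#' @param params defaults to the trajectory's parameters.
#' @param fill_fraction fraction of the final occupancy defining
#'   "filled"; default 0.9.
#' @return `proteodyn_chamber_report`: data.frame `time`,
#'   `molecules_inside`, `product_fraction` (`NA` where the chamber is
#'   empty), with attributes `capacity` and `time_to_fill`.
#' @export
chamber_occupancy <- function(trajectory, params = NULL,
                              fill_fraction = 0.9) {
  model <- attr(trajectory, "model")
  if (is.null(model) || !model$compartmentalised)
    stop("chamber occupancy requires a compartmental trajectory")
  params <- params %||% attr(trajectory, "params")
  g <- function(n) if (n %in% colnames(trajectory)) trajectory[[n]] else 0
  s_load <- g("S") + g("G2S") + g("EregS")
  p_load <- g("P") + g("G2P") + g("EregP")
  load <- s_load + p_load
  occ <- load / params[["E0"]]
  frac <- ifelse(load > 0, p_load / load, NA_real_)
  out <- data.frame(time = trajectory$time, molecules_inside = occ,
                    product_fraction = frac)
  final <- occ[length(occ)]
  ttf <- if (final > 0) {
    i <- which(occ >= fill_fraction * final)[1]
    trajectory$time[i]
  } else NA_real_
  attr(out, "capacity") <- params[["C"]]
  attr(out, "time_to_fill") <- ttf
  class(out) <- c("proteodyn_chamber_report", "data.frame")
  out
}

#' Capacity vs molecular volume consistency check
#'
#' The chamber capacity is expected to scale inversely with the volume of
#' the substrate molecule. Given per-substrate capacity estimates and
#' molecular volumes, reports every pairwise capacity ratio (larger over
#' smaller capacity), the corresponding inverse-volume ratio, and an
#' agreement score (smaller ratio over larger, 1 = perfect agreement).
#'
#' @param C_estimates named numeric vector of capacity estimates
#'   (molecules), >= 2 substrates.
#' @param molecular_volumes named numeric vector of molecular volumes
#'   (cubic Angstrom), same names; all > 0.
#' @return data.frame `pair`, `capacity_ratio`, `volume_ratio`,
#'   `agreement`; ratios reported to full precision with a two-decimal
#'   `capacity_ratio_2dp` convenience column.
#' @export
#' @examples
#' capacity_consistency(c(A = 200, B = 249), c(A = 936, B = 741))
capacity_consistency <- function(C_estimates, molecular_volumes) {
  if (length(C_estimates) < 2) stop("need at least two substrates")
  if (!setequal(names(C_estimates), names(molecular_volumes)))
    stop("capacity and volume names must match")
  if (any(molecular_volumes <= 0)) stop("molecular volumes must be > 0")
  nms <- names(C_estimates)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    # orient so the capacity ratio is >= 1 (smaller molecule on top)
    if (C_estimates[[a]] < C_estimates[[b]]) { t <- a; a <- b; b <- t }
    cr <- C_estimates[[a]] / C_estimates[[b]]
    vr <- molecular_volumes[[b]] / molecular_volumes[[a]]
    data.frame(pair = paste(a, b, sep = ":"),
               capacity_ratio = cr, volume_ratio = vr,
               agreement = min(cr, vr) / max(cr, vr))
  }))
  out$capacity_ratio_2dp <- round_dec(out$capacity_ratio, 2)
  rownames(out) <- NULL
  out
}

# decimal round-half-to-even at `digits` places (round() operates on the
# binary representation, so e.g. 249/200 would come out as 1.25)
round_dec <- function(x, digits = 2) {
  y <- x * 10^digits
  f <- floor(y)
  r <- y - f
  half <- abs(r - 0.5) < 1e-9
  up <- ifelse(half, f %% 2 == 1, r > 0.5)
  (f + as.numeric(up)) / 10^digits
}
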