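# One-step bimolecular binding model:  P + R <=> PR  with rate constants
# k_on (uM^-1 s^-1) and k_off (s^-1).  All closed-form relations used by the
# stopped-flow analysis live here; the numerical realisation of the mass-action
# dynamics is in ode.R.
#
# Unit conventions (used throughout the package):
#   concentrations  uM
#   time            s
#   k_on            uM^-1 s^-1
#   k_off           s^-1
#   K_d             nM  (reported scale; the uM -> nM conversion is isolated
#                        in compute_Kd)

#' Equilibrium dissociation constant from rate constants
#'
#' Computes `K_d = k_off / k_on`, converting from the internal uM scale to the
#' conventional nM reporting scale.
#'
#' @param k_on Association rate constant, uM^-1 s^-1. Must be positive.
#' @param k_off Dissociation rate constant, s^-1.
#' @return Dissociation constant in nM. Vectorised over both arguments.
#' @examples
#' compute_Kd(400, 6.2) # 15.5 nM
#' @export
compute_Kd <- function(k_on, k_off) {
  if (!is.numeric(k_on) || !is.numeric(k_off)) {
    stop("`k_on` and `k_off` must be numeric")
  }
  if (any(!is.finite(k_on)) || any(k_on <= 0)) {
    stop("`k_on` must be positive and finite (uM^-1 s^-1)")
  }
  if (any(!is.finite(k_off)) || any(k_off < 0)) {
    stop("`k_off` must be non-negative and finite (s^-1)")
  }
  1000 * k_off / k_on
}

#' Rate-constant pair for one RNA/protein complex
#'
#' Container for the association/dissociation rate constants of one
#' RNA-protein pair under one solution condition, with the derived
#' dissociation constant.
#'
#' @param k_on Association rate constant, uM^-1 s^-1 (> 0).
#' @param k_off Dissociation rate constant, s^-1 (>= 0).
#' @param k_on_se,k_off_se Standard errors (same units), optional.
#' @param label Free-text condition tag (e.g. "FRT_IRP1 @ 25 uM Mn2+").
#' @return An object of class `rate_parameters` with fields `k_on`, `k_off`,
#'   `k_on_se`, `k_off_se`, `K_d` (nM), `K_d_se` (nM, first-order propagation
#'   when both SEs are available) and `label`.
#' @examples
#' rate_parameters(400, 6.2, label = "FRT_IRP1")
#' @export
rate_parameters <- function(k_on, k_off, k_on_se = NA_real_, k_off_se = NA_real_,
                            label = "") {
  stopifnot(length(k_on) == 1L, length(k_off) == 1L)
  K_d <- compute_Kd(k_on, k_off)
  K_d_se <- if (is.finite(k_on_se) && is.finite(k_off_se) && k_off > 0) {
    K_d * sqrt((k_on_se / k_on)^2 + (k_off_se / k_off)^2)
  } else {
    NA_real_
  }
  structure(
    list(k_on = k_on, k_off = k_off,
         k_on_se = as.numeric(k_on_se), k_off_se = as.numeric(k_off_se),
         K_d = K_d, K_d_se = K_d_se, label = as.character(label)[1L]),
    class = "rate_parameters"
  )
}

#' @export
print.rate_parameters <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.finite(se)) sprintf("%.4g +/- %.2g", v, se) else sprintf("%.4g", v)
  }
  if (nzchar(x$label)) cat("<rate_parameters> ", x$label, "\n", sep = "")
  else cat("<rate_parameters>\n")
  cat("  k_on : ", fmt(x$k_on, x$k_on_se), " uM^-1 s^-1\n", sep = "")
  cat("  k_off: ", fmt(x$k_off, x$k_off_se), " s^-1\n", sep = "")
  cat("  K_d  : ", fmt(x$K_d, x$K_d_se), " nM (k_off/k_on)\n", sep = "")
  invisible(x)
}

.as_rate <- function(rate) {
  if (inherits(rate, "rate_parameters")) return(rate)
  if (is.list(rate) && all(c("k_on", "k_off") %in% names(rate))) {
    return(rate_parameters(rate$k_on, rate$k_off))
  }
  stop("`rate` must be a rate_parameters object (see rate_parameters())")
}

#' Single-exponential relaxation
#'
#' Evaluates `delta_r * exp(-k_obs * t) + r_f`, the mono-exponential time
#' course of an observable relaxing towards its final value `r_f`.
#'
#' @param t Time(s) after mixing, s (>= 0). Vectorised.
#' @param delta_r Amplitude (initial minus final signal), signal units.
#' @param k_obs Observed first-order rate constant, s^-1 (>= 0).
#' @param r_f Final signal value.
#' @return Signal at `t`, same units as `delta_r`/`r_f`.
#' @examples
#' single_exponential(0, 0.05, 100, 0.15) # 0.20
#' @export
single_exponential <- function(t, delta_r, k_obs, r_f) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be non-negative and finite")
  if (length(k_obs) != 1L || !is.finite(k_obs) || k_obs < 0) {
    stop("`k_obs` must be a single non-negative rate (s^-1)")
  }
  delta_r * exp(-k_obs * t) + r_f
}

#' Double-exponential relaxation
#'
#' Evaluates the biphasic relaxation
#' `delta_r1 * exp(-k_obs1 * t) + delta_r2 * exp(-k_obs2 * t) + r_f`.
#' Reduces to [single_exponential()] when `delta_r2 = 0`.
#'
#' @inheritParams single_exponential
#' @param delta_r1,delta_r2 Amplitudes of the two components.
#' @param k_obs1,k_obs2 Observed rate constants of the two components, s^-1.
#' @return Signal at `t`.
#' @export
double_exponential <- function(t, delta_r1, k_obs1, delta_r2, k_obs2, r_f) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be non-negative and finite")
  if (any(c(k_obs1, k_obs2) < 0)) stop("rate constants must be non-negative")
  delta_r1 * exp(-k_obs1 * t) + delta_r2 * exp(-k_obs2 * t) + r_f
}

#' Observed rate under pseudo-first-order conditions
#'
#' For a one-step bimolecular mechanism followed with the binding partner in
#' excess, the observed relaxation rate is linear in the partner
#' concentration: `k_obs = k_on * [P] + k_off`.
#'
#' @param rate A [rate_parameters()] object.
#' @param protein_conc Concentration of the excess partner, uM (>= 0).
#'   Vectorised.
#' @return Observed rate(s), s^-1.
#' @examples
#' kobs_linear(rate_parameters(400, 6.2), 1.0) # 406.2 s^-1
#' @export
kobs_linear <- function(rate, protein_conc) {
  rate <- .as_rate(rate)
  if (any(!is.finite(protein_conc)) || any(protein_conc < 0)) {
    stop("`protein_conc` must be non-negative (uM)")
  }
  rate$k_on * protein_conc + rate$k_off
}

#' Observed rate of a dilution (relaxation) experiment
#'
#' Rewrites the pseudo-first-order relation in terms of the equilibrium
#' constant: `k_obs = k_off * ([P]/K_d + 1)`, the form used to extract k_off
#' from the relaxation that follows dilution of a pre-formed complex.
#' Algebraically identical to [kobs_linear()] with `k_on = k_off / K_d`.
#'
#' @param k_off Dissociation rate constant, s^-1.
#' @param K_d Dissociation constant, nM (> 0).
#' @param protein_conc Free-protein concentration after dilution, uM.
#' @return Observed rate, s^-1.
#' @examples
#' kobs_dilution(6.2, 15.5, 1.0) # 406.2 s^-1
#' @export
kobs_dilution <- function(k_off, K_d, protein_conc) {
  if (any(!is.finite(K_d)) || any(K_d <= 0)) stop("`K_d` must be positive (nM)")
  if (any(protein_conc < 0)) stop("`protein_conc` must be non-negative (uM)")
  k_off * (protein_conc / (K_d / 1000) + 1)
}

#' Lifetime of a bimolecular complex
#'
#' The reciprocal relaxation rate of the one-step mechanism at the final
#' (post-mixing) concentrations: `1/tau = k_on * ([R] + [P]) + k_off`.
#'
#' @param rate A [rate_parameters()] object.
#' @param rna_final Final RNA concentration, uM (>= 0).
#' @param protein_final Final protein concentration, uM (>= 0).
#' @return Lifetime tau, in seconds.
#' @examples
#' complex_lifetime(rate_parameters(81, 4.8), 0.5, 0.1) # ~0.0187 s
#' @export
complex_lifetime <- function(rate, rna_final, protein_final) {
  rate <- .as_rate(rate)
  if (any(c(rna_final, protein_final) < 0)) {
    stop("concentrations must be non-negative (uM)")
  }
  denom <- rate$k_on * (rna_final + protein_final) + rate$k_off
  if (any(denom <= 0)) stop("total relaxation rate is zero; lifetime undefined")
  1 / denom
}

#' One protein species of a binding system
#'
#' @param name Protein identifier (e.g. "IRP1").
#' @param total Total concentration, uM (>= 0).
#' @param rate [rate_parameters()] for its complex with the RNA.
#' @return A `binding_protein` list.
#' @export
binding_protein <- function(name, total, rate) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(total) || total < 0) stop("`total` must be non-negative (uM)")
  structure(list(name = name, total = total, rate = .as_rate(rate)),
            class = "binding_protein")
}

#' Species inventory for a binding experiment
#'
#' Describes one RNA plus one or two proteins competing for it, with total
#' concentrations and per-complex rate constants. Totals are conserved by any
#' simulation started from the system.
#'
#' @param rna_total Total RNA concentration, uM (>= 0).
#' @param proteins A [binding_protein()] or a list of at most two of them.
#' @param initial_complexes Initial complex concentration(s), uM, one per
#'   protein (default 0, i.e. the association direction). Used by dilution
#'   experiments that start from a pre-equilibrated complex.
#' @param active_fraction Fraction of each protein competent for binding
#'   (multiplies the protein totals; default 1).
#' @return An object of class `binding_system`.
#' @examples
#' binding_system(0.05, binding_protein("IRP1", 1.0, rate_parameters(400, 6.2)))
#' @export
binding_system <- function(rna_total, proteins, initial_complexes = NULL,
                           active_fraction = 1) {
  if (!is.finite(rna_total) || rna_total < 0) {
    stop("`rna_total` must be non-negative (uM)")
  }
  if (inherits(proteins, "binding_protein")) proteins <- list(proteins)
  if (!is.list(proteins) || length(proteins) < 1L || length(proteins) > 2L ||
      !all(vapply(proteins, inherits, logical(1), "binding_protein"))) {
    stop("`proteins` must be one or two binding_protein() objects")
  }
  if (!is.finite(active_fraction) || active_fraction <= 0 || active_fraction > 1) {
    stop("`active_fraction` must be in (0, 1]")
  }
  for (i in seq_along(proteins)) {
    proteins[[i]]$total <- proteins[[i]]$total * active_fraction
  }
  np <- length(proteins)
  if (is.null(initial_complexes)) initial_complexes <- rep(0, np)
  if (length(initial_complexes) != np || any(initial_complexes < 0)) {
    stop("`initial_complexes` must give one non-negative value per protein")
  }
  for (i in seq_len(np)) {
    if (initial_complexes[i] > proteins[[i]]$total + 1e-12) {
      stop("initial complex exceeds the total of protein ", proteins[[i]]$name)
    }
  }
  if (sum(initial_complexes) > rna_total + 1e-12) {
    stop("initial complexes exceed the total RNA")
  }
  structure(list(rna_total = rna_total, proteins = proteins,
                 initial_complexes = initial_complexes),
            class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("<binding_system> RNA total ", x$rna_total, " uM\n", sep = "")
  for (i in seq_along(x$proteins)) {
    p <- x$proteins[[i]]
    cat(sprintf("  %-8s %g uM  (k_on %.4g, k_off %.4g, K_d %.4g nM), complex0 %g uM\n",
                p$name, p$total, p$rate$k_on, p$rate$k_off, p$rate$K_d,
                x$initial_complexes[i]))
  }
  invisible(x)
}

#' Instantaneous kinetic partition between two competing proteins
#'
#' Under kinetic control, RNA released into a mixture of two proteins is
#' initially captured in proportion to the association fluxes
#' `k_on_i * [P_i]`; the captured fraction for protein i is
#' `k_on_i P_i / (k_on_1 P_1 + k_on_2 P_2)`. This is the no-rebinding
#' (instantaneous flux) approximation; the time-resolved answer is available
#' from [simulate_binding_ode()].
#'
#' @param p1_total,p2_total Total protein concentrations, uM.
#' @param rate1,rate2 [rate_parameters()] for the two complexes.
#' @return Named numeric vector of capture fractions (sums to 1).
#' @examples
#' kinetic_partition(0.1, 0.1, rate_parameters(400, 6.2), rate_parameters(81, 4.8))
#' @export
kinetic_partition <- function(p1_total, p2_total, rate1, rate2) {
  rate1 <- .as_rate(rate1); rate2 <- .as_rate(rate2)
  if (any(c(p1_total, p2_total) < 0)) stop("protein totals must be non-negative")
  flux <- c(rate1$k_on * p1_total, rate2$k_on * p2_total)
  if (sum(flux) <= 0) stop("total association flux is zero; partition undefined")
  stats::setNames(flux / sum(flux), c("protein1", "protein2"))
}
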