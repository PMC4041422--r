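# Mass-action dynamics and equilibria of the one-step binding model, for one
# RNA and up to two competing proteins:
#   d[C_i]/dt = k_on,i [R][P_i] - k_off,i [C_i]
# The full state (free RNA, free proteins, complexes) is integrated so that
# mass conservation is a genuine check on the integrator, not an identity.
# A stiff-capable integrator with tight tolerances is used because observed
# rates span roughly 5-430 s^-1 and traces span milliseconds to seconds.

#' Integrate the mass-action binding dynamics
#'
#' Integrates the coupled mass-action equations of a [binding_system()] over a
#' time grid, starting from the system's initial complexes (default: all
#' species free, the association direction). Supports one or two proteins
#' competing for the same RNA.
#'
#' @param system A [binding_system()].
#' @param times Numeric vector of output times, s (non-negative, increasing).
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @return A `binding_trajectory`: a data.frame with columns `time`,
#'   `rna_free`, one `<name>_free` and one `<name>_complex` column per
#'   protein, with the originating system attached as attribute `system`.
#' @examples
#' sys <- binding_system(0.05, binding_protein("IRP1", 1, rate_parameters(400, 6.2)))
#' traj <- simulate_binding_ode(sys, seq(0, 0.05, length.out = 200))
#' @export
simulate_binding_ode <- function(system, times, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(system, "binding_system"))
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be a strictly increasing, non-negative numeric grid (s)")
  }
  np <- length(system$proteins)
  kon <- vapply(system$proteins, function(p) p$rate$k_on, numeric(1))
  koff <- vapply(system$proteins, function(p) p$rate$k_off, numeric(1))
  ptot <- vapply(system$proteins, function(p) p$total, numeric(1))
  c0 <- system$initial_complexes
  y0 <- c(system$rna_total - sum(c0), ptot - c0, c0)

  deriv <- function(t, y, parms) {
    r <- y[1L]
    p <- y[1L + seq_len(np)]
    cc <- y[1L + np + seq_len(np)]
    v <- kon * r * p - koff * cc
    list(c(-sum(v), -v, v))
  }

  grid <- if (times[1L] > 0) c(0, times) else times
  out <- tryCatch(
    deSolve::ode(y = y0, times = grid, func = deriv, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol),
    error = function(e) stop("ODE integration failed: ", conditionMessage(e))
  )
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1L] < 0) {
    stop("ODE integration failed (istate = ", diagn[1L], ")")
  }
  out <- as.data.frame(out)
  if (times[1L] > 0) out <- out[-1L, , drop = FALSE]

  vals <- as.matrix(out[, -1L, drop = FALSE])
  # lsoda can undershoot zero by ~atol near depletion; clip within tolerance,
  # treat anything worse as an integration defect.
  neg <- vals < 0
  if (any(neg)) {
    if (min(vals[neg]) < -1e4 * atol) {
      stop("negative concentrations beyond integrator tolerance (min = ",
           format(min(vals[neg])), " uM)")
    }
    vals[neg] <- 0
  }
  nms <- vapply(system$proteins, `[[`, character(1), "name")
  traj <- data.frame(time = out[[1L]], rna_free = vals[, 1L])
  for (i in seq_len(np)) traj[[paste0(nms[i], "_free")]] <- vals[, 1L + i]
  for (i in seq_len(np)) traj[[paste0(nms[i], "_complex")]] <- vals[, 1L + np + i]
  rownames(traj) <- NULL
  attr(traj, "system") <- system
  class(traj) <- c("binding_trajectory", "data.frame")
  traj
}

#' Mass-balance error of a simulated trajectory
#'
#' Maximum absolute deviation of each conserved total (RNA and each protein)
#' from its initial value, in uM.
#'
#' @param traj A `binding_trajectory` from [simulate_binding_ode()].
#' @return Named numeric vector of worst-case deviations, uM.
#' @export
mass_balance <- function(traj) {
  system <- attr(traj, "system")
  stopifnot(inherits(traj, "binding_trajectory"), inherits(system, "binding_system"))
  nms <- vapply(system$proteins, `[[`, character(1), "name")
  cplx <- sapply(nms, function(n) traj[[paste0(n, "_complex")]])
  cplx <- matrix(cplx, ncol = length(nms))
  out <- c(rna = max(abs(traj$rna_free + rowSums(cplx) - system$rna_total)))
  for (i in seq_along(nms)) {
    p <- system$proteins[[i]]
    out[nms[i]] <- max(abs(traj[[paste0(nms[i], "_free")]] + cplx[, i] - p$total))
  }
  out
}

#' Equilibrium complex concentration for a single protein
#'
#' Closed-form (numerically stable quadratic) solution of the one-protein
#' mass-balance equilibrium.
#'
#' @param rna_total,protein_total Total concentrations, uM.
#' @param K_d Dissociation constant, nM (> 0).
#' @return Equilibrium complex concentration, uM.
#' @export
equilibrium_complex <- function(rna_total, protein_total, K_d) {
  if (any(K_d <= 0)) stop("`K_d` must be positive (nM)")
  if (any(c(rna_total, protein_total) < 0)) stop("totals must be non-negative")
  kd <- K_d / 1000 # uM
  b <- rna_total + protein_total + kd
  # stable root: 2ab / (b + sqrt(b^2 - 4ab)) avoids cancellation
  2 * rna_total * protein_total /
    (b + sqrt(b^2 - 4 * rna_total * protein_total))
}

#' Equilibrium partition of RNA between two competing proteins
#'
#' Solves the coupled two-ligand equilibria for the fraction of total RNA that
#' is free, bound to protein 1, and bound to protein 2. The free-RNA
#' concentration is found by a bounded root search on the (monotone)
#' mass-balance residual, which is robust where selecting the physical root of
#' the equivalent cubic is not.
#'
#' @param rna_total,p1_total,p2_total Total concentrations, uM.
#' @param Kd1,Kd2 Dissociation constants of the two complexes, nM (> 0).
#' @return Named fractions `c(free, bound1, bound2)` summing to 1, with the
#'   species concentrations (uM) attached as attribute `concentrations`.
#' @examples
#' equilibrium_partition(0.01, 0.1, 0.1, Kd1 = 15.5, Kd2 = 59)
#' @export
equilibrium_partition <- function(rna_total, p1_total, p2_total, Kd1, Kd2) {
  if (any(c(Kd1, Kd2) <= 0)) stop("dissociation constants must be positive (nM)")
  if (any(c(rna_total, p1_total, p2_total) < 0)) {
    stop("totals must be non-negative (uM)")
  }
  if (rna_total == 0) stop("`rna_total` must be positive")
  kd <- c(Kd1, Kd2) / 1000 # uM
  ptot <- c(p1_total, p2_total)
  resid <- function(r) r + sum(ptot * r / (kd + r)) - rna_total
  sol <- tryCatch(
    stats::uniroot(resid, lower = 0, upper = rna_total, tol = 1e-15,
                   maxiter = 2000L),
    error = function(e) stop("equilibrium solve failed to converge: ",
                             conditionMessage(e))
  )
  r <- sol$root
  # one Newton polish: resid'(r) = 1 + sum(P Kd / (Kd + r)^2)
  r <- r - resid(r) / (1 + sum(ptot * kd / (kd + r)^2))
  r <- min(max(r, 0), rna_total)
  bound <- ptot * r / (kd + r)
  fr <- c(free = r, bound1 = bound[1L], bound2 = bound[2L]) / rna_total
  structure(fr, concentrations = c(rna_free = r, complex1 = bound[1L],
                                   complex2 = bound[2L]))
}
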