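# Synthetic stopped-flow traces and full experimental designs.
#
# The generator emulates the instrument and designs of the source experiments:
# 1-ms dead time, 1000 points per shot, 5-7 shots averaged, fixed labelled RNA
# at 0.05 uM titrated with protein (IRP1 anisotropy series), eIF4F held at
# 0.1 uM titrated with RNA (fluorescence series), Mn2+ at 0/5/25/50 uM, and
# 2-fold dilution relaxation experiments.

# Published rate constants (uM^-1 s^-1, s^-1) per RNA/protein pair and Mn2+
# concentration; the tabulated SDs are carried along for reference.
.rate_table <- local({
  tab <- rbind(
    data.frame(pair = "FRT_IRP1", mn_uM = c(0, 5, 25, 50),
               k_on = c(400, 176, 104, 65), k_on_se = c(7.3, 4.3, 3.5, 2.7),
               k_off = c(6.2, 9.7, 11.7, 12.0), k_off_se = c(0.3, 0.4, 0.3, 0.5)),
    data.frame(pair = "ACO2_IRP1", mn_uM = c(0, 5, 25, 50),
               k_on = c(51.5, 35.2, 17, 10.7), k_on_se = c(1.8, 1.6, 1.2, 0.7),
               k_off = c(7.0, 7.6, 7.8, 8.0), k_off_se = c(0.4, 0.3, 0.3, 0.4)),
    data.frame(pair = "FRT_eIF4F", mn_uM = c(0, 5, 25, 50),
               k_on = c(81, 119, 159, 228), k_on_se = c(3.3, 5.4, 6.7, 9.8),
               k_off = c(4.8, 3.3, 2.5, 1.8), k_off_se = c(0.3, 0.2, 0.1, 0.06))
  )
  tab
})

.normalize_pair <- function(pair_id) {
  p <- toupper(gsub("[^A-Za-z0-9]+", "_", pair_id))
  p <- sub("^IRP1_FRT$", "FRT_IRP1", p)
  p <- sub("^IRP1_ACO2$", "ACO2_IRP1", p)
  p <- sub("^EIF4F_FRT$", "FRT_EIF4F", p)
  sub("EIF4F", "eIF4F", p)
}

#' Tabulated rate constants by RNA/protein pair and Mn2+ concentration
#'
#' Looks up the association and dissociation rate constants measured for
#' `FRT_IRP1`, `ACO2_IRP1` and `FRT_eIF4F` at 0, 5, 25 or 50 uM Mn2+.
#' Optionally interpolates between tabulated Mn2+ levels, linearly on the log
#' of each rate constant (rates are positive and vary multiplicatively with
#' metal ion).
#'
#' @param pair_id One of `"FRT_IRP1"`, `"ACO2_IRP1"`, `"FRT_eIF4F"`
#'   (separators are normalised, so `"FRT.IRP1"` also works).
#' @param mn_uM Mn2+ concentration, uM.
#' @param interpolate If `TRUE`, log-linear interpolation for Mn2+ values
#'   inside the tabulated range; otherwise only tabulated values are accepted.
#' @return A [rate_parameters()] object (SEs only for tabulated rows).
#' @examples
#' rate_lookup("FRT_IRP1", 0)
#' rate_lookup("FRT_eIF4F", 25)
#' @export
rate_lookup <- function(pair_id, mn_uM, interpolate = FALSE) {
  pair <- .normalize_pair(pair_id)
  rows <- .rate_table[.rate_table$pair == pair, ]
  if (nrow(rows) == 0L) {
    stop("unknown pair `", pair_id, "`; known: ",
         paste(unique(.rate_table$pair), collapse = ", "))
  }
  lab <- function(mn) sprintf("%s @ %g uM Mn2+", pair, mn)
  hit <- which(rows$mn_uM == mn_uM)
  if (length(hit) == 1L) {
    r <- rows[hit, ]
    return(rate_parameters(r$k_on, r$k_off, r$k_on_se, r$k_off_se, lab(mn_uM)))
  }
  if (!interpolate) {
    stop("mn_uM = ", mn_uM, " is not tabulated for ", pair,
         " (use interpolate = TRUE for values in [",
         min(rows$mn_uM), ", ", max(rows$mn_uM), "])")
  }
  if (mn_uM < min(rows$mn_uM) || mn_uM > max(rows$mn_uM)) {
    stop("mn_uM = ", mn_uM, " outside the tabulated range [",
         min(rows$mn_uM), ", ", max(rows$mn_uM), "]")
  }
  kon <- exp(stats::approx(rows$mn_uM, log(rows$k_on), xout = mn_uM)$y)
  koff <- exp(stats::approx(rows$mn_uM, log(rows$k_off), xout = mn_uM)$y)
  rate_parameters(kon, koff, label = paste0(lab(mn_uM), " (interpolated)"))
}

#' Signal model mapping concentrations to the stopped-flow observable
#'
#' Maps the complex concentration to the recorded signal:
#' anisotropy `r(t) = baseline + span * C(t) / rna_total` (labelled RNA),
#' fluorescence `F(t) = baseline * (1 - span * C(t) / protein_total)`
#' (intrinsic protein fluorescence quenched on RNA binding; `span` is the
#' quench fraction q). Per-point Gaussian noise of standard deviation
#' `noise_sd` is added.
#'
#' The default signal constants are package inventions chosen so that the
#' trace amplitude-to-noise ratio is about 50, consistent with visibly clean
#' single-exponential records.
#'
#' @param kind `"anisotropy"` or `"fluorescence"`.
#' @param baseline Signal of the free observed species (`r_free` or `F0`).
#' @param span Anisotropy change at full binding, or quench fraction q in
#'   `[0, 1]` for fluorescence.
#' @param noise_sd Per-point Gaussian noise SD, signal units (>= 0).
#' @return A `signal_model` list.
#' @export
signal_model <- function(kind = c("anisotropy", "fluorescence"),
                         baseline = NULL, span = NULL, noise_sd = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    anisotropy = list(baseline = 0.05, span = 0.15, noise_sd = 0.002),
    fluorescence = list(baseline = 1.0, span = 0.3, noise_sd = 0.005)
  )
  m <- list(kind = kind,
            baseline = if (is.null(baseline)) defaults$baseline else baseline,
            span = if (is.null(span)) defaults$span else span,
            noise_sd = if (is.null(noise_sd)) defaults$noise_sd else noise_sd)
  if (!is.finite(m$noise_sd) || m$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (kind == "fluorescence" && (m$span < 0 || m$span > 1)) {
    stop("fluorescence quench fraction `span` must lie in [0, 1]")
  }
  structure(m, class = "signal_model")
}

#' One stopped-flow time course
#'
#' @param times Times, s; strictly increasing, first point at or after the
#'   instrument dead time.
#' @param signal Recorded signal (anisotropy, dimensionless, or fluorescence,
#'   arbitrary units).
#' @param signal_kind `"anisotropy"` or `"fluorescence"`.
#' @param condition Named list of condition metadata (concentrations in uM,
#'   `mn_uM`, `kcl_mM`, `temperature_C`, ids).
#' @param n_shots Number of instrument shots averaged into this trace.
#' @param seed Master seed used to generate the trace, or `NULL`.
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(times, signal, signal_kind = c("anisotropy", "fluorescence"),
                          condition = list(), n_shots = 1L, seed = NULL) {
  signal_kind <- match.arg(signal_kind)
  if (length(times) < 2L) stop("a trace needs at least 2 points")
  if (length(signal) != length(times)) stop("`times` and `signal` lengths differ")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be finite and strictly increasing")
  }
  if (any(!is.finite(signal))) stop("`signal` must be finite")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 signal_kind = signal_kind, condition = condition,
                 n_shots = as.integer(n_shots), seed = seed),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %s, %d points, t in [%.4g, %.4g] s, %d shot(s)\n",
              x$signal_kind, length(x$times), min(x$times), max(x$times),
              x$n_shots))
  if (length(x$condition)) {
    kv <- vapply(names(x$condition),
                 function(k) paste0(k, "=", format(x$condition[[k]])), character(1))
    cat("  condition: ", paste(kv, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(time_s = x$times, signal = x$signal)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic child-seed derivation (master seed -> per-shot seeds), kept
# below 2^31 so it is a valid set.seed() argument.
.child_seed <- function(master, index) {
  as.integer((as.double(master %% 1000003L) * 2011 + index * 7919) %% 2147483647)
}

# Identify which species carries the signal: the labelled RNA for anisotropy,
# the intrinsically fluorescent protein for fluorescence. The other species is
# the titrant whose concentration enters k_obs.
.trace_roles <- function(system, kind) {
  p <- system$proteins[[1L]]
  if (kind == "anisotropy") {
    list(observed_total = system$rna_total, titrant_total = p$total)
  } else {
    list(observed_total = p$total, titrant_total = system$rna_total)
  }
}

.map_signal <- function(C, model, observed_total) {
  f <- C / observed_total
  if (model$kind == "anisotropy") model$baseline + model$span * f
  else model$baseline * (1 - model$span * f)
}

#' Generate one synthetic stopped-flow trace
#'
#' Simulates the complex concentration for a one-protein [binding_system()],
#' maps it to the observable through a [signal_model()], adds i.i.d. Gaussian
#' noise and discards the instrument dead time. Deterministic given `seed`.
#'
#' Two mechanisms are available. `"relaxation"` (default) is the
#' pseudo-first-order description under which stopped-flow titrations are
#' analysed: the titrant is treated as undepleted, so the trace is exactly
#' single-exponential with rate `k_on * [titrant] + k_off` -- the model the
#' observed-rate regression assumes. `"mass_action"` integrates the full
#' bimolecular dynamics with depletion via [simulate_binding_ode()]; its best
#' single-exponential rate deviates from the linear relation as the titrant
#' excess shrinks (see the methods vignette).
#'
#' @param system One-protein [binding_system()]; totals are final (post-mix)
#'   concentrations.
#' @param model A [signal_model()]; its kind fixes which species is observed.
#' @param n_points Points per shot (default 1000).
#' @param t_end Acquisition end time, s; default
#'   `max(10 / k_obs_expected, 0.05)`.
#' @param dead_time Instrument dead time, s (default 1 ms).
#' @param seed Integer seed for the noise, or `NULL`.
#' @param mechanism `"relaxation"` or `"mass_action"`.
#' @return A [kinetic_trace()].
#' @examples
#' sys <- binding_system(0.05, binding_protein("IRP1", 1, rate_parameters(400, 6.2)))
#' tr <- generate_trace(sys, signal_model("anisotropy", noise_sd = 0))
#' @export
generate_trace <- function(system, model, n_points = 1000L, t_end = NULL,
                           dead_time = 1e-3, seed = NULL,
                           mechanism = c("relaxation", "mass_action")) {
  stopifnot(inherits(system, "binding_system"), inherits(model, "signal_model"))
  mechanism <- match.arg(mechanism)
  if (length(system$proteins) != 1L) {
    stop("trace generation supports a single protein species")
  }
  if (n_points < 2L) stop("`n_points` must be at least 2")
  if (model$kind == "anisotropy" && system$rna_total <= 0) {
    stop("anisotropy traces observe the RNA; `rna_total` must be positive")
  }
  if (model$kind == "fluorescence" && system$proteins[[1L]]$total <= 0) {
    stop("fluorescence traces observe the protein; its total must be positive")
  }
  p <- system$proteins[[1L]]
  rate <- p$rate
  roles <- .trace_roles(system, model$kind)
  k_exp <- kobs_linear(rate, roles$titrant_total)
  if (is.null(t_end)) t_end <- max(10 / k_exp, 0.05)
  if (t_end <= dead_time) stop("`t_end` must exceed the dead time")
  times <- seq(dead_time, t_end, length.out = n_points)

  C0 <- system$initial_complexes[1L]
  if (mechanism == "relaxation") {
    Tt <- roles$titrant_total
    Ceq <- roles$observed_total * Tt / (Tt + rate$K_d / 1000)
    C <- Ceq + (C0 - Ceq) * exp(-k_exp * times)
  } else {
    traj <- simulate_binding_ode(system, times)
    C <- traj[[paste0(p$name, "_complex")]]
  }
  sig <- .map_signal(C, model, roles$observed_total)
  if (model$noise_sd > 0) {
    noise <- .with_seed(seed, stats::rnorm(n_points, 0, model$noise_sd))
    sig <- sig + noise
  }
  cond <- list(pair = rate$label,
               rna_uM = system$rna_total, protein_uM = p$total,
               protein_id = p$name)
  kinetic_trace(times, sig, model$kind, condition = cond, n_shots = 1L,
                seed = seed)
}

#' Average repeated shots of the same experiment
#'
#' Pointwise mean of traces recorded on identical time grids under identical
#' conditions; the noise SD shrinks roughly as 1/sqrt(n).
#'
#' @param traces List of [kinetic_trace()] objects.
#' @return A single averaged [kinetic_trace()].
#' @export
average_shots <- function(traces) {
  if (inherits(traces, "kinetic_trace")) return(traces)
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "kinetic_trace")))
  if (length(traces) == 1L) return(traces[[1L]])
  t0 <- traces[[1L]]
  for (tr in traces[-1L]) {
    if (length(tr$times) != length(t0$times) ||
        max(abs(tr$times - t0$times)) > 1e-12 * max(t0$times)) {
      stop("shots recorded on different time grids cannot be averaged")
    }
    if (tr$signal_kind != t0$signal_kind) stop("mixed signal kinds")
  }
  sig <- rowMeans(vapply(traces, `[[`, numeric(length(t0$times)), "signal"))
  kinetic_trace(t0$times, sig, t0$signal_kind, condition = t0$condition,
                n_shots = sum(vapply(traces, `[[`, integer(1), "n_shots")),
                seed = t0$seed)
}

# ---- experimental design presets -------------------------------------------

.presets <- list(
  fig2_frt = list(kind = "anisotropy", pair = "FRT_IRP1", mn_uM = 0,
                  fixed_uM = 0.05, varied_uM = c(0.05, 0.2, 0.5, 1.0),
                  varied = "protein"),
  fig2_aco2 = list(kind = "anisotropy", pair = "ACO2_IRP1", mn_uM = 0,
                   fixed_uM = 0.05, varied_uM = c(0.05, 0.2, 0.5, 1.0),
                   varied = "protein"),
  fig3_frt_mn = list(kind = "anisotropy", pair = "FRT_IRP1",
                     mn_uM = c(0, 5, 25, 50),
                     fixed_uM = 0.05, varied_uM = c(0.05, 0.2, 0.5, 1.0),
                     varied = "protein"),
  fig3_aco2_mn = list(kind = "anisotropy", pair = "ACO2_IRP1",
                      mn_uM = c(0, 5, 25, 50),
                      fixed_uM = 0.05, varied_uM = c(0.05, 0.2, 0.5, 1.0),
                      varied = "protein"),
  fig7_eif4f = list(kind = "fluorescence", pair = "FRT_eIF4F", mn_uM = 0,
                    fixed_uM = 0.1, varied_uM = c(0.1, 0.2, 0.5),
                    varied = "rna"),
  fig7_eif4f_mn = list(kind = "fluorescence", pair = "FRT_eIF4F",
                       mn_uM = c(0, 5, 25, 50),
                       fixed_uM = 0.1, varied_uM = c(0.1, 0.2, 0.5),
                       varied = "rna")
)

#' Named experimental design template
#'
#' Returns the template of one of the built-in titration designs. All
#' concentrations are final (after mixing). In the anisotropy designs the
#' labelled RNA is fixed at 0.05 uM and the protein is varied over
#' 0.05/0.2/0.5/1.0 uM; in the fluorescence designs eIF4F is fixed at 0.1 uM
#' and the RNA is varied over 0.1/0.2/0.5 uM. The `_mn` variants repeat the
#' series at 0/5/25/50 uM Mn2+ using the tabulated rate constants.
#'
#' @param name Preset name; see [preset_names()].
#' @return A `design_preset` list with fields `name`, `kind`, `pair`,
#'   `mn_uM`, `fixed_uM`, `varied_uM`, `varied`, `n_shots`, `n_points`,
#'   `dead_time`.
#' @export
design_preset <- function(name) {
  key <- gsub("-", "_", tolower(name))
  if (!key %in% names(.presets)) {
    stop("unknown preset `", name, "`; available: ",
         paste(names(.presets), collapse = ", "))
  }
  p <- .presets[[key]]
  p$name <- key
  p$n_shots <- 5L
  p$n_points <- 1000L
  p$dead_time <- 1e-3
  structure(p, class = "design_preset")
}

#' @rdname design_preset
#' @export
preset_names <- function() names(.presets)

#' Generate a full titration series from a design preset
#'
#' For every condition (Mn2+ level) and every titrant concentration of the
#' design, generates `n_shots` noisy traces from per-shot child seeds and
#' averages them, mirroring the acquisition protocol. Reproducible given
#' `seed`.
#'
#' @param preset A [design_preset()] or its name.
#' @param seed Master seed (integer) or `NULL`.
#' @param noise_sd Override of the signal model noise SD (e.g. 0 for
#'   noiseless traces); `NULL` keeps the model default.
#' @param n_shots Override of the number of shots per trace.
#' @param mechanism Passed to [generate_trace()].
#' @return List of averaged [kinetic_trace()] objects, one per
#'   condition x concentration, each carrying its condition metadata.
#' @examples
#' series <- generate_titration_series("fig2_frt", seed = 1, noise_sd = 0)
#' length(series) # 4 concentrations
#' @export
generate_titration_series <- function(preset, seed = NULL, noise_sd = NULL,
                                      n_shots = NULL,
                                      mechanism = "relaxation") {
  if (is.character(preset)) preset <- design_preset(preset)
  stopifnot(inherits(preset, "design_preset"))
  if (is.null(n_shots)) n_shots <- preset$n_shots
  model <- signal_model(preset$kind, noise_sd = noise_sd)
  rna_id <- sub("_.*$", "", .normalize_pair(preset$pair))
  out <- list()
  idx <- 0L
  for (ci in seq_along(preset$mn_uM)) {
    mn <- preset$mn_uM[ci]
    rate <- rate_lookup(preset$pair, mn)
    for (conc in preset$varied_uM) {
      idx <- idx + 1L
      rna <- if (preset$varied == "rna") conc else preset$fixed_uM
      prot <- if (preset$varied == "protein") conc else preset$fixed_uM
      pname <- sub("^.*_", "", .normalize_pair(preset$pair))
      sys <- binding_system(rna, binding_protein(pname, prot, rate))
      shots <- lapply(seq_len(n_shots), function(s) {
        sh_seed <- if (is.null(seed)) NULL else .child_seed(seed, idx * 97L + s)
        generate_trace(sys, model, n_points = preset$n_points,
                       dead_time = preset$dead_time, seed = sh_seed,
                       mechanism = mechanism)
      })
      tr <- average_shots(shots)
      tr$seed <- seed
      tr$condition <- list(rna_id = rna_id, protein_id = pname,
                           rna_uM = rna, protein_uM = prot, mn_uM = mn,
                           kcl_mM = 100, temperature_C = 25,
                           varied = preset$varied, preset = preset$name)
      out[[idx]] <- tr
    }
  }
  out
}

#' Generate a dilution (relaxation) trace
#'
#' Emulates the dissociation experiment: an RNA/protein mixture is equilibrated
#' at the pre-mix concentrations, rapidly diluted `dilution_factor`-fold (into
#' buffer, or into buffer with a different Mn2+ level so that the rate
#' constants switch), and the relaxation towards the new equilibrium is
#' recorded. The post-dilution dynamics use the full mass-action integrator:
#' unlike an association titration, the relaxation starts near equilibrium, so
#' the trace is close to single-exponential with the linearised rate
#' `k_on ([R]_free,eq + [P]_free,eq) + k_off`.
#'
#' @param pre_system One-protein [binding_system()] at pre-mix (pre-dilution)
#'   concentrations; its rate parameters define the pre-equilibrium.
#' @param dilution_factor Dilution factor (>= 1); 2 for mixing with an equal
#'   volume.
#' @param post_rate [rate_parameters()] in force after dilution (default: the
#'   pre-mix rates, i.e. dilution into plain buffer).
#' @param model A [signal_model()] (anisotropy observes the RNA).
#' @param n_points,t_end,dead_time,seed As in [generate_trace()].
#' @return A [kinetic_trace()] whose condition records the dilution.
#' @export
generate_dilution_trace <- function(pre_system, dilution_factor = 2,
                                    post_rate = NULL,
                                    model = signal_model("anisotropy"),
                                    n_points = 1000L, t_end = NULL,
                                    dead_time = 1e-3, seed = NULL) {
  stopifnot(inherits(pre_system, "binding_system"))
  if (length(pre_system$proteins) != 1L) stop("dilution supports one protein")
  if (!is.finite(dilution_factor) || dilution_factor < 1) {
    stop("`dilution_factor` must be >= 1")
  }
  p <- pre_system$proteins[[1L]]
  if (is.null(post_rate)) post_rate <- p$rate
  post_rate <- .as_rate(post_rate)

  C_pre <- equilibrium_complex(pre_system$rna_total, p$total, p$rate$K_d)
  rna_post <- pre_system$rna_total / dilution_factor
  prot_post <- p$total / dilution_factor
  C0 <- C_pre / dilution_factor

  post_sys <- binding_system(rna_post,
                             binding_protein(p$name, prot_post, post_rate),
                             initial_complexes = C0)
  # linearised relaxation rate at the post-dilution equilibrium sets the window
  C_eq <- equilibrium_complex(rna_post, prot_post, post_rate$K_d)
  lam <- post_rate$k_on * ((rna_post - C_eq) + (prot_post - C_eq)) + post_rate$k_off
  if (is.null(t_end)) t_end <- max(10 / lam, 0.05)
  times <- seq(dead_time, t_end, length.out = n_points)

  traj <- simulate_binding_ode(post_sys, times)
  C <- traj[[paste0(p$name, "_complex")]]
  observed_total <- if (model$kind == "anisotropy") rna_post else prot_post
  sig <- .map_signal(C, model, observed_total)
  if (model$noise_sd > 0) {
    sig <- sig + .with_seed(seed, stats::rnorm(n_points, 0, model$noise_sd))
  }
  cond <- list(protein_id = p$name, rna_uM = rna_post, protein_uM = prot_post,
               dilution_factor = dilution_factor,
               pre_label = p$rate$label, post_label = post_rate$label)
  kinetic_trace(times, sig, model$kind, condition = cond, seed = seed)
}
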