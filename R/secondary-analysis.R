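# From per-trace observed rates to rate constants, condition tables, fold
# changes, dilution k_off estimates, lifetimes and competition summaries.

#' Rate constants from the k_obs versus concentration line
#'
#' Ordinary least-squares regression of observed rates on titrant
#' concentration: for the one-step mechanism `k_obs = k_on [P] + k_off`, the
#' slope is k_on and the y-intercept k_off. Equal weighting is used, matching
#' a design with the same number of replicate shots at every concentration.
#'
#' @param conc Titrant concentrations, uM; or a data.frame with columns
#'   `conc`, `k_obs` and optionally `se`.
#' @param k_obs Observed rates, s^-1.
#' @param se Optional standard errors of `k_obs` (recorded, not used as
#'   weights).
#' @param label Condition tag for the result.
#' @return A [rate_parameters()] object with standard errors, carrying the
#'   regression summary (slope, intercept, SEs, R-squared, n) as attribute
#'   `linear_fit`.
#' @examples
#' conc <- c(0.05, 0.2, 0.5, 1.0)
#' fit_kobs_vs_concentration(conc, 400 * conc + 6.2)
#' @export
fit_kobs_vs_concentration <- function(conc, k_obs = NULL, se = NULL, label = "") {
  if (is.data.frame(conc)) {
    df <- conc
    stopifnot(all(c("conc", "k_obs") %in% names(df)))
    se <- df$se
    k_obs <- df$k_obs
    conc <- df$conc
  }
  if (length(conc) != length(k_obs)) stop("`conc` and `k_obs` lengths differ")
  if (length(unique(conc)) < 2L) {
    stop("at least 2 distinct concentrations are required")
  }
  if (length(unique(conc)) < 3L) {
    warning("only 2 distinct concentrations: exact line, standard errors undefined")
  }
  fit <- stats::lm(k_obs ~ conc)
  # summary.lm warns about "essentially perfect fit" on noiseless input
  smry <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  cf <- smry$coefficients
  slope <- cf["conc", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  if (slope <= 0) stop("non-positive slope: no detectable association")
  if (intercept < 0) {
    warning("negative fitted intercept (k_off); reported as is, not clamped")
  }
  lf <- list(slope = slope, intercept = intercept,
             slope_se = cf["conc", "Std. Error"],
             intercept_se = cf["(Intercept)", "Std. Error"],
             r_squared = smry$r.squared,
             n = length(conc))
  rp <- rate_parameters(slope, max(intercept, 0),
                        k_on_se = lf$slope_se, k_off_se = lf$intercept_se,
                        label = label)
  # keep a (possibly negative) intercept visible even though rate_parameters
  # constrains k_off >= 0
  rp$k_off <- intercept
  rp$K_d <- 1000 * intercept / slope
  attr(rp, "linear_fit") <- lf
  rp
}

#' Dissociation rate from a dilution relaxation
#'
#' Inverts the dilution relation `k_obs = k_off ([P]/K_d + 1)`: given the
#' single-exponential rate fitted to the post-dilution relaxation and an
#' independently known K_d, returns `k_off = k_obs / (1 + [P]/K_d)`.
#'
#' @param k_obs_fitted Fitted relaxation rate, s^-1.
#' @param protein_conc Protein concentration after dilution, uM.
#' @param K_d_prior Previously determined dissociation constant, nM
#'   (`Inf` means no rebinding, so `k_off = k_obs`).
#' @return Dissociation rate estimate, s^-1.
#' @examples
#' analyze_dilution(406.2, 1.0, 15.5) # 6.2
#' @export
analyze_dilution <- function(k_obs_fitted, protein_conc, K_d_prior) {
  if (any(k_obs_fitted < 0) || any(protein_conc < 0)) {
    stop("rates and concentrations must be non-negative")
  }
  if (any(K_d_prior <= 0)) stop("`K_d_prior` must be positive (nM)")
  k_obs_fitted / (1 + protein_conc / (K_d_prior / 1000))
}

#' Ratio of a value under a condition to its control
#'
#' @param value_condition,value_control Values to compare; the control must be
#'   non-zero.
#' @return `value_condition / value_control`.
#' @seealso [fold_decrease()] for the "x-fold decrease" convention.
#' @export
fold_change <- function(value_condition, value_control) {
  if (any(value_control == 0)) stop("control value must be non-zero")
  value_condition / value_control
}

#' @rdname fold_change
#' @details `fold_decrease()` reports the conventional "x-fold decrease",
#'   i.e. `value_control / value_condition`.
#' @export
fold_decrease <- function(value_condition, value_control) {
  if (any(value_condition == 0)) stop("condition value must be non-zero")
  value_control / value_condition
}

#' Assemble a per-condition rate table with ratios to control
#'
#' Collects fitted rate constants across a condition axis (Mn2+ uM, KCl mM or
#' protein uM) into one table with the derived K_d column and per-row ratios
#' to the control condition.
#'
#' @param results Named list of [rate_parameters()]; names are the condition
#'   values (coerced to numeric for sorting).
#' @param control_condition The condition value serving as control (must be
#'   present among the names).
#' @param axis Label for the condition column (default `"mn_uM"`).
#' @return A `titration_result` data.frame with columns `<axis>`, `k_on`,
#'   `k_off`, `K_d`, SEs, and `k_on_ratio`, `k_off_ratio`, `K_d_ratio`
#'   (condition/control).
#' @examples
#' res <- list(`0` = rate_parameters(400, 6.2), `50` = rate_parameters(65, 12))
#' build_condition_table(res, 0)
#' @export
build_condition_table <- function(results, control_condition, axis = "mn_uM") {
  stopifnot(is.list(results), length(results) >= 1L, !is.null(names(results)))
  if (!all(vapply(results, inherits, logical(1), "rate_parameters"))) {
    stop("`results` must be a named list of rate_parameters")
  }
  conds <- suppressWarnings(as.numeric(names(results)))
  if (any(is.na(conds))) conds <- seq_along(results)
  if (anyDuplicated(conds)) stop("condition values must be unique")
  ctrl_idx <- which(conds == as.numeric(control_condition))
  if (length(ctrl_idx) != 1L) {
    stop("control condition ", control_condition, " not present")
  }
  ord <- order(conds)
  ctrl <- results[[ctrl_idx]]
  tab <- data.frame(
    condition = conds[ord],
    k_on = vapply(results[ord], `[[`, numeric(1), "k_on"),
    k_on_se = vapply(results[ord], `[[`, numeric(1), "k_on_se"),
    k_off = vapply(results[ord], `[[`, numeric(1), "k_off"),
    k_off_se = vapply(results[ord], `[[`, numeric(1), "k_off_se"),
    K_d = vapply(results[ord], `[[`, numeric(1), "K_d")
  )
  names(tab)[1L] <- axis
  tab$k_on_ratio <- tab$k_on / ctrl$k_on
  tab$k_off_ratio <- tab$k_off / ctrl$k_off
  tab$K_d_ratio <- tab$K_d / ctrl$K_d
  rownames(tab) <- NULL
  attr(tab, "control") <- as.numeric(control_condition)
  class(tab) <- c("titration_result", "data.frame")
  tab
}

#' Compare the lifetimes of two complexes
#'
#' Evaluates [complex_lifetime()] for two RNA/protein pairs at their final
#' mixing concentrations and reports the ratio.
#'
#' @param rate1,rate2 [rate_parameters()] of the two complexes.
#' @param conc1,conc2 Lists with elements `rna` and `protein` (uM); `conc2`
#'   defaults to `conc1`.
#' @return List with `tau1`, `tau2` (s) and `ratio = tau1/tau2`.
#' @examples
#' compare_complex_lifetimes(rate_parameters(81, 4.8), rate_parameters(400, 6.2),
#'                           list(rna = 0.5, protein = 0.1),
#'                           list(rna = 0.05, protein = 1.0))
#' @export
compare_complex_lifetimes <- function(rate1, rate2, conc1, conc2 = conc1) {
  tau1 <- complex_lifetime(rate1, conc1$rna, conc1$protein)
  tau2 <- complex_lifetime(rate2, conc2$rna, conc2$protein)
  list(tau1 = tau1, tau2 = tau2, ratio = tau1 / tau2)
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run a full titration analysis pipeline
#'
#' End-to-end composition of the stopped-flow workflow: generate (or load)
#' traces, fit single- and double-exponential models to each, select the
#' model by F-test, regress the observed rates on the titrant concentration
#' per condition, and assemble the condition table. Deterministic given the
#' seed.
#'
#' @param config Named list (or path to a YAML/JSON file readable by
#'   [read_run_config()]) with fields:
#'   \describe{
#'     \item{preset}{Design preset name (see [preset_names()]); or}
#'     \item{trace_files}{Character vector of trace CSV paths.}
#'     \item{seed}{Master seed (default 1).}
#'     \item{noise_sd}{Noise override for generated traces (e.g. 0).}
#'     \item{n_shots}{Shots per trace override.}
#'     \item{alpha}{Model-selection level (default 0.05).}
#'     \item{mechanism}{Trace synthesis mechanism (default "relaxation").}
#'   }
#' @return A `titration_report`: list with `fits` (per-trace data.frame:
#'   condition, concentration, k_obs, SE, model choice, F, p), `rates` (named
#'   list of [rate_parameters()] per condition), `table`
#'   (a [build_condition_table()] result when several conditions are present)
#'   and the echoed configuration.
#' @examples
#' rep <- run_titration_analysis(list(preset = "fig2_frt", noise_sd = 0, seed = 1))
#' rep$rates[["0"]]$K_d # 15.5 nM
#' @export
run_titration_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha

  traces <- .stage("traces", {
    if (!is.null(config$preset)) {
      .log_info("generating series from preset `", config$preset,
                "` (seed ", seed, ")")
      generate_titration_series(config$preset, seed = seed,
                                noise_sd = config$noise_sd,
                                n_shots = config$n_shots,
                                mechanism = if (is.null(config$mechanism))
                                  "relaxation" else config$mechanism)
    } else if (!is.null(config$trace_files)) {
      .log_info("reading ", length(config$trace_files), " trace file(s)")
      lapply(config$trace_files, read_trace)
    } else {
      stop("config needs either `preset` or `trace_files`")
    }
  })
  if (length(traces) == 0L) stop("[traces] empty trace set")

  fits <- .stage("exponential_fit", {
    rows <- lapply(traces, function(tr) {
      f1 <- fit_single_exponential(tr)
      f2 <- fit_double_exponential(tr)
      sel <- select_model(f1, f2, alpha = alpha)
      cond <- tr$condition
      titrant <- if (identical(cond$varied, "rna")) cond$rna_uM
                 else if (identical(cond$varied, "protein")) cond$protein_uM
                 else if (tr$signal_kind == "anisotropy") cond$protein_uM
                 else cond$rna_uM
      data.frame(
        mn_uM = if (is.null(cond$mn_uM)) NA_real_ else cond$mn_uM,
        kcl_mM = if (is.null(cond$kcl_mM)) NA_real_ else cond$kcl_mM,
        conc = titrant,
        k_obs = unname(f1$coefficients[["k_obs"]]),
        k_obs_se = unname(f1$se[["k_obs"]]),
        model = sel$choice, F = sel$F, p = sel$p,
        converged = f1$converged
      )
    })
    do.call(rbind, rows)
  })

  cond_key <- ifelse(is.na(fits$mn_uM), "na", format(fits$mn_uM))
  rates <- .stage("kobs_regression", {
    out <- list()
    for (key in unique(cond_key)) {
      sub <- fits[cond_key == key, ]
      out[[format(sub$mn_uM[1L])]] <-
        fit_kobs_vs_concentration(sub$conc, sub$k_obs, sub$k_obs_se,
                                  label = paste0("mn_uM=", sub$mn_uM[1L]))
    }
    out
  })

  table <- NULL
  if (length(rates) > 1L) {
    table <- .stage("condition_table", {
      ctrl <- min(as.numeric(names(rates)))
      build_condition_table(rates, ctrl, axis = "mn_uM")
    })
  }

  structure(list(config = config, seed = seed, fits = fits, rates = rates,
                 table = table),
            class = "titration_report")
}

#' @export
print.titration_report <- function(x, ...) {
  cat("<titration_report>")
  if (!is.null(x$config$preset)) cat(" preset =", x$config$preset)
  cat(", seed =", x$seed, "\n")
  for (nm in names(x$rates)) {
    r <- x$rates[[nm]]
    cat(sprintf("  condition %s: k_on = %.4g +/- %.2g, k_off = %.3g +/- %.2g, K_d = %.4g nM\n",
                nm, r$k_on, r$k_on_se, r$k_off, r$k_off_se, r$K_d))
  }
  if (!is.null(x$table)) {
    cat("  condition table (ratios vs control", attr(x$table, "control"), "):\n")
    print(as.data.frame(lapply(x$table, function(col)
      if (is.numeric(col)) signif(col, 4) else col)))
  }
  invisible(x)
}

#' Run a dilution (relaxation) analysis pipeline
#'
#' Generates a 2-fold dilution relaxation trace for a pre-equilibrated
#' RNA/protein complex (optionally diluting into Mn2+-containing buffer so
#' the rate constants switch), fits the single-exponential relaxation, and
#' converts the fitted rate into a k_off estimate via [analyze_dilution()]
#' using the tabulated K_d as prior.
#'
#' @param config List with fields `pair` (default "FRT_IRP1"), `mn_post`
#'   (Mn2+ after dilution, uM; default 0 = buffer only), `seed`, `noise_sd`,
#'   `rna_uM`/`protein_uM` (post-dilution targets, defaults 0.05 and 1.0),
#'   `dilution_factor` (default 2).
#' @return List with the fitted `k_obs`, the `k_off` estimate, the prior K_d
#'   used, the trace, and the generating rate parameters.
#' @examples
#' res <- run_dilution_analysis(list(pair = "FRT_IRP1", noise_sd = 0, seed = 1))
#' res$k_off
#' @export
run_dilution_analysis <- function(config = list()) {
  pair <- if (is.null(config$pair)) "FRT_IRP1" else config$pair
  mn_post <- if (is.null(config$mn_post)) 0 else config$mn_post
  dil <- if (is.null(config$dilution_factor)) 2 else config$dilution_factor
  rna_post <- if (is.null(config$rna_uM)) 0.05 else config$rna_uM
  prot_post <- if (is.null(config$protein_uM)) 1.0 else config$protein_uM

  pre_rate <- rate_lookup(pair, 0)
  post_rate <- rate_lookup(pair, mn_post)
  model <- signal_model("anisotropy", noise_sd = config$noise_sd)
  pname <- sub("^.*_", "", .normalize_pair(pair))
  pre_sys <- binding_system(rna_post * dil,
                            binding_protein(pname, prot_post * dil, pre_rate))
  .log_info("dilution run: ", pair, ", post-mix Mn2+ ", mn_post, " uM")
  tr <- generate_dilution_trace(pre_sys, dilution_factor = dil,
                                post_rate = post_rate, model = model,
                                seed = config$seed)
  fit <- fit_single_exponential(tr)
  k_obs <- unname(fit$coefficients[["k_obs"]])
  k_off <- analyze_dilution(k_obs, prot_post, post_rate$K_d)
  list(pair = pair, mn_post = mn_post, k_obs = k_obs, k_off = k_off,
       K_d_prior = post_rate$K_d, post_rate = post_rate, trace = tr,
       fit = fit)
}
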