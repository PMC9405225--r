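#' Run one pipeline stage and collect a run report
#'
#' Thin dispatcher over the package's analysis functions, used by the
#' command-line script and convenient for scripted batch runs. Every stage
#' returns a `run_report`: the resolved inputs, the computed quantities
#' (each with a unit string), accumulated warnings (boundary optima, low
#' KE-ratio probes, saturation guards) and the package version.
#'
#' Stages and their `args`:
#' * `"fit-kl"`: `trace` (path to a time/intensity table) or an
#'   [intensity_trace()], `a` (specific area, 1/m), optional `I_max`,
#'   `I_min`.
#' * `"fit-correlation"`: `data` (path to a Re/Sc/G/Sh table or a
#'   [correlation_dataset()]).
#' * `"predict"`: `rpm`, `volume_mL`, one of `area_cm2` / `specific_area`,
#'   optional `temperature`, `constants` (a [sherwood_constants()]; default
#'   the packaged experimental set).
#' * `"max-density"`: `kLa` (1/s) or the `predict` args, plus `qO2`
#'   (mol/cell/s) and optional `temperature`.
#' * `"turbulence-post"`: `field` (path or [gradient_field()]), `nu`;
#'   optional `Cw`, `C_eps`, `Sc_t`, `rho`, `literal_shear`.
#' * `"simulate"`: `kind` in trace/flow/sherwood/surface plus the matching
#'   spec arguments; optional `out` path to write the generated table.
#'
#' @param config A [default_config()]-style `run_config`.
#' @param stage One of "fit-kl", "fit-correlation", "predict",
#'   "max-density", "turbulence-post", "simulate".
#' @param args Named list of stage arguments (see above).
#' @return A list of class `run_report`.
#' @export
#' @examples
#' syn <- gen_luminescence(trace_spec(seed = 2))
#' run_pipeline(default_config(), "fit-kl", list(trace = syn$trace, a = 16.4))
run_pipeline <- function(config = default_config(), stage, args = list()) {
  stage <- match.arg(stage, c("fit-kl", "fit-correlation", "predict",
                              "max-density", "turbulence-post", "simulate"))
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  quantities <- list()
  qty <- function(name, value, unit) {
    quantities[[name]] <<- list(value = value, unit = unit)
  }
  inputs <- list(stage = stage, seed = config$seed,
                 args = vapply(args, function(a) {
                   if (is.character(a)) a else class(a)[1]
                 }, character(1)))

  if (stage == "fit-kl") {
    trace <- args$trace
    if (is.character(trace)) {
      trace <- read_trace_table(trace, I_max = args$I_max, I_min = args$I_min)
    }
    fit <- fit_kla(trace, a = args$a,
                   fix_endpoints = isTRUE(config$fit$fix_endpoints),
                   bracket = as.numeric(config$fit$kla_bracket_s),
                   tol = config$fit$kla_tol)
    if (fit$boundary) note("kLa optimum sits on the search bracket")
    qty("kLa", fit$kLa, "1/s"); qty("kLa_h", fit$kLa_h, "1/h")
    qty("kL", fit$kL, "m/s"); qty("sse", fit$sse, "counts^2")
    result <- fit
  } else if (stage == "fit-correlation") {
    data <- args$data
    if (is.character(data)) {
      data <- correlation_dataset(read_table(data, required = c("Re", "Sc", "G", "Sh")))
    }
    fit <- fit_sherwood(data, beta = config$fit$beta,
                        objective = config$fit$objective)
    qty("k", fit$constants$k, "-"); qty("alpha", fit$constants$alpha, "-")
    qty("beta", fit$constants$beta, "-"); qty("gamma", fit$constants$gamma, "-")
    qty("mean_ape", fit$mae, "%"); qty("max_ape", fit$max_ape, "%")
    result <- fit
  } else if (stage == "predict") {
    op <- operating_point(rpm = args$rpm, volume_mL = args$volume_mL,
                          area_cm2 = args$area_cm2,
                          specific_area = args$specific_area,
                          diameter = config$geometry$wheel_diameter_m,
                          temperature = args$temperature %||% 21)
    constants <- args$constants %||% read_sherwood_constants()$experimental
    pred <- predict_kla(op, constants = constants)
    qty("Sh", pred$Sh, "-"); qty("kL", pred$kL, "m/s")
    qty("kLa", pred$kLa, "1/s"); qty("kLa_h", pred$kLa_h, "1/h")
    result <- pred
  } else if (stage == "max-density") {
    kLa <- args$kLa
    temperature <- args$temperature %||% 21
    if (is.null(kLa)) {
      sub <- run_pipeline(config, "predict", args)
      kLa <- sub$quantities$kLa$value
    }
    C_sat <- oxygen_saturation(temperature,
                               pO2 = config$properties$solubility$pO2_atm)
    X <- max_cell_density(kLa, C_sat, args$qO2)
    qty("C_sat", C_sat, "mol/m3")
    qty("X", X$X_per_m3, "cells/m3"); qty("X_mL", X$X_per_mL, "cells/mL")
    result <- X
  } else if (stage == "turbulence-post") {
    field <- args$field
    if (is.character(field)) field <- read_field_table(field, nu = args$nu)
    tb <- config$turbulence
    diag <- turbulence_diagnostics(field,
                                   Cw = args$Cw %||% tb$Cw,
                                   C_eps = args$C_eps %||% tb$C_eps,
                                   Sc_t = args$Sc_t %||% tb$Sc_t,
                                   rho = args$rho %||% 998,
                                   literal_shear = isTRUE(args$literal_shear %||%
                                                            tb$literal_shear))
    summ <- summarize_distributions(diag, eps_threshold = tb$eps_threshold_m2s3)
    if (summ$frac_eps_above > 0) {
      note(sprintf("%.3g%% of reactor volume above the eps threshold %.3g m2/s3",
                   100 * summ$frac_eps_above, tb$eps_threshold_m2s3))
    }
    qty("mean_eps", sum(diag$eps * diag$cell_volume) / sum(diag$cell_volume), "m2/s3")
    qty("median_eta", summ$quantiles$value[summ$quantiles$variable == "eta" &
                                             summ$quantiles$prob == 0.5], "m")
    qty("frac_eps_above", summ$frac_eps_above, "-")
    result <- list(diagnostics = diag, summary = summ)
  } else { # simulate
    kind <- match.arg(args$kind, c("trace", "flow", "sherwood", "surface"))
    set.seed(config$seed)
    if (kind == "trace") {
      syn <- gen_luminescence(args$spec %||% trace_spec(seed = config$seed))
      tab <- data.frame(time_s = syn$trace$times, intensity = syn$trace$I_recorded)
      qty("kLa_true", if (is.function(syn$kLa_true)) NA_real_ else syn$kLa_true, "1/s")
    } else if (kind == "flow") {
      syn <- gen_flow(args$spec %||% flow_spec(seed = config$seed))
      tab <- as.data.frame(syn$field)
      if (!is.null(syn$truth$mean_eps_res)) {
        qty("mean_eps_res_true", syn$truth$mean_eps_res, "m2/s3")
      }
    } else if (kind == "sherwood") {
      syn <- gen_sherwood_dataset(args$spec %||% sh_dataset_spec(seed = config$seed))
      tab <- as.data.frame(syn)
      qty("k_true", attr(syn, "constants_true")$k, "-")
    } else {
      syn <- do.call(gen_surface_profile,
                     args$spec %||% list(kL_true = 2.68e-5, C_sat = 0.26,
                                         C_bulk = 0, D_AB = 2.1e-9,
                                         seed = config$seed))
      tab <- syn$faces
      qty("kL_true", attr(syn, "kL_true"), "m/s")
    }
    if (!is.null(args$out)) write_table(tab, args$out)
    result <- syn
  }

  structure(list(stage = stage, inputs = inputs, quantities = quantities,
                 warnings = warnings_log,
                 version = as.character(utils::packageVersion("vwoxy")),
                 result = result),
            class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("vwoxy run report - stage:", x$stage, "(v", x$version, ")\n")
  for (nm in names(x$quantities)) {
    q <- x$quantities[[nm]]
    cat(sprintf("  %-16s %.6g %s\n", nm, q$value, q$unit))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Write a run report
#'
#' Human-readable text plus a machine-readable YAML block in one file.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  txt <- utils::capture.output(print(report))
  machine <- yaml::as.yaml(list(stage = report$stage,
                                quantities = report$quantities,
                                warnings = as.list(report$warnings),
                                version = report$version))
  writeLines(c(txt, "", "---", machine), path)
  invisible(path)
}
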