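#' Load a run configuration
#'
#' Builds a validated run configuration from (in increasing precedence) the
#' package defaults, a named preset, a YAML or JSON config file, and a list
#' of explicit overrides (typically parsed command-line flags).  Unknown
#' keys are rejected with the offending key named.  All numeric model
#' quantities are on the link scale.
#'
#' @param file Optional path to a YAML (or JSON) configuration file with
#'   top-level keys among `command`, `layout`, `model`, `alpha`, `target`,
#'   `solve_for`, `grid`, `reps`, `seed`, `format`, `verbose`, `preset`.
#' @param preset Optional preset name (see [swd_preset()]).
#' @param overrides Named list merged last, same schema as the file.
#' @return An object of class `swd_config`.
#' @export
swd_load_config <- function(file = NULL, preset = NULL, overrides = list()) {
  cfg <- list(command = "power", alpha = 0.05, target = 0.8,
              solve_for = "n_per_cell", format = "table", verbose = FALSE,
              seed = 1, reps = 500, layout = list(), model = list())
  if (!is.null(preset)) cfg <- merge_config(cfg, preset_config(preset))
  if (!is.null(file)) {
    if (!file.exists(file)) {
      stop("config file not found: ", file, call. = FALSE)
    }
    parsed <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(file)
    }
    if (!is.null(parsed$preset)) {
      cfg <- merge_config(cfg, preset_config(parsed$preset))
      parsed$preset <- NULL
    }
    cfg <- merge_config(cfg, parsed)
  }
  cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = "swd_config")
}

config_schema <- list(
  top = c("command", "layout", "model", "alpha", "target", "solve_for",
          "grid", "reps", "seed", "format", "verbose"),
  layout = c("sequences", "periods", "clusters_per_sequence", "subclusters",
             "n_per_cell", "schedule", "custom"),
  model = c("family", "link", "prevalence", "intercept", "time_effects",
            "time_slope", "time_scores", "effect", "sd_cluster",
            "sd_treatment", "sd_time", "sd_subcluster", "dispersion",
            "size")
)

merge_config <- function(base, extra) {
  for (k in names(extra)) {
    if (k %in% c("layout", "model") && is.list(extra[[k]])) {
      for (k2 in names(extra[[k]])) base[[k]][[k2]] <- extra[[k]][[k2]]
    } else {
      base[[k]] <- extra[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), config_schema$top)
  if (length(bad)) {
    stop("unknown configuration key: ", bad[1L], call. = FALSE)
  }
  for (sec in c("layout", "model")) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      stop("unknown configuration key: ", sec, ".", bad[1L], call. = FALSE)
    }
  }
  if (!cfg$command %in% c("power", "samplesize", "curve", "simulate")) {
    stop("unknown command: ", cfg$command, call. = FALSE)
  }
  if (!cfg$format %in% c("table", "csv", "json")) {
    stop("unknown output format: ", cfg$format, call. = FALSE)
  }
  if (!cfg$solve_for %in% c("n_per_cell", "clusters")) {
    stop("solve_for must be 'n_per_cell' or 'clusters'", call. = FALSE)
  }
  invisible(cfg)
}

preset_config <- function(name) {
  des <- swd_preset(name)
  lay <- des$layout
  mod <- des$model
  list(
    layout = list(sequences = lay$n_sequences, periods = lay$n_periods,
                  clusters_per_sequence = lay$clusters_per_sequence,
                  subclusters = lay$subclusters,
                  n_per_cell = lay$n_per_cell),
    model = Filter(Negate(is.null), list(
      family = mod$family$family, link = mod$family$link,
      prevalence = mod$prevalence,
      intercept = if (is.null(mod$prevalence)) mod$intercept,
      time_effects = mod$time_effects, time_slope = mod$time_slope,
      time_scores = mod$time_scores, effect = mod$effect,
      sd_cluster = mod$sds$cluster, sd_treatment = mod$sds$treatment,
      sd_time = mod$sds$time, sd_subcluster = mod$sds$subcluster))
  )
}

#' Materialise the layout and model described by a configuration
#'
#' @param cfg An `swd_config` from [swd_load_config()].
#' @return An [swd_design()].
#' @export
swd_config_design <- function(cfg) {
  L <- cfg$layout
  for (k in c("sequences", "periods")) {
    if (is.null(L[[k]])) {
      stop("configuration is missing layout.", k, call. = FALSE)
    }
  }
  M <- cfg$model
  if (is.null(M$effect)) {
    stop("configuration is missing model.effect", call. = FALSE)
  }
  layout <- swd_layout(L$sequences, L$periods,
                       L$clusters_per_sequence %||% 1,
                       L$subclusters %||% 1, L$n_per_cell %||% 1,
                       schedule = if (!is.null(L$schedule))
                         matrix(unlist(L$schedule), nrow = L$sequences,
                                byrow = TRUE),
                       custom = isTRUE(L$custom))
  model <- swd_model(M$family %||% "bernoulli", M$link,
                     prevalence = M$prevalence, intercept = M$intercept,
                     time_effects = unlist(M$time_effects),
                     time_slope = M$time_slope,
                     time_scores = unlist(M$time_scores),
                     effect = M$effect,
                     sd_cluster = M$sd_cluster,
                     sd_treatment = M$sd_treatment,
                     sd_time = M$sd_time, sd_subcluster = M$sd_subcluster,
                     dispersion = M$dispersion, size = M$size %||% 1)
  swd_design(layout, model)
}

#' Serialize a result object
#'
#' Renders a power, sample-size, curve, or Monte-Carlo result as a plain
#' table (printed), CSV text, or JSON text with a deterministic field
#' order.
#'
#' @param x An `swd_power`, `swd_samplesize`, `swd_power_curve`, or
#'   `swd_mc` object (or an `swd_config` for round-tripping).
#' @param format `"table"`, `"csv"`, or `"json"`.
#' @return For `"table"`, the object invisibly (after printing); otherwise
#'   a character string.
#' @export
swd_emit <- function(x, format = c("table", "csv", "json")) {
  format <- match.arg(format)
  if (format == "table") {
    print(x)
    return(invisible(x))
  }
  payload <- result_payload(x)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  df <- if (is.data.frame(payload)) payload else
    as.data.frame(payload[!vapply(payload, is.list, logical(1))])
  txt <- utils::capture.output(utils::write.csv(df, row.names = FALSE))
  paste(txt, collapse = "\n")
}

result_payload <- function(x) {
  if (inherits(x, "swd_power")) {
    list(power = x$power, effect = x$beta_p, v0 = x$v0, va = x$va,
         alpha = x$alpha,
         design = list(sequences = x$layout$n_sequences,
                       periods = x$layout$n_periods,
                       clusters = total_clusters(x$layout),
                       subclusters = x$layout$subclusters,
                       n_per_cell = x$layout$n_per_cell))
  } else if (inherits(x, "swd_samplesize")) {
    list(variable = x$variable, solution = x$solution,
         achieved_power = x$achieved, target = x$target, alpha = x$alpha,
         total_clusters = x$total_clusters %||% total_clusters(x$layout),
         per_cluster_period = x$per_cluster_period %||%
           (x$layout$n_per_cell * x$layout$subclusters))
  } else if (inherits(x, "swd_power_curve")) {
    data.frame(variable = attr(x, "variable"), value = x$value,
               power = x$power)
  } else if (inherits(x, "swd_mc")) {
    list(reps = x$reps, n_converged = x$n_converged,
         n_boundary = x$n_boundary, n_used = x$n_used,
         empirical_var = x$empirical_var,
         empirical_power = x$empirical_power,
         analytic_var = x$analytic_var, analytic_power = x$analytic_power,
         ratio_variance = x$ratio_variance, ratio_power = x$ratio_power,
         unreliable = x$unreliable)
  } else if (inherits(x, "swd_config")) {
    unclass(x)
  } else {
    stop("no serializer for objects of class ", class(x)[1L], call. = FALSE)
  }
}

#' Write a configuration to YAML text
#'
#' Inverse of [swd_load_config()]: `swd_load_config(file)` on the written
#' text reproduces the configuration.
#'
#' @param cfg An `swd_config`.
#' @return A YAML character string.
#' @export
swd_emit_config <- function(cfg) {
  yaml::as.yaml(unclass(cfg))
}
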