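#' Built-in trial and simulation presets
#'
#' Parameterizations of the two worked applications and the simulation grid,
#' all on the log-odds scale.
#'
#' \describe{
#'   \item{`"ept"`}{Expedited partner therapy roll-out: 4 sequences over 5
#'     periods, 6 counties per sequence, binary chlamydia outcome with
#'     baseline prevalence 0.08, categorical period effects
#'     (-0.008, -0.08, -0.17, -0.11), intervention log odds ratio -0.3,
#'     random cluster intercept SD 0.2 and iid random period effects SD 0.12
#'     (one indicator per period).}
#'   \item{`"lire"`}{Spine-imaging report benchmark-prevalence trial: 5
#'     sequences over 6 periods, 20 clinics per sequence, 35 primary care
#'     providers (subclusters) per clinic, binary opioid-prescription
#'     outcome; the fitted-model intercept corresponds to a prevalence of
#'     roughly 0.19, time is linear in the period number (scores `1:6`,
#'     slope -0.124), intervention log odds ratio -0.055, random-effect SDs:
#'     clinic intercept 0.011, clinic-level treatment 0.0054, provider
#'     intercept 0.0015.}
#'   \item{`"sim_model1"`}{Simulation-grid design (3 sequences, 4 periods)
#'     with random cluster intercept and random cluster-level treatment
#'     effect.}
#'   \item{`"sim_model2"`}{Same design with random cluster intercept and iid
#'     random period effects.}
#' }
#'
#' For the simulation presets the defaults are the moderate point of the
#' grid (8 clusters per sequence, 100 individuals per cluster-period,
#' prevalence 0.12, effect 0.2, cluster SD 0.05, treatment/time SD 0.05);
#' the other grid points are reached through the arguments.
#'
#' @param name Preset name.
#' @param clusters_per_sequence,n_per_cell,prevalence,effect,sd_treatment,sd_time
#'   Overrides for the simulation presets (ignored with a warning for the
#'   trial presets).
#' @return An [swd_design()].
#' @examples
#' swd_power(swd_preset("ept"))
#' @export
swd_preset <- function(name = c("ept", "lire", "sim_model1", "sim_model2"),
                       clusters_per_sequence = NULL, n_per_cell = NULL,
                       prevalence = NULL, effect = NULL,
                       sd_treatment = NULL, sd_time = NULL) {
  name <- match.arg(name)
  sim_args <- list(clusters_per_sequence = clusters_per_sequence,
                   n_per_cell = n_per_cell, prevalence = prevalence,
                   effect = effect, sd_treatment = sd_treatment,
                   sd_time = sd_time)
  if (name %in% c("ept", "lire") &&
      any(!vapply(sim_args, is.null, logical(1)))) {
    warning("grid arguments are only used by the simulation presets; ",
            "modify the returned design instead", call. = FALSE)
  }
  switch(name,
    ept = swd_design(
      swd_layout(4, 5, clusters_per_sequence = 6, n_per_cell = 140),
      swd_model("bernoulli", prevalence = 0.08,
                time_effects = c(-0.008, -0.08, -0.17, -0.11),
                effect = -0.3, sd_cluster = 0.2, sd_time = 0.12)
    ),
    lire = swd_design(
      swd_layout(5, 6, clusters_per_sequence = 20, subclusters = 35,
                 n_per_cell = 4),
      swd_model("bernoulli", prevalence = 0.19,
                time_slope = -0.124, time_scores = 1:6,
                effect = -0.055, sd_cluster = 0.011,
                sd_treatment = 0.0054, sd_subcluster = 0.0015)
    ),
    sim_model1 = swd_design(
      swd_layout(3, 4,
                 clusters_per_sequence = clusters_per_sequence %||% 8,
                 n_per_cell = n_per_cell %||% 100),
      swd_model("bernoulli", prevalence = prevalence %||% 0.12,
                time_effects = c(0.1, 0.1, 0.1),
                effect = effect %||% 0.2,
                sd_cluster = 0.05,
                sd_treatment = sd_treatment %||% 0.05)
    ),
    sim_model2 = swd_design(
      swd_layout(3, 4,
                 clusters_per_sequence = clusters_per_sequence %||% 8,
                 n_per_cell = n_per_cell %||% 100),
      swd_model("bernoulli", prevalence = prevalence %||% 0.12,
                time_effects = c(0.1, 0.1, 0.1),
                effect = effect %||% 0.2,
                sd_cluster = 0.05,
                sd_time = sd_time %||% 0.05)
    )
  )
}
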