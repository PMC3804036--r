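#' Per-location cohort parameters
#'
#' Default per-location means used by [simulate_cohort()]: optimal
#' depths follow the cohort means reported for the three radial
#' palpation locations (Chon 3.76, Gwan 3.60, Cheok 5.01 mm), and the
#' stiffness coefficients are ordered so that at a given displacement
#' the contact pressure is highest at Gwan and lowest at Cheok, with
#' the linear/quadratic mix giving Gwan the smallest effective power-law
#' exponent and Chon the largest.
#'
#' @return named list of per-location parameter lists
#'   (`depth_mean_mm`, `stiffness_linear`, `stiffness_quad`).
#' @export
default_location_params <- function() {
  list(
    Chon  = list(depth_mean_mm = 3.76, stiffness_linear = 2,  stiffness_quad = 8),
    Gwan  = list(depth_mean_mm = 3.60, stiffness_linear = 20, stiffness_quad = 8),
    Cheok = list(depth_mean_mm = 5.01, stiffness_linear = 4,  stiffness_quad = 6)
  )
}

#' Simulate a measurement cohort
#'
#' Emulates a repeated-measures study: `n_subjects` subjects measured at
#' each location `n_repeats` times. Per subject and location the true
#' optimal depth is drawn from a normal distribution around the
#' location mean (between-subject SD `subject_depth_sd_mm`); each repeat
#' adds independent jitter (`repeat_jitter_sd_mm`) emulating probe
#' repositioning. Everything is driven by `seed`; per-recording seeds
#' are drawn from the master stream so the whole cohort is reproducible.
#'
#' With `signals = FALSE` only the parameter draws and ground-truth
#' index table are produced (no waveform synthesis) -- useful for
#' studying the cohort statistics at scale.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param locations character vector of location labels.
#' @param n_repeats repeated measures per subject-location.
#' @param seed integer master seed.
#' @param location_params per-location parameter list; see
#'   [default_location_params()]. Unknown labels fall back to the
#'   default config's depth and stiffness.
#' @param subject_depth_sd_mm between-subject SD of the optimal depth.
#' @param repeat_jitter_sd_mm repeat-to-repeat SD of the optimal depth.
#' @param signals logical; synthesise the recordings (`TRUE`) or only
#'   draw parameters (`FALSE`).
#' @param base_config [simulation_config()] supplying all remaining
#'   parameters.
#' @return An object of class `pulse_cohort`: list with
#'   \describe{
#'     \item{records}{list of records, each with `subject_id`,
#'       `location`, `rep`, `config`, and (if `signals`) `recording`,
#'       `truth`.}
#'     \item{truth_table}{data frame `subject_id`, `location`, `rep`,
#'       `true_pdi_mm`.}
#'   }
#' @examples
#' coh <- simulate_cohort(n_subjects = 3, n_repeats = 2, seed = 1,
#'                        signals = FALSE)
#' nrow(coh$truth_table)  # 3 subjects x 3 locations x 2 repeats
#' @export
simulate_cohort <- function(n_subjects = 18,
                            locations = c("Chon", "Gwan", "Cheok"),
                            n_repeats = 2,
                            seed = 1L,
                            location_params = default_location_params(),
                            subject_depth_sd_mm = 0.6,
                            repeat_jitter_sd_mm = 0.2,
                            signals = TRUE,
                            base_config = simulation_config()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(seed)
  records <- list()
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (loc in locations) {
      lp <- location_params[[loc]]
      if (is.null(lp)) {
        lp <- list(depth_mean_mm = base_config$optimal_depth_mm,
                   stiffness_linear = base_config$stiffness_linear,
                   stiffness_quad = base_config$stiffness_quad)
      }
      depth_subj <- rnorm(1, lp$depth_mean_mm, subject_depth_sd_mm)
      depth_subj <- min(max(depth_subj, 1), 6.5)
      for (r in seq_len(n_repeats)) {
        depth_rep <- depth_subj +
          if (repeat_jitter_sd_mm > 0) rnorm(1, 0, repeat_jitter_sd_mm) else 0
        depth_rep <- min(max(depth_rep, 1), 6.5)
        rec_seed <- sample.int(.Machine$integer.max - 1L, 1)
        cfg <- base_config
        cfg$optimal_depth_mm <- depth_rep
        cfg$stiffness_linear <- lp$stiffness_linear
        cfg$stiffness_quad <- lp$stiffness_quad
        cfg$seed <- rec_seed
        validate_sim_config(cfg)
        rec <- list(subject_id = s, location = loc, rep = r, config = cfg)
        if (signals) {
          sim <- withCallingHandlers(
            simulate_cetm(cfg),
            warning = function(w) {
              if (grepl("envelope truncated", conditionMessage(w))) {
                invokeRestart("muffleWarning")
              }
            }
          )
          rec$recording <- sim$recording
          rec$truth <- sim$truth
        }
        records[[length(records) + 1]] <- rec
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = s, location = loc, rep = r, true_pdi_mm = depth_rep
        )
      }
    }
  }
  structure(
    list(records = records, truth_table = do.call(rbind, rows)),
    class = "pulse_cohort"
  )
}

#' @export
print.pulse_cohort <- function(x, ...) {
  tt <- x$truth_table
  cat(sprintf("Simulated cohort: %d recordings (%d subjects x %d locations x %d repeats)%s\n",
              nrow(tt), length(unique(tt$subject_id)),
              length(unique(tt$location)), max(tt$rep),
              if (is.null(x$records[[1]]$recording)) " [parameters only]" else ""))
  invisible(x)
}

#' Run the assessment pipeline over a simulated cohort
#'
#' Applies [assess_depth()] to every recording of a cohort and collects
#' the indices into the standard cohort table.
#'
#' @param cohort a `pulse_cohort` simulated with `signals = TRUE`.
#' @param ... passed to [assess_depth()].
#' @return data frame with columns `subject_id`, `location`, `rep`,
#'   `ocp_mmHg`, `cfs_ocp`, `cfs_pad`, `pdi_mm`, `true_pdi_mm`.
#' @export
cohort_table <- function(cohort, ...) {
  stopifnot(inherits(cohort, "pulse_cohort"))
  rows <- lapply(cohort$records, function(rec) {
    if (is.null(rec$recording)) {
      stop("cohort was simulated with signals = FALSE; no recordings to assess")
    }
    fit <- assess_depth(rec$recording, ...)
    co <- coef(fit)
    data.frame(subject_id = rec$subject_id, location = rec$location,
               rep = rec$rep, ocp_mmHg = co[["ocp_mmHg"]],
               cfs_ocp = co[["cfs_ocp"]], cfs_pad = co[["cfs_pad"]],
               pdi_mm = co[["pdi_mm"]],
               true_pdi_mm = rec$truth$true_pdi_mm)
  })
  do.call(rbind, rows)
}
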