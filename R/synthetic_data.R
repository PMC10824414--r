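#' Specification of a synthetic study with known ground truth
#'
#' Bundles everything needed to simulate a complete study: the true shape
#' trajectory, true division thresholds, true compartment-model parameters,
#' the experimental design (which ages, how many mice, how many wells), and
#' the observation-noise settings.
#'
#' @param trajectory True [shape_trajectory()].
#' @param thresholds True [division_thresholds()].
#' @param ode_params True [model_params()].
#' @param ages_exvivo Ages (weeks) at which wells are cultured.
#' @param mice_per_age Integer vector (recycled) of mice per ex vivo age.
#' @param wells_per_mouse Wells cultured per mouse.
#' @param ages_invivo Ages at which bones are censused.
#' @param mice_per_age_invivo Mice per census age.
#' @param census_sigma Standard deviation of the multiplicative lognormal
#'   observation noise on counts (0 for noise-free data).
#' @param well_cells If positive, each well proportion is quantized as
#'   `k / well_cells` with `k ~ Binomial(well_cells, x)`, mimicking counting
#'   finitely many cells per well and producing occasional exact 0/1 wells;
#'   0 (default) records the beta draw itself.
#' @param bone_scale Named multipliers applied to both compartments per bone.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(trajectory, thresholds, ode_params,
                           ages_exvivo, mice_per_age = 3L,
                           wells_per_mouse = 60L,
                           ages_invivo, mice_per_age_invivo = 3L,
                           census_sigma = 0.05, well_cells = 0L,
                           bone_scale = c(femur = 1, pelvis = 1.4,
                                          sternum = 0.6),
                           seed = 1L) {
  stopifnot(inherits(trajectory, "shape_trajectory"),
            inherits(thresholds, "division_thresholds"),
            inherits(ode_params, "model_params"),
            census_sigma >= 0, wells_per_mouse >= 1,
            mice_per_age_invivo >= 1, well_cells >= 0,
            all(ages_exvivo >= trajectory$t0),
            all(ages_invivo >= ode_params$t0))
  mice_per_age <- rep_len(as.integer(mice_per_age), length(ages_exvivo))
  if (any(mice_per_age < 1)) stop("mice_per_age must be >= 1")
  structure(list(trajectory = trajectory, thresholds = thresholds,
                 ode_params = ode_params,
                 ages_exvivo = ages_exvivo, mice_per_age = mice_per_age,
                 wells_per_mouse = as.integer(wells_per_mouse),
                 ages_invivo = ages_invivo,
                 mice_per_age_invivo = as.integer(mice_per_age_invivo),
                 census_sigma = census_sigma,
                 well_cells = as.integer(well_cells),
                 bone_scale = bone_scale, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Default synthetic study mirroring the published design
#'
#' Returns a [generator_spec()] with the study layout used throughout the
#' package's validation: ex vivo wells at ages 4, 5, 6, 7, 8, 9, 15, 20, 22,
#' 48 and 52 weeks with the per-age mouse counts of the original experiments
#' (3, 3, 5, 3, 3, 3, 1, 4, 1, 3, 1) and 60 wells per mouse; an in vivo
#' census at 6, 15, 20, 25, 40, 52 and 72 weeks with 3 mice per age; true
#' thresholds (0.3, 0.8); true kinetics r = 0.172 per week, d = 0.1 per week,
#' S0 = 5140 and P0 = 1.01e5 at t0 = 4 weeks. The true shape trajectory is
#' calibrated so that the implied division-mode fractions equal the reference
#' values 52.4\% S-S / 24.9\% P-P at 10 weeks and 41.6\% S-S / 41.5\% P-P at
#' 70 weeks.
#'
#' @param seed Integer seed stored in the spec.
#' @param census_sigma Lognormal observation noise (default 0.05).
#' @return A `generator_spec`.
#' @export
paper_like_spec <- function(seed = 1L, census_sigma = 0.05) {
  traj <- shape_trajectory(
    t0 = 4,
    alpha = c(b1 = 0.901007960331, a1 = 0.3,
              b2 = 0.278465278613, a2 = 0.005),
    beta = c(b1 = 0.0635015380305, a1 = 0.3,
             b2 = 0.2111045824387, a2 = 0.002))
  generator_spec(
    trajectory = traj,
    thresholds = division_thresholds(0.3, 0.8),
    ode_params = model_params(r = 0.172, d = 0.1, S0 = 5.14e3, P0 = 1.01e5,
                              t0 = 4),
    ages_exvivo = c(4, 5, 6, 7, 8, 9, 15, 20, 22, 48, 52),
    mice_per_age = c(3, 3, 5, 3, 3, 3, 1, 4, 1, 3, 1),
    wells_per_mouse = 60L,
    ages_invivo = c(6, 15, 20, 25, 40, 52, 72),
    mice_per_age_invivo = 3L,
    census_sigma = census_sigma,
    seed = seed)
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate per-well proportions from the true age-dependent distribution
#'
#' For each ex vivo age, mouse and well, draws the well proportion from
#' `Beta(alpha(t), beta(t))` under the spec's true trajectory. With
#' `well_cells > 0` the draw is additionally quantized through a binomial
#' count, which produces occasional exact-0/1 wells and exercises the
#' boundary clamping of the estimation stage.
#'
#' @param spec A [generator_spec()].
#' @return A well-proportion data frame (see [read_well_proportions()]).
#' @export
generate_wells <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (k in seq_along(spec$ages_exvivo)) {
      t <- spec$ages_exvivo[k]
      ab <- eval_trajectory(spec$trajectory, t)
      for (m in seq_len(spec$mice_per_age[k])) {
        x <- stats::rbeta(spec$wells_per_mouse, ab$alpha, ab$beta)
        if (spec$well_cells > 0L)
          x <- stats::rbinom(length(x), spec$well_cells, x) / spec$well_cells
        rows[[length(rows) + 1L]] <- data.frame(
          age_weeks = t,
          mouse_id = sprintf("age%g_m%d", t, m),
          well_id = sprintf("w%02d", seq_len(spec$wells_per_mouse)),
          proportion = x)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_well_proportions(out)
    out
  })
}

#' Simulate a census time course from the true compartment model
#'
#' Integrates the compartment model under the spec's true trajectory,
#' thresholds and kinetic parameters, scales the curves by the per-bone
#' multipliers, and observes each (age, mouse, bone) with independent
#' multiplicative lognormal noise. Observations violating the subset
#' constraint `hsc <= ksl` (possible only under extreme noise, since S is a
#' small fraction of S+P) are redrawn.
#'
#' @param spec A [generator_spec()].
#' @return A census data frame (see [read_census()]).
#' @export
generate_census <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  fr <- make_fraction_fun(spec$trajectory, spec$thresholds)
  ages <- sort(unique(c(spec$ode_params$t0, spec$ages_invivo)))
  base <- integrate_model(spec$ode_params, fr, ages, method = "grid")
  base <- base[match(spec$ages_invivo, base$age_weeks), ]
  with_seed(spec$seed + 1L, {
    rows <- list()
    for (bone in names(spec$bone_scale)) {
      sc <- spec$bone_scale[[bone]]
      for (k in seq_along(spec$ages_invivo)) {
        for (m in seq_len(spec$mice_per_age_invivo)) {
          repeat {
            hsc <- sc * base$S[k] * exp(stats::rnorm(1, 0, spec$census_sigma))
            ksl <- sc * base$KSL[k] *
              exp(stats::rnorm(1, 0, spec$census_sigma))
            if (hsc <= ksl) break
          }
          rows[[length(rows) + 1L]] <- data.frame(
            age_weeks = spec$ages_invivo[k], bone = bone,
            mouse_id = sprintf("age%g_m%d", spec$ages_invivo[k], m),
            hsc_count = hsc, ksl_count = ksl)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_census(out)
    out
  })
}
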