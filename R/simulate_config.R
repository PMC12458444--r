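#' Default per-trait generative parameters for the phenotype-table simulator
#'
#' Each trait gets an intercept (female STD fly at 25 degrees C), additive
#' genotype contrasts against STD, a male-sex effect, a linear temperature
#' slope (per degree C, centered at 25), optional genotype-by-sex and
#' genotype-by-temperature interaction contrasts, a block random-intercept
#' SD `sigma_b`, and a residual SD `sigma_e`. Default effect directions
#' follow the biology being emulated: inverted homozygotes sleep less and
#' sit farther from food, males sleep more and startle harder, flies sleep
#' less and move faster when warm.
#'
#' @return Named list of per-trait parameter lists.
#' @export
default_trait_params <- function() {
  tp <- function(intercept, het, inv, sex_m, temp_slope,
                 gs_het = 0, gs_inv = 0, gt_het = 0, gt_inv = 0,
                 sigma_b, sigma_e, lower = -Inf, upper = Inf) {
    list(intercept = intercept,
         geno = c(HET = het, INV = inv),
         sex_m = sex_m, temp_slope = temp_slope,
         geno_sex = c(HET = gs_het, INV = gs_inv),
         geno_temp = c(HET = gt_het, INV = gt_inv),
         sigma_b = sigma_b, sigma_e = sigma_e,
         lower = lower, upper = upper)
  }
  list(
    sleep_min_per_hour = tp(30, -2.5, -5, 3, -1.2,
                            sigma_b = 2, sigma_e = 10, lower = 0, upper = 60),
    base_speed_mm_s = tp(0.6, 0, 0, 0, 0.03,
                         sigma_b = 0.05, sigma_e = 0.25, lower = 0),
    startle_duration_s = tp(60, 10, 20, 0, -2,
                            sigma_b = 5, sigma_e = 30, lower = 0),
    startle_magnitude_mm_s = tp(1.5, 0, 0, 0.3, 0.02,
                                sigma_b = 0.1, sigma_e = 0.8, lower = 0),
    prop_near_food = tp(0.40, -0.025, -0.05, 0, -0.008,
                        sigma_b = 0.02, sigma_e = 0.12, lower = 0, upper = 1),
    prop_far_food = tp(0.15, 0.025, 0.05, -0.02, 0,
                       sigma_b = 0.02, sigma_e = 0.10, lower = 0, upper = 1)
  )
}

#' Configure the cohort simulator
#'
#' Collects every generative parameter: the factorial design (genotype x
#' sex x temperature x block at `n_per_cell` flies per cell), the assay
#' geometry, the alternating sleep/wake renewal model, the movement
#' process, startle kinetics, block heterogeneity, and the per-trait
#' parameters used by [simulate_phenotype_table()].
#'
#' The trajectory-level model: a fly alternates exponential sleep bouts
#' (mean `mu_sleep_s`) and wake bouts (mean `mu_wake_s`). Asleep, position
#' is frozen. Awake, each step takes its direction from a mean-reverting
#' (rate `kappa_per_s` toward preferred position `p_star_mm`, noise
#' `sigma_x_mm`) increment and its magnitude from the wake bout's
#' log-normal speed draw, so derived speed equals the draw. Each stimulus
#' wakes the fly and adds a speed excursion `A_mm_s * exp(-t/tau_s)` that
#' keeps the fly awake until it decays below one step-noise unit.
#' Multipliers encode genotype/sex/temperature dependence of cell-level
#' parameters; `sigma_b_sleep_s` is the SD of an additive per-block shift
#' on the mean sleep-bout duration.
#'
#' @param seed Master seed; per-fly substreams are derived from it by a
#'   fixed counter scheme (see [simulate_cohort()]).
#' @param n_per_cell Flies per genotype x sex x temperature x block cell.
#' @param design An [assay_design()].
#' @param temperatures,blocks Levels of the environmental factors.
#' @param mu_sleep_s,mu_wake_s Mean sleep/wake bout durations (s) for the
#'   reference cell (female STD at 25 degrees C).
#' @param sleep_geno_mult,sleep_sex_mult Multipliers on `mu_sleep_s`.
#' @param sleep_temp_coef Log-linear temperature coefficient on
#'   `mu_sleep_s` (per degree C, centered at 25; negative = less sleep when
#'   warm).
#' @param v_meanlog,v_sdlog Log-normal wake-speed parameters (mm/s scale).
#' @param speed_temp_coef Log-linear temperature coefficient on wake speed.
#' @param kappa_per_s Mean-reversion rate toward `p_star_mm`.
#' @param p_star_mm Named vector of preferred positions per genotype (mm;
#'   0 = food end).
#' @param sigma_x_mm Step noise SD (mm) of the direction process.
#' @param A_mm_s Startle excursion amplitude (mm/s).
#' @param A_sex_mult Multiplier on `A_mm_s` by sex.
#' @param tau_s Startle decay time constant (s).
#' @param tau_geno_mult Multiplier on `tau_s` per genotype.
#' @param sigma_b_sleep_s SD (s) of the additive block shift on `mu_sleep_s`.
#' @param trait_params Per-trait generative parameters for
#'   [simulate_phenotype_table()]; see [default_trait_params()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_per_cell = 11L,
                              design = assay_design(),
                              temperatures = TEMPERATURE_LEVELS,
                              blocks = paste0("B", 1:3),
                              mu_sleep_s = 900,
                              mu_wake_s = 600,
                              sleep_geno_mult = c(STD = 1, HET = 0.85, INV = 0.7),
                              sleep_sex_mult = c(F = 1, M = 1.15),
                              sleep_temp_coef = -0.03,
                              v_meanlog = log(0.8),
                              v_sdlog = 0.4,
                              speed_temp_coef = 0.02,
                              kappa_per_s = 0.02,
                              p_star_mm = c(STD = 8, HET = 12, INV = 20),
                              sigma_x_mm = 0.5,
                              A_mm_s = 4,
                              A_sex_mult = c(F = 1, M = 1.2),
                              tau_s = 30,
                              tau_geno_mult = c(STD = 1, HET = 1.15, INV = 1.3),
                              sigma_b_sleep_s = 60,
                              trait_params = default_trait_params()) {
  stopifnot(inherits(design, "assay_design"))
  if (n_per_cell < 1L) stop("n_per_cell must be >= 1")
  if (mu_sleep_s <= 0 || mu_wake_s <= 0)
    stop("mean bout durations must be positive")
  if (tau_s <= 0 && A_mm_s > 0)
    stop("tau_s must be positive when the startle amplitude is nonzero")
  if (sigma_x_mm < 0 || kappa_per_s < 0 || sigma_b_sleep_s < 0 ||
      A_mm_s < 0 || v_sdlog < 0)
    stop("rates and SDs must be non-negative")
  L <- design$tube_length_mm
  if (any(p_star_mm < 0 | p_star_mm > L))
    stop("preferred positions must lie within [0, tube length]")
  stopifnot(all(GENOTYPE_LEVELS %in% names(p_star_mm)),
            all(GENOTYPE_LEVELS %in% names(sleep_geno_mult)),
            all(GENOTYPE_LEVELS %in% names(tau_geno_mult)),
            all(SEX_LEVELS %in% names(sleep_sex_mult)),
            all(SEX_LEVELS %in% names(A_sex_mult)))
  for (tn in names(trait_params)) {
    p <- trait_params[[tn]]
    if (p$sigma_e < 0) stop(tn, ": sigma_e must be non-negative")
    if (p$sigma_b < 0) stop(tn, ": sigma_b must be non-negative")
  }
  structure(
    list(seed = as.integer(seed), n_per_cell = as.integer(n_per_cell),
         design = design, temperatures = temperatures, blocks = blocks,
         mu_sleep_s = mu_sleep_s, mu_wake_s = mu_wake_s,
         sleep_geno_mult = sleep_geno_mult, sleep_sex_mult = sleep_sex_mult,
         sleep_temp_coef = sleep_temp_coef,
         v_meanlog = v_meanlog, v_sdlog = v_sdlog,
         speed_temp_coef = speed_temp_coef,
         kappa_per_s = kappa_per_s, p_star_mm = p_star_mm,
         sigma_x_mm = sigma_x_mm,
         A_mm_s = A_mm_s, A_sex_mult = A_sex_mult,
         tau_s = tau_s, tau_geno_mult = tau_geno_mult,
         sigma_b_sleep_s = sigma_b_sleep_s,
         trait_params = trait_params),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  n_cells <- 3L * 2L * length(x$temperatures) * length(x$blocks)
  cat(sprintf("Simulation config: seed %d, %d flies/cell x %d cells = %d flies\n",
              x$seed, x$n_per_cell, n_cells, x$n_per_cell * n_cells))
  cat(sprintf("  sleep/wake means %g/%g s; startle A=%g mm/s tau=%g s\n",
              x$mu_sleep_s, x$mu_wake_s, x$A_mm_s, x$tau_s))
  invisible(x)
}

# Resolve cell-level generative parameters for one fly's metadata,
# including the block shift on mean sleep-bout duration.
cell_params <- function(config, genotype, sex, temperature_c,
                        block_shift_s = 0) {
  dT <- temperature_c - 25
  mu_sleep <- config$mu_sleep_s *
    config$sleep_geno_mult[[genotype]] *
    config$sleep_sex_mult[[sex]] *
    exp(config$sleep_temp_coef * dT) + block_shift_s
  mu_sleep <- max(mu_sleep, 1)   # keep the renewal process well defined
  list(
    mu_sleep_s = mu_sleep,
    mu_wake_s = config$mu_wake_s,
    v_meanlog = config$v_meanlog + config$speed_temp_coef * dT,
    v_sdlog = config$v_sdlog,
    kappa_per_s = config$kappa_per_s,
    p_star_mm = config$p_star_mm[[genotype]],
    sigma_x_mm = config$sigma_x_mm,
    A_mm_s = config$A_mm_s * config$A_sex_mult[[sex]],
    tau_s = config$tau_s * config$tau_geno_mult[[genotype]]
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [simulation_config()] arguments;
#' design fields go under a `design:` block and per-trait parameters under
#' `trait_params:`. Missing fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$design)) {
    args$design <- do.call(assay_design, y$design)
    y$design <- NULL
  }
  if (!is.null(y$trait_params)) {
    tp <- default_trait_params()
    for (tn in names(y$trait_params)) {
      upd <- y$trait_params[[tn]]
      for (k in names(upd)) {
        v <- upd[[k]]
        tp[[tn]][[k]] <- if (k %in% c("geno", "geno_sex", "geno_temp"))
          unlist(v) else v
      }
    }
    args$trait_params <- tp
    y$trait_params <- NULL
  }
  for (k in c("p_star_mm", "sleep_geno_mult", "sleep_sex_mult",
              "tau_geno_mult", "A_sex_mult"))
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  do.call(simulation_config, c(args, y))
}
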