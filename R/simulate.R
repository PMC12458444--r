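#' Simulate one fly's trajectory
#'
#' Generates a 1-D tube trajectory from an alternating sleep/wake renewal
#' process. Sojourn times are exponential with cell-specific means (the
#' process is sampled on the recording grid through its memoryless
#' per-step transition probabilities, so observed bout durations remain
#' exponential). While asleep the position is frozen. While awake, each
#' step's direction comes from the sign of a mean-reverting increment
#' `kappa * (p_star - x) * dt + sigma_x * sqrt(dt) * Z` and its magnitude
#' from the wake bout's log-normal speed draw, so the derived speed
#' `|dx|/dt` equals the draw exactly (reflections at the tube ends aside).
#'
#' Each stimulus wakes the fly and adds a speed excursion
#' `A * exp(-(t - t_stim)/tau)`, evaluated at each step's midpoint; the
#' excursion keeps the fly awake until it decays below one step-noise
#' unit (`sigma_x`), after which normal sleep/wake alternation resumes.
#'
#' @param config A [simulation_config()].
#' @param metadata One fly's metadata: a list or one-row data.frame with
#'   `fly_id`, `genotype`, `sex`, `temperature_c`.
#' @param seed Substream seed for this fly (set before any draw); `NULL`
#'   to use the current RNG state.
#' @param block_shift_s Additive block shift (s) on the mean sleep-bout
#'   duration.
#' @return A [fly_trajectory()] with an extra logical element `asleep`
#'   giving the true simulated state at each sample.
#' @examples
#' cfg <- simulation_config(design = assay_design(recording_duration_s = 4000))
#' md <- list(fly_id = "f1", genotype = "INV", sex = "F", temperature_c = 25)
#' tr <- simulate_fly_trajectory(cfg, md, seed = 42)
#' @export
simulate_fly_trajectory <- function(config, metadata, seed = NULL,
                                    block_shift_s = 0) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  geno <- as.character(metadata$genotype)
  sex <- as.character(metadata$sex)
  p <- cell_params(config, geno, sex, metadata$temperature_c, block_shift_s)
  if (p$mu_sleep_s <= 0 || p$mu_wake_s <= 0)
    stop("mean bout durations must be positive")
  if (p$tau_s <= 0 && p$A_mm_s > 0)
    stop("tau must be positive when the startle amplitude is nonzero")

  des <- config$design
  dt <- des$dt_s
  L <- des$tube_length_mm
  n <- floor(des$recording_duration_s / dt)
  times <- (seq_len(n) - 1) * dt
  stim <- des$stimulus_times_s

  # Memoryless per-step transition probabilities of the renewal process.
  p_fall_asleep <- 1 - exp(-dt / p$mu_wake_s)
  p_wake_up <- 1 - exp(-dt / p$mu_sleep_s)

  noise_unit <- max(p$sigma_x_mm, 1e-6)
  startle_len <- if (p$A_mm_s > noise_unit)
    p$tau_s * log(p$A_mm_s / noise_unit) else 0

  awake <- runif(1) < p$mu_wake_s / (p$mu_wake_s + p$mu_sleep_s)
  v <- rlnorm(1, p$v_meanlog, p$v_sdlog)
  x <- runif(1, 0, L)

  pos <- numeric(n)
  asleep <- logical(n)
  pos[1L] <- x
  asleep[1L] <- !awake
  Z <- rnorm(n)
  U <- runif(n)

  si <- 1L
  n_stim <- length(stim)
  last_stim <- -Inf
  kappa <- p$kappa_per_s
  sx <- p$sigma_x_mm
  pstar <- p$p_star_mm
  A <- p$A_mm_s
  tau <- p$tau_s
  sqdt <- sqrt(dt)

  for (i in 2:n) {
    t <- times[i]
    # a stimulus fires once the step interval (t - dt, t] begins at/after it
    while (si <= n_stim && stim[si] <= t - dt + 1e-9) {
      last_stim <- stim[si]
      si <- si + 1L
      awake <- TRUE
      v <- rlnorm(1, p$v_meanlog, p$v_sdlog)
    }
    mid_lag <- t - dt / 2 - last_stim
    startled <- A > 0 && mid_lag < startle_len
    exc <- if (startled) A * exp(-mid_lag / tau) else 0

    if (awake) {
      draw <- kappa * (pstar - x) * dt + sx * sqdt * Z[i]
      if (draw != 0)
        x <- reflect_position(x + sign(draw) * (v + exc) * dt, L)
    }
    pos[i] <- x
    asleep[i] <- !awake

    # state transition for the next step; an active startle blocks sleep
    if (awake) {
      if (!startled && U[i] < p_fall_asleep) awake <- FALSE
    } else if (U[i] < p_wake_up) {
      awake <- TRUE
      v <- rlnorm(1, p$v_meanlog, p$v_sdlog)
    }
  }

  tr <- fly_trajectory(metadata$fly_id, times, pos, des)
  tr$asleep <- asleep
  tr
}

#' Simulate a full factorial cohort of fly trajectories
#'
#' Builds the genotype x sex x temperature x block design with
#' `n_per_cell` flies per cell, draws per-block additive shifts on the
#' mean sleep-bout duration (`N(0, sigma_b_sleep_s^2)`), and simulates
#' each fly on its own RNG substream derived from the master seed by a
#' fixed counter scheme, so enlarging a cohort never reshuffles existing
#' flies.
#'
#' @param config A [simulation_config()].
#' @param n_per_cell Override for `config$n_per_cell`.
#' @return A list with `trajectories` (named list of [fly_trajectory()]),
#'   `metadata` (data.frame), and `truth` (realized block shifts plus the
#'   resolved cell-level generative parameters, including each cell's
#'   expected asleep fraction `mu_S / (mu_S + mu_W)` and expected wake
#'   speed).
#' @export
simulate_cohort <- function(config, n_per_cell = config$n_per_cell) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_per_cell < 1L) stop("n_per_cell must be >= 1: zero cells requested")

  grid <- expand.grid(genotype = GENOTYPE_LEVELS, sex = SEX_LEVELS,
                      temperature_c = config$temperatures,
                      experiment_block = config$blocks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$cell_index <- seq_len(nrow(grid))

  set.seed(config$seed)
  block_shift <- stats::setNames(
    rnorm(length(config$blocks), 0, config$sigma_b_sleep_s), config$blocks)

  meta_rows <- list()
  trajectories <- list()
  for (ci in seq_len(nrow(grid))) {
    g <- grid[ci, ]
    for (j in seq_len(n_per_cell)) {
      fid <- sprintf("fly_%s_%s_%g_%s_%03d", g$genotype, g$sex,
                     g$temperature_c, g$experiment_block, j)
      md <- list(fly_id = fid, genotype = g$genotype, sex = g$sex,
                 temperature_c = g$temperature_c,
                 experiment_block = g$experiment_block,
                 cross_id = sprintf("cross_%s_%d", g$genotype,
                                    1 + (j %% 4L)))
      sub_seed <- fly_substream_seed(config$seed, g$cell_index, j)
      trajectories[[fid]] <- simulate_fly_trajectory(
        config, md, seed = sub_seed,
        block_shift_s = block_shift[[g$experiment_block]])
      meta_rows[[fid]] <- as.data.frame(md, stringsAsFactors = FALSE)
    }
  }
  metadata <- validate_metadata(do.call(rbind, meta_rows))
  rownames(metadata) <- NULL

  cell_truth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(ci) {
    g <- grid[ci, ]
    cp <- cell_params(config, g$genotype, g$sex, g$temperature_c,
                      block_shift[[g$experiment_block]])
    data.frame(g, mu_sleep_s = cp$mu_sleep_s, mu_wake_s = cp$mu_wake_s,
               asleep_fraction = cp$mu_sleep_s / (cp$mu_sleep_s + cp$mu_wake_s),
               expected_wake_speed = exp(cp$v_meanlog + cp$v_sdlog^2 / 2),
               p_star_mm = cp$p_star_mm, A_mm_s = cp$A_mm_s,
               tau_s = cp$tau_s, stringsAsFactors = FALSE)
  }))

  list(trajectories = trajectories, metadata = metadata,
       truth = list(block_shift_s = block_shift, cells = cell_truth,
                    seed = config$seed))
}

#' Simulate a per-fly phenotype table directly
#'
#' A shortcut past the trajectory level: draws the six traits from the
#' additive model the downstream analysis assumes, i.e.
#' `trait = intercept + genotype contrast + sex effect +
#' temperature slope * (T - 25) + genotype-by-covariate interaction +
#' block intercept (N(0, sigma_b^2)) + N(0, sigma_e^2)`,
#' clamped to each trait's natural range (e.g. proportions to `[0, 1]`).
#' Used for simulation studies (type-I error, power, parameter recovery)
#' where trajectory-level realism is irrelevant and speed matters.
#'
#' @param config A [simulation_config()]; effect sizes come from
#'   `config$trait_params`.
#' @param n_per_cell Override for `config$n_per_cell`.
#' @return A list with `phenotypes` (data.frame: fly_id + six traits),
#'   `metadata`, and `truth` (the generative parameters plus realized
#'   block effects per trait).
#' @export
simulate_phenotype_table <- function(config, n_per_cell = config$n_per_cell) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_per_cell < 1L) stop("n_per_cell must be >= 1: zero cells requested")
  set.seed(config$seed)

  grid <- expand.grid(genotype = GENOTYPE_LEVELS, sex = SEX_LEVELS,
                      temperature_c = config$temperatures,
                      experiment_block = config$blocks,
                      replicate = seq_len(n_per_cell),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nfly <- nrow(grid)
  grid$fly_id <- sprintf("fly_%s_%s_%g_%s_%03d", grid$genotype, grid$sex,
                         grid$temperature_c, grid$experiment_block,
                         grid$replicate)
  metadata <- data.frame(fly_id = grid$fly_id, genotype = grid$genotype,
                         sex = grid$sex, temperature_c = grid$temperature_c,
                         experiment_block = grid$experiment_block,
                         cross_id = sprintf("cross_%s_%d", grid$genotype,
                                            1 + (grid$replicate %% 4L)),
                         stringsAsFactors = FALSE)
  metadata <- validate_metadata(metadata)

  phen <- data.frame(fly_id = grid$fly_id, stringsAsFactors = FALSE)
  block_effects <- list()
  geno_idx <- match(grid$genotype, c("HET", "INV"))  # NA for STD
  is_m <- as.numeric(grid$sex == "M")
  dT <- grid$temperature_c - 25

  for (tn in names(config$trait_params)) {
    tp <- config$trait_params[[tn]]
    be <- stats::setNames(rnorm(length(config$blocks), 0, tp$sigma_b),
                          config$blocks)
    block_effects[[tn]] <- be
    gmain <- ifelse(is.na(geno_idx), 0, tp$geno[geno_idx])
    gsex <- ifelse(is.na(geno_idx), 0, tp$geno_sex[geno_idx]) * is_m
    gtemp <- ifelse(is.na(geno_idx), 0, tp$geno_temp[geno_idx]) * dT
    y <- tp$intercept + gmain + tp$sex_m * is_m + tp$temp_slope * dT +
      gsex + gtemp + be[as.character(grid$experiment_block)] +
      rnorm(nfly, 0, tp$sigma_e)
    phen[[tn]] <- pmin(pmax(y, tp$lower), tp$upper)
  }

  list(phenotypes = phen, metadata = metadata,
       truth = list(trait_params = config$trait_params,
                    block_effects = block_effects, seed = config$seed))
}
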