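#' Construct a single-fly trajectory record
#'
#' A `fly_trajectory` holds one fly's uniformly sampled 1-D positions along
#' the tube plus derived speeds. Speed at sample i is
#' `|position[i] - position[i-1]| / dt`, aligned to the later sample; the
#' first sample's speed is 0.
#'
#' @param fly_id Fly identifier (single string).
#' @param times Seconds since recording start; strictly increasing with a
#'   uniform step.
#' @param positions Positions in mm along the tube, within
#'   `[0, tube_length_mm]`; the food end is 0.
#' @param design An [assay_design()].
#' @return An object of class `fly_trajectory` with elements `fly_id`,
#'   `times`, `positions`, `speeds`, `dt_s`, `tube_length_mm`.
#' @export
fly_trajectory <- function(fly_id, times, positions, design) {
  stopifnot(inherits(design, "assay_design"))
  fly_id <- as.character(fly_id)
  times <- as.numeric(times)
  positions <- as.numeric(positions)
  if (length(fly_id) != 1L) stop("fly_id must be a single string")
  if (length(times) != length(positions))
    stop(sprintf("fly %s: times and positions differ in length", fly_id))
  if (length(times) < 2L)
    stop(sprintf("fly %s: need at least 2 samples", fly_id))
  dt <- design$dt_s
  steps <- diff(times)
  if (any(abs(steps - dt) > 1e-9 * dt))
    stop(sprintf("fly %s: non-uniform timestamps (expected step %g s)", fly_id, dt))
  L <- design$tube_length_mm
  if (any(positions < 0 | positions > L))
    stop(sprintf("fly %s: position outside [0, %g] mm", fly_id, L))
  speeds <- c(0, abs(diff(positions)) / dt)
  structure(
    list(fly_id = fly_id, times = times, positions = positions,
         speeds = speeds, dt_s = dt, tube_length_mm = L),
    class = "fly_trajectory"
  )
}

#' @export
print.fly_trajectory <- function(x, ...) {
  cat(sprintf("Fly %s: %d samples at dt = %g s, tube %g mm, mean speed %.3f mm/s\n",
              x$fly_id, length(x$times), x$dt_s, x$tube_length_mm,
              mean(x$speeds)))
  invisible(x)
}

#' @export
plot.fly_trajectory <- function(x, ...) {
  graphics::plot(x$times / 60, x$positions, type = "l",
                 xlab = "time (min)", ylab = "position (mm, 0 = food)",
                 main = paste("Fly", x$fly_id), ...)
  invisible(x)
}

#' Read fly trajectories from a long-format CSV
#'
#' Expects columns `fly_id`, `time_s`, `position_mm`. Rows are sorted by
#' time within fly; each fly becomes one [fly_trajectory()] with derived
#' speeds. Non-uniform timestamps, out-of-range positions, or duplicate
#' (fly, time) pairs are rejected with the offending fly named.
#'
#' @param path CSV file path.
#' @param design An [assay_design()].
#' @return A named list of `fly_trajectory` objects.
#' @export
read_trajectories <- function(path, design) {
  stopifnot(inherits(design, "assay_design"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "time_s", "position_mm")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    if (anyDuplicated(d$time_s))
      stop(sprintf("fly %s: duplicate (fly_id, time) rows", d$fly_id[1L]))
    fly_trajectory(d$fly_id[1L], d$time_s, d$position_mm, design)
  })
  out[order(names(out))]
}

#' Write fly trajectories to a long-format CSV
#'
#' Inverse of [read_trajectories()]: columns `fly_id,time_s,position_mm`.
#'
#' @param trajectories List of `fly_trajectory` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  dfs <- lapply(trajectories, function(tr) {
    data.frame(fly_id = tr$fly_id, time_s = tr$times,
               position_mm = tr$positions)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate per-fly metadata
#'
#' Expects columns `fly_id,genotype,sex,temperature_c,experiment_block,cross_id`.
#' Genotype must be one of STD/HET/INV, sex F/M, temperature one of
#' 20/25/30; fly_id must be unique.
#'
#' @param path Metadata CSV path.
#' @return A data.frame with genotype and sex as factors (STD and F as
#'   reference levels) and experiment_block as a factor.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata A data.frame of metadata to validate in place.
#' @export
validate_metadata <- function(metadata) {
  need <- c("fly_id", "genotype", "sex", "temperature_c",
            "experiment_block", "cross_id")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(metadata$fly_id))
    stop("duplicate fly_id in metadata")
  bad <- setdiff(unique(metadata$genotype), GENOTYPE_LEVELS)
  if (length(bad))
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$sex), SEX_LEVELS)
  if (length(bad))
    stop("unknown sex label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$temperature_c), TEMPERATURE_LEVELS)
  if (length(bad))
    stop("temperature outside {20, 25, 30}: ", paste(bad, collapse = ", "))
  metadata$genotype <- factor(metadata$genotype, levels = GENOTYPE_LEVELS)
  metadata$sex <- factor(metadata$sex, levels = SEX_LEVELS)
  metadata$experiment_block <- factor(metadata$experiment_block)
  metadata$fly_id <- as.character(metadata$fly_id)
  metadata
}

#' Cross-tabulate the experimental design
#'
#' Counts flies per genotype x sex x temperature x block cell and flags
#' empty cells, mirroring how a factorial cohort would be audited before
#' model fitting.
#'
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @return A list of class `design_summary` with elements `counts` (a
#'   4-way table), `empty_cells` (data.frame of empty combinations), and
#'   `n_flies`.
#' @export
validate_design <- function(metadata) {
  metadata <- validate_metadata(metadata)
  # genotype and sex keep their full level sets (a missing genotype is a
  # design hole); temperature and block are tabulated at observed levels
  counts <- table(genotype = metadata$genotype,
                  sex = metadata$sex,
                  temperature_c = factor(metadata$temperature_c),
                  experiment_block = metadata$experiment_block)
  empty <- as.data.frame(counts, stringsAsFactors = FALSE)
  empty <- empty[empty$Freq == 0L, setdiff(names(empty), "Freq"), drop = FALSE]
  structure(list(counts = counts, empty_cells = empty,
                 n_flies = nrow(metadata)),
            class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("Design summary: %d flies\n", x$n_flies))
  print(x$counts)
  if (nrow(x$empty_cells)) {
    cat(sprintf("WARNING: %d empty design cell(s):\n", nrow(x$empty_cells)))
    print(x$empty_cells, row.names = FALSE)
  } else cat("No empty design cells.\n")
  invisible(x)
}

# Fixed column order for the phenotype interchange table.
PHENOTYPE_COLUMNS <- c("fly_id", "sleep_min_per_hour", "base_speed_mm_s",
                       "startle_duration_s", "startle_magnitude_mm_s",
                       "prop_near_food", "prop_far_food")

#' Write a phenotype table to CSV
#'
#' One row per fly; the six trait columns are written in a fixed order
#' (`fly_id, sleep_min_per_hour, base_speed_mm_s, startle_duration_s,
#' startle_magnitude_mm_s, prop_near_food, prop_far_food`), followed by
#' any extra columns present (e.g. joined metadata).
#'
#' @param phenotypes Data.frame with at least the columns above.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  if (!all(PHENOTYPE_COLUMNS %in% names(phenotypes)))
    stop("phenotype table must have columns: ",
         paste(PHENOTYPE_COLUMNS, collapse = ", "))
  if (anyDuplicated(phenotypes$fly_id))
    stop("duplicate fly_id in phenotype table")
  extra <- setdiff(names(phenotypes), PHENOTYPE_COLUMNS)
  utils::write.csv(phenotypes[, c(PHENOTYPE_COLUMNS, extra), drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(PHENOTYPE_COLUMNS %in% names(df)))
    stop("not a phenotype table: missing required columns")
  df$fly_id <- as.character(df$fly_id)
  df
}
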