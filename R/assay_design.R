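#' Describe the physical assay: tube, sampling, and stimulus schedule
#'
#' An `assay_design` fixes the geometry and timing conventions every other
#' function assumes: tube length in mm with the food end at coordinate 0,
#' a uniform sampling interval, the mechanical-stimulus onsets, and the
#' total recording duration. A pre-stimulus baseline hour is required
#' because baseline speed, sleep, and occupancy are scored on it.
#'
#' @param tube_length_mm Tube length L in mm; positions lie in `[0, L]`.
#'   The food end is coordinate 0 by convention.
#' @param dt_s Sampling interval in seconds (uniform).
#' @param stimulus_times_s Strictly increasing stimulus onsets in seconds.
#'   The first must be at least 3600 s so a baseline hour exists.
#' @param recording_duration_s Total recording length in seconds; must
#'   exceed the last stimulus.
#' @return An object of class `assay_design`.
#' @examples
#' assay_design(stimulus_times_s = c(3600, 5400), recording_duration_s = 7200)
#' @export
assay_design <- function(tube_length_mm = 65,
                         dt_s = 1,
                         stimulus_times_s = c(3600, 5400, 7200, 9000),
                         recording_duration_s = 10800) {
  stopifnot(is.numeric(tube_length_mm), length(tube_length_mm) == 1L,
            tube_length_mm > 0,
            is.numeric(dt_s), length(dt_s) == 1L, dt_s > 0)
  if (length(stimulus_times_s) < 1L)
    stop("at least one stimulus time is required")
  if (any(diff(stimulus_times_s) <= 0))
    stop("stimulus_times_s must be strictly increasing")
  if (stimulus_times_s[1L] < 3600)
    stop("first stimulus must be at >= 3600 s: a pre-stimulus baseline hour is required")
  if (recording_duration_s <= max(stimulus_times_s))
    stop("recording_duration_s must exceed the last stimulus time")
  structure(
    list(tube_length_mm = tube_length_mm,
         dt_s = dt_s,
         stimulus_times_s = as.numeric(stimulus_times_s),
         recording_duration_s = as.numeric(recording_duration_s),
         food_end = 0),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Assay design:\n")
  cat(sprintf("  tube length: %g mm (food end at 0)\n", x$tube_length_mm))
  cat(sprintf("  sampling interval: %g s\n", x$dt_s))
  cat(sprintf("  stimuli (s): %s\n", paste(x$stimulus_times_s, collapse = ", ")))
  cat(sprintf("  recording: %g s\n", x$recording_duration_s))
  invisible(x)
}

# Closed label sets for metadata factors. STD is the reference genotype
# (standard arrangement); treatment contrasts are taken against it.
GENOTYPE_LEVELS <- c("STD", "HET", "INV")
SEX_LEVELS <- c("F", "M")
TEMPERATURE_LEVELS <- c(20, 25, 30)
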