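#' Six analyzable traits and whether each is a proportion
#' @noRd
TRAIT_NAMES <- c("sleep_min_per_hour", "base_speed_mm_s",
                 "startle_duration_s", "startle_magnitude_mm_s",
                 "prop_near_food", "prop_far_food")
PROPORTION_TRAITS <- c("prop_near_food", "prop_far_food")

TRAIT_LABELS <- c(sleep_min_per_hour = "Sleep",
                  base_speed_mm_s = "Base Speed",
                  startle_duration_s = "Startle Duration",
                  startle_magnitude_mm_s = "Startle Magnitude",
                  prop_near_food = "Prop_nearfood",
                  prop_far_food = "Prop_farfood")

#' Build the four-model nested ladder for one trait
#'
#' The ladder is null (block random intercept only), genotype, genotype +
#' covariate, and genotype * covariate, each with a random intercept per
#' experiment block. Sex is a 2-level factor; temperature is numeric in
#' degrees C (so it contributes a single slope parameter). Structural
#' parameter counts are therefore 3, 5, 6, 8 (fixed effects + block
#' variance + residual variance) and the successive likelihood-ratio df
#' are 2, 1, 2 for both covariates. Proportion traits are flagged for the
#' arcsine-square-root pre-transform.
#'
#' @param trait One of the six trait column names.
#' @param covariate `"sex"` or `"temperature"`.
#' @return List of four model specs (class `model_spec`), in ladder order.
#' @export
build_ladder <- function(trait, covariate = c("sex", "temperature")) {
  covariate <- match.arg(covariate)
  if (!trait %in% TRAIT_NAMES)
    stop("unknown trait: ", trait,
         " (expected one of ", paste(TRAIT_NAMES, collapse = ", "), ")")
  cov_var <- if (covariate == "sex") "sex" else "temperature_c"
  cov_npar <- 1L  # 2-level factor or numeric slope
  re <- "(1 | experiment_block)"
  mk <- function(label, fixed, npar) {
    rhs <- paste(c(fixed, re), collapse = " + ")
    structure(list(trait = trait, label = label, covariate = covariate,
                   fixed = fixed,
                   formula = stats::as.formula(paste(trait, "~", rhs)),
                   npar = npar,
                   transform = trait %in% PROPORTION_TRAITS),
              class = "model_spec")
  }
  cov_label <- if (covariate == "sex") "Sex Model" else "Temp Model"
  list(
    mk("Null Model", "1", 3L),
    mk("Inversion Model", "genotype", 5L),
    mk(cov_label, c("genotype", cov_var), 5L + cov_npar),
    mk("Interaction Model",
       c("genotype", cov_var, paste0("genotype:", cov_var)),
       5L + cov_npar + 2L * cov_npar)
  )
}

#' Fit one linear mixed model of the ladder
#'
#' Fits the spec's formula with `lme4::lmer` by maximum likelihood (not
#' REML: the ladder compares models differing in fixed effects, and the
#' likelihood-ratio tests are only valid under ML). The parameter count is
#' the structural one implied by the spec, not anything read off optimizer
#' internals; `AIC = 2*npar - 2*logLik` by construction.
#'
#' @param spec A spec from [build_ladder()].
#' @param data Data.frame with the trait, `genotype`, the covariate, and
#'   `experiment_block` (>= 2 levels).
#' @return List of class `fit_result`: `spec`, `fit` (the merMod), `npar`,
#'   `logLik`, `AIC`, `fixef` (estimates and SEs), `converged`,
#'   `messages`.
#' @export
fit_mixed <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  y <- data[[spec$trait]]
  if (is.null(y)) stop("trait column missing: ", spec$trait)
  if (!all(is.finite(y))) stop("non-finite trait values in ", spec$trait)
  if (length(unique(data$experiment_block)) < 2L)
    stop("only one experiment block present: the block random intercept is ",
         "inestimable; provide >= 2 blocks or drop the random effect")
  msgs <- character(0)
  formula <- spec$formula
  # a fixed term whose covariate has a single observed level is
  # inestimable and carries no information: drop it from the fitted
  # formula but keep the structural parameter count, so the ladder LRT
  # against the reduced model is exactly chisq = 0
  degenerate <- Filter(function(v) {
    x <- data[[v]]
    !is.null(x) && !is.numeric(x) && length(unique(as.character(x))) < 2L
  }, all.vars(stats::delete.response(stats::terms(formula))))
  degenerate <- setdiff(degenerate, "experiment_block")
  if (length(degenerate)) {
    keep <- Filter(function(term) {
      !any(vapply(degenerate, grepl, logical(1), x = term, fixed = TRUE))
    }, spec$fixed)
    if (!length(keep)) keep <- "1"
    formula <- stats::as.formula(
      paste(spec$trait, "~", paste(c(keep, "(1 | experiment_block)"),
                                   collapse = " + ")))
    msgs <- c(msgs, paste("dropped inestimable term(s) involving:",
                          paste(degenerate, collapse = ", ")))
  }
  notes <- msgs
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  ll <- as.numeric(stats::logLik(fit))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  structure(
    list(spec = spec, fit = fit, npar = spec$npar, logLik = ll,
         AIC = 2 * spec$npar - 2 * ll,
         fixef = data.frame(term = names(b), estimate = as.numeric(b),
                            se = as.numeric(se), stringsAsFactors = FALSE),
         converged = length(setdiff(msgs, notes)) == 0L, messages = msgs),
    class = "fit_result"
  )
}

#' Compare the fitted ladder with likelihood-ratio tests
#'
#' Each successive nested pair yields `Chisq = 2 * (logLik_full -
#' logLik_reduced)` on `Df = npar_full - npar_reduced` degrees of freedom,
#' with an upper-tail chi-squared p-value — the layout of a standard
#' mixed-model `anova()` table. Chi-squared statistics numerically below
#' zero by less than 1e-6 are clamped to 0; larger negatives indicate a
#' convergence failure and abort.
#'
#' @param fits List of four [fit_mixed()] results in ladder order.
#' @return Data.frame of class `model_comparison` with columns `Trait`,
#'   `Model`, `npar`, `AIC`, `logLik`, `Chisq`, `Df`, `p`.
#' @export
compare_ladder <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "fit_result")))
  npars <- vapply(fits, `[[`, numeric(1), "npar")
  if (any(diff(npars) <= 0))
    stop("model specs are not strictly nested (npar must increase)")
  traits <- vapply(fits, function(f) f$spec$trait, character(1))
  if (length(unique(traits)) != 1L)
    stop("all fits must model the same trait")
  lls <- vapply(fits, `[[`, numeric(1), "logLik")
  k <- length(fits)
  chisq <- df <- p <- rep(NA_real_, k)
  for (i in 2:k) {
    stat <- 2 * (lls[i] - lls[i - 1L])
    if (stat < -1e-6)
      stop(sprintf("negative LRT statistic (%.3g) for %s vs %s: convergence failure",
                   stat, fits[[i]]$spec$label, fits[[i - 1L]]$spec$label))
    chisq[i] <- max(stat, 0)
    df[i] <- npars[i] - npars[i - 1L]
    p[i] <- stats::pchisq(chisq[i], df[i], lower.tail = FALSE)
  }
  out <- data.frame(
    Trait = TRAIT_LABELS[[traits[1L]]],
    Model = vapply(fits, function(f) f$spec$label, character(1)),
    npar = npars,
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    logLik = lls,
    Chisq = chisq, Df = df, p = p,
    stringsAsFactors = FALSE)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Gated post-hoc pairwise t-tests between genotypes within strata
#'
#' Run only when the ladder flagged genotype: the gate passes when the
#' genotype main-effect LRT or the genotype-by-covariate interaction LRT
#' has p < `alpha`. All three genotype pairs are then tested within each
#' stratum (sex level or temperature level) with two-sample t-tests —
#' Welch by default, pooled-variance optionally — and unadjusted p-values.
#'
#' @param data Data.frame with the trait column, `genotype`, and the
#'   stratum column.
#' @param trait Trait column name.
#' @param stratum_var Column defining strata (`"sex"` or
#'   `"temperature_c"`).
#' @param gate A `model_comparison` table (or `NULL` to skip gating).
#' @param alpha Gate significance level (default 0.05).
#' @param var_equal Use pooled-variance t-tests instead of Welch.
#' @return Data.frame with columns `trait`, `stratum`, `group1`, `group2`,
#'   `t`, `df`, `p`, `mean1`, `mean2`, `n1`, `n2`; zero rows when the gate
#'   fails. Pairs with fewer than 2 observations in either genotype are
#'   skipped (recorded in the `skipped` attribute).
#' @export
posthoc_pairwise <- function(data, trait, stratum_var, gate = NULL,
                             alpha = 0.05, var_equal = FALSE) {
  empty <- data.frame(trait = character(0), stratum = character(0),
                      group1 = character(0), group2 = character(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      mean1 = numeric(0), mean2 = numeric(0),
                      n1 = integer(0), n2 = integer(0),
                      stringsAsFactors = FALSE)
  if (!is.null(gate)) {
    geno_rows <- gate$Model %in% c("Inversion Model", "Interaction Model")
    if (!any(gate$p[geno_rows] < alpha, na.rm = TRUE)) return(empty)
  }
  pairs <- utils::combn(GENOTYPE_LEVELS, 2)
  strata <- sort(unique(data[[stratum_var]]))
  rows <- list()
  skipped <- character(0)
  for (s in strata) {
    d <- data[data[[stratum_var]] == s, ]
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      y1 <- d[[trait]][d$genotype == g1]
      y2 <- d[[trait]][d$genotype == g2]
      if (length(y1) < 2L || length(y2) < 2L) {
        skipped <- c(skipped, sprintf("%s vs %s in stratum %s", g1, g2, s))
        next
      }
      if (stats::var(y1) + stats::var(y2) == 0) {
        # both groups constant: the t statistic degenerates
        d0 <- mean(y1) - mean(y2)
        tt <- list(statistic = if (d0 == 0) 0 else sign(d0) * Inf,
                   parameter = length(y1) + length(y2) - 2,
                   p.value = as.numeric(d0 == 0))
      } else {
        tt <- stats::t.test(y1, y2, var.equal = var_equal)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, stratum = as.character(s), group1 = g1, group2 = g2,
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, mean1 = mean(y1), mean2 = mean(y2),
        n1 = length(y1), n2 = length(y2), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "skipped") <- skipped
  out
}

#' Fit the nested inversion model ladder for one trait
#'
#' The central fitting function: fits the four nested linear mixed models
#' (null, genotype, genotype + covariate, genotype * covariate, each with
#' a block random intercept, by maximum likelihood) and compares them with
#' likelihood-ratio tests. Proportion traits are arcsine-square-root
#' transformed before fitting.
#'
#' @param trait Trait column name (one of the six).
#' @param data Data.frame holding the trait plus `genotype`, `sex` or
#'   `temperature_c`, and `experiment_block`.
#' @param covariate `"sex"` or `"temperature"`.
#' @param transform Apply the arcsine-square-root transform; default
#'   `TRUE` for proportion traits.
#' @return Object of class `inv_ladder` with the four fits, the
#'   model-comparison table, and the data used.
#' @seealso [run_analysis()] for the full six-trait analysis with post-hoc
#'   tests.
#' @examples
#' sim <- simulate_phenotype_table(simulation_config(seed = 7, n_per_cell = 5))
#' d <- merge(sim$phenotypes, sim$metadata, by = "fly_id")
#' lad <- inversion_ladder("sleep_min_per_hour", d[d$temperature_c == 25, ])
#' print(lad)
#' @export
inversion_ladder <- function(trait, data,
                             covariate = c("sex", "temperature"),
                             transform = NULL) {
  covariate <- match.arg(covariate)
  specs <- build_ladder(trait, covariate)
  if (is.null(transform)) transform <- specs[[1L]]$transform
  data <- as.data.frame(data)
  data$genotype <- factor(as.character(data$genotype),
                          levels = GENOTYPE_LEVELS)
  data$experiment_block <- factor(data$experiment_block)
  if (covariate == "sex")
    data$sex <- factor(as.character(data$sex), levels = SEX_LEVELS)
  if (transform) data[[trait]] <- arcsin_sqrt(data[[trait]])
  fits <- lapply(specs, fit_mixed, data = data)
  structure(
    list(trait = trait, covariate = covariate, transform = transform,
         fits = fits, table = compare_ladder(fits),
         n = nrow(data)),
    class = "inv_ladder")
}

#' @export
print.inv_ladder <- function(x, digits = 4, ...) {
  cat(sprintf("Nested mixed-model ladder for %s (covariate: %s%s), n = %d\n",
              TRAIT_LABELS[[x$trait]], x$covariate,
              if (x$transform) ", arcsin-sqrt transformed" else "", x$n))
  tab <- x$table
  tab$AIC <- round(tab$AIC, 2)
  tab$logLik <- round(tab$logLik, 2)
  tab$Chisq <- round(tab$Chisq, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.inv_ladder <- function(object, ...) {
  print(object)
  full <- object$fits[[length(object$fits)]]
  cat("\nFixed effects of the interaction model (treatment coding, STD/",
      if (object$covariate == "sex") "F" else "centered temperature",
      " reference):\n", sep = "")
  print(full$fixef, row.names = FALSE, digits = 4)
  if (!full$converged)
    cat("Convergence notes:", paste(full$messages, collapse = "; "), "\n")
  invisible(object)
}

#' @export
coef.inv_ladder <- function(object, model = length(object$fits), ...) {
  f <- object$fits[[model]]$fixef
  stats::setNames(f$estimate, f$term)
}

#' Run a full six-trait analysis (sex at 25 C, or temperature in females)
#'
#' Reproduces the two analysis designs: `"sex"` compares both sexes at
#' 25 degrees C only; `"temperature"` uses females only across 20/25/30
#' degrees C with temperature as a numeric covariate. For every trait it
#' fits the four-model ladder ([inversion_ladder()]) and, when the
#' genotype or interaction likelihood-ratio test is significant at
#' `alpha`, runs post-hoc pairwise t-tests between genotypes within each
#' stratum.
#'
#' @param phenotypes Phenotype table (see [compute_phenotypes()]).
#' @param metadata Metadata table (see [read_metadata()]).
#' @param analysis `"sex"` or `"temperature"`.
#' @param alpha Gate level for post-hoc tests (default 0.05).
#' @param var_equal Pooled-variance instead of Welch post-hoc t-tests.
#' @return Object of class `inv_analysis`: per-trait ladders and
#'   comparison tables, a combined post-hoc table, and the filtered data.
#' @export
run_analysis <- function(phenotypes, metadata,
                         analysis = c("sex", "temperature"),
                         alpha = 0.05, var_equal = FALSE) {
  analysis <- match.arg(analysis)
  metadata <- validate_metadata(as.data.frame(metadata))
  d <- merge(as.data.frame(phenotypes), metadata, by = "fly_id")
  if (!nrow(d)) stop("no flies shared between phenotypes and metadata")

  if (analysis == "sex") {
    d <- d[d$temperature_c == 25, ]
    for (s in SEX_LEVELS)
      if (!any(d$sex == s))
        stop("missing stratum for the sex analysis: no ", s,
             " flies at 25 C")
    covariate <- "sex"
    stratum_var <- "sex"
  } else {
    d <- d[d$sex == "F", ]
    for (tc in TEMPERATURE_LEVELS)
      if (!any(d$temperature_c == tc))
        stop("missing stratum for the temperature analysis: no female ",
             "flies at ", tc, " C")
    covariate <- "temperature"
    stratum_var <- "temperature_c"
  }
  d$genotype <- droplevels(d$genotype)
  if (nlevels(d$genotype) < 3L)
    stop("missing stratum: all three genotypes (STD, HET, INV) are required")

  ladders <- list()
  posthoc <- list()
  for (trait in TRAIT_NAMES) {
    lad <- inversion_ladder(trait, d, covariate)
    ladders[[trait]] <- lad
    # post-hoc tests run on the same (possibly transformed) scale as the fit
    dt <- d
    if (lad$transform) dt[[trait]] <- arcsin_sqrt(dt[[trait]])
    posthoc[[trait]] <- posthoc_pairwise(dt, trait, stratum_var,
                                         gate = lad$table, alpha = alpha,
                                         var_equal = var_equal)
  }
  ph <- do.call(rbind, posthoc)
  rownames(ph) <- NULL

  structure(
    list(analysis = analysis, alpha = alpha, ladders = ladders,
         tables = lapply(ladders, `[[`, "table"),
         posthoc = ph, data = d, n_flies = nrow(d),
         stratum_var = stratum_var),
    class = "inv_analysis")
}

#' @export
print.inv_analysis <- function(x, ...) {
  cat(sprintf("Inversion behavior analysis (%s mode): %d flies\n\n",
              x$analysis, x$n_flies))
  for (lad in x$ladders) { print(lad); cat("\n") }
  if (nrow(x$posthoc)) {
    cat(sprintf("Post-hoc pairwise t-tests (gate p < %g, unadjusted):\n",
                x$alpha))
    ph <- x$posthoc
    ph$t <- round(ph$t, 3); ph$df <- round(ph$df, 2)
    ph$p <- signif(ph$p, 3)
    ph$mean1 <- signif(ph$mean1, 4); ph$mean2 <- signif(ph$mean2, 4)
    print(ph, row.names = FALSE)
  } else cat("No post-hoc tests (no genotype-bearing LRT passed the gate).\n")
  invisible(x)
}

#' Combine an analysis's ladder tables into one long table
#' @param x An `inv_analysis`.
#' @return Data.frame stacking every trait's model-comparison rows.
#' @export
comparison_table <- function(x) {
  stopifnot(inherits(x, "inv_analysis"))
  out <- do.call(rbind, lapply(x$tables, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Plot genotype means with 95% error bars per stratum
#'
#' For each trait, plots the per-genotype mean and mean +/- 1.96 SE within
#' each stratum of the analysis (sex, or temperature level).
#'
#' @param x An `inv_analysis`.
#' @param traits Traits to plot (default all six).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.inv_analysis <- function(x, traits = TRAIT_NAMES, ...) {
  d <- x$data
  sv <- x$stratum_var
  strata <- sort(unique(d[[sv]]))
  old <- graphics::par(mfrow = c(2, ceiling(length(traits) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (trait in traits) {
    agg <- stats::aggregate(d[[trait]],
                            by = list(genotype = d$genotype,
                                      stratum = d[[sv]]),
                            FUN = function(v) c(mean = mean(v),
                                                se = stats::sd(v) / sqrt(length(v))))
    m <- agg$x[, "mean"]; se <- agg$x[, "se"]
    xi <- as.integer(factor(agg$stratum, levels = strata)) +
      (as.integer(agg$genotype) - 2) * 0.15
    ylim <- range(m - 2 * se, m + 2 * se)
    graphics::plot(xi, m, pch = 19, col = as.integer(agg$genotype),
                   xaxt = "n", xlab = sv, ylab = trait,
                   main = TRAIT_LABELS[[trait]], ylim = ylim,
                   xlim = c(0.5, length(strata) + 0.5))
    graphics::axis(1, at = seq_along(strata), labels = strata)
    ok <- is.finite(se) & se > 0
    if (any(ok))
      graphics::arrows(xi[ok], (m - 1.96 * se)[ok], xi[ok],
                       (m + 1.96 * se)[ok], angle = 90, code = 3,
                       length = 0.03, col = as.integer(agg$genotype)[ok])
  }
  graphics::legend("topright", legend = levels(d$genotype), pch = 19,
                   col = seq_len(3), bty = "n")
  invisible(x)
}
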