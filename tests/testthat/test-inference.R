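sim_data <- function(seed, n = 10, temps = c(20, 25, 30), tp = NULL) {
  args <- list(seed = seed, n_per_cell = n, temperatures = temps)
  if (!is.null(tp)) args$trait_params <- tp
  sim <- simulate_phenotype_table(do.call(simulation_config, args))
  merge(sim$phenotypes, sim$metadata, by = "fly_id")
}

test_that("ladder specs have the structural npar sequence 3, 5, 6, 8", {
  for (cov in c("sex", "temperature")) {
    specs <- build_ladder("sleep_min_per_hour", cov)
    expect_equal(vapply(specs, `[[`, numeric(1), "npar"), c(3, 5, 6, 8))
    expect_false("genotype" %in% specs[[1]]$fixed)
    expect_true("genotype" %in% specs[[2]]$fixed)
  }
  # proportion traits flagged for the arcsine pre-transform
  expect_true(build_ladder("prop_near_food", "sex")[[1]]$transform)
  expect_false(build_ladder("sleep_min_per_hour", "sex")[[1]]$transform)
  expect_error(build_ladder("wingspan", "sex"), "unknown trait")
})

test_that("mixed-model logLik matches OLS at the zero block-variance boundary", {
  # blocks with identical data have exactly zero between-block variance,
  # so the ML random-intercept estimate sits on the boundary and the mixed
  # logLik must coincide with ordinary least squares
  tp <- default_trait_params()
  tp$sleep_min_per_hour$sigma_b <- 0
  d1 <- sim_data(31, n = 15, temps = 25, tp = tp)
  d1 <- d1[d1$experiment_block == "B1", ]
  d <- do.call(rbind, lapply(c("B1", "B2", "B3"), function(b) {
    db <- d1; db$experiment_block <- b
    db$fly_id <- paste0(db$fly_id, b)
    db
  }))
  spec <- build_ladder("sleep_min_per_hour", "sex")[[4]]
  fm <- fit_mixed(spec, d)
  ols <- lm(sleep_min_per_hour ~ genotype + sex + genotype:sex, data = d)
  expect_lt(abs(fm$logLik - as.numeric(logLik(ols))), 1e-4)
})

test_that("fixed effects are invariant to duplicating every row", {
  d <- sim_data(32, n = 8, temps = 25)
  spec <- build_ladder("sleep_min_per_hour", "sex")[[3]]
  f1 <- fit_mixed(spec, d)
  f2 <- fit_mixed(spec, rbind(d, d))
  expect_equal(f1$fixef$estimate, f2$fixef$estimate, tolerance = 1e-6)
})

test_that("degenerate fits are handled: constant trait, single block", {
  d <- sim_data(33, n = 5, temps = 25)
  d$sleep_min_per_hour <- 42
  spec <- build_ladder("sleep_min_per_hour", "sex")[[1]]
  expect_no_error(fit_mixed(spec, d))

  d1 <- sim_data(34, n = 5, temps = 25)
  d1 <- d1[d1$experiment_block == "B1", ]
  expect_error(fit_mixed(spec, d1), "block")
})

test_that("AIC identity and logLik monotonicity hold across the ladder", {
  for (seed in 35:37) {
    d <- sim_data(seed, n = 8)
    for (cov in c("sex", "temperature")) {
      dd <- if (cov == "sex") d[d$temperature_c == 25, ] else d[d$sex == "F", ]
      lad <- inversion_ladder("startle_magnitude_mm_s", dd, cov)
      lls <- vapply(lad$fits, `[[`, numeric(1), "logLik")
      expect_true(all(diff(lls) > -1e-6))
      for (f in lad$fits)
        expect_identical(f$AIC, 2 * f$npar - 2 * f$logLik)
      expect_equal(lad$table$Df[-1], c(2, 1, 2))
    }
  }
})

test_that("a covariate with a single observed level yields chisq 0, p 1", {
  d <- sim_data(38, n = 10, temps = 25)
  d <- d[d$sex == "F", ]
  d$sex <- factor(d$sex, levels = c("F", "M"))
  lad <- inversion_ladder("sleep_min_per_hour", d, "sex")
  expect_equal(lad$table$Chisq[3], 0)
  expect_equal(lad$table$p[3], 1)
  expect_equal(lad$table$Df[3], 1)  # structural df retained
})

test_that("non-nested fit lists are rejected", {
  d <- sim_data(39, n = 5, temps = 25)
  specs <- build_ladder("sleep_min_per_hour", "sex")
  f2 <- fit_mixed(specs[[2]], d)
  f1 <- fit_mixed(specs[[1]], d)
  expect_error(compare_ladder(list(f2, f1)), "nested")
})

test_that("Welch post-hoc t matches the textbook formula", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                  genotype = rep(c("STD", "INV"), each = 3),
                  sex = "F")
  ph <- posthoc_pairwise(d, "y", "sex", gate = NULL)
  row <- ph[ph$group1 == "STD" & ph$group2 == "INV", ]
  # brute-force Welch: t = (m1-m2)/sqrt(s1^2/n1 + s2^2/n2), Satterthwaite df
  m1 <- 2; m2 <- 5; s2 <- 1  # var of {1,2,3} = var of {4,5,6} = 1
  t_want <- (m1 - m2) / sqrt(s2 / 3 + s2 / 3)
  df_want <- (s2 / 3 + s2 / 3)^2 / ((s2 / 3)^2 / 2 + (s2 / 3)^2 / 2)
  expect_equal(row$t, t_want, tolerance = 1e-12)
  expect_equal(row$t, -3.6742346, tolerance = 1e-6)
  expect_equal(row$df, df_want)
  expect_equal(row$df, 4)
})

test_that("post-hoc tests are gated and degenerate groups handled", {
  d <- data.frame(y = rep(7, 30),
                  genotype = rep(c("STD", "HET", "INV"), 10),
                  sex = rep(c("F", "M"), each = 15))
  ph <- posthoc_pairwise(d, "y", "sex", gate = NULL)
  expect_equal(nrow(ph), 6)  # 3 pairs x 2 strata
  expect_true(all(ph$t == 0))
  expect_true(all(ph$p == 1))

  # failing gate: empty result
  gate <- data.frame(Model = c("Null Model", "Inversion Model", "Sex Model",
                               "Interaction Model"),
                     p = c(NA, 0.5, 0.01, 0.9))
  expect_equal(nrow(posthoc_pairwise(d, "y", "sex", gate = gate)), 0)
  # passing gate via the interaction row
  gate$p <- c(NA, 0.5, 0.5, 0.01)
  expect_equal(nrow(posthoc_pairwise(d, "y", "sex", gate = gate)), 6)

  # a stratum with < 2 flies in a genotype is skipped and logged
  d2 <- d[-(which(d$genotype == "INV" & d$sex == "F")[-1]), ]
  ph2 <- posthoc_pairwise(d2, "y", "sex", gate = NULL)
  expect_equal(nrow(ph2), 4)
  expect_length(attr(ph2, "skipped"), 2)
})

test_that("run_analysis applies the documented filters", {
  sim <- simulate_phenotype_table(simulation_config(seed = 40, n_per_cell = 6))
  res_sex <- run_analysis(sim$phenotypes, sim$metadata, "sex")
  expect_true(all(res_sex$data$temperature_c == 25))
  expect_setequal(as.character(unique(res_sex$data$sex)), c("F", "M"))

  res_temp <- run_analysis(sim$phenotypes, sim$metadata, "temperature")
  expect_true(all(res_temp$data$sex == "F"))
  expect_setequal(unique(res_temp$data$temperature_c), c(20, 25, 30))

  # males at 20 C appear in neither analysis
  m20 <- sim$metadata$fly_id[sim$metadata$sex == "M" &
                             sim$metadata$temperature_c == 20]
  expect_false(any(m20 %in% res_sex$data$fly_id))
  expect_false(any(m20 %in% res_temp$data$fly_id))

  # missing stratum is rejected by name
  md_f <- sim$metadata[sim$metadata$sex == "F", ]
  expect_error(run_analysis(sim$phenotypes, md_f, "sex"), "M")
  md_25 <- sim$metadata[sim$metadata$temperature_c == 25, ]
  expect_error(run_analysis(sim$phenotypes, md_25, "temperature"), "20")

  # every trait got a 4-row ladder table shaped like the published ones
  for (tab in res_sex$tables) {
    expect_equal(nrow(tab), 4)
    expect_equal(tab$npar, c(3, 5, 6, 8))
    expect_equal(names(tab),
                 c("Trait", "Model", "npar", "AIC", "logLik", "Chisq", "Df", "p"))
  }
})

test_that("gate behavior: null genotype effects produce no post-hoc rows", {
  tp <- default_trait_params()
  for (tn in names(tp)) {
    tp[[tn]]$geno[] <- 0
    tp[[tn]]$geno_sex[] <- 0
    tp[[tn]]$geno_temp[] <- 0
  }
  sim <- simulate_phenotype_table(
    simulation_config(seed = 41, n_per_cell = 6, trait_params = tp))
  res <- run_analysis(sim$phenotypes, sim$metadata, "sex")
  gated_out <- vapply(names(res$tables), function(tn) {
    tab <- res$tables[[tn]]
    geno_p <- tab$p[tab$Model %in% c("Inversion Model", "Interaction Model")]
    if (all(geno_p >= 0.05)) {
      !any(res$posthoc$trait == tn)
    } else TRUE  # gate legitimately open for this trait
  }, logical(1))
  expect_true(all(gated_out))
})
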