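test_that("Gelman-Rubin PSRF matches hand computation and conventions", {
  # chains {1,2,3} and {2,3,4}: W = 1, means 2 and 3 so B = L * 0.5 = 1.5
  x <- cbind(c(1, 2, 3), c(2, 3, 4))
  expect_equal(gelman_rubin(x), sqrt((2 / 3 * 1 + 1.5 / 3) / 1))
  # identical constant chains return 1 by convention
  expect_equal(gelman_rubin(cbind(rep(2, 5), rep(2, 5))), 1)
  # list interface and errors
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(2, 3, 4))), gelman_rubin(x))
  expect_error(gelman_rubin(x[, 1, drop = FALSE]), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal retained lengths")
})

test_that("PSRF agrees with the coda implementation on random chains", {
  set.seed(8)
  x <- matrix(rnorm(4000), ncol = 4)
  ours <- gelman_rubin(x)
  ml <- coda::mcmc.list(lapply(seq_len(4), function(c2) coda::mcmc(x[, c2])))
  ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  # coda adds a sampling-variability d.f. correction; both must sit near 1
  expect_equal(ours, ref, tolerance = 0.01)
})

test_that("PSRF is near 1 for stationary chains and label-invariant", {
  set.seed(21)
  x <- matrix(rnorm(8 * 2000, mean = 3, sd = 2), ncol = 8)
  r <- gelman_rubin(x)
  expect_gte(r, 0.99)  # the estimator can sit a hair under 1 on iid chains
  expect_lte(r, 1.05)
  expect_equal(gelman_rubin(x[, sample(8)]), r)
  # diverged chains are flagged
  bad <- x; bad[, 1] <- bad[, 1] + 10
  expect_gt(gelman_rubin(bad), 1.2)
})

two_draw_fit <- function() {
  # hand-built fit: 2 x 2 km state space at side 1 (4 suitable pixels),
  # two retained draws, M = 3
  sp <- build_state_space(c(0, 2, 0, 2), side = 1)
  draws <- matrix(0, 2, 10,
                  dimnames = list(NULL, c("lam0", "beta_eff", "beta_sex",
                                          "sigma_F", "sigma_M", "theta",
                                          "psi", "psi_sex", "N_super", "D")))
  draws[, "N_super"] <- c(2, 1)
  draws[, "D"] <- density_from_nsuper(c(2, 1), suitable_area(sp))
  draws[, "psi_sex"] <- 0.5
  s <- rbind(c(1, 3, 2), c(1, 4, 2))
  z <- rbind(c(1, 1, 0), c(1, 0, 0))
  sex <- rbind(c(0, 1, 0), c(0, 1, 1))
  fake_fit(list(draws), list(s), list(z), list(sex), space = sp, M = 3)
}

test_that("density surface is the per-pixel mean of included centres", {
  fit <- two_draw_fit()
  surf <- density_surface(fit)
  # pixel 1 hosts an included centre in both draws; pixel 3 in one of two
  expect_equal(surf$density[1], 1 / fit$pixel_area)
  expect_equal(surf$density[3], 0.5 / fit$pixel_area)
  expect_equal(surf$density[c(2, 4)], c(0, 0))
  # conservation: sum over pixels x pixel area = posterior mean N_super
  expect_equal(sum(surf$density) * fit$pixel_area,
               mean(pooled_draws(fit)[, "N_super"]))
  expect_true(all(surf$density >= 0))
  # exported grid matches the state-space geometry
  expect_equal(surf$grid$ncols, fit$space$nx)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(surf$grid, f)
  expect_equal(read_ascii_grid(f)$values, surf$grid$values)
})

test_that("density surface demands stored latent traces", {
  fit <- two_draw_fit()
  fit$chains[[1]]$s <- NULL
  expect_error(density_surface(fit), "store_ac")
  expect_error(bayesian_pvalue(fit), "store_ac")
})

test_that("posterior summaries pool chains and respect fixed parameters", {
  pt <- c(lam0 = 0.01, beta_eff = 0.1, beta_sex = -0.2, sigma_F = 3,
          sigma_M = 8, theta = 0.8, psi = 0.45, psi_sex = 0.2,
          N_super = 150, D = 1.3)
  draws <- matrix(rep(pt, each = 4), 4, 10, dimnames = list(NULL, names(pt)))
  fit <- fake_fit(list(draws, draws), M = 300)
  summ <- summarize_posterior(fit)
  expect_equal(summ$n_samples, 8)
  expect_equal(summ$table$mean[summ$table$parameter == "sigma_M"], 8)
  expect_true(all(summ$table$sd == 0))
  expect_equal(summ$table$mean[summ$table$parameter == "sex_ratio"],
               sex_ratio(0.2))
  expect_equal(summ$max_psrf, 1)  # identical chains
  # variant 3 drops the fixed parameters from the table
  fit3 <- fake_fit(list(draws, draws), variant = model_variant(3), M = 300)
  t3 <- summarize_posterior(fit3)$table$parameter
  expect_false("beta_sex" %in% t3)
  expect_false("theta" %in% t3)
  # D linearity between summary rows
  expect_equal(summ$table$mean[summ$table$parameter == "D"],
               density_from_nsuper(
                 summ$table$mean[summ$table$parameter == "N_super"],
                 11538.46), tolerance = 1e-6)
})

test_that("posterior predictive p-value is calibrated on a well-specified fit", {
  sc <- scenario_config(extent_km = 12, buffer_km = 3, n_animals = 15, K = 10,
                        searchers = 1, daily_km = 30, lam0 = 0.08)
  sim <- simulate_survey(sc, seed = 31)
  enc <- build_encounter_array(sim$sightings, sim$effort)
  fit <- run_chains(enc, sim$space, M = 60, variant = model_variant(1),
                    config = sampler_config(iterations = 800, burnin = 200,
                                            thin = 2, chains = 2, seed = 9))
  pv <- bayesian_pvalue(fit, ndraws = 150, seed = 4)
  expect_gte(pv$p_value, 0)
  expect_lte(pv$p_value, 1)
  expect_length(pv$T_rep, length(pv$T_obs))
  expect_true(all(pv$T_obs >= 0))
  # the tie convention T_rep >= T_obs defines the reported value
  expect_equal(pv$p_value, mean(pv$T_rep >= pv$T_obs))
  # determinism given the seed
  pv2 <- bayesian_pvalue(fit, ndraws = 150, seed = 4)
  expect_identical(pv2$p_value, pv$p_value)
})

test_that("diagnostics report serializes verdicts to JSON", {
  sc <- scenario_config(extent_km = 10, buffer_km = 2, n_animals = 10, K = 8,
                        searchers = 1, daily_km = 25, lam0 = 0.1)
  sim <- simulate_survey(sc, seed = 13)
  enc <- build_encounter_array(sim$sightings, sim$effort)
  fit <- run_chains(enc, sim$space, M = 40, variant = model_variant(3),
                    config = sampler_config(iterations = 400, burnin = 100,
                                            thin = 2, chains = 2, seed = 2))
  rep <- diagnostics_report(fit, ndraws = 50, seed = 3)
  f <- tempfile(fileext = ".json")
  write_diagnostics(rep, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$model, 3)
  expect_equal(j$bayesian_p_value, rep$p_value)
  expect_type(j$converged, "logical")
  expect_equal(length(j$posterior), nrow(rep$summary$table))
})
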