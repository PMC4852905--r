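# small survey + fit used by several blocks
small_fit <- function(iterations = 300, burnin = 100, chains = 2, seed = 5,
                      variant = model_variant(1), M = 60, sim_seed = 7,
                      scales = NULL) {
  sc <- scenario_config(extent_km = 12, buffer_km = 3, n_animals = 15, K = 10,
                        searchers = 1, daily_km = 30, lam0 = 0.08)
  sim <- simulate_survey(sc, seed = sim_seed)
  enc <- build_encounter_array(sim$sightings, sim$effort)
  cfg <- sampler_config(iterations = iterations, burnin = burnin, thin = 2,
                        chains = chains, seed = seed,
                        proposal_scales = scales)
  list(sim = sim, enc = enc,
       fit = run_chains(enc, sim$space, M = M, variant = variant,
                        config = cfg))
}

test_that("conjugate psi update has the Beta posterior mean", {
  set.seed(1)
  z <- c(rep(1, 150), rep(0, 185))  # M = 335
  draws <- replicate(1e5, gibbs_update_psi(z))
  expect_equal(mean(draws), 151 / 337,
               tolerance = 3 * sd(draws) / sqrt(1e5) / (151 / 337))
  # sum z = 0: Beta(1, 1 + M) with mean 1 / (M + 2)
  set.seed(2)
  d0 <- replicate(2e4, gibbs_update_psi(rep(0, 10)))
  expect_equal(mean(d0), 1 / 12, tolerance = 0.02)
})

test_that("inclusion and sex full conditionals match hand computations", {
  expect_equal(inclusion_prob(0.37, 1), 0.37)      # zero effort: q = 1
  expect_equal(inclusion_prob(0.5, 0.81), 0.81 / 1.81)
  expect_equal(sex_conditional_prob(0.5, -1.3, -1.3), 0.5)
  # single-cell toy: pi_F = 0.1, pi_M = 0.3, undetected
  expect_equal(sex_conditional_prob(0.5, log(0.7), log(0.9)), 0.7 / 1.6)
  # no effort anywhere: equal likelihoods, probability psi_sex
  expect_equal(sex_conditional_prob(0.23, 0, 0), 0.23)
})

test_that("retained-draw bookkeeping follows (iterations - burnin) / thin", {
  out <- small_fit(iterations = 200, burnin = 100, chains = 2)
  expect_length(out$fit$chains, 2)
  for (ch in out$fit$chains)
    expect_equal(nrow(ch$draws), (200 - 100) %/% 2)
  # N_super consistency with the stored inclusion trace
  ch <- out$fit$chains[[1]]
  expect_equal(rowSums(ch$z), unname(ch$draws[, "N_super"]))
  expect_equal(ch$draws[, "D"],
               density_from_nsuper(ch$draws[, "N_super"],
                                   out$fit$suitable_area))
  # detected individuals always included; centres always suitable pixels
  expect_true(all(ch$z[, seq_len(out$enc$n)] == 1))
  expect_true(all(ch$s >= 1 & ch$s <= sum(out$sim$space$suitable)))
  # observed sexes never change
  expect_true(all(t(ch$sex[, seq_len(out$enc$n)]) == out$enc$sex))
})

test_that("runs with identical seeds are bit-identical", {
  a <- small_fit(seed = 42)
  b <- small_fit(seed = 42)
  expect_identical(a$fit$chains[[1]]$draws, b$fit$chains[[1]]$draws)
  expect_identical(a$fit$chains[[2]]$s, b$fit$chains[[2]]$s)
  c2 <- small_fit(seed = 43)
  expect_false(identical(a$fit$chains[[1]]$draws, c2$fit$chains[[1]]$draws))
})

test_that("zero proposal scale freezes a coordinate", {
  out <- small_fit(scales = c(theta_t = 0, beta_eff = 0))
  d <- pooled_draws(out$fit)
  expect_equal(unique(d[, "theta"]), 0.75)   # stays at its initial value
  expect_equal(unique(d[, "beta_eff"]), 0)
  expect_gt(length(unique(d[, "lam0"])), 10) # others move
})

test_that("fixed parameters never move under variants 3 and 4", {
  out3 <- small_fit(variant = model_variant(3))
  d3 <- pooled_draws(out3$fit)
  expect_true(all(d3[, "beta_sex"] == 0))
  expect_true(all(d3[, "theta"] == 0.75))
  out4 <- small_fit(variant = model_variant(4, theta_fixed = 0.6))
  d4 <- pooled_draws(out4$fit)
  expect_true(all(d4[, "theta"] == 0.6))
  expect_false(all(d4[, "beta_sex"] == 0))
})

test_that("M not exceeding n is rejected", {
  out <- small_fit()
  expect_error(run_chains(out$enc, out$sim$space, M = out$enc$n,
                          variant = model_variant(1),
                          config = sampler_config(iterations = 10, burnin = 5,
                                                  chains = 2)),
               "M must exceed")
})

test_that("a too-small M triggers the psi range warning", {
  out <- small_fit()
  expect_warning(
    run_chains(out$enc, out$sim$space, M = out$enc$n + 2,
               variant = model_variant(1),
               config = sampler_config(iterations = 150, burnin = 50,
                                       chains = 2, seed = 3)),
    "psi")
})

test_that("MCMC marginals of (z, s) match complete enumeration on a tiny instance", {
  # 3 x 2 state space (6 suitable pixels), 2 x 2 traps, K = 2, M = 3 with one
  # detected individual; detection parameters held fixed so the posterior over
  # (z, s) with psi integrated out is exactly enumerable.
  sp <- build_state_space(c(0, 3, 0, 2), side = 1)
  tr <- build_trap_grid(c(0, 2, 0, 2), side = 1)
  effmat <- matrix(c(1.5, 0.8, 2.0, 1.0,
                     1.0, 1.2, 0.5, 2.0), nrow = 4)
  eff <- toy_effort(tr, effmat)
  sg <- toy_sightings(list("A", "F", 0.5, 1.5, 0),  # trap 1, day 1
                      list("A", "F", 1.5, 0.5, 1))  # trap 4, day 2
  enc <- build_encounter_array(sg, eff)
  D <- distance_matrix(sp, tr)
  pars <- list(lam0 = 0.3, beta_eff = 0.2, beta_sex = 0,
               sigma_F = 1.2, sigma_M = 1.2, theta = 0.75)
  M <- 3

  # ---- exact enumeration (independent triple-loop oracle) --------------
  states <- expand.grid(z2 = 0:1, z3 = 0:1, s1 = 1:6, s2 = 1:6, s3 = 1:6)
  w <- numeric(nrow(states))
  for (r in seq_len(nrow(states))) {
    st <- states[r, ]
    z <- c(1, st$z2, st$z3)
    ll <- oracle_loglik(pars, z, sex = c(0, 0, 0),
                        s = c(st$s1, st$s2, st$s3),
                        det = enc$det, effmat = effmat, distmat = D)
    # psi integrated against Beta(1,1): Beta(1 + sum z, 1 + M - sum z)
    w[r] <- exp(ll) * beta(1 + sum(z), 1 + M - sum(z))
  }
  w <- w / sum(w)
  pz2 <- sum(w[states$z2 == 1])
  ps1 <- vapply(1:6, function(g) sum(w[states$s1 == g]), numeric(1))
  ps2 <- vapply(1:6, function(g) sum(w[states$s2 == g]), numeric(1))

  # ---- MCMC with detection parameters frozen at the oracle's values ----
  fit <- run_chains(enc, sp, M = 3, variant = model_variant(1),
    config = sampler_config(
      iterations = 42000, burnin = 2000, thin = 1, chains = 1,
      proposal_scales = c(log_lam0 = 0, beta_eff = 0, beta_sex = 0,
                          log_sigma_F = 0, log_sigma_M = 0, theta_t = 0),
      ac_halfwidth = 10, adapt = FALSE, seed = 17),
    init = pars)
  ch <- fit$chains[[1]]
  expect_true(all(ch$draws[, "lam0"] == pars$lam0))  # frozen as intended

  I_z2 <- ch$z[, 2]
  expect_lt(abs(mean(I_z2) - pz2), 3 * max(mcse(I_z2), 1e-3))
  for (g in 1:6) {
    I1 <- as.integer(ch$s[, 1] == g)
    expect_lt(abs(mean(I1) - ps1[g]), 3 * max(mcse(I1), 1e-3))
    I2g <- as.integer(ch$s[, 2] == g)
    expect_lt(abs(mean(I2g) - ps2[g]), 3 * max(mcse(I2g), 1e-3))
  }
})
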