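# Small hand-buildable fixtures and independent oracles used across tests.

# effort grid built directly from a matrix (J x K)
toy_effort <- function(traps, effmat,
                       occasions = seq(as.Date("2014-08-01"), by = "day",
                                       length.out = ncol(effmat))) {
  structure(list(effort = effmat, occasions = occasions, traps = traps),
            class = "effort_grid")
}

# sightings data frame from (id, sex, x, y, day-offset) rows
toy_sightings <- function(..., start = as.Date("2014-08-01")) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(individual_id = r[[1]], sex = r[[2]],
               x_km = as.numeric(r[[3]]), y_km = as.numeric(r[[4]]),
               date = start + as.integer(r[[5]]), time = "12:00:00",
               stringsAsFactors = FALSE)))
}

# Independent brute-force oracle for the complete-data log-likelihood:
# plain triple loop, probabilities written out from the cloglog formula,
# no shared code with the package internals.
oracle_loglik <- function(pars, z, sex, s, det, effmat, distmat) {
  M <- length(z); J <- nrow(effmat); K <- ncol(effmat)
  y <- array(0L, dim = c(M, J, K))
  if (nrow(det)) y[as.matrix(det)] <- 1L
  ll <- 0
  for (i in 1:M) {
    if (z[i] == 0) next
    sigma <- if (sex[i] == 1) pars$sigma_M else pars$sigma_F
    for (j in 1:J) for (k in 1:K) {
      if (effmat[j, k] <= 0) next
      eta <- log(pars$lam0) + pars$beta_eff * log(effmat[j, k]) +
        pars$beta_sex * sex[i] -
        (distmat[s[i], j] / sigma)^(2 * pars$theta)
      p <- 1 - exp(-exp(eta))
      ll <- ll + if (y[i, j, k] == 1) log(p) else log(1 - p)
    }
  }
  ll
}

# random small SECR instance for oracle comparisons
random_instance <- function(M = 4, J = 6, K = 3) {
  space <- build_state_space(c(0, 3, 0, 2), side = 1)
  traps <- build_trap_grid(c(0, 3, 0, 2), side = 1)
  effmat <- matrix(round(stats::runif(J * K, 0, 3), 2), J, K)
  effmat[sample(J * K, 3)] <- 0
  eff <- toy_effort(traps, effmat)
  pars <- scr_params(lam0 = stats::runif(1, 0.05, 0.5),
                     beta_eff = stats::rnorm(1, 0, 0.3),
                     beta_sex = stats::rnorm(1, 0, 0.3),
                     sigma_F = stats::runif(1, 0.5, 2),
                     sigma_M = stats::runif(1, 1, 4),
                     theta = stats::runif(1, 0.5, 1))
  z <- c(1, 1, rbinom(M - 2, 1, 0.5))
  sex <- rbinom(M, 1, 0.5)
  s <- sample.int(sum(space$suitable), M, replace = TRUE)
  # detections (both detected individuals get at least one) in active cells
  act <- which(effmat > 0, arr.ind = TRUE)
  pick <- act[sample(nrow(act), 3, replace = TRUE), , drop = FALSE]
  det <- unique(data.frame(ind = c(1L, 2L, sample(1:2, 1)),
                           trap = pick[, 1], occ = pick[, 2]))
  sightings <- data.frame(
    individual_id = sprintf("A%d", det$ind),
    sex = c("F", "M")[sex[det$ind] + 1],
    x_km = traps$x[det$trap], y_km = traps$y[det$trap],
    date = eff$occasions[det$occ], time = NA_character_)
  enc <- suppressWarnings(build_encounter_array(sightings, eff))
  list(space = space, traps = traps, eff = enc$effort, enc = enc,
       pars = pars, z = z, sex = sex, s = s,
       det = enc$det, effmat = enc$effort$effort,
       distmat = distance_matrix(space, traps))
}

# batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) series
mcse <- function(x, batches = 50) {
  n <- length(x)
  b <- floor(n / batches)
  m <- colMeans(matrix(x[seq_len(b * batches)], nrow = b))
  stats::sd(m) / sqrt(batches)
}

# minimal hand-built scr_fit for diagnostics tests
fake_fit <- function(draws_list, s_list = NULL, z_list = NULL,
                     sex_list = NULL, space = NULL, variant = model_variant(1),
                     M = NULL) {
  chains <- lapply(seq_along(draws_list), function(cc) {
    ch <- list(draws = draws_list[[cc]])
    if (!is.null(s_list)) {
      ch$s <- s_list[[cc]]; ch$z <- z_list[[cc]]; ch$sex <- sex_list[[cc]]
    }
    ch
  })
  if (is.null(space)) space <- build_state_space(c(0, 2, 0, 2), side = 0.65)
  structure(
    list(chains = chains, variant = variant,
         config = sampler_config(iterations = 10, burnin = 2, chains = length(chains)),
         M = M %||% ncol(s_list[[1]] %||% matrix(0, 1, 3)),
         n = 1, enc = NULL, space = space,
         suitable_area = suitable_area(space), pixel_area = space$side^2),
    class = "scr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
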