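#' Model parameters for the sex-specific SECR observation model
#'
#' @param lam0 basal encounter rate: expected encounters of an individual in
#'   one trap on one occasion when its activity centre sits on the trap
#'   centroid and 1 km of effort was spent there. Must be > 0.
#' @param beta_eff change in the cloglog of detection probability per unit
#'   log(effort in km).
#' @param beta_sex male minus female offset on the cloglog scale
#'   (female = 0, male = 1).
#' @param sigma_F,sigma_M sex-specific movement/detection scales (km); the
#'   rate at which detection probability declines with distance between the
#'   activity centre and the trap centroid. Must be > 0.
#' @param theta detection-function shape in `[0.5, 1]`: 0.5 gives a
#'   negative-exponential decline (activity concentrated at the centre),
#'   1 a Gaussian decline (more diffuse space use).
#' @param psi data-augmentation inclusion probability in (0, 1).
#' @param psi_sex proportion of the population that is male, in (0, 1).
#' @return a validated `scr_params` list.
#' @export
scr_params <- function(lam0, beta_eff = 0, beta_sex = 0,
                       sigma_F, sigma_M, theta = 0.75,
                       psi = 0.5, psi_sex = 0.5) {
  p <- structure(
    list(lam0 = lam0, beta_eff = beta_eff, beta_sex = beta_sex,
         sigma_F = sigma_F, sigma_M = sigma_M, theta = theta,
         psi = psi, psi_sex = psi_sex),
    class = "scr_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(p$lam0 > 0, p$sigma_F > 0, p$sigma_M > 0,
            p$theta >= 0.5, p$theta <= 1,
            p$psi > 0, p$psi < 1, p$psi_sex > 0, p$psi_sex < 1)
  invisible(p)
}

#' Candidate model variants
#'
#' Four a priori model structures differing in whether the sex offset on
#' detection probability is estimated and whether the detection-function
#' shape is estimated:
#' * 1: `beta_sex` free, `theta` free — the full model;
#' * 2: `beta_sex = 0` fixed, `theta` free (sigma stays sex-specific);
#' * 3: `beta_sex = 0` fixed, `theta` fixed;
#' * 4: `beta_sex` free, `theta` fixed.
#'
#' @param variant integer 1-4.
#' @param theta_fixed the value at which `theta` is held when fixed
#'   (default 0.75, the midpoint hybrid between negative-exponential and
#'   Gaussian).
#' @return a `model_variant` list with flags `fix_beta_sex`, `fix_theta`.
#' @export
model_variant <- function(variant, theta_fixed = 0.75) {
  stopifnot(variant %in% 1:4)
  structure(
    list(variant = as.integer(variant),
         fix_beta_sex = variant %in% c(2, 3),
         fix_theta = variant %in% c(3, 4),
         theta_fixed = theta_fixed),
    class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat(sprintf("model %d: beta_sex %s, theta %s\n", x$variant,
              if (x$fix_beta_sex) "= 0 (fixed)" else "free",
              if (x$fix_theta) sprintf("= %.3g (fixed)", x$theta_fixed)
              else "free"))
  invisible(x)
}

#' Detection kernel decay term
#'
#' `f(d) = (d / sigma)^(2 theta)`, the distance penalty subtracted from the
#' cloglog linear predictor. `exp(-f)` is Gaussian in `d` at `theta = 1` and
#' negative-exponential at `theta = 0.5`; `sigma` keeps km units for every
#' shape.
#'
#' @param d distance(s) in km, `>= 0`.
#' @param sigma movement scale in km, `> 0`.
#' @param theta shape in `[0.5, 1]`.
#' @return `f(d)`, same length as `d`.
#' @export
detection_kernel <- function(d, sigma, theta) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  stopifnot(all(d >= 0), all(theta >= 0.5), all(theta <= 1))
  (d / sigma)^(2 * theta)
}

#' Per-cell encounter probability
#'
#' Complementary log-log observation model:
#' `cloglog(pi) = log(lam0) + beta_eff * log(effort) + beta_sex * sex - f(d)`,
#' so `pi = 1 - exp(-exp(eta))`. A trap with zero effort on an occasion is
#' inactive and has probability 0 by contract (no `log(0)` is evaluated).
#'
#' @param params an `scr_params`.
#' @param sex 0 (female) or 1 (male); selects `sigma_F` or `sigma_M` and
#'   applies the `beta_sex` offset.
#' @param d distance (km) between activity centre and trap centroid.
#' @param effort km of search effort in the trap-occasion cell, `>= 0`.
#' @return detection probability in `[0, 1)`; vectorized over `d`/`effort`.
#' @export
encounter_prob <- function(params, sex, d, effort) {
  validate_params(params)
  stopifnot(all(sex %in% c(0, 1)), all(effort >= 0))
  n <- max(length(d), length(effort), length(sex))
  d <- rep_len(d, n); effort <- rep_len(effort, n); sex <- rep_len(sex, n)
  pi <- numeric(n)
  act <- effort > 0
  if (any(act)) {
    sigma <- ifelse(sex[act] == 1, params$sigma_M, params$sigma_F)
    eta <- log(params$lam0) + params$beta_eff * log(effort[act]) +
      params$beta_sex * sex[act] -
      detection_kernel(d[act], sigma, params$theta)
    pi[act] <- -expm1(-exp(eta))
  }
  pi
}

#' Complete-data log-likelihood of the augmented SECR model
#'
#' Bernoulli log-likelihood of the encounter histories given all latent
#' quantities, summed over individuals with `z = 1` and active trap-days.
#' Individuals with `z = 0` contribute nothing from the detection model;
#' detected individuals must have `z = 1`.
#'
#' This is the reference (clear, loop-structured) evaluation used by tests
#' and small problems; the sampler uses an algebraically identical cached
#' form that is checked against this one.
#'
#' @param params an `scr_params`.
#' @param state list with `z` (0/1, length M), `sex` (0/1, length M) and `s`
#'   (length M; row index into `distmat` of each activity centre).
#' @param enc an `encounter_data` (detected individuals come first; rows
#'   `n+1..M` are the all-zero augmented histories).
#' @param effort an `effort_grid` (usually `enc$effort`, i.e. after any
#'   effort flooring).
#' @param distmat suitable-pixel x trap distance matrix (km), see
#'   [distance_matrix()].
#' @return the log-likelihood (scalar).
#' @export
complete_data_loglik <- function(params, state, enc, effort, distmat) {
  validate_params(params)
  stopifnot(inherits(enc, "encounter_data"), inherits(effort, "effort_grid"))
  M <- length(state$z)
  stopifnot(length(state$sex) == M, length(state$s) == M, M >= enc$n)
  if (any(state$z[seq_len(enc$n)] != 1))
    stop("detected individuals must have z = 1")
  effmat <- effort$effort
  if (any(effmat[cbind(enc$det$trap, enc$det$occ)] == 0))
    stop("detection recorded at an inactive trap-day; apply the effort floor upstream")
  y <- encounter_array(enc)
  J <- nrow(effmat); K <- ncol(effmat)
  ll <- 0
  for (i in seq_len(M)) {
    if (state$z[i] == 0) next
    yi <- if (i <= enc$n) y[i, , ] else matrix(0L, J, K)
    pi <- encounter_prob(params, state$sex[i],
                         d = rep(distmat[state$s[i], ], times = K),
                         effort = as.vector(effmat))
    act <- as.vector(effmat) > 0
    yv <- as.vector(yi)[act]
    pv <- pi[act]
    ll <- ll + sum(yv * log(pv) + (1 - yv) * log1p(-pv))
  }
  ll
}

#' Log prior density of the model parameters (up to a constant)
#'
#' Flat improper priors on `log(lam0)`, `beta_eff` and `beta_sex`; flat
#' `Uniform[0, Inf)` on each sigma; `Uniform(0.5, 1)` on `theta`;
#' `Beta(1, 1)` on `psi` and on `psi_sex`. Parameters fixed by the model
#' variant contribute nothing. Returns `-Inf` outside any support.
#'
#' @param params an `scr_params`.
#' @param variant a `model_variant`.
#' @return log prior density up to an additive constant.
#' @export
log_prior <- function(params, variant = model_variant(1)) {
  p <- params
  if (!is.numeric(p$lam0) || p$lam0 <= 0) return(-Inf)
  if (p$sigma_F <= 0 || p$sigma_M <= 0) return(-Inf)
  if (p$psi <= 0 || p$psi >= 1) return(-Inf)
  if (p$psi_sex <= 0 || p$psi_sex >= 1) return(-Inf)
  if (!variant$fix_theta && (p$theta < 0.5 || p$theta > 1)) return(-Inf)
  0
}

#' Sex ratio implied by the proportion male
#'
#' @param psi_sex proportion of the population that is male, in (0, 1).
#' @return `(1 - psi_sex) / psi_sex`, the number of females per male.
#' @export
sex_ratio <- function(psi_sex) {
  if (any(psi_sex <= 0) || any(psi_sex >= 1))
    stop("psi_sex must lie strictly in (0, 1)")
  (1 - psi_sex) / psi_sex
}

#' Density from superpopulation size
#'
#' @param n_super number of individuals in the state space (posterior draw
#'   or posterior mean).
#' @param suitable_area_km2 area (km^2) of suitable habitat in the state
#'   space, `> 0`.
#' @return density in individuals per 100 km^2 of suitable habitat.
#' @export
density_from_nsuper <- function(n_super, suitable_area_km2) {
  if (!is.numeric(suitable_area_km2) || suitable_area_km2 <= 0)
    stop("suitable_area_km2 must be > 0")
  100 * n_super / suitable_area_km2
}
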