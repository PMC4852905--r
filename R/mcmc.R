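#' Sampler configuration
#'
#' @param iterations MCMC iterations per chain (default 11000).
#' @param burnin burn-in iterations discarded (default 1000).
#' @param thin thinning interval for retained draws (default 2, so the
#'   defaults retain `(11000 - 1000) / 2 = 5000` draws per chain).
#' @param chains number of independent chains (default 8; at least 2 are
#'   needed for convergence diagnostics).
#' @param proposal_scales named numeric of random-walk SDs on the sampling
#'   scales `log_lam0`, `beta_eff`, `beta_sex`, `log_sigma_F`,
#'   `log_sigma_M`, `theta_t` (logit of the rescaled shape). A scale of 0
#'   freezes that coordinate.
#' @param ac_halfwidth half-width (in state-space pixels) of the square
#'   proposal window for activity-centre moves (default 10).
#' @param adapt adapt proposal scales (Robbins-Monro toward ~35%
#'   acceptance) and the activity-centre window (toward 20-60%) during
#'   burn-in only; scales are frozen afterwards so retained draws satisfy
#'   detailed balance.
#' @param adapt_window iterations per adaptation step (default 50).
#' @param store_ac store per-draw latent states (activity centres, z, sex);
#'   required for density surfaces and posterior predictive checks.
#' @param seed master RNG seed; per-chain seeds are derived from it.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(iterations = 11000, burnin = 1000, thin = 2,
                           chains = 8, proposal_scales = NULL,
                           ac_halfwidth = 10, adapt = TRUE,
                           adapt_window = 50, store_ac = TRUE, seed = 1) {
  stopifnot(burnin < iterations, thin >= 1, chains >= 1)
  def <- c(log_lam0 = 0.4, beta_eff = 0.15, beta_sex = 0.5,
           log_sigma_F = 0.25, log_sigma_M = 0.25, theta_t = 0.6)
  if (!is.null(proposal_scales)) def[names(proposal_scales)] <- proposal_scales
  structure(
    list(iterations = as.integer(iterations), burnin = as.integer(burnin),
         thin = as.integer(thin), chains = as.integer(chains),
         proposal_scales = def, ac_halfwidth = as.integer(ac_halfwidth),
         adapt = isTRUE(adapt), adapt_window = as.integer(adapt_window),
         store_ac = isTRUE(store_ac), seed = as.integer(seed)),
    class = "sampler_config")
}

#' Conjugate Gibbs draw for the inclusion probability psi
#'
#' With `[N_super | M, psi] ~ Bin(M, psi)` and a `Beta(1, 1)` prior, the
#' full conditional is `Beta(1 + sum(z), 1 + M - sum(z))`.
#'
#' @param z 0/1 inclusion vector of length M.
#' @param M augmented population size (default `length(z)`).
#' @return one draw of psi.
#' @export
gibbs_update_psi <- function(z, M = length(z)) {
  stats::rbeta(1, 1 + sum(z), 1 + M - sum(z))
}

#' Full-conditional inclusion probability of an undetected individual
#'
#' `Pr(z = 1 | .) = psi * q / (psi * q + 1 - psi)` where `q` is the
#' probability of the all-zero encounter history at the individual's
#' activity centre and sex.
#'
#' @param psi inclusion probability.
#' @param q probability of an all-zero history (`prod(1 - pi)` over active
#'   cells); vectorized.
#' @return `Pr(z = 1 | .)`, same length as `q`.
#' @export
inclusion_prob <- function(psi, q) {
  psi * q / (psi * q + 1 - psi)
}

#' Full-conditional probability that a latent individual is male
#'
#' Odds male : female are `psi_sex * L_M : (1 - psi_sex) * L_F`, with the
#' likelihoods supplied on the log scale.
#'
#' @param psi_sex proportion male.
#' @param loglik_M,loglik_F log-likelihood of the individual's (all-zero)
#'   history under male and female parameters; vectorized.
#' @return `Pr(male | .)`.
#' @export
sex_conditional_prob <- function(psi_sex, loglik_M, loglik_F) {
  stats::plogis(log(psi_sex) - log1p(-psi_sex) + loglik_M - loglik_F)
}

# detection kernel rows exp(-f) for a block of individuals
kern_rows <- function(Drows, sigma, theta) exp(-(Drows / sigma)^(2 * theta))

# stable log(pi) + h for detected cells, with pi = 1 - exp(-h)
det_term <- function(h) log(-expm1(-h)) + h

#' Run the Metropolis-Hastings-within-Gibbs sampler
#'
#' Fits one of the four candidate sex-specific SECR models to search-
#' encounter data by MCMC over the free detection parameters and the
#' augmented latent state (activity centres, inclusion indicators, latent
#' sexes). Update order within a sweep: detection parameters, activity
#' centres, z, sex and psi_sex, psi, so the conjugate steps run last and
#' the recorded `N_super` is consistent within the iteration.
#'
#' Initialization: activity centres of detected individuals at the nearest
#' suitable pixel to the centroid of their detections, augmented ones
#' uniform over suitable pixels; sigmas at per-sex MMDM/2 (floored at
#' 0.5 km); `lam0` at detections per total effort km; `psi` at `n / M`;
#' `theta` at 0.75.
#'
#' @param enc an `encounter_data` (carries the effort grid).
#' @param space the `state_space` of candidate activity centres.
#' @param M augmented population size `n + n_z`; choose it so the posterior
#'   of `psi` stays inside (0.2, 0.8) — a warning is raised otherwise.
#' @param variant a `model_variant` (default the full model 1).
#' @param config a `sampler_config`.
#' @param init optional named list overriding initial parameter values
#'   (`lam0`, `beta_eff`, `beta_sex`, `sigma_F`, `sigma_M`, `theta`, `psi`,
#'   `psi_sex`); combined with zero proposal scales this holds parameters
#'   at fixed values.
#' @return an `scr_fit`: per-chain draw matrices (columns `lam0`,
#'   `beta_eff`, `beta_sex`, `sigma_F`, `sigma_M`, `theta`, `psi`,
#'   `psi_sex`, `N_super`, `D`), optional latent traces, acceptance rates,
#'   and references to the inputs.
#' @export
run_chains <- function(enc, space, M, variant = model_variant(1),
                       config = sampler_config(), init = NULL) {
  stopifnot(inherits(enc, "encounter_data"), inherits(space, "state_space"),
            inherits(variant, "model_variant"),
            inherits(config, "sampler_config"))
  if (M <= enc$n) stop("M must exceed the number of detected individuals")
  effort <- enc$effort
  traps <- effort$traps
  suit <- which(space$suitable)
  Dsuit <- distance_matrix(space, traps, suitable_only = TRUE)
  sarea <- suitable_area(space)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)

  chains <- vector("list", config$chains)
  for (cc in seq_len(config$chains)) {
    chains[[cc]] <- run_one_chain(enc, space, suit, Dsuit, M, variant,
                                  config, chain_seeds[cc], init)
  }
  fit <- structure(
    list(chains = chains, variant = variant, config = config, M = M,
         n = enc$n, enc = enc, space = space,
         suitable_area = sarea, pixel_area = space$side^2,
         chain_seeds = chain_seeds),
    class = "scr_fit")
  pm_psi <- mean(unlist(lapply(chains, function(ch) ch$draws[, "psi"])))
  if (pm_psi < 0.2 || pm_psi > 0.8)
    warning(sprintf(
      "posterior mean psi = %.2f lies outside (0.2, 0.8); reconsider M", pm_psi))
  fit
}

run_one_chain <- function(enc, space, suit, Dsuit, M, variant, config, seed,
                          init = NULL) {
  set.seed(seed)
  effmat <- enc$effort$effort
  J <- nrow(effmat); K <- ncol(effmat)
  Gs <- length(suit)
  n <- enc$n
  total_eff <- sum(effmat)

  # active-cell structures
  active <- effmat > 0
  logeff <- matrix(0, J, K); logeff[active] <- log(effmat[active])
  E_of <- function(beff) {
    w <- matrix(0, J, K); w[active] <- exp(beff * logeff[active])
    rowSums(w)
  }

  # detections
  di <- enc$det$ind; dj <- enc$det$trap; dk <- enc$det$occ
  dlogeff <- logeff[cbind(dj, dk)]
  ndet <- length(di)

  # suitable-pixel lookup grids for activity-centre proposals
  rcr <- ((suit - 1L) %/% space$nx) + 1L
  rcc <- ((suit - 1L) %% space$nx) + 1L
  idxmat <- matrix(NA_integer_, space$ny, space$nx)
  idxmat[cbind(rcr, rcc)] <- seq_len(Gs)

  # neighbour lists are cached per window half-width (w changes only a few
  # times, during burn-in adaptation)
  nbcache <- new.env(parent = emptyenv())
  neighbours <- function(w) {
    key <- as.character(w)
    nb <- nbcache[[key]]
    if (is.null(nb)) {
      nb <- vector("list", Gs)
      for (g in seq_len(Gs)) {
        r0 <- max(1L, rcr[g] - w); r1 <- min(space$ny, rcr[g] + w)
        c0 <- max(1L, rcc[g] - w); c1 <- min(space$nx, rcc[g] + w)
        v <- idxmat[r0:r1, c0:c1]
        nb[[g]] <- v[!is.na(v)]
      }
      nbcache[[key]] <- nb
    }
    nb
  }

  # ---- initial state -------------------------------------------------
  detected <- seq_len(M) <= n
  tx <- enc$effort$traps$x; ty <- enc$effort$traps$y
  sx <- space$x[suit]; sy <- space$y[suit]
  s <- integer(M)
  permax <- numeric(n)
  for (i in seq_len(n)) {
    jj <- dj[di == i]
    cx <- mean(tx[jj]); cy <- mean(ty[jj])
    s[i] <- which.min((sx - cx)^2 + (sy - cy)^2)
    permax[i] <- if (length(jj) > 1)
      max(stats::dist(cbind(tx[jj], ty[jj]))) else 0
  }
  s[!detected] <- sample.int(Gs, M - n, replace = TRUE)
  sexm <- integer(M)
  sexm[detected] <- enc$sex
  p <- list(lam0 = max(ndet / max(total_eff, 1), 1e-4),
            beta_eff = 0, beta_sex = 0,
            sigma_F = max(mean(permax[enc$sex == 0]) / 2, 0.5, na.rm = TRUE),
            sigma_M = max(mean(permax[enc$sex == 1]) / 2, 0.5, na.rm = TRUE),
            theta = if (variant$fix_theta) variant$theta_fixed else 0.75,
            psi = min(max(n / M, 0.05), 0.95),
            psi_sex = min(max(mean(enc$sex), 0.1), 0.9))
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(p))
    if (length(bad)) stop("unknown init parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(init)] <- init
  }
  if (variant$fix_beta_sex) p$beta_sex <- 0
  if (variant$fix_theta) p$theta <- variant$theta_fixed
  sexm[!detected] <- stats::rbinom(M - n, 1, p$psi_sex)
  z <- integer(M); z[detected] <- 1L
  z[!detected] <- stats::rbinom(M - n, 1, p$psi)

  # ---- cached quantities --------------------------------------------
  sig_of <- function(p, sexv) ifelse(sexv == 1, p$sigma_M, p$sigma_F)
  Ds <- Dsuit[s, , drop = FALSE]
  E <- E_of(p$beta_eff)
  make_kern <- function(p) {
    Kn <- matrix(0, M, J)
    f <- sexm == 0
    if (any(f)) Kn[f, ] <- kern_rows(Ds[f, , drop = FALSE], p$sigma_F, p$theta)
    if (any(!f)) Kn[!f, ] <- kern_rows(Ds[!f, , drop = FALSE], p$sigma_M, p$theta)
    Kn
  }
  Kern <- make_kern(p)
  KE <- drop(Kern %*% E)
  kd <- if (ndet) Kern[cbind(di, dj)] else numeric(0)

  # per-individual log-likelihood pieces given scalars of p and (KE, kd)
  pieces <- function(p, KE, kd) {
    A <- exp(log(p$lam0) + p$beta_sex * sexm)
    H <- A * KE
    detll <- numeric(M)
    if (ndet) {
      dh <- A[di] * exp(p$beta_eff * dlogeff) * kd
      agg <- rowsum(det_term(dh), di)
      detll[as.integer(rownames(agg))] <- agg
    }
    list(H = H, lli = -H + detll)
  }
  cur <- pieces(p, KE, kd)
  tot_ll <- function(lli) sum(lli[z == 1])

  retry <- 0
  while (!is.finite(tot_ll(cur$lli)) && retry < 10) {
    retry <- retry + 1
    s[!detected] <- sample.int(Gs, M - n, replace = TRUE)
    Ds <- Dsuit[s, , drop = FALSE]
    Kern <- make_kern(p)
    KE <- drop(Kern %*% E)
    kd <- if (ndet) Kern[cbind(di, dj)] else numeric(0)
    cur <- pieces(p, KE, kd)
  }
  if (!is.finite(tot_ll(cur$lli)))
    stop("non-finite log-likelihood at the initial state after retries")

  # ---- bookkeeping ---------------------------------------------------
  scales <- config$proposal_scales
  free <- c(log_lam0 = TRUE, beta_eff = TRUE,
            beta_sex = !variant$fix_beta_sex,
            log_sigma_F = TRUE, log_sigma_M = TRUE,
            theta_t = !variant$fix_theta)
  pnames <- names(free)[free & scales[names(free)] > 0]
  acc <- att <- stats::setNames(numeric(length(pnames)), pnames)
  acc_tot <- att_tot <- stats::setNames(numeric(length(pnames)), pnames)
  ac_acc <- ac_att <- 0; ac_acc_tot <- ac_att_tot <- 0
  w <- config$ac_halfwidth
  adapt_step <- 0

  nkeep <- (config$iterations - config$burnin) %/% config$thin
  parcols <- c("lam0", "beta_eff", "beta_sex", "sigma_F", "sigma_M",
               "theta", "psi", "psi_sex", "N_super", "D")
  draws <- matrix(NA_real_, nkeep, length(parcols),
                  dimnames = list(NULL, parcols))
  if (config$store_ac) {
    s_tr <- matrix(NA_integer_, nkeep, M)
    z_tr <- matrix(NA_integer_, nkeep, M)
    sex_tr <- matrix(NA_integer_, nkeep, M)
  }
  sarea <- suitable_area(space)
  # sigma prior is Uniform[0, sigma_max]; the cap (the state-space diagonal)
  # keeps the posterior proper when the kernel saturates at large sigma
  sigma_max <- sqrt((space$nx * space$side)^2 + (space$ny * space$side)^2)
  kept <- 0

  for (iter in seq_len(config$iterations)) {
    cll <- tot_ll(cur$lli)

    # ---- detection parameters (one-at-a-time random walk MH) --------
    for (pn in pnames) {
      att[pn] <- att[pn] + 1
      p2 <- p; jac <- 0
      if (pn == "log_lam0") {
        p2$lam0 <- exp(log(p$lam0) + stats::rnorm(1, 0, scales[pn]))
        new_KE <- KE; new_kd <- kd
      } else if (pn == "beta_eff") {
        p2$beta_eff <- p$beta_eff + stats::rnorm(1, 0, scales[pn])
        new_KE <- drop(Kern %*% E_of(p2$beta_eff)); new_kd <- kd
      } else if (pn == "beta_sex") {
        p2$beta_sex <- p$beta_sex + stats::rnorm(1, 0, scales[pn])
        new_KE <- KE; new_kd <- kd
      } else if (pn %in% c("log_sigma_F", "log_sigma_M")) {
        female <- pn == "log_sigma_F"
        sig <- if (female) p$sigma_F else p$sigma_M
        sig2 <- exp(log(sig) + stats::rnorm(1, 0, scales[pn]))
        if (sig2 > sigma_max) next   # outside the Uniform[0, sigma_max] support
        if (female) p2$sigma_F <- sig2 else p2$sigma_M <- sig2
        jac <- log(sig2) - log(sig)  # flat prior on sigma, walk on log sigma
        rows <- which(sexm == as.integer(!female))
        new_KE <- KE; new_kd <- kd
        if (length(rows)) {
          Kr <- kern_rows(Ds[rows, , drop = FALSE], sig2, p$theta)
          new_KE[rows] <- drop(Kr %*% E)
          if (ndet) {
            dc <- which(di %in% rows)
            if (length(dc))
              new_kd[dc] <- Kr[cbind(match(di[dc], rows), dj[dc])]
          }
        }
      } else { # theta_t
        # clamp the logit coordinate so theta never collapses onto the
        # closed boundary of (0.5, 1) by floating-point rounding
        u <- min(max(stats::qlogis((p$theta - 0.5) / 0.5), -30), 30)
        u2 <- min(max(u + stats::rnorm(1, 0, scales[pn]), -30), 30)
        p2$theta <- 0.5 + 0.5 * stats::plogis(u2)
        # U(0.5, 1) prior, walk on logit scale
        jac <- log(stats::plogis(u2) * (1 - stats::plogis(u2))) -
               log(stats::plogis(u) * (1 - stats::plogis(u)))
        Kn <- matrix(0, M, J)
        f <- sexm == 0
        if (any(f)) Kn[f, ] <- kern_rows(Ds[f, , drop = FALSE], p2$sigma_F, p2$theta)
        if (any(!f)) Kn[!f, ] <- kern_rows(Ds[!f, , drop = FALSE], p2$sigma_M, p2$theta)
        new_KE <- drop(Kn %*% E)
        new_kd <- if (ndet) Kn[cbind(di, dj)] else numeric(0)
      }
      new <- pieces(p2, new_KE, new_kd)
      nll <- tot_ll(new$lli)
      if (is.finite(nll) &&
          log(stats::runif(1)) < nll - cll + jac) {
        acc[pn] <- acc[pn] + 1
        p <- p2; cur <- new; cll <- nll
        KE <- new_KE; kd <- new_kd
        if (pn %in% c("log_sigma_F", "log_sigma_M", "theta_t"))
          Kern <- make_kern(p)   # refresh rows under accepted kernel
        if (pn == "beta_eff") E <- E_of(p$beta_eff)
      }
    }

    # ---- activity centres -------------------------------------------
    Ai <- exp(log(p$lam0) + p$beta_sex * sexm)
    nb <- neighbours(w)
    sigv <- c(p$sigma_F, p$sigma_M)[sexm + 1L]
    u_pick <- stats::runif(M); u_acc <- stats::runif(M)
    for (i in seq_len(M)) {
      ac_att <- ac_att + 1
      fwd <- nb[[s[i]]]
      g2 <- fwd[min(length(fwd), 1L + as.integer(u_pick[i] * length(fwd)))]
      if (g2 == s[i]) { ac_acc <- ac_acc + 1; next }
      row2 <- kern_rows(Dsuit[g2, , drop = FALSE], sigv[i], p$theta)
      KE2 <- sum(row2 * E)
      lr <- log(length(fwd)) - log(length(nb[[g2]]))
      dci <- if (ndet) which(di == i) else integer(0)
      if (z[i] == 1) {
        H2 <- Ai[i] * KE2
        dll2 <- 0
        if (length(dci)) {
          dh2 <- Ai[i] * exp(p$beta_eff * dlogeff[dci]) * row2[dj[dci]]
          dll2 <- sum(det_term(dh2))
        }
        lli2 <- -H2 + dll2
        lr <- lr + lli2 - cur$lli[i]
      }
      if (is.finite(lr) && log(u_acc[i]) < lr) {
        ac_acc <- ac_acc + 1
        s[i] <- g2
        Ds[i, ] <- Dsuit[g2, ]
        Kern[i, ] <- row2
        KE[i] <- KE2
        cur$H[i] <- Ai[i] * KE2
        if (length(dci)) kd[dci] <- row2[dj[dci]]
        if (z[i] == 1) cur$lli[i] <- lli2
        else {
          dll <- 0
          if (length(dci)) dll <- sum(det_term(Ai[i] * exp(p$beta_eff * dlogeff[dci]) * kd[dci]))
          cur$lli[i] <- -cur$H[i] + dll
        }
      }
    }

    # ---- inclusion indicators z -------------------------------------
    und <- which(!detected)
    if (length(und)) {
      q <- exp(-cur$H[und])
      z[und] <- stats::rbinom(length(und), 1, inclusion_prob(p$psi, q))
    }

    # ---- latent sexes and psi_sex -----------------------------------
    if (length(und)) {
      KF <- kern_rows(Ds[und, , drop = FALSE], p$sigma_F, p$theta)
      KM <- kern_rows(Ds[und, , drop = FALSE], p$sigma_M, p$theta)
      HF <- exp(log(p$lam0)) * drop(KF %*% E)
      HM <- exp(log(p$lam0) + p$beta_sex) * drop(KM %*% E)
      pmale <- ifelse(z[und] == 1,
                      sex_conditional_prob(p$psi_sex, -HM, -HF),
                      p$psi_sex)
      newsex <- stats::rbinom(length(und), 1, pmale)
      chg <- which(newsex != sexm[und])
      if (length(chg)) {
        sexm[und[chg]] <- newsex[chg]
        male <- newsex[chg] == 1
        Kern[und[chg][male], ] <- KM[chg[male], ]
        Kern[und[chg][!male], ] <- KF[chg[!male], ]
      }
      # refresh caches for all undetected (sex-dependent scale A)
      KE[und] <- ifelse(newsex == 1, drop(KM %*% E), drop(KF %*% E))
      cur$H[und] <- ifelse(newsex == 1, HM, HF)
      cur$lli[und] <- -cur$H[und]
    }
    nz <- sum(z)
    p$psi_sex <- stats::rbeta(1, 1 + sum(sexm[z == 1]),
                              1 + sum(z) - sum(sexm[z == 1]))

    # ---- psi ---------------------------------------------------------
    p$psi <- gibbs_update_psi(z, M)

    # ---- adaptation (burn-in only) ----------------------------------
    if (config$adapt && iter <= config$burnin &&
        iter %% config$adapt_window == 0) {
      adapt_step <- adapt_step + 1
      step <- 1 / sqrt(adapt_step)
      for (pn in pnames) {
        if (att[pn] > 0)
          scales[pn] <- min(10, max(1e-3,
            scales[pn] * exp(step * (acc[pn] / att[pn] - 0.35))))
      }
      acr <- if (ac_att > 0) ac_acc / ac_att else 0.4
      if (acr < 0.2) w <- max(2L, as.integer(round(w / 1.4)))
      if (acr > 0.6) w <- min(max(space$nx, space$ny),
                              as.integer(round(w * 1.4)))
      acc_tot <- acc_tot + acc; att_tot <- att_tot + att
      ac_acc_tot <- ac_acc_tot + ac_acc; ac_att_tot <- ac_att_tot + ac_att
      acc[] <- 0; att[] <- 0; ac_acc <- 0; ac_att <- 0
    }

    # ---- record ------------------------------------------------------
    if (iter > config$burnin &&
        (iter - config$burnin) %% config$thin == 0) {
      kept <- kept + 1
      draws[kept, ] <- c(p$lam0, p$beta_eff, p$beta_sex, p$sigma_F,
                         p$sigma_M, p$theta, p$psi, p$psi_sex, nz,
                         density_from_nsuper(nz, sarea))
      if (config$store_ac) {
        s_tr[kept, ] <- s
        z_tr[kept, ] <- z
        sex_tr[kept, ] <- sexm
      }
    }
  }

  acc_tot <- acc_tot + acc; att_tot <- att_tot + att
  ac_acc_tot <- ac_acc_tot + ac_acc; ac_att_tot <- ac_att_tot + ac_att
  out <- list(draws = draws[seq_len(kept), , drop = FALSE],
              accept = c(acc_tot / pmax(att_tot, 1),
                         activity_centre = ac_acc_tot / max(ac_att_tot, 1)),
              scales = scales, ac_halfwidth = w, seed = seed)
  if (config$store_ac) {
    out$s <- s_tr[seq_len(kept), , drop = FALSE]
    out$z <- z_tr[seq_len(kept), , drop = FALSE]
    out$sex <- sex_tr[seq_len(kept), , drop = FALSE]
  }
  out
}

#' @export
print.scr_fit <- function(x, ...) {
  nk <- sum(vapply(x$chains, function(ch) nrow(ch$draws), integer(1)))
  cat(sprintf(
    "scr_fit: model %d, %d chains, %d retained draws (M = %d, n = %d)\n",
    x$variant$variant, length(x$chains), nk, x$M, x$n))
  invisible(x)
}

#' Pool retained draws across chains
#'
#' @param fit an `scr_fit`.
#' @return one matrix of draws, chains stacked in order.
#' @export
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "scr_fit"))
  do.call(rbind, lapply(fit$chains, function(ch) ch$draws))
}
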