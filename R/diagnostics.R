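#' Gelman-Rubin potential scale reduction factor
#'
#' `PSRF = sqrt(((L - 1) / L * W + B / L) / W)` with `W` the mean
#' within-chain variance and `B = L * var(chain means)` the between-chain
#' variance, for chains of equal retained length `L`. Values near 1
#' indicate the chains have mixed into a common distribution. Chains that
#' are all identical constants return 1 by convention.
#'
#' @param x draws for one parameter: a matrix (iterations x chains) or a
#'   list of equal-length numeric vectors.
#' @return the PSRF (scalar, `>= 1` up to numerical tolerance).
#' @export
gelman_rubin <- function(x) {
  if (is.list(x)) {
    if (length(unique(lengths(x))) != 1)
      stop("chains must have equal retained lengths")
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("at least 2 chains are required")
  L <- nrow(x)
  if (L < 2) stop("chains must have length >= 2")
  W <- mean(apply(x, 2, stats::var))
  B <- L * stats::var(colMeans(x))
  if (W == 0) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Posterior summary table for a fitted model
#'
#' Pooled-chain posterior means and standard deviations of every free
#' parameter plus `N_super`, the density `D` (per 100 km^2 of suitable
#' habitat) and the derived sex ratio (females per male), together with the
#' retained-sample count and the maximum Gelman-Rubin PSRF over the
#' monitored quantities.
#'
#' @param fit an `scr_fit`.
#' @param p_value optional Bayesian p-value (from [bayesian_pvalue()]) to
#'   attach to the report.
#' @return an `scr_summary`: list with `table` (data frame `parameter`,
#'   `mean`, `sd`, `psrf`), `n_samples`, `max_psrf`, `p_value`, `variant`.
#' @export
summarize_posterior <- function(fit, p_value = NA_real_) {
  stopifnot(inherits(fit, "scr_fit"))
  pool <- pooled_draws(fit)
  drop_cols <- character(0)
  if (fit$variant$fix_beta_sex) drop_cols <- c(drop_cols, "beta_sex")
  if (fit$variant$fix_theta) drop_cols <- c(drop_cols, "theta")
  cols <- setdiff(colnames(pool), drop_cols)
  sexr <- sex_ratio(pool[, "psi_sex"])
  tab <- data.frame(
    parameter = c(cols, "sex_ratio"),
    mean = c(colMeans(pool[, cols, drop = FALSE]), mean(sexr)),
    sd = c(apply(pool[, cols, drop = FALSE], 2, stats::sd), stats::sd(sexr)),
    stringsAsFactors = FALSE)
  psrf <- rep(NA_real_, nrow(tab))
  if (length(fit$chains) >= 2) {
    L <- min(vapply(fit$chains, function(ch) nrow(ch$draws), integer(1)))
    for (a in seq_along(cols)) {
      m <- vapply(fit$chains,
                  function(ch) ch$draws[seq_len(L), cols[a]],
                  numeric(L))
      psrf[a] <- gelman_rubin(m)
    }
  }
  tab$psrf <- psrf
  structure(
    list(table = tab, n_samples = nrow(pool),
         max_psrf = if (all(is.na(psrf))) NA_real_ else max(psrf, na.rm = TRUE),
         p_value = p_value, variant = fit$variant$variant),
    class = "scr_summary")
}

#' @export
print.scr_summary <- function(x, ...) {
  cat(sprintf("Model %d: %d retained samples, max PSRF %.3f, Bayesian p-value %s\n",
              x$variant, x$n_samples,
              ifelse(is.na(x$max_psrf), NA, x$max_psrf),
              ifelse(is.na(x$p_value), "NA", sprintf("%.3f", x$p_value))))
  df <- x$table
  df$mean <- signif(df$mean, 4); df$sd <- signif(df$sd, 4)
  df$psrf <- round(df$psrf, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bayesian p-value model-adequacy check
#'
#' Posterior predictive check with a Freeman-Tukey discrepancy on
#' individual encounter totals: for each sampled retained draw,
#' `T = sum over individuals with z = 1 of (sqrt(y_i.) - sqrt(e_i.))^2`
#' where `y_i.` is the individual's total encounter count (0 for augmented
#' individuals) and `e_i.` the expected total under the draw's parameters
#' and latent state; a replicate encounter history is simulated from the
#' same draw and the p-value is the proportion of draws with
#' `T_rep >= T_obs`. Values near 0 or 1 flag model inadequacy; the
#' adequacy band used by `diagnostics_report()` is (0.15, 0.85).
#'
#' @param fit an `scr_fit` run with `store_ac = TRUE`.
#' @param ndraws number of retained draws (sampled evenly across the pooled
#'   chains) to evaluate (default 200).
#' @param seed RNG seed for the replicate simulations.
#' @return list with `p_value`, `T_obs`, `T_rep` (vectors over evaluated
#'   draws).
#' @export
bayesian_pvalue <- function(fit, ndraws = 200, seed = 1) {
  stopifnot(inherits(fit, "scr_fit"))
  if (is.null(fit$chains[[1]][["s"]]))
    stop("latent traces absent: re-run the sampler with store_ac = TRUE")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  enc <- fit$enc
  effmat <- enc$effort$effort
  traps <- enc$effort$traps
  act <- which(effmat > 0)                    # linear indices over J x K
  jact <- ((act - 1L) %% nrow(effmat)) + 1L
  wact <- effmat[act]
  Dsuit <- distance_matrix(fit$space, traps, suitable_only = TRUE)
  yobs <- tabulate(enc$det$ind, nbins = enc$n)

  pool_s <- do.call(rbind, lapply(fit$chains, function(ch) ch[["s"]]))
  pool_z <- do.call(rbind, lapply(fit$chains, function(ch) ch$z))
  pool_sex <- do.call(rbind, lapply(fit$chains, function(ch) ch$sex))
  pool <- pooled_draws(fit)
  nd <- nrow(pool)
  use <- unique(round(seq(1, nd, length.out = min(ndraws, nd))))

  T_obs <- T_rep <- numeric(length(use))
  for (a in seq_along(use)) {
    r <- use[a]
    pr <- as.list(pool[r, ])
    zi <- which(pool_z[r, ] == 1)
    si <- pool_s[r, zi]
    sx <- pool_sex[r, zi]
    sig <- ifelse(sx == 1, pr$sigma_M, pr$sigma_F)
    # hazard per (included individual, active cell)
    Kr <- exp(-(Dsuit[si, jact, drop = FALSE] / sig)^(2 * pr$theta))
    h <- exp(log(pr$lam0) + pr$beta_sex * sx) * Kr *
      rep(wact^pr$beta_eff, each = length(zi))
    pi <- -expm1(-h)
    e_i <- rowSums(pi)
    y_i <- ifelse(zi <= enc$n, yobs[pmin(zi, enc$n)], 0)
    y_i[zi > enc$n] <- 0
    T_obs[a] <- sum((sqrt(y_i) - sqrt(e_i))^2)
    yrep <- matrix(stats::runif(length(pi)) < pi, nrow = length(zi))
    T_rep[a] <- sum((sqrt(rowSums(yrep)) - sqrt(e_i))^2)
  }
  list(p_value = mean(T_rep >= T_obs), T_obs = T_obs, T_rep = T_rep)
}

#' Pixel-level posterior density surface
#'
#' For each suitable state-space pixel, the posterior mean number of
#' included activity centres in the pixel divided by the pixel area:
#' expected individuals per km^2. Summing the surface times the pixel area
#' recovers the posterior mean of `N_super` exactly.
#'
#' @param fit an `scr_fit` run with `store_ac = TRUE`.
#' @return a `density_surface`: list with `density` (per suitable pixel,
#'   ind/km^2), `space`, `pixel_area`, and `grid` (an `ascii_grid` over the
#'   full state space; unsuitable pixels are NODATA).
#' @export
density_surface <- function(fit) {
  stopifnot(inherits(fit, "scr_fit"))
  if (is.null(fit$chains[[1]][["s"]]))
    stop("latent traces absent: re-run the sampler with store_ac = TRUE")
  s <- do.call(rbind, lapply(fit$chains, function(ch) ch[["s"]]))
  z <- do.call(rbind, lapply(fit$chains, function(ch) ch$z))
  Gs <- sum(fit$space$suitable)
  counts <- tabulate(s[z == 1], nbins = Gs)
  dens <- counts / nrow(s) / fit$pixel_area
  structure(
    list(density = dens, space = fit$space, pixel_area = fit$pixel_area,
         grid = state_space_grid(fit$space, dens)),
    class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf(
    "density_surface: %d suitable pixels; %.4f-%.4f ind/km^2; implied N = %.1f\n",
    length(x$density), min(x$density), max(x$density),
    sum(x$density) * x$pixel_area))
  invisible(x)
}

#' Diagnostics report for a fitted model
#'
#' Bundles the posterior summary, convergence verdict (max PSRF < 1.2) and
#' adequacy verdict (Bayesian p-value inside (0.15, 0.85)), and can be
#' serialized to JSON.
#'
#' @param fit an `scr_fit`.
#' @param ndraws draws used for the posterior predictive check.
#' @param seed RNG seed for the check.
#' @return a `diagnostics_report` list.
#' @export
diagnostics_report <- function(fit, ndraws = 200, seed = 1) {
  pv <- bayesian_pvalue(fit, ndraws = ndraws, seed = seed)
  summ <- summarize_posterior(fit, p_value = pv$p_value)
  structure(
    list(summary = summ, p_value = pv$p_value,
         max_psrf = summ$max_psrf,
         converged = !is.na(summ$max_psrf) && summ$max_psrf < 1.2,
         adequate = pv$p_value > 0.15 && pv$p_value < 0.85,
         discrepancy = "Freeman-Tukey on individual encounter totals"),
    class = "diagnostics_report")
}

#' Write a diagnostics report as JSON
#'
#' @param report a `diagnostics_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(report, path) {
  stopifnot(inherits(report, "diagnostics_report"))
  out <- list(
    model = report$summary$variant,
    n_samples = report$summary$n_samples,
    max_psrf = report$max_psrf,
    bayesian_p_value = report$p_value,
    converged = report$converged,
    adequate = report$adequate,
    discrepancy = report$discrepancy,
    posterior = report$summary$table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
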