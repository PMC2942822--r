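#' Weighted distance between observations and a simulated trajectory
#'
#' The fit criterion weights each squared deviation by the inverse of the
#' measurement standard deviation (not the variance: inverse-variance
#' weighting overemphasizes very low concentrations, uniform weighting
#' overemphasizes high ones):
#'
#' * `fval_chi_sqr = sum_m (pred_m - mean_m)^2 / sd_m`
#' * `fit_quality  = sqrt(fval_chi_sqr / N)`
#'
#' With `weighting = "var"` the conventional chi-square
#' `(pred - mean)^2 / sd^2` is used instead, for sensitivity studies.
#'
#' @param dataset An `fk_dataset`; every `(organ, time)` must be present
#'   in the trajectory and all SDs must be positive (floor them first,
#'   see [floor_sd()]).
#' @param trajectory An `fk_trajectory` sampled at the dataset times.
#' @param weighting `"sd"` (default) or `"var"`.
#' @return List with `fval_chi_sqr` and `fit_quality`.
#' @export
weighted_distance <- function(dataset, trajectory,
                              weighting = c("sd", "var")) {
  weighting <- match.arg(weighting)
  ti <- match(dataset$time, trajectory$times)
  oi <- match(dataset$organ, rownames(trajectory$content))
  if (anyNA(ti) || anyNA(oi)) {
    stop("trajectory lacks predictions for some (organ, time) points")
  }
  if (any(dataset$sd <= 0)) stop("all SDs must be > 0; apply floor_sd()")
  pred <- trajectory$content[cbind(oi, ti)]
  dev2 <- (pred - dataset$mean)^2
  w <- if (weighting == "sd") 1 / dataset$sd else 1 / dataset$sd^2
  fval <- sum(dev2 * w)
  list(fval_chi_sqr = fval, fit_quality = sqrt(fval / nrow(dataset)))
}

#' Floor small standard deviations
#'
#' Zero or near-zero SDs would give single observations infinite weight.
#' Per organ, SDs below `frac` times the organ's maximum mean are raised
#' to that floor (absolute floor `frac` % dose for organs that never rise
#' above zero).
#'
#' @param dataset An `fk_dataset`.
#' @param frac Floor as a fraction of the organ's maximum mean.
#' @return The dataset with floored SDs.
#' @export
floor_sd <- function(dataset, frac = 0.01) {
  for (org in unique(dataset$organ)) {
    idx <- dataset$organ == org
    fl <- frac * max(dataset$mean[idx], frac)
    dataset$sd[idx] <- pmax(dataset$sd[idx], fl)
  }
  dataset
}

# --- internal parameterization -------------------------------------------
# Free parameters are optimized in an unconstrained space:
#   * with a fixed total plasma clearance, the free plasma-exit rates are
#     shares of the remaining budget via a softmax (first share gauge-fixed
#     to weight 0), so the constraint holds exactly at every iterate;
#   * all other free rates are log-transformed (they span ~3 decades).
.make_param_map <- function(topology, total_clearance, fixed) {
  pn <- topology$edges$param
  plasma <- pn[topology$edges$source == topology$central &
                 topology$edges$target != EXTERNAL]
  fixed_names <- names(fixed)
  if (length(fixed) > 0 && is.null(fixed_names)) {
    stop("fixed must be a named vector of rates")
  }
  bad <- setdiff(fixed_names, pn)
  if (length(bad) > 0) stop("unknown fixed parameters: ",
                            paste(bad, collapse = ", "))
  free_plasma <- setdiff(plasma, fixed_names)
  free_other <- setdiff(setdiff(pn, plasma), fixed_names)
  constrained <- !is.null(total_clearance)
  budget <- NULL
  if (constrained) {
    budget <- total_clearance - sum(fixed[intersect(fixed_names, plasma)])
    if (budget < 0) stop("fixed plasma rates exceed total_clearance")
    n_simplex <- max(length(free_plasma) - 1, 0)
  } else {
    n_simplex <- 0
    free_other <- c(free_plasma, free_other)
    free_plasma <- character(0)
  }
  list(plasma = plasma, free_plasma = free_plasma,
       free_other = free_other, fixed = fixed, budget = budget,
       n_simplex = n_simplex,
       n_theta = n_simplex + length(free_other))
}

.theta_to_rates <- function(theta, map) {
  rates <- numeric(0)
  if (length(map$free_plasma) > 0) {
    w <- c(0, theta[seq_len(map$n_simplex)])
    sh <- exp(w - max(w))
    rates <- stats::setNames(map$budget * sh / sum(sh), map$free_plasma)
  }
  if (length(map$free_other) > 0) {
    lo <- theta[map$n_simplex + seq_along(map$free_other)]
    lo <- pmin(pmax(lo, -30), 30)  # guard exp overflow in free steps
    rates <- c(rates, stats::setNames(exp(lo), map$free_other))
  }
  c(rates, map$fixed)
}

.rates_to_theta <- function(rates, map) {
  theta <- numeric(0)
  if (length(map$free_plasma) > 0) {
    v <- pmax(rates[map$free_plasma], 1e-8)
    w <- log(v) - log(v[1])
    theta <- w[-1]
  }
  c(theta, log(pmax(rates[map$free_other], 1e-8)))
}

# Data-informed deterministic starting point. The tracer logic of a
# mammillary system suggests direct initial guesses: organ contents at the
# first timepoint are roughly proportional to the plasma-exit shares
# (plasma clearance is complete well before 12 h), and an organ's total
# exit rate is approximated by the steepest post-peak log-slope of its
# curve (the late tail decays with the system's slowest mode instead, so
# it would badly underestimate fast exits). Compartments with several
# exit edges split the estimated total 90/10 in favour of the first edge.
.informed_start <- function(dataset, topology, total_clearance) {
  ts <- sort(unique(dataset$time))
  t1 <- ts[1]
  get <- function(org, t) {
    v <- dataset$mean[dataset$organ == org & dataset$time == t]
    if (length(v) == 1) v else NA_real_
  }
  pe <- topology$edges[topology$edges$source == topology$central &
                         topology$edges$target != EXTERNAL, ]
  w1 <- vapply(pe$target, function(o) max(get(o, t1), 1e-3, na.rm = TRUE),
               numeric(1))
  scale <- if (is.null(total_clearance)) 20 else total_clearance
  kp <- scale * w1 / sum(w1)
  exit <- vapply(topology$compartments, function(o) {
    x <- vapply(ts, function(t) get(o, t), numeric(1))
    keep <- is.finite(x) & x > 0
    x <- x[keep]
    tt <- ts[keep]
    if (length(x) < 2) return(0.1)
    p <- which.max(x)
    if (p == length(x)) return(0.05)  # still accumulating: slow exit
    slopes <- -diff(log(x[p:length(x)])) / diff(tt[p:length(x)])
    min(max(max(slopes), 0.01), 5)
  }, numeric(1))
  rates <- stats::setNames(numeric(nrow(topology$edges)),
                           topology$edges$param)
  rates[pe$param] <- kp
  other <- topology$edges[topology$edges$source != topology$central, ]
  for (src in unique(other$source)) {
    pars <- other$param[other$source == src]
    split <- if (length(pars) == 1) 1 else
      c(0.9, rep(0.1 / (length(pars) - 1), length(pars) - 1))
    rates[pars] <- exit[src] * split
  }
  rates
}

# weighted residual vector at a parameter vector (for LM polish)
.residuals_fun <- function(dataset, topology, map, weighting) {
  times <- sort(unique(dataset$time))
  w <- if (weighting == "sd") 1 / dataset$sd else 1 / dataset$sd^2
  sw <- sqrt(w)
  function(theta) {
    rates <- .theta_to_rates(theta, map)
    tr <- simulate_tracer(topology, rates, times)
    ti <- match(dataset$time, tr$times)
    oi <- match(dataset$organ, rownames(tr$content))
    (tr$content[cbind(oi, ti)] - dataset$mean) * sw
  }
}

# Levenberg-Marquardt refinement with forward-difference Jacobian.
# The fit is a (near) zero-residual nonlinear least-squares problem, where
# Gauss-Newton steps converge quadratically; used to polish the best
# multi-start solution to high precision.
.lm_polish <- function(theta, rfun, maxit = 40, tol = 1e-12) {
  safe_rfun <- function(th) {
    tryCatch(rfun(th), error = function(e) NULL)
  }
  rfun <- function(th) {
    r <- safe_rfun(th)
    if (is.null(r) || any(!is.finite(r))) return(NULL)
    r
  }
  r <- rfun(theta)
  if (is.null(r)) return(list(theta = theta, fval = Inf, iter = 0))
  f <- sum(r^2)
  lambda <- 1e-3
  npar <- length(theta)
  for (it in seq_len(maxit)) {
    J <- matrix(0, length(r), npar)
    h <- pmax(1e-6, 1e-7 * abs(theta))
    jac_ok <- TRUE
    for (j in seq_len(npar)) {
      tp <- theta; tp[j] <- tp[j] + h[j]
      rj <- rfun(tp)
      if (is.null(rj)) { jac_ok <- FALSE; break }
      J[, j] <- (rj - r) / h[j]
    }
    if (!jac_ok) break
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    for (try in 1:8) {
      step <- tryCatch(
        -solve(H + lambda * diag(diag(H) + 1e-12, npar), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        tn <- theta + as.numeric(step)
        rn <- rfun(tn)
        fn <- if (is.null(rn)) Inf else sum(rn^2)
        if (is.finite(fn) && fn < f) {
          theta <- tn; r <- rn
          improved <- TRUE
          lambda <- max(lambda / 4, 1e-10)
          if (f - fn < tol * max(f, 1e-300)) {
            return(list(theta = theta, fval = fn, iter = it))
          }
          f <- fn
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  list(theta = theta, fval = f, iter = maxit)
}

#' Estimate clearance constants from a tracer dataset
#'
#' Weighted least-squares estimation of the model's fractional clearance
#' constants. The 13 plasma-exit rates are parameterized as non-negative
#' shares on a simplex scaled to `total_clearance`, so the fixed total
#' plasma turnover (default 20 pool turnovers per day) is enforced
#' exactly; all other rates are optimized in log space. The optimizer
#' runs L-BFGS-B from `n_starts` seeded random initializations (plus
#' `start_at` if supplied) and polishes the best solution with a
#' Levenberg-Marquardt refinement of the weighted residuals.
#'
#' @param dataset An `fk_dataset` (normalized; SDs are floored internally).
#' @param topology An `fk_topology`.
#' @param total_clearance Fixed total plasma clearance (1/day), or `NULL`
#'   to leave the plasma-exit rates unconstrained.
#' @param n_starts Number of random multi-starts.
#' @param seed Integer seed; together with the dataset it fully
#'   determines the result.
#' @param fixed Optional named vector of rates held fixed.
#' @param weighting See [weighted_distance()].
#' @param sd_floor_frac See [floor_sd()].
#' @param start_at Optional named rate vector used as an additional
#'   (deterministic) start, e.g. the point estimate when refitting
#'   resampled data.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param polish Apply the Levenberg-Marquardt refinement (default TRUE).
#' @param informed_start Also start from a deterministic data-informed
#'   guess (plasma shares from the first-timepoint organ contents, exit
#'   rates from the late-time log-slopes); default TRUE.
#' @return An object of class `fk_fit`: list with `rates`,
#'   `fval_chi_sqr`, `fit_quality`, `n_starts`, `converged`, `seed`,
#'   `total_clearance`, `weighting`.
#' @export
fit_rates <- function(dataset, topology = build_topology(),
                      total_clearance = 20, n_starts = 50, seed = 1,
                      fixed = NULL, weighting = c("sd", "var"),
                      sd_floor_frac = 0.01, start_at = NULL,
                      maxit = 200, polish = TRUE,
                      informed_start = TRUE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(dataset, "fk_dataset"))
  if (!is.null(total_clearance) && total_clearance <= 0) {
    stop("total_clearance must be > 0")
  }
  missing_org <- setdiff(unique(topology$edges$source[
    topology$edges$source != EXTERNAL]), unique(dataset$organ))
  if (length(missing_org) > 0) {
    stop("dataset lacks whole-organ coverage: ",
         paste(missing_org, collapse = ", "))
  }
  dataset <- floor_sd(dataset, sd_floor_frac)
  if (!is.null(fixed)) fixed <- unlist(fixed)
  map <- .make_param_map(topology, total_clearance, fixed)
  rfun <- .residuals_fun(dataset, topology, map, weighting)
  objective <- function(theta) {
    f <- tryCatch(sum(rfun(theta)^2), error = function(e) NA_real_)
    if (!is.finite(f)) 1e12 else f
  }

  n_eval <- nrow(dataset)
  if (map$n_theta == 0) {  # everything fixed: evaluate, no search
    rates <- validate_rates(.theta_to_rates(numeric(0), map), topology)
    fval <- objective(numeric(0))
    return(structure(list(
      rates = rates, fval_chi_sqr = fval,
      fit_quality = sqrt(fval / n_eval), n_starts = 0L,
      converged = TRUE, seed = seed,
      total_clearance = total_clearance, weighting = weighting),
      class = "fk_fit"))
  }

  starts <- list()
  if (!is.null(start_at)) {
    starts[[length(starts) + 1]] <- .rates_to_theta(
      validate_rates(start_at, topology), map)
  }
  if (informed_start) {
    th <- tryCatch(
      .rates_to_theta(.informed_start(dataset, topology, total_clearance),
                      map),
      error = function(e) NULL)
    if (!is.null(th)) starts[[length(starts) + 1]] <- th
  }
  if (n_starts > 0) {
    for (s in seq_len(n_starts)) {
      set.seed((seed * 1009L + s) %% 2147483647L)
      w0 <- stats::rnorm(map$n_simplex, 0, 1.5)
      l0 <- stats::runif(length(map$free_other), log(0.02), log(5))
      starts[[length(starts) + 1]] <- c(w0, l0)
    }
  }
  if (length(starts) == 0) stop("no starting point: n_starts = 0 and no start_at")

  lower <- c(rep(-25, map$n_simplex), rep(log(1e-5), length(map$free_other)))
  upper <- c(rep(25, map$n_simplex), rep(log(1e3), length(map$free_other)))
  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e12) {
    stop("no finite-criterion start found")
  }
  theta <- best$par
  fval <- best$value
  if (polish) {
    pol <- .lm_polish(theta, rfun)
    if (pol$fval <= fval) {
      theta <- pol$theta
      fval <- pol$fval
    }
  }
  rates <- validate_rates(.theta_to_rates(theta, map), topology)
  structure(list(
    rates = rates, fval_chi_sqr = fval,
    fit_quality = sqrt(fval / n_eval),
    n_starts = length(starts), converged = best$convergence == 0,
    seed = seed, total_clearance = total_clearance,
    weighting = weighting),
    class = "fk_fit")
}

#' @export
print.fk_fit <- function(x, ...) {
  cat("Ferrokinetic fit:", length(x$rates), "rate constants,",
      x$n_starts, "starts, seed", x$seed, "\n")
  cat("  fval_chi_sqr:", format(x$fval_chi_sqr, digits = 5),
      " fit_quality:", format(x$fit_quality, digits = 4), "\n")
  if (!is.null(x$total_clearance)) {
    cat("  total plasma clearance fixed at", x$total_clearance, "/day\n")
  }
  invisible(x)
}

#' Monte-Carlo resampling of a tracer dataset and refitting
#'
#' Generates `n_replicates` artificial datasets sharing the mean and
#' standard deviation structure of the observed data (per-cell Gaussian
#' draws, negatives clipped to zero), refits each one, and collects the
#' replicate estimates. Replicate fits start from the point estimate of
#' the original data (plus `n_starts` random starts, default none), which
#' keeps the procedure reproducible and affordable.
#'
#' @inheritParams fit_rates
#' @param n_replicates Number of resampled datasets (>= 2).
#' @param n_starts Random multi-starts of the point fit on the original
#'   data.
#' @param replicate_n_starts Extra random starts per replicate fit;
#'   replicates always start from the point estimate (the replicates
#'   perturb the data, not the basin), so the default is 0.
#' @param ... Passed on to [fit_rates()] for both the point and the
#'   replicate fits.
#' @return An object of class `fk_ensemble`: list with `fits`,
#'   `estimates` (replicates x parameters matrix), `point` (the original
#'   fit), `n_replicates`, `seed`, `failed` (indices of failed
#'   replicates).
#' @export
resample_fit <- function(dataset, n_replicates = 200, seed = 1,
                         topology = build_topology(), n_starts = 10,
                         replicate_n_starts = 0, ...) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  point <- fit_rates(dataset, topology = topology, seed = seed,
                     n_starts = n_starts, ...)
  fits <- vector("list", n_replicates)
  failed <- integer(0)
  for (r in seq_len(n_replicates)) {
    set.seed((seed * 7919L + r) %% 2147483647L)
    d <- dataset
    d$mean <- pmax(stats::rnorm(nrow(d), d$mean, d$sd), 0)
    fits[[r]] <- tryCatch(
      fit_rates(d, topology = topology, seed = seed + r,
                n_starts = replicate_n_starts, start_at = point$rates,
                informed_start = FALSE, ...),
      error = function(e) NULL)
    if (is.null(fits[[r]])) failed <- c(failed, r)
  }
  if (length(failed) > n_replicates / 2) {
    stop("more than half of the replicate fits failed")
  }
  ok <- fits[!vapply(fits, is.null, logical(1))]
  est <- do.call(rbind, lapply(ok, function(f) f$rates))
  structure(list(fits = ok, estimates = est, point = point,
                 n_replicates = n_replicates, seed = seed,
                 failed = failed),
            class = "fk_ensemble")
}

#' Sextile scatter interval of resampled parameter estimates
#'
#' Per parameter, the lower and upper bound are the 1/6 and 5/6 empirical
#' quantiles (linear interpolation, R quantile type 7) of the replicate
#' estimates: a sextile-truncated sample of the observed parameter
#' variation. For Gaussian estimates this interval approaches
#' `(z(5/6) - z(1/6)) * sigma = 1.93 sigma`, i.e. about twice the
#' standard deviation.
#'
#' @param ensemble An `fk_ensemble`, or a numeric matrix of replicate
#'   estimates (replicates x parameters).
#' @param probs Quantile pair, default `c(1/6, 5/6)`.
#' @return Object of class `fk_bounds`: data.frame `param`, `lower`,
#'   `upper`.
#' @export
parameter_bounds <- function(ensemble, probs = c(1 / 6, 5 / 6)) {
  est <- if (inherits(ensemble, "fk_ensemble")) ensemble$estimates
         else as.matrix(ensemble)
  if (nrow(est) < 1) stop("ensemble is empty")
  stopifnot(probs[1] <= probs[2])
  q <- apply(est, 2, stats::quantile, probs = probs, names = FALSE,
             type = 7)
  structure(data.frame(param = colnames(est),
                       lower = q[1, ], upper = q[2, ],
                       row.names = NULL),
            class = c("fk_bounds", "data.frame"))
}

#' Multi-start identifiability scan
#'
#' A simplified surrogate for alternating-conditional-expectation style
#' identifiability exploration: the fit is repeated from many seeded
#' random starting points, all solutions whose criterion lies within
#' `accept_factor` of the best are retained, and the per-parameter spread
#' and pairwise correlations across this acceptable set are reported.
#' Parameter pairs that co-vary strongly (|correlation| above
#' `cor_threshold`) while being individually poorly pinned down (relative
#' spread above `spread_min`) are flagged as practically non-identifiable
#' -- typically compartments whose reflux and body-loss exits can trade
#' off against each other, or plasma-exit rates when the total clearance
#' is left free with no early-time data.
#'
#' @inheritParams fit_rates
#' @param accept_factor Fits with `fval <= best * accept_factor + 1e-6`
#'   are retained.
#' @param cor_threshold Absolute correlation above which a pair is
#'   flagged.
#' @param spread_min Minimum relative spread (sd/mean) for a parameter to
#'   participate in flagging; tighter parameters count as identified.
#' @param ... Passed to [fit_rates()] (each call runs one random start).
#'   Unless overridden, scan fits run with `polish = FALSE` and
#'   `informed_start = FALSE`: fully converged fits collapse onto a
#'   single optimum even along a practically flat ridge, whereas
#'   moderately optimized multi-starts scatter along it -- which is the
#'   signal this scan looks for.
#' @return Object of class `fk_idscan`: list with `estimates` (accepted
#'   fits x parameters), `fval` (all starts), `accepted` (logical),
#'   `spread` (per-parameter relative spread), `correlation` (matrix or
#'   NULL), `flags` (data.frame `param1`, `param2`, `correlation`).
#' @export
identifiability_scan <- function(dataset, topology = build_topology(),
                                 n_starts = 50, seed = 1,
                                 accept_factor = 1.05,
                                 cor_threshold = 0.9,
                                 spread_min = 0.01, ...) {
  dots <- list(...)
  if (is.null(dots$polish)) dots$polish <- FALSE
  if (is.null(dots$informed_start)) dots$informed_start <- FALSE
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(
      do.call(fit_rates,
              c(list(dataset, topology = topology, n_starts = 1,
                     seed = (seed * 131L + s) %% 2147483647L), dots)),
      error = function(e) NULL)
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop("no successful fits in scan")
  fval <- vapply(fits, function(f) f$fval_chi_sqr, numeric(1))
  best <- min(fval)
  accepted <- fval <= best * accept_factor + 1e-6
  est <- do.call(rbind, lapply(fits[accepted], function(f) f$rates))
  mu <- colMeans(est)
  spread <- apply(est, 2, stats::sd) / pmax(abs(mu), 1e-12)
  flags <- data.frame(param1 = character(0), param2 = character(0),
                      correlation = numeric(0))
  correlation <- NULL
  if (nrow(est) >= 3) {
    loose <- names(spread)[spread > spread_min]
    if (length(loose) >= 2) {
      correlation <- suppressWarnings(stats::cor(est[, loose, drop = FALSE]))
      pairs <- which(abs(correlation) > cor_threshold &
                       upper.tri(correlation), arr.ind = TRUE)
      if (nrow(pairs) > 0) {
        flags <- data.frame(
          param1 = rownames(correlation)[pairs[, 1]],
          param2 = colnames(correlation)[pairs[, 2]],
          correlation = correlation[pairs])
      }
    }
  }
  structure(list(estimates = est, fval = fval, accepted = accepted,
                 spread = spread, correlation = correlation,
                 flags = flags, seed = seed),
            class = "fk_idscan")
}

#' @export
print.fk_idscan <- function(x, ...) {
  cat("Identifiability scan:", length(x$fval), "starts,",
      sum(x$accepted), "accepted fits\n")
  if (nrow(x$flags) > 0) {
    cat("  flagged interdependent pairs:\n")
    print(x$flags)
  } else {
    cat("  no interdependent parameter pairs flagged\n")
  }
  invisible(x)
}

#' Write a fit (with optional bounds) as a publication-shaped CSV
#'
#' Emits one row per rate constant with columns
#' `param,best_fit,lower,upper`, followed by two criterion rows
#' (`fval_chi_sqr`, `fit_quality`) in the `best_fit` column.
#'
#' @param fit An `fk_fit`.
#' @param bounds Optional `fk_bounds`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_fit_csv <- function(fit, path, bounds = NULL) {
  df <- data.frame(param = names(fit$rates),
                   best_fit = unname(fit$rates),
                   lower = NA_real_, upper = NA_real_)
  if (!is.null(bounds)) {
    m <- match(df$param, bounds$param)
    df$lower <- bounds$lower[m]
    df$upper <- bounds$upper[m]
  }
  df <- rbind(df,
              data.frame(param = c("fval_chi_sqr", "fit_quality"),
                         best_fit = c(fit$fval_chi_sqr, fit$fit_quality),
                         lower = NA_real_, upper = NA_real_))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
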