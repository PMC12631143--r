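#' Calibrate the healthy-reference model to observed concentrations
#'
#' Fits a chosen subset of structural parameters to healthy-volunteer
#' concentration--time observations by minimizing the sum of squared
#' log10 residuals between simulated and observed concentrations, with a
#' Monte-Carlo multi-start around box bounds followed by local
#' quasi-Newton refinement (L-BFGS-B on log-parameters).
#'
#' Only a structurally identifiable subset should be fitted from
#' concentration data alone: bioavailability `F` is confounded with
#' volumes, and the individual elimination routes (secretion, hepatic,
#' biliary) enter the healthy model only through their sum, so the default
#' subset frees the dominant route (`CL_sec`) together with absorption and
#' distribution constants and holds the minor routes at their priors.
#' Candidate solutions violating the baseline clearance-share constraints
#' (renal share > 0.8, secretion share in 0.6--0.8) are penalized.
#'
#' @param params0 Starting [pbpk_parameters()]; also supplies the fixed
#'   values of parameters not in `fit_params`.
#' @param observations data.frame with columns `subject`, `dose_mg`,
#'   `time_h`, `conc_umol_L`; must span at least two distinct doses.
#' @param fit_params Character vector of parameters to fit.
#' @param bounds Named list of `c(lower, upper)` boxes per fitted
#'   parameter; defaults to a 4-fold box around `params0`.
#' @param n_starts Number of Monte-Carlo starts (the first start is
#'   `params0` itself).
#' @param seed Seed for the random starts.
#' @param individual The [pbpk_individual()] the observations refer to.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @return A list of class `pbpk_calibration`: `params` (fitted
#'   `pbpk_parameters`), `objective`, `starts` (per-start data.frame with
#'   objective and convergence code), `bound_active` (named logical),
#'   `n_obs`.
#' @export
calibrate_healthy <- function(params0, observations,
                              fit_params = c("ka", "Vc", "Q", "CL_sec"),
                              bounds = NULL,
                              n_starts = 4, seed = 1,
                              individual = reference_individual(),
                              maxit = 60) {
  stopifnot(inherits(params0, "pbpk_parameters"))
  req <- c("dose_mg", "time_h", "conc_umol_L")
  if (!all(req %in% names(observations))) {
    stop("observations must have columns dose_mg, time_h, conc_umol_L")
  }
  obs <- observations[observations$conc_umol_L > 0 &
                        observations$time_h > 0, , drop = FALSE]
  if (length(unique(obs$dose_mg)) < 2) {
    stop("observations must span at least two distinct doses", call. = FALSE)
  }
  if (is.null(bounds)) {
    bounds <- lapply(fit_params, function(nm) {
      c(params0[[nm]] / 4, min(params0[[nm]] * 4,
                               if (nm %in% c("F", "fu")) 1 else Inf))
    })
    names(bounds) <- fit_params
  }
  if (!all(fit_params %in% names(bounds))) {
    stop("`bounds` must cover every fitted parameter", call. = FALSE)
  }
  lower <- log(vapply(bounds, `[`, 0, 1L))
  upper <- log(vapply(bounds, `[`, 0, 2L))
  if (any(!is.finite(lower)) || any(lower >= upper)) {
    stop("invalid bounds box", call. = FALSE)
  }

  doses <- sort(unique(obs$dose_mg))
  times_by_dose <- lapply(doses, function(d) sort(unique(
    obs$time_h[obs$dose_mg == d])))
  obj <- function(logtheta) {
    p <- params0
    p[fit_params] <- as.list(exp(logtheta))
    class(p) <- "pbpk_parameters"
    sh <- clearance_shares(p, individual)
    pen <- 0
    if (sh[["renal_share"]] <= 0.8) {
      pen <- pen + 1e3 * (0.8 - sh[["renal_share"]])
    }
    if (sh[["secretion_share"]] < 0.6) {
      pen <- pen + 1e3 * (0.6 - sh[["secretion_share"]])
    }
    if (sh[["secretion_share"]] > 0.8) {
      pen <- pen + 1e3 * (sh[["secretion_share"]] - 0.8)
    }
    sse <- 0
    for (i in seq_along(doses)) {
      tt <- times_by_dose[[i]]
      prof <- simulate_profile(p, individual, pbpk_regimen(doses[i]),
                               dt = max(min(diff(c(0, tt))) / 2, 0.05),
                               duration_h = max(tt))
      pred <- stats::approx(prof$time_h, prof$conc_umol_L, xout = tt)$y
      sel <- obs$dose_mg == doses[i]
      po <- pred[match(obs$time_h[sel], tt)]
      ok <- po > 0
      sse <- sse + sum((log10(po[ok]) -
                          log10(obs$conc_umol_L[sel][ok]))^2) +
        1e3 * sum(!ok)
    }
    if (!is.finite(sse)) return(1e10)
    sse + pen
  }

  start0 <- log(vapply(fit_params, function(nm) params0[[nm]], 0))
  starts <- with_rng(seed, {
    extra <- replicate(max(n_starts - 1, 0),
                       stats::runif(length(fit_params), lower, upper))
    cbind(start0, extra, deparse.level = 0)
  })
  fits <- lapply(seq_len(ncol(starts)), function(j) {
    stats::optim(starts[, j], obj, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 1e9))
  })
  objs <- vapply(fits, function(f) f$value, 0)
  best <- fits[[which.min(objs)]]
  theta <- exp(best$par)
  fitted <- params0
  fitted[fit_params] <- as.list(theta)
  class(fitted) <- "pbpk_parameters"
  tol <- 1e-4
  bound_active <- (best$par - lower < tol) | (upper - best$par < tol)
  names(bound_active) <- fit_params
  structure(list(params = fitted,
                 objective = best$value,
                 starts = data.frame(start = seq_along(objs),
                                     objective = objs,
                                     convergence = vapply(fits, function(f)
                                       f$convergence, 0L)),
                 bound_active = bound_active,
                 n_obs = nrow(obs)),
            class = "pbpk_calibration")
}

#' @export
print.pbpk_calibration <- function(x, ...) {
  cat(sprintf("<pbpk_calibration> objective %.4g over %d observations, %d starts\n",
              x$objective, x$n_obs, nrow(x$starts)))
  if (any(x$bound_active)) {
    cat("  bound-active:", paste(names(x$bound_active)[x$bound_active],
                                 collapse = ", "), "\n")
  }
  invisible(x)
}
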