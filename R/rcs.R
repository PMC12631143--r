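#' Restricted cubic spline dose--Cmax model
#'
#' A four-knot restricted cubic spline linking weekly oral methotrexate
#' dose M (mg) to peak plasma concentration Cmax (umol/L):
#' \deqn{Cmax = \beta_0 + \beta_1 M + \beta_2 f_1(M) + \beta_3 f_2(M)}
#' where the nonlinear basis functions are truncated-power combinations
#' constrained so the curve is exactly linear below the first and above
#' the last knot. Under the `"harrell_scaled"` convention each basis
#' function is divided by `(k4 - k1)^2` so the nonlinear coefficients are
#' on the scale of the linear term.
#'
#' @param beta Numeric length-4 vector `(beta0, beta1, beta2, beta3)`.
#' @param knots Strictly increasing numeric length-4 vector of knot doses
#'   (mg).
#' @param scaling `"harrell_scaled"` (default) or `"unscaled"`.
#' @return An object of class `rcs_model`.
#' @export
rcs_model <- function(beta, knots, scaling = c("harrell_scaled", "unscaled")) {
  scaling <- match.arg(scaling)
  if (length(beta) != 4L || !all(is.finite(beta))) {
    stop("`beta` must be 4 finite coefficients", call. = FALSE)
  }
  if (length(knots) != 4L || any(diff(knots) <= 0)) {
    stop("`knots` must be 4 strictly increasing doses", call. = FALSE)
  }
  structure(list(beta = as.numeric(beta), knots = as.numeric(knots),
                 scaling = scaling),
            class = "rcs_model")
}

#' Published dose--Cmax spline for low-dose methotrexate
#'
#' The reported four-knot spline relating weekly oral dose to first-dose
#' Cmax in adults with normal renal function: coefficients
#' (0.0636, 0.0139, 0.0542, -0.0912) with knots at 5, 7.5, 15 and
#' 22.5 mg. The nonlinear terms are evaluated under the Harrell scaling
#' convention; as printed, the raw coefficient magnitudes would otherwise
#' imply physiologically impossible concentrations.
#'
#' @return An `rcs_model`.
#' @export
published_rcs_model <- function() {
  rcs_model(beta = c(0.0636, 0.0139, 0.0542, -0.0912),
            knots = c(5, 7.5, 15, 22.5),
            scaling = "harrell_scaled")
}

#' Restricted cubic spline basis
#'
#' Evaluates the two nonlinear basis functions of the four-knot
#' restricted cubic spline at given doses. Each cubic term `(x - k)^3`
#' is truncated to zero where `x <= k`, which makes the resulting curve
#' linear for doses at or below the first knot and (in combination with
#' the tail constraint) linear again at or beyond the last knot.
#'
#' @param dose Numeric vector of doses (mg).
#' @param knots Strictly increasing length-4 knot vector.
#' @param scaling `"harrell_scaled"` divides each basis function by
#'   `(k4 - k1)^2`; `"unscaled"` leaves the raw cubic scale.
#' @return Matrix with columns `f1`, `f2`.
#' @export
rcs_basis <- function(dose, knots, scaling = c("harrell_scaled", "unscaled")) {
  scaling <- match.arg(scaling)
  if (length(knots) != 4L || any(diff(knots) <= 0)) {
    stop("`knots` must be 4 strictly increasing doses", call. = FALSE)
  }
  k <- knots
  tp <- function(x, kn) pmax(x - kn, 0)^3
  w3 <- function(kj) (k[4] - kj) / (k[4] - k[3])
  w4 <- function(kj) (k[3] - kj) / (k[4] - k[3])
  f1 <- tp(dose, k[1]) - w3(k[1]) * tp(dose, k[3]) + w4(k[1]) * tp(dose, k[4])
  f2 <- tp(dose, k[2]) - w3(k[2]) * tp(dose, k[3]) + w4(k[2]) * tp(dose, k[4])
  if (scaling == "harrell_scaled") {
    sc <- (k[4] - k[1])^2
    f1 <- f1 / sc
    f2 <- f2 / sc
  }
  cbind(f1 = f1, f2 = f2)
}

#' Evaluate the spline at given doses
#'
#' @param model An [rcs_model()].
#' @param dose Numeric vector of nonnegative doses (mg).
#' @return Predicted Cmax (umol/L), same length as `dose`.
#' @export
evaluate_rcs <- function(model, dose) {
  stopifnot(inherits(model, "rcs_model"))
  if (any(dose < 0)) stop("`dose` must be nonnegative", call. = FALSE)
  B <- rcs_basis(dose, model$knots, model$scaling)
  unname(model$beta[1] + model$beta[2] * dose +
           model$beta[3] * B[, "f1"] + model$beta[4] * B[, "f2"])
}

#' Fit a four-knot restricted cubic spline by ordinary least squares
#'
#' Knots default to the 0.05, 0.275, 0.725 and 0.95 empirical quantiles
#' of the observed doses; they can be fixed explicitly (e.g. to compare
#' against a generating model on the same basis). The design is the
#' 4-column matrix (1, M, f1, f2) and the fit is OLS. Model parsimony is
#' scored as `AIC = n * log(RSS / n) + 2 * 4`.
#'
#' @param data data.frame with columns `dose_mg` (> 0) and `cmax_umol_L`
#'   (>= 0); at least 8 rows and 4 distinct doses.
#' @param knots Optional explicit knot vector (length 4, increasing).
#' @param scaling Basis scaling convention, as in [rcs_basis()].
#' @return A list with components `model` (the fitted [rcs_model()]),
#'   `aic`, `rss` and `n`.
#' @export
fit_rcs <- function(data, knots = NULL,
                    scaling = c("harrell_scaled", "unscaled")) {
  scaling <- match.arg(scaling)
  if (!all(c("dose_mg", "cmax_umol_L") %in% names(data))) {
    stop("`data` must have columns dose_mg and cmax_umol_L", call. = FALSE)
  }
  dose <- data$dose_mg
  y <- data$cmax_umol_L
  if (length(dose) < 8 || length(unique(dose)) < 4) {
    stop("need >= 8 rows and >= 4 distinct doses to fit", call. = FALSE)
  }
  if (any(dose <= 0) || any(y < 0)) {
    stop("doses must be positive and Cmax nonnegative", call. = FALSE)
  }
  if (is.null(knots)) {
    knots <- unname(stats::quantile(dose, c(0.05, 0.275, 0.725, 0.95)))
    if (any(diff(knots) <= 0)) {
      stop("dose quantiles do not yield 4 distinct knots", call. = FALSE)
    }
  }
  B <- rcs_basis(dose, knots, scaling)
  X <- cbind(1, dose, B)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    stop(paste("rank-deficient spline design: the doses do not activate the",
               "nonlinear basis (all observations in the linear region)"),
         call. = FALSE)
  }
  fit <- qr.coef(qrX, y)
  res <- y - X %*% fit
  rss <- sum(res^2)
  n <- length(y)
  list(model = rcs_model(as.numeric(fit), knots, scaling),
       aic = n * log(rss / n) + 2 * 4,
       rss = rss, n = n)
}

#' Invert the spline for the dose attaining a target Cmax
#'
#' Finds the dose at which the fitted curve reaches `target_cmax`, by
#' bracketed root finding on `dose_range`. The curve must be strictly
#' increasing on the range (checked on a fine grid); the root satisfies
#' `|Cmax(dose) - target| < 1e-9`.
#'
#' @param model An [rcs_model()].
#' @param target_cmax Target Cmax (umol/L).
#' @param dose_range Length-2 search interval (mg), lower bound >= 0.
#' @return The dose in mg.
#' @export
invert_for_dose <- function(model, target_cmax, dose_range) {
  stopifnot(inherits(model, "rcs_model"), length(dose_range) == 2L)
  lo <- dose_range[1]; hi <- dose_range[2]
  if (lo < 0 || hi <= lo) stop("invalid dose range", call. = FALSE)
  grid <- seq(lo, hi, length.out = 2001L)
  fv <- evaluate_rcs(model, grid)
  dif <- diff(fv)
  if (any(dif <= 0)) {
    turns <- grid[which(dif <= 0)]
    stop(sprintf(
      "model is not strictly increasing on [%g, %g]; first turning near dose %.3g",
      lo, hi, turns[1]), call. = FALSE)
  }
  flo <- fv[1] - target_cmax
  fhi <- fv[length(fv)] - target_cmax
  if (flo > 0 || fhi < 0) {
    stop(sprintf(
      "target %.4g umol/L not bracketed on [%g, %g] (curve spans [%.4g, %.4g])",
      target_cmax, lo, hi, fv[1], fv[length(fv)]), call. = FALSE)
  }
  root <- stats::uniroot(function(d) evaluate_rcs(model, d) - target_cmax,
                         lower = lo, upper = hi, tol = 1e-12)$root
  if (abs(evaluate_rcs(model, root) - target_cmax) >= 1e-9) {
    stop("root refinement did not reach tolerance", call. = FALSE)
  }
  root
}

#' Read and write spline models as flat key-value text
#'
#' @param model An [rcs_model()].
#' @param path File path.
#' @return `read_rcs_model()` returns an `rcs_model`;
#'   `write_rcs_model()` returns `path` invisibly.
#' @export
write_rcs_model <- function(model, path) {
  stopifnot(inherits(model, "rcs_model"))
  lines <- c(sprintf("beta%d = %.12g", 0:3, model$beta),
             sprintf("k%d = %.12g", 1:4, model$knots),
             sprintf("scaling = %s", model$scaling))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rcs_model
#' @export
read_rcs_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(trimws(lines))], "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  rcs_model(beta = as.numeric(vals[sprintf("beta%d", 0:3)]),
            knots = as.numeric(vals[sprintf("k%d", 1:4)]),
            scaling = vals[["scaling"]])
}
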