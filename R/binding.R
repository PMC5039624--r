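# Single-site quadratic binding isotherm: prediction and Kd fitting.

#' Fraction of labelled species bound, exact single-site model
#'
#' Solves the two-state mass-action equilibrium P + L <-> PL without the
#' ligand-excess approximation:
#' \deqn{f_b = \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2P}.}
#' The exact quadratic form matters when the observed and titrant species
#' are at comparable concentrations, where the hyperbolic approximation is
#' biased.
#'
#' @param P Total concentration of the observed species, uM (> 0).
#' @param L Total titrant concentration, uM (>= 0); vectorised.
#' @param Kd Dissociation constant, uM (>= 0).
#' @return Fraction bound in \[0, 1\]; increasing in `L`, decreasing in `Kd`.
#' @export
#' @examples
#' fraction_bound(20, 60, 140)  # 0.27985
fraction_bound <- function(P, L, Kd) {
  if (!is.numeric(P) || length(P) != 1 || !is.finite(P) || P <= 0)
    stop_validation("P must be a single positive concentration")
  if (any(L < 0) || any(!is.finite(L)))
    stop_validation("L must be finite and >= 0")
  if (any(Kd < 0) || any(!is.finite(Kd)))
    stop_validation("Kd must be finite and >= 0")
  s <- P + L + Kd
  disc <- s^2 - 4 * P * L
  disc[disc < 0] <- 0  # guard FP noise at the stoichiometric point
  fb <- (s - sqrt(disc)) / (2 * P)
  pmin(pmax(fb, 0), 1)
}

#' Predicted observable change for a titration point
#'
#' @inheritParams fraction_bound
#' @param delta_max Maximum change of the observable at saturation.
#' @return `delta_max * fraction_bound(P, L, Kd)`.
#' @export
predict_delta_obs <- function(P, L, Kd, delta_max) {
  delta_max * fraction_bound(P, L, Kd)
}

#' Fit the dissociation constant from a titration response
#'
#' Ordinary least-squares fit of the single-site quadratic model
#' `delta_obs = delta_max * fraction_bound(P, L, Kd)` to per-point responses
#' (intensity changes from the free state for broadening-dominated residues,
#' or combined shift changes -- the machinery is observable-agnostic).
#'
#' For any fixed Kd the optimal `delta_max` is linear least squares, so the
#' fit profiles the residual sum of squares over a log-spaced Kd grid within
#' the box \[`kd_lower`, `kd_upper`\] and polishes the best bracket with
#' one-dimensional optimisation.  The procedure is deterministic: identical
#' inputs give identical fits.
#'
#' A hyperbolic (ligand-excess) variant `delta_max * L / (L + Kd)` is
#' available for comparison via `model = "hyperbolic"`.
#'
#' @param observations data.frame with columns `L` (titrant, uM) and
#'   `delta_obs`, or a numeric vector `delta_obs` with `L` supplied
#'   separately.
#' @param P Observed-species total concentration, uM.
#' @param L Titrant concentrations if `observations` is a bare vector.
#' @param model `"quadratic"` (exact, default) or `"hyperbolic"`.
#' @param kd_lower,kd_upper Box constraints on Kd, uM.
#' @param n_grid Size of the log-spaced Kd profile grid.
#' @return A `binding_fit`: `Kd`, `delta_max`, `rss`, `se_Kd`,
#'   `se_delta_max`, `at_bound` flag, `fitted` values, model name.
#' @export
#' @examples
#' L <- c(10, 20, 60, 100)
#' y <- predict_delta_obs(20, L, 140, 1)
#' fit_kd(data.frame(L = L, delta_obs = y), P = 20)
fit_kd <- function(observations, P, L = NULL,
                   model = c("quadratic", "hyperbolic"),
                   kd_lower = 1e-3, kd_upper = 1e6, n_grid = 200) {
  model <- match.arg(model)
  if (is.data.frame(observations)) {
    L <- observations$L
    y <- observations$delta_obs
  } else {
    y <- as.numeric(observations)
  }
  if (is.null(L) || length(L) != length(y))
    stop_validation("need titrant concentrations L matching delta_obs")
  ok <- is.finite(L) & is.finite(y)
  L <- L[ok]; y <- y[ok]
  if (length(y) < 3)
    stop_validation("need >= 3 observations to fit (Kd, delta_max)")
  if (length(unique(L[L > 0])) < 2)
    stop_validation("need >= 2 distinct nonzero titrant concentrations")
  if (all(y == 0))
    stop_data("degenerate data: all delta_obs are zero")

  fb_of <- function(kd) {
    if (model == "quadratic") fraction_bound(P, L, kd) else L / (L + kd)
  }
  dmax_cap <- 10 * max(abs(y))
  # profiled RSS: optimal delta_max for fixed Kd is closed-form OLS
  profile <- function(log10kd) {
    fb <- fb_of(10^log10kd)
    ss <- sum(fb^2)
    dm <- if (ss == 0) 0 else sum(fb * y) / ss
    dm <- min(max(dm, 0), dmax_cap)
    sum((y - dm * fb)^2)
  }
  lo <- log10(kd_lower); hi <- log10(kd_upper)
  grid <- seq(lo, hi, length.out = n_grid)
  rss_grid <- vapply(grid, profile, numeric(1))
  i0 <- which.min(rss_grid)
  bl <- grid[max(i0 - 1L, 1L)]; bu <- grid[min(i0 + 1L, n_grid)]
  opt <- stats::optimize(profile, lower = bl, upper = bu, tol = 1e-12)
  # accept the better of grid point and polished optimum
  if (opt$objective <= rss_grid[i0]) {
    log10kd <- opt$minimum; rss <- opt$objective
  } else {
    log10kd <- grid[i0]; rss <- rss_grid[i0]
  }
  Kd <- 10^log10kd
  fb <- fb_of(Kd)
  delta_max <- min(max(sum(fb * y) / sum(fb^2), 0), dmax_cap)
  fitted <- delta_max * fb
  rss <- sum((y - fitted)^2)
  at_bound <- (Kd / kd_lower < 1.01) || (kd_upper / Kd < 1.01)

  se <- binding_se(L, y, P, Kd, delta_max, rss, model)
  structure(list(Kd = Kd, delta_max = delta_max, rss = rss,
                 se_Kd = se[1], se_delta_max = se[2],
                 at_bound = at_bound, model = model, P = P,
                 L = L, delta_obs = y, fitted = fitted),
            class = "binding_fit")
}

# Approximate standard errors from the Gauss-Newton covariance
# sigma^2 (J'J)^-1 with a forward-difference Jacobian; NA when the fit is
# interpolating (zero residual d.o.f. variance) or the system is singular.
binding_se <- function(L, y, P, Kd, delta_max, rss, model) {
  n <- length(y); p <- 2L
  if (n <= p) return(c(NA_real_, NA_real_))
  pred <- function(kd, dm) {
    fb <- if (model == "quadratic") fraction_bound(P, L, kd) else L / (L + kd)
    dm * fb
  }
  h1 <- max(Kd * 1e-6, 1e-12); h2 <- max(abs(delta_max) * 1e-6, 1e-12)
  J <- cbind((pred(Kd + h1, delta_max) - pred(Kd, delta_max)) / h1,
             (pred(Kd, delta_max + h2) - pred(Kd, delta_max)) / h2)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * rss / (n - p), error = function(e) NULL)
  if (is.null(cov)) return(c(NA_real_, NA_real_))
  sqrt(pmax(diag(cov), 0))
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s single-site model, n = %d\n",
              x$model, length(x$L)))
  cat(sprintf("  Kd        = %.4g uM (se %.3g)%s\n", x$Kd, x$se_Kd,
              if (x$at_bound) "  [at bound]" else ""))
  cat(sprintf("  delta_max = %.4g (se %.3g)\n", x$delta_max, x$se_delta_max))
  cat(sprintf("  RSS       = %.4g\n", x$rss))
  invisible(x)
}

#' Write a binding-fit report
#'
#' @param fit A `binding_fit`.
#' @param path Output path; `.json` suffix selects JSON, otherwise CSV.
#' @return The report list, invisibly.
#' @export
write_binding_fit <- function(fit, path) {
  rep <- list(Kd_uM = fit$Kd, delta_max = fit$delta_max, rss = fit$rss,
              se_Kd = fit$se_Kd, at_bound = fit$at_bound, model = fit$model)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(rep), path, row.names = FALSE)
  }
  invisible(rep)
}
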