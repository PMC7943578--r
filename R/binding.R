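# Quadratic tight-binding (ligand-depletion) saturation model and fitting.
# The model describes a titration in which one component is held at a fixed
# total concentration c (e.g. a fluorophore at 0.1 uM) while the binding
# partner is varied; because c is not negligible relative to Kd, the free
# and total concentrations differ and the bound fraction is the physical
# root of a quadratic rather than a simple hyperbola.

#' Quadratic tight-binding saturation signal
#'
#' `y = bmax * ((c + x + kd) - sqrt((c + x + kd)^2 - 4 c x)) / (2 c)`.
#'
#' This is the physically meaningful (minus) root of the binding quadratic:
#' it satisfies `y(0) = 0`, is monotone non-decreasing in `x`, and saturates
#' at `bmax`. (The plus root diverges and gives a non-zero signal at zero
#' titrant, so it cannot describe a titration.) For `c << kd` the curve
#' reduces to the hyperbola `bmax * x / (x + kd)`.
#'
#' @param x concentration(s) of the variable component (uM), non-negative.
#' @param kd dissociation constant (uM).
#' @param bmax signal when all of the constant component is bound.
#' @param c total concentration of the constant component (uM), positive.
#' @return Signal value(s), in `[0, bmax]`.
#' @export
fraction_bound <- function(x, kd, bmax, c) {
  if (any(x < 0)) stop("x must be non-negative")
  if (any(kd < 0)) stop("kd must be non-negative")
  if (any(c <= 0)) stop("c must be positive")
  term <- c + x + kd
  disc <- pmax(term^2 - 4 * c * x, 0)
  bmax * (term - sqrt(disc)) / (2 * c)
}

#' Fit the tight-binding model to a titration curve
#'
#' Least-squares estimates of `(kd, bmax)` with `c` fixed at its known
#' experimental value, using multi-start Levenberg-Marquardt over a
#' log-spaced grid of `kd` starting values. Confidence intervals come from a
#' seeded residual-resampling bootstrap.
#'
#' @param curve a `binding_curve` (see [simulate_binding_curve()] /
#'   [read_binding_curve()]) or a data frame with columns `x`, `y`.
#' @param c constant-component concentration (uM); taken from the curve when
#'   present.
#' @param kd_starts log-spaced grid of `kd` starting values (uM).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return An object of class `binding_fit`: `estimates` (kd, bmax),
#'   `se`, `ci_kd`, `ci_bmax` (percentile bootstrap), `rss`, `converged`,
#'   and `wide_ci` (TRUE when the kd CI spans more than a factor of 10,
#'   flagging an unidentifiable fit, e.g. a titration that never
#'   approaches saturation).
#' @export
fit_binding <- function(curve, c = NULL,
                        kd_starts = 10^seq(-3, 3, length.out = 7),
                        n_boot = 1000L, seed = 1L, conf = 0.95) {
  if (inherits(curve, "binding_curve")) {
    df <- data.frame(x = curve$x, y = curve$y)
    if (is.null(c)) c <- curve$c
  } else {
    df <- as.data.frame(curve)
  }
  if (is.null(c)) stop("constant-component concentration c is required")
  if (nrow(df) < 4L) stop("need at least 4 titration points")

  fit_once <- function(data, kd0, bmax0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ fraction_bound(x, kd, bmax, c = c), data = data,
        start = list(kd = kd0, bmax = bmax0),
        lower = c(kd = 0, bmax = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  bmax0 <- max(df$y)
  fits <- lapply(kd_starts, function(k0) fit_once(df, k0, bmax0))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) {
    stop("binding fit failed to converge from every start; check that the ",
         "titration spans the transition (x range vs kd) and that c is ",
         "correct")
  }
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  est <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA_real_, bmax = NA_real_))
  fitted_y <- stats::fitted(best)
  resid_y <- stats::residuals(best)

  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 2L, dimnames = list(NULL, c("kd", "bmax")))
  for (b in seq_len(n_boot)) {
    yb <- fitted_y + sample(resid_y, replace = TRUE)
    fb <- fit_once(data.frame(x = df$x, y = yb), est[["kd"]], est[["bmax"]])
    if (!is.null(fb)) boot[b, ] <- stats::coef(fb)
  }
  alpha <- (1 - conf) / 2
  ci_kd <- stats::quantile(boot[, "kd"], c(alpha, 1 - alpha), na.rm = TRUE,
                           names = FALSE)
  ci_bmax <- stats::quantile(boot[, "bmax"], c(alpha, 1 - alpha),
                             na.rm = TRUE, names = FALSE)
  wide <- is.finite(ci_kd[1]) && ci_kd[1] > 0 &&
    (ci_kd[2] / ci_kd[1] > 10)
  if (!is.finite(ci_kd[1]) || ci_kd[1] <= 0) {
    wide <- TRUE
  }
  structure(
    list(estimates = est, se = se, ci_kd = ci_kd, ci_bmax = ci_bmax,
         rss = min(rss), converged = TRUE, c = c, n_boot = n_boot,
         conf = conf, wide_ci = wide),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "tight-binding fit (c = %g uM): Kd = %.4g uM [%.4g, %.4g], Bmax = %.4g%s\n",
    x$c, x$estimates[["kd"]], x$ci_kd[1], x$ci_kd[2],
    x$estimates[["bmax"]],
    if (x$wide_ci) "  (CI wide: poorly identified)" else ""))
  invisible(x)
}

#' Write a binding fit as JSON
#'
#' @param fit a `binding_fit`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_binding_fit <- function(fit, path) {
  out <- list(kd = fit$estimates[["kd"]], bmax = fit$estimates[["bmax"]],
              se_kd = unname(fit$se[1]), se_bmax = unname(fit$se[2]),
              ci_kd = fit$ci_kd, ci_bmax = fit$ci_bmax, rss = fit$rss,
              c = fit$c, conf = fit$conf, wide_ci = fit$wide_ci)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
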