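#' AFM force-indentation curve
#'
#' Sampled (time, indentation, force) triplets from a nanoindentation
#' approach segment, plus the probe metadata needed for contact-mechanics
#' fitting. `indentation_m` is the probe position coordinate (increasing
#' into the sample); the contact point along this axis is a free parameter
#' of the fits, so an arbitrary origin is fine.
#'
#' @param time_s strictly increasing sample times, s.
#' @param indentation_m probe position, m.
#' @param force_N measured force, N.
#' @param bead_radius_m indenter sphere radius (default 18.5 um — a 37 um
#'   polystyrene bead).
#' @param poisson_ratio sample Poisson's ratio (default 0.5, incompressible).
#' @param speed_m_s approach speed (default 7 um/s).
#' @param spring_constant_N_m cantilever spring constant (typical
#'   0.027-0.039 N/m).
#' @param setpoint_N force setpoint ending the approach (default 12 nN).
#' @return A `force_curve` object.
#' @export
force_curve <- function(time_s, indentation_m, force_N,
                        bead_radius_m = 18.5e-6, poisson_ratio = 0.5,
                        speed_m_s = 7e-6, spring_constant_N_m = 0.033,
                        setpoint_N = 12e-9) {
  n <- length(time_s)
  if (length(indentation_m) != n || length(force_N) != n)
    stop("time, indentation and force must have equal length", call. = FALSE)
  if (n && any(diff(time_s) <= 0))
    stop("`time_s` must be strictly increasing", call. = FALSE)
  assert_scalar_number(bead_radius_m, "bead_radius_m", lower = 0, strict_lower = TRUE)
  assert_scalar_number(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5)
  structure(list(time_s = time_s, indentation_m = indentation_m,
                 force_N = force_N, bead_radius_m = bead_radius_m,
                 poisson_ratio = poisson_ratio, speed_m_s = speed_m_s,
                 spring_constant_N_m = spring_constant_N_m,
                 setpoint_N = setpoint_N),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force curve: %d samples, %.2f s, max force %.2f nN\n",
              length(x$time_s), diff(range(x$time_s)), max(x$force_N) * 1e9))
  cat(sprintf("  R = %.1f um, nu = %.2f, v = %.1f um/s\n",
              x$bead_radius_m * 1e6, x$poisson_ratio, x$speed_m_s * 1e6))
  invisible(x)
}

#' Contact-model force laws
#'
#' `hertz_force()` is the Hertz solution for a rigid sphere on an elastic
#' half-space, \eqn{F = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}}.
#' `kvm_force()` is the constant-speed approach solution of the
#' Kelvin-Voigt-Maxwell viscoelastic network with Hertzian sphere geometry
#' used throughout this package,
#' \deqn{F = \frac{4\sqrt{R}}{3(1-\nu^2)}\left(E\,\delta^{3/2} +
#'   \tfrac{3}{2}\,\eta\, v\, \delta^{1/2}\right),}
#' which yields the apparent Young's modulus \eqn{E} and apparent viscosity
#' \eqn{\eta} and reduces exactly to the Hertz law as \eqn{\eta \to 0}.
#'
#' @param delta_m indentation depth beyond contact, m (values < 0 give 0).
#' @param E_Pa apparent Young's modulus, Pa.
#' @param eta_Pa_s apparent viscosity, Pa s.
#' @param speed_m_s indentation speed, m/s.
#' @param R_m sphere radius, m.
#' @param nu Poisson's ratio.
#' @return Force in N.
#' @export
#' @examples
#' hertz_force(3e-6, 500) * 1e9  # 19.87 nN
hertz_force <- function(delta_m, E_Pa, R_m = 18.5e-6, nu = 0.5) {
  d <- pmax(delta_m, 0)
  (4 / 3) * (E_Pa / (1 - nu^2)) * sqrt(R_m) * d^1.5
}

#' @rdname hertz_force
#' @export
kvm_force <- function(delta_m, E_Pa, eta_Pa_s, speed_m_s = 7e-6,
                      R_m = 18.5e-6, nu = 0.5) {
  d <- pmax(delta_m, 0)
  (4 * sqrt(R_m)) / (3 * (1 - nu^2)) *
    (E_Pa * d^1.5 + 1.5 * eta_Pa_s * speed_m_s * sqrt(d))
}

# Profile least squares over the contact point z_c. Given z_c the model is
# linear in (baseline, E[, eta]); search z_c on a grid, then refine by
# optimize(). Returns the final conditional linear fit.
profile_contact_fit <- function(curve, model = c("hertz", "kvm"),
                                max_indentation_m = Inf) {
  model <- match.arg(model)
  z <- curve$indentation_m
  f <- curve$force_N
  n <- length(z)
  if (n < 20L) stop("need at least 20 samples", call. = FALSE)
  if (diff(range(f)) == 0)
    stop("no contact detected: force signal is constant", call. = FALSE)
  R <- curve$bead_radius_m; nu <- curve$poisson_ratio
  v <- curve$speed_m_s
  C <- (4 * sqrt(R)) / (3 * (1 - nu^2))

  fit_at <- function(zc) {
    d <- z - zc
    use <- d <= max_indentation_m      # 3-um limit counts indentation past contact
    d <- pmax(d[use], 0)
    y <- f[use]
    X <- if (model == "hertz") cbind(1, C * d^1.5)
         else cbind(1, C * d^1.5, C * 1.5 * v * sqrt(d))
    if (sum(d > 0) < 10L) return(NULL)  # need >= 10 post-contact samples
    ft <- stats::lm.fit(X, y)
    list(zc = zc, coef = ft$coefficients, rss = sum(ft$residuals^2),
         n = length(y), p = ncol(X), X = X, y = y)
  }
  rng <- range(z)
  grid <- seq(rng[1], rng[2] - 0.05 * diff(rng), length.out = 120L)
  rss <- vapply(grid, function(zc) {
    ft <- fit_at(zc); if (is.null(ft)) Inf else ft$rss
  }, numeric(1))
  if (!any(is.finite(rss)))
    stop("no contact detected: too few post-contact samples", call. = FALSE)
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(zc) {
    ft <- fit_at(zc); if (is.null(ft)) Inf else ft$rss
  }, c(lo, hi), tol = 1e-12)
  best <- fit_at(opt$minimum)
  if (is.null(best)) best <- fit_at(grid[i])
  best
}

# standard errors of the conditional linear fit (contact point held fixed);
# columns are rescaled to unit norm first — the raw design mixes scales of
# 1 and ~1e-10 and its normal matrix is numerically singular
linfit_se <- function(best) {
  dof <- best$n - best$p
  s2 <- if (dof > 0) best$rss / dof else NA_real_
  sc <- sqrt(colSums(best$X^2))
  sc[sc == 0] <- 1
  Xs <- sweep(best$X, 2, sc, `/`)
  cov_s <- tryCatch(solve(crossprod(Xs)), error = function(e) NULL)
  if (is.null(cov_s)) return(rep(NA_real_, best$p))
  sqrt(diag(cov_s) * s2) / sc
}

#' Hertz spherical-indenter fit
#'
#' Least-squares fit of the Hertz sphere law to a force-indentation curve
#' with the contact point and a baseline force offset as free parameters.
#' Only samples indented at most `max_indentation_m` beyond the fitted
#' contact point enter the fit (3 um by default), together with all
#' pre-contact samples that pin the baseline.
#'
#' @param curve a [force_curve()].
#' @param max_indentation_m indentation-depth cutoff, m (default 3e-6).
#' @return A `visco_fit`: list with `model`, `E_Pa`, `E_se`, `eta_Pa_s`
#'   (`NA` for Hertz), `contact_point_m`, `baseline_N`, `rss`, `n_fit`,
#'   `converged`.
#' @export
hertz_sphere_fit <- function(curve, max_indentation_m = 3e-6) {
  stopifnot(inherits(curve, "force_curve"))
  best <- profile_contact_fit(curve, "hertz", max_indentation_m)
  se <- linfit_se(best)
  E <- unname(best$coef[2])
  if (!is.finite(E) || E <= 0)
    stop("Hertz fit did not converge to a positive modulus", call. = FALSE)
  structure(list(model = "hertz", E_Pa = E, E_se = unname(se[2]),
                 eta_Pa_s = NA_real_, eta_se = NA_real_,
                 contact_point_m = best$zc, baseline_N = unname(best$coef[1]),
                 rss = best$rss, n_fit = best$n, converged = TRUE),
            class = "visco_fit")
}

#' Kelvin-Voigt-Maxwell viscoelastic fit
#'
#' Fits the constant-speed KVM approach solution (see [kvm_force()]) with
#' free contact point, baseline, apparent Young's modulus and apparent
#' viscosity. A negative viscosity solution is rejected and the curve is
#' refitted with \eqn{\eta = 0} (elastic limit), flagged in the result.
#'
#' @param curve a [force_curve()].
#' @param max_indentation_m optional indentation-depth cutoff, m.
#' @return A `visco_fit` (see [hertz_sphere_fit()]); `eta_clamped` reports
#'   whether the viscosity was clamped at zero.
#' @export
kvm_fit <- function(curve, max_indentation_m = Inf) {
  stopifnot(inherits(curve, "force_curve"))
  best <- profile_contact_fit(curve, "kvm", max_indentation_m)
  se <- linfit_se(best)
  E <- unname(best$coef[2]); eta <- unname(best$coef[3])
  clamped <- FALSE
  if (!is.finite(eta) || eta < 0) {
    h <- hertz_sphere_fit(curve, max_indentation_m)
    return(structure(list(model = "kvm", E_Pa = h$E_Pa, E_se = h$E_se,
                          eta_Pa_s = 0, eta_se = NA_real_,
                          contact_point_m = h$contact_point_m,
                          baseline_N = h$baseline_N, rss = h$rss,
                          n_fit = h$n_fit, converged = TRUE,
                          eta_clamped = TRUE),
                     class = "visco_fit"))
  }
  if (!is.finite(E) || E <= 0)
    stop("KVM fit did not converge to a positive modulus", call. = FALSE)
  structure(list(model = "kvm", E_Pa = E, E_se = unname(se[2]),
                 eta_Pa_s = eta, eta_se = unname(se[3]),
                 contact_point_m = best$zc, baseline_N = unname(best$coef[1]),
                 rss = best$rss, n_fit = best$n, converged = TRUE,
                 eta_clamped = clamped),
            class = "visco_fit")
}

#' @export
print.visco_fit <- function(x, ...) {
  cat(sprintf("%s fit: E = %.1f Pa (SE %.2g)", toupper(x$model), x$E_Pa, x$E_se))
  if (x$model == "kvm")
    cat(sprintf(", eta = %.2f Pa.s (SE %.2g)", x$eta_Pa_s, x$eta_se))
  cat(sprintf("\n  contact point %.3f um, n = %d, RSS %.3g\n",
              x$contact_point_m * 1e6, x$n_fit, x$rss))
  invisible(x)
}

#' Contact-point estimate with uncertainty
#'
#' Estimates the tip-sample contact position from the joint Hertz fit
#' (contact point as a free parameter, baseline-offset corrected) and
#' attaches an approximate 95% confidence interval from the curvature of
#' the profile residual sum of squares.
#'
#' @param curve a [force_curve()].
#' @param baseline_fraction minimum fraction of samples that must precede
#'   the fitted contact (default 0.05); shorter baselines are an error.
#' @return list with `contact_point_m`, `ci_m` (length-2), `E_Pa`.
#' @export
contact_point_estimate <- function(curve, baseline_fraction = 0.05) {
  stopifnot(inherits(curve, "force_curve"))
  fit <- hertz_sphere_fit(curve)
  # reject fits indistinguishable from noise: modulus must be resolved
  if (!is.finite(fit$E_se) || fit$E_Pa / fit$E_se < 3)
    stop("no contact point detectable: modulus not resolved above noise",
         call. = FALSE)
  n_pre <- sum(curve$indentation_m < fit$contact_point_m)
  if (n_pre < baseline_fraction * length(curve$indentation_m))
    stop("pre-contact baseline shorter than ", 100 * baseline_fraction,
         "% of samples", call. = FALSE)
  # profile-RSS curvature -> SE of the contact point
  z <- fit$contact_point_m
  h <- diff(range(curve$indentation_m)) / 200
  rss_at <- function(zc) {
    d <- curve$indentation_m - zc
    use <- d <= 3e-6
    dd <- pmax(d[use], 0)
    C <- (4 * sqrt(curve$bead_radius_m)) / (3 * (1 - curve$poisson_ratio^2))
    X <- cbind(1, C * dd^1.5)
    sum(stats::lm.fit(X, curve$force_N[use])$residuals^2)
  }
  r0 <- rss_at(z); rp <- rss_at(z + h); rm <- rss_at(z - h)
  curv <- (rp - 2 * r0 + rm) / h^2
  dof <- fit$n_fit - 3L
  s2 <- r0 / max(dof, 1L)
  se <- if (is.finite(curv) && curv > 0) sqrt(2 * s2 / curv) else NA_real_
  list(contact_point_m = z,
       ci_m = z + c(-1.96, 1.96) * se,
       se_m = se, E_Pa = fit$E_Pa)
}

#' Read and write force curves as TSV
#'
#' Columns `time_s`, `indentation_m`, `force_N`; probe metadata travels in a
#' JSON sidecar (`<path>.json`).
#'
#' @param curve a [force_curve()].
#' @param path TSV path.
#' @return `write_force_curve` returns `path` invisibly; `read_force_curve`
#'   a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.table(
    data.frame(time_s = curve$time_s, indentation_m = curve$indentation_m,
               force_N = curve$force_N),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- curve[setdiff(names(curve), c("time_s", "indentation_m", "force_N"))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  d <- utils::read.delim(path)
  meta <- list()
  if (file.exists(paste0(path, ".json")))
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  do.call(force_curve, c(list(time_s = d$time_s,
                              indentation_m = d$indentation_m,
                              force_N = d$force_N), meta))
}
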