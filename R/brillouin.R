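#' Two-component refractive-index to mass-density model
#'
#' Links a measured refractive index to absolute mass density by decomposing
#' the tissue into an aqueous fluid phase and a dry-mass (protein/nucleic
#' acid) phase. The dry-mass concentration follows from the refractive-index
#' increment \eqn{\alpha}: \eqn{c = (n - n_f)/\alpha}, and the absolute
#' density is \eqn{\rho = \rho_f + (1 - \theta \rho_f)\, c}, where
#' \eqn{\theta} is the partial specific volume of the dry mass and
#' \eqn{n_f, \rho_f} describe the fluid phase.
#'
#' The shipped defaults use \eqn{\alpha = 0.1919} mL/g (proteins and nucleic
#' acids) and \eqn{\theta = 0.73} mL/g, with a water-like fluid phase
#' (\eqn{\rho_f = 1000} kg/m^3) whose refractive index
#' \eqn{n_f = 1.340298} was fixed by a one-time joint calibration against
#' four independently measured (frequency shift, refractive index, modulus)
#' condition means from spinal lesion tissue (see the methods vignette).
#'
#' @param alpha refractive-index increment of the dry mass, mL/g.
#' @param theta partial specific volume of the dry mass, mL/g.
#' @param n_fluid refractive index of the fluid phase.
#' @param rho_fluid mass density of the fluid phase, kg/m^3.
#' @param sigma_alpha,sigma_theta,sigma_n_fluid,sigma_rho_fluid standard
#'   uncertainties of the four constants (same units; default 0).
#' @return An object of class `density_model`.
#' @seealso [mass_density_from_ri()], [longitudinal_modulus()]
#' @export
#' @examples
#' m <- density_model()
#' mass_density_from_ri(1.3636, m)
density_model <- function(alpha = 0.1919, theta = 0.73,
                          n_fluid = 1.340298, rho_fluid = 1000,
                          sigma_alpha = 0, sigma_theta = 0,
                          sigma_n_fluid = 0, sigma_rho_fluid = 0) {
  assert_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  assert_scalar_number(theta, "theta", lower = 0)
  assert_scalar_number(n_fluid, "n_fluid", lower = 1)
  assert_scalar_number(rho_fluid, "rho_fluid", lower = 0, strict_lower = TRUE)
  for (s in c(sigma_alpha, sigma_theta, sigma_n_fluid, sigma_rho_fluid))
    if (s < 0) stop("uncertainties must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, theta = theta, n_fluid = n_fluid,
                 rho_fluid = rho_fluid,
                 sigma = c(alpha = sigma_alpha, theta = sigma_theta,
                           n_fluid = sigma_n_fluid, rho_fluid = sigma_rho_fluid)),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat("Two-component density model\n")
  cat(sprintf("  alpha = %.4f mL/g, theta = %.2f mL/g\n", x$alpha, x$theta))
  cat(sprintf("  fluid: n_f = %.6f, rho_f = %.1f kg/m^3\n",
              x$n_fluid, x$rho_fluid))
  invisible(x)
}

#' Convert refractive index to dry-mass concentration and absolute density
#'
#' @param n refractive index value(s); must be `>= n_fluid` of the model.
#' @param model a [density_model()].
#' @return A data.frame with columns `n`, `concentration` (dry-mass
#'   concentration, kg/m^3) and `density` (absolute mass density, kg/m^3).
#' @export
#' @examples
#' mass_density_from_ri(1.3636, density_model())
mass_density_from_ri <- function(n, model = density_model()) {
  stopifnot(inherits(model, "density_model"))
  if (!is.numeric(n) || any(!is.finite(n)))
    stop("`n` must be finite numeric", call. = FALSE)
  if (any(n < model$n_fluid))
    stop(sprintf(
      "refractive index below the fluid phase (n < n_f = %.6f): negative dry-mass concentration",
      model$n_fluid), call. = FALSE)
  # alpha, theta in mL/g == 1e-3 m^3/kg; concentration comes out in kg/m^3
  alpha_si <- model$alpha * 1e-3
  theta_si <- model$theta * 1e-3
  conc <- (n - model$n_fluid) / alpha_si
  rho <- model$rho_fluid + (1 - theta_si * model$rho_fluid) * conc
  data.frame(n = n, concentration = conc, density = rho)
}

#' Longitudinal modulus from the Brillouin frequency shift
#'
#' Inverts the Brillouin scattering relation
#' \deqn{\nu_B = \frac{2 n \sqrt{M'}}{\lambda_0 \sqrt{\rho}} \sin(\vartheta/2)}
#' for the longitudinal modulus:
#' \eqn{M' = \rho \left(\nu_B \lambda_0 / (2 n \sin(\vartheta/2))\right)^2}.
#' The mass density is taken from the two-component model unless supplied
#' directly. The longitudinal compressibility \eqn{\kappa_L = 1/M'} is
#' attached.
#'
#' @param nu_B Brillouin frequency shift(s), GHz.
#' @param n refractive index (same length or scalar).
#' @param model a [density_model()]; ignored when `density` is given.
#' @param lambda0_nm incident wavelength, nm (default 780.24).
#' @param theta_deg scattering angle, degrees (default 180, backscattering,
#'   so that \eqn{\sin(\vartheta/2) = 1}).
#' @param density optional mass density kg/m^3, bypassing the model.
#' @return data.frame with `nu_B`, `n`, `density` (kg/m^3), `M_prime` (GPa)
#'   and `kappa_L` (1/GPa).
#' @export
#' @examples
#' longitudinal_modulus(5.324, 1.3636)
longitudinal_modulus <- function(nu_B, n, model = density_model(),
                                 lambda0_nm = 780.24, theta_deg = 180,
                                 density = NULL) {
  if (any(nu_B <= 0)) stop("`nu_B` must be > 0", call. = FALSE)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  assert_scalar_number(lambda0_nm, "lambda0_nm", lower = 0, strict_lower = TRUE)
  rho <- if (is.null(density)) mass_density_from_ri(n, model)$density else density
  s <- sin(theta_deg / 2 * pi / 180)
  v <- nu_B * 1e9 * lambda0_nm * 1e-9 / (2 * n * s)  # acoustic phase velocity, m/s
  M <- rho * v^2 / 1e9                               # GPa
  data.frame(nu_B = nu_B, n = n, density = rho, M_prime = M, kappa_L = 1 / M)
}

#' Gaussian uncertainty propagation for the longitudinal modulus
#'
#' First-order propagation
#' \eqn{\sigma_{M'}^2 = \sum_i (\partial M'/\partial x_i)^2 \sigma_i^2}
#' over the measured inputs (\eqn{\nu_B}, \eqn{n}) and the density-model
#' constants (\eqn{\alpha}, \eqn{\theta}, \eqn{n_f}, \eqn{\rho_f}), with
#' analytic partial derivatives. A seeded Monte-Carlo cross-check is
#' available via `mc_samples`.
#'
#' @inheritParams longitudinal_modulus
#' @param sigma_nu_B,sigma_n standard uncertainties of the measured shift
#'   (GHz) and refractive index.
#' @param mc_samples if > 0, additionally estimate `sigma_M_mc` from this
#'   many Monte-Carlo draws (all inputs independent Gaussian).
#' @param seed RNG seed for the Monte-Carlo draw.
#' @return list with `M_prime` (GPa), `sigma_M` (GPa), `budget` (data.frame
#'   of per-input variance contributions, GPa^2) and, when requested,
#'   `sigma_M_mc`.
#' @export
#' @examples
#' propagate_uncertainty(5.324, 1.3636, sigma_nu_B = 0.004, sigma_n = 0.0005)
propagate_uncertainty <- function(nu_B, n, model = density_model(),
                                  sigma_nu_B = 0, sigma_n = 0,
                                  lambda0_nm = 780.24, theta_deg = 180,
                                  mc_samples = 0, seed = 1) {
  stopifnot(inherits(model, "density_model"))
  if (sigma_nu_B < 0 || sigma_n < 0) stop("sigmas must be >= 0", call. = FALSE)
  s <- sin(theta_deg / 2 * pi / 180)
  alpha_si <- model$alpha * 1e-3
  theta_si <- model$theta * 1e-3
  conc <- (n - model$n_fluid) / alpha_si
  rho <- model$rho_fluid + (1 - theta_si * model$rho_fluid) * conc
  v <- nu_B * 1e9 * lambda0_nm * 1e-9 / (2 * n * s)  # acoustic velocity, m/s
  A <- v^2 / 1e9                                     # M' = rho * A, GPa
  M <- rho * A

  dfac <- (1 - theta_si * model$rho_fluid)
  partials <- c(
    nu_B     = 2 * M / nu_B,
    n        = A * dfac / alpha_si - 2 * M / n,
    alpha    = -A * dfac * conc / alpha_si * 1e-3,   # per mL/g
    theta    = -A * model$rho_fluid * conc * 1e-3,   # per mL/g
    n_fluid  = -A * dfac / alpha_si,
    rho_fluid = A * (1 - theta_si * conc)
  )
  sigmas <- c(nu_B = sigma_nu_B, n = sigma_n, model$sigma)
  contrib <- (partials[names(sigmas)] * sigmas)^2
  sigma_M <- sqrt(sum(contrib))
  out <- list(
    M_prime = M, sigma_M = sigma_M,
    budget = data.frame(input = names(contrib),
                        partial = unname(partials[names(sigmas)]),
                        sigma = unname(sigmas),
                        variance_GPa2 = unname(contrib),
                        share = if (sigma_M > 0) unname(contrib) / sigma_M^2 else 0)
  )
  if (mc_samples > 0) {
    out$sigma_M_mc <- with_seed(sub_seed(seed, "mc"), {
      draw <- function(mu, sd) if (sd > 0) stats::rnorm(mc_samples, mu, sd) else rep(mu, mc_samples)
      nu_d <- draw(nu_B, sigma_nu_B)
      n_d <- draw(n, sigma_n)
      al_d <- draw(model$alpha, model$sigma[["alpha"]]) * 1e-3
      th_d <- draw(model$theta, model$sigma[["theta"]]) * 1e-3
      nf_d <- draw(model$n_fluid, model$sigma[["n_fluid"]])
      rf_d <- draw(model$rho_fluid, model$sigma[["rho_fluid"]])
      c_d <- (n_d - nf_d) / al_d
      rho_d <- rf_d + (1 - th_d * rf_d) * c_d
      M_d <- rho_d * (nu_d * 1e9 * lambda0_nm * 1e-9 / (2 * n_d * s))^2 / 1e9
      stats::sd(M_d)
    })
  }
  out
}
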