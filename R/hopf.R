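#' Coefficients of the delayed characteristic equation
#'
#' With the delay acting on the cross-coupling term \eqn{a_{12} v(t -
#' \tau)}, each product-network mode \eqn{(\Lambda_\alpha^R,
#' \Lambda_\beta^E)} has transcendental characteristic equation
#' \deqn{\lambda^2 + B_1 \lambda + B_2 + B_3 e^{-\lambda \tau} = 0,}
#' with
#' \eqn{B_1 = -Tr_0 - (D_u^E + D_v^E)\Lambda_\beta^E - (D_u^R +
#' D_v^R)\Lambda_\alpha^R},
#' \eqn{B_2 = (D_v^E \Lambda_\beta^E + D_v^R \Lambda_\alpha^R + a_{22})
#' (D_u^E \Lambda_\beta^E + D_u^R \Lambda_\alpha^R + a_{11})} and
#' \eqn{B_3 = -a_{12} a_{21}}. Substituting \eqn{\lambda = i\omega}
#' reduces the crossing condition to the quadratic \eqn{x^2 + p x + q =
#' 0} in \eqn{x = \omega^2}, with \eqn{p = B_1^2 - 2 B_2}, \eqn{q =
#' B_2^2 - B_3^2} (not to be confused with the graph connection
#' probability).
#'
#' @param lin an \code{"fhn_linearization"}.
#' @param diff a \code{"diffusion_params"}.
#' @param lambda_R,lambda_E layer Laplacian eigenvalues (default 0:
#'   the uncoupled node).
#' @return An object of class \code{"char_coeffs"} with fields
#'   \code{B1}, \code{B2}, \code{B3}, \code{p}, \code{q}.
#' @examples
#' characteristic_coeffs(linearize(fhn_model()), diffusion_params())
#' @export
characteristic_coeffs <- function(lin, diff = diffusion_params(),
                                  lambda_R = 0, lambda_E = 0) {
  stopifnot(inherits(lin, "fhn_linearization"),
            inherits(diff, "diffusion_params"))
  B1 <- -lin$tr0 - (diff$du_E + diff$dv_E) * lambda_E -
    (diff$du_R + diff$dv_R) * lambda_R
  B2 <- (diff$dv_E * lambda_E + diff$dv_R * lambda_R + lin$a22) *
    (diff$du_E * lambda_E + diff$du_R * lambda_R + lin$a11)
  B3 <- -lin$a12 * lin$a21
  structure(list(B1 = B1, B2 = B2, B3 = B3,
                 p = B1^2 - 2 * B2, q = B2^2 - B3^2,
                 lambda_R = lambda_R, lambda_E = lambda_E),
            class = "char_coeffs")
}

#' @export
print.char_coeffs <- function(x, ...) {
  cat(sprintf("characteristic coefficients: B1 = %g, B2 = %g, B3 = %g\n",
              x$B1, x$B2, x$B3))
  cat(sprintf("  crossing quadratic: p = %g, q = %g\n", x$p, x$q))
  invisible(x)
}

#' Hopf bifurcation point of the delayed characteristic equation
#'
#' In the single-positive-root regime \eqn{q < 0}, \eqn{p > 0} the
#' crossing quadratic \eqn{x^2 + p x + q = 0} has exactly one positive
#' root \eqn{x_0}, giving the crossing frequency \eqn{\omega_0 =
#' \sqrt{x_0}}. The critical delays solve
#' \eqn{B_3 \cos(\omega_0 \tau) = \omega_0^2 - B_2} and
#' \eqn{B_3 \sin(\omega_0 \tau) = B_1 \omega_0} simultaneously; the
#' two-argument angle (wrapped to \eqn{[0, 2\pi)}) fixes the quadrant,
#' and the Hopf threshold \eqn{\tau_0} is the smallest positive
#' solution. The transversality derivative at the crossing is
#' \deqn{\frac{d\,\mathrm{Re}\lambda(\tau_0)}{d\tau} =
#'   \frac{\omega_0^2 (2\omega_0^2 + p)}{\Theta}, \quad
#'   \Theta = (-\omega_0^2\tau_0 + B_2\tau_0 + B_1)^2 +
#'            (B_1\omega_0\tau_0 + 2\omega_0)^2,}
#' which is positive in this regime, so roots genuinely cross into the
#' right half plane and all roots have negative real part for
#' \eqn{\tau \in [0, \tau_0)}.
#'
#' Other sign patterns of \eqn{(p, q)} fall outside this regime and
#' return \code{exists = FALSE} with the failing condition recorded;
#' non-existence is a value, not an error.
#'
#' @param coeffs a \code{"char_coeffs"}.
#' @param n_branches number of delay branches \eqn{\tau_0^{(j)}},
#'   \eqn{j = 0, \ldots,} \code{n_branches - 1} to return.
#' @return An object of class \code{"hopf_point"}: list with
#'   \code{exists}, \code{omega0}, \code{tau0}, \code{tau_list},
#'   \code{theta}, \code{dRe_dtau}, \code{dlambda_dtau} (the complex
#'   closed-form derivative \eqn{d\lambda/d\tau} at the crossing) and
#'   \code{reason} when \code{exists} is \code{FALSE}.
#' @examples
#' solve_hopf(characteristic_coeffs(linearize(fhn_model())))
#' @export
solve_hopf <- function(coeffs, n_branches = 4L) {
  stopifnot(inherits(coeffs, "char_coeffs"))
  p <- coeffs$p; q <- coeffs$q
  none <- function(reason)
    structure(list(exists = FALSE, reason = reason,
                   omega0 = NA_real_, tau0 = NA_real_,
                   tau_list = numeric(0), theta = NA_real_,
                   dRe_dtau = NA_real_,
                   dlambda_dtau = NA_complex_, coeffs = coeffs),
              class = "hopf_point")
  if (q >= 0) return(none("q = B2^2 - B3^2 >= 0: no guaranteed positive root"))
  if (p <= 0) return(none("p = B1^2 - 2*B2 <= 0: outside the single-root regime"))
  x0 <- (-p + sqrt(p^2 - 4 * q)) / 2
  if (x0 <= 0) return(none("crossing quadratic has no positive root"))
  omega0 <- sqrt(x0)
  B1 <- coeffs$B1; B2 <- coeffs$B2; B3 <- coeffs$B3
  ang <- atan2(B1 * omega0 / B3, (omega0^2 - B2) / B3) %% (2 * pi)
  tau_list <- (ang + 2 * pi * (seq_len(n_branches) - 1)) / omega0
  tau0 <- tau_list[1]
  theta <- (-omega0^2 * tau0 + B2 * tau0 + B1)^2 +
    (B1 * omega0 * tau0 + 2 * omega0)^2
  dRe <- omega0^2 * (2 * omega0^2 + p) / theta
  lam <- complex(imaginary = omega0)
  dl <- B3 * lam * exp(-lam * tau0) /
    (2 * lam + B1 - B3 * tau0 * exp(-lam * tau0))
  structure(list(exists = TRUE, reason = NULL,
                 omega0 = omega0, tau0 = tau0, tau_list = tau_list,
                 theta = theta, dRe_dtau = dRe, dlambda_dtau = dl,
                 coeffs = coeffs),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  if (!x$exists) {
    cat("no Hopf crossing:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("Hopf point: omega0 = %.6f, tau0 = %.6f\n",
              x$omega0, x$tau0))
  cat(sprintf("  transversality dRe(lambda)/dtau = %.6f\n", x$dRe_dtau))
  invisible(x)
}

#' Residual of the delayed characteristic equation
#'
#' Evaluates \eqn{|\lambda^2 + B_1 \lambda + B_2 + B_3 e^{-\lambda
#' \tau}|}; a verification oracle for computed crossing points (the
#' residual at \eqn{(i\omega_0, \tau_0)} should vanish).
#'
#' @param coeffs a \code{"char_coeffs"}.
#' @param lambda complex argument.
#' @param tau delay.
#' @return Nonnegative residual modulus.
#' @export
characteristic_root_residual <- function(coeffs, lambda, tau) {
  stopifnot(inherits(coeffs, "char_coeffs"))
  Mod(lambda^2 + coeffs$B1 * lambda + coeffs$B2 +
        coeffs$B3 * exp(-lambda * tau))
}

#' Hopf delay threshold across a product spectrum
#'
#' Computes the per-mode Hopf point for every eigenvalue pair of a
#' product spectrum and the network threshold: the minimum \eqn{\tau_0}
#' over all modes admitting a crossing. Modes outside the
#' single-positive-root regime (\code{exists = FALSE}) are excluded
#' from the minimum.
#'
#' @param lin an \code{"fhn_linearization"}.
#' @param diff a \code{"diffusion_params"}.
#' @param spectrum a \code{"product_spectrum"}.
#' @return An object of class \code{"hopf_spectrum"}: list with
#'   \code{table} (data frame: \code{lambda_R}, \code{lambda_E},
#'   \code{lambda_sum}, \code{exists}, \code{omega0}, \code{tau0},
#'   \code{dRe_dtau}), \code{tau0_min} and the index
#'   \code{critical_mode} of the minimizing mode.
#' @export
tau0_over_spectrum <- function(lin, diff, spectrum) {
  stopifnot(inherits(spectrum, "product_spectrum"))
  pr <- spectrum$pairs
  hp <- lapply(seq_len(nrow(pr)), function(i) {
    solve_hopf(characteristic_coeffs(lin, diff,
                                     pr$lambda_R[i], pr$lambda_E[i]))
  })
  tab <- data.frame(
    lambda_R = pr$lambda_R, lambda_E = pr$lambda_E,
    lambda_sum = pr$lambda_sum,
    exists = vapply(hp, `[[`, logical(1), "exists"),
    omega0 = vapply(hp, `[[`, numeric(1), "omega0"),
    tau0 = vapply(hp, `[[`, numeric(1), "tau0"),
    dRe_dtau = vapply(hp, `[[`, numeric(1), "dRe_dtau"))
  idx <- which(tab$exists)
  crit <- if (length(idx)) idx[which.min(tab$tau0[idx])] else NA_integer_
  structure(list(table = tab,
                 tau0_min = if (is.na(crit)) NA_real_ else tab$tau0[crit],
                 critical_mode = crit,
                 points = hp),
            class = "hopf_spectrum")
}

#' @export
print.hopf_spectrum <- function(x, ...) {
  cat(sprintf("Hopf thresholds over %d product modes (%d admit a crossing)\n",
              nrow(x$table), sum(x$table$exists)))
  if (!is.na(x$tau0_min))
    cat(sprintf("  network threshold: tau0 = %.6f at mode %d (lambda sum %.4f)\n",
                x$tau0_min, x$critical_mode,
                x$table$lambda_sum[x$critical_mode]))
  invisible(x)
}
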