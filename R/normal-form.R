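#' Critical eigenvectors of the delayed system at the Hopf point
#'
#' At the crossing \eqn{(\pm i\omega_0, \tau_0)} the infinitesimal
#' generator of the delayed linearization and its formal adjoint have
#' eigenvectors \eqn{q(\theta) = (1, q_2)^T e^{i\omega_0\tau_0\theta}}
#' and \eqn{q^*(s) = \kappa (q_1^*, 1)^T e^{i\omega_0\tau_0 s}} with
#' \deqn{q_2 = \frac{a_{21}}{i\omega_0 - a_{22}}, \quad
#'   q_1^* = \frac{-a_{21}}{i\omega_0 + a_{11}},}
#' and the normalization constant chosen so that the bilinear inner
#' product satisfies \eqn{\langle q^*, q \rangle = 1}:
#' \eqn{\bar\kappa = 1 / (\bar q_1^* + q_2 + \tau_0 a_{12} \bar q_1^*
#' q_2 e^{-i\omega_0\tau_0})}. For a network mode the diagonal entries
#' carry the diffusion shifts \eqn{a_{11} + D_u^R\Lambda_\alpha +
#' D_u^E\Lambda_\beta} and \eqn{a_{22} + D_v^R\Lambda_\alpha +
#' D_v^E\Lambda_\beta}.
#'
#' @param lin an \code{"fhn_linearization"}.
#' @param hopf a \code{"hopf_point"} with \code{exists = TRUE}; its
#'   embedded coefficients carry the mode's eigenvalue pair.
#' @param diff a \code{"diffusion_params"} (defaults to no diffusion,
#'   the single-node case).
#' @return An object of class \code{"hopf_eigvectors"}: list with
#'   complex scalars \code{q2}, \code{q1_star}, \code{kappa},
#'   \code{kappa_bar} and the effective diagonal entries \code{a11},
#'   \code{a22}.
#' @export
hopf_eigvectors <- function(lin, hopf, diff = diffusion_params()) {
  stopifnot(inherits(lin, "fhn_linearization"),
            inherits(hopf, "hopf_point"))
  if (!hopf$exists)
    stop("no Hopf crossing exists for these coefficients", call. = FALSE)
  eff <- effective_entries(lin, diff, hopf$coeffs$lambda_R,
                           hopf$coeffs$lambda_E)
  w0 <- hopf$omega0; tau0 <- hopf$tau0
  d1 <- complex(imaginary = w0) - eff$a22
  d2 <- complex(imaginary = w0) + eff$a11
  if (Mod(d1) < 1e-12 || Mod(d2) < 1e-12)
    stop("degenerate eigenvector denominator (|i*omega0 - a22| or ",
         "|i*omega0 + a11| ~ 0)", call. = FALSE)
  q2 <- lin$a21 / d1
  q1s <- -lin$a21 / d2
  kbar <- 1 / (Conj(q1s) + q2 +
                 tau0 * lin$a12 * Conj(q1s) * q2 *
                 exp(complex(imaginary = -w0 * tau0)))
  structure(list(q2 = q2, q1_star = q1s,
                 kappa = Conj(kbar), kappa_bar = kbar,
                 a11 = eff$a11, a22 = eff$a22),
            class = "hopf_eigvectors")
}

# diffusion-shifted diagonal Jacobian entries for a product mode
effective_entries <- function(lin, diff, lambda_R, lambda_E) {
  list(a11 = lin$a11 + diff$du_R * lambda_R + diff$du_E * lambda_E,
       a22 = lin$a22 + diff$dv_R * lambda_R + diff$dv_E * lambda_E)
}

#' Constant vectors of the second-order center-manifold terms
#'
#' The second-order coefficients \eqn{W_{20}(\theta)}, \eqn{W_{11}(\theta)}
#' of the center-manifold expansion each contain a constant particular
#' vector, \eqn{\ell_1} and \eqn{\ell_2}, obtained from two 2x2 linear
#' systems: the \eqn{2i\omega_0}-shifted system (with
#' \eqn{e^{-2i\omega_0\tau_0}} on the delayed coupling entry) and the
#' zero-frequency system. Their common right-hand side is twice the
#' quadratic coefficient of the shifted nonlinearity in the first
#' component (so \eqn{(-2u^*, 0)^T} for the as-printed variant).
#'
#' @param lin an \code{"fhn_linearization"} (supplies the nonlinearity
#'   variant through its \code{quad_coeff}).
#' @param hopf a \code{"hopf_point"} with \code{exists = TRUE}.
#' @param diff a \code{"diffusion_params"}.
#' @return List with complex 2-vectors \code{ell1}, \code{ell2} and the
#'   back-substitution residuals \code{residual1}, \code{residual2}.
#' @export
solve_ell <- function(lin, hopf, diff = diffusion_params()) {
  stopifnot(inherits(lin, "fhn_linearization"),
            inherits(hopf, "hopf_point"))
  if (!hopf$exists)
    stop("no Hopf crossing exists for these coefficients", call. = FALSE)
  eff <- effective_entries(lin, diff, hopf$coeffs$lambda_R,
                           hopf$coeffs$lambda_E)
  w0 <- hopf$omega0; tau0 <- hopf$tau0
  two_iw <- complex(imaginary = 2 * w0)
  M1 <- matrix(c(two_iw - eff$a11, -lin$a21,
                 -lin$a12 * exp(-two_iw * tau0), two_iw - eff$a22),
               2, 2)
  M2 <- matrix(c(-eff$a11, -lin$a21, -lin$a12, -eff$a22), 2, 2)
  rhs <- c(2 * lin$quad_coeff, 0)
  if (Mod(det2(M1)) < 1e-12)
    stop("2*i*omega0-shifted system is singular (resonance)", call. = FALSE)
  if (Mod(det2(M2)) < 1e-12)
    stop("zero-frequency system is singular (resonance)", call. = FALSE)
  ell1 <- solve(M1, rhs) + 0i
  ell2 <- solve(M2, rhs) + 0i
  list(ell1 = ell1, ell2 = ell2,
       residual1 = max(Mod(M1 %*% ell1 - rhs)),
       residual2 = max(Mod(M2 %*% ell2 - rhs)))
}

det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]

#' Hopf normal form and bifurcation classification
#'
#' Center-manifold reduction of the delayed system at the crossing
#' \eqn{(\pm i\omega_0, \tau_0)}, following the Hassard procedure. The
#' reduced equation \eqn{\dot z = i\omega_0\tau_0 z + g(z, \bar z)} has
#' expansion coefficients
#' \deqn{g_{20} = g_{11} = g_{02} = 2\tau_0\bar\kappa\bar q_1^* Q,
#'  \quad g_{21} = 2\tau_0\bar\kappa\bar q_1^*\left[Q\,(2 W_{11}^{(1)}(0)
#'  + W_{20}^{(1)}(0)) + 3 C\right],}
#' where \eqn{Q} and \eqn{C} are the quadratic and cubic coefficients
#' of the shifted nonlinearity (variant-dependent, carried by
#' \code{lin}; \eqn{Q = -u^*}, \eqn{C = -1/3} for the as-printed
#' variant). From these,
#' \deqn{c_1(0) = \frac{i}{2\omega_0\tau_0}\left(g_{11}g_{20} -
#'   2|g_{11}|^2 - \tfrac13|g_{02}|^2\right) + \tfrac12 g_{21},}
#' and the bifurcation quantities are \eqn{\mu_2 = -\mathrm{Re}\,c_1(0)
#' / \mathrm{Re}\,\lambda'(\tau_0)} (direction), \eqn{\beta_2 =
#' 2\,\mathrm{Re}\,c_1(0)} (Floquet exponent) and \eqn{T_2 =
#' -(\mathrm{Im}\,c_1(0) + \mu_2\,\mathrm{Im}\,\lambda'(\tau_0)) /
#' \omega_0} (period correction). \eqn{\lambda'(\tau_0)} is the exact
#' closed-form derivative of the characteristic root, not a finite
#' difference.
#'
#' Classification: \eqn{\mu_2 > 0} supercritical / \eqn{\mu_2 < 0}
#' subcritical; \eqn{T_2 > 0} period-increasing; \eqn{\beta_2 > 0}
#' orbitally unstable periodic solutions.
#'
#' @param lin an \code{"fhn_linearization"} (choose the nonlinearity
#'   variant in \code{\link{linearize}}).
#' @param hopf a \code{"hopf_point"}; defaults to the crossing of the
#'   mode \eqn{\Lambda_\alpha = \Lambda_\beta = 0} implied by
#'   \code{lin} and \code{diff}.
#' @param diff a \code{"diffusion_params"}.
#' @return An object of class \code{"fhn_normal_form"}: list with the
#'   eigvector data, \code{g20}, \code{g11}, \code{g02}, \code{g21},
#'   \code{ell1}, \code{ell2}, \code{W20_0}, \code{W11_0}, \code{c1_0},
#'   \code{dlambda_dtau}, \code{mu2}, \code{beta2}, \code{T2},
#'   \code{classification} (character vector of three labels) and the
#'   inputs.
#' @examples
#' lin <- linearize(fhn_model())
#' nf <- normal_form(lin)
#' nf$c1_0
#' @export
normal_form <- function(lin, hopf = NULL, diff = diffusion_params()) {
  stopifnot(inherits(lin, "fhn_linearization"))
  if (is.null(hopf))
    hopf <- solve_hopf(characteristic_coeffs(lin, diff))
  if (!hopf$exists)
    stop("no Hopf crossing exists for these coefficients", call. = FALSE)
  ev <- hopf_eigvectors(lin, hopf, diff)
  w0 <- hopf$omega0; tau0 <- hopf$tau0
  Q <- lin$quad_coeff; C <- lin$cubic_coeff
  kq <- ev$kappa_bar * Conj(ev$q1_star)
  g20 <- 2 * tau0 * kq * Q
  g11 <- g20; g02 <- g20
  ells <- solve_ell(lin, hopf, diff)
  qv <- c(1, ev$q2)
  W20_0 <- 1i * g20 / (w0 * tau0) * qv +
    1i * Conj(g02) / (3 * w0 * tau0) * Conj(qv) + ells$ell1
  W11_0 <- -1i * g11 / (w0 * tau0) * qv +
    1i * Conj(g11) / (w0 * tau0) * Conj(qv) + ells$ell2
  g21 <- 2 * tau0 * kq * (Q * (2 * W11_0[1] + W20_0[1]) + 3 * C)
  c1 <- 1i / (2 * w0 * tau0) *
    (g11 * g20 - 2 * Mod(g11)^2 - Mod(g02)^2 / 3) + g21 / 2
  dl <- hopf$dlambda_dtau
  mu2 <- -Re(c1) / Re(dl)
  beta2 <- 2 * Re(c1)
  T2 <- -(Im(c1) + mu2 * Im(dl)) / w0
  cls <- c(direction = if (mu2 > 0) "supercritical" else "subcritical",
           period = if (T2 > 0) "period-increasing" else "period-decreasing",
           orbit = if (beta2 > 0) "orbitally-unstable" else "orbitally-stable")
  structure(list(eigvectors = ev,
                 g20 = g20, g11 = g11, g02 = g02, g21 = g21,
                 ell1 = ells$ell1, ell2 = ells$ell2,
                 W20_0 = W20_0, W11_0 = W11_0,
                 c1_0 = c1, dlambda_dtau = dl,
                 mu2 = mu2, beta2 = beta2, T2 = T2,
                 classification = cls,
                 omega0 = w0, tau0 = tau0,
                 variant = lin$variant,
                 lin = lin, diff = diff, hopf = hopf),
            class = "fhn_normal_form")
}

#' @export
print.fhn_normal_form <- function(x, ...) {
  cat("Hopf normal form (Hassard quantities)\n")
  cat(sprintf("  at omega0 = %.6f, tau0 = %.6f, nonlinearity variant '%s'\n",
              x$omega0, x$tau0, x$variant))
  cat(sprintf("  c1(0) = %.6f %+.6fi\n", Re(x$c1_0), Im(x$c1_0)))
  cat(sprintf("  mu2 = %.6f, beta2 = %.6f, T2 = %.6f\n",
              x$mu2, x$beta2, x$T2))
  cat("  classification:", paste(x$classification, collapse = ", "), "\n")
  invisible(x)
}
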