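#' Per-layer diffusion coefficients
#'
#' Diffusion strengths of the two state variables on the two layers of
#' the product network. Most analyses in the source model use equal
#' coefficients across layers, so the two-argument form
#' \code{diffusion_params(du, dv)} is the common entry point; the
#' four-coefficient form supports layer-asymmetric diffusion.
#'
#' @param du,dv common diffusion coefficients of \eqn{u} and \eqn{v}.
#' @param du_R,du_E,dv_R,dv_E per-layer overrides (default the common
#'   values). All must be finite and nonnegative.
#' @return An object of class \code{"diffusion_params"}.
#' @examples
#' diffusion_params(du = 0.01, dv = 8)
#' @export
diffusion_params <- function(du = 0, dv = 0, du_R = du, du_E = du,
                             dv_R = dv, dv_E = dv) {
  x <- c(du_R = du_R, du_E = du_E, dv_R = dv_R, dv_E = dv_E)
  if (!all(is.finite(x)) || any(x < 0))
    stop("diffusion coefficients must be finite and nonnegative",
         call. = FALSE)
  structure(as.list(x), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("diffusion: Du = (%g, %g), Dv = (%g, %g) on layers (R, E)\n",
              x$du_R, x$du_E, x$dv_R, x$dv_E))
  invisible(x)
}

#' Network Turing-instability quadratic form
#'
#' For a product-network mode with layer eigenvalues
#' \eqn{(\Lambda_\alpha^R, \Lambda_\beta^E)} the homogeneous equilibrium
#' loses stability to that mode iff
#' \deqn{\Delta_0 + \Lambda_\beta^E(a_{22}D_u^E + a_{11}D_v^E)
#'   + \Lambda_\alpha^R(a_{22}D_u^R + a_{11}D_v^R)
#'   + (\Lambda_\beta^E)^2 D_u^E D_v^E
#'   + \Lambda_\alpha^R \Lambda_\beta^E (D_u^E D_v^R + D_u^R D_v^E)
#'   + (\Lambda_\alpha^R)^2 D_u^R D_v^R < 0.}
#' With equal per-layer coefficients this reduces to the dispersion
#' curve \eqn{y(\Lambda) = \Delta_0 + (a_{22}D_u + a_{11}D_v)\Lambda +
#' D_u D_v \Lambda^2} in the eigenvalue sum \eqn{\Lambda}.
#'
#' The criterion presumes a stable base state; a warning is issued if
#' the equilibrium fails \code{\link{check_h1}}.
#'
#' @param lin an \code{"fhn_linearization"}.
#' @param diff a \code{"diffusion_params"}.
#' @param lambda_R,lambda_E layer Laplacian eigenvalues (nonpositive in
#'   this package's sign convention); vectorized.
#' @return The value(s) of the quadratic form; negative means the mode
#'   is linearly unstable.
#' @examples
#' lin <- linearize(fhn_model())
#' h2_value(lin, diffusion_params(0.01, 10), -3, -2)
#' @export
h2_value <- function(lin, diff, lambda_R, lambda_E) {
  stopifnot(inherits(lin, "fhn_linearization"),
            inherits(diff, "diffusion_params"))
  if (!check_h1(lin))
    warning("base equilibrium is not stable without diffusion; ",
            "the Turing criterion presumes a stable base state")
  h2_value_(lin, diff, lambda_R, lambda_E)
}

# unchecked core, shared by classify_spectrum (one warning, not n_r*n_e)
h2_value_ <- function(lin, diff, lambda_R, lambda_E) {
  lin$det0 +
    lambda_E * (lin$a22 * diff$du_E + lin$a11 * diff$dv_E) +
    lambda_R * (lin$a22 * diff$du_R + lin$a11 * diff$dv_R) +
    lambda_E^2 * diff$du_E * diff$dv_E +
    lambda_R * lambda_E * (diff$du_E * diff$dv_R + diff$du_R * diff$dv_E) +
    lambda_R^2 * diff$du_R * diff$dv_R
}

#' Classify every product-network mode for Turing instability
#'
#' Evaluates \code{\link{h2_value}} on each \eqn{(\alpha, \beta)} pair
#' of a \code{\link{product_spectrum}} and summarises whether any mode
#' is unstable. When the diffusion coefficients are equal across layers
#' the unstable window of the reduced dispersion curve
#' \eqn{y(\Lambda) = 0} is reported as well (the open interval between
#' its real roots, if any).
#'
#' A mode with \code{h2 == 0} exactly is marginal, not unstable.
#'
#' @param lin an \code{"fhn_linearization"} (must satisfy
#'   \code{\link{check_h1}}; warned otherwise).
#' @param diff a \code{"diffusion_params"}.
#' @param spectrum a \code{"product_spectrum"}.
#' @return An object of class \code{"turing_analysis"}: list with
#'   \code{points} (the spectrum data frame plus columns \code{h2} and
#'   \code{unstable}), \code{any_unstable}, \code{n_unstable} and
#'   \code{window} (length-2 numeric, \code{NA} if closed or
#'   layer-asymmetric).
#' @export
classify_spectrum <- function(lin, diff, spectrum) {
  stopifnot(inherits(spectrum, "product_spectrum"))
  if (!check_h1(lin))
    warning("base equilibrium is not stable without diffusion; ",
            "the Turing criterion presumes a stable base state")
  pts <- spectrum$pairs
  pts$h2 <- h2_value_(lin, diff, pts$lambda_R, pts$lambda_E)
  pts$unstable <- pts$h2 < 0
  window <- dispersion_window(lin, diff)
  structure(list(points = pts,
                 any_unstable = any(pts$unstable),
                 n_unstable = sum(pts$unstable),
                 window = window,
                 diff = diff),
            class = "turing_analysis")
}

# real roots of y(Lambda) = det0 + (a22 du + a11 dv) Lambda + du dv Lambda^2,
# i.e. the unstable Lambda-window, for layer-symmetric diffusion
dispersion_window <- function(lin, diff) {
  if (diff$du_R != diff$du_E || diff$dv_R != diff$dv_E)
    return(c(NA_real_, NA_real_))
  du <- diff$du_R; dv <- diff$dv_R
  b <- lin$a22 * du + lin$a11 * dv
  if (du * dv == 0) {
    if (b <= 0) return(c(NA_real_, NA_real_))
    return(c(-Inf, -lin$det0 / b))   # linear dispersion: unstable tail
  }
  disc <- b^2 - 4 * lin$det0 * du * dv
  if (disc <= 0 || b <= 0) return(c(NA_real_, NA_real_))
  sort((-b + c(-1, 1) * sqrt(disc)) / (2 * du * dv))
}

#' @export
print.turing_analysis <- function(x, ...) {
  cat(sprintf("Turing mode analysis over %d product modes\n",
              nrow(x$points)))
  if (!any(is.na(x$window)))
    cat(sprintf("  unstable window: (%.4f, %.4f)\n",
                x$window[1], x$window[2]))
  cat(sprintf("  unstable modes: %d -> Turing instability %s\n",
              x$n_unstable,
              if (x$any_unstable) "PREDICTED" else "not predicted"))
  invisible(x)
}

#' Critical v-diffusion for Turing onset (continuous spectrum)
#'
#' In the continuous relaxation, where the mode variable \eqn{\Lambda}
#' can take any nonpositive value, Turing instability first occurs when
#' \eqn{a_{22}D_u + a_{11}D_v > 0} and the dispersion discriminant
#' \eqn{(a_{22}D_u + a_{11}D_v)^2 - 4\Delta_0 D_u D_v} turns positive.
#' For fixed \eqn{D_u} this gives the critical \eqn{D_v} as the larger
#' root of the quadratic
#' \eqn{a_{11}^2 D_v^2 + (2 a_{11} a_{22} D_u - 4 \Delta_0 D_u) D_v +
#' a_{22}^2 D_u^2 = 0}.
#'
#' @param lin an \code{"fhn_linearization"} with \eqn{a_{11} > 0} (the
#'   activator condition; otherwise no finite threshold exists and an
#'   error is raised).
#' @param du the u-diffusion coefficient, > 0.
#' @return The critical \eqn{D_v} (numeric scalar); \code{Inf} if the
#'   quadratic has no positive real solution.
#' @examples
#' critical_dv(linearize(fhn_model()), du = 0.01)  # about 8.396
#' @export
critical_dv <- function(lin, du) {
  stopifnot(inherits(lin, "fhn_linearization"))
  if (du <= 0) stop("'du' must be positive", call. = FALSE)
  if (!check_h1(lin))
    warning("base equilibrium is not stable without diffusion")
  if (lin$a11 <= 0)
    stop("no Turing threshold: a11 <= 0, the activator condition ",
         "a22*Du + a11*Dv > 0 cannot hold for positive diffusion",
         call. = FALSE)
  A <- lin$a11^2
  B <- 2 * lin$a11 * lin$a22 * du - 4 * lin$det0 * du
  C <- (lin$a22 * du)^2
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(Inf)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  ok <- roots > 0 & (lin$a22 * du + lin$a11 * roots) > 0
  if (!any(ok)) return(Inf)
  max(roots[ok])
}

#' Critical v-diffusion for a specific product spectrum
#'
#' The discrete counterpart of \code{\link{critical_dv}}: the smallest
#' \eqn{D_v} at which some actual eigenvalue sum of the given product
#' spectrum becomes unstable. Because the criterion is linear in
#' \eqn{D_v} at fixed \eqn{\Lambda}, each mode has threshold
#' \eqn{D_v(\Lambda) = -(\Delta_0 + a_{22}D_u\Lambda) /
#' (\Lambda(a_{11} + D_u \Lambda))} where the denominator is negative;
#' the network threshold is the minimum over modes. Discrete spectra
#' can miss the continuous window, so this value is \eqn{\ge} the
#' continuous threshold.
#'
#' @param lin an \code{"fhn_linearization"}.
#' @param du common u-diffusion coefficient (> 0).
#' @param spectrum a \code{"product_spectrum"}.
#' @return Smallest \eqn{D_v} rendering some mode unstable; \code{Inf}
#'   if no mode can be destabilized at this \code{du}.
#' @export
network_critical_dv <- function(lin, du, spectrum) {
  stopifnot(inherits(spectrum, "product_spectrum"))
  if (du <= 0) stop("'du' must be positive", call. = FALSE)
  lam <- unique(spectrum$pairs$lambda_sum)
  g <- lam * (lin$a11 + du * lam)
  num <- lin$det0 + lin$a22 * du * lam
  thr <- ifelse(g < 0 & num > 0, -num / g, Inf)
  min(thr)
}
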