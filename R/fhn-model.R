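#' FitzHugh-Nagumo model specification
#'
#' Construct a FitzHugh-Nagumo (FHN) model
#' \deqn{du/dt = c(u - u^3/3 - a v + I), \quad dv/dt = c(b u - v + d),}
#' where \eqn{u} is the fast membrane potential and \eqn{v} the slow
#' recovery variable. The constructor solves for all real equilibria,
#' classifies the equilibrium cubic by its discriminant, and stores the
#' result so downstream analyses (linearization, Turing and Hopf
#' analysis, simulation) can be driven from one object.
#'
#' Equilibria satisfy \eqn{u^3 + 3(ab-1)u + 3(ad-I) = 0} with
#' \eqn{v^* = b u^* + d}. With \eqn{\varrho = (3/2)(ad - I)} the cubic
#' discriminant is \eqn{\Delta = \varrho^2 + (ab-1)^3}; its sign decides
#' whether there are one, two or three real equilibria (a triple zero
#' root when \eqn{ab = 1} and \eqn{ad = I}).
#'
#' @param a coupling intensity from \eqn{v} to \eqn{u} (dimensionless).
#' @param b coupling intensity from \eqn{u} to \eqn{v}.
#' @param c timescale constant; must be nonzero.
#' @param d constant offset in the recovery equation.
#' @param I external input current.
#'
#' @return An object of class \code{"fhn_model"}: a list with components
#'   \code{params} (named vector), \code{classification} (see
#'   \code{\link{classify_cubic}}) and \code{equilibria} (a data frame
#'   with columns \code{u_star}, \code{v_star}, \code{case_label},
#'   \code{residual}, roots sorted ascending).
#'
#' @examples
#' m <- fhn_model(a = 1, b = 1, c = 2, d = 1, I = 0.7)
#' m$equilibria
#' coef(m)
#' @export
fhn_model <- function(a = 1, b = 1, c = 2, d = 1, I = 0.7) {
  p <- c(a = a, b = b, c = c, d = d, I = I)
  if (!all(is.finite(p)))
    stop("all FHN parameters must be finite numbers", call. = FALSE)
  if (c == 0)
    stop("timescale constant 'c' must be nonzero", call. = FALSE)
  cls <- classify_cubic(a = a, b = b, d = d, I = I)
  eq <- solve_equilibria_(a, b, d, I, cls)
  structure(list(params = p, classification = cls, equilibria = eq),
            class = "fhn_model")
}

#' Classify the equilibrium cubic by its discriminant
#'
#' The equilibrium cubic \eqn{u^3 + 3(ab-1)u + 3(ad-I) = 0} is
#' classified through \eqn{\varrho = (3/2)(ad-I)} and
#' \eqn{\Delta = \varrho^2 + (ab-1)^3}:
#' \describe{
#'   \item{(i) \code{triple-zero}}{\eqn{ab-1 = 0} and \eqn{ad-I = 0}: a
#'     triple zero root (the trace of the Jacobian there is 0).}
#'   \item{(ii) \code{one-real}}{\eqn{\Delta > 0}: a single real root.}
#'   \item{(iii) \code{two-real}}{\eqn{\Delta = 0}, \eqn{ab \ne 1},
#'     \eqn{ad \ne I}: two distinct real roots, one of them double; the
#'     determinant of the Jacobian vanishes at the double root.}
#'   \item{(iv) \code{three-real}}{\eqn{\Delta < 0}: three unequal real
#'     roots.}
#' }
#' Zero tests use absolute tolerance \code{tol}; inputs within the
#' tolerance of a case boundary are classified to the boundary case.
#'
#' @param a,b,d,I model parameters (see \code{\link{fhn_model}}); a
#'   fitted \code{"fhn_model"} may be passed as \code{a}.
#' @param tol absolute tolerance of the zero tests (default \code{1e-12}).
#' @return A list of class \code{"fhn_cubic"} with \code{rho},
#'   \code{delta}, \code{case} (roman numeral) and \code{case_label}.
#' @examples
#' classify_cubic(a = 1, b = 1, d = 1, I = 0.7)  # one real root
#' @export
classify_cubic <- function(a, b, d, I, tol = 1e-12) {
  if (inherits(a, "fhn_model")) {
    p <- a$params
    a <- p[["a"]]; b <- p[["b"]]; d <- p[["d"]]; I <- p[["I"]]
  }
  k1 <- a * b - 1          # cubic is u^3 + 3*k1*u + 2*rho = 0, rho = 1.5*k2
  k2 <- a * d - I
  rho <- 1.5 * k2
  delta <- rho^2 + k1^3
  if (abs(k1) <= tol && abs(k2) <= tol) {
    case <- "i"; lab <- "triple-zero"
  } else if (delta > tol) {
    case <- "ii"; lab <- "one-real"
  } else if (abs(delta) <= tol) {
    case <- "iii"; lab <- "two-real"
  } else {
    case <- "iv"; lab <- "three-real"
  }
  structure(list(rho = rho, delta = delta, case = case, case_label = lab),
            class = "fhn_cubic")
}

# Cardano solution of u^3 + 3(ab-1)u + 3(ad-I) = 0, following the
# discriminant cases; complex arithmetic throughout to avoid branch
# errors, then a Newton polish and an imaginary-part cut.
solve_equilibria_ <- function(a, b, d, I, cls) {
  k1 <- a * b - 1
  rho <- cls$rho
  f  <- function(u) u^3 + 3 * k1 * u + 3 * (a * d - I)
  fp <- function(u) 3 * u^2 + 3 * k1
  roots <- switch(cls$case,
    i = 0,
    iii = {
      r <- ccbrt(rho)
      sort(c(-2 * r, r))
    },
    {
      # cases (ii) and (iv): Cardano with complex cube roots
      sdelta <- sqrt(as.complex(cls$delta))
      A <- ccbrt(-rho + sdelta)
      B <- ccbrt(-rho - sdelta)
      w <- complex(real = -0.5, imaginary = sqrt(3) / 2)
      cand <- c(A + B, w * A + w^2 * B, w^2 * A + w * B)
      re <- Re(cand)[abs(Im(cand)) < 1e-8 * (1 + Mod(cand))]
      if (cls$case == "ii") re <- re[which.min(abs(f(re)))]
      sort(unique(re))
    })
  # Newton polish (skip where f' ~ 0, i.e. double/triple roots)
  for (it in 1:3) {
    d1 <- fp(roots)
    ok <- abs(d1) > 1e-8
    roots[ok] <- roots[ok] - f(roots[ok]) / d1[ok]
  }
  data.frame(u_star = roots,
             v_star = b * roots + d,
             case_label = cls$case_label,
             residual = abs(f(roots)))
}

# principal real cube root for real x, complex cube root otherwise
ccbrt <- function(x) {
  if (is.complex(x) && abs(Im(x)) > 0) return(x^(1/3))
  x <- Re(x)
  sign(x) * abs(x)^(1/3)
}

#' Linearize the FHN model at an equilibrium
#'
#' Shifting coordinates to the equilibrium \eqn{(u^*, v^*)} gives
#' \eqn{du/dt = a_{11} u + a_{12} v + f(u)}, \eqn{dv/dt = a_{21} u +
#' a_{22} v} with Jacobian entries \eqn{a_{11} = c(1-u^{*2})},
#' \eqn{a_{12} = -ac}, \eqn{a_{21} = bc}, \eqn{a_{22} = -c}, determinant
#' \eqn{\Delta_0 = c^2(u^{*2}+ab-1)} and trace \eqn{Tr_0 = -c u^{*2}}.
#'
#' The shifted nonlinearity admits two conventions, selected by
#' \code{variant}: \code{"printed"} uses \eqn{f(u) = -u^* u^2 - u^3/3}
#' (quadratic coefficient \eqn{-u^*}, cubic \eqn{-1/3}); the
#' \code{"c-scaled"} variant multiplies both by \eqn{c}, which is what a
#' direct Taylor expansion of the model equations yields. The default is
#' \code{"printed"}; the choice only affects the nonlinear (normal-form)
#' quantities, never the Jacobian. See the package vignette for why both
#' are provided.
#'
#' @param model an \code{"fhn_model"}.
#' @param equilibrium index into \code{model$equilibria} (default 1; in
#'   the one-real-root case this is the unique equilibrium).
#' @param variant \code{"printed"} or \code{"c-scaled"} shifted
#'   nonlinearity (see Details).
#' @return An object of class \code{"fhn_linearization"}: list with
#'   \code{a11}, \code{a12}, \code{a21}, \code{a22}, \code{det0},
#'   \code{tr0}, \code{quad_coeff}, \code{cubic_coeff}, \code{variant},
#'   \code{u_star}, \code{v_star} and the model parameters.
#' @examples
#' m <- fhn_model()
#' lin <- linearize(m)
#' c(lin$a11, lin$det0, lin$tr0)
#' @export
linearize <- function(model, equilibrium = 1L,
                      variant = c("printed", "c-scaled")) {
  stopifnot(inherits(model, "fhn_model"))
  variant <- match.arg(variant)
  eq <- model$equilibria[equilibrium, ]
  if (nrow(eq) != 1L || is.na(eq$u_star))
    stop("no equilibrium with index ", equilibrium, call. = FALSE)
  p <- model$params
  us <- eq$u_star
  cc <- p[["c"]]
  scale <- if (variant == "printed") 1 else cc
  structure(list(
    a11 = cc * (1 - us^2),
    a12 = -p[["a"]] * cc,
    a21 = p[["b"]] * cc,
    a22 = -cc,
    det0 = cc^2 * (us^2 + p[["a"]] * p[["b"]] - 1),
    tr0 = -cc * us^2,
    quad_coeff = -us * scale,
    cubic_coeff = -scale / 3,
    variant = variant,
    u_star = us, v_star = eq$v_star,
    params = p
  ), class = "fhn_linearization")
}

#' Local stability of the equilibrium without diffusion
#'
#' Routh-Hurwitz test for the uncoupled node: the equilibrium is
#' asymptotically stable iff \eqn{c u^{*2} > 0} and
#' \eqn{u^{*2} + ab - 1 > 0} (equivalently \eqn{Tr_0 < 0} and
#' \eqn{\Delta_0 > 0}). Equality is treated as failure (marginal case).
#'
#' @param lin an \code{"fhn_linearization"}.
#' @return \code{TRUE} iff both inequalities hold strictly.
#' @examples
#' check_h1(linearize(fhn_model()))
#' @export
check_h1 <- function(lin) {
  stopifnot(inherits(lin, "fhn_linearization"))
  p <- lin$params
  us2 <- lin$u_star^2
  (p[["c"]] * us2 > 0) && (us2 + p[["a"]] * p[["b"]] - 1 > 0)
}

#' @export
print.fhn_model <- function(x, ...) {
  p <- x$params
  cat("FitzHugh-Nagumo model\n")
  cat(sprintf("  a = %g, b = %g, c = %g, d = %g, I = %g\n",
              p[["a"]], p[["b"]], p[["c"]], p[["d"]], p[["I"]]))
  cat(sprintf("  cubic: rho = %g, delta = %g, case (%s) %s\n",
              x$classification$rho, x$classification$delta,
              x$classification$case, x$classification$case_label))
  cat(sprintf("  %d equilibrium point(s):\n", nrow(x$equilibria)))
  print(x$equilibria, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fhn_model <- function(object, ...) object$params

#' @export
summary.fhn_model <- function(object, ...) {
  lin <- lapply(seq_len(nrow(object$equilibria)),
                function(i) linearize(object, i))
  stab <- vapply(lin, check_h1, logical(1))
  out <- object$equilibria
  out$stable <- stab
  out$det0 <- vapply(lin, `[[`, numeric(1), "det0")
  out$tr0 <- vapply(lin, `[[`, numeric(1), "tr0")
  structure(list(model = object, table = out), class = "summary.fhn_model")
}

#' @export
print.summary.fhn_model <- function(x, ...) {
  print(x$model)
  cat("\nStability (no diffusion, no delay):\n")
  print(x$table[, c("u_star", "det0", "tr0", "stable")], row.names = FALSE)
  invisible(x)
}

#' @export
print.fhn_linearization <- function(x, ...) {
  cat("FHN linearization at u* =", format(x$u_star), "\n")
  cat(sprintf("  J = [[%g, %g], [%g, %g]]\n", x$a11, x$a12, x$a21, x$a22))
  cat(sprintf("  det0 = %g, tr0 = %g, variant = %s\n",
              x$det0, x$tr0, x$variant))
  invisible(x)
}
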