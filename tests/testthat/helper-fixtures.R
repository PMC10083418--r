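# shared fixtures and independent oracles used across the test files

base_model <- function() fhn_model(a = 1, b = 1, c = 2, d = 1, I = 0.7)
base_lin <- function(...) linearize(base_model(), ...)

# characteristic coefficients assembled directly (bypasses linearize),
# for randomized coefficient draws
mk_coeffs <- function(B1, B2, B3) {
  structure(list(B1 = B1, B2 = B2, B3 = B3,
                 p = B1^2 - 2 * B2, q = B2^2 - B3^2,
                 lambda_R = 0, lambda_E = 0),
            class = "char_coeffs")
}

# random coefficients satisfying the single-positive-root regime
# (q < 0, p > 0)
rand_crossing_coeffs <- function() {
  B3 <- sample(c(-1, 1), 1) * runif(1, 0.5, 5)
  B2 <- runif(1, -0.9, 0.9) * abs(B3)
  B1 <- sqrt(2 * max(B2, 0)) + runif(1, 0.1, 3)
  mk_coeffs(B1, B2, B3)
}

# Newton continuation of a characteristic root lambda(tau) of
# lambda^2 + B1 lambda + B2 + B3 exp(-lambda tau) = 0, independent of
# the package's crossing solver
char_root_newton <- function(cf, tau, lam0) {
  lam <- lam0
  for (i in 1:100) {
    f <- lam^2 + cf$B1 * lam + cf$B2 + cf$B3 * exp(-lam * tau)
    fp <- 2 * lam + cf$B1 - cf$B3 * tau * exp(-lam * tau)
    step <- f / fp
    lam <- lam - step
    if (Mod(step) < 1e-13) break
  }
  lam
}

# finite-difference estimate of d Re(lambda)/d tau at a crossing
fd_transversality <- function(cf, hp, h = 1e-6) {
  lam0 <- complex(imaginary = hp$omega0)
  lp <- char_root_newton(cf, hp$tau0 + h, lam0)
  lm <- char_root_newton(cf, hp$tau0 - h, lam0)
  (Re(lp) - Re(lm)) / (2 * h)
}

# numerical quadrature of the adjoint bilinear form
# <psi, phi> = conj(psi(0))' phi(0)
#              + tau0 * int_{-1}^0 conj(psi(xi+1))' J1 phi(xi) dxi,
# for the exponential eigenfunctions at a Hopf point; independent of
# the closed-form normalization used inside the package
bilinear_quadrature <- function(lin, hopf, psi_vec, phi_vec, conj_phi = FALSE) {
  w0 <- hopf$omega0; tau0 <- hopf$tau0
  J1 <- matrix(c(0, 0, lin$a12, 0), 2, 2)
  phi <- function(xi) {
    e <- exp(complex(imaginary = (if (conj_phi) -1 else 1) * w0 * tau0 * xi))
    (if (conj_phi) Conj(phi_vec) else phi_vec) * e
  }
  psi_bar <- function(s) Conj(psi_vec * exp(complex(imaginary = w0 * tau0 * s)))
  f <- function(xi) {
    vapply(xi, function(x)
      sum(psi_bar(x + 1) * as.vector(J1 %*% phi(x))), complex(1))
  }
  xs <- seq(-1, 0, length.out = 2001)
  fx <- f(xs)
  integral <- sum((fx[-1] + fx[-length(fx)]) / 2) * (xs[2] - xs[1])
  sum(psi_bar(0) * phi(0)) + tau0 * integral
}

# brute-force bisection root of a continuous scalar function
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
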