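#' Simulation configuration
#'
#' Settings for the fixed-step integrators. Fixed-step schemes are used
#' throughout (RK4 when the system is deterministic and undelayed,
#' explicit Euler with a linearly interpolated history buffer when
#' delayed, Euler-Maruyama when noisy) so that delayed and stochastic
#' paths are exactly reproducible under seeding.
#'
#' @param dt time step (> 0; default 0.005).
#' @param t_end integration horizon (default 200).
#' @param tau delay on the cross-coupling term \eqn{a_{12} v(t-\tau)}
#'   (0 = no delay). The history is constant: \eqn{v(t) = v(0)} for
#'   \eqn{t \in [-\tau, 0]}.
#' @param noise additive noise amplitude \eqn{np} on the membrane
#'   potential: each node's \eqn{u} update receives an independent
#'   Gaussian increment of standard deviation \code{noise * sqrt(dt)}
#'   (0 = deterministic).
#' @param seed RNG seed governing the initial perturbation and the
#'   noise path (independent substreams).
#' @param init \code{"equilibrium"} (start exactly at the homogeneous
#'   equilibrium) or \code{"perturbed"} (add an i.i.d. uniform
#'   perturbation of amplitude \code{perturb_amp} to each node's
#'   membrane potential \eqn{u}; the recovery variable starts at its
#'   equilibrium value).
#' @param perturb_amp half-width of the uniform initial perturbation
#'   (default 0.01).
#' @param save_every store every k-th step in the returned trajectory
#'   (default 10; step 0 is always stored).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 0.005, t_end = 200, tau = 0, noise = 0,
                       seed = 1L, init = c("equilibrium", "perturbed"),
                       perturb_amp = 0.01, save_every = 10L) {
  init <- match.arg(init)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (t_end <= dt) stop("'t_end' must exceed 'dt'", call. = FALSE)
  if (tau < 0) stop("'tau' must be nonnegative", call. = FALSE)
  if (noise < 0) stop("'noise' must be nonnegative", call. = FALSE)
  structure(list(dt = dt, t_end = t_end, tau = tau, noise = noise,
                 seed = as.integer(seed), init = init,
                 perturb_amp = perturb_amp,
                 save_every = as.integer(save_every)),
            class = "sim_config")
}

#' Integrate the multilayer FHN system
#'
#' Integrates the full nonlinear model in original coordinates,
#' \deqn{\dot u = c(u - u^3/3 - a v_\tau + I) + L_u u, \quad
#'       \dot v = c(b u - v + d) + L_v v,}
#' on the Cartesian product of two network layers, where \eqn{L_u =
#' D_u^R L^R \otimes I + D_u^E I \otimes L^E} (and likewise \eqn{L_v})
#' and \eqn{v_\tau = v(t - \tau)} when a delay is configured (only the
#' cross-coupling term is delayed). With \code{layers = NULL} a single
#' uncoupled node is integrated.
#'
#' Integrator selection follows the configuration: RK4 for
#' deterministic undelayed runs, explicit Euler (method of steps,
#' linear interpolation in the history buffer) when \code{tau > 0},
#' Euler-Maruyama increments on \eqn{u} when \code{noise > 0}. A run
#' with \code{noise = 0} on the stochastic path is bit-identical to the
#' deterministic Euler path.
#'
#' @param model an \code{"fhn_model"}.
#' @param layers list with components \code{R} and \code{E} (objects of
#'   class \code{"layer_graph"}), or \code{NULL} for one node.
#' @param diff a \code{"diffusion_params"}.
#' @param config a \code{"sim_config"}.
#' @param equilibrium index of the equilibrium used as the homogeneous
#'   base state.
#' @return An object of class \code{"fhn_trajectory"}: list with
#'   \code{times}, matrices \code{u} and \code{v} (nodes x saved
#'   times), \code{config}, \code{equilibrium} and \code{n_nodes}.
#' @examples
#' m <- fhn_model()
#' tr <- fhn_simulate(m, config = sim_config(t_end = 10, tau = 0.6,
#'                                           init = "perturbed"))
#' range(tr$u)
#' @export
fhn_simulate <- function(model, layers = NULL,
                         diff = diffusion_params(),
                         config = sim_config(), equilibrium = 1L) {
  stopifnot(inherits(model, "fhn_model"), inherits(config, "sim_config"))
  p <- model$params
  eq <- model$equilibria[equilibrium, ]
  if (nrow(eq) != 1L || is.na(eq$u_star))
    stop("no equilibrium with index ", equilibrium, call. = FALSE)

  if (is.null(layers)) {
    n <- 1L
    Lu <- Lv <- NULL
  } else {
    stopifnot(inherits(layers$R, "layer_graph"),
              inherits(layers$E, "layer_graph"))
    n <- layers$R$n * layers$E$n
    Lu <- product_laplacian(layers$R, layers$E, diff$du_R, diff$du_E)
    Lv <- product_laplacian(layers$R, layers$E, diff$dv_R, diff$dv_E)
  }

  u <- rep(eq$u_star, n)
  v <- rep(eq$v_star, n)
  if (config$init == "perturbed") {
    # stimuli act on the membrane potential: perturb u only (see vignette)
    u <- u + with_seed(substream_seed(config$seed, "perturb"),
                       stats::runif(n, -config$perturb_amp,
                                    config$perturb_amp))
  }

  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
  d <- p[["d"]]; I <- p[["I"]]
  dt <- config$dt
  n_steps <- ceiling(config$t_end / dt)
  keep <- unique(c(seq(0L, n_steps, by = config$save_every), n_steps))
  n_keep <- length(keep)
  U <- matrix(NA_real_, n, n_keep)
  V <- matrix(NA_real_, n, n_keep)
  U[, 1] <- u; V[, 1] <- v
  ki <- 2L

  du_dt <- function(u, v_coupling) {
    r <- cc * (u - u^3 / 3 - a * v_coupling + I)
    if (!is.null(Lu)) r <- r + as.vector(Lu %*% u)
    r
  }
  dv_dt <- function(u, v) {
    r <- cc * (b * u - v + d)
    if (!is.null(Lv)) r <- r + as.vector(Lv %*% v)
    r
  }

  use_rk4 <- config$tau == 0 && config$noise == 0
  stochastic <- config$noise > 0
  if (stochastic) {
    # dedicate the loop's RNG to the noise substream, restoring the
    # caller's stream on exit (no other RNG use happens in the loop)
    had_rs <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_rs) old_rs <- get(".Random.seed", envir = globalenv())
    on.exit(if (had_rs) assign(".Random.seed", old_rs, envir = globalenv()),
            add = TRUE)
    set.seed(substream_seed(config$seed, "noise"))
  }

  # delay bookkeeping: ring buffer of v over the last tau window
  if (config$tau > 0) {
    lag <- config$tau / dt
    hcap <- as.integer(ceiling(lag)) + 2L
    hist_v <- matrix(v, n, hcap)      # constant history v(t) = v(0), t <= 0
    hpos <- 1L                         # column holding step k's v
  }

  for (k in seq_len(n_steps)) {
    if (use_rk4) {
      k1u <- du_dt(u, v);                  k1v <- dv_dt(u, v)
      u2 <- u + dt / 2 * k1u;              v2 <- v + dt / 2 * k1v
      k2u <- du_dt(u2, v2);                k2v <- dv_dt(u2, v2)
      u3 <- u + dt / 2 * k2u;              v3 <- v + dt / 2 * k2v
      k3u <- du_dt(u3, v3);                k3v <- dv_dt(u3, v3)
      u4 <- u + dt * k3u;                  v4 <- v + dt * k3v
      k4u <- du_dt(u4, v4);                k4v <- dv_dt(u4, v4)
      u <- u + dt / 6 * (k1u + 2 * k2u + 2 * k3u + k4u)
      v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    } else {
      if (config$tau > 0) {
        s <- (k - 1L) - lag              # delayed index on the step grid
        if (s <= 0) {
          vdel <- hist_v[, 1L]           # constant pre-history
        } else {
          i0 <- floor(s); fr <- s - i0
          c0 <- ring_col(hpos, (k - 1L) - i0, hcap)
          c1 <- ring_col(hpos, (k - 1L) - i0 - 1L, hcap)
          vdel <- (1 - fr) * hist_v[, c0] + fr * hist_v[, c1]
        }
      } else vdel <- v
      un <- u + dt * du_dt(u, vdel)
      vn <- v + dt * dv_dt(u, v)
      if (stochastic)
        un <- un + config$noise * sqrt(dt) * stats::rnorm(n)
      u <- un; v <- vn
      if (config$tau > 0) {
        hpos <- hpos %% hcap + 1L
        hist_v[, hpos] <- v
      }
    }
    if (ki <= n_keep && k == keep[ki]) {
      if (!all(is.finite(u)) || !all(is.finite(v)))
        stop(sprintf("state diverged (non-finite) at t = %.4f", k * dt),
             call. = FALSE)
      U[, ki] <- u; V[, ki] <- v
      ki <- ki + 1L
    }
  }
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop(sprintf("state diverged (non-finite) at t = %.4f", n_steps * dt),
         call. = FALSE)

  structure(list(times = keep * dt, u = U, v = V,
                 config = config, equilibrium = eq, n_nodes = n),
            class = "fhn_trajectory")
}

# column of the ring buffer holding the v of absolute step `step`, given
# that column `hpos` holds the most recent step `cur`
ring_col <- function(hpos, back, hcap) {
  ((hpos - 1L - back) %% hcap) + 1L
}

#' @export
print.fhn_trajectory <- function(x, ...) {
  cat(sprintf("FHN trajectory: %d node(s), t in [0, %g], %d samples\n",
              x$n_nodes, max(x$times), length(x$times)))
  cat(sprintf("  u range [%.4g, %.4g], v range [%.4g, %.4g]\n",
              min(x$u), max(x$u), min(x$v), max(x$v)))
  cfg <- x$config
  cat(sprintf("  dt = %g, tau = %g, noise = %g, seed = %d\n",
              cfg$dt, cfg$tau, cfg$noise, cfg$seed))
  invisible(x)
}

#' @rdname fhn_simulate
#' @param object an \code{"fhn_model"} (for the \code{simulate} method).
#' @param nsim number of trajectories (method returns a list when
#'   \code{nsim > 1}).
#' @param seed overrides \code{config$seed}; successive replicates use
#'   \code{seed}, \code{seed + 1}, ...
#' @param ... passed on to \code{fhn_simulate}.
#' @export
simulate.fhn_model <- function(object, nsim = 1, seed = NULL,
                               config = sim_config(), ...) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    fhn_simulate(object, config = cfg, ...)
  })
  if (nsim == 1) out[[1]] else out
}

#' Node-by-time pattern matrix
#'
#' Extracts the membrane-potential matrix of a trajectory for heatmap
#' display. With \code{sort_nodes}, rows are ordered by the
#' time-averaged \eqn{u} over the terminal window (descending, ties by
#' node index), the usual presentation for network Turing patterns.
#'
#' @param traj an \code{"fhn_trajectory"}.
#' @param sort_nodes sort rows by terminal-window mean activity.
#' @param window fraction of the trajectory (from the end) used for the
#'   sorting average (default 0.25).
#' @return Numeric matrix (nodes x times) with attribute \code{"order"}
#'   giving the row permutation applied.
#' @export
pattern_matrix <- function(traj, sort_nodes = TRUE, window = 0.25) {
  stopifnot(inherits(traj, "fhn_trajectory"))
  M <- traj$u
  ord <- seq_len(nrow(M))
  if (sort_nodes) {
    iw <- traj$times >= (1 - window) * max(traj$times)
    avg <- rowMeans(M[, iw, drop = FALSE])
    ord <- order(-avg, seq_len(nrow(M)))
    M <- M[ord, , drop = FALSE]
  }
  attr(M, "order") <- ord
  M
}

#' Synchrony index of a trajectory
#'
#' Measures how coherently the nodes oscillate over a time window:
#' \deqn{S = 1 - \frac{\overline{\mathrm{Var}_\mathrm{nodes}(u(t))}}
#'   {\overline{\mathrm{Var}_\mathrm{nodes}(u(t))} +
#'    \overline{\mathrm{Var}_t(u_i)}},}
#' the time-averaged cross-node variance relative to itself plus the
#' node-averaged temporal variance. Perfectly synchronized oscillation
#' gives 1; independent equal-power node signals give about 0.5; the
#' index decreases as cross-node dispersion grows.
#'
#' @param traj an \code{"fhn_trajectory"}.
#' @param window numeric length-2 time interval, or \code{NULL} for the
#'   terminal quarter of the run.
#' @return Scalar in \eqn{[0, 1]}. A constant trajectory returns 1 with
#'   a degenerate-input warning.
#' @export
synchrony_index <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "fhn_trajectory"))
  if (is.null(window)) window <- c(0.75, 1) * max(traj$times)
  iw <- traj$times >= window[1] & traj$times <= window[2]
  if (sum(iw) < 2) stop("window contains fewer than 2 samples", call. = FALSE)
  Uw <- traj$u[, iw, drop = FALSE]
  v_cross <- mean(apply(Uw, 2, stats::var))
  v_temp <- mean(apply(Uw, 1, stats::var))
  if (v_cross + v_temp == 0) {
    warning("constant trajectory over the window; synchrony defined as 1")
    return(1)
  }
  1 - v_cross / (v_cross + v_temp)
}

#' Simulated Turing-onset test
#'
#' The simulation counterpart of \code{\link{classify_spectrum}}: start
#' at the homogeneous equilibrium plus a small random perturbation,
#' integrate deterministically, and report whether the cross-node
#' standard deviation of \eqn{u} grew by more than a factor of 10 by
#' the end of the run (pattern onset) or not (relaxation back to rest).
#'
#' @param model an \code{"fhn_model"}.
#' @param layers list with layer graphs \code{R} and \code{E}.
#' @param diff a \code{"diffusion_params"}.
#' @param config a \code{"sim_config"} with \code{init = "perturbed"};
#'   zero perturbation trivially returns \code{FALSE}.
#' @param growth_factor onset threshold on the terminal/initial
#'   cross-node standard-deviation ratio (default 10).
#' @return Logical; attributes \code{sd_initial}, \code{sd_final},
#'   \code{ratio}.
#' @export
amplitude_growth_test <- function(model, layers, diff, config,
                                  growth_factor = 10) {
  stopifnot(inherits(config, "sim_config"))
  if (config$init != "perturbed")
    config$init <- "perturbed"
  tr <- fhn_simulate(model, layers, diff, config)
  sd0 <- stats::sd(tr$u[, 1])
  sd1 <- stats::sd(tr$u[, ncol(tr$u)])
  res <- (sd0 > 0) && (sd1 > growth_factor * sd0)
  attr(res, "sd_initial") <- sd0
  attr(res, "sd_final") <- sd1
  attr(res, "ratio") <- if (sd0 > 0) sd1 / sd0 else NA_real_
  res
}
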