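#' Swarm configuration
#'
#' Hyperparameters of the particle swarm with time-varying acceleration
#' coefficients (TVAC) and linearly decaying inertia. Defaults follow
#' the widely used settings: the cognitive coefficient decays from 2.5
#' to 0.5 while the social coefficient grows from 0.5 to 2.5, inertia
#' decays from 0.9 to 0.4, 25 particles, and a budget of 1000 objective
#' function calls. One objective call is one full-dataset accuracy
#' evaluation of one particle position; the schedules interpolate on
#' the call counter (or on iterations when `max_iter` is set, in which
#' case `max_calls` is ignored).
#'
#' @param omega_max,omega_min Initial and final inertia weight.
#' @param c1_max,c1_min Initial and final cognitive coefficient.
#' @param c2_min,c2_max Initial and final social coefficient.
#' @param n_particles Number of particles in the swarm.
#' @param max_calls Budget of objective-function calls (termination).
#' @param max_iter Optional iteration budget; overrides `max_calls`.
#' @param lower,upper Per-dimension bounds on the weights.
#' @param v_max Per-dimension velocity cap; defaults to `upper - lower`.
#' @param seed Integer RNG seed; makes a run fully reproducible.
#' @param shared_draws Draw one `r1`, `r2` pair per particle update
#'   instead of one pair per dimension (default `FALSE`: per-dimension).
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(omega_max = 0.9, omega_min = 0.4,
                         c1_max = 2.5, c1_min = 0.5,
                         c2_min = 0.5, c2_max = 2.5,
                         n_particles = 25L, max_calls = 1000L,
                         max_iter = NULL, lower = 0, upper = 1,
                         v_max = upper - lower, seed = 1L,
                         shared_draws = FALSE) {
  stopifnot(omega_max >= omega_min, c1_max >= c1_min, c2_max >= c2_min,
            upper > lower, v_max > 0, n_particles >= 1, max_calls >= 1,
            is.null(max_iter) || max_iter >= 1)
  structure(list(omega_max = omega_max, omega_min = omega_min,
                 c1_max = c1_max, c1_min = c1_min,
                 c2_min = c2_min, c2_max = c2_max,
                 n_particles = as.integer(n_particles),
                 max_calls = as.integer(max_calls),
                 max_iter = if (!is.null(max_iter)) as.integer(max_iter),
                 lower = lower, upper = upper, v_max = v_max,
                 seed = as.integer(seed), shared_draws = shared_draws),
            class = "swarm_config")
}

#' @export
print.swarm_config <- function(x, ...) {
  cat("<swarm_config> ", x$n_particles, " particles, ",
      if (is.null(x$max_iter)) paste0(x$max_calls, " objective calls")
      else paste0(x$max_iter, " iterations"),
      "; omega ", x$omega_max, "->", x$omega_min,
      ", c1 ", x$c1_max, "->", x$c1_min,
      ", c2 ", x$c2_min, "->", x$c2_max,
      ", bounds [", x$lower, ", ", x$upper, "], seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# linear schedule: value `from` at t = 0, `to` at t = budget
.sched_lin <- function(t, budget, from, to) {
  (from - to) * (budget - t) / budget + to
}

.check_calls <- function(calls, config) {
  if (any(calls < 0) || any(calls > config$max_calls)) {
    stop("calls must lie in [0, max_calls]", call. = FALSE)
  }
}

#' Time-varying coefficient schedules
#'
#' The cognitive coefficient `c1` decays linearly from `c1_max` to
#' `c1_min` over the call budget, the social coefficient `c2` grows
#' from `c2_min` to `c2_max`, and the inertia weight decays from
#' `omega_max` to `omega_min`. Early in a run particles explore under a
#' strong cognitive pull; late in the run the social pull drives
#' convergence on the swarm's best-known position.
#'
#' @param calls Current objective-call count, in `[0, max_calls]`.
#' @param config A [swarm_config()].
#' @return The coefficient value at `calls`.
#' @examples
#' cfg <- swarm_config()
#' c1_at(0, cfg)     # 2.5
#' c2_at(1000, cfg)  # 2.5
#' omega_at(500, cfg)
#' @export
c1_at <- function(calls, config = swarm_config()) {
  .check_calls(calls, config)
  .sched_lin(calls, config$max_calls, config$c1_max, config$c1_min)
}

#' @rdname c1_at
#' @export
c2_at <- function(calls, config = swarm_config()) {
  .check_calls(calls, config)
  .sched_lin(calls, config$max_calls, config$c2_min, config$c2_max)
}

#' @rdname c1_at
#' @export
omega_at <- function(calls, config = swarm_config()) {
  .check_calls(calls, config)
  .sched_lin(calls, config$max_calls, config$omega_max, config$omega_min)
}

#' Particle velocity update
#'
#' `V = omega * V' + c1 * r1 * (Pb - X') + c2 * r2 * (Pg - X')`,
#' componentwise, then clamped to `[-v_max, v_max]`.
#'
#' @param velocity Current velocity `V'`.
#' @param position Current position `X'`.
#' @param p_best Particle's personal best position `Pb`.
#' @param g_best Swarm's global best position `Pg`.
#' @param omega,c1,c2 Inertia and acceleration coefficients.
#' @param r1,r2 Random draws in `[0, 1]` (scalar or per-dimension).
#' @param v_max Velocity cap.
#' @return Updated velocity vector.
#' @export
update_velocity <- function(velocity, position, p_best, g_best,
                            omega, c1, c2, r1, r2, v_max = Inf) {
  d <- length(position)
  if (length(velocity) != d || length(p_best) != d || length(g_best) != d) {
    stop("velocity, position, p_best and g_best must share one dimension",
         call. = FALSE)
  }
  v <- omega * velocity + c1 * r1 * (p_best - position) +
    c2 * r2 * (g_best - position)
  pmin(pmax(v, -v_max), v_max)
}

#' Particle position update
#'
#' `X = X' + V`, componentwise, clamped to `[lower, upper]`.
#'
#' @param position Current position.
#' @param velocity Updated velocity.
#' @param lower,upper Box bounds.
#' @return Updated position vector.
#' @export
update_position <- function(position, velocity, lower = 0, upper = 1) {
  if (length(position) != length(velocity)) {
    stop("position and velocity dimensions differ", call. = FALSE)
  }
  pmin(pmax(position + velocity, lower), upper)
}

#' Particle swarm maximization over a box
#'
#' The low-level optimizer: maximizes `objective` over
#' `[lower, upper]^d` with TVAC schedules. Particles are updated
#' asynchronously (the global best can improve within a sweep); the
#' global best is replaced only on strict improvement, so ties keep the
#' first achiever and runs are deterministic given the seed.
#'
#' @param objective Function mapping a length-`d` numeric vector to a
#'   scalar fitness (higher is better).
#' @param d Problem dimension.
#' @param config A [swarm_config()].
#' @param init Optional matrix (`k x d`) of starting positions for the
#'   first `k` particles; remaining particles start uniformly at random
#'   in the box. Velocities start at zero.
#' @param fixed Optional numeric vector of length `d` with `NA` for
#'   free dimensions; non-`NA` entries are frozen at the given value.
#' @return A list with `par` (best position), `value` (its fitness),
#'   `calls`, `iterations`, and `history` (data frame of `calls` and
#'   the running global-best `fitness`, nondecreasing).
#' @export
pso_optimize <- function(objective, d, config = swarm_config(),
                         init = NULL, fixed = NULL) {
  stopifnot(is.function(objective), d >= 1)
  set.seed(config$seed)
  np <- config$n_particles
  free <- rep(TRUE, d)
  fixed_vals <- NULL
  if (!is.null(fixed)) {
    stopifnot(length(fixed) == d)
    free <- is.na(fixed)
    fixed_vals <- fixed[!free]
  }
  pos <- matrix(stats::runif(np * d, config$lower, config$upper), np, d)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), np)
    pos[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  if (!is.null(fixed_vals)) {
    pos[, !free] <- matrix(fixed_vals, np, sum(!free), byrow = TRUE)
  }
  vel <- matrix(0, np, d)
  pb <- pos
  pbf <- rep(-Inf, np)
  gb <- pos[1, ]
  gbf <- -Inf
  iter_mode <- !is.null(config$max_iter)
  budget <- if (iter_mode) config$max_iter else config$max_calls
  calls <- 0L
  iter <- 0L
  hist_calls <- integer(0)
  hist_fit <- numeric(0)
  repeat {
    iter <- iter + 1L
    for (k in seq_len(np)) {
      if (!iter_mode && calls >= config$max_calls) break
      f <- objective(pos[k, ])
      calls <- calls + 1L
      if (f > pbf[k]) {
        pbf[k] <- f
        pb[k, ] <- pos[k, ]
      }
      if (f > gbf) {
        gbf <- f
        gb <- pos[k, ]
      }
      hist_calls <- c(hist_calls, calls)
      hist_fit <- c(hist_fit, gbf)
      t <- if (iter_mode) min(iter, budget) else calls
      omega <- .sched_lin(t, budget, config$omega_max, config$omega_min)
      c1 <- .sched_lin(t, budget, config$c1_max, config$c1_min)
      c2 <- .sched_lin(t, budget, config$c2_min, config$c2_max)
      if (config$shared_draws) {
        r1 <- stats::runif(1)
        r2 <- stats::runif(1)
      } else {
        r1 <- stats::runif(d)
        r2 <- stats::runif(d)
      }
      v <- update_velocity(vel[k, ], pos[k, ], pb[k, ], gb,
                           omega, c1, c2, r1, r2, config$v_max)
      v[!free] <- 0
      x <- update_position(pos[k, ], v, config$lower, config$upper)
      vel[k, ] <- v
      pos[k, ] <- x
    }
    done <- if (iter_mode) iter >= budget else calls >= config$max_calls
    if (done) break
  }
  list(par = gb, value = gbf, calls = calls, iterations = iter,
       history = data.frame(calls = hist_calls, fitness = hist_fit))
}

#' Brute-force lattice oracle
#'
#' Exhaustively evaluates `objective` on the lattice
#' `{lower, lower + step, ..., upper}^d` and returns the maximizer
#' (first in lexicographic order on ties). Intended as an independent
#' check on the swarm optimizer at small dimension; a combinatorial
#' guard rejects `d > dimension_cap`.
#'
#' @param objective Fitness function as in [pso_optimize()].
#' @param d Dimension.
#' @param step Lattice spacing.
#' @param lower,upper Box bounds.
#' @param dimension_cap Maximum allowed `d` (default 4).
#' @return A list with `par` and `value`.
#' @export
grid_oracle <- function(objective, d, step = 0.1, lower = 0, upper = 1,
                        dimension_cap = 4L) {
  stopifnot(d >= 1, step > 0)
  if (d > dimension_cap) {
    stop("grid_oracle: dimension ", d, " exceeds cap ", dimension_cap,
         call. = FALSE)
  }
  pts <- seq(lower, upper, by = step)
  grid <- do.call(expand.grid, rep(list(pts), d))
  ord <- do.call(order, as.list(grid))
  best <- NULL
  best_f <- -Inf
  for (r in ord) {
    w <- as.numeric(grid[r, ])
    f <- objective(w)
    if (f > best_f) {
      best_f <- f
      best <- w
    }
  }
  list(par = best, value = best_f)
}
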