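# Charge-state dynamics of a heavy atom at fixed local fluence.
#
# The reduced model is a pure-jump ladder on q = 0..Z: state q absorbs at
# rate sigma(q) * F * g(t); each absorption ejects the photoelectron plus an
# Auger-cascade burst A drawn from the atom's cascade pmf, treated as
# instantaneous (Auger lifetimes are far below the pulse duration). Cascade
# sizes are truncated at the photoionization floor: the drawn A is
# conditioned on q + 1 + A <= q_floor, and if no admissible size exists the
# event carries the atom exactly to q_floor. The floor is the terminal charge
# of the ladder; allowing overshoot past it systematically over-ionizes the
# high-fluence case (see the methods vignette).

# Post-event charges reachable from q, with their probabilities.
.jump_targets <- function(atom, q) {
  sizes <- as.integer(names(atom$cascade_pmf))
  p <- atom$cascade_pmf
  cap <- min(atom$Z, atom$q_floor)
  ok <- q + 1L + sizes <= cap
  if (any(ok)) {
    list(q = q + 1L + sizes[ok], p = p[ok] / sum(p[ok]))
  } else {
    list(q = cap, p = 1)
  }
}

# Generator matrix (Z+1 x Z+1, column = from-state) at fluence F under a
# flat-top temporal profile: rate_q = sigma(q) [um^2] * F [um^-2] / duration.
.ladder_generator <- function(atom, fluence, temporal) {
  nq <- atom$Z + 1L
  A <- matrix(0, nq, nq)
  for (q in 0:(atom$Z - 1L)) {
    r <- cross_section(atom, q) * .UM2_PER_BARN * fluence / temporal$duration
    if (r <= 0) next
    A[q + 1L, q + 1L] <- A[q + 1L, q + 1L] - r
    tg <- .jump_targets(atom, q)
    for (k in seq_along(tg$q)) {
      A[tg$q[k] + 1L, q + 1L] <- A[tg$q[k] + 1L, q + 1L] + r * tg$p[k]
    }
  }
  A
}

#' Evolve charge-state populations at fixed fluence
#'
#' Solves the master equation of the reduced ladder over the flat-top pulse.
#' Because the generator is time-independent for a flat-top, the one-step
#' propagator `expm(A * dt)` is exact at the grid points; `dt` only controls
#' the resolution of the stored trajectory (and of downstream time
#' quadrature) and is halved automatically until the per-step absorption
#' probability is below 0.1.
#'
#' @param atom An [atom_model()].
#' @param fluence Local fluence in photons um^-2.
#' @param temporal A [temporal_profile()].
#' @param dt Requested time step in fs (default 0.05).
#' @return Object of class `charge_trajectory`: `times` (fs), `populations`
#'   (matrix, rows = times, columns = charge states `0..Z`), plus the inputs.
#' @examples
#' gd <- load_atom_model(element = "Gd")
#' tr <- evolve_populations(gd, 1.3e11, temporal_profile(40))
#' mean_bound_electrons(tr, 40)
#' @export
evolve_populations <- function(atom, fluence, temporal, dt = 0.05) {
  stopifnot(inherits(atom, "atom_model"), inherits(temporal, "temporal_profile"))
  if (fluence < 0) .stopf("fluence must be >= 0")
  if (!.is_number(dt) || dt <= 0) .stopf("dt must be > 0")
  rmax <- max(cross_section(atom, 0:(atom$Z)) * .UM2_PER_BARN) *
    fluence / temporal$duration
  while (rmax * dt >= 0.1) dt <- dt / 2
  nt <- max(2L, ceiling(temporal$duration / dt))
  times <- seq(0, temporal$duration, length.out = nt + 1L)
  nq <- atom$Z + 1L
  P <- matrix(0, nt + 1L, nq)
  P[1L, 1L] <- 1
  if (fluence > 0) {
    A <- .ladder_generator(atom, fluence, temporal)
    M <- as.matrix(Matrix::expm(A * (times[2L] - times[1L])))
    for (i in seq_len(nt)) {
      p <- M %*% P[i, ]
      s <- sum(p)
      if (abs(s - 1) > 1e-9 || any(p < -1e-12)) {
        .stopf("population conservation violated at step %d (sum = %.3e)", i, s)
      }
      P[i + 1L, ] <- pmax(p, 0) / s
    }
  } else {
    P[, 1L] <- 1
  }
  structure(list(times = times, populations = P, atom = atom,
                 fluence = fluence, temporal = temporal, dt = times[2L] - times[1L]),
            class = "charge_trajectory")
}

#' @export
print.charge_trajectory <- function(x, ...) {
  cat(sprintf("<charge_trajectory> %s at F = %.4g photons/um^2, %d steps over %.3g fs\n",
              x$atom$element, x$fluence, length(x$times) - 1L, max(x$times)))
  cat(sprintf("  end-of-pulse mean charge: %.2f\n",
              sum(x$populations[nrow(x$populations), ] * (0:x$atom$Z))))
  invisible(x)
}

#' Monte Carlo ensemble of charge trajectories
#'
#' Simulates `n` independent realizations of the same jump process as
#' [evolve_populations()] by direct event-driven sampling (constant rates
#' between jumps under the flat-top profile). Fully reproducible: the seed is
#' recorded in the result and the caller's RNG state is untouched.
#'
#' @param atom An [atom_model()].
#' @param fluence Photons um^-2.
#' @param temporal A [temporal_profile()].
#' @param n Number of realizations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `mc_ensemble`: lists `event_times` and
#'   `charges` (post-event charge per event) per realization, plus metadata.
#' @export
simulate_monte_carlo <- function(atom, fluence, temporal, n, seed) {
  stopifnot(inherits(atom, "atom_model"), inherits(temporal, "temporal_profile"))
  if (!.is_number(n) || n < 1) .stopf("n must be >= 1")
  n <- as.integer(n)
  sizes <- as.integer(names(atom$cascade_pmf))
  rate_of <- function(q) {
    cross_section(atom, q) * .UM2_PER_BARN * fluence / temporal$duration
  }
  out_t <- vector("list", n)
  out_q <- vector("list", n)
  .with_seed(seed, {
    for (i in seq_len(n)) {
      t <- 0; q <- 0L
      ev_t <- numeric(0); ev_q <- integer(0)
      repeat {
        r <- rate_of(q)
        if (r <= 0) break
        t <- t + rexp(1L, r)
        if (t >= temporal$duration) break
        tg <- .jump_targets(atom, q)
        q <- if (length(tg$q) == 1L) tg$q else {
          tg$q[sample.int(length(tg$q), 1L, prob = tg$p)]
        }
        ev_t <- c(ev_t, t); ev_q <- c(ev_q, q)
      }
      out_t[[i]] <- ev_t; out_q[[i]] <- ev_q
    }
  })
  structure(list(event_times = out_t, charges = out_q, n = n, seed = seed,
                 atom = atom, fluence = fluence, temporal = temporal),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  nev <- vapply(x$event_times, length, integer(1))
  cat(sprintf("<mc_ensemble> n = %d realizations, seed = %d, mean events/realization = %.2f\n",
              x$n, x$seed, mean(nev)))
  invisible(x)
}

# Per-realization time-averaged bound electrons over [0, gate] (exact for the
# piecewise-constant charge path).
.mc_time_averaged_bound <- function(ens, gate = NULL) {
  Tg <- if (is.null(gate)) ens$temporal$duration else gate
  Z <- ens$atom$Z
  vapply(seq_len(ens$n), function(i) {
    et <- ens$event_times[[i]]; qs <- ens$charges[[i]]
    keep <- et < Tg
    et <- et[keep]; qs <- qs[keep]
    bounds <- c(0, et, Tg)
    qpath <- c(0L, qs)
    Z - sum(qpath * diff(bounds)) / Tg
  }, numeric(1))
}

# Empirical charge-state populations of an ensemble at time t.
.mc_populations_at <- function(ens, t) {
  Z <- ens$atom$Z
  counts <- numeric(Z + 1L)
  for (i in seq_len(ens$n)) {
    et <- ens$event_times[[i]]
    k <- sum(et <= t)
    q <- if (k == 0L) 0L else ens$charges[[i]][k]
    counts[q + 1L] <- counts[q + 1L] + 1
  }
  counts / ens$n
}

#' Mean bound electrons along a trajectory
#'
#' `sum_q P_q(t) * (Z - q)`, with linear interpolation of the populations
#' between grid points.
#'
#' @param traj A `charge_trajectory` from [evolve_populations()].
#' @param t Time(s) in fs, within the trajectory support.
#' @return Expected number of bound electrons at each `t`.
#' @export
mean_bound_electrons <- function(traj, t) {
  stopifnot(inherits(traj, "charge_trajectory"))
  if (any(t < min(traj$times) - 1e-9 | t > max(traj$times) + 1e-9)) {
    .stopf("t outside the trajectory time grid [%.3g, %.3g] fs",
           min(traj$times), max(traj$times))
  }
  bound <- as.vector(traj$populations %*% (traj$atom$Z - 0:traj$atom$Z))
  approx(traj$times, bound, xout = pmin(pmax(t, min(traj$times)), max(traj$times)))$y
}

#' Export a trajectory as a data frame
#'
#' @param x A `charge_trajectory`.
#' @param ... Unused.
#' @return data.frame with `time_fs` and one `P_q` column per charge state.
#' @export
as.data.frame.charge_trajectory <- function(x, ...) {
  df <- data.frame(time_fs = x$times)
  P <- x$populations
  colnames(P) <- paste0("P_", 0:x$atom$Z)
  cbind(df, as.data.frame(P))
}
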