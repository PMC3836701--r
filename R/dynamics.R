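#' Simulation configuration
#'
#' Defaults follow the production protocol of the coarse-grained models:
#' 15 fs time step, friction 0.1 ps^-1, 25 Angstrom nonbonded cutoff.
#'
#' @param timestep_fs integration time step, femtoseconds.
#' @param friction Langevin friction, ps^-1 (0 = deterministic dynamics).
#' @param temperature K.
#' @param box cubic box edge, Angstrom (0 = no periodicity).
#' @param n_steps total number of steps.
#' @param save_every save interval in steps (must divide `n_steps`).
#' @param seed integer random seed.
#' @param shake constrain virtual bond lengths with SHAKE.
#' @param shake_tol relative SHAKE tolerance.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(timestep_fs = 15, friction = 0.1, temperature = 300,
                       box = 100, n_steps = 10000, save_every = 10,
                       seed = 1, shake = TRUE, shake_tol = 1e-8) {
  stopifnot(timestep_fs > 0, friction >= 0, n_steps >= 1,
            n_steps %% save_every == 0)
  structure(list(timestep_fs = timestep_fs, friction = friction,
                 temperature = temperature, box = box, n_steps = n_steps,
                 save_every = save_every, seed = as.integer(seed),
                 shake = shake, shake_tol = shake_tol),
            class = "SimulationConfig")
}

#' Run Langevin dynamics
#'
#' BAOAB-splitting Langevin integrator with post-step SHAKE on the virtual
#' bonds, in a periodic cubic box.  The same seed, configuration, and
#' topology give a bit-identical trajectory.  Coordinates are stored both
#' wrapped (for analysis) and unwrapped (for diffusion checks).
#'
#' @param topology a `GoTopology`.
#' @param config a `SimulationConfig`.
#' @param start_coords n x 3 starting coordinates; defaults to the native
#'   coordinates.
#' @param start_velocities n x 3 starting velocities (A/ps); defaults to a
#'   Maxwell-Boltzmann draw at `config$temperature` from the seed.
#' @return a `Trajectory`: list with `frames` (nframes x n x 3 wrapped),
#'   `frames_unwrapped`, `time_ps`, `epot`, `ekin`, `temperature`, `box`,
#'   `seed`, and final phase-space point (`x_final`, `v_final`).
#' @export
run_langevin <- function(topology, config, start_coords = topology$coords,
                         start_velocities = NULL) {
  x0 <- as.matrix(start_coords)
  n <- nrow(topology$particles)
  if (nrow(x0) != n) stop("start coordinates do not match topology")
  if (is.null(start_velocities)) {
    set.seed(config$seed)
    sig <- sqrt(.kB * config$temperature * 418.4 / topology$particles$mass)
    start_velocities <- matrix(rnorm(3 * n), n, 3) * sig
  }
  sys <- topology_to_sys(topology, config$box)
  res <- cpp_run_langevin(sys, x0, as.matrix(start_velocities),
                          as.integer(config$n_steps),
                          config$timestep_fs / 1000, config$friction,
                          config$temperature,
                          as.integer(config$save_every),
                          as.integer(config$seed),
                          isTRUE(config$shake), config$shake_tol, 500L)
  structure(list(frames = res$frames, frames_unwrapped = res$frames_unwrapped,
                 time_ps = res$times, epot = res$epot, ekin = res$ekin,
                 temperature = config$temperature, box = config$box,
                 seed = config$seed, n_particles = n,
                 frame_spacing_ps = config$save_every *
                   config$timestep_fs / 1000,
                 x_final = res$x_final, v_final = res$v_final),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d particles, %.4g ps (T = %g K, box %g A)\n",
              dim(x$frames)[1], x$n_particles, max(x$time_ps),
              x$temperature, x$box))
  invisible(x)
}

# frame k as an n x 3 matrix
frame_coords <- function(trajectory, k, unwrapped = FALSE) {
  a <- if (unwrapped) trajectory$frames_unwrapped else trajectory$frames
  matrix(a[k, , ], ncol = 3)
}

#' Default replica-exchange temperature ladder
#'
#' Geometric ladder between the endpoints; the production protocol uses
#' eight replicas spanning 270 to 400 K.
#'
#' @param n_replicas number of replicas (>= 2).
#' @param t_min,t_max endpoint temperatures, K.
#' @return numeric vector of temperatures, strictly increasing.
#' @export
rex_ladder <- function(n_replicas = 8, t_min = 270, t_max = 400) {
  stopifnot(n_replicas >= 2, t_max > t_min)
  t_min * (t_max / t_min)^(seq(0, 1, length.out = n_replicas))
}

#' Temperature replica exchange
#'
#' Runs one Langevin segment per replica between exchange attempts.
#' Neighbor swaps alternate between even and odd pairs and are accepted with
#' the Metropolis criterion `min(1, exp[(beta_i - beta_j)(U_i - U_j)])`;
#' configurations swap and velocities are rescaled by
#' `sqrt(T_new / T_old)`.
#'
#' @param topology a `GoTopology`.
#' @param config a `SimulationConfig`; `n_steps` is the total per replica
#'   and must be a multiple of `exchange_interval`.
#' @param ladder temperature ladder (K), strictly increasing.
#' @param exchange_interval steps between exchange attempts.
#' @param start_coords shared starting coordinates (default native).
#' @return a `RexResult`: per-replica wrapped frame arrays and energy
#'   series, the ladder, and per-neighbor-pair attempt/acceptance counts.
#' @export
run_rex <- function(topology, config, ladder = rex_ladder(),
                    exchange_interval = 1000,
                    start_coords = topology$coords) {
  stopifnot(length(ladder) >= 2, !is.unsorted(ladder, strictly = TRUE),
            config$n_steps %% exchange_interval == 0)
  nrep <- length(ladder)
  ncycle <- config$n_steps %/% exchange_interval
  sys <- topology_to_sys(topology, config$box)
  n <- nrow(topology$particles)
  x <- replicate(nrep, as.matrix(start_coords), simplify = FALSE)
  set.seed(config$seed)
  v <- lapply(seq_len(nrep), function(r) {
    sig <- sqrt(.kB * ladder[r] * 418.4 / topology$particles$mass)
    matrix(rnorm(3 * n), n, 3) * sig
  })
  seeds <- sample.int(2^30, nrep * ncycle)
  nsave_cycle <- exchange_interval %/% config$save_every
  frames <- lapply(seq_len(nrep), function(r)
    array(NA_real_, c(ncycle * nsave_cycle, n, 3)))
  epot <- matrix(NA_real_, ncycle * nsave_cycle, nrep)
  times <- numeric(ncycle * nsave_cycle)
  attempts <- accepts <- integer(nrep - 1)
  u_last <- numeric(nrep)
  walker <- seq_len(nrep)  # which walker currently occupies each rung
  walker_hist <- matrix(NA_integer_, ncycle, nrep)

  for (cy in seq_len(ncycle)) {
    for (r in seq_len(nrep)) {
      res <- cpp_run_langevin(sys, x[[r]], v[[r]],
                              as.integer(exchange_interval),
                              config$timestep_fs / 1000, config$friction,
                              ladder[r], as.integer(config$save_every),
                              as.integer(seeds[(cy - 1) * nrep + r]),
                              isTRUE(config$shake), config$shake_tol, 500L)
      x[[r]] <- res$x_final
      v[[r]] <- res$v_final
      rows <- (cy - 1) * nsave_cycle + seq_len(nsave_cycle)
      frames[[r]][rows, , ] <- array(res$frames, c(nsave_cycle, n, 3))
      epot[rows, r] <- res$epot
      if (r == 1)
        times[rows] <- (cy - 1) * exchange_interval *
          config$timestep_fs / 1000 + res$times
      u_last[r] <- res$epot[length(res$epot)]
    }
    first <- if (cy %% 2 == 1) 1 else 2
    if (first > nrep - 1) next
    for (p in seq(first, nrep - 1, by = 2)) {
      attempts[p] <- attempts[p] + 1L
      bi <- 1 / (.kB * ladder[p]); bj <- 1 / (.kB * ladder[p + 1])
      logp <- (bi - bj) * (u_last[p] - u_last[p + 1])
      if (log(runif(1)) < logp) {
        accepts[p] <- accepts[p] + 1L
        tmp <- x[[p]]; x[[p]] <- x[[p + 1]]; x[[p + 1]] <- tmp
        sc_up <- sqrt(ladder[p] / ladder[p + 1])
        tmpv <- v[[p]]
        v[[p]] <- v[[p + 1]] * sc_up
        v[[p + 1]] <- tmpv / sc_up
        tmpu <- u_last[p]; u_last[p] <- u_last[p + 1]; u_last[p + 1] <- tmpu
        tmpw <- walker[p]; walker[p] <- walker[p + 1]; walker[p + 1] <- tmpw
      }
    }
    walker_hist[cy, ] <- walker
  }
  structure(list(frames = frames, epot = epot, time_ps = times,
                 ladder = ladder, attempts = attempts, accepts = accepts,
                 walker = walker_hist,
                 box = config$box, seed = config$seed, n_particles = n,
                 frame_spacing_ps = config$save_every *
                   config$timestep_fs / 1000),
            class = "RexResult")
}

#' @export
print.RexResult <- function(x, ...) {
  cat(sprintf("RexResult: %d replicas (%.0f-%.0f K), %d frames each\n",
              length(x$ladder), min(x$ladder), max(x$ladder),
              nrow(x$epot)))
  cat("  acceptance:",
      paste(sprintf("%.2f", x$accepts / pmax(1, x$attempts)),
            collapse = " "), "\n")
  invisible(x)
}
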