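# Two-stage model calibration: intramolecular contact strengths are scaled
# to reproduce the residual helicity of the unbound IDP, then intermolecular
# strengths are scaled so the computed dissociation constant matches the
# experimental value to order of magnitude.  Charged models are re-calibrated
# after charge assignment by re-running the same two stages.

# vectorized pseudo-dihedral over frames for particles i,j,k,l (1-based)
dihedral_frames <- function(fr, i, j, k, l, box = 0) {
  d <- function(a, b) cbind(mi(fr[, b, 1] - fr[, a, 1], box),
                            mi(fr[, b, 2] - fr[, a, 2], box),
                            mi(fr[, b, 3] - fr[, a, 3], box))
  b1 <- d(i, j); b2 <- d(j, k); b3 <- d(k, l)
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  atan2(rowSums(cr(n1, n2) * b2) / nb2, rowSums(n1 * n2))
}

#' Per-residue residual helicity of a single-chain trajectory
#'
#' A residue i is counted helical in a frame when its native (i, i+4)
#' contact -- where present in the topology -- is formed (inter-C-alpha
#' distance within `tol` of native) and the pseudo-dihedral over C-alpha
#' (i-1, i, i+1, i+2) is within `angle_tol` degrees of its native value.
#' Residues without a native (i, i+4) contact score 0 (designed coil).
#'
#' @param trajectory a `Trajectory` (or frames array) of the unbound chain.
#' @param topology the single-chain `GoTopology`.
#' @param tol contact formation tolerance, Angstrom.
#' @param angle_tol pseudo-dihedral tolerance, degrees.
#' @return data frame with `residue` (global 0-based) and `helicity` in
#'   `[0, 1]`.
#' @export
residual_helicity <- function(trajectory, topology, tol = 1.0,
                              angle_tol = 40) {
  n <- sum(topology$particles$chain != "_het")
  if (n < 5) stop("chain shorter than 5 residues")
  fr <- as_frames(trajectory)
  box <- if (inherits(trajectory, "Trajectory")) trajectory$box else 0
  ct <- topology$contacts
  dh <- topology$dihedrals
  hel <- numeric(n)
  for (i in 0:(n - 1)) {
    row <- which(ct$i == i & ct$j == i + 4 & ct$class != "inter")
    drow <- which(dh$i == i - 1)
    if (length(row) == 0 || length(drow) == 0) { hel[i + 1] <- 0; next }
    r <- pair_dist(fr, i + 1, i + 5, box)
    formed <- abs(r - ct$r_native[row[1]]) <= tol
    phi <- dihedral_frames(fr, i, i + 1, i + 2, i + 3, box)
    dphi <- abs(phi - dh$phi0[drow[1]])
    dphi <- pmin(dphi, 2 * pi - dphi)
    hel[i + 1] <- mean(formed & (dphi <= angle_tol * pi / 180))
  }
  data.frame(residue = 0:(n - 1), helicity = hel)
}

#' Calibrate the intramolecular scaling to a target residual helicity
#'
#' Bisection on `lambda_intra` over the search bracket; each evaluation is
#' a fixed-length unbound Langevin run at 300 K followed by
#' [residual_helicity()].  Helicity increases monotonically with
#' `lambda_intra`, so bisection is well posed.  Stops when the mean
#' helicity over `helix_residues` is within `tol` of the target or the
#' bracket shrinks below `bracket_tol`.  The unscaled (`lambda = 1`)
#' helicity is reported alongside.
#'
#' @param topology an (unscaled) single-chain `GoTopology`.
#' @param target_helicity target mean helicity, in (0, 1).
#' @param config a `SimulationConfig` for the evaluation runs (300 K).
#' @param helix_residues 0-based residue indices over which the mean is
#'   taken; default: residues owning a native (i, i+4) contact.
#' @param bracket search interval for `lambda_intra`.
#' @param tol helicity tolerance.
#' @param bracket_tol minimum bracket width.
#' @return list with `lambda_intra`, `achieved`, `lambda1_helicity`, and
#'   the evaluation `trace`.
#' @export
calibrate_intra <- function(topology, target_helicity, config,
                            helix_residues = NULL, bracket = c(0.1, 1.5),
                            tol = 0.05, bracket_tol = 0.01) {
  stopifnot(target_helicity > 0, target_helicity < 1)
  if (is.null(helix_residues)) {
    ct <- topology$contacts
    helix_residues <- ct$i[ct$j == ct$i + 4 & ct$class != "inter"]
  }
  evalh <- function(lam, seed_shift = 0) {
    tp <- scale_topology(topology, lambda_intra = lam)
    cf <- config
    cf$seed <- config$seed + seed_shift
    tr <- run_langevin(tp, cf)
    h <- residual_helicity(tr, tp)
    mean(h$helicity[h$residue %in% helix_residues])
  }
  trace <- data.frame(lambda = numeric(0), helicity = numeric(0))
  note <- function(lam, h) trace <<- rbind(trace,
                                           data.frame(lambda = lam,
                                                      helicity = h))
  h_lo <- evalh(bracket[1]); note(bracket[1], h_lo)
  h_hi <- evalh(bracket[2]); note(bracket[2], h_hi)
  h1 <- evalh(1.0); note(1.0, h1)
  if (target_helicity < h_lo - tol || target_helicity > h_hi + tol)
    stop(sprintf("target helicity %.3f unreachable in bracket: h(%.2f) = %.3f, h(%.2f) = %.3f",
                 target_helicity, bracket[1], h_lo, bracket[2], h_hi))
  lo <- bracket[1]; hi <- bracket[2]
  lam <- 1.0; h <- h1
  while (abs(h - target_helicity) >= tol && (hi - lo) >= bracket_tol) {
    lam <- (lo + hi) / 2
    h <- evalh(lam)
    note(lam, h)
    if (h < target_helicity) lo <- lam else hi <- lam
  }
  list(lambda_intra = lam, achieved = h, lambda1_helicity = h1,
       trace = trace)
}

#' Calibrate the intermolecular scaling to a target dissociation constant
#'
#' Bisection in `log(lambda_inter)`; each evaluation is a replica-exchange
#' run followed by WHAM and [dissociation_constant()] at 300 K.  K_D
#' decreases monotonically as `lambda_inter` increases.  The search accepts
#' as soon as the computed K_D is within one order of magnitude of the
#' target (the computed K_D is very sensitive to small changes of the
#' intermolecular scaling, so a tighter criterion is rarely meaningful at
#' short sampling).
#'
#' @param topology a two-chain `GoTopology` with `lambda_intra` already
#'   calibrated.
#' @param target_kd target dissociation constant, mol/L.
#' @param config a `SimulationConfig` for the per-replica runs.
#' @param ladder replica temperature ladder, K.
#' @param exchange_interval steps between exchange attempts.
#' @param bracket search interval for `lambda_inter`.
#' @param max_iter bisection iteration cap.
#' @param unbound_rule,bound_threshold forwarded to
#'   [dissociation_constant()].
#' @return list with `lambda_inter`, `kd`, and the evaluation `trace`.
#' @export
calibrate_inter <- function(topology, target_kd, config,
                            ladder = rex_ladder(), exchange_interval = 1000,
                            bracket = c(0.3, 3), max_iter = 12,
                            unbound_rule = "no_native",
                            bound_threshold = NULL) {
  stopifnot(target_kd > 0)
  evalkd <- function(lam) {
    tp <- scale_topology(topology, lambda_inter = lam)
    rex <- run_rex(tp, config, ladder, exchange_interval)
    series <- lapply(seq_along(ladder), function(r) rex$epot[, r])
    wh <- wham(series, ladder)
    ni <- unlist(lapply(seq_along(ladder), function(r) {
      inter <- tp$contacts[tp$contacts$class == "inter", , drop = FALSE]
      native_contact_count(array(rex$frames[[r]],
                                 dim(rex$frames[[r]])), inter, rex$box)
    }))
    kd <- tryCatch(
      dissociation_constant(wh, ni, config$box, 300, unbound_rule,
                            bound_threshold),
      error = function(e)
        stop("REX sampling did not resolve both bound and unbound states (",
             conditionMessage(e), "); use longer runs", call. = FALSE))
    kd$kd
  }
  trace <- data.frame(lambda = numeric(0), kd = numeric(0))
  llo <- log(bracket[1]); lhi <- log(bracket[2])
  lam <- 1.0
  for (it in seq_len(max_iter)) {
    kd <- evalkd(lam)
    trace <- rbind(trace, data.frame(lambda = lam, kd = kd))
    if (abs(log10(kd / target_kd)) <= 1) break
    if (kd > target_kd) llo <- log(lam) else lhi <- log(lam)
    lam <- exp((llo + lhi) / 2)
  }
  list(lambda_inter = trace$lambda[nrow(trace)], kd = trace$kd[nrow(trace)],
       trace = trace)
}

#' Run a production simulation at the melting temperature
#'
#' Single-temperature Langevin dynamics at `t_m`, followed by the standard
#' observable series, 15-ps smoothing, three-state assignment, and the
#' kinetic rate summary.  Verifies that bound and unbound states are
#' sampled with similar probability and warns (with the achieved split)
#' when the imbalance is worse than 80/20.
#'
#' @param topology a calibrated two-chain `GoTopology`.
#' @param t_m production temperature, K.
#' @param config a `SimulationConfig` (its `temperature` is overridden by
#'   `t_m`).
#' @param bound_threshold native intermolecular contact count defining the
#'   bound state.
#' @param smoothing_ps running-average window for state assignment, ps.
#' @return list with `trajectory`, `observables`, `states`, `rates`,
#'   `bound_fraction`.
#' @export
run_production <- function(topology, t_m, config, bound_threshold,
                           smoothing_ps = 15) {
  config$temperature <- t_m
  tr <- run_langevin(topology, config)
  obs <- compute_observables(tr, topology)
  dt <- tr$frame_spacing_ps
  ni_s <- smooth_series(obs$n_inter, smoothing_ps, dt)
  nn_s <- smooth_series(obs$n_nonspec, smoothing_ps, dt)
  states <- assign_states(ni_s, nn_s, bound_threshold, dt)
  rates <- transition_stats(states)
  bf <- mean(states$labels == "B")
  if (bf < 0.2 || bf > 0.8)
    warning(sprintf(
      "bound/unbound split %.2f/%.2f is worse than 80/20; adjust T (%s)",
      bf, 1 - bf,
      if (bf < 0.2) "lower T to stabilize binding" else "raise T"))
  list(trajectory = tr, observables = obs, states = states, rates = rates,
       bound_fraction = bf)
}
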