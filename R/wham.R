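#' Binless temperature WHAM
#'
#' Combines potential-energy samples from several temperatures into a single
#' reweighting machine.  The per-temperature free-energy offsets `f_k` are
#' iterated to self-consistency; per-sample log-weights can then be
#' evaluated at any query temperature inside the sampled range, so any
#' per-sample observable can be reweighted (binless formulation; no
#' histogram binning is involved).
#'
#' @param energy_series list of numeric vectors, one per temperature
#'   (kcal/mol).
#' @param temperatures numeric vector of the same length, K.
#' @param tol convergence tolerance on `max |delta f_k|` (dimensionless).
#' @param max_iter iteration cap; non-convergence is an error.
#' @return a `WhamResult`: `f` (offsets, first fixed to 0), `u` (pooled
#'   samples), `n_k`, `beta_k`, `iterations`, `max_delta`, and the sample
#'   provenance (`which_series`).
#' @export
wham <- function(energy_series, temperatures, tol = 1e-8, max_iter = 10000) {
  stopifnot(length(energy_series) == length(temperatures),
            length(temperatures) >= 1,
            all(vapply(energy_series, length, 1L) > 0))
  betas <- 1 / (.kB * temperatures)
  u <- unlist(energy_series, use.names = FALSE)
  n_k <- vapply(energy_series, length, 1L)
  which_series <- rep(seq_along(energy_series), n_k)
  K <- length(betas)
  f <- numeric(K)
  if (K == 1) {
    return(structure(list(f = f, u = u, n_k = n_k, beta_k = betas,
                          temperatures = temperatures, iterations = 0L,
                          max_delta = 0, which_series = which_series),
                     class = "WhamResult"))
  }
  # -beta_k * U_n matrix built once (K x N)
  negbU <- -outer(betas, u)
  logN <- log(n_k)
  it <- 0L
  repeat {
    it <- it + 1L
    # log denominator per sample: logsumexp_k (logN_k + f_k + negbU[k, n])
    m <- negbU + (logN + f)
    mx <- apply(m, 2, max)
    logden <- mx + log(colSums(exp(sweep(m, 2, mx))))
    fnew <- vapply(seq_len(K), function(k) {
      a <- negbU[k, ] - logden
      am <- max(a)
      -(am + log(sum(exp(a - am))))
    }, 1.0)
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
    if (it >= max_iter)
      stop(sprintf("WHAM did not converge: max|df| = %.3g after %d iterations",
                   delta, it))
  }
  structure(list(f = f, u = u, n_k = n_k, beta_k = betas,
                 temperatures = temperatures, iterations = it,
                 max_delta = delta, which_series = which_series),
            class = "WhamResult")
}

#' @export
print.WhamResult <- function(x, ...) {
  cat(sprintf("WhamResult: %d temperatures (%.0f-%.0f K), %d samples, %d iterations\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), length(x$u), x$iterations))
  invisible(x)
}

#' Normalized per-sample weights at a query temperature
#'
#' @param wham_result a `WhamResult`.
#' @param temperature query temperature, K (inside the sampled range).
#' @return numeric vector of weights summing to 1 over the pooled samples.
#' @export
wham_weights <- function(wham_result, temperature) {
  beta <- 1 / (.kB * temperature)
  if (length(wham_result$beta_k) == 1) {
    n <- length(wham_result$u)
    return(rep(1 / n, n))
  }
  m <- -outer(wham_result$beta_k, wham_result$u) +
    (log(wham_result$n_k) + wham_result$f)
  mx <- apply(m, 2, max)
  logden <- mx + log(colSums(exp(sweep(m, 2, mx))))
  lw <- -beta * wham_result$u - logden
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Reweighted expectation of a per-sample observable
#'
#' @inheritParams wham_weights
#' @param observable numeric vector aligned with the pooled samples.
#' @return scalar expectation value at the query temperature.
#' @export
wham_expectation <- function(wham_result, observable, temperature) {
  stopifnot(length(observable) == length(wham_result$u))
  sum(wham_weights(wham_result, temperature) * observable)
}

#' Heat capacity from WHAM reweighting
#'
#' `C_V(T) = (<U^2>_T - <U>_T^2) / (k_B T^2)`, in kcal/mol/K.
#'
#' @param wham_result a `WhamResult`.
#' @param t_grid temperatures, K.
#' @return data frame with `temperature` and `cv`.
#' @export
heat_capacity <- function(wham_result, t_grid) {
  if (length(t_grid) == 0)
    return(data.frame(temperature = numeric(0), cv = numeric(0)))
  cv <- vapply(t_grid, function(tt) {
    w <- wham_weights(wham_result, tt)
    mu <- sum(w * wham_result$u)
    (sum(w * wham_result$u^2) - mu^2) / (.kB * tt^2)
  }, 1.0)
  data.frame(temperature = t_grid, cv = cv)
}

#' Melting temperature from the heat-capacity peak and P_bound crossing
#'
#' Locates the C_V(T) peak, then the temperature where the reweighted bound
#' probability crosses 0.5 (linear interpolation on the grid), following the
#' protocol of locating T_m from the heat-capacity curve and fine-tuning it
#' so that bound and unbound states are sampled with similar probability.
#'
#' @param wham_result a `WhamResult`.
#' @param bound_indicator 0/1 (or logical) per pooled sample.
#' @param t_grid temperatures to scan, K.
#' @return list with `tm` (the P = 0.5 crossing), `cv_peak` (the C_V peak
#'   temperature), and the scanned `p_bound` data frame.
#' @export
melting_temperature <- function(wham_result, bound_indicator, t_grid) {
  stopifnot(length(bound_indicator) == length(wham_result$u))
  b <- as.numeric(bound_indicator)
  cvd <- heat_capacity(wham_result, t_grid)
  pb <- vapply(t_grid, function(tt)
    wham_expectation(wham_result, b, tt), 1.0)
  crossings <- which(diff(sign(pb - 0.5)) != 0)
  if (length(crossings) == 0)
    stop(sprintf("P_bound does not cross 0.5 in [%g, %g] K (%.3f at low end, %.3f at high end)",
                 min(t_grid), max(t_grid), pb[1], pb[length(pb)]))
  k <- crossings[1]
  tm <- t_grid[k] + (0.5 - pb[k]) * (t_grid[k + 1] - t_grid[k]) /
    (pb[k + 1] - pb[k])
  list(tm = tm, cv_peak = cvd$temperature[which.max(cvd$cv)],
       p_bound = data.frame(temperature = t_grid, p_bound = pb))
}

#' Effective concentration of one molecular pair in a cubic box
#'
#' `C_eff = 1 / (N_A V)` with `V = edge^3` converted to litres.  A 100
#' Angstrom box gives 1.66 mM; 105 Angstrom gives 1.43 mM.
#'
#' @param box_edge cubic box edge, Angstrom.
#' @return concentration in mol/L.
#' @export
effective_concentration <- function(box_edge) {
  stopifnot(box_edge > 0)
  v_litre <- box_edge^3 * 1e-27
  1 / (6.02214076e23 * v_litre)
}

#' Dissociation constant from bound/unbound probabilities
#'
#' For a single pair per box, `K_D = C_eff P_U^2 / (1 - P_U)` at the query
#' temperature (default 300 K).  The default unbound rule counts frames
#' without any native intermolecular contact (`N_inter = 0`); the
#' `"complement"` rule uses `P_U = 1 - P_bound` with `P_bound = P[N_inter >=
#' bound_threshold]`, for complexes whose 1D free-energy profile lacks a
#' barrier between the unbound and partially bound states.
#'
#' @param wham_result a `WhamResult`.
#' @param n_inter numeric vector of native intermolecular contact counts per
#'   pooled sample.
#' @param box_edge cubic box edge, Angstrom.
#' @param temperature query temperature, K.
#' @param unbound_rule `"no_native"` (default) or `"complement"`.
#' @param bound_threshold `N_inter` threshold defining the bound state
#'   (required for the `"complement"` rule).
#' @return list with `kd` (mol/L), `p_unbound`, `c_eff`.
#' @export
dissociation_constant <- function(wham_result, n_inter, box_edge,
                                  temperature = 300,
                                  unbound_rule = c("no_native", "complement"),
                                  bound_threshold = NULL) {
  unbound_rule <- match.arg(unbound_rule)
  stopifnot(length(n_inter) == length(wham_result$u))
  if (unbound_rule == "no_native") {
    pu <- wham_expectation(wham_result, as.numeric(n_inter == 0), temperature)
  } else {
    if (is.null(bound_threshold))
      stop("bound_threshold is required for the complement rule")
    pb <- wham_expectation(wham_result,
                           as.numeric(n_inter >= bound_threshold),
                           temperature)
    pu <- 1 - pb
  }
  if (pu <= 0 || pu >= 1)
    stop(sprintf("unbound probability is %g; K_D unresolvable at %g K",
                 pu, temperature))
  ce <- effective_concentration(box_edge)
  list(kd = ce * pu^2 / (1 - pu), p_unbound = pu, c_eff = ce)
}

#' Reweighted free-energy surface
#'
#' `F = -k_B T ln P` over a (1D or 2D) histogram of per-sample observables,
#' in units of `k_B T` at the query temperature, anchored so the minimum
#' over occupied bins is exactly 0.  Empty bins are masked (NA), not zero.
#'
#' @param wham_result a `WhamResult`.
#' @param obs_x per-sample observable for the x axis.
#' @param obs_y optional observable for a second axis.
#' @param temperature query temperature, K.
#' @param bins number of bins per axis, or a list of two explicit bin-edge
#'   vectors.
#' @return a `FreeEnergySurface`: `x_mid` (and `y_mid`), `f` (vector or
#'   matrix, kT units), `mask` (TRUE = occupied), axis `edges`.
#' @export
free_energy_surface <- function(wham_result, obs_x, obs_y = NULL,
                                temperature, bins = 40) {
  stopifnot(all(is.finite(obs_x)), length(obs_x) == length(wham_result$u))
  w <- wham_weights(wham_result, temperature)
  mkedges <- function(v, nb) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = nb + 1)
  }
  if (is.list(bins)) {
    ex <- bins[[1]]
    ey <- if (length(bins) > 1) bins[[2]] else NULL
  } else {
    ex <- mkedges(obs_x, bins)
    ey <- if (!is.null(obs_y)) mkedges(obs_y, bins) else NULL
  }
  ix <- findInterval(obs_x, ex, rightmost.closed = TRUE, all.inside = TRUE)
  if (is.null(obs_y)) {
    p <- vapply(seq_len(length(ex) - 1),
                function(b) sum(w[ix == b]), 1.0)
    mask <- p > 0
    if (sum(mask) <= 1)
      warning("all samples fall in a single bin")
    f <- ifelse(mask, -log(p), NA_real_)
    f <- f - min(f, na.rm = TRUE)
    out <- list(x_mid = (head(ex, -1) + tail(ex, -1)) / 2, f = f,
                mask = mask, edges = list(x = ex),
                temperature = temperature)
  } else {
    stopifnot(all(is.finite(obs_y)))
    iy <- findInterval(obs_y, ey, rightmost.closed = TRUE, all.inside = TRUE)
    nx <- length(ex) - 1; ny <- length(ey) - 1
    p <- matrix(0, nx, ny)
    for (s in seq_along(w)) p[ix[s], iy[s]] <- p[ix[s], iy[s]] + w[s]
    mask <- p > 0
    if (sum(mask) <= 1)
      warning("all samples fall in a single bin")
    f <- ifelse(mask, -log(p), NA_real_)
    f <- f - min(f, na.rm = TRUE)
    out <- list(x_mid = (head(ex, -1) + tail(ex, -1)) / 2,
                y_mid = (head(ey, -1) + tail(ey, -1)) / 2,
                f = f, mask = mask, edges = list(x = ex, y = ey),
                temperature = temperature)
  }
  structure(out, class = "FreeEnergySurface")
}

#' Export a free-energy surface as a tabular data frame
#'
#' @param surface a `FreeEnergySurface`.
#' @return data frame of bin centers and free energy (kT units).
#' @export
surface_table <- function(surface) {
  if (is.null(surface$y_mid))
    data.frame(x = surface$x_mid, f_kt = surface$f)
  else
    data.frame(x = rep(surface$x_mid, times = length(surface$y_mid)),
               y = rep(surface$y_mid, each = length(surface$x_mid)),
               f_kt = as.vector(surface$f))
}
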