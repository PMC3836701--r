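# Three-state kinetic decomposition of binding trajectories: running-average
# smoothing of contact-count series, U/CC/B state assignment, transition
# counting, mean first passage times, and the capture / escape / evolution
# rate constants of the collision complex.

#' Centered running average of a series
#'
#' Smoothing is applied to the contact-count series (not to state labels)
#' before state assignment, to avoid counting fictitious transitions driven
#' by rapid small fluctuations.  The window is `ceiling(window_ps /
#' frame_spacing_ps)` frames, centered, shrinking at the edges; a window of
#' 0 returns the input unchanged.
#'
#' @param series numeric vector.
#' @param window_ps smoothing window, ps (default 15).
#' @param frame_spacing_ps frame spacing, ps.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_series <- function(series, window_ps = 15, frame_spacing_ps) {
  stopifnot(window_ps >= 0, frame_spacing_ps > 0)
  if (window_ps == 0 || length(series) < 2) return(series)
  w <- ceiling(window_ps / frame_spacing_ps)
  if (w <= 1) return(series)
  n <- length(series)
  half_lo <- floor((w - 1) / 2)
  half_hi <- ceiling((w - 1) / 2)
  cs <- c(0, cumsum(series))
  lo <- pmax(1, seq_len(n) - half_lo)
  hi <- pmin(n, seq_len(n) + half_hi)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Assign unbound / collision-complex / bound states
#'
#' Frame labels from (already smoothed) contact-count series: `U` when the
#' smoothed native intermolecular count and the smoothed nonspecific count
#' are both below 0.5; `CC` when the nonspecific count is >= 0.5 but the
#' native count is below 0.5; `B` when the native count reaches
#' `bound_threshold`.  Frames with `0.5 <= N_inter < bound_threshold`
#' (partially bound intermediates) inherit the previous non-ambiguous label
#' (`CC` at the trajectory start) -- intermediates are not a fourth state.
#'
#' @param n_inter smoothed native intermolecular contact counts.
#' @param n_nonspec smoothed nonspecific contact counts.
#' @param bound_threshold minimum native intermolecular contact count of the
#'   bound state (e.g., 11 for p53-TAD1/TAZ2, 26/23/24 for HIF-1a/TAZ1
#'   depending on the charge model, 30 for NCBD/ACTR).
#' @param frame_spacing_ps frame spacing, ps (carried into the result).
#' @return a `StateTrajectory`: `labels` (character vector of "U"/"CC"/"B"),
#'   `episodes` (state, start/end frame, duration in ns, with zero-length CC
#'   visits inserted at direct U->B label changes), `frame_spacing_ps`,
#'   `bound_threshold`.
#' @export
assign_states <- function(n_inter, n_nonspec, bound_threshold,
                          frame_spacing_ps = 1) {
  stopifnot(length(n_inter) == length(n_nonspec), bound_threshold >= 1)
  lab <- rep(NA_character_, length(n_inter))
  lab[n_inter >= bound_threshold] <- "B"
  unbound_zone <- n_inter < 0.5
  lab[unbound_zone & n_nonspec < 0.5] <- "U"
  lab[unbound_zone & n_nonspec >= 0.5] <- "CC"
  # ambiguous frames inherit the previous non-ambiguous label
  if (anyNA(lab)) {
    idx <- seq_along(lab)
    known <- which(!is.na(lab))
    if (length(known) == 0) {
      lab[] <- "CC"
    } else {
      filled <- findInterval(idx, known)
      lab <- ifelse(filled == 0, "CC", lab[known[pmax(filled, 1)]])
    }
  }
  structure(list(labels = lab,
                 episodes = episodes_from_labels(lab, frame_spacing_ps),
                 frame_spacing_ps = frame_spacing_ps,
                 bound_threshold = bound_threshold),
            class = "StateTrajectory")
}

# run-length episodes, with zero-length CC visits inserted at direct U<->B
# label changes so the three-state bookkeeping stays closed
episodes_from_labels <- function(lab, frame_spacing_ps) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  ep <- data.frame(state = r$values, start = ends - r$lengths + 1,
                   end = ends, n_frames = r$lengths,
                   stringsAsFactors = FALSE)
  ne <- nrow(ep)
  if (ne > 1) {
    direct <- which((ep$state[-ne] == "U" & ep$state[-1] == "B") |
                      (ep$state[-ne] == "B" & ep$state[-1] == "U"))
    if (length(direct) > 0) {
      ins <- data.frame(state = "CC", start = ep$end[direct],
                        end = ep$end[direct], n_frames = 0L,
                        stringsAsFactors = FALSE)
      ep <- rbind(ep, ins)[order(c(seq_len(ne), direct + 0.5)), ]
      rownames(ep) <- NULL
    }
  }
  ep$duration_ns <- ep$n_frames * frame_spacing_ps / 1000
  ep
}

#' @export
print.StateTrajectory <- function(x, ...) {
  tb <- table(factor(x$labels, levels = c("U", "CC", "B")))
  cat(sprintf("StateTrajectory: %d frames (U %.1f%%, CC %.1f%%, B %.1f%%), %d episodes\n",
              length(x$labels), 100 * tb["U"] / length(x$labels),
              100 * tb["CC"] / length(x$labels),
              100 * tb["B"] / length(x$labels), nrow(x$episodes)))
  invisible(x)
}

# core episode-level statistics; episodes with both boundaries observed
# (i.e., excluding the first and last episodes) are "complete"
episode_stats <- function(states) {
  ep <- states$episodes
  ne <- nrow(ep)
  complete <- if (ne > 2) 2:(ne - 1) else integer(0)
  stlv <- c("U", "CC", "B")
  fa <- factor(ep$state[complete], levels = stlv)
  fb <- factor(ep$state[complete + 1], levels = stlv)
  counts <- unclass(table(fa, fb))
  dimnames(counts) <- list(stlv, stlv)
  dur_sums <- matrix(0, 3, 3, dimnames = list(stlv, stlv))
  agg <- tapply(ep$duration_ns[complete], list(fa, fb), sum)
  dur_sums[!is.na(agg)] <- agg[!is.na(agg)]
  mfpt <- matrix(NA_real_, 3, 3, dimnames = list(stlv, stlv))
  nz <- counts > 0
  mfpt[nz] <- dur_sums[nz] / counts[nz]
  list(counts = counts, mfpt = mfpt, complete = complete)
}

# wall-clock first-passage times: from each entry into X until the first
# subsequent frame in Y, over entries that reach Y
fpt_matrix <- function(states) {
  ep <- states$episodes
  stlv <- c("U", "CC", "B")
  out <- matrix(NA_real_, 3, 3, dimnames = list(stlv, stlv))
  ne <- nrow(ep)
  entry_t <- cumsum(c(0, ep$duration_ns))[seq_len(ne)]
  for (x in stlv) for (y in setdiff(stlv, x)) {
    # next occurrence of y strictly after each episode, scanned from the end
    nexty <- rep(NA_integer_, ne)
    nxt <- NA_integer_
    for (e in ne:1) {
      nexty[e] <- nxt
      if (ep$state[e] == y) nxt <- e
    }
    entries <- which(ep$state == x & seq_len(ne) > 1 & !is.na(nexty))
    if (length(entries) > 0)
      out[x, y] <- mean(entry_t[nexty[entries]] - entry_t[entries])
  }
  out
}

#' Transition statistics and effective rate constants
#'
#' From a `StateTrajectory`, computes: the conditional mean first passage
#' times `MFPT(X -> Y)` (mean residence time in X per visit, over visits
#' whose next state is Y -- the convention under which the CC lifetime may
#' depend on the destination because unmodeled intermediates exist);
#' transition counts; the reversible binding-and-folding transition rate
#' `k_TS = N_TS / t_tot` where `N_TS` counts completed U -> B plus B -> U
#' passages; the capture rate `k_cap = 1 / MFPT(U -> CC)`; the escape and
#' evolution rates `k_esc = N_esc / T_CC` and `k_evo = N_evo / T_CC` over
#' the total residence time `T_CC` of complete collision-complex episodes;
#' and on/off rates from the mean residence times of the unbound (U + CC)
#' and bound macro-states.  Half-split uncertainties (|first half - second
#' half|) are attached for the four headline rates.
#'
#' @param states a `StateTrajectory`.
#' @param t_tot_ns total simulated time, ns; defaults to the label count
#'   times the frame spacing.
#' @return a `RateSummary` list; rates whose transition count is 0 are
#'   reported as 0 and flagged in `$flags`.
#' @export
transition_stats <- function(states, t_tot_ns = NULL) {
  if (nrow(states$episodes) < 1) stop("trajectory has no episodes")
  dt_ns <- states$frame_spacing_ps / 1000
  if (is.null(t_tot_ns)) t_tot_ns <- length(states$labels) * dt_ns
  es <- episode_stats(states)
  flags <- character(0)

  main <- rate_block(states, t_tot_ns)
  # half-split uncertainty
  n <- length(states$labels)
  halves <- list(seq_len(n %/% 2), (n %/% 2 + 1):n)
  hv <- lapply(halves, function(ix) {
    sub <- assign_states_from_labels(states$labels[ix],
                                     states$frame_spacing_ps,
                                     states$bound_threshold)
    rate_block(sub, length(ix) * dt_ns)
  })
  unc <- abs(unlist(hv[[1]][c("k_ts", "k_cap", "k_esc", "k_evo")]) -
               unlist(hv[[2]][c("k_ts", "k_cap", "k_esc", "k_evo")]))
  names(unc) <- c("k_ts", "k_cap", "k_esc", "k_evo")

  for (nm in c("k_ts", "k_cap", "k_esc", "k_evo", "k_on", "k_off"))
    if (main[[paste0("n_", sub("k_", "", nm))]] == 0)
      flags <- c(flags, paste0(nm, ": zero transition count"))

  structure(c(main,
              list(mfpt = es$mfpt, counts = es$counts,
                   fpt = fpt_matrix(states), uncertainty = unc,
                   flags = flags, t_tot_ns = t_tot_ns)),
            class = "RateSummary")
}

# rebuild a StateTrajectory from an existing label vector (no re-smoothing)
assign_states_from_labels <- function(labels, frame_spacing_ps,
                                      bound_threshold) {
  structure(list(labels = labels,
                 episodes = episodes_from_labels(labels, frame_spacing_ps),
                 frame_spacing_ps = frame_spacing_ps,
                 bound_threshold = bound_threshold),
            class = "StateTrajectory")
}

# headline rates from one StateTrajectory
rate_block <- function(states, t_tot_ns) {
  es <- episode_stats(states)
  ep <- states$episodes
  cc_complete <- intersect(es$complete, which(ep$state == "CC"))
  t_cc <- sum(ep$duration_ns[cc_complete])
  n_esc <- es$counts["CC", "U"]
  n_evo <- es$counts["CC", "B"]
  # N_TS: completed passages between the U and B states (CC dropped)
  seq_ub <- ep$state[ep$state != "CC"]
  if (length(seq_ub) > 1) {
    seq_ub <- rle(seq_ub)$values
    n_ts <- length(seq_ub) - 1L
  } else n_ts <- 0L
  k_ts <- n_ts / (t_tot_ns / 1000)  # 1/us
  mf_ucc <- es$mfpt["U", "CC"]
  n_cap <- es$counts["U", "CC"]
  k_cap <- if (n_cap > 0 && is.finite(mf_ucc) && mf_ucc > 0) 1 / mf_ucc else 0
  k_esc <- if (t_cc > 0) n_esc / t_cc else 0
  k_evo <- if (t_cc > 0) n_evo / t_cc else 0
  # macro-state residence: merge U and CC
  macro <- rle(ifelse(ep$state == "B", "B", "UB"))
  mep_state <- macro$values
  # durations of merged episodes
  bnd <- cumsum(macro$lengths)
  cdur <- cumsum(ep$duration_ns)
  mdur <- diff(c(0, cdur[bnd]))
  mcomplete <- if (length(mep_state) > 2) 2:(length(mep_state) - 1) else integer(0)
  tau_ub <- mean(mdur[mcomplete][mep_state[mcomplete] == "UB"])
  tau_b <- mean(mdur[mcomplete][mep_state[mcomplete] == "B"])
  n_on <- sum(mep_state[mcomplete] == "UB")
  n_off <- sum(mep_state[mcomplete] == "B")
  list(k_ts = k_ts, k_cap = k_cap, k_esc = k_esc, k_evo = k_evo,
       k_on = if (n_on > 0 && is.finite(tau_ub) && tau_ub > 0) 1 / tau_ub else 0,
       k_off = if (n_off > 0 && is.finite(tau_b) && tau_b > 0) 1 / tau_b else 0,
       n_ts = n_ts, n_cap = n_cap, n_esc = n_esc, n_evo = n_evo,
       n_on = n_on, n_off = n_off, t_cc_ns = t_cc)
}

#' @export
print.RateSummary <- function(x, ...) {
  cat(sprintf("RateSummary over %.4g ns:\n", x$t_tot_ns))
  cat(sprintf("  k_TS  %.4g 1/us (N_TS = %d)\n", x$k_ts, x$n_ts))
  cat(sprintf("  k_cap %.4g 1/ns   k_esc %.4g 1/ns   k_evo %.4g 1/ns\n",
              x$k_cap, x$k_esc, x$k_evo))
  cat(sprintf("  k_on  %.4g 1/ns   k_off %.4g 1/ns\n", x$k_on, x$k_off))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fraction of collision-complex episodes that evolve to the bound state
#'
#' `N_evo / (N_evo + N_esc)` over complete CC episodes (episodes truncated
#' by the trajectory ends are excluded).  On the same labeling this equals
#' `k_evo / (k_evo + k_esc)` exactly.
#'
#' @param states a `StateTrajectory`.
#' @return fraction in `[0, 1]`.
#' @export
evolution_fraction <- function(states) {
  es <- episode_stats(states)
  n_evo <- es$counts["CC", "B"]
  n_esc <- es$counts["CC", "U"]
  if (n_evo + n_esc == 0) stop("no completed collision-complex episodes")
  n_evo / (n_evo + n_esc)
}

#' Serialize a rate summary as JSON
#'
#' @param rates a `RateSummary`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_rate_summary <- function(rates, path) {
  obj <- unclass(rates)
  obj$mfpt <- as.data.frame(obj$mfpt)
  obj$fpt <- as.data.frame(obj$fpt)
  obj$counts <- as.data.frame(obj$counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
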