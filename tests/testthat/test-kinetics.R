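test_that("running average: identity, constants, hand-computed step", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(smooth_series(x, 0, 1), x)
  expect_equal(smooth_series(rep(4, 10), 15, 1), rep(4, 10))
  # window 15 ps at 5 ps spacing -> 3 frames, centered, shrinking edges
  s <- smooth_series(c(0, 0, 6, 0, 0), 15, 5)
  expect_equal(s, c(0, 2, 2, 2, 0))
  # edge shrinkage: first value averages the first two frames only
  s2 <- smooth_series(c(3, 9, 3, 3), 15, 5)
  expect_equal(s2[1], 6)
})

test_that("state assignment follows the published three-state criteria", {
  # (0 native, 0 nonspecific) -> U; (0, >=1) -> CC; N_inter >= 11 -> B
  st <- assign_states(c(0, 0, 11, 12), c(0, 3, 5, 0), bound_threshold = 11)
  expect_equal(st$labels[1:4], c("U", "CC", "B", "B"))
  # partially bound intermediates inherit the previous label
  st2 <- assign_states(c(0, 0, 5, 5, 11, 5, 0), c(0, 2, 2, 2, 2, 2, 0), 11)
  expect_equal(st2$labels, c("U", "CC", "CC", "CC", "B", "B", "U"))
  # ambiguous start defaults to CC
  st3 <- assign_states(c(4, 4, 0), c(1, 1, 0), 11)
  expect_equal(st3$labels, c("CC", "CC", "U"))
  # exhaustive labeling
  mk <- make_markov_trajectory(length_ns = 100, frame_spacing_ns = 0.01,
                               seed = 2)
  st4 <- assign_states(mk$n_inter, mk$n_nonspec, mk$bound_threshold, 10)
  expect_equal(sum(st4$labels %in% c("U", "CC", "B")), length(st4$labels))
  expect_equal(st4$labels, mk$states_true)
})

test_that("direct U<->B label changes insert a zero-length CC visit", {
  st <- assign_states(c(0, 0, 12, 12, 0), c(0, 0, 4, 4, 0), 11)
  ep <- st$episodes
  expect_equal(ep$state, c("U", "CC", "B", "CC", "U"))
  expect_equal(ep$n_frames[c(2, 4)], c(0L, 0L))
  # episodes tile the trajectory
  expect_equal(sum(ep$n_frames), length(st$labels))
})

test_that("smoothing cannot increase the transition count", {
  set.seed(3)
  mk <- make_markov_trajectory(length_ns = 2000, frame_spacing_ns = 0.005,
                               seed = 3)
  # overlay fast fluctuation noise on the contact series
  ni <- mk$n_inter + rbinom(length(mk$n_inter), 1, 0.1)
  nn <- mk$n_nonspec + rbinom(length(mk$n_nonspec), 1, 0.2)
  dt <- 5
  raw <- transition_stats(assign_states(ni, nn, mk$bound_threshold, dt))
  smo <- transition_stats(assign_states(smooth_series(ni, 15, dt),
                                        smooth_series(nn, 15, dt),
                                        mk$bound_threshold, dt))
  expect_lte(smo$n_ts, raw$n_ts)
})

test_that("rates and MFPTs match the independent brute-force oracle", {
  mk <- make_markov_trajectory(length_ns = 2000, frame_spacing_ns = 0.01,
                               seed = 4)
  st <- assign_states(mk$n_inter, mk$n_nonspec, mk$bound_threshold, 10)
  rs <- transition_stats(st)
  oracle <- naive_episode_rates(st$labels, 0.01)
  expect_equal(rs$k_cap, oracle$k_cap, tolerance = 1e-12)
  expect_equal(rs$k_esc, oracle$k_esc, tolerance = 1e-12)
  expect_equal(rs$k_evo, oracle$k_evo, tolerance = 1e-12)
  expect_equal(rs$n_ts, oracle$n_ts)
  expect_equal(rs$n_esc, oracle$n_esc)
  expect_equal(rs$n_evo, oracle$n_evo)
  # definitional identities
  expect_equal(unname(rs$k_cap * rs$mfpt["U", "CC"]), 1)
  expect_equal(evolution_fraction(st),
               rs$k_evo / (rs$k_evo + rs$k_esc), tolerance = 1e-12)
  expect_equal(evolution_fraction(st),
               rs$n_evo / (rs$n_evo + rs$n_esc), tolerance = 1e-12)
})

test_that("generator rates are recovered within three bootstrap SE", {
  mk <- make_markov_trajectory(k_cap = 1.0, k_esc = 5.0, k_evo = 0.5,
                               k_unbind = 0.5, length_ns = 1e4,
                               frame_spacing_ns = 0.001, seed = 11)
  st <- assign_states(mk$n_inter, mk$n_nonspec, mk$bound_threshold, 1)
  rs <- transition_stats(st)
  se <- bootstrap_rate_se(st)
  expect_lt(abs(rs$k_cap - 1.0), 3 * se["k_cap"] + 0.01)
  expect_lt(abs(rs$k_esc - 5.0), 3 * se["k_esc"] + 0.05)
  expect_lt(abs(rs$k_evo - 0.5), 3 * se["k_evo"] + 0.005)
  # evolution fraction equals the branching ratio of the generator
  expect_equal(evolution_fraction(st), 0.5 / 5.5, tolerance = 0.15)
})

test_that("wall-clock first passage U->B matches the analytic CTMC value", {
  k_cap <- 1; k_esc <- 5; k_evo <- 0.5
  mk <- make_markov_trajectory(k_cap, k_esc, k_evo, k_unbind = 0.5,
                               length_ns = 1e4, frame_spacing_ns = 0.001,
                               seed = 12)
  st <- assign_states(mk$n_inter, mk$n_nonspec, mk$bound_threshold, 1)
  rs <- transition_stats(st)
  # tau_U = 1/k_cap + tau_CC ; tau_CC = 1/(k_esc+k_evo) + P_esc * tau_U
  p_esc <- k_esc / (k_esc + k_evo)
  tau_cc <- (1 / (k_esc + k_evo) + p_esc / k_cap) / (1 - p_esc)
  tau_u <- 1 / k_cap + tau_cc
  expect_equal(rs$fpt["U", "B"], tau_u, tolerance = 0.1)
  expect_equal(rs$fpt["U", "CC"], 1 / k_cap, tolerance = 0.05)
})

test_that("zero-count rates report 0 with a flag, not an error", {
  # trajectory that never binds
  st <- assign_states(rep(0, 100), rep(c(0, 2), 50), 11, 10)
  rs <- transition_stats(st)
  expect_equal(rs$k_evo, 0)
  expect_true(any(grepl("k_evo", rs$flags)))
  # no completed CC episode at all -> evolution_fraction errors
  st2 <- assign_states(rep(0, 10), rep(0, 10), 11, 10)
  expect_error(evolution_fraction(st2), "no completed")
})

test_that("half-split uncertainties are reported for the headline rates", {
  mk <- make_markov_trajectory(length_ns = 2000, frame_spacing_ns = 0.01,
                               seed = 13)
  st <- assign_states(mk$n_inter, mk$n_nonspec, mk$bound_threshold, 10)
  rs <- transition_stats(st)
  expect_named(rs$uncertainty, c("k_ts", "k_cap", "k_esc", "k_evo"))
  expect_true(all(is.finite(rs$uncertainty)))
})
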