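# Shared fixtures, built once per test run.  All are deterministic.

kB <- 0.0019872

toy <- make_toy_complex()
toy_resnames <- unlist(lapply(toy$structure$chains, function(c) c$resnames))
toy_contacts <- flavor_contacts(toy$contacts_truth, toy_resnames,
                                uniform_flavoring(), 1.0)
toy_topology <- build_topology(toy$structure, toy_contacts, cutoff = 20)

helix <- make_toy_helix(len = 16)
helix_resnames <- helix$structure$chains$A$resnames
helix_contacts <- flavor_contacts(helix$contacts_truth, helix_resnames,
                                  uniform_flavoring(), 1.0)
helix_topology <- build_topology(helix$structure, helix_contacts)

# a random perturbed configuration of the toy complex, reused by force checks
set.seed(7)
toy_perturbed <- toy_topology$coords +
  matrix(rnorm(nrow(toy_topology$coords) * 3, sd = 0.3),
         ncol = 3)

# independent brute-force episode statistics: a naive loop over frames,
# used as the oracle for transition_stats
naive_episode_rates <- function(labels, dt_ns) {
  ep_state <- character(0)
  ep_len <- integer(0)
  cur <- labels[1]
  len <- 1L
  for (k in 2:length(labels)) {
    if (labels[k] == cur) {
      len <- len + 1L
    } else {
      ep_state <- c(ep_state, cur)
      ep_len <- c(ep_len, len)
      # direct U<->B changes pass through a zero-length CC visit
      if ((cur == "U" && labels[k] == "B") ||
          (cur == "B" && labels[k] == "U")) {
        ep_state <- c(ep_state, "CC")
        ep_len <- c(ep_len, 0L)
      }
      cur <- labels[k]
      len <- 1L
    }
  }
  ep_state <- c(ep_state, cur)
  ep_len <- c(ep_len, len)
  ne <- length(ep_state)
  complete <- if (ne > 2) 2:(ne - 1) else integer(0)
  dur <- ep_len * dt_ns
  u_dur <- dur[complete][ep_state[complete] == "U" &
                           ep_state[complete + 1] == "CC"]
  cc_idx <- complete[ep_state[complete] == "CC"]
  n_esc <- sum(ep_state[cc_idx + 1] == "U")
  n_evo <- sum(ep_state[cc_idx + 1] == "B")
  t_cc <- sum(dur[cc_idx])
  red <- rle(ep_state[ep_state != "CC"])$values
  list(k_cap = if (length(u_dur)) 1 / mean(u_dur) else 0,
       k_esc = if (t_cc > 0) n_esc / t_cc else 0,
       k_evo = if (t_cc > 0) n_evo / t_cc else 0,
       n_ts = max(0L, length(red) - 1L),
       n_esc = n_esc, n_evo = n_evo)
}

# bootstrap standard errors of the collision-complex rates by resampling
# complete episodes
bootstrap_rate_se <- function(states, n_boot = 200, seed = 99) {
  ep <- states$episodes
  ne <- nrow(ep)
  complete <- if (ne > 2) 2:(ne - 1) else integer(0)
  u_dur <- ep$duration_ns[complete][ep$state[complete] == "U"]
  cc_idx <- complete[ep$state[complete] == "CC"]
  cc_dur <- ep$duration_ns[cc_idx]
  cc_out <- ep$state[cc_idx + 1]
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    iu <- sample(seq_along(u_dur), replace = TRUE)
    ic <- sample(seq_along(cc_dur), replace = TRUE)
    tcc <- sum(cc_dur[ic])
    c(k_cap = 1 / mean(u_dur[iu]),
      k_esc = sum(cc_out[ic] == "U") / tcc,
      k_evo = sum(cc_out[ic] == "B") / tcc)
  }, c(k_cap = 0, k_esc = 0, k_evo = 0))
  apply(reps, 1, sd)
}
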