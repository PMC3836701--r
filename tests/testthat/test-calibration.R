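test_that("residual helicity: native frames = 1, extended frames = 0", {
  native <- helix_topology$coords
  frames <- array(rep(native, each = 3), c(3, nrow(native), 3))
  h <- residual_helicity(frames, helix_topology)
  # interior helical residues (i >= 1 so the i-1 pseudo-dihedral exists)
  has_i4 <- helix_contacts$i[helix_contacts$j == helix_contacts$i + 4]
  interior <- setdiff(has_i4, 0)
  expect_true(all(h$helicity[h$residue %in% interior] == 1))
  expect_equal(h$helicity[h$residue == 0], 0)
  # fully extended chain: nothing helical
  ext <- cbind(0, 0, 3.8 * (seq_len(nrow(native)) - 1))
  h0 <- residual_helicity(array(ext, c(1, nrow(native), 3)), helix_topology)
  expect_true(all(h0$helicity == 0))
  # chains shorter than 5 are rejected
  short <- make_toy_helix(len = 5)
  tshort <- build_topology(short$structure,
                           flavor_contacts(short$contacts_truth,
                                           short$structure$chains$A$resnames,
                                           uniform_flavoring(), 1))
  tshort$particles <- tshort$particles[1:4, ]
  expect_error(residual_helicity(array(0, c(1, 4, 3)), tshort), "shorter")
})

test_that("helicity increases monotonically with the intramolecular scale", {
  cfg <- sim_config(timestep_fs = 15, friction = 0.1, temperature = 300,
                    box = 0, n_steps = 5e4, save_every = 100, seed = 5)
  hs <- vapply(c(0.3, 0.8, 1.4), function(lam) {
    tp <- scale_topology(helix_topology, lambda_intra = lam)
    tr <- run_langevin(tp, cfg)
    mean(residual_helicity(tr, tp)$helicity)
  }, 1.0)
  expect_true(all(diff(hs) > 0))
})

test_that("intramolecular calibration hits its target and flags over-stabilization", {
  cfg <- sim_config(timestep_fs = 15, friction = 0.1, temperature = 300,
                    box = 0, n_steps = 5e4, save_every = 100, seed = 5)
  cal <- calibrate_intra(helix_topology, target_helicity = 0.4, config = cfg)
  expect_lt(abs(cal$achieved - 0.4), 0.06)
  expect_true(cal$lambda_intra > 0.1 && cal$lambda_intra < 1.5)
  # the unscaled model over-stabilizes the helix relative to the target
  expect_gt(cal$lambda1_helicity, 0.4)
  # fixed point: targeting the lambda = 1 helicity returns lambda ~ 1
  cal1 <- calibrate_intra(helix_topology,
                          target_helicity = cal$lambda1_helicity,
                          config = cfg, tol = 0.05)
  expect_equal(cal1$lambda_intra, 1, tolerance = 0.35)
  # unreachable target errors with the bracket end helicities
  expect_error(calibrate_intra(helix_topology, target_helicity = 0.999,
                               config = cfg), "unreachable")
})

test_that("binding affinity decreases as the intermolecular scale grows", {
  cfg <- sim_config(timestep_fs = 15, friction = 0.1, temperature = 300,
                    box = 50, n_steps = 4e4, save_every = 100, seed = 7)
  lad <- rex_ladder(4, 280, 400)
  kds <- vapply(c(1.0, 1.8), function(lam) {
    tp <- scale_topology(toy_topology, lambda_inter = lam)
    rex <- run_rex(tp, cfg, lad, exchange_interval = 2000)
    wh <- wham(lapply(seq_along(lad), function(r) rex$epot[, r]), lad)
    inter <- tp$contacts[tp$contacts$class == "inter", ]
    ni <- unlist(lapply(seq_along(lad), function(r)
      native_contact_count(array(rex$frames[[r]], dim(rex$frames[[r]])),
                           inter, 50)))
    dissociation_constant(wh, ni, 50, 300)$kd
  }, 1.0)
  expect_gt(kds[1], kds[2])
})

test_that("intermolecular calibration reaches the target order of magnitude", {
  cfg <- sim_config(timestep_fs = 15, friction = 0.1, temperature = 300,
                    box = 50, n_steps = 4e4, save_every = 100, seed = 7)
  cal <- calibrate_inter(toy_topology, target_kd = 2e-3, config = cfg,
                         ladder = rex_ladder(4, 280, 400),
                         exchange_interval = 2000)
  expect_lte(abs(log10(cal$kd / 2e-3)), 1)
  expect_true(nrow(cal$trace) >= 1)
})

test_that("production runs are deterministic and report the state split", {
  tp <- scale_topology(toy_topology, lambda_inter = 1.6)
  cfg <- sim_config(timestep_fs = 15, friction = 0.1, temperature = 345,
                    box = 50, n_steps = 1e5, save_every = 100, seed = 9)
  p1 <- suppressWarnings(run_production(tp, t_m = 345, config = cfg,
                                        bound_threshold = 6))
  p2 <- suppressWarnings(run_production(tp, t_m = 345, config = cfg,
                                        bound_threshold = 6))
  expect_identical(p1$rates$k_ts, p2$rates$k_ts)
  expect_identical(p1$rates$counts, p2$rates$counts)
  expect_true(p1$bound_fraction >= 0 && p1$bound_fraction <= 1)
  # simulation defaults follow the production protocol
  def <- sim_config()
  expect_equal(def$timestep_fs, 15)
  expect_equal(def$friction, 0.1)
  expect_equal(sim_config()$box, 100)
})
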