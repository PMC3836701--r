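test_that("single-temperature WHAM gives uniform weights", {
  ts <- make_thermo_samples("harmonic", 300, n = 500, seed = 1)
  wh <- wham(ts$energies, 300)
  w <- wham_weights(wh, 300)
  expect_equal(w, rep(1 / 500, 500))
})

test_that("WHAM recovers harmonic-oscillator thermodynamics", {
  ts <- make_thermo_samples("harmonic", c(270, 300, 330), n = 5000,
                            seed = 2, n_modes = 3)
  wh <- wham(ts$energies, ts$temperatures)
  # reweighted mean energy at an intermediate temperature: k_B T/2 per mode
  for (tt in c(285, 315)) {
    expect_equal(wham_expectation(wh, wh$u, tt), 3 * 0.5 * kB * tt,
                 tolerance = 0.02)
  }
  # C_V = k_B/2 per mode, flat in T
  cv <- heat_capacity(wh, c(280, 300, 320))
  expect_equal(cv$cv, rep(1.5 * kB, 3), tolerance = 0.05)
  # weights at a sampled temperature reproduce that series' mean energy
  expect_equal(wham_expectation(wh, wh$u, 300),
               mean(ts$energies[[2]]), tolerance = 0.02)
  # empty grid
  expect_equal(nrow(heat_capacity(wh, numeric(0))), 0)
})

test_that("WHAM recovers two-level occupancies and the Schottky peak", {
  de <- 1.2; g1 <- 1  # non-degenerate gap: Schottky peak near de/(2.4 kB)
  ts <- make_thermo_samples("two-level", c(180, 250, 320), n = 8000,
                            seed = 3, delta_e = de, g0 = 1, g1 = g1)
  wh <- wham(ts$energies, ts$temperatures)
  lv <- unlist(ts$levels)
  closed <- function(tt) {
    b <- 1 / (kB * tt)
    g1 * exp(-b * de) / (1 + g1 * exp(-b * de))
  }
  for (tt in c(220, 290)) {
    expect_equal(wham_expectation(wh, lv, tt), closed(tt), tolerance = 0.03)
  }
  # Schottky anomaly: C_V peak at the analytic temperature within one step
  tg <- seq(190, 310, by = 2.5)
  cv <- heat_capacity(wh, tg)
  analytic_cv <- function(tt) {
    p <- closed(tt)
    de^2 * p * (1 - p) / (kB * tt^2)
  }
  t_star <- optimize(function(t) -analytic_cv(t), c(150, 350))$minimum
  expect_lt(abs(tg[which.max(cv$cv)] - t_star), 2 * 2.5 + 1e-9)
})

test_that("melting temperature: crossing matches the two-state closed form", {
  # two-level system calibrated so P(bound) = 0.5 at T* = 280 K
  de <- 1.5
  g1 <- exp(de / (kB * 280))  # Delta E = T* Delta S
  ts <- make_thermo_samples("two-level", c(240, 280, 320), n = 8000,
                            seed = 4, delta_e = de, g0 = 1, g1 = g1)
  wh <- wham(ts$energies, ts$temperatures)
  lv <- unlist(ts$levels)
  mt <- melting_temperature(wh, lv == 0, seq(245, 315, by = 1))
  expect_equal(mt$tm, 280, tolerance = 0.02)
  # degenerate indicator: no crossing is an error reporting the ends
  expect_error(melting_temperature(wh, rep(1, length(lv)),
                                   seq(245, 315, by = 5)),
               "does not cross")
})

test_that("effective concentration reproduces the printed box values", {
  expect_equal(signif(1000 * effective_concentration(100), 3), 1.66)
  expect_equal(signif(1000 * effective_concentration(105), 3), 1.43)
  expect_equal(effective_concentration(200),
               effective_concentration(100) / 8, tolerance = 1e-12)
})

test_that("dissociation constant: formula, recovery and limits", {
  # symmetric point: P_U = 0.5 in a 100 A box -> K_D = C_eff / 2
  n <- 20000
  set.seed(5)
  ni <- rbinom(n, 1, 0.5) * 12   # exactly two states: 0 or 12 contacts
  wh <- wham(list(rnorm(n, 10, 1)), 300)
  pu_hat <- mean(ni == 0)
  kd <- dissociation_constant(wh, ni, 100, 300)
  expect_equal(kd$kd, effective_concentration(100) * pu_hat^2 / (1 - pu_hat),
               tolerance = 1e-12)
  expect_equal(kd$kd, 0.5 * effective_concentration(100), tolerance = 0.05)
  # prescribed binding free energy recovered within sampling error
  dg <- 2.0  # kcal/mol, bound more stable
  ce <- effective_concentration(80)
  kd_true <- ce * exp(-dg / (kB * 300))  # from P_U^2/P_B = exp(-beta dG)
  pu <- uniroot(function(p) p^2 / (1 - p) - exp(-dg / (kB * 300)),
                c(1e-6, 1 - 1e-6))$root
  set.seed(6)
  ni2 <- ifelse(runif(n) < pu, 0L, 12L)
  kd2 <- dissociation_constant(wham(list(rnorm(n)), 300), ni2, 80, 300)
  expect_equal(kd2$kd, kd_true, tolerance = 0.1)
  # complement rule agrees for a barrier-less two-state series
  kd3 <- dissociation_constant(wham(list(rnorm(n)), 300), ni2, 80, 300,
                               unbound_rule = "complement",
                               bound_threshold = 6)
  expect_equal(kd3$kd, kd2$kd, tolerance = 1e-12)
  # degenerate probabilities are an error
  expect_error(dissociation_constant(wham(list(rnorm(100)), 300),
                                     rep(0, 100), 100),
               "unresolvable")
  # doubling the box volume halves C_eff and K_D at fixed probabilities
  kd_big <- dissociation_constant(wham(list(rnorm(n)), 300), ni2,
                                  80 * 2^(1 / 3), 300)
  expect_equal(kd_big$kd, kd2$kd / 2, tolerance = 1e-9)
})

test_that("free-energy surfaces: flat, Gaussian curvature, anchoring", {
  set.seed(7)
  n <- 40000
  wh <- wham(list(rnorm(n)), 300)
  # uniform samples give a flat surface
  fs_flat <- free_energy_surface(wh, runif(n), temperature = 300, bins = 10)
  expect_lt(max(fs_flat$f, na.rm = TRUE), 0.15)
  expect_equal(min(fs_flat$f, na.rm = TRUE), 0)
  # 2D Gaussian: F = r^2 / (2 sigma^2) in kT, curvature recoverable
  sigma <- 1.3
  x <- rnorm(n, sd = sigma); y <- rnorm(n, sd = sigma)
  edges <- seq(-5.2, 5.2, by = 0.4)  # spans 4 sigma: no edge clamping
  fs <- free_energy_surface(wh, pmax(pmin(x, 5), -5), pmax(pmin(y, 5), -5),
                            temperature = 300, bins = list(edges, edges))
  tab <- surface_table(fs)
  tab <- tab[!is.na(tab$f_kt) & tab$f_kt < 3, ]  # well-populated bins
  r2 <- tab$x^2 + tab$y^2
  fit <- lm(tab$f_kt ~ r2)
  expect_equal(unname(coef(fit)[2]), 1 / (2 * sigma^2), tolerance = 0.1)
  expect_equal(min(fs$f, na.rm = TRUE), 0)
  # duplication invariance (up to the anchor)
  wh2 <- wham(list(c(wh$u, wh$u)), 300)
  fs2 <- free_energy_surface(wh2, rep(pmax(pmin(x, 5), -5), 2),
                             rep(pmax(pmin(y, 5), -5), 2),
                             temperature = 300, bins = list(edges, edges))
  expect_equal(fs2$f, fs$f, tolerance = 1e-9)
})
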