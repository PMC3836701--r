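test_that("Debye length follows the closed form and its scalings", {
  expect_equal(debye_length(0.05, 300, 80), 13.68, tolerance = 0.01)
  expect_equal(debye_length(0.2, 300, 80), debye_length(0.05, 300, 80) / 2,
               tolerance = 1e-12)
  expect_equal(debye_length(0.05, 300, 160),
               debye_length(0.05, 300, 80) * sqrt(2), tolerance = 1e-12)
  expect_identical(debye_length(0), Inf)
})

test_that("Debye-Hueckel pair energy: Coulomb limit, shift, screening", {
  expect_equal(debye_huckel_pair(0, 1, 5), 0)
  # unscreened, unshifted Coulomb arithmetic: -332.0636 / (80 * 10)
  expect_equal(debye_huckel_pair(1, -1, 10, cutoff = Inf),
               -332.0636 / 800, tolerance = 1e-9)
  # shifted form vanishes at and beyond the cutoff
  expect_equal(debye_huckel_pair(1, -1, 25), 0)
  expect_equal(debye_huckel_pair(1, -1, 30), 0)
  # screening keeps the energy between the unscreened value and zero
  r <- seq(2, 24, by = 0.5)
  u0 <- debye_huckel_pair(1, -1, r, ionic_strength = 0)
  us <- debye_huckel_pair(1, -1, r, ionic_strength = 0.05)
  expect_true(all(abs(us) < abs(u0)))
  expect_true(all(us * u0 >= 0))
})

test_that("12-10 well has its minimum -eps at r_native", {
  expect_equal(native_contact_energy(6, 6, 1.7), -1.7)
  expect_lt(abs(native_contact_energy(1e5, 6, 1.7)), 1e-20)
  h <- 1e-6
  deriv <- (native_contact_energy(6 + h, 6, 1.7) -
              native_contact_energy(6 - h, 6, 1.7)) / (2 * h)
  expect_lt(abs(deriv), 1e-6)
  expect_gt(native_contact_energy(4, 6, 1.7), 0)  # repulsive core
})

test_that("potential energy breakdown sums and is translation invariant", {
  e <- potential_energy(toy_topology, toy_perturbed, forces = TRUE)
  b <- e$breakdown
  expect_equal(b[["total"]],
               sum(b[setdiff(names(b), "total")]), tolerance = 1e-9)
  shifted <- potential_energy(toy_topology, toy_perturbed + 13.7)
  expect_equal(shifted$breakdown[["total"]], b[["total"]], tolerance = 1e-9)
  # rotation invariance for an isolated (non-wrapped) configuration
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- potential_energy(toy_topology, toy_perturbed %*% rot)
  expect_equal(rotated$breakdown[["total"]], b[["total"]], tolerance = 1e-8)
  # PBC translation invariance across the boundary
  box <- 50
  e1 <- potential_energy(toy_topology, toy_perturbed, box = box)
  e2 <- potential_energy(toy_topology, toy_perturbed + box, box = box)
  expect_equal(e1$breakdown[["total"]], e2$breakdown[["total"]],
               tolerance = 1e-9)
})

test_that("native structure minimizes the Go terms", {
  # build the topology from the builder's own contact scan so native
  # distances are self-consistent with the (PDB-precision) coordinates
  ct <- identify_native_contacts(toy$structure, cutoff = 6.5)
  ct <- flavor_contacts(ct, toy_resnames, uniform_flavoring(), 1.0)
  topo0 <- build_topology(toy$structure, ct, cutoff = 20)
  topo0$eps_rep <- 0  # the excluded-volume tail is not referenced to native
  e0 <- potential_energy(topo0, forces = TRUE)
  # contacts + angles + dihedrals are at their joint minimum at native
  expect_lt(max(abs(e0$forces)), 1e-4)
  # equal to -sum(eps) up to the small cutoff shift of each well
  expect_equal(e0$breakdown[["contact_intra"]],
               -sum(ct$eps[ct$class != "inter"]), tolerance = 1e-4)
})

test_that("analytic forces are the exact negative gradient", {
  ef <- potential_energy(toy_topology, toy_perturbed, forces = TRUE)
  fn <- numerical_forces(toy_topology, toy_perturbed)
  expect_lt(max(abs(ef$forces - fn)), 1e-5)
  # charged model too (Debye-Hueckel term included)
  tq <- assign_charges(toy_topology, "explicit")
  tq$ionic_strength <- 0.05
  eq <- potential_energy(tq, toy_perturbed, forces = TRUE)
  fq <- numerical_forces(tq, toy_perturbed)
  expect_lt(max(abs(eq$forces - fq)), 1e-5)
})

test_that("zeroed charges reproduce the uncharged model term by term", {
  tq <- assign_charges(toy_topology, "explicit")
  tq$particles$charge[] <- 0
  e1 <- potential_energy(toy_topology, toy_perturbed)$breakdown
  e2 <- potential_energy(tq, toy_perturbed)$breakdown
  expect_equal(e1, e2)
  # and the electrostatic term is identically zero
  expect_equal(e2[["electrostatic"]], 0)
})

test_that("overlapping particles are rejected", {
  x <- toy_topology$coords
  x[2, ] <- x[5, ]
  expect_error(potential_energy(toy_topology, x), "overlap")
})
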