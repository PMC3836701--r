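test_that("contact formation uses the 1.0 A native-distance tolerance", {
  expect_true(contact_formed(7.9, 7.0))
  expect_false(contact_formed(8.1, 7.0))
  expect_true(contact_formed(7.0, 7.0))
  expect_true(contact_formed(6.0, 7.0))
  expect_false(contact_formed(5.9, 7.0))
})

test_that("native-contact fractions match brute force and the native frame", {
  native <- toy_topology$coords
  inter <- toy_contacts[toy_contacts$class == "inter", ]
  intra_a <- toy_contacts[toy_contacts$class == "intra_A", ]
  expect_equal(fraction_native(native, inter), 1)
  expect_equal(fraction_native(native, intra_a), 1)
  expect_equal(fraction_native(native, toy_contacts), 1)
  # chains separated by 60 A: Q_inter = 0
  apart <- native
  apart[21:32, 1] <- apart[21:32, 1] + 60
  expect_equal(fraction_native(apart, inter), 0)
  # random frames: brute-force per-contact evaluation
  set.seed(11)
  frames <- array(rep(native, each = 5), c(5, nrow(native), 3)) +
    array(rnorm(5 * nrow(native) * 3, sd = 1.5), c(5, nrow(native), 3))
  q <- fraction_native(frames, toy_contacts, box = 50)
  brute <- vapply(1:5, function(f) {
    x <- matrix(frames[f, , ], ncol = 3)
    formed <- 0
    for (k in seq_len(nrow(toy_contacts))) {
      d <- x[toy_contacts$i[k] + 1, ] - x[toy_contacts$j[k] + 1, ]
      d <- d - 50 * round(d / 50)
      if (abs(sqrt(sum(d^2)) - toy_contacts$r_native[k]) <= 1)
        formed <- formed + 1
    }
    formed / nrow(toy_contacts)
  }, 1.0)
  expect_equal(q, brute)
  expect_error(fraction_native(native, toy_contacts[0, ]), "empty")
})

test_that("Q is non-increasing when the tolerance is tightened", {
  set.seed(12)
  frames <- array(rep(toy_topology$coords, each = 8),
                  c(8, nrow(toy_topology$coords), 3)) +
    array(rnorm(8 * 32 * 3, sd = 1), c(8, 32, 3))
  q_tight <- fraction_native(frames, toy_contacts, tol = 0.5)
  q_wide <- fraction_native(frames, toy_contacts, tol = 1.0)
  expect_true(all(q_tight <= q_wide))
})

test_that("Q over a contact union is the size-weighted mean of subsets", {
  set.seed(13)
  frames <- array(rep(toy_topology$coords, each = 4), c(4, 32, 3)) +
    array(rnorm(4 * 32 * 3, sd = 1), c(4, 32, 3))
  sub_a <- toy_contacts[toy_contacts$class == "intra_A", ]
  sub_b <- toy_contacts[toy_contacts$class == "intra_B", ]
  both <- rbind(sub_a, sub_b)
  qu <- fraction_native(frames, both)
  qa <- fraction_native(frames, sub_a)
  qb <- fraction_native(frames, sub_b)
  expect_equal(qu, (nrow(sub_a) * qa + nrow(sub_b) * qb) / nrow(both))
})

test_that("nonspecific contact counts follow the 10 A cutoff", {
  # hand-placed pair: 9.9 A counts, 10.1 A does not
  x <- rbind(c(0, 0, 0), c(9.9, 0, 0))
  expect_equal(nonspecific_contacts(x, 1, 2), 1L)
  x[2, 1] <- 10.1
  expect_equal(nonspecific_contacts(x, 1, 2), 0L)
  # far-separated chains
  apart <- toy_topology$coords
  apart[21:32, 1] <- apart[21:32, 1] + 80
  expect_equal(nonspecific_contacts(apart, 1:20, 21:32), 0L)
  # brute-force oracle on a random frame, with native pairs excluded
  set.seed(14)
  x <- toy_topology$coords + matrix(rnorm(96, sd = 2), ncol = 3)
  inter <- toy_contacts[toy_contacts$class == "inter", ]
  got <- nonspecific_contacts(x, 1:20, 21:32, box = 50,
                              exclude_native = inter)
  nat_key <- paste(inter$i, inter$j)
  cnt <- 0
  for (a in 1:20) for (b in 21:32) {
    if (paste(a - 1, b - 1) %in% nat_key) next
    d <- x[a, ] - x[b, ]
    d <- d - 50 * round(d / 50)
    if (sqrt(sum(d^2)) <= 10) cnt <- cnt + 1
  }
  expect_equal(got, as.integer(cnt))
})

test_that("binding RMSD: identity, displacement and rigid-motion invariance", {
  native <- toy_topology$coords
  expect_equal(binding_rmsd(native, native, 1:20, 21:32), 0, tolerance = 1e-9)
  # rigidly translate the IDP by 5 A: after perfect substrate alignment
  # the binding RMSD is exactly 5
  moved <- native
  moved[21:32, ] <- moved[21:32, ] + matrix(c(3, 4, 0), 12, 3, byrow = TRUE)
  expect_equal(binding_rmsd(moved, native, 1:20, 21:32), 5, tolerance = 1e-9)
  # whole-complex rigid transform leaves the binding RMSD unchanged
  th <- 0.9
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rigid <- moved %*% rot + matrix(c(10, -5, 3), 32, 3, byrow = TRUE)
  expect_equal(binding_rmsd(rigid, native, 1:20, 21:32), 5, tolerance = 1e-9)
  expect_error(binding_rmsd(native, native, 1:2, 21:32), "3 alignment")
})

test_that("center-of-mass separation: arithmetic and the PBC bound", {
  x <- rbind(c(0, 0, 0), c(0, 0, 0), c(25, 0, 0), c(25, 0, 0))
  expect_equal(center_separation(x, 1:2, 3:4, box = 100), 25)
  expect_equal(center_separation(x, 1:2, 1:2), 0)
  # under minimum image the separation never exceeds edge * sqrt(3) / 2
  set.seed(15)
  for (rep in 1:20) {
    y <- matrix(runif(12, 0, 300), 4, 3)
    expect_lte(center_separation(y, 1:2, 3:4, box = 40), 40 * sqrt(3) / 2)
  }
})

test_that("observables are invariant under periodic wrapping", {
  set.seed(16)
  x <- toy_topology$coords + matrix(rnorm(96, sd = 1), ncol = 3)
  box <- 50
  wrapped <- x - box * floor(x / box)
  expect_equal(fraction_native(x, toy_contacts, box),
               fraction_native(wrapped, toy_contacts, box))
  expect_equal(nonspecific_contacts(x, 1:20, 21:32, box),
               nonspecific_contacts(wrapped, 1:20, 21:32, box))
  expect_equal(center_separation(x, 1:20, 21:32, box),
               center_separation(wrapped, 1:20, 21:32, box),
               tolerance = 1e-9)
})

test_that("contact probability maps recover planted frequencies", {
  native <- toy_topology$coords
  apart <- native
  apart[21:32, 1] <- apart[21:32, 1] + 80
  # single frame: probabilities are 0 or 1
  m1 <- contact_probability_map(native, 1:20, 21:32)
  expect_true(all(m1$probability %in% c(0, 1)))
  # all-far ensemble: all zeros
  m0 <- contact_probability_map(apart, 1:20, 21:32)
  expect_true(all(m0$probability == 0))
  # planted ensemble: 3 bound frames out of 10 -> contact residues at 0.3
  frames <- array(NA_real_, c(10, 32, 3))
  for (f in 1:10) frames[f, , ] <- if (f <= 3) native else apart
  mm <- contact_probability_map(frames, 1:20, 21:32)
  expect_equal(sort(unique(mm$probability)), c(0, 0.3))
  expect_equal(mm$probability[mm$probability > 0],
               0.3 * m1$probability[m1$probability > 0])
})
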