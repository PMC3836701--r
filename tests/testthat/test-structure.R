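test_that("PDB round trip preserves chains, residues and coordinates", {
  st <- toy$structure
  expect_length(st$chains, 2)
  expect_equal(vapply(st$chains, function(c) length(c$resnames), 1L),
               c(A = 20L, B = 12L))
  # coordinates survive PDB formatting to 3 decimals
  reloaded <- load_complex(paste(toy$pdb, collapse = "\n"), c("A", "B"))
  expect_equal(all_ca(reloaded), all_ca(st), tolerance = 1e-8)
  # a 5-residue single-chain fixture
  tiny <- make_toy_helix(len = 5)
  expect_length(tiny$structure$chains, 1)
  expect_equal(nrow(tiny$structure$chains$A$ca), 5)
})

test_that("loader rejects malformed input", {
  bad <- toy$pdb
  ca_a <- which(grepl(" CA ", bad) & substr(bad, 22, 22) == "A")
  bad <- bad[-ca_a[2]]  # drop the CA of chain A residue 2
  expect_error(load_complex(paste(bad, collapse = "\n"), c("A", "B")),
               "CA")
  unk <- sub("ALA", "XYZ", toy$pdb[1])
  expect_error(load_complex(paste(c(unk, toy$pdb[-1]), collapse = "\n"),
                            c("A", "B")),
               "unknown residue")
  expect_error(load_complex(paste(toy$pdb, collapse = "\n"), c("A", "Q")),
               "not present")
})

test_that("native contacts equal the brute-force enumeration", {
  ct <- identify_native_contacts(toy$structure,
                                 cutoff = toy$criterion$cutoff,
                                 min_seq_sep = toy$criterion$min_seq_sep)
  tr <- toy$contacts_truth
  expect_equal(paste(ct$i, ct$j, ct$class), paste(tr$i, tr$j, tr$class))
  expect_equal(ct$r_native, tr$r_native, tolerance = 1e-3)
  # far-separated chains share no intermolecular contacts
  far <- make_toy_complex(separation = 60)
  expect_equal(sum(far$contacts_truth$class == "inter"), 0)
  ctf <- identify_native_contacts(far$structure, cutoff = 6.5)
  expect_equal(sum(ctf$class == "inter"), 0)
  # classes partition; no duplicate pairs
  expect_false(any(duplicated(ct[, c("i", "j")])))
  # intramolecular sequence separation respected
  intra <- ct[ct$class != "inter", ]
  expect_true(all(intra$j - intra$i >= 3))
})

test_that("contact identification is symmetric in chain order", {
  fwd <- identify_native_contacts(load_complex(paste(toy$pdb, collapse = "\n"),
                                               c("A", "B")), cutoff = 6.5)
  rev <- identify_native_contacts(load_complex(paste(toy$pdb, collapse = "\n"),
                                               c("B", "A")), cutoff = 6.5)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sum(fwd$class == "inter"), sum(rev$class == "inter"))
  # permute reversed indices back to forward numbering and compare sets
  n_a <- 20; n_b <- 12
  remap <- function(i) ifelse(i < n_b, i + n_a, i - n_b)
  key_rev <- apply(cbind(remap(rev$i), remap(rev$j)), 1,
                   function(p) paste(sort(p), collapse = "-"))
  key_fwd <- paste(fwd$i, fwd$j, sep = "-")
  expect_setequal(key_rev, key_fwd)
})

test_that("flavoring sets well depths with the stated normalization", {
  ct <- toy$contacts_truth
  u <- flavor_contacts(ct, toy_resnames, uniform_flavoring(), 1.3)
  expect_true(all(u$eps == 1.3))
  z <- flavor_contacts(ct, toy_resnames, uniform_flavoring(), 0)
  expect_true(all(z$eps == 0))
  d <- flavor_contacts(ct, toy_resnames, default_flavoring(), 0.7)
  expect_equal(mean(d$eps), 0.7, tolerance = 1e-9)
  expect_true(all(d$eps > 0))
  m <- default_flavoring()$matrix
  expect_equal(m, t(m))
  bad_names <- toy_resnames
  bad_names[3] <- "XXX"
  expect_error(flavor_contacts(ct, bad_names, default_flavoring()), "XXX")
})

test_that("charge assignment follows the K/R/D/E (+zinc) convention", {
  tp <- assign_charges(toy_topology, "explicit")
  q <- tp$particles$charge
  nm <- tp$particles$name
  expect_true(all(q[nm %in% c("LYS", "ARG")] == 1))
  expect_true(all(q[nm %in% c("ASP", "GLU")] == -1))
  expect_true(all(q[!nm %in% c("LYS", "ARG", "ASP", "GLU", "ZN")] == 0))
  expect_equal(assign_charges(tp, "none")$particles$charge, rep(0, length(q)))
  # K-R-D-E peptide: charges (+1, +1, -1, -1), net 0
  krde <- make_toy_helix(len = 8, seq = "KRDE")
  tk <- assign_charges(build_topology(krde$structure,
                                      flavor_contacts(krde$contacts_truth,
                                                      krde$structure$chains$A$resnames,
                                                      uniform_flavoring(), 1)),
                       "explicit")
  expect_equal(tk$particles$charge, rep(c(1, 1, -1, -1), 2))
  expect_equal(sum(tk$particles$charge), 0)
  # poly-Gly: no charges in either mode
  gg <- make_toy_helix(len = 8, seq = "G")
  tg <- assign_charges(build_topology(gg$structure,
                                      flavor_contacts(gg$contacts_truth, rep("GLY", 8),
                                                      uniform_flavoring(), 1)),
                       "explicit")
  expect_true(all(tg$particles$charge == 0))
  # zinc carries +2
  zn <- make_toy_complex(add_zinc = TRUE)
  tz <- build_topology(zn$structure,
                       flavor_contacts(zn$contacts_truth,
                                       unlist(lapply(zn$structure$chains,
                                                     function(c) c$resnames)),
                                       uniform_flavoring(), 1),
                       charge_mode = "explicit")
  expect_equal(tz$particles$charge[tz$particles$name == "ZN"], 2)
})

test_that("topology scaling is multiplicative, composable and invertible", {
  t1 <- scale_topology(toy_topology, 1, 1)
  expect_equal(t1$contacts$eps, toy_topology$contacts$eps)
  t2 <- scale_topology(scale_topology(toy_topology, 0.5, 1), 0.5, 1)
  intra <- toy_topology$contacts$class != "inter"
  expect_equal(t2$contacts$eps[intra], 0.25 * toy_topology$contacts$eps[intra])
  expect_equal(t2$contacts$eps[!intra], toy_topology$contacts$eps[!intra])
  t3 <- scale_topology(scale_topology(toy_topology, 2, 3), 0.5, 1 / 3)
  expect_equal(t3$contacts$eps, toy_topology$contacts$eps, tolerance = 1e-12)
  expect_error(scale_topology(toy_topology, -1, 1), "positive")
  # charges never alter bonded or contact parameters
  tq <- assign_charges(toy_topology, "explicit")
  expect_equal(tq$contacts, toy_topology$contacts)
  expect_equal(tq$bonds, toy_topology$bonds)
})

test_that("model files round-trip through YAML", {
  path <- tempfile(fileext = ".yml")
  tp <- assign_charges(scale_topology(toy_topology, 0.8, 1.7), "explicit")
  write_topology(tp, path)
  back <- read_topology(path)
  expect_equal(back$contacts$eps, tp$contacts$eps, tolerance = 1e-10)
  expect_equal(back$particles$charge, tp$particles$charge)
  expect_equal(back$coords, tp$coords, tolerance = 1e-10)
  expect_equal(back$lambda_inter, 1.7)
  expect_equal(back$charge_mode, "explicit")
  unlink(path)
})
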