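# Synthetic fixtures: every stage of the pipeline can be built and tested
# without external data.  Toy complexes are ideal-geometry Ca (+ dummy CB)
# two-chain structures with known contacts and charges; Markov trajectories
# carry known transition rates; thermo samples come from models with
# closed-form thermodynamics.

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# ideal alpha-helix CA trace: radius 2.3 A, rise 1.5 A, 100 deg/residue
helix_ca <- function(n, phase = 0) {
  t <- seq_len(n) - 1
  ang <- phase + t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

# dummy side-chain bead radially outward from the helix axis
helix_cb <- function(ca, axis_xy = c(0, 0)) {
  rad <- cbind(ca[, 1] - axis_xy[1], ca[, 2] - axis_xy[2], 0)
  rad <- rad / sqrt(rowSums(rad^2))
  ca + 1.5 * rad
}

format_atom <- function(serial, name, resname, chain, resno, xyz,
                        record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), resname, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.0, 0.0,
          substr(name, 1, 1))
}

#' Generate a toy two-chain helical complex with known ground truth
#'
#' Chain A (the "substrate") and chain B (the "IDP") are ideal alpha
#' helices packed side by side at the given axis separation, each residue
#' carrying a C-alpha and (except glycine) a dummy outward-pointing CB bead
#' so heavy-atom contact criteria and SASA are exercisable.  Default
#' sequences give chain A a positively charged face and chain B a negative
#' net charge, emulating the charge complementarity of IDP binding
#' interfaces.  The generator returns its own ground truth: the contact set
#' from a brute-force all-pairs scan at the stated criterion and the
#' per-residue charge table.
#'
#' @param len_a,len_b chain lengths (>= 5).
#' @param seq_a,seq_b 1-letter sequences (recycled to length); defaults
#'   `"ALKA"` / `"LADE"` patterns.
#' @param separation helix-axis separation, Angstrom.
#' @param contact_cutoff heavy-atom contact cutoff (Angstrom) used for the
#'   ground-truth scan; the CA/CB toy geometry is coarser than a real
#'   all-atom structure, so the default is looser than the all-atom 4.5.
#' @param min_seq_sep minimum intramolecular sequence separation.
#' @param add_zinc also emit one zinc site near chain A's midpoint.
#' @param jitter Gaussian positional noise (Angstrom), seeded.
#' @param seed integer seed (matters only when `jitter > 0`).
#' @return list with `pdb` (PDB text lines), `structure` (the parsed
#'   `ComplexStructure`), `contacts_truth` (brute-force contact table),
#'   `charges_truth` (per-residue data frame), `criterion`.
#' @export
make_toy_complex <- function(len_a = 20, len_b = 12, seq_a = NULL,
                             seq_b = NULL, separation = 10,
                             contact_cutoff = 6.5, min_seq_sep = 3,
                             add_zinc = FALSE, jitter = 0, seed = 1) {
  stopifnot(len_a >= 5, len_b >= 5)
  expand_seq <- function(s, n, default) {
    if (is.null(s)) s <- default
    s1 <- strsplit(s, "")[[1]]
    .aa1to3[rep(s1, length.out = n)]
  }
  rn_a <- unname(expand_seq(seq_a, len_a, "ALKA"))
  rn_b <- unname(expand_seq(seq_b, len_b, "LADE"))

  ca_a <- helix_ca(len_a)
  # chain B: parallel helix, phase pi so its face points back at chain A,
  # z-centred against chain A
  ca_b <- helix_ca(len_b, phase = pi)
  ca_b[, 1] <- separation - (ca_b[, 1])      # mirror about the midplane
  ca_b[, 2] <- -ca_b[, 2]
  ca_b[, 3] <- ca_b[, 3] + (max(ca_a[, 3]) - max(ca_b[, 3])) / 2
  if (jitter > 0) {
    set.seed(seed)
    ca_a <- ca_a + matrix(rnorm(3 * len_a, sd = jitter), len_a, 3)
    ca_b <- ca_b + matrix(rnorm(3 * len_b, sd = jitter), len_b, 3)
  }
  cb_a <- helix_cb(ca_a, c(0, 0))
  cb_b <- helix_cb(ca_b, c(separation, 0))

  lines <- character(0)
  serial <- 0
  emit_chain <- function(ca, cb, rn, chain) {
    out <- character(0)
    for (k in seq_len(nrow(ca))) {
      serial <<- serial + 1
      out <- c(out, format_atom(serial, "CA", rn[k], chain, k, ca[k, ]))
      if (rn[k] != "GLY") {
        serial <<- serial + 1
        out <- c(out, format_atom(serial, "CB", rn[k], chain, k, cb[k, ]))
      }
    }
    out
  }
  lines <- c(emit_chain(ca_a, cb_a, rn_a, "A"),
             emit_chain(ca_b, cb_b, rn_b, "B"))
  zn_xyz <- NULL
  if (add_zinc) {
    mid <- round(len_a / 2)
    zn_xyz <- colMeans(ca_a[c(mid, mid + 3), ]) + c(-4, 0, 0)
    serial <- serial + 1
    lines <- c(lines,
               sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       "HETATM", serial, " ZN", "ZN", "Z", 1,
                       zn_xyz[1], zn_xyz[2], zn_xyz[3], 1.0, 0.0, "ZN"))
  }
  lines <- c(lines, "END")

  st <- load_complex(paste(lines, collapse = "\n"), c("A", "B"))
  # ground truth by brute-force all-pairs scan over the generator's own
  # atom coordinates
  atoms <- rbind(
    data.frame(res = seq_len(len_a) - 1L, x = ca_a[, 1], y = ca_a[, 2],
               z = ca_a[, 3]),
    data.frame(res = seq_len(len_a) - 1L, x = cb_a[, 1], y = cb_a[, 2],
               z = cb_a[, 3])[rn_a != "GLY", ],
    data.frame(res = len_a + seq_len(len_b) - 1L, x = ca_b[, 1],
               y = ca_b[, 2], z = ca_b[, 3]),
    data.frame(res = len_a + seq_len(len_b) - 1L, x = cb_b[, 1],
               y = cb_b[, 2], z = cb_b[, 3])[rn_b != "GLY", ])
  ca_all <- rbind(ca_a, ca_b)
  truth <- list()
  for (p in seq_len(nrow(atoms) - 1)) {
    for (q in (p + 1):nrow(atoms)) {
      ri <- atoms$res[p]; rj <- atoms$res[q]
      if (ri >= rj) next
      same <- (ri < len_a) == (rj < len_a)
      if (same && rj - ri < min_seq_sep) next
      d <- sqrt((atoms$x[p] - atoms$x[q])^2 + (atoms$y[p] - atoms$y[q])^2 +
                  (atoms$z[p] - atoms$z[q])^2)
      if (d <= contact_cutoff) {
        key <- paste(ri, rj)
        if (is.null(truth[[key]]))
          truth[[key]] <- data.frame(
            i = ri, j = rj,
            r_native = sqrt(sum((ca_all[ri + 1, ] - ca_all[rj + 1, ])^2)),
            eps = NA_real_,
            class = if (!same) "inter"
                    else if (ri < len_a) "intra_A" else "intra_B",
            stringsAsFactors = FALSE)
      }
    }
  }
  contacts_truth <- do.call(rbind, unname(truth))
  contacts_truth <- contacts_truth[order(contacts_truth$i, contacts_truth$j), ]
  rownames(contacts_truth) <- NULL
  class(contacts_truth) <- c("contact_table", "data.frame")
  resn <- c(rn_a, rn_b)
  charges_truth <- data.frame(
    residue = seq_along(resn) - 1L, name = resn,
    chain = rep(c("A", "B"), c(len_a, len_b)),
    charge = unname(.aa_charge[resn]), stringsAsFactors = FALSE)
  list(pdb = lines, structure = st, contacts_truth = contacts_truth,
       charges_truth = charges_truth, zinc = zn_xyz,
       criterion = list(cutoff = contact_cutoff, min_seq_sep = min_seq_sep))
}

#' Generate a single-chain toy helix (for calibration tests)
#'
#' @inheritParams make_toy_complex
#' @param len chain length.
#' @param seq 1-letter sequence pattern.
#' @return same layout as [make_toy_complex()] but single-chain.
#' @export
make_toy_helix <- function(len = 16, seq = "ALKA", contact_cutoff = 6.5,
                           min_seq_sep = 3) {
  full <- make_toy_complex(len_a = len, len_b = 5, seq_a = seq,
                           separation = 60,  # partner far away: no inter
                           contact_cutoff = contact_cutoff,
                           min_seq_sep = min_seq_sep)
  st <- load_complex(paste(full$pdb, collapse = "\n"), "A")
  ct <- full$contacts_truth
  ct <- ct[ct$class == "intra_A", , drop = FALSE]
  rownames(ct) <- NULL
  list(pdb = full$pdb, structure = st, contacts_truth = ct,
       charges_truth = full$charges_truth[full$charges_truth$chain == "A", ],
       criterion = full$criterion)
}

#' Minimal two-particle system bound by a single harmonic pair potential
#'
#' Two free beads (no bonds, angles, or dihedrals) joined by one harmonic
#' distance restraint -- the simplest system whose separation distribution
#' has a closed Boltzmann form `P(r) propto r^2 exp(-beta k (r - r0)^2)`,
#' used to validate the Langevin sampler.
#'
#' @param r0 rest separation, Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @param mass bead mass, Da.
#' @return a `GoTopology` with two particles at separation `r0`.
#' @export
make_pair_system <- function(r0 = 8, k = 2, mass = 110) {
  structure(list(
    particles = data.frame(name = c("ALA", "ALA"), chain = c("A", "B"),
                           mass = mass, charge = 0,
                           stringsAsFactors = FALSE),
    coords = rbind(c(0, 0, 0), c(r0, 0, 0)),
    bonds = NULL, angles = NULL, dihedrals = NULL,
    contacts = empty_contacts(),
    restraints = data.frame(i = 0L, j = 1L, r0 = r0, k = k),
    sigma_rep = 0.0, eps_rep = 0.0,
    k_angle = 0, k_dih1 = 0, k_dih3 = 0, k_bond = 0,
    lambda_intra = 1, lambda_inter = 1, charge_mode = "none",
    epsilon_r = 80, ionic_strength = 0, elec_temperature = 300,
    cutoff = 1e6,
    provenance = list(source = "synthetic pair system")),
    class = "GoTopology")
}

#' Simulate a synthetic three-state Markov trajectory with known rates
#'
#' Gillespie simulation of the continuous-time chain
#' `U <-> CC <-> B` with the supplied rates (1/ns), discretized at the
#' frame spacing.  Also emits native / nonspecific contact-count series
#' consistent with the state labels (bound frames above the threshold,
#' collision frames with nonspecific contacts only), so the full
#' `assign_states -> transition_stats` path can be exercised against the
#' generator's rate matrix.
#'
#' @param k_cap,k_esc,k_evo,k_unbind rates in 1/ns: U->CC, CC->U, CC->B,
#'   B->CC.
#' @param length_ns trajectory length, ns.
#' @param frame_spacing_ns frame spacing, ns.
#' @param bound_threshold native-contact count defining the bound state.
#' @param seed integer seed.
#' @return list with `states_true` (per-frame "U"/"CC"/"B"), `n_inter`,
#'   `n_nonspec`, `time_ns`, `rates` (the generator's rate matrix), and the
#'   raw jump chain (`jump_times`, `jump_states`).
#' @export
make_markov_trajectory <- function(k_cap = 1.0, k_esc = 5.0, k_evo = 0.5,
                                   k_unbind = 0.5, length_ns = 1e4,
                                   frame_spacing_ns = 0.1,
                                   bound_threshold = 10, seed = 1) {
  q <- matrix(0, 3, 3, dimnames = list(c("U", "CC", "B"), c("U", "CC", "B")))
  q["U", "CC"] <- k_cap
  q["CC", "U"] <- k_esc
  q["CC", "B"] <- k_evo
  q["B", "CC"] <- k_unbind
  jump <- cpp_gillespie(q, length_ns, 0L, as.integer(seed))
  tgrid <- seq(frame_spacing_ns, length_ns, by = frame_spacing_ns)
  idx <- findInterval(tgrid, jump$times)
  st <- c("U", "CC", "B")[jump$states[idx] + 1]
  set.seed(seed)
  nf <- length(st)
  n_inter <- integer(nf)
  n_nonspec <- integer(nf)
  is_cc <- st == "CC"
  is_b <- st == "B"
  n_nonspec[is_cc] <- sample(1:5, sum(is_cc), replace = TRUE)
  n_inter[is_b] <- bound_threshold + sample(0:5, sum(is_b), replace = TRUE)
  n_nonspec[is_b] <- sample(3:10, sum(is_b), replace = TRUE)
  list(states_true = st, n_inter = n_inter, n_nonspec = n_nonspec,
       time_ns = tgrid, rates = q, bound_threshold = bound_threshold,
       jump_times = jump$times, jump_states = jump$states)
}

#' Exact Boltzmann samples from models with closed-form thermodynamics
#'
#' `"harmonic"`: `n_modes` independent harmonic modes; the potential energy
#' at temperature T is `(k_B T / 2) * chi^2(n_modes)`, so `<U> = n_modes
#' k_B T / 2` and `C_V = n_modes k_B / 2`.  `"two-level"`: levels 0 and
#' `delta_e` with degeneracies `g0`, `g1`; occupancy follows the two-state
#' closed form and `C_V` has a Schottky peak.
#'
#' @param model `"harmonic"` or `"two-level"`.
#' @param temperatures numeric vector, K.
#' @param n samples per temperature (>= 100).
#' @param seed integer seed.
#' @param n_modes number of harmonic modes.
#' @param delta_e two-level gap, kcal/mol.
#' @param g0,g1 degeneracies.
#' @return list with `energies` (list per temperature), `temperatures`,
#'   and for the two-level model `levels` (list of 0/1 indicators).
#' @export
make_thermo_samples <- function(model = c("harmonic", "two-level"),
                                temperatures, n = 1000, seed = 1,
                                n_modes = 1, delta_e = 2, g0 = 1, g1 = 1) {
  model <- match.arg(model)
  stopifnot(n >= 100)
  set.seed(seed)
  if (model == "harmonic") {
    energies <- lapply(temperatures, function(tt)
      0.5 * .kB * tt * stats::rchisq(n, df = n_modes))
    list(energies = energies, temperatures = temperatures, model = model,
         n_modes = n_modes)
  } else {
    levels <- lapply(temperatures, function(tt) {
      p1 <- g1 * exp(-delta_e / (.kB * tt)) /
        (g0 + g1 * exp(-delta_e / (.kB * tt)))
      rbinom(n, 1, p1)
    })
    energies <- lapply(levels, function(l) l * delta_e)
    list(energies = energies, temperatures = temperatures, model = model,
         levels = levels, delta_e = delta_e, g0 = g0, g1 = g1)
  }
}
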