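#' Load a protein-protein complex structure from a PDB file
#'
#' Reads a PDB entry (ATOM/HETATM records; the first MODEL of a multi-model
#' NMR entry) and returns a `ComplexStructure`: the selected chains in
#' selection order with per-residue C-alpha coordinates and, when present,
#' all-atom records and hetero zinc sites with their coordinating residues.
#'
#' Residues are renumbered contiguously from 0 within each chain; a global
#' 0-based index, contiguous across chains in selection order, is used by all
#' downstream topology operations.
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB-format
#'   lines (anything containing a newline or of length > 1 is treated as
#'   text).
#' @param chain_selection character vector of chain identifiers; chains are
#'   returned in this order.
#' @param zinc_coord_cutoff heavy-atom distance (Angstrom) within which a
#'   residue is considered to coordinate a zinc ion.
#' @return an object of class `ComplexStructure`: list with `chains` (each
#'   with `id`, `resnames`, `ca` m x 3 matrix, `atoms` data frame or NULL)
#'   and `zinc` (data frame of sites with coordinates and coordinating
#'   residue global indices).
#' @export
load_complex <- function(pdb_source, chain_selection,
                         zinc_coord_cutoff = 3.0) {
  is_text <- length(pdb_source) > 1 || grepl("\n", pdb_source[1]) ||
    grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER)", pdb_source[1])
  if (is_text) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    writeLines(unlist(strsplit(pdb_source, "\n")), tf)
    pdb <- bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(pdb_source, multi = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  missing_ch <- setdiff(chain_selection, unique(at$chain))
  if (length(missing_ch) > 0)
    stop("chain(s) not present in PDB: ", paste(missing_ch, collapse = ", "))

  chains <- list()
  offset <- 0L
  for (ch in chain_selection) {
    rows <- at[at$chain == ch & at$type == "ATOM", , drop = FALSE]
    # drop altLoc duplicates: keep first occurrence per (resno, elety)
    rows <- rows[!duplicated(rows[, c("resno", "elety")]), , drop = FALSE]
    resnos <- unique(rows$resno)
    if (length(resnos) < 2)
      stop("chain ", ch, " has fewer than 2 residues")
    resnames <- character(length(resnos))
    ca <- matrix(NA_real_, length(resnos), 3)
    atoms <- NULL
    atom_list <- vector("list", length(resnos))
    for (k in seq_along(resnos)) {
      rr <- rows[rows$resno == resnos[k], , drop = FALSE]
      rn <- rr$resid[1]
      if (!(rn %in% .aa3))
        stop("unknown residue name '", rn, "' at chain ", ch,
             " residue ", resnos[k])
      resnames[k] <- rn
      cas <- rr[rr$elety == "CA", , drop = FALSE]
      if (nrow(cas) != 1)
        stop("residue ", resnos[k], " (", rn, ") in chain ", ch,
             if (nrow(cas) == 0) " lacks a CA atom" else " has multiple CA atoms")
      ca[k, ] <- as.numeric(cas[1, c("x", "y", "z")])
      heavy <- rr[!grepl("^H", rr$elety), , drop = FALSE]
      atom_list[[k]] <- data.frame(
        res_local = k - 1L, res_global = offset + k - 1L,
        name = heavy$elety, resname = rn,
        x = heavy$x, y = heavy$y, z = heavy$z,
        stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, atom_list)
    # "all-atom" means more than just backbone CA records
    if (all(atoms$name == "CA")) atoms <- NULL
    if (any(!is.finite(ca))) stop("non-finite CA coordinates in chain ", ch)
    chains[[ch]] <- list(id = ch, resnames = resnames, ca = ca, atoms = atoms)
    offset <- offset + length(resnos)
  }

  # hetero zinc sites
  het <- at[at$type == "HETATM" & toupper(at$resid) %in% c("ZN", "ZN2"),
            , drop = FALSE]
  zinc <- NULL
  if (nrow(het) > 0) {
    allat <- do.call(rbind, lapply(chains, function(c) {
      if (!is.null(c$atoms)) c$atoms else {
        data.frame(res_local = seq_along(c$resnames) - 1L,
                   res_global = NA, name = "CA", resname = c$resnames,
                   x = c$ca[, 1], y = c$ca[, 2], z = c$ca[, 3])
      }
    }))
    # recompute global indices after rbind across chains
    glob <- global_index_map(chains)
    zinc <- lapply(seq_len(nrow(het)), function(z) {
      zc <- as.numeric(het[z, c("x", "y", "z")])
      d <- sqrt((allat$x - zc[1])^2 + (allat$y - zc[2])^2 +
                  (allat$z - zc[3])^2)
      hits <- unique(allat$res_global[d <= zinc_coord_cutoff])
      if (length(hits) == 0) {
        # CA-only fallback: nearest CA within 8 A
        cas <- allat[allat$name == "CA", ]
        dca <- sqrt((cas$x - zc[1])^2 + (cas$y - zc[2])^2 +
                      (cas$z - zc[3])^2)
        hits <- unique(cas$res_global[dca <= 8])
      }
      list(xyz = zc, coord_residues = sort(hits))
    })
  }
  structure(list(chains = chains, zinc = zinc,
                 source = if (is_text) "text" else basename(pdb_source)),
            class = "ComplexStructure")
}

# fill res_global consistently across chains (selection order, 0-based)
global_index_map <- function(chains) {
  offset <- 0L
  for (k in seq_along(chains)) {
    m <- length(chains[[k]]$resnames)
    if (!is.null(chains[[k]]$atoms))
      chains[[k]]$atoms$res_global <- chains[[k]]$atoms$res_local + offset
    offset <- offset + m
  }
  chains
}

#' @export
print.ComplexStructure <- function(x, ...) {
  cat("ComplexStructure:", length(x$chains), "chain(s):",
      paste(sprintf("%s (%d aa)", names(x$chains),
                    vapply(x$chains, function(c) length(c$resnames), 1L)),
            collapse = ", "), "\n")
  if (length(x$zinc) > 0) cat("  ", length(x$zinc), "zinc site(s)\n")
  invisible(x)
}

#' Number of residues and concatenated helpers
#' @param structure a `ComplexStructure`
#' @return integer count of residues over all chains
#' @export
n_residues <- function(structure) {
  sum(vapply(structure$chains, function(c) length(c$resnames), 1L))
}

# concatenated CA coordinates (n x 3) in global index order
all_ca <- function(structure) {
  do.call(rbind, lapply(structure$chains, function(c) c$ca))
}

# residue names in global index order
all_resnames <- function(structure) {
  unlist(lapply(structure$chains, function(c) c$resnames), use.names = FALSE)
}

# chain id per global residue index
chain_of_residue <- function(structure) {
  rep(names(structure$chains),
      vapply(structure$chains, function(c) length(c$resnames), 1L))
}

#' Identify native contacts of a complex structure
#'
#' A residue pair (i, j) is a native contact when any heavy-atom pair between
#' the two residues lies within `cutoff` in the native structure (falling
#' back to the C-alpha pair when no all-atom records exist) and, for
#' intramolecular pairs, the sequence separation is at least `min_seq_sep`.
#' Each contact stores the native C-alpha--C-alpha distance and its class
#' (intramolecular per chain, or intermolecular).
#'
#' @param structure a `ComplexStructure`.
#' @param cutoff heavy-atom (or fallback C-alpha) distance cutoff, Angstrom.
#' @param min_seq_sep minimum intramolecular sequence separation (>= 2).
#' @param allow_ca_fallback if FALSE, error when all-atom records are absent.
#' @return data frame of class `contact_table`: columns `i`, `j` (global
#'   0-based, i < j), `r_native`, `eps` (NA until flavored), `class`.
#' @export
identify_native_contacts <- function(structure, cutoff = 4.5,
                                     min_seq_sep = 3,
                                     allow_ca_fallback = TRUE) {
  stopifnot(cutoff > 0, min_seq_sep >= 2)
  chains <- global_index_map(structure$chains)
  has_atoms <- all(vapply(chains, function(c) !is.null(c$atoms), TRUE))
  if (!has_atoms && !allow_ca_fallback)
    stop("structure lacks all-atom records and CA fallback is disabled")
  ca <- all_ca(structure)
  resch <- chain_of_residue(structure)
  n <- nrow(ca)
  if (has_atoms) {
    atoms <- do.call(rbind, lapply(chains, function(c) c$atoms))
  } else {
    atoms <- data.frame(res_global = 0:(n - 1), x = ca[, 1], y = ca[, 2],
                        z = ca[, 3])
  }
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  ares <- atoms$res_global
  # all atom pairs within cutoff -> candidate residue pairs
  d2 <- cutoff^2
  nb <- which(as.matrix(stats::dist(axyz))^2 <= d2, arr.ind = TRUE)
  nb <- nb[nb[, 1] < nb[, 2], , drop = FALSE]
  ri <- pmin(ares[nb[, 1]], ares[nb[, 2]])
  rj <- pmax(ares[nb[, 1]], ares[nb[, 2]])
  keep <- ri < rj
  pairs <- unique(data.frame(i = ri[keep], j = rj[keep]))
  if (nrow(pairs) == 0)
    return(empty_contacts())
  same_chain <- resch[pairs$i + 1] == resch[pairs$j + 1]
  ok <- !same_chain | (pairs$j - pairs$i >= min_seq_sep)
  pairs <- pairs[ok, , drop = FALSE]
  same_chain <- same_chain[ok]
  cls <- ifelse(same_chain,
                paste0("intra_", resch[pairs$i + 1]), "inter")
  rn <- sqrt(rowSums((ca[pairs$i + 1, , drop = FALSE] -
                        ca[pairs$j + 1, , drop = FALSE])^2))
  out <- data.frame(i = pairs$i, j = pairs$j, r_native = rn,
                    eps = NA_real_, class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

empty_contacts <- function() {
  out <- data.frame(i = integer(0), j = integer(0), r_native = numeric(0),
                    eps = numeric(0), class = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Sequence-flavoring schemes for contact well depths
#'
#' `uniform_flavoring()` gives every residue pair weight 1.
#' `default_flavoring()` loads the shipped 20 x 20 statistical
#' contact-energy matrix built as the geometric-mean factorization
#' `w_ij = sqrt(e_i e_j)` of per-residue contact-energy magnitudes.
#' Under the default `"contacts-mean"` normalization the weights are rescaled
#' so that their mean over the model's own contact list is exactly 1, making
#' the mean assigned well depth equal to the base epsilon.
#'
#' @param normalization `"contacts-mean"` (default) or `"none"`.
#' @return a `FlavoringScheme`: list with `matrix` (20 x 20, symmetric,
#'   positive, dimnames = 3-letter residue codes) and `normalization`.
#' @export
uniform_flavoring <- function(normalization = "contacts-mean") {
  m <- matrix(1, 20, 20, dimnames = list(.aa3, .aa3))
  structure(list(matrix = m, normalization = normalization),
            class = "FlavoringScheme")
}

#' @rdname uniform_flavoring
#' @export
default_flavoring <- function(normalization = "contacts-mean") {
  f <- system.file("extdata", "contact_energy_weights.tsv",
                   package = "bindfold")
  tab <- read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  e <- setNames(tab$e, tab$res)[.aa3]
  m <- sqrt(outer(e, e))
  dimnames(m) <- list(.aa3, .aa3)
  structure(list(matrix = m, normalization = normalization),
            class = "FlavoringScheme")
}

#' Assign flavored well depths to a contact list
#'
#' Sets `eps_ij = base_epsilon * w_ij`, where the pair weights come from the
#' flavoring matrix, normalized (by default) so that the mean weight over
#' these contacts is 1 (hence mean eps equals `base_epsilon`).
#'
#' @param contacts a `contact_table`.
#' @param resnames 3-letter residue names in global index order.
#' @param flavoring a `FlavoringScheme`.
#' @param base_epsilon base well depth, kcal/mol.
#' @return the contact table with `eps` filled in.
#' @export
flavor_contacts <- function(contacts, resnames,
                            flavoring = uniform_flavoring(),
                            base_epsilon = 1.0) {
  if (nrow(contacts) == 0) return(contacts)
  rn_i <- resnames[contacts$i + 1]
  rn_j <- resnames[contacts$j + 1]
  unknown <- setdiff(unique(c(rn_i, rn_j)), rownames(flavoring$matrix))
  if (length(unknown) > 0)
    stop("residue(s) not covered by flavoring matrix: ",
         paste(unknown, collapse = ", "))
  w <- flavoring$matrix[cbind(rn_i, rn_j)]
  if (identical(flavoring$normalization, "contacts-mean")) w <- w / mean(w)
  contacts$eps <- base_epsilon * w
  contacts
}

#' Build a C-alpha Go topology from a complex structure
#'
#' Assembles particles (one bead per residue at the C-alpha position, plus
#' one bead per zinc ion), virtual bonds between consecutive residues,
#' native angles and dihedrals, the flavored native-contact list, zinc
#' harmonic distance restraints, and model parameters.
#'
#' @param structure a `ComplexStructure`.
#' @param contacts a flavored `contact_table` (see
#'   [identify_native_contacts()] and [flavor_contacts()]); if `eps` is
#'   still NA, uniform flavoring with `base_epsilon` is applied.
#' @param charge_mode `"none"` or `"explicit"` (Lys/Arg +1, Asp/Glu -1,
#'   zinc +2).
#' @param base_epsilon base contact well depth, kcal/mol.
#' @param flavoring `FlavoringScheme` used when `contacts$eps` is unset.
#' @param sigma_rep excluded-volume diameter, Angstrom.
#' @param eps_rep excluded-volume prefactor, kcal/mol.
#' @param k_angle,k_dih1,k_dih3 bonded force constants (kcal/mol/rad^2 and
#'   kcal/mol).
#' @param k_bond harmonic bond constant used only when SHAKE is off.
#' @param zinc_k zinc restraint force constant, kcal/mol/A^2.
#' @param epsilon_r solvent dielectric constant.
#' @param ionic_strength mol/L (0 = unscreened Coulomb).
#' @param elec_temperature temperature (K) entering the Debye length.
#' @param cutoff nonbonded cutoff, Angstrom.
#' @return an object of class `GoTopology`.
#' @export
build_topology <- function(structure, contacts = NULL,
                           charge_mode = c("none", "explicit"),
                           base_epsilon = 1.0,
                           flavoring = uniform_flavoring(),
                           sigma_rep = 4.0, eps_rep = 1.0,
                           k_angle = 20, k_dih1 = 0.4, k_dih3 = 0.2,
                           k_bond = 100, zinc_k = 50,
                           epsilon_r = 80, ionic_strength = 0,
                           elec_temperature = 300, cutoff = 25) {
  charge_mode <- match.arg(charge_mode)
  if (is.null(contacts)) contacts <- identify_native_contacts(structure)
  resnames <- all_resnames(structure)
  if (nrow(contacts) > 0 && anyNA(contacts$eps))
    contacts <- flavor_contacts(contacts, resnames, flavoring, base_epsilon)
  ca <- all_ca(structure)
  n <- nrow(ca)
  chain <- chain_of_residue(structure)
  particles <- data.frame(
    name = resnames, chain = chain, mass = .default_mass,
    charge = 0, stringsAsFactors = FALSE)

  bonds <- angles <- dihedrals <- NULL
  offset <- 0L
  for (c in structure$chains) {
    m <- length(c$resnames)
    idx <- offset + seq_len(m) - 1L
    xyz <- c$ca
    if (m >= 2) {
      i <- idx[-m]; j <- idx[-1]
      r0 <- sqrt(rowSums((xyz[-m, , drop = FALSE] -
                            xyz[-1, , drop = FALSE])^2))
      bonds <- rbind(bonds, data.frame(i = i, j = j, r0 = r0))
    }
    if (m >= 3) {
      ii <- idx[1:(m - 2)]; jj <- idx[2:(m - 1)]; kk <- idx[3:m]
      t0 <- vapply(seq_len(m - 2), function(q)
        vec_angle(xyz[q, ], xyz[q + 1, ], xyz[q + 2, ]), 1.0)
      angles <- rbind(angles, data.frame(i = ii, j = jj, k = kk, theta0 = t0))
    }
    if (m >= 4) {
      p0 <- vapply(seq_len(m - 3), function(q)
        vec_dihedral(xyz[q, ], xyz[q + 1, ], xyz[q + 2, ], xyz[q + 3, ]), 1.0)
      dihedrals <- rbind(dihedrals, data.frame(
        i = idx[1:(m - 3)], j = idx[2:(m - 2)], k = idx[3:(m - 1)],
        l = idx[4:m], phi0 = p0))
    }
    offset <- offset + m
  }

  # zinc particles appended after residues
  coords <- ca
  restraints <- NULL
  if (length(structure$zinc) > 0) {
    for (z in structure$zinc) {
      zi <- nrow(coords)  # 0-based index of the new particle
      coords <- rbind(coords, z$xyz)
      particles <- rbind(particles, data.frame(
        name = "ZN", chain = "_het", mass = .zinc_mass, charge = 0,
        stringsAsFactors = FALSE))
      for (r in z$coord_residues) {
        d0 <- sqrt(sum((z$xyz - ca[r + 1, ])^2))
        restraints <- rbind(restraints, data.frame(
          i = zi, j = r, r0 = d0, k = zinc_k))
      }
    }
  }
  rownames(particles) <- NULL
  topo <- structure(list(
    particles = particles, coords = coords,
    bonds = bonds, angles = angles, dihedrals = dihedrals,
    contacts = contacts, restraints = restraints,
    sigma_rep = sigma_rep, eps_rep = eps_rep,
    k_angle = k_angle, k_dih1 = k_dih1, k_dih3 = k_dih3, k_bond = k_bond,
    lambda_intra = 1.0, lambda_inter = 1.0,
    charge_mode = "none",
    epsilon_r = epsilon_r, ionic_strength = ionic_strength,
    elec_temperature = elec_temperature, cutoff = cutoff,
    provenance = list(source = structure$source,
                      n_chains = length(structure$chains),
                      chain_lengths = vapply(structure$chains,
                                             function(c) length(c$resnames),
                                             1L))),
    class = "GoTopology")
  assign_charges(topo, charge_mode)
}

vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

vec_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  atan2(sum(pracma_cross(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Assign explicit charges to a Go topology
#'
#' In `"explicit"` mode, Lys and Arg beads carry +1, Asp and Glu carry -1,
#' zinc carries +2, all other residues 0 (histidine is treated as neutral).
#' In `"none"` mode every charge is 0.  Charges never alter bonded or
#' contact parameters.
#'
#' @param topology a `GoTopology`.
#' @param charge_mode `"none"` or `"explicit"`.
#' @return the topology with charges set.
#' @export
assign_charges <- function(topology, charge_mode = c("none", "explicit")) {
  charge_mode <- match.arg(charge_mode)
  q <- rep(0, nrow(topology$particles))
  if (charge_mode == "explicit") {
    nm <- topology$particles$name
    q[nm %in% c("LYS", "ARG")] <- 1
    q[nm %in% c("ASP", "GLU")] <- -1
    q[nm == "ZN"] <- 2
  }
  topology$particles$charge <- q
  topology$charge_mode <- charge_mode
  topology
}

#' Scale native-contact well depths
#'
#' Multiplies intramolecular contact depths by `lambda_intra` and
#' intermolecular depths by `lambda_inter`; all other terms are untouched.
#' The operation is multiplicative and composable, and the cumulative
#' factors are tracked on the topology.
#'
#' @param topology a `GoTopology`.
#' @param lambda_intra,lambda_inter positive scaling factors.
#' @return the scaled topology.
#' @export
scale_topology <- function(topology, lambda_intra = 1, lambda_inter = 1) {
  if (lambda_intra <= 0 || lambda_inter <= 0)
    stop("scaling factors must be positive")
  if (nrow(topology$contacts) > 0) {
    inter <- topology$contacts$class == "inter"
    topology$contacts$eps[inter] <- topology$contacts$eps[inter] * lambda_inter
    topology$contacts$eps[!inter] <- topology$contacts$eps[!inter] * lambda_intra
  }
  topology$lambda_intra <- topology$lambda_intra * lambda_intra
  topology$lambda_inter <- topology$lambda_inter * lambda_inter
  topology
}

#' @export
print.GoTopology <- function(x, ...) {
  ct <- table(factor(x$contacts$class %in% "inter",
                     levels = c(FALSE, TRUE), labels = c("intra", "inter")))
  cat("GoTopology:", nrow(x$particles), "particles,",
      nrow(x$bonds), "bonds,", nrow(x$contacts), "contacts (",
      ct["intra"], "intra /", ct["inter"], "inter ),",
      "charges:", x$charge_mode, "\n")
  cat(sprintf("  lambda_intra %.4g  lambda_inter %.4g  eps_r %g  I %g M\n",
              x$lambda_intra, x$lambda_inter, x$epsilon_r, x$ionic_strength))
  invisible(x)
}

#' Write / read a Go model file
#'
#' Self-describing YAML serialization of a `GoTopology`, including particles
#' with charges, bonded terms, contacts with native distances / depths /
#' classes, scaling factors, and provenance.  Global residue indexing is
#' 0-based and contiguous across chains in selection order.
#'
#' @param topology a `GoTopology`.
#' @param path output (input) file path.
#' @return `read_topology` returns the `GoTopology`.
#' @export
write_topology <- function(topology, path) {
  obj <- unclass(topology)
  obj$coords <- as.vector(t(topology$coords))
  obj$header <- paste("bindfold Go model; residue indices are global,",
                      "0-based, contiguous across chains in selection order")
  for (nm in c("particles", "bonds", "angles", "dihedrals", "contacts",
               "restraints"))
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.list(as.data.frame(obj[[nm]]))
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$header <- NULL
  for (nm in c("particles", "bonds", "angles", "dihedrals", "contacts",
               "restraints"))
    if (!is.null(obj[[nm]]))
      obj[[nm]] <- as.data.frame(obj[[nm]], stringsAsFactors = FALSE)
  obj$coords <- matrix(obj$coords, ncol = 3, byrow = TRUE)
  if (!is.null(obj$contacts))
    class(obj$contacts) <- c("contact_table", "data.frame")
  if (!is.null(obj$provenance$chain_lengths))
    obj$provenance$chain_lengths <- unlist(obj$provenance$chain_lengths)
  structure(obj, class = "GoTopology")
}
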