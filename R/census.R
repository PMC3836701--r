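# Charge census of the IDP, its binding site, and the vicinity of the
# binding site: interface residues by solvent-accessibility change upon
# complex formation, surface residues by relative accessibility, vicinity
# by Ca-Ca distance to the bound IDP.

.atom_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                 P = 1.80, ZN = 1.39)

atom_radius <- function(name) {
  el <- ifelse(toupper(name) %in% c("ZN", "ZN2"), "ZN",
               substr(toupper(name), 1, 1))
  r <- .atom_radii[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

# quasi-uniform sphere points (Fibonacci lattice)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# flat atom table (name, resname, res_global, chain, x, y, z) for a
# ComplexStructure, restricted to the given chain ids
census_atoms <- function(structure, chains = names(structure$chains)) {
  chl <- global_index_map(structure$chains)
  rows <- lapply(chl[chains], function(c) {
    if (is.null(c$atoms))
      stop("chain ", c$id, " lacks all-atom records; SASA needs them")
    cbind(c$atoms, chain = c$id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe of radius `probe` over each atom using a quasi-uniform
#' point lattice (default 960 points per atom) and sums exposed area per
#' residue.
#'
#' @param atoms data frame with columns `name`, `res_global`, `x`, `y`,
#'   `z` (e.g., from a `ComplexStructure` chain's `atoms`).
#' @param probe probe radius, Angstrom.
#' @param n_points sphere points per atom (>= 960 recommended).
#' @return data frame with `res_global` and `sasa` (Angstrom^2).
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atom_radius(atoms$name) + probe
  n <- nrow(xyz)
  sp <- sphere_points(n_points)
  area <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sweep(sp * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nbr) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & dj2 > rad[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * mean(free)
  }
  stats::aggregate(list(sasa = area), by = list(res_global = atoms$res_global),
                   FUN = sum)
}

#' Interface residues by solvent-accessibility change
#'
#' Residues whose solvent-accessible surface area decreases by strictly
#' more than `delta_min` (default 1.0 Angstrom^2) upon complex formation,
#' comparing each chain in isolation against the full complex.
#'
#' @param structure a `ComplexStructure` with all-atom records.
#' @param probe,n_points forwarded to [sasa()].
#' @param delta_min strict lower bound on the SASA change, Angstrom^2.
#' @return data frame with `res_global`, `chain`, `dsasa`, flag
#'   `interface`.
#' @export
interface_residues <- function(structure, probe = 1.4, n_points = 960,
                               delta_min = 1.0) {
  at_all <- census_atoms(structure)
  s_complex <- sasa(at_all, probe, n_points)
  rows <- lapply(names(structure$chains), function(ch) {
    at <- census_atoms(structure, ch)
    s_iso <- sasa(at, probe, n_points)
    m <- merge(s_iso, s_complex, by = "res_global",
               suffixes = c("_iso", "_cpx"))
    data.frame(res_global = m$res_global, chain = ch,
               dsasa = m$sasa_iso - m$sasa_cpx,
               sasa_complex = m$sasa_cpx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$interface <- out$dsasa > delta_min
  out[order(out$res_global), ]
}

#' Vicinity of the IDP binding site
#'
#' Substrate residues with more than 5 percent relative solvent
#' accessibility (against shipped per-residue maximal SASA reference
#' values), within 15 Angstrom minimum Ca-Ca distance from the bound IDP,
#' and not themselves interface residues.
#'
#' @param structure a `ComplexStructure`.
#' @param idp_chain chain id of the IDP.
#' @param interface output of [interface_residues()] (computed if NULL).
#' @param access_min relative accessibility threshold (fraction).
#' @param dist_max Ca-Ca distance threshold, Angstrom.
#' @param probe,n_points forwarded to [sasa()].
#' @return data frame of substrate residues with `res_global`,
#'   `rel_access`, `min_ca_dist`, flag `vicinity`.
#' @export
vicinity_residues <- function(structure, idp_chain, interface = NULL,
                              access_min = 0.05, dist_max = 15,
                              probe = 1.4, n_points = 960) {
  if (is.null(interface))
    interface <- interface_residues(structure, probe, n_points)
  f <- system.file("extdata", "max_sasa_tien2013.tsv", package = "bindfold")
  maxs <- read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
  maxv <- setNames(maxs$max_sasa, maxs$res)
  resch <- chain_of_residue(structure)
  resnm <- all_resnames(structure)
  ca <- all_ca(structure)
  idp_idx <- which(resch == idp_chain)
  sub_idx <- which(resch != idp_chain)
  dmat <- sqrt(outer(rowSums(ca[sub_idx, , drop = FALSE]^2), rep(1, length(idp_idx))) -
                 2 * ca[sub_idx, , drop = FALSE] %*% t(ca[idp_idx, , drop = FALSE]) +
                 outer(rep(1, length(sub_idx)), rowSums(ca[idp_idx, , drop = FALSE]^2)))
  mind <- apply(dmat, 1, min)
  sc <- interface[match(sub_idx - 1, interface$res_global), ]
  rel <- sc$sasa_complex / unname(maxv[resnm[sub_idx]])
  out <- data.frame(res_global = sub_idx - 1L, chain = resch[sub_idx],
                    name = resnm[sub_idx], rel_access = rel,
                    min_ca_dist = mind,
                    interface = sc$interface, stringsAsFactors = FALSE)
  out$vicinity <- out$rel_access > access_min & out$min_ca_dist <= dist_max &
    !out$interface
  out
}

#' Charge census of IDP, binding site, and vicinity
#'
#' Counts of charged residues (Lys, Arg, Asp, Glu; His neutral) and net
#' charges (+1/+1/-1/-1) for three regions: the IDP chain, the substrate
#' interface ("binding site"), and the vicinity shell.  Binding site and
#' vicinity are disjoint by construction.
#'
#' @param structure a `ComplexStructure` with all-atom records.
#' @param idp_chain chain id of the IDP.
#' @param probe,n_points forwarded to [sasa()].
#' @return a `CensusReport`: per-region counts, net charges, and residue
#'   membership tables with justification values.
#' @export
charge_census <- function(structure, idp_chain, probe = 1.4,
                          n_points = 960) {
  interface <- interface_residues(structure, probe, n_points)
  vic <- vicinity_residues(structure, idp_chain, interface,
                           probe = probe, n_points = n_points)
  resch <- chain_of_residue(structure)
  resnm <- all_resnames(structure)
  idp_res <- which(resch == idp_chain) - 1L
  site_res <- interface$res_global[interface$interface &
                                     interface$chain != idp_chain]
  vic_res <- vic$res_global[vic$vicinity]
  count_region <- function(res) {
    nm <- resnm[res + 1]
    q <- unname(.aa_charge[nm])
    list(n_charged = sum(q != 0), net = sum(q), residues = res)
  }
  structure(list(idp = count_region(idp_res),
                 binding_site = count_region(site_res),
                 vicinity = count_region(vic_res),
                 interface_table = interface, vicinity_table = vic),
            class = "CensusReport")
}

#' @export
print.CensusReport <- function(x, ...) {
  fmt <- function(r) sprintf("%d(%+d)", r$n_charged, r$net)
  cat("CensusReport (charged residues, net charge):\n")
  cat("  IDP:", fmt(x$idp), " binding site:", fmt(x$binding_site),
      " vicinity:", fmt(x$vicinity), "\n")
  invisible(x)
}
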