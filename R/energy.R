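#' Debye screening length
#'
#' `lambda_D = sqrt(eps_r eps_0 k_B T / (2 N_A e^2 I))`, in Angstrom, for a
#' 1:1 salt of ionic strength `I` (mol/L).  `I = 0` returns `Inf`
#' (unscreened Coulomb).
#'
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param epsilon_r relative dielectric constant (the model default is 80).
#' @return screening length in Angstrom.
#' @export
debye_length <- function(ionic_strength, temperature = 300, epsilon_r = 80) {
  stopifnot(ionic_strength >= 0, temperature > 0, epsilon_r > 0)
  if (ionic_strength == 0) return(Inf)
  eps0 <- 8.8541878128e-12   # F/m
  kb <- 1.380649e-23         # J/K
  na <- 6.02214076e23
  e <- 1.602176634e-19       # C
  lam_m <- sqrt(epsilon_r * eps0 * kb * temperature /
                  (2 * na * e^2 * ionic_strength * 1000))
  lam_m * 1e10
}

#' Debye-Hueckel pair energy
#'
#' Screened Coulomb interaction
#' `U = k_C q_i q_j exp(-r/lambda_D) / (eps_r r)`, shifted so that
#' `U(cutoff) = 0`, and 0 beyond the cutoff.  At zero ionic strength this
#' reduces to the (shifted) Coulomb potential over `eps_r`.
#'
#' @param qi,qj charges in elementary charge units.
#' @param r separation, Angstrom.
#' @param epsilon_r dielectric constant.
#' @param ionic_strength mol/L.
#' @param temperature K (enters the screening length).
#' @param cutoff Angstrom; `Inf` disables shifting/truncation.
#' @return energy in kcal/mol.
#' @export
debye_huckel_pair <- function(qi, qj, r, epsilon_r = 80, ionic_strength = 0,
                              temperature = 300, cutoff = 25) {
  stopifnot(all(r > 0))
  lam <- debye_length(ionic_strength, temperature, epsilon_r)
  kap <- if (is.finite(lam)) 1 / lam else 0
  a <- .kC * qi * qj / epsilon_r
  u <- a * exp(-kap * r) / r
  if (is.finite(cutoff)) {
    u <- u - a * exp(-kap * cutoff) / cutoff
    u[r >= cutoff] <- 0
  }
  u
}

#' 12-10 native-contact pair energy
#'
#' `U(r) = eps [5 (r0/r)^12 - 6 (r0/r)^10]`; minimum `-eps` at `r = r0`.
#'
#' @param r separation, Angstrom (vectorized).
#' @param r_native native separation, Angstrom.
#' @param eps well depth, kcal/mol.
#' @return energy in kcal/mol.
#' @export
native_contact_energy <- function(r, r_native, eps) {
  stopifnot(all(r > 0), r_native > 0)
  s <- (r_native / r)^2
  eps * (5 * s^6 - 6 * s^5)
}

# Flatten a GoTopology into the list consumed by the compiled core:
# builds the full nonbonded pair list (excluded-volume and native pairs),
# excluding bonded (|i-j| = 1), 1-3 (|i-j| = 2) intra pairs, and
# zinc-restraint partners.  Electrostatics applies to every listed pair with
# nonzero charge product.
topology_to_sys <- function(topology, box = 0) {
  p <- topology$particles
  n <- nrow(p)
  chain <- p$chain
  # candidate pairs i < j
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1] - 1L; j <- pr[, 2] - 1L
  same <- chain[i + 1] == chain[j + 1] & chain[i + 1] != "_het"
  sep <- j - i
  excl <- same & sep < 3
  if (!is.null(topology$restraints) && nrow(topology$restraints) > 0) {
    rkey <- paste(pmin(topology$restraints$i, topology$restraints$j),
                  pmax(topology$restraints$i, topology$restraints$j))
    excl <- excl | paste(i, j) %in% rkey
  }
  i <- i[!excl]; j <- j[!excl]
  key <- paste(i, j)
  type <- integer(length(i))
  r0 <- numeric(length(i))
  epsv <- numeric(length(i))
  clsv <- integer(length(i))
  ct <- topology$contacts
  if (!is.null(ct) && nrow(ct) > 0) {
    ckey <- paste(ct$i, ct$j)
    m <- match(ckey, key)
    if (anyNA(m)) stop("native contact pair missing from nonbonded list")
    type[m] <- 1L
    r0[m] <- ct$r_native
    epsv[m] <- ct$eps
    clsv[m] <- as.integer(ct$class == "inter")
  }
  kap <- {
    lam <- debye_length(topology$ionic_strength, topology$elec_temperature,
                        topology$epsilon_r)
    if (is.finite(lam)) 1 / lam else 0
  }
  empty_int <- integer(0); empty_num <- numeric(0)
  b <- topology$bonds
  a <- topology$angles
  d <- topology$dihedrals
  r <- topology$restraints
  list(
    n = n, mass = p$mass, charge = p$charge,
    b_i = if (is.null(b)) empty_int else as.integer(b$i),
    b_j = if (is.null(b)) empty_int else as.integer(b$j),
    b_r0 = if (is.null(b)) empty_num else b$r0,
    k_bond = topology$k_bond,
    a_i = if (is.null(a)) empty_int else as.integer(a$i),
    a_j = if (is.null(a)) empty_int else as.integer(a$j),
    a_k = if (is.null(a)) empty_int else as.integer(a$k),
    a_t0 = if (is.null(a)) empty_num else a$theta0,
    k_angle = topology$k_angle,
    d_i = if (is.null(d)) empty_int else as.integer(d$i),
    d_j = if (is.null(d)) empty_int else as.integer(d$j),
    d_k = if (is.null(d)) empty_int else as.integer(d$k),
    d_l = if (is.null(d)) empty_int else as.integer(d$l),
    d_p0 = if (is.null(d)) empty_num else d$phi0,
    k_dih1 = topology$k_dih1, k_dih3 = topology$k_dih3,
    p_i = as.integer(i), p_j = as.integer(j), p_type = type, p_cls = clsv,
    p_r0 = r0, p_eps = epsv,
    r_i = if (is.null(r)) empty_int else as.integer(r$i),
    r_j = if (is.null(r)) empty_int else as.integer(r$j),
    r_r0 = if (is.null(r)) empty_num else r$r0,
    r_k = if (is.null(r)) empty_num else r$k,
    sigma_rep = topology$sigma_rep, eps_rep = topology$eps_rep,
    cutoff = topology$cutoff,
    kc_over_epsr = .kC / topology$epsilon_r, kappa = kap,
    box = box)
}

#' Potential energy breakdown (and forces) of a configuration
#'
#' Evaluates the full coarse-grained potential under the minimum-image
#' convention: bonded terms (bonds reported as 0 when SHAKE constrains
#' them), native-contact 12-10 wells split intra/inter, excluded volume on
#' non-native nonbonded pairs, shifted Debye-Hueckel electrostatics, and
#' zinc restraints.  The breakdown sums to the total.
#'
#' @param topology a `GoTopology`.
#' @param coords n x 3 coordinate matrix (Angstrom); defaults to the native
#'   coordinates stored on the topology.
#' @param box cubic box edge, Angstrom; 0 disables periodicity.
#' @param constrained_bonds treat virtual bonds as SHAKE-constrained (bond
#'   energy = 0).
#' @param forces also return the analytic forces (kcal/mol/A).
#' @return list with `breakdown` (named numeric vector, incl. `total`) and,
#'   when requested, `forces`.
#' @export
potential_energy <- function(topology, coords = topology$coords, box = 0,
                             constrained_bonds = TRUE, forces = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topology$particles))
    stop("coordinate count does not match topology")
  if (box > 0 && box <= 2 * topology$cutoff)
    warning("box edge is not larger than twice the cutoff")
  sys <- topology_to_sys(topology, box)
  cpp_energy_forces(sys, coords, constrained_bonds, forces)
}

#' Numerical forces by central differences (testing oracle)
#'
#' @inheritParams potential_energy
#' @param h finite-difference step, Angstrom.
#' @return n x 3 matrix of forces, kcal/mol/A.
#' @export
numerical_forces <- function(topology, coords, box = 0,
                             constrained_bonds = TRUE, h = 1e-5) {
  coords <- as.matrix(coords)
  f <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (k in 1:3) {
      cp <- coords; cp[i, k] <- cp[i, k] + h
      cm <- coords; cm[i, k] <- cm[i, k] - h
      up <- potential_energy(topology, cp, box, constrained_bonds)$breakdown[["total"]]
      um <- potential_energy(topology, cm, box, constrained_bonds)$breakdown[["total"]]
      f[i, k] <- -(up - um) / (2 * h)
    }
  }
  f
}
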