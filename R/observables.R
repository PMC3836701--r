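# Per-frame reaction coordinates: native-contact fractions and counts,
# nonspecific contact counts, binding RMSD, center-of-mass separation, and
# collision-ensemble contact-probability maps.  All distances use the
# minimum-image convention; every observable is invariant under periodic
# wrapping of the input coordinates.

# normalize frames input to an nf x n x 3 array
as_frames <- function(x) {
  if (inherits(x, "Trajectory")) x <- x$frames
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  x
}

# minimum-image component-wise difference
mi <- function(d, box) if (box > 0) d - box * round(d / box) else d

# nf-vector of distances between particles i and j (1-based) across frames
pair_dist <- function(fr, i, j, box) {
  dx <- mi(fr[, i, 1] - fr[, j, 1], box)
  dy <- mi(fr[, i, 2] - fr[, j, 2], box)
  dz <- mi(fr[, i, 3] - fr[, j, 3], box)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Native-contact formation criterion
#'
#' A native contact is formed when the inter-C-alpha distance is within
#' `tol` (default 1.0 Angstrom) of its distance in the native complex.
#'
#' @param r observed distance(s), Angstrom.
#' @param r_native native distance, Angstrom.
#' @param tol formation tolerance, Angstrom.
#' @return logical vector.
#' @export
contact_formed <- function(r, r_native, tol = 1.0) {
  stopifnot(all(r > 0), all(r_native > 0))
  abs(r - r_native) <= tol
}

#' Per-frame count of formed native contacts
#'
#' @param frames a `Trajectory`, an nf x n x 3 array, or an n x 3 matrix.
#' @param contacts a `contact_table` subset (e.g., the intermolecular
#'   contacts).
#' @param box cubic box edge, Angstrom (0 = no periodicity).
#' @param tol formation tolerance, Angstrom.
#' @return integer vector, one count per frame.
#' @export
native_contact_count <- function(frames, contacts, box = 0, tol = 1.0) {
  fr <- as_frames(frames)
  if (nrow(contacts) == 0) return(integer(dim(fr)[1]))
  cnt <- numeric(dim(fr)[1])
  for (k in seq_len(nrow(contacts))) {
    r <- pair_dist(fr, contacts$i[k] + 1, contacts$j[k] + 1, box)
    cnt <- cnt + (abs(r - contacts$r_native[k]) <= tol)
  }
  as.integer(cnt)
}

#' Fraction of native contacts formed (Q)
#'
#' @inheritParams native_contact_count
#' @return numeric vector in `[0, 1]`, one value per frame.
#' @export
fraction_native <- function(frames, contacts, box = 0, tol = 1.0) {
  if (nrow(contacts) == 0) stop("empty contact subset")
  native_contact_count(frames, contacts, box, tol) / nrow(contacts)
}

#' Per-frame count of nonspecific intermolecular contacts
#'
#' Counts inter-group C-alpha pairs within `cutoff` (default 10 Angstrom).
#' When `exclude_native` contacts are supplied, pairs that are native
#' intermolecular contacts are excluded, so that the collision-complex
#' definition ("at least one nonspecific but no specific contact") is
#' disjoint from native contact formation.
#'
#' @param frames trajectory frames (see [native_contact_count()]).
#' @param group_a,group_b 1-based particle indices of the two chains.
#' @param box cubic box edge, Angstrom.
#' @param cutoff contact cutoff, Angstrom.
#' @param exclude_native optional `contact_table` whose (i, j) pairs are
#'   dropped from the count.
#' @return integer vector, one count per frame.
#' @export
nonspecific_contacts <- function(frames, group_a, group_b, box = 0,
                                 cutoff = 10, exclude_native = NULL) {
  fr <- as_frames(frames)
  pairs <- expand.grid(i = group_a, j = group_b)
  if (!is.null(exclude_native) && nrow(exclude_native) > 0) {
    nat <- paste(pmin(exclude_native$i, exclude_native$j),
                 pmax(exclude_native$i, exclude_native$j))
    key <- paste(pmin(pairs$i, pairs$j) - 1, pmax(pairs$i, pairs$j) - 1)
    pairs <- pairs[!(key %in% nat), , drop = FALSE]
  }
  cnt <- numeric(dim(fr)[1])
  for (k in seq_len(nrow(pairs)))
    cnt <- cnt + (pair_dist(fr, pairs$i[k], pairs$j[k], box) <= cutoff)
  as.integer(cnt)
}

# Kabsch optimal superposition: returns coords2 rotated/translated onto
# coords1 using the subset 'idx' for the fit
kabsch_fit <- function(ref, mob, idx) {
  a <- ref[idx, , drop = FALSE]
  b <- mob[idx, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  h <- t(sweep(b, 2, cb)) %*% sweep(a, 2, ca)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mob, 2, cb) %*% t(r), 2, ca, "+")
}

#' Binding RMSD of the IDP after substrate alignment
#'
#' Each frame is optimally superposed (Kabsch) onto the native complex using
#' only `align_idx` (the folded substrate), and the RMSD is then computed
#' over `rmsd_idx` (the IDP).  For two-IDP complexes, pass the whole complex
#' as both subsets to get the regular RMSD.
#'
#' @param frames trajectory frames.
#' @param native n x 3 native coordinates.
#' @param align_idx 1-based indices used for the superposition (>= 3).
#' @param rmsd_idx 1-based indices over which the RMSD is computed.
#' @return numeric vector of RMSD values, Angstrom.
#' @export
binding_rmsd <- function(frames, native, align_idx, rmsd_idx) {
  if (length(align_idx) < 3) stop("need at least 3 alignment particles")
  if (length(rmsd_idx) < 1) stop("empty RMSD subset")
  fr <- as_frames(frames)
  vapply(seq_len(dim(fr)[1]), function(k) {
    x <- matrix(fr[k, , ], ncol = 3)
    fitted <- kabsch_fit(native, x, align_idx)
    sqrt(mean(rowSums((fitted[rmsd_idx, , drop = FALSE] -
                         native[rmsd_idx, , drop = FALSE])^2)))
  }, 1.0)
}

#' Center-of-mass separation between two chains
#'
#' Group centroids (uniform masses) with each group's coordinates re-imaged
#' relative to its first particle, then the minimum-image distance between
#' the two centroids.
#'
#' @inheritParams nonspecific_contacts
#' @return numeric vector, Angstrom.
#' @export
center_separation <- function(frames, group_a, group_b, box = 0) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  fr <- as_frames(frames)
  centroid <- function(idx) {
    ref <- fr[, idx[1], , drop = FALSE]
    sx <- sy <- sz <- 0
    for (i in idx) {
      sx <- sx + ref[, 1, 1] + mi(fr[, i, 1] - ref[, 1, 1], box)
      sy <- sy + ref[, 1, 2] + mi(fr[, i, 2] - ref[, 1, 2], box)
      sz <- sz + ref[, 1, 3] + mi(fr[, i, 3] - ref[, 1, 3], box)
    }
    cbind(sx, sy, sz) / length(idx)
  }
  ca <- centroid(group_a)
  cb <- centroid(group_b)
  unname(sqrt(mi(ca[, 1] - cb[, 1], box)^2 + mi(ca[, 2] - cb[, 2], box)^2 +
                mi(ca[, 3] - cb[, 3], box)^2))
}

#' Per-residue intermolecular contact probability over an ensemble
#'
#' For each residue, the fraction of frames in which it has at least one
#' intermolecular C-alpha pair within `cutoff` -- the quantity used to map
#' where an IDP touches the substrate surface in the collision-complex
#' ensemble.
#'
#' @inheritParams nonspecific_contacts
#' @return data frame with `residue` (1-based index), `group`
#'   (`"A"`/`"B"`), `probability`.
#' @export
contact_probability_map <- function(frames, group_a, group_b, box = 0,
                                    cutoff = 10) {
  fr <- as_frames(frames)
  nf <- dim(fr)[1]
  if (nf == 0) stop("empty ensemble")
  hit_a <- matrix(FALSE, nf, length(group_a))
  hit_b <- matrix(FALSE, nf, length(group_b))
  for (ai in seq_along(group_a)) {
    for (bi in seq_along(group_b)) {
      inc <- pair_dist(fr, group_a[ai], group_b[bi], box) <= cutoff
      hit_a[, ai] <- hit_a[, ai] | inc
      hit_b[, bi] <- hit_b[, bi] | inc
    }
  }
  data.frame(residue = c(group_a, group_b),
             group = rep(c("A", "B"), c(length(group_a), length(group_b))),
             probability = c(colMeans(hit_a), colMeans(hit_b)))
}

#' Compute the standard observable series for a two-chain trajectory
#'
#' Convenience wrapper producing the per-frame reaction coordinates used
#' throughout the analysis: `q_inter`, per-chain `q_intra`, the native
#' intermolecular contact count `n_inter`, the nonspecific (non-native)
#' intermolecular contact count `n_nonspec`, and the center-of-mass
#' separation `r_cm`.
#'
#' @param trajectory a `Trajectory` (or frames array).
#' @param topology the `GoTopology` the trajectory was run with.
#' @param box box edge override; defaults to the trajectory's box.
#' @param tol native-contact formation tolerance, Angstrom.
#' @param nonspec_cutoff nonspecific contact cutoff, Angstrom.
#' @return data frame (one row per frame) with a `time_ps` column when the
#'   input is a `Trajectory`.
#' @export
compute_observables <- function(trajectory, topology, box = NULL, tol = 1.0,
                                nonspec_cutoff = 10) {
  if (is.null(box))
    box <- if (inherits(trajectory, "Trajectory")) trajectory$box else 0
  fr <- as_frames(trajectory)
  ch <- topology$particles$chain
  chains <- setdiff(unique(ch), "_het")
  if (length(chains) != 2)
    stop("compute_observables expects a two-chain topology")
  ga <- which(ch == chains[1])
  gb <- which(ch == chains[2])
  ct <- topology$contacts
  inter <- ct[ct$class == "inter", , drop = FALSE]
  out <- data.frame(row.names = seq_len(dim(fr)[1]))
  if (inherits(trajectory, "Trajectory")) out$time_ps <- trajectory$time_ps
  out$n_inter <- native_contact_count(fr, inter, box, tol)
  out$q_inter <- if (nrow(inter) > 0) out$n_inter / nrow(inter) else 0
  for (cc in chains) {
    sub <- ct[ct$class == paste0("intra_", cc), , drop = FALSE]
    out[[paste0("q_intra_", cc)]] <-
      if (nrow(sub) > 0) fraction_native(fr, sub, box, tol) else NA_real_
  }
  out$n_nonspec <- nonspecific_contacts(fr, ga, gb, box, nonspec_cutoff,
                                        exclude_native = inter)
  out$r_cm <- center_separation(fr, ga, gb, box)
  out
}
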