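#' Enumerate dimers in a cluster
#'
#' Considers every unordered pair of molecules and keeps those whose
#' intermolecular distance falls below the threshold.  The distance is the
#' centroid-to-centroid separation (`"centroid"`), the nearest
#' intermolecular atom-pair distance (`"atom-pair"`), or the latter with
#' both atoms' vdW radii subtracted (`"vdw-adjusted"`).  Each record also
#' carries the dimer's geometric fingerprint: the sorted vector of all
#' intermolecular atom-pair distances, which is invariant under rigid
#' motions and reflections of the pair.
#'
#' @param cluster an `aggrex_structure`.
#' @param metric one of "centroid", "atom-pair", "vdw-adjusted".
#' @param threshold distance threshold, Angstrom.
#' @param molecules optional list of atom-index sets (default: segmented
#'   from the cluster, or the `"molecules"` attribute if present).
#' @return list of dimer records: `mol_a`, `mol_b` (atom index vectors),
#'   `i`, `j` (molecule numbers), `centroid_distance`, `fingerprint`.
#' @export
enumerate_dimers <- function(cluster, metric = c("centroid", "atom-pair",
                                                 "vdw-adjusted"),
                             threshold, molecules = NULL) {
  metric <- match.arg(metric)
  if (is.null(molecules))
    molecules <- attr(cluster, "molecules") %||% segment_molecules(cluster)
  if (length(molecules) < 2)
    stop("cluster must contain at least two molecules")
  pos <- positions(cluster)
  vdw <- cluster$atoms$vdw_radius
  out <- list()
  for (i in seq_len(length(molecules) - 1)) {
    for (j in (i + 1):length(molecules)) {
      a <- molecules[[i]]; b <- molecules[[j]]
      ca <- colMeans(pos[a, , drop = FALSE])
      cb <- colMeans(pos[b, , drop = FALSE])
      cd <- sqrt(sum((ca - cb)^2))
      dmat <- .cross_distances(pos[a, , drop = FALSE], pos[b, , drop = FALSE])
      dist <- switch(metric,
        "centroid" = cd,
        "atom-pair" = min(dmat),
        "vdw-adjusted" = min(dmat - outer(vdw[a], vdw[b], `+`)))
      if (dist >= threshold) next
      out[[length(out) + 1]] <- list(
        mol_a = a, mol_b = b, i = i, j = j,
        centroid_distance = cd,
        fingerprint = sort(as.vector(dmat)))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cross_distances <- function(pa, pb) {
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  sqrt(pmax(d2, 0))
}

#' Deduplicate symmetry-equivalent dimers
#'
#' In a crystal the cell symmetry produces groups of dimers identical up to
#' a rotation or reflection; their sorted-distance fingerprints coincide.
#' A greedy pass keeps the first representative of each group: two dimers
#' are equivalent iff their fingerprints have the same length and the RMSD
#' between the sorted vectors is below `rmsd_tol` (default 1e-4 A).
#'
#' @param dimers list of dimer records from [enumerate_dimers()].
#' @param rmsd_tol fingerprint RMSD threshold, Angstrom.
#' @return sub-list of unique dimers, first occurrences kept.
#' @export
deduplicate_dimers <- function(dimers, rmsd_tol = 1e-4) {
  keep <- list()
  for (d in dimers) {
    dup <- any(vapply(keep, function(k) {
      length(k$fingerprint) == length(d$fingerprint) &&
        sqrt(mean((k$fingerprint - d$fingerprint)^2)) < rmsd_tol
    }, TRUE))
    if (!dup) keep[[length(keep) + 1]] <- d
  }
  keep
}

#' Principal axes of a (near-planar) molecule
#'
#' Characteristic orthonormal axes for dimer-arrangement analysis:
#' \enumerate{
#'   \item all atoms are projected onto the least-squares average plane
#'     (singular value decomposition of the centered coordinates; the
#'     smallest singular direction is the plane normal);
#'   \item the two longest projected interatomic distances form a
#'     quadrilateral ABCD with AC > BD and AB the longest side, fixing an
#'     arbitrary but consistent direction;
#'   \item with midpoints H = [AB], G = [BC], F = [CD], E = [DA], the
#'     principal axis a runs E to G and the secondary axis b runs F to H;
#'   \item a and b are normalized and rotated by equal and opposite
#'     in-plane half-angles until perpendicular; the tertiary axis is
#'     c = a x b.
#' }
#' If one atom belongs to both longest distances, B and C coincide
#' (degenerate quadrilateral) and the construction remains valid.  With
#' `long_axis_mode = TRUE`, a is simply the unit vector of the single
#' longest projected interatomic distance and b the in-plane perpendicular.
#'
#' @param mol an `aggrex_structure` (molecule).
#' @param ignore_elements element symbols excluded from the analysis
#'   (e.g. "H").
#' @param long_axis_mode use the single longest interatomic distance as a.
#' @return object of class `aggrex_axes`: list with unit vectors `a`, `b`,
#'   `c` (right-handed, pairwise orthogonal to 1e-10).
#' @export
principal_axes <- function(mol, ignore_elements = character(0),
                           long_axis_mode = FALSE) {
  use <- which(!(mol$atoms$element %in% ignore_elements))
  if (length(use) < 3) stop("need at least 3 non-ignored atoms")
  p <- unname(positions(mol)[use, , drop = FALSE])
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  sv <- svd(pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("atoms are collinear; no average plane is defined")
  normal <- sv$v[, 3]
  proj <- pc - outer(as.vector(pc %*% normal), normal)
  # all pairwise projected distances, longest two segments
  np <- nrow(proj)
  pr <- t(utils::combn(np, 2))
  dd <- sqrt(rowSums((proj[pr[, 1], , drop = FALSE] -
                      proj[pr[, 2], , drop = FALSE])^2))
  ord <- order(-dd, pr[, 1], pr[, 2])   # deterministic tie-break
  s1 <- pr[ord[1], ]                    # endpoints of longest distance (A, C)
  if (long_axis_mode) {
    a <- proj[s1[2], ] - proj[s1[1], ]
    a <- a / sqrt(sum(a^2))
    b <- .cross3(normal, a)
    b <- b / sqrt(sum(b^2))
    return(structure(list(a = a, b = b, c = .cross3(a, b)),
                     class = "aggrex_axes"))
  }
  # second longest distance not equal to the first segment
  k2 <- ord[min(2, length(ord))]
  s2 <- pr[k2, ]
  AC <- s1
  BD <- s2
  # choose labels so that side AB is the longest of the four sides
  cand <- list(c(AC[1], BD[1], AC[2], BD[2]), c(AC[1], BD[2], AC[2], BD[1]),
               c(AC[2], BD[1], AC[1], BD[2]), c(AC[2], BD[2], AC[1], BD[1]))
  side_ab <- vapply(cand, function(q)
    sqrt(sum((proj[q[1], ] - proj[q[2], ])^2)), 0)
  q <- cand[[which.max(side_ab)]]
  A <- proj[q[1], ]; B <- proj[q[2], ]; C <- proj[q[3], ]; D <- proj[q[4], ]
  H <- (A + B) / 2; G <- (B + C) / 2; Fm <- (C + D) / 2; E <- (D + A) / 2
  a <- G - E
  b <- H - Fm
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("degenerate axis construction")
  a <- a / na; b <- b / nb
  # symmetric orthogonalization: rotate a and b by equal, opposite angles
  u <- (a + b); u <- u / sqrt(sum(u^2))
  v <- (a - b); v <- v / sqrt(sum(v^2))
  a2 <- (u + v) / sqrt(2)
  b2 <- (u - v) / sqrt(2)
  structure(list(a = a2, b = b2, c = .cross3(a2, b2)), class = "aggrex_axes")
}

.cross3 <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                            x[3] * y[1] - x[1] * y[3],
                            x[1] * y[2] - x[2] * y[1])

#' @export
print.aggrex_axes <- function(x, ...) {
  cat("principal  a:", sprintf("% .6f", x$a), "\n")
  cat("secondary  b:", sprintf("% .6f", x$b), "\n")
  cat("tertiary   c:", sprintf("% .6f", x$c), "\n")
  invisible(x)
}

.angle_deg <- function(u, v) {
  cuv <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cuv))) * 180 / pi
}

#' Angles between same axes of two monomers
#'
#' alpha, beta, gamma are the angles between the principal, secondary and
#' tertiary axes of the two molecules, in degrees, each in [0, 180]
#' (unfolded: a dimer and its inversion-related partner are distinct).
#'
#' @param ax1,ax2 `aggrex_axes` of the two monomers.
#' @return named numeric vector `c(alpha=, beta=, gamma=)`.
#' @export
dimer_angles <- function(ax1, ax2) {
  c(alpha = .angle_deg(ax1$a, ax2$a),
    beta = .angle_deg(ax1$b, ax2$b),
    gamma = .angle_deg(ax1$c, ax2$c))
}

#' Slip angle of a dimer
#'
#' Smallest acute angle between the centroid-to-centroid axis and either
#' monomer's tertiary (plane-normal) axis, in degrees within [0, 90].
#' Values near 0 indicate cofacial stacking (large pi-pi overlap); values
#' near 90 a fully slipped arrangement.
#'
#' @param ax1,ax2 `aggrex_axes` of the monomers.
#' @param centroid1,centroid2 the two centroids (length-3 vectors, A).
#' @return angle in degrees.
#' @export
slip_angle <- function(ax1, ax2, centroid1, centroid2) {
  u <- centroid2 - centroid1
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("coincident centroids")
  u <- u / nu
  acute <- function(c3) {
    a <- .angle_deg(u, c3)
    min(a, 180 - a)
  }
  min(acute(ax1$c), acute(ax2$c))
}

#' Classify a dimer arrangement
#'
#' Heuristic assignment to the archetypal packing motifs from the inter-axis
#' angles and the slip angle.  Default thresholds (configurable):
#' face-to-face when gamma (folded to [0,90]) < 30 deg and slip < 30 deg;
#' parallel-displaced when gamma < 30 deg but slip >= 30 deg; edge-to-face
#' when gamma is within 30 deg of perpendicular; otherwise "other".
#'
#' @param angles named vector from [dimer_angles()].
#' @param slip slip angle, degrees.
#' @param gamma_planar gamma threshold for near-parallel planes (deg).
#' @param slip_stacked slip threshold separating stacked from displaced.
#' @return one of "face-to-face", "parallel-displaced", "edge-to-face",
#'   "other".
#' @export
classify_dimer <- function(angles, slip, gamma_planar = 30,
                           slip_stacked = 30) {
  g <- angles[["gamma"]]
  gfold <- min(g, 180 - g)
  if (gfold < gamma_planar) {
    if (slip < slip_stacked) "face-to-face" else "parallel-displaced"
  } else if (g >= 60 && g <= 120) {
    "edge-to-face"
  } else "other"
}

#' Full dimer characterization table
#'
#' Convenience driver: enumerate, deduplicate, and characterize every unique
#' dimer of a cluster.
#'
#' @inheritParams enumerate_dimers
#' @param rmsd_tol fingerprint dedup tolerance, Angstrom.
#' @param ignore_elements elements excluded from the axis construction.
#' @return data.frame with one row per unique dimer: molecule numbers,
#'   centroid distance, alpha, beta, gamma, slip, archetype.
#' @export
characterize_dimers <- function(cluster, metric = "centroid", threshold = 10,
                                rmsd_tol = 1e-4,
                                ignore_elements = character(0),
                                molecules = NULL) {
  if (is.null(molecules))
    molecules <- attr(cluster, "molecules") %||% segment_molecules(cluster)
  dimers <- enumerate_dimers(cluster, metric, threshold, molecules)
  uniq <- deduplicate_dimers(dimers, rmsd_tol)
  rows <- lapply(uniq, function(d) {
    ax1 <- principal_axes(structure_slice(cluster, d$mol_a), ignore_elements)
    ax2 <- principal_axes(structure_slice(cluster, d$mol_b), ignore_elements)
    ang <- dimer_angles(ax1, ax2)
    sl <- slip_angle(ax1, ax2, centroid(cluster, d$mol_a),
                     centroid(cluster, d$mol_b))
    data.frame(mol_i = d$i, mol_j = d$j,
               centroid_distance = d$centroid_distance,
               alpha = ang[["alpha"]], beta = ang[["beta"]],
               gamma = ang[["gamma"]], slip = sl,
               archetype = classify_dimer(ang, sl))
  })
  do.call(rbind, rows)
}
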