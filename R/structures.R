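#' Bonding scheme
#'
#' Defines when two atoms count as bonded.  `center-distance` compares the
#' nucleus-nucleus distance with the threshold directly; `covalent-edge`
#' and `vdw-edge` first subtract the two atoms' covalent or van der Waals
#' radii, so the threshold is a slack on the touching distance of the
#' corresponding spheres.
#'
#' @param mode one of "center-distance", "covalent-edge", "vdw-edge".
#' @param threshold distance threshold in Angstrom (> 0).  Default 0.4 A of
#'   slack under covalent-edge, a robust choice for organic molecules.
#' @return an object of class `aggrex_bonding`.
#' @export
bonding_scheme <- function(mode = c("covalent-edge", "center-distance", "vdw-edge"),
                           threshold = if (match.arg(mode) == "center-distance") 1.8 else 0.4) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold > 0)
  structure(list(mode = mode, threshold = threshold), class = "aggrex_bonding")
}

#' Molecular structure container
#'
#' An ordered collection of atom sites (element, Cartesian position in
#' Angstrom, partial charge in e, covalent and van der Waals radii) with
#' optional lattice vectors and a bonding scheme.  This is the universal
#' geometry object of the package: unit cells, supercells, clusters and
#' single molecules are all `aggrex_structure`s.
#'
#' @param elements character vector of element symbols ("" for bare point
#'   charges).
#' @param positions n x 3 numeric matrix of Cartesian coordinates, Angstrom.
#' @param charges per-atom partial charges (e); recycled, default 0.
#' @param lattice optional 3 x 3 matrix whose rows are the lattice vectors
#'   (Angstrom); must have nonzero determinant.
#' @param bonding an [bonding_scheme()] object.
#' @param comment free-text comment (kept verbatim on XYZ round-trips).
#' @return an object of class `aggrex_structure` with components `atoms`
#'   (data.frame: element, x, y, z, charge, cov_radius, vdw_radius),
#'   `lattice`, `bonding`, `comment`.
#' @export
new_structure <- function(elements, positions, charges = 0, lattice = NULL,
                          bonding = bonding_scheme(), comment = "") {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  stopifnot(length(elements) == n, all(is.finite(positions)))
  charges <- rep_len(as.numeric(charges), n)
  rad <- element_radii(elements)
  if (!is.null(lattice)) {
    lattice <- matrix(as.numeric(lattice), 3, 3)
    if (abs(det(lattice)) < 1e-12) stop("lattice matrix is singular")
  }
  structure(list(
    atoms = data.frame(element = as.character(elements),
                       x = positions[, 1], y = positions[, 2], z = positions[, 3],
                       charge = charges,
                       cov_radius = rad$cov, vdw_radius = rad$vdw,
                       stringsAsFactors = FALSE),
    lattice = lattice, bonding = bonding, comment = comment),
    class = "aggrex_structure")
}

#' @export
print.aggrex_structure <- function(x, ...) {
  cat(sprintf("<aggrex_structure> %d atoms%s, bonding %s (%.2f A)\n",
              nrow(x$atoms),
              if (is.null(x$lattice)) "" else ", periodic",
              x$bonding$mode, x$bonding$threshold))
  invisible(x)
}

#' Number of atoms
#' @param s an `aggrex_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Cartesian positions
#' @param s an `aggrex_structure`.
#' @return n x 3 matrix, Angstrom.
#' @export
positions <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

`positions<-` <- function(s, value) {
  value <- matrix(value, ncol = 3)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Extract a sub-structure by atom indices
#'
#' @param s an `aggrex_structure`.
#' @param indices atom indices (1-based) to keep, order preserved.
#' @param drop_lattice drop the lattice from the slice (default TRUE:
#'   a molecule cut out of a cell is a finite object).
#' @return an `aggrex_structure` with the selected atoms.
#' @export
structure_slice <- function(s, indices, drop_lattice = TRUE) {
  stopifnot(all(indices >= 1), all(indices <= n_atoms(s)))
  out <- s
  out$atoms <- s$atoms[indices, , drop = FALSE]
  rownames(out$atoms) <- NULL
  if (drop_lattice) out$lattice <- NULL
  out
}

# ---- file I/O -------------------------------------------------------------

#' Read an XYZ file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` records in
#' Angstrom.  An optional fifth numeric column is read as per-atom partial
#' charge (the package's charge-file convention).
#'
#' @param path file path.
#' @param bonding bonding scheme attached to the result.
#' @return an `aggrex_structure`; the comment line is preserved verbatim.
#' @export
read_xyz <- function(path, bonding = bonding_scheme()) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed atom count on line 1 of ", path)
  comment <- if (length(lines) >= 2) lines[2] else ""
  rec <- lines[-(1:2)]
  rec <- rec[cumsum(nzchar(trimws(rec))) <= n & nzchar(trimws(rec))]
  if (length(rec) < n)
    stop("XYZ file declares ", n, " atoms but has ", length(rec),
         " records: ", path)
  rec <- rec[seq_len(n)]
  toks <- strsplit(trimws(rec), "\\s+")
  elements <- vapply(toks, `[`, "", 1L)
  num <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]][-1]))
    if (length(v) < 3 || any(is.na(v[1:3])))
      stop("non-numeric coordinates on atom line ", i, " of ", path)
    v
  })
  pos <- t(vapply(num, function(v) v[1:3], numeric(3)))
  charges <- vapply(num, function(v) if (length(v) >= 4 && !is.na(v[4])) v[4] else 0, 0)
  new_structure(elements, pos, charges, bonding = bonding, comment = comment)
}

#' Write an XYZ file
#'
#' @param s an `aggrex_structure`.
#' @param path output path.
#' @param charges if TRUE, append the partial charge as a fifth column.
#' @param digits coordinate precision (decimal places).
#' @return invisibly, `path`.
#' @export
write_xyz <- function(s, path, charges = FALSE, digits = 6) {
  pos <- positions(s)
  fmt <- paste0("%-3s % .", digits, "f % .", digits, "f % .", digits, "f")
  body <- sprintf(fmt, s$atoms$element, pos[, 1], pos[, 2], pos[, 3])
  if (charges)
    body <- paste0(body, sprintf(paste0(" % .", digits, "f"), s$atoms$charge))
  writeLines(c(as.character(n_atoms(s)), s$comment, body), path)
  invisible(path)
}

#' Read lattice vectors
#'
#' Three lines of three floats (Angstrom); row i of the result is lattice
#' vector i.
#'
#' @param path file path.
#' @return 3 x 3 numeric matrix.
#' @export
read_lattice <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) != 3)
    stop("lattice file must have exactly 3 lines, found ", length(lines),
         ": ", path)
  rows <- lapply(lines, function(l) suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]])))
  if (any(vapply(rows, length, 0L) != 3) || any(is.na(unlist(rows))))
    stop("each lattice line must hold 3 numbers: ", path)
  do.call(rbind, rows)
}

# ---- bonding and segmentation --------------------------------------------

# pairwise bonded atom pairs; periodic = minimum-image distances
.bond_pairs <- function(s, periodic = FALSE) {
  n <- n_atoms(s)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  pos <- positions(s)
  real_atom <- s$atoms$element != ""
  idx <- which(real_atom | s$bonding$mode == "center-distance")
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2))
  pr <- t(utils::combn(idx, 2))
  d <- pos[pr[, 1], , drop = FALSE] - pos[pr[, 2], , drop = FALSE]
  if (periodic) {
    if (is.null(s$lattice)) stop("periodic bonding requires a lattice")
    inv <- solve(s$lattice)
    f <- d %*% inv
    f <- f - round(f)
    d <- f %*% s$lattice
  }
  dist <- sqrt(rowSums(d * d))
  thr <- s$bonding$threshold
  hit <- switch(s$bonding$mode,
    "center-distance" = dist < thr,
    "covalent-edge" = dist - s$atoms$cov_radius[pr[, 1]] -
                      s$atoms$cov_radius[pr[, 2]] < thr,
    "vdw-edge" = dist - s$atoms$vdw_radius[pr[, 1]] -
                 s$atoms$vdw_radius[pr[, 2]] < thr)
  hit[is.na(hit)] <- FALSE
  pr[hit, , drop = FALSE]
}

#' Detect bonds
#'
#' Applies the structure's bonding scheme to every atom pair and returns a
#' symmetric adjacency list.  Bare point-charge sites (empty element) never
#' bond under the radius-based modes.
#'
#' @param s an `aggrex_structure`.
#' @param periodic use minimum-image distances (requires a lattice).
#' @return list of length `n_atoms(s)`; element i is the sorted integer
#'   vector of atoms bonded to atom i.
#' @export
detect_bonds <- function(s, periodic = FALSE) {
  n <- n_atoms(s)
  adj <- rep(list(integer(0)), n)
  pr <- .bond_pairs(s, periodic)
  if (nrow(pr)) {
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

.bond_graph <- function(s, periodic = FALSE) {
  pr <- .bond_pairs(s, periodic)
  igraph::make_graph(edges = as.vector(t(pr)), n = n_atoms(s),
                     directed = FALSE)
}

#' Segment a structure into molecules
#'
#' Connected components of the bond graph: every atom belongs to exactly one
#' molecule.
#'
#' @param s an `aggrex_structure` with a bonding scheme.
#' @param periodic use minimum-image bonding (for unit cells whose molecules
#'   straddle the boundary).
#' @return list of sorted integer index vectors, one per molecule, ordered
#'   by their smallest atom index.
#' @export
segment_molecules <- function(s, periodic = FALSE) {
  if (n_atoms(s) == 0) return(list())
  g <- .bond_graph(s, periodic)
  memb <- igraph::components(g)$membership
  comp <- lapply(unname(split(seq_len(n_atoms(s)), memb)), sort)
  comp[order(vapply(comp, min, 0L))]
}

#' Unweighted centroid of a molecule
#'
#' @param s an `aggrex_structure`.
#' @param m integer vector of atom indices (default: all atoms).
#' @return length-3 numeric vector, Angstrom.
#' @export
centroid <- function(s, m = seq_len(n_atoms(s))) {
  if (length(m) == 0) stop("empty index set has no centroid")
  colMeans(positions(s)[m, , drop = FALSE])
}

# ---- periodic operations --------------------------------------------------

#' Build a supercell
#'
#' Replicates the cell contents over `na x nb x nc` lattice translations and
#' scales the lattice vectors accordingly.  Elements and charges are
#' preserved on every image.
#'
#' @param s an `aggrex_structure` with a lattice.
#' @param na,nb,nc positive integer repeat counts along the three vectors.
#' @return an `aggrex_structure` with `na*nb*nc*n_atoms(s)` atoms.
#' @export
make_supercell <- function(s, na, nb, nc) {
  if (is.null(s$lattice)) stop("make_supercell requires a lattice")
  stopifnot(na >= 1, nb >= 1, nc >= 1)
  shifts <- as.matrix(expand.grid(ia = 0:(na - 1), ib = 0:(nb - 1),
                                  ic = 0:(nc - 1)))
  pos <- positions(s)
  allpos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    pos + matrix(shifts[k, ] %*% s$lattice, nrow(pos), 3, byrow = TRUE)
  }))
  out <- new_structure(rep(s$atoms$element, nrow(shifts)), allpos,
                       rep(s$atoms$charge, nrow(shifts)),
                       lattice = s$lattice * c(na, nb, nc),
                       bonding = s$bonding, comment = s$comment)
  out
}

# cell heights: distance between opposite faces, per lattice direction
.cell_heights <- function(lattice) {
  v <- abs(det(lattice))
  vapply(1:3, function(i) {
    jk <- setdiff(1:3, i)
    cr <- c(lattice[jk[1], 2] * lattice[jk[2], 3] - lattice[jk[1], 3] * lattice[jk[2], 2],
            lattice[jk[1], 3] * lattice[jk[2], 1] - lattice[jk[1], 1] * lattice[jk[2], 3],
            lattice[jk[1], 1] * lattice[jk[2], 2] - lattice[jk[1], 2] * lattice[jk[2], 1])
    v / sqrt(sum(cr^2))
  }, 0)
}

#' Make every molecule geometrically whole
#'
#' Molecules split by the periodic boundary are reassembled: starting from a
#' seed atom each molecule is grown bond by bond, translating every newly
#' reached atom by the minimum-image lattice shift relative to its parent.
#' Finally each molecule is translated so its fractional centroid lies in
#' [0, 1).
#'
#' @param s an `aggrex_structure` with a lattice.
#' @return an `aggrex_structure` whose bond graph is connected per molecule
#'   without periodic images.
#' @export
complete_molecules <- function(s) {
  if (is.null(s$lattice)) stop("complete_molecules requires a lattice")
  n <- n_atoms(s)
  if (n == 0) return(s)
  inv <- solve(s$lattice)
  frac <- positions(s) %*% inv
  pr <- .bond_pairs(s, periodic = TRUE)
  half_h <- min(.cell_heights(s$lattice)) / 2
  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(pr))) {
    adj[[pr[k, 1]]] <- c(adj[[pr[k, 1]]], pr[k, 2])
    adj[[pr[k, 2]]] <- c(adj[[pr[k, 2]]], pr[k, 1])
  }
  newfrac <- frac
  seen <- logical(n)
  for (seed in seq_len(n)) {
    if (seen[seed]) next
    seen[seed] <- TRUE
    newfrac[seed, ] <- frac[seed, ] - floor(frac[seed, ])
    queue <- seed
    mol <- seed
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (seen[j]) next
        d <- frac[j, ] - newfrac[i, ]
        shift <- round(d)
        newfrac[j, ] <- frac[j, ] - shift
        cart <- (newfrac[j, ] - newfrac[i, ]) %*% s$lattice
        if (sqrt(sum(cart^2)) > half_h)
          stop("molecule spans more than half the cell; completion ambiguous")
        seen[j] <- TRUE
        queue <- c(queue, j)
        mol <- c(mol, j)
      }
    }
    cmf <- colMeans(newfrac[mol, , drop = FALSE])
    newfrac[mol, ] <- newfrac[mol, ] -
      matrix(floor(cmf), length(mol), 3, byrow = TRUE)
  }
  out <- s
  positions(out) <- newfrac %*% s$lattice
  out
}

#' Extract a spherical cluster of whole molecules
#'
#' Generates enough periodic images of the (completed) cell contents to
#' cover a sphere of the given radius about the origin and keeps each
#' molecule image that meets the inclusion rule.  By default a molecule is
#' included when any of its atoms lies within the radius and is then kept
#' whole (the usual embedded-cluster convention); `strict_all_atoms = TRUE`
#' requires every atom inside.  Duplicate images (identical within 1e-6 A)
#' are removed.
#'
#' @param s an `aggrex_structure` with a lattice.
#' @param radius sphere radius about the Cartesian origin, Angstrom (> 0).
#' @param strict_all_atoms require all atoms within the radius.
#' @param center sphere center, default `c(0,0,0)`.
#' @return a finite (lattice-free) `aggrex_structure`; attribute
#'   `"molecules"` holds the index sets of its molecules.
#' @export
build_cluster <- function(s, radius, strict_all_atoms = FALSE,
                          center = c(0, 0, 0)) {
  if (is.null(s$lattice)) stop("build_cluster requires a lattice")
  if (radius <= 0) stop("radius must be positive")
  whole <- complete_molecules(s)
  mols <- segment_molecules(whole)
  pos <- positions(whole)
  heights <- .cell_heights(whole$lattice)
  extent <- max(vapply(mols, function(m) {
    c0 <- colMeans(pos[m, , drop = FALSE])
    max(sqrt(rowSums((pos[m, , drop = FALSE] -
                        matrix(c0, length(m), 3, byrow = TRUE))^2)))
  }, 0))
  nrep <- ceiling((radius + extent + max(abs(center))) / heights) + 1L
  keep_el <- character(0); keep_pos <- NULL; keep_q <- numeric(0)
  keep_mols <- list(); seen_keys <- character(0)
  for (ia in -nrep[1]:nrep[1]) for (ib in -nrep[2]:nrep[2])
    for (ic in -nrep[3]:nrep[3]) {
      tvec <- c(ia, ib, ic) %*% whole$lattice
      for (m in mols) {
        p <- pos[m, , drop = FALSE] + matrix(tvec, length(m), 3, byrow = TRUE)
        d <- sqrt(rowSums((p - matrix(center, length(m), 3, byrow = TRUE))^2))
        ok <- if (strict_all_atoms) all(d <= radius) else any(d <= radius)
        if (!ok) next
        key <- paste(whole$atoms$element[m][order(m)][1],
                     paste(sprintf("%.6f", colMeans(p)), collapse = ","),
                     length(m))
        if (key %in% seen_keys) next
        seen_keys <- c(seen_keys, key)
        i0 <- length(keep_el)
        keep_el <- c(keep_el, whole$atoms$element[m])
        keep_q <- c(keep_q, whole$atoms$charge[m])
        keep_pos <- rbind(keep_pos, p)
        keep_mols <- c(keep_mols, list(i0 + seq_along(m)))
      }
    }
  if (is.null(keep_pos)) stop("no molecule found within radius ", radius)
  out <- new_structure(keep_el, keep_pos, keep_q, bonding = s$bonding,
                       comment = sprintf("cluster r=%g A", radius))
  attr(out, "molecules") <- keep_mols
  out
}
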