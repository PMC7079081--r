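#' Volumetric grid
#'
#' A regular (generally parallelepiped-voxel) scalar field: origin, three
#' voxel edge vectors, voxel counts, and one value per voxel.  Values are
#' stored flat in the Gaussian-cube ordering (the third index fastest).
#'
#' @param origin length-3 vector, Angstrom.
#' @param axes 3 x 3 matrix; row i is the voxel edge vector along grid
#'   direction i, Angstrom.
#' @param counts three positive integers.
#' @param values numeric vector of length `prod(counts)` (default zeros).
#' @return an object of class `aggrex_grid`.
#' @export
volumetric_grid <- function(origin, axes, counts, values = NULL) {
  axes <- matrix(as.numeric(axes), 3, 3)
  counts <- as.integer(counts)
  stopifnot(length(origin) == 3, length(counts) == 3, all(counts > 0),
            abs(det(axes)) > 0)
  if (is.null(values)) values <- numeric(prod(counts))
  if (length(values) != prod(counts))
    stop("values length ", length(values), " != prod(counts) ", prod(counts))
  structure(list(origin = as.numeric(origin), axes = axes, counts = counts,
                 values = as.numeric(values)),
            class = "aggrex_grid")
}

#' Voxel volume of a grid (cubic Angstrom)
#' @param grid an `aggrex_grid`.
#' @export
voxel_volume <- function(grid) abs(det(grid$axes))

# voxel center coordinates, rows in cube (z-fastest) order
.grid_points <- function(grid) {
  idx <- as.matrix(expand.grid(k = seq_len(grid$counts[3]) - 1,
                               j = seq_len(grid$counts[2]) - 1,
                               i = seq_len(grid$counts[1]) - 1))
  idx <- idx[, c("i", "j", "k")]
  sweep(idx %*% grid$axes, 2, grid$origin, `+`)
}

#' Write a Gaussian cube file
#'
#' Standard layout: two comment lines; atom count and origin; three
#' voxel-count/axis lines; one line per atom (atomic number, charge,
#' position); values in z-fastest order, six per line.  All lengths are
#' converted from Angstrom to Bohr as the cube convention requires.
#'
#' @param grid an `aggrex_grid`.
#' @param s the `aggrex_structure` whose atoms head the file.
#' @param path output path.
#' @param comment two-line comment (character vector length <= 2).
#' @return invisibly, `path`.
#' @export
write_cube <- function(grid, s, path, comment = c("aggrex cube", "")) {
  b <- BOHR_PER_ANGSTROM
  comment <- c(comment, "", "")[1:2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n_atoms(s),
                     grid$origin[1] * b, grid$origin[2] * b,
                     grid$origin[3] * b), con)
  for (i in 1:3)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$counts[i],
                       grid$axes[i, 1] * b, grid$axes[i, 2] * b,
                       grid$axes[i, 3] * b), con)
  z <- .atomic_numbers[s$atoms$element]
  z[is.na(z)] <- 0
  pos <- positions(s) * b
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, as.numeric(z),
                     pos[, 1], pos[, 2], pos[, 3]), con)
  v <- grid$values
  pad <- (-length(v)) %% 6
  vm <- matrix(c(v, rep(NA_real_, pad)), ncol = 6, byrow = TRUE)
  lines <- apply(vm, 1, function(r)
    paste(sprintf("%13.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path cube file path.
#' @return list with `grid` (an `aggrex_grid`, lengths in Angstrom) and
#'   `structure` (an `aggrex_structure` with elements recovered from atomic
#'   numbers).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  a <- ANGSTROM_PER_BOHR
  hdr <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])
  natoms <- as.integer(hdr[1])
  origin <- hdr[2:4] * a
  counts <- integer(3); axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    v <- as.numeric(strsplit(trimws(lines[3 + i]), "\\s+")[[1]])
    counts[i] <- as.integer(v[1])
    axes[i, ] <- v[2:4] * a
  }
  atoms <- lines[7:(6 + natoms)]
  am <- do.call(rbind, lapply(atoms, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  elems <- names(.atomic_numbers)[match(am[, 1], .atomic_numbers)]
  elems[is.na(elems)] <- "X"
  s <- new_structure(elems, am[, 3:5] * a, charges = 0)
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natoms))]), "\\s+")))
  vals <- vals[!is.na(vals)]
  list(grid = volumetric_grid(origin, axes, counts, vals), structure = s)
}

# ---- Voronoi / vdW volumes -----------------------------------------------

# bounding grid over the cluster: extent + max vdw radius + padding
.bounding_grid <- function(s, spacing, padding = 2) {
  pos <- positions(s)
  rad <- s$atoms$vdw_radius
  rad[is.na(rad)] <- 0
  lo <- apply(pos, 2, min) - max(rad) - padding
  hi <- apply(pos, 2, max) + max(rad) + padding
  counts <- pmax(1L, ceiling((hi - lo) / spacing))
  volumetric_grid(lo + spacing / 2, diag(spacing, 3), counts)
}

#' Union-of-spheres van der Waals volume
#'
#' Grid-occupancy measure of the union of the atoms' vdW spheres, counting
#' overlaps once.
#'
#' @param mol an `aggrex_structure` (typically a molecule slice).
#' @param spacing grid spacing, Angstrom (default 0.2).
#' @param grid optional pre-built `aggrex_grid` to evaluate on.
#' @return volume in cubic Angstrom; attribute `"grid"` carries the 0/1
#'   occupancy grid.
#' @export
vdw_volume <- function(mol, spacing = 0.2, grid = NULL) {
  stopifnot(spacing > 0)
  if (is.null(grid)) grid <- .bounding_grid(mol, spacing)
  pts <- .grid_points(grid)
  occ <- .in_vdw_union(pts, mol, seq_len(n_atoms(mol)))
  grid$values <- as.numeric(occ)
  v <- sum(occ) * voxel_volume(grid)
  attr(v, "grid") <- grid
  v
}

.in_vdw_union <- function(pts, s, idx) {
  occ <- logical(nrow(pts))
  pos <- positions(s)
  for (a in idx) {
    r <- s$atoms$vdw_radius[a]
    if (is.na(r) || s$atoms$element[a] == "") next
    d2 <- (pts[, 1] - pos[a, 1])^2 + (pts[, 2] - pos[a, 2])^2 +
          (pts[, 3] - pos[a, 3])^2
    occ <- occ | (d2 <= r * r)
  }
  occ
}

#' Grid-based Voronoi volume of a molecule in a cluster
#'
#' Each voxel of a bounding grid is assigned to the atom that minimizes the
#' vdW-scaled distance |p - r_a| / r_vdW(a) — the scaling grants heavier,
#' larger atoms more space than hydrogens.  The molecule's Voronoi volume
#' V_V is the volume of voxels whose winning atom belongs to the target
#' molecule; V_vdW is its union-of-spheres volume on the same grid, and
#' V_union the measure of the set union of the two regions.  The volumetric
#' index Vi = V_V / V_vdW is a normalized packing-tightness measure.
#' Equidistant voxels go to the lowest atom index; bare point charges are
#' excluded.
#'
#' @param cluster an `aggrex_structure` holding all molecules.
#' @param target integer atom indices of the target molecule.
#' @param spacing grid spacing, Angstrom (default 0.2).
#' @param padding box padding beyond cluster extent + max vdW radius (A).
#' @return object of class `aggrex_voronoi`: list with `V_V`, `V_vdW`,
#'   `V_union`, `Vi`, `interior` (TRUE when the target's Voronoi region does
#'   not touch the box boundary), and cube-ready occupancy `grids`
#'   (`voro`, `vdw`, `union`).
#' @export
voronoi_volume <- function(cluster, target, spacing = 0.2, padding = 2) {
  if (length(target) == 0) stop("empty target molecule")
  stopifnot(spacing > 0, all(target >= 1), all(target <= n_atoms(cluster)))
  grid <- .bounding_grid(cluster, spacing, padding)
  pts <- .grid_points(grid)
  pos <- positions(cluster)
  usable <- which(cluster$atoms$element != "" &
                  !is.na(cluster$atoms$vdw_radius))
  if (!length(usable)) stop("no atoms with radii in cluster")
  best <- rep(Inf, nrow(pts))
  winner <- integer(nrow(pts))
  for (a in usable) {
    d <- sqrt((pts[, 1] - pos[a, 1])^2 + (pts[, 2] - pos[a, 2])^2 +
              (pts[, 3] - pos[a, 3])^2) / cluster$atoms$vdw_radius[a]
    hit <- d < best            # strict: ties keep the lowest atom index
    best[hit] <- d[hit]
    winner[hit] <- a
  }
  voro <- winner %in% target
  vdw <- .in_vdw_union(pts, cluster, intersect(target, usable))
  uni <- voro | vdw
  vv <- voxel_volume(grid)
  # boundary contact check: any winning voxel on an outer grid layer
  dimk <- grid$counts
  arr <- array(voro, dim = rev(dimk))  # z fastest -> dims (z, y, x)
  interior <- !(any(arr[1, , ]) || any(arr[dimk[3], , ]) ||
                any(arr[, 1, ]) || any(arr[, dimk[2], ]) ||
                any(arr[, , 1]) || any(arr[, , dimk[1]]))
  mkgrid <- function(v) volumetric_grid(grid$origin, grid$axes, grid$counts,
                                        as.numeric(v))
  res <- list(V_V = sum(voro) * vv, V_vdW = sum(vdw) * vv,
              V_union = sum(uni) * vv,
              Vi = sum(voro) / max(sum(vdw), 1),
              interior = interior,
              grids = list(voro = mkgrid(voro), vdw = mkgrid(vdw),
                           union = mkgrid(uni)))
  res$Vi <- res$V_V / res$V_vdW
  class(res) <- "aggrex_voronoi"
  res
}

#' @export
print.aggrex_voronoi <- function(x, ...) {
  cat(sprintf("Voronoi volume      V_V    = %10.3f A^3\n", x$V_V))
  cat(sprintf("vdW union volume    V_vdW  = %10.3f A^3\n", x$V_vdW))
  cat(sprintf("Union volume        V_uni  = %10.3f A^3\n", x$V_union))
  cat(sprintf("Volumetric index    Vi     = %10.4f\n", x$Vi))
  if (!x$interior)
    cat("warning: Voronoi region touches the box boundary (surface molecule)\n")
  invisible(x)
}

#' Volumetric packing index
#'
#' Ratio of a molecule's Voronoi volume to its vdW union volume; values
#' near 1 indicate tight packing.
#'
#' @param V_V Voronoi volume, cubic Angstrom.
#' @param V_vdW vdW union volume, cubic Angstrom (> 0).
#' @return dimensionless index V_V / V_vdW.
#' @export
volumetric_index <- function(V_V, V_vdW) {
  if (V_vdW <= 0) stop("V_vdW must be positive")
  V_V / V_vdW
}
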