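#' Point charge array
#'
#' Positions plus charge values used for electrostatic and Ewald embedding.
#' Each charge carries a zone label: `fixed` charges keep their nominal
#' values during fitting, `fitted` ones are free parameters.
#'
#' @param positions n x 3 matrix, Angstrom.
#' @param charges numeric vector, e.
#' @param zone character vector of "fixed"/"fitted" (default all "fixed").
#' @return object of class `aggrex_charges`.
#' @export
point_charge_array <- function(positions, charges,
                               zone = rep("fixed", length(charges))) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  stopifnot(nrow(positions) == length(charges),
            length(zone) == length(charges),
            all(zone %in% c("fixed", "fitted")),
            all(is.finite(positions)), all(is.finite(charges)))
  structure(list(positions = positions, charges = as.numeric(charges),
                 zone = zone),
            class = "aggrex_charges")
}

#' @export
print.aggrex_charges <- function(x, ...) {
  cat(sprintf("<aggrex_charges> %d charges (%d fitted), total %.6f e\n",
              length(x$charges), sum(x$zone == "fitted"), sum(x$charges)))
  invisible(x)
}

#' Write a point-charge file (x y z q per line, Angstrom / e)
#' @param pc an `aggrex_charges`.
#' @param path output path.
#' @export
write_point_charges <- function(pc, path) {
  writeLines(sprintf("% .8f % .8f % .8f % .8f", pc$positions[, 1],
                     pc$positions[, 2], pc$positions[, 3], pc$charges), path)
  invisible(path)
}

#' Read a point-charge file
#' @param path file with one `x y z q` line per charge (Angstrom, e).
#' @return an `aggrex_charges`.
#' @export
read_point_charges <- function(path) {
  m <- as.matrix(utils::read.table(path))
  point_charge_array(m[, 1:3], m[, 4])
}

.erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Ewald summation parameters
#'
#' @param gamma Ewald splitting constant, 1/Bohr; default 5.6 / (shortest
#'   cell height in Bohr), chosen when the lattice is known.
#' @param real_cutoff real-space cutoff, Bohr (NULL = auto by doubling).
#' @param recip_cutoff reciprocal-space cutoff on |G|, 1/Bohr (NULL = auto).
#' @param target_accuracy convergence goal for the doubling check, Hartree/e.
#' @return list of class `aggrex_ewald_params`.
#' @export
ewald_params <- function(gamma = NULL, real_cutoff = NULL,
                         recip_cutoff = NULL, target_accuracy = 1e-6) {
  structure(list(gamma = gamma, real_cutoff = real_cutoff,
                 recip_cutoff = recip_cutoff,
                 target_accuracy = target_accuracy),
            class = "aggrex_ewald_params")
}

# one Ewald evaluation at fixed cutoffs; everything in Bohr / e / Hartree
.ewald_eval <- function(r, sites, q, latt, gamma, rcut, gcut) {
  vol <- abs(det(latt))
  # real-space: images L within rcut of r - R_s
  nmax <- ceiling(rcut / .cell_heights(latt)) + 1L
  V <- 0
  for (ia in -nmax[1]:nmax[1]) for (ib in -nmax[2]:nmax[2])
    for (ic in -nmax[3]:nmax[3]) {
      L <- c(ia, ib, ic) %*% latt
      d <- sweep(sites, 2, as.numeric(r - L), `-`)
      dist <- sqrt(rowSums(d * d))
      self <- dist < 1e-8
      far <- !self & dist <= rcut
      V <- V + sum(q[far] * .erfc(gamma * dist[far]) / dist[far])
      # divergent L=0, s=i term replaced by the self-correction
      if (any(self)) V <- V - 2 * gamma * sum(q[self]) / sqrt(pi)
    }
  # reciprocal-space over G != 0 with |G| <= gcut
  recip <- 2 * pi * t(solve(latt))
  mmax <- ceiling(gcut / .cell_heights(recip)) + 1L
  grid <- as.matrix(expand.grid(-mmax[1]:mmax[1], -mmax[2]:mmax[2],
                                -mmax[3]:mmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  G <- grid %*% recip
  G2 <- rowSums(G * G)
  keep <- sqrt(G2) <= gcut
  G <- G[keep, , drop = FALSE]; G2 <- G2[keep]
  phase <- G %*% (r - t(sites))    # nG x nsites of G.(r - R_s)
  Sq <- cos(phase) %*% q
  V + 4 * pi / vol * sum(exp(-G2 / (4 * gamma^2)) / G2 * Sq)
}

#' Ewald lattice potential
#'
#' Electrostatic potential of the infinite periodic repetition of a neutral
#' unit cell of point charges, at an arbitrary point: the conditionally
#' convergent Madelung sum is split into a short-range real-space part
#' (complementary error function screened) and a rapidly converging
#' reciprocal-space part.  When the evaluation point coincides with a
#' lattice site the divergent self term is replaced by -2 gamma q_i /
#' sqrt(pi), which yields the potential felt by that site.  Atomic units:
#' the result is in Hartree/e with inputs converted from Angstrom.
#'
#' @param cell an `aggrex_structure` with lattice and per-atom charges
#'   summing to zero.
#' @param r evaluation point(s): length-3 vector or n x 3 matrix, Angstrom.
#' @param params an [ewald_params()]; unset members are auto-chosen
#'   (gamma = 5.6/Lmin and cutoffs doubled until two successive evaluations
#'   agree within `target_accuracy`).
#' @return potential value(s), Hartree/e.
#' @export
ewald_potential <- function(cell, r, params = ewald_params()) {
  if (is.null(cell$lattice)) stop("ewald_potential requires a lattice")
  q <- cell$atoms$charge
  if (abs(sum(q)) > 1e-8)
    stop(sprintf("unit cell must be neutral (total charge %.3g e)", sum(q)))
  latt <- cell$lattice * BOHR_PER_ANGSTROM
  sites <- positions(cell) * BOHR_PER_ANGSTROM
  r <- matrix(r, ncol = 3) * BOHR_PER_ANGSTROM
  hmin <- min(.cell_heights(latt))
  gamma <- params$gamma %||% (5.6 / hmin)
  rcut <- params$real_cutoff %||% (1.25 * hmin)
  gcut <- params$recip_cutoff %||% (8 * gamma)
  auto <- is.null(params$real_cutoff) && is.null(params$recip_cutoff)
  evalAll <- function(rc, gc) vapply(seq_len(nrow(r)), function(i)
    .ewald_eval(r[i, ], sites, q, latt, gamma, rc, gc), 0)
  V <- evalAll(rcut, gcut)
  # doubling check: converged cutoffs change the answer by < target_accuracy
  V2 <- evalAll(2 * rcut, 1.5 * gcut)
  it <- 0
  while (max(abs(V2 - V)) > params$target_accuracy && it < 3 && auto) {
    rcut <- 2 * rcut; gcut <- 1.5 * gcut
    V <- V2
    V2 <- evalAll(2 * rcut, 1.5 * gcut)
    it <- it + 1
  }
  if (max(abs(V2 - V)) > params$target_accuracy)
    warning(sprintf("Ewald cutoffs not converged to %g (delta %.3g)",
                    params$target_accuracy, max(abs(V2 - V))))
  if (length(V2) == 1) as.numeric(V2) else V2
}

#' Fit a finite point-charge array to the Ewald potential
#'
#' Klintenberg-style embedding array: point charges are laid out on the
#' crystal sites of a supercell around the origin; charges inside a fixed
#' zone (a sphere enclosing the inner region plus a margin) keep their
#' nominal values, while the outer-zone charges are adjusted by constrained
#' linear least squares so that the array reproduces the Ewald potential of
#' the infinite crystal at the inner-region atomic sites.  The total charge
#' and the total dipole moment of the array are constrained to zero exactly
#' (Lagrange multipliers).
#'
#' @param cell neutral `aggrex_structure` with lattice and charges.
#' @param inner_region `aggrex_structure` whose atomic sites are the
#'   potential-matching targets (e.g. the QM cluster).
#' @param n_charges approximate total number of array charges (default
#'   1000; the classic recipe uses ~10000).
#' @param check_sites optional m x 3 matrix (Angstrom) of sites where the
#'   potential is matched; default: the inner-region atom positions.
#' @param r_fix fixed-zone radius, Angstrom; default inner-region bounding
#'   sphere + 2 A.
#' @param params [ewald_params()] for the reference potential.
#' @return an `aggrex_charges` array (positions in Angstrom); attributes
#'   `"residual_before"` and `"residual_after"` give the max absolute
#'   potential mismatch at the check sites.
#' @export
fit_ewald_charges <- function(cell, inner_region, n_charges = 1000,
                              check_sites = NULL, r_fix = NULL,
                              params = ewald_params()) {
  if (is.null(cell$lattice)) stop("fit_ewald_charges requires a lattice")
  natoms <- n_atoms(cell)
  k <- max(1L, ceiling(((n_charges / natoms)^(1 / 3) - 1) / 2))
  shifts <- as.matrix(expand.grid(-k:k, -k:k, -k:k))
  pos0 <- positions(cell)
  allpos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    pos0 + matrix(shifts[s, ] %*% cell$lattice, natoms, 3, byrow = TRUE)))
  allq <- rep(cell$atoms$charge, nrow(shifts))
  inner_pos <- positions(inner_region)
  if (is.null(check_sites)) check_sites <- inner_pos
  check_sites <- matrix(check_sites, ncol = 3)
  ctr <- colMeans(inner_pos)
  if (is.null(r_fix))
    r_fix <- max(sqrt(rowSums(sweep(inner_pos, 2, ctr)^2))) + 2
  dctr <- sqrt(rowSums(sweep(allpos, 2, ctr)^2))
  fitted <- dctr > r_fix
  if (sum(fitted) < 4)
    stop("fewer than 4 fitted charges; constraints infeasible - ",
         "increase n_charges or shrink r_fix")
  # reference potential and interaction matrices in atomic units
  Vref <- ewald_potential(cell, check_sites, params)
  b2a <- BOHR_PER_ANGSTROM
  D <- .cross_distances(check_sites * b2a, allpos * b2a)
  D[D < 1e-8] <- Inf   # a site does not see its own charge
  A <- 1 / D
  resid0 <- (A %*% allq) - Vref
  Afit <- A[, fitted, drop = FALSE]
  bfix <- Vref - A[, !fitted, drop = FALSE] %*% allq[!fitted]
  # constraints: total charge and dipole of the whole array are zero
  Cm <- rbind(1, t(allpos[fitted, , drop = FALSE] * b2a))
  d <- c(-sum(allq[!fitted]),
         -colSums(allpos[!fitted, , drop = FALSE] * b2a * allq[!fitted]))
  nf <- sum(fitted)
  # the fit is underdetermined (many more outer charges than match
  # conditions): take the minimal change from the nominal charges that
  # satisfies the potential match and the charge/dipole constraints
  M <- rbind(Afit, Cm)
  rhs <- c(bfix, d) - M %*% allq[fitted]
  delta <- tryCatch(
    crossprod(M, solve(tcrossprod(M), rhs)),
    error = function(e)
      stop("charge-fitting constraints infeasible (", conditionMessage(e),
           "); increase n_charges"))
  qnew <- allq
  qnew[fitted] <- allq[fitted] + as.numeric(delta)
  resid1 <- (A %*% qnew) - Vref
  out <- point_charge_array(allpos, qnew,
                            ifelse(fitted, "fitted", "fixed"))
  attr(out, "residual_before") <- max(abs(resid0))
  attr(out, "residual_after") <- max(abs(resid1))
  out
}

# ---- connectivity fingerprints -------------------------------------------

#' Bond-order (shortest-path) matrix of a molecule
#'
#' B_ij is the number of bonds on the shortest path between atoms i and j
#' of the molecule's bond graph (0 on the diagonal, 1 for bonded pairs).
#' This is the converged fixed point of iteratively extending first
#' connections through common neighbors.
#'
#' @param mol a connected `aggrex_structure`.
#' @return integer matrix with attribute `"elements"`.
#' @export
bond_order_matrix <- function(mol) {
  g <- .bond_graph(mol)
  B <- igraph::distances(g)
  if (any(is.infinite(B))) {
    comp <- segment_molecules(mol)
    stop("molecule is disconnected (", length(comp), " fragments: ",
         paste(vapply(comp, function(m) paste0("{", paste(m, collapse = ","),
                                               "}"), ""), collapse = " "),
         ")")
  }
  B <- matrix(as.integer(B), nrow(B))
  attr(B, "elements") <- mol$atoms$element
  B
}

#' Connectivity fingerprint of an atom
#'
#' An atom's identity within its molecule: its own element plus, for every
#' other atom, that atom's element and its bond distance.  Encoded as a
#' canonical string so equal fingerprints compare with `==`; chemically
#' equivalent atoms (e.g. the three hydrogens of a methyl group) share one
#' fingerprint.
#'
#' @param B bond-order matrix from [bond_order_matrix()].
#' @param i atom index.
#' @param elements element symbols (default: taken from `B`'s attribute).
#' @return character scalar, e.g. `"H|C:1,H:2,H:2,O:2,H:3"`.
#' @export
atom_fingerprint <- function(B, i, elements = attr(B, "elements")) {
  stopifnot(!is.null(elements), i >= 1, i <= nrow(B))
  others <- setdiff(seq_len(nrow(B)), i)
  shells <- paste0(elements[others], ":", B[i, others])
  ord <- order(B[i, others], elements[others])
  paste0(elements[i], "|", paste(shells[ord], collapse = ","))
}

.molecule_fingerprints <- function(s, molecules = NULL) {
  if (is.null(molecules)) molecules <- segment_molecules(s)
  fp <- character(n_atoms(s))
  for (m in molecules) {
    B <- bond_order_matrix(structure_slice(s, m))
    for (k in seq_along(m)) fp[m[k]] <- atom_fingerprint(B, k)
  }
  fp
}

#' Redistribute reference charges by atom identity
#'
#' Maps partial charges from a reference structure (e.g. a single-molecule
#' population analysis) onto any finite or periodic ensemble of the same
#' molecules: every target atom receives the mean charge of the reference
#' atoms sharing its connectivity fingerprint.
#'
#' @param reference `aggrex_structure` with meaningful charges.
#' @param target `aggrex_structure` whose atoms all match some reference
#'   fingerprint.
#' @return `target` with charges assigned.
#' @export
assign_charges <- function(reference, target) {
  fref <- .molecule_fingerprints(reference)
  qmap <- tapply(reference$atoms$charge, fref, mean)
  ftar <- .molecule_fingerprints(target)
  hit <- match(ftar, names(qmap))
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    stop(sprintf("no reference atom matches target atom %d (%s): %s",
                 bad, target$atoms$element[bad], ftar[bad]))
  }
  target$atoms$charge <- as.numeric(qmap[hit])
  target
}

#' Self-consistent point-charge embedding loop
#'
#' Iterates the mutual polarization between the embedded region and its
#' crystal environment: (1) region 1 is embedded in a point-charge array
#' derived from the current cell charges; (2) the calculator performs a
#' population analysis of region 1 in the requested state; (3) the
#' resulting fractional charges are redistributed onto the unit cell by
#' connectivity fingerprint; (4) repeat until the population analysis stops
#' changing.  Convergence: max per-atom difference between the analysis and
#' the charges that produced its embedding is below `tol`.
#'
#' @param calc calculator (see [make_calculator()]) with `population`
#'   capability.
#' @param cell neutral periodic `aggrex_structure` (charges are the
#'   starting guess).
#' @param region1 atom indices of the embedded molecule within `cell`.
#' @param state "ground" or "excited" population analysis.
#' @param tol convergence threshold on per-atom charge change, e.
#' @param max_iter iteration cap.
#' @param mixing linear mixing factor on charge updates (1 = undamped).
#' @param embedding_builder function(cell) -> `aggrex_charges` building the
#'   embedding array from the current cell charges; default: Ewald-fitted
#'   array via [fit_ewald_charges()].
#' @return list with `charges` (final embedding array), `cell` (updated
#'   charges), `iterations`, and `trace` (max charge change per iteration).
#' @export
sc_embedding_loop <- function(calc, cell, region1,
                              state = c("ground", "excited"),
                              tol = 1e-4, max_iter = 50, mixing = 1,
                              embedding_builder = NULL) {
  state <- match.arg(state)
  istate <- if (state == "excited") 1L else 0L
  if (!("population" %in% calc$capabilities))
    stop("calculator does not provide population analysis")
  if (is.null(embedding_builder))
    embedding_builder <- function(cl)
      fit_ewald_charges(cl, structure_slice(cl, region1))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    emb <- embedding_builder(cell)
    geom <- structure_slice(cell, region1)
    res <- calc$evaluate(geom, emb, istate)
    if (is.null(res$populations))
      stop("calculator returned no populations")
    qcur <- cell$atoms$charge[region1]
    qpop <- res$populations
    change <- max(abs(qpop - qcur))
    trace <- c(trace, change)
    if (change < tol)
      return(list(charges = emb, cell = cell, iterations = it,
                  trace = trace))
    qmix <- qcur + mixing * (qpop - qcur)
    ref <- geom
    ref$atoms$charge <- qmix
    cell <- assign_charges(ref, cell)
  }
  stop("self-consistent embedding did not converge in ", max_iter,
       " iterations; charge-change trace: ",
       paste(sprintf("%.2e", trace), collapse = " "))
}
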