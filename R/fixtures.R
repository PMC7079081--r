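#' Deterministic toy crystal generator
#'
#' Small synthetic unit cells for exercising the geometry, Voronoi, dimer
#' and Ewald machinery without external data:
#' \describe{
#'   \item{rocksalt}{conventional cubic cell, 8 sites of alternating +q/-q
#'     (Na/Cl labels); nearest-neighbor distance a/2.}
#'   \item{cscl}{2-site cubic cell, +q at the corner, -q at the body
#'     center (Cs/Cl labels).}
#'   \item{herringbone-diatomic}{two symmetry-related diatomic molecules
#'     per monoclinic-like cell, tilted by +/- `tilt` degrees from the c
#'     axis — a minimal herringbone motif.}
#'   \item{planar-quad}{one planar 4-atom (3 x 1 A rectangle) molecule
#'     centered in a 10 A cubic cell.}
#' }
#'
#' @param motif one of "rocksalt", "cscl", "herringbone-diatomic",
#'   "planar-quad".
#' @param a lattice constant, Angstrom (cubic motifs) — for the
#'   herringbone motif the cell is (a, 1.25 a, 1.5 a).
#' @param charge magnitude of the site charges for the ionic motifs, e.
#' @param bond_length diatomic bond length (herringbone), Angstrom.
#' @param tilt herringbone tilt angle, degrees.
#' @return an `aggrex_structure` with lattice and charges; always
#'   charge-neutral.
#' @export
make_toy_crystal <- function(motif = c("rocksalt", "cscl",
                                       "herringbone-diatomic",
                                       "planar-quad"),
                             a = 4, charge = 1, bond_length = 1.1,
                             tilt = 30) {
  motif <- match.arg(motif)
  stopifnot(a > 0)
  if (motif == "rocksalt") {
    frac <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
                  c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
    el <- c(rep("Na", 4), rep("Cl", 4))
    q <- c(rep(charge, 4), rep(-charge, 4))
    latt <- diag(a, 3)
    s <- new_structure(el, frac %*% latt, q, lattice = latt,
                       bonding = bonding_scheme("center-distance",
                                                threshold = a / 2 * 0.9))
  } else if (motif == "cscl") {
    latt <- diag(a, 3)
    s <- new_structure(c("Cs", "Cl"), rbind(c(0, 0, 0), c(.5, .5, .5)) %*% latt,
                       c(charge, -charge), lattice = latt,
                       bonding = bonding_scheme("center-distance",
                                                threshold = a * 0.8))
  } else if (motif == "herringbone-diatomic") {
    latt <- diag(c(a, 1.25 * a, 1.5 * a))
    th <- tilt * pi / 180
    half <- bond_length / 2 * c(sin(th), 0, cos(th))
    c1 <- c(0.25, 0.25, 0.25) %*% latt
    c2 <- c(0.75, 0.75, 0.75) %*% latt
    pos <- rbind(c1 - half, c1 + half,
                 c2 - half * c(-1, 1, 1), c2 + half * c(-1, 1, 1))
    s <- new_structure(rep("N", 4), pos, rep(c(0.1, -0.1), 2),
                       lattice = latt,
                       bonding = bonding_scheme("center-distance",
                                                threshold = bond_length * 1.2))
  } else {
    latt <- diag(max(a, 10), 3)
    ctr <- c(.5, .5, .5) %*% latt
    pos <- rbind(c(-1.5, -0.5, 0), c(1.5, -0.5, 0),
                 c(1.5, 0.5, 0), c(-1.5, 0.5, 0))
    pos <- sweep(pos, 2, as.numeric(ctr), `+`)
    # bond both rectangle edges (1 and 3 A) but not the 3.16 A diagonal
    s <- new_structure(rep("C", 4), pos, 0, lattice = latt,
                       bonding = bonding_scheme("center-distance",
                                                threshold = 3.1))
  }
  s
}

#' A methanol molecule at a standard geometry
#'
#' Six-atom CH3OH with textbook bond lengths and tetrahedral-ish angles;
#' handy as a connected reference molecule for bonding, fingerprint and
#' charge-assignment work.  Atom order: C, O, H(methyl) x3, H(hydroxyl).
#'
#' @param charges optional per-atom charges (default: small plausible
#'   Mulliken-like values summing to zero).
#' @return an `aggrex_structure`.
#' @export
make_methanol <- function(charges = c(-0.30, -0.50, 0.10, 0.10, 0.10, 0.50)) {
  pos <- rbind(
    C = c(0.0000, 0.0000, 0.0000),
    O = c(1.4200, 0.0000, 0.0000),
    H1 = c(-0.3633, 1.0277, 0.0000),
    H2 = c(-0.3633, -0.5139, 0.8901),
    H3 = c(-0.3633, -0.5139, -0.8901),
    H4 = c(1.7300, 0.8900, 0.0000))
  new_structure(c("C", "O", "H", "H", "H", "H"), pos, charges)
}

#' Random single-excitation wavefunction generator
#'
#' Seed-deterministic two-fragment CIS-like wavefunctions for stress
#' testing the exciton indices: identity AO overlap, random orthonormal MO
#' coefficients, and random amplitudes normalized to sum(sigma C^2) = 1.
#' With `localized = TRUE` the MOs are rotated only within each fragment's
#' AO block, so every orbital is 100% on one fragment (A-occupied,
#' B-occupied, A-virtual, B-virtual blocks in that order).
#'
#' @param n_occ_A,n_vir_A,n_occ_B,n_vir_B orbital counts per fragment.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param n_states number of excited states to generate.
#' @param localized generate fragment-pure orbitals.
#' @return an `aggrex_wavefunction`; MOs ordered occupied(A,B) then
#'   virtual(A,B); AOs ordered fragment A then B.
#' @export
random_cis_wavefunction <- function(n_occ_A = 4, n_vir_A = 4, n_occ_B = 4,
                                    n_vir_B = 4, seed = NULL, n_states = 1,
                                    localized = FALSE) {
  stopifnot(n_occ_A > 0, n_vir_A > 0, n_occ_B > 0, n_vir_B > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  nA <- n_occ_A + n_vir_A
  nB <- n_occ_B + n_vir_B
  n <- nA + nB
  rand_orth <- function(k) qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  if (localized) {
    QA <- rand_orth(nA)
    QB <- rand_orth(nB)
    # columns: occA, occB, virA, virB; AO rows: A block then B block
    mo <- matrix(0, n, n)
    mo[1:nA, c(1:n_occ_A, n_occ_A + n_occ_B + 1:n_vir_A)] <- QA
    mo[nA + 1:nB, c(n_occ_A + 1:n_occ_B,
                    n_occ_A + n_occ_B + n_vir_A + 1:n_vir_B)] <- QB
  } else {
    mo <- rand_orth(n)
  }
  n_occ <- n_occ_A + n_occ_B
  pairs <- expand.grid(i = seq_len(n_occ), j = n_occ + seq_len(n - n_occ))
  amps <- lapply(seq_len(n_states), function(st) {
    C <- stats::rnorm(nrow(pairs))
    C <- C / sqrt(sum(C^2))   # all i < j so sigma = +1
    data.frame(i = pairs$i, j = pairs$j, C = C)
  })
  wavefunction_data(mo, diag(n),
                    c(rep("A", nA), rep("B", nB)), amps)
}

#' Analytic mock potential-energy surfaces
#'
#' Pure calculators over flat coordinate space, used wherever a real
#' quantum-chemistry program would sit behind the calculator contract:
#' \describe{
#'   \item{quadratic}{E = e0 + k/2 |x - x0|^2 over all 3N coordinates.}
#'   \item{double-well}{E = h (x1^2 - w^2)^2 + omega/2 sum(rest^2), two
#'     minima at x1 = +/- w.}
#'   \item{two-state-conical}{2-state model over the first two coordinates
#'     (x, y): E(+/-) = omega/2 (x^2 + y^2) +/- sqrt((kappa x)^2 +
#'     (c y)^2) + omega/2 sum(rest^2); the states are degenerate on the
#'     seam x = y = 0.}
#' }
#' Coordinates are taken verbatim from the geometry's position matrix
#' (flattened column-major: all x, then all y, then all z; for a single
#' atom this is just its (x, y, z)), so energies are analytic functions of
#' whatever coordinate unit the geometry uses.  If `embedding_coupling` is nonzero,
#' a Coulomb-like term couples every atom to the embedding charges:
#' E += coupling * sum_c q_c sum_a 1/|r_a - R_c|, with matching gradient.
#'
#' @param form PES form, see above.
#' @param x0 minimum position (quadratic): vector recycled to 3N.
#' @param k,e0 quadratic force constant and offset.
#' @param h,w double-well height scale and half-separation.
#' @param kappa,cc,omega conical-model tuning/coupling/harmonic constants.
#' @param embedding_coupling scale of the embedding Coulomb term.
#' @param populations fixed per-atom charges to report, or a function
#'   (geometry, embedding, state) -> charges for self-consistency mocks.
#' @return an `aggrex_calculator` with energy, gradient, excited-state
#'   (conical form) and population (when `populations` given) capability.
#' @export
make_mock_calculator <- function(form = c("quadratic", "double-well",
                                          "two-state-conical"),
                                 x0 = 0, k = 1, e0 = 0, h = 1, w = 1,
                                 kappa = 1, cc = 1, omega = 1,
                                 embedding_coupling = 0,
                                 populations = NULL) {
  form <- match.arg(form)
  emb_term <- function(geom, emb) {
    if (is.null(emb) || embedding_coupling == 0)
      return(list(e = 0, g = matrix(0, n_atoms(geom), 3)))
    p <- positions(geom)
    d <- .cross_distances(p, emb$positions)
    e <- embedding_coupling * sum(sweep(1 / d, 2, emb$charges, `*`))
    g <- matrix(0, nrow(p), 3)
    for (dim in 1:3) {
      diff <- outer(p[, dim], emb$positions[, dim], `-`)
      g[, dim] <- -embedding_coupling *
        rowSums(sweep(diff / d^3, 2, emb$charges, `*`))
    }
    list(e = e, g = g)
  }
  core <- switch(form,
    "quadratic" = function(x, state) {
      xr <- rep_len(x0, length(x))
      list(e = e0 + k / 2 * sum((x - xr)^2), g = k * (x - xr))
    },
    "double-well" = function(x, state) {
      g <- omega * x
      g[1] <- 4 * h * x[1] * (x[1]^2 - w^2)
      list(e = h * (x[1]^2 - w^2)^2 + omega / 2 * sum(x[-1]^2), g = g)
    },
    "two-state-conical" = function(x, state) {
      r <- sqrt((kappa * x[1])^2 + (cc * x[2])^2)
      sgn <- if (state > 0) 1 else -1
      e <- omega / 2 * sum(x^2) + sgn * r
      g <- omega * x
      if (r > 1e-12) {
        g[1] <- g[1] + sgn * kappa^2 * x[1] / r
        g[2] <- g[2] + sgn * cc^2 * x[2] / r
      }
      list(e = e, g = g)
    })
  caps <- c("energy", "gradient")
  if (form == "two-state-conical") caps <- c(caps, "excited_states")
  if (!is.null(populations)) caps <- c(caps, "population")
  make_calculator(function(geometry, embedding = NULL, state = 0L) {
    x <- as.vector(positions(geometry))
    res <- core(x, state)
    et <- emb_term(geometry, embedding)
    pops <- if (is.function(populations))
      populations(geometry, embedding, state)
    else populations
    list(energy = res$e + et$e,
         gradient = matrix(res$g, ncol = 3) + et$g,
         populations = pops)
  }, capabilities = caps)
}
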