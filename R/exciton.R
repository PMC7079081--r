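#' Wavefunction data for a two-fragment system
#'
#' Program-agnostic container for the quantities needed by the exciton
#' classification indices: MO coefficients over an AO basis, the AO overlap
#' matrix, the fragment (A/B) each AO belongs to, and single-excitation
#' (CIS/TDDFT) amplitudes per excited state.
#'
#' @param mo_coefficients AO x MO numeric matrix (column k = MO k).
#' @param ao_overlap symmetric positive-definite AO overlap matrix S.
#' @param fragment_of_ao character vector ("A"/"B"), one entry per AO.
#' @param amplitudes list (one per excited state) of data.frames with
#'   columns `i` (occupied MO), `j` (virtual MO), `C` (amplitude); the
#'   signed normalization is sum(sigma * C^2) = 1 with sigma = +1 for
#'   i < j and -1 for i > j.
#' @param renormalize divide amplitudes by sqrt(|sum(sigma C^2)|) on input
#'   (different quantum-chemistry programs use different closed-shell
#'   conventions).
#' @return object of class `aggrex_wavefunction`.
#' @export
wavefunction_data <- function(mo_coefficients, ao_overlap, fragment_of_ao,
                              amplitudes, renormalize = FALSE) {
  mo_coefficients <- as.matrix(mo_coefficients)
  ao_overlap <- as.matrix(ao_overlap)
  stopifnot(nrow(mo_coefficients) == nrow(ao_overlap),
            ncol(ao_overlap) == nrow(ao_overlap),
            length(fragment_of_ao) == nrow(ao_overlap),
            all(fragment_of_ao %in% c("A", "B")))
  if (max(abs(ao_overlap - t(ao_overlap))) > 1e-10)
    stop("AO overlap matrix must be symmetric")
  amplitudes <- lapply(amplitudes, function(a) {
    a <- as.data.frame(a)
    stopifnot(all(c("i", "j", "C") %in% names(a)))
    if (renormalize) {
      s <- sum(.sigma_ij(a$i, a$j) * a$C^2)
      if (abs(s) < 1e-12) stop("cannot renormalize: sum(sigma C^2) ~ 0")
      a$C <- a$C / sqrt(abs(s))
    }
    a
  })
  structure(list(mo_coefficients = mo_coefficients, ao_overlap = ao_overlap,
                 fragment_of_ao = as.character(fragment_of_ao),
                 amplitudes = amplitudes),
            class = "aggrex_wavefunction")
}

.sigma_ij <- function(i, j) ifelse(i < j, 1, -1)

#' Mulliken fragment density of one molecular orbital
#'
#' Integrated Mulliken density of MO k on fragment A:
#' rho_A^k = sum_{mu in A, nu in A} c_mu c_nu S_munu
#'         + sum_{mu in A, nu in B} c_mu c_nu S_munu,
#' i.e. fragment A's diagonal block plus its full share of the A-B overlap
#' cross terms.  For an S-normalized MO, rho_A + rho_B = 1.
#'
#' @param w an `aggrex_wavefunction`.
#' @param fragment "A" or "B".
#' @param k MO index (column of the coefficient matrix).
#' @return fragment density in electrons.
#' @export
mulliken_fragment_density <- function(w, fragment = c("A", "B"), k) {
  fragment <- match.arg(fragment)
  c_k <- w$mo_coefficients[, k]
  nrm <- as.numeric(t(c_k) %*% w$ao_overlap %*% c_k)
  if (abs(nrm - 1) > 1e-6)
    stop(sprintf("MO %d is not S-normalized (c'Sc = %.8f)", k, nrm))
  inA <- w$fragment_of_ao == fragment
  sum((c_k[inA] * (w$ao_overlap[inA, , drop = FALSE] %*% c_k)))
}

#' Exciton classification indices
#'
#' For excited state I with single-excitation amplitudes C_{i->j} and
#' Mulliken fragment densities rho_A of the involved orbitals:
#' sumP_A = sum sigma C^2 (rho_A^j + rho_A^i)  and
#' deltaP_A = sum sigma C^2 (rho_A^j - rho_A^i),
#' with sigma = +1 for i < j and -1 otherwise.  Both are in electrons, with
#' bounds 0 <= sumP <= 2 and -1 <= deltaP <= 1.  sumP near 2 (0) marks a
#' transition confined to fragment A (B); deltaP near -1 (+1) marks net
#' charge transfer A->B (B->A).
#'
#' @param w an `aggrex_wavefunction`.
#' @param state excited-state index (into `w$amplitudes`).
#' @param fragment fragment label, default "A".
#' @return list with `sumP`, `deltaP` (e-) and `label` from
#'   [classify_exciton()].
#' @export
exciton_indices <- function(w, state, fragment = "A") {
  amp <- w$amplitudes[[state]]
  sig <- .sigma_ij(amp$i, amp$j)
  nrm <- sum(sig * amp$C^2)
  if (abs(nrm - 1) > 1e-6)
    stop(sprintf("amplitudes not normalized: sum(sigma C^2) = %.8f", nrm))
  orbs <- sort(unique(c(amp$i, amp$j)))
  rho <- vapply(orbs, function(k)
    mulliken_fragment_density(w, fragment, k), 0)
  names(rho) <- orbs
  ri <- rho[as.character(amp$i)]
  rj <- rho[as.character(amp$j)]
  sumP <- sum(sig * amp$C^2 * (rj + ri))
  deltaP <- sum(sig * amp$C^2 * (rj - ri))
  list(sumP = sumP, deltaP = deltaP,
       label = classify_exciton(sumP, deltaP))
}

#' Classify an exciton from its indices
#'
#' An excitation less than `threshold` (default 0.5 e-) away from an
#' extreme value of either index is assigned that type; charge-transfer
#' tests take precedence over localization tests, and anything else is a
#' delocalized Frenkel exciton.
#'
#' @param sumP sum index, within [0, 2].
#' @param deltaP difference index, within [-1, 1].
#' @param threshold closeness-to-extreme threshold, e-.
#' @return one of "CT(A->B)", "CT(B->A)", "LOC(A)", "LOC(B)", "DELOC".
#' @export
classify_exciton <- function(sumP, deltaP, threshold = 0.5) {
  if (sumP < -1e-9 || sumP > 2 + 1e-9 || abs(deltaP) > 1 + 1e-9)
    stop("indices out of bounds: sumP in [0,2], deltaP in [-1,1]")
  if (abs(deltaP - (-1)) < threshold) return("CT(A->B)")
  if (abs(deltaP - 1) < threshold) return("CT(B->A)")
  if (abs(sumP - 2) < threshold) return("LOC(A)")
  if (abs(sumP - 0) < threshold) return("LOC(B)")
  "DELOC"
}

# ---- couplings ------------------------------------------------------------

#' Point-dipole-approximation exciton coupling
#'
#' Kasha model: J = (mu_i . mu_j) / R^3
#'                - 3 (mu_i . R_ij)(R_ij . mu_j) / R^5,
#' with R_ij the vector between the monomer centroids.  Atomic units
#' throughout (dipoles in a.u., positions in Bohr, J in Hartree).
#'
#' @param mu_i,mu_j transition dipole moments, length-3, a.u.
#' @param R_i,R_j monomer centroid positions, Bohr.
#' @return coupling in Hartree.
#' @export
coupling_pda <- function(mu_i, mu_j, R_i, R_j) {
  Rij <- R_j - R_i
  R <- sqrt(sum(Rij^2))
  if (R < 1e-12) stop("coincident monomer centroids")
  sum(mu_i * mu_j) / R^3 - 3 * sum(mu_i * Rij) * sum(Rij * mu_j) / R^5
}

#' Atomic-transition-charge exciton coupling
#'
#' Coulomb interaction between the two monomers' atomic transition charges:
#' J = sum_a sum_b q_a q_b / |R_a - R_b| (Hartree, with charges in e and
#' distances in Bohr).
#'
#' @param q_i,q_j per-atom transition charges of the two monomers, e.
#' @param pos_i,pos_j atom position matrices (n x 3).
#' @param unit unit of the positions: "angstrom" (default, converted) or
#'   "bohr".
#' @return coupling in Hartree.
#' @export
coupling_atc <- function(q_i, pos_i, q_j, pos_j,
                         unit = c("angstrom", "bohr")) {
  unit <- match.arg(unit)
  pos_i <- matrix(pos_i, ncol = 3); pos_j <- matrix(pos_j, ncol = 3)
  stopifnot(length(q_i) == nrow(pos_i), length(q_j) == nrow(pos_j))
  if (unit == "angstrom") {
    pos_i <- pos_i * BOHR_PER_ANGSTROM
    pos_j <- pos_j * BOHR_PER_ANGSTROM
  }
  d <- .cross_distances(pos_i, pos_j)
  if (any(d < 1e-10)) stop("coincident atoms between the two monomers")
  sum(outer(q_i, q_j) / d)
}

#' Half-gap exciton coupling
#'
#' For a resonant dimer the S1/S2 splitting equals twice the exciton
#' coupling, so |J| = (E2 - E1) / 2.  Exact when the constituent monomers
#' are in perfect resonance; an approximation otherwise.
#'
#' @param E1,E2 the two adiabatic state energies (any unit), E2 >= E1.
#' @return |J| in the unit of the inputs.
#' @export
coupling_half_gap <- function(E1, E2) {
  if (E2 < E1) stop("E2 must be >= E1")
  (E2 - E1) / 2
}

#' Diabatization of adiabatic states by property matching
#'
#' Property-based diabatization: given N adiabatic
#' energies and an excited-state property per adiabatic state (transition
#' dipole moments as length-3 vectors, or atomic transition charges as
#' per-atom vectors), plus the same property computed for the N isolated
#' monomers in their aggregate orientation, form the overlap matrix
#' M_kl = <prop_k^adiabatic, prop_l^reference>, take its singular value
#' decomposition M = U Sigma V', and build the best unitary adiabatic->
#' diabatic map C = (U V')'.  The diabatic Hamiltonian is
#' H_D = C diag(E) C'; its off-diagonal elements are the exciton couplings
#' and its eigenvalues reproduce the adiabatic energies exactly.
#'
#' @param E_adiabatic numeric vector of N adiabatic energies.
#' @param props_adiabatic matrix whose N columns are the adiabatic
#'   properties (3 x N for TDMs, natoms x N for ATCs).
#' @param props_reference matrix of the N isolated-monomer (diabatic
#'   reference) properties, same shape.
#' @return object of class `aggrex_diabatic`: list with `H` (N x N,
#'   symmetric, unit of the input energies), `C` (the unitary map), and
#'   `couplings` (the lower-triangle off-diagonals).
#' @export
diabatize <- function(E_adiabatic, props_adiabatic, props_reference) {
  PA <- as.matrix(props_adiabatic)
  PR <- as.matrix(props_reference)
  N <- length(E_adiabatic)
  stopifnot(N >= 2, ncol(PA) == N, ncol(PR) == N, nrow(PA) == nrow(PR))
  M <- t(PA) %*% PR
  sv <- svd(M)
  if (min(sv$d) < 1e-10 * max(sv$d, 1))
    stop("property overlap matrix is rank deficient; ",
         "choose a different excited-state property")
  C <- t(sv$u %*% t(sv$v))
  H <- C %*% diag(E_adiabatic, N) %*% t(C)
  H <- (H + t(H)) / 2
  structure(list(H = H, C = C, couplings = H[lower.tri(H)]),
            class = "aggrex_diabatic")
}

#' @export
print.aggrex_diabatic <- function(x, ...) {
  cat("Diabatic Hamiltonian:\n")
  print(signif(x$H, 8))
  cat("couplings (lower triangle):", sprintf("% .6g", x$couplings), "\n")
  invisible(x)
}

# ---- JSON exchange --------------------------------------------------------

#' Read excited-state data from the JSON exchange format
#'
#' Neutral interchange schema used to decouple the analysis from any
#' particular quantum-chemistry program.  Recognized top-level fields (all
#' optional except where a downstream function needs them):
#' `energies` (state energies), `tdms` (N x 3), `atcs` (N x natoms),
#' `mo_coefficients` (AO x MO), `ao_overlap`, `fragment_of_ao`,
#' `amplitudes` (list of {i, j, C} records per state).
#'
#' @param path JSON file path.
#' @return list mirroring the fields; `wavefunction` is an
#'   `aggrex_wavefunction` when the orbital fields are present.
#' @export
read_state_json <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- list(energies = d$energies,
              tdms = if (!is.null(d$tdms)) matrix(unlist(d$tdms), ncol = 3,
                                                  byrow = is.list(d$tdms))
                     else NULL,
              atcs = d$atcs,
              centroid = d$centroid,
              positions = if (!is.null(d$positions))
                matrix(unlist(d$positions), ncol = 3,
                       byrow = is.list(d$positions)) else NULL)
  if (!is.null(d$mo_coefficients) && !is.null(d$ao_overlap) &&
      !is.null(d$fragment_of_ao) && !is.null(d$amplitudes)) {
    as_mat <- function(x) {
      if (is.matrix(x)) x
      else do.call(rbind, lapply(x, unlist))
    }
    amps <- d$amplitudes
    if (is.data.frame(amps)) amps <- list(amps)
    out$wavefunction <- wavefunction_data(as_mat(d$mo_coefficients),
                                          as_mat(d$ao_overlap),
                                          d$fragment_of_ao, amps)
  }
  out
}

#' Write excited-state data to the JSON exchange format
#'
#' @param x list with any of the fields documented in [read_state_json()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_state_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
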