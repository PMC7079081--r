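# minimal hand-built wavefunctions ------------------------------------------

# 2 AOs (one per fragment), identity overlap unless given
wf2 <- function(mo, amps, S = diag(2))
  wavefunction_data(mo, S, c("A", "B"), amps)

# block-localized 4-orbital system: AOs (A1, A2, B1, B2); MOs: occA, occB,
# virA, virB each purely on one fragment
wf_localized <- function(amps) {
  mo <- matrix(0, 4, 4)
  mo[1, 1] <- 1  # occ on A
  mo[3, 2] <- 1  # occ on B
  mo[2, 3] <- 1  # vir on A
  mo[4, 4] <- 1  # vir on B
  wavefunction_data(mo, diag(4), c("A", "A", "B", "B"), amps)
}

test_that("Mulliken fragment density covers pure, split and overlapping cases", {
  # MO entirely on A
  w <- wf2(matrix(c(1, 0, 0, 1), 2), list(data.frame(i = 1, j = 2, C = 1)))
  expect_equal(mulliken_fragment_density(w, "A", 1), 1)
  expect_equal(mulliken_fragment_density(w, "B", 1), 0)
  # equal split, identity overlap
  weq <- wf2(cbind(c(1, 1) / sqrt(2), c(1, -1) / sqrt(2)),
             list(data.frame(i = 1, j = 2, C = 1)))
  expect_equal(mulliken_fragment_density(weq, "A", 1), 0.5)
  # non-orthogonal AOs: S12 = 0.3, c = (1,1)/sqrt(2 + 0.6)
  S <- matrix(c(1, .3, .3, 1), 2)
  cvec <- c(1, 1) / sqrt(2.6)
  other <- c(1, -1) / sqrt(1.4)   # S-normalized partner
  wno <- wf2(cbind(cvec, other), list(data.frame(i = 1, j = 2, C = 1)), S)
  rhoA_hand <- cvec[1]^2 + cvec[1] * cvec[2] * 0.3   # direct expansion
  expect_equal(mulliken_fragment_density(wno, "A", 1), rhoA_hand)
  expect_equal(mulliken_fragment_density(wno, "A", 1) +
                 mulliken_fragment_density(wno, "B", 1), 1, tolerance = 1e-10)
  # unnormalized MO is rejected with the norm in the message
  bad <- wf2(matrix(c(2, 0, 0, 1), 2), list(data.frame(i = 1, j = 2, C = 1)))
  expect_error(mulliken_fragment_density(bad, "A", 1), "not S-normalized")
})

test_that("exciton indices hit the localized and charge-transfer limits", {
  # A-occ -> A-vir: LOC(A) limit
  w <- wf_localized(list(data.frame(i = 1, j = 3, C = 1)))
  r <- exciton_indices(w, 1)
  expect_equal(r$sumP, 2)
  expect_equal(r$deltaP, 0)
  expect_equal(r$label, "LOC(A)")
  # A-occ -> B-vir: CT(A->B) limit
  w <- wf_localized(list(data.frame(i = 1, j = 4, C = 1)))
  r <- exciton_indices(w, 1)
  expect_equal(r$sumP, 1)
  expect_equal(r$deltaP, -1)
  expect_equal(r$label, "CT(A->B)")
  # occupied on A, virtual split 50/50 between fragments
  mo <- matrix(0, 4, 4)
  mo[1, 1] <- 1; mo[3, 2] <- 1
  mo[c(2, 4), 3] <- 1 / sqrt(2)
  mo[c(2, 4), 4] <- c(1, -1) / sqrt(2)
  w <- wavefunction_data(mo, diag(4), c("A", "A", "B", "B"),
                         list(data.frame(i = 1, j = 3, C = 1)))
  r <- exciton_indices(w, 1)
  expect_equal(r$sumP, 1.5)     # direct evaluation: 1*(0.5 + 1)
  expect_equal(r$deltaP, -0.5)
})

test_that("amplitude normalization is enforced and renormalize fixes it", {
  bad <- list(data.frame(i = 1, j = 3, C = 2))
  w <- wf_localized(lapply(bad, identity))
  expect_error(exciton_indices(w, 1), "not normalized")
  wr <- wavefunction_data(diag(4), diag(4), c("A", "A", "B", "B"), bad,
                          renormalize = TRUE)
  expect_equal(sum(wr$amplitudes[[1]]$C^2), 1)
})

test_that("index bounds and fragment antisymmetry hold over random wavefunctions", {
  for (seed in 1:40) {
    w <- random_cis_wavefunction(2, 2, 2, 2, seed = seed)
    rA <- exciton_indices(w, 1, "A")
    rB <- exciton_indices(w, 1, "B")
    expect_gte(rA$sumP, 0); expect_lte(rA$sumP, 2)
    expect_gte(rA$deltaP, -1); expect_lte(rA$deltaP, 1)
    expect_equal(rA$sumP + rB$sumP, 2, tolerance = 1e-10)
    expect_equal(rA$deltaP, -rB$deltaP, tolerance = 1e-10)
  }
})

test_that("classification matches the reference perylene-style assignments", {
  expect_equal(classify_exciton(0.95, 0.90), "CT(B->A)")
  expect_equal(classify_exciton(1.88, 0.07), "LOC(A)")
  expect_equal(classify_exciton(1.0, 0.0), "DELOC")
  expect_equal(classify_exciton(0.2, -0.1), "LOC(B)")
  expect_equal(classify_exciton(1.1, -0.8), "CT(A->B)")
  expect_error(classify_exciton(2.5, 0), "bounds")
})

test_that("point-dipole coupling reproduces the textbook orientations", {
  # parallel unit dipoles perpendicular to R at 5 Bohr
  expect_equal(coupling_pda(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), c(5, 0, 0)),
               1 / 125)
  # collinear head-to-tail dipoles
  expect_equal(coupling_pda(c(1, 0, 0), c(1, 0, 0), c(0, 0, 0), c(5, 0, 0)),
               1 / 125 - 3 * 25 / 5^5)
  # sign flip of one dipole negates J
  expect_equal(coupling_pda(-c(0, 0, 1), c(0, 0, 1), c(0, 0, 0), c(5, 0, 0)),
               -1 / 125)
  expect_error(coupling_pda(c(0, 0, 1), c(0, 0, 1), c(1, 1, 1), c(1, 1, 1)),
               "coincident")
})

test_that("transition-charge coupling: point charges, permutation, far-field", {
  expect_equal(coupling_atc(0.1, c(0, 0, 0), -0.1, c(4, 0, 0), unit = "bohr"),
               -0.0025)
  # atom-order permutation leaves J unchanged
  set.seed(3)
  q1 <- rnorm(4, sd = .1); q2 <- rnorm(5, sd = .1)
  p1 <- matrix(rnorm(12), 4); p2 <- matrix(rnorm(15), 5) + 10
  perm <- sample(4)
  expect_equal(coupling_atc(q1[perm], p1[perm, ], q2, p2, unit = "bohr"),
               coupling_atc(q1, p1, q2, p2, unit = "bohr"))
  # far field: ATC approaches PDA computed from the ATC dipoles
  q <- c(0.3, -0.3)                      # dipole 0.3 * 1 Bohr
  pa <- rbind(c(0, 0, 0.5), c(0, 0, -0.5))
  R <- 80                                # 80x the monomer size
  pb <- pa + matrix(rep(c(R, 0, 0), 2), 2, byrow = TRUE)
  Jatc <- coupling_atc(q, pa, q, pb, unit = "bohr")
  mu <- colSums(q * pa)
  Jpda <- coupling_pda(mu, mu, c(0, 0, 0), c(R, 0, 0))
  expect_equal(Jatc / Jpda, 1, tolerance = 0.01)
})

test_that("half-gap halves the adiabatic splitting and matches 2x2 theory", {
  expect_equal(coupling_half_gap(3.0, 3.2), 0.1)
  expect_equal(coupling_half_gap(2.5, 2.5), 0)
  expect_error(coupling_half_gap(3.2, 3.0), ">=")
  # symmetric 2x2 diabatic Hamiltonian: eigenvalue gap is exactly 2|J|
  J <- 0.073
  H <- matrix(c(2.1, J, J, 2.1), 2)
  ev <- sort(eigen(H, symmetric = TRUE)$values)
  expect_equal(coupling_half_gap(ev[1], ev[2]), abs(J), tolerance = 1e-12)
})

test_that("diabatization recovers planted 2x2 and 3x3 Hamiltonians", {
  # identity case: reference equals adiabatic properties
  P <- cbind(c(1, 0, 0), c(0, 1, 0))
  d0 <- diabatize(c(2.0, 2.4), P, P)
  expect_equal(d0$C, diag(2), tolerance = 1e-12)
  expect_equal(d0$H[1, 2], 0, tolerance = 1e-12)

  plant_recover <- function(Hd, Pref) {
    eg <- eigen(Hd, symmetric = TRUE)
    Pad <- Pref %*% eg$vectors          # adiabatic props from eigvecs
    diabatize(eg$values, Pad, Pref)
  }
  H2 <- matrix(c(2.2, 0.1, 0.1, 2.2), 2)
  d2 <- plant_recover(H2, cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(d2$H, H2, tolerance = 1e-10)

  H3 <- matrix(c(2.0, 0.10, 0.05,
                 0.10, 2.1, 0.02,
                 0.05, 0.02, 2.3), 3)
  d3 <- plant_recover(H3, diag(3))
  expect_equal(d3$H, H3, tolerance = 1e-10)
  # eigenvalues of H_D are the adiabatic energies (unitary similarity)
  expect_equal(sort(eigen(d3$H, symmetric = TRUE)$values),
               sort(eigen(H3, symmetric = TRUE)$values), tolerance = 1e-10)
})

test_that("diabatization absorbs adiabatic phases; reference flips only flip J's sign", {
  H2 <- matrix(c(2.2, 0.1, 0.1, 2.2), 2)
  eg <- eigen(H2, symmetric = TRUE)
  Pref <- cbind(c(1, 0, 0), c(0, 1, 0))
  Pad <- Pref %*% eg$vectors
  base <- diabatize(eg$values, Pad, Pref)$H
  # an adiabatic state's phase is unobservable: H_D unchanged
  flipA <- Pad; flipA[, 1] <- -flipA[, 1]
  expect_equal(diabatize(eg$values, flipA, Pref)$H, base, tolerance = 1e-10)
  # a diabatic (reference) phase flips the sign of its couplings only
  flipR <- Pref; flipR[, 2] <- -flipR[, 2]
  flipped <- diabatize(eg$values, Pad, flipR)$H
  expect_equal(diag(flipped), diag(base), tolerance = 1e-10)
  expect_equal(abs(flipped), abs(base), tolerance = 1e-10)
})

test_that("rank-deficient property overlap is rejected with advice", {
  P <- cbind(c(1, 0, 0), c(1, 0, 0))   # identical reference properties
  expect_error(diabatize(c(2, 2.4), P, P), "rank deficient")
})

test_that("excited-state JSON exchange round-trips couplings inputs", {
  f <- withr::local_tempfile(fileext = ".json")
  x <- list(energies = c(2.0, 2.4),
            tdms = matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE))
  write_state_json(x, f)
  back <- read_state_json(f)
  expect_equal(back$energies, x$energies)
  expect_equal(back$tdms, x$tdms, ignore_attr = TRUE)
})
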