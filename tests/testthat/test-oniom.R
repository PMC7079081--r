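# two single-atom "molecules" 5 A apart; region 1 = atom 1
two_atom_system <- function(high, low, mode = "mechanical",
                            embedding = NULL) {
  geom <- new_structure(c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0)),
                        charges = c(0, 0.3),
                        bonding = bonding_scheme("center-distance", 1.5))
  oniom_system(geom, 1, high, low, mode, embedding)
}

test_that("subtractive ONIOM energy is plain arithmetic with cancellation", {
  expect_equal(oniom_energy(-2.0, -5.0, -1.5), -5.5)
  # high = low collapses to the full-system low energy
  e <- runif(1)
  expect_equal(oniom_energy(e, -7.3, e), -7.3)
  # linearity in each argument
  expect_equal(oniom_energy(1 + 2, 0, 0),
               oniom_energy(1, 0, 0) + oniom_energy(2, 0, 0))
})

test_that("region boundaries may not cross covalent bonds", {
  me <- make_methanol()
  calc <- make_mock_calculator("quadratic")
  expect_error(oniom_system(me, 1:3, calc, calc), "whole molecules")
})

test_that("electrostatic embedding enters only the region-1 terms", {
  high <- make_mock_calculator("quadratic", k = 2, embedding_coupling = 1)
  low <- make_mock_calculator("quadratic", k = 1, embedding_coupling = 1)
  emb <- point_charge_array(matrix(c(0, 3, 0), 1), 0.5)
  sys <- two_atom_system(high, low, "OEEC", emb)
  g1 <- structure_slice(sys$geometry, 1)
  # hand-composed combination of the three calculator calls
  eh1 <- high$evaluate(g1, emb, 0)$energy
  el12 <- low$evaluate(sys$geometry, NULL, 0)$energy
  el1 <- low$evaluate(g1, emb, 0)$energy
  expect_equal(oniom_ee_energy(sys), eh1 + el12 - el1)
})

test_that("zero embedding charges reduce to the mechanical combination", {
  high <- make_mock_calculator("quadratic", k = 2, embedding_coupling = 1)
  low <- make_mock_calculator("quadratic", k = 1, embedding_coupling = 1)
  emb0 <- point_charge_array(matrix(c(0, 3, 0), 1), 0)
  sys_e <- two_atom_system(high, low, "OEEC", emb0)
  sys_m <- two_atom_system(high, low, "mechanical")
  expect_equal(oniom_ee_energy(sys_e), oniom_ee_energy(sys_m),
               tolerance = 1e-12)
})

test_that("identical levels with identical embedding collapse exactly", {
  calc <- make_mock_calculator("quadratic", k = 1.3, x0 = 0.2,
                               embedding_coupling = 0.7)
  # mechanical mode: E = E(1) + E(12) - E(1) = E(12) at machine precision
  sys <- two_atom_system(calc, calc, "mechanical")
  full <- calc$evaluate(sys$geometry, NULL, 0)$energy
  expect_identical(oniom_ee_energy(sys), full)
  # gradient equals the full-system gradient restricted to region 1
  gfull <- calc$evaluate(sys$geometry, NULL, 0)$gradient
  expect_equal(oniom_gradient(sys), gfull[1, , drop = FALSE],
               tolerance = 1e-14)
})

test_that("ONIOM gradients pass central finite differences", {
  high <- make_mock_calculator("quadratic", k = 2, x0 = 0.5,
                               embedding_coupling = 1)
  low <- make_mock_calculator("quadratic", k = 1, embedding_coupling = 1)
  emb <- point_charge_array(rbind(c(0, 3, 0), c(1, -4, 2)), c(0.5, -0.5))
  sys <- two_atom_system(high, low, "OEEC", emb)
  geom <- sys$geometry
  x0 <- as.vector(positions(geom)[1, , drop = FALSE])
  g <- as.vector(oniom_gradient(sys, geom))
  h <- 1e-5
  set1 <- function(x) {
    p <- positions(geom); p[1, ] <- x
    g2 <- geom
    g2$atoms$x <- p[, 1]; g2$atoms$y <- p[, 2]; g2$atoms$z <- p[, 3]
    g2
  }
  for (dim in 1:3) {
    xp <- x0; xp[dim] <- xp[dim] + h
    xm <- x0; xm[dim] <- xm[dim] - h
    fd <- (oniom_ee_energy(sys, set1(xp)) -
             oniom_ee_energy(sys, set1(xm))) / (2 * h)
    expect_equal(g[dim], fd, tolerance = 1e-6)
  }
})

test_that("translation-invariant mocks give translation-invariant gradients", {
  calc <- make_mock_calculator("double-well", h = 0.4, w = 1.2, omega = 0)
  geom <- new_structure("C", matrix(c(0.4, 0, 0), 1))
  sys <- oniom_system(geom, 1, calc, calc, "mechanical")
  g1 <- oniom_gradient(sys, geom)
  # the double-well depends only on coordinate 1: shifting y, z is neutral
  geom2 <- translate_structure(geom, c(0, 7, -3))
  expect_equal(oniom_gradient(sys, geom2), g1, tolerance = 1e-12)
})

test_that("minimization finds the quadratic bowl minimum", {
  calc <- make_mock_calculator("quadratic", x0 = c(1, 2, 3), k = 2)
  geom <- new_structure("C", matrix(0, 1, 3))
  sys <- oniom_system(geom, 1, calc, calc, "mechanical")
  res <- optimize_minimum(sys, tol = 1e-7)
  expect_true(res$converged)
  expect_equal(as.vector(positions(res$geometry)), c(1, 2, 3),
               tolerance = 1e-6)
  # the final energy never exceeds the starting energy
  expect_lte(res$energy, res$trace[1])
  expect_equal(min(res$trace), res$energy, tolerance = 1e-12)
})

test_that("minimization stays in the starting basin of a double well", {
  calc <- make_mock_calculator("double-well", h = 1, w = 1.5, omega = 1)
  sys_r <- oniom_system(new_structure("C", matrix(c(0.4, 0, 0), 1)), 1,
                        calc, calc, "mechanical")
  res_r <- optimize_minimum(sys_r, tol = 1e-8)
  expect_equal(unname(positions(res_r$geometry)[1, 1]), 1.5,
               tolerance = 1e-5)
  sys_l <- oniom_system(new_structure("C", matrix(c(-0.4, 0, 0), 1)), 1,
                        calc, calc, "mechanical")
  res_l <- optimize_minimum(sys_l, tol = 1e-8)
  expect_equal(unname(positions(res_l$geometry)[1, 1]), -1.5,
               tolerance = 1e-5)
})

test_that("region 2 coordinates and embedding are untouched by optimization", {
  calc <- make_mock_calculator("quadratic", x0 = 0.5, k = 1)
  emb <- point_charge_array(matrix(c(0, 3, 0), 1), 0.25)
  sys <- two_atom_system(calc, calc, "OEEC", emb)
  res <- optimize_minimum(sys, tol = 1e-7)
  expect_identical(positions(res$geometry)[2, ], positions(sys$geometry)[2, ])
  expect_identical(sys$embedding, emb)
})

test_that("the gap penalty has the documented limits and monotonicity", {
  expect_equal(penalty_function(1.3, 1.3), 1.3)          # degenerate limit
  expect_equal(penalty_function(0, 1, sigma = 3.5, alpha = 0.02),
               0.5 + 3.5 / 1.02)
  expect_warning(f <- penalty_function(1, 0), "reordered")
  expect_equal(f, penalty_function(0, 1))
  # increasing gap at fixed mean increases F
  mean_e <- 2
  F_of_gap <- function(d) penalty_function(mean_e - d / 2, mean_e + d / 2)
  gaps <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(vapply(gaps, F_of_gap, 0)) > 0))
})

test_that("MECI search matches a dense grid oracle on the conical model", {
  kappa <- 0.8; cc <- 0.5; omega <- 0.3
  calc <- make_mock_calculator("two-state-conical", kappa = kappa, cc = cc,
                               omega = omega)
  geom <- new_structure("C", matrix(c(0.9, 0.7, 0), 1))
  sys <- oniom_system(geom, 1, calc, calc, "mechanical")
  res <- optimize_meci(sys, gap_tol = 1e-3, tol = 1e-6)
  expect_lt(res$gap, 1e-3)
  # oracle: dense grid search of min mean energy subject to the gap bound
  gx <- seq(-1, 1, by = 0.01)
  grid <- expand.grid(x = gx, y = gx)
  e0 <- omega / 2 * (grid$x^2 + grid$y^2) -
    sqrt((kappa * grid$x)^2 + (cc * grid$y)^2)
  e1 <- omega / 2 * (grid$x^2 + grid$y^2) +
    sqrt((kappa * grid$x)^2 + (cc * grid$y)^2)
  ok <- (e1 - e0) < 1e-3
  best <- which.min(((e0 + e1) / 2)[ok])
  oracle <- grid[ok, ][best, ]
  found <- positions(res$geometry)[1, 1:2]
  expect_equal(as.numeric(found), as.numeric(c(oracle$x, oracle$y)),
               tolerance = 0.011)   # grid resolution
  expect_equal(res$mean_energy, ((e0 + e1) / 2)[ok][best],
               tolerance = 1e-3)
})

test_that("at zero coupling the penalty search reduces to mean-energy descent", {
  calc <- make_mock_calculator("two-state-conical", kappa = 0.8, cc = 0,
                               omega = 0.3)
  # cc = 0: states cross along x = 0 (a seam); F = mean energy there
  geom <- new_structure("C", matrix(c(0.5, 0.8, 0), 1))
  sys <- oniom_system(geom, 1, calc, calc, "mechanical")
  res <- optimize_meci(sys, gap_tol = 1e-3, tol = 1e-7)
  expect_lt(abs(positions(res$geometry)[1, 1]), 1e-3)
  expect_lt(res$mean_energy, 1e-5)   # seam minimum at the origin
})

test_that("raising sigma never increases the final gap", {
  calc <- make_mock_calculator("two-state-conical", kappa = 0.8, cc = 0.5,
                               omega = 0.3)
  geom <- new_structure("C", matrix(c(0.9, 0.7, 0), 1))
  sys <- oniom_system(geom, 1, calc, calc, "mechanical")
  gaps <- vapply(c(1, 3.5, 10), function(sg) {
    optimize_meci(sys, sigma = sg, gap_tol = 0.05, tol = 1e-8,
                  sigma_steps = 1)$gap
  }, 0)
  expect_true(all(diff(gaps) <= 1e-6))
})

test_that("missing excited-state capability raises a clear error", {
  calc <- make_mock_calculator("quadratic")
  sys <- two_atom_system(calc, calc)
  expect_error(oniom_ee_energy(sys, state = 1), "excited_states")
  expect_error(optimize_meci(sys), "excited_states")
})
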