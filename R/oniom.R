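#' Calculator contract
#'
#' The pluggable energy/gradient/population provider that stands in for an
#' external electronic-structure program.  A calculator is a pure function
#' of (geometry, embedding, state): identical inputs must give identical
#' outputs.  Gradients are reported per atom in Hartree per coordinate
#' unit, with the same coordinate convention as the geometry handed in.
#'
#' @param evaluate function(geometry, embedding, state) returning a list
#'   with `energy` (scalar), optionally `gradient` (n x 3 matrix) and
#'   `populations` (per-atom charges, e).  `embedding` is an
#'   `aggrex_charges` or NULL; `state` an integer (0 = ground).
#' @param capabilities character subset of
#'   c("energy", "gradient", "excited_states", "population").
#' @return object of class `aggrex_calculator`.
#' @export
make_calculator <- function(evaluate,
                            capabilities = c("energy", "gradient")) {
  stopifnot(is.function(evaluate),
            all(capabilities %in% c("energy", "gradient", "excited_states",
                                    "population")))
  structure(list(evaluate = evaluate, capabilities = capabilities),
            class = "aggrex_calculator")
}

.check_capability <- function(calc, cap) {
  if (!(cap %in% calc$capabilities))
    stop("calculator lacks capability: ", cap)
}

#' Subtractive ONIOM energy
#'
#' E_high:low(1 u 2) = E_high(1) + E_low(1 u 2) - E_low(1): the high-level
#' energy of the active region plus the low-level environment correction.
#'
#' @param E_high_1 high-level energy of region 1, Hartree.
#' @param E_low_12 low-level energy of the full system.
#' @param E_low_1 low-level energy of region 1.
#' @return combined energy, Hartree.
#' @export
oniom_energy <- function(E_high_1, E_low_12, E_low_1)
  E_high_1 + E_low_12 - E_low_1

#' ONIOM system definition
#'
#' Two disjoint whole-molecule regions, a calculator per level, an
#' embedding model and (for the embedded models) a prepared point-charge
#' array.  Embedding models: `mechanical` (no charges), `OEC` (region-2
#' atomic charges), `OEEC` (Ewald-fitted array), `SC-OEEC-S0` /
#' `SC-OEEC-S1` (self-consistent arrays equilibrated in the ground or
#' excited state).  Region boundaries may not cross covalent bonds: regions
#' must be unions of whole molecules.
#'
#' @param geometry full-system `aggrex_structure` (region 1 u 2).
#' @param region1 atom indices of the active region.
#' @param high_calc,low_calc `aggrex_calculator`s.
#' @param embedding_mode one of "mechanical", "OEC", "OEEC", "SC-OEEC-S0",
#'   "SC-OEEC-S1".
#' @param embedding `aggrex_charges` for the embedded models; for OEC it is
#'   derived from the region-2 atoms when omitted.
#' @return object of class `aggrex_oniom`.
#' @export
oniom_system <- function(geometry, region1, high_calc, low_calc,
                         embedding_mode = c("mechanical", "OEC", "OEEC",
                                            "SC-OEEC-S0", "SC-OEEC-S1"),
                         embedding = NULL) {
  embedding_mode <- match.arg(embedding_mode)
  region1 <- sort(as.integer(region1))
  region2 <- setdiff(seq_len(n_atoms(geometry)), region1)
  mols <- segment_molecules(geometry)
  for (m in mols) {
    n_in <- sum(m %in% region1)
    if (n_in > 0 && n_in < length(m))
      stop("region boundary crosses a molecule (covalent bond); ",
           "regions must contain whole molecules")
  }
  if (embedding_mode == "OEC" && is.null(embedding) && length(region2))
    embedding <- point_charge_array(positions(geometry)[region2, , drop = FALSE],
                                    geometry$atoms$charge[region2])
  if (embedding_mode %in% c("OEEC", "SC-OEEC-S0", "SC-OEEC-S1") &&
      is.null(embedding))
    stop("embedding mode ", embedding_mode,
         " requires a prepared point-charge array")
  structure(list(geometry = geometry, region1 = region1, region2 = region2,
                 high_calc = high_calc, low_calc = low_calc,
                 embedding_mode = embedding_mode, embedding = embedding),
            class = "aggrex_oniom")
}

.oniom_terms <- function(system, geometry, state, need_gradient = FALSE) {
  if (state > 0) .check_capability(system$high_calc, "excited_states")
  emb <- if (system$embedding_mode == "mechanical") NULL else system$embedding
  g1 <- structure_slice(geometry, system$region1)
  # the point-charge array enters only the two region-1 terms
  high1 <- system$high_calc$evaluate(g1, emb, state)
  low12 <- system$low_calc$evaluate(geometry, NULL, 0L)
  low1 <- system$low_calc$evaluate(g1, emb, 0L)
  list(high1 = high1, low12 = low12, low1 = low1)
}

#' ONIOM electrostatically embedded energy
#'
#' E(1 u 2) = E_high^EE(1) + E_low(1 u 2) - E_low^EE(1): the point-charge
#' array polarizes only the two region-1 terms (adding it to the full
#' low-level term would merely shift the energy by a constant for a fixed
#' environment).  The high-level term is evaluated at the requested state.
#'
#' @param system an `aggrex_oniom`.
#' @param geometry full-system structure (default: the system's); only
#'   region-1 coordinates may differ from the system geometry.
#' @param state electronic state for the high-level term (0 = ground).
#' @return energy in Hartree.
#' @export
oniom_ee_energy <- function(system, geometry = system$geometry, state = 0L) {
  tr <- .oniom_terms(system, geometry, state)
  oniom_energy(tr$high1$energy, tr$low12$energy, tr$low1$energy)
}

#' ONIOM gradient over region-1 atoms
#'
#' grad E = grad E_high^EE(1) + grad E_low(1 u 2)|region1 - grad
#' E_low^EE(1); region 2 and the embedding charges are frozen.
#'
#' @inheritParams oniom_ee_energy
#' @return matrix (n_region1 x 3), Hartree per coordinate unit.
#' @export
oniom_gradient <- function(system, geometry = system$geometry, state = 0L) {
  .check_capability(system$high_calc, "gradient")
  .check_capability(system$low_calc, "gradient")
  tr <- .oniom_terms(system, geometry, state)
  r1 <- match(system$region1, seq_len(n_atoms(geometry)))
  tr$high1$gradient + tr$low12$gradient[r1, , drop = FALSE] -
    tr$low1$gradient
}

.set_region1 <- function(system, geometry, x) {
  p <- positions(geometry)
  p[system$region1, ] <- matrix(x, ncol = 3)
  positions(geometry) <- p
  geometry
}

#' Quasi-Newton minimization of an ONIOM potential-energy surface
#'
#' BFGS-family (L-BFGS-B) minimization over region-1 coordinates only;
#' region 2 and the embedding are frozen.  Convergence: largest absolute
#' gradient component below `tol`.
#'
#' @param system an `aggrex_oniom`.
#' @param geometry starting geometry (default: the system's).
#' @param state electronic state of the high-level term.
#' @param tol gradient convergence threshold (default 3e-4 Hartree per
#'   coordinate unit).
#' @param max_steps iteration cap.
#' @return object of class `aggrex_pes_result`: list with `geometry`,
#'   `energy`, `trace` (energy per accepted step), `converged`,
#'   `max_gradient`.
#' @export
optimize_minimum <- function(system, geometry = system$geometry, state = 0L,
                             tol = 3e-4, max_steps = 500) {
  x0 <- as.vector(positions(geometry)[system$region1, , drop = FALSE])
  trace <- numeric(0)
  fn <- function(x) {
    e <- oniom_ee_energy(system, .set_region1(system, geometry, x), state)
    trace <<- c(trace, e)
    e
  }
  gr <- function(x)
    as.vector(oniom_gradient(system, .set_region1(system, geometry, x),
                             state))
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_steps, pgtol = tol,
                                     factr = 10))
  gfin <- gr(opt$par)
  converged <- max(abs(gfin)) < tol
  if (!converged && opt$convergence != 0)
    stop("minimization did not converge (max |g| = ",
         signif(max(abs(gfin)), 3), "); energy trace: ",
         paste(sprintf("%.6f", utils::tail(trace, 5)), collapse = " "))
  structure(list(geometry = .set_region1(system, geometry, opt$par),
                 energy = opt$value, trace = trace, converged = converged,
                 max_gradient = max(abs(gfin))),
            class = "aggrex_pes_result")
}

#' Gap-penalty objective for conical-intersection search
#'
#' F = (E1 + E0)/2 + sigma * dE^2 / (dE + alpha) with dE = E1 - E0: the
#' mean energy of the two states plus a smooth penalty that vanishes with
#' the gap, so minimizing F drives the system to the lowest point of the
#' intersection seam without nonadiabatic coupling vectors.  `alpha` must
#' be much smaller than typical gaps; `sigma` weights the penalty.
#'
#' @param E0,E1 state energies, Hartree (reordered with a warning if
#'   E1 < E0).
#' @param sigma penalty multiplier (> 0), default 3.5.
#' @param alpha smoothing parameter, Hartree (> 0), default 0.02.
#' @return penalty value F, Hartree.
#' @export
penalty_function <- function(E0, E1, sigma = 3.5, alpha = 0.02) {
  stopifnot(sigma > 0, alpha > 0)
  if (E1 < E0) {
    warning("E1 < E0: states reordered by energy")
    tmp <- E0; E0 <- E1; E1 <- tmp
  }
  dE <- E1 - E0
  (E1 + E0) / 2 + sigma * dE^2 / (dE + alpha)
}

# d/d(dE) of the penalty term
.penalty_dgap <- function(dE, alpha) (dE^2 + 2 * alpha * dE) / (dE + alpha)^2

#' Minimal-energy conical intersection search
#'
#' Minimizes the penalty function over region-1 coordinates using the two
#' lowest states of the high-level calculator (states `state0` and
#' `state1`).  Success requires the final gap below `gap_tol`; on
#' stagnation above it, an error suggests raising sigma (an optional
#' geometric sigma-stepping schedule is provided).
#'
#' @param system an `aggrex_oniom` whose high-level calculator has
#'   excited-state energies and gradients.
#' @param geometry starting geometry.
#' @param sigma,alpha penalty parameters, see [penalty_function()].
#' @param gap_tol target energy gap, Hartree (default 1e-3).
#' @param tol gradient threshold on F.
#' @param max_steps optimizer cap per sigma stage.
#' @param sigma_steps number of sigma-stepping stages (sigma doubles each
#'   stage until the gap criterion is met).
#' @param state0,state1 the two states defining the intersection.
#' @return `aggrex_pes_result` with extra fields `gap` and `mean_energy`.
#' @export
optimize_meci <- function(system, geometry = system$geometry, sigma = 3.5,
                          alpha = 0.02, gap_tol = 1e-3, tol = 3e-4,
                          max_steps = 500, sigma_steps = 3,
                          state0 = 0L, state1 = 1L) {
  .check_capability(system$high_calc, "excited_states")
  two_state <- function(x) {
    g <- .set_region1(system, geometry, x)
    t0 <- .oniom_terms(system, g, state0)
    t1 <- .oniom_terms(system, g, state1)
    e0 <- oniom_energy(t0$high1$energy, t0$low12$energy, t0$low1$energy)
    e1 <- oniom_energy(t1$high1$energy, t1$low12$energy, t1$low1$energy)
    r1 <- system$region1
    g0 <- t0$high1$gradient + t0$low12$gradient[r1, , drop = FALSE] -
      t0$low1$gradient
    g1 <- t1$high1$gradient + t1$low12$gradient[r1, , drop = FALSE] -
      t1$low1$gradient
    if (e1 < e0) { tmp <- e0; e0 <- e1; e1 <- tmp
                   tmp <- g0; g0 <- g1; g1 <- tmp }
    list(e0 = e0, e1 = e1, g0 = g0, g1 = g1)
  }
  x <- as.vector(positions(geometry)[system$region1, , drop = FALSE])
  trace <- numeric(0)
  sig <- sigma
  for (stage in seq_len(max(1, sigma_steps))) {
    fn <- function(x) {
      st <- two_state(x)
      f <- (st$e1 + st$e0) / 2 +
        sig * (st$e1 - st$e0)^2 / ((st$e1 - st$e0) + alpha)
      trace <<- c(trace, f)
      f
    }
    gr <- function(x) {
      st <- two_state(x)
      dE <- st$e1 - st$e0
      as.vector((st$g1 + st$g0) / 2 +
                  sig * .penalty_dgap(dE, alpha) * (st$g1 - st$g0))
    }
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_steps, pgtol = tol,
                                       factr = 10))
    x <- opt$par
    st <- two_state(x)
    if (st$e1 - st$e0 < gap_tol) break
    sig <- sig * 2
  }
  st <- two_state(x)
  gap <- st$e1 - st$e0
  if (gap >= gap_tol)
    stop(sprintf(paste0("gap stagnated at %.3g Hartree (> %g); consider a ",
                        "larger sigma or more sigma_steps"), gap, gap_tol))
  structure(list(geometry = .set_region1(system, geometry, x),
                 energy = (st$e1 + st$e0) / 2, trace = trace,
                 converged = TRUE, gap = gap,
                 mean_energy = (st$e1 + st$e0) / 2),
            class = "aggrex_pes_result")
}

#' @export
print.aggrex_pes_result <- function(x, ...) {
  cat(sprintf("<aggrex_pes_result> E = %.8f Hartree, %s after %d evaluations\n",
              x$energy, if (x$converged) "converged" else "NOT converged",
              length(x$trace)))
  if (!is.null(x$gap)) cat(sprintf("  state gap: %.3g Hartree\n", x$gap))
  invisible(x)
}
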