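## Finite-difference linearized Poisson-Boltzmann solver and the energy
## primitives built on it.

#' Solver settings
#'
#' @param ionicStrength mol/L (default 0.2; the 0.05-0.2 range is typical)
#' @param temperature K
#' @param convergenceTol relative residual tolerance (1e-6)
#' @param maxIterations SOR cap
#' @param boundary "debye" (screened monopole sum on the box faces) or
#'   "coulombic" (unscreened)
#' @param omega SOR over-relaxation factor; NA picks
#'   \code{2 / (1 + sin(pi / max(dims)))}
#' @param sternRadius ion-exclusion shell beyond atom radii, Angstrom
#' @return a \linkS4class{SolverSettings}
#' @export
solverSettings <- function(ionicStrength = 0.2, temperature = 298,
                           convergenceTol = 1e-6, maxIterations = 20000L,
                           boundary = c("debye", "coulombic"), omega = NA_real_,
                           sternRadius = 2.0) {
  boundary <- match.arg(boundary)
  new("SolverSettings", ionicStrength = ionicStrength,
      temperature = temperature, convergenceTol = convergenceTol,
      maxIterations = as.integer(maxIterations), boundary = boundary,
      omega = omega, sternRadius = sternRadius)
}

.kappaOf <- function(map, settings) {
  sqrt(debyeKappaSq(settings@ionicStrength, map@epsSolvent,
                    settings@temperature))
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Discretizes div(eps grad phi) - eps_w kappa^2 phi = -4 pi C rho on the
#' map's grid (7-point stencil, harmonic-mean face permittivities, trilinear
#' charge assignment, Dirichlet screened-monopole boundary) and solves by
#' red-black SOR. kappa^2 is nonzero only on salt-masked (solvent, non-Stern)
#' nodes.
#'
#' @param map a \linkS4class{DielectricMap}
#' @param positions n x 3 charge positions (Angstrom), inside the box margins
#' @param charges n charges (e)
#' @param settings a \linkS4class{SolverSettings}
#' @param boundaryPhi optional full grid array carrying precomputed Dirichlet
#'   boundary values (used by focusing)
#' @return a \linkS4class{PotentialGrid} (phi in kcal/mol/e)
#' @export
solvePB <- function(map, positions, charges, settings = solverSettings(),
                    boundaryPhi = NULL) {
  grid <- map@grid
  h <- grid@spacing
  dims <- grid@dims
  positions <- rbind(positions)
  kappa <- .kappaOf(map, settings)
  kbar2 <- map@epsSolvent * kappa^2
  ## charges outside a focused sub-box act only through its boundary values
  lo <- grid@origin + h
  hi <- grid@origin + (dims - 2) * h
  inBox <- positions[, 1] > lo[1] & positions[, 1] < hi[1] &
    positions[, 2] > lo[2] & positions[, 2] < hi[2] &
    positions[, 3] > lo[3] & positions[, 3] < hi[3]
  if (any(!inBox) && is.null(boundaryPhi))
    stop("charges outside the grid box margins")
  src <- cpp_spread_charges(positions[inBox, , drop = FALSE],
                            charges[inBox], grid@origin, h, dims)
  b <- 4 * pi * .COULOMB * src / h
  if (is.null(boundaryPhi)) {
    kb <- if (settings@boundary == "debye") kappa else 0
    phi0 <- cpp_boundary_phi(positions, charges, grid@origin, h, dims,
                             map@epsSolvent, kb, .COULOMB)
  } else {
    phi0 <- as.numeric(boundaryPhi)
  }
  omega <- settings@omega
  if (is.na(omega)) omega <- 2 / (1 + sin(pi / max(dims)))
  res <- cpp_pb_sor(as.numeric(map@eps), as.numeric(map@saltMask), b, phi0,
                    dims, kbar2 * h^2, omega, settings@convergenceTol,
                    settings@maxIterations)
  if (!res$converged) {
    e <- simpleError(sprintf(
      "PB solver did not converge in %d iterations (last residual %.3g)",
      res$iterations, utils::tail(res$residuals, 1)))
    attr(e, "residuals") <- res$residuals
    stop(e)
  }
  new("PotentialGrid", grid = grid, phi = array(res$phi, dim = dims),
      charges = list(pos = positions, q = charges),
      iterations = as.integer(res$iterations), converged = TRUE)
}

#' Evaluate a potential grid at points (trilinear interpolation)
#'
#' @param pgrid a \linkS4class{PotentialGrid}
#' @param points m x 3 matrix
#' @return potentials, kcal/mol/e
#' @export
potentialAt <- function(pgrid, points) {
  cpp_trilinear(as.numeric(pgrid@phi), pgrid@grid@dims, pgrid@grid@origin,
                pgrid@grid@spacing, rbind(points))
}

## fill only the face nodes of `grid` by trilinear interpolation from a
## coarse potential
.focusBoundary <- function(coarse, grid) {
  dims <- grid@dims
  ax <- .gridAxes(grid)
  faceIdx <- which(array(
    outer(outer(seq_len(dims[1]) %in% c(1, dims[1]),
                seq_len(dims[2]) %in% c(1, dims[2]), "|"),
          seq_len(dims[3]) %in% c(1, dims[3]), "|"), dim = dims))
  kk <- arrayInd(faceIdx, dims)
  pts <- cbind(ax[[1]][kk[, 1]], ax[[2]][kk[, 2]], ax[[3]][kk[, 3]])
  vals <- potentialAt(coarse, pts)
  phi0 <- array(0, dim = dims)
  phi0[faceIdx] <- vals
  phi0
}

#' Two-level focused solve
#'
#' Solves on a coarse map spanning the whole box, then on a fine map whose
#' Dirichlet boundary is interpolated from the coarse solution.
#'
#' @param coarseMap,fineMap \linkS4class{DielectricMap}s on nested grids
#' @param positions,charges source charges
#' @param settings solver settings
#' @return list(coarse, fine) of \linkS4class{PotentialGrid}s
#' @export
solvePBFocused <- function(coarseMap, fineMap, positions, charges,
                           settings = solverSettings()) {
  coarse <- solvePB(coarseMap, positions, charges, settings)
  phi0 <- .focusBoundary(coarse, fineMap@grid)
  fine <- solvePB(fineMap, positions, charges, settings, boundaryPhi = phi0)
  list(coarse = coarse, fine = fine)
}

.isMapPair <- function(maps) is.list(maps) && !is(maps, "DielectricMap")

.solveAny <- function(maps, positions, charges, settings) {
  if (.isMapPair(maps))
    solvePBFocused(maps$coarse, maps$fine, positions, charges, settings)
  else list(coarse = NULL, fine = solvePB(maps, positions, charges, settings))
}

## evaluate phi at points, preferring the fine grid where points fall well
## inside it
.evalAny <- function(sol, points) {
  points <- rbind(points)
  fine <- sol$fine
  if (is.null(sol$coarse)) return(potentialAt(fine, points))
  g <- fine@grid
  lo <- g@origin + g@spacing
  hi <- g@origin + (g@dims - 2) * g@spacing
  inFine <- points[, 1] >= lo[1] & points[, 1] <= hi[1] &
    points[, 2] >= lo[2] & points[, 2] <= hi[2] &
    points[, 3] >= lo[3] & points[, 3] <= hi[3]
  out <- numeric(nrow(points))
  if (any(inFine)) out[inFine] <- potentialAt(fine, points[inFine, ,
                                                           drop = FALSE])
  if (any(!inFine)) out[!inFine] <- potentialAt(sol$coarse,
                                                points[!inFine, , drop = FALSE])
  out
}

.sameGrid <- function(a, b) {
  ga <- if (.isMapPair(a)) a$fine@grid else a@grid
  gb <- if (.isMapPair(b)) b$fine@grid else b@grid
  identical(ga@dims, gb@dims) && ga@spacing == gb@spacing &&
    max(abs(ga@origin - gb@origin)) < 1e-9
}

#' Dielectric response (Born-type) transfer energy
#'
#' Grid self-energies cancel between two runs of the same charge set at
#' identical grid placement in two environments:
#' \code{dG = 0.5 sum q (phi_env - phi_ref)}. With \code{env} the
#' protein/membrane map and \code{ref} the same cavity in pure water this is
#' the transfer component of the pKa shift, in kcal/mol.
#'
#' @param envMaps,refMaps a \linkS4class{DielectricMap} or a
#'   list(coarse, fine) pair; fine grids must coincide exactly
#' @param positions,charges the site charge distribution
#' @param settings solver settings
#' @return kcal/mol
#' @export
dielectricResponseEnergy <- function(envMaps, refMaps, positions, charges,
                                     settings = solverSettings()) {
  if (all(abs(charges) < 1e-15)) return(0)
  if (!.sameGrid(envMaps, refMaps))
    stop("grid placement differs between paired runs; ",
         "self-energy cancellation requires identical grids")
  positions <- rbind(positions)
  se <- .solveAny(envMaps, positions, charges, settings)
  sr <- .solveAny(refMaps, positions, charges, settings)
  0.5 * sum(charges * (.evalAny(se, positions) - .evalAny(sr, positions)))
}

#' Screened interaction energy between two charge sets
#'
#' Solves with set i as source and evaluates \code{sum q_j phi_i(r_j)}.
#'
#' @param maps environment map (or focused pair)
#' @param posI,qI source charge set
#' @param posJ,qJ probe charge set
#' @param settings solver settings
#' @return kcal/mol
#' @export
interactionEnergy <- function(maps, posI, qI, posJ, qJ,
                              settings = solverSettings()) {
  posI <- rbind(posI); posJ <- rbind(posJ)
  d2 <- outer(rowSums(posI^2), rowSums(posJ^2), "+") -
    2 * posI %*% t(posJ)
  if (min(d2) < 1e-12)
    stop("overlapping charge positions between interacting sites")
  if (all(abs(qJ) < 1e-15) || all(abs(qI) < 1e-15)) return(0)
  sol <- .solveAny(maps, posI, qI, settings)
  sum(qJ * .evalAny(sol, posJ))
}

#' Background (permanent-field) energy at a site
#'
#' Potential of the permanent background charges evaluated against the
#' site's protonation charge difference: \code{sum dq_a phi_back(r_a)} with
#' \code{dq = protonated - deprotonated}. The background set must exclude the
#' variable-charge atoms of every titratable site.
#'
#' @param maps environment map (or focused pair)
#' @param bgPositions,bgCharges the permanent background charge set
#' @param sitePositions,siteDq the site's difference distribution
#' @param settings solver settings
#' @return kcal/mol
#' @export
backgroundEnergy <- function(maps, bgPositions, bgCharges, sitePositions,
                             siteDq, settings = solverSettings()) {
  if (!length(bgCharges) || all(abs(bgCharges) < 1e-15)) return(0)
  sitePositions <- rbind(sitePositions)
  bgPositions <- rbind(bgPositions)
  d2 <- outer(rowSums(bgPositions^2), rowSums(sitePositions^2), "+") -
    2 * bgPositions %*% t(sitePositions)
  if (min(d2) < 1e-12)
    stop("background charge set contains atoms of a titratable group")
  sol <- .solveAny(maps, bgPositions, bgCharges, settings)
  sum(siteDq * .evalAny(sol, sitePositions))
}
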