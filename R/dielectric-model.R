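## Heterogeneous dielectric mapping: four-layer protein interior from polar
## atom density, implicit membrane slab, solvent.

#' Construct a grid specification
#'
#' @param coords n x 3 matrix of atom coordinates to enclose (or NULL with an
#'   explicit \code{origin}/\code{dims})
#' @param spacing node spacing in Angstrom (0.50 by default)
#' @param margin padding per side in Angstrom (10-17 typical; 15 default)
#' @param origin,dims explicit geometry overriding \code{coords}
#' @return a \linkS4class{GridSpec}
#' @export
gridSpec <- function(coords = NULL, spacing = 0.5, margin = 15,
                     origin = NULL, dims = NULL) {
  if (is.null(origin)) {
    stopifnot(!is.null(coords))
    coords <- rbind(coords)
    lo <- apply(coords, 2, min) - margin
    hi <- apply(coords, 2, max) + margin
    origin <- floor(lo / spacing) * spacing
    dims <- as.integer(ceiling((hi - origin) / spacing)) + 1L
  }
  new("GridSpec", origin = as.numeric(origin), spacing = spacing,
      dims = as.integer(dims))
}

.gridAxes <- function(grid) {
  lapply(1:3, function(d)
    grid@origin[d] + (seq_len(grid@dims[d]) - 1) * grid@spacing)
}

#' Construct an implicit membrane slab
#'
#' @param coreZmin,coreZmax z bounds of the acyl core (Angstrom)
#' @param headThickness headgroup band per leaflet (Angstrom, default 8)
#' @param epsCore core permittivity (2.0, or 2.5 for sensitivity checks)
#' @param epsHead headgroup permittivity (20 or 40)
#' @return a \linkS4class{MembraneSlab}
#' @export
membraneSlab <- function(coreZmin = -13.5, coreZmax = 13.5,
                         headThickness = 8, epsCore = 2.0, epsHead = 20) {
  new("MembraneSlab", coreZmin = coreZmin, coreZmax = coreZmax,
      headThickness = headThickness, epsCore = epsCore, epsHead = epsHead)
}

#' Local density of polar side-chain atoms
#'
#' Counts side-chain oxygen and nitrogen atoms (backbone N and O excluded)
#' within a hard-sphere kernel of the given radius around a point, divided by
#' the kernel volume.
#'
#' @param structure parameterized structure
#' @param point 3-vector, Angstrom
#' @param kernelRadius kernel radius, Angstrom (default 5)
#' @return atoms per cubic Angstrom
#' @export
polarDensity <- function(structure, point, kernelRadius = 5) {
  stopifnot(kernelRadius > 0)
  pc <- polarAtomCoords(structure)
  if (!nrow(pc)) return(0)
  d2 <- colSums((t(pc) - point)^2)
  sum(d2 <= kernelRadius^2) / (4 / 3 * pi * kernelRadius^3)
}

#' Coordinates of polar side-chain atoms (side-chain O and N)
#'
#' @param structure parameterized structure
#' @return m x 3 matrix
#' @export
polarAtomCoords <- function(structure) {
  a <- atoms(structure)
  sel <- a$element %in% c("N", "O") & !a$name %in% c("N", "O", "OXT")
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

#' Default monotone density-to-permittivity mapping
#'
#' Piecewise-linear curve through configurable (density, eps) breakpoints,
#' constant beyond the ends. Defaults place near-zero polar density in the
#' lowest layer and densely polar, loop-like neighbourhoods in the highest.
#'
#' @param breakpoints 2-column matrix (density in atoms/A^3, eps)
#' @return function(density) -> eps
#' @export
defaultEpsMapping <- function(breakpoints = cbind(
  density = c(0, 0.004, 0.008, 0.015), eps = c(3, 5, 10, 20))) {
  bp <- breakpoints[order(breakpoints[, 1]), , drop = FALSE]
  if (any(diff(bp[, 2]) < 0)) stop("mapping must be monotone non-decreasing")
  stats::approxfun(bp[, 1], bp[, 2], rule = 2)
}

.quantizeEps <- function(v, levels) {
  levels <- sort(levels)
  mids <- (levels[-1] + levels[-length(levels)]) / 2
  ## ties at a midpoint break upward (findInterval: mids[i] <= v)
  levels[findInterval(v, mids) + 1L]
}

#' Build the spatial permittivity map of a structure
#'
#' Nodes inside the solvent-excluded molecular surface (probe radius 1.4 A)
#' receive the four-layer quantization of the polar-density mapping; nodes
#' outside are solvent (eps 81) until \code{\link{applyMembrane}} overrides
#' them. The Stern ion-exclusion shell (default 2 A beyond atom radii) is
#' recorded in the salt mask.
#'
#' @param structure parameterized structure (radii assigned)
#' @param grid a \linkS4class{GridSpec}
#' @param mapping monotone density -> eps function
#' @param levels the discrete protein layers (default 3, 5, 10, 20)
#' @param probe solvent probe radius, Angstrom
#' @param kernelRadius polar-density kernel radius, Angstrom
#' @param ionicStrength mol/L for the solvent region
#' @param epsSolvent solvent permittivity (81)
#' @param sternRadius ion-exclusion shell, Angstrom
#' @return a \linkS4class{DielectricMap}
#' @export
buildEpsMap <- function(structure, grid, mapping = defaultEpsMapping(),
                        levels = c(3, 5, 10, 20), probe = 1.4,
                        kernelRadius = 5, ionicStrength = 0.2,
                        epsSolvent = 81, sternRadius = 2.0) {
  a <- atoms(structure)
  if (any(is.na(a$radius))) stop("structure radii unset; run assignParse()")
  pos <- as.matrix(a[, c("x", "y", "z")])
  dims <- grid@dims
  h <- grid@spacing
  n <- prod(dims)
  if (nrow(pos)) {
    mask <- cpp_ses_mask(pos, a$radius, grid@origin, h, dims, probe)
  } else mask <- integer(n)
  inside <- mask > 0L

  labels <- array(.REGION[["solvent"]], dim = dims)
  eps <- array(epsSolvent, dim = dims)
  if (any(inside)) {
    pc <- polarAtomCoords(structure)
    dens <- if (nrow(pc))
      cpp_polar_counts(pc, grid@origin, h, dims, kernelRadius) /
        (4 / 3 * pi * kernelRadius^3)
    else numeric(n)
    epsRaw <- mapping(dens[inside])
    if (any(epsRaw < 1)) stop("mapping returned eps < 1")
    lev <- .quantizeEps(epsRaw, levels)
    eps[inside] <- lev
    labels[inside] <- .REGION[match(lev, c(3, 5, 10, 20))]
  }
  stern <- if (nrow(pos))
    cpp_inflate(pos, a$radius + sternRadius, grid@origin, h, dims)
  else integer(n)
  salt <- array(as.numeric(labels == .REGION[["solvent"]] & stern == 0L),
                dim = dims)
  new("DielectricMap", grid = grid, eps = eps, labels = labels,
      ionicStrength = ionicStrength, epsSolvent = epsSolvent,
      saltMask = salt)
}

#' Homogeneous permittivity map (for analytic fixtures)
#'
#' @param grid a \linkS4class{GridSpec}
#' @param eps uniform permittivity
#' @param ionicStrength mol/L (salt everywhere when > 0)
#' @return a \linkS4class{DielectricMap}
#' @export
uniformEpsMap <- function(grid, eps, ionicStrength = 0) {
  dims <- grid@dims
  new("DielectricMap", grid = grid,
      eps = array(eps, dim = dims),
      labels = array(.REGION[["solvent"]], dim = dims),
      ionicStrength = ionicStrength, epsSolvent = eps,
      saltMask = array(as.numeric(ionicStrength > 0), dim = dims))
}

#' Spherical two-dielectric map (Born fixture)
#'
#' Inside radius \code{a} of \code{center}: \code{epsIn}; outside:
#' \code{epsOut}. No salt.
#'
#' @param grid a \linkS4class{GridSpec}
#' @param center sphere centre
#' @param a sphere radius, Angstrom
#' @param epsIn,epsOut permittivities
#' @return a \linkS4class{DielectricMap}
#' @export
sphereEpsMap <- function(grid, center, a, epsIn, epsOut) {
  ax <- .gridAxes(grid)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  inside <- r2 <= a^2
  eps <- array(epsOut, dim = grid@dims)
  eps[inside] <- epsIn
  labels <- array(.REGION[["solvent"]], dim = grid@dims)
  labels[inside] <- .REGION[["protein_layer_3"]]
  new("DielectricMap", grid = grid, eps = eps, labels = labels,
      ionicStrength = 0, epsSolvent = epsOut,
      saltMask = array(0, dim = grid@dims))
}

#' Overlay an implicit membrane slab on a permittivity map
#'
#' Non-protein nodes with z inside the acyl core get \code{epsCore}; those in
#' the headgroup bands get \code{epsHead}. Protein nodes keep their layer
#' permittivity. Membrane nodes carry no mobile ions.
#'
#' @param map a \linkS4class{DielectricMap}
#' @param slab a \linkS4class{MembraneSlab}
#' @param strict error when the slab core lies outside the box z range
#'   (relaxed for focused sub-boxes, which clip the slab)
#' @return the modified map
#' @export
applyMembrane <- function(map, slab, strict = TRUE) {
  grid <- map@grid
  zax <- .gridAxes(grid)[[3]]
  zmin <- min(zax); zmax <- max(zax)
  if (strict && (slab@coreZmin < zmin || slab@coreZmax > zmax))
    stop("membrane slab extends outside the grid box")
  protein <- map@labels <= .REGION[["protein_layer_20"]]
  zarr <- array(rep(zax, each = prod(grid@dims[1:2])), dim = grid@dims)
  core <- !protein & zarr >= slab@coreZmin & zarr <= slab@coreZmax
  head <- !protein & !core &
    ((zarr >= slab@coreZmin - slab@headThickness & zarr < slab@coreZmin) |
       (zarr > slab@coreZmax & zarr <= slab@coreZmax + slab@headThickness))
  map@eps[core] <- slab@epsCore
  map@eps[head] <- slab@epsHead
  map@labels[core] <- .REGION[["membrane_core"]]
  map@labels[head] <- .REGION[["membrane_head"]]
  map@saltMask[core | head] <- 0
  map
}

#' Region label codes
#'
#' @return named integer vector mapping region names to label codes
#' @export
regionCodes <- function() .REGION
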