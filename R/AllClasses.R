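#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ContinuumPKa, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Grid geometry
## ---------------------------------------------------------------------------

#' Regular 3D grid specification
#'
#' Node-centred cubic lattice: node (i, j, k) (1-based in R) sits at
#' \code{origin + spacing * (i-1, j-1, k-1)}.
#'
#' @slot origin numeric(3), Angstrom
#' @slot spacing numeric(1), Angstrom
#' @slot dims integer(3), number of nodes per axis
#' @exportClass GridSpec
setClass("GridSpec", representation(
  origin = "numeric", spacing = "numeric", dims = "integer"
), validity = function(object) {
  if (length(object@origin) != 3) return("origin must have length 3")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@dims) != 3 || any(object@dims < 2))
    return("dims must be 3 integers >= 2")
  TRUE
})

#' Implicit membrane slab
#'
#' A dielectric slab normal to z with a low-permittivity acyl core flanked by
#' two higher-permittivity headgroup bands.
#'
#' @slot coreZmin,coreZmax z bounds of the acyl core, Angstrom
#' @slot headThickness headgroup band thickness per leaflet, Angstrom
#' @slot epsCore,epsHead relative permittivities of core and headgroup regions
#' @exportClass MembraneSlab
setClass("MembraneSlab", representation(
  coreZmin = "numeric", coreZmax = "numeric", headThickness = "numeric",
  epsCore = "numeric", epsHead = "numeric"
), validity = function(object) {
  if (object@coreZmin >= object@coreZmax) return("coreZmin must be < coreZmax")
  if (object@epsCore >= object@epsHead) return("epsCore must be < epsHead")
  if (object@headThickness < 0) return("headThickness must be >= 0")
  if (object@epsCore < 1) return("permittivities must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## Structures and sites
## ---------------------------------------------------------------------------

#' Atomic structure with electrostatic parameters
#'
#' Ordered atom table with coordinates and (once assigned) partial charges and
#' radii. Columns of \code{atoms}: serial, name, element, resname, resno,
#' chain, x, y, z, charge, radius.
#'
#' @slot atoms data.frame of atoms in file order
#' @slot chains character vector of chain identifiers
#' @slot frameId integer frame index (0 for a single structure)
#' @exportClass ParameterizedStructure
setClass("ParameterizedStructure", representation(
  atoms = "data.frame", chains = "character", frameId = "integer"
), validity = function(object) {
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z", "charge", "radius")
  if (!all(need %in% colnames(object@atoms)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  r <- object@atoms$radius
  if (any(!is.na(r) & r < 0)) return("radii must be >= 0")
  if (nrow(object@atoms) && any(!nzchar(object@atoms$chain)))
    return("chain ids must be non-empty")
  TRUE
})

#' A titratable site
#'
#' One protonatable residue with its model pKa, acid/base character, and the
#' side-chain charge maps of the two protonation forms.
#'
#' @slot siteId string "chain:resno:resname"
#' @slot residueType 3-letter code (ASP, GLU, TYR, LYS, ARG, HIS, CYS, ...)
#' @slot acidOrBase "acid" or "base"
#' @slot modelPka model-compound pKa in water
#' @slot protonatedCharges,deprotonatedCharges named numeric, atom name -> e
#' @slot parents named character, hydrogen atom -> parent heavy atom (used to
#'   collapse charges of hydrogens absent from the coordinates)
#' @slot chain,resno location of the residue
#' @exportClass TitratableSite
setClass("TitratableSite", representation(
  siteId = "character", residueType = "character", acidOrBase = "character",
  modelPka = "numeric", protonatedCharges = "numeric",
  deprotonatedCharges = "numeric", parents = "character",
  chain = "character", resno = "integer"
), validity = function(object) {
  if (!object@acidOrBase %in% c("acid", "base"))
    return("acidOrBase must be 'acid' or 'base'")
  dq <- sum(object@protonatedCharges) - sum(object@deprotonatedCharges)
  if (abs(dq - 1) > 1e-9)
    return("protonated minus deprotonated charges must sum to exactly +1 e")
  chg <- if (object@acidOrBase == "acid") sum(object@deprotonatedCharges)
         else sum(object@protonatedCharges)
  want <- if (object@acidOrBase == "acid") -1 else 1
  if (abs(chg - want) > 1e-9)
    return("charged-form side chain must carry the formal charge of its class")
  TRUE
})

## ---------------------------------------------------------------------------
## Dielectric map and potentials
## ---------------------------------------------------------------------------

#' Spatial static permittivity map
#'
#' @slot grid GridSpec
#' @slot eps 3D numeric array of relative permittivities (>= 1)
#' @slot labels 3D integer array of region codes (see \code{regionCodes})
#' @slot ionicStrength mol/L (salt lives in solvent-labelled nodes outside the
#'   Stern layer)
#' @slot epsSolvent solvent permittivity (81 by default)
#' @slot saltMask 3D 0/1 array marking ion-accessible nodes
#' @exportClass DielectricMap
setClass("DielectricMap", representation(
  grid = "GridSpec", eps = "array", labels = "array",
  ionicStrength = "numeric", epsSolvent = "numeric", saltMask = "array"
), validity = function(object) {
  if (!identical(dim(object@eps), dim(object@labels)))
    return("eps and labels must share dimensions")
  if (any(object@eps < 1)) return("permittivities must be >= 1")
  if (object@ionicStrength < 0) return("ionic strength must be >= 0")
  TRUE
})

#' Electrostatic potential on a grid
#'
#' @slot grid GridSpec
#' @slot phi 3D array, kcal/mol/e
#' @slot charges list(pos = n x 3 matrix, q = numeric) that generated phi
#' @slot iterations,converged solver diagnostics
#' @exportClass PotentialGrid
setClass("PotentialGrid", representation(
  grid = "GridSpec", phi = "array", charges = "list",
  iterations = "integer", converged = "logical"
))

#' Finite-difference solver settings
#'
#' @slot ionicStrength mol/L (default 0.2)
#' @slot temperature K
#' @slot convergenceTol relative residual tolerance
#' @slot maxIterations SOR iteration cap
#' @slot boundary "debye" (screened monopole sum) or "coulombic"
#' @slot omega SOR relaxation factor (NA = auto)
#' @slot sternRadius ion-exclusion shell beyond atom radii, Angstrom
#' @exportClass SolverSettings
setClass("SolverSettings", representation(
  ionicStrength = "numeric", temperature = "numeric",
  convergenceTol = "numeric", maxIterations = "integer",
  boundary = "character", omega = "numeric", sternRadius = "numeric"
), validity = function(object) {
  if (object@convergenceTol <= 0) return("convergenceTol must be > 0")
  if (object@ionicStrength < 0) return("ionicStrength must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Energies, titration, ensembles
## ---------------------------------------------------------------------------

#' Per-site energy components and site-site couplings
#'
#' All values in pKa units. \code{intrinsicPka = modelPka + bornShift +
#' backgroundShift}; \code{W} is symmetric with zero diagonal, positive for
#' like-sign charge differences.
#'
#' @slot siteIds character
#' @slot modelPka,bornShift,backgroundShift,intrinsicPka numeric per site
#' @slot W symmetric site-site interaction matrix, pKa units
#' @slot frameId integer
#' @exportClass EnergyLedger
setClass("EnergyLedger", representation(
  siteIds = "character", modelPka = "numeric", bornShift = "numeric",
  backgroundShift = "numeric", intrinsicPka = "numeric", W = "matrix",
  frameId = "integer"
), validity = function(object) {
  n <- length(object@siteIds)
  if (!all(lengths(list(object@modelPka, object@bornShift,
                        object@backgroundShift, object@intrinsicPka)) == n))
    return("per-site component vectors must match siteIds length")
  if (n > 0) {
    if (!all(dim(object@W) == c(n, n))) return("W must be n x n")
    if (any(abs(diag(object@W)) > 1e-12)) return("diag(W) must be zero")
    asym <- max(abs(object@W - t(object@W)))
    scale <- max(abs(object@W), 1e-10)
    if (asym > 0.01 * scale + 1e-9) return("W must be symmetric within 1%")
  }
  chk <- object@modelPka + object@bornShift + object@backgroundShift
  if (n > 0 && max(abs(chk - object@intrinsicPka)) > 1e-9)
    return("intrinsicPka must equal modelPka + bornShift + backgroundShift")
  TRUE
})

#' Multi-site protonation model
#'
#' @slot siteIds character
#' @slot intrinsicPka numeric
#' @slot acidOrBase character ("acid"/"base" per site)
#' @slot W symmetric interaction matrix, pKa units
#' @slot pHGrid strictly increasing pH values
#' @exportClass MicrostateModel
setClass("MicrostateModel", representation(
  siteIds = "character", intrinsicPka = "numeric", acidOrBase = "character",
  W = "matrix", pHGrid = "numeric"
), validity = function(object) {
  n <- length(object@siteIds)
  if (length(object@intrinsicPka) != n || length(object@acidOrBase) != n)
    return("per-site vectors must match siteIds length")
  if (n > 0 && !all(dim(object@W) == c(n, n))) return("W must be n x n")
  if (n > 1 && max(abs(object@W - t(object@W))) > 1e-9)
    return("W must be symmetric")
  if (is.unsorted(object@pHGrid, strictly = TRUE))
    return("pHGrid must be strictly increasing")
  if (!all(object@acidOrBase %in% c("acid", "base")))
    return("acidOrBase entries must be 'acid' or 'base'")
  TRUE
})

#' Titration result
#'
#' @slot pHGrid pH values
#' @slot fractions nPH x nSites matrix of protonation probabilities
#' @slot siteIds character
#' @slot pkaHalf per-site pKa from the half-protonation crossing
#' @slot mcError per-site sampling standard error (0 for exact enumeration)
#' @slot seFractions nPH x nSites matrix of per-point standard errors
#' @slot seed integer seed used (NA for exact)
#' @slot method "exact" or "mc"
#' @exportClass TitrationResult
setClass("TitrationResult", representation(
  pHGrid = "numeric", fractions = "matrix", siteIds = "character",
  pkaHalf = "numeric", mcError = "numeric", seFractions = "matrix",
  seed = "integer", method = "character"
), validity = function(object) {
  f <- object@fractions
  if (length(f) && (min(f) < -1e-9 || max(f) > 1 + 1e-9))
    return("fractions must lie in [0, 1]")
  if (!object@method %in% c("exact", "mc"))
    return("method must be 'exact' or 'mc'")
  TRUE
})

#' Per-frame component ledger over an ensemble of snapshots
#'
#' @slot frames list of EnergyLedger, one per snapshot
#' @slot siteIds shared site list
#' @slot totals nFrames x nSites matrix of per-frame total shifts (born +
#'   background + thresholded pair terms), pKa units
#' @slot wThreshold pair inclusion threshold, pKa units
#' @exportClass FrameLedger
setClass("FrameLedger", representation(
  frames = "list", siteIds = "character", totals = "matrix",
  wThreshold = "numeric"
), validity = function(object) {
  ids <- lapply(object@frames, function(f) f@siteIds)
  if (length(ids) && !all(vapply(ids, identical, logical(1), y = object@siteIds)))
    return("all frames must share the same site list")
  fid <- vapply(object@frames, function(f) f@frameId, integer(1))
  if (length(fid) > 1 && any(diff(fid) <= 0))
    return("frame ids must be strictly increasing")
  TRUE
})

#' Ensemble uncertainty report
#'
#' @slot table per-site data.frame: siteId, meanTotal, sdTotal, pka,
#'   uncertainty, nEff
#' @slot strongPairs data.frame of pairs above the interaction threshold
#' @slot medianSd median SD over the designated site subset
#' @exportClass UncertaintyReport
setClass("UncertaintyReport", representation(
  table = "data.frame", strongPairs = "data.frame", medianSd = "numeric"
), validity = function(object) {
  if (nrow(object@table) && any(object@table$sdTotal < 0, na.rm = TRUE))
    return("SDs must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Sequence records
## ---------------------------------------------------------------------------

#' A protein coding sequence
#'
#' @slot nucleotides string over A/C/G/T, ATG-initiated, stop-terminated
#' @slot id identifier
#' @exportClass CodingSequence
setClass("CodingSequence", representation(
  nucleotides = "character", id = "character"
), validity = function(object) {
  nt <- object@nucleotides
  if (grepl("[^ACGT]", nt)) return("nucleotides must be over {A,C,G,T}")
  if (nchar(nt) %% 3 != 0) return("length must be divisible by 3")
  if (substr(nt, 1, 3) != "ATG") return("CDS must start with ATG")
  last <- substr(nt, nchar(nt) - 2, nchar(nt))
  if (!last %in% c("TAA", "TAG", "TGA")) return("CDS must end with a stop codon")
  TRUE
})

#' A translated protein with transit-peptide annotation
#'
#' @slot sequence 1-letter amino-acid string
#' @slot transitPeptideLength residues cleaved from the N terminus (NA if not
#'   annotated)
#' @slot matureStart 1-based index of the first mature residue
#' @exportClass ProteinRecord
setClass("ProteinRecord", representation(
  sequence = "character", transitPeptideLength = "integer",
  matureStart = "integer"
))
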