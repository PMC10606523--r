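## Assembly of Born, background, and site-site interaction components into
## intrinsic pKa values and the interaction matrix.

#' Pipeline configuration
#'
#' Bundles the grid, dielectric, membrane, solver, site-selection and
#' titration settings of a run. Spacings follow finite-difference practice
#' for pKa work: a coarse pass over the whole box and a focused fine pass
#' around each site.
#'
#' @param coarseSpacing coarse grid spacing, Angstrom
#' @param fineSpacing focused grid spacing, Angstrom (0.5 default)
#' @param margin box padding per side, Angstrom (10-17 typical)
#' @param focusHalfwidth half-width of the focused box around a site, Angstrom
#' @param probe solvent probe radius, Angstrom
#' @param kernelRadius polar-density kernel, Angstrom
#' @param epsLevels protein layer permittivities
#' @param mapping density -> eps function (NULL = default piecewise-linear)
#' @param epsSolvent solvent permittivity
#' @param membrane a \linkS4class{MembraneSlab} or NULL
#' @param solver a \linkS4class{SolverSettings}
#' @param policy a site policy from \code{\link{sitePolicy}}
#' @param table parameter table
#' @param pHGrid titration pH grid
#' @param scans,burnIn,batches Monte Carlo schedule
#' @param seed RNG seed recorded in outputs
#' @return a config list
#' @export
pkaConfig <- function(coarseSpacing = 1.0, fineSpacing = 0.5, margin = 12,
                      focusHalfwidth = 6, probe = 1.4, kernelRadius = 5,
                      epsLevels = c(3, 5, 10, 20), mapping = NULL,
                      epsSolvent = 81, membrane = NULL,
                      solver = solverSettings(), policy = sitePolicy(),
                      table = loadParameterTable(),
                      pHGrid = seq(0, 14, by = 0.2), scans = 50000L,
                      burnIn = 1000L, batches = 10L, seed = 1L) {
  if (is.null(mapping)) mapping <- defaultEpsMapping()
  list(coarseSpacing = coarseSpacing, fineSpacing = fineSpacing,
       margin = margin, focusHalfwidth = focusHalfwidth, probe = probe,
       kernelRadius = kernelRadius, epsLevels = epsLevels, mapping = mapping,
       epsSolvent = epsSolvent, membrane = membrane, solver = solver,
       policy = policy, table = table, pHGrid = pHGrid,
       scans = as.integer(scans), burnIn = as.integer(burnIn),
       batches = as.integer(batches), seed = as.integer(seed))
}

.mapFor <- function(structure, grid, config, withMembrane = TRUE) {
  m <- buildEpsMap(structure, grid, mapping = config$mapping,
                   levels = config$epsLevels, probe = config$probe,
                   kernelRadius = config$kernelRadius,
                   ionicStrength = config$solver@ionicStrength,
                   epsSolvent = config$epsSolvent,
                   sternRadius = config$solver@sternRadius)
  if (withMembrane && !is.null(config$membrane))
    m <- applyMembrane(m, config$membrane, strict = FALSE)
  m
}

## fine grid centred on `center`, snapped to the fine lattice for
## translation-consistent placement
.fineGrid <- function(center, config) {
  hw <- config$focusHalfwidth
  hf <- config$fineSpacing
  origin <- floor((center - hw) / hf) * hf
  dims <- as.integer(ceiling(2 * hw / hf)) + 1L
  gridSpec(origin = origin, dims = rep(dims, 3), spacing = hf)
}

#' Build environment maps for a structure
#'
#' @param structure parameterized structure
#' @param config from \code{\link{pkaConfig}}
#' @param focusCenter optional 3-vector; adds a focused fine map around it
#' @param coarseMap optional precomputed coarse map (reused across sites)
#' @return a \linkS4class{DielectricMap} or list(coarse, fine)
#' @export
buildEnvironmentMaps <- function(structure, config = pkaConfig(),
                                 focusCenter = NULL, coarseMap = NULL) {
  if (is.null(coarseMap)) {
    pos <- as.matrix(atoms(structure)[, c("x", "y", "z")])
    grid <- gridSpec(pos, spacing = config$coarseSpacing,
                     margin = config$margin)
    coarseMap <- .mapFor(structure, grid, config)
  }
  if (is.null(focusCenter)) return(coarseMap)
  fineMap <- .mapFor(structure, .fineGrid(focusCenter, config), config)
  list(coarse = coarseMap, fine = fineMap)
}

.residueOnly <- function(structure, site) {
  a <- atoms(structure)
  keep <- a$chain == site@chain & a$resno == site@resno
  .newStructure(a[keep, , drop = FALSE], structure@frameId)
}

## model-compound maps: same grids as envMaps, cavity from the site residue
## alone, no membrane, same solvent
.referenceMaps <- function(structure, site, config, envMaps) {
  ref <- .residueOnly(structure, site)
  if (.isMapPair(envMaps)) {
    list(coarse = .mapFor(ref, envMaps$coarse@grid, config,
                          withMembrane = FALSE),
         fine = .mapFor(ref, envMaps$fine@grid, config, withMembrane = FALSE))
  } else {
    .mapFor(ref, envMaps@grid, config, withMembrane = FALSE)
  }
}

.backgroundSet <- function(structure, sites) {
  a <- atoms(structure)
  excl <- unique(unlist(lapply(sites, function(s)
    siteAtomIndices(structure, s))))
  keep <- setdiff(seq_len(nrow(a)), excl)
  keep <- keep[abs(a$charge[keep]) > 1e-12]
  list(pos = as.matrix(a[keep, c("x", "y", "z"), drop = FALSE]),
       q = a$charge[keep])
}

.siteCenter <- function(structure, site) {
  a <- atoms(structure)
  idx <- siteAtomIndices(structure, site)
  colMeans(a[idx, c("x", "y", "z"), drop = FALSE])
}

#' Intrinsic pKa of one site
#'
#' Computes the Born-type shift from the thermodynamic cycle on both
#' protonation forms (transfer of each form between the model-compound water
#' environment and the protein/membrane environment at identical grid
#' placement) and the background shift from the permanent-charge field, then
#' \code{intrinsic = model + bornShift + backgroundShift}. The acid/base sign
#' behaviour (burial raises acid pKa, lowers base pKa) emerges from the cycle
#' rather than from a per-class flag.
#'
#' @param site a \linkS4class{TitratableSite}
#' @param structure parameterized structure containing the site
#' @param config from \code{\link{pkaConfig}}
#' @param envMaps optional prebuilt environment maps (must be focused on the
#'   site when provided)
#' @param sites all titratable sites (their variable atoms are excluded from
#'   the background); defaults to just this site
#' @return list(bornShift, backgroundShift, intrinsicPka) in pKa units
#' @export
computeIntrinsicPka <- function(site, structure, config = pkaConfig(),
                                envMaps = NULL, sites = list(site)) {
  if (is.null(envMaps))
    envMaps <- buildEnvironmentMaps(structure, config,
                                    focusCenter = .siteCenter(structure, site))
  refMaps <- .referenceMaps(structure, site, config, envMaps)
  setProt <- siteChargeSet(structure, site, "protonated")
  setDep <- siteChargeSet(structure, site, "deprotonated")
  s <- config$solver
  ddgDep <- dielectricResponseEnergy(envMaps, refMaps, setDep$pos, setDep$q, s)
  ddgProt <- dielectricResponseEnergy(envMaps, refMaps, setProt$pos,
                                      setProt$q, s)
  bornShift <- (ddgDep - ddgProt) / .PK_KCAL

  diff <- siteChargeSet(structure, site, "difference")
  dqDep <- -diff$q  # deprotonated minus protonated
  bg <- .backgroundSet(structure, sites)
  gBackEnv <- backgroundEnergy(envMaps, bg$pos, bg$q, diff$pos, dqDep, s)
  refStruct <- .residueOnly(structure, site)
  bgRef <- .backgroundSet(refStruct, list(site))
  gBackRef <- if (length(bgRef$q))
    backgroundEnergy(refMaps, bgRef$pos, bgRef$q, diff$pos, dqDep, s) else 0
  backgroundShift <- (gBackEnv - gBackRef) / .PK_KCAL

  intrinsic <- site@modelPka + bornShift + backgroundShift
  list(bornShift = bornShift, backgroundShift = backgroundShift,
       intrinsicPka = intrinsic)
}

#' Site-site interaction matrix
#'
#' W[i, j] is the screened interaction between the protonation charge
#' differences of sites i and j in pKa units, computed by solving with site
#' i's difference distribution and probing at site j, then symmetrized as
#' (W + t(W)) / 2 with zero diagonal.
#'
#' @param structure parameterized structure
#' @param sites list of \linkS4class{TitratableSite}
#' @param config from \code{\link{pkaConfig}}
#' @param coarseMap optional precomputed environment map
#' @return symmetric matrix, pKa units
#' @export
computeInteractionMatrix <- function(structure, sites, config = pkaConfig(),
                                     coarseMap = NULL) {
  n <- length(sites)
  W <- matrix(0, n, n,
              dimnames = list(vapply(sites, function(s) s@siteId, ""),
                              vapply(sites, function(s) s@siteId, "")))
  if (n < 2) return(W)
  if (is.null(coarseMap))
    coarseMap <- buildEnvironmentMaps(structure, config)
  diffs <- lapply(sites, function(s) siteChargeSet(structure, s, "difference"))
  s <- config$solver
  for (i in seq_len(n)) {
    sol <- .solveAny(coarseMap, diffs[[i]]$pos, diffs[[i]]$q, s)
    for (j in seq_len(n)) {
      if (j == i) next
      W[i, j] <- sum(diffs[[j]]$q *
                       .evalAny(sol, diffs[[j]]$pos)) / .PK_KCAL
    }
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

#' Full per-frame energy ledger
#'
#' @param structure parameterized structure
#' @param config from \code{\link{pkaConfig}}
#' @param sites optional site list (found by policy otherwise)
#' @param frameId frame index recorded in the ledger
#' @return an \linkS4class{EnergyLedger}
#' @export
computeEnergyLedger <- function(structure, config = pkaConfig(), sites = NULL,
                                frameId = 0L) {
  if (is.null(sites))
    sites <- findTitratableSites(structure, config$policy, config$table)
  if (!length(sites))
    return(new("EnergyLedger", siteIds = character(0), modelPka = numeric(0),
               bornShift = numeric(0), backgroundShift = numeric(0),
               intrinsicPka = numeric(0), W = matrix(0, 0, 0),
               frameId = as.integer(frameId)))
  pos <- as.matrix(atoms(structure)[, c("x", "y", "z")])
  coarseGrid <- gridSpec(pos, spacing = config$coarseSpacing,
                         margin = config$margin)
  coarseMap <- .mapFor(structure, coarseGrid, config)
  comp <- lapply(sites, function(site) {
    env <- buildEnvironmentMaps(structure, config,
                                focusCenter = .siteCenter(structure, site),
                                coarseMap = coarseMap)
    computeIntrinsicPka(site, structure, config, envMaps = env, sites = sites)
  })
  W <- computeInteractionMatrix(structure, sites, config,
                                coarseMap = coarseMap)
  new("EnergyLedger",
      siteIds = vapply(sites, function(s) s@siteId, ""),
      modelPka = vapply(sites, function(s) s@modelPka, 0),
      bornShift = vapply(comp, `[[`, 0, "bornShift"),
      backgroundShift = vapply(comp, `[[`, 0, "backgroundShift"),
      intrinsicPka = vapply(comp, `[[`, 0, "intrinsicPka"),
      W = W, frameId = as.integer(frameId))
}

#' Single-frame pKa computation
#'
#' Sites, energy ledger, titration, extracted pKa values.
#'
#' @param structure parameterized structure
#' @param config from \code{\link{pkaConfig}}
#' @param method "exact", "mc" or "auto" (exact for <= 20 sites)
#' @return list(sites, ledger, titration)
#' @export
computePka <- function(structure, config = pkaConfig(),
                       method = c("auto", "exact", "mc")) {
  method <- match.arg(method)
  sites <- findTitratableSites(structure, config$policy, config$table)
  ledger <- computeEnergyLedger(structure, config, sites)
  model <- microstateModelFromLedger(ledger, sites, config$pHGrid)
  titr <- if (method == "exact" ||
              (method == "auto" && length(sites) <= 20)) {
    titrateExact(model)
  } else {
    titrateMC(model, scans = config$scans, burnIn = config$burnIn,
              batches = config$batches, seed = config$seed)
  }
  list(sites = sites, ledger = ledger, titration = titr)
}

#' Parameter sensitivity scan
#'
#' Re-runs the pKa computation under one-at-a-time variations of the
#' headgroup permittivity, core permittivity, and ionic strength, reporting
#' per-site pKa changes versus the baseline configuration to 0.01 pKa units.
#'
#' @param structure parameterized structure
#' @param config baseline configuration (its membrane slab, when present,
#'   supplies the baseline eps values)
#' @param epsHead,epsCore,ionicStrength values to scan
#' @return data.frame(siteId, parameter, value, pka, dPka)
#' @export
sensitivityScan <- function(structure, config = pkaConfig(),
                            epsHead = c(20, 40), epsCore = c(2.0, 2.5),
                            ionicStrength = c(0.05, 0.2)) {
  base <- computePka(structure, config)
  basePka <- pkaHalf(base$titration)
  out <- list()
  addVariant <- function(cfg, param, value) {
    r <- computePka(structure, cfg)
    p <- pkaHalf(r$titration)
    out[[length(out) + 1]] <<- data.frame(
      siteId = names(p), parameter = param, value = value, pka = round(p, 2),
      dPka = round(p - basePka[names(p)], 2), row.names = NULL)
  }
  if (!is.null(config$membrane)) {
    for (eh in epsHead) {
      if (eh == config$membrane@epsHead) next
      cfg <- config
      cfg$membrane@epsHead <- eh
      addVariant(cfg, "epsHead", eh)
    }
    for (ec in epsCore) {
      if (ec == config$membrane@epsCore) next
      cfg <- config
      cfg$membrane@epsCore <- ec
      addVariant(cfg, "epsCore", ec)
    }
  }
  for (is_ in ionicStrength) {
    if (is_ == config$solver@ionicStrength) next
    cfg <- config
    cfg$solver@ionicStrength <- is_
    addVariant(cfg, "ionicStrength", is_)
  }
  if (!length(out))
    return(data.frame(siteId = character(0), parameter = character(0),
                      value = numeric(0), pka = numeric(0),
                      dPka = numeric(0)))
  do.call(rbind, out)
}
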