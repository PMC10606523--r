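## Multi-site protonation statistical mechanics.
##
## Microstate energies in pH units (energy / 2.303 kT):
##   E(x, pH) = sum_i x_i (pH - pKa_intr,i)
##            + 1/2 sum_{i != j} W_ij dq_i(x_i) dq_j(x_j)
## with x_i in {0, 1} (1 = protonated) and dq_i = x_i - ref_i, the deviation
## of the site charge from its charged reference state (acids deprotonated,
## ref 0; bases protonated, ref 1).

#' Construct a multi-site protonation model
#'
#' @param siteIds site identifiers
#' @param intrinsicPka per-site intrinsic pKa
#' @param acidOrBase "acid"/"base" per site
#' @param W symmetric interaction matrix, pKa units (0 matrix if omitted)
#' @param pHGrid strictly increasing pH values (default 0..14 step 0.2)
#' @return a \linkS4class{MicrostateModel}
#' @export
microstateModel <- function(siteIds, intrinsicPka, acidOrBase,
                            W = NULL, pHGrid = seq(0, 14, by = 0.2)) {
  n <- length(siteIds)
  if (is.null(W)) W <- matrix(0, n, n)
  new("MicrostateModel", siteIds = as.character(siteIds),
      intrinsicPka = as.numeric(intrinsicPka),
      acidOrBase = as.character(acidOrBase), W = as.matrix(W),
      pHGrid = as.numeric(pHGrid))
}

#' Model from an energy ledger
#'
#' @param ledger an \linkS4class{EnergyLedger}
#' @param sites the site list the ledger was computed from
#' @param pHGrid pH grid
#' @return a \linkS4class{MicrostateModel}
#' @export
microstateModelFromLedger <- function(ledger, sites,
                                      pHGrid = seq(0, 14, by = 0.2)) {
  microstateModel(ledger@siteIds, ledger@intrinsicPka,
                  vapply(sites, function(s) s@acidOrBase, ""),
                  W = ledger@W, pHGrid = pHGrid)
}

.refState <- function(model) ifelse(model@acidOrBase == "acid", 0, 1)

#' Energy of a protonation microstate
#'
#' @param model a \linkS4class{MicrostateModel}
#' @param state binary vector (1 = protonated), length = number of sites
#' @param pH pH value
#' @return energy in pH units (energy / 2.303 kT)
#' @export
microstateEnergy <- function(model, state, pH) {
  n <- length(model@siteIds)
  if (length(state) != n)
    stop("state length ", length(state), " does not match ", n, " sites")
  state <- as.numeric(state)
  dq <- state - .refState(model)
  sum(state * (pH - model@intrinsicPka)) +
    0.5 * sum(model@W * outer(dq, dq)) -
    0.5 * sum(diag(model@W) * dq^2)
}

#' Exact titration by full enumeration
#'
#' Boltzmann sum over all 2^N microstates at each pH. The state distribution
#' is normalized exactly, so fractions are exact expectation values.
#'
#' @param model a \linkS4class{MicrostateModel} with at most 20 sites
#' @return a \linkS4class{TitrationResult} (method "exact", mcError 0)
#' @export
titrateExact <- function(model) {
  n <- length(model@siteIds)
  if (n > 20)
    stop("exact enumeration limited to 20 sites (2^N states); use titrateMC()")
  pH <- model@pHGrid
  if (n == 0)
    return(new("TitrationResult", pHGrid = pH,
               fractions = matrix(0, length(pH), 0), siteIds = character(0),
               pkaHalf = numeric(0), mcError = numeric(0),
               seFractions = matrix(0, length(pH), 0), seed = NA_integer_,
               method = "exact"))
  states <- as.matrix(expand.grid(rep(list(0:1), n)))[, seq_len(n),
                                                      drop = FALSE]
  colnames(states) <- model@siteIds
  dq <- sweep(states, 2, .refState(model))
  pairE <- 0.5 * rowSums((dq %*% model@W) * dq)
  nProt <- drop(states %*% model@intrinsicPka)
  tot <- rowSums(states)
  frac <- matrix(NA_real_, length(pH), n,
                 dimnames = list(NULL, model@siteIds))
  for (p in seq_along(pH)) {
    E <- tot * pH[p] - nProt + pairE
    E <- E - min(E)
    w <- 10^(-E)
    w <- w / sum(w)
    frac[p, ] <- colSums(w * states)
  }
  pka <- vapply(seq_len(n), function(i)
    tryCatch(pkaFromCurve(pH, frac[, i], intrinsic = model@intrinsicPka[i],
                          quiet = TRUE), error = function(e) NA_real_), 0)
  new("TitrationResult", pHGrid = pH, fractions = frac,
      siteIds = model@siteIds, pkaHalf = pka, mcError = numeric(n),
      seFractions = matrix(0, length(pH), n), seed = NA_integer_,
      method = "exact")
}

#' Metropolis Monte Carlo titration
#'
#' Single-site flips plus joint flips of strongly coupled pairs
#' (|W| > 2 pKa units), with burn-in and batch-mean standard errors.
#' Reproducible for a given seed.
#'
#' @param model a \linkS4class{MicrostateModel}
#' @param scans production scans per pH (one scan = one attempted flip per
#'   site plus the pair moves)
#' @param burnIn discarded initial scans
#' @param batches number of batches for the batch-mean error
#' @param seed RNG seed
#' @param pairThreshold |W| above which a pair receives joint moves
#' @return a \linkS4class{TitrationResult} (method "mc")
#' @export
titrateMC <- function(model, scans = 50000L, burnIn = 1000L, batches = 10L,
                      seed = 1L, pairThreshold = 2.0) {
  stopifnot(scans >= 1)
  n <- length(model@siteIds)
  set.seed(seed)
  res <- cpp_mc_titrate(model@intrinsicPka, model@W,
                        as.integer(.refState(model)), model@pHGrid,
                        as.integer(burnIn), as.integer(scans),
                        as.integer(batches), pairThreshold)
  frac <- res$fractions
  colnames(frac) <- model@siteIds
  pka <- vapply(seq_len(n), function(i)
    tryCatch(pkaFromCurve(model@pHGrid, frac[, i],
                          intrinsic = model@intrinsicPka[i], quiet = TRUE),
             error = function(e) NA_real_), 0)
  new("TitrationResult", pHGrid = model@pHGrid, fractions = frac,
      siteIds = model@siteIds, pkaHalf = pka,
      mcError = apply(res$se, 2, max), seFractions = res$se,
      seed = as.integer(seed), method = "mc")
}

#' pKa from the half-protonation crossing of a titration curve
#'
#' Linear interpolation of the 0.5 crossing between bracketing grid points
#' (the "graphical assessment"). With multiple crossings the one nearest the
#' site's intrinsic pKa is taken and a warning is raised.
#'
#' @param pH pH grid
#' @param fractions protonation fractions at each pH
#' @param intrinsic intrinsic pKa used to disambiguate multiple crossings
#' @param quiet suppress the multiple-crossing warning
#' @return pKa (pH of half-protonation)
#' @export
pkaFromCurve <- function(pH, fractions, intrinsic = NULL, quiet = FALSE) {
  stopifnot(length(pH) == length(fractions))
  d <- fractions - 0.5
  hit <- which(d == 0)
  cross <- which(d[-length(d)] * d[-1] < 0)
  cands <- c(pH[hit],
             vapply(cross, function(i) {
               pH[i] + (0.5 - fractions[i]) * (pH[i + 1] - pH[i]) /
                 (fractions[i + 1] - fractions[i])
             }, 0))
  if (!length(cands))
    stop("titration curve never crosses 0.5 within the pH grid [",
         min(pH), ", ", max(pH), "]; widen the grid")
  if (length(cands) > 1) {
    if (!quiet)
      warning("multiple half-protonation crossings; choosing the one ",
              "nearest the intrinsic pKa")
    anchor <- if (is.null(intrinsic)) stats::median(cands) else intrinsic
    cands <- cands[which.min(abs(cands - anchor))]
  }
  unname(cands)
}

#' Error study of the graphical pKa extraction
#'
#' Draws small multi-site toy models (random intrinsic pKas, random
#' interaction energies up to \code{wMax} pKa units), enumerates their exact
#' titration curves on a coarse pH grid, extracts pKa by linear interpolation
#' of the half-protonation crossing, and compares against the crossing
#' located on a dense reference grid. The maximum absolute deviation bounds
#' the "graphical assessment" error of the pipeline.
#'
#' @param nModels number of random toy models (sites cycle 1..maxSites)
#' @param maxSites largest model size
#' @param seed RNG seed
#' @param coarseStep production pH grid step (0.2)
#' @param refStep dense reference grid step (0.001)
#' @param wMax interaction magnitude cap, pKa units
#' @return list(maxAbsError, perModel data.frame, nSites)
#' @export
graphicalPkaError <- function(nModels = 20, maxSites = 5, seed = 1,
                              coarseStep = 0.2, refStep = 0.001, wMax = 2) {
  set.seed(seed)
  coarse <- seq(0, 14, by = coarseStep)
  devs <- numeric(0)
  rows <- list()
  for (mIdx in seq_len(nModels)) {
    n <- (mIdx - 1) %% maxSites + 1
    pka <- stats::runif(n, 3, 11)
    ab <- sample(c("acid", "base"), n, replace = TRUE)
    W <- matrix(0, n, n)
    if (n > 1) {
      for (i in seq_len(n - 1))
        for (j in seq(i + 1, n))
          if (stats::runif(1) < 0.4)
            W[i, j] <- W[j, i] <- stats::runif(1, -wMax, wMax)
    }
    m <- microstateModel(paste0("s", seq_len(n)), pka, ab, W = W,
                         pHGrid = coarse)
    est <- pkaHalf(titrateExact(m))
    ## dense reference around each coarse estimate
    ref <- vapply(seq_len(n), function(i) {
      grid <- seq(max(0, est[i] - 0.6), min(14, est[i] + 0.6), by = refStep)
      mr <- microstateModel(m@siteIds, pka, ab, W = W, pHGrid = grid)
      pkaHalf(titrateExact(mr))[i]
    }, 0)
    d <- abs(est - ref)
    devs <- c(devs, d)
    rows[[mIdx]] <- data.frame(model = mIdx, nSites = n, maxDev = max(d))
  }
  list(maxAbsError = max(devs), perModel = do.call(rbind, rows),
       nSites = length(devs))
}

#' Ideal single-site (Henderson-Hasselbalch) curve
#'
#' @param pH pH values
#' @param pka site pKa
#' @return protonation fraction 1 / (1 + 10^(pH - pKa))
#' @export
hendersonHasselbalch <- function(pH, pka) 1 / (1 + 10^(pH - pka))
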