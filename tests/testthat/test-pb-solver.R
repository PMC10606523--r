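test_that("uniform-medium potential matches Coulomb's law", {
  g <- gridSpec(matrix(0, 1, 3), spacing = 0.5, margin = 13)
  m <- uniformEpsMap(g, 81, 0)
  s <- solverSettings(ionicStrength = 0)
  pg <- solvePB(m, matrix(0, 1, 3), 1, s)
  ## >= 5 grid lengths from the charge
  for (r in c(3, 5, 8)) {
    phi <- potentialAt(pg, matrix(c(r, 0, 0), 1, 3))
    expect_rel(phi, 332.0636 / (81 * r), 0.02)
  }
})

test_that("zero source gives an identically zero potential", {
  g <- gridSpec(matrix(0, 1, 3), spacing = 1.0, margin = 8)
  m <- uniformEpsMap(g, 81, 0.2)
  pg <- solvePB(m, matrix(0, 1, 3), 0, solverSettings())
  expect_true(all(abs(pg@phi) < 1e-12))
})

test_that("salt screening reproduces the Debye-Hueckel form", {
  g <- gridSpec(matrix(0, 1, 3), spacing = 0.5, margin = 13)
  m <- uniformEpsMap(g, 81, 0.2)
  s <- solverSettings(ionicStrength = 0.2)
  kap <- sqrt(debyeKappaSq(0.2, 81))
  expect_rel(1 / kap, 6.8, 0.03)  # ~6.8 A Debye length at 0.2 M
  pg <- solvePB(m, matrix(0, 1, 3), 1, s)
  for (r in c(4, 6, 9)) {
    phi <- potentialAt(pg, matrix(c(0, r, 0), 1, 3))
    expect_rel(phi, 332.0636 * exp(-kap * r) / (81 * r), 0.04)
  }
})

test_that("Born transfer energy matches the analytic sphere", {
  fix <- makeBornSphere(q = 1, a = 2, epsFrom = 81, epsTo = 4)
  ctr <- c(0, 0, 0)
  gC <- gridSpec(matrix(ctr, 1, 3), spacing = 1.0, margin = 14)
  gF <- gridSpec(origin = c(-6, -6, -6), dims = rep(49L, 3), spacing = 0.25)
  s <- solverSettings(ionicStrength = 0)
  mk <- function(g, epsOut) sphereEpsMap(g, ctr, 2.0, 2.0, epsOut)
  env <- list(coarse = mk(gC, 4), fine = mk(gF, 4))
  ref <- list(coarse = mk(gC, 81), fine = mk(gF, 81))
  pos <- matrix(ctr, 1, 3)
  ddg <- dielectricResponseEnergy(env, ref, pos, 1, s)
  expect_rel(ddg, fix$analytic, 0.03)
  ## identical environments cancel exactly
  expect_equal(dielectricResponseEnergy(env, env, pos, 1, s), 0,
               tolerance = 1e-12)
  ## quadratic scaling in the charge
  ddg2 <- dielectricResponseEnergy(env, ref, pos, 2, s)
  expect_rel(ddg2, 4 * ddg, 1e-6)
  ## mismatched grids are rejected
  gBad <- gridSpec(origin = c(-6, -6, -6), dims = rep(47L, 3), spacing = 0.25)
  envBad <- list(coarse = mk(gC, 4), fine = mk(gBad, 4))
  expect_error(dielectricResponseEnergy(envBad, ref, pos, 1, s),
               "grid placement")
})

test_that("grid refinement reduces the Born-oracle error monotonically", {
  ctr <- c(0, 0, 0)
  ana <- makeBornSphere()$analytic
  s <- solverSettings(ionicStrength = 0)
  gC <- gridSpec(matrix(ctr, 1, 3), spacing = 1.0, margin = 14)
  err <- vapply(c(0.5, 0.25), function(h) {
    n <- as.integer(2 * 6 / h) + 1L
    gF <- gridSpec(origin = c(-6, -6, -6), dims = rep(n, 3), spacing = h)
    mk <- function(g, epsOut) sphereEpsMap(g, ctr, 2.0, 2.0, epsOut)
    ddg <- dielectricResponseEnergy(
      list(coarse = mk(gC, 4), fine = mk(gF, 4)),
      list(coarse = mk(gC, 81), fine = mk(gF, 81)),
      matrix(ctr, 1, 3), 1, s)
    abs(ddg / ana - 1)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("pair interactions match Coulomb and are reciprocal", {
  fix <- makeChargePair(1, 1, 6, eps = 20)
  g <- gridSpec(matrix(c(-3, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE),
                spacing = 0.5, margin = 10)
  m <- uniformEpsMap(g, 20, 0)
  s <- solverSettings(ionicStrength = 0)
  pI <- matrix(c(-3, 0, 0), 1, 3); pJ <- matrix(c(3, 0, 0), 1, 3)
  w <- interactionEnergy(m, pI, 1, pJ, 1, s)
  expect_rel(w, fix$analytic, 0.02)       # 2.77 kcal/mol
  wJI <- interactionEnergy(m, pJ, 1, pI, 1, s)
  expect_lt(abs(w - wJI) / abs(w), 0.01)  # Green's-function symmetry
  expect_equal(interactionEnergy(m, pI, 1, pJ, 0, s), 0)
  expect_error(interactionEnergy(m, pI, 1, pI, 1, s), "overlap")
})

test_that("salt strictly weakens solvent-separated interactions", {
  g <- gridSpec(matrix(c(-4, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE),
                spacing = 0.6, margin = 11)
  w <- vapply(c(0, 0.05, 0.1, 0.2), function(I) {
    m <- uniformEpsMap(g, 81, I)
    interactionEnergy(m, matrix(c(-4, 0, 0), 1, 3), 1,
                      matrix(c(4, 0, 0), 1, 3), 1,
                      solverSettings(ionicStrength = I))
  }, 0)
  expect_true(all(diff(w) < 0))
})

test_that("background energy matches a Coulomb oracle", {
  ## single -0.5 e background charge 4 A from a +1 e site, eps 10, no salt
  g <- gridSpec(matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE),
                spacing = 0.4, margin = 10)
  m <- uniformEpsMap(g, 10, 0)
  s <- solverSettings(ionicStrength = 0)
  gB <- backgroundEnergy(m, matrix(0, 1, 3), -0.5, matrix(c(4, 0, 0), 1, 3),
                         1, s)
  expect_rel(gB, 332.0636 * (-0.5) / (10 * 4), 0.02)  # -4.15 kcal/mol
  expect_equal(backgroundEnergy(m, matrix(0, 1, 3), numeric(0),
                                matrix(c(4, 0, 0), 1, 3), 1, s), 0)
  expect_error(backgroundEnergy(m, matrix(c(4, 0, 0), 1, 3), 0.3,
                                matrix(c(4, 0, 0), 1, 3), 1, s),
               "titratable")
})

test_that("helix backbone dipole field matches a brute-force Coulomb sum", {
  hx <- gluHelix(nRes = 8, position = 4)
  sites <- findTitratableSites(hx)
  diffSet <- siteChargeSet(hx, sites[[1]], "difference")
  bgIdx <- setdiff(seq_len(nrow(atoms(hx))), siteAtomIndices(hx, sites[[1]]))
  a <- atoms(hx)
  bgIdx <- bgIdx[abs(a$charge[bgIdx]) > 1e-12]
  bgPos <- as.matrix(a[bgIdx, c("x", "y", "z")])
  bgQ <- a$charge[bgIdx]
  g <- gridSpec(as.matrix(a[, c("x", "y", "z")]), spacing = 0.4, margin = 10)
  m <- uniformEpsMap(g, 20, 0)
  s <- solverSettings(ionicStrength = 0)
  gB <- backgroundEnergy(m, bgPos, bgQ, diffSet$pos, -diffSet$q, s)
  oracle <- coulombSum(bgPos, bgQ, diffSet$pos, -diffSet$q, 20)
  expect_lt(abs(gB - oracle) / max(abs(oracle), 0.1), 0.05)
})

test_that("response energies survive non-integer grid translations", {
  ctr <- c(0, 0, 0)
  s <- solverSettings(ionicStrength = 0)
  born <- function(shift) {
    c2 <- ctr + shift
    gC <- gridSpec(matrix(c2, 1, 3), spacing = 1.0, margin = 12)
    gF <- gridSpec(origin = c2 - 5.5, dims = rep(23L, 3), spacing = 0.5)
    mk <- function(g, epsOut) sphereEpsMap(g, c2, 2.0, 2.0, epsOut)
    dielectricResponseEnergy(list(coarse = mk(gC, 4), fine = mk(gF, 4)),
                             list(coarse = mk(gC, 81), fine = mk(gF, 81)),
                             matrix(c2, 1, 3), 1, s)
  }
  e1 <- born(c(0, 0, 0))
  e2 <- born(c(0.37, -0.21, 0.13))  # non-integer number of cells
  expect_lt(abs(e2 - e1) / abs(e1), 0.005)
})

test_that("non-convergence raises an error carrying the residual history", {
  g <- gridSpec(matrix(0, 1, 3), spacing = 0.5, margin = 10)
  m <- uniformEpsMap(g, 81, 0)
  s <- solverSettings(ionicStrength = 0, maxIterations = 3L)
  err <- tryCatch(solvePB(m, matrix(0, 1, 3), 1, s), error = identity)
  expect_s3_class(err, "simpleError")
  expect_true(length(attr(err, "residuals")) >= 1)
})
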