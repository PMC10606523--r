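## Shared fixtures and fast settings for the suite. Grids are intentionally
## coarse where a test checks bookkeeping rather than field accuracy.

fastConfig <- function(..., ionicStrength = 0.1) {
  pkaConfig(coarseSpacing = 1.2, fineSpacing = 0.6, margin = 9,
            focusHalfwidth = 5,
            solver = solverSettings(ionicStrength = ionicStrength), ...)
}

gluHelix <- function(nRes = 12, position = 6, type = "GLU", ...) {
  makeHelixInSlab(placements = data.frame(type = type, position = position),
                  nRes = nRes, ...)
}

## brute-force Coulomb interaction of two charge sets in a uniform medium
coulombSum <- function(posA, qA, posB, qB, eps) {
  posA <- rbind(posA); posB <- rbind(posB)
  tot <- 0
  for (i in seq_along(qA))
    for (j in seq_along(qB)) {
      r <- sqrt(sum((posA[i, ] - posB[j, ])^2))
      tot <- tot + 332.0636 * qA[i] * qB[j] / (eps * r)
    }
  tot
}

## minimal PQR/PDB fragments
twoAtomPdb <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "END")

expect_rel <- function(value, target, tol) {
  expect_lt(abs(value / target - 1), tol)
}
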