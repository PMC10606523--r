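test_that("microstate energies match hand enumeration", {
  ## two acids, intrinsic 4.0 / 5.0, W = 2.0, at pH 5.0:
  ## E = x1 (5-4) + x2 (5-5) + 2 x1 x2 -> 0, 1, 0, 3
  W <- matrix(c(0, 2, 2, 0), 2, 2)
  m <- microstateModel(c("a", "b"), c(4, 5), c("acid", "acid"), W = W)
  expect_equal(microstateEnergy(m, c(0, 0), 5), 0)
  expect_equal(microstateEnergy(m, c(1, 0), 5), 1)
  expect_equal(microstateEnergy(m, c(0, 1), 5), 0)
  expect_equal(microstateEnergy(m, c(1, 1), 5), 3)
  ## single acid at pH = pKa: both states equal energy
  m1 <- microstateModel("a", 6, "acid")
  expect_equal(microstateEnergy(m1, 1, 6), microstateEnergy(m1, 0, 6))
  ## all-reference state has no pair term (bases ref = protonated)
  mb <- microstateModel(c("a", "b"), c(6, 10), c("acid", "base"),
                        W = matrix(c(0, 3, 3, 0), 2, 2))
  expect_equal(microstateEnergy(mb, c(0, 1), 7),
               sum(c(0, 1) * (7 - c(6, 10))))
  expect_error(microstateEnergy(m1, c(1, 0), 6), "length")
})

test_that("exact enumeration reproduces Henderson-Hasselbalch", {
  m <- microstateModel("a", 6, "acid")
  r <- titrateExact(m)
  expect_equal(unname(protonationFractions(r)[r@pHGrid == 6, 1]), 0.5,
               tolerance = 1e-12)
  expect_equal(unname(protonationFractions(r)[, 1]),
               hendersonHasselbalch(r@pHGrid, 6), tolerance = 1e-12)
  expect_equal(mcError(r), c(a = 0))
})

test_that("non-interacting sites factorize", {
  m2 <- microstateModel(c("a", "b"), c(4.5, 9.1), c("acid", "base"))
  r2 <- titrateExact(m2)
  expect_equal(unname(protonationFractions(r2)[, 1]),
               hendersonHasselbalch(r2@pHGrid, 4.5), tolerance = 1e-12)
  expect_equal(unname(protonationFractions(r2)[, 2]),
               hendersonHasselbalch(r2@pHGrid, 9.1), tolerance = 1e-12)
})

test_that("coupled symmetric acids share a curve with split apparent pKas", {
  W <- matrix(c(0, 2, 2, 0), 2, 2)
  m <- microstateModel(c("a", "b"), c(4, 4), c("acid", "acid"), W = W)
  r <- titrateExact(m)
  f <- protonationFractions(r)
  expect_equal(f[, 1], f[, 2], tolerance = 1e-12, ignore_attr = TRUE)
  ## 4-state partition function oracle at pH 5
  pH <- 5
  E <- c(0, pH - 4, pH - 4, 2 * (pH - 4) + 2)
  w <- 10^(-E); w <- w / sum(w)
  expect_equal(unname(f[r@pHGrid == 5, 1]), w[2] + w[4], tolerance = 1e-12)
  ## apparent pKas split around the intrinsic value: the first protonation
  ## titrates at ~pKa_intr, the second at ~pKa_intr - W, so the shared
  ## half-protonation point sits near pKa_intr - W/2
  expect_equal(pkaHalf(r)[["a"]], 4.0 - 2.0 / 2, tolerance = 0.05)
})

test_that("exact enumeration refuses > 20 sites", {
  m <- microstateModel(paste0("s", 1:21), rep(7, 21), rep("acid", 21))
  expect_error(titrateExact(m), "titrateMC")
})

test_that("MC agrees with exact enumeration on a coupled 12-site toy", {
  set.seed(42)
  n <- 12
  W <- matrix(0, n, n)
  W[1, 2] <- W[2, 1] <- 1.2
  W[3, 4] <- W[4, 3] <- 2.6   # strong pair exercises joint flips
  W[5, 6] <- W[6, 5] <- 0.5
  m <- microstateModel(paste0("s", 1:n), runif(n, 3.5, 10.5),
                       sample(c("acid", "base"), n, TRUE), W = W)
  ex <- titrateExact(m)
  mc <- titrateMC(m, scans = 50000, burnIn = 1000, seed = 5)
  expect_lt(max(abs(protonationFractions(ex) - protonationFractions(mc))),
            0.01)
  ## W == 0 reduces to independent Henderson-Hasselbalch
  m0 <- microstateModel(c("a", "b"), c(5, 9), c("acid", "base"))
  mc0 <- titrateMC(m0, scans = 20000, seed = 3)
  hh <- cbind(hendersonHasselbalch(m0@pHGrid, 5),
              hendersonHasselbalch(m0@pHGrid, 9))
  expect_lt(max(abs(protonationFractions(mc0) - hh)), 0.012)
})

test_that("MC is seed-reproducible and seed-consistent", {
  m <- microstateModel(c("a", "b"), c(5.2, 8.8), c("acid", "base"),
                       W = matrix(c(0, 0.8, 0.8, 0), 2, 2))
  r1 <- titrateMC(m, scans = 20000, seed = 11)
  r1b <- titrateMC(m, scans = 20000, seed = 11)
  expect_identical(protonationFractions(r1), protonationFractions(r1b))
  r2 <- titrateMC(m, scans = 20000, seed = 12)
  pooled <- sqrt(r1@seFractions^2 + r2@seFractions^2)
  dev <- abs(protonationFractions(r1) - protonationFractions(r2))
  ## two independent seeds agree within a few pooled batch-mean errors
  expect_lt(max(dev - 4 * pooled - 1e-3), 0)
})

test_that("site permutation permutes outputs identically", {
  W <- matrix(c(0, 1.5, 0.3, 1.5, 0, 0, 0.3, 0, 0), 3, 3)
  m <- microstateModel(c("a", "b", "c"), c(4, 6, 9),
                       c("acid", "acid", "base"), W = W)
  perm <- c(3, 1, 2)
  mp <- microstateModel(m@siteIds[perm], m@intrinsicPka[perm],
                        m@acidOrBase[perm], W = W[perm, perm])
  r <- titrateExact(m); rp <- titrateExact(mp)
  expect_equal(protonationFractions(rp),
               protonationFractions(r)[, perm], tolerance = 1e-12)
})

test_that("half-protonation extraction interpolates the 0.5 crossing", {
  expect_equal(pkaFromCurve(c(6.0, 6.2), c(0.6, 0.4)), 6.1)
  ## exact single-site curve on the 0.2 grid recovers pKa within 0.03
  m <- microstateModel("a", 7.37, "acid")
  r <- titrateExact(m)
  expect_lt(abs(pkaHalf(r)[["a"]] - 7.37), 0.03)
  ## curve never reaching 0.5 errors
  expect_error(pkaFromCurve(seq(0, 14, 0.2),
                            rep(0.9, length(seq(0, 14, 0.2)))),
               "widen")
  ## multiple crossings resolve toward the intrinsic value, with a warning
  pH <- c(1, 2, 3, 4, 5)
  f <- c(0.9, 0.4, 0.6, 0.4, 0.1)
  expect_warning(v <- pkaFromCurve(pH, f, intrinsic = 4.2), "multiple")
  expect_equal(v, 3.5)
})

test_that("exact state probabilities are normalized", {
  ## normalization check through an independent partition-function sum
  set.seed(7)
  n <- 4
  W <- matrix(0.4, n, n); diag(W) <- 0
  m <- microstateModel(paste0("s", 1:n), runif(n, 4, 10),
                       c("acid", "acid", "base", "base"),
                       W = W, pHGrid = c(3, 7, 11))
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  for (pH in m@pHGrid) {
    E <- apply(states, 1, function(x) microstateEnergy(m, x, pH))
    p <- 10^(-(E - min(E))); p <- p / sum(p)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    fr <- colSums(p * states)
    r <- titrateExact(m)
    expect_equal(unname(fr),
                 unname(protonationFractions(r)[m@pHGrid == pH, ]),
                 tolerance = 1e-10)
  }
})
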