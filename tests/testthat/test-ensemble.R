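## synthetic per-frame ledgers with known components
syntheticLedgers <- function(nFrames, born, back, W, noiseSd = 0,
                             seed = 1, acid = TRUE) {
  set.seed(seed)
  n <- length(born)
  ids <- paste0("s", seq_len(n))
  model <- rep(if (acid) 4.4 else 10.4, n)
  lapply(seq_len(nFrames), function(f) {
    b <- born + rnorm(n, 0, noiseSd)
    g <- back + rnorm(n, 0, noiseSd)
    new("EnergyLedger", siteIds = ids, modelPka = model, bornShift = b,
        backgroundShift = g, intrinsicPka = model + b + g, W = W,
        frameId = f)
  })
}

test_that("identical frames give identical per-frame components", {
  hx <- gluHelix(nRes = 8, position = 4)
  frames <- makePseudoTrajectory(hx, 0, 3, seed = 9)
  fl <- perFrameComponents(frames, fastConfig())
  expect_equal(fl@totals[1, ], fl@totals[2, ])
  expect_equal(fl@totals[2, ], fl@totals[3, ])
  expect_equal(length(fl@frames), 3)
})

test_that("weak pairs are excluded from the thresholded total", {
  W03 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  W07 <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  l03 <- frameLedger(syntheticLedgers(3, c(1, 1), c(0, 0), W03))
  l07 <- frameLedger(syntheticLedgers(3, c(1, 1), c(0, 0), W07))
  expect_equal(unname(l03@totals[1, ]), c(1, 1))          # 0.3 dropped
  expect_equal(unname(l07@totals[1, ]), c(1.7, 1.7))      # 0.7 kept
  expect_equal(nrow(fluctuationSd(l07)@strongPairs), 1)
  expect_equal(nrow(fluctuationSd(l03)@strongPairs), 0)
})

test_that("fluctuation SDs follow the sample definition", {
  W <- matrix(0, 1, 1)
  led <- syntheticLedgers(3, 0, 0, W)
  led[[1]]@bornShift <- 1; led[[1]]@intrinsicPka <- 5.4
  led[[2]]@bornShift <- 2; led[[2]]@intrinsicPka <- 6.4
  led[[3]]@bornShift <- 3; led[[3]]@intrinsicPka <- 7.4
  rep <- fluctuationSd(frameLedger(led))
  expect_equal(rep@table$sdTotal, 1)
  ## constant series
  repc <- fluctuationSd(frameLedger(syntheticLedgers(4, 2, -1,
                                                     matrix(0, 1, 1))))
  expect_equal(repc@table$sdTotal, 0)
  expect_error(fluctuationSd(frameLedger(syntheticLedgers(1, 0, 0,
                                                          matrix(0, 1, 1)))),
               "2 frames")
})

test_that("median SD is taken over the designated subset", {
  W <- matrix(0, 3, 3)
  led <- syntheticLedgers(2, c(0, 0, 0), c(0, 0, 0), W)
  led[[1]]@bornShift <- c(0, 0, 0)
  led[[1]]@intrinsicPka <- led[[1]]@modelPka
  led[[2]]@bornShift <- sqrt(2) * c(0.4, 0.9, 1.5)
  led[[2]]@intrinsicPka <- led[[2]]@modelPka + led[[2]]@bornShift
  rep <- fluctuationSd(frameLedger(led))
  expect_equal(rep@table$sdTotal, c(0.4, 0.9, 1.5), tolerance = 1e-12)
  expect_equal(rep@medianSd, 0.9, tolerance = 1e-12)
  rep2 <- fluctuationSd(frameLedger(led), subset = c("s1", "s2"))
  expect_equal(rep2@medianSd, 0.65, tolerance = 1e-12)
})

test_that("SD scales linearly with component noise", {
  W <- matrix(0, 2, 2)
  l1 <- frameLedger(syntheticLedgers(200, c(1, -1), c(0, 0), W,
                                     noiseSd = 0.1, seed = 4))
  l2 <- frameLedger(syntheticLedgers(200, c(1, -1), c(0, 0), W,
                                     noiseSd = 0.3, seed = 4))
  r <- fluctuationSd(l2)@table$sdTotal / fluctuationSd(l1)@table$sdTotal
  expect_equal(r, c(3, 3), tolerance = 0.05)
})

test_that("SD grows with trajectory jitter", {
  hx <- gluHelix(nRes = 8, position = 4)
  cfg <- fastConfig()
  sdOf <- function(sigma) {
    frames <- makePseudoTrajectory(hx, sigma, 4, seed = 21)
    fl <- perFrameComponents(frames, cfg)
    fluctuationSd(fl)@table$sdTotal
  }
  expect_gt(sdOf(0.25), sdOf(0.05))
})

test_that("averaged pKa recovers generating values on synthetic ensembles", {
  gen <- c(5.5, 7.0, 9.0) - 4.4   # born shifts giving known intrinsic pKas
  W <- matrix(0, 3, 3)
  led <- syntheticLedgers(60, gen, c(0, 0, 0), W, noiseSd = 0.25, seed = 8)
  fl <- frameLedger(led)
  sitesStub <- lapply(paste0("s", 1:3), function(id)
    new("TitratableSite", siteId = id, residueType = "GLU",
        acidOrBase = "acid", modelPka = 4.4,
        protonatedCharges = c(OE2 = -0.45, HE2 = 0.45),
        deprotonatedCharges = c(OE2 = -1.0),
        parents = c(HE2 = "OE2"), chain = "A", resno = 1L))
  rep <- averagedPka(fl, sitesStub)
  tol <- rep@table$uncertainty + 0.03   # SE plus extraction error
  expect_true(all(abs(rep@table$pka - c(5.5, 7.0, 9.0)) <= tol + 1e-9))
  ## identical frames: zero uncertainty
  led0 <- syntheticLedgers(5, gen, c(0, 0, 0), W, noiseSd = 0)
  rep0 <- averagedPka(frameLedger(led0), sitesStub)
  expect_equal(rep0@table$uncertainty, c(0, 0, 0))
  ## single frame: flagged undefined uncertainty
  expect_warning(
    rep1 <- averagedPka(frameLedger(led0[1]), sitesStub), "single frame")
  expect_true(all(is.na(rep1@table$uncertainty)))
  expect_equal(rep1@table$pka, c(5.5, 7.0, 9.0), tolerance = 0.03)
})

test_that("averaging order is immaterial for weakly coupled systems", {
  gen <- c(1.0, 2.5)
  W <- matrix(c(0, 0.05, 0.05, 0), 2, 2)
  led <- syntheticLedgers(40, gen, c(0.2, -0.1), W, noiseSd = 0.15,
                          seed = 12)
  fl <- frameLedger(led)
  sitesStub <- lapply(paste0("s", 1:2), function(id)
    new("TitratableSite", siteId = id, residueType = "GLU",
        acidOrBase = "acid", modelPka = 4.4,
        protonatedCharges = c(OE2 = -0.45, HE2 = 0.45),
        deprotonatedCharges = c(OE2 = -1.0),
        parents = c(HE2 = "OE2"), chain = "A", resno = 1L))
  rc <- averagedPka(fl, sitesStub, order = "components")
  rp <- averagedPka(fl, sitesStub, order = "pka")
  expect_true(all(abs(rc@table$pka - rp@table$pka) <=
                    rc@table$uncertainty + rp@table$uncertainty + 0.05))
})

test_that("frames with differing site content are rejected", {
  hx <- gluHelix(nRes = 8, position = 4)
  f1 <- makePseudoTrajectory(hx, 0.05, 2, seed = 1)
  a <- atoms(f1[[2]])
  a$resname[a$resno == 4] <- "ALA"
  a <- a[a$name %in% c("N", "HN", "CA", "C", "O", "CB") | a$resno != 4, ]
  f1[[2]] <- assignParse(new("ParameterizedStructure", atoms = a,
                             chains = "A", frameId = 2L))
  expect_error(perFrameComponents(f1, fastConfig()), "site list")
})
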