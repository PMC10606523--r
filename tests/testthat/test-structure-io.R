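test_that("PDB fragments parse with charges unset and order preserved", {
  s <- readStructure(text = twoAtomPdb, format = "pdb")
  a <- atoms(s)
  expect_equal(nrow(a), 2)
  expect_equal(a$name, c("N", "CA"))
  expect_true(all(is.na(a$charge)))
  expect_equal(a$resno, c(1, 1))
  expect_equal(a$x, c(11.104, 11.639))
})

test_that("PQR charge and radius columns pass through", {
  pqr <- "ATOM      1  OE1 GLU A   1       1.000   2.000   3.000 -0.5500 1.5000"
  s <- readStructure(text = pqr, format = "pqr")
  expect_equal(atoms(s)$charge, -0.55)
  expect_equal(atoms(s)$radius, 1.50)
})

test_that("solvent stripping removes water records", {
  lines <- c(twoAtomPdb[1:2],
             "HETATM    3  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
             "END")
  s <- readStructure(text = lines, format = "pdb", stripSolvent = TRUE)
  expect_equal(nrow(atoms(s)), 2)
  s2 <- readStructure(text = lines, format = "pdb", stripSolvent = FALSE)
  expect_equal(nrow(atoms(s2)), 3)
})

test_that("malformed and duplicate records are rejected", {
  expect_error(readStructure(text = c("ATOM broken line", "END"),
                             format = "pdb"), "malformed")
  dup <- c(twoAtomPdb[1], twoAtomPdb[1], "END")
  expect_error(readStructure(text = dup, format = "pdb"), "duplicate")
})

test_that("parameter assignment reproduces formal charges per residue", {
  hx <- makeHelixInSlab(placements = data.frame(
    type = c("GLU", "LYS", "ASP", "ARG", "TYR"),
    position = c(3, 6, 9, 12, 15)), nRes = 17)
  audit <- residueChargeAudit(hx)
  expect_true(all(abs(audit$net - audit$formal) < 1e-6))
  expect_equal(audit$formal[audit$resname == "GLU"], -1L)
  expect_equal(audit$formal[audit$resname == "ASP"], -1L)
  expect_equal(audit$formal[audit$resname == "LYS"], 1L)
  expect_equal(audit$formal[audit$resname == "ARG"], 1L)
  expect_equal(audit$formal[audit$resname == "TYR"], 0L)
  expect_equal(sum(audit$formal[audit$resname == "ALA"]), 0L)
})

test_that("parameter assignment is idempotent", {
  hx <- gluHelix()
  hx2 <- assignParse(hx)
  expect_identical(atoms(hx), atoms(hx2))
})

test_that("unknown residues are reported, not silently zero-charged", {
  a <- atoms(gluHelix())
  a$resname[a$resno == 1] <- "XXX"
  bad <- new("ParameterizedStructure", atoms = a, chains = "A",
             frameId = 0L)
  expect_error(assignParse(bad), "XXX")
})

test_that("PQR round trip preserves coordinates and parameters", {
  hx <- gluHelix()
  f <- tempfile(fileext = ".pqr")
  writePqr(hx, f)
  back <- readStructure(f)
  expect_equal(as.matrix(atoms(back)[, c("x", "y", "z")]),
               as.matrix(atoms(hx)[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(atoms(back)$charge, atoms(hx)$charge, tolerance = 1e-4)
  expect_equal(atoms(back)$radius, atoms(hx)$radius, tolerance = 1e-4)
})

test_that("titratable site detection matches the sequence census", {
  sc <- syntheticPsbsCds(seed = 3)
  mature <- cleaveTransitPeptide(translateCds(sc$cds), 41)
  cens <- ionogenicCensus(mature)
  hx <- makeHelixInSlab(sequence = mature)
  sites <- findTitratableSites(
    hx, sitePolicy(include = c("ASP", "GLU", "LYS", "ARG", "TYR")))
  expect_equal(length(sites), cens$total)
  expect_equal(length(sites), 42)
  types <- table(vapply(sites, function(s) s@residueType, ""))
  expect_equal(as.integer(types[c("ARG", "LYS", "TYR", "GLU", "ASP")]),
               as.integer(c(cens$R, cens$K, cens$Y, cens$E, cens$D)))
  ## ordering deterministic by (chain, resno)
  resnos <- vapply(sites, function(s) s@resno, 0L)
  expect_false(is.unsorted(resnos))

  ## single-Tyr whitelist narrows 42 to 39
  tyr1 <- sort(unique(atoms(hx)$resno[atoms(hx)$resname == "TYR"]))[1]
  s39 <- findTitratableSites(
    hx, sitePolicy(include = c("ASP", "GLU", "LYS", "ARG"),
                   tyrWhitelist = tyr1))
  expect_equal(length(s39), 39)
})

test_that("structures without titratable residues give an empty site list", {
  poly <- makeHelixInSlab(nRes = 8)
  expect_length(findTitratableSites(poly), 0)
})

test_that("sites missing required side-chain atoms raise an error", {
  hx <- gluHelix()
  a <- atoms(hx)
  a <- a[!(a$resno == 6 & a$name == "OE2"), ]
  broken <- new("ParameterizedStructure", atoms = a, chains = "A",
                frameId = 0L)
  expect_error(findTitratableSites(broken), "OE2")
})

test_that("site charge maps obey the protonation invariants", {
  tab <- loadParameterTable()
  for (res in names(tab$titratable)) {
    t <- tab$titratable[[res]]
    dq <- sum(unlist(t$protonated)) - sum(unlist(t$deprotonated))
    expect_equal(dq, 1, tolerance = 1e-9)
    charged <- if (t$class == "acid") sum(unlist(t$deprotonated))
               else sum(unlist(t$protonated))
    expect_equal(abs(charged), 1, tolerance = 1e-9)
  }
})

test_that("multi-model PDB write/read round trips frames", {
  hx <- gluHelix(nRes = 5, position = 3)
  frames <- makePseudoTrajectory(hx, 0.1, 3, seed = 2)
  f <- tempfile(fileext = ".pdb")
  writePdb(frames, f)
  back <- readFrames(f)
  expect_length(back, 3)
  dev <- abs(as.matrix(atoms(back[[2]])[, c("x", "y", "z")]) -
               as.matrix(atoms(frames[[2]])[, c("x", "y", "z")]))
  expect_lt(max(dev), 6e-4)  # coordinates printed to 3 decimals
})
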