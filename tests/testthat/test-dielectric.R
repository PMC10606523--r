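test_that("polar density counts side-chain O/N over the kernel volume", {
  hx <- gluHelix()
  a <- atoms(hx)
  oe1 <- as.numeric(a[a$name == "OE1", c("x", "y", "z")])
  ## point 3 A from a single polar atom, kernel 5 A, far from the others
  probe <- oe1 + c(3, 0, 0)
  pc <- polarAtomCoords(hx)
  nIn <- sum(colSums((t(pc) - probe)^2) <= 25)
  expect_equal(polarDensity(hx, probe, 5),
               nIn / (4 / 3 * pi * 125), tolerance = 1e-12)
  ## far away: zero
  expect_equal(polarDensity(hx, oe1 + c(100, 0, 0), 5), 0)
})

test_that("backbone carbonyl oxygens are not polar side-chain atoms", {
  poly <- makeHelixInSlab(nRes = 6)  # poly-Ala: backbone N/O only
  expect_equal(nrow(polarAtomCoords(poly)), 0)
  o <- as.numeric(atoms(poly)[atoms(poly)$name == "O", ][1, c("x", "y", "z")])
  expect_equal(polarDensity(poly, o, 5), 0)
})

test_that("eps map separates protein layers from solvent", {
  poly <- makeHelixInSlab(nRes = 10)
  g <- gridSpec(as.matrix(atoms(poly)[, c("x", "y", "z")]),
                spacing = 0.8, margin = 8)
  m <- buildEpsMap(poly, g, ionicStrength = 0)
  codes <- regionCodes()
  ## poly-Ala interior has no polar side chains: lowest layer
  inside <- m@labels <= codes[["protein_layer_20"]]
  expect_true(any(inside))
  expect_true(all(m@eps[inside] == 3))
  expect_true(all(m@eps[!inside] == 81))
  ## every voxel labelled exactly once with a known code
  expect_true(all(m@labels %in% codes))
  ## corner voxel is solvent
  expect_equal(m@eps[1, 1, 1], 81)
})

test_that("constant mapping lands on the nearest layer, ties upward", {
  poly <- makeHelixInSlab(nRes = 8)
  g <- gridSpec(as.matrix(atoms(poly)[, c("x", "y", "z")]),
                spacing = 1.0, margin = 6)
  m12 <- buildEpsMap(poly, g, mapping = function(d) rep(12, length(d)),
                     ionicStrength = 0)
  inside <- m12@labels <= regionCodes()[["protein_layer_20"]]
  expect_true(all(m12@eps[inside] == 10))
  ## tie at 4.0 (midpoint of 3 and 5) breaks upward
  m4 <- buildEpsMap(poly, g, mapping = function(d) rep(4, length(d)),
                    ionicStrength = 0)
  expect_true(all(m4@eps[m4@labels <= 4] == 5))
  expect_error(buildEpsMap(poly, g, mapping = function(d) rep(0.5, length(d))),
               "eps < 1")
})

test_that("membrane slab overlays non-protein voxels only", {
  slab <- membraneSlab(coreZmin = -6, coreZmax = 6, headThickness = 5,
                       epsCore = 2.0, epsHead = 40)
  hx <- gluHelix(nRes = 10, slab = slab)
  g <- gridSpec(as.matrix(atoms(hx)[, c("x", "y", "z")]),
                spacing = 1.0, margin = 10)
  m0 <- buildEpsMap(hx, g, ionicStrength = 0.2)
  m <- applyMembrane(m0, slab)
  codes <- regionCodes()
  ax <- lapply(1:3, function(d) g@origin[d] + (seq_len(g@dims[d]) - 1) * 1.0)
  ## solvent voxel at the slab midplane -> core eps
  i <- c(2, 2, which.min(abs(ax[[3]] - 0)))
  expect_equal(m@eps[i[1], i[2], i[3]], 2.0)
  expect_equal(unname(m@labels[i[1], i[2], i[3]]), unname(codes[["membrane_core"]]))
  ## headgroup band voxel
  k <- which.min(abs(ax[[3]] - 8.5))
  expect_equal(m@eps[2, 2, k], 40)
  ## protein voxels unchanged
  prot <- m0@labels <= codes[["protein_layer_20"]]
  expect_identical(m@eps[prot], m0@eps[prot])
  ## membrane carries no mobile ions
  expect_true(all(m@saltMask[m@labels %in%
                               codes[c("membrane_core", "membrane_head")]] == 0))
  ## eps values restricted to the declared set
  expect_true(all(m@eps %in% c(3, 5, 10, 20, 2.0, 40, 81)))
  ## slab entirely outside the box errors
  expect_error(applyMembrane(m0, membraneSlab(coreZmin = 500, coreZmax = 520)),
               "outside")
})

test_that("eps map is invariant under joint translation of structure and grid",
{
  hx <- gluHelix(nRes = 8)
  g1 <- gridSpec(as.matrix(atoms(hx)[, c("x", "y", "z")]),
                 spacing = 1.0, margin = 7)
  m1 <- buildEpsMap(hx, g1, ionicStrength = 0)
  shift <- c(3.3, -2.1, 5.7)
  a2 <- atoms(hx)
  a2$x <- a2$x + shift[1]; a2$y <- a2$y + shift[2]; a2$z <- a2$z + shift[3]
  hx2 <- new("ParameterizedStructure", atoms = a2, chains = "A",
             frameId = 0L)
  g2 <- gridSpec(origin = g1@origin + shift, dims = g1@dims, spacing = 1.0)
  m2 <- buildEpsMap(hx2, g2, ionicStrength = 0)
  expect_identical(m1@eps, m2@eps)
  expect_identical(m1@labels, m2@labels)
})

test_that("density-to-eps mapping is monotone through quantization", {
  map <- defaultEpsMapping()
  d <- seq(0, 0.03, by = 1e-3)
  eps <- map(d)
  expect_true(all(diff(eps) >= 0))
  expect_error(defaultEpsMapping(cbind(c(0, 0.01), c(5, 3))), "monotone")
})

test_that("DX grid export round trips", {
  g <- gridSpec(origin = c(-2, -3, -4), dims = c(5L, 6L, 7L), spacing = 0.5)
  vals <- array(rnorm(prod(g@dims)), dim = g@dims)
  f <- tempfile(fileext = ".dx")
  writeDx(vals, g, f)
  back <- readDx(f)
  expect_equal(back$values, vals, tolerance = 1e-5)
  expect_equal(back$grid@origin, g@origin)
  expect_equal(back$grid@dims, g@dims)
})
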