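test_that("ideal helices yield near-zero bending and canonical rise/twist", {
  h <- makeIdealHelix(30, rise = 1.5, twist = 100)
  g <- helanalGeometry(h, "ideal")
  expect_lt(g@maxBending, 1)
  expect_equal(g@risePerResidue, 1.5, tolerance = 0.05)
  expect_equal(g@twistPerResidue, 100, tolerance = 1)
  expect_equal(nrow(g@windowAxes), 30 - 8)
  expect_lt(vectorAngle(g@overallAxis, c(0, 0, 1)), 1)
  expect_error(helanalGeometry(makeIdealHelix(8)), ">= 9")
})

test_that("an engineered 30 degree kink is localized with correct magnitude", {
  k <- makeKinkedHelix(15, 15, 30)
  g <- helanalGeometry(k, "kinked")
  expect_equal(g@maxBending, 30, tolerance = 3)
  junction <- which.max(g@bendingAngles)
  # the peak lies at windows spanning the residue-15/16 junction
  expect_true(junction >= 8 && junction <= 15)
  # helanal outputs are invariant under rigid transforms
  set.seed(5)
  R <- randomRotation()
  k2 <- sweep(k %*% t(R), 2L, -rnorm(3, sd = 30))
  g2 <- helanalGeometry(k2)
  expect_equal(g2@bendingAngles, g@bendingAngles, tolerance = 1e-6)
  expect_equal(g2@twistPerResidue, g@twistPerResidue, tolerance = 1e-6)
  expect_equal(g2@risePerResidue, g@risePerResidue, tolerance = 1e-6)
})

test_that("break detection thresholds behave as bounds", {
  ideal <- helanalGeometry(makeIdealHelix(30))
  expect_equal(nrow(detectBreaks(ideal)), 0L)
  kinked <- helanalGeometry(makeKinkedHelix(15, 15, 30))
  hits <- detectBreaks(kinked, threshold = 20)
  expect_gt(nrow(hits), 0L)
  # one contiguous run of windows around the junction
  expect_equal(sort(hits$window), seq(min(hits$window), max(hits$window)))
  expect_true(all(hits$bending > 20))
  expect_equal(hits$bending, sort(hits$bending, decreasing = TRUE))
  expect_equal(nrow(detectBreaks(kinked, threshold = 180)), 0L)
})

test_that("overall axis tracks the generator axis on ideal helices", {
  for (axis in list(c(0, 0, 1), c(1, 1, 1), c(-0.3, 0.8, 0.6))) {
    h <- makeIdealHelix(24, axis = axis)
    g <- helanalGeometry(h)
    u <- axis / sqrt(sum(axis^2))
    expect_lt(vectorAngle(g@overallAxis, u), 1)
  }
})

test_that("helix ends project onto the membrane plane orthogonally", {
  toy <- makeToyTransporter()
  s <- toy$structure; ann <- toy$annotation; mem <- toy$membrane
  pr <- projectHelixEnds(s, ann, mem)
  expect_setequal(unique(pr$helix), paste0("TH", 1:12))
  expect_setequal(unique(pr$side), c("intracellular", "extracellular"))
  # a point already in the membrane-center plane projects to itself:
  # reconstruct each projected point and check the residual is along z
  basis <- membranePlaneBasis(mem)
  for (i in seq_len(nrow(pr))) {
    p3 <- conftor:::.endAnchor(s, ann, pr$helix[i], pr$side[i], 1L, mem)
    back <- membraneCenter(mem) + pr$x[i] * basis[1, ] + pr$y[i] * basis[2, ]
    resid <- p3 - back
    inplane <- resid - sum(resid * membraneNormal(mem)) * membraneNormal(mem)
    expect_lt(max(abs(inplane)), 1e-9)
  }
  # projected inter-end distances never exceed the 3D distances
  i1 <- which(pr$helix == "TH1" & pr$side == "extracellular")
  i2 <- which(pr$helix == "TH7" & pr$side == "extracellular")
  d2 <- sqrt((pr$x[i1] - pr$x[i2])^2 + (pr$y[i1] - pr$y[i2])^2)
  p1 <- conftor:::.endAnchor(s, ann, "TH1", "extracellular", 1L, mem)
  p2 <- conftor:::.endAnchor(s, ann, "TH7", "extracellular", 1L, mem)
  expect_lte(d2, sqrt(sum((p1 - p2)^2)) + 1e-12)
})

test_that("an in-plane point with normal z projects to its own x,y", {
  # helix end exactly on the membrane-center plane at (3,4,0)
  atoms <- data.frame(type = "ATOM", chain = "A", resno = 1:9, insert = "",
                      resid = "ALA", elety = "CA")
  rod <- conftor:::.rodCa(c(3, 4, 0), c(0.6, 0.8, 0), 9, 1.5)
  s <- proteinStructure("flat", atoms, rod)
  ann <- regionAnnotation(data.frame(region = "TH1", chain = "A",
                                     start = 1L, end = 9L))
  mem <- membraneModel(c(0, 0, 0), c(0, 0, 1), 30)
  pr <- projectHelixEnds(s, ann, mem)
  first <- pr[pr$x^2 + pr$y^2 == min(pr$x^2 + pr$y^2), ]
  expect_equal(c(first$x, first$y), c(3, 4), tolerance = 1e-9)
})

test_that("a displaced helix is flagged in end-projection comparison", {
  toy <- makeToyTransporter()
  s <- toy$structure; ann <- toy$annotation; mem <- toy$membrane
  # displace TH7 by 10 A in-plane
  sel <- which(atomData(s)$chain == "A" &
                 atomData(s)$resno >= regions(ann)$start[regions(ann)$region == "TH7"] &
                 atomData(s)$resno <= regions(ann)$end[regions(ann)$region == "TH7"])
  xyz <- modelCoords(s)
  xyz[sel, 1] <- xyz[sel, 1] + 6
  xyz[sel, 2] <- xyz[sel, 2] + 8
  s2 <- proteinStructure("displaced", atomData(s), xyz)
  a <- projectHelixEnds(s, ann, mem)
  b <- projectHelixEnds(s2, ann, mem)
  cmp <- compareEndProjections(a, b, outlierThreshold = 5)
  flagged <- cmp[cmp$outlier, ]
  expect_setequal(unique(flagged$helix), "TH7")
  expect_equal(flagged$displacement, c(10, 10), tolerance = 1e-9)
  other <- cmp[cmp$helix != "TH7", ]
  expect_lt(max(other$displacement), 1e-9)
  # identical sets: zero displacement, no flags; huge threshold: no flags
  same <- compareEndProjections(a, a)
  expect_false(any(same$outlier))
  expect_lt(max(same$displacement), 1e-12)
  expect_false(any(compareEndProjections(a, b, outlierThreshold = 1e6)$outlier))
  # key mismatch is an error
  expect_error(compareEndProjections(a, b[-1, ]), "keys")
})

test_that("projection into a reference frame uses the reference membrane", {
  toy <- makeToyTransporter()
  R <- rotationAboutAxis(c(0, 1, 0), 25)
  moved <- transformStructure(toy$structure, R, c(10, 5, -4))
  movedMem <- transformMembrane(toy$membrane, R, c(10, 5, -4))
  prRef <- projectHelixEnds(toy$structure, toy$annotation, toy$membrane)
  prMoved <- projectHelixEnds(moved, toy$annotation, movedMem,
                              reference = toy$structure,
                              referenceAnnotation = toy$annotation,
                              referenceMembrane = toy$membrane)
  cmp <- compareEndProjections(prRef, prMoved)
  expect_lt(max(cmp$displacement), 1e-6)
})
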