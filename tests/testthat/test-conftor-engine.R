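test_that("the built-in registry encodes the standard anchor constructions", {
  reg <- builtinConftorRegistry()
  expect_true(all(c("THV1", "THV2", "THX1", "THX2", "ICV1", "ICV2",
                    "ICX1", "ICX2", "NBDV1", "NBDV2", "NBDX1", "NBDX2",
                    "S6", "WAH", "WAH1_SIG2", "WAH2_SIG1") %in% names(reg)))
  thx1 <- reg$THX1
  expect_identical(thx1@origin@kind, "cog_of_helix_ends")
  expect_identical(sort(thx1@origin@targets$region), c("TH4", "TH5"))
  expect_true(all(thx1@origin@targets$end == "intracellular"))
  expect_true(all(thx1@tip@targets$end == "extracellular"))
  nbdx1 <- reg$NBDX1
  expect_identical(nbdx1@tip@kind, "single_ca")
  expect_identical(nbdx1@tip@targets$region, "S9_1")
  expect_identical(nbdx1@tip@targets$end, "first")
  # every spec resolves to distinct origin/tip on the toy transporter
  toy <- makeToyTransporter()
  for (sp in reg) {
    cf <- computeConftor(toy$structure, toy$annotation, sp, toy$membrane)
    expect_gt(sqrt(sum(conftorVector(cf)^2)), 0.5)
  }
})

test_that("conftor anchors resolve by definition on constructed geometry", {
  toy <- makeToyTransporter(toyTransporterParams(thxAngle = 40, icvAngle = 45))
  s <- toy$structure; ann <- toy$annotation; mem <- toy$membrane
  # THV-style vector along an untilted vertical helix: TH1 is a straight
  # rod along z spanning 30 A
  spec <- conftorSpec("TH1V", anchorSpec("single_ca", "TH1", "intracellular"),
                      anchorSpec("single_ca", "TH1", "extracellular"), "TH")
  cf <- computeConftor(s, ann, spec, mem)
  expect_equal(conftorVector(cf), c(0, 0, 30), tolerance = 1e-9)
  # NBDX vector = S9 first residue minus coupling-helix COG
  nbdx1 <- computeConftor(s, ann, "NBDX1", mem)
  chCog <- centerOfGeometry(regionCa(s, ann, c("CH1", "CH2")))
  s9first <- regionCa(s, ann, "S9_1")[1, ]
  expect_equal(conftorVector(nbdx1), s9first - chCog, tolerance = 1e-9)
})

test_that("TM conftors anti-aligned with the membrane normal are flipped with a warning", {
  toy <- makeToyTransporter()
  # a sequence-anchored TM vector (first -> last residue); TH1 residues run
  # intracellular -> extracellular, so against an inverted membrane normal
  # the intracellular -> extracellular convention is violated
  spec <- conftorSpec("TH1SEQ", anchorSpec("single_ca", "TH1", "first"),
                      anchorSpec("single_ca", "TH1", "last"), "TH")
  flipped <- membraneModel(membraneCenter(toy$membrane), c(0, 0, -1),
                           membraneThickness(toy$membrane))
  expect_warning(
    cf <- computeConftor(toy$structure, toy$annotation, spec, flipped),
    "swapped")
  # after the swap the vector satisfies the convention w.r.t. that normal
  expect_gt(sum(conftorVector(cf) * c(0, 0, -1)), 0)
  # with the consistent membrane no warning is emitted
  expect_silent(cf2 <- computeConftor(toy$structure, toy$annotation, spec,
                                      toy$membrane))
  expect_equal(conftorVector(cf2), c(0, 0, 30), tolerance = 1e-9)
})

test_that("conftor angles recover generator truth and are rigid-body invariant", {
  toy <- makeToyTransporter(toyTransporterParams(thxAngle = 40, icvAngle = 55))
  s <- toy$structure; ann <- toy$annotation; mem <- toy$membrane
  expect_equal(conftorAngle(s, ann, "THX1", "THX2", mem), 40, tolerance = 1e-6)
  expect_equal(conftorAngle(s, ann, "ICV1", "ICV2", mem), 55, tolerance = 1e-6)
  set.seed(19)
  for (i in 1:5) {
    R <- randomRotation(); t <- rnorm(3, sd = 20)
    s2 <- transformStructure(s, R, t)
    m2 <- transformMembrane(mem, R, t)
    expect_equal(conftorAngle(s2, ann, "THX1", "THX2", m2), 40, tolerance = 1e-9)
  }
})

test_that("occluded-prototype geometry yields the 26 degree THX angle", {
  toy <- makeToyTransporter(toyTransporterParams(thxAngle = 26, icvAngle = 53))
  got <- conftorAngle(toy$structure, toy$annotation, "THX1", "THX2", toy$membrane)
  expect_equal(got, 26, tolerance = 1e-6)
  cl <- classifyConformation(list(thx_angle = got, icv_angle = 53))
  expect_identical(cl@label, "occluded")
})

test_that("conftor length metrics: span, ext and int", {
  toy <- makeToyTransporter(toyTransporterParams(nbdIntDistance = 50,
                                                 nbdExtDistance = 40))
  s <- toy$structure; ann <- toy$annotation; mem <- toy$membrane
  expect_equal(conftorLength(s, ann, "NBDX", "int", mem), 50, tolerance = 1e-9)
  expect_equal(conftorLength(s, ann, "NBDX", "ext", mem), 40, tolerance = 1e-9)
  expect_equal(conftorLength(s, ann, "WAH", "span", mem),
               toy$truth$wah_length, tolerance = 1e-9)
  # Pythagorean span on a hand-built conftor
  cf <- new("Conftor", name = "x", origin = c(0, 0, 0), tip = c(3, 4, 0))
  expect_equal(sqrt(sum(conftorVector(cf)^2)), 5)
  # bottom-open geometry: NBD bottoms splay outward, so ext < int
  open <- makeToyTransporter(toyTransporterParams(nbdIntDistance = 60,
                                                  nbdExtDistance = 35))
  expect_lt(conftorLength(open$structure, ann, "NBDX", "ext", mem),
            conftorLength(open$structure, ann, "NBDX", "int", mem))
})

test_that("classification follows the printed class-angle signatures", {
  expect_identical(classifyConformation(list(thx_angle = 46, icv_angle = 43))@label,
                   "bottom_open_inward_facing")
  expect_identical(classifyConformation(list(thx_angle = 26, icv_angle = 53))@label,
                   "occluded")
  expect_identical(classifyConformation(list(thx_angle = 35, icv_angle = 60))@label,
                   "bottom_closed_outward_facing")
  expect_identical(classifyConformation(list(thx_angle = 39, icv_angle = 38))@label,
                   "bottom_closed_inward_facing")
  expect_error(classifyConformation(list(thx_angle = 40)), "icv_angle")
})

test_that("metrics equidistant between two prototypes raise the ambiguity flag", {
  p <- conformationPrototypes()
  mid <- c(thx_angle = mean(p["bottom_closed_outward_facing", "thx"],
                            p["occluded", "thx"]),
           icv_angle = mean(c(p["bottom_closed_outward_facing", "icv"],
                              p["occluded", "icv"])))
  mid <- list(thx_angle = (35 + 26) / 2, icv_angle = (60 + 53) / 2)
  cl <- classifyConformation(mid)
  expect_true(cl@ambiguityFlag)
  # NBDX ext separation resolves an inward-facing tie
  tie <- list(thx_angle = (46 + 39) / 2, icv_angle = (43 + 38) / 2)
  expect_true(classifyConformation(tie)@ambiguityFlag)
  tie$nbdx_ext_length <- 48
  clOpen <- classifyConformation(tie)
  expect_identical(clOpen@label, "bottom_open_inward_facing")
  expect_false(clOpen@ambiguityFlag)
  tie$nbdx_ext_length <- 32
  expect_identical(classifyConformation(tie)@label, "bottom_closed_inward_facing")
})

test_that("parameter recovery and classification over a grid of toy transporters", {
  p <- conformationPrototypes()
  for (thx in c(20, 30, 40, 50)) {
    for (icv in c(35, 45, 55)) {
      toy <- makeToyTransporter(toyTransporterParams(thxAngle = thx, icvAngle = icv))
      got <- computeMetrics(toy$structure, toy$annotation,
                            c("angle:THX1:THX2", "angle:ICV1:ICV2"),
                            toy$membrane)
      expect_equal(unname(got[1]), thx, tolerance = 1e-6)
      expect_equal(unname(got[2]), icv, tolerance = 1e-6)
      cl <- classifyConformation(list(thx_angle = got[[1]], icv_angle = got[[2]]))
      if (!cl@ambiguityFlag) {
        nearest <- rownames(p)[which.min((thx - p$thx)^2 + (icv - p$icv)^2)]
        expect_identical(cl@label, nearest)
      }
    }
  }
})

test_that("swapping the symmetric halves leaves symmetric metrics unchanged", {
  toy <- makeToyTransporter(toyTransporterParams(thxAngle = 44, icvAngle = 41))
  e <- regions(toy$annotation)
  swap <- c(TH4 = "TH10", TH5 = "TH11", TH10 = "TH4", TH11 = "TH5",
            ICD1 = "ICD3", ICD2 = "ICD4", ICD3 = "ICD1", ICD4 = "ICD2",
            CH1 = "CH3", CH2 = "CH4", CH3 = "CH1", CH4 = "CH2",
            WAH1 = "WAH2", WAH2 = "WAH1", SIG1 = "SIG2", SIG2 = "SIG1",
            S6_1 = "S6_2", S6_2 = "S6_1", S9_1 = "S9_2", S9_2 = "S9_1")
  e$region <- ifelse(e$region %in% names(swap), swap[e$region], e$region)
  swapped <- regionAnnotation(e)
  metrics <- c("angle:THX1:THX2", "angle:ICV1:ICV2", "length:NBDX:ext",
               "length:NBDX:int", "length:WAH", "length:S6")
  a <- computeMetrics(toy$structure, toy$annotation, metrics, toy$membrane)
  b <- computeMetrics(toy$structure, swapped, metrics, toy$membrane)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("trajectory metrics preserve frame order and match the generator schedule", {
  start <- toyTransporterParams(nbdIntDistance = 80)
  end <- toyTransporterParams(nbdIntDistance = 50)
  traj <- makeClosingTrajectory(start, end, 20)
  series <- trajectoryMetrics(traj$frames, traj$annotation,
                              c("length:NBDX:int", "length:WAH1_SIG2",
                                "length:WAH2_SIG1"),
                              traj$membrane)
  intLen <- series[["length:NBDX:int"]]
  expect_equal(intLen@frameIndices, 1:20)
  expect_equal(intLen@values, seq(80, 50, length.out = 20), tolerance = 1e-6)
  expect_true(all(diff(intLen@values) < 0))
  # independent series per requested metric
  expect_length(series, 3L)
  expect_identical(series[["length:WAH1_SIG2"]]@metricName, "length:WAH1_SIG2")

  # constant trajectory: constant series
  const <- makeClosingTrajectory(start, start, 5)
  s2 <- trajectoryMetrics(const$frames, const$annotation, "length:NBDX:int",
                          const$membrane)[[1]]
  expect_equal(diff(range(s2@values)), 0, tolerance = 1e-9)
})

test_that("a frame missing annotated residues is reported by frame number", {
  traj <- makeClosingTrajectory(toyTransporterParams(),
                                toyTransporterParams(thxAngle = 30), 3)
  s <- traj$frames
  bad <- regions(traj$annotation)
  bad$start[bad$region == "TH4"] <- 9500L
  bad$end[bad$region == "TH4"] <- 9520L
  expect_error(
    trajectoryMetrics(s, regionAnnotation(bad), "angle:THX1:THX2",
                      traj$membrane),
    "frame 1")
})
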