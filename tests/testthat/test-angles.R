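# Landmark sets used here are in generic (ap, rl) mm coordinates with the
# midline along +ap; left points have rl > 0 relative to the axis.
lmFrom <- function(AFL, PFL, AFR, PFR, VBC = c(0, 0), SP = c(10, 0)) {
  landmarkSet(AFR = AFR, PFR = PFR, AFL = AFL, PFL = PFL, VBC = VBC, SP = SP)
}

test_that("angle formula reproduces hand trigonometry", {
  # u = PFL - AFL = (-3, 4), v = (10, 0): cos = |−30|/(5·10) ... -> arccos(0.6)?
  # Worked by hand: u.v = -30, |u| = 5, |v| = 10, |cos| = 0.6 -> 53.13 deg.
  # The classic 3-4-5 case from the other orientation gives arccos(0.8):
  lm <- lmFrom(AFL = c(2, 5), PFL = c(6, 2), AFR = c(2, -5), PFR = c(6, -2),
               VBC = c(0, 0), SP = c(10, 0))
  # u = (4, -3), v = (10, 0): |cos| = 40/50 = 0.8 -> 36.8699 deg
  ang <- computeAngles(lm)
  expect_equal(thetaLeft(ang), acos(0.8) * 180 / pi, tolerance = 1e-9)
  expect_equal(thetaLeft(ang), 36.8699, tolerance = 1e-4)
})

test_that("collinear and perpendicular facet lines give 0 and 90 degrees", {
  lm0 <- lmFrom(AFL = c(2, 3), PFL = c(8, 3), AFR = c(2, -3), PFR = c(8, -3))
  ang <- computeAngles(lm0)
  expect_equal(thetaLeft(ang), 0)
  expect_equal(thetaRight(ang), 0)
  expect_equal(asymmetry(ang), 0)

  lm90 <- lmFrom(AFL = c(5, 2), PFL = c(5, 8), AFR = c(5, -2), PFR = c(5, -8))
  expect_equal(thetaLeft(computeAngles(lm90)), 90)
})

test_that("angles are invariant to facet line direction and rigid rotation", {
  set.seed(42)
  for (k in 1:20) {
    th <- runif(2, 5, 85) * pi / 180
    L <- runif(1, 5, 15)
    lm <- lmFrom(AFL = c(2, 4), PFL = c(2, 4) + L * c(cos(th[1]), sin(th[1])),
                 AFR = c(2, -4), PFR = c(2, -4) + L * c(cos(th[2]), -sin(th[2])))
    a1 <- computeAngles(lm)
    expect_true(thetaLeft(a1) >= 0 && thetaLeft(a1) <= 90)
    # swapping AF and PF leaves the acute angle unchanged
    sw <- landmarkSet(AFR = lm@PFR, PFR = lm@AFR, AFL = lm@PFL, PFL = lm@AFL,
                      VBC = lm@VBC, SP = lm@SP)
    expect_equal(thetaLeft(computeAngles(sw)), thetaLeft(a1), tolerance = 1e-9)
    # rigid rotation about a random point changes nothing
    phi <- runif(1, 0, 2 * pi); ctr <- runif(2, -5, 5)
    Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    rot <- function(p) as.numeric(Rm %*% (p - ctr) + ctr)
    lmR <- landmarkSet(AFR = rot(lm@AFR), PFR = rot(lm@PFR), AFL = rot(lm@AFL),
                       PFL = rot(lm@PFL), VBC = rot(lm@VBC), SP = rot(lm@SP))
    a2 <- computeAngles(lmR)
    expect_equal(thetaLeft(a2), thetaLeft(a1), tolerance = 1e-9)
    expect_equal(thetaRight(a2), thetaRight(a1), tolerance = 1e-9)
  }
})

test_that("mirrored landmarks negate the asymmetry exactly", {
  lm <- lmFrom(AFL = c(2, 3), PFL = c(9, 7), AFR = c(1, -4), PFR = c(8, -5))
  a <- computeAngles(lm)
  mir <- landmarkSet(AFR = lm@AFL * c(1, -1), PFR = lm@PFL * c(1, -1),
                     AFL = lm@AFR * c(1, -1), PFL = lm@PFR * c(1, -1),
                     VBC = lm@VBC, SP = lm@SP)
  expect_equal(asymmetry(computeAngles(mir)), -asymmetry(a))
})

test_that("degenerate axes are rejected", {
  expect_error(computeAngles(lmFrom(AFL = c(2, 3), PFL = c(2, 3),
                                    AFR = c(2, -3), PFR = c(6, -2))),
               class = "DegenerateAxisError")
})

test_that("tropism calls use strict thresholds and graded bands", {
  expect_true(classifyTropism(facetAngles(48, 36), 10)@isTropism)
  expect_false(classifyTropism(facetAngles(40, 35), 7)@isTropism)
  expect_false(classifyTropism(facetAngles(42, 35), 7)@isTropism)  # == is not >
  expect_equal(classifyTropism(facetAngles(43, 35), 7,
                               scheme = "mohanty2017")@grade, "moderate")
  expect_equal(classifyTropism(facetAngles(41, 35), 7,
                               scheme = "mohanty2017")@grade, "mild")
  expect_equal(classifyTropism(facetAngles(36, 35), 7,
                               scheme = "mohanty2017")@grade, "none")
  expect_equal(classifyTropism(facetAngles(55, 35), 7,
                               scheme = "mohanty2017")@grade, "severe")
  # band bounds: exclusive lower, inclusive upper (7 falls in (5, 7] = mild)
  expect_equal(classifyTropism(facetAngles(42, 35), 7,
                               scheme = "mohanty2017")@grade, "mild")
  expect_equal(classifyTropism(facetAngles(50, 35), 7,
                               scheme = "mohanty2017")@grade, "moderate")
})

test_that("cohort summary computes means, SE, pooled averages and prevalence", {
  rec <- function(id, sex, level, l, r)
    data.frame(id = id, sex = sex, level = level, thetaLeft = l, thetaRight = r)
  df <- rbind(rec("a", "female", "L3/4", 38, 35), rec("b", "female", "L3/4", 40, 36),
              rec("c", "female", "L3/4", 46, 35), rec("d", "female", "L3/4", 47, 36))
  s <- summarizeCohort(df, thresholds = c(7, 10))
  cell <- s$cells[1, ]
  expect_equal(cell$n, 4)
  expect_equal(cell$meanLeft, mean(c(38, 40, 46, 47)))
  expect_equal(cell$seLeft, sd(c(38, 40, 46, 47)) / 2)
  expect_equal(cell$meanAverage, (cell$meanLeft + cell$meanRight) / 2)
  # asymmetries are {3, 4, 11, 11}: prevalence 2 at 7 deg, 2 at 10 deg
  p7 <- s$prevalence[s$prevalence$threshold == 7, ]
  expect_equal(p7$count, 2); expect_equal(p7$percent, 50)

  # enumerated example: |asymmetry| {3, 8, 11, 12} -> 3 (75%) at 7, 2 (50%) at 10
  df2 <- rbind(rec("a", "male", "L4/5", 40, 37), rec("b", "male", "L4/5", 45, 37),
               rec("c", "male", "L4/5", 48, 37), rec("d", "male", "L4/5", 49, 37))
  s2 <- summarizeCohort(df2, thresholds = c(7, 10))
  expect_equal(s2$prevalence$count, c(3, 2))
  expect_equal(s2$prevalence$percent, c(75, 50))
  # prevalence equals brute-force count for any threshold
  for (th in c(2, 7.5, 11.5)) {
    sb <- summarizeCohort(df2, thresholds = th)
    expect_equal(sb$prevalence$count,
                 sum(abs(df2$thetaLeft - df2$thetaRight) > th))
  }
})

test_that("single-record cells warn and report SE 0; empty input errors", {
  df <- data.frame(id = "a", sex = "female", level = "L4/5",
                   thetaLeft = 44, thetaRight = 40)
  expect_warning(s <- summarizeCohort(df), class = "DegenerateCellWarning")
  expect_equal(s$cells$seLeft, 0)
  expect_equal(s$cells$meanLeft, 44)
  expect_error(summarizeCohort(df[0, ]), class = "EmptyCellError")
})

test_that("asymmetry histogram counts every observation once", {
  x <- c(-12.3, -4, 0, 0.1, 3, 9.9, 25)
  h <- asymmetryHistogram(x, binWidth = 5)
  expect_equal(sum(h$count), length(x))
})
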