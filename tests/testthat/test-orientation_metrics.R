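# Structure-tensor organization metrics and the orientation estimator.

test_that("OOP closed forms: aligned, isotropic, 75/25 split", {
  m1 <- structure_tensor_metrics(unit_vecs(rep(0, 20)))
  expect_equal(m1$oop, 1)
  expect_equal(m1$director_deg, 0)
  m2 <- structure_tensor_metrics(unit_vecs(c(rep(0, 10), rep(90, 10))))
  expect_equal(m2$oop, 0)
  m3 <- structure_tensor_metrics(unit_vecs(c(rep(0, 75), rep(90, 25))))
  expect_equal(m3$oop, 0.5)
  expect_equal(m3$director_deg, 0)
  expect_equal(m3$lambda_max, 0.75)
  # raw-eigenvalue convention
  m3r <- structure_tensor_metrics(unit_vecs(c(rep(0, 75), rep(90, 25))),
                                  convention = "raw_eigenvalue")
  expect_equal(m3r$oop, 0.75)
  expect_error(structure_tensor_metrics(matrix(numeric(0), 0, 2)), "empty")
  expect_error(structure_tensor_metrics(cbind(1, 1)), "unit")
})

test_that("eigen OOP matches the brute-force phi-grid oracle on random sets", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    v <- unit_vecs(runif(n, 0, 180))
    a <- structure_tensor_metrics(v)
    b <- oop_bruteforce(v)
    expect_equal(a$oop, b$oop, tolerance = 1e-4)
    expect_lte(axial_diff(a$director_deg, b$director_deg), 0.05)
  }
})

test_that("OOP is rotation-invariant, duplication-invariant; director equivariant", {
  set.seed(15)
  ang <- runif(30, 0, 180)
  base <- structure_tensor_metrics(unit_vecs(ang))
  for (rot in c(17, 63, 90, 141)) {
    m <- structure_tensor_metrics(unit_vecs(ang + rot))
    expect_equal(m$oop, base$oop, tolerance = 1e-12)
    expect_lte(axial_diff(m$director_deg, base$director_deg + rot), 1e-6)
  }
  dup <- structure_tensor_metrics(unit_vecs(rep(ang, 3)))
  expect_equal(dup$oop, base$oop, tolerance = 1e-12)
  expect_gte(base$oop, 0); expect_lte(base$oop, 1)
})

test_that("10,000 uniform axial vectors give OOP below 0.05 in >= 95% of trials", {
  set.seed(16)
  oops <- replicate(100, structure_tensor_metrics(unit_vecs(runif(1e4, 0, 180)))$oop)
  expect_gte(mean(oops < 0.05), 0.95)
})

test_that("axial angle between vectors folds to [0, 90]", {
  expect_equal(angle_between_axes(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_between_axes(c(1, 0), c(-1, 0)), 0)
  expect_equal(angle_between_axes(c(1, 0), c(cos(pi / 6), sin(pi / 6))), 30)
  set.seed(17)
  for (i in 1:25) {
    p <- unit_vecs(runif(1, 0, 360))[1, ]
    q <- unit_vecs(runif(1, 0, 360))[1, ]
    th <- angle_between_axes(p, q)
    expect_gte(th, 0); expect_lte(th, 90)
  }
  expect_error(angle_between_axes(c(0, 0), c(1, 0)), "zero")
})

test_that("actin fraction uses all three counts in the denominator", {
  expect_equal(actin_fraction(300, 700, 0), 0.3)
  expect_equal(actin_fraction(300, 500, 200), 0.3)
  expect_equal(actin_fraction(42, 0, 0), 1)
  expect_equal(actin_fraction(300, 500, 200, type = "fibroblast"), 0.5)
  expect_error(actin_fraction(0, 0, 0), "zero")
})

test_that("stripe fields are recovered within 2 degrees and equivariantly", {
  for (a in c(0, 30, 60, 115)) {
    f <- estimate_orientation_field(make_stripes(a))
    expect_gt(sum(f$valid), 5000)
    errs <- axial_diff(f$angle_deg[f$valid], a)
    expect_gte(mean(errs <= 2), 0.95)
  }
  # physically rotating the input rotates the recovered axis
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  f0 <- estimate_orientation_field(make_stripes(25))
  f90 <- estimate_orientation_field(rot90(make_stripes(25)))
  d0 <- structure_tensor_metrics(field_vectors(f0))$director_deg
  d90 <- structure_tensor_metrics(field_vectors(f90))$director_deg
  expect_lte(axial_diff(d90, d0 + 90), 3)
  # constant image: no gradients, empty validity mask
  fc <- estimate_orientation_field(matrix(4, 64, 64))
  expect_equal(sum(fc$valid), 0)
})

test_that("class vector selection partitions valid actin vectors", {
  H <- 60; W <- 60
  ang <- matrix(runif(H * W, 0, 180), H, W)
  valid <- matrix(runif(H * W) < 0.8, H, W)
  field <- orientation_field(ang, valid)
  semantic <- matrix(0L, H, W)
  semantic[1:20, ] <- 1L     # striated
  semantic[21:40, ] <- 2L    # other
  afg <- matrix(TRUE, H, W)
  vcm <- select_class_vectors(field, semantic, afg, "cardiomyocyte")
  vfb <- select_class_vectors(field, semantic, afg, "fibroblast")
  voth <- select_class_vectors(field, semantic, afg, "other")
  expect_equal(nrow(vcm) + nrow(vfb) + nrow(voth), sum(valid))
  expect_equal(nrow(vcm), sum(valid[1:20, ]))
  # semantic map all striated -> fibroblast set empty
  vfb0 <- select_class_vectors(field, matrix(1L, H, W), afg, "fibroblast")
  expect_equal(nrow(vfb0), 0L)
  # Other pixels are excluded from both primary sets
  expect_equal(nrow(voth), sum(valid[21:40, ]))
})

test_that("cell-type parameter recovery on a near-confluent two-cell scene", {
  cells <- list(
    cell_descriptor("striated_myocyte", c(128, 110), 25, length_px = 200,
                    width_px = 90),
    cell_descriptor("fibroblast", c(128, 260), 115, length_px = 200,
                    width_px = 90))
  sc <- generate_scene(scene_spec(cells = cells, background_noise_sd = 10,
                                  seed = 3))
  f <- estimate_orientation_field(sc$actin)
  afg <- sc$truth_celltype != 0L
  met <- organization_metrics(f, sc$truth_class, afg, stretch_angle_deg = 0)
  cm <- met[met$cell_type == "cardiomyocyte", ]
  fb <- met[met$cell_type == "fibroblast", ]
  expect_lte(axial_diff(cm$director_deg, 25), 2)
  expect_lte(axial_diff(fb$director_deg, 115), 2)
  expect_gte(cm$oop, 0.9)
  expect_gte(fb$oop, 0.9)
  expect_equal(cm$angle_to_stretch_deg, axial_diff(cm$director_deg, 0))
  expect_equal(cm$actin_fraction + fb$actin_fraction, 1)
})
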