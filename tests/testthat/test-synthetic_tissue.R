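# Synthetic tissue generator: exact truth, determinism, channel semantics.

test_that("identical spec and seed give bitwise-identical scenes", {
  spec <- scene_spec(cells = list(
    cell_descriptor("striated_myocyte", c(100, 150), 40),
    cell_descriptor("fibroblast", c(180, 220), 120)), seed = 5L)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$actin$pixels, b$actin$pixels)
  expect_identical(a$alpha_actinin$pixels, b$alpha_actinin$pixels)
  expect_identical(a$truth_class, b$truth_class)
  expect_identical(a$truth_nuclei, b$truth_nuclei)
})

test_that("single myocyte: truth orientation exact, stripes at 1/period along the axis", {
  period <- 8
  sc <- generate_scene(scene_spec(cells = list(
    cell_descriptor("striated_myocyte", c(128, 168), 30, length_px = 120,
                    width_px = 60, striation_period_px = period)),
    background_noise_sd = 0, seed = 2))
  inside <- sc$truth_celltype == 1L
  expect_true(all(sc$truth_orientation$angle_deg[inside] == 30))
  expect_true(all(sc$truth_orientation$valid == inside))
  # sample alpha-actinin along the cell axis through the centroid: the power
  # spectrum must peak at spatial frequency 1/period
  t <- 30 * pi / 180
  s <- seq(-40, 40)
  rows <- round(128 + s * sin(t)); cols <- round(168 + s * cos(t))
  prof <- sc$alpha_actinin$pixels[cbind(rows, cols)]
  pw <- Mod(fft(prof - mean(prof)))[2:floor(length(prof) / 2)]
  freq <- (seq_along(pw)) / length(prof)
  expect_equal(freq[which.max(pw)], 1 / period, tolerance = 0.02)
})

test_that("fibroblasts carry no alpha-actinin signal above background", {
  sc <- generate_scene(scene_spec(cells = list(
    cell_descriptor("fibroblast", c(128, 168), 115, length_px = 100,
                    width_px = 40)), seed = 3))
  incell <- mean(sc$alpha_actinin$pixels[sc$truth_celltype == 3L])
  bg <- mean(sc$alpha_actinin$pixels[sc$truth_celltype == 0L])
  expect_lt(abs(incell - bg), 2)   # noise-only on both sides
  # actin channel is clearly elevated inside the same cell
  expect_gt(mean(sc$actin$pixels[sc$truth_celltype == 3L]), bg + 30)
})

test_that("overlap of different cell types is flagged and later draw wins", {
  sc <- generate_scene(scene_spec(cells = list(
    cell_descriptor("striated_myocyte", c(128, 160), 0, length_px = 80,
                    width_px = 40),
    cell_descriptor("fibroblast", c(128, 180), 90, length_px = 80,
                    width_px = 40)), seed = 4))
  expect_gt(sum(sc$overlap), 0)
  expect_true(all(sc$truth_celltype[sc$overlap] == 3L))  # fibroblast drawn last
})

test_that("wellset myocyte counts follow the binomial draw", {
  ws <- generate_wellset(1, 1, cells_per_well = 5, base_seed = 9)
  expect_equal(ws$manifest$n_myocyte, 5L)
  expect_equal(ws$manifest$true_cm_actin_fraction, 1)
  ws0 <- generate_wellset(1, 0, cells_per_well = 5, base_seed = 9)
  expect_equal(ws0$manifest$n_myocyte, 0L)
  expect_equal(max(ws0$scenes[[1]]$truth_class), 0L)  # no alpha-actinin cells
  # 200 cells at fraction 0.5: count within the central 99% binomial interval
  ws5 <- generate_wellset(1, 0.5, cells_per_well = 200, base_seed = 21,
                          shape = c(640, 640))
  bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(ws5$manifest$n_myocyte, bounds[1])
  expect_lte(ws5$manifest$n_myocyte, bounds[2])
  expect_error(generate_wellset(1, 0.5, cells_per_well = 0), "positive")
})

test_that("write_scene produces the layout run_well consumes", {
  d <- withr::local_tempdir()
  ws <- generate_wellset(1, 0.5, cells_per_well = 4, base_seed = 33)
  write_scene(ws$scenes[[1]], d)
  expect_true(all(file.exists(file.path(d,
    c("actin.tif", "alpha_actinin.tif", "nuclei.tif", "truth_class.tif",
      "truth_nuclei.tif", "scene.json")))))
  back <- load_class_map(file.path(d, "truth_class.tif"))
  expect_identical(back, ws$scenes[[1]]$truth_class)
})
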