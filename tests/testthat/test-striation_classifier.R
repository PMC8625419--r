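# Diffusion, top-hat, binarization, superpixels, striation geometry,
# superpixel classification and nucleus label assignment.

test_that("coherence diffusion: identity on constants, bounded, noise-robust stripes", {
  cst <- matrix(7, 64, 64)
  expect_lt(max(abs(coherence_diffuse(cst, n_iter = 5) - 7)), 1e-9)

  set.seed(8)
  img <- make_stripes(35, lambda = 8, H = 96, W = 96) +
    matrix(rnorm(96 * 96, 0, 15), 96, 96)
  out <- coherence_diffuse(img)
  expect_gte(min(out), min(img))   # maximum principle
  expect_lte(max(out), max(img))
  expect_error(coherence_diffuse(matrix(c(NA, 1:63), 8, 8)), "non-finite")

  # stripe-frequency amplitude survives diffusion better than an isotropic
  # Gaussian spending the same diffusion-time budget (sigma^2 = 2 * n * tau)
  amp_at <- function(m) {
    v <- m[48, 20:80]
    p <- Mod(fft(v - mean(v)))
    max(p[2:floor(length(v) / 2)])
  }
  n_iter <- 15; tau <- 0.15
  iso <- cpp_gaussian_blur(img, sqrt(2 * n_iter * tau))
  dif <- coherence_diffuse(img, n_iter = n_iter, tau = tau)
  expect_gte(amp_at(dif), amp_at(iso))
})

test_that("white top-hat isolates thin bright lines and is bounded by the input", {
  expect_true(all(tophat_striations(matrix(5, 32, 32)) == 0))
  img <- matrix(10, 64, 64)
  lines_at <- seq(8, 56, by = 8)
  img[lines_at, ] <- 110   # 1-px-wide bright lines, spacing 8
  th <- tophat_striations(img, selem_radius = 3)
  expect_true(all(th[lines_at, 4:60] >= 0.9 * 100))
  expect_true(all(th[-lines_at, ] == 0))
  set.seed(1)
  rnd <- matrix(runif(32 * 32, 0, 9), 32, 32)
  th2 <- tophat_striations(rnd, 2)
  expect_true(all(th2 >= 0))
  expect_true(all(th2 <= rnd + 1e-12))
})

test_that("binarization: empty images, bimodal Otsu, adaptive stripe recovery", {
  z <- matrix(0, 32, 32)
  expect_true(all(!binarize(z, "adaptive_local_mean")))
  expect_warning(gm <- binarize(z, "global_otsu"), "all-zero")
  expect_true(all(!gm))
  bi <- matrix(10, 40, 40); bi[1:10, ] <- 100
  gm2 <- binarize(bi, "global_otsu")
  expect_identical(unname(gm2), unname(bi == 100))
  # adaptive mask recovers stripe pixels (Jaccard vs upper half of sinusoid)
  s <- make_stripes(20, lambda = 8, H = 96, W = 96)
  truth <- s > 100
  am <- binarize(s, "adaptive_local_mean", window = 15)
  expect_gte(sum(am & truth) / sum(am | truth), 0.8)
})

test_that("SLIC partitions the image into compact connected regions", {
  set.seed(3)
  img <- matrix(rnorm(150 * 150, 50, 5), 150, 150)
  sp <- compute_superpixels(img, n = 200)
  expect_true(all(sp$labels >= 1))
  expect_equal(sort(unique(as.vector(sp$labels))), seq_len(sp$n_regions))
  expect_gte(sp$n_regions, 100)   # within [0.5 n, 1.5 n]
  expect_lte(sp$n_regions, 300)
  # constant image: near-equal tiling
  spc <- compute_superpixels(matrix(1, 150, 150), n = 200)
  areas <- tabulate(spc$labels)
  expect_lt(sd(areas) / mean(areas), 0.5)
  # determinism + regions are 4-connected
  sp2 <- compute_superpixels(img, n = 200)
  expect_identical(sp$labels, sp2$labels)
  for (id in c(1L, 57L, sp$n_regions)) {
    msk <- sp$labels == id
    cc <- cpp_label_components(matrix(as.integer(msk), 150, 150), 4L)
    expect_equal(max(cc[msk]), 1L)
  }
  expect_error(compute_superpixels(img, n = 1), "at least 2")
  expect_error(compute_superpixels(img, n = 1e6), "exceeds")
})

test_that("object orientation map recovers the cell axis and is rotation-equivariant", {
  sc <- generate_scene(scene_spec(cells = list(
    cell_descriptor("striated_myocyte", c(128, 168), 30, length_px = 110,
                    width_px = 50)), seed = 6))
  fg <- sc$truth_class != 0L
  oo <- object_orientation_map(sc$alpha_actinin, fg)
  errs <- axial_diff(oo$angle_deg[oo$valid], 30)
  expect_gte(mean(errs <= 3), 0.9)
  # rotate image + mask by 90 degrees: orientations shift by 90 (mod 180)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  oor <- object_orientation_map(rot90(sc$alpha_actinin$pixels), rot90(fg))
  errs_r <- axial_diff(oor$angle_deg[oor$valid], 30 + 90)
  expect_gte(mean(errs_r <= 3), 0.9)
  expect_error(object_orientation_map(sc$alpha_actinin, fg & FALSE), "empty")
  # single-pixel objects carry no orientation
  tiny <- matrix(FALSE, 64, 64); tiny[5, 5] <- TRUE
  oo1 <- object_orientation_map(matrix(rnorm(64 * 64), 64), tiny,
                                min_pixels = 3)
  expect_equal(sum(oo1$valid), 0)
})

test_that("striation component orientations follow their principal axes", {
  m <- matrix(FALSE, 64, 64)
  m[20, 11:20] <- TRUE                      # horizontal 10 x 1 line
  for (k in 0:9) m[30 + k, (30 + k):(31 + k)] <- TRUE  # 45-deg staircase line
  m[50, 5:6] <- TRUE                        # 2-pixel component: ignored
  st <- striation_orientations(m)
  expect_equal(length(st$angle_deg), 2L)
  a <- sort(st$angle_deg)
  expect_lt(axial_diff(a[1], 0), 1e-6)
  expect_lt(axial_diff(a[2], 45), 5)
  expect_true(all(is.na(st$pixel_angle[50, 5:6])))
  expect_error(striation_orientations(matrix(FALSE, 8, 8)), "empty")
})

test_that("superpixel striation rule follows the dot-product and coverage thresholds", {
  # one superpixel covering the whole (small) frame, constructed inputs
  H <- 40; W <- 40
  part <- matrix(1L, H, W)
  fg <- matrix(3L, H, W)
  obj <- orientation_field(matrix(0, H, W), matrix(TRUE, H, W))  # axis at 0
  gmask_hi <- matrix(FALSE, H, W); gmask_hi[, seq(1, W, by = 12)] <- TRUE # 8%
  # perpendicular striations: vertical lines (axis 90 vs object 0 -> |dot|=0)
  am <- matrix(FALSE, H, W); am[, seq(2, W, by = 7)] <- TRUE  # ~15% coverage
  st <- striation_orientations(am)
  cmap <- classify_striated_superpixels(part, fg, obj, st, gmask_hi)
  expect_true(all(cmap == 1L))
  # parallel striations (|dot| = 1): Other regardless of coverage
  # (horizontal striation lines, object axis also horizontal)
  amp <- matrix(FALSE, H, W); amp[seq(2, H, by = 7), ] <- TRUE
  stp <- striation_orientations(amp)
  cmap2 <- classify_striated_superpixels(part, fg, obj, stp, gmask_hi)
  expect_true(all(cmap2 == 2L))
  # no striation pixels at all -> Other (both criteria fail)
  empty_st <- list(labels = matrix(0L, H, W),
                   angle_deg = setNames(numeric(0), character(0)),
                   size = integer(0), pixel_angle = matrix(NA_real_, H, W))
  cmap3 <- classify_striated_superpixels(part, fg, obj, empty_st,
                                         matrix(FALSE, H, W))
  expect_true(all(cmap3 == 2L))
  # insufficient global coverage blocks the striated call
  cmap4 <- classify_striated_superpixels(part, fg, obj, st,
                                         matrix(FALSE, H, W))
  expect_true(all(cmap4 == 2L))
  # non-foreground pixels are Background
  fg2 <- fg; fg2[, 1:20] <- 0L
  cmap5 <- classify_striated_superpixels(part, fg2, obj, st, gmask_hi)
  expect_true(all(cmap5[, 1:20] == 0L))
  expect_error(classify_striated_superpixels(matrix(0L, H, W), fg, obj, st,
                                             gmask_hi), "empty")
})

test_that("lowering perp_cover never flips StriatedMyocyte to Other", {
  model <- fixture_model()
  sc <- fixture_train_scenes()[[2]]
  cls <- classify_actinin(sc$alpha_actinin, model, myotype_config())
  st <- striation_orientations(cls$adaptive_mask)
  oo <- cls$object_orientation
  for (pc in c(0.10, 0.05, 0.02)) {
    cm <- classify_striated_superpixels(cls$superpixels, cls$foreground, oo,
                                        st, cls$global_mask, perp_cover = pc)
    if (pc == 0.10) base <- cm
    expect_true(all(cm[base == 1L] == 1L))
  }
})

test_that("nucleus labels use the mode with the 0.4 threshold and tie rule", {
  cmap <- matrix(0L, 30, 30)
  cmap[1:10, ] <- 1L           # striated band
  nuc <- matrix(0L, 30, 30)
  nuc[3:6, 3:6] <- 1L          # fully inside striated region
  nuc[8:17, 10:14] <- 2L       # 30% striated (rows 8:10), 70% background
  nuc[6:15, 20:24] <- 3L       # exactly 50/50 striated/background
  rec <- assign_nucleus_labels(nuc, cmap, threshold = 0.4)
  expect_equal(rec$assigned_class[rec$nucleus_id == 1], "striated_myocyte")
  expect_equal(rec$mode_proportion[rec$nucleus_id == 1], 1)
  # nucleus 2: background is the mode at 0.7 -> assigned background
  expect_equal(rec$assigned_class[rec$nucleus_id == 2], "background")
  expect_equal(rec$prop_striated_myocyte[rec$nucleus_id == 2], 0.3)
  expect_true(is.na(rec$assigned_class[rec$nucleus_id == 3]))  # tie
  # sub-threshold mode: three classes 0.35 / 0.35 ... construct direct case
  cmap2 <- matrix(0L, 20, 20)
  cmap2[1:7, 1] <- 1L; cmap2[8:14, 1] <- 2L
  nuc2 <- matrix(0L, 20, 20); nuc2[1:20, 1] <- 1L
  rec2 <- assign_nucleus_labels(nuc2, cmap2, threshold = 0.4)
  expect_equal(rec2$mode_proportion, 0.35)
  expect_true(is.na(rec2$assigned_class))
})

test_that("simple nucleus segmentation recovers synthetic nuclei", {
  ws <- generate_wellset(1, 0.5, cells_per_well = 6, base_seed = 44)
  sc <- ws$scenes[[1]]
  lab <- segment_nuclei(sc$nuclei)
  expect_equal(max(lab), 6L, tolerance = 0)
})
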