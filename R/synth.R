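# Synthetic co-culture scenes with exact ground truth.
#
# Cells are rendered as rotated elliptical Gaussian envelopes carrying a
# multiplicative 1-D fibril texture across the cell axis (so actin fibrils run
# along the axis).  Striated myocytes additionally modulate their
# alpha-actinin signal with a sinusoid along the axis, i.e. z-line stripes
# perpendicular to the axis.  "Other" cells are alpha-actinin positive with
# no stripes; fibroblasts carry no alpha-actinin at all.  Truth maps are
# exact by construction.

#' Describe one synthetic cell
#'
#' @param cell_type `"striated_myocyte"`, `"fibroblast"` or `"other"`.
#' @param centroid numeric `(row, col)` centre in pixels.
#' @param axis_angle_deg cell axis angle in `[0, 180)` degrees, measured from
#'   the +x (column) axis.
#' @param length_px,width_px ellipse diameters along/across the axis.
#' @param striation_period_px sarcomere z-line spacing (myocytes only),
#'   at least 4 px so stripes are resolvable.
#' @param striation_contrast stripe modulation depth in `[0, 1]`.
#' @param fibril_contrast depth of the actin fibril texture.
#' @param striation_offset_deg rotation of the stripe normal away from the
#'   cell axis; 0 (default) gives z-lines perpendicular to the axis, 90 gives
#'   the pathological parallel-striation control.
#' @return A `cell_descriptor` list.
#' @export
cell_descriptor <- function(cell_type = c("striated_myocyte", "fibroblast", "other"),
                            centroid, axis_angle_deg, length_px = 64,
                            width_px = 18, striation_period_px = 8,
                            striation_contrast = 0.5, fibril_contrast = 0.5,
                            striation_offset_deg = 0) {
  cell_type <- match.arg(cell_type)
  stopifnot(length_px > 0, width_px > 0, striation_contrast >= 0,
            striation_contrast <= 1)
  if (cell_type == "striated_myocyte" && striation_period_px < 4)
    stop("striation_period_px must be >= 4 for resolvable stripes")
  structure(list(cell_type = cell_type, centroid = centroid,
                 axis_angle_deg = axis_angle_deg %% 180,
                 length_px = length_px, width_px = width_px,
                 striation_period_px = striation_period_px,
                 striation_contrast = striation_contrast,
                 fibril_contrast = fibril_contrast,
                 striation_offset_deg = striation_offset_deg),
            class = "cell_descriptor")
}

#' Specify a synthetic scene
#'
#' Identical spec + seed always produces bitwise-identical scenes.
#'
#' @param shape `(H, W)` image shape in pixels.
#' @param cells list of [cell_descriptor] objects.
#' @param background_noise_sd additive Gaussian noise SD (clipped at zero).
#' @param signal_level peak cell intensity; the default signal/noise ratio is
#'   5 (100 / 20).
#' @param background_level constant offset added to every channel.
#' @param seed integer RNG seed for the scene.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(shape = c(256, 336), cells = list(),
                       background_noise_sd = 20, signal_level = 100,
                       background_level = 10, seed = 1L) {
  stopifnot(length(shape) == 2, background_noise_sd >= 0, signal_level > 0)
  structure(list(shape = as.integer(shape), cells = cells,
                 background_noise_sd = background_noise_sd,
                 signal_level = signal_level,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# band-pass 1-D texture profile, zero mean, unit sd; the pass band sets the
# fibril spacing (~2*pi*pass_sigma px) so fibrils survive the estimator's
# pre-smoothing
fibril_profile <- function(n, pass_sigma = 1.5, stop_sigma = 5) {
  raw <- rnorm(n + 40)
  sm1 <- as.vector(cpp_gaussian_blur(matrix(raw, nrow = 1), pass_sigma))
  sm2 <- as.vector(cpp_gaussian_blur(matrix(raw, nrow = 1), stop_sigma))
  bp <- (sm1 - sm2)[21:(20 + n)]
  s <- sd(bp)
  if (s > 0) bp <- bp / s
  pmax(pmin(bp, 2), -2)
}

CELLTYPE_CODES <- c(none = 0L, striated_myocyte = 1L, other = 2L, fibroblast = 3L)

#' Generate a synthetic multi-channel scene
#'
#' Renders all cells of a [scene_spec] and returns the three channels plus
#' exact ground truth.  Overlap pixels between cells are resolved by draw
#' order (the later cell wins) and flagged in `overlap`.
#'
#' @param spec a [scene_spec].
#' @return A list with `actin`, `alpha_actinin`, `nuclei` ([channel_image]s),
#'   `truth_class` (alpha-actinin semantic codes 0/1/2; fibroblast regions are
#'   Background in that channel), `truth_celltype` (0 none, 1 myocyte,
#'   2 other, 3 fibroblast), `truth_orientation` (an `orientation_field`
#'   valid at every cell pixel), `truth_nuclei` (instance labels), `overlap`
#'   (logical mask) and the `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  actin <- matrix(0, H, W); actinin <- matrix(0, H, W); nuc <- matrix(0, H, W)
  truth_class <- matrix(0L, H, W)
  truth_celltype <- matrix(0L, H, W)
  truth_angle <- matrix(NA_real_, H, W)
  truth_nuclei <- matrix(0L, H, W)
  overlap <- matrix(FALSE, H, W)

  with_seed(spec$seed, {
    for (ci in seq_along(spec$cells)) {
      cell <- spec$cells[[ci]]
      th <- cell$axis_angle_deg * pi / 180
      cy <- cell$centroid[1]; cx <- cell$centroid[2]
      hl <- cell$length_px / 2; hw <- cell$width_px / 2
      half <- ceiling(max(hl, hw)) + 2L
      r0 <- max(1L, floor(cy) - half); r1 <- min(H, ceiling(cy) + half)
      c0 <- max(1L, floor(cx) - half); c1 <- min(W, ceiling(cx) + half)
      rows <- r0:r1; cols <- c0:c1
      rr <- matrix(rows, length(rows), length(cols))
      cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      u <- (cc - cx) * cos(th) + (rr - cy) * sin(th)
      v <- -(cc - cx) * sin(th) + (rr - cy) * cos(th)
      rho2 <- (u / hl)^2 + (v / hw)^2
      inside <- rho2 <= 1
      if (!any(inside)) next
      # flat-topped (super-Gaussian) envelope: nearly constant over the cell
      # body so in-cell gradients come from texture, with a soft rim
      env <- exp(-0.5 * (1.25 * rho2)^3)
      # fibril texture varies across the axis (along v)
      vgrid <- seq(floor(-hw) - 2, ceiling(hw) + 2)
      prof <- fibril_profile(length(vgrid))
      tex <- 1 + cell$fibril_contrast *
        approx(vgrid, prof, xout = pmin(pmax(v, min(vgrid)), max(vgrid)))$y
      tex <- pmax(tex, 0.2)
      sig <- spec$signal_level
      add <- sig * env * tex * inside
      actin[rows, cols] <- actin[rows, cols] + add
      if (cell$cell_type == "striated_myocyte") {
        off <- cell$striation_offset_deg * pi / 180
        w_coord <- u * cos(off) + v * sin(off)
        stripe <- 1 + cell$striation_contrast *
          cos(2 * pi * w_coord / cell$striation_period_px)
        actinin[rows, cols] <- actinin[rows, cols] +
          sig * env * stripe / (1 + cell$striation_contrast) * inside
      } else if (cell$cell_type == "other") {
        actinin[rows, cols] <- actinin[rows, cols] + sig * env * inside
      }
      code <- CELLTYPE_CODES[[cell$cell_type]]
      prev <- truth_celltype[rows, cols]
      clash <- inside & prev != 0L & prev != code
      if (any(clash)) {
        om <- overlap[rows, cols]; om[clash] <- TRUE
        overlap[rows, cols] <- om
      }
      tc <- truth_celltype[rows, cols]; tc[inside] <- code
      truth_celltype[rows, cols] <- tc
      sc <- truth_class[rows, cols]
      sc[inside] <- switch(cell$cell_type, striated_myocyte = 1L,
                           other = 2L, fibroblast = 0L)
      truth_class[rows, cols] <- sc
      ta <- truth_angle[rows, cols]; ta[inside] <- cell$axis_angle_deg
      truth_angle[rows, cols] <- ta
      # nucleus: small ellipse at the centroid
      rn <- max(3, cell$width_px / 4)
      nin <- (u^2 + v^2) <= rn^2
      nuc[rows, cols] <- nuc[rows, cols] + sig * exp(-0.5 * (u^2 + v^2) / (rn / 1.5)^2) * nin
      tn <- truth_nuclei[rows, cols]; tn[nin] <- ci
      truth_nuclei[rows, cols] <- tn
    }
    bg <- spec$background_level
    if (spec$background_noise_sd > 0) {
      actin <- actin + rnorm(H * W, bg, spec$background_noise_sd)
      actinin <- actinin + rnorm(H * W, bg, spec$background_noise_sd)
      nuc <- nuc + rnorm(H * W, bg, spec$background_noise_sd)
    } else {
      actin <- actin + bg; actinin <- actinin + bg; nuc <- nuc + bg
    }
  })
  clip <- function(m) pmin(pmax(m, 0), 65535)
  list(actin = channel_image(clip(actin), "actin"),
       alpha_actinin = channel_image(clip(actinin), "alpha_actinin"),
       nuclei = channel_image(clip(nuc), "nuclei"),
       truth_class = truth_class,
       truth_celltype = truth_celltype,
       truth_orientation = orientation_field(truth_angle, !is.na(truth_angle)),
       truth_nuclei = truth_nuclei,
       overlap = overlap,
       spec = spec)
}

# place cells at jittered grid positions so a requested count fits the frame
place_centroids <- function(n, H, W, margin) {
  gc <- ceiling(sqrt(n * W / H)); gr <- ceiling(n / gc)
  ys <- seq(margin, H - margin, length.out = gr)
  xs <- seq(margin, W - margin, length.out = gc)
  grid <- expand.grid(row = ys, col = xs)
  grid <- grid[seq_len(n), , drop = FALSE]
  jit <- min(diff(range(ys)) / max(1, gr - 1), diff(range(xs)) / max(1, gc - 1)) / 6
  if (!is.finite(jit) || jit <= 0) jit <- margin / 4
  grid$row <- pmin(pmax(grid$row + runif(n, -jit, jit), margin), H - margin)
  grid$col <- pmin(pmax(grid$col + runif(n, -jit, jit), margin), W - margin)
  grid
}

#' Generate a set of synthetic wells at a given myocyte fraction
#'
#' Emulates a co-culture density sweep: each cell is independently a striated
#' myocyte with probability `myocyte_fraction` (a binomial draw per cell),
#' otherwise a fibroblast (or, with probability `other_fraction`, an
#' alpha-actinin-positive unstriated "other" cell).  Myocytes and fibroblasts
#' get type-specific axis angles so co-oriented vs counter-oriented
#' populations can be emulated.
#'
#' @param n_wells number of wells.
#' @param myocyte_fraction probability a cell is a myocyte, in `[0, 1]`.
#' @param cells_per_well cells per scene (must be > 0).
#' @param base_seed wells use seeds `base_seed + 1 .. base_seed + n_wells`.
#' @param shape scene shape.
#' @param myocyte_angle_deg,fibroblast_angle_deg type mean axis angles.
#' @param angle_jitter_sd per-cell angular jitter (degrees).
#' @param other_fraction probability a non-myocyte is "other".
#' @param striation_contrast,background_noise_sd,signal_level scene controls
#'   (defaults: contrast 0.5, signal/noise = 100/20 = 5).
#' @return List with `scenes` (list of [generate_scene] outputs) and
#'   `manifest` (data frame with per-well seeds, type counts and ground-truth
#'   actin fractions computed from the truth maps).
#' @export
generate_wellset <- function(n_wells, myocyte_fraction, cells_per_well = 12,
                             base_seed = 1L, shape = c(256, 336),
                             myocyte_angle_deg = 25, fibroblast_angle_deg = 115,
                             angle_jitter_sd = 5, other_fraction = 0,
                             striation_contrast = 0.5,
                             background_noise_sd = 20, signal_level = 100) {
  stopifnot(myocyte_fraction >= 0, myocyte_fraction <= 1)
  if (cells_per_well <= 0) stop("cells_per_well must be positive")
  scenes <- vector("list", n_wells)
  rows <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    seed <- base_seed + w
    cells <- with_seed(seed * 2L + 1L, {
      is_myo <- rbinom(cells_per_well, 1, myocyte_fraction) == 1
      is_other <- !is_myo & rbinom(cells_per_well, 1, other_fraction) == 1
      cen <- place_centroids(cells_per_well, shape[1], shape[2], margin = 34)
      lapply(seq_len(cells_per_well), function(i) {
        type <- if (is_myo[i]) "striated_myocyte"
                else if (is_other[i]) "other" else "fibroblast"
        mu <- if (is_myo[i]) myocyte_angle_deg else fibroblast_angle_deg
        cell_descriptor(type,
                        centroid = c(cen$row[i], cen$col[i]),
                        axis_angle_deg = (mu + rnorm(1, 0, angle_jitter_sd)) %% 180,
                        length_px = runif(1, 76, 100),
                        width_px = runif(1, 26, 38),
                        striation_period_px = 8,
                        striation_contrast = striation_contrast)
      })
    })
    sc <- generate_scene(scene_spec(shape = shape, cells = cells,
                                    background_noise_sd = background_noise_sd,
                                    signal_level = signal_level, seed = seed))
    scenes[[w]] <- sc
    ct <- table(factor(vapply(cells, `[[`, "", "cell_type"),
                       levels = c("striated_myocyte", "fibroblast", "other")))
    tot_cell_px <- sum(sc$truth_celltype != 0)
    rows[[w]] <- data.frame(
      well = w, seed = seed,
      n_myocyte = as.integer(ct[["striated_myocyte"]]),
      n_fibroblast = as.integer(ct[["fibroblast"]]),
      n_other = as.integer(ct[["other"]]),
      true_cm_actin_fraction = if (tot_cell_px > 0)
        sum(sc$truth_celltype == 1L) / tot_cell_px else NA_real_,
      true_fb_actin_fraction = if (tot_cell_px > 0)
        sum(sc$truth_celltype == 3L) / tot_cell_px else NA_real_)
  }
  list(scenes = scenes, manifest = do.call(rbind, rows))
}

#' Write a synthetic scene to a well directory
#'
#' Writes `actin.tif`, `alpha_actinin.tif`, `nuclei.tif`, the ground-truth
#' maps and a JSON manifest, matching the layout [run_well()] consumes.
#'
#' @param scene output of [generate_scene()].
#' @param dir directory to create.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_channel(scene$actin, file.path(dir, "actin.tif"))
  save_channel(scene$alpha_actinin, file.path(dir, "alpha_actinin.tif"))
  save_channel(scene$nuclei, file.path(dir, "nuclei.tif"))
  save_class_map(scene$truth_class, file.path(dir, "truth_class.tif"))
  save_label_map(scene$truth_nuclei, file.path(dir, "truth_nuclei.tif"))
  save_label_map(scene$truth_celltype, file.path(dir, "truth_celltype.tif"))
  jsonlite::write_json(list(seed = scene$spec$seed, shape = scene$spec$shape,
                            n_cells = length(scene$spec$cells)),
                       file.path(dir, "scene.json"), auto_unbox = TRUE)
  invisible(dir)
}
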