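# Striated Myocyte vs Other resolution of the foreground.
#
# Sarcomeric z-lines are enhanced by coherence-preserving anisotropic
# diffusion followed by a white top-hat, binarized two ways (adaptive mask
# for per-striation geometry, global mask for striation abundance).  The
# image is partitioned into ~200 SLIC superpixels; a foreground superpixel is
# a Striated Myocyte region iff enough of its foreground pixels lie on
# striation components roughly perpendicular to the local object axis
# (|dot| < 0.8 on unit axial vectors) AND the global mask covers at least 5%
# of it.  Nuclei inherit the modal class within their boundary.

#' Coherence-preserving anisotropic diffusion
#'
#' Edge/coherence-enhancing diffusion (Weickert lineage): smoothing is strong
#' along locally coherent structures and weak across them, so periodic
#' striations survive while noise is suppressed.  The update is clamped to
#' the input range, so the global maximum never increases and the global
#' minimum never decreases.
#'
#' @param img [channel_image] or numeric matrix; must be finite.
#' @param n_iter number of explicit diffusion steps (>= 1).
#' @param tau time step.
#' @param alpha baseline conductance in `(0, 1)`.
#' @param contrast_quantile the coherence contrast parameter is set to this
#'   quantile of the gradient magnitude of the input.
#' @param rho structure-tensor integration scale (px).
#' @param sigma_grad gradient regularization scale (px): gradients driving
#'   the diffusion tensor are measured on a Gaussian-smoothed copy so pixel
#'   noise cannot seed spurious coherent streaks.
#' @return Diffused matrix of the same shape.
#' @export
coherence_diffuse <- function(img, n_iter = 15, tau = 0.15, alpha = 0.01,
                              contrast_quantile = 0.8, rho = 2,
                              sigma_grad = 1) {
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  if (any(!is.finite(m))) stop("non-finite input")
  stopifnot(n_iter >= 1)
  ms <- if (sigma_grad > 0) cpp_gaussian_blur(m, sigma_grad) else m
  g <- cpp_sobel(ms)
  gm <- sqrt(g$gx^2 + g$gy^2)
  contrast <- as.numeric(quantile(gm, contrast_quantile))
  if (contrast <= 0) contrast <- 1e-6
  cpp_coherence_diffuse(m, as.integer(n_iter), tau, alpha, contrast, rho,
                        sigma_grad)
}

#' White top-hat striation enhancement
#'
#' Image minus its morphological opening with a disk, isolating bright
#' structures thinner than the disk; output is nonnegative and bounded by the
#' input.  The default radius is half the expected z-line spacing.
#'
#' @param img [channel_image] or matrix.
#' @param selem_radius disk radius in pixels (>= 1).
#' @return Nonnegative matrix of the same shape.
#' @export
tophat_striations <- function(img, selem_radius = 4) {
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  stopifnot(selem_radius >= 1)
  opening <- cpp_dilate_disk(cpp_erode_disk(m, as.integer(selem_radius)),
                             as.integer(selem_radius))
  pmax(m - opening, 0)
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * 256), 255) + 1L, 256L)
  w <- cumsum(h)
  mu <- cumsum(h * (seq_len(256) - 1))
  n <- w[256]; mtot <- mu[256]
  between <- (mtot * w - mu * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)  # first maximizer
  rng[1] + (k - 0.5) / 256 * diff(rng)
}

#' Binarize a (top-hat filtered) image
#'
#' `adaptive_local_mean`: pixel > local mean over a `window` plus `offset`
#' (per-striation geometry).  `global_otsu`: Otsu threshold computed on the
#' nonzero pixels (striation abundance).
#'
#' @param img [channel_image] or matrix.
#' @param method `"adaptive_local_mean"` or `"global_otsu"`.
#' @param window odd window for the local mean.
#' @param offset added to the local mean.
#' @param roi optional logical matrix: the Otsu threshold is computed from
#'   these pixels only (e.g. the tissue foreground, so background noise does
#'   not drag the threshold down); the mask is still evaluated everywhere.
#' @return Logical mask.
#' @export
binarize <- function(img, method = c("adaptive_local_mean", "global_otsu"),
                     window = 15, offset = 0, roi = NULL) {
  method <- match.arg(method)
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  if (method == "adaptive_local_mean") {
    if (window %% 2 == 0) window <- window + 1
    m > cpp_box_mean(m, as.integer(window)) + offset
  } else {
    nz <- if (is.null(roi)) m else m[roi != 0]
    nz <- nz[nz != 0]
    if (length(nz) == 0) {
      warning("all-zero image: empty global mask")
      return(matrix(FALSE, nrow(m), ncol(m)))
    }
    m > otsu_threshold(nz)
  }
}

#' SLIC superpixels
#'
#' Partitions the image into approximately `n` compact, 4-connected regions
#' using simple linear iterative clustering on the (internally rescaled)
#' intensities.  The algorithm is deterministic (grid initialization, fixed
#' iteration count); `seed` is accepted for interface uniformity but unused.
#'
#' @param img [channel_image] or matrix.
#' @param n target region count (default 200).
#' @param compactness spatial regularization weight.
#' @param seed unused (deterministic algorithm).
#' @param n_iter clustering iterations.
#' @return Object of class `superpixels` with `labels` (integer matrix,
#'   values 1..K) and `n_regions`.
#' @export
compute_superpixels <- function(img, n = 200, compactness = 0.1, seed = NULL,
                                n_iter = 10) {
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  if (n < 2) stop("n must be at least 2")
  if (n > length(m)) stop("n exceeds the pixel count")
  rng <- range(m)
  ms <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  lab <- cpp_slic(ms, as.integer(n), compactness, as.integer(n_iter))
  structure(list(labels = lab, n_regions = max(lab), target_n = n),
            class = "superpixels")
}

#' @export
print.superpixels <- function(x, ...) {
  cat(sprintf("<superpixels> %d regions (target %d), %d x %d px\n",
              x$n_regions, x$target_n, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Object orientation map of the foreground
#'
#' Smooths the alpha-actinin image with a Gaussian (sigma = 5 by default) so
#' striations wash out and the cell envelope dominates, estimates per-pixel
#' orientations with [estimate_orientation_field()], then pools them over
#' each 4-connected foreground object into the object's director and
#' rasterizes that axis back to the object's pixels.  Pooling makes the axis
#' robust at cell tips, where the local envelope orientation follows the rim
#' rather than the cell.  Objects with fewer than `min_pixels` pixels (or
#' fewer than 3 valid orientation estimates) carry no orientation.
#'
#' @param img alpha-actinin [channel_image] or matrix.
#' @param foreground_mask logical (or code) matrix; must be nonempty.
#' @param sigma Gaussian smoothing SD.
#' @param block_size,coherence_cutoff passed to the estimator.
#' @param min_pixels minimum object size.
#' @return An [orientation_field] valid only inside sufficiently large
#'   foreground objects.
#' @export
object_orientation_map <- function(img, foreground_mask, sigma = 5,
                                   block_size = 8, coherence_cutoff = 0.1,
                                   min_pixels = 3) {
  fg <- foreground_mask != 0
  if (!any(fg)) stop("empty foreground mask")
  f <- estimate_orientation_field(img, sigma_smooth = sigma,
                                  block_size = block_size,
                                  coherence_cutoff = coherence_cutoff,
                                  border_margin = 0)
  comp <- cpp_label_components(matrix(as.integer(fg), nrow(fg), ncol(fg)),
                               connectivity = 8L)
  angle <- matrix(NA_real_, nrow(fg), ncol(fg))
  valid <- matrix(FALSE, nrow(fg), ncol(fg))
  for (id in seq_len(max(comp))) {
    idx <- which(comp == id)
    if (length(idx) < min_pixels) next
    va <- f$angle_deg[idx][f$valid[idx]] * pi / 180
    if (length(va) < 3) next
    dir <- structure_tensor_metrics(cbind(cos(va), sin(va)))$director_deg
    angle[idx] <- dir
    valid[idx] <- TRUE
  }
  orientation_field(angle, valid, f$coherence)
}

#' Per-striation orientations
#'
#' Labels the 4-connected components of the adaptive striation mask and
#' assigns each component with at least `min_pixels` pixels a unit axial
#' vector along its principal axis (PCA of pixel coordinates); smaller
#' components are ignored.
#'
#' @param adaptive_mask logical matrix (nonempty).
#' @param min_pixels minimum component size (default 3).
#' @return List with `labels` (component id per pixel, 0 elsewhere or
#'   ignored), `angle_deg` (per-component axis, named by id), `size`
#'   (per-component pixel count) and `pixel_angle` (angles rasterized to
#'   component pixels, NA elsewhere).
#' @export
striation_orientations <- function(adaptive_mask, min_pixels = 3) {
  if (!any(adaptive_mask)) stop("empty striation mask")
  comp <- cpp_label_components(matrix(as.integer(adaptive_mask),
                                      nrow(adaptive_mask), ncol(adaptive_mask)),
                               connectivity = 4L)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_pixels)
  angle <- setNames(rep(NA_real_, length(keep)), keep)
  pix_angle <- matrix(NA_real_, nrow(comp), ncol(comp))
  labels <- comp
  labels[!(comp %in% keep)] <- 0L
  for (i in seq_along(keep)) {
    id <- keep[i]
    idx <- which(comp == id)
    y <- (idx - 1) %% nrow(comp) + 1
    x <- (idx - 1) %/% nrow(comp) + 1
    cv <- stats::cov(cbind(x, y))
    e <- eigen(cv, symmetric = TRUE)
    a <- (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
    angle[i] <- a
    pix_angle[idx] <- a
  }
  list(labels = labels, angle_deg = angle,
       size = setNames(sizes[keep], keep), pixel_angle = pix_angle)
}

#' Superpixel-level Striated Myocyte vs Other classification
#'
#' For each superpixel the object axis is the director of the valid object
#' orientation vectors among its foreground pixels.  A striation component is
#' "perpendicular" when the absolute dot product of its axis with the object
#' axis is below `dot_thresh` (axial vectors, so antiparallel counts as
#' parallel).  The superpixel is Striated Myocyte iff (i) at least
#' `perp_cover` of its foreground pixels lie on perpendicular striation
#' components and (ii) at least `global_cover` of them are positive in the
#' global mask; otherwise it is Other.  Non-foreground pixels, and all pixels
#' of superpixels with less than `min_foreground` foreground, are Background.
#'
#' @param partition a `superpixels` object or integer label matrix.
#' @param foreground logical or `{0,3}` code matrix from
#'   [classify_foreground()].
#' @param object_orient [orientation_field] from [object_orientation_map()].
#' @param striations result of [striation_orientations()].
#' @param global_mask logical matrix from the global binarization.
#' @param dot_thresh,perp_cover,global_cover decision thresholds (defaults
#'   0.8 / 0.10 / 0.05).
#' @param min_foreground minimum foreground fraction for a superpixel to be
#'   evaluated at all.
#' @return Integer semantic class map with codes `{0, 1, 2}`.
#' @export
classify_striated_superpixels <- function(partition, foreground, object_orient,
                                          striations, global_mask,
                                          dot_thresh = 0.8, perp_cover = 0.10,
                                          global_cover = 0.05,
                                          min_foreground = 0.10) {
  labels <- if (inherits(partition, "superpixels")) partition$labels
            else as.matrix(partition)
  if (max(labels) < 1) stop("empty partition")
  fg <- foreground != 0
  stopifnot(all(dim(labels) == dim(fg)),
            all(dim(labels) == dim(object_orient)),
            all(dim(labels) == dim(global_mask)))
  codes <- class_codes()
  out <- matrix(codes[["background"]], nrow(labels), ncol(labels))
  comp_angle <- striations$angle_deg
  comp_ids <- as.integer(names(comp_angle))
  ang <- object_orient$angle_deg
  val <- object_orient$valid
  pix_by_sp <- split(seq_along(labels), as.vector(labels))
  for (sp in seq_len(max(labels))) {
    idx <- pix_by_sp[[as.character(sp)]]
    if (is.null(idx)) next
    fg_idx <- idx[fg[idx]]
    if (length(fg_idx) / length(idx) < min_foreground) next
    va <- ang[fg_idx][val[fg_idx]] * pi / 180
    if (length(va) == 0) { out[fg_idx] <- codes[["other"]]; next }
    vec <- cbind(cos(va), sin(va))
    obj <- structure_tensor_metrics(vec)$director
    # perpendicular-striation coverage among foreground pixels
    comp_here <- striations$labels[fg_idx]
    perp_ids <- comp_ids[vapply(seq_along(comp_ids), function(j) {
      a <- comp_angle[j] * pi / 180
      abs(cos(a) * obj[1] + sin(a) * obj[2]) < dot_thresh
    }, TRUE)]
    perp_frac <- mean(comp_here %in% perp_ids & comp_here > 0)
    glob_frac <- mean(global_mask[fg_idx])
    out[fg_idx] <- if (perp_frac >= perp_cover && glob_frac >= global_cover)
      codes[["striated_myocyte"]] else codes[["other"]]
  }
  storage.mode(out) <- "integer"
  out
}

#' Assign class labels to nuclei
#'
#' Each nucleus inherits the most common (mode) semantic class within its
#' boundary, provided the mode accounts for at least `threshold` of its
#' pixels; ties and sub-threshold modes leave the nucleus unassigned.
#'
#' @param nuclei_labelmap integer instance labels (0 = no nucleus).
#' @param class_map semantic class map (codes 0/1/2).
#' @param threshold minimum mode proportion (default 0.4).
#' @return Data frame with one row per nucleus: `nucleus_id`, `n_pixels`,
#'   per-class coverage proportions, `mode_proportion`, `assigned_class`
#'   (`NA` if unassigned).
#' @export
assign_nucleus_labels <- function(nuclei_labelmap, class_map, threshold = 0.4) {
  stopifnot(all(dim(nuclei_labelmap) == dim(class_map)))
  ids <- sort(unique(nuclei_labelmap[nuclei_labelmap > 0]))
  codes <- class_codes()[1:3]
  out <- lapply(ids, function(id) {
    px <- class_map[nuclei_labelmap == id]
    if (length(px) == 0) stop("empty nucleus: ", id)
    props <- vapply(codes, function(cc) mean(px == cc), 0)
    mx <- max(props)
    tie <- sum(props == mx) > 1
    assigned <- if (!tie && mx >= threshold) names(codes)[which.max(props)]
                else NA_character_
    data.frame(nucleus_id = id, n_pixels = length(px),
               prop_background = props[["background"]],
               prop_striated_myocyte = props[["striated_myocyte"]],
               prop_other = props[["other"]],
               mode_proportion = mx, assigned_class = assigned)
  })
  do.call(rbind, out)
}

#' Simple nucleus segmentation fallback
#'
#' Otsu threshold on the Gaussian-smoothed nuclei channel followed by
#' 4-connected component labeling.  Intended for synthetic fixtures where
#' nuclei never touch; real data should provide externally produced instance
#' label maps (e.g. from StarDist).
#'
#' @param img nuclei [channel_image] or matrix.
#' @param sigma smoothing SD.
#' @param min_size discard components smaller than this.
#' @return Integer instance label map.
#' @export
segment_nuclei <- function(img, sigma = 2, min_size = 9) {
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  sm <- cpp_gaussian_blur(m, sigma)
  mask <- sm > otsu_threshold(as.vector(sm))
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(m), ncol(m)),
                              connectivity = 4L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  remap <- integer(max(lab) + 1L)
  remap[keep + 1L] <- seq_along(keep)
  matrix(remap[lab + 1L], nrow(m), ncol(m))
}
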