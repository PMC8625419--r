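# Actin orientation estimation and organization metrics.
#
# Orientation is axial: an angle and its opposite describe the same fiber, so
# every consumer works modulo 180 degrees.  Organization of a vector set is
# summarized by the mean dyadic (structure) tensor T = mean_i r_i r_i^T; the
# director is the eigenvector of its largest eigenvalue and the orientational
# order parameter is reported as oop = 2*lambda_max - 1, which maps isotropy
# to 0 and perfect alignment to 1 (lambda_max itself lives in [0.5, 1] for
# unit axial vectors; the raw eigenvalue is available as a convention switch).

#' Construct an orientation field
#'
#' @param angle_deg numeric matrix of axial angles in `[0, 180)` (NA where
#'   invalid).
#' @param valid logical matrix of the same shape.
#' @param coherence optional numeric matrix of block coherences.
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(angle_deg, valid, coherence = NULL) {
  stopifnot(all(dim(angle_deg) == dim(valid)))
  angle_deg[!valid] <- NA_real_
  angle_deg[valid] <- angle_deg[valid] %% 180
  structure(list(angle_deg = angle_deg, valid = valid, coherence = coherence),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d x %d px, %d valid (%.1f%%)\n",
              nrow(x$angle_deg), ncol(x$angle_deg), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' @export
dim.orientation_field <- function(x) dim(x$angle_deg)

#' Extract unit axial vectors from an orientation field
#'
#' @param field an `orientation_field`.
#' @param mask optional logical matrix restricting the selection.
#' @return n x 2 matrix of unit vectors `(x, y)`.
#' @export
field_vectors <- function(field, mask = NULL) {
  sel <- field$valid
  if (!is.null(mask)) sel <- sel & mask
  ang <- field$angle_deg[sel] * pi / 180
  cbind(x = cos(ang), y = sin(ang))
}

#' Estimate per-pixel actin orientation
#'
#' The image is Gaussian-smoothed, standardized to zero mean and unit
#' variance, and Sobel gradients are accumulated over sliding blocks (least
#' mean square orientation estimation).  The ridge axis is
#' `90 + 0.5 * atan2(2*sum(GxGy), sum(Gx^2 - Gy^2))` degrees, perpendicular
#' to the dominant gradient.  A pixel is valid when the block coherence
#' `|(sum(Gx^2-Gy^2), 2*sum(GxGy))| / sum(Gx^2+Gy^2)` reaches
#' `coherence_cutoff`.
#'
#' @param img a [channel_image] or numeric matrix.
#' @param sigma_smooth Gaussian pre-smoothing SD in px (0 to skip).
#' @param block_size accumulation window; even values are widened to the next
#'   odd integer so the window is centred.
#' @param coherence_cutoff minimum block coherence in `[0, 1]`.
#' @param border_margin pixels next to the border marked invalid because
#'   their gradient blocks draw on reflection-padded data; `"auto"` (default)
#'   uses `ceil(block/2) + ceil(2 * sigma_smooth) + 1`.
#' @return An [orientation_field]; a constant image yields an empty validity
#'   mask.
#' @export
estimate_orientation_field <- function(img, sigma_smooth = 2, block_size = 8,
                                       coherence_cutoff = 0.2,
                                       border_margin = "auto") {
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  if (sigma_smooth > 0) m <- cpp_gaussian_blur(m, sigma_smooth)
  s <- sd(m)
  if (s == 0) {
    return(orientation_field(matrix(NA_real_, nrow(m), ncol(m)),
                             matrix(FALSE, nrow(m), ncol(m)),
                             matrix(0, nrow(m), ncol(m))))
  }
  m <- (m - mean(m)) / s
  g <- cpp_sobel(m)
  w <- as.integer(block_size)
  if (w %% 2 == 0) w <- w + 1L
  jxx <- cpp_box_mean(g$gx * g$gx, w)
  jyy <- cpp_box_mean(g$gy * g$gy, w)
  jxy <- cpp_box_mean(g$gx * g$gy, w)
  a <- jxx - jyy
  b <- 2 * jxy
  denom <- jxx + jyy
  coh <- matrix(0, nrow(m), ncol(m))
  ok <- denom > 1e-12
  coh[ok] <- sqrt(a[ok]^2 + b[ok]^2) / denom[ok]
  angle <- (90 + 0.5 * atan2(b, a) * 180 / pi) %% 180
  valid <- ok & coh >= coherence_cutoff
  if (identical(border_margin, "auto"))
    border_margin <- ceiling(w / 2) + ceiling(2 * sigma_smooth) + 1
  if (border_margin > 0) {
    nr <- nrow(m); nc <- ncol(m)
    edge <- outer(pmin(seq_len(nr), rev(seq_len(nr))) - 1,
                  pmin(seq_len(nc), rev(seq_len(nc))) - 1, pmin) < border_margin
    valid[edge] <- FALSE
  }
  orientation_field(angle, valid, coh)
}

#' Separate orientation vectors by cell type
#'
#' Cardiomyocyte vectors are the valid actin vectors at Striated Myocyte
#' pixels of the alpha-actinin class map; fibroblast vectors are valid actin
#' vectors inside the actin foreground whose alpha-actinin class is
#' Background (fibroblasts carry actin but no alpha-actinin).  Pixels of
#' class Other are excluded from both sets but counted in the actin-fraction
#' denominator.
#'
#' @param field actin [orientation_field].
#' @param semantic_map class map with codes of [class_codes()].
#' @param actin_foreground logical matrix marking actin-positive pixels.
#' @param cell_type `"cardiomyocyte"`, `"fibroblast"` or `"other"`.
#' @return n x 2 matrix of unit axial vectors.
#' @export
select_class_vectors <- function(field, semantic_map, actin_foreground,
                                 cell_type = c("cardiomyocyte", "fibroblast",
                                               "other")) {
  cell_type <- match.arg(cell_type)
  stopifnot(all(dim(field) == dim(semantic_map)),
            all(dim(field) == dim(actin_foreground)))
  codes <- class_codes()
  mask <- switch(cell_type,
    cardiomyocyte = semantic_map == codes[["striated_myocyte"]],
    fibroblast = actin_foreground & semantic_map == codes[["background"]],
    other = semantic_map == codes[["other"]])
  field_vectors(field, mask)
}

#' Structure-tensor organization metrics
#'
#' Computes the mean dyadic tensor of a set of unit axial vectors and returns
#' the orientational order parameter and the director.
#'
#' @param vectors n x 2 matrix of unit vectors (checked to 1e-6).
#' @param convention `"normalized"` (default): `oop = 2*lambda_max - 1` in
#'   `[0, 1]`; `"raw_eigenvalue"`: `oop = lambda_max` in `[0.5, 1]`.
#' @return List with `oop`, `director` (unit axial vector), `director_deg` in
#'   `[0, 180)`, `lambda_max`, `n_vectors` and `convention`.
#' @export
structure_tensor_metrics <- function(vectors,
                                     convention = c("normalized",
                                                    "raw_eigenvalue")) {
  convention <- match.arg(convention)
  vectors <- rbind(vectors)
  n <- nrow(vectors)
  if (n < 1) stop("empty vector set")
  norms <- sqrt(rowSums(vectors^2))
  if (any(abs(norms - 1) > 1e-6)) stop("vectors must be unit length")
  Tbar <- crossprod(vectors) / n
  e <- eigen(Tbar, symmetric = TRUE)
  lmax <- e$values[1]
  v <- e$vectors[, 1]
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  v <- c(cos(ang * pi / 180), sin(ang * pi / 180))
  oop <- if (convention == "normalized")
    min(max(2 * lmax - 1, 0), 1) else lmax
  list(oop = oop, director = v, director_deg = ang, lambda_max = lmax,
       n_vectors = n, convention = convention)
}

#' Angle between two axes
#'
#' Inverse cosine of the absolute dot product of two unit vectors, so that
#' antiparallel axes coincide; the result lies in `[0, 90]` degrees.
#'
#' @param p,q unit 2-vectors.
#' @return Angle in degrees.
#' @export
angle_between_axes <- function(p, q) {
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np < 1e-12 || nq < 1e-12) stop("zero vector")
  d <- abs(sum(p * q) / (np * nq))
  acos(min(d, 1)) * 180 / pi
}

#' Cell-type actin fraction
#'
#' Number of orientation vectors attributed to one cell type divided by all
#' actin vectors in the field (cardiomyocyte + fibroblast + other).
#'
#' @param cm_count,fb_count,other_count nonnegative vector counts.
#' @param type which numerator to use.
#' @return Fraction in `[0, 1]`.
#' @export
actin_fraction <- function(cm_count, fb_count, other_count = 0,
                           type = c("cardiomyocyte", "fibroblast")) {
  type <- match.arg(type)
  stopifnot(cm_count >= 0, fb_count >= 0, other_count >= 0)
  total <- cm_count + fb_count + other_count
  if (total == 0) stop("no actin vectors: total count is zero")
  num <- if (type == "cardiomyocyte") cm_count else fb_count
  num / total
}

#' Per-cell-type organization metrics for one field of view
#'
#' @param field actin [orientation_field].
#' @param semantic_map alpha-actinin class map.
#' @param actin_foreground logical actin mask.
#' @param stretch_angle_deg stretch axis, degrees from +x.
#' @param oop_convention see [structure_tensor_metrics()].
#' @return Data frame with one row per cell type (`cardiomyocyte`,
#'   `fibroblast`): `oop`, `director_deg`, `angle_to_stretch_deg`,
#'   `n_vectors`, `actin_fraction`.  Types with no vectors get NA metrics.
#' @export
organization_metrics <- function(field, semantic_map, actin_foreground,
                                 stretch_angle_deg = 0,
                                 oop_convention = "normalized") {
  stretch <- axis_vector(stretch_angle_deg)
  vcm <- select_class_vectors(field, semantic_map, actin_foreground,
                              "cardiomyocyte")
  vfb <- select_class_vectors(field, semantic_map, actin_foreground,
                              "fibroblast")
  voth <- select_class_vectors(field, semantic_map, actin_foreground, "other")
  counts <- c(cardiomyocyte = nrow(vcm), fibroblast = nrow(vfb))
  n_other <- nrow(voth)
  total <- sum(counts) + n_other
  one_row <- function(type, vecs) {
    if (nrow(vecs) == 0) {
      return(data.frame(cell_type = type, oop = NA_real_,
                        director_deg = NA_real_,
                        angle_to_stretch_deg = NA_real_, n_vectors = 0L,
                        actin_fraction = if (total > 0) 0 else NA_real_))
    }
    mt <- structure_tensor_metrics(vecs, convention = oop_convention)
    data.frame(cell_type = type, oop = mt$oop,
               director_deg = mt$director_deg,
               angle_to_stretch_deg = angle_between_axes(mt$director, stretch),
               n_vectors = mt$n_vectors,
               actin_fraction = actin_fraction(
                 counts[["cardiomyocyte"]], counts[["fibroblast"]], n_other,
                 type = type))
  }
  rbind(one_row("cardiomyocyte", vcm), one_row("fibroblast", vfb))
}

#' Quiver-style QC plot of an orientation field
#'
#' @param x an `orientation_field`.
#' @param step subsampling step in pixels.
#' @param scale arrow half-length in pixels.
#' @param ... passed to [graphics::image()].
#' @export
plot.orientation_field <- function(x, step = 8, scale = 3, ...) {
  nr <- nrow(x$angle_deg); nc <- ncol(x$angle_deg)
  graphics::image(seq_len(nc), seq_len(nr), t(x$valid)[, nr:1],
                  col = grDevices::gray(c(0.95, 0.7)), xlab = "x", ylab = "y",
                  ...)
  rows <- seq(1, nr, by = step); cols <- seq(1, nc, by = step)
  for (r in rows) for (c in cols) {
    if (!x$valid[r, c]) next
    t <- x$angle_deg[r, c] * pi / 180
    graphics::arrows(c - scale * cos(t), nr - (r - scale * sin(t)) + 1,
                     c + scale * cos(t), nr - (r + scale * sin(t)) + 1,
                     length = 0, col = "purple")
  }
  invisible(x)
}
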