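#' Bundle six rotational rhizotron views
#'
#' The imaging chain starts from six grayscale captures of a cylindrical
#' rhizotron taken at 60 degree intervals; consecutive views overlap
#' horizontally. Images are numeric matrices (row 1 = image top) with
#' intensities in `[0, 1]`.
#'
#' @param views List of exactly six matrices of identical dimensions.
#' @param tube_id Tube identifier.
#' @param time Acquisition time (days).
#' @param coeff Pixel-size coefficient (length units per pixel) carried to
#'   [projected_area()]; default 0.0042 as used by the source pipeline for
#'   600 dpi captures (note that 25.4/600 would be ~0.0423 mm/px; the
#'   printed coefficient is kept as the default and is configurable).
#' @return An object of class `view_stack`.
#' @export
view_stack <- function(views, tube_id = "tube", time = 0, coeff = 0.0042) {
  if (length(views) != 6L) stop("exactly six views are required")
  dims <- vapply(views, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all views must have identical dimensions")
  for (v in views) {
    if (any(!is.finite(v))) stop("views contain non-finite pixels")
    if (min(v) < 0 || max(v) > 1) stop("view intensities must lie in [0, 1]")
  }
  structure(list(views = views, tube_id = tube_id, time = time, coeff = coeff),
            class = "view_stack")
}

#' Stitch six rotational views into a panorama
#'
#' Merges the views left to right into a single 360-degree panorama.
#' Rotation correction is approximated by horizontal translation: the
#' overlap between each pair of adjacent views is estimated by 1-D
#' normalized cross-correlation of their boundary strips, and overlapping
#' columns are averaged. The procedure is deterministic.
#'
#' @param stack A [view_stack()] or a plain list of equal-size matrices.
#' @param overlap `NULL` to estimate each overlap by cross-correlation, or a
#'   single non-negative integer fixing the overlap for every pair
#'   (`0` = plain concatenation).
#' @param max_overlap Largest overlap considered during estimation
#'   (defaults to half the view width).
#' @return The panorama matrix, with attribute `offsets` giving the
#'   estimated left-edge position (0-based columns) of each view.
#' @export
stitch_panorama <- function(stack, overlap = NULL, max_overlap = NULL) {
  views <- if (inherits(stack, "view_stack")) stack$views else stack
  dims <- vapply(views, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all views must have identical dimensions")
  w <- ncol(views[[1L]])
  if (is.null(max_overlap)) max_overlap <- w %/% 2L

  estimate_overlap <- function(a, b) {
    best_o <- 0L; best_cc <- -Inf
    for (o in seq_len(max_overlap)) {
      sa <- a[, (w - o + 1L):w, drop = FALSE]
      sb <- b[, 1L:o, drop = FALSE]
      va <- as.vector(sa); vb <- as.vector(sb)
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
      cc <- stats::cor(va, vb)
      if (cc > best_cc) { best_cc <- cc; best_o <- o }
    }
    best_o
  }

  n <- length(views)
  overlaps <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    overlaps[i] <- if (is.null(overlap)) {
      estimate_overlap(views[[i]], views[[i + 1L]])
    } else as.integer(overlap)
  }
  offsets <- c(0L, cumsum(w - overlaps))
  total <- offsets[n] + w
  pano <- matrix(0, nrow(views[[1L]]), total)
  wt <- matrix(0, nrow(views[[1L]]), total)
  for (i in seq_len(n)) {
    idx <- (offsets[i] + 1L):(offsets[i] + w)
    pano[, idx] <- pano[, idx] + views[[i]]
    wt[, idx] <- wt[, idx] + 1
  }
  pano <- pano / pmax(wt, 1)
  attr(pano, "offsets") <- offsets
  pano
}

#' Low-rank SVD denoising
#'
#' Replaces the image by its best rank-`rank` approximation in the
#' least-squares sense (truncated singular value decomposition), then clips
#' to `[0, 1]`. By the Eckart-Young theorem the approximation error is
#' non-increasing in the rank.
#'
#' @param image Numeric matrix.
#' @param rank Positive integer, at most `min(nrow, ncol)`.
#' @return Denoised matrix of the same dimensions.
#' @export
svd_denoise <- function(image, rank) {
  rank <- as.integer(rank)
  if (is.na(rank) || rank < 1L) stop("`rank` must be a positive integer")
  if (rank > min(dim(image))) stop("`rank` exceeds min(nrow, ncol)")
  s <- svd(image, nu = rank, nv = rank)
  approx <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
  pmin(pmax(approx, 0), 1)
}

# Discrete Laplacian-of-Gaussian kernel at scale sigma, normalized to zero
# sum so flat regions give zero response.
log_kernel <- function(sigma, half_width = ceiling(3 * sigma)) {
  ax <- seq(-half_width, half_width)
  g <- outer(ax, ax, function(x, y) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  g - mean(g)
}

#' Segment roots with a Laplacian-of-Gaussian filter
#'
#' Root pixels are isolated in two coupled steps: the LoG response of the
#' (polarity-normalised) image at scale `sigma` delimits the root support —
#' ridge-like structures give positive response out to the zero crossing —
#' and an Otsu threshold computed over that support separates root from
#' background intensity inside it. Interior holes left where thick root
#' clusters drive the LoG response negative are filled. Roots darker than
#' the background are the default polarity; switching the flag on a
#' contrast-inverted image yields the identical mask.
#'
#' @param image Numeric matrix in `[0, 1]`, all pixels finite.
#' @param sigma LoG scale in pixels (about half the expected root stroke
#'   width); must be positive.
#' @param threshold Binarisation rule; only `"otsu"` is implemented.
#' @param polarity `"dark"` if roots are darker than the background
#'   (default), `"bright"` otherwise.
#' @return A logical mask of the same dimensions.
#' @export
segment_roots <- function(image, sigma = 1.5, threshold = "otsu",
                          polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  threshold <- match.arg(threshold, "otsu")
  if (sigma <= 0) stop("`sigma` must be positive")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  empty <- matrix(FALSE, nrow(image), ncol(image))
  j <- if (polarity == "dark") 1 - image else image
  k <- log_kernel(sigma)
  resp <- -EBImage::imageData(EBImage::filter2(j, k, boundary = "replicate"))
  if (max(resp) <= 1e-10) return(empty)  # flat image: no structure
  support <- resp > 0
  vals <- j[support]
  if (diff(range(vals)) == 0) return(empty)
  th <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1L)), range = c(0, 1))
  cand <- j > th
  # keep candidate components corroborated by the LoG support: root clusters
  # always intersect it at their ridges, isolated dark noise does not
  lab <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(cand), nrow(cand)))),
                nrow(cand))
  keep <- setdiff(unique(lab[support & cand]), 0L)
  mask <- matrix(lab %in% keep & lab > 0L, nrow(cand))
  fill_small_holes(mask, max_hole = ceiling(16 * sigma^2))
}

# Fill enclosed background components below `max_hole` pixels. Thin interior
# gaps from the LoG support (negative response inside thick root clusters)
# are closed; large background regions merely encircled by crossing roots
# stay background.
fill_small_holes <- function(mask, max_hole) {
  bg <- matrix(as.numeric(!mask), nrow(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(bg)), nrow(mask))
  if (max(lab) == 0L) return(mask)
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  fill <- setdiff(which(sizes <= max_hole), border_ids)
  mask | (lab %in% fill & lab > 0L)
}

#' Keep the main root component connected to the image top
#'
#' Roots enter the rhizotron picture from the seed at the top, so among the
#' 8-connected components of the mask only the largest one whose topmost
#' pixel lies within the top band of rows is retained; floating specks and
#' artefacts elsewhere are removed. Never adds pixels; an empty mask stays
#' empty.
#'
#' @param mask Logical matrix.
#' @param top_band Fraction of image height counted as "the top"
#'   (default 0.1).
#' @return Cleaned logical mask.
#' @export
clean_top_connected <- function(mask, top_band = 0.1) {
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  band_limit <- max(1L, ceiling(top_band * nrow(mask)))
  ids <- seq_len(max(lab))
  top_row <- vapply(ids, function(i) min(which(lab == i, arr.ind = TRUE)[, 1L]), 0L)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  candidates <- ids[top_row <= band_limit]
  if (!length(candidates))
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  keep <- candidates[which.max(sizes[candidates])]
  lab == keep
}

#' Projected root area from a binary mask
#'
#' The projected area is the count of foreground pixels; conversion to
#' physical units multiplies by the squared pixel-size coefficient.
#'
#' @param mask Logical matrix.
#' @param coeff Length units per pixel (> 0); default 0.0042.
#' @return A list with `pixels` and `area` (`pixels * coeff^2`).
#' @export
projected_area <- function(mask, coeff = 0.0042) {
  if (coeff <= 0) stop("`coeff` must be positive")
  px <- sum(mask)
  list(pixels = px, area = px * coeff^2)
}

#' Run the full view-to-area segmentation chain
#'
#' Panorama stitching, SVD denoising, LoG segmentation and top-connected
#' cleaning in sequence, ending in the projected root area.
#'
#' @param stack A [view_stack()].
#' @param rank SVD rank for denoising (`NULL` skips denoising).
#' @param sigma LoG scale in pixels.
#' @param top_band Top band fraction for [clean_top_connected()].
#' @param overlap Overlap handling passed to [stitch_panorama()].
#' @param polarity Root polarity passed to [segment_roots()].
#' @return A list with `panorama`, `denoised`, `mask`, `pixels`, `area`.
#' @export
segment_pipeline <- function(stack, rank = 60L, sigma = 1.5, top_band = 0.1,
                             overlap = NULL, polarity = "dark") {
  pano <- stitch_panorama(stack, overlap = overlap)
  den <- if (is.null(rank)) pano else svd_denoise(pano, rank = min(rank, min(dim(pano))))
  mask <- segment_roots(den, sigma = sigma, polarity = polarity)
  mask <- clean_top_connected(mask, top_band = top_band)
  pa <- projected_area(mask, coeff = stack$coeff)
  list(panorama = pano, denoised = den, mask = mask,
       pixels = pa$pixels, area = pa$area)
}

#' Descriptive B-spline fit of a root growth curve
#'
#' Least-squares fit of a cubic (by default) B-spline basis to a projected
#' root-area time series, evaluable (with first derivative) at arbitrary
#' times within the observed range. This is a descriptive per-tube fit;
#' no mixed-model inference is attached.
#'
#' @param time Strictly increasing observation times.
#' @param area Projected areas (same length).
#' @param df Basis dimension (number of spline coefficients).
#' @param degree Spline degree.
#' @return An object of class `growth_spline` with `predict(object, t)` and
#'   `deriv` support via [predict.growth_spline()].
#' @export
fit_growth_spline <- function(time, area, df = 5L, degree = 3L) {
  if (length(time) != length(area)) stop("`time` and `area` lengths differ")
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (df < degree + 1L) stop("`df` must be at least degree + 1")
  if (length(time) < df + 1L)
    stop("need at least df + 1 = ", df + 1L, " time points")
  basis <- splines::bs(time, df = df, degree = degree, intercept = FALSE)
  fit <- stats::lm.fit(cbind(1, basis), area)
  structure(list(coefficients = fit$coefficients,
                 knots = attr(basis, "knots"),
                 boundary = attr(basis, "Boundary.knots"),
                 degree = degree, df = df,
                 fitted = as.numeric(cbind(1, basis) %*% fit$coefficients),
                 time = time, area = area),
            class = "growth_spline")
}

#' Evaluate a fitted growth spline
#'
#' @param object A `growth_spline`.
#' @param newtime Times at which to evaluate (within the fitted range).
#' @param deriv 0 for the curve, 1 for its first derivative.
#' @param ... Unused.
#' @return Numeric vector of fitted values or derivatives.
#' @export
predict.growth_spline <- function(object, newtime = object$time, deriv = 0L, ...) {
  ord <- object$degree + 1L
  kn <- c(rep(object$boundary[1L], ord), object$knots,
          rep(object$boundary[2L], ord))
  full <- splines::splineDesign(kn, newtime, ord = ord,
                                derivs = rep(deriv, length(newtime)),
                                outer.ok = TRUE)
  # column 1 of the full basis is dropped by bs(intercept = FALSE)
  b <- full[, -1L, drop = FALSE]
  co <- object$coefficients
  if (deriv == 0L) as.numeric(co[1L] + b %*% co[-1L])
  else as.numeric(b %*% co[-1L])
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel images are averaged to one channel; intensities are
#' returned in `[0, 1]` as a plain matrix.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  pmin(pmax(img, 0), 1)
}

#' Write a binary mask as a PNG
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
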