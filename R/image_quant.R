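#' Generate a synthetic two/three-channel cell image
#'
#' Stands in for a perforated-cell micrograph: a `marker` channel
#' (Golgi marker filling an elliptical Golgi region), a `liposome`
#' channel with Gaussian puncta placed inside the Golgi mask with
#' probability `p_golgi` (uniformly over the cell otherwise), and a
#' `construct` channel with a diffuse cytosolic level and a
#' Golgi-enriched level `rho` times above it. All channels share a
#' uniform background and optional Gaussian/Poisson noise; the ground
#' truth (masks, punctum table, noise model, planted enrichment) is
#' recorded.
#'
#' @param shape `c(ny, nx)` image size in pixels.
#' @param golgi_center,golgi_radii Ellipse center `(x, y)` and radii
#'   (pixels) of the Golgi region.
#' @param cell_center,cell_radii Ellipse of the whole cell (contains
#'   the Golgi by construction of the defaults).
#' @param n_puncta Number of liposome puncta (>= 0).
#' @param punctum_intensity Peak intensity per punctum (FU).
#' @param punctum_sigma Gaussian radius of a punctum (pixels).
#' @param p_golgi Probability that a punctum falls in the Golgi region.
#' @param marker_level Marker intensity inside the Golgi region (FU).
#' @param cytosol_level Construct intensity above background in the
#'   cytosol (FU).
#' @param rho Planted Golgi/cytosol enrichment of the construct
#'   channel.
#' @param background Uniform background (FU).
#' @param noise_sd Additive Gaussian noise s.d. (FU; 0 disables).
#' @param poisson If `TRUE`, apply Poisson resampling to each channel.
#' @param pixel_size Physical pixel size (micrometre), metadata only.
#' @param seed Integer seed.
#' @return A `synthetic_cell_image`: `channels` (named list of
#'   matrices), `ground_truth` (Golgi/cell masks, punctum table,
#'   `background`, `noise_sd`, `rho`), `pixel_size`, `seed`.
#' @export
make_cell_image <- function(shape = c(192, 192),
                            golgi_center = c(70, 96),
                            golgi_radii = c(28, 18),
                            cell_center = c(96, 96),
                            cell_radii = c(88, 80),
                            n_puncta = 80, punctum_intensity = 400,
                            punctum_sigma = 1.5, p_golgi = 0.8,
                            marker_level = 500, cytosol_level = 100,
                            rho = 5, background = 50, noise_sd = 10,
                            poisson = FALSE, pixel_size = 0.1,
                            seed = 1) {
  if (any(c(n_puncta, punctum_intensity, punctum_sigma, background,
            noise_sd, marker_level, cytosol_level, rho) < 0) ||
      p_golgi < 0 || p_golgi > 1) {
    stop("image parameters must be non-negative (p_golgi in [0, 1])")
  }
  ny <- shape[1]; nx <- shape[2]
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yy <- matrix(rep(seq_len(ny), nx), ny, nx)
  in_ellipse <- function(cen, rad) {
    ((xx - cen[1]) / rad[1])^2 + ((yy - cen[2]) / rad[2])^2 <= 1
  }
  golgi <- in_ellipse(golgi_center, golgi_radii)
  cell <- in_ellipse(cell_center, cell_radii)
  if (n_puncta > 0 && p_golgi > 0 && !any(golgi)) {
    stop("puncta requested with p_golgi > 0 but the Golgi mask is empty")
  }
  withr::with_seed(seed, {
    marker <- background + marker_level * golgi
    construct <- background + cytosol_level * (cell & !golgi) +
      rho * cytosol_level * golgi
    liposome <- matrix(background, ny, nx)
    puncta <- data.frame(x = numeric(0), y = numeric(0),
                         intensity = numeric(0), in_golgi = logical(0))
    if (n_puncta > 0) {
      golgi_px <- which(golgi)
      cell_px <- which(cell)
      to_golgi <- stats::runif(n_puncta) < p_golgi
      pick <- integer(n_puncta)
      if (any(to_golgi)) {
        pick[to_golgi] <- sample(golgi_px, sum(to_golgi), replace = TRUE)
      }
      if (any(!to_golgi)) {
        pick[!to_golgi] <- sample(cell_px, sum(!to_golgi), replace = TRUE)
      }
      px <- ((pick - 1) %/% ny) + 1
      py <- ((pick - 1) %% ny) + 1
      w <- ceiling(4 * punctum_sigma)
      for (i in seq_len(n_puncta)) {
        ix <- max(1, px[i] - w):min(nx, px[i] + w)
        iy <- max(1, py[i] - w):min(ny, py[i] + w)
        g <- punctum_intensity *
          exp(-(outer((iy - py[i])^2, (ix - px[i])^2, "+")) /
                (2 * punctum_sigma^2))
        liposome[iy, ix] <- liposome[iy, ix] + g
      }
      puncta <- data.frame(x = px, y = py,
                           intensity = punctum_intensity,
                           in_golgi = golgi[cbind(py, px)])
    }
    channels <- list(marker = marker, liposome = liposome,
                     construct = construct)
    if (poisson) {
      channels <- lapply(channels, function(ch) {
        matrix(stats::rpois(length(ch), pmax(ch, 0)), ny, nx)
      })
    }
    if (noise_sd > 0) {
      channels <- lapply(channels, function(ch) {
        pmax(ch + matrix(stats::rnorm(length(ch), 0, noise_sd), ny, nx), 0)
      })
    }
  })
  structure(list(channels = channels,
                 ground_truth = list(golgi_mask = golgi,
                                     cell_mask = cell, puncta = puncta,
                                     background = background,
                                     noise_sd = noise_sd,
                                     poisson = poisson, rho = rho),
                 pixel_size = pixel_size, seed = seed),
            class = "synthetic_cell_image")
}

#' @export
print.synthetic_cell_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("Synthetic cell image ", d[1], "x", d[2], " px, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  cat("  puncta:", nrow(x$ground_truth$puncta),
      "; planted Golgi/cytosol enrichment rho =",
      x$ground_truth$rho, "\n")
  invisible(x)
}

#' Threshold a marker channel into a mask
#'
#' Determines the organelle region from a marker channel, either by
#' Otsu's method (via EBImage, on the intensity-normalized channel) or
#' by a fixed threshold (`mask = channel > threshold`).
#'
#' @param channel Numeric matrix.
#' @param rule `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `rule = "fixed"` (same units as the
#'   channel).
#' @return Logical mask matrix.
#' @export
marker_mask <- function(channel, rule = c("otsu", "fixed"),
                        threshold = NULL) {
  rule <- match.arg(rule)
  if (length(channel) == 0) stop("channel is empty")
  if (rule == "fixed") {
    if (is.null(threshold)) stop("rule = 'fixed' requires a threshold")
    return(channel > threshold)
  }
  rng <- range(channel)
  if (diff(rng) == 0) {
    stop("marker channel is constant; Otsu threshold is undefined")
  }
  norm <- (channel - rng[1]) / diff(rng)
  t_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  channel > rng[1] + t_norm * diff(rng)
}

#' Mean intensity over a mask
#'
#' @param channel Numeric matrix.
#' @param mask Logical matrix of the same shape with at least one
#'   `TRUE` pixel.
#' @return Mean of `channel` over the masked pixels (FU).
#' @export
masked_mean_intensity <- function(channel, mask) {
  if (!identical(dim(channel), dim(mask))) {
    stop("channel and mask must have identical dimensions")
  }
  if (!any(mask)) stop("mask is empty")
  mean(channel[mask])
}

#' Background-subtracted Golgi/cytosol ratio
#'
#' The quantification convention for construct localization: the
#' background (mean over a declared background ROI) is subtracted from
#' the mean intensities of two equal-area ROIs placed in the Golgi and
#' in the cytosol, and their ratio is returned. Negative numerators or
#' denominators are clamped to zero and flagged.
#'
#' @param channel Numeric matrix.
#' @param golgi_roi,cytosol_roi Logical masks of equal pixel area.
#' @param background_roi Logical mask disjoint from both ROIs.
#' @return A `golgi_ratio` list: `ratio`, `golgi_mean`,
#'   `cytosol_mean`, `background`, `roi_area`, `status` (`"ok"`,
#'   `"undefined"` when the cytosol mean equals the background),
#'   `clamped`.
#' @export
golgi_cytosol_ratio <- function(channel, golgi_roi, cytosol_roi,
                                background_roi) {
  if (sum(golgi_roi) != sum(cytosol_roi)) {
    stop("Golgi and cytosol ROIs must have the same pixel area (",
         sum(golgi_roi), " vs ", sum(cytosol_roi), ")")
  }
  if (any(background_roi & (golgi_roi | cytosol_roi))) {
    stop("background ROI must be disjoint from the Golgi/cytosol ROIs")
  }
  bg <- masked_mean_intensity(channel, background_roi)
  gm <- masked_mean_intensity(channel, golgi_roi)
  cm <- masked_mean_intensity(channel, cytosol_roi)
  num <- gm - bg; den <- cm - bg
  clamped <- FALSE
  if (num < 0) { num <- 0; clamped <- TRUE }
  if (den < 0) { den <- 0; clamped <- TRUE }
  status <- if (den == 0) "undefined" else "ok"
  structure(list(ratio = if (den == 0) NA_real_ else num / den,
                 golgi_mean = gm, cytosol_mean = cm, background = bg,
                 roi_area = sum(golgi_roi), status = status,
                 clamped = clamped), class = "golgi_ratio")
}

#' @export
print.golgi_ratio <- function(x, ...) {
  cat("Golgi/cytosol ratio:",
      if (x$status == "ok") signif(x$ratio, 4) else "undefined",
      "(background", signif(x$background, 4), ", ROI area",
      x$roi_area, "px)\n")
  if (x$clamped) cat("  note: negative background-subtracted mean",
                     "clamped to 0\n")
  invisible(x)
}

#' Pearson colocalization coefficient
#'
#' Standard Pearson correlation of two channels over the in-mask
#' pixels (whole frame when `mask` is `NULL`). Affine rescaling of
#' either channel leaves the coefficient unchanged.
#'
#' @param ch1,ch2 Numeric matrices of identical shape.
#' @param mask Optional logical mask (>= 2 pixels in scope).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  if (!identical(dim(ch1), dim(ch2))) {
    stop("channels must have identical dimensions")
  }
  v1 <- if (is.null(mask)) as.vector(ch1) else ch1[mask]
  v2 <- if (is.null(mask)) as.vector(ch2) else ch2[mask]
  if (length(v1) < 2) stop("need at least 2 pixels in scope")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("Pearson coefficient undefined: a channel has zero variance ",
         "in the scoped region")
  }
  stats::cor(v1, v2)
}

#' Rectangular region of interest
#'
#' Explicit pixel-set ROI helper (ROIs in this package are always
#' explicit masks, never interactive selections).
#'
#' @param shape `c(ny, nx)` image size.
#' @param x0,y0 Top-left corner (1-based, inclusive).
#' @param w,h Width and height in pixels.
#' @return Logical mask matrix.
#' @export
roi_rect <- function(shape, x0, y0, w, h) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (x0 < 1 || y0 < 1 || x0 + w - 1 > shape[2] ||
      y0 + h - 1 > shape[1]) {
    stop("ROI extends outside the image")
  }
  m[y0:(y0 + h - 1), x0:(x0 + w - 1)] <- TRUE
  m
}
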