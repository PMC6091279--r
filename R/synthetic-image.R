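# Synthetic segmented-plant rasters: binary masks with known analytic area
# and perimeter, plus colour rasters filled with a known HSV colour.

# pixel-centre coordinate grids for an nrow x ncol canvas
# convention: row-major grid, origin at the top-left corner of the canvas;
# pixel (i, j) has centre (x = j - 0.5, y = i - 0.5), y increasing downward.
.pixel_centres <- function(nrow, ncol) {
  list(
    x = matrix(rep(seq_len(ncol) - 0.5, each = nrow), nrow, ncol),
    y = matrix(rep(seq_len(nrow) - 0.5, times = ncol), nrow, ncol)
  )
}

#' Render a synthetic segmented plant image
#'
#' Rasterises an analytic shape — disk, axis-aligned ellipse, axis-aligned
#' square, or a "rosette" (union of ellipses around a centre) — onto a
#' binary mask. A pixel is foreground iff its centre lies inside the
#' analytic shape. The analytic area and perimeter of the shape are
#' recorded as ground truth, alongside a colour raster filled with a known
#' HSV colour inside the mask.
#'
#' @param shape `"disk"`, `"ellipse"`, `"square"` or `"rosette"`.
#' @param size shape size in px: radius for `disk`; `c(a, b)` semi-axes for
#'   `ellipse`; side length for `square`; for `rosette`, a list of
#'   `list(cx, cy, a, b, angle)` lobes (angle in radians), or a single
#'   `c(a, b)` used for `n_lobes` lobes placed around the centre.
#' @param canvas_px canvas side length (square canvas).
#' @param n_lobes number of rosette lobes when `size` is a single `c(a, b)`.
#' @param hsv_color foreground colour as `c(h, s, v)` with h in degrees
#'   0-360 and s, v in 0-1 (default a leaf green, h = 120).
#' @param seed optional seed; only used to jitter rosette lobe placement.
#' @return a list of class `plant_image`: `mask` (logical matrix),
#'   `color` (array h x w x 3, values 0-1), `truth` (list with
#'   `analytic_area_px`, `analytic_perimeter_px`, `hsv_color`).
#' @export
#' @examples
#' img <- render_plant_image("disk", size = 50, canvas_px = 128)
#' img$truth$analytic_area_px   # pi * 50^2
render_plant_image <- function(shape = c("disk", "ellipse", "square", "rosette"),
                               size,
                               canvas_px = 256L,
                               n_lobes = 3L,
                               hsv_color = c(120, 0.7, 0.55),
                               seed = NULL) {
  shape <- match.arg(shape)
  check_count(canvas_px, "canvas_px", min = 2L)
  if (!is.null(seed)) {
    check_count(seed, "seed")
    set.seed(seed)
  }
  g <- .pixel_centres(canvas_px, canvas_px)
  cx <- canvas_px / 2
  cy <- canvas_px / 2

  ellipse_area <- function(a, b) pi * a * b
  # Ramanujan's perimeter approximation, exact enough for ground truth
  ellipse_perim <- function(a, b) {
    h <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  }

  inside_ellipse <- function(x, y, cx, cy, a, b, angle = 0) {
    dx <- x - cx
    dy <- y - cy
    u <- dx * cos(angle) + dy * sin(angle)
    v <- -dx * sin(angle) + dy * cos(angle)
    (u / a)^2 + (v / b)^2 <= 1
  }

  if (shape == "disk") {
    r <- check_positive(size[1], "size")
    if (2 * r > canvas_px) {
      abort_boreff("disk exceeds canvas", "boreff_config_error")
    }
    mask <- inside_ellipse(g$x, g$y, cx, cy, r, r)
    truth <- list(analytic_area_px = pi * r^2,
                  analytic_perimeter_px = 2 * pi * r)
  } else if (shape == "ellipse") {
    if (length(size) != 2L) {
      abort_boreff("ellipse `size` must be c(a, b) semi-axes",
                   "boreff_config_error")
    }
    a <- check_positive(size[1], "size[1]")
    b <- check_positive(size[2], "size[2]")
    if (2 * max(a, b) > canvas_px) {
      abort_boreff("ellipse exceeds canvas", "boreff_config_error")
    }
    mask <- inside_ellipse(g$x, g$y, cx, cy, a, b)
    truth <- list(analytic_area_px = ellipse_area(a, b),
                  analytic_perimeter_px = ellipse_perim(a, b))
  } else if (shape == "square") {
    s <- check_positive(size[1], "size")
    if (s > canvas_px) {
      abort_boreff("square exceeds canvas", "boreff_config_error")
    }
    # axis-aligned, pixel-grid-aligned square: left edge at integer offset
    x0 <- floor(cx - s / 2)
    y0 <- floor(cy - s / 2)
    mask <- g$x > x0 & g$x < x0 + s & g$y > y0 & g$y < y0 + s
    truth <- list(analytic_area_px = s^2, analytic_perimeter_px = 4 * s)
  } else { # rosette
    if (is.numeric(size) && length(size) == 2L) {
      a <- size[1]
      b <- size[2]
      check_count(n_lobes, "n_lobes", min = 1L)
      angles <- seq(0, 2 * pi, length.out = n_lobes + 1L)[-(n_lobes + 1L)]
      reach <- a * 1.05
      lobes <- lapply(angles, function(th) {
        list(cx = cx + reach * cos(th), cy = cy + reach * sin(th),
             a = a, b = b, angle = th)
      })
    } else if (is.list(size)) {
      lobes <- size
    } else {
      abort_boreff("rosette `size` must be c(a, b) or a list of lobes",
                   "boreff_config_error")
    }
    mask <- matrix(FALSE, canvas_px, canvas_px)
    area <- 0
    perim <- 0
    for (lb in lobes) {
      m <- inside_ellipse(g$x, g$y, lb$cx, lb$cy, lb$a, lb$b,
                          lb$angle %||% 0)
      mask <- mask | m
      area <- area + ellipse_area(lb$a, lb$b)
      perim <- perim + ellipse_perim(lb$a, lb$b)
    }
    # analytic area/perimeter are additive only for disjoint lobes; record
    # the sums and whether overlap occurred so callers know when they apply
    overlap <- sum(vapply(lobes, function(lb) {
      sum(inside_ellipse(g$x, g$y, lb$cx, lb$cy, lb$a, lb$b, lb$angle %||% 0))
    }, numeric(1))) > sum(mask)
    truth <- list(analytic_area_px = area, analytic_perimeter_px = perim,
                  lobes_disjoint = !overlap)
    if (max(g$x[mask], -Inf) > canvas_px || min(g$x[mask], Inf) < 0) {
      abort_boreff("rosette exceeds canvas", "boreff_config_error")
    }
  }

  if (!any(mask)) {
    abort_boreff("rendered shape produced an empty mask", "boreff_config_error")
  }
  rgb01 <- grDevices::hsv(hsv_color[1] / 360, hsv_color[2], hsv_color[3])
  rgb3 <- as.vector(grDevices::col2rgb(rgb01)) / 255
  color <- array(0, dim = c(canvas_px, canvas_px, 3L))
  for (k in 1:3) {
    ch <- matrix(0, canvas_px, canvas_px)
    ch[mask] <- rgb3[k]
    color[, , k] <- ch
  }
  truth$hsv_color <- hsv_color
  structure(list(mask = mask, color = color, truth = truth),
            class = "plant_image")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write / read a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0. On reading, any
#' nonzero pixel is foreground.
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' Write / read an RGB raster as an 8-bit PNG
#'
#' @param color array h x w x 3 with values in 0-1.
#' @param path file path.
#' @return `write_color_png()` returns `path` invisibly; `read_color_png()`
#'   returns an h x w x 3 array in 0-1.
#' @export
write_color_png <- function(color, path) {
  stopifnot(length(dim(color)) == 3L)
  png::writePNG(color, path)
  invisible(path)
}

#' @rdname write_color_png
#' @export
read_color_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), dim = c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE]
}
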