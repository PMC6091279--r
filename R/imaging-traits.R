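# Trait extraction from segmented plant images: biomass-, architecture- and
# colour-related features of the default 12-feature set.

#' Default imaging feature set
#'
#' The 12 default features, spanning the three categories used in
#' high-throughput shoot phenotyping:
#' biomass-related (`projected_area_px`, `border_length_px`), architectural
#' (`convex_hull_area_px`, `bounding_height_px`, `bounding_width_px`,
#' `compactness`) and colour-related (`mean_hue`, `mean_saturation`,
#' `mean_r`, `mean_g`, `mean_b`, `mean_l`). HSV value is computed by
#' [extract_color_traits()] but not part of the default set: V = max(R,G,B)
#' is nearly collinear with LAB lightness, which is kept instead.
#'
#' @return character vector of 12 feature names.
#' @export
default_feature_set <- function() {
  c("projected_area_px", "border_length_px", "convex_hull_area_px",
    "bounding_height_px", "bounding_width_px", "compactness",
    "mean_hue", "mean_saturation", "mean_r", "mean_g", "mean_b", "mean_l")
}

.check_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_boreff("mask must be a 2-D binary matrix", "boreff_data_error")
  }
  if (!any(mask)) {
    abort_boreff("empty segmentation: mask has no foreground pixels",
                 "boreff_empty_mask_error")
  }
  mask
}

# shoelace area of a polygon given vertex coordinates
.polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Extract geometry traits from a binary mask
#'
#' * `projected_area_px`: foreground pixel count (the projected top-view
#'   leaf area, the validated biomass proxy).
#' * `border_length_px`: number of foreground pixels 4-adjacent to a
#'   background pixel or to the image edge (inner-boundary count; this is
#'   the "pixels at the border between foreground and background" trait).
#' * `convex_hull_area_px`: area of the convex hull of the foreground
#'   pixels, taking each pixel as a unit square (its four corners enter the
#'   hull), so a filled rectangle has hull area equal to its pixel count.
#' * `bounding_height_px`, `bounding_width_px`: bounding-box extent in rows
#'   and columns.
#' * `compactness`: `projected_area_px / convex_hull_area_px`, in (0, 1].
#'
#' @param mask logical (or 0/1 numeric) matrix; must contain at least one
#'   foreground pixel (an empty mask is an error, not a zero row).
#' @return a named list of the six geometry features.
#' @export
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
#' extract_geometry_traits(m)$border_length_px  # 12
extract_geometry_traits <- function(mask) {
  mask <- .check_mask(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  area <- sum(mask)

  # 4-neighbourhood background test with the image edge as background
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  border <- core & !(up & down & left & right)
  border_length <- sum(border)

  idx <- which(mask, arr.ind = TRUE)
  rows <- idx[, 1]
  cols <- idx[, 2]
  height <- diff(range(rows)) + 1L
  width <- diff(range(cols)) + 1L

  # convex hull over pixel corners (each pixel spans a unit square)
  cx <- c(cols - 1, cols, cols - 1, cols)
  cy <- c(rows - 1, rows - 1, rows, rows)
  h <- grDevices::chull(cx, cy)
  hull_area <- .polygon_area(cx[h], cy[h])

  list(
    projected_area_px = area,
    border_length_px = border_length,
    convex_hull_area_px = hull_area,
    bounding_height_px = as.integer(height),
    bounding_width_px = as.integer(width),
    compactness = area / hull_area
  )
}

#' Extract colour traits over the foreground of a colour raster
#'
#' Per-channel arithmetic means over foreground pixels in three colour
#' spaces: RGB (`mean_r`, `mean_g`, `mean_b`, channel values 0-1), HSV
#' (`mean_hue` in degrees 0-360, `mean_saturation`, `mean_value` in 0-1;
#' hue is averaged arithmetically, adequate for the narrow hue ranges of
#' plant foregrounds), and LAB lightness `mean_l` (0-100, sRGB with D65
#' white point via [grDevices::convertColor()]). Background pixels never
#' enter any mean.
#'
#' @param color_raster array h x w x 3 with values in 0-1 (or 0-255, which
#'   is rescaled).
#' @param mask logical matrix of the same h x w; at least one foreground
#'   pixel.
#' @return a named list of the seven colour features.
#' @export
extract_color_traits <- function(color_raster, mask) {
  mask <- .check_mask(mask)
  if (length(dim(color_raster)) != 3L || dim(color_raster)[3] < 3L) {
    abort_boreff("color raster must be an h x w x 3 array",
                 "boreff_data_error")
  }
  if (!all(dim(color_raster)[1:2] == dim(mask))) {
    abort_boreff("color raster and mask dimensions differ",
                 "boreff_data_error")
  }
  if (max(color_raster) > 1) color_raster <- color_raster / 255
  r <- color_raster[, , 1][mask]
  g <- color_raster[, , 2][mask]
  b <- color_raster[, , 3][mask]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  lab <- grDevices::convertColor(cbind(r, g, b), from = "sRGB", to = "Lab")
  list(
    mean_hue = mean(hsv["h", ]) * 360,
    mean_saturation = mean(hsv["s", ]),
    mean_value = mean(hsv["v", ]),
    mean_r = mean(r),
    mean_g = mean(g),
    mean_b = mean(b),
    mean_l = mean(lab[, "L"])
  )
}

#' Assemble the per-plant, per-day feature table
#'
#' Runs [extract_geometry_traits()] (and [extract_color_traits()] when a
#' colour raster is present) over a set of segmented images and returns one
#' row per plant per imaging day with the configured feature set. Images
#' without a colour raster get `NA` in the colour features — flagged
#' missing, never silently zero.
#'
#' @param images a data frame (or tibble) with columns `plant_id`, `das`,
#'   a list-column `mask`, and optionally a list-column `color` (h x w x 3
#'   arrays or `NULL`).
#' @param features feature names to keep (default [default_feature_set()]).
#' @return a tibble with `plant_id`, `das` and one column per feature.
#' @export
assemble_feature_table <- function(images, features = default_feature_set()) {
  req <- c("plant_id", "das", "mask")
  if (!all(req %in% names(images))) {
    abort_boreff("`images` needs columns plant_id, das and mask",
                 "boreff_data_error")
  }
  dup <- duplicated(images[c("plant_id", "das")])
  if (any(dup)) {
    offenders <- unique(paste0(images$plant_id[dup], " @ DAS ",
                               images$das[dup]))
    abort_boreff(paste0("duplicate (plant, day) entries: ",
                        paste(offenders, collapse = ", ")),
                 "boreff_data_error")
  }
  all_color <- c("mean_hue", "mean_saturation", "mean_value",
                 "mean_r", "mean_g", "mean_b", "mean_l")
  rows <- lapply(seq_len(nrow(images)), function(i) {
    geo <- extract_geometry_traits(images$mask[[i]])
    col <- if ("color" %in% names(images) && !is.null(images$color[[i]])) {
      extract_color_traits(images$color[[i]], images$mask[[i]])
    } else {
      setNames(as.list(rep(NA_real_, length(all_color))), all_color)
    }
    tibble::as_tibble(c(list(plant_id = images$plant_id[i],
                             das = images$das[i]),
                        geo, col))
  })
  out <- dplyr::bind_rows(rows)
  unknown <- setdiff(features, setdiff(names(out), c("plant_id", "das")))
  if (length(unknown) > 0) {
    abort_boreff(paste0("unknown feature(s): ", paste(unknown, collapse = ", ")),
                 "boreff_config_error")
  }
  out[, c("plant_id", "das", features)]
}
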