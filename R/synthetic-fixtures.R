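# Deterministic geometric fixtures with analytically known measurements.
# These exist so that every measurement operation can be tested against
# closed-form geometry instead of against itself.

#' Geometric shape specification for fixture masks
#'
#' @param kind One of `"disk"`, `"rectangle"`, `"ellipse"`,
#'   `"plus_pentomino"`, `"single_pixel"`.
#' @param row,col Position (disk/ellipse/plus: center; rectangle: top-left
#'   corner), in pixels.
#' @param radius Disk radius (px).
#' @param width,height Rectangle extent in columns / rows (px).
#' @param axes Ellipse semi-axes `c(row_semi_axis, col_semi_axis)` (px).
#' @param intensity Paint intensity in `[0, 255]` (used when shapes are
#'   rendered onto grayscale canvases; fixture masks are binary).
#' @return A `"shape_spec"` list with analytic measurement fields
#'   `area`, `perimeter`, `feret`, `hull_area` of the continuous shape.
#' @export
shape_spec <- function(kind = c("disk", "rectangle", "ellipse",
                                "plus_pentomino", "single_pixel"),
                       row, col, radius = NULL, width = NULL, height = NULL,
                       axes = NULL, intensity = 0) {
  kind <- match.arg(kind)
  if (intensity < 0 || intensity > 255) stop("`intensity` must lie in [0, 255]")
  exp_m <- switch(kind,
    disk = {
      if (is.null(radius) || radius <= 0) stop("disk needs a positive `radius`")
      list(area = pi * radius^2, perimeter = 2 * pi * radius,
           feret = 2 * radius, hull_area = pi * radius^2)
    },
    rectangle = {
      if (is.null(width) || is.null(height) || width < 1 || height < 1)
        stop("rectangle needs `width` and `height` >= 1")
      list(area = width * height, perimeter = 2 * (width + height),
           feret = sqrt(width^2 + height^2), hull_area = width * height)
    },
    ellipse = {
      if (is.null(axes) || length(axes) != 2 || any(axes <= 0))
        stop("ellipse needs positive `axes = c(a, b)`")
      a <- axes[1]; b <- axes[2]
      list(area = pi * a * b,
           perimeter = pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))),
           feret = 2 * max(a, b), hull_area = pi * a * b)
    },
    plus_pentomino = list(area = 5, perimeter = 12, feret = sqrt(10),
                          hull_area = 7),
    single_pixel = list(area = 1, perimeter = 4, feret = sqrt(2),
                        hull_area = 1)
  )
  structure(list(kind = kind, row = row, col = col, radius = radius,
                 width = width, height = height, axes = axes,
                 intensity = intensity, expected = exp_m),
            class = "shape_spec")
}

# pixel coordinates (n x 2 matrix) covered by a shape
rasterize_shape <- function(s) {
  switch(s$kind,
    disk = {
      r <- s$radius
      ii <- floor(s$row - r):ceiling(s$row + r)
      jj <- floor(s$col - r):ceiling(s$col + r)
      g <- expand.grid(row = ii, col = jj)
      g <- g[(g$row - s$row)^2 + (g$col - s$col)^2 <= r^2, ]
      as.matrix(g)
    },
    rectangle = as.matrix(expand.grid(row = s$row + seq_len(s$height) - 1,
                                      col = s$col + seq_len(s$width) - 1)),
    ellipse = {
      a <- s$axes[1]; b <- s$axes[2]
      ii <- floor(s$row - a):ceiling(s$row + a)
      jj <- floor(s$col - b):ceiling(s$col + b)
      g <- expand.grid(row = ii, col = jj)
      g <- g[((g$row - s$row) / a)^2 + ((g$col - s$col) / b)^2 <= 1, ]
      as.matrix(g)
    },
    plus_pentomino = cbind(row = s$row + c(0, -1, 1, 0, 0),
                           col = s$col + c(0, 0, 0, -1, 1)),
    single_pixel = cbind(row = s$row, col = s$col)
  )
}

#' Render non-overlapping shapes into a binary fixture mask
#'
#' Shapes must fit fully inside the image and must neither overlap nor
#' touch (no 8-neighbourhood contact), so each shape maps to exactly one
#' labeled particle downstream. Alongside the mask, the analytic
#' measurements of each continuous shape are returned to serve as oracle
#' values, together with the exact rasterized pixel count.
#'
#' @param shapes List of [shape_spec()] objects.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param pixel_size_um Physical pixel size attached to the mask.
#' @return A list: `mask` (a `"binary_mask"`) and `expected` (data frame
#'   with one row per shape: `kind`, `area`, `perimeter`, `feret`,
#'   `hull_area` of the continuous shape, plus `area_px_rendered`).
#' @export
fixture_mask <- function(shapes, dim = c(128, 128), pixel_size_um = 1.4) {
  if (inherits(shapes, "shape_spec")) shapes <- list(shapes)
  m <- matrix(FALSE, dim[1], dim[2])
  halo <- matrix(FALSE, dim[1], dim[2])  # shapes plus 1-px margin
  rows <- lapply(shapes, function(s) {
    px <- rasterize_shape(s)
    if (any(px[, 1] < 1 | px[, 1] > dim[1] | px[, 2] < 1 | px[, 2] > dim[2]))
      stop(sprintf("shape '%s' does not fit inside the %d x %d image",
                   s$kind, dim[1], dim[2]))
    if (any(halo[px])) stop("shapes overlap or touch; fixture rejected")
    m[px] <<- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      p2 <- cbind(pmin(pmax(px[, 1] + dr, 1), dim[1]),
                  pmin(pmax(px[, 2] + dc, 1), dim[2]))
      halo[p2] <<- TRUE
    }
    data.frame(kind = s$kind, area = s$expected$area,
               perimeter = s$expected$perimeter, feret = s$expected$feret,
               hull_area = s$expected$hull_area, area_px_rendered = nrow(px))
  })
  list(mask = new_binary_mask(m, threshold = NA_real_,
                              pixel_size_um = pixel_size_um),
       expected = do.call(rbind, rows))
}
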