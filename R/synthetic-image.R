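# Seeded renderer of tumor-like grayscale images: dark irregular
# epithelial clusters, scattered dark single cells, optional sub-cellular
# debris specks, on a light noisy background. Intensities are chosen so
# that every binarization threshold in use (automatic or fixed 220/240/
# 250) segments exactly the same stained pixels, which keeps the ground
# truth of the rendered scene valid for every arm of the screening grid.

#' Parameters of the synthetic tumor image generator
#'
#' Defaults emulate pan-cytokeratin-stained sections at 1.4 um/px: a
#' near-white background (mean 253, clipped to stay strictly above the
#' 250 threshold), a handful of large irregular stained clusters (unions
#' of 5-50 overlapping disks along a random walk, which the 0.8
#' circularity filter must reject), scattered round single cells whose
#' rendered areas fall in the 20-60 px band (diameters about 7-11 um),
#' and small non-informative debris specks in the 1-10 px band emulating
#' staining noise.
#'
#' @param dim Image size `c(rows, cols)` in pixels.
#' @param background_mean,background_sd Background intensity model;
#'   rendered background is clipped to `[251, 255]` so it stays strictly
#'   above the fixed thresholds.
#' @param cluster_lambda Poisson mean of the cluster count per image.
#' @param max_clusters Hard cap on the rendered cluster count (keeps the
#'   requested scene placeable on the canvas).
#' @param cluster_intensity,cell_intensity,debris_intensity Intensity
#'   ranges of stained structures; must stay strictly below 220.
#' @param cluster_n_disks Range of disks per cluster random walk.
#' @param cluster_disk_radius Disk radius range of the cluster walk (px).
#' @param cluster_step_frac Walk step as a fraction of the summed radii of
#'   consecutive disks (kept below 1 so clusters stay connected).
#' @param n_cells Number of scattered single cells to render.
#' @param cell_radius Single-cell radius range (px); validated so that
#'   rendered cell areas lie in the 20-60 px band.
#' @param debris_lambda Poisson mean of the debris speck count (set to 0
#'   to disable debris).
#' @param debris_radius Debris radius range (px, below single-cell size).
#' @param pixel_size_um Physical pixel size (default 1.4).
#' @return A `"morphology_spec"` list.
#' @export
morphology_spec <- function(dim = c(256, 256),
                            background_mean = 253, background_sd = 1.2,
                            cluster_lambda = 12,
                            max_clusters = 30,
                            cluster_intensity = c(40, 140),
                            cluster_n_disks = c(5, 50),
                            cluster_disk_radius = c(2, 4.5),
                            cluster_step_frac = c(0.5, 0.95),
                            n_cells = 12,
                            cell_radius = c(2.8, 4.05),
                            cell_intensity = c(40, 160),
                            debris_lambda = 25,
                            debris_radius = c(0.4, 1.55),
                            debris_intensity = c(40, 160),
                            pixel_size_um = 1.4) {
  if (n_cells < 0 || n_cells != round(n_cells)) stop("`n_cells` must be a non-negative integer")
  if (background_mean <= 250)
    stop("background must sit strictly above the fixed thresholds (mean > 250)")
  stains <- c(cluster_intensity, cell_intensity, debris_intensity)
  if (any(stains < 0) || any(stains >= 220))
    stop("stain intensities must lie in [0, 220)")
  if (pi * cell_radius[1]^2 < 20 || pi * cell_radius[2]^2 > 60)
    stop("`cell_radius` must keep rendered cell areas inside the 20-60 px band")
  structure(as.list(environment()), class = "morphology_spec")
}

# paint a hard (non-anti-aliased) disk of continuous center/radius
paint_disk <- function(img, cr, cc, r, value) {
  ii <- max(1, floor(cr - r)):min(nrow(img), ceiling(cr + r))
  jj <- max(1, floor(cc - r)):min(ncol(img), ceiling(cc + r))
  sel <- outer(ii, jj, function(i, j) (i - cr)^2 + (j - cc)^2 <= r^2)
  img[ii, jj][sel] <- value
  img
}

disk_pixels <- function(dim, cr, cc, r) {
  ii <- as.integer(max(1, floor(cr - r))):as.integer(min(dim[1], ceiling(cr + r)))
  jj <- as.integer(max(1, floor(cc - r))):as.integer(min(dim[2], ceiling(cc + r)))
  ni <- length(ii)
  rows <- rep.int(ii, length(jj))
  cols <- rep(jj, each = ni)
  sel <- (rows - cr)^2 + (cols - cc)^2 <= r^2
  cbind(rows[sel], cols[sel])
}

runif1 <- function(range) runif(1, range[1], range[2])

#' Render one synthetic tumor image
#'
#' Places the requested objects by rejection sampling so that cells,
#' clusters and debris are pairwise disjoint (with a 1-px separating
#' halo, so 8-connected labeling keeps them apart); all objects are hard
#' intensity disks without anti-aliasing, so fixed thresholds segment
#' them exactly. The same seed always produces a bit-identical image.
#'
#' @param spec A [morphology_spec()].
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return A list: `image` (a [gray_image]) and `truth` (rendered ground
#'   truth: `n_cells`, `n_clusters`, `n_debris`, per-cell centers/radii).
#' @export
render_tumor_image <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "morphology_spec"))
  with_seed(seed, {
    nr <- spec$dim[1]; nc <- spec$dim[2]
    bg <- matrix(pmin(255, pmax(251, round(
      rnorm(nr * nc, spec$background_mean, spec$background_sd)))), nr, nc)
    img <- bg
    occupied <- matrix(FALSE, nr, nc)  # objects + 1-px halo

    # pixel sets are handled as linear (column-major) indices
    as_lin <- function(px) (px[, 2] - 1L) * nr + px[, 1]
    claim <- function(px) {  # mark pixels plus a 1-px halo as occupied
      n_px <- nrow(px)
      rows <- pmin.int(pmax.int(rep(px[, 1], 9) +
                                  rep(c(-1L, 0L, 1L), each = 3 * n_px), 1L), nr)
      cols <- pmin.int(pmax.int(rep(px[, 2], 9) +
                                  rep(rep(c(-1L, 0L, 1L), each = n_px), 3), 1L), nc)
      occupied[(cols - 1L) * nr + rows] <<- TRUE
    }
    free <- function(px) nrow(px) > 0 && !any(occupied[as_lin(px)])

    n_clusters <- min(rpois(1, spec$cluster_lambda), spec$max_clusters)
    for (k in seq_len(n_clusters)) {
      placed <- FALSE
      for (try in 1:200) {
        ndisks <- sample(spec$cluster_n_disks[1]:spec$cluster_n_disks[2], 1)
        cr <- runif(1, 8, nr - 8); cc <- runif(1, 8, nc - 8)
        px <- NULL
        r0 <- cr; c0 <- cc
        rad_prev <- runif1(spec$cluster_disk_radius)
        for (dk in seq_len(ndisks)) {
          rad <- runif1(spec$cluster_disk_radius)
          px <- rbind(px, disk_pixels(spec$dim, r0, c0, rad))
          ang <- runif(1, 0, 2 * pi)
          # step bounded by the summed radii so the walk stays connected
          step <- runif1(spec$cluster_step_frac) * (rad_prev + rad)
          r0 <- min(max(r0 + step * sin(ang), 3), nr - 3)
          c0 <- min(max(c0 + step * cos(ang), 3), nc - 3)
          rad_prev <- rad
        }
        lin <- unique(as_lin(px))
        px <- cbind((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
        if (free(px)) {
          img[lin] <- round(runif1(spec$cluster_intensity))
          claim(px)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("image too small to place the requested clusters")
    }

    cell_centers <- matrix(numeric(0), 0, 2)
    cell_radii <- numeric(0)
    for (k in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (try in 1:200) {
        rad <- runif1(spec$cell_radius)
        cr <- runif(1, rad + 1, nr - rad - 1)
        cc <- runif(1, rad + 1, nc - rad - 1)
        px <- disk_pixels(spec$dim, cr, cc, rad)
        if (free(px)) {
          img[px] <- round(runif1(spec$cell_intensity))
          claim(px)
          cell_centers <- rbind(cell_centers, c(cr, cc))
          cell_radii <- c(cell_radii, rad)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("image too small to place the requested single cells")
    }

    n_debris <- if (spec$debris_lambda > 0) rpois(1, spec$debris_lambda) else 0L
    placed_debris <- 0L
    for (k in seq_len(n_debris)) {
      for (try in 1:50) {
        rad <- runif1(spec$debris_radius)
        cr <- runif(1, 3, nr - 3); cc <- runif(1, 3, nc - 3)
        px <- disk_pixels(spec$dim, cr, cc, rad)
        if (nrow(px) == 0)  # sub-pixel radius: render the nearest pixel
          px <- cbind(round(cr), round(cc))
        if (free(px)) {
          img[px] <- round(runif1(spec$debris_intensity))
          claim(px)
          placed_debris <- placed_debris + 1L
          break
        }
      }
    }

    list(image = gray_image(img, spec$pixel_size_um),
         truth = list(n_cells = spec$n_cells, n_clusters = n_clusters,
                      n_debris = placed_debris,
                      cell_centers = cell_centers, cell_radii = cell_radii))
  })
}
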