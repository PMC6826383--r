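# Aggregation of filtered particles into per-image features and
# per-patient averages.
#
# Count-type features (count, total_area, average_size) are defined for
# every image, including particle-free ones (where they are 0). Shape
# means (circularity, solidity) are undefined on particle-free images and
# propagate as NA; patient-level averaging skips those images, and a
# patient whose shape feature is missing in every image stays NA.

feature_names <- function() {
  c("count", "total_area", "average_size", "circularity", "solidity")
}

#' Per-image features of a filtered particle subset
#'
#' @param particles Data frame of measured (and typically filtered)
#'   particles from one image, see [measure_particles()] and
#'   [apply_filter()].
#' @return One-row data frame with `count`, `total_area` (px),
#'   `average_size` (px, `total_area / count`), `circularity` and
#'   `solidity` (arithmetic means over particles; NA when `count` is 0).
#' @export
image_features <- function(particles) {
  n <- nrow(particles)
  if (n == 0) {
    return(data.frame(count = 0, total_area = 0, average_size = 0,
                      circularity = NA_real_, solidity = NA_real_))
  }
  total <- sum(particles$area_px)
  data.frame(count = n, total_area = total, average_size = total / n,
             circularity = mean(particles$circularity),
             solidity = mean(particles$solidity))
}

#' Per-patient feature averages across images
#'
#' Arithmetic mean of each feature over a patient's images (typically
#' 5-6). Shape features skip images without particles; if no image has a
#' particle, the patient's shape feature is NA.
#'
#' @param images Data frame with one row per image, as produced by
#'   [image_features()] (rows may be `rbind`-ed).
#' @return One-row data frame with the same feature columns.
#' @export
patient_features <- function(images) {
  if (is.null(nrow(images)) || nrow(images) == 0)
    stop("a patient needs at least one image")
  shape_mean <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  data.frame(count = mean(images$count),
             total_area = mean(images$total_area),
             average_size = mean(images$average_size),
             circularity = shape_mean(images$circularity),
             solidity = shape_mean(images$solidity))
}
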