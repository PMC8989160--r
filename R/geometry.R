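# Point-cloud ROI machinery: back-projection, sphere seed selection,
# regression plane, normal-axis cylinder, membership, centroid.

#' Operator ROI seed
#'
#' @param xc,yc seed pixel (zero-based image coordinates; `xc` along width)
#' @param radius_px selection radius in pixels (default 8)
#' @return object of class `roi_spec`
#' @export
roi_spec <- function(xc, yc, radius_px = 8) {
  stopifnot(radius_px > 0)
  structure(list(xc = xc, yc = yc, radius_px = radius_px),
            class = "roi_spec")
}

#' Back-project a depth frame to a point cloud
#'
#' For each valid pixel (u, v) with depth z the camera-frame point is
#' `((u - cx) * z / fx, (v - cy) * z / fy, z)`. Invalid (`NA`) pixels are
#' excluded; source pixel coordinates are preserved so pixel-space
#' selections remain possible after back-projection.
#'
#' @param frame H x W depth matrix (mm, `NA` = missing)
#' @param intrinsics `camera_intrinsics`
#' @return object of class `point_cloud`: list with `points` (N x 3 matrix,
#'   mm) and `pixel_index` (N x 2 matrix of zero-based (u, v))
#' @export
depth_to_pointcloud <- function(frame, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  if (nrow(frame) != intrinsics$height || ncol(frame) != intrinsics$width)
    stop("frame dimensions do not match intrinsics")
  H <- nrow(frame)
  idx <- which(is.finite(frame))
  v <- (idx - 1) %% H
  u <- (idx - 1) %/% H
  z <- frame[idx]
  pts <- cbind(x = (u - intrinsics$cx) * z / intrinsics$fx,
               y = (v - intrinsics$cy) * z / intrinsics$fy,
               z = z)
  structure(list(points = pts, pixel_index = cbind(u = u, v = v)),
            class = "point_cloud")
}

subset_cloud <- function(cloud, keep) {
  structure(list(points = cloud$points[keep, , drop = FALSE],
                 pixel_index = cloud$pixel_index[keep, , drop = FALSE]),
            class = "point_cloud")
}

#' Select the spherical (pixel-disc) seed neighbourhood
#'
#' Returns the cloud points whose source pixel lies within `radius_px` of
#' the seed, i.e. `(u - xc)^2 + (v - yc)^2 <= radius_px^2`. The selection
#' is made in pixel space because the seed itself is given in pixels.
#'
#' @param cloud `point_cloud`
#' @param spec `roi_spec`
#' @return `point_cloud` subset
#' @export
select_sphere_roi <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "roi_spec"))
  du <- cloud$pixel_index[, 1] - spec$xc
  dv <- cloud$pixel_index[, 2] - spec$yc
  keep <- du * du + dv * dv <= spec$radius_px^2
  if (!any(keep))
    stop("ROI seed error: no valid pixel within the selection radius")
  subset_cloud(cloud, keep)
}

#' Fit the ROI regression plane
#'
#' Ordinary least squares of z on (x, y): `z ~ a*x + b*y + c`. The unit
#' normal `(a, b, -1) / ||(a, b, -1)||` is re-oriented to point towards the
#' camera (negative dot product with the viewing direction to the patch).
#'
#' @param cloud `point_cloud` with at least three non-collinear points
#' @return list with plane coefficients `a`, `b`, `c` and unit `normal`
#' @export
fit_plane <- function(cloud) {
  pts <- cloud$points
  if (nrow(pts) < 3)
    stop("degenerate ROI: fewer than 3 points for the plane fit")
  X <- cbind(pts[, 1], pts[, 2], 1)
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("degenerate ROI: rank-deficient plane fit (collinear points)")
  coefs <- qr.coef(qrX, pts[, 3])
  n <- c(coefs[1], coefs[2], -1)
  n <- n / vnorm(n)
  centre <- colMeans(pts)
  if (sum(n * centre) > 0) n <- -n  # orient towards the camera origin
  list(a = unname(coefs[1]), b = unname(coefs[2]), c = unname(coefs[3]),
       normal = unname(n))
}

#' Build the tracking cylinder from the seed neighbourhood
#'
#' The cylinder base centre is the seed point projected onto the fitted
#' plane, its axis is the plane normal, and its radius is the pixel radius
#' converted to millimetres at the ROI depth (`radius_px * z0 / fx`), so
#' that membership becomes a genuine 3D test. If the seed pixel itself has
#' no depth, the nearest valid pixel within `radius_px` is used.
#'
#' @param roi_points `point_cloud` subset from [select_sphere_roi()]
#' @param spec `roi_spec`
#' @param intrinsics `camera_intrinsics`
#' @return object of class `roi_model`: list with base centre `c0` (mm),
#'   unit axis `n` (towards the camera) and `radius_mm`
#' @export
build_cylinder <- function(roi_points, spec, intrinsics) {
  pl <- fit_plane(roi_points)
  du <- roi_points$pixel_index[, 1] - spec$xc
  dv <- roi_points$pixel_index[, 2] - spec$yc
  d2 <- du * du + dv * dv
  seed_row <- which.min(d2)  # exact seed pixel when valid, else nearest
  p <- roi_points$points[seed_row, ]
  # project onto plane a*x + b*y - z = -c
  m <- c(pl$a, pl$b, -1)
  p0 <- p - ((sum(m * p) + pl$c) / sum(m * m)) * m
  radius_mm <- unname(spec$radius_px * p0[3] / intrinsics$fx)
  structure(list(c0 = unname(p0), n = pl$normal, radius_mm = radius_mm,
                 plane = pl),
            class = "roi_model")
}

#' Points inside the tracking cylinder
#'
#' Membership by radial distance from the cylinder axis:
#' `||(p - c0) - ((p - c0) . n) n|| <= radius_mm`. The cylinder is
#' unbounded along its axis; the downstream 15 cm displacement cut bounds
#' it in practice.
#'
#' @param cloud `point_cloud`
#' @param model `roi_model`
#' @return `point_cloud` subset (possibly empty; an empty ROI marks the
#'   frame missing downstream)
#' @export
points_in_cylinder <- function(cloud, model) {
  stopifnot(inherits(model, "roi_model"))
  rel <- sweep(cloud$points, 2, model$c0)
  axial <- rel %*% model$n
  rad2 <- rowSums(rel * rel) - axial^2
  subset_cloud(cloud, rad2 <= model$radius_mm^2 + 1e-9)
}

#' ROI centroid and camera distance
#'
#' @param roi_points non-empty `point_cloud`
#' @return list with `centroid` (x, y, z means, mm) and `distance` `P`, the
#'   Euclidean distance from the camera origin to the centroid (mm)
#' @export
centroid_and_distance <- function(roi_points) {
  if (nrow(roi_points$points) < 1)
    stop("empty ROI: no points to average")
  ctr <- colMeans(roi_points$points)
  list(centroid = unname(ctr), distance = vnorm(ctr))
}
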