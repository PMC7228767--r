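#' Construct a plane
#'
#' A plane is `{x : normal . x = offset}` with a unit normal (dimensionless)
#' and offset in nm.
#'
#' @param normal length-3 numeric, normalized internally (must be non-zero)
#' @param offset nm
#' @param rms optional RMS perpendicular residual of a fit, nm
#' @return object of class `plane`
#' @export
plane <- function(normal, offset, rms = NA_real_) {
  n <- as.numeric(normal)
  len <- sqrt(sum(n^2))
  if (!is.finite(len) || len == 0) stopf("plane normal must be non-zero")
  n <- n / len
  structure(list(normal = n, offset = as.numeric(offset) / len, rms = rms),
            class = "plane")
}

signed_dist <- function(pl, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  drop(p %*% pl$normal) - pl$offset
}

#' Fit a plane to a point cloud by total least squares
#'
#' The normal is the direction of smallest variance of the centred cloud
#' (smallest right singular vector); the offset places the plane through the
#' centroid. The RMS perpendicular residual is reported in the `rms` field.
#' The normal's sign is fixed deterministically (largest-magnitude component
#' positive).
#'
#' @param points n x 3 matrix of physical positions (nm), n >= 3, not
#'   collinear
#' @return a [plane()]
#' @export
fit_plane <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 3) stopf("plane fit needs >= 3 points, got %d", nrow(p))
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q)
  if (sv$d[2] <= max(sv$d[1] * 1e-12, 1e-300))
    stopf("degenerate point cloud (collinear): plane is not determined")
  n <- sv$v[, 3]
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  res <- drop(q %*% n)
  plane(n, sum(n * ctr), rms = sqrt(mean(res^2)))
}

#' Construct the IPL reference frame from the two SAC planes
#'
#' The frame maps physical positions to normalized IPL depth: the OFF SAC
#' plane is `depth_at_off` (default 0) and the ON SAC plane `depth_at_on`
#' (default 1), so depth increases toward the ganglion cell layer (GCL). The
#' ON/GCL side must be declared explicitly through `orientation_ref`, a
#' physical point on the GCL side of both planes — there is no silent sign
#' guessing: an `orientation_ref` inconsistent with the plane labels is an
#' error.
#'
#' @param plane_off,plane_on fitted [plane()]s of the OFF and ON SAC dendritic
#'   plexuses
#' @param orientation_ref physical point (nm) on the GCL side
#' @param depth_at_off,depth_at_on depth values assigned to the two planes
#' @param max_angle_deg reject frames whose plane normals disagree by more
#'   than this (default 15 degrees); a warning is raised above `warn_angle_deg`
#' @param warn_angle_deg see above (default 5)
#' @return object of class `ipl_frame`
#' @export
ipl_frame <- function(plane_off, plane_on, orientation_ref,
                      depth_at_off = 0, depth_at_on = 1,
                      max_angle_deg = 15, warn_angle_deg = 5) {
  if (depth_at_off == depth_at_on)
    stopf("depth_at_off and depth_at_on must differ")
  # align the two normals to point the same way
  if (sum(plane_off$normal * plane_on$normal) < 0)
    plane_on <- plane(-plane_on$normal, -plane_on$offset, plane_on$rms)
  ang <- angle_deg(plane_off$normal, plane_on$normal)
  if (ang > max_angle_deg)
    stopf("SAC plane normals disagree by %.2f deg (> %g deg limit)",
          ang, max_angle_deg)
  if (ang > warn_angle_deg)
    warnf("SAC plane normals disagree by %.2f deg", ang)
  axis <- plane_off$normal + plane_on$normal
  axis <- axis / sqrt(sum(axis^2))
  # provisional separation along the mean normal, to orient the axis
  p_on <- plane_on$normal * plane_on$offset
  sep0 <- sum(axis * p_on) - sum(axis * (plane_off$normal * plane_off$offset))
  if (sep0 < 0) axis <- -axis  # orient the axis from OFF toward ON
  # separation anchored at orientation_ref: distance to the OFF plane of the
  # point where the axis line through orientation_ref crosses the ON plane.
  # This anchor moves rigidly with the volume, so normalized depth is exactly
  # invariant under rigid motions even when the planes are not parallel.
  ref <- as.numeric(orientation_ref)
  denom <- sum(plane_on$normal * axis)
  t_on <- (plane_on$offset - sum(plane_on$normal * ref)) / denom
  x_on <- ref + t_on * axis
  n_off <- plane_off$normal; o_off <- plane_off$offset
  if (sum(n_off * axis) < 0) { n_off <- -n_off; o_off <- -o_off }
  sep <- sum(n_off * x_on) - o_off
  if (sep <= 0) stopf("SAC planes coincide: separation must be > 0")
  fr <- structure(list(plane_off = plane_off, plane_on = plane_on,
                       axis = axis, separation = sep,
                       depth_at_off = depth_at_off, depth_at_on = depth_at_on,
                       orientation_ref = as.numeric(orientation_ref)),
                  class = "ipl_frame")
  dref <- ipl_depth(orientation_ref, fr, check = FALSE)
  mid <- (depth_at_off + depth_at_on) / 2
  if ((depth_at_on > depth_at_off && dref <= mid) ||
      (depth_at_on < depth_at_off && dref >= mid))
    stopf(paste("orientation_ref (normalized depth %.2f) does not lie on the",
                "ON/GCL side of the frame; check plane labels"), dref)
  fr
}

angle_deg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' Normalized IPL depth of physical positions
#'
#' Signed perpendicular distance to the OFF SAC plane divided by the
#' inter-plane separation (measured along the mean normal), affinely mapped so
#' the OFF plane sits at `depth_at_off` and the ON plane at `depth_at_on`.
#' Depth increases toward the GCL.
#'
#' @param points length-3 vector or n x 3 matrix of physical positions (nm)
#' @param frame an [ipl_frame()]
#' @param check internal
#' @return numeric vector of dimensionless depths
#' @export
ipl_depth <- function(points, frame, check = TRUE) {
  p <- if (is.matrix(points) || is.data.frame(points))
    as.matrix(points)[, 1:3, drop = FALSE] else matrix(as.numeric(points), ncol = 3)
  # distance to the OFF plane along its own normal, oriented along the axis
  n_off <- frame$plane_off$normal
  o_off <- frame$plane_off$offset
  if (sum(n_off * frame$axis) < 0) { n_off <- -n_off; o_off <- -o_off }
  raw <- (drop(p %*% n_off) - o_off) / frame$separation
  frame$depth_at_off + raw * (frame$depth_at_on - frame$depth_at_off)
}

# Rodrigues rotation matrix taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {  # opposite: rotate pi about any perpendicular
    perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    k <- perp - sum(perp * u) * u; k <- k / sqrt(sum(k^2))
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    return(diag(3) + 2 * K %*% K)
  }
  k <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(k^2)); k <- k / s
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(acos(c_)) * K + (1 - c_) * (K %*% K)
}

#' Tilt-correct a volume to the SAC planes
#'
#' Applies one global rigid rotation about the volume centroid that maps the
#' frame's laminar axis (mean SAC normal) onto the z axis `(0, 0, 1)`.
#' Pairwise distances are preserved (rigid motion); normalized IPL depth is
#' invariant under the correction.
#'
#' @param forest a [skeleton_forest()]
#' @param frame an [ipl_frame()]
#' @return list(forest, frame, rotation, centroid_nm, angle_deg)
#' @export
tilt_correct <- function(forest, frame) {
  R <- rotation_between(frame$axis, c(0, 0, 1))
  allp <- do.call(rbind, lapply(forest$skeletons, node_phys, forest$scale))
  ctr <- if (is.null(allp) || !nrow(allp)) c(0, 0, 0) else colMeans(allp)
  rot_point <- function(p) {
    q <- sweep(as.matrix(p), 2, ctr)
    sweep(q %*% t(R), 2, ctr, `+`)
  }
  out <- forest
  for (k in seq_along(out$skeletons)) {
    sk <- out$skeletons[[k]]
    if (!nrow(sk$nodes)) next
    pv <- rot_point(node_phys(sk, forest$scale))
    sk$nodes$x <- pv[, 1] / forest$scale[1]
    sk$nodes$y <- pv[, 2] / forest$scale[2]
    sk$nodes$z <- pv[, 3] / forest$scale[3]
    out$skeletons[[k]] <- sk
  }
  rot_plane <- function(pl) {
    n2 <- drop(R %*% pl$normal)
    p0 <- rot_point(matrix(pl$normal * pl$offset, ncol = 3))
    plane(n2, sum(n2 * p0), pl$rms)
  }
  fr2 <- ipl_frame(rot_plane(frame$plane_off), rot_plane(frame$plane_on),
                   drop(rot_point(matrix(frame$orientation_ref, ncol = 3))),
                   frame$depth_at_off, frame$depth_at_on)
  list(forest = out, frame = fr2, rotation = R, centroid_nm = ctr,
       angle_deg = angle_deg(frame$axis, c(0, 0, 1)))
}

#' Assign a laminar zone from normalized depth
#'
#' Zones are half-open on depth: `outer_OFF` (< 0, sclerad to the OFF SAC
#' plane), `between_SAC` (\[0, 1)), `inner_ON` (\[1, sub_on)) and `sub_ON`
#' (>= sub_on, the deepest stratum toward the GCL).
#'
#' @param depth numeric vector of normalized depths
#' @param sub_on boundary splitting the inner zone (default 1.5)
#' @return character vector of zone labels
#' @export
assign_laminar_zone <- function(depth, sub_on = 1.5) {
  ifelse(depth < 0, "outer_OFF",
         ifelse(depth < 1, "between_SAC",
                ifelse(depth < sub_on, "inner_ON", "sub_ON")))
}

#' Serialize / restore an IPL frame as JSON
#'
#' Written beside pipeline outputs so every downstream table is reproducible.
#'
#' @param frame an [ipl_frame()]
#' @param path JSON file path
#' @return `path` (write) / an [ipl_frame()] (read)
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(list(
    plane_off = list(normal = frame$plane_off$normal,
                     offset = frame$plane_off$offset, rms = frame$plane_off$rms),
    plane_on = list(normal = frame$plane_on$normal,
                    offset = frame$plane_on$offset, rms = frame$plane_on$rms),
    depth_at_off = frame$depth_at_off, depth_at_on = frame$depth_at_on,
    orientation_ref = frame$orientation_ref), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_json
#' @export
read_frame_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ipl_frame(plane(j$plane_off$normal, j$plane_off$offset, j$plane_off$rms %||% NA_real_),
            plane(j$plane_on$normal, j$plane_on$offset, j$plane_on$rms %||% NA_real_),
            j$orientation_ref, j$depth_at_off, j$depth_at_on)
}
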