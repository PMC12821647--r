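#' Mobile reference-plane gaze projection
#'
#' Each 60 Hz tracker frame carries a head pose and a gaze ray. A head-anchored
#' reference plane is placed at a fixed distance along the head direction
#' (112 cm by default, roughly the screen distance of a fixed-base simulator),
#' and the gaze ray is intersected with that plane, yielding 2-D plane
#' coordinates on which oculomotor events and spatial binning operate.
#'
#' @name gaze-geometry
NULL

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the per-frame reference plane
#'
#' The plane passes through `head_position + distance * head_direction` with
#' the head direction as its normal. An orthonormal in-plane basis is completed
#' deterministically: `basis_u = normalize(normal x world_up)` with world up
#' `(0, 1, 0)` (falling back to `(1, 0, 0)` when the normal is vertical), and
#' `basis_v = normal x basis_u`.
#'
#' @param head_position numeric length-3, head position (cm).
#' @param head_direction numeric length-3, head direction; normalised internally.
#' @param distance plane distance along the head direction (cm); default 112.
#' @return A `gaze_plane` object: list with `normal`, `point`, `offset`
#'   (`D = normal . point`), `basis_u`, `basis_v`.
#' @examples
#' pl <- build_reference_plane(c(0, 0, 0), c(0, 0, 1), 112)
#' pl$point  # (0, 0, 112)
#' @export
build_reference_plane <- function(head_position, head_direction, distance = 112) {
  stopifnot(length(head_position) == 3, length(head_direction) == 3,
            is.finite(distance))
  nn <- sqrt(sum(head_direction^2))
  if (nn < 1e-12) stop("head_direction must be non-zero")
  normal <- head_direction / nn
  point <- head_position + distance * normal
  up <- c(0, 1, 0)
  u <- cross3(normal, up)
  if (sqrt(sum(u^2)) < 1e-9) u <- cross3(normal, c(1, 0, 0))
  u <- u / sqrt(sum(u^2))
  v <- cross3(normal, u)
  structure(
    list(normal = normal, point = point, offset = sum(normal * point),
         basis_u = u, basis_v = v),
    class = "gaze_plane"
  )
}

#' Intersect a gaze ray with a reference plane
#'
#' Solves the 3x3 linear system formed by the plane equation and two
#' line-membership constraints (components of `direction x (p - origin) = 0`,
#' dropping the component of largest `|direction|` so the system is always
#' full rank for a non-parallel ray). Rays parallel to the plane or lying in
#' it have `|normal . direction|` below `parallel_tol` and yield `NULL`
#' (no intersection).
#'
#' @param gaze_position numeric length-3 ray origin (cm).
#' @param gaze_direction numeric length-3 unit ray direction.
#' @param plane a [build_reference_plane()] object.
#' @param parallel_tol tolerance on `|normal . direction|`; default `1e-9`.
#' @return `NULL` if no intersection, else a list with the 3-D `point`, the
#'   ray parameter `t` (cm along the unit direction; `t <= 0` means the plane
#'   is behind the origin), and in-plane coordinates `u`, `v` (cm).
#' @export
intersect_ray_plane <- function(gaze_position, gaze_direction, plane,
                                parallel_tol = 1e-9) {
  stopifnot(inherits(plane, "gaze_plane"),
            length(gaze_position) == 3, length(gaze_direction) == 3)
  d <- gaze_direction
  o <- gaze_position
  if (abs(sum(plane$normal * d)) < parallel_tol) return(NULL)
  # rows of d x (p - o) = 0; row k involves the two components other than k
  rows <- rbind(c(0, d[3], -d[2]),
                c(-d[3], 0, d[1]),
                c(d[2], -d[1], 0))
  rhs <- c(d[3] * o[2] - d[2] * o[3],
           d[1] * o[3] - d[3] * o[1],
           d[2] * o[1] - d[1] * o[2])
  keep <- setdiff(1:3, which.max(abs(d)))
  A <- rbind(plane$normal, rows[keep, , drop = FALSE])
  b <- c(plane$offset, rhs[keep])
  p <- as.numeric(solve(A, b))
  rel <- p - plane$point
  list(point = p,
       t = sum((p - o) * d) / sum(d * d),
       u = sum(rel * plane$basis_u),
       v = sum(rel * plane$basis_v))
}

#' Project a sequence of gaze frames onto per-frame reference planes
#'
#' For every frame a distinct plane is built from that frame's head pose and
#' the gaze ray is intersected with it. Frames are dropped (but their indices
#' recorded, for window-quality accounting) when the validity flag is off,
#' either tracking quality is below `quality_threshold`, the ray is parallel
#' to the plane, or the intersection lies behind the gaze origin (`t <= 0`).
#'
#' @param frames data frame in the gaze-frames dialect (see [read_gaze_csv()]).
#' @param distance plane distance (cm), default 112.
#' @param px_per_cm pixel scale of the plane chart, default 32.
#' @param quality_threshold frames with `head_q` or `gaze_q` strictly below
#'   this are discarded; default 1.0 (only optimal-quality frames kept).
#' @param parallel_tol tolerance for the parallel-ray test.
#' @return list with `points` (tibble: `frame_index`, `t_s`, `u_cm`, `v_cm`,
#'   `u_px`, `v_px`) and `invalid_frames` (integer indices of dropped frames).
#' @export
project_frames <- function(frames, distance = 112, px_per_cm = 32,
                           quality_threshold = 1.0, parallel_tol = 1e-9) {
  req <- c("t_s", "head_x_cm", "head_y_cm", "head_z_cm",
           "headdir_x", "headdir_y", "headdir_z",
           "gazeorig_x_cm", "gazeorig_y_cm", "gazeorig_z_cm",
           "gazedir_x", "gazedir_y", "gazedir_z",
           "head_q", "gaze_q", "valid")
  miss <- setdiff(req, names(frames))
  if (length(miss)) stop("missing gaze frame columns: ", paste(miss, collapse = ", "))
  n <- nrow(frames)
  if (n == 0) {
    return(list(points = tibble::tibble(frame_index = integer(), t_s = numeric(),
                                        u_cm = numeric(), v_cm = numeric(),
                                        u_px = numeric(), v_px = numeric()),
                invalid_frames = integer()))
  }
  hd <- cbind(frames$headdir_x, frames$headdir_y, frames$headdir_z)
  hd <- hd / sqrt(rowSums(hd^2))
  hp <- cbind(frames$head_x_cm, frames$head_y_cm, frames$head_z_cm)
  go <- cbind(frames$gazeorig_x_cm, frames$gazeorig_y_cm, frames$gazeorig_z_cm)
  gd <- cbind(frames$gazedir_x, frames$gazedir_y, frames$gazedir_z)
  gd <- gd / sqrt(rowSums(gd^2))

  pt <- hp + distance * hd                       # plane point, normal = hd
  offset <- rowSums(hd * pt)
  denom <- rowSums(hd * gd)
  tt <- (offset - rowSums(hd * go)) / denom
  ok <- as.logical(frames$valid) &
    frames$head_q >= quality_threshold &
    frames$gaze_q >= quality_threshold &
    abs(denom) >= parallel_tol &
    is.finite(tt) & tt > 0

  # in-plane basis: u = normal x (0,1,0), fallback (1,0,0) when vertical
  u <- cbind(-hd[, 3], 0, hd[, 1])
  vert <- sqrt(rowSums(u^2)) < 1e-9
  if (any(vert)) {
    # normal x (1,0,0) = (0, nz, -ny)
    u[vert, ] <- cbind(0, hd[vert, 3], -hd[vert, 2])
  }
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(hd[, 2] * u[, 3] - hd[, 3] * u[, 2],
             hd[, 3] * u[, 1] - hd[, 1] * u[, 3],
             hd[, 1] * u[, 2] - hd[, 2] * u[, 1])

  p3 <- go + tt * gd
  rel <- p3 - pt
  u_cm <- rowSums(rel * u)
  v_cm <- rowSums(rel * v)
  idx <- which(ok)
  ui <- u_cm[idx]
  vi <- v_cm[idx]
  list(
    points = tibble::tibble(
      frame_index = idx,
      t_s = frames$t_s[idx],
      u_cm = ui,
      v_cm = vi,
      u_px = ui * px_per_cm,
      v_px = vi * px_per_cm
    ),
    invalid_frames = which(!ok)
  )
}
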