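# Small 3D vector helpers. All coordinates are in mm, angles in degrees at the
# user surface and radians internally; frames are right-handed.

vec3 <- function(x, y = NULL, z = NULL) {
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  stopifnot(length(v) == 3L)
  v
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < 1e-12) abort("cannot normalize a zero-length vector", class = "archolimb_geometry_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Rotation matrix for a right-handed rotation of `theta` radians about unit
# axis `a` (Rodrigues form).
rot_axis_angle <- function(a, theta) {
  a <- unit3(a)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Any rotation taking +z onto unit vector `d` (used to pose cylinder frames).
frame_from_axis <- function(d) {
  d <- unit3(d)
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x <- unit3(cross3(ref, d))
  y <- cross3(d, x)
  cbind(x, y, d)
}

# Distance from point p to the segment a-b, plus the closest point.
point_segment_closest <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  q <- a + t * ab
  list(t = t, point = q, dist = norm3(p - q))
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}
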