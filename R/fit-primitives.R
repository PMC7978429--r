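#' Least-squares sphere fit to a bone point cloud
#'
#' Fits a sphere to digitized articular-surface points (e.g. the femoral head
#' or the internal surface of the acetabulum) by the algebraic (Coope) linear
#' least-squares fit followed by one Gauss-Newton geometric refinement pass.
#' Used to place ball-and-socket hip joint centers.
#'
#' @param points A numeric matrix or data frame with three columns (x, y, z in
#'   mm), one digitized point per row. At least 4 non-coplanar points.
#' @return An object of class `sphere_primitive`: a list with `center` (length
#'   3, mm), `radius` (mm) and `rms` (root-mean-square radial residual, mm).
#' @examples
#' oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
#'              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
#' fit_sphere(oct)
#' @export
fit_sphere <- function(points) {
  P <- as_point_matrix(points)
  if (nrow(P) < 4L) {
    abort("sphere fitting needs at least 4 points", class = "archolimb_degenerate_geometry")
  }
  check_not_coplanar(P, what = "sphere")
  # Algebraic fit: |p|^2 = 2 c.p + (r^2 - |c|^2), linear in (c, d).
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  # One geometric Gauss-Newton pass on sum (|p - c| - r)^2.
  for (i in 1:2) {
    d <- sweep(P, 2, center)
    r_i <- sqrt(rowSums(d^2))
    J <- cbind(-d / r_i, -1)
    res <- r_i - radius
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    center <- center + step[1:3]
    radius <- radius + step[4]
  }
  if (radius <= 0) abort("degenerate sphere fit (non-positive radius)", class = "archolimb_degenerate_geometry")
  rms <- sqrt(mean((sqrt(rowSums(sweep(P, 2, center)^2)) - radius)^2))
  structure(list(center = unname(center), radius = unname(radius), rms = rms),
            class = "sphere_primitive")
}

#' Least-squares cylinder fit to a bone point cloud
#'
#' Fits a circular cylinder to digitized condylar points (distal femoral
#' condyles for the knee; astragalus/calcaneum surface for the ankle). The
#' axis direction is optimized so that the points projected onto the plane
#' normal to the axis fall on the best-fitting circle; the reported
#' `axis_point` is the midpoint of the points' axial extent, which is where
#' single-degree-of-freedom knee and ankle rotation centers are placed.
#'
#' @inheritParams fit_sphere
#' @param axis_hint Optional length-3 vector: the returned `axis_dir` is
#'   flipped, if needed, to have a positive dot product with this hint. Used
#'   to orient flexion-extension axes laterally.
#' @return An object of class `cylinder_primitive`: a list with `axis_point`
#'   (mm), `axis_dir` (unit vector), `radius` (mm), `half_length` (mm) and
#'   `rms` (radial residual, mm).
#' @export
fit_cylinder <- function(points, axis_hint = NULL) {
  P <- as_point_matrix(points)
  if (nrow(P) < 6L) {
    abort("cylinder fitting needs at least 6 points", class = "archolimb_degenerate_geometry")
  }
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    abort("cylinder fit is degenerate: points are (nearly) collinear",
          class = "archolimb_degenerate_geometry")
  }
  circle_obj <- function(axis) {
    B <- frame_from_axis(axis)
    uv <- Pc %*% B[, 1:2]
    cf <- fit_circle2d(uv)
    cf$rss
  }
  # Axis direction parameterized by spherical angles; try all three principal
  # directions as starts (short wide and long thin clouds both occur).
  starts <- lapply(1:3, function(k) sv$v[, k])
  best <- NULL
  for (s in starts) {
    th0 <- c(acos(max(-1, min(1, s[3]))), atan2(s[2], s[1]))
    op <- optim(th0, function(th) {
      circle_obj(c(sin(th[1]) * cos(th[2]), sin(th[1]) * sin(th[2]), cos(th[1])))
    }, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 4000))
    if (is.null(best) || op$value < best$value) best <- op
  }
  th <- best$par
  axis <- c(sin(th[1]) * cos(th[2]), sin(th[1]) * sin(th[2]), cos(th[1]))
  B <- frame_from_axis(axis)
  uv <- Pc %*% B[, 1:2]
  cf <- fit_circle2d(uv)
  w <- as.numeric(Pc %*% axis)
  if (diff(range(w)) < 1e-6 * max(cf$radius, 1)) {
    abort("cylinder fit is degenerate: points lie on a single axial ring",
          class = "archolimb_degenerate_geometry")
  }
  center3 <- ctr + B[, 1] * cf$center[1] + B[, 2] * cf$center[2]
  # Long-axis midpoint of the points' axial extent.
  wj <- as.numeric(sweep(P, 2, center3) %*% axis)
  axis_point <- center3 + axis * mean(range(wj))
  if (!is.null(axis_hint) && sum(axis * axis_hint) < 0) axis <- -axis
  rms <- sqrt(cf$rss / nrow(P))
  structure(list(axis_point = axis_point, axis_dir = axis, radius = cf$radius,
                 half_length = diff(range(wj)) / 2, rms = rms),
            class = "cylinder_primitive")
}

# Kasa algebraic circle fit with one geometric refinement; returns center,
# radius and geometric residual sum of squares.
fit_circle2d <- function(uv) {
  A <- cbind(2 * uv, 1)
  b <- rowSums(uv^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(list(center = c(0, 0), radius = 0, rss = Inf))
  center <- sol[1:2]
  radius <- sqrt(max(sol[3] + sum(center^2), 0))
  for (i in 1:2) {
    d <- sweep(uv, 2, center)
    r_i <- sqrt(rowSums(d^2))
    if (any(r_i < 1e-12)) break
    J <- cbind(-d / r_i, -1)
    res <- r_i - radius
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    center <- center + step[1:2]
    radius <- radius + step[3]
  }
  r_i <- sqrt(rowSums(sweep(uv, 2, center)^2))
  list(center = unname(center), radius = unname(radius),
       rss = sum((r_i - radius)^2))
}

as_point_matrix <- function(points) {
  P <- as.matrix(points)
  if (ncol(P) != 3L) abort("points must have three columns (x, y, z)")
  storage.mode(P) <- "double"
  if (anyNA(P)) abort("points contain missing values")
  unname(P)
}

check_not_coplanar <- function(P, what) {
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    abort(paste0(what, " fit is degenerate: points are coplanar"),
          class = "archolimb_degenerate_geometry")
  }
  invisible(TRUE)
}

#' @export
print.sphere_primitive <- function(x, ...) {
  cat(sprintf("<sphere> center (%.3f, %.3f, %.3f) mm, radius %.3f mm, rms %.2e mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms))
  invisible(x)
}

#' @export
print.cylinder_primitive <- function(x, ...) {
  cat(sprintf("<cylinder> axis point (%.3f, %.3f, %.3f) mm, dir (%.3f, %.3f, %.3f), radius %.3f mm, rms %.2e mm\n",
              x$axis_point[1], x$axis_point[2], x$axis_point[3],
              x$axis_dir[1], x$axis_dir[2], x$axis_dir[3], x$radius, x$rms))
  invisible(x)
}
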