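# Muscle-tendon path routing: straight segments between fixed (origin, via,
# insertion) points, deflected by assigned wrapping surfaces. Cylinder and
# sphere wraps use exact tangent-arc-tangent constructions (the cylinder arc
# is the geodesic of the unrolled plane); ellipsoid wraps use an iterative
# taut-path relaxation.

#' Route a muscle-tendon path at a pose
#'
#' @param model A `limb_model`.
#' @param pose A [pose()].
#' @param mtu An `mtu_path` or the name of an MTU in the model.
#' @param fk Optional precomputed [forward_kinematics()] for this pose.
#' @param arc_points Number of points used to discretize contact arcs in the
#'   returned polyline (lengths are computed in closed form, not from the
#'   discretization).
#' @return A `path_polyline`: list with `points` (world-frame polyline
#'   matrix), `length` (mm) and `wrapped` (names of engaged surfaces).
#' @export
route_path <- function(model, pose, mtu, fk = NULL, arc_points = 33L) {
  if (is.character(mtu)) {
    mtu <- model$mtus[[mtu]] %||%
      abort(paste0("no MTU named ", mtu, " in model"), class = "archolimb_config_error")
  }
  if (is.null(fk)) fk <- forward_kinematics(model, pose)
  fixed <- c(list(mtu$origin), mtu$via, list(mtu$insertion))
  W <- do.call(rbind, lapply(fixed, function(a) to_world(fk, a$segment, a$point)))
  surfaces <- lapply(mtu$wraps, function(wn) posed_surface(model, fk, model$wraps[[wn]]))
  pts <- list()
  total <- 0
  wrapped <- character()
  for (i in seq_len(nrow(W) - 1L)) {
    pieces <- list(list(a = W[i, ], b = W[i + 1L, ]))
    for (s in surfaces) {
      new_pieces <- list()
      for (pc in pieces) {
        if (!is.null(pc$arc)) { new_pieces <- c(new_pieces, list(pc)); next }
        wr <- wrap_segment(pc$a, pc$b, s, mtu$name, arc_points)
        if (is.null(wr)) {
          new_pieces <- c(new_pieces, list(pc))
        } else {
          wrapped <- union(wrapped, s$name)
          new_pieces <- c(new_pieces, wr)
        }
      }
      pieces <- new_pieces
    }
    for (pc in pieces) {
      if (!is.null(pc$arc)) {
        pts <- c(pts, list(pc$arc))
        total <- total + pc$len
      } else {
        pts <- c(pts, list(rbind(pc$a, pc$b)))
        total <- total + norm3(pc$b - pc$a)
      }
    }
  }
  allpts <- do.call(rbind, pts)
  keep <- c(TRUE, rowSums(abs(diff(allpts))) > 1e-12)
  structure(list(points = allpts[keep, , drop = FALSE], length = total,
                 wrapped = wrapped, mtu = mtu$name),
            class = "path_polyline")
}

#' @export
print.path_polyline <- function(x, ...) {
  cat(sprintf("<path_polyline> %s: length %.4f mm, %d points%s\n", x$mtu, x$length,
              nrow(x$points),
              if (length(x$wrapped)) paste0(", wrapped on ", paste(x$wrapped, collapse = ", ")) else ""))
  invisible(x)
}

posed_surface <- function(model, fk, w) {
  f <- fk[[w$segment]]
  list(name = w$name, shape = w$shape,
       center = f$t + as.numeric(f$R %*% w$center),
       axis = as.numeric(f$R %*% w$axis),
       R_seg = f$R, radius = w$radius, wrap_side = w$wrap_side)
}

# Dispatch one straight piece against one posed surface. Returns NULL when
# the surface is not engaged, otherwise a list of pieces (tangent lines and
# an arc piece carrying its exact length).
wrap_segment <- function(a, b, s, mtu_name, arc_points) {
  switch(s$shape,
    cylinder = wrap_cylinder(a, b, s, mtu_name, arc_points),
    sphere = wrap_sphere(a, b, s, mtu_name, arc_points),
    ellipsoid = wrap_ellipsoid(a, b, s, mtu_name)
  )
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# Cylinder wrap via the unrolled-plane construction. In the cylinder frame
# (z along the axis) the planar projection is a 2D tangent-arc-tangent path;
# the z coordinate varies linearly with unrolled arc length, which is the
# cylinder geodesic. `wrap_side = +1` traverses the contact arc
# counterclockwise viewed from +axis (the surface then lies right of the
# path), `-1` clockwise.
wrap_cylinder <- function(a, b, s, mtu_name, arc_points) {
  B <- frame_from_axis(s$axis)
  al <- as.numeric(t(B) %*% (a - s$center))
  bl <- as.numeric(t(B) %*% (b - s$center))
  a2 <- al[1:2]; b2 <- bl[1:2]
  R <- s$radius[1]
  da <- sqrt(sum(a2^2)); db <- sqrt(sum(b2^2))
  if (da < R - 1e-9 || db < R - 1e-9) {
    abort(paste0("MTU ", mtu_name, ": attachment lies inside wrap surface ", s$name),
          class = "archolimb_geometry_error")
  }
  side <- s$wrap_side
  cl <- point_segment_closest(c(0, 0, 0), c(a2, 0), c(b2, 0))
  on_free_side <- cross2(b2 - a2, -a2) * side >= 0
  if (cl$dist >= R && on_free_side) return(NULL)
  alpha_a <- acos(min(1, R / da))
  alpha_b <- acos(min(1, R / db))
  phi_a <- atan2(a2[2], a2[1])
  phi_b <- atan2(b2[2], b2[1])
  t1 <- phi_a + side * alpha_a
  t2 <- phi_b - side * alpha_b
  delta <- (side * (t2 - t1)) %% (2 * pi)
  if (delta > 1.75 * pi) return(NULL)  # segment passes on the far side
  l1 <- sqrt(max(da^2 - R^2, 0))
  l2 <- sqrt(max(db^2 - R^2, 0))
  arc2 <- R * delta
  P <- l1 + arc2 + l2
  dz <- bl[3] - al[3]
  z_at <- function(u) al[3] + dz * u / P  # u = unrolled arc length from a
  th <- t1 + side * seq(0, delta, length.out = arc_points)
  arc_pts_local <- cbind(R * cos(th), R * sin(th), z_at(l1 + R * (th - t1) * side))
  T1w <- as.numeric(B %*% c(R * cos(t1), R * sin(t1), z_at(l1))) + s$center
  T2w <- as.numeric(B %*% c(R * cos(t2), R * sin(t2), z_at(l1 + arc2))) + s$center
  arc_w <- sweep(arc_pts_local %*% t(B), 2, s$center, FUN = "+")
  len_total <- sqrt(P^2 + dz^2)
  scale3 <- len_total / P  # each planar piece stretches uniformly when unrolled
  list(
    list(a = a, b = T1w, arc = rbind(a, T1w), len = l1 * scale3),
    list(a = T1w, b = T2w, arc = arc_w, len = arc2 * scale3),
    list(a = T2w, b = b, arc = rbind(T2w, b), len = l2 * scale3)
  )
}

# Sphere wrap: the taut path lies in the plane through both endpoints and the
# sphere center; within that plane it is tangent-great-circle-tangent. The
# shorter of the two tangent choices is taken.
wrap_sphere <- function(a, b, s, mtu_name, arc_points) {
  C <- s$center
  R <- s$radius[1]
  da <- norm3(a - C); db <- norm3(b - C)
  if (da < R - 1e-9 || db < R - 1e-9) {
    abort(paste0("MTU ", mtu_name, ": attachment lies inside wrap surface ", s$name),
          class = "archolimb_geometry_error")
  }
  cl <- point_segment_closest(C, a, b)
  if (cl$dist >= R) return(NULL)
  n <- cross3(a - C, b - C)
  if (norm3(n) < 1e-9 * da * db) n <- cross3(a - C, if (abs((a - C)[1]) < 0.9 * da) c(1, 0, 0) else c(0, 1, 0))
  e1 <- unit3(a - C)
  e2 <- unit3(cross3(unit3(n), e1))
  a2 <- c(da, 0)
  b2 <- c(sum((b - C) * e1), sum((b - C) * e2))
  best <- NULL
  for (side in c(1, -1)) {
    alpha_a <- acos(min(1, R / da)); alpha_b <- acos(min(1, R / sqrt(sum(b2^2))))
    phi_a <- 0; phi_b <- atan2(b2[2], b2[1])
    t1 <- phi_a + side * alpha_a
    t2 <- phi_b - side * alpha_b
    delta <- (side * (t2 - t1)) %% (2 * pi)
    len <- sqrt(max(da^2 - R^2, 0)) + R * delta + sqrt(max(sum(b2^2) - R^2, 0))
    if (is.null(best) || len < best$len) best <- list(side = side, t1 = t1, delta = delta, len = len)
  }
  side <- best$side
  th <- best$t1 + side * seq(0, best$delta, length.out = arc_points)
  arc_w <- t(vapply(th, function(tt) C + R * (cos(tt) * e1 + sin(tt) * e2), numeric(3)))
  T1 <- arc_w[1, ]; T2 <- arc_w[nrow(arc_w), ]
  list(
    list(a = a, b = T1, arc = rbind(a, T1), len = norm3(T1 - a)),
    list(a = T1, b = T2, arc = arc_w, len = R * best$delta),
    list(a = T2, b = b, arc = rbind(T2, b), len = norm3(b - T2))
  )
}

# Ellipsoid wrap: iterative taut-path relaxation. A dense polyline is
# repeatedly smoothed (which shortens it) while points are projected out of
# the ellipsoid interior, converging on the taut path over the surface.
# Tolerance: 1e-4 of the mean semi-axis on the maximum point displacement.
wrap_ellipsoid <- function(a, b, s, mtu_name, n_pts = 81L, max_iter = 4000L) {
  C <- s$center
  Rm <- s$R_seg  # ellipsoid axes fixed in its segment frame
  radii <- s$radius
  to_loc <- function(p) as.numeric(t(Rm) %*% (p - C))
  to_wld <- function(p) C + as.numeric(Rm %*% p)
  q <- function(p) sum((p / radii)^2)  # <1 inside
  al <- to_loc(a); bl <- to_loc(b)
  if (q(al) < 1 || q(bl) < 1) {
    abort(paste0("MTU ", mtu_name, ": attachment lies inside wrap surface ", s$name),
          class = "archolimb_geometry_error")
  }
  tt <- seq(0, 1, length.out = 257L)
  seg_pts <- outer(1 - tt, al) + outer(tt, bl)
  if (all(rowSums(sweep(seg_pts, 2, radii, "/")^2) >= 1)) return(NULL)
  tt <- seq(0, 1, length.out = n_pts)
  P <- outer(1 - tt, al) + outer(tt, bl)
  tol <- 1e-4 * mean(radii)
  project_out <- function(P) {
    qv <- rowSums(sweep(P, 2, radii, "/")^2)
    inside <- qv < 1
    if (any(inside)) {
      P[inside, ] <- P[inside, , drop = FALSE] / sqrt(qv[inside])
    }
    P
  }
  P <- project_out(P)
  idx <- 2:(n_pts - 1L)
  for (it in seq_len(max_iter)) {
    P_new <- P
    P_new[idx, ] <- 0.5 * (P[idx - 1L, ] + P[idx + 1L, ])
    P_new <- project_out(P_new)
    move <- max(sqrt(rowSums((P_new - P)^2)))
    P <- P_new
    if (move < tol) break
  }
  W <- t(apply(P, 1, to_wld))
  len <- polyline_length(W)
  list(list(a = a, b = b, arc = W, len = len))
}
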