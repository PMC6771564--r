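# Mesh-based anterior caliber measurement. Coordinates are in nanometres.

#' Triangulated cell-surface mesh
#'
#' Minimal indexed triangle-mesh container: an n x 3 matrix of vertex
#' coordinates (nm) and an m x 3 integer matrix of vertex indices. Outward
#' per-triangle normals are computed lazily from the winding order;
#' generators in this package wind triangles counter-clockwise seen from
#' outside.
#'
#' @param vertices Numeric n x 3 matrix, nm.
#' @param triangles Integer m x 3 matrix of 1-based vertex indices.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(triangles < 1 | triangles > nrow(vertices))) {
    stop("triangle indices out of range")
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is_watertight(x)) "watertight" else "NOT watertight"))
  invisible(x)
}

#' Is every mesh edge shared by exactly two triangles?
#'
#' @param mesh A [surface_mesh()].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

triangle_geometry <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  list(a = a, e1 = e1, e2 = e2, normal = n / pmax(len, .Machine$double.xmin),
       centroid = (a + b + c_) / 3, area2 = len)
}

#' Point on a surface path at a given arclength
#'
#' Linear interpolation along an ordered polyline of on-surface points, at
#' cumulative arclength `s` from the first point.
#'
#' @param path Numeric k x 3 matrix of polyline points (nm), anterior tip
#'   first.
#' @param s Arclength from the start, nm.
#' @return Length-3 numeric point.
#' @export
point_at_arclength <- function(path, s) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 3, nrow(path) >= 2, is.numeric(s), length(s) == 1)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                         path[-nrow(path), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive path points must be distinct")
  cum <- c(0, cumsum(seg))
  if (s < 0 || s > cum[length(cum)] + 1e-9) {
    stop(sprintf("arclength %.1f nm exceeds path length %.1f nm",
                 s, cum[length(cum)]))
  }
  s <- min(s, cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  frac <- (s - cum[i]) / seg[i]
  path[i, ] + frac * (path[i + 1, ] - path[i, ])
}

# Moller-Trumbore ray/triangle intersection, vectorised over triangles.
# Returns the distances t >= 0 along the ray (NA where no hit).
ray_triangle_hits <- function(geom, origin, dir) {
  h <- cbind(dir[2] * geom$e2[, 3] - dir[3] * geom$e2[, 2],
             dir[3] * geom$e2[, 1] - dir[1] * geom$e2[, 3],
             dir[1] * geom$e2[, 2] - dir[2] * geom$e2[, 1])
  det <- rowSums(geom$e1 * h)
  s <- sweep(-geom$a, 2, origin, "+")          # origin - a
  u <- rowSums(s * h) / det
  q <- cbind(s[, 2] * geom$e1[, 3] - s[, 3] * geom$e1[, 2],
             s[, 3] * geom$e1[, 1] - s[, 1] * geom$e1[, 3],
             s[, 1] * geom$e1[, 2] - s[, 2] * geom$e1[, 1])
  v <- (dir[1] * q[, 1] + dir[2] * q[, 2] + dir[3] * q[, 3]) / det
  t <- rowSums(geom$e2 * q) / det
  eps <- 1e-9
  ok <- abs(det) > 1e-300 & u >= -eps & v >= -eps & (u + v) <= 1 + eps &
    t > 0
  t[!ok] <- NA_real_
  t
}

#' Cross-cell caliber by sphere expansion from an on-surface point
#'
#' Emulates measuring a cell's local diameter by growing a sphere centred
#' on a point of the cell surface until it meets the surface on the
#' opposite side: the first contact with the far wall lies along the
#' inward surface normal at the centre, so the caliber is obtained by
#' casting a ray from the centre along the inward normal and taking the
#' distance to the first triangle crossed from inside (outward normal
#' facing along the ray). Triangles within `exclusion_radius` of the
#' centre — the wall the centre itself sits on — are never candidates.
#' For a circular cylinder of radius R with the centre on the wall, the
#' result is the diameter 2R.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param center On-surface point (length-3, nm).
#' @param exclusion_radius Radius (nm) around the centre within which
#'   triangles are ignored as the local patch; default 300 nm.
#' @return Caliber (sphere radius at opposite-wall contact), nm.
#' @export
opposite_caliber <- function(mesh, center, exclusion_radius = 300) {
  stopifnot(inherits(mesh, "surface_mesh"), length(center) == 3)
  if (!is_watertight(mesh)) {
    stop("mesh is not watertight; refusing to measure an open surface")
  }
  geom <- triangle_geometry(mesh)
  d2 <- rowSums(sweep(geom$centroid, 2, center)^2)
  near <- which(d2 == min(d2))[1]
  # sanity: the centre should sit on (or very near) the surface
  bbox_diag <- sqrt(sum((apply(mesh$vertices, 2, max) -
                           apply(mesh$vertices, 2, min))^2))
  if (sqrt(min(d2)) > 0.05 * bbox_diag) {
    stop("center is not close to the mesh surface")
  }
  dir <- -geom$normal[near, ]                  # inward surface normal
  t_hit <- ray_triangle_hits(geom, center, dir)
  local <- d2 <= exclusion_radius^2
  facing <- geom$normal %*% dir > 0            # crossed from inside
  t_hit[local | !facing] <- NA_real_
  if (all(is.na(t_hit))) {
    stop("no opposite wall found along the inward normal")
  }
  min(t_hit, na.rm = TRUE)
}

#' Anterior caliber: cross-cell width a fixed arclength from the tip
#'
#' Walks `arclength` (default 2 µm) from the anterior tip along the
#' on-surface path that follows the flagellum, then measures the caliber
#' there by [opposite_caliber()]. This is the measurement that separates
#' the non-tapered anterior of new-flagellum daughters from the tapered
#' anterior of old-flagellum daughters.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param path Anterior path: k x 3 matrix from the tip running posterior.
#' @param arclength Distance along the path, nm (default 2000 = 2 µm).
#' @param exclusion_radius Passed to [opposite_caliber()].
#' @return Caliber in nm.
#' @export
anterior_caliber <- function(mesh, path, arclength = 2000,
                             exclusion_radius = 300) {
  center <- point_at_arclength(path, arclength)
  opposite_caliber(mesh, center, exclusion_radius = exclusion_radius)
}
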