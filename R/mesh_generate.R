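#' Analytic tapered-tube mesh with an on-surface anterior path
#'
#' Builds a watertight surface of revolution around the z axis with radius
#' profile `r(z)` on `[0, length]`, closed by an apex or a disk fan at each
#' end, plus the meridian polyline from the anterior tip (z = 0) running
#' posteriorly along the surface — the path used for anterior-caliber
#' measurement. Because the radius profile is analytic, the true caliber
#' `2 r(z)` is available for any point, making these meshes exact fixtures
#' for the sphere-expansion measurement: profiles can emulate the
#' non-tapered anterior of a new-flagellum daughter or the tapered anterior
#' of an old-flagellum daughter.
#'
#' @param radius_fun Function `r(z)` in nm, positive on `(0, length]`
#'   (may be 0 at the ends, giving an apex).
#' @param length Tube length along z, nm.
#' @param n_axial Number of axial sample intervals.
#' @param n_circ Number of circumferential segments.
#' @return List with `mesh` (a [surface_mesh()]), `path` (meridian polyline,
#'   anterior tip first), `radius_fun`, and `z_of_arclength`, a function
#'   mapping arclength along the path to axial position z.
#' @examples
#' tube <- generate_tapered_tube(function(z) rep(450, length(z)), 6000)
#' anterior_caliber(tube$mesh, tube$path)  # ~900 nm: cylinder diameter
#' @export
generate_tapered_tube <- function(radius_fun, length, n_axial = 120L,
                                  n_circ = 48L) {
  stopifnot(is.function(radius_fun), length > 0, n_axial >= 4, n_circ >= 8)
  z <- seq(0, length, length.out = n_axial + 1L)
  r <- radius_fun(z)
  if (length(r) == 1L) r <- rep(r, length(z))
  if (any(!is.finite(r)) || any(r < 0) || any(r[-c(1, length(r))] <= 0)) {
    stop("radius profile must be positive on the interior of (0, length]")
  }
  theta <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  apex_lo <- r[1] < 1e-9
  apex_hi <- r[length(r)] < 1e-9
  ring_z <- z
  ring_r <- r
  if (apex_lo) { ring_z <- ring_z[-1]; ring_r <- ring_r[-1] }
  if (apex_hi) { n <- length(ring_z); ring_z <- ring_z[-n]; ring_r <- ring_r[-n] }
  n_ring <- length(ring_z)
  verts <- do.call(rbind, lapply(seq_len(n_ring), function(i) {
    cbind(ring_r[i] * cos(theta), ring_r[i] * sin(theta), ring_z[i])
  }))
  ring_idx <- function(i) ((i - 1L) * n_circ) + seq_len(n_circ)
  tris <- list()
  nxt <- function(j) j %% n_circ + 1L
  # side quads, wound counter-clockwise seen from outside (+r direction)
  for (i in seq_len(n_ring - 1L)) {
    lo <- ring_idx(i); hi <- ring_idx(i + 1L)
    for (j in seq_len(n_circ)) {
      tris[[length(tris) + 1L]] <- c(lo[j], hi[nxt(j)], hi[j])
      tris[[length(tris) + 1L]] <- c(lo[j], lo[nxt(j)], hi[nxt(j)])
    }
  }
  # anterior closure at z = 0 (outward normal -z)
  if (apex_lo) {
    verts <- rbind(verts, c(0, 0, 0))
    apex <- nrow(verts)
    lo <- ring_idx(1L)
    for (j in seq_len(n_circ)) {
      tris[[length(tris) + 1L]] <- c(apex, lo[nxt(j)], lo[j])
    }
  } else {
    verts <- rbind(verts, c(0, 0, ring_z[1]))
    cen <- nrow(verts)
    lo <- ring_idx(1L)
    for (j in seq_len(n_circ)) {
      tris[[length(tris) + 1L]] <- c(cen, lo[nxt(j)], lo[j])
    }
  }
  # posterior closure at z = length (outward normal +z)
  if (apex_hi) {
    verts <- rbind(verts, c(0, 0, length))
    apex <- nrow(verts)
    hi <- ring_idx(n_ring)
    for (j in seq_len(n_circ)) {
      tris[[length(tris) + 1L]] <- c(apex, hi[j], hi[nxt(j)])
    }
  } else {
    verts <- rbind(verts, c(0, 0, ring_z[n_ring]))
    cen <- nrow(verts)
    hi <- ring_idx(n_ring)
    for (j in seq_len(n_circ)) {
      tris[[length(tris) + 1L]] <- c(cen, hi[j], hi[nxt(j)])
    }
  }
  mesh <- surface_mesh(verts, do.call(rbind, tris))

  # meridian path at theta = 0, from the anterior tip posteriorly
  path <- cbind(r, 0, z)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                         path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  z_of_arclength <- function(s) {
    stopifnot(s >= 0, s <= cum[length(cum)] + 1e-9)
    stats::approx(cum, path[, 3], xout = min(s, cum[length(cum)]))$y
  }
  list(mesh = mesh, path = path, radius_fun = radius_fun,
       z_of_arclength = z_of_arclength)
}

#' Linear-taper radius profile
#'
#' Convenience profile `r(z) = r_tip + (r_base - r_tip) * z / length`,
#' for building tubes whose caliber at a chosen arclength is known
#' analytically.
#'
#' @param r_tip Radius at the anterior tip (z = 0), nm.
#' @param r_base Radius at the posterior end, nm.
#' @param length Tube length, nm.
#' @return A function of z.
#' @export
linear_taper <- function(r_tip, r_base, length) {
  force(r_tip); force(r_base); force(length)
  function(z) r_tip + (r_base - r_tip) * z / length
}
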