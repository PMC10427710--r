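# Planar polygon primitives used by the segmentation module. Rings are
# matrices of vertices (x, y) in order, not closed (last vertex != first).

poly_close <- function(v) rbind(v, v[1, , drop = FALSE])

poly_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Unsigned polygon area (shoelace formula)
#' @param v vertex matrix (two columns, ordered ring, not closed)
#' @return area in squared coordinate units
#' @keywords internal
poly_area <- function(v) abs(poly_area_signed(v))

poly_perimeter <- function(v) {
  d <- diff(poly_close(v))
  sum(sqrt(rowSums(d^2)))
}

poly_centroid <- function(v) {
  a <- poly_area_signed(v)
  if (abs(a) < 1e-300) return(colMeans(v))
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

poly_is_convex <- function(v) {
  n <- nrow(v)
  if (n < 4) return(TRUE)
  vc <- rbind(v, v[1:2, , drop = FALSE])
  cr <- vapply(seq_len(n), function(i) {
    a <- vc[i, ]; b <- vc[i + 1, ]; d <- vc[i + 2, ]
    (b[1] - a[1]) * (d[2] - b[2]) - (b[2] - a[2]) * (d[1] - b[1])
  }, numeric(1))
  all(cr >= -1e-12 * max(abs(v))) || all(cr <= 1e-12 * max(abs(v)))
}

seg_intersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

# ring validity: >= 3 vertices, finite, positive area, simple
check_ring <- function(v, id = "<polygon>") {
  if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 3) {
    abort(sprintf("polygon '%s': ring needs >= 3 two-dimensional vertices", id))
  }
  if (any(!is.finite(v))) abort(sprintf("polygon '%s': non-finite vertex", id))
  if (nrow(v) > 3 && isTRUE(all(v[1, ] == v[nrow(v), ]))) {
    v <- v[-nrow(v), , drop = FALSE]  # tolerate closed rings on input
  }
  if (poly_area(v) <= 0) abort(sprintf("polygon '%s': zero or degenerate area", id))
  n <- nrow(v)
  vc <- poly_close(v)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (seg_intersects(vc[i, ], vc[i + 1, ], vc[j, ], vc[j + 1, ])) {
        abort(sprintf("polygon '%s': self-intersecting ring (edges %d and %d)",
                      id, i, j))
      }
    }
  }
  v
}

# Sutherland-Hodgman clip of an arbitrary simple subject ring against a
# CONVEX clip ring. The output ring may contain degenerate zero-width
# bridges when the true intersection is disconnected; its shoelace area is
# still the exact intersection area, which is all callers use.
clip_convex <- function(subject, clip) {
  if (poly_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])  # >=0 is inside (left)
    n <- nrow(out)
    nxt <- c(2:n, 1)
    res <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      j <- nxt[i]
      ci <- side[i] >= 0; cj <- side[j] >= 0
      if (ci) res <- rbind(res, out[i, ])
      if (xor(ci, cj)) {
        t <- side[i] / (side[i] - side[j])
        res <- rbind(res, out[i, ] + t * (out[j, ] - out[i, ]))
      }
    }
    out <- res
  }
  if (nrow(out) < 3) NULL else out
}

# O(n^2) ear clipping triangulation of a simple ring (used so non-convex
# polygons can serve as clip regions; triangles partition the ring)
ear_clip <- function(v) {
  if (poly_area_signed(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  idx <- seq_len(nrow(v))
  tris <- list()
  guard <- 0
  while (length(idx) > 3) {
    guard <- guard + 1
    if (guard > 10000) abort("ear clipping failed to converge (degenerate ring?)")
    n <- length(idx)
    found <- FALSE
    for (k in seq_len(n)) {
      i0 <- idx[if (k == 1) n else k - 1]
      i1 <- idx[k]
      i2 <- idx[if (k == n) 1 else k + 1]
      a <- v[i0, ]; b <- v[i1, ]; cc <- v[i2, ]
      cross <- (b[1] - a[1]) * (cc[2] - b[2]) - (b[2] - a[2]) * (cc[1] - b[1])
      if (cross <= 1e-14 * max(abs(v), 1)) next  # reflex or degenerate
      tri <- rbind(a, b, cc)
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others)) {
        inside <- cpp_points_in_polygon(v[others, , drop = FALSE], tri)
        # vertices exactly on the ear edges are tolerated
        strictly_in <- inside & cpp_dist_to_chain(v[others, , drop = FALSE],
                                                  poly_close(tri)) > 1e-9
        if (any(strictly_in)) next
      }
      tris[[length(tris) + 1]] <- tri
      idx <- idx[-k]
      found <- TRUE
      break
    }
    if (!found) abort("ear clipping failed (non-simple ring?)")
  }
  tris[[length(tris) + 1]] <- v[idx, , drop = FALSE]
  tris
}

#' Exact intersection area of two simple polygons
#'
#' Clips against the convex polygon directly; a non-convex clip region is
#' triangulated first (the triangles partition it, so areas add).
#' @param a,b vertex matrices (ordered simple rings)
#' @return intersection area
#' @keywords internal
poly_intersection_area <- function(a, b) {
  if (poly_is_convex(b)) {
    out <- clip_convex(a, b)
    return(if (is.null(out)) 0 else poly_area(out))
  }
  if (poly_is_convex(a)) {
    out <- clip_convex(b, a)
    return(if (is.null(out)) 0 else poly_area(out))
  }
  sum(vapply(ear_clip(b), function(tri) {
    out <- clip_convex(a, tri)
    if (is.null(out)) 0 else poly_area(out)
  }, numeric(1)))
}

bbox_overlaps <- function(a, b) {
  !(max(a[, 1]) < min(b[, 1]) || max(b[, 1]) < min(a[, 1]) ||
      max(a[, 2]) < min(b[, 2]) || max(b[, 2]) < min(a[, 2]))
}

# Area of rescue ∩ (union of primaries). Pairwise inclusion-exclusion:
# exact whenever no point is covered by three or more primary polygons
# (segmentation outputs are near-disjoint; generator primaries are disjoint).
area_vs_union <- function(rescue, primaries) {
  cand <- keep(primaries, ~ bbox_overlaps(rescue, .x))
  if (!length(cand)) return(0)
  a1 <- vapply(cand, function(p) poly_intersection_area(rescue, p), numeric(1))
  total <- sum(a1)
  live <- which(a1 > 0)
  if (length(live) > 1) {
    for (ii in seq_along(live)) {
      for (jj in seq_along(live)) {
        if (jj <= ii) next
        pi_ <- cand[[live[ii]]]; pj <- cand[[live[jj]]]
        if (!bbox_overlaps(pi_, pj)) next
        ri <- if (poly_is_convex(pi_)) clip_convex(rescue, pi_) else NULL
        if (is.null(ri)) {
          # fall back: intersect the pair first, then with rescue
          # (only reachable for non-convex primaries)
          pij <- poly_intersection_area(pi_, pj)
          if (pij > 0) {
            warn("overlapping non-convex primary polygons: union overlap approximated pairwise")
          }
          next
        }
        total <- total - poly_intersection_area(ri, pj)
      }
    }
  }
  max(0, min(total, poly_area(rescue)))
}
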