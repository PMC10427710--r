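#' Alpha-extreme points of a planar point set
#'
#' A point is alpha-extreme when an open ball of radius `alpha` exists with
#' the point on its boundary and no other input point inside. Alpha-extreme
#' points are the vertex set of the alpha-shape; as `alpha` grows they tend
#' to the convex-hull vertices, and for `alpha` below half the minimum
#' pairwise distance every point is extreme.
#'
#' @param points a two-column matrix or a data frame with columns `x`, `y`
#'   (coordinates in micrometers).
#' @param alpha ball radius in the same units (default 100, a tight boundary
#'   estimate for retinal sections at native scale).
#' @return an integer vector of row indices of the extreme points.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
#' alpha_extreme_points(sq, alpha = 100)  # corners only
alpha_extreme_points <- function(points, alpha = 100) {
  m <- as_xy_matrix(points)
  check_number(alpha, "alpha")
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (nrow(m) < 3) abort("need at least 3 points")
  if (collinear_points(m)) abort("points must not all be collinear")
  which(cpp_alpha_extreme(m, alpha))
}

collinear_points <- function(m) {
  if (nrow(m) < 3) return(TRUE)
  v <- sweep(m[-1, , drop = FALSE], 2, m[1, ])
  cr <- v[, 1] * v[1, 2] - v[, 2] * v[1, 1]
  all(abs(cr) < 1e-10 * max(1, max(abs(m))))
}

#' Build the alpha-shape of a point set
#'
#' Edges connect pairs of alpha-extreme points that admit an empty open ball
#' of radius `alpha` through both. Each edge records its two candidate
#' witness ball centers and which of them are empty; the witness geometry is
#' what later distinguishes apical from basal boundary arcs. Only the largest
#' closed component (cycle) of the edge graph is retained, mirroring the
#' single outer boundary of one tissue section.
#'
#' @inheritParams alpha_extreme_points
#' @param keep_all_components keep every closed component instead of only the
#'   largest (useful for fixtures with several rings).
#' @return an object of class `alpha_shape`: list with `alpha`, `points`,
#'   `extreme` (indices), and `edges` (tibble: `i`, `j`, witness centers
#'   `cx`, `cy` of the empty ball(s), `both_empty`).
#' @export
build_alpha_shape <- function(points, alpha = 100, keep_all_components = FALSE) {
  m <- as_xy_matrix(points)
  ext <- alpha_extreme_points(m, alpha)
  em <- cpp_alpha_edges(m, alpha, as.integer(ext))
  if (nrow(em) == 0) {
    abort(sprintf("no alpha-shape edges at alpha = %g: points too sparse for this alpha",
                  alpha))
  }
  edges <- tibble(
    i = as.integer(em[, "i"]), j = as.integer(em[, "j"]),
    c1x = em[, "c1x"], c1y = em[, "c1y"], empty1 = em[, "empty1"] > 0,
    c2x = em[, "c2x"], c2y = em[, "c2y"], empty2 = em[, "empty2"] > 0
  )
  # canonical witness: the (or an) empty ball center
  edges <- edges |>
    mutate(
      cx = ifelse(.data$empty1, .data$c1x, .data$c2x),
      cy = ifelse(.data$empty1, .data$c1y, .data$c2y),
      cx2 = ifelse(.data$empty1 & .data$empty2, .data$c2x, NA_real_),
      cy2 = ifelse(.data$empty1 & .data$empty2, .data$c2y, NA_real_),
      both_empty = .data$empty1 & .data$empty2
    ) |>
    select("i", "j", "cx", "cy", "cx2", "cy2", "both_empty")
  comp <- edge_components(edges, nrow(m))
  closed <- keep(comp, function(rows) component_is_closed(edges, rows))
  if (!length(closed)) {
    abort(sprintf("no closed boundary component at alpha = %g: points too sparse for this alpha",
                  alpha))
  }
  if (keep_all_components) {
    keep_rows <- sort(unlist(closed))
  } else {
    keep_rows <- closed[[which.max(lengths(closed))]]
  }
  structure(
    list(alpha = alpha, points = m, extreme = ext,
         edges = edges[keep_rows, , drop = FALSE],
         all_edges = edges),
    class = "alpha_shape"
  )
}

# connected components of the edge graph, as lists of edge-row indices
edge_components <- function(edges, n_points) {
  if (nrow(edges) == 0) return(list())
  verts <- sort(unique(c(edges$i, edges$j)))
  vid <- match(seq_len(n_points), verts)
  parent <- seq_along(verts)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(vid[edges$i[r]]); b <- find(vid[edges$j[r]])
    if (a != b) parent[a] <- b
  }
  comp_of_edge <- vapply(seq_len(nrow(edges)), function(r) find(vid[edges$i[r]]),
                         integer(1))
  split(seq_len(nrow(edges)), comp_of_edge)
}

# a component is closed when every one of its vertices has even degree >= 2
# (a simple cycle has all degrees exactly 2; dangling chains have degree-1 ends)
component_is_closed <- function(edges, rows) {
  deg <- table(c(edges$i[rows], edges$j[rows]))
  all(deg >= 2 & deg %% 2 == 0)
}

#' Least-squares tissue center of a point set
#'
#' Arc-shaped sections are assumed to curve around a hypothetical tissue
#' center; the center of curvature is estimated by an algebraic (Kasa)
#' least-squares circle fit of all centroids. Degenerate fits (collinear or
#' near-collinear input) fall back to the point centroid with a warning.
#'
#' @inheritParams alpha_extreme_points
#' @return a length-2 numeric vector (x, y).
#' @export
estimate_tissue_center <- function(points) {
  m <- as_xy_matrix(points)
  if (nrow(m) < 3) abort("need at least 3 points")
  if (collinear_points(m)) {
    warn("degenerate circle fit; falling back to the point centroid")
    return(colMeans(m))
  }
  ctr <- colMeans(m)
  x <- m[, 1] - ctr[1]; y <- m[, 2] - ctr[2]
  z <- x^2 + y^2
  Mxx <- mean(x^2); Myy <- mean(y^2); Mxy <- mean(x * y)
  Mxz <- mean(x * z); Myz <- mean(y * z); Mzz <- mean(z^2)
  Mz <- Mxx + Myy
  cov_xy <- Mxx * Myy - Mxy^2
  var_z <- Mzz - Mz^2
  a3 <- 4 * Mz
  a2 <- -3 * Mz^2 - Mzz
  a1 <- var_z * Mz + 4 * cov_xy * Mz - Mxz^2 - Myz^2
  a0 <- Mxz * (Mxz * Myy - Myz * Mxy) + Myz * (Myz * Mxx - Mxz * Mxy) -
    var_z * cov_xy
  # Newton iteration from 0 for the smallest positive root (Taubin fit)
  eta <- 0
  for (it in 1:50) {
    p <- a0 + eta * (a1 + eta * (a2 + eta * a3))
    dp <- a1 + eta * (2 * a2 + 3 * a3 * eta)
    if (!is.finite(p) || !is.finite(dp) || dp == 0) break
    step <- p / dp
    eta <- eta - step
    if (abs(step) < 1e-14 * max(1, abs(eta))) break
  }
  det <- eta^2 - eta * Mz + cov_xy
  if (!is.finite(det) || abs(det) < 1e-14 * max(1, Mz^2)) {
    warn("degenerate circle fit; falling back to the point centroid")
    return(ctr)
  }
  a <- (Mxz * (Myy - eta) - Myz * Mxy) / det / 2
  b <- (Myz * (Mxx - eta) - Mxz * Mxy) / det / 2
  c(a + ctr[1], b + ctr[2])
}

#' Split alpha-shape edges into apical, basal and lateral boundary chains
#'
#' An edge is apical when its empty witness ball lies radially farther from
#' the tissue center than the edge midpoint (the arc bulges outward), basal
#' when nearer (the arc bulges inward). Edges whose midpoints fall in the
#' extreme angular tails of the section are labeled lateral (section cut
#' ends carry no laminar information). Isolated label disagreements along the
#' chain are corrected by single-pass majority smoothing, an automated stand-in
#' for manual curation of a handful of mislabeled arcs.
#'
#' @param shape an [build_alpha_shape()] result.
#' @param tissue_center length-2 numeric; see [estimate_tissue_center()].
#' @param lateral_fraction fraction of the section's angular extent excluded
#'   at each end (default 0.025).
#' @return an object of class `boundary_chains`: list with `apical`, `basal`
#'   and `lateral` segment matrices (columns x1, y1, x2, y2, in chain order),
#'   `edges` (tibble with per-edge `role`), and `tissue_center`. Contiguous
#'   polylines for export come from [chain_polylines()].
#' @export
classify_boundary_edges <- function(shape, tissue_center,
                                    lateral_fraction = 0.025) {
  stopifnot(inherits(shape, "alpha_shape"))
  check_number(lateral_fraction, "lateral_fraction", 0, 0.49)
  ctr <- as.numeric(tissue_center)
  if (length(ctr) != 2 || any(!is.finite(ctr))) {
    abort("`tissue_center` must be a finite length-2 point")
  }
  edges <- shape$edges
  if (any(!is.finite(edges$cx))) abort("edges are missing witness centers")
  pts <- shape$points
  mx <- (pts[edges$i, 1] + pts[edges$j, 1]) / 2
  my <- (pts[edges$i, 2] + pts[edges$j, 2]) / 2
  r_mid <- sqrt((mx - ctr[1])^2 + (my - ctr[2])^2)
  r_wit <- sqrt((edges$cx - ctr[1])^2 + (edges$cy - ctr[2])^2)
  lab <- ifelse(r_wit > r_mid, "apical", "basal")
  # when both witness balls are empty the edge bounds a thin protrusion and
  # the radial rule is ambiguous: leave it NA for the smoothing pass
  lab[edges$both_empty] <- NA

  # order edges along the closed chain, then mark the angular tails lateral
  ord <- order_chain(edges)
  theta <- atan2(my - ctr[2], mx - ctr[1])
  span <- angular_span(theta)
  rel <- ((theta - span$min) %% (2 * pi)) / span$width
  lateral <- rel < lateral_fraction | rel > 1 - lateral_fraction
  lab[lateral] <- "lateral"

  lab <- smooth_labels(lab, ord)
  edges$role <- lab
  edges$mid_x <- mx
  edges$mid_y <- my
  seg_of <- function(role) {
    rows <- ord[edges$role[ord] == role]
    if (!length(rows)) return(NULL)
    cbind(pts[edges$i[rows], 1], pts[edges$i[rows], 2],
          pts[edges$j[rows], 1], pts[edges$j[rows], 2])
  }
  structure(
    list(apical = seg_of("apical"), basal = seg_of("basal"),
         lateral = seg_of("lateral"),
         edges = edges, order = ord, tissue_center = ctr),
    class = "boundary_chains"
  )
}

#' Contiguous boundary polylines of one role
#'
#' Stitches a role's boundary segments into one polyline per connected run
#' (lateral gaps split the chain); used for GeoJSON export and plotting.
#' Distance computations always use the raw segment sets.
#'
#' @param chains a [classify_boundary_edges()] result.
#' @param role `"apical"`, `"basal"` or `"lateral"`.
#' @return list of polyline matrices.
#' @export
chain_polylines <- function(chains, role = c("apical", "basal", "lateral")) {
  role <- match.arg(role)
  segs <- chains[[role]]
  if (is.null(segs)) return(list())
  runs <- list()
  cur <- segs[1, , drop = FALSE]
  out <- list(rbind(cur[, 1:2], cur[, 3:4]))
  if (nrow(segs) > 1) {
    for (r in 2:nrow(segs)) {
      s <- segs[r, ]
      last <- out[[length(out)]]
      tail_pt <- last[nrow(last), ]
      head_pt <- last[1, ]
      if (isTRUE(all(abs(tail_pt - s[1:2]) < 1e-9))) {
        out[[length(out)]] <- rbind(last, s[3:4])
      } else if (isTRUE(all(abs(tail_pt - s[3:4]) < 1e-9))) {
        out[[length(out)]] <- rbind(last, s[1:2])
      } else if (isTRUE(all(abs(head_pt - s[3:4]) < 1e-9))) {
        out[[length(out)]] <- rbind(s[1:2], last)
      } else if (isTRUE(all(abs(head_pt - s[1:2]) < 1e-9))) {
        out[[length(out)]] <- rbind(s[3:4], last)
      } else {
        out[[length(out) + 1]] <- rbind(s[1:2], s[3:4])
      }
    }
  }
  out
}

# walk the (cycle) edge list into a consistent traversal order
order_chain <- function(edges) {
  n <- nrow(edges)
  adj <- list()
  for (r in seq_len(n)) {
    for (v in c(edges$i[r], edges$j[r])) {
      key <- as.character(v)
      adj[[key]] <- c(adj[[key]], r)
    }
  }
  used <- logical(n)
  ord <- integer(0)
  cur <- 1L
  cur_v <- edges$i[1]
  for (step in seq_len(n)) {
    ord <- c(ord, cur)
    used[cur] <- TRUE
    nxt_v <- if (edges$i[cur] == cur_v) edges$j[cur] else edges$i[cur]
    cands <- adj[[as.character(nxt_v)]]
    cands <- cands[!used[cands]]
    if (!length(cands)) break
    cur <- cands[1]
    cur_v <- nxt_v
  }
  c(ord, setdiff(seq_len(n), ord))
}

angular_span <- function(theta) {
  # find the largest angular gap; the section occupies its complement
  ts <- sort(theta)
  gaps <- diff(c(ts, ts[1] + 2 * pi))
  k <- which.max(gaps)
  start <- if (k == length(ts)) ts[1] else ts[k + 1]
  width <- 2 * pi - gaps[k]
  list(min = start, width = max(width, 1e-9))
}

# single-pass majority smoothing along the chain: an edge whose two chain
# neighbours agree with each other but not with it takes their label
smooth_labels <- function(lab, ord) {
  n <- length(ord)
  if (n < 3) return(lab)
  orig <- lab[ord]
  out <- orig
  for (k in seq_len(n)) {
    prev <- orig[if (k == 1) n else k - 1]
    nxt <- orig[if (k == n) 1 else k + 1]
    if (!is.na(prev) && !is.na(nxt) && prev == nxt && prev != "lateral" &&
        (is.na(orig[k]) || (orig[k] != prev && orig[k] != "lateral"))) {
      out[k] <- prev
    }
  }
  # any remaining NA adopts its previous non-lateral neighbour
  for (k in seq_len(n)) {
    if (is.na(out[k])) {
      prev <- out[if (k == 1) n else k - 1]
      out[k] <- if (!is.na(prev) && prev != "lateral") prev else "basal"
    }
  }
  res <- lab
  res[ord] <- out
  res
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("<alpha_shape> alpha = %g, %d points, %d extreme, %d edges in largest closed component\n",
              x$alpha, nrow(x$points), length(x$extreme), nrow(x$edges)))
  invisible(x)
}

#' @export
print.boundary_chains <- function(x, ...) {
  tab <- table(x$edges$role)
  cat(sprintf("<boundary_chains> %s; tissue center (%.1f, %.1f)\n",
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              x$tissue_center[1], x$tissue_center[2]))
  invisible(x)
}
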