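# Independent brute-force oracles. These deliberately use different
# algorithms from the package internals: the extreme-point oracle tests
# every arc endpoint against every blocking disk (the package sweeps sorted
# intervals); the edge oracle enumerates all pairs against all points; the
# minimum-enclosing-circle oracle enumerates all pair/triple circles.

# p is alpha-extreme iff the circle of candidate ball centers around p is not
# fully covered by the open forbidden arcs of the other points. A finite
# union of open arcs fails to cover the circle iff some arc endpoint is
# uncovered (or there are no arcs at all).
oracle_alpha_extreme_one <- function(pts, i, alpha) {
  p <- pts[i, ]
  v <- sweep(pts[-i, , drop = FALSE], 2, p)
  d <- sqrt(rowSums(v^2))
  sel <- d > 0 & d < 2 * alpha
  if (!any(sel)) return(TRUE)
  phi <- atan2(v[sel, 2], v[sel, 1])
  w <- acos(pmin(1, d[sel] / (2 * alpha)))
  ends <- c(phi - w, phi + w)
  covered_by_any <- vapply(ends, function(e) {
    any(cos(e - phi) > d[sel] / (2 * alpha) + 1e-12)
  }, logical(1))
  any(!covered_by_any)
}

oracle_alpha_extreme <- function(pts, alpha) {
  which(vapply(seq_len(nrow(pts)), function(i)
    oracle_alpha_extreme_one(pts, i, alpha), logical(1)))
}

# all unordered pairs admitting an empty open witness ball of radius alpha
oracle_alpha_edges <- function(pts, alpha) {
  n <- nrow(pts)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dvec <- pts[j, ] - pts[i, ]
      d <- sqrt(sum(dvec^2))
      if (d == 0 || d >= 2 * alpha) next
      mid <- (pts[i, ] + pts[j, ]) / 2
      h <- sqrt(max(0, alpha^2 - d^2 / 4))
      perp <- c(-dvec[2], dvec[1]) / d
      ok <- FALSE
      for (sgn in c(1, -1)) {
        ctr <- mid + sgn * h * perp
        dd <- sqrt(rowSums(sweep(pts[-c(i, j), , drop = FALSE], 2, ctr)^2))
        if (all(dd >= alpha - 1e-9 * alpha)) { ok <- TRUE; break }
      }
      if (ok) out <- rbind(out, c(i, j))
    }
  }
  out
}

circumcircle <- function(a, b, cc) {
  d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(cc^2)
  ux <- (a2 * (b[2] - cc[2]) + b2 * (cc[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (cc[1] - b[1]) + b2 * (a[1] - cc[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, sqrt(sum((a - c(ux, uy))^2)))
}

# exhaustive minimum enclosing circle: best circle over all point pairs
# (as diameter) and all triples (circumcircle) that contains every point
oracle_mec <- function(pts) {
  n <- nrow(pts)
  best <- c(pts[1, ], 0)
  if (n == 1) return(best)
  best <- NULL
  contains_all <- function(c3) {
    all(sqrt(rowSums(sweep(pts, 2, c3[1:2])^2)) <= c3[3] * (1 + 1e-10) + 1e-10)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      c3 <- c((pts[i, ] + pts[j, ]) / 2, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
      if (contains_all(c3) && (is.null(best) || c3[3] < best[3])) best <- c3
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          c3 <- circumcircle(pts[i, ], pts[j, ], pts[k, ])
          if (!is.null(c3) && contains_all(c3) &&
              (is.null(best) || c3[3] < best[3])) best <- c3
        }
      }
    }
  }
  best
}

# axis-aligned rectangle intersection area (closed form)
oracle_rect_intersection <- function(r1, r2) {
  # rectangles as c(x1, y1, x2, y2)
  w <- max(0, min(r1[3], r2[3]) - max(r1[1], r2[1]))
  h <- max(0, min(r1[4], r2[4]) - max(r1[2], r2[2]))
  w * h
}

rect_poly <- function(r) {
  cbind(c(r[1], r[3], r[3], r[1]), c(r[2], r[2], r[4], r[4]))
}

# discretized point-to-polyline distance (dense sampling along segments)
oracle_dist_to_chain <- function(p, chain, n_samp = 20000) {
  best <- Inf
  for (s in seq_len(nrow(chain) - 1)) {
    t <- seq(0, 1, length.out = n_samp)
    px <- chain[s, 1] + t * (chain[s + 1, 1] - chain[s, 1])
    py <- chain[s, 2] + t * (chain[s + 1, 2] - chain[s, 2])
    best <- min(best, min(sqrt((px - p[1])^2 + (py - p[2])^2)))
  }
  best
}

# hypergeometric upper-tail probability P(X >= k), X ~ Hyper(N, K, n)
oracle_hyper_tail <- function(k, N, K, n) {
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

# textbook Pearson correlation
oracle_pcc <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
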