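#' Minimum distance from points to a boundary polyline
#'
#' Exact minimum over the chain's segments of the point-to-segment distance
#' (perpendicular foot when it falls inside the segment, nearest endpoint
#' otherwise).
#'
#' @param points a two-column matrix or data frame with `x`, `y` (micrometers).
#' @param chain a polyline (matrix of ordered vertices, two columns) or an
#'   explicit segment set (four columns: x1, y1, x2, y2).
#' @return numeric vector of distances, one per point.
#' @export
distance_to_chain <- function(points, chain) {
  m <- as_xy_matrix(points)
  cpp_dist_to_segments(m, as_segments(chain))
}

as_segments <- function(chain) {
  if (is.null(chain) || !is.matrix(chain)) {
    abort("`chain` must be a polyline or segment matrix with at least one segment")
  }
  if (ncol(chain) == 4) {
    if (nrow(chain) < 1) abort("`chain` has no segments")
    return(chain)
  }
  if (ncol(chain) == 2) {
    if (nrow(chain) < 2) abort("`chain` must have at least one segment")
    n <- nrow(chain)
    return(cbind(chain[-n, 1], chain[-n, 2], chain[-1, 1], chain[-1, 2]))
  }
  abort("`chain` must have 2 (polyline) or 4 (segments) columns")
}

#' Normalized laminar depth of cells between two boundary chains
#'
#' For each cell the perpendicular distances to the apical and basal boundary
#' chains are computed and combined into the dimensionless depth ratio that
#' normalizes layer thickness across sections. By default depth is measured
#' from the apical boundary (`depth_ratio` = d_apical / (d_apical + d_basal);
#' 0 = apical boundary, 1 = basal boundary), so "top 20% of the layer" reads
#' as `depth_ratio <= 0.2`. Set `from = "basal"` to flip the convention; both
#' raw distances are always returned so either reading is recoverable.
#'
#' @param cells data frame with columns `cell_id`, `x`, `y`.
#' @param chains a [classify_boundary_edges()] result (or any list with
#'   `apical` and `basal` polyline matrices).
#' @param from reference boundary for the ratio: `"apical"` (default) or
#'   `"basal"`.
#' @return a tibble with `cell_id`, `d_apical`, `d_basal`, `depth_ratio`, and
#'   `degenerate` (TRUE when both distances are zero and the ratio is
#'   undefined).
#' @export
normalized_depth <- function(cells, chains, from = c("apical", "basal")) {
  from <- match.arg(from)
  check_columns(cells, c("cell_id", "x", "y"), "`cells`")
  if (is.null(chains$apical) || is.null(chains$basal)) {
    abort("both apical and basal chains are required")
  }
  m <- as_xy_matrix(cells)
  d_ap <- cpp_dist_to_segments(m, as_segments(chains$apical))
  d_ba <- cpp_dist_to_segments(m, as_segments(chains$basal))
  tot <- d_ap + d_ba
  degenerate <- tot <= 0
  if (any(degenerate)) {
    warn(sprintf("%d cell(s) have zero distance to both chains; depth ratio undefined",
                 sum(degenerate)))
  }
  num <- if (from == "apical") d_ap else d_ba
  tibble(
    cell_id = cells$cell_id,
    d_apical = d_ap,
    d_basal = d_ba,
    depth_ratio = ifelse(degenerate, NA_real_, num / tot),
    degenerate = degenerate
  )
}
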