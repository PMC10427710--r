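#' Construct a segmentation polygon set
#'
#' @param polygons a named list of vertex matrices (ordered simple rings,
#'   two columns, coordinates in image pixels or micrometers), or a tibble
#'   with columns `cell_id` and list-column `vertices`.
#' @param source label for the producing segmenter (`"primary"`, `"rescue"`,
#'   or `"merged"`).
#' @param validate check every ring (simple, positive area); rejected rings
#'   abort with the polygon id.
#' @return a `segmentation_set` tibble: `cell_id`, `vertices`, `source`.
#' @export
segmentation_set <- function(polygons, source = "primary", validate = TRUE) {
  if (is.data.frame(polygons)) {
    check_columns(polygons, c("cell_id", "vertices"), "`polygons`")
    tab <- tibble(cell_id = as.character(polygons$cell_id),
                  vertices = polygons$vertices)
    if ("source" %in% names(polygons) && missing(source)) {
      tab$source <- polygons$source
    } else {
      tab$source <- source
    }
  } else {
    if (is.null(names(polygons)) || anyNA(names(polygons)) ||
        any(names(polygons) == "")) {
      abort("`polygons` must be a named list (names are cell ids)")
    }
    tab <- tibble(cell_id = names(polygons),
                  vertices = unname(polygons), source = source)
  }
  if (anyDuplicated(tab$cell_id)) abort("cell ids must be unique")
  if (validate) {
    tab$vertices <- map2(tab$vertices, tab$cell_id, check_ring)
  }
  class(tab) <- c("segmentation_set", class(tab))
  tab
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf("<segmentation_set> %d polygons (%s)\n", nrow(x),
              paste(unique(x$source), collapse = ", ")))
  invisible(x)
}

seg_bboxes <- function(set) {
  t(vapply(set$vertices, function(v) {
    c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2]))
  }, numeric(4)))
}

#' Fuse two segmentation polygon sets by the overlap-rescue rule
#'
#' All primary polygons are kept. A rescue polygon is added only when its
#' overlap with the union of the primary polygons is strictly below
#' `overlap_threshold`, measured as intersection area divided by the rescue
#' polygon's own area (set `denominator = "primary"` to normalize by the
#' largest intersected primary polygon instead). The default threshold of
#' 0.001 (0.1%) rescues cells the primary segmenter missed, typically in the
#' ganglion cell layer, without creating doublets.
#'
#' @param primary,rescue `segmentation_set` objects (see
#'   [segmentation_set()]).
#' @param overlap_threshold fraction in `[0, 1]`; strict `<` at the bound.
#' @param denominator area normalizing the overlap: the rescue polygon
#'   (`"rescue"`, default) or the intersected primary polygon (`"primary"`).
#' @return a merged `segmentation_set`; attribute `overlap` holds the
#'   per-rescue-polygon computed overlap fraction.
#' @export
merge_segmentations <- function(primary, rescue, overlap_threshold = 0.001,
                                denominator = c("rescue", "primary")) {
  denominator <- match.arg(denominator)
  check_number(overlap_threshold, "overlap_threshold", 0, 1)
  stopifnot(inherits(primary, "segmentation_set"),
            inherits(rescue, "segmentation_set"))
  pb <- seg_bboxes(primary)
  overlap <- vapply(seq_len(nrow(rescue)), function(k) {
    v <- rescue$vertices[[k]]
    cand <- which(!(pb[, 2] < min(v[, 1]) | pb[, 1] > max(v[, 1]) |
                      pb[, 4] < min(v[, 2]) | pb[, 3] > max(v[, 2])))
    if (!length(cand)) return(0)
    inter <- area_vs_union(v, primary$vertices[cand])
    denom <- if (denominator == "rescue") {
      poly_area(v)
    } else {
      areas <- vapply(primary$vertices[cand],
                      function(p) poly_intersection_area(v, p), numeric(1))
      if (all(areas == 0)) poly_area(v) else
        poly_area(primary$vertices[cand][[which.max(areas)]])
    }
    inter / denom
  }, numeric(1))
  # strict "<" at the bound; fractions within 1e-6 relative of the threshold
  # are treated as equal to it (clipping noise must not flip the rule)
  keep <- overlap < overlap_threshold * (1 - 1e-6)
  out <- bind_rows(
    primary,
    rescue[keep, , drop = FALSE]
  )
  if (anyDuplicated(out$cell_id)) {
    abort("merged set has duplicated cell ids; disambiguate rescue ids first")
  }
  out$source <- c(rep("primary", nrow(primary)),
                  rep("rescue", sum(keep)))
  class(out) <- c("segmentation_set", class(tibble()))
  attr(out, "overlap") <- tibble(cell_id = rescue$cell_id,
                                 overlap_fraction = overlap,
                                 retained = keep)
  out
}

#' Per-polygon QC metrics
#'
#' Computes the five filter quantities per cell polygon: unsigned shoelace
#' area, perimeter, exact minimum-enclosing-circle radius of the vertices
#' (Welzl's algorithm), mean DAPI intensity (supplied externally; image
#' processing is out of scope), and total assigned transcripts.
#'
#' @param polygons a `segmentation_set`.
#' @param spots optional transcript table with an `cell_id` assignment column
#'   (see [assign_transcripts()]); when absent, `total_transcripts` is `NA`.
#' @param dapi optional tibble `cell_id`, `dapi_mean`.
#' @return tibble: `cell_id`, `area`, `perimeter`, `mec_radius`, `dapi_mean`,
#'   `total_transcripts`.
#' @export
polygon_metrics <- function(polygons, spots = NULL, dapi = NULL) {
  stopifnot(inherits(polygons, "segmentation_set"))
  out <- tibble(
    cell_id = polygons$cell_id,
    area = map_dbl(polygons$vertices, poly_area),
    perimeter = map_dbl(polygons$vertices, poly_perimeter),
    mec_radius = map_dbl(polygons$vertices,
                         function(v) cpp_min_enclosing_circle(v)[["r"]])
  )
  if (!is.null(dapi)) {
    check_columns(dapi, c("cell_id", "dapi_mean"), "`dapi`")
    out$dapi_mean <- dapi$dapi_mean[match(out$cell_id, dapi$cell_id)]
  } else {
    out$dapi_mean <- NA_real_
  }
  if (!is.null(spots)) {
    check_columns(spots, "cell_id", "`spots`")
    tt <- table(spots$cell_id)
    out$total_transcripts <- as.integer(tt[out$cell_id])
    out$total_transcripts[is.na(out$total_transcripts)] <- 0L
  } else {
    out$total_transcripts <- NA_integer_
  }
  out
}

#' Minimum enclosing circle of a point set
#'
#' Exact smallest circle containing all points (Welzl's move-to-front
#' algorithm). Two points at distance d give radius d/2.
#'
#' @param points two-column matrix or data frame with `x`, `y`.
#' @return named numeric: `x`, `y`, `r`.
#' @export
min_enclosing_circle <- function(points) {
  m <- if (is.matrix(points) && ncol(points) == 2) {
    storage.mode(points) <- "double"; points
  } else as_xy_matrix(points)
  cpp_min_enclosing_circle(m)
}

#' Assign decoded transcripts to segmented cells
#'
#' Each spot is assigned to exactly one cell: the polygon that contains it,
#' otherwise the polygon with minimum boundary distance. Candidates are
#' retrieved by centroid proximity and the pool is expanded until the nearest
#' candidate's boundary distance is certified minimal (any unexamined polygon
#' is at least its centroid distance minus the maximal polygon radius away).
#' Exact ties go to the lexicographically smallest `cell_id`.
#'
#' @param spots tibble with `gene`, `x`, `y`.
#' @param polygons a `segmentation_set`.
#' @param pool initial candidate pool size (default 10).
#' @param max_dist optional cap: spots farther than this from every polygon
#'   stay unassigned (`NA`); default `NULL`, no cap.
#' @return `spots` with an added/overwritten `cell_id` column.
#' @export
assign_transcripts <- function(spots, polygons, pool = 10, max_dist = NULL) {
  stopifnot(inherits(polygons, "segmentation_set"))
  if (!nrow(polygons)) abort("empty polygon set")
  check_columns(spots, c("x", "y"), "`spots`")
  ord <- order(polygons$cell_id)
  polys <- polygons$vertices[ord]
  ids <- polygons$cell_id[ord]
  centroids <- t(vapply(polys, poly_centroid, numeric(2)))
  idx <- cpp_assign_spots(as_xy_matrix(spots), polys, centroids,
                          as.integer(pool),
                          if (is.null(max_dist)) -1 else max_dist)
  spots$cell_id <- ids[idx]
  spots
}

# the five QC interval filters, bounds as printed (all inclusive)
default_qc_thresholds <- function() {
  list(dapi_min = 80, mec_min = 10, mec_max = 80, area_min = 500,
       area_max = 10000, perimeter_min = 50, perimeter_max = 400,
       transcripts_min = 10)
}

#' Quality-control filter on per-cell polygon metrics
#'
#' A cell is retained iff mean DAPI intensity >= 80, minimum-enclosing-circle
#' radius in \[10, 80\], polygon area in \[500, 10,000\], perimeter in
#' \[50, 400\] and total transcripts >= 10 (all bounds inclusive; pixel
#' units for the geometric quantities). Thresholds are overridable. Cells
#' with missing metrics are reported in the `missing` attribute rather than
#' silently dropped.
#'
#' @param metrics a [polygon_metrics()] tibble.
#' @param thresholds named list overriding any of
#'   `dapi_min, mec_min, mec_max, area_min, area_max, perimeter_min,
#'   perimeter_max, transcripts_min`.
#' @return the retained subset of `metrics`, with attributes `retained_ids`
#'   and `missing` (cell ids with any missing metric).
#' @export
qc_filter <- function(metrics, thresholds = list()) {
  check_columns(metrics, c("cell_id", "area", "perimeter", "mec_radius",
                           "dapi_mean", "total_transcripts"), "`metrics`")
  th <- modifyList(default_qc_thresholds(), thresholds)
  m <- metrics
  has_na <- !stats::complete.cases(m[c("area", "perimeter", "mec_radius",
                                       "dapi_mean", "total_transcripts")])
  if (any(has_na)) {
    warn(sprintf("%d cell(s) have missing metrics and cannot be filtered: %s",
                 sum(has_na),
                 paste(head(m$cell_id[has_na], 5), collapse = ", ")))
  }
  pass <- !has_na &
    m$dapi_mean >= th$dapi_min &
    m$mec_radius >= th$mec_min & m$mec_radius <= th$mec_max &
    m$area >= th$area_min & m$area <= th$area_max &
    m$perimeter >= th$perimeter_min & m$perimeter <= th$perimeter_max &
    m$total_transcripts >= th$transcripts_min
  out <- m[pass, , drop = FALSE]
  attr(out, "retained_ids") <- m$cell_id[pass]
  attr(out, "missing") <- m$cell_id[has_na]
  out
}
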