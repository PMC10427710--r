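# polygon-set fusion, transcript assignment, QC filtering

sq_set <- function(..., source = "primary") {
  polys <- list(...)
  segmentation_set(polys, source = source)
}

test_that("the merge rule keeps exactly the sub-threshold rescue polygons", {
  primary <- sq_set(P1 = rect_poly(c(0, 0, 10, 10)))
  # disjoint rescue square is retained
  r_far <- sq_set(R1 = rect_poly(c(20, 20, 30, 30)), source = "rescue")
  m1 <- merge_segmentations(primary, r_far)
  expect_setequal(m1$cell_id, c("P1", "R1"))
  # fully contained rescue square (overlap fraction 1) is dropped
  r_in <- sq_set(R2 = rect_poly(c(2, 2, 5, 5)), source = "rescue")
  m2 <- merge_segmentations(primary, r_in)
  expect_identical(m2$cell_id, "P1")
  # overlap exactly at the threshold is dropped (strict <), just below kept
  r_thr <- sq_set(R3 = rect_poly(c(0, 0, 10, 10)), source = "rescue")
  p_at <- sq_set(P1 = rect_poly(c(9.99, 0, 19.99, 10)))    # fraction 0.001
  p_below <- sq_set(P1 = rect_poly(c(9.999, 0, 19.999, 10)))  # fraction 1e-4
  expect_false("R3" %in% merge_segmentations(p_at, r_thr)$cell_id)
  expect_true("R3" %in% merge_segmentations(p_below, r_thr)$cell_id)
})

test_that("merging is idempotent and never keeps an over-threshold rescue", {
  set.seed(31)
  prim <- list()
  for (k in 1:25) {
    ctr <- runif(2, 0, 200)
    prim[[sprintf("P%02d", k)]] <- stratafish:::regular_polygon(ctr, 6, k = 8)
  }
  resc <- list()
  for (k in 1:25) {
    ctr <- runif(2, 0, 200)
    resc[[sprintf("R%02d", k)]] <- stratafish:::regular_polygon(ctr, 6, k = 8)
  }
  primary <- segmentation_set(prim)
  rescue <- segmentation_set(resc, source = "rescue")
  m1 <- merge_segmentations(primary, rescue)
  # every retained rescue polygon is verified below threshold by clipping
  kept <- m1$cell_id[m1$source == "rescue"]
  for (id in kept) {
    v <- rescue$vertices[[match(id, rescue$cell_id)]]
    frac <- stratafish:::area_vs_union(v, primary$vertices) /
      stratafish:::poly_area(v)
    expect_lt(frac, 0.001)
  }
  # merging the merged set with the same rescue set changes nothing
  m2 <- merge_segmentations(m1, rescue)
  expect_identical(m2$cell_id, m1$cell_id)
  # a retained rescue polygon whose id collides with a primary id is refused
  clash <- segmentation_set(list(P01 = rect_poly(c(900, 900, 910, 910))),
                            source = "rescue")
  expect_error(merge_segmentations(primary, clash), "duplicated")
})

test_that("polygon metrics carry the five filter quantities", {
  s <- 30
  set <- sq_set(A = rect_poly(c(0, 0, s, s)))
  met <- polygon_metrics(
    set,
    spots = tibble::tibble(cell_id = rep("A", 12)),
    dapi = tibble::tibble(cell_id = "A", dapi_mean = 101)
  )
  expect_equal(met$area, s^2)
  expect_equal(met$perimeter, 4 * s)
  expect_equal(met$mec_radius, s * sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(met$dapi_mean, 101)
  expect_equal(met$total_transcripts, 12L)
  # isoperimetric and enclosing-circle invariants
  expect_lte(met$area, pi * met$mec_radius^2)
  expect_gte(met$perimeter^2, 4 * pi * met$area)
})

test_that("transcripts go to the containing, else nearest, polygon", {
  polys <- sq_set(B = rect_poly(c(20, 0, 30, 10)),
                  A = rect_poly(c(0, 0, 10, 10)))
  spots <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    x = c(5, 11, 15), y = c(5, 5, 5)
  )
  out <- assign_transcripts(spots, polys)
  # inside A; nearer A's boundary; exactly equidistant -> smaller id wins
  expect_identical(out$cell_id, c("A", "A", "A"))
  out2 <- assign_transcripts(tibble::tibble(gene = "g", x = 16, y = 5), polys)
  expect_identical(out2$cell_id, "B")
  # optional distance cap leaves remote spots unassigned
  far <- assign_transcripts(tibble::tibble(gene = "g", x = 500, y = 500),
                            polys, max_dist = 50)
  expect_true(is.na(far$cell_id))
  expect_error(assign_transcripts(spots, polys[0, ]), "empty")
})

test_that("assignment matches brute force over all polygons", {
  set.seed(41)
  polys <- list()
  for (k in 1:30) {
    polys[[sprintf("C%02d", k)]] <-
      stratafish:::regular_polygon(runif(2, 0, 100), runif(1, 2, 5),
                                   k = sample(3:9, 1))
  }
  set <- segmentation_set(polys)
  spots <- tibble::tibble(gene = "g", x = runif(200, -10, 110),
                          y = runif(200, -10, 110))
  got <- assign_transcripts(spots, set)$cell_id
  # brute force: containment first, else minimal boundary distance
  ora <- vapply(seq_len(nrow(spots)), function(s) {
    p <- c(spots$x[s], spots$y[s])
    d <- vapply(set$vertices, function(v) {
      if (stratafish:::cpp_points_in_polygon(rbind(p), v)) return(0)
      min(distance_to_chain(rbind(p), stratafish:::poly_close(v)))
    }, numeric(1))
    set$cell_id[which.min(d)]
  }, character(1))
  expect_identical(got, ora)
  # conservation: each spot assigned exactly once, totals add up
  expect_false(anyNA(got))
  expect_equal(sum(table(got)), nrow(spots))
})

test_that("qc_filter applies the five inclusive interval tests", {
  base <- tibble::tibble(
    cell_id = "x", area = 800, perimeter = 120, mec_radius = 20,
    dapi_mean = 150, total_transcripts = 40L
  )
  expect_identical(qc_filter(base)$cell_id, "x")
  # exactly at every lower bound: retained (inclusive bounds as printed)
  at <- tibble::tibble(cell_id = "b", area = 500, perimeter = 50,
                       mec_radius = 10, dapi_mean = 80,
                       total_transcripts = 10L)
  expect_identical(qc_filter(at)$cell_id, "b")
  # dapi just below the bound: removed
  low <- at; low$dapi_mean <- 79.99
  expect_identical(nrow(qc_filter(low)), 0L)
  # each upper bound is inclusive too
  hi <- tibble::tibble(cell_id = "h", area = 10000, perimeter = 400,
                       mec_radius = 80, dapi_mean = 80,
                       total_transcripts = 10L)
  expect_identical(qc_filter(hi)$cell_id, "h")
  # missing metric: reported, not silently dropped
  miss <- base; miss$mec_radius <- NA_real_
  expect_warning(out <- qc_filter(miss), "missing")
  expect_identical(attr(out, "missing"), "x")
})

test_that("qc_filter equals a naive conjunction and is threshold-monotone", {
  set.seed(17)
  m <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:300),
    area = runif(300, 100, 12000),
    perimeter = runif(300, 20, 500),
    mec_radius = runif(300, 2, 100),
    dapi_mean = runif(300, 0, 200),
    total_transcripts = rpois(300, 15)
  )
  got <- qc_filter(m)$cell_id
  naive <- m$cell_id[
    m$dapi_mean >= 80 &
      m$mec_radius >= 10 & m$mec_radius <= 80 &
      m$area >= 500 & m$area <= 10000 &
      m$perimeter >= 50 & m$perimeter <= 400 &
      m$total_transcripts >= 10
  ]
  expect_identical(got, naive)
  # tightening any single threshold never enlarges the retained set
  for (th in list(list(dapi_min = 100), list(area_min = 1000),
                  list(mec_max = 50), list(perimeter_min = 100),
                  list(transcripts_min = 20))) {
    expect_true(all(qc_filter(m, th)$cell_id %in% got))
  }
})

test_that("segmentation sets validate rings and round-trip GeoJSON", {
  expect_error(segmentation_set(list(Z = rbind(c(0, 0), c(1, 1), c(2, 2)))),
               "Z")
  set <- sq_set(A = rect_poly(c(0, 0, 10, 10)),
                B = stratafish:::regular_polygon(c(50, 50), 5, k = 7))
  tf <- withr::local_tempfile(fileext = ".geojson")
  write_polygons(set, tf)
  back <- read_polygons(tf)
  expect_setequal(back$cell_id, set$cell_id)
  for (id in set$cell_id) {
    expect_equal(back$vertices[[match(id, back$cell_id)]],
                 set$vertices[[match(id, set$cell_id)]])
  }
})
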