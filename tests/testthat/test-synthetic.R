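# synthetic layered-tissue generator: determinism, placement laws, counts,
# reference pairing, segmentation fixture truth

test_that("identical seeds give bit-identical sections", {
  st <- small_subtypes()
  s1 <- generate_section(small_spec(seed = 5), st)
  s2 <- generate_section(small_spec(seed = 5), st)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$latents, s2$latents)
  s3 <- generate_section(small_spec(seed = 6), st)
  expect_false(identical(s1$cells$x, s3$cells$x))
})

test_that("every centroid lies inside its layer band and angular span", {
  st <- small_subtypes()
  spec <- small_spec(seed = 3)
  sec <- generate_section(spec, st)
  r <- sqrt(sec$cells$x^2 + sec$cells$y^2)
  th <- atan2(sec$cells$y, sec$cells$x)
  for (ly in names(spec$layer_radii)) {
    rr <- spec$layer_radii[[ly]]
    sel <- sec$truth$layer == ly
    expect_true(all(r[sel] >= rr[1] - 1e-9 & r[sel] <= rr[2] + 1e-9))
  }
  expect_true(all(th >= spec$angular_span[1] - 1e-9 &
                    th <= spec$angular_span[2] + 1e-9))
  # exactly one truth record per cell
  expect_identical(sort(sec$truth$cell_id), sort(sec$cells$cell_id))
})

test_that("displacement ratios are honored", {
  # degenerate ratio 0: all AC cells stay in the INL
  st0 <- small_subtypes(displacement_ratios = NULL, background_displacement = 0)
  sec0 <- generate_section(small_spec(seed = 2), st0)
  expect_true(all(sec0$truth$layer[sec0$truth$major_type == "AC"] == "INL"))
  # ratio 0.5 with ~400 cells: binomial 3-sigma bound
  st5 <- small_subtypes(displacement_ratios = c(AC01 = 0.5))
  spec <- section_spec(densities = c(GCL = 0.02, INL = 0.3, ONL = 0.02),
                       seed = 7)
  sec5 <- generate_section(spec, st5)
  ac1 <- sec5$truth[sec5$truth$subtype == "AC01", ]
  expect_gte(nrow(ac1), 400)
  frac <- mean(ac1$layer == "GCL")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(ac1)) + 0.02)
})

test_that("per-cell totals average to the target count", {
  st <- small_subtypes()
  spec <- section_spec(densities = c(GCL = 0.05, INL = 0.3, ONL = 0.3),
                       seed = 9)
  sec <- generate_section(spec, st)
  tot <- Matrix::rowSums(sec$counts)
  expect_gte(length(tot), 10000)
  expect_lt(abs(mean(tot) - 80), 1)
})

test_that("per-subtype depth distribution follows its Beta law", {
  st <- small_subtypes()
  spec <- section_spec(densities = c(GCL = 0.02, INL = 0.5, ONL = 0.02),
                       seed = 13)
  sec <- generate_section(spec, st)
  rbc <- sec$truth[sec$truth$subtype == "RBC" & sec$truth$layer == "INL", ]
  expect_gte(nrow(rbc), 2000)
  ks <- suppressWarnings(stats::ks.test(rbc$depth, stats::pbeta,
                                        shape1 = 2, shape2 = 8))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid generator inputs are rejected with messages", {
  st <- small_subtypes()
  expect_error(generate_section(small_spec(seed = 1), st[0, ]), "empty")
  expect_error(section_spec(layer_radii = list(INL = c(900, 900)), seed = 1),
               "zero-area")
  expect_error(section_spec(seed = 1, angular_span = c(2, 1)), "theta_min")
  bad <- st
  bad$expression_profile[[3]] <- rep(NA_real_, nrow(attr(st, "genes")))
  expect_error(generate_section(small_spec(seed = 1), bad), "profile")
  expect_error(section_spec(), "seed")
})

test_that("reference cells share the subtype latent structure", {
  st <- small_subtypes()
  ref <- generate_reference(st, n_cells = 600, seed = 4)
  # labels partition the cells
  expect_equal(sum(table(ref$labels$subtype)), 600)
  expect_setequal(unique(ref$labels$subtype), st$name)
  # nearest-centroid classification of reference latents is near-perfect at
  # the default (>= 6 sigma) separation
  mu <- do.call(cbind, st$latent_mean)
  d2 <- vapply(seq_len(ncol(mu)), function(k) {
    colSums((t(ref$latents) - mu[, k])^2)
  }, numeric(nrow(ref$latents)))
  pred <- st$name[max.col(-d2)]
  expect_gte(mean(pred == ref$labels$subtype), 0.99)
  # zero latent noise collapses each subtype to one point
  st0 <- small_subtypes()
  st0$latent_sd <- 1e-12
  ref0 <- generate_reference(st0, n_cells = 100, seed = 4)
  by_sub <- split(seq_len(100), ref0$labels$subtype)
  for (ix in by_sub) {
    if (length(ix) > 1) {
      expect_lt(max(dist(ref0$latents[ix, , drop = FALSE])), 1e-9)
    }
  }
  expect_error(generate_reference(st, n_cells = 3), "at least")
})

test_that("reference and section determinism is seed-driven", {
  st <- small_subtypes()
  r1 <- generate_reference(st, n_cells = 300, seed = 11)
  r2 <- generate_reference(st, n_cells = 300, seed = 11)
  expect_identical(r1$latents, r2$latents)
  expect_identical(as.matrix(r1$counts), as.matrix(r2$counts))
})

test_that("segmentation fixture records exact overlap truth and conserves spots", {
  st <- small_subtypes()
  sec <- generate_section(section_spec(
    densities = c(GCL = 0.005, INL = 0.01, ONL = 0.008), seed = 21), st)
  fx <- generate_segmentation_fixture(sec, seed = 22)
  # total generated spots equal the count-matrix mass
  expect_identical(nrow(fx$spots), as.integer(sum(sec$counts)))
  # constructed pair overlaps are exact by polygon clipping
  for (k in seq_len(nrow(fx$truth$overlap_pairs))) {
    tp <- fx$truth$overlap_pairs[k, ]
    rp <- fx$rescue$vertices[[match(tp$cell_id, fx$rescue$cell_id)]]
    pp <- fx$primary$vertices[[match(tp$pairs_with, fx$primary$cell_id)]]
    got <- stratafish:::poly_intersection_area(rp, pp) /
      stratafish:::poly_area(rp)
    expect_equal(got, tp$overlap_fraction, tolerance = 1e-6)
  }
  # requested fraction 0.05 on a known-area square: area = fraction x area
  fx2 <- generate_segmentation_fixture(
    sec, params = list(overlap_fractions = 0.05), seed = 23)
  tp <- fx2$truth$overlap_pairs[1, ]
  rp <- fx2$rescue$vertices[[match(tp$cell_id, fx2$rescue$cell_id)]]
  pp <- fx2$primary$vertices[[match(tp$pairs_with, fx2$primary$cell_id)]]
  expect_equal(stratafish:::poly_intersection_area(rp, pp),
               0.05 * stratafish:::poly_area(rp), tolerance = 1e-8)
  # spots lie inside their owner polygon
  own <- fx$truth$owner
  one <- own$cell_id[!is.na(own$polygon_id)][1]
  pid <- own$polygon_id[own$cell_id == one]
  pv <- if (pid %in% fx$primary$cell_id) {
    fx$primary$vertices[[match(pid, fx$primary$cell_id)]]
  } else {
    fx$rescue$vertices[[match(pid, fx$rescue$cell_id)]]
  }
  sp <- fx$spots[fx$spots$true_cell == one, ]
  if (nrow(sp)) {
    expect_true(all(stratafish:::cpp_points_in_polygon(cbind(sp$x, sp$y), pv)))
  }
  expect_error(
    generate_segmentation_fixture(sec, params = list(overlap_fractions = 1.2)),
    "\\[0, 1\\]")
})

test_that("band fixture is uniform in the band with exact radial truth", {
  band <- generate_band_fixture(500, r_range = c(900, 1100), seed = 1)
  r <- sqrt(band$x^2 + band$y^2)
  expect_equal(r, band$r)
  expect_true(all(r >= 900 & r <= 1100))
  expect_equal(band$depth_true, (1100 - r) / 200)
  expect_error(generate_band_fixture(10, r_range = c(5, 5)), "zero-area")
})
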