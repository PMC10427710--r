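# layer assignment, displacement permutation test, quadrants, regional
# composition, laminar summaries

test_that("layer assignment follows the radial side of the basal chain", {
  # band 900-1100 stands in for the INL; cells below 900 are "GCL"
  band <- generate_band_fixture(1500, seed = 5)
  sh <- build_alpha_shape(band, alpha = 100)
  ch <- classify_boundary_edges(sh, estimate_tissue_center(band))
  th <- runif(50, pi / 3, 2 * pi / 3)
  probes <- tibble::tibble(
    cell_id = sprintf("p%02d", 1:50),
    x = c(950 * cos(th[1:25]), 850 * cos(th[26:50])),
    y = c(950 * sin(th[1:25]), 850 * sin(th[26:50]))
  )
  lay <- assign_layer(probes, ch)
  expect_true(all(lay$layer[1:25] == "INL"))
  expect_true(all(lay$layer[26:50] == "GCL"))
  expect_error(assign_layer(probes, list(basal = NULL)), "basal")
})

test_that("refined AC layer assignment recovers ground truth", {
  st <- small_subtypes()
  sec <- generate_section(small_spec(seed = 31), st)
  out <- assign_ac_layers(sec$cells, passes = 1)
  tru <- sec$truth[match(out$layers$cell_id, sec$truth$cell_id), ]
  ok <- out$layers$layer %in% c("INL", "GCL")
  # >= 99% accuracy away from the chain itself
  off <- out$layers$d_basal > 2
  expect_gte(mean((out$layers$layer == tru$layer)[ok & off]), 0.99)
})

test_that("permutation p-value matches the exact hypergeometric tail", {
  # one section, 100 ACs, 50 in the GCL, subtype S of 10 cells all displaced
  cells <- tibble::tibble(
    section = "s1",
    subtype = c(rep("S", 10), rep("other", 90)),
    layer = c(rep("GCL", 10), rep("GCL", 40), rep("INL", 50))
  )
  res <- displacement_test(cells, n_perm = 1000, seed = 42)
  p_exact <- oracle_hyper_tail(10, 100, 50, 10)  # = C(50,10)/C(100,10)
  got <- tidy(res)$p_value[tidy(res)$subtype == "S"]
  mc_sigma <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(got - p_exact), 3 * mc_sigma + 1e-12)
  expect_equal(tidy(res)$observed_prop[tidy(res)$subtype == "S"], 1)
})

test_that("a subtype absent from the GCL is never called displaced", {
  cells <- tibble::tibble(
    section = "s1",
    subtype = rep(c("A", "B"), each = 50),
    layer = c(rep("INL", 50), rep("GCL", 25), rep("INL", 25))
  )
  res <- tidy(displacement_test(cells, n_perm = 500, seed = 1))
  expect_gt(res$p_value[res$subtype == "A"], 0.95)
  expect_false(res$significant[res$subtype == "A"])
})

test_that("the permutation stream is reproducible and conserves counts", {
  set.seed(99)
  cells <- tibble::tibble(
    section = rep(c("s1", "s2"), each = 100),
    subtype = sample(c("A", "B", "C"), 200, TRUE),
    layer = sample(c("INL", "GCL"), 200, TRUE, prob = c(0.7, 0.3))
  )
  r1 <- displacement_test(cells, n_perm = 300, seed = 7)
  r2 <- displacement_test(cells, n_perm = 300, seed = 7)
  expect_identical(tidy(r1)$p_value, tidy(r2)$p_value)
  r3 <- displacement_test(cells, n_perm = 300, seed = 8)
  expect_false(identical(tidy(r1)$p_value, tidy(r3)$p_value))
  # p_value is consistent with the stored null proportions
  obs <- tidy(r1)$observed_prop
  recomputed <- colMeans(r1$null_props >
                           matrix(obs, nrow(r1$null_props), ncol(r1$null_props),
                                  byrow = TRUE))
  expect_equal(tidy(r1)$p_value, unname(recomputed))
  # permutations preserve the global GCL mass per subtype-size weighting
  tot <- sum(cells$layer == "GCL")
  n_by_sub <- table(cells$subtype)
  counts <- sweep(r1$null_props, 2, as.numeric(n_by_sub[sort(names(n_by_sub))]),
                  "*")
  expect_true(all(abs(rowSums(counts) - tot) < 1e-9))
  # conservative estimator never returns zero
  r4 <- displacement_test(cells, n_perm = 100, conservative = TRUE, seed = 1)
  expect_true(all(tidy(r4)$p_value > 0))
  expect_error(displacement_test(cells, n_perm = 0), "n_perm")
  bad <- cells; bad$layer[1] <- "ONL"
  expect_error(displacement_test(bad), "ONL")
})

test_that("quadrant assignment splits at the x midpoint with explicit mapping", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"),
                          x = c(0, 25, 75), y = c(0, 1, 2))
  # x spans [0, 100] after adding the extremes
  cells <- rbind(cells, tibble::tibble(cell_id = "d", x = 100, y = 0))
  out <- assign_quadrants(cells, "dorsal-ventral",
                          c(left = "dorsal", right = "ventral"))
  expect_identical(out$region, c("dorsal", "dorsal", "ventral", "ventral"))
  # rotation equivariance: pre-rotating the input and undoing it via the
  # rotation argument gives identical regions
  ang <- 0.7
  rot <- cells
  rot$x <- cells$x * cos(ang) + cells$y * sin(ang)
  rot$y <- -cells$x * sin(ang) + cells$y * cos(ang)
  out2 <- assign_quadrants(rot, "dorsal-ventral",
                           c(left = "dorsal", right = "ventral"),
                           rotation = -ang)
  expect_identical(out2$region, out$region)
  expect_error(assign_quadrants(cells, "sideways",
                                c(left = "dorsal", right = "ventral")),
               "orientation")
  expect_error(assign_quadrants(cells, "dorsal-ventral"), "metadata")
  expect_error(assign_quadrants(cells, "dorsal-ventral",
                                c(left = "up", right = "down")), "dorsal")
})

test_that("generated region truth is recovered by the quadrant rule", {
  st <- small_subtypes()
  sec <- generate_section(small_spec(seed = 55), st)
  out <- assign_quadrants(sec$cells, "dorsal-ventral",
                          c(left = "dorsal", right = "ventral"))
  expect_identical(out$region, sec$truth$region)
})

test_that("regional composition comparison behaves at the extremes", {
  # identical proportions in every section: p = 1
  cells <- tidyr::crossing(
    section = c("s1", "s2", "s3"),
    region = c("dorsal", "ventral"),
    subtype = c("A", "B"),
    idx = 1:10
  ) |> dplyr::mutate(major_type = "BC", cell_id = dplyr::row_number())
  cmp <- compare_regional_composition(cells, unit = "subtype",
                                      normalization = "all_cells")
  expect_true(all(tidy(cmp)$p_value == 1))
  # proportions sum to 1 within each section-region under all-cells
  sums <- cmp$per_section |>
    dplyr::group_by(section, region) |>
    dplyr::summarise(s = sum(prop), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # a unit absent from all sections is reported, not tested
  one <- cells[cells$subtype == "A", ]
  one$region <- rep(c("dorsal", "ventral"), length.out = nrow(one))
  cmp2 <- compare_regional_composition(one, unit = "subtype")
  expect_true(all(tidy(cmp2)$tested))
  expect_error(compare_regional_composition(cells[cells$region == "dorsal", ]),
               "two regions")
})

test_that("a seeded RBC dorsal-ventral difference is detected across sections", {
  # BC-only sections: RBC 35% of BCs dorsally vs 30% ventrally
  st <- small_subtypes()
  st_bc <- st[st$major_type == "BC", ]
  st_bc$abundance <- st_bc$abundance / sum(st_bc$abundance)
  st_bc$abundance2 <- st_bc$abundance2 / sum(st_bc$abundance2)
  attr(st_bc, "genes") <- attr(st, "genes")
  secs <- lapply(1:5, function(i) {
    spec <- section_spec(layer_radii = list(INL = c(835, 895)),
                         densities = c(INL = 0.05), seed = 700 + i)
    generate_section(spec, st_bc, section_id = sprintf("S%d", i))
  })
  cells <- dplyr::bind_rows(lapply(secs, function(s) {
    qr <- assign_quadrants(s$cells, "dorsal-ventral",
                           c(left = "dorsal", right = "ventral"))
    dplyr::left_join(s$cells, qr, by = "cell_id")
  }))
  cmp <- tidy(compare_regional_composition(cells, unit = "subtype",
                                           normalization = "within_major"))
  rbc <- cmp[cmp$unit == "RBC", ]
  expect_true(rbc$significant)
  expect_gt(rbc$mean_dorsal, rbc$mean_ventral)
})

test_that("laminar summaries and pairwise tests behave correctly", {
  set.seed(3)
  n <- 500
  depths <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:(2 * n)),
    depth_ratio = c(rbeta(n, 2, 8), rbeta(n, 8, 2))
  )
  labels <- tibble::tibble(
    cell_id = depths$cell_id,
    subtype = rep(c("apicalward", "basalward"), each = n),
    section = rep(sprintf("s%d", 1:5), 2 * n / 5)
  )
  out <- summarize_laminar_positions(depths, labels)
  s <- out$summary
  expect_equal(s$median[s$subtype == "apicalward"], 0.18, tolerance = 0.05)
  expect_equal(s$median[s$subtype == "basalward"], 0.82, tolerance = 0.05)
  # decisive separation (the test aggregates to 5 per-section means per group,
  # so the attainable p is bounded by the Welch degrees of freedom)
  expect_lt(out$tests$p_value, 1e-6)
  # quantiles agree with the reference implementation
  expect_equal(s$q1[1], unname(quantile(depths$depth_ratio[labels$subtype ==
                                                             s$subtype[1]], 0.25)))
  # identical depth vectors: t = 0, p = 1
  d2 <- depths; d2$depth_ratio <- rep(d2$depth_ratio[1:n], 2)
  out2 <- summarize_laminar_positions(d2, labels)
  expect_equal(out2$tests$t_statistic, 0)
  expect_equal(out2$tests$p_value, 1)
  # subtypes below min_cells are excluded and reported
  lab3 <- labels; lab3$subtype[1:5] <- "rare"
  out3 <- summarize_laminar_positions(depths, lab3, min_cells = 10)
  expect_true("rare" %in% out3$excluded)
})

test_that("tidy and glance return the documented shapes", {
  cells <- tibble::tibble(section = "s1",
                          subtype = rep(c("A", "B"), each = 30),
                          layer = sample(c("INL", "GCL"), 60, TRUE))
  res <- displacement_test(cells, n_perm = 50, seed = 2)
  td <- tidy(res)
  expect_named(td, c("subtype", "n_inl", "n_gcl", "observed_prop", "p_value",
                     "significant"))
  gl <- glance(res)
  expect_equal(gl$n_perm, 50)
  expect_equal(gl$n_subtypes, 2)
})
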