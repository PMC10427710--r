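#' Assign amacrine cells to their resident layer from the INL boundary
#'
#' Uses the basal chain of the INL boundary: a cell radially outward of its
#' nearest point on the basal chain (with respect to the tissue center) lies
#' in the INL; radially inward lies in the GCL (displaced). Cells radially
#' outward of the apical chain are outside the layer system and flagged
#' `"outside"`.
#'
#' @param cells tibble with `cell_id`, `x`, `y`.
#' @param chains a [classify_boundary_edges()] result for the INL.
#' @return tibble: `cell_id`, `layer` in `{"INL", "GCL", "outside"}`,
#'   `d_basal` (signed-side distance bookkeeping: distance to the basal
#'   chain).
#' @export
assign_layer <- function(cells, chains) {
  if (is.null(chains$basal)) abort("INL basal chain is required")
  check_columns(cells, c("cell_id", "x", "y"), "`cells`")
  m <- as_xy_matrix(cells)
  ctr <- chains$tissue_center
  near_b <- cpp_nearest_on_segments(m, as_segments(chains$basal))
  r_cell <- sqrt((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2)
  r_chain <- sqrt((near_b[, 1] - ctr[1])^2 + (near_b[, 2] - ctr[2])^2)
  layer <- ifelse(r_cell > r_chain, "INL", "GCL")
  if (!is.null(chains$apical)) {
    near_a <- cpp_nearest_on_segments(m, as_segments(chains$apical))
    r_ap <- sqrt((near_a[, 1] - ctr[1])^2 + (near_a[, 2] - ctr[2])^2)
    layer[r_cell > r_ap & layer == "INL"] <- "outside"
  }
  tibble(cell_id = cells$cell_id, layer = layer, d_basal = near_b[, 3])
}

#' Assign amacrine layers with boundary refinement
#'
#' The INL boundary is first estimated from cells of the unambiguous
#' INL-resident major types (BC, HC, MG). Because amacrine somata dominate
#' the basal INL stratum, that first boundary sits slightly inside the true
#' basal edge; each refinement pass rebuilds the alpha-shape including the
#' amacrine cells currently assigned to the INL and reassigns. The plexiform
#' gap between INL and GCL keeps the refinement from crossing into the GCL.
#' This is the automated counterpart of interactively correcting mislabeled
#' boundary arcs.
#'
#' @param cells full per-section cell table (`cell_id`, `x`, `y`,
#'   `major_type`).
#' @param alpha alpha-shape radius in micrometers (default 100).
#' @param lateral_fraction angular tail fraction excluded per end.
#' @param passes refinement passes after the initial assignment (default 1).
#' @param tissue_center optional; estimated from all cells when missing.
#' @return list: `layers` (tibble `cell_id`, `layer` for the AC cells) and
#'   `chains` (the final [classify_boundary_edges()] result).
#' @export
assign_ac_layers <- function(cells, alpha = 100, lateral_fraction = 0.025,
                             passes = 1, tissue_center = NULL) {
  check_columns(cells, c("cell_id", "x", "y", "major_type"), "`cells`")
  proxy <- cells |> filter(.data$major_type %in% c("BC", "HC", "MG"))
  acs <- cells |> filter(.data$major_type == "AC")
  if (!nrow(proxy)) abort("no INL-resident proxy cells (BC/HC/MG)")
  ctr <- tissue_center %||% estimate_tissue_center(cells)
  chains <- classify_boundary_edges(build_alpha_shape(proxy, alpha = alpha),
                                    ctr, lateral_fraction = lateral_fraction)
  lay <- assign_layer(acs, chains)
  for (p in seq_len(passes)) {
    inl_acs <- acs[lay$layer == "INL", , drop = FALSE]
    cloud <- bind_rows(proxy[c("cell_id", "x", "y")],
                       inl_acs[c("cell_id", "x", "y")])
    chains <- classify_boundary_edges(build_alpha_shape(cloud, alpha = alpha),
                                      ctr, lateral_fraction = lateral_fraction)
    lay <- assign_layer(acs, chains)
  }
  list(layers = lay, chains = chains)
}

#' Summarize laminar positions per subtype and test pairwise differences
#'
#' Box-plot summaries (median, quartiles, 1.5 IQR whisker bounds) of the
#' normalized laminar depth per subtype, and two-sided pairwise t-tests on
#' per-section mean depths, Benjamini-Hochberg adjusted.
#'
#' @param depths a [normalized_depth()] tibble (or any tibble with `cell_id`,
#'   `depth_ratio`).
#' @param labels tibble with `cell_id`, `subtype`, and `section`.
#' @param min_cells subtypes below this count are excluded and reported in
#'   the `excluded` attribute (default 10).
#' @return list of class `laminar_summary`: `summary` (per-subtype tibble)
#'   and `tests` (pairwise tibble with `t_statistic`, `p_value`, `p_adjusted`).
#' @export
summarize_laminar_positions <- function(depths, labels, min_cells = 10) {
  check_columns(depths, c("cell_id", "depth_ratio"), "`depths`")
  check_columns(labels, c("cell_id", "subtype", "section"), "`labels`")
  df <- inner_join(depths, labels, by = "cell_id") |>
    filter(!is.na(.data$depth_ratio))
  counts <- count(df, .data$subtype)
  excluded <- counts$subtype[counts$n < min_cells]
  df <- filter(df, !.data$subtype %in% excluded)
  if (length(unique(df$subtype)) < 2) {
    abort("need at least 2 subtypes with enough cells")
  }
  summ <- df |>
    group_by(.data$subtype) |>
    summarise(
      n = n(),
      median = median(.data$depth_ratio),
      q1 = quantile(.data$depth_ratio, 0.25, names = FALSE),
      q3 = quantile(.data$depth_ratio, 0.75, names = FALSE),
      mean = mean(.data$depth_ratio)
    ) |>
    mutate(
      whisker_low = pmax(.data$q1 - 1.5 * (.data$q3 - .data$q1),
                         vapply(.data$subtype, function(s)
                           min(df$depth_ratio[df$subtype == s]), numeric(1))),
      whisker_high = pmin(.data$q3 + 1.5 * (.data$q3 - .data$q1),
                          vapply(.data$subtype, function(s)
                            max(df$depth_ratio[df$subtype == s]), numeric(1)))
    )
  # per-section mean depth per subtype is the replication unit for the tests
  per_sec <- df |>
    group_by(.data$subtype, .data$section) |>
    summarise(mean_depth = mean(.data$depth_ratio), .groups = "drop")
  subs <- sort(unique(per_sec$subtype))
  pairs <- utils::combn(subs, 2)
  tests <- map(seq_len(ncol(pairs)), function(k) {
    a <- per_sec$mean_depth[per_sec$subtype == pairs[1, k]]
    b <- per_sec$mean_depth[per_sec$subtype == pairs[2, k]]
    if (length(a) < 2 || length(b) < 2 ||
        (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(a, b)
    }
    tibble(subtype_a = pairs[1, k], subtype_b = pairs[2, k],
           t_statistic = unname(tt$statistic), p_value = tt$p.value)
  }) |> list_rbind()
  tests$p_adjusted <- p.adjust(tests$p_value, method = "BH")
  structure(list(summary = summ, tests = tests, excluded = excluded),
            class = "laminar_summary")
}

#' Permutation test for preferential subtype displacement into the GCL
#'
#' For each amacrine subtype, the observed proportion of its cells resident
#' in the GCL is compared with a null built by shuffling subtype labels
#' within each tissue section (layer labels fixed), `n_perm` times. The
#' p-value is the fraction of permutations with a null GCL proportion
#' strictly greater than the observed one; a subtype is significant when
#' p < `alpha` and it has at least `min_cells` cells. The plain estimator can
#' return exactly 0; `conservative = TRUE` switches to (k+1)/(n_perm+1).
#'
#' @param ac_cells tibble with `section`, `subtype`, `layer`
#'   (`"INL"`/`"GCL"`).
#' @param n_perm number of permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param min_cells minimum cells per subtype for a stable call (default 10).
#' @param conservative use the (k+1)/(n_perm+1) p-value estimator.
#' @param seed integer seed; fully determines the permutation stream.
#' @return an object of class `displacement_test`; use [tidy()] for the
#'   per-subtype table (`n_inl`, `n_gcl`, `observed_prop`, `p_value`,
#'   `significant`) and `$null_props` for the permutation null matrix.
#' @export
displacement_test <- function(ac_cells, n_perm = 1000, alpha = 0.05,
                              min_cells = 10, conservative = FALSE, seed = 1) {
  check_columns(ac_cells, c("section", "subtype", "layer"), "`ac_cells`")
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  bad <- !ac_cells$layer %in% c("INL", "GCL")
  if (any(bad)) {
    abort(sprintf("unknown layer label(s): %s",
                  paste(unique(ac_cells$layer[bad]), collapse = ", ")))
  }
  subs <- sort(unique(ac_cells$subtype))
  n_sub <- length(subs)
  sub_i <- match(ac_cells$subtype, subs)
  gcl <- as.numeric(ac_cells$layer == "GCL")
  n_tot <- tabulate(sub_i, n_sub)
  obs_gcl <- vapply(seq_len(n_sub), function(s) sum(gcl[sub_i == s]), numeric(1))
  obs_prop <- obs_gcl / n_tot

  null_counts <- matrix(0, n_perm, n_sub)
  with_seed(derive_seed(seed, "displacement-perm"), {
    for (sec in unique(ac_cells$section)) {
      ii <- which(ac_cells$section == sec)
      g <- gcl[ii]
      s <- sub_i[ii]
      n <- length(ii)
      # shuffled subtype labels, one column per permutation
      perm_labels <- vapply(seq_len(n_perm), function(b) s[sample.int(n)],
                            integer(n))
      for (t2 in seq_len(n_sub)) {
        null_counts[, t2] <- null_counts[, t2] +
          as.numeric(crossprod(g, perm_labels == t2))
      }
    }
  })
  null_props <- sweep(null_counts, 2, n_tot, "/")
  k_greater <- colSums(null_props > matrix(obs_prop, n_perm, n_sub, byrow = TRUE))
  p <- if (conservative) (k_greater + 1) / (n_perm + 1) else k_greater / n_perm
  res <- tibble(
    subtype = subs,
    n_inl = as.integer(n_tot - obs_gcl),
    n_gcl = as.integer(obs_gcl),
    observed_prop = obs_prop,
    p_value = p,
    significant = p < alpha & n_tot >= min_cells
  )
  structure(
    list(result = res, null_props = null_props, n_perm = n_perm,
         alpha = alpha, min_cells = min_cells, conservative = conservative,
         seed = seed),
    class = "displacement_test"
  )
}

#' @export
print.displacement_test <- function(x, ...) {
  cat(sprintf("<displacement_test> %d subtypes, %d permutations, alpha = %g\n",
              nrow(x$result), x$n_perm, x$alpha))
  print(x$result, ...)
  invisible(x)
}

#' @rdname displacement_test
#' @param x a `displacement_test` object.
#' @param ... unused.
#' @export
tidy.displacement_test <- function(x, ...) x$result

#' @rdname displacement_test
#' @export
glance.displacement_test <- function(x, ...) {
  tibble(n_subtypes = nrow(x$result), n_perm = x$n_perm, alpha = x$alpha,
         n_significant = sum(x$result$significant),
         min_cells = x$min_cells, seed = x$seed)
}

#' Assign retinal quadrant regions to cells of an oriented section
#'
#' After rotating the section so its most posterior part (the optic nerve
#' side) points up, cells are split at the midpoint between the minimum and
#' maximum x coordinate; the left and right halves map to the two anatomical
#' regions through explicit metadata (never guessed from coordinates).
#'
#' @param cells tibble with `cell_id`, `x`, `y`.
#' @param orientation `"dorsal-ventral"` or `"temporal-nasal"`.
#' @param region_mapping named character, e.g.
#'   `c(left = "dorsal", right = "ventral")`.
#' @param rotation rotation angle in radians applied before splitting
#'   (default 0: the input is already posterior-at-top).
#' @return tibble: `cell_id`, `region`.
#' @export
assign_quadrants <- function(cells, orientation, region_mapping, rotation = 0) {
  if (missing(orientation) || !orientation %in% c("dorsal-ventral", "temporal-nasal")) {
    abort("`orientation` must be \"dorsal-ventral\" or \"temporal-nasal\" (never guessed)")
  }
  if (missing(region_mapping) || !setequal(names(region_mapping), c("left", "right"))) {
    abort("`region_mapping` with `left` and `right` entries is required metadata")
  }
  expected <- if (orientation == "dorsal-ventral") c("dorsal", "ventral") else c("temporal", "nasal")
  if (!setequal(unname(region_mapping), expected)) {
    abort(sprintf("region mapping must name %s", paste(expected, collapse = " and ")))
  }
  check_columns(cells, c("cell_id", "x", "y"), "`cells`")
  x <- cells$x * cos(rotation) - cells$y * sin(rotation)
  mid <- (min(x) + max(x)) / 2
  tibble(cell_id = cells$cell_id,
         region = unname(region_mapping[ifelse(x < mid, "left", "right")]))
}

#' Compare subtype composition between two regions across sections
#'
#' Per section and region, the proportion of each unit (subtype or major
#' type) is computed under the chosen normalization (all cells, or within the
#' unit's major type), then the two regions are compared by a two-sided
#' two-sample t-test across sections; differences with p < 0.05 are flagged
#' significant.
#'
#' @param cells tibble with `cell_id`, `section`, `region`, `major_type`,
#'   `subtype`.
#' @param unit `"subtype"` or `"major_type"`.
#' @param normalization `"all_cells"` or `"within_major"`.
#' @param alpha significance level (default 0.05).
#' @return an object of class `region_comparison`; [tidy()] gives one row per
#'   unit with the region means, `t_statistic`, `p_value`, `significant`.
#' @export
compare_regional_composition <- function(cells,
                                         unit = c("subtype", "major_type"),
                                         normalization = c("all_cells", "within_major"),
                                         alpha = 0.05) {
  unit <- match.arg(unit)
  normalization <- match.arg(normalization)
  check_columns(cells, c("section", "region", "major_type", "subtype"),
                "`cells`")
  regions <- sort(unique(cells$region))
  if (length(regions) != 2) abort("exactly two regions are required")
  u <- cells[[unit]]
  denom_group <- if (normalization == "all_cells") NULL else cells$major_type
  df <- tibble(section = cells$section, region = cells$region, unit = u,
               major = cells$major_type)
  props <- df |>
    group_by(.data$section, .data$region, .data$unit, .data$major) |>
    summarise(n = n(), .groups = "drop")
  if (normalization == "all_cells") {
    props <- props |>
      group_by(.data$section, .data$region) |>
      mutate(prop = .data$n / sum(.data$n)) |>
      ungroup()
  } else {
    props <- props |>
      group_by(.data$section, .data$region, .data$major) |>
      mutate(prop = .data$n / sum(.data$n)) |>
      ungroup()
  }
  units <- sort(unique(props$unit))
  n_sec <- length(unique(df$section))
  res <- map(units, function(un) {
    a <- props$prop[props$unit == un & props$region == regions[1]]
    b <- props$prop[props$unit == un & props$region == regions[2]]
    if (!length(a) && !length(b)) {
      return(tibble(unit = un, tested = FALSE, mean_a = NA_real_,
                    mean_b = NA_real_, t_statistic = NA_real_,
                    p_value = NA_real_, significant = NA))
    }
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(unit = un, tested = FALSE, mean_a = mean(a),
                    mean_b = mean(b), t_statistic = NA_real_,
                    p_value = NA_real_, significant = NA))
    }
    if (sd(c(a - mean(a), b - mean(b))) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- t.test(a, b)
    }
    tibble(unit = un, tested = TRUE, mean_a = mean(a), mean_b = mean(b),
           t_statistic = unname(tt$statistic), p_value = tt$p.value,
           significant = tt$p.value < alpha)
  }) |> list_rbind()
  names(res)[names(res) == "mean_a"] <- paste0("mean_", regions[1])
  names(res)[names(res) == "mean_b"] <- paste0("mean_", regions[2])
  structure(
    list(result = res, regions = regions, unit = unit,
         normalization = normalization, alpha = alpha,
         per_section = props, n_sections = n_sec),
    class = "region_comparison"
  )
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("<region_comparison> %s vs %s by %s (normalized by %s)\n",
              x$regions[1], x$regions[2], x$unit, x$normalization))
  print(x$result, ...)
  invisible(x)
}

#' @rdname compare_regional_composition
#' @param x a `region_comparison` object.
#' @param ... unused.
#' @export
tidy.region_comparison <- function(x, ...) x$result

#' @rdname compare_regional_composition
#' @export
glance.region_comparison <- function(x, ...) {
  tibble(unit = x$unit, normalization = x$normalization,
         n_sections = x$n_sections,
         n_tested = sum(x$result$tested),
         n_significant = sum(x$result$significant, na.rm = TRUE),
         alpha = x$alpha)
}
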