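# Synthetic layered-tissue generator: arc-shaped sections with three nuclear
# layers (GCL innermost, then INL, then ONL), per-subtype laminar depth laws,
# seeded displacement of amacrine cells into the GCL, marker-structured
# counts at MERFISH panel scale (~80 transcripts/cell), paired reference
# data sharing per-subtype latent structure, and segmentation fixtures.
# Every generated cell carries a ground-truth record.

# per-layer major-type composition of the generated sections (fractions of
# the layer's cells; majors absent from the supplied subtype table are
# dropped and the remainder renormalized)
LAYER_MIX <- list(
  ONL = c(Rod = 0.97, Cone = 0.03),
  INL = c(BC = 0.40, AC = 0.34, MG = 0.16, HC = 0.10),
  GCL = c(RGC = 1)
)

#' Specify the geometry of one arc-shaped tissue section
#'
#' Sections are modeled as concentric arc bands around a tissue center at
#' native retinal curvature: the ganglion cell layer (GCL) innermost, the
#' inner nuclear layer (INL) above it and the outer nuclear layer (ONL)
#' outermost, with gaps for the plexiform layers. Defaults give roughly
#' 18,000-20,000 cells per section, the per-section scale of a MERFISH
#' retina experiment.
#'
#' @param center tissue center (x, y) in micrometers.
#' @param layer_radii named list of radial intervals `c(inner, outer)` in
#'   micrometers for any subset of GCL, INL, ONL; intervals must be strictly
#'   increasing and non-overlapping, ordered GCL innermost.
#' @param angular_span `c(theta_min, theta_max)` in radians.
#' @param densities named numeric, cells per square micrometer per layer.
#' @param orientation `"dorsal-ventral"` or `"temporal-nasal"`.
#' @param region_mapping named character of length 2 mapping `left`/`right`
#'   (after posterior-at-top rotation) to the two anatomical regions.
#' @param seed integer seed; mandatory, fully determines the section.
#' @return a `section_spec` object (validated list).
#' @export
section_spec <- function(center = c(0, 0),
                         layer_radii = list(GCL = c(800, 825),
                                            INL = c(835, 895),
                                            ONL = c(905, 975)),
                         angular_span = c(pi / 4, 3 * pi / 4),
                         densities = c(GCL = 0.04, INL = 0.08, ONL = 0.10),
                         orientation = c("dorsal-ventral", "temporal-nasal"),
                         region_mapping = NULL,
                         seed) {
  orientation <- match.arg(orientation)
  if (missing(seed)) abort("`seed` is mandatory in a section spec")
  check_number(seed, "seed")
  if (length(center) != 2 || any(!is.finite(center))) {
    abort("`center` must be a finite (x, y) point")
  }
  if (!length(layer_radii) || !all(names(layer_radii) %in% c("GCL", "INL", "ONL"))) {
    abort("`layer_radii` must name a subset of GCL, INL, ONL")
  }
  for (ly in names(layer_radii)) {
    if (diff(layer_radii[[ly]]) <= 0) abort(sprintf("layer %s has a zero-area band", ly))
  }
  flat <- unlist(layer_radii[intersect(c("GCL", "INL", "ONL"), names(layer_radii))])
  if (any(!is.finite(flat)) || any(diff(flat) <= 0) || any(flat <= 0)) {
    abort("radial intervals must be positive, strictly increasing and non-overlapping (GCL innermost)")
  }
  if (length(angular_span) != 2 || angular_span[1] >= angular_span[2]) {
    abort("`angular_span` must be c(theta_min, theta_max) with theta_min < theta_max")
  }
  densities <- densities[names(layer_radii)]
  if (any(is.na(densities)) || any(densities <= 0)) {
    abort("`densities` must be positive for every layer in `layer_radii`")
  }
  if (is.null(region_mapping)) {
    region_mapping <- if (orientation == "dorsal-ventral") {
      c(left = "dorsal", right = "ventral")
    } else {
      c(left = "temporal", right = "nasal")
    }
  }
  if (!setequal(names(region_mapping), c("left", "right"))) {
    abort("`region_mapping` must map exactly `left` and `right`")
  }
  structure(
    list(center = as.numeric(center), layer_radii = layer_radii,
         angular_span = as.numeric(angular_span), densities = densities,
         orientation = orientation, region_mapping = region_mapping,
         seed = as.integer(seed)),
    class = "section_spec"
  )
}

#' Build a gene universe with a designated MERFISH panel subset
#'
#' @param n_genes total genes in the universe.
#' @param n_panel leading subset measured by the imaging panel.
#' @return tibble with `gene`, `panel`.
#' @export
gene_universe <- function(n_genes = 500, n_panel = 300) {
  if (n_panel > n_genes) abort("`n_panel` cannot exceed `n_genes`")
  tibble(
    gene = sprintf("g%04d", seq_len(n_genes)),
    panel = seq_len(n_genes) <= n_panel
  )
}

#' Default retinal subtype table
#'
#' Builds a table of cell subtypes with the laminar structure of the mouse
#' retina: rods and cones in the ONL; bipolar (BC, including an apically
#' positioned rod bipolar RBC and a basally positioned BC1B-like subtype),
#' amacrine (AC, twelve subtypes of which three are preferentially displaced
#' into the GCL at ratios 0.2/0.5/0.8 over a 0.05 background), horizontal
#' and Mueller glia subtypes in the INL; and ganglion cells in the GCL.
#' Laminar depth follows a Beta law per subtype; expression profiles are
#' marker-structured over the gene universe (per-major marker blocks plus
#' per-subtype markers and pervasive log-normal subtype variation); latent
#' means are placed with a guaranteed minimum pairwise separation.
#'
#' The RBC abundance within BC is 0.35 in the first (left) region and 0.30
#' in the second, emulating the dorsal-ventral asymmetry of rod bipolar
#' cells; all other subtypes are symmetric.
#'
#' @param genes a [gene_universe()] tibble.
#' @param latent_dim dimension of the shared co-embedding latents.
#' @param latent_sep minimum pairwise separation of subtype latent means, in
#'   units of `latent_sd`.
#' @param latent_sd within-subtype latent standard deviation.
#' @param seed integer seed for profile and latent construction.
#' @param displacement_ratios named displacement ratios for AC subtypes that
#'   deviate from `background_displacement`.
#' @param background_displacement displacement ratio of the remaining ACs.
#' @return a `subtype_table` tibble (one row per subtype) with list-columns
#'   `expression_profile` and `latent_mean`; the gene universe is attached as
#'   attribute `genes`.
#' @export
retina_subtypes <- function(genes = gene_universe(),
                            latent_dim = 15,
                            latent_sep = 6,
                            latent_sd = 1,
                            seed = 42,
                            displacement_ratios = c(AC03 = 0.2, AC07 = 0.5,
                                                    AC11 = 0.8),
                            background_displacement = 0.05) {
  check_number(latent_dim, "latent_dim", 2)
  check_number(background_displacement, "background_displacement", 0, 1)
  base <- tribble(
    ~name,   ~major_type, ~w,    ~w2,   ~depth_a, ~depth_b,
    "Rod",   "Rod",       1,     NA,    2,   2,
    "Cone",  "Cone",      1,     NA,    1.5, 4,
    "RBC",   "BC",        0.35,  0.30,  2,   8,
    "BC_A",  "BC",        0.20,  NA,    3,   5,
    "BC_B",  "BC",        0.20,  NA,    4,   4,
    "BC_C",  "BC",        0.20,  NA,    5,   2.5,
    "BC1B",  "BC",        0.05,  NA,    6,   4,
    "HC",    "HC",        1,     NA,    1.5, 12,
    "MG",    "MG",        1,     NA,    1.3, 1.3,
    "RGC_A", "RGC",       0.6,   NA,    3,   3,
    "RGC_B", "RGC",       0.4,   NA,    3,   3
  )
  acs <- tibble(
    name = sprintf("AC%02d", 1:12),
    major_type = "AC",
    w = 1 / 12, w2 = NA_real_,
    # glycinergic-like apical half and GABAergic-like basal half
    depth_a = rep(c(4, 6), each = 6),
    depth_b = rep(c(5, 3), each = 6)
  )
  tab <- bind_rows(base, acs)
  tab$displacement_ratio <- ifelse(tab$major_type == "AC",
                                   background_displacement, 0)
  if (length(displacement_ratios)) {
    miss <- setdiff(names(displacement_ratios), tab$name)
    if (length(miss)) abort(sprintf("unknown subtype(s) in displacement_ratios: %s",
                                    paste(miss, collapse = ", ")))
    tab$displacement_ratio[match(names(displacement_ratios), tab$name)] <-
      unname(displacement_ratios)
  }
  # normalize abundances within each major type; in the second region,
  # subtypes with an explicit w2 take exactly that share and the remaining
  # subtypes absorb the complement in proportion to their first-region weights
  tab <- tab |>
    group_by(.data$major_type) |>
    mutate(
      abundance = .data$w / sum(.data$w),
      w2n = .data$w2 / sum(.data$w),  # explicit second-region share
      abundance2 = ifelse(
        is.na(.data$w2n),
        .data$abundance * (1 - sum(.data$w2n, na.rm = TRUE)) /
          max(sum(.data$abundance[is.na(.data$w2n)]), 1e-12),
        .data$w2n
      )
    ) |>
    ungroup() |>
    select(-"w", -"w2", -"w2n")

  n_genes <- nrow(genes)
  n_sub <- nrow(tab)
  with_seed(derive_seed(seed, "subtype-profiles"), {
    base_level <- exp(rnorm(n_genes, 0, 0.5))
    # per-major marker blocks within the panel (8 genes each), then 2
    # panel marker genes per subtype, then pervasive subtype variation
    majors <- unique(tab$major_type)
    panel_idx <- which(genes$panel)
    blocks <- split(panel_idx[seq_len(min(length(panel_idx), 8 * length(majors)))],
                    rep(seq_along(majors), each = 8))
    names(blocks) <- majors
    next_free <- setdiff(panel_idx, unlist(blocks))
    sub_markers <- split(next_free[seq_len(min(length(next_free), 2 * n_sub))],
                         rep(seq_len(n_sub), each = 2))
    profiles <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      prof <- base_level * exp(rnorm(n_genes, 0, 0.6))
      prof[blocks[[tab$major_type[s]]]] <- prof[blocks[[tab$major_type[s]]]] * 10
      if (s <= length(sub_markers)) prof[sub_markers[[s]]] <- prof[sub_markers[[s]]] * 8
      profiles[[s]] <- prof
    }
    # maximin placement of latent means with guaranteed pairwise separation
    min_sep <- latent_sep * latent_sd
    means <- list()
    tries <- 0
    while (length(means) < n_sub) {
      cand <- rnorm(latent_dim, 0, max(2.5, min_sep / 2))
      ok <- all(vapply(means, function(m) sqrt(sum((m - cand)^2)) >= min_sep,
                       logical(1)))
      if (ok) means[[length(means) + 1]] <- cand
      tries <- tries + 1
      if (tries > 100000) abort("could not place latent means at the requested separation")
    }
  })
  tab$expression_profile <- profiles
  tab$latent_mean <- means
  tab$latent_sd <- latent_sd
  marker_sets <- lapply(blocks, function(ix) genes$gene[ix])
  attr(tab, "genes") <- genes
  attr(tab, "marker_sets") <- marker_sets
  class(tab) <- c("subtype_table", class(tab))
  tab
}

check_subtypes <- function(subtypes) {
  if (is.null(subtypes) || !nrow(subtypes)) abort("subtype list is empty")
  check_columns(subtypes, c("name", "major_type", "abundance", "depth_a",
                            "depth_b", "displacement_ratio",
                            "expression_profile", "latent_mean", "latent_sd"),
                "subtype table")
  if (any(subtypes$depth_a <= 0 | subtypes$depth_b <= 0)) {
    abort("Beta depth parameters must be positive")
  }
  if (any(subtypes$displacement_ratio < 0 | subtypes$displacement_ratio > 1)) {
    abort("displacement_ratio must be in [0, 1]")
  }
  bad <- vapply(subtypes$expression_profile,
                function(p) any(!is.finite(p)) || any(p < 0) || sum(p) == 0,
                logical(1))
  if (any(bad)) {
    abort(sprintf("non-finite or non-positive expression profile for subtype(s): %s",
                  paste(subtypes$name[bad], collapse = ", ")))
  }
  sums <- subtypes |>
    group_by(.data$major_type) |>
    summarise(s = sum(.data$abundance))
  if (any(abs(sums$s - 1) > 1e-8)) {
    abort("abundances within each major type must sum to 1")
  }
  if (any(subtypes$latent_sd <= 0)) abort("latent_sd must be positive")
  invisible(subtypes)
}

#' Generate one synthetic tissue section with ground truth
#'
#' Places cells in the arc bands of `spec` at per-subtype Beta-distributed
#' normalized depths (0 = apical = outer edge of the band), displaces each
#' amacrine cell into the GCL with its subtype's displacement probability,
#' draws panel-gene counts as Poisson around the subtype expression profile
#' scaled to `target_total` transcripts per cell, and draws shared-embedding
#' latents from the subtype Gaussians. Subtype composition may differ between
#' the two halves of the section (column `abundance2`), emulating regional
#' asymmetries.
#'
#' @param spec a [section_spec()].
#' @param subtypes a [retina_subtypes()]-style table.
#' @param target_total mean transcripts per cell over the panel (default 80).
#' @param section_id label stored with every cell.
#' @return a `retina_section` list: `cells` (tibble: cell_id, section, x, y,
#'   major_type, subtype), `counts` (sparse cells x panel-genes), `latents`
#'   (matrix), `truth` (tibble with true layer, depth, region, displacement),
#'   `genes`, `spec`.
#' @export
generate_section <- function(spec, subtypes, target_total = 80,
                             section_id = "S1") {
  stopifnot(inherits(spec, "section_spec"))
  check_subtypes(subtypes)
  check_number(target_total, "target_total", 1)
  genes <- attr(subtypes, "genes")
  if (is.null(genes)) abort("subtype table lacks the `genes` attribute")

  with_seed(derive_seed(spec$seed, paste0("section-", section_id)), {
    th <- spec$angular_span
    mid_theta <- mean(th)
    rows <- list()
    for (layer in names(spec$layer_radii)) {
      rr <- spec$layer_radii[[layer]]
      area <- 0.5 * (th[2] - th[1]) * (rr[2]^2 - rr[1]^2)
      n <- round(area * spec$densities[[layer]])
      if (n == 0) next
      mix <- LAYER_MIX[[layer]]
      mix <- mix[names(mix) %in% subtypes$major_type]
      if (!length(mix)) next
      mix <- mix / sum(mix)
      theta <- runif(n, th[1], th[2])
      # left half of the section is the larger-angle side (posterior at top)
      side2 <- theta < mid_theta
      major <- sample(names(mix), n, replace = TRUE, prob = mix)
      sub <- character(n)
      for (mj in unique(major)) {
        st <- subtypes[subtypes$major_type == mj, ]
        sel1 <- which(major == mj & !side2)
        sel2 <- which(major == mj & side2)
        ab2 <- if ("abundance2" %in% names(st)) st$abundance2 else st$abundance
        if (length(sel1)) sub[sel1] <- sample(st$name, length(sel1), TRUE, st$abundance)
        if (length(sel2)) sub[sel2] <- sample(st$name, length(sel2), TRUE, ab2)
      }
      rows[[layer]] <- tibble(layer = layer, theta = theta, subtype = sub,
                              major_type = major)
    }
    if (!length(rows)) abort("no cells generated: no layer/major-type overlap")
    cells <- bind_rows(rows)
    n <- nrow(cells)
    si <- match(cells$subtype, subtypes$name)

    # amacrine displacement into the GCL
    disp <- rbinom(n, 1, subtypes$displacement_ratio[si]) == 1 &
      cells$major_type == "AC"
    if (any(disp) && !"GCL" %in% names(spec$layer_radii)) {
      abort("displaced cells require a GCL band in the section spec")
    }
    layer_true <- ifelse(disp, "GCL", cells$layer)

    # radial placement: Beta depth within the resident band, 0 = apical
    # (outer) edge; displaced cells are uniform within the GCL band
    depth <- rbeta(n, subtypes$depth_a[si], subtypes$depth_b[si])
    depth[disp] <- runif(sum(disp))
    r_in <- unname(vapply(layer_true, function(l) spec$layer_radii[[l]][1],
                          numeric(1)))
    r_out <- unname(vapply(layer_true, function(l) spec$layer_radii[[l]][2],
                           numeric(1)))
    r <- r_out - depth * (r_out - r_in)
    x <- spec$center[1] + r * cos(cells$theta)
    y <- spec$center[2] + r * sin(cells$theta)

    # region truth follows the analysis rule: split at the x midpoint
    mid_x <- (min(x) + max(x)) / 2
    region <- unname(spec$region_mapping[ifelse(x < mid_x, "left", "right")])

    cell_id <- sprintf("%s_c%05d", section_id, seq_len(n))
    panel <- genes$gene[genes$panel]
    prof <- do.call(cbind, subtypes$expression_profile)  # genes x subtypes
    lam_panel <- prof[genes$panel, si, drop = FALSE]
    lam_panel <- sweep(lam_panel, 2, colSums(lam_panel), "/") * target_total
    counts_dense <- matrix(rpois(length(lam_panel), lam_panel),
                           nrow = length(panel))
    counts <- methods::as(Matrix::Matrix(t(counts_dense), sparse = TRUE),
                          "CsparseMatrix")
    dimnames(counts) <- list(cell_id, panel)

    d <- length(subtypes$latent_mean[[1]])
    mu <- do.call(cbind, subtypes$latent_mean)  # d x subtypes
    latents <- t(mu[, si, drop = FALSE] +
                   matrix(rnorm(d * n, 0, rep(subtypes$latent_sd[si], each = d)),
                          nrow = d))
    rownames(latents) <- cell_id

    out_cells <- tibble(
      cell_id = cell_id, section = section_id, x = x, y = y,
      major_type = cells$major_type, subtype = cells$subtype
    )
    truth <- tibble(
      cell_id = cell_id, section = section_id,
      subtype = cells$subtype, major_type = cells$major_type,
      layer = layer_true, displaced = disp,
      depth = depth, region = region,
      requested_displacement = subtypes$displacement_ratio[si]
    )
    structure(
      list(cells = out_cells, counts = counts, latents = latents,
           truth = truth, genes = genes, spec = spec),
      class = "retina_section"
    )
  })
}

#' @export
print.retina_section <- function(x, ...) {
  cat(sprintf("<retina_section> %d cells, %d panel genes, layers: %s\n",
              nrow(x$cells), ncol(x$counts),
              paste(names(x$spec$layer_radii), collapse = "/")))
  invisible(x)
}

#' Generate a paired single-cell reference set
#'
#' Reference cells carry subtype labels, counts over the full gene universe
#' (deeper than the imaging panel, emulating scRNA-seq), and latents drawn
#' from the same per-subtype Gaussians as the query sections, emulating a
#' successful co-embedding of the two modalities.
#'
#' @param subtypes a [retina_subtypes()]-style table.
#' @param n_cells number of reference cells (at least one per subtype).
#' @param n_genes genes measured (>= panel size; defaults to the full universe).
#' @param target_total mean transcripts per reference cell (default 1000).
#' @param seed integer seed.
#' @return a `reference_set`: list with `counts` (sparse cells x genes),
#'   `labels` (tibble: cell_id, subtype, major_type), `latents`, `genes`.
#' @export
generate_reference <- function(subtypes, n_cells = 5000, n_genes = NULL,
                               target_total = 1000, seed = 1) {
  check_subtypes(subtypes)
  genes <- attr(subtypes, "genes")
  if (is.null(n_genes)) n_genes <- nrow(genes)
  n_panel <- sum(genes$panel)
  if (n_genes < n_panel) abort("`n_genes` must cover at least the panel")
  if (n_cells < nrow(subtypes)) {
    abort("`n_cells` must be at least the number of subtypes")
  }
  mu <- do.call(cbind, subtypes$latent_mean)
  if (min(stats::dist(t(mu))) <= 0) abort("subtype latent means must be pairwise distinct")

  with_seed(derive_seed(seed, "reference"), {
    n_sub <- nrow(subtypes)
    lab <- c(seq_len(n_sub),
             sample(seq_len(n_sub), n_cells - n_sub, replace = TRUE))
    lab <- sample(lab)  # shuffle so subtype blocks are not contiguous
    cell_id <- sprintf("ref_c%05d", seq_len(n_cells))
    gsel <- seq_len(n_genes)
    prof <- do.call(cbind, subtypes$expression_profile)[gsel, , drop = FALSE]
    lam <- sweep(prof[, lab, drop = FALSE], 2,
                 colSums(prof[, lab, drop = FALSE]), "/") * target_total
    counts <- methods::as(Matrix::Matrix(
      t(matrix(rpois(length(lam), lam), nrow = n_genes)), sparse = TRUE),
      "CsparseMatrix")
    dimnames(counts) <- list(cell_id, genes$gene[gsel])
    d <- nrow(mu)
    latents <- t(mu[, lab, drop = FALSE] +
                   matrix(rnorm(d * n_cells, 0,
                                rep(subtypes$latent_sd[lab], each = d)),
                          nrow = d))
    rownames(latents) <- cell_id
    structure(
      list(counts = counts,
           labels = tibble(cell_id = cell_id,
                           subtype = subtypes$name[lab],
                           major_type = subtypes$major_type[lab]),
           latents = latents,
           genes = genes[gsel, ]),
      class = "reference_set"
    )
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d cells, %d genes, %d subtypes\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$labels$subtype))))
  invisible(x)
}

# uniform sampling inside a convex polygon by triangle-fan decomposition
sample_in_polygon <- function(v, n) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  nv <- nrow(v)
  tri_areas <- vapply(2:(nv - 1), function(k) {
    poly_area(v[c(1, k, k + 1), , drop = FALSE])
  }, numeric(1))
  tk <- sample.int(nv - 2, n, replace = TRUE, prob = tri_areas)
  a <- v[1, ]
  b <- v[tk + 1, , drop = FALSE]
  cc <- v[tk + 2, , drop = FALSE]
  u1 <- runif(n); u2 <- runif(n)
  flip <- u1 + u2 > 1
  u1[flip] <- 1 - u1[flip]; u2[flip] <- 1 - u2[flip]
  cbind(a[1] + u1 * (b[, 1] - a[1]) + u2 * (cc[, 1] - a[1]),
        a[2] + u1 * (b[, 2] - a[2]) + u2 * (cc[, 2] - a[2]))
}

regular_polygon <- function(center, radius, k = 12, phase = 0) {
  ang <- phase + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
}

#' Generate a two-segmenter polygon fixture for a cell table
#'
#' Emulates the raw material of dual segmentation: a primary polygon set
#' covering most cells, a rescue set covering the remainder plus a block of
#' rescue polygons constructed with exact, recorded overlap fractions against
#' paired primary squares (so the merge rule can be verified against truth),
#' decoded transcript spots scattered inside each cell's polygon according to
#' the count matrix, and per-cell DAPI intensities drawn so the QC threshold
#' bites. Segmentation coordinates are in image pixels (the QC bounds are
#' pixel quantities); centroids are scaled from micrometers by `px_per_um`.
#'
#' @param section a `retina_section` (or a list with `cells` and `counts`).
#' @param params list of overrides: `primary_fraction` (cells with a primary
#'   polygon, default 0.85), `overlap_fractions` (exact area-overlap fractions
#'   for the constructed rescue/primary square pairs, default
#'   `c(0, 1e-4, 1e-3, 0.01, 1)`), `px_per_um` (default 9.26), `poly_radius`
#'   (regular-polygon circumradius in px, default 14), `square_side` (side of
#'   the overlap-pair squares in px, default 26), `dapi_mean` (default 150),
#'   `dapi_sd` (default 40).
#' @param seed integer seed.
#' @return list with `primary` and `rescue` (`segmentation_set` tibbles),
#'   `spots` (tibble: gene, x, y, true_cell), `dapi` (tibble: cell_id,
#'   dapi_mean), and `truth` (per-cell polygon assignment and the exact
#'   overlap fraction of constructed pairs).
#' @export
generate_segmentation_fixture <- function(section, params = list(), seed = 1) {
  cells <- section$cells
  if (is.null(cells) || !nrow(cells)) abort("`section` has no cells")
  p <- modifyList(list(primary_fraction = 0.85,
                       overlap_fractions = c(0, 1e-4, 1e-3, 0.01, 1),
                       px_per_um = 9.26, poly_radius = 14,
                       square_side = 26, dapi_mean = 150, dapi_sd = 40),
                  params)
  if (any(p$overlap_fractions < 0 | p$overlap_fractions > 1)) {
    abort("overlap fractions must be in [0, 1]")
  }
  with_seed(derive_seed(seed, "segmentation-fixture"), {
    n <- nrow(cells)
    px <- cbind(cells$x, cells$y) * p$px_per_um
    n_primary <- max(1, round(p$primary_fraction * n))
    prim_idx <- sort(sample.int(n, n_primary))
    resc_idx <- setdiff(seq_len(n), prim_idx)

    make_poly <- function(i) {
      regular_polygon(px[i, ], p$poly_radius * runif(1, 0.85, 1.2),
                      k = 12, phase = runif(1, 0, pi / 6))
    }
    s <- p$square_side
    square <- function(center) {
      cbind(center[1] + c(-s, s, s, -s) / 2, center[2] + c(-s, -s, s, s) / 2)
    }
    primary_polys <- vector("list", n_primary)
    names(primary_polys) <- cells$cell_id[prim_idx]
    for (k in seq_along(prim_idx)) {
      primary_polys[[k]] <- make_poly(prim_idx[k])
    }
    # overlap-pair block: synthetic primary squares paired with shifted
    # rescue squares, placed on an isolated row below the tissue so the
    # recorded overlap fraction is exact (no neighbour contamination)
    n_over <- length(p$overlap_fractions)
    truth_over <- tibble(cell_id = character(0), pairs_with = character(0),
                         overlap_fraction = numeric(0))
    over_centers <- NULL
    if (n_over) {
      y0 <- min(px[, 2]) - 20 * s
      over_centers <- cbind(min(px[, 1]) + (seq_len(n_over) - 1) * 6 * s, y0)
      for (k in seq_len(n_over)) {
        primary_polys[[sprintf("prim_over_%02d", k)]] <- square(over_centers[k, ])
      }
    }
    # rescue: own polygons for uncovered cells plus the overlap-pair squares
    rescue_polys <- list()
    for (i in resc_idx) {
      rescue_polys[[paste0("resc_", cells$cell_id[i])]] <- make_poly(i)
    }
    for (k in seq_len(n_over)) {
      f <- p$overlap_fractions[k]
      dx <- s * (1 - f)
      id <- sprintf("resc_over_%02d", k)
      rescue_polys[[id]] <- square(over_centers[k, ] + c(dx, 0))
      truth_over <- add_row(truth_over, cell_id = id,
                            pairs_with = sprintf("prim_over_%02d", k),
                            overlap_fraction = f)
    }
    primary <- segmentation_set(primary_polys, source = "primary")
    rescue <- segmentation_set(rescue_polys, source = "rescue")

    # scatter transcript spots inside each cell's polygon per the counts
    counts <- section$counts
    poly_of <- c(primary_polys, rescue_polys)
    owner <- setNames(rep(NA_character_, n), cells$cell_id)
    owner[cells$cell_id[prim_idx]] <- cells$cell_id[prim_idx]
    owner[cells$cell_id[resc_idx]] <- paste0("resc_", cells$cell_id[resc_idx])
    trip <- Matrix::summary(methods::as(counts, "TsparseMatrix"))
    per_cell <- split(seq_len(nrow(trip)), trip$i)
    spot_rows <- vector("list", length(per_cell))
    gene_names <- colnames(counts)
    for (k in seq_along(per_cell)) {
      rows <- per_cell[[k]]
      i <- trip$i[rows[1]]
      tot <- sum(trip$x[rows])
      xy <- sample_in_polygon(poly_of[[owner[i]]], tot)
      spot_rows[[k]] <- tibble(
        gene = rep(gene_names[trip$j[rows]], trip$x[rows]),
        x = xy[, 1], y = xy[, 2],
        true_cell = cells$cell_id[i]
      )
    }
    spots <- bind_rows(spot_rows)
    all_ids <- c(names(primary_polys), names(rescue_polys))
    dapi <- tibble(cell_id = all_ids,
                   dapi_mean = pmax(0, rnorm(length(all_ids),
                                             p$dapi_mean, p$dapi_sd)))
    list(primary = primary, rescue = rescue, spots = spots, dapi = dapi,
         truth = list(overlap_pairs = truth_over,
                      owner = tibble(cell_id = cells$cell_id,
                                     polygon_id = unname(owner))))
  })
}

#' Uniform arc-band fixture with exact radial depth truth
#'
#' Scatters points uniformly (in area) in an arc band at native retinal
#' curvature; the true apical-referenced normalized depth of a point at
#' radius r is (r_outer - r) / (r_outer - r_inner). Used to validate
#' boundary recovery and the depth ratio end to end.
#'
#' @param n number of points.
#' @param r_range `c(inner, outer)` radii in micrometers.
#' @param angular_span `c(theta_min, theta_max)` radians.
#' @param center tissue center.
#' @param seed integer seed.
#' @return tibble: `cell_id`, `x`, `y`, `r`, `depth_true`.
#' @export
generate_band_fixture <- function(n = 2000, r_range = c(900, 1100),
                                  angular_span = c(pi / 4, 3 * pi / 4),
                                  center = c(0, 0), seed = 1) {
  if (diff(r_range) <= 0) abort("zero-area band")
  with_seed(derive_seed(seed, "band-fixture"), {
    r <- sqrt(runif(n, r_range[1]^2, r_range[2]^2))
    th <- runif(n, angular_span[1], angular_span[2])
    tibble(
      cell_id = sprintf("band_c%05d", seq_len(n)),
      x = center[1] + r * cos(th),
      y = center[2] + r * sin(th),
      r = r,
      depth_true = (r_range[2] - r) / (r_range[2] - r_range[1])
    )
  })
}
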