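# End-to-end pipeline: simulate -> segment-merge -> qc -> boundaries ->
# depth -> layer-assignment -> displacement -> transfer -> impute -> regions.
# Stages are skippable; every run emits a manifest with per-stage wall clock
# and md5 checksums of all written outputs. No stage mutates its inputs on
# disk; everything goes to the configured run directory.

# INL boundary point cloud: majors resident in the INL whose cells never
# leave it (ACs are excluded because displaced ACs sit in the GCL)
INL_PROXY_MAJORS <- c("BC", "HC", "MG")

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order on synthetic or on-disk inputs,
#' writes all declared outputs under `config$out_dir`, and returns a run
#' manifest. Deterministic for a fixed config (identical reruns give
#' identical output checksums).
#'
#' @param config a [read_config()] result (or a list/path accepted by it).
#' @return a `run_manifest` (invisibly): tool version, config hash, per-stage
#'   wall clock, output checksums, warnings.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- read_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$warnings <- character(0)
  manifest <- list(
    tool_version = as.character(utils::packageVersion("stratafish")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = list()
  )
  stage_defs <- list(
    "simulate" = stage_simulate,
    "segment-merge" = stage_segment_merge,
    "qc" = stage_qc,
    "boundaries" = stage_boundaries,
    "depth" = stage_depth,
    "layer-assignment" = stage_layers,
    "displacement" = stage_displacement,
    "transfer" = stage_transfer,
    "impute" = stage_impute,
    "regions" = stage_regions
  )
  for (nm in names(stage_defs)) {
    if (!nm %in% config$stages) next
    t0 <- proc.time()[["elapsed"]]
    outputs <- withCallingHandlers(
      tryCatch(
        stage_defs[[nm]](config, state),
        error = function(e) {
          abort(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)))
        }
      ),
      warning = function(w) {
        state$warnings <- c(state$warnings,
                            sprintf("[%s] %s", nm, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    elapsed <- proc.time()[["elapsed"]] - t0
    sums <- if (length(outputs)) {
      s <- tools::md5sum(outputs)
      setNames(unname(s), basename(outputs))
    } else NULL
    manifest$stages[[nm]] <- list(seconds = round(elapsed, 3),
                                  outputs = as.list(sums))
    inform(sprintf("stage %-16s %6.1fs  %d output(s)", nm, elapsed,
                   length(outputs)))
  }
  manifest$warnings <- state$warnings
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> stratafish %s, seed %s, %d stage(s), %d warning(s)\n",
              x$tool_version, x$seed, length(x$stages), length(x$warnings)))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-16s %8.1fs  %d output(s)\n", nm, x$stages[[nm]]$seconds,
                length(x$stages[[nm]]$outputs)))
  }
  invisible(x)
}

need <- function(state, what, stage) {
  if (is.null(state[[what]])) {
    abort(sprintf("requires '%s', which no earlier stage produced (offending input: %s)",
                  stage, what))
  }
  state[[what]]
}

stage_simulate <- function(config, state) {
  genes <- gene_universe(config$n_genes, config$n_panel)
  subtypes <- retina_subtypes(genes, seed = config$seed)
  sections <- map(seq_len(config$n_sections), function(i) {
    spec <- section_spec(orientation = config$orientation,
                         region_mapping = config$region_mapping,
                         densities = config$densities,
                         seed = derive_seed(config$seed, sprintf("sec%d", i)))
    generate_section(spec, subtypes, target_total = config$target_total,
                     section_id = sprintf("S%d", i))
  })
  state$subtypes <- subtypes
  state$sections <- sections
  state$reference <- generate_reference(subtypes, n_cells = config$n_reference,
                                        seed = derive_seed(config$seed, "ref"))
  state$fixtures <- map(seq_along(sections), function(i) {
    generate_segmentation_fixture(sections[[i]],
                                  seed = derive_seed(config$seed,
                                                     sprintf("fix%d", i)))
  })
  out <- character(0)
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    p <- file.path(config$out_dir, sprintf("section%d_cells.csv", i))
    write_cells(sec$cells, p)
    tpath <- file.path(config$out_dir, sprintf("section%d_truth.csv", i))
    readr::write_csv(sec$truth, tpath, progress = FALSE)
    stem <- file.path(config$out_dir, sprintf("section%d_counts", i))
    write_counts(sec$counts, stem)
    lpath <- file.path(config$out_dir, sprintf("section%d_latents.csv", i))
    write_latents(sec$latents, lpath)
    out <- c(out, p, tpath, paste0(stem, c(".mtx", ".cells.tsv", ".genes.tsv")),
             lpath)
  }
  rstem <- file.path(config$out_dir, "reference_counts")
  write_counts(state$reference$counts, rstem)
  rl <- file.path(config$out_dir, "reference_latents.csv")
  write_latents(state$reference$latents, rl)
  c(out, paste0(rstem, c(".mtx", ".cells.tsv", ".genes.tsv")), rl)
}

stage_segment_merge <- function(config, state) {
  fixtures <- need(state, "fixtures", "segment-merge")
  out <- character(0)
  state$merged <- vector("list", length(fixtures))
  state$assigned_spots <- vector("list", length(fixtures))
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    merged <- merge_segmentations(fx$primary, fx$rescue,
                                  overlap_threshold = config$overlap_threshold)
    spots <- assign_transcripts(fx$spots, merged)
    state$merged[[i]] <- merged
    state$assigned_spots[[i]] <- spots
    gp <- file.path(config$out_dir, sprintf("section%d_merged.geojson", i))
    write_polygons(merged, gp)
    sp <- file.path(config$out_dir, sprintf("section%d_spots.csv", i))
    write_spots(spots, sp)
    out <- c(out, gp, sp)
  }
  out
}

stage_qc <- function(config, state) {
  merged <- need(state, "merged", "qc")
  fixtures <- need(state, "fixtures", "qc")
  sections <- need(state, "sections", "qc")
  out <- character(0)
  state$qc_cells <- vector("list", length(merged))
  for (i in seq_along(merged)) {
    metrics <- polygon_metrics(merged[[i]], state$assigned_spots[[i]],
                               fixtures[[i]]$dapi)
    kept <- qc_filter(metrics, config$qc_thresholds)
    # map retained polygon ids back to generated cells
    owner <- fixtures[[i]]$truth$owner
    retained_cells <- owner$cell_id[owner$polygon_id %in% kept$cell_id]
    state$qc_cells[[i]] <- sections[[i]]$cells |>
      filter(.data$cell_id %in% retained_cells)
    mp <- file.path(config$out_dir, sprintf("section%d_qc_metrics.csv", i))
    readr::write_csv(metrics |>
                       mutate(retained = .data$cell_id %in% kept$cell_id),
                     mp, progress = FALSE)
    out <- c(out, mp)
  }
  out
}

stage_boundaries <- function(config, state) {
  sections <- need(state, "sections", "boundaries")
  cells <- state$qc_cells %||% map(sections, "cells")
  out <- character(0)
  state$chains <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    cc <- cells[[i]]
    inl <- cc |> filter(.data$major_type %in% INL_PROXY_MAJORS)
    ctr <- estimate_tissue_center(cc)
    shape <- build_alpha_shape(inl, alpha = config$alpha)
    chains <- classify_boundary_edges(shape, ctr,
                                      lateral_fraction = config$lateral_fraction)
    state$chains[[i]] <- chains
    gp <- file.path(config$out_dir, sprintf("section%d_boundaries.geojson", i))
    write_boundary_chains(chains, gp)
    out <- c(out, gp)
  }
  out
}

# chains as GeoJSON LineStrings (one per contiguous run) with a "role" property
write_boundary_chains <- function(chains, path) {
  feat <- function(mat, role) {
    list(type = "Feature", properties = list(role = role),
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(mat)), function(i)
             c(mat[i, 1], mat[i, 2]))
         ))
  }
  features <- list()
  for (role in c("apical", "basal", "lateral")) {
    for (pl in chain_polylines(chains, role)) {
      features <- c(features, list(feat(pl, role)))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stage_depth <- function(config, state) {
  sections <- need(state, "sections", "depth")
  chains <- need(state, "chains", "depth")
  cells <- state$qc_cells %||% map(sections, "cells")
  out <- character(0)
  state$depths <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    cc <- cells[[i]] |>
      filter(.data$major_type %in% c(INL_PROXY_MAJORS, "AC"))
    dep <- normalized_depth(cc, chains[[i]], from = config$depth_from)
    state$depths[[i]] <- dep
    dp <- file.path(config$out_dir, sprintf("section%d_depth.csv", i))
    readr::write_csv(dep, dp, progress = FALSE)
    out <- c(out, dp)
  }
  # laminar position summary across sections
  all_dep <- list_rbind(state$depths)
  labels <- list_rbind(map(seq_along(sections), function(i) {
    cells[[i]] |> select("cell_id", "subtype", "section")
  }))
  state$laminar <- summarize_laminar_positions(all_dep, labels,
                                               min_cells = config$min_cells)
  lp <- file.path(config$out_dir, "laminar_positions.csv")
  readr::write_csv(state$laminar$summary, lp, progress = FALSE)
  tp <- file.path(config$out_dir, "laminar_pairwise_tests.csv")
  readr::write_csv(state$laminar$tests, tp, progress = FALSE)
  c(out, lp, tp)
}

stage_layers <- function(config, state) {
  sections <- need(state, "sections", "layer-assignment")
  chains <- need(state, "chains", "layer-assignment")
  cells <- state$qc_cells %||% map(sections, "cells")
  out <- character(0)
  state$ac_layers <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    acs <- cells[[i]] |> filter(.data$major_type == "AC")
    ref <- assign_ac_layers(cells[[i]], alpha = config$alpha,
                            lateral_fraction = config$lateral_fraction,
                            tissue_center = chains[[i]]$tissue_center)
    lay <- ref$layers
    state$ac_layers[[i]] <- acs |>
      select("cell_id", "section", "subtype") |>
      left_join(lay |> select("cell_id", "layer"), by = "cell_id")
    lp <- file.path(config$out_dir, sprintf("section%d_ac_layers.csv", i))
    readr::write_csv(state$ac_layers[[i]], lp, progress = FALSE)
    out <- c(out, lp)
  }
  out
}

stage_displacement <- function(config, state) {
  ac <- list_rbind(need(state, "ac_layers", "displacement")) |>
    filter(.data$layer %in% c("INL", "GCL"))
  res <- displacement_test(ac, n_perm = config$n_perm,
                           alpha = config$alpha_level,
                           min_cells = config$min_cells,
                           seed = derive_seed(config$seed, "perm"))
  state$displacement <- res
  dp <- file.path(config$out_dir, "displacement.csv")
  readr::write_csv(tidy(res), dp, progress = FALSE)
  jp <- file.path(config$out_dir, "displacement_params.json")
  jsonlite::write_json(
    list(n_perm = res$n_perm, alpha = res$alpha, min_cells = res$min_cells,
         seed = res$seed, conservative = res$conservative),
    jp, auto_unbox = TRUE, digits = NA)
  c(dp, jp)
}

stage_transfer <- function(config, state) {
  sections <- need(state, "sections", "transfer")
  ref <- need(state, "reference", "transfer")
  classifier <- train_reference_classifier(ref, seed = derive_seed(config$seed, "svm"))
  out <- character(0)
  state$transfer <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    tr <- transfer_labels(sections[[i]]$latents, ref, classifier,
                          k = config$k_transfer)
    state$transfer[[i]] <- tr
    tp <- file.path(config$out_dir, sprintf("section%d_transfer.csv", i))
    readr::write_csv(tidy(tr), tp, progress = FALSE)
    out <- c(out, tp)
  }
  state$classifier <- classifier
  out
}

stage_impute <- function(config, state) {
  sections <- need(state, "sections", "impute")
  ref <- need(state, "reference", "impute")
  transfer <- need(state, "transfer", "impute")
  major_of <- setNames(ref$labels$major_type, ref$labels$subtype)
  out <- character(0)
  state$imputed <- vector("list", length(sections))
  for (i in seq_along(sections)) {
    q <- sections[[i]]$latents
    qt <- unname(major_of[tidy(transfer[[i]])$assigned])
    imp <- impute_expression(q, qt, ref, mode = config$impute_mode,
                             k = config$k_impute,
                             measured = sections[[i]]$counts)
    ev <- evaluate_imputation(imp$expression, as.matrix(sections[[i]]$counts))
    state$imputed[[i]] <- list(imputation = imp, eval = ev)
    ep <- file.path(config$out_dir, sprintf("section%d_imputation_pcc.csv", i))
    readr::write_csv(ev$per_gene, ep, progress = FALSE)
    out <- c(out, ep)
  }
  out
}

stage_regions <- function(config, state) {
  sections <- need(state, "sections", "regions")
  cells <- state$qc_cells %||% map(sections, "cells")
  lab <- list_rbind(map(seq_along(sections), function(i) {
    cc <- cells[[i]]
    qr <- assign_quadrants(cc, orientation = config$orientation,
                           region_mapping = config$region_mapping)
    left_join(cc, qr, by = "cell_id")
  }))
  cmp <- compare_regional_composition(lab, unit = "subtype",
                                      normalization = "within_major",
                                      alpha = config$alpha_level)
  state$regions <- cmp
  rp <- file.path(config$out_dir, "region_composition.csv")
  readr::write_csv(tidy(cmp), rp, progress = FALSE)
  rp
}
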