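# Readers and writers for the pipeline's on-disk formats. All tables are
# UTF-8 CSV with a header row and "." decimal; counts are Matrix Market with
# genes.tsv/cells.tsv index files (1-based indices per the MM standard);
# polygons are GeoJSON FeatureCollections in planar micrometer/pixel
# coordinates (a documented dialect: the coordinates are not geographic).
# Writers use canonical field ordering so write(read(x)) is byte-stable.

# base-R CSV reader: exact (correctly rounded) double parsing, so that
# write(read(file)) reproduces the file bytes; all-NA columns come back
# logical and are promoted to numeric
read_csv_exact <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  for (col in names(df)) {
    if (is.logical(df[[col]]) && all(is.na(df[[col]]))) {
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  df
}

#' Read and write pipeline cell tables
#'
#' @param path file path.
#' @param cells tibble with at least `cell_id`, `x`, `y`.
#' @return `read_cells`: a validated tibble.
#' @export
read_cells <- function(path) {
  df <- read_csv_exact(path)
  check_columns(df, c("cell_id", "x", "y"), basename(path))
  for (col in c("x", "y")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("%s: column `%s` is not numeric (first bad row: %s)",
                    basename(path), col, bad %||% "?"))
    }
  }
  if (anyNA(df$x) || anyNA(df$y)) {
    abort(sprintf("%s: missing coordinates (row %d)", basename(path),
                  which(is.na(df$x) | is.na(df$y))[1]))
  }
  df
}

#' @rdname read_cells
#' @export
write_cells <- function(cells, path) {
  check_columns(cells, c("cell_id", "x", "y"), "`cells`")
  lead <- intersect(c("cell_id", "section", "x", "y"), names(cells))
  readr::write_csv(cells[c(lead, setdiff(names(cells), lead))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write decoded transcript spot tables
#'
#' @param path file path.
#' @param spots tibble with `gene`, `x`, `y` and optionally `cell_id`.
#' @export
read_spots <- function(path) {
  df <- read_csv_exact(path)
  check_columns(df, c("gene", "x", "y"), basename(path))
  if (!is.numeric(df$x) || !is.numeric(df$y)) {
    abort(sprintf("%s: spot coordinates must be numeric", basename(path)))
  }
  if (anyNA(df$x) || anyNA(df$y)) {
    abort(sprintf("%s: non-finite spot coordinates (row %d)", basename(path),
                  which(is.na(df$x) | is.na(df$y))[1]))
  }
  df
}

#' @rdname read_spots
#' @export
write_spots <- function(spots, path) {
  check_columns(spots, c("gene", "x", "y"), "`spots`")
  lead <- intersect(c("gene", "x", "y", "cell_id"), names(spots))
  readr::write_csv(spots[c(lead, setdiff(names(spots), lead))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write segmentation polygons as GeoJSON
#'
#' One Feature per cell with property `cell_id` (and `source`); geometry is a
#' Polygon whose single ring is closed (first position repeated last).
#' Unclosed rings are rejected, naming the feature.
#'
#' @param path file path.
#' @param set a `segmentation_set`.
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort(sprintf("%s: not a GeoJSON FeatureCollection", basename(path)))
  }
  polys <- list()
  sources <- character(0)
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- f$properties$cell_id %||% sprintf("feature_%d", k)
    if (!identical(f$geometry$type, "Polygon")) {
      abort(sprintf("%s: feature '%s' is not a Polygon", basename(path), id))
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) < 4 || any(m[1, ] != m[nrow(m), ])) {
      abort(sprintf("%s: feature '%s' has an unclosed ring", basename(path), id))
    }
    polys[[id]] <- m[-nrow(m), , drop = FALSE]
    sources[id] <- f$properties$source %||% "primary"
  }
  out <- segmentation_set(polys, validate = TRUE)
  out$source <- unname(sources[out$cell_id])
  out
}

#' @rdname read_polygons
#' @export
write_polygons <- function(set, path) {
  stopifnot(inherits(set, "segmentation_set"))
  features <- map(seq_len(nrow(set)), function(k) {
    v <- poly_close(set$vertices[[k]])
    list(
      type = "Feature",
      properties = list(cell_id = set$cell_id[k], source = set$source[k]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write sparse count matrices (Matrix Market + index files)
#'
#' `<stem>.mtx` holds the cells x genes counts; `<stem>.cells.tsv` and
#' `<stem>.genes.tsv` hold the row and column names (one per line).
#'
#' @param stem path without extension.
#' @param counts sparse or dense cells x genes matrix with dimnames.
#' @export
read_counts <- function(stem) {
  mtx <- paste0(stem, ".mtx")
  m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
    abort(sprintf("%s: malformed Matrix Market file (%s)", basename(mtx),
                  conditionMessage(e)))
  })
  cells <- readLines(paste0(stem, ".cells.tsv"))
  genes <- readLines(paste0(stem, ".genes.tsv"))
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    abort(sprintf("%s: dimensions %dx%d do not match index files (%d cells, %d genes)",
                  basename(mtx), nrow(m), ncol(m), length(cells), length(genes)))
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  m
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, stem) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".cells.tsv"))
  writeLines(colnames(counts), paste0(stem, ".genes.tsv"))
  invisible(stem)
}

#' Read and write latent embeddings
#'
#' CSV with `cell_id` then `z1..zd`.
#' @param path file path.
#' @param latents matrix with rownames.
#' @export
read_latents <- function(path) {
  df <- read_csv_exact(path)
  check_columns(df, "cell_id", basename(path))
  zcols <- setdiff(names(df), "cell_id")
  if (!length(zcols) || !all(vapply(df[zcols], is.numeric, logical(1)))) {
    abort(sprintf("%s: latent columns must be numeric", basename(path)))
  }
  m <- as.matrix(df[zcols])
  if (any(!is.finite(m))) abort(sprintf("%s: non-finite latent values", basename(path)))
  rownames(m) <- df$cell_id
  m
}

#' @rdname read_latents
#' @export
write_latents <- function(latents, path) {
  df <- as_tibble(latents, .name_repair = ~ sprintf("z%d", seq_along(.x)))
  df <- bind_cols(tibble(cell_id = rownames(latents)), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

# ---- pipeline configuration -------------------------------------------------

config_defaults <- function() {
  list(
    seed = NULL,
    out_dir = "stratafish_run",
    stages = c("simulate", "segment-merge", "qc", "boundaries", "depth",
               "layer-assignment", "displacement", "transfer", "impute",
               "regions"),
    n_sections = 2,
    densities = c(GCL = 0.04, INL = 0.08, ONL = 0.10),
    n_genes = 400, n_panel = 300,
    target_total = 80,
    n_reference = 3000,
    alpha = 100,
    lateral_fraction = 0.025,
    depth_from = "apical",
    overlap_threshold = 0.001,
    qc_thresholds = list(),
    n_perm = 1000,
    alpha_level = 0.05,
    min_cells = 10,
    k_transfer = 3,
    k_impute = 30,
    impute_mode = "kernel",
    orientation = "dorsal-ventral",
    region_mapping = c(left = "dorsal", right = "ventral"),
    inputs = list()
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML with the documented keys only; unknown keys are rejected and `seed`
#' is mandatory. Every numeric parameter is range-checked.
#'
#' @param path YAML file path, or a list to validate directly.
#' @return a validated `pipeline_config` list with defaults filled in.
#' @export
read_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defs, raw)
  if (is.null(cfg$seed)) abort("`seed` is mandatory in the config")
  check_number(cfg$seed, "seed")
  check_number(cfg$alpha, "alpha", 1e-9)
  check_number(cfg$overlap_threshold, "overlap_threshold", 0, 1)
  check_number(cfg$n_perm, "n_perm", 1)
  check_number(cfg$alpha_level, "alpha_level", 0, 1)
  check_number(cfg$k_transfer, "k_transfer", 1)
  check_number(cfg$k_impute, "k_impute", 1)
  check_number(cfg$lateral_fraction, "lateral_fraction", 0, 0.49)
  if (!cfg$depth_from %in% c("apical", "basal")) {
    abort("`depth_from` must be \"apical\" or \"basal\"")
  }
  if (!cfg$impute_mode %in% c("kernel", "fit")) {
    abort("`impute_mode` must be \"kernel\" or \"fit\"")
  }
  bad <- setdiff(cfg$stages, config_defaults()$stages)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  cfg$region_mapping <- unlist(cfg$region_mapping)
  cfg$densities <- unlist(cfg$densities)
  if (!all(names(cfg$densities) %in% c("GCL", "INL", "ONL")) ||
      any(cfg$densities <= 0)) {
    abort("`densities` must be positive values for GCL/INL/ONL")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$region_mapping <- as.list(x$region_mapping)
  yaml::write_yaml(x, path)
  invisible(path)
}
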