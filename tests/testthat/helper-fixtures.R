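# shared fixtures, built in code

# compact subtype table over a small gene universe (fast tests)
small_subtypes <- function(n_genes = 200, n_panel = 150, seed = 42, ...) {
  retina_subtypes(gene_universe(n_genes, n_panel), seed = seed, ...)
}

# low-density section spec (a few thousand cells)
small_spec <- function(seed = 1, ...) {
  section_spec(densities = c(GCL = 0.01, INL = 0.02, ONL = 0.015),
               seed = seed, ...)
}

# manual parallel boundary chains: apical at y = y_ap, basal at y = y_ba
flat_chains <- function(y_ap = 10, y_ba = 0, x_range = c(-100, 100)) {
  structure(
    list(
      apical = cbind(x_range[1], y_ap, x_range[2], y_ap),
      basal = cbind(x_range[1], y_ba, x_range[2], y_ba),
      tissue_center = c(mean(x_range), -1e6)
    ),
    class = "boundary_chains"
  )
}

# minimal reference-like object from explicit pieces
ref_set <- function(latents, subtype, major_type = subtype, counts = NULL) {
  n <- nrow(latents)
  ids <- sprintf("r%03d", seq_len(n))
  rownames(latents) <- ids
  if (is.null(counts)) {
    counts <- matrix(0, n, 2, dimnames = list(ids, c("gA", "gB")))
  } else {
    rownames(counts) <- ids
  }
  structure(
    list(counts = counts,
         labels = tibble::tibble(cell_id = ids, subtype = subtype,
                                 major_type = major_type),
         latents = latents,
         genes = tibble::tibble(gene = colnames(counts),
                                panel = rep(TRUE, ncol(counts)))),
    class = "reference_set"
  )
}
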