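#' Annotate major cell types from marker gene scores
#'
#' Automated marker scoring: counts are library-size normalized and per-gene
#' z-scored across cells; each type's score is the mean z-score over its
#' marker genes and cells take the argmax type. All-zero cells and exact ties
#' are labeled `"unassigned"`. Marker genes absent from the matrix are
#' skipped with a warning.
#'
#' @param counts cells x genes matrix (sparse or dense) with dimnames.
#' @param marker_sets named list: type -> character vector of marker genes.
#' @return tibble: `cell_id`, `major_type`, `score`.
#' @export
annotate_major_types <- function(counts, marker_sets) {
  if (!length(marker_sets) || any(!lengths(marker_sets))) {
    abort("every marker set must be non-empty")
  }
  genes <- colnames(counts)
  marker_sets <- imap(marker_sets, function(ms, type) {
    missing <- setdiff(ms, genes)
    if (length(missing)) {
      warn(sprintf("marker(s) absent for %s: %s", type,
                   paste(missing, collapse = ", ")))
    }
    intersect(ms, genes)
  })
  if (any(!lengths(marker_sets))) {
    abort("a marker set has no genes present in the count matrix")
  }
  libsize <- Matrix::rowSums(counts)
  zero_cell <- libsize == 0
  norm <- counts / pmax(libsize, 1)
  norm <- as.matrix(norm)
  mu <- colMeans(norm)
  sdv <- apply(norm, 2, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(norm, 2, mu), 2, sdv, "/")
  scores <- vapply(marker_sets, function(ms) {
    rowMeans(z[, ms, drop = FALSE])
  }, numeric(nrow(counts)))
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(nrow(scores)), best)]
  n_at_max <- rowSums(scores == best_score)
  type <- colnames(scores)[best]
  type[n_at_max > 1 | zero_cell] <- "unassigned"
  tibble(cell_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
         major_type = type, score = best_score)
}

#' Train a multi-class maximum-margin classifier on reference latents
#'
#' Fits a linear-kernel multi-class SVM (one-vs-one with pairwise-coupling
#' probability calibration) on the reference co-embedding latents against the
#' known reference subtype labels. Training is deterministic for a fixed
#' seed (the probability calibration uses internal cross-validation).
#'
#' @param ref a `reference_set` (see [generate_reference()]), or any list
#'   with `latents` (matrix) and `labels` (tibble with `subtype`).
#' @param cost SVM cost parameter (default 10).
#' @param seed integer seed.
#' @return a fitted classifier of class `svm`.
#' @export
train_reference_classifier <- function(ref, cost = 10, seed = 1) {
  lab <- factor(ref$labels$subtype)
  if (nlevels(lab) < 2) abort("need at least 2 reference classes")
  if (any(table(lab) < 2)) abort("every class needs at least 2 reference cells")
  with_seed(derive_seed(seed, "svm-train"), {
    e1071::svm(x = ref$latents, y = lab, kernel = "linear", cost = cost,
               probability = TRUE, scale = FALSE)
  })
}

#' Transfer reference subtype labels to query cells
#'
#' For each query cell, its `k` nearest reference cells in the shared
#' co-embedding latent space are found (Euclidean metric); the mean of their
#' latent representations is the classification feature, scored against the
#' trained classifier; the label with maximum class probability is assigned.
#'
#' @param query query latents: matrix (cells x d) with rownames, or a
#'   `retina_section`.
#' @param ref a `reference_set`.
#' @param classifier a [train_reference_classifier()] fit (trained if `NULL`).
#' @param k number of reference neighbors averaged (default 3).
#' @param seed seed used only when `classifier` is trained here.
#' @return an object of class `label_transfer`; [tidy()] gives `cell_id`,
#'   `assigned`, `probability`; `$probabilities` is the full class-probability
#'   matrix and `$neighbors` the reference neighbor ids.
#' @export
transfer_labels <- function(query, ref, classifier = NULL, k = 3, seed = 1) {
  q <- if (inherits(query, "retina_section")) query$latents else query
  if (!is.matrix(q)) abort("`query` must be a latent matrix or a retina_section")
  if (ncol(q) != ncol(ref$latents)) {
    abort("query and reference latent dimensions differ")
  }
  if (k < 1 || k > nrow(ref$latents)) abort("`k` must be in [1, n_reference]")
  if (is.null(classifier)) classifier <- train_reference_classifier(ref, seed = seed)
  nn <- cpp_knn(ref$latents, q, as.integer(k))
  # neighbor-averaged latent feature
  feat <- matrix(0, nrow(q), ncol(q))
  for (j in seq_len(k)) {
    feat <- feat + ref$latents[nn$idx[, j], , drop = FALSE]
  }
  feat <- feat / k
  pred <- stats::predict(classifier, feat, probability = TRUE)
  prob <- attr(pred, "probabilities")
  best <- max.col(prob, ties.method = "first")
  cell_id <- rownames(q) %||% as.character(seq_len(nrow(q)))
  res <- tibble(
    cell_id = cell_id,
    assigned = colnames(prob)[best],
    probability = prob[cbind(seq_len(nrow(prob)), best)]
  )
  structure(
    list(result = res, probabilities = prob,
         neighbors = matrix(ref$labels$cell_id[nn$idx], ncol = k),
         k = k),
    class = "label_transfer"
  )
}

#' @rdname transfer_labels
#' @param x a `label_transfer` object.
#' @param ... unused.
#' @export
tidy.label_transfer <- function(x, ...) x$result

#' @export
print.label_transfer <- function(x, ...) {
  cat(sprintf("<label_transfer> %d query cells, k = %d, %d classes\n",
              nrow(x$result), x$k, ncol(x$probabilities)))
  invisible(x)
}

#' Impute full-transcriptome expression restricted to same-type reference cells
#'
#' Per query cell, the candidate pool is its `k` nearest reference cells in
#' the shared latent space **of the same cell type** (major type by default;
#' pass subtype labels to restrict within subtypes). Imputed expression is a
#' weighted sum of candidate reference expression with weights on the
#' simplex:
#' * `mode = "kernel"`: Gaussian kernel on latent distance, bandwidth equal
#'   to the median candidate distance of the cell, normalized to sum to 1.
#' * `mode = "fit"`: starting from the kernel weights, softmax-parameterized
#'   weights are optimized by monotone backtracking gradient ascent to
#'   maximize the mean per-gene Pearson correlation between imputed and
#'   measured panel genes (convergence when the objective improves by less
#'   than `tol`; at most `max_iter` iterations). Because every accepted step
#'   improves the objective, fit mode never scores below kernel mode.
#'
#' Query cells whose type is absent from the reference are flagged and left
#' unimputed (NA rows). Weights never cross the type restriction.
#'
#' @param query query latents (cells x d matrix with rownames).
#' @param query_types character vector of cell types aligned with `query`
#'   rows.
#' @param ref a `reference_set`; the restriction uses `ref$labels$major_type`
#'   unless `ref_types` is given.
#' @param mode `"kernel"` (default) or `"fit"`.
#' @param k candidate reference neighbors per cell (default 30).
#' @param measured panel-gene measured matrix (cells x genes), required for
#'   `mode = "fit"`.
#' @param ref_types optional reference type labels overriding major types.
#' @param tol,max_iter fit-mode convergence tolerance (objective change,
#'   default 1e-5) and iteration cap (default 50).
#' @return an object of class `imputation`: `expression` (cells x genes
#'   matrix), `weights` (list per cell: named weight vectors over reference
#'   cells), `flagged` (cell ids not imputed), `mode`; for fit mode also
#'   `objective` (trace of the mean panel PCC).
#' @export
impute_expression <- function(query, query_types, ref,
                              mode = c("kernel", "fit"), k = 30,
                              measured = NULL, ref_types = NULL,
                              tol = 1e-5, max_iter = 50) {
  mode <- match.arg(mode)
  if (!is.matrix(query)) abort("`query` must be a latent matrix")
  if (length(query_types) != nrow(query)) {
    abort("`query_types` must align with query rows")
  }
  rtypes <- ref_types %||% ref$labels$major_type
  if (length(rtypes) != nrow(ref$latents)) {
    abort("reference type labels must align with reference cells")
  }
  if (mode == "fit" && is.null(measured)) {
    abort("fit mode requires the measured panel matrix")
  }
  refX <- as.matrix(ref$counts)
  genes <- colnames(refX)
  cell_id <- rownames(query) %||% as.character(seq_len(nrow(query)))
  nq <- nrow(query)
  flagged <- character(0)

  cand_idx <- matrix(NA_integer_, nq, k)
  cand_dist <- matrix(NA_real_, nq, k)
  for (ty in unique(query_types)) {
    qi <- which(query_types == ty)
    ri <- which(rtypes == ty)
    if (!length(ri)) {
      flagged <- c(flagged, cell_id[qi])
      next
    }
    kk <- min(k, length(ri))
    nn <- cpp_knn(ref$latents[ri, , drop = FALSE],
                  query[qi, , drop = FALSE], as.integer(kk))
    cand_idx[qi, seq_len(kk)] <- matrix(ri[nn$idx], ncol = kk)
    cand_dist[qi, seq_len(kk)] <- nn$dist
  }
  ok <- !cell_id %in% flagged
  W <- matrix(0, nq, k)
  for (i in which(ok)) {
    d <- cand_dist[i, !is.na(cand_idx[i, ])]
    bw <- median(d)
    if (!is.finite(bw) || bw <= 0) bw <- 1
    w <- exp(-(d / bw)^2 / 2)
    W[i, seq_along(w)] <- w / sum(w)
  }

  impute_from <- function(W) {
    out <- matrix(NA_real_, nq, ncol(refX),
                  dimnames = list(cell_id, genes))
    for (i in which(ok)) {
      ci <- cand_idx[i, !is.na(cand_idx[i, ])]
      out[i, ] <- crossprod(refX[ci, , drop = FALSE], W[i, seq_along(ci)])
    }
    out
  }

  objective_trace <- NULL
  if (mode == "fit") {
    panel <- intersect(colnames(measured), genes)
    if (!length(panel)) abort("no shared panel genes between measured and reference")
    Mq <- as.matrix(measured)[ok, panel, drop = FALSE]
    refP <- refX[, panel, drop = FALSE]
    live <- which(ok)
    mean_pcc <- function(X) {
      cc <- vapply(seq_along(panel), function(g) {
        x <- X[, g]; m <- Mq[, g]
        if (sd(x) == 0 || sd(m) == 0) return(NA_real_)
        cor(x, m)
      }, numeric(1))
      mean(cc, na.rm = TRUE)
    }
    imp_panel <- function(W) {
      X <- matrix(0, length(live), length(panel))
      for (r in seq_along(live)) {
        i <- live[r]
        ci <- cand_idx[i, !is.na(cand_idx[i, ])]
        X[r, ] <- crossprod(refP[ci, , drop = FALSE], W[i, seq_along(ci)])
      }
      X
    }
    # softmax parameterization theta; kernel start
    theta <- W
    theta[ok, ] <- log(pmax(W[ok, , drop = FALSE], 1e-12))
    softmax_rows <- function(th) {
      out <- matrix(0, nq, k)
      for (r in seq_along(live)) {
        i <- live[r]
        nv <- sum(!is.na(cand_idx[i, ]))
        e <- exp(th[i, seq_len(nv)] - max(th[i, seq_len(nv)]))
        out[i, seq_len(nv)] <- e / sum(e)
      }
      out
    }
    W <- softmax_rows(theta)
    X <- imp_panel(W)
    f <- mean_pcc(X)
    objective_trace <- f
    step <- 1
    nO <- length(live)
    for (it in seq_len(max_iter)) {
      # analytic gradient of mean per-gene PCC wrt imputed panel entries
      G <- matrix(0, nO, length(panel))
      for (g in seq_along(panel)) {
        x <- X[, g]; m <- Mq[, g]
        sx <- sd(x); sm <- sd(m)
        if (sx == 0 || sm == 0) next
        xc <- x - mean(x); mc <- m - mean(m)
        r <- sum(xc * mc) / ((nO - 1) * sx * sm)
        G[, g] <- (mc / ((nO - 1) * sx * sm) - r * xc / ((nO - 1) * sx^2)) /
          length(panel)
      }
      # chain rule through candidate expression and the softmax
      grad_theta <- matrix(0, nq, k)
      for (r in seq_along(live)) {
        i <- live[r]
        ci <- cand_idx[i, !is.na(cand_idx[i, ])]
        gw <- as.numeric(refP[ci, , drop = FALSE] %*% G[r, ])
        w <- W[i, seq_along(ci)]
        grad_theta[i, seq_along(ci)] <- w * (gw - sum(w * gw))
      }
      improved <- FALSE
      while (step > 1e-8) {
        theta_new <- theta + step * grad_theta /
          max(sqrt(mean(grad_theta[ok, ]^2)), 1e-12)
        W_new <- softmax_rows(theta_new)
        X_new <- imp_panel(W_new)
        f_new <- mean_pcc(X_new)
        if (is.finite(f_new) && f_new > f) {
          theta <- theta_new; W <- W_new; X <- X_new
          improved <- TRUE
          delta <- f_new - f
          f <- f_new
          objective_trace <- c(objective_trace, f)
          if (delta < tol) improved <- FALSE  # converged
          break
        }
        step <- step / 2
      }
      if (!improved) break
      step <- min(step * 2, 10)
    }
  }

  expression <- impute_from(W)
  weights <- vector("list", nq)
  names(weights) <- cell_id
  for (i in which(ok)) {
    ci <- cand_idx[i, !is.na(cand_idx[i, ])]
    weights[[i]] <- setNames(W[i, seq_along(ci)], ref$labels$cell_id[ci])
  }
  structure(
    list(expression = expression, weights = weights, flagged = flagged,
         mode = mode, k = k, objective = objective_trace,
         candidate_types = rtypes),
    class = "imputation"
  )
}

#' @export
print.imputation <- function(x, ...) {
  cat(sprintf("<imputation> %d cells x %d genes, mode = %s, k = %d, %d flagged\n",
              nrow(x$expression), ncol(x$expression), x$mode, x$k,
              length(x$flagged)))
  invisible(x)
}

#' Evaluate imputation fidelity by per-gene Pearson correlation
#'
#' Correlates imputed against measured expression across cells for each
#' shared gene (typically the imaging panel). Zero-variance genes are
#' reported as undefined (`NA`) and excluded from the summaries.
#'
#' @param imputed,measured cells x genes matrices with dimnames; cells are
#'   matched by rowname.
#' @param genes genes to evaluate (default: all shared genes).
#' @return list of class `imputation_eval`: `per_gene` tibble (`gene`,
#'   `pcc`), `median_pcc`, `mean_pcc`, `n_undefined`.
#' @export
evaluate_imputation <- function(imputed, measured, genes = NULL) {
  shared_g <- intersect(colnames(imputed), colnames(measured))
  if (!is.null(genes)) shared_g <- intersect(shared_g, genes)
  if (!length(shared_g)) abort("no shared genes to evaluate")
  shared_c <- intersect(rownames(imputed), rownames(measured))
  if (!length(shared_c)) abort("no shared cells to evaluate")
  A <- as.matrix(imputed)[shared_c, shared_g, drop = FALSE]
  B <- as.matrix(measured)[shared_c, shared_g, drop = FALSE]
  keep_rows <- stats::complete.cases(A)
  A <- A[keep_rows, , drop = FALSE]
  B <- B[keep_rows, , drop = FALSE]
  pcc <- vapply(seq_along(shared_g), function(g) {
    if (sd(A[, g]) == 0 || sd(B[, g]) == 0) return(NA_real_)
    cor(A[, g], B[, g])
  }, numeric(1))
  per_gene <- tibble(gene = shared_g, pcc = pcc)
  structure(
    list(per_gene = per_gene,
         median_pcc = median(pcc, na.rm = TRUE),
         mean_pcc = mean(pcc, na.rm = TRUE),
         n_undefined = sum(is.na(pcc)),
         n_cells = nrow(A)),
    class = "imputation_eval"
  )
}

#' @export
print.imputation_eval <- function(x, ...) {
  cat(sprintf("<imputation_eval> %d genes on %d cells: median PCC %.3f, mean PCC %.3f (%d undefined)\n",
              nrow(x$per_gene), x$n_cells, x$median_pcc, x$mean_pcc,
              x$n_undefined))
  invisible(x)
}
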