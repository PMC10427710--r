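# marker annotation, label transfer, type-restricted imputation, evaluation

test_that("marker scoring assigns the dominant type and flags ambiguity", {
  counts <- rbind(
    rodcell = c(Pde6a = 9, Pde6b = 7, Vsx2 = 0, Grm6 = 0, Pax6 = 1),
    bccell  = c(Pde6a = 0, Pde6b = 1, Vsx2 = 8, Grm6 = 6, Pax6 = 0),
    empty   = c(Pde6a = 0, Pde6b = 0, Vsx2 = 0, Grm6 = 0, Pax6 = 0)
  )
  markers <- list(Rod = c("Pde6a", "Pde6b"), BC = c("Vsx2", "Grm6"))
  out <- annotate_major_types(counts, markers)
  expect_identical(out$major_type, c("Rod", "BC", "unassigned"))
  # absent marker genes are skipped with a warning
  expect_warning(
    annotate_major_types(counts, list(Rod = c("Pde6a", "NOPE"),
                                      BC = "Vsx2")),
    "NOPE")
  expect_error(annotate_major_types(counts, list(Rod = character(0))),
               "non-empty")
})

test_that("marker scoring recovers major types on synthetic data", {
  st <- small_subtypes()
  sec <- generate_section(small_spec(seed = 61), st)
  out <- annotate_major_types(sec$counts, attr(st, "marker_sets"))
  expect_gte(mean(out$major_type == sec$truth$major_type), 0.95)
})

test_that("the reference classifier separates well-spaced classes", {
  set.seed(8)
  lat <- rbind(matrix(rnorm(200 * 5), ncol = 5),
               matrix(rnorm(200 * 5, mean = 10), ncol = 5))  # 10 sigma apart
  ref <- ref_set(lat, subtype = rep(c("A", "B"), each = 200))
  clf <- train_reference_classifier(ref, seed = 3)
  pred <- predict(clf, lat)
  expect_gte(mean(pred == ref$labels$subtype), 0.999)
  # determinism: retraining with the same seed gives identical predictions
  clf2 <- train_reference_classifier(ref, seed = 3)
  q <- matrix(rnorm(50 * 5, mean = 5), ncol = 5)
  p1 <- predict(clf, q, probability = TRUE)
  p2 <- predict(clf2, q, probability = TRUE)
  expect_identical(attr(p1, "probabilities"), attr(p2, "probabilities"))
  expect_error(train_reference_classifier(
    ref_set(lat, subtype = rep("A", 400))), "2 reference classes")
})

test_that("label permutation drives held-out accuracy to chance", {
  set.seed(12)
  k <- 5
  mu <- diag(k) * 12
  lat <- do.call(rbind, lapply(1:k, function(i)
    matrix(rnorm(120 * k, mean = rep(mu[i, ], each = 120)), ncol = k)))
  labs <- rep(LETTERS[1:k], each = 120)
  shuffled <- sample(labs)
  ref <- ref_set(lat, subtype = shuffled)
  clf <- train_reference_classifier(ref, seed = 5)
  qlat <- do.call(rbind, lapply(1:k, function(i)
    matrix(rnorm(40 * k, mean = rep(mu[i, ], each = 40)), ncol = k)))
  qlab <- rep(LETTERS[1:k], each = 40)
  tr <- transfer_labels(qlat, ref, clf, k = 3)
  expect_lt(mean(tidy(tr)$assigned == qlab), 0.4)  # ~ 1/k expected
})

test_that("transfer uses neighbour-averaged features and max probability", {
  lat <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(10, 10), c(10.1, 10), c(10, 10.1))
  ref <- ref_set(lat, subtype = rep(c("A", "B"), each = 3))
  clf <- train_reference_classifier(ref, seed = 1)
  # query exactly on a reference cell, k = 1
  tr1 <- transfer_labels(rbind(c(10, 10)), ref, clf, k = 1)
  expect_identical(tidy(tr1)$assigned, "B")
  # query at the centroid of the three same-class cells, k = 3
  tr3 <- transfer_labels(rbind(colMeans(lat[1:3, ])), ref, clf, k = 3)
  expect_identical(tidy(tr3)$assigned, "A")
  # probabilities sum to 1 and the assignment is the argmax
  expect_equal(unname(rowSums(tr3$probabilities)), 1, tolerance = 1e-9)
  expect_error(transfer_labels(rbind(c(0, 0)), ref, clf, k = 99), "k")
  expect_error(transfer_labels(rbind(c(0, 0, 0)), ref, clf), "dimensions")
})

test_that("synthetic transfer at default separation is near-perfect", {
  st <- small_subtypes()
  sec <- generate_section(small_spec(seed = 71), st)
  ref <- generate_reference(st, n_cells = 1500, seed = 72)
  tr <- transfer_labels(sec$latents, ref, k = 3, seed = 73)
  expect_gte(mean(tidy(tr)$assigned == sec$truth$subtype), 0.95)
})

test_that("kernel imputation is exact in the identity case", {
  set.seed(21)
  lat <- matrix(rnorm(40 * 3), ncol = 3)
  counts <- matrix(rpois(40 * 6, 5), ncol = 6,
                   dimnames = list(NULL, sprintf("g%d", 1:6)))
  ref <- ref_set(lat, subtype = rep(c("A", "B"), 20), counts = counts)
  q <- lat
  rownames(q) <- sprintf("q%03d", 1:40)
  imp <- impute_expression(q, ref$labels$major_type, ref, mode = "kernel",
                           k = 1)
  expect_equal(unname(imp$expression), unname(counts))
})

test_that("imputation never crosses the type restriction", {
  # a different-type reference cell at zero latent distance gets weight 0
  lat <- rbind(c(0, 0), c(0, 0), c(5, 5))
  counts <- matrix(c(100, 0, 0, 0, 100, 50), ncol = 2,
                   dimnames = list(NULL, c("gA", "gB")))
  ref <- ref_set(lat, subtype = c("A", "B", "A"), counts = counts)
  q <- rbind(q1 = c(0, 0))
  imp <- impute_expression(q, "A", ref, k = 2)
  w <- imp$weights[["q1"]]
  expect_setequal(names(w), c("r001", "r003"))  # never r002 (type B)
  types_used <- ref$labels$major_type[match(names(w), ref$labels$cell_id)]
  expect_true(all(types_used == "A"))
  expect_equal(sum(w), 1)
  # k = 2 equidistant same-type neighbours average arithmetically
  lat2 <- rbind(c(1, 0), c(-1, 0), c(0, 8))
  counts2 <- matrix(c(10, 20, 600, 4, 8, 600), ncol = 2,
                    dimnames = list(NULL, c("gA", "gB")))
  ref2 <- ref_set(lat2, subtype = c("A", "A", "B"), counts = counts2)
  imp2 <- impute_expression(rbind(q1 = c(0, 0)), "A", ref2, k = 2)
  expect_equal(unname(imp2$expression[1, ]), c(15, 6))
  # a query type absent from the reference is flagged, not imputed
  imp3 <- impute_expression(rbind(q1 = c(0, 0)), "Z", ref2, k = 2)
  expect_identical(imp3$flagged, "q1")
  expect_true(all(is.na(imp3$expression)))
})

test_that("imputed values stay in the convex hull of candidate expression", {
  st <- small_subtypes()
  sec <- generate_section(small_spec(seed = 81), st)
  ref <- generate_reference(st, n_cells = 800, seed = 82)
  sub <- 1:200
  imp <- impute_expression(sec$latents[sub, ], sec$truth$major_type[sub], ref,
                           k = 10)
  refX <- as.matrix(ref$counts)
  for (i in c(1, 50, 200)) {
    w <- imp$weights[[i]]
    expect_equal(sum(w), 1, tolerance = 1e-9)
    cand <- refX[match(names(w), ref$labels$cell_id), , drop = FALSE]
    expect_true(all(imp$expression[i, ] >= apply(cand, 2, min) - 1e-9))
    expect_true(all(imp$expression[i, ] <= apply(cand, 2, max) + 1e-9))
    types_used <- ref$labels$major_type[match(names(w), ref$labels$cell_id)]
    expect_true(all(types_used == sec$truth$major_type[sub][i]))
  }
})

test_that("fit mode never scores below kernel mode on the panel objective", {
  st <- small_subtypes()
  sec <- generate_section(small_spec(seed = 91), st)
  ref <- generate_reference(st, n_cells = 600, seed = 92)
  sub <- 1:150
  measured <- as.matrix(sec$counts[sub, ])
  q <- sec$latents[sub, ]
  qt <- sec$truth$major_type[sub]
  impk <- impute_expression(q, qt, ref, mode = "kernel", k = 15)
  impf <- impute_expression(q, qt, ref, mode = "fit", k = 15,
                            measured = measured, max_iter = 10)
  panel <- colnames(measured)
  evk <- evaluate_imputation(impk$expression, measured, genes = panel)
  evf <- evaluate_imputation(impf$expression, measured, genes = panel)
  expect_gte(evf$mean_pcc, evk$mean_pcc - 1e-12)
  # the optimizer trace is monotone non-decreasing
  expect_true(all(diff(impf$objective) >= -1e-12))
})

test_that("per-gene correlation evaluation matches the textbook formula", {
  set.seed(14)
  A <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("c%d", 1:20), sprintf("g%d", 1:10)))
  B <- matrix(rnorm(200), 20, 10, dimnames = dimnames(A))
  ev <- evaluate_imputation(A, B)
  for (g in 1:10) {
    expect_equal(ev$per_gene$pcc[g], oracle_pcc(A[, g], B[, g]),
                 tolerance = 1e-12)
  }
  # identity and sign flip
  expect_true(all(abs(evaluate_imputation(A, A)$per_gene$pcc - 1) < 1e-12))
  expect_true(all(abs(evaluate_imputation(A, -A)$per_gene$pcc + 1) < 1e-12))
  # zero-variance genes are undefined and excluded from summaries
  A0 <- A; A0[, 1] <- 5
  ev0 <- evaluate_imputation(A0, B)
  expect_true(is.na(ev0$per_gene$pcc[1]))
  expect_equal(ev0$n_undefined, 1)
  expect_error(evaluate_imputation(A[, 1:2], B[, 3:4]), "shared genes")
})
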