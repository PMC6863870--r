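# helper: a tiny noiseless two-class reference where exactly 10 genes
# differ and the per-cell totals are equal, so CPM touches nothing else
noiseless_two_class <- function() {
  base <- rep(20, 30)
  a <- base; b <- base
  a[1:5] <- 30; b[1:5] <- 10   # up in A
  a[6:10] <- 10; b[6:10] <- 30 # up in B; totals stay equal
  counts <- cbind(a, a, a, b, b, b)
  count_matrix(counts, sprintf("g%02d", 1:30), rep("endogenous", 30),
               sprintf("c%d", 1:6))
}

test_that("markers are exactly the differing genes in the noiseless case", {
  m <- noiseless_two_class()
  atlas <- build_reference(m, c("A", "A", "A", "B", "B", "B"))
  expect_setequal(atlas$markers, sprintf("g%02d", 1:10))
  # permuting cells leaves the atlas unchanged
  perm <- c(4, 1, 5, 2, 6, 3)
  atlas2 <- build_reference(subset_counts(m, cells = perm),
                            c("B", "A", "B", "A", "B", "A"))
  expect_equal(atlas$profiles, atlas2$profiles)
  expect_identical(atlas$markers, atlas2$markers)
  expect_error(build_reference(m, c("A", "A", "A", "B", "B", "C")), "C")
})

test_that("planted synthetic markers are recovered", {
  sc <- synth_config(seed = 2)
  r <- generate_reference_counts(sc, n_per_class = 200)
  atlas <- build_reference(r$counts, r$labels)
  planted <- sprintf("gene%04d", 1:150)
  expect_gte(mean(planted %in% atlas$markers), 0.95)
})

test_that("class correlations match the textbook computation", {
  m <- noiseless_two_class()
  atlas <- build_reference(m, c("A", "A", "A", "B", "B", "B"))
  profA <- atlas$profiles[atlas$markers, "A"]
  # a cell equal to a class median correlates 1.0 with it
  r <- correlate_to_classes(atlas$profiles[, "A"], atlas)
  expect_equal(unname(r["A"]), 1)
  # the reflection about the mean correlates -1.0
  refl <- 2 * mean(profA) - profA
  r2 <- correlate_to_classes(refl, atlas)
  expect_equal(unname(r2["A"]), -1)
  # random cell vs atlas: textbook formula to 1e-12
  set.seed(5)
  cell <- setNames(runif(length(atlas$markers), 0, 10), atlas$markers)
  r3 <- correlate_to_classes(cell, atlas)
  for (cl in atlas$class_names)
    expect_equal(unname(r3[cl]),
                 oracle_pearson(cell, atlas$profiles[atlas$markers, cl]),
                 tolerance = 1e-12)
  expect_error(correlate_to_classes(cell, atlas, gene_subset = "g01"),
               "at least 3")
})

test_that("bootstrap classification is deterministic and grid-valued", {
  sc <- small_config(seed = 6)
  r <- generate_reference_counts(sc, n_per_class = 50)
  atlas <- build_reference(r$counts, r$labels, top_k = 20)
  q <- generate_query_cells(small_config(lowq_fraction = 0, seed = 6),
                            n_per_pool = 40)
  norm <- log2_cpm(q$counts)
  params <- classifier_params(n_boot = 40, seed = 9)
  res1 <- classify_cells(norm, atlas, params)
  res2 <- classify_cells(norm, atlas, params)
  expect_identical(res1, res2)
  expect_true(all(abs(res1$certainty * 40 -
                      round(res1$certainty * 40)) < 1e-9))
  expect_true(all(res1$certainty >= 0 & res1$certainty <= 1))
  # classification contract: classified iff certainty strictly above
  # threshold and class not low quality
  expect_equal(res1$classified, res1$certainty > 0.5)
})

test_that("a noiseless class-median cell is classified with certainty 1", {
  m <- noiseless_two_class()
  atlas <- build_reference(m, c("A", "A", "A", "B", "B", "B"))
  norm <- cbind(cellA = atlas$profiles[, "A"])
  res <- classify_cells(norm, atlas, classifier_params(n_boot = 25, seed = 1))
  expect_equal(res$best_class, "A")
  expect_equal(res$certainty, 1)
  expect_true(res$classified)
  # adding a constant to every gene leaves Pearson classification alone
  res_shift <- classify_cells(norm + 5, atlas,
                              classifier_params(n_boot = 25, seed = 1))
  expect_equal(res_shift$certainty, res$certainty)
  expect_equal(res_shift$best_class, res$best_class)
})

test_that("a cell midway between two classes hovers at certainty 1/2", {
  # exact exchange symmetry: markers come in pairs whose values swap
  # between the classes, and the cell sits at the pair midpoints, so
  # each bootstrap vote is a fair coin and certainty ~ Binom(n, 1/2)/n
  set.seed(13)
  n_pair <- 20
  x <- runif(n_pair, 2, 8)
  y <- x + sample(c(-1, 1), n_pair, TRUE) * runif(n_pair, 0.5, 1.5)
  profA <- as.vector(rbind(x, y))
  profB <- as.vector(rbind(y, x))
  genes <- sprintf("m%02d", seq_len(2 * n_pair))
  atlas <- structure(list(class_names = c("A", "B"),
                          profiles = matrix(c(profA, profB), ncol = 2,
                                            dimnames = list(genes, c("A", "B"))),
                          markers = genes, lowq_classes = character()),
                     class = "ReferenceAtlas")
  norm <- matrix(as.vector(rbind((x + y) / 2, (x + y) / 2)), ncol = 1,
                 dimnames = list(genes, "cell"))
  certs <- vapply(1:20, function(s)
    classify_cells(norm, atlas, classifier_params(seed = s))$certainty,
    numeric(1))
  expect_gte(min(certs), 0.5)      # two classes: modal vote >= half
  expect_lte(max(certs), 0.7)      # ... but never far above chance
  expect_lt(mean(certs), 0.6)
  # the strict > 0.5 rule: an exact 50/50 split stays unclassified
  res <- classify_cells(norm, atlas, classifier_params(seed = 17))
  expect_equal(res$certainty, 0.5)
  expect_false(res$classified)
})

test_that("full marker set makes certainty degenerate", {
  m <- noiseless_two_class()
  atlas <- build_reference(m, c("A", "A", "A", "B", "B", "B"))
  set.seed(3)
  norm <- cbind(c1 = atlas$profiles[, "A"] + rnorm(30, 0, 0.3))
  res <- classify_cells(norm, atlas,
                        classifier_params(marker_fraction = 1, seed = 2))
  expect_true(res$certainty %in% c(0, 1))
})

test_that("cells mapping to low-quality classes are left unclassified", {
  m <- noiseless_two_class()
  atlas <- build_reference(m, c("A", "A", "A", "B", "B", "B"),
                           lowq_classes = "B")
  norm <- cbind(cellB = atlas$profiles[, "B"])
  res <- classify_cells(norm, atlas, classifier_params(n_boot = 25, seed = 1))
  expect_equal(res$best_class, "B")
  expect_equal(res$certainty, 1)
  expect_false(res$classified)
})

test_that("synthetic plates are classified accurately", {
  sc <- synth_config(lowq_fraction = 0, seed = 41)
  r <- generate_reference_counts(sc, n_per_class = 100)
  atlas <- build_reference(r$counts, r$labels)
  q <- generate_query_cells(sc, n_per_pool = 100, seed = 43)
  norm <- log2_cpm(q$counts)
  res <- classify_cells(norm, atlas, classifier_params(seed = 44))
  expect_gte(mean(res$classified), 0.9)
  truth <- q$truth$true_class[match(res$cell_id, q$truth$cell_id)]
  acc <- mean(res$best_class[res$classified] == truth[res$classified])
  expect_gte(acc, 0.95)
})

test_that("atlas round-trips through its serialized form", {
  sc <- small_config(seed = 51)
  r <- generate_reference_counts(sc, n_per_class = 30)
  atlas <- build_reference(r$counts, r$labels, top_k = 15,
                           lowq_classes = "Rrad")
  dir <- tempfile("atlas")
  write_atlas(atlas, dir)
  back <- read_atlas(dir)
  expect_equal(back$class_names, atlas$class_names)
  expect_identical(back$markers, atlas$markers)
  expect_identical(back$lowq_classes, atlas$lowq_classes)
  expect_equal(back$profiles, atlas$profiles, tolerance = 1e-12)
})

test_that("composition tables count and normalize per pool", {
  res <- data.frame(
    cell_id = sprintf("c%02d", 1:40),
    best_class = c(rep("Agmat", 32), rep("Adamts2", 2), rep("Rrad", 6)),
    certainty = 1,
    classified = c(rep(TRUE, 34), rep(FALSE, 6)),
    n_boot = 100, stringsAsFactors = FALSE)
  ann <- data.frame(cell_id = res$cell_id, pool = "aIP",
                    stringsAsFactors = FALSE)
  ct <- composition_table(res, ann)
  agmat <- ct$composition$prop[ct$composition$class == "Agmat"]
  adam <- ct$composition$prop[ct$composition$class == "Adamts2"]
  expect_equal(round(100 * agmat, 1), 94.1)
  expect_equal(round(100 * adam, 1), 5.9)
  expect_equal(sum(ct$composition$n), ct$totals$n_classified)
  expect_equal(ct$totals$n_unclassified, 6)
  expect_error(composition_table(res, ann[-1, ]), "annotation missing")
})

test_that("chi-square composition tests match closed forms", {
  # observed proportional to reference: statistic 0, p 1
  r <- chi_square_composition(c(30, 20, 10), c(0.5, 1 / 3, 1 / 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # (10, 0) against (0.5, 0.5): statistic 10, df 1, p from the tail
  r2 <- chi_square_composition(c(10, 0), c(0.5, 0.5))
  expect_equal(r2$statistic, 10)
  expect_equal(r2$df, 1)
  expect_equal(r2$p_value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # 2x2 contingency mode equals the classical formula
  a <- 12; b <- 5; c <- 7; d <- 16
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  r3 <- chi_square_composition(c(a, b), c(c, d), mode = "contingency")
  expect_equal(r3$statistic, stat, tolerance = 1e-9)
  expect_error(chi_square_composition(c(0, 0), c(0.5, 0.5)), "zero")
})
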