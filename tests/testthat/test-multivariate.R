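test_that("the signal matrix holds per-pair ln RORs with zero-cell correction", {
  # hand fixture: 2 drugs x 2 PTs plus comparator reports
  rows <- dplyr::bind_rows(
    make_rows(setNames(lapply(1:10, function(i)
      list(drugs = "X", pts = if (i <= 4) "P1" else "P2")), paste0("x", 1:10))),
    make_rows(setNames(lapply(1:10, function(i)
      list(drugs = "Y", pts = if (i <= 1) "P1" else "P2")), paste0("y", 1:10))),
    make_rows(setNames(lapply(1:20, function(i)
      list(drugs = "Z", pts = if (i <= 5) "P1" else "P2")), paste0("z", 1:20))))
  m <- build_signal_matrix(rows, c("X", "Y"), c("P1", "P2"))
  # hand-computed cells, e.g. (X, P1): a=4 b=6 c=6 d=24
  expect_equal(m["X", "P1"], log((4 * 24) / (6 * 6)))
  expect_equal(m["Y", "P2"], log((9 * 9) / (1 * 21)))
  expect_true(all(is.finite(m)))

  # a drug never co-reported with a PT gets a finite negative cell
  rows2 <- dplyr::bind_rows(rows,
    make_rows(list(w = list(drugs = "W", pts = "P2"))))
  m2 <- build_signal_matrix(rows2, c("X", "W"), c("P1", "P2"))
  expect_true(is.finite(m2["W", "P1"]))
  expect_lt(m2["W", "P1"], 0)

  # report-count filter drops rare terms; empty selections are errors
  m3 <- build_signal_matrix(rows, c("X", "Y"), c("P1", "P2"),
                            min_pt_reports = 11)
  expect_equal(colnames(m3), "P2")
  expect_error(build_signal_matrix(rows, character(), "P1"), "non-empty")
  expect_error(build_signal_matrix(rows, "X", "P1", min_pt_reports = 1e6),
               "min_pt_reports")
})

test_that("null-simulation matrix cells are centred on zero", {
  cfg <- sim_config(8000, test_drug_catalog(6), test_pt_catalog(4, 4),
                    seed = 600)
  rows <- sim_to_rows(simulate_reports(cfg))
  m <- build_signal_matrix(rows, cfg$drugs$drug_name, event_pts(cfg$pts))
  se <- stats::sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m)), 3 * se + 0.05)
})

test_that("PCA explained ratios follow the closed form for two columns", {
  # construct columns with an exact sample correlation r = 0.6
  r <- 0.6
  n <- 50
  set.seed(71)
  z <- scale(matrix(rnorm(n * 2), n, 2))
  z <- qr.Q(qr(z)) * sqrt(n - 1)            # exactly orthonormal columns
  m <- cbind(z[, 1], r * z[, 1] + sqrt(1 - r^2) * z[, 2])
  expect_equal(cor(m)[1, 2], r, tolerance = 1e-12)
  p <- signal_pca(m)
  expect_equal(p$explained_ratio, c((1 + r) / 2, (1 - r) / 2))

  # duplicated column: the shared component explains everything
  dup <- cbind(z[, 1], z[, 1] + 0)
  pd <- signal_pca(dup)
  expect_equal(pd$explained_ratio[1], 1)
})

test_that("PCA conserves variance, reconstructs, and fixes signs", {
  set.seed(72)
  m <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(paste0("d", 1:15), paste0("t", 1:6)))
  p <- signal_pca(m)
  expect_equal(sum(p$explained_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(p$explained_ratio) <= 1e-12))
  # orthogonal components
  g <- crossprod(p$loadings)
  expect_equal(g, diag(ncol(m)), ignore_attr = TRUE, tolerance = 1e-8)
  # full reconstruction of the standardized matrix
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec, scale(m), ignore_attr = TRUE, tolerance = 1e-8)
  # sign convention: each component's largest-magnitude loading positive
  for (j in seq_len(ncol(p$loadings))) {
    l <- p$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # explained ratios are invariant to row permutation
  p2 <- signal_pca(m[sample(nrow(m)), ])
  expect_equal(p2$explained_ratio, p$explained_ratio)
  # zero-variance columns are dropped with a warning
  m0 <- cbind(m, constant = 1)
  expect_warning(p0 <- signal_pca(m0), "zero-variance")
  expect_equal(nrow(p0$loadings), ncol(m))
})

test_that("Ward clustering reproduces the brute-force merge order", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  tree <- ward_cluster(x)
  sets <- hclust_merge_sets(tree)
  expect_equal(sets[[1]], c(1, 2))
  expect_equal(sets[[2]], c(3, 4))
  cl <- cut_clusters(tree, 2)
  expect_equal(unname(cl), c(1, 1, 2, 2))

  # identical points merge first at height zero
  y <- matrix(c(5, 5, 9), ncol = 1)
  t2 <- ward_cluster(y)
  expect_equal(t2$height[1], 0)
  expect_equal(hclust_merge_sets(t2)[[1]], c(1, 2))

  # random fixtures across sizes and dimensions match the oracle exactly
  set.seed(81)
  for (n in 2:7) {
    for (rep in 1:4) {
      z <- matrix(rnorm(n * sample(1:3, 1)), nrow = n)
      tz <- ward_cluster(z, n_components = ncol(z))
      oz <- oracle_ward(z)
      expect_equal(hclust_merge_sets(tz), oz$merge_sets)
      expect_equal(tz$height, oz$heights, tolerance = 1e-8)
      expect_true(all(diff(tz$height) >= -1e-12))  # monotone heights
    }
  }
})

test_that("cluster merges are invariant to rigid rotations of the scores", {
  set.seed(82)
  x <- matrix(rnorm(9 * 3), 9, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  t1 <- ward_cluster(x)
  t2 <- ward_cluster(x %*% rot)
  expect_equal(hclust_merge_sets(t1), hclust_merge_sets(t2))
  expect_equal(t1$height, t2$height, tolerance = 1e-10)
})

test_that("tree cuts cover the degenerate and fixture cases", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  tree <- ward_cluster(x)
  expect_equal(unname(cut_clusters(tree, 1)), rep(1, 4))
  expect_equal(length(unique(cut_clusters(tree, 4))), 4)
  expect_error(cut_clusters(tree, 0), "k must lie")
  expect_error(cut_clusters(tree, 5), "k must lie")
})

test_that("the venous/arterial axis comparison applies Welch's t to loadings", {
  fake_pca <- function(loads) {
    structure(list(loadings = loads,
                   scores = matrix(0, 2, ncol(loads)),
                   explained_ratio = rep(1 / ncol(loads), ncol(loads)),
                   k = ncol(loads), scale = TRUE),
              class = "signal_pca")
  }
  terms <- tibble::tibble(
    pt = paste0("T", 1:7),
    scope = c(rep("venous", 3), rep("arterial", 3), "mixed"))
  class(terms) <- c("smq_term_set", class(terms))
  # groups {1,2,3} vs {2,3,4} on component 2; mixed term excluded
  loads <- cbind(rnorm(7), c(1, 2, 3, 2, 3, 4, 100))
  rownames(loads) <- terms$pt
  out <- smq_axis_comparison(fake_pca(loads), terms, component = 2)
  expect_equal(out$t, -1.224745, tolerance = 1e-6)
  expect_equal(out$df, 4, tolerance = 1e-9)
  expect_equal(out$mean_venous, 2)
  expect_equal(out$mean_arterial, 3)
  # identical groups: t = 0, p = 1
  loads2 <- cbind(rnorm(7), c(1, 2, 3, 1, 2, 3, 0))
  rownames(loads2) <- terms$pt
  out2 <- smq_axis_comparison(fake_pca(loads2), terms, component = 2)
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  expect_error(smq_axis_comparison(fake_pca(loads), terms, component = 3),
               "not retained")
})

test_that("a shared venous latent factor separates the scope means", {
  set.seed(83)
  n_drugs <- 30
  factor_v <- rnorm(n_drugs, sd = 2)
  venous_cols <- sapply(1:4, function(i) factor_v + rnorm(n_drugs, sd = 0.3))
  arterial_cols <- sapply(1:4, function(i) rnorm(n_drugs))
  m <- cbind(venous_cols, arterial_cols)
  dimnames(m) <- list(paste0("d", 1:n_drugs), paste0("T", 1:8))
  terms <- tibble::tibble(pt = paste0("T", 1:8),
                          scope = rep(c("venous", "arterial"), each = 4))
  class(terms) <- c("smq_term_set", class(terms))
  p <- signal_pca(m)
  out <- smq_axis_comparison(p, terms, component = 1)
  expect_gt(out$mean_venous, out$mean_arterial)
  expect_lt(out$p, 0.01)
})

test_that("dendrogram exports round-trip and keep monotone heights", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  tree <- ward_cluster(x)
  dir <- withr::local_tempdir()
  paths <- export_dendrogram(tree, dir, scores = x, k = 2)
  expect_true(all(file.exists(paths)))

  # round trip: the parsed JSON carries the same cophenetic structure
  parsed <- read_dendrogram(paths[["json"]])
  coph <- dendro_cophenetic(parsed)
  ref <- as.matrix(cophenetic(tree))
  expect_equal(coph[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)

  # heights are non-decreasing along the serialized merges
  collect_heights <- function(nd) {
    if (is.null(nd$children)) return(numeric())
    c(unlist(lapply(nd$children, collect_heights)), nd$height)
  }
  expect_true(!is.unsorted(collect_heights(parsed), strictly = FALSE))

  # flat cluster table matches the k = 2 cut
  flat <- readr::read_csv(paths[["clusters"]], show_col_types = FALSE)
  expect_equal(sort(unique(flat$cluster)), c(1, 2))

  # two-leaf tree: a single merge and a two-tip Newick string
  t2 <- ward_cluster(matrix(c(0, 3), ncol = 1,
                            dimnames = list(c("A", "B"), NULL)))
  d2 <- withr::local_tempdir()
  p2 <- export_dendrogram(t2, d2)
  nd <- read_dendrogram(p2[["json"]])
  expect_equal(length(nd$children), 2)
  expect_setequal(vapply(nd$children, `[[`, character(1), "label"),
                  c("A", "B"))
  phy <- ape::read.tree(p2[["newick"]])
  expect_setequal(phy$tip.label, c("A", "B"))
  expect_equal(length(phy$tip.label), 2)
})
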