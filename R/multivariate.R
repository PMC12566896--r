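# Drug-by-term ln(ROR) signal matrix, PCA, Ward clustering, and exports.

#' Build the drug-by-term ln(ROR) signal matrix
#'
#' For each (drug, preferred term) pair, builds the 2x2 table of the drug
#' against that single term over the full report table, applies the
#' Haldane correction whenever a cell is zero, and stores `ln(ROR)`. All
#' cells are therefore finite. Terms are first filtered by their total
#' report count across all drugs (`min_pt_reports`), mirroring the usual
#' restriction of multivariate profiling to well-reported events.
#'
#' @param rows deduplicated integrated report tibble (all drugs, not just
#'   the cohort: other drugs form the comparator).
#' @param drugs ordered character vector of drugs (matrix rows); normally
#'   the flagged signal drugs.
#' @param pts ordered character vector of candidate preferred terms
#'   (matrix columns), e.g. `thrombosis_terms()$pt`.
#' @param min_pt_reports minimum total report rows for a term to be kept.
#' @return numeric matrix of ln(ROR) values with drug row names and term
#'   column names.
#' @export
build_signal_matrix <- function(rows, drugs, pts, min_pt_reports = 0) {
  drugs <- unique(normalize_drug_name(drugs))
  pts <- unique(normalize_pt(pts))
  if (length(drugs) == 0 || length(pts) == 0) {
    stop("build_signal_matrix() needs non-empty drug and term lists",
         call. = FALSE)
  }
  pt_counts <- table(rows$pt)
  have <- pts[pts %in% names(pt_counts)]
  keep <- have[pt_counts[have] >= min_pt_reports]
  if (length(keep) == 0) {
    stop("no preferred term reaches min_pt_reports = ", min_pt_reports,
         call. = FALSE)
  }
  N <- nrow(rows)
  sub <- rows[rows$drug_name %in% drugs & rows$pt %in% keep, ]
  A <- matrix(0, length(drugs), length(keep), dimnames = list(drugs, keep))
  if (nrow(sub) > 0) {
    tab <- table(factor(sub$drug_name, levels = drugs),
                 factor(sub$pt, levels = keep))
    A[] <- as.numeric(tab)
  }
  row_tot <- table(factor(rows$drug_name[rows$drug_name %in% drugs],
                          levels = drugs))
  col_tot <- pt_counts[keep]
  B <- matrix(as.numeric(row_tot), length(drugs), length(keep)) - A
  C <- matrix(as.numeric(col_tot), length(drugs), length(keep),
              byrow = TRUE) - A
  D <- N - A - B - C
  corr <- 0.5 * (A == 0 | B == 0 | C == 0 | D == 0)
  log(((A + corr) * (D + corr)) / ((B + corr) * (C + corr)))
}

#' Principal component analysis of a signal matrix
#'
#' Column-standardized (correlation-scale) PCA by default, the usual
#' choice when event columns have widely different reporting volumes;
#' `scale = FALSE` switches to covariance-scale PCA. Zero-variance
#' columns are dropped with a warning before standardization. Component
#' signs are fixed so that each component's largest-magnitude loading is
#' positive, making score plots reproducible.
#'
#' @param m numeric matrix (drugs x terms), e.g. from
#'   [build_signal_matrix()].
#' @param k number of components to retain in `loadings`/`scores`;
#'   defaults to all.
#' @param scale logical; standardize columns to unit variance.
#' @return an object of class `signal_pca`: list with `loadings` (terms x
#'   k), `scores` (drugs x k), `explained_ratio` (all components,
#'   non-increasing, summing to 1), `k`, `scale`.
#' @export
signal_pca <- function(m, k = NULL, scale = TRUE) {
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("signal_pca() needs at least 2 rows and 2 columns", call. = FALSE)
  }
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance column(s)",
            call. = FALSE)
    m <- m[, v > 0, drop = FALSE]
    if (ncol(m) < 2) stop("fewer than 2 informative columns", call. = FALSE)
  }
  pr <- prcomp(m, center = TRUE, scale. = scale)
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  pr$rotation <- sweep(pr$rotation, 2, flip, `*`)
  pr$x <- sweep(pr$x, 2, flip, `*`)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  if (is.null(k)) k <- ncol(pr$rotation)
  k <- min(k, ncol(pr$rotation))
  structure(list(loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 scores = pr$x[, seq_len(k), drop = FALSE],
                 explained_ratio = expl, k = k, scale = scale),
            class = "signal_pca")
}

#' @export
print.signal_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "drugs x", nrow(x$loadings), "terms;",
      "explained (first 3):",
      paste0(round(100 * head(x$explained_ratio, 3), 2), "%", collapse = ", "),
      "\n")
  invisible(x)
}

#' Ward clustering of principal-component scores
#'
#' Agglomerative clustering with the Ward criterion (minimum increase in
#' total within-cluster sum of squares), computed as `hclust` method
#' `"ward.D2"` on Euclidean distances over the first `n_components` score
#' columns. Merge heights equal `sqrt(2 * delta_ESS)` and are
#' non-decreasing.
#'
#' @param scores numeric matrix of coordinates (e.g. `$scores` of a
#'   [signal_pca()]), with row names as labels.
#' @param n_components number of leading columns to use.
#' @return an `hclust` object (merge history, heights, labels).
#' @export
ward_cluster <- function(scores, n_components = 3) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (nrow(scores) < 2) stop("ward_cluster() needs at least 2 rows",
                             call. = FALSE)
  x <- scores[, seq_len(min(n_components, ncol(scores))), drop = FALSE]
  hclust(dist(x), method = "ward.D2")
}

#' Cut a cluster tree into k groups
#'
#' @param tree an `hclust` object from [ward_cluster()].
#' @param k number of clusters, between 1 and the number of leaves.
#' @return named integer vector of cluster labels.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]", call. = FALSE)
  cutree(tree, k = k)
}

#' Compare venous versus arterial term loadings on one component
#'
#' Splits the preferred-term loadings of the chosen principal component
#' by SMQ scope, excludes mixed/unspecified-vessel terms, and compares
#' the venous and arterial groups with Welch's unequal-variance t test.
#' The unit of analysis is the event term (its loading), the quantity
#' that carries the arterial/venous annotation in the term set.
#'
#' @param pca a [signal_pca()] object whose loading row names are
#'   preferred terms.
#' @param terms an `smq_term_set` with scopes.
#' @param component component index (default 2, the axis that typically
#'   separates venous from arterial profiles).
#' @return list with `mean_venous`, `mean_arterial`, `t`, `df`, `p`,
#'   `n_venous`, `n_arterial`.
#' @export
smq_axis_comparison <- function(pca, terms, component = 2) {
  if (component > ncol(pca$loadings)) {
    stop("component ", component, " not retained in the PCA", call. = FALSE)
  }
  ld <- pca$loadings[, component]
  scope <- terms$scope[match(normalize_pt(names(ld)), terms$pt)]
  ven <- ld[!is.na(scope) & scope == "venous"]
  art <- ld[!is.na(scope) & scope == "arterial"]
  if (length(ven) < 2 || length(art) < 2) {
    stop("need at least 2 venous and 2 arterial terms with loadings",
         call. = FALSE)
  }
  tt <- t.test(ven, art)  # Welch by default
  list(mean_venous = mean(ven), mean_arterial = mean(art),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_venous = length(ven), n_arterial = length(art))
}

# recursive nested representation of an hclust tree
.dendro_node <- function(tree, node) {
  if (node < 0) {
    list(label = tree$labels[-node], height = 0)
  } else {
    list(height = tree$height[node],
         children = list(.dendro_node(tree, tree$merge[node, 1]),
                         .dendro_node(tree, tree$merge[node, 2])))
  }
}

#' Nested-list representation of a cluster tree
#'
#' @param tree an `hclust` object.
#' @return nested list: leaves carry `label` and `height = 0`, internal
#'   nodes carry `height` and two `children`. Heights are non-decreasing
#'   from leaves to root for Ward trees.
#' @export
dendrogram_json <- function(tree) {
  .dendro_node(tree, nrow(tree$merge))
}

#' Export a cluster tree and flat cluster tables
#'
#' Writes the nested merge structure as JSON, optionally a Newick string
#' (branch lengths are merge-height differences, via [ape::as.phylo()]),
#' and, when scores are supplied, a flat `clusters.csv` with the cluster
#' assignment and leading component coordinates of each drug.
#'
#' @param tree an `hclust` object.
#' @param dir output directory.
#' @param scores optional score matrix (row names matching tree labels).
#' @param k number of clusters for the flat assignment.
#' @param newick logical; also write `dendrogram.nwk`.
#' @return invisibly, a named vector of written paths.
#' @export
export_dendrogram <- function(tree, dir, scores = NULL, k = 4,
                              newick = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "dendrogram.json"))
  jsonlite::write_json(dendrogram_json(tree), paths["json"],
                       auto_unbox = TRUE, digits = NA)
  if (newick) {
    paths["newick"] <- file.path(dir, "dendrogram.nwk")
    ape::write.tree(ape::as.phylo(tree), paths["newick"])
  }
  if (!is.null(scores)) {
    k <- min(k, length(tree$order))
    cl <- cut_clusters(tree, k)
    sc <- scores[match(names(cl), rownames(scores)), , drop = FALSE]
    flat <- tibble::tibble(drug_name = names(cl), cluster = unname(cl))
    for (j in seq_len(min(3, ncol(sc)))) flat[[paste0("PC", j)]] <- sc[, j]
    paths["clusters"] <- file.path(dir, "clusters.csv")
    readr::write_csv(flat, paths["clusters"])
  }
  invisible(paths)
}

#' Read a dendrogram JSON back into its nested-list form
#'
#' Inverse of the JSON export: `read_dendrogram(path)` returns the same
#' nested structure [dendrogram_json()] produced (round-trip identity up
#' to numeric precision).
#'
#' @param path JSON file path.
#' @return nested list.
#' @export
read_dendrogram <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Pairwise merge heights implied by a nested dendrogram
#'
#' Flattens a nested dendrogram (as from [dendrogram_json()] or
#' [read_dendrogram()]) into the cophenetic matrix: the merge height at
#' which each pair of leaves first joins. Useful for comparing a
#' serialized tree with the `hclust` object it came from.
#'
#' @param node nested dendrogram list.
#' @return a symmetric matrix with leaf labels as dimnames.
#' @export
dendro_cophenetic <- function(node) {
  leaves <- function(nd) {
    if (!is.null(nd$label)) nd$label
    else unlist(lapply(nd$children, leaves))
  }
  labs <- leaves(node)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  fill <- function(nd) {
    if (is.null(nd$children)) return(invisible())
    l1 <- leaves(nd$children[[1]]); l2 <- leaves(nd$children[[2]])
    m[l1, l2] <<- nd$height
    m[l2, l1] <<- nd$height
    lapply(nd$children, fill)
    invisible()
  }
  fill(node)
  m
}
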