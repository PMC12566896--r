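# Independent oracles used by the test suite. These deliberately avoid the
# code paths they check: the Fisher oracle enumerates the hypergeometric
# distribution directly, and the Ward oracle recomputes within-cluster
# sums of squares from scratch at every step instead of using a
# Lance-Williams update.

# two-sided Fisher p by full enumeration of the conditional distribution
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b          # draws (drug rows)
  c1 <- a + c          # white balls (event rows)
  N <- a + b + c + d
  lo <- max(0, r1 - (N - c1))
  hi <- min(r1, c1)
  supp <- lo:hi
  probs <- stats::dhyper(supp, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# greedy Ward agglomeration with the merge cost (increase in total
# within-cluster sum of squares) computed exhaustively from coordinates
oracle_ward <- function(x) {
  x <- as.matrix(x)
  ess <- function(idx) {
    y <- x[idx, , drop = FALSE]
    sum(sweep(y, 2, colMeans(y))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  merge_sets <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in 1:(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merge_sets <- c(merge_sets, list(merged))
    heights <- c(heights, sqrt(2 * best_cost))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(merge_sets = merge_sets, heights = heights)
}

# the sequence of merged leaf sets an hclust object implies
hclust_merge_sets <- function(h) {
  sets <- vector("list", nrow(h$merge))
  for (s in seq_len(nrow(h$merge))) {
    grab <- function(k) if (k < 0) -k else sets[[k]]
    sets[[s]] <- sort(c(grab(h$merge[s, 1]), grab(h$merge[s, 2])))
  }
  sets
}

# compact builder for integrated report rows: cases is a named list
# mapping case_id -> list(drugs = ..., pts = ...); the cross product of
# each case's drugs and PTs is emitted
make_rows <- function(cases) {
  out <- lapply(names(cases), function(id) {
    expand.grid(case_id = id, drug_name = cases[[id]]$drugs,
                pt = cases[[id]]$pts, stringsAsFactors = FALSE)
  })
  tibble::as_tibble(do.call(rbind, out))[, c("case_id", "drug_name", "pt")]
}

# small default catalogs for generator-based tests
test_drug_catalog <- function(n_drugs = 10) {
  tibble::tibble(drug_name = sprintf("DRUG%02d", seq_len(n_drugs)))
}

test_pt_catalog <- function(n_event = 3, n_background = 7,
                            base_event = 0.02, base_background = 0.05) {
  tibble::tibble(
    pt = c(sprintf("EVENT%02d", seq_len(n_event)),
           sprintf("BACKGROUND%02d", seq_len(n_background))),
    base_p = c(rep(base_event, n_event), rep(base_background, n_background)),
    scope = c(rep(c("venous", "arterial", "mixed"), length.out = n_event),
              rep("none", n_background))
  )
}

event_pts <- function(pts) pts$pt[pts$scope != "none"]

# integrate -> dedup -> monotherapy on generator output
sim_to_rows <- function(sim, monotherapy = TRUE) {
  rows <- dedup_reports(integrate_reports(sim$drug, sim$reac))
  if (monotherapy) rows <- monotherapy_filter(rows) else rows
}

scaffold_fixture_path <- function() {
  system.file("extdata", "scaffold_fixture.tsv", package = "steroidror")
}

read_scaffold_fixture <- function() {
  readr::read_tsv(scaffold_fixture_path(),
                  col_types = readr::cols(drug_name = "c", smiles = "c",
                                          is_steroid = "l"),
                  progress = FALSE)
}
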