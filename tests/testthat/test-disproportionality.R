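ct <- contingency_table

test_that("report rows cross-tabulate into exact cells", {
  rows <- make_rows(list(
    `1` = list(drugs = "X", pts = c("DVT", "HEADACHE")),
    `2` = list(drugs = "X", pts = "DVT"),
    `3` = list(drugs = "Y", pts = c("DVT", "NAUSEA", "HEADACHE")),
    `4` = list(drugs = "Z", pts = c("NAUSEA", "HEADACHE", "RASH"))))
  tab <- contingency(rows, "X", "DVT")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 2, b = 1, c = 1, d = 5))
  expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(rows))
  # event set covering every PT forces b = d = 0
  tab_all <- contingency(rows, "X", unique(rows$pt))
  expect_equal(c(tab_all$b, tab_all$d), c(0, 0))
  # absent drug: a = b = 0, not an error
  tab_none <- contingency(rows, "ABSENT", "DVT")
  expect_equal(c(tab_none$a, tab_none$b), c(0, 0))
})

test_that("the Haldane correction fires only on zero cells", {
  expect_equal(unlist(haldane(ct(0, 10, 5, 20))[c("a", "b", "c", "d")]),
               c(a = 0.5, b = 10.5, c = 5.5, d = 20.5))
  expect_true(haldane(ct(0, 10, 5, 20))$corrected)
  expect_identical(haldane(ct(1, 1, 1, 1)), ct(1, 1, 1, 1))
  all_zero <- haldane(ct(0, 0, 0, 0))
  expect_equal(ror(all_zero), 1)
})

test_that("the reporting odds ratio follows the cross-product formula", {
  expect_equal(ror(ct(5, 5, 5, 5)), 1)
  expect_equal(ror(ct(20, 80, 10, 90)), 2.25)
  expect_equal(ror(haldane(ct(0, 10, 5, 20))), 10.25 / 57.75)
  expect_error(ror(ct(5, 0, 5, 5)), "haldane")
})

test_that("ROR is scale-invariant and strictly increasing in a", {
  set.seed(3)
  for (i in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    k <- runif(1, 0.1, 10)
    t1 <- ct(cells[1], cells[2], cells[3], cells[4])
    t2 <- ct(k * cells[1], k * cells[2], k * cells[3], k * cells[4])
    expect_equal(ror(t1), ror(t2))
    t3 <- ct(cells[1] + 1, cells[2], cells[3], cells[4])
    expect_gt(ror(t3), ror(t1))
  }
})

test_that("the Woolf interval matches its closed form and degenerate cases", {
  ci <- ror_ci(ct(20, 80, 10, 90), z = 1.96)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(unname(ci),
               exp(log(2.25) + c(-1, 1) * 1.96 * se))
  expect_equal(round(unname(ci), 3), c(0.994, 5.092))
  # symmetric about 1 on the log scale for a balanced table
  ci_bal <- ror_ci(ct(5, 5, 5, 5), z = 1.96)
  expect_equal(log(ci_bal[["low"]]), -log(ci_bal[["high"]]))
  # z = 0 collapses the interval onto the estimate
  expect_equal(unname(ror_ci(ct(20, 80, 10, 90), z = 0)), c(2.25, 2.25))
  expect_error(ror_ci(ct(0, 5, 5, 5)), "haldane")
})

test_that("Fisher p matches enumeration and rejects corrected cells", {
  expect_equal(fisher_p(ct(5, 5, 5, 5)), 1)
  expect_equal(fisher_p(ct(1, 9, 9, 1)), 202 / 184756)
  expect_equal(fisher_p(ct(10, 0, 0, 10)), 2 / choose(20, 10))
  expect_error(fisher_p(haldane(ct(0, 5, 5, 5))), "integer")
  expect_error(fisher_p(ct(1.3, 2, 3, 4)), "integer")
  # transposition symmetry and random-table agreement with the oracle
  set.seed(19)
  for (i in 1:40) {
    cells <- sample(0:15, 4, replace = TRUE)
    if (sum(cells) == 0) next
    p <- fisher_p(ct(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(p, fisher_p(ct(cells[1], cells[3], cells[2], cells[4])))
    expect_equal(p, oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("signal scan flags by effect, significance and report volume", {
  # drug at 999 rows with a huge effect stays unflagged at the 1000 cutoff
  rows <- dplyr::bind_rows(
    make_rows(setNames(lapply(1:999, function(i)
      list(drugs = "BIG", pts = if (i <= 500) "DVT" else "OTHER")),
      paste0("b", 1:999))),
    make_rows(setNames(lapply(1:2000, function(i)
      list(drugs = "REF", pts = if (i <= 20) "DVT" else "OTHER")),
      paste0("r", 1:2000))))
  res <- signal_scan(rows, c("BIG", "REF"), "DVT", min_drug_reports = 1000)
  big <- res[res$drug_name == "BIG", ]
  expect_equal(big$n_drug_reports, 999)
  expect_gt(big$ln_ror, 0)
  expect_lt(big$p, 0.05)
  expect_false(big$flagged)
  res2 <- signal_scan(rows, "BIG", "DVT", min_drug_reports = 999)
  expect_true(res2$flagged)
})

test_that("a strong simulated effect is flagged at scale", {
  drugs <- test_drug_catalog(5)
  pts <- test_pt_catalog(2, 3, base_event = 0.01)
  cfg <- sim_config(50000, drugs, pts,
                    effects = tibble::tibble(drug_name = "DRUG01",
                                             pt = "EVENT01", theta = 3),
                    seed = 404)
  rows <- sim_to_rows(simulate_reports(cfg))
  res <- signal_scan(rows, drugs$drug_name, "EVENT01", min_drug_reports = 1)
  expect_true(res$flagged[res$drug_name == "DRUG01"])
  expect_false(any(res$flagged[res$drug_name != "DRUG01"] &
                     res$p[res$drug_name != "DRUG01"] < 1e-4))
})

test_that("volcano coordinates use the stated axes and flooring", {
  res <- tibble::tibble(drug_name = c("A", "B", "C"),
                        ror = c(1, 2.25, 3), p = c(1, 0.01, 0),
                        flagged = c(FALSE, TRUE, TRUE))
  pts <- volcano_points(res)
  expect_equal(pts$y[1], 0)            # p = 1
  expect_equal(pts$x[1], 0)            # ROR = 1
  expect_equal(pts$x[2], log(2.25))
  expect_equal(pts$y[2], 2)
  expect_equal(pts$y[3], 300)          # floored at 1e-300
})

test_that("stratified RORs compare each stratum to all other labelled strata", {
  # two strata with identical event proportions: both RORs are 1
  rows <- dplyr::bind_rows(
    make_rows(setNames(lapply(1:20, function(i)
      list(drugs = "X", pts = if (i <= 5) "DVT" else "OTHER")),
      paste0("a", 1:20))),
    make_rows(setNames(lapply(1:40, function(i)
      list(drugs = "X", pts = if (i <= 10) "DVT" else "OTHER")),
      paste0("b", 1:40))))
  strata <- setNames(c(rep("ORAL", 20), rep("TOPICAL", 40)),
                     c(paste0("a", 1:20), paste0("b", 1:40)))
  out <- stratified_ror(rows, strata, "DVT")
  expect_equal(out$ror, c(1, 1))

  # hand-built 3-stratum fixture: cells and RORs computed by hand
  rows3 <- tibble::tibble(
    case_id = as.character(1:60),
    drug_name = "X",
    pt = c(rep("DVT", 12), rep("OTHER", 8),    # S1: 12/8
           rep("DVT", 5), rep("OTHER", 15),    # S2: 5/15
           rep("DVT", 10), rep("OTHER", 10)))  # S3: 10/10
  lab3 <- setNames(rep(c("S1", "S2", "S3"), each = 20), rows3$case_id)
  out3 <- stratified_ror(rows3, lab3, "DVT")
  expect_equal(out3$a, c(12, 5, 10))
  expect_equal(out3$ror,
               c((12 * 25) / (8 * 15),   # S1 vs S2+S3
                 (5 * 18) / (15 * 22),   # S2 vs S1+S3
                 (10 * 23) / (10 * 17))) # S3 vs S1+S2
  # unlabeled cases are excluded
  out3b <- stratified_ror(rows3, lab3[1:40], "DVT")
  expect_equal(nrow(out3b), 2)
})

test_that("a route-specific simulated effect shows up in its stratum", {
  drugs <- tibble::tibble(drug_name = c("DORAL", "DPATCH"),
                          route = c("ORAL", "TRANSDERMAL"))
  pts <- test_pt_catalog(2, 3, base_event = 0.02)
  cfg <- sim_config(20000, drugs, pts,
                    effects = tibble::tibble(drug_name = "DORAL",
                                             pt = "EVENT01", theta = 4),
                    polypharmacy_prob = 0, seed = 500)
  sim <- simulate_reports(cfg)
  rows <- sim_to_rows(sim)
  strata <- case_strata(drug = sim$drug, by = "route")
  out <- stratified_ror(rows, strata, "EVENT01")
  oral <- out[out$stratum == "ORAL", ]
  expect_gt(oral$ror, 1.5)
  expect_lt(oral$p, 0.001)
})

test_that("age comparison reports medians and a rank-sum p-value", {
  mk <- function(ids, pts) {
    tibble::tibble(case_id = ids, drug_name = "X", pt = pts)
  }
  # {1..100} vs {51..150}: median difference 50, overwhelming evidence
  rows <- mk(as.character(1:200), rep(c("DVT", "OTHER"), each = 100))
  demo <- tibble::tibble(case_id = as.character(1:200),
                         sex = "F", age_years = c(1:100, 51:150),
                         age_invalid = FALSE)
  out <- age_comparison(rows, demo, "DVT")
  expect_equal(out$median_event, 50.5)
  expect_equal(out$median_nonevent, 100.5)
  expect_lt(out$p, 1e-3)
  expect_equal(out$p,
               suppressWarnings(wilcox.test(1:100, 51:150,
                                            exact = FALSE)$p.value))
  # identical age distributions: p = 1, equal medians
  demo2 <- tibble::tibble(case_id = as.character(1:200), sex = "F",
                          age_years = rep(1:100, 2), age_invalid = FALSE)
  out2 <- age_comparison(rows, demo2, "DVT")
  expect_equal(out2$median_event, out2$median_nonevent)
  expect_equal(out2$p, 1)
  # no event cases: hard error
  expect_error(age_comparison(mk("1", "OTHER"), demo, "DVT"), "event")
})

test_that("class summary reproduces printed flag proportions", {
  # classes with 3/4 and 12/17 flagged members: 75.0% and 70.6%
  drugs <- c(sprintf("AND%02d", 1:4), sprintf("PRO%02d", 1:17))
  class_map <- tibble::tibble(
    drug_name = drugs,
    class = rep(c("Androgen", "Progestogen"), c(4, 17)))
  results <- tibble::tibble(
    drug_name = drugs,
    flagged = c(rep(TRUE, 3), FALSE, rep(TRUE, 12), rep(FALSE, 5)))
  rows <- make_rows(setNames(lapply(seq_along(drugs), function(i)
    list(drugs = drugs[i], pts = c("DVT", "OTHER"))),
    paste0("c", seq_along(drugs))))
  out <- class_summary(results, class_map, rows, "DVT")
  expect_equal(out$pct_flagged[out$class == "Androgen"], 75.0)
  expect_equal(out$n_flagged[out$class == "Androgen"], 3)
  expect_equal(out$n_total[out$class == "Androgen"], 4)
  expect_equal(out$pct_flagged[out$class == "Progestogen"], 70.6)
  # pooled 2x2 for a class sums member cells against non-members
  tab <- contingency(rows, drugs[1:4], "DVT")
  expect_equal(out$ror[out$class == "Androgen"],
               ror(haldane(tab)))
})

test_that("classes absent from the screen are omitted with a warning", {
  class_map <- tibble::tibble(drug_name = c("A", "B"),
                              class = c("Androgen", "Estrogen"))
  results <- tibble::tibble(drug_name = "A", flagged = TRUE)
  rows <- make_rows(list(`1` = list(drugs = "A", pts = c("DVT", "OTHER"))))
  expect_warning(out <- class_summary(results, class_map, rows, "DVT"),
                 "Estrogen")
  expect_false("Estrogen" %in% out$class)
})
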