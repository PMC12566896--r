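# Synthetic spontaneous-report generator with closed-form ground truth.
#
# The generative model is deliberately the simplest structure under which
# the reporting odds ratio is identifiable: each case receives one drug
# (or several, with configurable probability), and each preferred term is
# included independently with probability
#
#   p(case, t) = odds_t * prod(theta[d, t]) / (1 + odds_t * prod(theta[d, t]))
#
# where odds_t = base_p_t / (1 - base_p_t) is the baseline reporting odds
# of term t and theta[d, t] is the configured reporting-odds multiplier of
# drug d on term t (theta == 1 everywhere is the null). Expected 2x2 cell
# counts, and hence the expected ROR, follow in closed form and are exposed
# through expected_contingency() as the recovery target for tests.

#' Configuration for the synthetic report generator
#'
#' @param n_cases number of cases (reports) to simulate.
#' @param drugs tibble describing the drug catalog, with columns
#'   `drug_name` (required), and optionally `weight` (relative sampling
#'   weight, default equal), `route` (administration route written to the
#'   DRUG table), `smiles`, `class`.
#' @param pts tibble describing the preferred-term catalog: `pt`
#'   (required), `base_p` (baseline per-case reporting probability, in
#'   (0,1)), and optionally `scope` (`"arterial"`, `"venous"`, `"mixed"`
#'   or `"none"` for background terms).
#' @param effects optional tibble of reporting-odds multipliers:
#'   `drug_name`, `pt`, `theta` (finite, >= 0). Unlisted pairs default to
#'   `theta = 1` (no effect).
#' @param polypharmacy_prob probability that a case reports two or more
#'   drugs (the extra count is 1 + Poisson(0.5), truncated to the catalog
#'   size).
#' @param duplicate_prob probability that a case's DRUG and REAC rows are
#'   emitted twice verbatim, exercising downstream deduplication.
#' @param p_female probability that a case is female.
#' @param age_mean,age_sd age distribution in years (normal, truncated to
#'   \[0, 110\]).
#' @param start_window length-2 character/Date vector giving the therapy
#'   start-date window (uniform).
#' @param seed integer seed; identical configurations with identical seeds
#'   generate identical tables.
#' @return a validated `sim_config` object (a list).
#' @export
sim_config <- function(n_cases,
                       drugs,
                       pts,
                       effects = NULL,
                       polypharmacy_prob = 0.1,
                       duplicate_prob = 0.05,
                       p_female = 0.6,
                       age_mean = 58,
                       age_sd = 18,
                       start_window = c("2015-01-01", "2024-09-30"),
                       seed = 1L) {
  drugs <- tibble::as_tibble(drugs)
  pts <- tibble::as_tibble(pts)
  stopifnot_config <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  stopifnot_config(is.numeric(n_cases) && length(n_cases) == 1 && n_cases >= 1,
                   "n_cases must be a positive integer")
  stopifnot_config("drug_name" %in% names(drugs) && nrow(drugs) > 0,
                   "drugs needs a non-empty drug_name column")
  stopifnot_config(all(c("pt", "base_p") %in% names(pts)) && nrow(pts) > 0,
                   "pts needs non-empty pt and base_p columns")
  drugs$drug_name <- normalize_drug_name(drugs$drug_name)
  pts$pt <- normalize_pt(pts$pt)
  stopifnot_config(!anyDuplicated(drugs$drug_name), "duplicate drug_name in catalog")
  stopifnot_config(!anyDuplicated(pts$pt), "duplicate pt in catalog")
  if (!("weight" %in% names(drugs))) drugs$weight <- 1
  if (!("route" %in% names(drugs))) drugs$route <- "ORAL"
  if (!("scope" %in% names(pts))) pts$scope <- "none"
  stopifnot_config(all(is.finite(drugs$weight)) && all(drugs$weight > 0),
                   "drug weights must be positive and finite")
  stopifnot_config(all(is.finite(pts$base_p)) && all(pts$base_p > 0) &&
                     all(pts$base_p < 1),
                   "baseline probabilities must lie in (0, 1)")
  stopifnot_config(all(pts$scope %in% c("arterial", "venous", "mixed", "none")),
                   "pt scope must be arterial/venous/mixed/none")
  for (p in c(polypharmacy_prob, duplicate_prob, p_female)) {
    stopifnot_config(is.numeric(p) && length(p) == 1 && p >= 0 && p <= 1,
                     "probabilities must lie in [0, 1]")
  }
  stopifnot_config(is.numeric(age_sd) && age_sd >= 0, "age_sd must be >= 0")
  start_window <- as.Date(start_window)
  stopifnot_config(length(start_window) == 2 && !anyNA(start_window) &&
                     start_window[1] <= start_window[2],
                   "start_window must be two ordered dates")
  theta <- matrix(1, nrow(drugs), nrow(pts),
                  dimnames = list(drugs$drug_name, pts$pt))
  if (!is.null(effects) && nrow(effects) > 0) {
    effects <- tibble::as_tibble(effects)
    stopifnot_config(all(c("drug_name", "pt", "theta") %in% names(effects)),
                     "effects needs drug_name, pt, theta columns")
    effects$drug_name <- normalize_drug_name(effects$drug_name)
    effects$pt <- normalize_pt(effects$pt)
    stopifnot_config(all(effects$drug_name %in% drugs$drug_name),
                     "effects refer to drugs absent from the catalog")
    stopifnot_config(all(effects$pt %in% pts$pt),
                     "effects refer to preferred terms absent from the catalog")
    stopifnot_config(all(is.finite(effects$theta)) && all(effects$theta >= 0),
                     "theta must be finite and >= 0")
    theta[cbind(match(effects$drug_name, drugs$drug_name),
                match(effects$pt, pts$pt))] <- effects$theta
  }
  structure(list(n_cases = as.integer(n_cases), drugs = drugs, pts = pts,
                 theta = theta, polypharmacy_prob = polypharmacy_prob,
                 duplicate_prob = duplicate_prob, p_female = p_female,
                 age_mean = age_mean, age_sd = age_sd,
                 start_window = start_window, seed = as.integer(seed)),
            class = "sim_config")
}

# per-(drug, pt) inclusion probabilities implied by the model, D x T
.inclusion_probs <- function(config) {
  odds0 <- config$pts$base_p / (1 - config$pts$base_p)
  odds <- sweep(config$theta, 2, odds0, `*`)
  odds / (1 + odds)
}

#' Simulate FAERS-shaped report tables
#'
#' Draws cases under the configured generative model and returns the four
#' record tables in the same layout [read_faers()] produces, plus a ground
#' truth list. Reproducible: the same configuration (including its seed)
#' yields identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `drug`, `reac`, `demo`, `ther` (tibbles) and
#'   `truth` (list with `cases`: per-case tibble of drug count, duplicate
#'   flag, sex and age; and `config`).
#' @export
simulate_reports <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  set.seed(config$seed)
  n <- config$n_cases
  D <- nrow(config$drugs)
  ids <- sprintf("C%08d", seq_len(n))

  # drugs per case: 1, or 2+ with probability polypharmacy_prob
  poly <- runif(n) < config$polypharmacy_prob & D >= 2
  n_drugs <- ifelse(poly, pmin(2L + rpois(n, 0.5), D), 1L)
  w <- config$drugs$weight / sum(config$drugs$weight)
  first <- sample.int(D, n, replace = TRUE, prob = w)
  case_idx <- seq_len(n)
  extra_list <- lapply(which(poly), function(i) {
    k <- n_drugs[i] - 1L
    pool <- setdiff(seq_len(D), first[i])
    pool[sample.int(length(pool), k)]
  })
  drug_pairs <- tibble::tibble(
    case = c(case_idx, rep(which(poly), lengths(extra_list))),
    drug = c(first, unlist(extra_list)),
    role = c(rep("PS", n), rep("C", sum(lengths(extra_list))))
  ) %>% dplyr::arrange(.data$case)

  # per-case, per-term inclusion probability: baseline odds scaled by the
  # product of theta over the case's drugs
  logtheta <- log(.inclusion_probs(config) /
                    (1 - .inclusion_probs(config)))  # logit scale, D x T
  # logit(p_case_t) = logit(base) + sum_d log theta; equivalently sum the
  # per-drug logits and subtract the extra baseline copies
  base_logit <- log(config$pts$base_p / (1 - config$pts$base_p))
  sum_logit <- rowsum(logtheta[drug_pairs$drug, , drop = FALSE],
                      group = drug_pairs$case, reorder = TRUE)
  extra <- tabulate(drug_pairs$case, nbins = n) - 1L
  logit_case <- sum_logit - outer(extra, base_logit)
  p_case <- 1 / (1 + exp(-logit_case))
  incl <- matrix(runif(n * ncol(p_case)), n) < p_case
  hits <- which(incl, arr.ind = TRUE)

  drug_tbl <- tibble::tibble(
    case_id = ids[drug_pairs$case],
    drug_name = config$drugs$drug_name[drug_pairs$drug],
    role_code = drug_pairs$role,
    route = config$drugs$route[drug_pairs$drug]
  )
  reac_tbl <- tibble::tibble(case_id = ids[hits[, 1]],
                             pt = config$pts$pt[hits[, 2]]) %>%
    dplyr::arrange(.data$case_id)

  sex <- ifelse(runif(n) < config$p_female, "F", "M")
  age <- rnorm(n, config$age_mean, config$age_sd)
  while (any(bad <- age < 0 | age > 110)) {  # truncated normal by rejection
    age[bad] <- rnorm(sum(bad), config$age_mean, config$age_sd)
  }
  demo_tbl <- tibble::tibble(case_id = ids, sex = sex,
                             age_years = round(age, 1),
                             age_invalid = FALSE)

  span <- as.integer(config$start_window[2] - config$start_window[1])
  ther_tbl <- tibble::tibble(
    case_id = ids[drug_pairs$case],
    drug_name = config$drugs$drug_name[drug_pairs$drug],
    start_date = config$start_window[1] +
      sample.int(span + 1L, nrow(drug_pairs), replace = TRUE) - 1L
  )
  ther_tbl$start_year <- as.integer(format(ther_tbl$start_date, "%Y"))

  dup <- runif(n) < config$duplicate_prob
  if (any(dup)) {
    dup_ids <- ids[dup]
    drug_tbl <- dplyr::bind_rows(drug_tbl, drug_tbl[drug_tbl$case_id %in% dup_ids, ])
    reac_tbl <- dplyr::bind_rows(reac_tbl, reac_tbl[reac_tbl$case_id %in% dup_ids, ])
  }

  truth <- list(
    cases = tibble::tibble(case_id = ids, n_drugs = n_drugs,
                           duplicated = dup, sex = sex,
                           age_years = round(age, 1)),
    config = config
  )
  list(drug = drug_tbl, reac = reac_tbl, demo = demo_tbl, ther = ther_tbl,
       truth = truth)
}

#' Expected 2x2 contingency table under the generative model
#'
#' Closed-form expected cell counts of the integrated, deduplicated,
#' monotherapy-filtered report table for a given drug against a preferred-
#' term set, computed from the configured probabilities (no simulation).
#' Serves as the recovery target when validating the estimation pipeline
#' against the generator.
#'
#' With w_g the normalized catalog weight of drug g, n_mono the expected
#' number of monotherapy cases and p_gt the per-case inclusion probability
#' of term t under drug g, the expected cells are
#' `a = n_mono * w_g * sum(p_gt, t in S)`, `b` the complement over terms,
#' and `c`, `d` the corresponding sums over all other drugs.
#'
#' @param config a [sim_config()] object.
#' @param drug drug name (must be in the catalog).
#' @param pt_set character vector of preferred terms forming the event set
#'   (each must be in the catalog), or an `smq_term_set` from
#'   [read_term_set()].
#' @return a [contingency_table()] of expected (non-integer) counts, with
#'   attribute `expected_ror`.
#' @export
expected_contingency <- function(config, drug, pt_set) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  drug <- normalize_drug_name(drug)
  if (inherits(pt_set, "smq_term_set")) pt_set <- pt_set$pt
  pt_set <- normalize_pt(pt_set)
  if (!(drug %in% config$drugs$drug_name)) {
    stop("unknown drug: ", drug, call. = FALSE)
  }
  unknown <- setdiff(pt_set, config$pts$pt)
  if (length(unknown) > 0) {
    stop("unknown preferred term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  P <- .inclusion_probs(config)               # D x T
  w <- config$drugs$weight / sum(config$drugs$weight)
  n_mono <- config$n_cases * (1 - config$polypharmacy_prob)
  in_set <- config$pts$pt %in% pt_set
  g <- match(drug, config$drugs$drug_name)
  per_drug_event <- P[, in_set, drop = FALSE] %*% rep(1, sum(in_set))
  per_drug_other <- P[, !in_set, drop = FALSE] %*% rep(1, sum(!in_set))
  a <- n_mono * w[g] * per_drug_event[g]
  b <- n_mono * w[g] * per_drug_other[g]
  cc <- n_mono * sum(w[-g] * per_drug_event[-g])
  dd <- n_mono * sum(w[-g] * per_drug_other[-g])
  tab <- contingency_table(a, b, cc, dd)
  attr(tab, "expected_ror") <- (a * dd) / (b * cc)
  tab
}

#' @rdname expected_contingency
#' @return `expected_ror()`: the expected reporting odds ratio (a number).
#' @export
expected_ror <- function(config, drug, pt_set) {
  attr(expected_contingency(config, drug, pt_set), "expected_ror")
}

#' Write simulated tables in the FAERS quarterly dialect
#'
#' Writes `drug.txt`, `reac.txt`, `demo.txt` and `ther.txt` under `dir`
#' using FAERS column names and the `$` delimiter (configurable), in the
#' exact dialect [read_faers()] ingests, so generated data round-trips
#' losslessly.
#'
#' @param tables list as returned by [simulate_reports()].
#' @param dir output directory (created if needed).
#' @param delim field delimiter.
#' @return invisibly, the paths of the four files.
#' @export
write_faers <- function(tables, dir, delim = "$") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("drug.txt", "reac.txt", "demo.txt", "ther.txt"))
  readr::write_delim(
    dplyr::rename(tables$drug, primaryid = "case_id", drugname = "drug_name",
                  role_cod = "role_code"),
    paths[1], delim = delim)
  readr::write_delim(
    dplyr::rename(tables$reac, primaryid = "case_id"),
    paths[2], delim = delim)
  demo <- tibble::tibble(primaryid = tables$demo$case_id,
                         sex = tables$demo$sex,
                         age = tables$demo$age_years,
                         age_cod = "YR")
  readr::write_delim(demo, paths[3], delim = delim)
  ther <- tibble::tibble(primaryid = tables$ther$case_id,
                         drugname = tables$ther$drug_name,
                         start_dt = format(tables$ther$start_date, "%Y%m%d"))
  readr::write_delim(ther, paths[4], delim = delim)
  invisible(setNames(paths, c("drug", "reac", "demo", "ther")))
}

#' Write generator ground truth as JSON
#'
#' Exports the closed-form expected contingency cells and expected ROR for
#' every (drug, single preferred term) pair of a configuration, plus the
#' catalog and thresholds, for provenance alongside simulated tables.
#'
#' @param config a [sim_config()] object.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_sim_truth <- function(config, path) {
  pairs <- expand.grid(drug = config$drugs$drug_name, pt = config$pts$pt,
                       stringsAsFactors = FALSE)
  pairs <- tibble::as_tibble(pairs)
  cells <- lapply(seq_len(nrow(pairs)), function(i) {
    tab <- expected_contingency(config, pairs$drug[i], pairs$pt[i])
    list(drug = pairs$drug[i], pt = pairs$pt[i],
         a = tab$a, b = tab$b, c = tab$c, d = tab$d,
         expected_ror = attr(tab, "expected_ror"))
  })
  jsonlite::write_json(list(n_cases = config$n_cases,
                            polypharmacy_prob = config$polypharmacy_prob,
                            duplicate_prob = config$duplicate_prob,
                            seed = config$seed,
                            pairs = cells),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
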