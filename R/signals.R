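# Drug-level signal screening and the stratified / class-level summaries.

# shared helper: ROR, Woolf CI and Fisher p for integer cells, applying the
# Haldane correction to the estimate/CI only when a zero cell occurs.
.signal_stats <- function(a, b, cc, dd, z = qnorm(0.975)) {
  raw <- contingency_table(a, b, cc, dd)
  p <- fisher_p(raw)
  est <- haldane(raw)
  ci <- ror_ci(est, z = z)
  list(ror = ror(est), ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
       p = p, corrected = est$corrected)
}

#' Screen a drug cohort for disproportionate event reporting
#'
#' Builds the drug-versus-event 2x2 table for every cohort drug over the
#' integrated report table, and computes the reporting odds ratio, Woolf
#' confidence interval and two-sided Fisher exact p-value. The Haldane
#' correction is applied to the ROR and interval only when a zero cell
#' occurs; the exact test always uses the raw integer cells. A drug is
#' flagged as a signal when `ln(ROR) > 0`, `p < alpha` and the drug's
#' total adverse-event row count (`a + b`) reaches `min_drug_reports`.
#'
#' No multiplicity correction is applied by default (screening convention
#' with raw p-values); `bh = TRUE` switches the flag rule to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param rows deduplicated (and, typically, monotherapy-filtered)
#'   integrated report tibble.
#' @param cohort character vector of drug names to screen.
#' @param terms event term set ([read_term_set()]) or character vector of
#'   preferred terms.
#' @param alpha significance level for the flag rule.
#' @param min_drug_reports minimum total adverse-event rows for a drug to
#'   be eligible.
#' @param bh logical; use Benjamini-Hochberg adjusted p-values in the
#'   flag rule.
#' @param z normal quantile for the confidence interval.
#' @return tibble with one row per cohort drug: `drug_name`, `a`, `b`,
#'   `c`, `d`, `ror`, `ci_low`, `ci_high`, `p`, `ln_ror`, `neg_log10_p`,
#'   `n_drug_reports`, `corrected`, `flagged`.
#' @export
signal_scan <- function(rows, cohort, terms, alpha = 0.05,
                        min_drug_reports = 1000, bh = FALSE,
                        z = qnorm(0.975)) {
  cohort <- unique(normalize_drug_name(cohort))
  pts <- if (inherits(terms, "smq_term_set")) terms$pt else normalize_pt(terms)
  is_event <- rows$pt %in% pts
  N <- nrow(rows)
  A_tot <- sum(is_event)
  counts <- tibble::tibble(drug_name = rows$drug_name, event = is_event) %>%
    dplyr::filter(.data$drug_name %in% cohort) %>%
    dplyr::group_by(.data$drug_name) %>%
    dplyr::summarise(a = sum(.data$event), n = dplyr::n(), .groups = "drop")
  a <- counts$a[match(cohort, counts$drug_name)]
  n <- counts$n[match(cohort, counts$drug_name)]
  a[is.na(a)] <- 0L
  n[is.na(n)] <- 0L
  b <- n - a
  cc <- A_tot - a
  dd <- (N - A_tot) - b
  stats_list <- lapply(seq_along(cohort), function(i) {
    .signal_stats(a[i], b[i], cc[i], dd[i], z = z)
  })
  out <- tibble::tibble(
    drug_name = cohort,
    a = a, b = b, c = cc, d = dd,
    ror = vapply(stats_list, `[[`, numeric(1), "ror"),
    ci_low = vapply(stats_list, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(stats_list, `[[`, numeric(1), "ci_high"),
    p = vapply(stats_list, `[[`, numeric(1), "p"),
    corrected = vapply(stats_list, `[[`, logical(1), "corrected"),
    n_drug_reports = n
  )
  out$ln_ror <- log(out$ror)
  out$neg_log10_p <- -log10(pmax(out$p, 1e-300))
  p_rule <- if (bh) p.adjust(out$p, method = "BH") else out$p
  out$flagged <- out$ln_ror > 0 & p_rule < alpha &
    out$n_drug_reports >= min_drug_reports
  out[, c("drug_name", "a", "b", "c", "d", "ror", "ci_low", "ci_high", "p",
          "ln_ror", "neg_log10_p", "n_drug_reports", "corrected", "flagged")]
}

#' Volcano-plot coordinates for a signal scan
#'
#' `x = ln(ROR)` (natural log), `y = -log10(p)` (common log), with the
#' p-value floored before the log so the ordinate stays finite.
#'
#' @param results tibble from [signal_scan()].
#' @param p_floor smallest p-value used for the ordinate.
#' @return tibble with `drug_name`, `x`, `y`, `flagged`.
#' @export
volcano_points <- function(results, p_floor = 1e-300) {
  tibble::tibble(drug_name = results$drug_name,
                 x = log(results$ror),
                 y = -log10(pmax(results$p, p_floor)),
                 flagged = results$flagged)
}

#' Volcano plot of a signal scan
#'
#' @param results tibble from [signal_scan()].
#' @param alpha significance level drawn as a horizontal guide.
#' @return a ggplot object.
#' @export
plot_volcano <- function(results, alpha = 0.05) {
  pts <- volcano_points(results)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "ln(ROR)", y = expression(-log[10](italic(p))),
                  colour = "signal") +
    ggplot2::theme_minimal()
}

#' Stratified reporting odds ratios
#'
#' For each stratum label L (e.g. a route of administration or sex), the
#' 2x2 table opposes rows from cases labelled L (`a` event rows, `b`
#' non-event rows) to rows from cases carrying any other label (`c`, `d`).
#' Unlabelled cases are excluded throughout, which makes the comparator
#' "all other labelled strata" -- an explicit choice, since spontaneous-
#' report tables typically leave many cases unlabelled.
#'
#' @param rows deduplicated integrated report tibble.
#' @param strata named character vector mapping `case_id` to a stratum
#'   label, or a tibble with columns `case_id`, `label`.
#' @param terms event term set or character vector of preferred terms.
#' @param z normal quantile for the confidence interval.
#' @return tibble with one row per stratum: `stratum`, `a`, `b`, `c`,
#'   `d`, `ror`, `ci_low`, `ci_high`, `p`.
#' @export
stratified_ror <- function(rows, strata, terms, z = qnorm(0.975)) {
  if (is.data.frame(strata)) {
    strata <- setNames(as.character(strata$label), strata$case_id)
  }
  lab <- strata[rows$case_id]
  keep <- !is.na(lab)
  rows <- rows[keep, ]
  lab <- lab[keep]
  if (nrow(rows) == 0) stop("no rows fall in a labelled stratum", call. = FALSE)
  pts <- if (inherits(terms, "smq_term_set")) terms$pt else normalize_pt(terms)
  is_event <- rows$pt %in% pts
  out <- lapply(sort(unique(lab)), function(L) {
    inL <- lab == L
    a <- sum(inL & is_event); b <- sum(inL & !is_event)
    cc <- sum(!inL & is_event); dd <- sum(!inL & !is_event)
    s <- .signal_stats(a, b, cc, dd, z = z)
    tibble::tibble(stratum = L, a = a, b = b, c = cc, d = dd,
                   ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
                   p = s$p)
  })
  dplyr::bind_rows(out)
}

#' Compare patient age between event and non-event cases
#'
#' Case-level comparison: a case counts as an event case when at least one
#' of its report rows carries a term-set preferred term. Reports medians
#' of both groups and a two-sided Wilcoxon rank-sum p-value (chosen to
#' match a median-based summary; ages are far from normal in spontaneous
#' reports). Cases without a valid age are excluded.
#'
#' @param rows deduplicated integrated report tibble.
#' @param demo demographics tibble from `read_faers(kind = "demo")`.
#' @param terms event term set or character vector of preferred terms.
#' @return list with `median_event`, `median_nonevent`, `n_event`,
#'   `n_nonevent`, `p`.
#' @export
age_comparison <- function(rows, demo, terms) {
  pts <- if (inherits(terms, "smq_term_set")) terms$pt else normalize_pt(terms)
  case_event <- rows %>%
    dplyr::group_by(.data$case_id) %>%
    dplyr::summarise(event = any(.data$pt %in% pts), .groups = "drop")
  x <- dplyr::inner_join(case_event, demo, by = "case_id") %>%
    dplyr::filter(!is.na(.data$age_years))
  ages_e <- x$age_years[x$event]
  ages_n <- x$age_years[!x$event]
  if (length(ages_e) == 0 || length(ages_n) == 0) {
    stop("age_comparison() needs at least one event and one non-event case ",
         "with a valid age", call. = FALSE)
  }
  p <- suppressWarnings(wilcox.test(ages_e, ages_n, exact = FALSE)$p.value)
  list(median_event = median(ages_e), median_nonevent = median(ages_n),
       n_event = length(ages_e), n_nonevent = length(ages_n), p = p)
}

#' Class-level signal summary
#'
#' Aggregates a signal scan by steroid class: the number of flagged
#' members, the number of members screened, their percentage (one
#' decimal), and a pooled reporting odds ratio from the class-pooled 2x2
#' table (cells summed over member drugs, against all non-member
#' reports). Classes from the map with no member among the screened drugs
#' are omitted with a warning; screened drugs absent from the map are
#' grouped as `"unclassified"`.
#'
#' @param results tibble from [signal_scan()].
#' @param class_map tibble from [read_class_map()].
#' @param rows the report tibble the scan was computed on.
#' @param terms the event term set the scan used.
#' @param z normal quantile for the confidence interval.
#' @return tibble with `class`, `n_flagged`, `n_total`, `pct_flagged`,
#'   `ror`, `ci_low`, `ci_high`, `p`.
#' @export
class_summary <- function(results, class_map, rows, terms,
                          z = qnorm(0.975)) {
  cls <- classify_drug(results$drug_name, class_map)
  absent <- setdiff(unique(class_map$class), unique(cls))
  if (length(absent) > 0) {
    warning("class(es) with no member among screened drugs omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  pts <- if (inherits(terms, "smq_term_set")) terms$pt else normalize_pt(terms)
  out <- lapply(sort(unique(cls)), function(k) {
    members <- results$drug_name[cls == k]
    tab <- contingency(rows, members, pts)
    s <- .signal_stats(tab$a, tab$b, tab$c, tab$d, z = z)
    nf <- sum(results$flagged[cls == k])
    nt <- length(members)
    tibble::tibble(class = k, n_flagged = nf, n_total = nt,
                   pct_flagged = round(100 * nf / nt, 1),
                   ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
                   p = s$p)
  })
  dplyr::bind_rows(out)
}

#' Derive case-level strata from demographics or drug tables
#'
#' Convenience builder for [stratified_ror()]: `by = "sex"` labels cases
#' `F`/`M` from the demographics table (unknown sex excluded);
#' `by = "route"` labels each case with the single administration route
#' of its reported drugs (cases reporting several distinct routes, or no
#' route, are excluded).
#'
#' @param demo demographics tibble (for `by = "sex"`).
#' @param drug drug tibble (for `by = "route"`).
#' @param by `"sex"` or `"route"`.
#' @return named character vector mapping case_id to label.
#' @export
case_strata <- function(demo = NULL, drug = NULL, by = c("sex", "route")) {
  by <- match.arg(by)
  if (by == "sex") {
    if (is.null(demo)) stop("by = 'sex' needs a demo table", call. = FALSE)
    x <- demo[demo$sex %in% c("F", "M"), ]
    return(setNames(x$sex, x$case_id))
  }
  if (is.null(drug)) stop("by = 'route' needs a drug table", call. = FALSE)
  x <- drug %>%
    dplyr::filter(!is.na(.data$route), nzchar(.data$route)) %>%
    dplyr::distinct(.data$case_id, .data$route) %>%
    dplyr::group_by(.data$case_id) %>%
    dplyr::filter(dplyr::n() == 1) %>%
    dplyr::ungroup()
  setNames(x$route, x$case_id)
}
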