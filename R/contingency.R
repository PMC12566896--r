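# 2x2 contingency machinery: construction, Haldane continuity correction,
# reporting odds ratio, Woolf confidence interval, Fisher exact test.

#' Build a 2x2 reporting contingency table
#'
#' The four cells follow the usual pharmacovigilance cross-tabulation:
#' `a` reports with the drug and the event, `b` with the drug without the
#' event, `c` the event among all other reports, `d` neither. Cells may be
#' non-integer (expected counts, corrected counts); Fisher testing demands
#' raw integers.
#'
#' @param a,b,c,d non-negative finite cell counts.
#' @param corrected logical; whether the Haldane correction has been
#'   applied.
#' @return an object of class `contingency_2x2`.
#' @export
contingency_table <- function(a, b, c, d, corrected = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("contingency cells must be finite and non-negative", call. = FALSE)
  }
  # an all-zero table is permitted so haldane() can regularize it
  structure(list(a = a, b = b, c = c, d = d, corrected = corrected),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("2x2 reporting table", if (x$corrected) "(Haldane-corrected)", "\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("drug", "other"), c("event", "non-event")))
  print(m)
  invisible(x)
}

#' Haldane continuity correction
#'
#' If any cell of the table is zero, adds 0.5 to all four cells so that the
#' odds ratio and its log-scale standard error stay finite; otherwise the
#' table is returned unchanged. The correction is applied to ROR and
#' confidence-interval computation only -- Fisher's exact test must always
#' see the raw integer cells.
#'
#' @param t a [contingency_table()].
#' @return the (possibly corrected) table, with `corrected` set
#'   accordingly.
#' @export
haldane <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (any(c(t$a, t$b, t$c, t$d) == 0)) {
    contingency_table(t$a + 0.5, t$b + 0.5, t$c + 0.5, t$d + 0.5,
                      corrected = TRUE)
  } else {
    t
  }
}

#' Reporting odds ratio
#'
#' `ror(t)` returns `(a * d) / (b * c)`: the odds of the event being
#' reported with the drug relative to the same odds among all other
#' reports. A zero denominator on an uncorrected table is a hard error
#' directing the caller to [haldane()].
#'
#' @param t a [contingency_table()].
#' @return a non-negative ratio.
#' @export
ror <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$b * t$c == 0) {
    stop("zero denominator cell; apply haldane() before ror()", call. = FALSE)
  }
  (t$a * t$d) / (t$b * t$c)
}

#' Woolf (log-scale) confidence interval for the ROR
#'
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. All four cells must
#' be positive (guaranteed after [haldane()] whenever a zero occurs).
#'
#' @param t a [contingency_table()].
#' @param z standard-normal quantile; 1.96 for a 95% interval.
#' @return named numeric vector `c(low, high)`.
#' @export
ror_ci <- function(t, z = qnorm(0.975)) {
  stopifnot(inherits(t, "contingency_2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells <= 0)) {
    stop("all cells must be positive for the Woolf interval; apply haldane()",
         call. = FALSE)
  }
  se <- sqrt(sum(1 / cells))
  est <- log(ror(t))
  c(low = exp(est - z * se), high = exp(est + z * se))
}

#' Two-sided Fisher exact p-value
#'
#' Exact two-sided p-value for the 2x2 table by the point-probability
#' (minimum-likelihood) rule: the sum of hypergeometric point
#' probabilities not exceeding that of the observed table. Requires raw
#' integer cells; corrected (half-integer) tables are rejected because the
#' continuity correction must never precede exact testing.
#'
#' @param t a [contingency_table()].
#' @return p-value in (0, 1].
#' @export
fisher_p <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (t$corrected || any(abs(cells - round(cells)) > 1e-9)) {
    stop("fisher_p() needs raw integer cells; test before any correction",
         call. = FALSE)
  }
  m <- matrix(round(cells), 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Count a drug-by-event contingency table from report rows
#'
#' Cross-tabulates the integrated report table for one drug (or a set of
#' drugs, e.g. a drug class) against a preferred-term set: `a` rows with
#' the drug and a term-set PT, `b` with the drug and any other PT, `c`/`d`
#' the same split over all other drugs. The four cells always sum to the
#' total row count. A drug absent from the rows yields `a = b = 0`, not an
#' error.
#'
#' @param rows deduplicated integrated report tibble.
#' @param drug character vector of drug name(s) forming the exposure.
#' @param terms an `smq_term_set` from [read_term_set()], or a character
#'   vector of preferred terms.
#' @return an uncorrected [contingency_table()] of integer counts.
#' @export
contingency <- function(rows, drug, terms) {
  drug <- normalize_drug_name(drug)
  pts <- if (inherits(terms, "smq_term_set")) terms$pt else normalize_pt(terms)
  is_drug <- rows$drug_name %in% drug
  is_event <- rows$pt %in% pts
  contingency_table(sum(is_drug & is_event), sum(is_drug & !is_event),
                    sum(!is_drug & is_event), sum(!is_drug & !is_event))
}
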