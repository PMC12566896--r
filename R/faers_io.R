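# Ingestion of FAERS-dialect quarterly ASCII tables and construction of the
# integrated (case, drug, preferred term) report table.

.faers_kinds <- list(
  drug = list(mandatory = c("primaryid", "drugname"),
              optional  = c("role_cod", "route", "caseversion")),
  reac = list(mandatory = c("primaryid", "pt"),
              optional  = character()),
  demo = list(mandatory = c("primaryid", "sex", "age"),
              optional  = c("age_cod")),
  ther = list(mandatory = c("primaryid", "start_dt"),
              optional  = c("drugname"))
)

# FAERS age unit codes -> multiplier to years. Unknown codes are treated as
# years; DEC is decades.
.age_unit_years <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                     DY = 1 / 365.25, HR = 1 / 8766)

.convert_age_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod) | age_cod == "", "YR", age_cod)))
  mult <- unname(.age_unit_years[cod])
  mult[is.na(mult)] <- 1
  age * mult
}

#' Read one FAERS-dialect table
#'
#' Reads a quarterly FAERS ASCII table (or an equivalent CSV) into a tidy
#' tibble with normalized keys. The four supported kinds are `"drug"`
#' (columns `primaryid`, `drugname`, optionally `role_cod`, `route`),
#' `"reac"` (`primaryid`, `pt`), `"demo"` (`primaryid`, `sex`, `age`,
#' optionally `age_cod`) and `"ther"` (`primaryid`, `start_dt`, optionally
#' `drugname`). Column name matching is case-insensitive; a missing
#' mandatory column is a hard error naming the column.
#'
#' Records with an empty case identifier or (for `drug`/`reac`) an empty
#' name/term are skipped, not fatal; the number of skipped records is
#' reported via [message()] and attached as attribute `n_skipped`. Ages are
#' converted to years using the FAERS unit code (`YR`, `DEC`, `MON`, `WK`,
#' `DY`, `HR`); converted ages outside \[0, 130\] years are treated as
#' invalid: the record is kept with `age_years = NA` and `age_invalid =
#' TRUE`.
#'
#' @param path file path.
#' @param kind one of `"drug"`, `"reac"`, `"demo"`, `"ther"`.
#' @param delim field delimiter; FAERS quarterly files use `"$"`. Pass
#'   `","` for CSV input.
#' @return a tibble; columns depend on `kind`:
#'   * `drug`: `case_id`, `drug_name`, `role_code`, `route`
#'     (plus `caseversion` when present in the file);
#'   * `reac`: `case_id`, `pt`;
#'   * `demo`: `case_id`, `sex` (`"F"`, `"M"` or `"unknown"`),
#'     `age_years`, `age_invalid`;
#'   * `ther`: `case_id`, `drug_name` (`NA` if absent), `start_date`,
#'     `start_year`.
#' @export
read_faers <- function(path, kind = c("drug", "reac", "demo", "ther"),
                       delim = "$") {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("cannot read FAERS table: file does not exist: ", path, call. = FALSE)
  }
  spec <- .faers_kinds[[kind]]
  raw <- readr::read_delim(path, delim = delim, trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(spec$mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("FAERS ", toupper(kind), " table ", path,
         " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_bad_lines <- nrow(readr::problems(raw))
  out <- switch(kind,
    drug = {
      x <- tibble::tibble(
        case_id   = trimws(raw$primaryid),
        drug_name = normalize_drug_name(raw$drugname),
        role_code = if ("role_cod" %in% names(raw)) toupper(trimws(raw$role_cod)) else NA_character_,
        route     = if ("route" %in% names(raw)) normalize_drug_name(raw$route) else NA_character_
      )
      if ("caseversion" %in% names(raw)) {
        x$caseversion <- suppressWarnings(as.integer(raw$caseversion))
      }
      keep <- !is.na(x$case_id) & x$case_id != "" &
        !is.na(x$drug_name) & x$drug_name != ""
      structure(x[keep, ], n_skipped = sum(!keep))
    },
    reac = {
      x <- tibble::tibble(
        case_id = trimws(raw$primaryid),
        pt      = normalize_pt(raw$pt)
      )
      keep <- !is.na(x$case_id) & x$case_id != "" & !is.na(x$pt) & x$pt != ""
      structure(x[keep, ], n_skipped = sum(!keep))
    },
    demo = {
      sex <- toupper(trimws(raw$sex))
      sex[!(sex %in% c("F", "M"))] <- "unknown"
      age <- .convert_age_years(raw$age,
                                if ("age_cod" %in% names(raw)) raw$age_cod else NA)
      invalid <- !is.na(age) & (age < 0 | age > 130)
      age[invalid] <- NA_real_
      x <- tibble::tibble(
        case_id = trimws(raw$primaryid),
        sex = sex,
        age_years = age,
        age_invalid = invalid
      )
      keep <- !is.na(x$case_id) & x$case_id != ""
      structure(x[keep, ], n_skipped = sum(!keep))
    },
    ther = {
      dt <- trimws(raw$start_dt)
      year <- suppressWarnings(as.integer(substr(dt, 1, 4)))
      year[!is.na(year) & (year < 1900 | year > 2200)] <- NA_integer_
      date <- suppressWarnings(as.Date(ifelse(nchar(dt) == 8, dt, NA), "%Y%m%d"))
      x <- tibble::tibble(
        case_id = trimws(raw$primaryid),
        drug_name = if ("drugname" %in% names(raw)) normalize_drug_name(raw$drugname) else NA_character_,
        start_date = date,
        start_year = year
      )
      keep <- !is.na(x$case_id) & x$case_id != ""
      structure(x[keep, ], n_skipped = sum(!keep))
    }
  )
  n_skipped <- attr(out, "n_skipped") + n_bad_lines
  attr(out, "n_skipped") <- n_skipped
  if (n_skipped > 0) {
    message("read_faers(", kind, "): skipped ", n_skipped,
            " malformed or incomplete record(s)")
  }
  out
}

#' Integrate drug and reaction tables into the report table
#'
#' Inner-joins the DRUG and REAC tables on the case identifier, so that
#' each output row is one (case, drug, preferred term) combination: a case
#' reporting k drugs and m preferred terms contributes k x m rows. This is
#' the row layout on which all downstream 2x2 contingency counts are
#' defined.
#'
#' @param drug_tbl tibble as returned by `read_faers(kind = "drug")`.
#' @param reac_tbl tibble as returned by `read_faers(kind = "reac")`.
#' @return tibble with columns `case_id`, `drug_name`, `pt` (plus
#'   `caseversion` when present on `drug_tbl`).
#' @export
integrate_reports <- function(drug_tbl, reac_tbl) {
  if (nrow(drug_tbl) == 0 || nrow(reac_tbl) == 0) {
    stop("integrate_reports() needs non-empty drug and reaction tables",
         call. = FALSE)
  }
  keep <- intersect(c("case_id", "drug_name", "caseversion"), names(drug_tbl))
  out <- dplyr::inner_join(drug_tbl[, keep],
                           reac_tbl[, c("case_id", "pt")],
                           by = "case_id", relationship = "many-to-many")
  if (nrow(out) == 0) {
    warning("integrate_reports(): no case identifiers in common; ",
            "result is empty", call. = FALSE)
  }
  out
}

#' Remove duplicate report rows
#'
#' Deduplicates the integrated table on the (case, drug, preferred term)
#' triple, keeping the first occurrence so row order is stable. When a
#' `caseversion` column is present (FAERS ships superseded versions of the
#' same case), only rows carrying each case's highest version are kept
#' before the triple-level deduplication. Idempotent.
#'
#' @param rows integrated report tibble (`case_id`, `drug_name`, `pt`).
#' @return tibble with at most one row per (case, drug, pt) triple.
#' @export
dedup_reports <- function(rows) {
  if ("caseversion" %in% names(rows) && nrow(rows) > 0) {
    rows <- rows %>%
      dplyr::group_by(.data$case_id) %>%
      dplyr::filter(is.na(.data$caseversion) |
                      .data$caseversion == max(.data$caseversion, na.rm = TRUE)) %>%
      dplyr::ungroup()
  }
  dplyr::distinct(rows, .data$case_id, .data$drug_name, .data$pt,
                  .keep_all = TRUE)
}

#' Restrict to monotherapy cases
#'
#' Keeps only rows belonging to cases whose set of distinct (normalized)
#' drug names has size one, so that each retained adverse event is
#' unambiguously attributable to a single drug. By default every reported
#' drug counts towards polypharmacy regardless of its role code; with
#' `suspect_only = TRUE` and a drug table supplying role codes, only
#' suspect drugs (`PS`, `SS`) are counted, so cases whose extra drugs are
#' all concomitant still pass.
#'
#' @param rows deduplicated integrated report tibble.
#' @param drug_tbl optional drug table with `case_id`, `drug_name`,
#'   `role_code`; required when `suspect_only = TRUE`.
#' @param suspect_only logical; count only suspect drugs when deciding
#'   monotherapy.
#' @return the filtered tibble; the preferred-term multiset within each
#'   retained case is unchanged.
#' @export
monotherapy_filter <- function(rows, drug_tbl = NULL, suspect_only = FALSE) {
  if (nrow(rows) == 0) return(rows)
  if (suspect_only) {
    if (is.null(drug_tbl) || !("role_code" %in% names(drug_tbl))) {
      stop("suspect_only = TRUE needs a drug table with a role_code column",
           call. = FALSE)
    }
    counted <- drug_tbl %>%
      dplyr::filter(.data$role_code %in% c("PS", "SS")) %>%
      dplyr::distinct(.data$case_id, .data$drug_name)
  } else {
    counted <- dplyr::distinct(rows, .data$case_id, .data$drug_name)
  }
  mono_cases <- counted %>%
    dplyr::count(.data$case_id) %>%
    dplyr::filter(.data$n == 1) %>%
    dplyr::pull(.data$case_id)
  rows[rows$case_id %in% mono_cases, ]
}
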