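# SMQ-scoped preferred-term sets. MedDRA itself is licensed and is not
# bundled: term sets are supplied as flat TSV files (pt, scope). The
# packaged thrombosis set covers the narrow-scope preferred terms of the
# arterial, venous and unspecified/mixed embolism-and-thrombosis SMQs that
# recur in spontaneous-report analyses of thrombotic risk; its per-term
# scope labels are this package's curation from SMQ membership (ambiguous
# terms default to "mixed") and can be overridden by supplying a user file.

.valid_scopes <- c("arterial", "venous", "mixed")

#' Load an SMQ-scoped preferred-term set
#'
#' Reads a TSV with columns `pt` and `scope` (one of `"arterial"`,
#' `"venous"`, `"mixed"`). Preferred terms are matched case-insensitively
#' with collapsed whitespace. Listing the same PT twice with conflicting
#' scopes is a hard error; exact duplicates are collapsed. An empty file
#' yields an empty set with a warning.
#'
#' @param path TSV file path.
#' @param name label for the set; defaults to the file name.
#' @return a tibble of class `smq_term_set` with columns `pt`, `scope`.
#' @export
read_term_set <- function(path, name = basename(path)) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("pt", "scope") %in% names(raw))) {
    stop("term-set file needs pt and scope columns: ", path, call. = FALSE)
  }
  out <- tibble::tibble(pt = normalize_pt(raw$pt),
                        scope = tolower(trimws(raw$scope)))
  out <- dplyr::distinct(out)
  if (nrow(out) == 0) {
    warning("term-set file is empty: ", path, call. = FALSE)
  }
  bad <- setdiff(unique(out$scope), .valid_scopes)
  if (length(bad) > 0) {
    stop("unknown scope label(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  conflict <- out$pt[duplicated(out$pt)]
  if (length(conflict) > 0) {
    stop("conflicting scopes for preferred term(s): ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  structure(out, class = c("smq_term_set", class(out)), name = name)
}

#' Packaged thrombosis preferred-term set
#'
#' The 52 thrombosis-related preferred terms shipped with the package,
#' with curated arterial/venous/mixed scope labels (see file-level notes
#' in `inst/extdata/thrombosis_smq_terms.tsv`).
#'
#' @return an `smq_term_set` tibble.
#' @export
thrombosis_terms <- function() {
  read_term_set(system.file("extdata", "thrombosis_smq_terms.tsv",
                            package = "steroidror"),
                name = "thrombosis")
}

#' Test preferred terms for term-set membership
#'
#' Case-insensitive, whitespace-normalized membership of preferred terms
#' in an SMQ term set.
#'
#' @param pt character vector of preferred terms.
#' @param set an `smq_term_set`.
#' @return logical vector.
#' @export
is_thrombosis_event <- function(pt, set) {
  normalize_pt(pt) %in% set$pt
}
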