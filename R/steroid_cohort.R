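# Steroid cohort selection by substructure match against the tetracyclic
# 6-6-6-5 gonane carbon skeleton, plus the in-market filter and
# physiological-class labelling.

#' Default steroid-backbone SMARTS pattern
#'
#' The gonane (6-6-6-5 tetracyclic) carbon skeleton written with
#' element-only atoms (`[#6]`) and any-order bonds (`~`), so saturated,
#' unsaturated and aromatic variants (e.g. the estrane aromatic A ring)
#' all match. No stereochemistry or charge constraints.
#'
#' @return a SMARTS string.
#' @export
steroid_scaffold <- function() {
  paste0("[#6]~1~[#6]~[#6]~2~[#6]~[#6]~[#6]~3~[#6](~[#6]~[#6]~[#6]~4~",
         "[#6]~[#6]~[#6]~[#6]~[#6]~3~4)~[#6]~2~[#6]~1")
}

#' Substructure match of SMILES against a scaffold pattern
#'
#' Tests whether each molecule contains the pattern as a subgraph, using
#' OpenBabel SMARTS matching (via ChemmineR/ChemmineOB). The result is
#' invariant to SMILES canonicalization. An unparseable SMILES is a
#' distinct outcome (`NA`), never silently `FALSE`.
#'
#' @param smiles character vector of SMILES strings.
#' @param pattern SMARTS pattern; defaults to [steroid_scaffold()].
#' @return logical vector: `TRUE` (match), `FALSE` (valid molecule, no
#'   match), `NA` (invalid structure).
#' @export
matches_scaffold <- function(smiles, pattern = steroid_scaffold()) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA)
    res <- NA
    utils::capture.output({  # silence converter progress chatter
      sdf <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "mol"))),
        error = function(e) NULL)
      if (!is.null(sdf) && ChemmineR::validSDF(sdf)) {
        n <- tryCatch(
          ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = FALSE),
          error = function(e) stop("SMARTS matching failed for pattern: ",
                                   pattern, call. = FALSE))
        res <- unname(n > 0)
      }
    })
    res
  }, logical(1), USE.NAMES = FALSE)
}

#' Read a drug-name to SMILES dictionary
#'
#' TSV with columns `drug_name` and `smiles`. Names are normalized with
#' [normalize_drug_name()]; duplicated names keep their first entry. This
#' local dictionary replaces any live structure-database lookup so the
#' cohort step runs fully offline; a resolver producing the same two
#' columns can be swapped in upstream.
#'
#' @param path TSV file path.
#' @return tibble with columns `drug_name`, `smiles`.
#' @export
read_smiles_dict <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("drug_name", "smiles") %in% names(raw))) {
    stop("SMILES dictionary needs drug_name and smiles columns: ", path,
         call. = FALSE)
  }
  out <- tibble::tibble(drug_name = normalize_drug_name(raw$drug_name),
                        smiles = trimws(raw$smiles))
  out[!duplicated(out$drug_name), ]
}

#' Select the steroid cohort by scaffold match
#'
#' Looks each drug name up in the SMILES dictionary and matches its
#' structure against the scaffold pattern. Names absent from the
#' dictionary are reported as `unmapped`; unparseable structures as
#' `invalid`. An optional allowlist force-includes names that have no
#' usable structure (group labels such as "STEROIDS", botanical extracts)
#' but that the analysis should still carry.
#'
#' @param drug_names character vector of candidate drug names.
#' @param dict SMILES dictionary from [read_smiles_dict()].
#' @param pattern SMARTS pattern; defaults to [steroid_scaffold()].
#' @param allowlist optional character vector of names to force-include.
#' @return list with `report` (tibble: `drug_name`, `smiles`, `status`,
#'   `in_cohort`), and the disjoint name sets `cohort`, `nonmatching`,
#'   `unmapped`, `invalid`. `status` is one of `matched`, `nonmatching`,
#'   `unmapped`, `invalid`, `allowlisted`.
#' @export
build_cohort <- function(drug_names, dict, pattern = steroid_scaffold(),
                         allowlist = NULL) {
  if (is.null(dict) || nrow(dict) == 0) {
    stop("empty SMILES dictionary", call. = FALSE)
  }
  names_n <- unique(normalize_drug_name(drug_names))
  allow <- normalize_drug_name(allowlist)
  idx <- match(names_n, dict$drug_name)
  smiles <- dict$smiles[idx]
  status <- rep(NA_character_, length(names_n))
  status[is.na(idx)] <- "unmapped"
  todo <- which(!is.na(idx))
  if (length(todo) > 0) {
    m <- matches_scaffold(smiles[todo], pattern)
    status[todo][is.na(m)] <- "invalid"
    status[todo][!is.na(m) & m] <- "matched"
    status[todo][!is.na(m) & !m] <- "nonmatching"
  }
  status[names_n %in% allow & status != "matched"] <- "allowlisted"
  report <- tibble::tibble(drug_name = names_n, smiles = smiles,
                           status = status,
                           in_cohort = status %in% c("matched", "allowlisted"))
  list(report = report,
       cohort = report$drug_name[report$in_cohort],
       nonmatching = report$drug_name[report$status == "nonmatching"],
       unmapped = report$drug_name[report$status == "unmapped"],
       invalid = report$drug_name[report$status == "invalid"])
}

#' In-market filter from therapy start dates
#'
#' Returns the drugs having at least one therapy record whose start year
#' is at or after the cutoff -- evidence that the drug is still being
#' administered. Records without a parseable date are ignored and counted
#' (attribute `n_dateless`).
#'
#' @param ther therapy tibble from `read_faers(kind = "ther")` (needs
#'   `drug_name` and `start_year`).
#' @param cutoff_year first year counting as current use.
#' @return character vector of drug names, with attribute `n_dateless`.
#' @export
market_filter <- function(ther, cutoff_year = 2024) {
  if (!all(c("drug_name", "start_year") %in% names(ther))) {
    stop("market_filter() needs drug_name and start_year columns",
         call. = FALSE)
  }
  if (all(is.na(ther$drug_name))) {
    stop("therapy table carries no drug names; supply a dialect with a ",
         "drugname column or join drug sequences upstream", call. = FALSE)
  }
  dateless <- sum(is.na(ther$start_year))
  keep <- ther[!is.na(ther$start_year) & ther$start_year >= cutoff_year, ]
  structure(sort(unique(keep$drug_name[!is.na(keep$drug_name)])),
            n_dateless = dateless)
}

#' Read a drug-to-class map
#'
#' TSV with columns `drug_name` and `class`. Class labels are validated
#' against a closed label set (by default the packaged steroid
#' classification labels); pass `labels = NULL` to skip validation.
#'
#' @param path TSV file path.
#' @param labels character vector of allowed class labels, or `NULL`.
#' @return tibble with columns `drug_name`, `class`.
#' @export
read_class_map <- function(path, labels = steroid_class_labels()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("drug_name", "class") %in% names(raw))) {
    stop("class map needs drug_name and class columns: ", path, call. = FALSE)
  }
  out <- tibble::tibble(drug_name = normalize_drug_name(raw$drug_name),
                        class = trimws(raw$class))
  if (!is.null(labels)) {
    bad <- setdiff(unique(out$class), labels)
    if (length(bad) > 0) {
      stop("class label(s) outside the allowed set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out[!duplicated(out$drug_name), ]
}

#' Packaged steroid classification labels
#'
#' The 18 physiological/receptor/ATC-derived steroid class labels used for
#' class-level summaries.
#'
#' @return character vector of class labels.
#' @export
steroid_class_labels <- function() {
  readr::read_tsv(system.file("extdata", "steroid_class_labels.tsv",
                              package = "steroidror"),
                  col_types = "c", progress = FALSE)$class
}

#' Packaged drug-to-class map for signal-positive steroids
#'
#' @return tibble with columns `drug_name`, `class`.
#' @export
steroid_drug_classes <- function() {
  read_class_map(system.file("extdata", "steroid_drug_classes.tsv",
                             package = "steroidror"))
}

#' Map drug names to steroid classes
#'
#' Total function: names absent from the map get `"unclassified"`.
#'
#' @param drug_name character vector.
#' @param class_map tibble from [read_class_map()]; defaults to the
#'   packaged map.
#' @return character vector of class labels.
#' @export
classify_drug <- function(drug_name, class_map = steroid_drug_classes()) {
  idx <- match(normalize_drug_name(drug_name), class_map$drug_name)
  out <- class_map$class[idx]
  out[is.na(out) | !nzchar(normalize_drug_name(drug_name))] <- "unclassified"
  out
}
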