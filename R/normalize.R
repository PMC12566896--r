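#' Normalize drug names and preferred terms
#'
#' FAERS drug names and MedDRA preferred terms are matched as normalized
#' keys: uppercased, trimmed, with internal whitespace collapsed to single
#' spaces. No salt stripping or synonym mapping is applied here; brand to
#' generic mapping, where needed, is a user-supplied dictionary concern.
#'
#' @param x character vector of raw names.
#' @return character vector of normalized keys; `NA` stays `NA`.
#' @examples
#' normalize_drug_name("  prednisolone   sodium ")
#' @export
normalize_drug_name <- function(x) {
  stringr::str_squish(toupper(as.character(x)))
}

#' @rdname normalize_drug_name
#' @export
normalize_pt <- function(x) {
  stringr::str_squish(toupper(as.character(x)))
}
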