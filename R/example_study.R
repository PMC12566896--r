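# A self-contained simulated study used by the analysis scripts and the
# worked examples: 20 drugs (the packaged scaffold fixture: 10 steroids,
# 10 non-steroid comparators), six thrombosis preferred terms plus six
# background terms, and planted reporting-odds effects shaped like the
# signals this pipeline is built to find -- strong venous signals on the
# sex-hormone drugs and an arterial signal on the mineralocorticoid-
# receptor antagonist. Effect sizes are chosen so that the planted drugs
# are detected with high power at the default scale.

#' Configuration of the packaged demonstration study
#'
#' Builds a [sim_config()] whose drug catalog is the packaged 20-molecule
#' scaffold fixture and whose event catalog contains nine thrombosis
#' preferred terms (four venous, three arterial, two mixed/unspecified)
#' plus six background terms. Planted reporting-odds multipliers: 4 on
#' the venous terms for TESTOSTERONE, ESTRADIOL and NORETHISTERONE; 2.5
#' on the venous terms for ESTRONE and PROGESTERONE; 3 on the arterial
#' terms for SPIRONOLACTONE and 2.5 for DEXAMETHASONE; all other pairs
#' are null.
#'
#' @param n_cases number of simulated cases.
#' @param seed generator seed.
#' @return a `sim_config` object.
#' @export
example_study_config <- function(n_cases = 50000, seed = 1L) {
  fx <- readr::read_tsv(system.file("extdata", "scaffold_fixture.tsv",
                                    package = "steroidror"),
                        col_types = readr::cols(drug_name = "c",
                                                smiles = "c",
                                                is_steroid = "l"),
                        progress = FALSE)
  routes <- rep(c("ORAL", "TRANSDERMAL", "TOPICAL", "INTRAVENOUS", "VAGINAL"),
                length.out = nrow(fx))
  drugs <- tibble::tibble(drug_name = fx$drug_name, route = routes)
  terms <- thrombosis_terms()
  venous_terms <- c("DEEP VEIN THROMBOSIS", "PULMONARY EMBOLISM",
                    "EMBOLISM VENOUS", "VENOUS THROMBOSIS")
  arterial_terms <- c("MYOCARDIAL INFARCTION", "CEREBRAL INFARCTION",
                      "ISCHAEMIC STROKE")
  event <- c(venous_terms, arterial_terms, "EMBOLISM", "THROMBOSIS")
  pts <- tibble::tibble(
    pt = c(event, paste0("BACKGROUND", 1:6)),
    base_p = c(rep(0.012, length(event)), rep(0.06, 6)),
    scope = c(terms$scope[match(event, terms$pt)], rep("none", 6)))
  eff <- function(drugs, pts, theta) {
    out <- tidyr::crossing(drug_name = drugs, pt = pts)
    out$theta <- theta
    out
  }
  effects <- dplyr::bind_rows(
    eff(c("TESTOSTERONE", "ESTRADIOL", "NORETHISTERONE"), venous_terms, 4),
    eff(c("ESTRONE", "PROGESTERONE"), venous_terms, 2.5),
    eff("SPIRONOLACTONE", arterial_terms, 3),
    eff("DEXAMETHASONE", arterial_terms, 2.5))
  sim_config(n_cases, drugs, pts, effects = effects,
             polypharmacy_prob = 0.1, duplicate_prob = 0.05,
             p_female = 0.6, age_mean = 58, age_sd = 18, seed = seed)
}

#' Drugs carrying planted effects in the demonstration study
#'
#' @return named list: `venous` and `arterial` drug-name vectors, and
#'   `strong` -- the subset with the largest multipliers, detectable with
#'   high power even at small simulated scales.
#' @export
example_study_truth <- function() {
  list(venous = c("TESTOSTERONE", "ESTRADIOL", "NORETHISTERONE",
                  "ESTRONE", "PROGESTERONE"),
       arterial = c("SPIRONOLACTONE", "DEXAMETHASONE"),
       strong = c("TESTOSTERONE", "ESTRADIOL", "NORETHISTERONE"))
}
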