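# End-to-end convenience: registry -> cohort -> TRD classification ->
# matching -> conditioning -> windowed summaries -> two-part analysis.

#' Run the full TRD analysis pipeline on a registry bundle
#'
#' Builds the first-time MDD cohort, classifies treatment resistance,
#' matches TRD cases 1:2 to non-TRD controls, restricts to complete
#' follow-up, aggregates the HRU/cost outcome grid over the index windows,
#' and (optionally) fits the two-part model for every outcome.
#'
#' @param bundle a `registry_bundle` (e.g. from [simulate_registry()] or
#'   [load_registry()]).
#' @param config a [default_code_config()]; defaults to the bundle's.
#' @param seed matching seed.
#' @param outcomes which outcome columns to summarize (default: all);
#'   restricting speeds up simulation studies.
#' @param windows windows to aggregate (default both; calibration studies
#'   only need `"post"`).
#' @param fit run [run_outcome_grid()] on the summaries.
#' @return list: `cohort`, `trd`, `matched`, `attrition` (named list of
#'   logs), `summaries`, and `grid` when `fit = TRUE`.
#' @export
run_trd_pipeline <- function(bundle, config = NULL, seed = 20150101L,
                             outcomes = NULL, windows = c("pre", "post"),
                             fit = FALSE) {
  config <- config %||% bundle$config
  cb <- build_cohort(bundle, config)
  cohort <- cb$cohort
  trd <- cb$trd
  cases <- trd[is_trd == TRUE][cohort, on = "person_id", nomatch = 0L]
  controls <- cohort[!trd[is_trd == TRUE], on = "person_id"]
  mres <- match_cohort(cases, controls, seed = seed, config = config)
  cres <- condition_followup(mres$matched, bundle$persons, bundle$diagnoses,
                             config)
  out <- list(cohort = cohort, trd = trd, matched = cres$matched,
              attrition = list(cohort = cb$attrition,
                               matching = mres$attrition,
                               conditioning = cres$attrition))
  if (nrow(cres$matched)) {
    s <- compute_hru_summaries(bundle, cres$matched, config,
                               windows = windows, outcomes = outcomes)
    out$summaries <- s
    if (fit) out$grid <- run_outcome_grid(s, config)
  }
  out
}
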