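#' Run the full triage pipeline
#'
#' Convenience wrapper chaining the pipeline stages: population presence
#' lookup in the two background stores, four-tool prediction, consensus
#' classification, pedigree summarization and report assembly.
#'
#' @param catalog a [VariantCatalog-class].
#' @param esp,exac [PopulationStore-class] objects for the ESP-like and
#'   ExAC-like cohorts.
#' @param pedigrees optional pedigree table.
#' @param policy a [consensusPolicy()].
#' @param seed optional seed recorded in the report's provenance.
#' @return a [SummaryReport-class].
#' @examples
#' fx <- makeStudyFixture()
#' triageReport(fx$catalog, fx$esp, fx$exac, fx$pedigrees)
#' @export
triageReport <- function(catalog, esp, exac, pedigrees = NULL,
                         policy = consensusPolicy(), seed = NULL) {
  presences <- list(lookupPresence(catalog, esp),
                    lookupPresence(catalog, exac))
  names(presences) <- c(cohortId(esp), cohortId(exac))
  cls <- classifyCatalog(catalog, policy = policy)
  buildReport(catalog, presences, cls, pedigrees = pedigrees, seed = seed)
}
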