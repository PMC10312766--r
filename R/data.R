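#' Reference cohort summaries bundled with the package
#'
#' Per-condition EV/uL summary statistics (mean, median, SEM, CV over
#' replicate ROIs) for three capture/stain qSMLM experiments on raw mouse
#' biofluids: a hepatocyte-tracer plasma assay, a pan-neuronal-tracer
#' plasma assay, and the matching CSF assay, each with its tracer-negative
#' control animal. These serve as worked-example inputs for the
#' contribution estimators and the summary-table consistency check; they
#' are measured values, not simulator output.
#'
#' @param experiment optional filter: one of `"hepatocyte_plasma"`,
#'   `"neuron_plasma"`, `"neuron_csf"`.
#' @return data.frame with columns `experiment`, `fluid`, `cohort`
#'   (test/control), `capture`, `stain`, `n_roi`, `mean`, `median`, `sem`,
#'   `cv`.
#' @examples
#' ref <- referenceCohortSummaries("hepatocyte_plasma")
#' with(ref, mean[capture == "HsCD81" & stain == "mouse_panel" &
#'                cohort == "test"] /
#'           mean[capture == "MmCD81" & stain == "mouse_panel" &
#'                cohort == "test"])
#' @export
referenceCohortSummaries <- function(experiment = NULL) {
  path <- system.file("extdata", "reference_cohort_summaries.csv",
                      package = "smlmEV", mustWork = TRUE)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(experiment)) {
    experiment <- match.arg(experiment, unique(ref$experiment))
    ref <- ref[ref$experiment == experiment, , drop = FALSE]
  }
  ref
}
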