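# One-call pipeline evaluation: confounds -> design -> ROI denoising ->
# Ledoit-Wolf connectivity -> metrics, for each requested pipeline preset.

#' Evaluate denoising pipelines on one subject
#'
#' Computes confounds once per mask variant (the lesion ICA once in total),
#' denoises the region time series under each pipeline design, estimates the
#' Ledoit-Wolf connectivity matrix, and returns a [metrics_report()] per
#' pipeline.
#'
#' @param bold 4D [volume_image].
#' @param ctx a [subject_context].
#' @param atlas an [atlas_spec].
#' @param pipelines pipeline names (see [pipeline_spec()]).
#' @param seed RNG seed for the ICA and the modularity restarts.
#' @param subject subject id carried into the reports.
#' @param include_gsr forwarded to [pipeline_spec()].
#' @return Named list of `metrics_report`s, one per pipeline, with the
#'   connectivity matrices attached as attribute `"fc"`.
#' @export
evaluate_pipelines <- function(bold, ctx, atlas,
                               pipelines = c("compcorgs", "compcorlesiongs",
                                             "iclesioncompcorgs"),
                               seed = 1L, subject = "sub-01",
                               include_gsr = TRUE) {
  specs <- lapply(pipelines, pipeline_spec, include_gsr = include_gsr)
  need_ica <- any(vapply(specs, function(s) s$use_ica, logical(1)))
  ica <- if (need_ica)
    lesion_ica(bold, ctx$brain_mask, ctx$lesion_mask, seed = seed) else NULL
  cfs <- list()
  for (v in unique(vapply(specs, function(s) s$variant, character(1))))
    cfs[[v]] <- compute_confounds(bold, ctx, variant = v,
                                  ica_result = if (v == "lesion_adjusted")
                                    ica else NULL, seed = seed)
  reports <- list()
  fcs <- list()
  for (spec in specs) {
    series <- denoise_roi_series(bold, ctx, spec, cfs[[spec$variant]], atlas)
    fcm <- fc_matrix(series)
    reports[[spec$name]] <- metrics_report(fcm, atlas, ctx$lesion_mask,
                                           pipeline = spec$name,
                                           subject = subject, q_seed = seed)
    fcs[[spec$name]] <- fcm
  }
  attr(reports, "fc") <- fcs
  reports
}
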