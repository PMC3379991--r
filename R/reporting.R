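# Report generation: CSV/JSON outputs for the base case, sensitivity
# sweeps and PSA, each tied to a run manifest.

config_fingerprint <- function(params) {
  txt <- paste(deparse(as_plain_list(unclass(params))), collapse = "")
  bytes <- utf8ToInt(txt)
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 4294967295)
}

#' Run manifest
#'
#' Provenance record written next to every set of outputs: a fingerprint of
#' the fully-resolved configuration, the seed(s), package version,
#' timestamp and the conventions chosen for this run (cetuximab unit
#' price, sex mix, discounting convention).
#'
#' @param params a `cea_parameters` object.
#' @param seed seed(s) used, if any.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(params, seed = NULL) {
  structure(list(
    config_fingerprint = config_fingerprint(params),
    seed = seed,
    package_version = as.character(utils::packageVersion("markovcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    conventions = list(
      unit_price_per_mg = params$costs$unit_price_per_mg,
      sex_mix = params$settings$sex_mix,
      discounting = "(1+annual)^(-t/12) per monthly cycle t",
      progression_risk_scaling = "multiplies monthly probabilities",
      half_cycle = params$settings$half_cycle
    )
  ), class = "run_manifest")
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

econ_as_list <- function(r) {
  list(arm = r$arm, discounted = list(cost = r$cost, qaly = r$qaly,
                                      ly = r$ly),
       undiscounted = list(cost = r$cost0, qaly = r$qaly0, ly = r$ly0),
       cost_components = as.list(r$cost_components))
}

#' Write base-case outputs
#'
#' Writes per-arm cohort traces (tidy CSV), a JSON summary with both arms'
#' discounted and undiscounted results, the increments and the ICER, and
#' the run manifest.
#'
#' @param model a fitted `cea_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_base_case <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in c("P", "C"))
    write_trace(model$traces[[arm]],
                file.path(dir, paste0("trace_", arm, ".csv")))
  cmp <- model$comparison
  summary <- list(
    horizon = model$horizon,
    arms = lapply(model$results, econ_as_list),
    incremental = list(delta_cost = cmp$delta_cost,
                       delta_qaly = cmp$delta_qaly,
                       delta_ly = cmp$delta_ly,
                       icer_qaly = cmp$icer_qaly,
                       icer_ly = cmp$icer_ly,
                       dominance = cmp$dominance))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(run_manifest(model$params), dir)
  invisible(dir)
}

#' Write sensitivity-sweep outputs
#'
#' @param sweep a `cea_sweep` data frame.
#' @param params the parameters behind the base case (for the manifest).
#' @param dir output directory.
#' @param name file stem for the CSV.
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, params, dir, name = "sweep") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sweep, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE)
  write_manifest(run_manifest(params), dir)
  invisible(dir)
}

#' Write PSA outputs
#'
#' Writes the replicate-level samples and the CEAC as CSV, the EVPI per
#' willingness-to-pay value as JSON, scatter and CEAC plots as PNG, and
#' the manifest.
#'
#' @param psa a `cea_psa`.
#' @param params the base-case parameters.
#' @param dir output directory.
#' @param wtp_grid willingness-to-pay grid for CEAC and EVPI.
#' @return `dir`, invisibly.
#' @export
write_psa <- function(psa, params, dir, wtp_grid = seq(0, 5e5, 1e4)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(psa$samples, file.path(dir, "psa_samples.csv"),
                   row.names = FALSE)
  cc <- ceac(psa, wtp_grid)
  utils::write.csv(cc, file.path(dir, "ceac.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(wtp = wtp_grid, evpi = evpi(psa, wtp_grid)),
    file.path(dir, "evpi.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  grDevices::png(file.path(dir, "ce_plane.png"), 800, 600)
  plot(psa, "scatter"); grDevices::dev.off()
  grDevices::png(file.path(dir, "ceac.png"), 800, 600)
  plot(psa, "ceac", wtp_grid = wtp_grid); grDevices::dev.off()
  write_manifest(run_manifest(params, seed = psa$seed), dir)
  invisible(dir)
}
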