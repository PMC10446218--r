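## Run orchestration helpers for the analysis scripts: output-directory
## manifests and bulk CSV export.

#' Write a run manifest
#'
#' Records what produced the contents of an output directory: timestamp,
#' package version, seed(s), the MD5 of the scenario config, a snapshot of
#' the model settings and the list of files written. Re-running with the
#' same config and seeds reproduces every deterministic output bit for bit.
#'
#' @param outdir Output directory (created if missing).
#' @param scenario The `ce_scenario` that was run.
#' @param seed Integer seed(s) used, or `NULL` for deterministic runs.
#' @param files Character vector of output file names in `outdir`.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(outdir, scenario, seed = NULL, files = character()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- file.path(tempdir(), "manifest-config.yaml")
  save_config(scenario, cfg)
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("mbcmarkov")),
    scenario = scenario$name,
    config_md5 = unname(tools::md5sum(cfg)),
    seed = seed,
    settings = unclass(scenario$settings),
    outputs = files)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the per-cycle trace of every strategy in a comparison
#'
#' @param ce A `ce_result` from [compare_strategies()].
#' @param outdir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
export_traces_csv <- function(ce, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (id in names(ce$traces)) {
    f <- file.path(outdir, sprintf("trace_%s.csv", id))
    write.csv(trace_to_df(ce$traces[[id]]), f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  invisible(files)
}
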