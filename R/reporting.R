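# Run manifests: every exported results directory carries a small JSON
# record of the configuration, seed and package version that produced it.

#' Write a run manifest
#'
#' @param out_dir Directory the results were written to.
#' @param command Short label of the analysis that ran (e.g. "base_case",
#'   "psa").
#' @param config_path Path of the configuration used (hashed with MD5), or
#'   `NULL` for in-memory configurations.
#' @param seed RNG seed, or `NA` for deterministic analyses.
#' @param cfg The `study_config` used (horizon recorded).
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(out_dir, command, cfg, config_path = NULL,
                           seed = NA) {
  man <- list(
    command = command,
    config_path = config_path,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    seed = seed,
    horizon_years = cfg$econ$horizon_years,
    scenario = cfg$meta$scenario %||% NA,
    package_version = as.character(utils::packageVersion("icdcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
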