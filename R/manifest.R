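## Reproducibility manifest emitted by the command-line front-end.

#' Build a reproducibility manifest for a run
#'
#' Records the command, the full parameter set, the seed, md5 checksums of
#' the input files and the package version, so any stochastic output can be
#' regenerated bit-for-bit by re-running with the same manifest.
#'
#' @param command subcommand name.
#' @param params named list of parameters (seeds included).
#' @param inputs character vector of input file paths (existing files are
#'   checksummed).
#' @return list ready for JSON serialisation.
#' @export
run_manifest <- function(command, params = list(), inputs = character()) {
  files <- inputs[file.exists(inputs)]
  list(command = command,
       params = params,
       input_md5 = as.list(setNames(tools::md5sum(files), files)),
       package = "chronosym",
       version = as.character(utils::packageVersion("chronosym")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a result object (plus manifest) as JSON
#'
#' @param x result list.
#' @param path output path.
#' @param manifest optional [run_manifest()] to embed under `$manifest`.
#' @return the path, invisibly.
#' @export
write_result_json <- function(x, path, manifest = NULL) {
  if (!is.null(manifest)) x <- c(x, list(manifest = manifest))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
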