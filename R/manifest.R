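#' Run manifests: reproducibility records for experiment outputs
#'
#' A run manifest snapshots everything needed to reproduce an experiment's
#' output files byte for byte: the scenario configuration, the master seed
#' and per-replicate substream seeds, the package version, and an inventory
#' of output files with MD5 checksums.  `verify_manifest()` re-checksums the
#' inventory and reports any file that is missing or differs.
#'
#' @param config a [scenario_config()] (stored as a round-trippable list).
#' @param seed master seed of the run.
#' @param files character vector of output file paths.
#' @param replicate_seeds integer vector of per-replicate seeds, if any.
#' @return `run_manifest()`: a list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, files, replicate_seeds = NULL) {
  files <- as.character(files)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0)
    stop("manifest files do not exist: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(
    list(config = unclass(config)[!vapply(unclass(config), is.null,
                                          logical(1))],
         seed = seed,
         replicate_seeds = replicate_seeds,
         version = as.character(utils::packageVersion("phylodecline")),
         files = data.frame(path = files,
                            md5 = unname(tools::md5sum(files)))),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path file path for the JSON manifest.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "run_manifest")
}

#' @rdname run_manifest
#' @return `verify_manifest()`: `TRUE` invisibly, or an error naming the
#'   offending files.
#' @export
verify_manifest <- function(manifest) {
  f <- manifest$files
  missing <- f$path[!file.exists(f$path)]
  if (length(missing) > 0)
    stop("missing files: ", paste(missing, collapse = ", "), call. = FALSE)
  now <- unname(tools::md5sum(f$path))
  bad <- f$path[now != f$md5]
  if (length(bad) > 0)
    stop("checksum mismatch: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Restore a `scenario_config` from a manifest's snapshot
#'
#' @param manifest a `run_manifest`.
#' @return a validated [scenario_config()].
#' @export
manifest_config <- function(manifest) {
  do.call(scenario_config, manifest$config)
}
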