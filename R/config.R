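#' Load the model configuration
#'
#' Reads the packaged YAML configuration (or a user-supplied one) holding
#' every tunable constant of the analysis: region intake and consumption
#' profiles, EAR cut-points, program dose schedules, cost streams, mortality
#' envelopes, optimizer and pathway settings. The packaged file documents the
#' provenance of each value (printed / calibrated / assumed).
#'
#' @param path path to a YAML configuration; default is the packaged file.
#' @return a nested list with class `"vaplan_config"`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vaplan-config.yaml", package = "vaplan")
    if (path == "") {   # not installed (e.g. pkgload); fall back to source tree
      path <- file.path("inst", "extdata", "vaplan-config.yaml")
    }
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  required <- c("regions", "ear", "programs", "costs", "mortality",
                "optimizer", "pathways", "monte_carlo")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("malformed config, missing sections: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(REGIONS, names(cfg$regions))
  if (length(bad)) stop("config lacks region profiles for: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class(cfg) <- c("vaplan_config", "list")
  cfg
}

config_cache <- new.env(parent = emptyenv())

#' Default configuration (cached)
#' @return the packaged configuration list.
#' @export
default_config <- function() {
  if (is.null(config_cache$cfg)) config_cache$cfg <- load_config()
  config_cache$cfg
}

#' EAR table from a configuration
#' @param config a configuration list.
#' @return tibble in the [default_ear_table()] layout.
#' @export
config_ear_table <- function(config = default_config()) {
  default_ear_table(ear_6_11 = config$ear$age_6_11,
                    ear_12_47 = config$ear$age_12_47,
                    ear_48_59 = config$ear$age_48_59)
}

# A short fingerprint of a configuration, recorded in output manifests so
# every artifact can be traced to the exact settings that produced it.
config_hash <- function(config = default_config()) {
  x <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # tiny polynomial rolling hash; avoids a digest dependency
  h <- 5381
  for (b in utf8ToInt(as.character(x))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records seed(s), configuration hash, package version, file paths and a
#' timestamp next to pipeline outputs, so that every output references the
#' run that produced it.
#'
#' @param path file to write (JSON).
#' @param seed integer seed(s) used by the run.
#' @param files named list/vector of output paths.
#' @param config configuration used.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, files = list(), config = default_config()) {
  manifest <- list(
    package = "vaplan",
    version = as.character(utils::packageVersion("vaplan")),
    config_hash = config_hash(config),
    seed = seed,
    files = files,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
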