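config_schema <- c("nx", "ny", "nz", "n_mic", "n_mm", "n_cd8", "n_treg",
                   "bmsc_spacing", "horizon_h", "dt_h", "D", "boundary",
                   "sdf1_rate", "tgfb_rate_mm", "tgfb_rate_bmsc",
                   "replicates", "btz_nM", "len_uM", "thal_uM",
                   "start_h", "duration_h")

#' Parse a simulation configuration file
#'
#' Reads a YAML (or JSON) run configuration, rejects unknown keys, fills
#' every documented default and returns the validated [habm_config()].
#' Drug keys (`btz_nM`, `len_uM`, `thal_uM`, `start_h`, `duration_h`)
#' populate the regimen.
#'
#' @param path Path to the configuration file; an empty file yields the
#'   full default configuration.
#' @return A `habm_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_schema)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  reg_keys <- c("btz_nM", "len_uM", "thal_uM", "start_h", "duration_h")
  reg <- do.call(drug_regimen, raw[intersect(names(raw), reg_keys)])
  args <- raw[setdiff(names(raw), reg_keys)]
  args$regimen <- reg
  do.call(habm_config, args)
}

#' Serialise a configuration to a named list
#'
#' Round-trips with [parse_config()]: writing the returned list as YAML
#' and parsing it reproduces the configuration.
#'
#' @param config A `habm_config`.
#' @return Named list of scalar settings.
#' @export
serialize_config <- function(config) {
  list(nx = config$domain$nx, ny = config$domain$ny, nz = config$domain$nz,
       n_mic = config$n_mic, n_mm = config$n_mm, n_cd8 = config$n_cd8,
       n_treg = config$n_treg, bmsc_spacing = config$bmsc_spacing,
       horizon_h = config$horizon_h, dt_h = config$dt_h, D = config$D,
       boundary = config$boundary, sdf1_rate = config$sdf1_rate,
       tgfb_rate_mm = config$tgfb_rate_mm,
       tgfb_rate_bmsc = config$tgfb_rate_bmsc,
       replicates = config$replicates,
       btz_nM = config$regimen$btz_nM, len_uM = config$regimen$len_uM,
       thal_uM = config$regimen$thal_uM,
       start_h = config$regimen$start_h,
       duration_h = config$regimen$duration_h)
}

#' Run manifest
#'
#' A reproducibility record emitted alongside command-line outputs:
#' configuration digest, master seed, package version and wall-clock.
#'
#' @param config A `habm_config`.
#' @param seed Master seed.
#' @param outputs Character vector of output paths.
#' @return Named list suitable for JSON serialisation.
#' @export
run_manifest <- function(config, seed, outputs = character()) {
  cfg <- serialize_config(config)
  chars <- utf8ToInt(paste(names(cfg), unlist(cfg), collapse = ";"))
  list(config = cfg,
       config_hash = sum(chars * seq_along(chars)) %% 2^31,
       seed = seed,
       package_version = as.character(utils::packageVersion("habm")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}
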