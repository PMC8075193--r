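#' Write a synthetic ASL dataset to disk
#'
#' Writes the series as 4-D NIfTI (depths stacked along the first spatial
#' axis), a sidecar TSV with columns `volume_index`, `time_s`, `parity`,
#' `boxcar`, and a YAML config holding the design parameters and seed.
#'
#' @param series an `asl_timeseries` carrying a `design` attribute (as
#'   produced by [generate_laminar_asl()]), or supply `design` explicitly.
#' @param dir output directory (created if missing).
#' @param design the `stimulus_design`; defaults to `attr(series, "design")`.
#' @param seed optional seed to record in the config.
#' @return `dir`, invisibly.
#' @export
write_asl_dataset <- function(series, dir, design = attr(series, "design"),
                              seed = NULL) {
  stopifnot(inherits(series, "asl_timeseries"),
            inherits(design, "stimulus_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- nrow(series$values)
  n <- ncol(series$values)
  vol <- array(series$values, dim = c(k, 1, 1, n))
  img <- RNifti::asNifti(vol, pixdim = c(1, 1, 1, series$tr))
  RNifti::writeNifti(img, file.path(dir, "asl.nii.gz"))
  utils::write.table(
    data.frame(volume_index = seq_len(n) - 1,
               time_s = volume_times(series),
               parity = series$parity,
               boxcar = boxcar(design)),
    file.path(dir, "asl_events.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- list(design = design[c("lead_in", "n_blocks", "on_duration",
                                "off_duration", "tr", "n_volumes")],
              seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "asl_config.yaml"))
  invisible(dir)
}

#' Read an ASL dataset written by [write_asl_dataset()]
#'
#' @param dir directory holding `asl.nii.gz`, `asl_events.tsv`,
#'   `asl_config.yaml`.
#' @return an `asl_timeseries` with the `design` attribute restored.
#' @export
read_asl_dataset <- function(dir) {
  img <- RNifti::readNifti(file.path(dir, "asl.nii.gz"))
  ev <- utils::read.delim(file.path(dir, "asl_events.tsv"))
  cfg <- yaml::read_yaml(file.path(dir, "asl_config.yaml"))
  d <- do.call(make_block_design, cfg$design)
  dm <- dim(img)
  values <- matrix(img, nrow = dm[1], ncol = dm[4])
  out <- asl_timeseries(values, ev$parity, d$tr)
  attr(out, "design") <- d
  attr(out, "seed") <- cfg$seed
  out
}

#' Write a laminar profile as TSV
#'
#' Columns: `depth_norm`, `value`, `sem`.
#'
#' @param profile a `laminar_profile`.
#' @param path output file path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(depth_norm = profile$depth, value = profile$value,
               sem = profile$dispersion),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a laminar profile TSV written by [write_profile_tsv()]
#' @param path file path.
#' @return a `laminar_profile`.
#' @export
read_profile_tsv <- function(path) {
  d <- utils::read.delim(path)
  laminar_profile(d$depth_norm, d$value, d$sem)
}
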