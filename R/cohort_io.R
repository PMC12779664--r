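#' Write and read a cohort as plain-text files
#'
#' The cohort is written as `subjects.csv` (one row per subject),
#' `readings.csv` (long format: id, day, measure, value) and a
#' `latent.json` sidecar holding the generator truths (and masked original
#' values if any). User-supplied data with the same schema can be read
#' back with [read_cohort()]; the latent sidecar is optional.
#'
#' @param cohort a `kb_cohort`
#' @param dir directory to write into (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "kb_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cohort$readings, file.path(dir, "readings.csv"), row.names = FALSE)
  sidecar <- list(latent = cohort$latent,
                  masked_original = cohort$masked_original)
  jsonlite::write_json(sidecar, file.path(dir, "latent.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  readings <- read.csv(file.path(dir, "readings.csv"), stringsAsFactors = FALSE)
  latent <- NULL
  masked <- NULL
  sp <- file.path(dir, "latent.json")
  if (file.exists(sp)) {
    sidecar <- jsonlite::read_json(sp, simplifyVector = TRUE)
    latent <- as.data.frame(sidecar$latent)
    masked <- if (length(sidecar$masked_original))
      as.data.frame(sidecar$masked_original) else NULL
  }
  structure(list(subjects = subjects, readings = readings, latent = latent,
                 masked_original = masked, config = NULL),
            class = "kb_cohort")
}

#' Read a synthetic or pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [synthetic_config()] (under
#' `synthetic:`) and [run_pipeline()] settings (`horizon_years`,
#' `weighting`, `m_imputations`, `hr_applied`, `target_fraction`,
#' `delta_grid`, `n_bootstrap`, `out_dir`, `seed`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a named list
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
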