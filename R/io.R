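# Readers and writers for the pipeline's tabular interfaces: the three
# survey inputs with strict header validation, per-species design bundles,
# and persisted posterior draws.

.required_headers <- list(
  areas = c("area_id", "x_km", "y_km", "elevation_m", "n_deposition",
            "n_application", "forest", "arable", "grassland", "settlement",
            "roads", "rocks_amt", "wetland_amt", "shoreline_amt"),
  counts = c("area_id", "species_id", "year", "territories"),
  traits = c("species_id", "habitat_guild", "nesting_guild",
             "migration_guild", "food_guild", "is_farmland", "is_alpine")
)

.read_validated <- function(path, what) {
  df <- read_seeded_csv(path)
  missing <- setdiff(.required_headers[[what]], names(df))
  if (length(missing)) {
    stop(sprintf("%s table %s lacks required column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read the three survey input tables
#'
#' Reads the survey-area, territory-count and species-trait CSVs (as
#' written by [run_pipeline()] or prepared externally) and validates that
#' every required column is present before anything downstream runs.
#' Survey areas with missing N deposition are dropped globally here, before
#' any species-level processing.
#'
#' @param areas_csv,counts_csv,traits_csv File paths.
#' @return List with validated data frames `areas`, `counts`, `traits`.
#' @export
read_survey_data <- function(areas_csv, counts_csv, traits_csv) {
  areas <- .read_validated(areas_csv, "areas")
  drop <- is.na(areas$n_deposition) | is.na(areas$n_application)
  if (any(drop)) {
    message("dropping ", sum(drop), " survey area(s) with missing N data")
    areas <- areas[!drop, , drop = FALSE]
  }
  counts <- .read_validated(counts_csv, "counts")
  counts <- counts[counts$area_id %in% areas$area_id, , drop = FALSE]
  list(areas = areas,
       counts = counts,
       traits = .read_validated(traits_csv, "traits"))
}

#' Write a per-species design bundle
#'
#' Persists a `species_dataset` as a design-matrix CSV (response and year
#' index alongside the covariate columns) plus a JSON sidecar with the
#' standardization record, so effect curves can be reconstructed exactly.
#'
#' @param dataset A `species_dataset` from [build_design()].
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_design_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- dataset$species_id
  mat <- cbind(dataset$response, year_index = dataset$year_index,
               as.data.frame(dataset$X))
  csv <- file.path(dir, paste0(sp, "_design.csv"))
  utils::write.csv(mat, csv, row.names = FALSE)
  meta <- list(species_id = sp, n_variable = dataset$n_variable,
               years = dataset$years,
               logN_percentiles = unname(dataset$logN_q),
               standardization = dataset$std_record)
  js <- file.path(dir, paste0(sp, "_standardization.json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv, js))
}

#' Persist posterior draws with their sampler metadata
#'
#' One CSV row per draw with named parameter columns, plus a JSON sidecar
#' carrying the sampler metadata (seed, method, convergence summaries).
#'
#' @param fit A `zinb_fit`.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(fit$species_id, "_draws.csv"))
  utils::write.csv(as.data.frame(fit$draws), csv, row.names = FALSE)
  js <- file.path(dir, paste0(fit$species_id, "_sampler_meta.json"))
  jsonlite::write_json(fit$meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
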