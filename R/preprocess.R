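# Inclusion filters and covariate transforms producing per-species
# model-ready designs.

#' Species inclusion filter by occupancy
#'
#' A species is retained when it was found (at least one territory in at
#' least one study year) in at least `min_areas` distinct survey areas;
#' occupancy is pooled over years.
#'
#' @param counts Count table (`area_id`, `species_id`, `year`, `territories`).
#' @param min_areas Occupancy threshold, default 50 areas.
#' @return Character vector of included species ids (possibly empty).
#' @export
filter_species <- function(counts, min_areas = 50) {
  if (is.null(counts) || nrow(counts) == 0L) stop("`counts` must be non-empty")
  occ <- counts[counts$territories > 0, c("species_id", "area_id")]
  n_occ <- tapply(occ$area_id, occ$species_id,
                  function(a) length(unique(a)))
  sort(names(n_occ)[n_occ >= min_areas])
}

#' Range-proximity filter for one species
#'
#' Restricts a species' analysis set to survey areas within `radius_km`
#' (Euclidean, cell centre to cell centre, boundary inclusive) of an area
#' where the species was found, dropping regions outside its range where
#' absences are uninformative. Occupied areas are always included.
#'
#' @param areas Survey-area table with `x_km`, `y_km`.
#' @param counts Count table.
#' @param species_id Single species id present in `counts`.
#' @param radius_km Inclusion radius, default 10 km.
#' @return Character vector of included `area_id`s.
#' @export
proximity_filter <- function(areas, counts, species_id, radius_km = 10) {
  cc <- counts[counts$species_id == species_id, , drop = FALSE]
  occ_ids <- unique(cc$area_id[cc$territories > 0])
  occ_ids <- intersect(occ_ids, areas$area_id)
  if (length(occ_ids) == 0L) {
    stop("species ", species_id, " has no occupied survey area")
  }
  occ <- areas$area_id %in% occ_ids
  ox <- areas$x_km[occ]; oy <- areas$y_km[occ]
  d2min <- vapply(seq_len(nrow(areas)), function(i) {
    min((areas$x_km[i] - ox)^2 + (areas$y_km[i] - oy)^2)
  }, numeric(1))
  keep <- occ | d2min <= radius_km^2
  areas$area_id[keep]
}

#' Build a model-ready per-species dataset
#'
#' Applies the covariate conventions of the territory model: the species' N
#' variable is atmospheric deposition, plus agricultural application for
#' farmland species; its logarithm is centred and scaled to 1 SD over the
#' included areas and enters as a cubic (`x_N`, `x_N2`, `x_N3`, raw powers
#' of the standardized value). Elevation, forest, arable and roads enter
#' linear plus quadratic, settlement linear, all standardized the same way;
#' rocks, wetland and shoreline are reduced to presence/absence because they
#' are mostly zero; grassland is omitted (the fractions are near-redundant);
#' arable terms are omitted for alpine species. The response is the
#' territory count per included area and year (missing records count as 0),
#' with year kept as a grouping index.
#'
#' @param areas Survey-area table, already restricted to the species'
#'   analysis set (see [proximity_filter()]).
#' @param counts Count table (any species; filtered internally).
#' @param traits One-row traits entry (needs `species_id`, `is_farmland`,
#'   `is_alpine`).
#' @param years Optional integer vector of years; defaults to the years in
#'   `counts`.
#' @return An object of class `species_dataset`: response table, design
#'   matrix `X`, `year_index`, standardization record, per-area table and
#'   cached log-N percentiles.
#' @export
build_design <- function(areas, counts, traits, years = NULL) {
  traits <- as.list(traits)
  sp <- traits$species_id
  n_var <- areas$n_deposition +
    if (isTRUE(traits$is_farmland)) areas$n_application else 0
  if (any(is.na(n_var))) stop("missing N values in included areas")
  dc <- .design_columns(areas, n_var)
  X <- dc$X
  record <- dc$record

  if (isTRUE(traits$is_alpine)) {
    X <- X[, setdiff(colnames(X), c("arable", "arable2")), drop = FALSE]
  }
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (any(!keep)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  record <- record[record$column %in% colnames(X), , drop = FALSE]

  cc <- counts[counts$species_id == sp &
                 counts$area_id %in% areas$area_id, , drop = FALSE]
  if (is.null(years)) years <- sort(unique(counts$year))
  grid <- expand.grid(area_id = areas$area_id, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(cc$area_id, cc$year)
  m <- match(paste(grid$area_id, grid$year), key)
  grid$territories <- ifelse(is.na(m), 0L, cc$territories[m])

  area_index <- match(grid$area_id, areas$area_id)
  year_index <- match(grid$year, years)

  area_tab <- data.frame(
    area_id = areas$area_id,
    x_km = areas$x_km, y_km = areas$y_km,
    elevation_m = areas$elevation_m,
    N = n_var, x_N = dc$x_N,
    territories_total = as.numeric(
      tapply(grid$territories, area_index, sum)[as.character(seq_len(nrow(areas)))]),
    stringsAsFactors = FALSE
  )

  structure(list(
    species_id = sp,
    is_farmland = isTRUE(traits$is_farmland),
    is_alpine = isTRUE(traits$is_alpine),
    response = grid,
    X = X[area_index, , drop = FALSE],
    area_index = area_index,
    year_index = year_index,
    years = years,
    std_record = record,
    area_tab = area_tab,
    logN_q = .quantile7(dc$x_N, c(0.15, 0.85)),
    n_variable = if (isTRUE(traits$is_farmland))
      "deposition_plus_application" else "deposition"
  ), class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  cat("<species_dataset> ", x$species_id, "\n",
      "  areas: ", nrow(x$area_tab),
      "  years: ", length(x$years),
      "  rows: ", nrow(x$response),
      "  covariates: ", ncol(x$X), "\n",
      "  N variable: ", x$n_variable, "\n", sep = "")
  invisible(x)
}
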