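# Guild-level aggregation of species slope results: counts and rounded
# percentages of negative / positive / no-linear species per guild.

#' Percentage of a guild, reported as a rounded integer
#'
#' `round(100 * count / n_species)` with ties rounded half away from zero —
#' the convention under which e.g. 15 of 37 species is reported as 41%.
#'
#' @param count Numerator count(s).
#' @param n_species Guild size(s).
#' @return Integer-valued numeric vector.
#' @export
guild_percentage <- function(count, n_species) {
  round_half_away(100 * count / n_species)
}

#' Summarize slope results per guild on one axis
#'
#' Counts, per guild level, the species with and without a linear
#' relationship and those with a well-supported negative or positive one,
#' and reports each as an integer percentage of all species in the guild
#' (with and without linear relationships). On the nesting axis, species
#' with `nesting_guild == "none"` are excluded.
#'
#' @param results Data frame of species results with `species_id`,
#'   `support` and `rel_mean` (one row per species, e.g. rbind of
#'   [as.data.frame.slope_result()] rows).
#' @param traits Species-trait table.
#' @param axis One of `"habitat"`, `"nesting"`, `"migration"`, `"food"`.
#' @return Data frame with one row per guild level: `guild_axis`,
#'   `guild_level`, `n_species`, `n_linear`, `n_no_linear`,
#'   `n_neg_supported`, `n_pos_supported`, `pct_no_linear`,
#'   `pct_neg_supported`, `pct_pos_supported`.
#' @export
summarize_guilds <- function(results, traits,
                             axis = c("habitat", "nesting", "migration",
                                      "food")) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_guild")
  m <- match(results$species_id, traits$species_id)
  if (any(is.na(m))) {
    stop("every species in `results` needs a row in `traits`")
  }
  level <- traits[[col]][m]
  allowed <- .guild_levels[[axis]]
  bad <- setdiff(unique(level), allowed)
  if (length(bad)) {
    stop("unknown ", axis, " guild level(s): ", paste(bad, collapse = ", "))
  }
  keep <- if (axis == "nesting") level != "none" else rep(TRUE, length(level))
  res <- results[keep, , drop = FALSE]
  level <- level[keep]

  levels_present <- intersect(allowed, unique(level))
  rows <- lapply(levels_present, function(lv) {
    r <- res[level == lv, , drop = FALSE]
    n <- nrow(r)
    n_nl <- sum(r$support == "no_linear")
    n_neg <- sum(r$support == "negative_supported")
    n_pos <- sum(r$support == "positive_supported")
    data.frame(guild_axis = axis, guild_level = lv,
               n_species = n, n_linear = n - n_nl, n_no_linear = n_nl,
               n_neg_supported = n_neg, n_pos_supported = n_pos,
               pct_no_linear = guild_percentage(n_nl, n),
               pct_neg_supported = guild_percentage(n_neg, n),
               pct_pos_supported = guild_percentage(n_pos, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-wide tally of linear relationships
#'
#' Splits the cohort into species with and without a linear relationship,
#' the linear ones by the sign of the posterior-mean relative slope
#' (a slope of exactly 0 counts as negative, a documented deterministic
#' tie-break), and counts the well-supported negative and positive calls.
#'
#' @param results Species results data frame (see [summarize_guilds()]).
#' @return Named list: `n_linear`, `n_negative`, `n_positive`,
#'   `n_neg_supported`, `n_pos_supported`, `n_no_linear`.
#' @export
overall_tally <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("`results` must be non-empty")
  }
  lin <- results$support != "no_linear"
  list(n_linear = sum(lin),
       n_negative = sum(lin & results$rel_mean <= 0),
       n_positive = sum(lin & results$rel_mean > 0),
       n_neg_supported = sum(results$support == "negative_supported"),
       n_pos_supported = sum(results$support == "positive_supported"),
       n_no_linear = sum(!lin))
}

#' Human-readable guild report
#'
#' Formats a guild summary table as "X out of N (P%)" lines per guild.
#'
#' @param summary Output of [summarize_guilds()].
#' @return Character vector of report lines.
#' @export
format_guild_report <- function(summary) {
  vapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    sprintf(paste0("%s/%s: %d species; no linear %d out of %d (%d%%); ",
                   "supported negative %d (%d%%), positive %d (%d%%)"),
            s$guild_axis, s$guild_level, s$n_species, s$n_no_linear,
            s$n_species, s$pct_no_linear, s$n_neg_supported,
            s$pct_neg_supported, s$n_pos_supported, s$pct_pos_supported)
  }, character(1))
}
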