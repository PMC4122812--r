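#' Reference season starts observed in Krakow, 1991-2012
#'
#' Cumulative-sum season start days of the Alnus, Corylus and Betula
#' airborne pollen seasons recorded by the Krakow monitoring station
#' (volumetric trap, city centre). 1992 and 1996 are missing for Alnus and
#' Corylus because of technical problems with the record; 2011 and 2012
#' are the model-verification years, kept apart from the 1991-2010
#' training period.
#'
#' @param taxon optional taxon filter.
#' @param period `"training"` (1991-2010), `"verification"` (2011-2012) or
#'   `"all"`.
#' @return data frame `taxon, year, day, season_type` (`day` is the
#'   day-of-year of the season start; `NA` for excluded years).
#' @export
krakow_season_starts <- function(taxon = NULL,
                                 period = c("all", "training", "verification")) {
  period <- match.arg(period)
  years <- 1991:2012
  alnus <- c(67, NA, 36, 12, 39, NA, 55, 43, 35, 40, 39, 25, 66, 51, 77, 84,
             14, 20, 63, 66, 42, 66)
  corylus <- c(67, NA, 36, 13, 38, NA, 55, 45, 36, 41, 39, 31, 70, 48, 76, 85,
               11, 21, 63, 74, 43, 73)
  betula <- c(96, 105, 111, 91, 109, 113, 90, 93, 94, 104, 97, 87, 103, 97,
              99, 101, 98, 97, 97, 90, 96, 94)
  df <- rbind(
    data.frame(taxon = "Alnus", year = years, day = alnus),
    data.frame(taxon = "Corylus", year = years, day = corylus),
    data.frame(taxon = "Betula", year = years, day = betula))
  df$season_type <- NA_character_
  for (tx in unique(df$taxon)) {
    sel <- df$taxon == tx & !is.na(df$day)
    df$season_type[sel] <- classify_season_type(df$day[sel], taxon_config(tx),
                                                strict = FALSE)
  }
  if (!is.null(taxon)) df <- df[df$taxon %in% taxon, , drop = FALSE]
  if (period == "training") df <- df[df$year <= 2010, , drop = FALSE]
  if (period == "verification") df <- df[df$year >= 2011, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Reference verification local minima (Krakow, 2011-2012)
#'
#' The pre-season "local minima" considered when verifying the onset
#' models on the 2011 and 2012 Krakow seasons: for each minimum, its
#' day-of-year and the 5-day running mean of maximum temperature (Alnus,
#' Corylus) or mean temperature (Betula) on that day.
#'
#' @param taxon optional taxon filter.
#' @return data frame `taxon, year, day, t5`.
#' @export
krakow_verification_minima <- function(taxon = NULL) {
  df <- rbind(
    data.frame(taxon = "Alnus", year = 2011L, day = c(6L, 25L, 33L),
               t5 = c(0.9, -0.1, -0.7)),
    data.frame(taxon = "Alnus", year = 2012L, day = c(10L, 18L, 36L, 43L, 60L),
               t5 = c(4.3, 0.0, -12.4, -8.6, 5.6)),
    data.frame(taxon = "Corylus", year = 2011L, day = c(6L, 25L, 33L),
               t5 = c(0.9, -0.1, -0.7)),
    data.frame(taxon = "Corylus", year = 2012L,
               day = c(10L, 18L, 36L, 43L, 60L, 68L),
               t5 = c(4.3, 0.0, -12.4, -8.6, 5.6, 3.7)),
    data.frame(taxon = "Betula", year = 2011L, day = c(80L, 89L),
               t5 = c(3.4, 5.56)),
    data.frame(taxon = "Betula", year = 2012L, day = c(67L, 82L, 86L, 93L),
               t5 = c(-1.84, 8.38, 8.68, 5.52)))
  if (!is.null(taxon)) df <- df[df$taxon %in% taxon, , drop = FALSE]
  rownames(df) <- NULL
  df
}
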