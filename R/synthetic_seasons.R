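#' Synthetic flowering seasons
#'
#' Seeded generator of per-accession daily flower-count time series with
#' flowering-stage labels. Bud, blooming and withered counts follow three
#' lagged unimodal (Gaussian-shaped) curves: the bud curve precedes the
#' bloom curve by `bud_lead` days, the withered curve follows by
#' `wither_lag` days. Daily counts are negative-binomial around the curve
#' value with user-set overdispersion (`noise_dispersion = 0` is exact,
#' noiseless mode). Stage labels follow the cumulative-bloom rule: a day is
#' IFS until cumulative (noiseless) bloom reaches 10% of the season total,
#' EFS to 40%, MFS to 60%, LFS to 90%, and TFS after, so labels form a
#' non-decreasing progression over the season.
#'
#' @param accession_id accession (germplasm line) identifier
#' @param season_start a `Date`, day 0 of the season
#' @param season_length season length in days
#' @param peak_day day offset of maximal bloom
#' @param peak_amplitude expected blooming count at peak
#' @param bud_lead days by which the bud curve precedes the bloom curve
#' @param wither_lag days by which the withered curve follows
#' @param noise_dispersion negative-binomial overdispersion phi
#'   (variance = mu + phi * mu^2); 0 disables noise
#' @param seed integer seed
#' @return a `season_spec` list
#' @export
season_spec <- function(accession_id = "ACC1",
                        season_start = as.Date("2023-11-01"),
                        season_length = 60, peak_day = 30,
                        peak_amplitude = 80, bud_lead = 7, wither_lag = 7,
                        noise_dispersion = 0.05, seed = 0L) {
  stopifnot(season_length > 0, peak_amplitude > 0, noise_dispersion >= 0)
  structure(list(accession_id = accession_id,
                 season_start = as.Date(season_start),
                 season_length = season_length, peak_day = peak_day,
                 peak_amplitude = peak_amplitude, bud_lead = bud_lead,
                 wither_lag = wither_lag,
                 noise_dispersion = noise_dispersion,
                 seed = as.integer(seed)),
            class = "season_spec")
}

# the three expected-count curves at day offset t
season_curves <- function(spec, t) {
  s <- spec$season_length / 8
  bloom <- spec$peak_amplitude * exp(-(t - spec$peak_day)^2 / (2 * s^2))
  bud <- 1.3 * spec$peak_amplitude *
    exp(-(t - (spec$peak_day - spec$bud_lead))^2 / (2 * s^2))
  wither <- 0.7 * spec$peak_amplitude *
    exp(-(t - (spec$peak_day + spec$wither_lag))^2 / (2 * s^2))
  cbind(bud = bud, bloom = bloom, wither = wither)
}

# stage label per day offset from the cumulative noiseless bloom curve
season_stages <- function(spec, t) {
  days <- 0:spec$season_length
  cum <- cumsum(season_curves(spec, days)[, "bloom"])
  frac <- cum / cum[length(cum)]
  stage_of <- function(ti) {
    if (ti < 0) return("IFS")
    f <- frac[min(length(frac), max(1, floor(ti) + 1))]
    if (f < 0.10) "IFS" else if (f < 0.40) "EFS" else if (f < 0.60) "MFS"
    else if (f < 0.90) "LFS" else "TFS"
  }
  vapply(t, stage_of, "")
}

#' Generate a flowering-season count series
#'
#' @param spec a [season_spec()]
#' @param sampling_dates `Date` vector of observation dates (empty gives an
#'   empty series); dates must lie within the season window
#' @param replicates raw records per date (use 3 to feed the
#'   three-sample-averaging rule of the stage-dataset builder)
#' @return data.frame with columns accession, date, bud, b_flower,
#'   w_flower, stage
#' @export
generate_season <- function(spec, sampling_dates, replicates = 1) {
  stopifnot(inherits(spec, "season_spec"))
  sampling_dates <- as.Date(sampling_dates)
  if (!length(sampling_dates))
    return(data.frame(accession = character(0), date = as.Date(character(0)),
                      bud = integer(0), b_flower = integer(0),
                      w_flower = integer(0), stage = character(0)))
  t <- as.numeric(sampling_dates - spec$season_start)
  if (any(t > spec$season_length))
    stop("sampling dates extend beyond the season window")
  with_seed(spec$seed, {
    rows <- lapply(seq_along(t), function(i) {
      mu <- pmax(season_curves(spec, t[i]), 0)
      draw <- function(m) {
        if (spec$noise_dispersion == 0) rep(as.integer(round(m)), replicates)
        else as.integer(rnbinom(replicates, size = 1 / spec$noise_dispersion,
                                mu = m))
      }
      data.frame(accession = spec$accession_id,
                 date = sampling_dates[i],
                 bud = draw(mu[1, "bud"]),
                 b_flower = draw(mu[1, "bloom"]),
                 w_flower = draw(mu[1, "wither"]),
                 stage = season_stages(spec, t[i]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a season series as CSV
#'
#' Columns `accession,date,bud,b_flower,w_flower,stage`.
#'
#' @param series data.frame from [generate_season()]
#' @param path output path
#' @export
write_season_csv <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}
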