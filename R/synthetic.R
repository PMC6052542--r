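#' Configuration for the synthetic reactor series generator
#'
#' Defines the study conditions emulated by the generator: a stillage-fed
#' flow-through fermenter sampled on a fixed cadence for 252 days, an
#' acclimation phase during which carbohydrate conversion ramps up and
#' odd-chain acids rise then fall, and a steady state in which each product
#' concentration is its target conversion times the feed COD, perturbed by
#' multiplicative lognormal measurement noise.
#'
#' @param feed A `feed_reference` (default: stillage batch 1) or list of
#'   them with `batch_switch_day` transitions.
#' @param srt Retention time, days.
#' @param duration_days Run length, days.
#' @param sampling_interval_days Sampling cadence, days.
#' @param acclimation List: `duration_days` of the acclimation phase and
#'   `odd_chain_peak_fraction`, the peak share of monocarboxylates that is
#'   odd-chain early in the run (decays to ~0 by steady state).
#' @param targets List of steady-state targets: `scfa_conversion`,
#'   `mcfa_conversion` and `carbohydrate_conversion` (fractions of feed COD
#'   and feed carbohydrate), `hexanoate_octanoate_cod_ratio`, and
#'   `acetic_share_of_scfa`.
#' @param offgas_fraction Fraction of feed COD leaving as off-gas at steady
#'   state (sets total soluble COD of the samples).
#' @param noise_cv Relative SD of the multiplicative lognormal measurement
#'   noise (0 disables noise and the RNG entirely).
#' @param seed RNG seed (the single source of randomness).
#' @param batch_switch_day Feed transition day(s) when `feed` is a list.
#' @return Class `synthetic_reactor_config`.
#' @export
synthetic_reactor_config <- function(feed = stillage_batch1(),
                                     srt = 6, duration_days = 252,
                                     sampling_interval_days = 6,
                                     acclimation = list(duration_days = 30,
                                                        odd_chain_peak_fraction = 0.35),
                                     targets = list(
                                       scfa_conversion = 0.204,
                                       mcfa_conversion = 0.177,
                                       carbohydrate_conversion = 0.97,
                                       hexanoate_octanoate_cod_ratio = 0.16 / 0.017,
                                       acetic_share_of_scfa = 0.054 / 0.204
                                     ),
                                     offgas_fraction = 0.091,
                                     noise_cv = 0.02, seed = 1,
                                     batch_switch_day = 120) {
  conv <- c(targets$scfa_conversion, targets$mcfa_conversion)
  if (any(conv < 0) || any(conv > 1) ||
      targets$carbohydrate_conversion < 0 || targets$carbohydrate_conversion > 1) {
    stop("conversion targets must lie in [0, 1]")
  }
  if (sum(conv) + offgas_fraction > 1) {
    stop("conversion targets plus off-gas exceed the feed COD mass balance")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (srt <= 0 || duration_days <= 0 || sampling_interval_days <= 0) {
    stop("srt, duration and sampling interval must be positive")
  }
  structure(list(feed = feed, srt = srt, duration_days = duration_days,
                 sampling_interval_days = sampling_interval_days,
                 acclimation = acclimation, targets = targets,
                 offgas_fraction = offgas_fraction, noise_cv = noise_cv,
                 seed = seed, batch_switch_day = batch_switch_day),
            class = "synthetic_reactor_config")
}

# Logistic ramp over the acclimation phase; identically 1 afterwards so
# noiseless steady-state recovery is exact.
.acclimation_ramp <- function(t, dur) {
  ifelse(t >= dur, 1, 1 / (1 + exp(-(t - dur / 2) / (dur / 10))))
}

# Gamma-shaped odd-chain pulse, zero outside the acclimation phase.
.odd_chain_shape <- function(t, dur) {
  tp <- dur / 3
  ifelse(t >= dur, 0, (t / tp) * exp(1 - t / tp))
}

#' Generate a synthetic reactor time series
#'
#' Produces a `reactor_series` whose steady-state samples recover the
#' configured conversion targets exactly when `noise_cv = 0` and up to
#' multiplicative lognormal noise otherwise. During acclimation, product
#' concentrations ramp up logistically and a configurable share of the
#' monocarboxylates appears as odd-chain acids (propionic, pentanoic,
#' heptanoic), rising then falling - the odd/even split leaves the class
#' totals (SCFA, MCFA) unchanged. Total soluble COD respects the off-gas
#' fraction; residual carbohydrate follows the carbohydrate conversion
#' target. Deterministic under a fixed seed.
#'
#' @param config A `synthetic_reactor_config`.
#' @return A `reactor_series`.
#' @export
generate_reactor_series <- function(config = synthetic_reactor_config()) {
  stopifnot(inherits(config, "synthetic_reactor_config"))
  feeds <- if (inherits(config$feed, "feed_reference")) list(config$feed) else config$feed
  times <- seq(config$sampling_interval_days, config$duration_days,
               by = config$sampling_interval_days)
  tg <- config$targets
  cv <- config$noise_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  if (cv > 0) set.seed(config$seed)
  dummy <- reactor_series(
    data.frame(time_day = 0, compound = "total_soluble_cod", value = 0),
    feeds, config$srt, config$batch_switch_day
  )
  rows <- lapply(times, function(t) {
    feed <- .active_feed(dummy, t)
    fcod <- feed$total_soluble_cod
    r <- .acclimation_ramp(t, config$acclimation$duration_days)
    odd <- config$acclimation$odd_chain_peak_fraction *
      .odd_chain_shape(t, config$acclimation$duration_days)
    scfa <- tg$scfa_conversion * r * fcod
    mcfa <- tg$mcfa_conversion * r * fcod
    hr <- tg$hexanoate_octanoate_cod_ratio
    base <- c(
      acetic = (1 - odd) * tg$acetic_share_of_scfa * scfa,
      butyric = (1 - odd) * (1 - tg$acetic_share_of_scfa) * scfa,
      propionic = odd * scfa / 2,
      pentanoic = odd * scfa / 2,
      hexanoic = (1 - odd) * mcfa * hr / (1 + hr),
      octanoic = (1 - odd) * mcfa / (1 + hr),
      heptanoic = odd * mcfa,
      total_carbohydrate = (1 - tg$carbohydrate_conversion * r) *
        feed$total_carbohydrate,
      total_soluble_cod = (1 - config$offgas_fraction * r) * fcod
    )
    eps <- if (cv > 0) {
      stats::rlnorm(length(base), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, length(base))
    data.frame(time_day = t, compound = names(base),
               value = unname(base * eps), sd = unname(base * cv),
               stringsAsFactors = FALSE)
  })
  reactor_series(do.call(rbind, rows), feeds, config$srt,
                 config$batch_switch_day)
}

#' Write a reactor series or feed reference to long-format CSV
#'
#' Columns `time_day, compound, value, unit, sd` (feed files omit
#' `time_day`), values in the canonical mg COD/L.
#'
#' @param series A `reactor_series`.
#' @param feed A `feed_reference`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- series$samples
  df$unit <- "mg_COD_per_L"
  df <- df[, intersect(c("time_day", "compound", "value", "unit", "sd"),
                       names(df))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
write_feed_csv <- function(feed, path) {
  df <- feed$components
  df$unit <- "mg_COD_per_L"
  df <- rbind(
    df[, c("compound", "value", "unit")],
    data.frame(compound = c("total_soluble_cod", "total_carbohydrate"),
               value = c(feed$total_soluble_cod, feed$total_carbohydrate),
               unit = "mg_COD_per_L")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feed reference from long-format CSV
#'
#' Inverse of [write_feed_csv()]; rows named `total_soluble_cod` and
#' `total_carbohydrate` populate the totals.
#'
#' @param path CSV path.
#' @param batch_id Identifier for the loaded batch.
#' @param registry Compound registry for unit conversion.
#' @return A `feed_reference`.
#' @export
read_feed_csv <- function(path, batch_id = basename(path),
                          registry = compound_registry()) {
  df <- read_concentration_csv(path, registry)
  tot <- function(nm) {
    v <- df$value[df$compound == nm]
    if (length(v)) v else NA_real_
  }
  comp <- df[!df$compound %in% c("total_soluble_cod", "total_carbohydrate"), ,
             drop = FALSE]
  feed_reference(batch_id, comp[, intersect(c("compound", "value", "sd"),
                                            names(comp))],
                 total_soluble_cod = tot("total_soluble_cod"),
                 total_carbohydrate = tot("total_carbohydrate"))
}

#' Read a reactor series from long-format CSV
#'
#' @param path Series CSV (columns `time_day, compound, value, unit, sd`).
#' @param feeds A `feed_reference` or list of them.
#' @param srt Retention time, days.
#' @param batch_switch_day Feed transition day(s).
#' @param registry Compound registry for unit conversion.
#' @return A `reactor_series`.
#' @export
read_series_csv <- function(path, feeds, srt, batch_switch_day = 120,
                            registry = compound_registry()) {
  df <- read_concentration_csv(path, registry)
  if (!nrow(df)) stop("series file '", path, "' contains no samples")
  reactor_series(df, feeds, srt, batch_switch_day)
}
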