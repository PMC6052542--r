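#' Construct a feed reference
#'
#' A feed reference fixes the composition of the stillage (or hydrolysate)
#' batch against which reactor samples are compared. All component values are
#' in mg COD/L; the identified components need not sum to the total soluble
#' COD (the gap is the unknown COD pool).
#'
#' @param batch_id Identifier for the feed batch.
#' @param components data.frame with columns `compound` and `value`
#'   (mg COD/L); an optional `sd` column carries technical-replicate SDs.
#' @param total_soluble_cod Total soluble COD of the feed, mg COD/L.
#' @param total_carbohydrate Total carbohydrate (anthrone), mg COD/L.
#' @return An object of class `feed_reference`.
#' @export
feed_reference <- function(batch_id, components, total_soluble_cod,
                           total_carbohydrate = NA_real_) {
  stopifnot(is.data.frame(components),
            all(c("compound", "value") %in% names(components)))
  if (any(components$value < 0)) stop("component concentrations must be >= 0")
  if (total_soluble_cod <= 0) stop("total_soluble_cod must be positive")
  structure(list(batch_id = batch_id, components = components,
                 total_soluble_cod = total_soluble_cod,
                 total_carbohydrate = total_carbohydrate),
            class = "feed_reference")
}

#' Packaged stillage and hydrolysate compositions
#'
#' Reference compositions of the two switchgrass stillage batches and of the
#' hydrolysate before and after the ethanologenic yeast fermentation, as
#' characterized analytically (all values mg COD/L). These serve as feed
#' references for reactor metrics, as defaults for the synthetic generator,
#' and as inputs to [feed_characterization()].
#'
#' @return A `feed_reference`.
#' @export
stillage_batch1 <- function() {
  feed_reference(
    "stillage_batch_1",
    data.frame(
      compound = c("unknown", "xylose", "other_carbohydrates", "acetamide",
                   "glycerol", "acetic", "protein", "ethanol"),
      # unknown COD is by definition the measured total minus the COD of
      # identified components, so the composition closes exactly
      value = c(95400 - 54000, 20800, 19300, 4030, 3900, 2550, 2200, 1220),
      sd = c(3250, 148, 2310, 270, 32.1, 21.1, 145, 305)
    ),
    total_soluble_cod = 95400,
    total_carbohydrate = 20800 + 19300
  )
}

#' @rdname stillage_batch1
#' @export
stillage_batch2 <- function() {
  feed_reference(
    "stillage_batch_2",
    data.frame(
      compound = c("unknown", "xylose", "other_carbohydrates", "acetamide",
                   "glycerol", "acetic", "protein", "ethanol"),
      value = c(95800 - 50600, 20900, 15500, 4200, 3920, 2580, 1910, 1590),
      sd = c(3190, 168, 2230, 340, 36.3, 20.5, 162, 161)
    ),
    total_soluble_cod = 95800,
    total_carbohydrate = 20900 + 15500
  )
}

#' @rdname stillage_batch1
#' @export
hydrolysate_reference <- function() {
  feed_reference(
    "hydrolysate",
    data.frame(
      compound = c("glucose", "xylose", "glycerol", "acetic", "ethanol"),
      value = c(56000, 36000, 310, 2065, 0),
      sd = c(300, 230, 0.86, 30, NA)
    ),
    total_soluble_cod = 56000 + 36000 + 310 + 2065
  )
}

#' @rdname stillage_batch1
#' @export
fermented_hydrolysate_reference <- function() {
  feed_reference(
    "fermented_hydrolysate",
    data.frame(
      compound = c("glucose", "xylose", "glycerol", "acetic", "ethanol"),
      value = c(44, 19000, 2500, 1600, 51000),
      sd = c(1.7, 4500, 130, 68, 2900)
    ),
    total_soluble_cod = 160000
  )
}

#' Construct a reactor time series
#'
#' Bundles time-ordered concentration measurements with the feed reference(s)
#' active over the run and the solids retention time. The reactor is a
#' flow-through CSTR, so SRT equals HRT.
#'
#' @param samples Long-format data.frame with columns `time_day`, `compound`,
#'   `value` (mg COD/L) and optionally `sd`. Reserved compound names
#'   `total_soluble_cod` and `total_carbohydrate` carry the per-time totals.
#' @param feeds A single `feed_reference` or a list of them, applied in
#'   order; the active feed switches at `batch_switch_day`.
#' @param srt Solids retention time in days (> 0).
#' @param batch_switch_day Day(s) at which the feed switches to the next
#'   batch; length must be `length(feeds) - 1`.
#' @return An object of class `reactor_series`.
#' @export
reactor_series <- function(samples, feeds, srt, batch_switch_day = 120) {
  stopifnot(is.data.frame(samples),
            all(c("time_day", "compound", "value") %in% names(samples)))
  if (srt <= 0) stop("srt must be positive")
  if (inherits(feeds, "feed_reference")) feeds <- list(feeds)
  if (length(feeds) > 1 && length(batch_switch_day) != length(feeds) - 1) {
    stop("need one batch_switch_day per feed transition")
  }
  times <- sort(unique(samples$time_day))
  if (any(times < 0)) stop("sample times must be >= 0")
  structure(list(samples = samples, feeds = feeds, srt = srt,
                 batch_switch_day = batch_switch_day),
            class = "reactor_series")
}

# Feed reference active at a given time.
.active_feed <- function(series, time) {
  idx <- 1 + sum(time >= series$batch_switch_day[seq_len(length(series$feeds) - 1)])
  series$feeds[[idx]]
}

#' Read a reactor series (or feed) from CSV
#'
#' Long format with columns `time_day` (absent for a feed file), `compound`,
#' `value`, `unit` (`mg_per_L` or `mg_COD_per_L`) and optional `sd`. Raw-mass
#' values are converted to the canonical mg COD/L at ingestion using the
#' compound registry.
#'
#' @param path CSV file path.
#' @param registry Compound registry for unit conversion.
#' @return A data.frame in canonical mg COD/L units.
#' @export
read_concentration_csv <- function(path, registry = compound_registry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"unit" %in% names(df)) df$unit <- "mg_COD_per_L"
  bad <- setdiff(unique(df$unit), c("mg_per_L", "mg_COD_per_L"))
  if (length(bad)) stop("unknown unit(s): ", paste(bad, collapse = ", "))
  raw <- df$unit == "mg_per_L"
  if (any(raw)) {
    fac <- vapply(df$compound[raw], cod_factor, numeric(1), registry = registry)
    df$value[raw] <- df$value[raw] * fac
    if ("sd" %in% names(df)) df$sd[raw] <- df$sd[raw] * fac
    df$unit <- "mg_COD_per_L"
  }
  df
}

#' Per-time-point reactor performance metrics
#'
#' Computes, at each sampled time, the COD removal, carbohydrate conversion,
#' and conversion of feed COD to short- (C2-C5) and medium-chain (C6-C8)
#' fatty acids, plus the MCFA and odd-chain shares of total monocarboxylates.
#' Conversions divide gross product COD in the reactor by the total soluble
#' COD of the active feed batch; feed-borne acids are not subtracted unless
#' `net_of_feed = TRUE`. Negative values arising from measurement noise are
#' retained (no truncation) to keep window means unbiased.
#'
#' @param series A `reactor_series`.
#' @param net_of_feed If TRUE, feed concentrations of each acid are
#'   subtracted from reactor concentrations before computing conversions.
#' @param registry Compound registry for chain-length classification.
#' @return data.frame with columns `time_day`, `cod_removed`,
#'   `carbohydrate_conversion`, `scfa_conversion`, `mcfa_conversion`,
#'   `mcfa_share_of_acids`, `ocfa_fraction` (all percent).
#' @export
performance_metrics <- function(series, net_of_feed = FALSE,
                                registry = compound_registry()) {
  stopifnot(inherits(series, "reactor_series"))
  samples <- series$samples
  times <- sort(unique(samples$time_day))
  rows <- lapply(times, function(t) {
    feed <- .active_feed(series, t)
    if (feed$total_soluble_cod <= 0) {
      stop("feed total soluble COD is zero at day ", t, "; metrics undefined")
    }
    s <- samples[samples$time_day == t, , drop = FALSE]
    total <- s$value[s$compound == "total_soluble_cod"]
    carbs <- s$value[s$compound == "total_carbohydrate"]
    comp <- s[!s$compound %in% c("total_soluble_cod", "total_carbohydrate"), ,
              drop = FALSE]
    conc <- comp$value
    if (net_of_feed) {
      fv <- setNames(feed$components$value, feed$components$compound)
      conc <- conc - ifelse(is.na(fv[comp$compound]), 0, fv[comp$compound])
    }
    cls <- .compound_classes(comp$compound, registry)
    par <- .compound_parity(comp$compound, registry)
    scfa <- sum(conc[cls == "SCFA"])
    mcfa <- sum(conc[cls == "MCFA"])
    mono <- scfa + mcfa
    odd <- sum(conc[(cls %in% c("SCFA", "MCFA")) & par == "odd_chain"])
    data.frame(
      time_day = t,
      cod_removed = if (length(total)) {
        100 * (feed$total_soluble_cod - total) / feed$total_soluble_cod
      } else NA_real_,
      carbohydrate_conversion = if (length(carbs) && !is.na(feed$total_carbohydrate)) {
        100 * (feed$total_carbohydrate - carbs) / feed$total_carbohydrate
      } else NA_real_,
      scfa_conversion = 100 * scfa / feed$total_soluble_cod,
      mcfa_conversion = 100 * mcfa / feed$total_soluble_cod,
      mcfa_share_of_acids = if (mono > 0) 100 * mcfa / mono else NA_real_,
      ocfa_fraction = if (mono > 0) 100 * odd / mono else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Steady-state window summary of performance metrics
#'
#' Arithmetic mean and sample (n-1) standard deviation of each metric over
#' all records inside the window (inclusive bounds).
#'
#' @param records Output of [performance_metrics()].
#' @param window Numeric length-2: start and end day.
#' @return A list with `window`, `n`, and per-metric `mean` and `sd`
#'   named vectors.
#' @export
steady_state_summary <- function(records, window = c(30, 252)) {
  stopifnot(is.data.frame(records), length(window) == 2, window[1] < window[2])
  inside <- records$time_day >= window[1] & records$time_day <= window[2]
  if (sum(inside) < 2) {
    stop(sprintf(
      "fewer than 2 records in window [%g, %g]; available times span [%g, %g]",
      window[1], window[2], min(records$time_day), max(records$time_day)
    ))
  }
  sub <- records[inside, setdiff(names(records), "time_day"), drop = FALSE]
  list(window = window, n = sum(inside),
       mean = vapply(sub, function(x) mean(x, na.rm = TRUE), numeric(1)),
       sd = vapply(sub, function(x) stats::sd(x, na.rm = TRUE), numeric(1)))
}

#' Volumetric productivity and titer relative to solubility
#'
#' For a flow-through CSTR at steady state, the volumetric productivity of a
#' product equals its reactor concentration divided by the retention time.
#' Productivity is reported on a COD basis (g COD per L per day) - the only
#' basis under which the productivities, titers and aqueous solubilities of
#' hexanoic and octanoic acid are mutually consistent; the basis is carried
#' in the output. The titer fraction converts the mean COD titer to mass via
#' the compound's ThOD and divides by its aqueous solubility.
#'
#' @param series A `reactor_series`.
#' @param product Compound name (must be registered; needs a solubility for
#'   the titer fraction).
#' @param window Steady-state window in days.
#' @param registry Compound registry.
#' @return List with `productivity_g_cod_per_L_day`, `titer_g_cod_per_L`,
#'   `titer_g_per_L`, `titer_fraction_pct`, `basis = "COD"`.
#' @export
productivity_and_titer <- function(series, product, window = c(30, 252),
                                   registry = compound_registry()) {
  stopifnot(inherits(series, "reactor_series"))
  spec <- get_compound(product, registry)
  s <- series$samples
  inside <- s$compound == product & s$time_day >= window[1] & s$time_day <= window[2]
  conc_mg <- s$value[inside]
  if (!length(conc_mg)) stop("no measurements of ", product, " in window")
  titer_cod <- mean(conc_mg) / 1000            # g COD/L
  productivity <- titer_cod / series$srt       # g COD/L/day
  titer_mass <- titer_cod / spec$thod          # g/L
  frac <- if (is.na(spec$solubility_g_per_L)) {
    warning("no solubility registered for ", product, "; titer fraction omitted")
    NA_real_
  } else {
    100 * titer_mass / spec$solubility_g_per_L
  }
  list(productivity_g_cod_per_L_day = productivity,
       titer_g_cod_per_L = titer_cod, titer_g_per_L = titer_mass,
       titer_fraction_pct = frac, basis = "COD")
}

#' Titer fraction implied by a volumetric productivity
#'
#' Inverts the CSTR steady-state relation: a productivity P (g COD/L/day)
#' sustained at retention time SRT implies a titer of P*SRT g COD/L, i.e.
#' P*SRT/ThOD g/L of product mass, reported as a percent of the compound's
#' aqueous solubility.
#'
#' @param productivity Volumetric productivity in g COD per L per day.
#' @param srt Retention time in days.
#' @param product Compound name with registered solubility.
#' @param registry Compound registry.
#' @return Titer as percent of aqueous solubility.
#' @export
titer_fraction_from_productivity <- function(productivity, srt, product,
                                             registry = compound_registry()) {
  spec <- get_compound(product, registry)
  if (is.na(spec$solubility_g_per_L)) stop("no solubility registered for ", product)
  100 * productivity * srt / (spec$thod * spec$solubility_g_per_L)
}

#' Characterize the ethanol-fermentation and distillation steps
#'
#' Compares the hydrolysate before and after the ethanologenic fermentation
#' and the resulting stillage: percent of each sugar consumed, the fraction
#' of fermented-hydrolysate COD retained in stillage after distillation, and
#' the residual ethanol carried into stillage.
#'
#' @param hydrolysate,fermented `feed_reference` objects for the hydrolysate
#'   before and after yeast fermentation.
#' @param stillage A `feed_reference` or list of them (multiple batches are
#'   averaged).
#' @return List with `glucose_consumed_pct`, `xylose_consumed_pct`,
#'   `stillage_cod_fraction_pct`, `residual_ethanol_pct`.
#' @export
feed_characterization <- function(hydrolysate = hydrolysate_reference(),
                                  fermented = fermented_hydrolysate_reference(),
                                  stillage = list(stillage_batch1(), stillage_batch2())) {
  if (inherits(stillage, "feed_reference")) stillage <- list(stillage)
  getc <- function(ref, nm) {
    v <- ref$components$value[ref$components$compound == nm]
    if (!length(v)) {
      warning("component '", nm, "' missing from ", ref$batch_id)
      return(NA_real_)
    }
    v
  }
  consumed <- function(nm) {
    before <- getc(hydrolysate, nm); after <- getc(fermented, nm)
    100 * (before - after) / before
  }
  still_cod <- mean(vapply(stillage, function(s) s$total_soluble_cod, numeric(1)))
  still_etoh <- mean(vapply(stillage, getc, numeric(1), nm = "ethanol"))
  list(
    glucose_consumed_pct = consumed("glucose"),
    xylose_consumed_pct = consumed("xylose"),
    stillage_cod_fraction_pct = 100 * still_cod / fermented$total_soluble_cod,
    residual_ethanol_pct = 100 * still_etoh / getc(fermented, "ethanol")
  )
}
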