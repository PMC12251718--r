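# Seeded generator of per-subject coupled CGM + 4 Hz skin-temperature
# recordings with ground-truth labels. Glucose is a label-generating
# process (baseline + meal excursions + hypoglycemic episodes + AR(1)
# noise), not a metabolic simulation. Temperature is a circadian two-level
# profile (distal skin temperature rises at night) plus AR(1) noise whose
# innovation SD can be coupled to below-range episodes (cv_effect), with a
# level shift during daytime hyperglycemia and a slow drift during
# nighttime hyperglycemia. Defects (sub-28 degC artifact runs, single
# outlier spikes at local mean + 6 SD, missing segments) are injected into
# disjoint window sets and recorded in a ground-truth sidecar.

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of an 8-10 day free-living monitoring
#' campaign in subjects at risk of diabetes: 9 days, 5-min CGM cadence,
#' 4 Hz temperature, about 3% missing CGM samples and 5% missing
#' temperature, a minority of subjects (6 of 15) experiencing hypoglycemic
#' episodes, and wrist skin temperature around 31.5 degC by day rising to
#' 33.5 degC at night.
#'
#' The circadian level switch is aligned to the backward 5-minute analysis
#' windows: a sample takes the day/night level of the window it terminates,
#' so each labeled window holds samples of a single circadian phase. Set
#' `circadian_offset_min` to a nonzero value to misalign the switch for
#' robustness checks.
#'
#' @param n_subjects,days Cohort size and monitoring span (days).
#' @param cgm_period_s,temp_hz Sampling cadences of the two streams.
#' @param start_time Recording start (local clock), midnight-aligned by
#'   default so CGM timestamps fall on the wall-clock 5-minute grid.
#' @param glucose_baseline,glucose_baseline_sd Cohort mean and
#'   between-subject SD of baseline glucose, mg/dL.
#' @param glucose_noise_sd,glucose_noise_phi Stationary SD and lag-1
#'   autocorrelation of the CGM noise process.
#' @param meal_times_h,meal_time_jitter_h,meal_amp_mean,meal_amp_sd,meal_width_min
#'   Daily meal-excursion timing (hours; the default includes a late
#'   evening snack so hyperglycemia occurs in both periods), timing jitter
#'   SD, amplitude mean and SD (mg/dL; amplitudes large enough to cross
#'   140 regularly) and Gaussian width (minutes).
#' @param hypo_subjects Number of subjects assigned hypoglycemic episodes.
#' @param hypo_rate_per_day,hypo_duration_min,hypo_nadir_mg_dl,hypo_hours
#'   Episode rate, mean duration, mean nadir, and allowed start-hour window.
#' @param day_level_c,night_level_c Day/night skin-temperature levels,
#'   degC; night must exceed day (distal circadian rise at sleep).
#' @param subject_level_sd Between-subject SD of the temperature level.
#' @param ar_phi,ar_innovation_sd AR(1) coefficient and innovation SD of
#'   the 4 Hz temperature noise (slow dynamics).
#' @param daytime_hours,circadian_offset_min Circadian switch hours and
#'   optional misalignment (minutes).
#' @param artifact_rate,outlier_rate Fractions of analysis windows driven
#'   below 28 degC / given a single spike at local mean + 6 SD.
#' @param temp_missing_pct,cgm_missing_pct Percent of windows with deleted
#'   temperature chunks / percent of CGM samples made missing.
#' @param cgm_missing_value_frac Fraction of missing CGM samples emitted as
#'   rows with an empty value cell (the rest are dropped rows).
#' @param cv_effect Multiplier on the temperature innovation SD during
#'   below-range (BR) samples; 1 disables the coupling.
#' @param level_effect_day_c Temperature shift (degC) during daytime
#'   above-range (AR) samples; 0 disables.
#' @param retro_effect_c_per_h Slow drift (degC/hour) during contiguous
#'   nighttime AR runs; 0 disables.
#' @param iid_glucose If TRUE, glucose samples are drawn serially
#'   independent from N(`iid_glucose_mean`, `iid_glucose_sd`) instead of
#'   the baseline + meals + episodes process. This makes the glycemic
#'   label sequence exchangeable within (and across) periods, the
#'   null-calibration regime under which rank tests on the running
#'   retrospective metrics are exactly valid; see the methods vignette.
#' @param iid_glucose_mean,iid_glucose_sd Mean and SD (mg/dL) of the
#'   serially independent glucose mode.
#' @param seed Integer seed; fixing it makes the cohort (including file
#'   bytes) fully reproducible.
#' @return A named list of class `tg_synth_config`.
#' @export
tg_synth_config <- function(n_subjects = 15, days = 9,
                            cgm_period_s = 300, temp_hz = 4,
                            start_time = "2024-03-01 00:00:00",
                            glucose_baseline = 100, glucose_baseline_sd = 8,
                            glucose_noise_sd = 6, glucose_noise_phi = 0.8,
                            meal_times_h = c(7.5, 12.5, 19, 22.5),
                            meal_time_jitter_h = 0.75,
                            meal_amp_mean = 40, meal_amp_sd = 15,
                            meal_width_min = 40,
                            hypo_subjects = 6,
                            hypo_rate_per_day = 0.8,
                            hypo_duration_min = 40,
                            hypo_nadir_mg_dl = 60,
                            hypo_hours = c(0, 24),
                            day_level_c = 31.5, night_level_c = 33.5,
                            subject_level_sd = 0.3,
                            ar_phi = 0.97, ar_innovation_sd = 0.03,
                            daytime_hours = c(6, 21),
                            circadian_offset_min = 0,
                            artifact_rate = 0.06, outlier_rate = 0.02,
                            temp_missing_pct = 5, cgm_missing_pct = 3,
                            cgm_missing_value_frac = 0.5,
                            cv_effect = 3, level_effect_day_c = 0.3,
                            retro_effect_c_per_h = 0.15,
                            iid_glucose = FALSE,
                            iid_glucose_mean = 110, iid_glucose_sd = 25,
                            seed = NULL) {
  stopifnot(night_level_c > day_level_c,
            artifact_rate >= 0, artifact_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            temp_missing_pct >= 0, temp_missing_pct <= 100,
            cgm_missing_pct >= 0, cgm_missing_pct <= 100,
            cgm_missing_value_frac >= 0, cgm_missing_value_frac <= 1,
            hypo_subjects <= n_subjects,
            abs(ar_phi) < 1, cv_effect > 0)
  cfg <- as.list(environment())
  cfg$start_time <- as.POSIXct(start_time, tz = TG_TZ)
  class(cfg) <- "tg_synth_config"
  cfg
}

ar1_noise <- function(n, phi, inno_sd) {
  # inno_sd: scalar or per-sample vector; starts at the stationary law
  init <- rnorm(1, 0, inno_sd[1] / sqrt(1 - phi^2))
  as.numeric(filter(rnorm(n) * inno_sd, phi, method = "recursive", init = init))
}

#' Generate one subject's CGM trace with ground-truth labels
#'
#' @param cfg A [tg_synth_config()] list.
#' @param subject_id Identifier written into the trace.
#' @param hypo_subject Whether this subject experiences hypoglycemic
#'   episodes.
#' @return A list with `trace` (a `cgm_trace`, missing rows dropped or
#'   blanked per config), `grid` (full-grid ground truth: `time`,
#'   `glucose`, `range`, `cgm_missing`, `in_episode`) and `episodes`.
#' @export
generate_cgm <- function(cfg, subject_id = "S01", hypo_subject = FALSE) {
  n <- as.integer(cfg$days * 86400 / cfg$cgm_period_s) + 1L
  tsec <- cfg$cgm_period_s * (0:(n - 1L))
  th <- tsec / 3600
  times <- cfg$start_time + tsec
  in_episode <- rep(FALSE, n)
  episodes <- data.frame(start = as.POSIXct(character(), tz = TG_TZ),
                         end = as.POSIXct(character(), tz = TG_TZ),
                         nadir = numeric())
  if (cfg$iid_glucose) {
    g <- pmax(round(rnorm(n, cfg$iid_glucose_mean, cfg$iid_glucose_sd)), 45)
    return(finish_cgm(cfg, g, times, in_episode, episodes, subject_id, n))
  }
  g <- cfg$glucose_baseline + rnorm(1, 0, cfg$glucose_baseline_sd)
  g <- rep(g, n)
  for (d in 0:(cfg$days - 1)) {
    for (mt in cfg$meal_times_h) {
      center <- d * 24 + mt + rnorm(1, 0, cfg$meal_time_jitter_h)
      amp <- max(rnorm(1, cfg$meal_amp_mean, cfg$meal_amp_sd), 0)
      g <- g + amp * exp(-0.5 * ((th - center) / (cfg$meal_width_min / 60))^2)
    }
  }
  g <- g + ar1_noise(n, cfg$glucose_noise_phi,
                     cfg$glucose_noise_sd * sqrt(1 - cfg$glucose_noise_phi^2))
  # keep glycemia at or above the tight range unless an episode drives it
  g <- pmax(g, 72)
  if (hypo_subject) {
    n_ep <- rpois(1, cfg$hypo_rate_per_day * cfg$days)
    for (e in seq_len(n_ep)) {
      d <- sample.int(cfg$days, 1) - 1
      center <- d * 24 + runif(1, cfg$hypo_hours[1], cfg$hypo_hours[2])
      dur_h <- max(rnorm(1, cfg$hypo_duration_min, 10), 20) / 60
      nadir <- min(max(rnorm(1, cfg$hypo_nadir_mg_dl, 4), 50), 67)
      f <- exp(-((th - center) / (dur_h / 2))^4)   # flat-top depression
      g <- g - (g - nadir) * f
      in_episode <- in_episode | f > 0.5
      episodes <- rbind(episodes,
                        data.frame(start = cfg$start_time + (center - dur_h / 2) * 3600,
                                   end = cfg$start_time + (center + dur_h / 2) * 3600,
                                   nadir = nadir))
    }
  }
  g <- pmax(round(g), 45)
  finish_cgm(cfg, g, times, in_episode, episodes, subject_id, n)
}

# label the final glucose values, apply block missingness, build the trace
finish_cgm <- function(cfg, g, times, in_episode, episodes, subject_id, n) {
  range_lab <- classify_glycemia(g)
  n_miss <- round(cfg$cgm_missing_pct / 100 * n)
  missing <- rep("none", n)
  miss_idx <- integer()
  while (length(miss_idx) < n_miss) {
    len <- 1 + rpois(1, 4)
    s <- sample.int(n, 1)
    miss_idx <- unique(c(miss_idx, seq(s, min(s + len - 1, n))))
  }
  miss_idx <- head(miss_idx, n_miss)
  if (length(miss_idx)) {
    as_value <- runif(length(miss_idx)) < cfg$cgm_missing_value_frac
    missing[miss_idx[as_value]] <- "value"
    missing[miss_idx[!as_value]] <- "row"
  }
  grid <- data.frame(time = times, glucose = g, range = range_lab,
                     cgm_missing = missing, in_episode = in_episode)
  keep <- missing != "row"
  val <- ifelse(missing == "value", NA_real_, g)[keep]
  trace <- new_trace(times[keep], val, "glucose", subject_id, "cgm_trace")
  list(trace = trace, grid = grid, episodes = episodes)
}

# ceiling division to the 5-min analysis-window grid, in integer quarter
# seconds relative to the recording start (exact; no floating point)
ceil_to_window <- function(q, wq) -((-q) %/% wq) * wq

# The sample grid (timestamps, window membership, circadian phase) is a
# pure function of the span and cadences; memoize it, since every subject
# of a cohort shares it.
.grid_cache <- new.env(parent = emptyenv())

temp_grid <- function(cfg, n_cgm) {
  key <- paste(n_cgm, cfg$cgm_period_s, cfg$temp_hz, cfg$daytime_hours[1],
               cfg$daytime_hours[2], cfg$circadian_offset_min,
               cfg$day_level_c, cfg$night_level_c,
               as.numeric(cfg$start_time), sep = "|")
  g <- .grid_cache[[key]]
  if (!is.null(g)) return(g)
  qpw <- as.integer(cfg$cgm_period_s * cfg$temp_hz)
  n_t <- n_cgm * qpw
  q <- seq_len(n_t) - qpw                  # quarter-sec index; first = 1 - qpw
  wq <- ceil_to_window(q, qpw)             # window-end index (quarters)
  we_clock <- ((wq / cfg$temp_hz) + cfg$circadian_offset_min * 60) %% 86400
  h_end <- we_clock / 3600
  day_phase <- h_end >= cfg$daytime_hours[1] & h_end < cfg$daytime_hours[2]
  g <- list(qpw = qpw, n_t = n_t,
            tnum = as.numeric(cfg$start_time) + q / cfg$temp_hz,
            win_j = wq %/% qpw + 1L,       # 1-based CGM grid row
            day_phase = day_phase,
            level_base = c(cfg$night_level_c, cfg$day_level_c)[day_phase + 1L])
  .grid_cache[[key]] <- g
  g
}

#' Generate one subject's 4 Hz temperature trace coupled to a CGM truth
#'
#' The stream starts one full window before the first CGM sample so every
#' CGM timestamp can own a complete backward window. Coupling, defect
#' injection and deletions follow the configuration; defect windows are
#' disjoint by construction and recorded per CGM timestamp.
#'
#' @param cfg A [tg_synth_config()] list.
#' @param cgm Output of [generate_cgm()] for the same subject.
#' @param subject_id Identifier written into the trace.
#' @return A list with `trace` (a `temp_trace`) and `defects` (per CGM
#'   timestamp: `none`, `missing_temp`, `artifact` or `outlier`).
#' @export
generate_temperature <- function(cfg, cgm, subject_id = "S01") {
  n_cgm <- nrow(cgm$grid)
  grid <- temp_grid(cfg, n_cgm)
  qpw <- grid$qpw; n_t <- grid$n_t
  tnum <- grid$tnum; win_j <- grid$win_j; day_phase <- grid$day_phase
  level <- grid$level_base + rnorm(1, 0, cfg$subject_level_sd)
  inno <- cfg$ar_innovation_sd
  if (cfg$cv_effect != 1 || cfg$level_effect_day_c != 0) {
    lab <- as.character(cgm$grid$range)[win_j]
    if (cfg$cv_effect != 1) {
      inno <- rep(cfg$ar_innovation_sd, n_t)
      br <- lab == "BR"
      inno[br] <- inno[br] * cfg$cv_effect
    }
    if (cfg$level_effect_day_c != 0) {
      ard <- lab == "AR" & day_phase
      level[ard] <- level[ard] + cfg$level_effect_day_c
    }
  }
  if (cfg$retro_effect_c_per_h != 0) {
    arn <- cgm$grid$range == "AR" &
      classify_period(cgm$grid$time, cfg$daytime_hours) == "nighttime"
    r <- rle(as.vector(arn))
    pos <- sequence(r$lengths) - 1L            # window index within each run
    drift_w <- ifelse(rep(r$values, r$lengths),
                      pos * cfg$cgm_period_s / 3600 * cfg$retro_effect_c_per_h, 0)
    level <- level + drift_w[win_j]
  }
  x <- .ar1_temp_cpp(level, cfg$ar_phi, inno)   # rounded to device precision

  # defect injection on disjoint window sets (grid rows)
  defects <- rep("none", n_cgm)
  avail <- seq_len(n_cgm)
  pick <- function(k) {
    k <- min(k, length(avail))
    idx <- if (k > 0) sort(avail[sample.int(length(avail), k)]) else integer()
    avail <<- setdiff(avail, idx)
    idx
  }
  art_w <- pick(round(cfg$artifact_rate * n_cgm))
  out_w <- pick(round(cfg$outlier_rate * n_cgm))
  mis_w <- pick(round(cfg$temp_missing_pct / 100 * n_cgm))
  defects[art_w] <- "artifact"
  defects[out_w] <- "outlier"
  defects[mis_w] <- "missing_temp"
  # window j (1-based grid row) covers sample rows (j-1)*qpw + 1 .. j*qpw
  win_rows <- function(j) ((j - 1L) * qpw + 1L):(j * qpw)
  in_artifact <- rep(FALSE, n_t)
  for (j in art_w) {
    rows <- win_rows(j)
    len <- sample(20:200, 1)
    s <- sample(length(rows) - len + 1, 1)
    sel <- rows[s:(s + len - 1)]
    x[sel] <- round(28 - runif(len, 1, 2.5), 2)   # forced below the artifact floor
    in_artifact[rows] <- TRUE
  }
  if (length(art_w)) {
    # guarantee non-artifact windows never dip below the floor
    x[!in_artifact] <- pmax(x[!in_artifact], 28)
  }
  for (j in out_w) {
    rows <- win_rows(j)
    w <- x[rows]
    s <- sd(w)
    x[rows[sample.int(length(rows), 1)]] <- round(mean(w) + 6 * max(s, 0.02), 2)
  }
  if (length(mis_w)) {
    keep <- rep(TRUE, n_t)
    for (j in mis_w) {
      rows <- win_rows(j)
      len <- sample(40:qpw, 1)
      s <- sample(length(rows) - len + 1, 1)
      keep[rows[s:(s + len - 1)]] <- FALSE
    }
    tnum <- tnum[keep]; x <- x[keep]
  }
  trace <- new_trace(.POSIXct(tnum, tz = TG_TZ),
                     x, "temperature", subject_id, "temp_trace")
  list(trace = trace,
       defects = data.frame(time = cgm$grid$time, defect = defects))
}

#' Generate a full synthetic cohort
#'
#' Draws the hypoglycemia-prone subject subset, generates every subject's
#' coupled trace pair and, when `out_dir` is given, writes per-subject
#' folders in the deposit dialect (`Dexcom.csv`, `TEMP.csv`) together with
#' ground-truth sidecars (`ground_truth.csv`, `episodes.csv`). With a
#' fixed `cfg$seed` the output — including file bytes — is fully
#' deterministic.
#'
#' @param cfg A [tg_synth_config()] list.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list of per-subject lists (`cgm`, `temp`, `truth`)
#'   with attribute `hypo_subjects`.
#' @export
generate_cohort <- function(cfg = tg_synth_config(), out_dir = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  hypo <- sort(sample.int(cfg$n_subjects, cfg$hypo_subjects))
  subjects <- vector("list", cfg$n_subjects)
  names(subjects) <- ids
  for (i in seq_len(cfg$n_subjects)) {
    subjects[[i]] <- generate_subject(cfg, ids[i], i %in% hypo)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
    for (i in seq_len(cfg$n_subjects)) {
      sdir <- file.path(out_dir, ids[i])
      dir.create(sdir, showWarnings = FALSE)
      write_trace_csv(subjects[[i]]$cgm, file.path(sdir, "Dexcom.csv"))
      write_trace_csv(subjects[[i]]$temp, file.path(sdir, "TEMP.csv"))
      truth <- subjects[[i]]$truth
      gt <- truth$grid
      gt$defect <- truth$defects$defect
      gt$time <- format(gt$time, "%Y-%m-%d %H:%M:%S", tz = TG_TZ)
      write.csv(gt, file.path(sdir, "ground_truth.csv"), row.names = FALSE,
                quote = FALSE)
      ep <- truth$episodes
      ep$start <- format(ep$start, "%Y-%m-%d %H:%M:%S", tz = TG_TZ)
      ep$end <- format(ep$end, "%Y-%m-%d %H:%M:%S", tz = TG_TZ)
      write.csv(ep, file.path(sdir, "episodes.csv"), row.names = FALSE,
                quote = FALSE)
    }
  }
  attr(subjects, "hypo_subjects") <- ids[hypo]
  invisible(subjects)
}

#' Generate one subject (both traces plus ground truth)
#'
#' @inheritParams generate_cgm
#' @return A list with `cgm` (`cgm_trace`), `temp` (`temp_trace`) and
#'   `truth` (`grid`, `episodes`, `defects`).
#' @export
generate_subject <- function(cfg, subject_id = "S01", hypo_subject = FALSE) {
  cg <- generate_cgm(cfg, subject_id, hypo_subject)
  tp <- generate_temperature(cfg, cg, subject_id)
  list(cgm = cg$trace, temp = tp$trace,
       truth = list(grid = cg$grid, episodes = cg$episodes,
                    defects = tp$defects))
}
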