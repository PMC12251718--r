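#' Analysis configuration
#'
#' Builds the configuration list consumed by the preprocessing, metrics,
#' stratification and statistics stages. Defaults follow the reference
#' analysis settings: 5-minute backward windows at 4 Hz (N = 1200 samples),
#' a 28 degree Celsius artifact floor, a mean +/- 5 SD within-window outlier
#' rule, subject exclusion above 20% missing CGM samples, the 70-140 mg/dL
#' tight range, and a 06:00-21:00 daytime period.
#'
#' @param artifact_floor_c Artifact threshold in degrees Celsius; any window
#'   containing a sample strictly below it is discarded.
#' @param outlier_sd_multiplier Multiplier k of the within-window SD; a
#'   window containing a sample strictly outside mean +/- k*SD is discarded.
#' @param cgm_missing_exclusion_pct Subjects with a strictly greater
#'   percentage of missing CGM samples are excluded.
#' @param window_seconds Window length in seconds (backward from each CGM
#'   timestamp).
#' @param temp_hz Nominal temperature sampling rate in Hz.
#' @param tight_range_mg_dl Length-2 numeric, inclusive bounds of the
#'   in-range (IR) glycemic interval in mg/dL.
#' @param daytime_hours Length-2 numeric, daytime is the half-open clock
#'   interval [first, second) in hours.
#' @param m_refs_c Length-2 numeric, reference temperatures (degrees
#'   Celsius) for the two M-value adaptations (maximal and mean skin
#'   temperature references).
#' @param m_value_form `"cubed_abs"` computes mean(|10*log10(x/r)|^3) per
#'   window (the M-value convention from the glycemic literature);
#'   `"literal"` computes mean(|10*log10((x/r)^3)|) = 30*mean(|log10(x/r)|),
#'   available for sensitivity checks.
#' @param sd_denominator `"sample"` (n-1) or `"population"` (n) for the
#'   within-window SD used in screening and in SD_T.
#' @param reset_daily If TRUE, the retrospective running metrics restart at
#'   each calendar-day boundary instead of spanning the whole recording.
#' @param min_group_size Smallest group size at which a Wilcoxon comparison
#'   is attempted (4 is the smallest size at which a two-sided exact
#'   rank-sum test can reach p < 0.05).
#' @param fdr_scope `"per_cell"` corrects across the metric family within
#'   each (subject, contrast, period) cell; `"pooled_periods"` pools the
#'   day and night p-values of a (subject, contrast) pair.
#' @param sqrt_transform If TRUE the cohort mixed-effects models are fitted
#'   on square-root-transformed metric values (variance roughly
#'   proportional to the mean for most of these metrics).
#' @return A named list of class `tg_config`.
#' @export
#' @examples
#' cfg <- tg_config()
#' cfg$window_seconds * cfg$temp_hz   # samples per full window
tg_config <- function(artifact_floor_c = 28,
                      outlier_sd_multiplier = 5,
                      cgm_missing_exclusion_pct = 20,
                      window_seconds = 300,
                      temp_hz = 4,
                      tight_range_mg_dl = c(70, 140),
                      daytime_hours = c(6, 21),
                      m_refs_c = c(36, 32),
                      m_value_form = c("cubed_abs", "literal"),
                      sd_denominator = c("sample", "population"),
                      reset_daily = FALSE,
                      min_group_size = 4,
                      fdr_scope = c("per_cell", "pooled_periods"),
                      sqrt_transform = TRUE) {
  stopifnot(length(tight_range_mg_dl) == 2, tight_range_mg_dl[1] < tight_range_mg_dl[2],
            length(daytime_hours) == 2, length(m_refs_c) == 2,
            window_seconds > 0, temp_hz > 0,
            cgm_missing_exclusion_pct > 0, cgm_missing_exclusion_pct <= 100,
            min_group_size >= 2)
  cfg <- list(
    artifact_floor_c = artifact_floor_c,
    outlier_sd_multiplier = outlier_sd_multiplier,
    cgm_missing_exclusion_pct = cgm_missing_exclusion_pct,
    window_seconds = window_seconds,
    temp_hz = temp_hz,
    samples_per_window = as.integer(round(window_seconds * temp_hz)),
    tight_range_mg_dl = tight_range_mg_dl,
    daytime_hours = daytime_hours,
    m_refs_c = m_refs_c,
    m_value_form = match.arg(m_value_form),
    sd_denominator = match.arg(sd_denominator),
    reset_daily = isTRUE(reset_daily),
    min_group_size = min_group_size,
    fdr_scope = match.arg(fdr_scope),
    sqrt_transform = isTRUE(sqrt_transform)
  )
  class(cfg) <- "tg_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their [tg_config()] defaults; unknown keys
#' are rejected.
#'
#' @param path Path to a YAML file whose keys match [tg_config()] arguments.
#' @return A `tg_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(tg_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(tg_config, raw)
}
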