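#' Round half away from zero to an integer
#'
#' Reported day counts use conventional half-up rounding (94.5 days -> 95)
#' rather than banker's rounding.
#'
#' @param x Numeric.
#' @return Rounded values.
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Load the packaged subject treatment table
#'
#' Series-1 exposure, time to tumor progression and survival for the four
#' trial subjects, transcribed from the published treatment table.
#' A002's off-protocol retreatment (series 2/3) is carried in separate
#' `*_s23` columns and never enters the series-1 cohort summaries.
#'
#' @param path Optional CSV path; defaults to the packaged fixture.
#' @return `data.frame` of subject records.
#' @export
load_subject_records <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trial_treatment.csv",
                        package = "allovax", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "inoculations", "days_on_treatment",
            "ttp_days", "survival_months")
  if (!all(need %in% names(df)))
    stop("subject table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  num <- c("inoculations", "days_on_treatment", "ttp_days",
           "survival_months")
  if (any(df[num] < 0, na.rm = TRUE))
    stop("counts and durations must be non-negative", call. = FALSE)
  df
}

#' Load the packaged baseline/demography table
#' @param path Optional CSV path; defaults to the packaged fixture.
#' @return `data.frame` with at least `subject_id`, `age_years`, `ecog`.
#' @export
load_baseline_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trial_baseline.csv",
                        package = "allovax", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load the packaged adverse-event table
#' @param path Optional CSV path; defaults to the packaged fixture.
#' @return `data.frame` with `term`, `n_patients`, `grade_range`.
#' @export
load_adverse_events <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trial_adverse_events.csv",
                        package = "allovax", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(grade_range = "character"))
  stopifnot(all(c("term", "n_patients", "grade_range") %in% names(df)),
            all(df$n_patients >= 1))
  df
}

.median_summary <- function(x, unit) {
  stopifnot(length(x) >= 1L, !anyNA(x))
  m <- median(x)
  list(median = m, median_rounded = round_half_up(m),
       range = range(x), unit = unit)
}

#' Summarize series-1 treatment exposure
#'
#' Median and range of inoculation counts and days on treatment. Medians
#' over an even number of subjects are the mean of the central pair,
#' reported both raw and rounded half-up to integer days.
#'
#' @param records Subject records (see [load_subject_records()]).
#' @return List with `inoculations` and `days_on_treatment`, each holding
#'   `median`, `median_rounded`, `range`.
#' @export
summarize_exposure <- function(records) {
  if (!nrow(records)) stop("no subject records", call. = FALSE)
  list(inoculations = .median_summary(records$inoculations, "count"),
       days_on_treatment = .median_summary(records$days_on_treatment,
                                           "days"))
}

#' Summarize series-1 time to tumor progression
#'
#' @param records Subject records.
#' @return `median`, `median_rounded`, `range`, in days.
#' @export
summarize_ttp <- function(records) {
  if (!nrow(records)) stop("no subject records", call. = FALSE)
  .median_summary(records$ttp_days, "days")
}

#' Count subjects surviving beyond a threshold
#'
#' Strict inequality, matching statements of the form "overall survival
#' was more than 33 months".
#'
#' @param records Subject records.
#' @param threshold_months Threshold in months (non-negative).
#' @return Integer count.
#' @export
survival_exceeding <- function(records, threshold_months) {
  stopifnot(threshold_months >= 0)
  sum(records$survival_months > threshold_months)
}

#' Tally adverse events
#'
#' Each term counts once per affected patient; repeat observations of the
#' same event in the same patient are added on top.
#'
#' @param records Adverse-event records (see [load_adverse_events()]).
#' @param repeat_observations Number of repeat observations (>= 0).
#' @return List with `distinct_term_patient_pairs` and `total_events`.
#' @export
tally_adverse_events <- function(records, repeat_observations = 0L) {
  stopifnot(repeat_observations >= 0)
  s <- if (nrow(records)) sum(records$n_patients) else 0L
  list(distinct_term_patient_pairs = s,
       total_events = s + repeat_observations)
}

#' Largest skin-test reaction per subject, visit and measure
#'
#' Delayed-type hypersensitivity readings are taken at four inoculation
#' sites; the largest diameter per visit is the reported reaction,
#' separately for erythema and induration.
#'
#' @param measurements `data.frame` with `subject_id`, `visit`, `site`,
#'   `erythema_diameter`, `induration_diameter` (mm, non-negative).
#' @return `data.frame` with one row per subject x visit and columns
#'   `max_erythema`, `max_induration`.
#' @export
max_reaction_per_visit <- function(measurements) {
  need <- c("subject_id", "visit", "erythema_diameter",
            "induration_diameter")
  stopifnot(all(need %in% names(measurements)), nrow(measurements) >= 1L,
            all(measurements$erythema_diameter >= 0),
            all(measurements$induration_diameter >= 0))
  agg <- aggregate(cbind(max_erythema = erythema_diameter,
                         max_induration = induration_diameter) ~
                     subject_id + visit,
                   data = measurements, FUN = max)
  agg[order(agg$subject_id, agg$visit), , drop = FALSE]
}

#' Percent change in serum IgG binding (MFI) relative to baseline
#'
#' \eqn{100 (MFI - MFI_{baseline})/MFI_{baseline}}; the two samples must
#' be from the same subject at the same serum dilution.
#'
#' @param sample,baseline Lists (or one-row data frames) with
#'   `subject_id`, `dilution`, `mfi`.
#' @return Percent change (negative = decline).
#' @export
percent_change_mfi <- function(sample, baseline) {
  if (!identical(sample$subject_id, baseline$subject_id))
    stop("sample and baseline are from different subjects", call. = FALSE)
  if (!identical(sample$dilution, baseline$dilution))
    stop("sample and baseline use different serum dilutions",
         call. = FALSE)
  if (baseline$mfi <= 0)
    stop("baseline MFI must be positive", call. = FALSE)
  100 * (sample$mfi - baseline$mfi) / baseline$mfi
}

#' Relative expression from qRT-PCR threshold cycles
#'
#' Delta-delta-Ct quantification against a reference gene (e.g. ACTB) and
#' a calibrator sample:
#' \eqn{\Delta\Delta Ct = (Ct_{target} - Ct_{ref})_{sample} -
#'      (Ct_{target} - Ct_{ref})_{calibrator}},
#' fold change \eqn{2^{-\Delta\Delta Ct}}, percent = 100 x fold.
#'
#' @param sample,calibrator Lists with `ct_target` and `ct_ref`.
#' @return List with `ddct`, `fold`, `percent_of_calibrator`.
#' @export
qpcr_relative_expression <- function(sample, calibrator) {
  cts <- c(sample$ct_target, sample$ct_ref, calibrator$ct_target,
           calibrator$ct_ref)
  if (length(cts) != 4L || anyNA(cts))
    stop("all four Ct values must be present", call. = FALSE)
  stopifnot(all(cts > 0))
  ddct <- (sample$ct_target - sample$ct_ref) -
    (calibrator$ct_target - calibrator$ct_ref)
  fold <- 2^(-ddct)
  list(ddct = ddct, fold = fold, percent_of_calibrator = 100 * fold)
}

#' Full clinical summary
#'
#' Bundles exposure, time to progression, survival, adverse-event and
#' baseline summaries into one list (serializable to JSON).
#'
#' @param subjects Subject records (default: packaged fixture).
#' @param baseline Baseline table (default: packaged fixture).
#' @param adverse_events Adverse-event table (default: packaged fixture).
#' @param repeat_observations Repeat AE observations, default 3.
#' @param survival_threshold_months Survival threshold, default 33.
#' @return Nested list of summary statistics.
#' @export
clinical_summary <- function(subjects = load_subject_records(),
                             baseline = load_baseline_table(),
                             adverse_events = load_adverse_events(),
                             repeat_observations = 3L,
                             survival_threshold_months = 33) {
  list(exposure = summarize_exposure(subjects),
       ttp = summarize_ttp(subjects),
       survival = list(
         threshold_months = survival_threshold_months,
         n_exceeding = survival_exceeding(subjects,
                                          survival_threshold_months),
         min_months = min(subjects$survival_months),
         max_months = max(subjects$survival_months)),
       adverse_events = tally_adverse_events(adverse_events,
                                             repeat_observations),
       baseline = list(min_age_years = min(baseline$age_years),
                       max_age_years = max(baseline$age_years),
                       n_subjects = nrow(baseline)))
}

#' @importFrom stats aggregate
NULL
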