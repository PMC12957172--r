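#' Index date of one patient
#'
#' The index date is the earliest diagnosis date carrying any index-disease
#' code.
#'
#' @param diagnoses diagnosis table (`patient_id`, `condition_code`,
#'   `diagnosis_date`).
#' @param patient_id the patient.
#' @param index_codes character vector of index-disease codes.
#' @return a `Date`, or `NA` (with the exclusion handled by the caller) when
#'   the patient has no qualifying record.
#' @export
assign_index_date <- function(diagnoses, patient_id, index_codes) {
  sel <- diagnoses$patient_id == patient_id &
    diagnoses$condition_code %in% index_codes
  if (!any(sel)) return(as.Date(NA))
  min(as.Date(diagnoses$diagnosis_date[sel]))
}

# Vectorised variant: earliest index-coded diagnosis date per patient.
assign_index_dates <- function(diagnoses, index_codes) {
  d <- diagnoses[diagnoses$condition_code %in% index_codes, ]
  if (!nrow(d)) return(data.frame(patient_id = character(0),
                                  index_date = as.Date(character(0))))
  agg <- stats::aggregate(list(index_date = as.Date(d$diagnosis_date)),
                          by = list(patient_id = d$patient_id), FUN = min)
  agg
}

#' Observed follow-up in years
#'
#' Calendar-day count between index date and last recorded visit, divided by
#' 365.25.
#'
#' @param index_date,last_visit_date calendar dates (vectorised).
#' @return nonnegative numeric years.
#' @export
observed_followup <- function(index_date, last_visit_date) {
  days <- as.numeric(as.Date(last_visit_date) - as.Date(index_date))
  if (any(days < 0, na.rm = TRUE))
    stopf("data error: last_visit_date precedes index_date for patient index %s",
          paste(which(days < 0), collapse = ", "))
  days / 365.25
}

#' 1:1 exact matching on sex and index age
#'
#' Within every (sex, index age in years) stratum, `min(n_cases,
#' n_comparators)` pairs are formed. Which patients enter pairs is decided by
#' a seeded uniform draw without replacement over ids sorted
#' lexicographically first, so the result is deterministic for a fixed seed
#' and independent of input row order.
#'
#' @param cases,comparators patient tables with `patient_id`, `sex`,
#'   `index_age_years`.
#' @param seed integer seed for the within-stratum draws.
#' @return list with `pairs` (`case_id`, `comparator_id`, `sex`,
#'   `index_age_years`) and `unmatched` (`patient_id`, `cohort`, `reason`).
#' @export
match_cohorts <- function(cases, comparators, seed = 1L) {
  if (!nrow(cases) || !nrow(comparators))
    stopf("match_cohorts: both patient tables must be nonempty")
  stratum <- function(df) paste(df$sex, df$index_age_years, sep = "|")
  cs <- split(cases$patient_id, stratum(cases))
  ps <- split(comparators$patient_id, stratum(comparators))
  pairs <- list()
  unmatched <- list()
  for (st in sort(union(names(cs), names(ps)))) {
    case_ids <- sort(cs[[st]] %||% character(0))
    comp_ids <- sort(ps[[st]] %||% character(0))
    k <- min(length(case_ids), length(comp_ids))
    sel_cases <- case_ids
    sel_comps <- comp_ids
    if (k > 0) {
      with_stream(seed, paste0("match.", st), {
        if (length(case_ids) > k) sel_cases <- sort(sample(case_ids, k))
        sel_comps <- sample(comp_ids, k)
      })
      parts <- strsplit(st, "|", fixed = TRUE)[[1]]
      pairs[[st]] <- data.frame(
        case_id = sel_cases, comparator_id = sel_comps[seq_len(k)],
        sex = parts[1], index_age_years = as.integer(parts[2]),
        stringsAsFactors = FALSE
      )
    }
    um_case <- setdiff(case_ids, sel_cases[seq_len(min(k, length(sel_cases)))])
    if (k == 0) um_case <- case_ids
    um_comp <- setdiff(comp_ids, if (k > 0) sel_comps[seq_len(k)] else character(0))
    if (length(um_case))
      unmatched[[paste0(st, ".case")]] <- data.frame(
        patient_id = um_case, cohort = "cases",
        reason = if (length(comp_ids) == 0) "no_comparator_in_stratum"
                 else "insufficient_comparators_in_stratum",
        stringsAsFactors = FALSE)
    if (length(um_comp))
      unmatched[[paste0(st, ".comp")]] <- data.frame(
        patient_id = um_comp, cohort = "comparators",
        reason = if (length(case_ids) == 0) "no_case_in_stratum"
                 else "excess_comparators_in_stratum",
        stringsAsFactors = FALSE)
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), comparator_id = character(0),
               sex = character(0), index_age_years = integer(0))
  um_df <- if (length(unmatched)) do.call(rbind, unmatched) else
    data.frame(patient_id = character(0), cohort = character(0),
               reason = character(0))
  rownames(pairs_df) <- rownames(um_df) <- NULL
  list(pairs = pairs_df, unmatched = um_df)
}

#' Comorbid conditions of one patient
#'
#' Codes recorded on or after the patient's index date, restricted to the
#' chapter whitelist and excluding index-disease (diabetes) codes.
#' Same-day codes at the index visit count: first-visit coding commonly
#' includes concurrent diagnoses, so the comparison is `>=`, not `>`.
#' Diabetes-specific complication codes (e.g. diabetic nephropathy) are not
#' index-disease codes and remain eligible.
#'
#' @param patient one row of the patient table (needs `patient_id`,
#'   `index_date`).
#' @param diagnoses diagnosis table.
#' @param catalog condition catalog (`condition_code`, `icd10_chapter`,
#'   `is_index_disease`).
#' @param chapters chapter whitelist, Roman numerals (default I-XIV).
#' @return character vector (set) of condition codes.
#' @export
extract_comorbidities <- function(patient, diagnoses, catalog,
                                  chapters = roman_chapters(1:14)) {
  d <- diagnoses[diagnoses$patient_id == patient$patient_id, ]
  unknown <- setdiff(d$condition_code, catalog$condition_code)
  if (length(unknown))
    stopf("configuration error: diagnosis code(s) missing from catalog: %s",
          paste(sort(unique(unknown)), collapse = ", "))
  m <- match(d$condition_code, catalog$condition_code)
  keep <- as.Date(d$diagnosis_date) >= as.Date(patient$index_date) &
    catalog$icd10_chapter[m] %in% chapters &
    catalog$is_index_disease[m] == 0L
  sort(unique(d$condition_code[keep]))
}

# Vectorised comorbidity extraction: long (patient_id, condition_code) table
# for all patients at once. Same rules as extract_comorbidities().
build_profiles <- function(patients, diagnoses, catalog,
                           chapters = roman_chapters(1:14)) {
  unknown <- setdiff(diagnoses$condition_code, catalog$condition_code)
  if (length(unknown))
    stopf("configuration error: diagnosis code(s) missing from catalog: %s",
          paste(sort(unique(unknown)), collapse = ", "))
  m <- match(diagnoses$condition_code, catalog$condition_code)
  pidx <- match(diagnoses$patient_id, patients$patient_id)
  keep <- !is.na(pidx) &
    as.Date(diagnoses$diagnosis_date) >= as.Date(patients$index_date)[pidx] &
    catalog$icd10_chapter[m] %in% chapters &
    catalog$is_index_disease[m] == 0L
  long <- unique(diagnoses[keep, c("patient_id", "condition_code")])
  long <- long[order(long$patient_id, long$condition_code), ]
  rownames(long) <- NULL
  long
}

#' Per-cohort prevalence filter
#'
#' A condition is retained within a diabetes-type cohort iff the fraction of
#' that cohort's patients carrying it is at least `threshold` (inclusive:
#' exactly 1% is retained). The filter is applied per cohort, pooling sexes;
#' the retained list is then shared by that cohort's male and female
#' networks.
#'
#' @param profiles long (`patient_id`, `condition_code`) comorbidity table.
#' @param patients patient table with `patient_id`, `diabetes_type`.
#' @param threshold retention threshold (default 0.01).
#' @return list with `retained` (named list: cohort -> code vector),
#'   `prevalence` (data.frame `cohort`, `condition_code`, `count`,
#'   `prevalence`) and `profiles` (input rewritten to retained codes only).
#' @export
prevalence_filter <- function(profiles, patients, threshold = 0.01) {
  cohorts <- unique(patients$diabetes_type)
  retained <- stats::setNames(vector("list", length(cohorts)), cohorts)
  prev_rows <- list()
  keep_row <- logical(nrow(profiles))
  type_of <- patients$diabetes_type[match(profiles$patient_id,
                                          patients$patient_id)]
  for (co in cohorts) {
    n_co <- sum(patients$diabetes_type == co)
    if (n_co == 0) stopf("prevalence_filter: empty cohort %s", co)
    sub <- profiles[type_of == co, ]
    counts <- table(sub$condition_code)
    prev <- as.numeric(counts) / n_co
    codes <- names(counts)
    retained[[co]] <- sort(codes[prev >= threshold])
    prev_rows[[co]] <- data.frame(
      cohort = co, condition_code = codes,
      count = as.integer(counts), prevalence = prev,
      stringsAsFactors = FALSE
    )
  }
  for (co in cohorts)
    keep_row <- keep_row | (type_of == co &
                              profiles$condition_code %in% retained[[co]])
  out <- profiles[keep_row, ]
  rownames(out) <- NULL
  prevalence <- do.call(rbind, prev_rows)
  prevalence <- prevalence[order(prevalence$cohort, prevalence$condition_code), ]
  rownames(prevalence) <- NULL
  list(retained = retained, prevalence = prevalence, profiles = out)
}

#' Multimorbidity flag
#'
#' TRUE iff a patient carries two or more retained comorbid conditions
#' (the index disease itself excluded upstream).
#'
#' @param conditions character vector of a patient's retained condition
#'   codes.
#' @return logical.
#' @export
flag_multimorbidity <- function(conditions) {
  length(unique(conditions)) >= 2L
}
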