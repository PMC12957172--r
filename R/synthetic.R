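#' Subgroup labels used throughout the pipeline
#'
#' The four analysis subgroups: diabetes type crossed with sex.
#' @return Character vector of subgroup labels.
#' @export
subgroup_labels <- function() {
  c("T1DM_male", "T1DM_female", "T2DM_male", "T2DM_female")
}

subgroup_of <- function(diabetes_type, sex) paste(diabetes_type, sex, sep = "_")

AGE_BANDS <- data.frame(
  band  = c("10-17", "18-39", "40-59", "60-79"),
  lower = c(10L, 18L, 40L, 60L),
  upper = c(17L, 39L, 59L, 79L),
  stringsAsFactors = FALSE
)

#' Illustrative default condition catalog
#'
#' Twenty-two grouped chronic conditions spanning ICD-10 chapters I-XIV, with
#' baseline prevalence (referenced to T1DM males) and multiplicative
#' female / T2DM prevalence ratios. The set uses the disease vocabulary of
#' diabetes multimorbidity studies (hypertension, dyslipidemia, diabetic
#' microvascular complications, ...) but the prevalences are illustrative:
#' real grouped-condition dictionaries are institution specific, so the
#' catalog is fully user-configurable via [synthetic_config()].
#'
#' @return data.frame with columns `code`, `label`, `chapter` (Roman numeral),
#'   `prevalence`, `rr_female`, `rr_t2dm`.
#' @export
default_condition_specs <- function() {
  spec <- rbind(
    c("HTN",    "Hypertension",                  "IX",   0.28, 0.90, 1.25),
    c("DLP",    "Dyslipidemia",                  "IV",   0.26, 0.95, 1.25),
    c("IHD",    "Ischemic heart disease",        "IX",   0.12, 0.80, 1.20),
    c("CBVD",   "Cerebrovascular disease",       "IX",   0.10, 0.85, 1.20),
    c("STR",    "Stroke",                        "IX",   0.06, 0.80, 1.15),
    c("PVD",    "Peripheral vascular disease",   "IX",   0.06, 0.85, 1.10),
    c("DNEPH",  "Diabetic nephropathy",          "XIV",  0.09, 0.90, 0.90),
    c("DNEURO", "Diabetic neuropathy",           "VI",   0.09, 0.95, 0.90),
    c("DEYE",   "Diabetic eye complications",    "VII",  0.10, 1.00, 0.85),
    c("CAT",    "Cataract",                      "VII",  0.08, 1.10, 1.10),
    c("NAFLD",  "Nonalcoholic fatty liver disease", "XI", 0.11, 0.85, 1.25),
    c("CGAS",   "Chronic gastritis",             "XI",   0.09, 1.15, 1.00),
    c("CHEP",   "Chronic viral hepatitis",       "I",    0.04, 0.80, 1.00),
    c("CIRR",   "Cirrhosis",                     "XI",   0.02, 0.75, 1.00),
    c("ASTH",   "Asthma",                        "X",    0.04, 1.10, 1.00),
    c("COPD",   "Chronic obstructive pulmonary disease", "X", 0.04, 0.75, 1.15),
    c("OST",    "Osteoporosis",                  "XIII", 0.05, 1.80, 1.05),
    c("OA",     "Osteoarthritis",                "XIII", 0.07, 1.30, 1.10),
    c("ANXD",   "Anxiety or depression",         "V",    0.05, 1.50, 0.95),
    c("THYR",   "Thyroid disorder",              "IV",   0.09, 2.00, 0.85),
    c("CKD",    "Chronic kidney disease",        "XIV",  0.07, 0.85, 1.10),
    c("ANEM",   "Anemia",                        "III",  0.05, 1.40, 1.00)
  )
  data.frame(
    code = spec[, 1], label = spec[, 2], chapter = spec[, 3],
    prevalence = as.numeric(spec[, 4]),
    rr_female = as.numeric(spec[, 5]),
    rr_t2dm = as.numeric(spec[, 6]),
    stringsAsFactors = FALSE
  )
}

#' Default planted co-occurring pairs
#'
#' Subgroup-specific excess co-occurrence planted on top of otherwise
#' independent condition indicators. The default layout mirrors the kind of
#' subgroup-unique pairing reported for sex-stratified diabetes networks
#' (male T1DM: eye complications-stroke, PVD-NAFLD; female T1DM:
#' nephropathy-gastritis, neuropathy-osteoporosis, gastritis-asthma;
#' female T2DM: hypertension-asthma).
#'
#' Within a planted pair, `code_i` is held fixed and `code_j` is re-drawn
#' conditional on it, so a code may appear as `code_j` at most once per
#' subgroup and never after it already took part in an earlier pair of the
#' same subgroup.
#'
#' @return data.frame with columns `code_i`, `code_j`, `subgroups`
#'   (`;`-separated subgroup labels) and `odds_ratio`.
#' @export
default_planted_pairs <- function() {
  data.frame(
    code_i = c("DEYE", "PVD",   "DNEPH", "DNEURO", "CGAS", "HTN"),
    code_j = c("STR",  "NAFLD", "CGAS",  "OST",    "ASTH", "ASTH"),
    subgroups = c("T1DM_male", "T1DM_male", "T1DM_female", "T1DM_female",
                  "T1DM_female", "T2DM_female"),
    odds_ratio = c(6, 6, 6, 6, 6, 4),
    stringsAsFactors = FALSE
  )
}

# Log-normal parameters from a printed median and interquartile range.
lognormal_from_quartiles <- function(median, q1, q3) {
  z75 <- stats::qnorm(0.75)
  list(meanlog = log(median), sdlog = (log(q3) - log(q1)) / (2 * z75))
}

#' Default laboratory value distributions
#'
#' One row per lab x diabetes type x sex. Approximately normal labs (HbA1c,
#' TC, LDL-C, HDL-C) carry mean/SD in `location`/`scale`; right-skewed labs
#' (TG, ALT, AST, ALP, GGT, UA, UMA) are log-normal with `location` = meanlog
#' and `scale` = sdlog, fitted from group medians and quartiles. The defaults
#' are calibrated to published per-type, per-sex summaries of matched
#' T1DM/T2DM cohorts; HbA1c is on the IFCC scale (mmol/mol).
#'
#' @return data.frame with columns `lab`, `family`, `diabetes_type`, `sex`,
#'   `location`, `scale`.
#' @export
default_lab_specs <- function() {
  norm <- function(lab, t1m, t1f, t2m, t2f) {
    data.frame(
      lab = lab, family = "normal",
      diabetes_type = rep(c("T1DM", "T2DM"), each = 2),
      sex = rep(c("male", "female"), 2),
      location = c(t1m[1], t1f[1], t2m[1], t2f[1]),
      scale = c(t1m[2], t1f[2], t2m[2], t2f[2]),
      stringsAsFactors = FALSE
    )
  }
  lnorm <- function(lab, t1m, t1f, t2m, t2f) {
    p <- lapply(list(t1m, t1f, t2m, t2f),
                function(v) lognormal_from_quartiles(v[1], v[2], v[3]))
    data.frame(
      lab = lab, family = "lognormal",
      diabetes_type = rep(c("T1DM", "T2DM"), each = 2),
      sex = rep(c("male", "female"), 2),
      location = vapply(p, `[[`, numeric(1), "meanlog"),
      scale = vapply(p, `[[`, numeric(1), "sdlog"),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    norm("hba1c", c(64, 24),    c(60, 22),    c(60, 20),    c(55, 20)),
    norm("tc",    c(4.48, 1.33), c(4.91, 1.28), c(4.40, 1.25), c(4.82, 1.23)),
    norm("ldlc",  c(2.68, 1.02), c(2.87, 1.02), c(2.63, 0.97), c(2.86, 1.00)),
    norm("hdlc",  c(1.23, 0.38), c(1.48, 0.45), c(1.11, 0.32), c(1.33, 0.39)),
    lnorm("tg",  c(1.13, 0.79, 1.72),  c(1.12, 0.77, 1.72),
                 c(1.39, 0.98, 2.07),  c(1.43, 1.00, 2.10)),
    lnorm("alt", c(20.0, 14.0, 29.1),  c(17.0, 12.0, 24.0),
                 c(22.65, 16.0, 34.0), c(18.9, 13.0, 28.0)),
    lnorm("ast", c(20.0, 15.0, 26.56), c(19.2, 14.0, 25.98),
                 c(21.0, 15.3, 27.05), c(20.0, 15.0, 26.4)),
    lnorm("alp", c(76.0, 62.0, 96.55), c(74.0, 59.0, 94.0),
                 c(73.0, 60.0, 90.0),  c(73.0, 58.4, 93.0)),
    lnorm("ggt", c(21.6, 15.0, 34.0),  c(16.0, 12.0, 26.0),
                 c(25.0, 17.5, 41.0),  c(20.0, 14.0, 31.3)),
    lnorm("ua",  c(327.9, 265.8, 400.0), c(274.3, 220.0, 341.2),
                 c(349.0, 287.0, 416.1), c(297.0, 241.1, 362.0)),
    lnorm("uma", c(12.8, 7.91, 56.2),  c(11.0, 6.6, 29.3),
                 c(19.0, 10.2, 73.68), c(14.84, 10.0, 44.3))
  )
}

#' Default observed-follow-up distributions
#'
#' Log-normal per diabetes type, fitted from group median and IQR of observed
#' follow-up in years (T1DM 3.80 (1.36, 7.13); T2DM 8.28 (4.85, 10.34)).
#' @return data.frame with columns `diabetes_type`, `meanlog`, `sdlog`.
#' @export
default_followup_spec <- function() {
  t1 <- lognormal_from_quartiles(3.80, 1.36, 7.13)
  t2 <- lognormal_from_quartiles(8.28, 4.85, 10.34)
  data.frame(
    diabetes_type = c("T1DM", "T2DM"),
    meanlog = c(t1$meanlog, t2$meanlog),
    sdlog = c(t1$sdlog, t2$sdlog),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic EHR cohort generator
#'
#' Assembles and validates the full parameterisation of the two-cohort
#' (T1DM / matched T2DM) synthetic extract. Defaults emulate the study
#' conditions of a 2014-2023 hospital-linkage diabetes cohort: 18,971
#' patients per cohort, 49.4% female, the four age bands 10-17 / 18-39 /
#' 40-59 / 60-79 weighted 3.6/27.7/32.9/35.9%, per-type x per-sex lab
#' distributions and follow-up fitted to printed summaries, and planted
#' subgroup-specific co-occurring pairs.
#'
#' @param n_per_cohort patients per diabetes-type cohort.
#' @param sex_fraction_female proportion female in `[0,1]`.
#' @param age_band_weights nonnegative weights over the four age bands.
#' @param condition_specs condition catalog, see [default_condition_specs()].
#' @param planted_pairs planted pair table, see [default_planted_pairs()].
#' @param lab_specs lab distribution table, see [default_lab_specs()].
#' @param followup_spec follow-up distribution, see [default_followup_spec()].
#' @param index_window two calendar dates bounding index dates.
#' @param unmatched_fraction fraction of T2DM comparators whose index age is
#'   re-drawn independently, to exercise matching-failure paths (default 0:
#'   comparators copy the T1DM (sex, age) multiset so exact matching
#'   always succeeds).
#' @param seed integer root seed; all stages draw from substreams derived
#'   from it.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_per_cohort = 18971L,
                             sex_fraction_female = 0.4939,
                             age_band_weights = c(0.036, 0.277, 0.329, 0.359),
                             condition_specs = default_condition_specs(),
                             planted_pairs = default_planted_pairs(),
                             lab_specs = default_lab_specs(),
                             followup_spec = default_followup_spec(),
                             index_window = as.Date(c("2014-01-01", "2023-12-31")),
                             unmatched_fraction = 0,
                             seed = 1L) {
  cfg <- structure(
    list(
      n_per_cohort = as.integer(n_per_cohort),
      sex_fraction_female = sex_fraction_female,
      age_band_weights = age_band_weights,
      condition_specs = condition_specs,
      planted_pairs = planted_pairs,
      lab_specs = lab_specs,
      followup_spec = followup_spec,
      index_window = as.Date(index_window),
      unmatched_fraction = unmatched_fraction,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

# Per-subgroup marginal probability of a condition.
subgroup_prevalence <- function(spec_row, subgroup) {
  p <- spec_row$prevalence
  if (grepl("female", subgroup)) p <- p * spec_row$rr_female
  if (grepl("T2DM", subgroup)) p <- p * spec_row$rr_t2dm
  p
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$n_per_cohort) != 1L || is.na(cfg$n_per_cohort) ||
      cfg$n_per_cohort < 1L)
    stopf("configuration error in field 'n_per_cohort': must be a positive integer")
  if (!is.numeric(cfg$sex_fraction_female) ||
      cfg$sex_fraction_female < 0 || cfg$sex_fraction_female > 1)
    stopf("configuration error in field 'sex_fraction_female': must lie in [0,1]")
  w <- cfg$age_band_weights
  if (length(w) != 4L || any(!is.finite(w)) || any(w < 0) || sum(w) <= 0)
    stopf("configuration error in field 'age_band_weights': need 4 nonnegative weights with positive sum")
  cs <- cfg$condition_specs
  need <- c("code", "label", "chapter", "prevalence", "rr_female", "rr_t2dm")
  if (!all(need %in% names(cs)))
    stopf("configuration error in field 'condition_specs': missing column(s) %s",
          paste(setdiff(need, names(cs)), collapse = ", "))
  if (anyDuplicated(cs$code))
    stopf("configuration error in field 'condition_specs': duplicated code(s)")
  if (any(cs$prevalence < 0 | cs$prevalence > 1))
    stopf("configuration error in field 'condition_specs': prevalence outside [0,1]")
  for (sg in subgroup_labels()) {
    p <- vapply(seq_len(nrow(cs)),
                function(i) subgroup_prevalence(cs[i, ], sg), numeric(1))
    if (any(p < 0 | p > 1))
      stopf("configuration error in field 'condition_specs': subgroup %s marginal probability outside [0,1] for code(s) %s",
            sg, paste(cs$code[p < 0 | p > 1], collapse = ", "))
  }
  pp <- cfg$planted_pairs
  if (nrow(pp) > 0) {
    unknown <- setdiff(c(pp$code_i, pp$code_j), cs$code)
    if (length(unknown))
      stopf("configuration error in field 'planted_pairs': unknown code(s) %s",
            paste(unknown, collapse = ", "))
    if (any(pp$odds_ratio <= 0))
      stopf("configuration error in field 'planted_pairs': odds_ratio must be > 0")
    if (any(pp$code_i == pp$code_j))
      stopf("configuration error in field 'planted_pairs': self-pair not allowed")
    # code_j must be fresh within its subgroup (conditional re-draw would
    # otherwise destroy an earlier pair's planted association)
    for (sg in subgroup_labels()) {
      rows <- which(vapply(strsplit(pp$subgroups, ";"),
                           function(s) sg %in% trimws(s), logical(1)))
      seen <- character(0)
      for (r in rows) {
        if (pp$code_j[r] %in% seen)
          stopf("configuration error in field 'planted_pairs': code %s re-used as code_j in subgroup %s",
                pp$code_j[r], sg)
        seen <- union(seen, c(pp$code_i[r], pp$code_j[r]))
      }
    }
  }
  ls <- cfg$lab_specs
  if (nrow(ls) > 0) {
    if (!all(ls$family %in% c("normal", "lognormal")))
      stopf("configuration error in field 'lab_specs': family must be 'normal' or 'lognormal'")
    combos <- with(ls, table(lab, diabetes_type, sex))
    if (any(combos != 1L))
      stopf("configuration error in field 'lab_specs': need exactly one row per lab x diabetes_type x sex")
  }
  if (!all(c("T1DM", "T2DM") %in% cfg$followup_spec$diabetes_type))
    stopf("configuration error in field 'followup_spec': need rows for T1DM and T2DM")
  if (cfg$index_window[2] < cfg$index_window[1])
    stopf("configuration error in field 'index_window': end precedes start")
  if (cfg$unmatched_fraction < 0 || cfg$unmatched_fraction > 1)
    stopf("configuration error in field 'unmatched_fraction': must lie in [0,1]")
  invisible(cfg)
}

# Exact 2x2 joint cell with margins (p, q) and odds ratio theta: the unique
# root of theta = p11*p00/(p10*p01) in [max(0, p+q-1), min(p, q)] (the table
# iterative proportional fitting converges to).
plackett_p11 <- function(p, q, theta) {
  if (theta == 1) return(p * q)
  s <- 1 + (p + q) * (theta - 1)
  (s - sqrt(s^2 - 4 * theta * (theta - 1) * p * q)) / (2 * (theta - 1))
}

#' Ground truth implied by a synthetic configuration
#'
#' Re-keys the planted pair table by subgroup and records, per lab and sex,
#' the sign of the configured T1DM-vs-T2DM location difference. Derivable
#' from the configuration alone; used as truth for recovery experiments.
#'
#' @param config a [synthetic_config()].
#' @return list with `pairs` (named list: subgroup -> data.frame of
#'   `code_i`, `code_j`, `odds_ratio`) and `lab_shift_direction`
#'   (data.frame `lab`, `sex`, `direction` in -1/0/1).
#' @export
planted_truth <- function(config) {
  validate_synthetic_config(config)
  pp <- config$planted_pairs
  empty <- data.frame(code_i = character(0), code_j = character(0),
                      odds_ratio = numeric(0), stringsAsFactors = FALSE)
  pairs <- stats::setNames(vector("list", 4), subgroup_labels())
  for (sg in subgroup_labels()) {
    if (!nrow(pp)) {
      pairs[[sg]] <- empty
      next
    }
    keep <- vapply(strsplit(pp$subgroups, ";"),
                   function(s) sg %in% trimws(s), logical(1))
    pairs[[sg]] <- pp[keep, c("code_i", "code_j", "odds_ratio"), drop = FALSE]
    rownames(pairs[[sg]]) <- NULL
  }
  ls <- config$lab_specs
  dir <- NULL
  for (lab in unique(ls$lab)) {
    for (sx in c("male", "female")) {
      l1 <- ls$location[ls$lab == lab & ls$diabetes_type == "T1DM" & ls$sex == sx]
      l2 <- ls$location[ls$lab == lab & ls$diabetes_type == "T2DM" & ls$sex == sx]
      dir <- rbind(dir, data.frame(lab = lab, sex = sx,
                                   direction = sign(l1 - l2)))
    }
  }
  list(pairs = pairs, lab_shift_direction = dir)
}

#' Generate a synthetic two-cohort EHR extract
#'
#' Draws a T1DM cohort and a T2DM comparator cohort whose (sex, index age)
#' multiset copies the T1DM cohort (so 1:1 exact matching succeeds by
#' default). Condition indicators are independent Bernoulli draws at the
#' configured subgroup marginals; each planted pair is then re-drawn jointly
#' from the exact 2x2 table matching the configured odds ratio while
#' preserving both marginals. Comorbidity diagnosis dates fall within
#' `[index_date, last_visit_date]`; each patient additionally carries one
#' index-disease diagnosis (code `DM1` or `DM2`) on the index date.
#'
#' Identical configuration (including its `seed`) yields bit-identical
#' tables.
#'
#' @param config a [synthetic_config()].
#' @return list with `patients` (one row per patient: `patient_id`, `sex`,
#'   `diabetes_type`, `index_age_years`, `index_date`, `last_visit_date`,
#'   one column per lab), `diagnoses` (`patient_id`, `condition_code`,
#'   `diagnosis_date`), `catalog` (`condition_code`, `label`,
#'   `icd10_chapter`, `is_index_disease`).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_per_cohort
  root <- config$seed
  n_all <- 2L * n

  # demographics: T1DM drawn, T2DM copies the (sex, age) multiset
  sex1 <- with_stream(root, "sex",
                      ifelse(stats::runif(n) < config$sex_fraction_female,
                             "female", "male"))
  w <- config$age_band_weights / sum(config$age_band_weights)
  band <- with_stream(root, "ageband", sample.int(4L, n, replace = TRUE, prob = w))
  span <- AGE_BANDS$upper - AGE_BANDS$lower + 1L
  age1 <- with_stream(root, "age",
                      AGE_BANDS$lower[band] +
                        as.integer(floor(stats::runif(n) * span[band])))
  sex2 <- sex1
  age2 <- age1
  if (config$unmatched_fraction > 0) {
    k <- ceiling(config$unmatched_fraction * n)
    idx <- with_stream(root, "unmatched.idx", sample.int(n, k))
    age2[idx] <- with_stream(root, "unmatched.age",
                             sample(10:79, k, replace = TRUE))
  }

  patients <- data.frame(
    patient_id = c(sprintf("T1-%06d", seq_len(n)), sprintf("T2-%06d", seq_len(n))),
    sex = c(sex1, sex2),
    diabetes_type = rep(c("T1DM", "T2DM"), each = n),
    index_age_years = c(age1, age2),
    stringsAsFactors = FALSE
  )
  subgroup <- subgroup_of(patients$diabetes_type, patients$sex)

  # calendar: index date uniform over the window; follow-up per cohort
  ndays <- as.integer(config$index_window[2] - config$index_window[1]) + 1L
  patients$index_date <- config$index_window[1] +
    with_stream(root, "index_date",
                as.integer(floor(stats::runif(n_all) * ndays)))
  fu <- numeric(n_all)
  for (ty in c("T1DM", "T2DM")) {
    fs <- config$followup_spec[config$followup_spec$diabetes_type == ty, ]
    sel <- patients$diabetes_type == ty
    fu[sel] <- with_stream(root, paste0("followup.", ty),
                           stats::rlnorm(sum(sel), fs$meanlog, fs$sdlog))
  }
  patients$last_visit_date <- patients$index_date + as.integer(round(fu * 365.25))

  # labs, per lab substream; draws grouped by (type, sex) in fixed order
  ls <- config$lab_specs
  for (lab in unique(ls$lab)) {
    vals <- numeric(n_all)
    with_stream(root, paste0("lab.", lab), {
      for (ty in c("T1DM", "T2DM")) for (sx in c("male", "female")) {
        row <- ls[ls$lab == lab & ls$diabetes_type == ty & ls$sex == sx, ]
        sel <- patients$diabetes_type == ty & patients$sex == sx
        vals[sel] <- if (row$family == "normal") {
          pmax(0, stats::rnorm(sum(sel), row$location, row$scale))
        } else {
          stats::rlnorm(sum(sel), row$location, row$scale)
        }
      }
    })
    patients[[lab]] <- vals
  }

  # condition indicators: independent per condition, one substream each
  cs <- config$condition_specs
  k <- nrow(cs)
  X <- matrix(FALSE, n_all, k, dimnames = list(NULL, cs$code))
  sg_prev <- matrix(0, k, 4, dimnames = list(cs$code, subgroup_labels()))
  for (sg in subgroup_labels()) for (i in seq_len(k))
    sg_prev[i, sg] <- subgroup_prevalence(cs[i, ], sg)
  for (i in seq_len(k)) {
    p_vec <- sg_prev[i, subgroup]
    X[, i] <- with_stream(root, paste0("cond.", cs$code[i]),
                          stats::runif(n_all) < p_vec)
  }

  # planted pairs: re-draw code_j | code_i from the exact odds-ratio table
  pp <- config$planted_pairs
  if (nrow(pp)) for (r in seq_len(nrow(pp))) {
    for (sg in trimws(strsplit(pp$subgroups[r], ";")[[1]])) {
      sel <- which(subgroup == sg)
      if (!length(sel)) next
      p_i <- sg_prev[pp$code_i[r], sg]
      p_j <- sg_prev[pp$code_j[r], sg]
      if (p_i <= 0 || p_j <= 0 || p_i >= 1) next
      p11 <- plackett_p11(p_i, p_j, pp$odds_ratio[r])
      pj_given_i <- p11 / p_i
      pj_given_not_i <- (p_j - p11) / (1 - p_i)
      u <- with_stream(root, paste0("plant.", pp$code_i[r], ".", pp$code_j[r], ".", sg),
                       stats::runif(length(sel)))
      has_i <- X[sel, pp$code_i[r]]
      X[sel, pp$code_j[r]] <- u < ifelse(has_i, pj_given_i, pj_given_not_i)
    }
  }

  # diagnosis rows: index-disease record on the index date, comorbidities
  # uniform within [index_date, last_visit_date]
  dm_code <- ifelse(patients$diabetes_type == "T1DM", "DM1", "DM2")
  diag_list <- list(data.frame(
    patient_id = patients$patient_id,
    condition_code = dm_code,
    diagnosis_date = patients$index_date,
    stringsAsFactors = FALSE
  ))
  span_days <- as.integer(patients$last_visit_date - patients$index_date)
  for (i in seq_len(k)) {
    who <- which(X[, i])
    if (!length(who)) next
    offs <- with_stream(root, paste0("diagdate.", cs$code[i]),
                        as.integer(floor(stats::runif(length(who)) *
                                           (span_days[who] + 1L))))
    diag_list[[length(diag_list) + 1L]] <- data.frame(
      patient_id = patients$patient_id[who],
      condition_code = cs$code[i],
      diagnosis_date = patients$index_date[who] + offs,
      stringsAsFactors = FALSE
    )
  }
  diagnoses <- do.call(rbind, diag_list)
  rownames(diagnoses) <- NULL

  catalog <- data.frame(
    condition_code = c("DM1", "DM2", cs$code),
    label = c("Type 1 diabetes mellitus", "Type 2 diabetes mellitus", cs$label),
    icd10_chapter = c("IV", "IV", cs$chapter),
    is_index_disease = c(1L, 1L, rep(0L, k)),
    stringsAsFactors = FALSE
  )

  list(patients = patients, diagnoses = diagnoses, catalog = catalog)
}

#' Write a synthetic extract to plain CSV files
#'
#' Writes `patients.csv`, `diagnoses.csv` and `catalog.csv` (ISO-8601 dates)
#' into `dir`.
#' @param extract result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_extract_csv <- function(extract, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "diagnoses.csv", "catalog.csv"))
  utils::write.csv(extract$patients, paths[1], row.names = FALSE)
  utils::write.csv(extract$diagnoses, paths[2], row.names = FALSE)
  utils::write.csv(extract$catalog, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read an extract from CSV files
#'
#' Inverse of [write_extract_csv()]; accepts the same schema for real
#' extracts.
#' @param dir directory containing `patients.csv`, `diagnoses.csv`,
#'   `catalog.csv`.
#' @return list with `patients`, `diagnoses`, `catalog`.
#' @export
read_extract_csv <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  diagnoses <- utils::read.csv(file.path(dir, "diagnoses.csv"),
                               stringsAsFactors = FALSE)
  catalog <- utils::read.csv(file.path(dir, "catalog.csv"),
                             stringsAsFactors = FALSE)
  for (col in c("index_date", "last_visit_date"))
    patients[[col]] <- as.Date(patients[[col]])
  diagnoses$diagnosis_date <- as.Date(diagnoses$diagnosis_date)
  list(patients = patients, diagnoses = diagnoses, catalog = catalog)
}
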