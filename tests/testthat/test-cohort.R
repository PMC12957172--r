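test_that("index date is the earliest index-coded diagnosis", {
  d <- data.frame(
    patient_id = c("A", "A", "A", "B"),
    condition_code = c("DM1", "DM1", "HTN", "DM1"),
    diagnosis_date = as.Date(c("2016-05-01", "2014-03-02", "2013-01-01",
                               "2020-06-30")),
    stringsAsFactors = FALSE
  )
  # minimum over index codes only: the earlier HTN record does not count
  expect_equal(assign_index_date(d, "A", "DM1"), as.Date("2014-03-02"))
  expect_equal(assign_index_date(d, "B", "DM1"), as.Date("2020-06-30"))
  expect_true(is.na(assign_index_date(d, "A", "DM9")))
})

test_that("observed follow-up is a calendar day count over 365.25", {
  expect_equal(observed_followup("2014-01-01", "2014-01-01"), 0)
  expect_equal(observed_followup("2014-01-01", "2017-01-01"), 1096 / 365.25)
  expect_equal(observed_followup("2014-01-01", "2014-01-02"), 1 / 365.25)
  expect_error(observed_followup("2015-01-01", "2014-01-01"), "data error")
})

test_that("exact matching pairs strata correctly and deterministically", {
  cases <- data.frame(
    patient_id = c("a1", "a2", "a3", "a4", "a5"),
    sex = c("male", "male", "male", "female", "female"),
    index_age_years = c(50, 50, 50, 30, 41),
    stringsAsFactors = FALSE
  )
  comps <- data.frame(
    patient_id = c("b1", "b2", "b3"),
    sex = c("male", "female", "female"),
    index_age_years = c(50, 30, 30),
    stringsAsFactors = FALSE
  )
  m <- match_cohorts(cases, comps, seed = 9)
  # stratum (male,50): 3 cases, 1 comparator -> 1 pair + 2 unmatched cases
  # stratum (female,30): 1 case, 2 comparators -> 1 pair + 1 unmatched comp
  # stratum (female,41): no comparator -> case unmatched
  expect_equal(nrow(m$pairs), 2)
  expect_true(all(m$pairs$sex == c("female", "male")) ||
                all(m$pairs$sex == c("male", "female")))
  expect_setequal(
    m$unmatched$reason,
    c("insufficient_comparators_in_stratum", "excess_comparators_in_stratum",
      "no_comparator_in_stratum"))
  # matching exactness within every pair
  cs <- cases[match(m$pairs$case_id, cases$patient_id), ]
  cp <- comps[match(m$pairs$comparator_id, comps$patient_id), ]
  expect_equal(cs$sex, cp$sex)
  expect_equal(cs$index_age_years, cp$index_age_years)
  # |pairs| = sum over strata of min(cases, comparators)
  key <- function(df) paste(df$sex, df$index_age_years)
  mins <- sapply(union(key(cases), key(comps)), function(k)
    min(sum(key(cases) == k), sum(key(comps) == k)))
  expect_equal(nrow(m$pairs), sum(mins))
})

test_that("matching is invariant to input row order for a fixed seed", {
  withr::with_seed(101, {
    n <- 60
    cases <- data.frame(
      patient_id = sprintf("c%02d", 1:n),
      sex = sample(c("male", "female"), n, TRUE),
      index_age_years = sample(40:43, n, TRUE), stringsAsFactors = FALSE)
    comps <- data.frame(
      patient_id = sprintf("k%02d", 1:n),
      sex = sample(c("male", "female"), n, TRUE),
      index_age_years = sample(40:43, n, TRUE), stringsAsFactors = FALSE)
  })
  m1 <- match_cohorts(cases, comps, seed = 4)
  shuffle <- function(df) df[sample(nrow(df)), ]
  withr::with_seed(999, {
    m2 <- match_cohorts(shuffle(cases), shuffle(comps), seed = 4)
  })
  o1 <- m1$pairs[order(m1$pairs$case_id), ]
  o2 <- m2$pairs[order(m2$pairs$case_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("comorbidity extraction applies date, chapter and index rules", {
  patient <- data.frame(patient_id = "A", index_date = as.Date("2015-01-01"),
                        stringsAsFactors = FALSE)
  catalog <- data.frame(
    condition_code = c("DM1", "HTN", "PREG", "OST", "DLP", "CHEP"),
    label = c("diabetes", "hypertension", "pregnancy-related", "osteoporosis",
              "dyslipidemia", "hepatitis"),
    icd10_chapter = c("IV", "IX", "XV", "XIII", "IV", "I"),
    is_index_disease = c(1L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  diagnoses <- data.frame(
    patient_id = "A",
    condition_code = c("DM1", "HTN", "PREG", "OST", "DLP", "CHEP"),
    diagnosis_date = as.Date(c("2015-01-01", "2015-01-01", "2016-02-02",
                               "2014-12-31", "2016-05-05", "2017-07-07")),
    stringsAsFactors = FALSE
  )
  # 6 records: DM1 excluded (index disease), PREG excluded (chapter XV),
  # OST excluded (before index date); same-day HTN counts (on-or-after rule)
  expect_equal(extract_comorbidities(patient, diagnoses, catalog),
               c("CHEP", "DLP", "HTN"))
  bad <- rbind(diagnoses,
               data.frame(patient_id = "A", condition_code = "ZZZ",
                          diagnosis_date = as.Date("2016-01-01")))
  expect_error(extract_comorbidities(patient, bad, catalog), "ZZZ")
})

test_that("profile building is order-independent and idempotent", {
  cfg <- tiny_config(seed = 6, n = 150)
  ex <- generate_cohort(cfg)
  ex$patients$index_date <- ex$patients$index_date  # already dated
  p1 <- mmnet:::build_profiles(ex$patients, ex$diagnoses, ex$catalog)
  shuffled <- withr::with_seed(1, ex$diagnoses[sample(nrow(ex$diagnoses)), ])
  p2 <- mmnet:::build_profiles(ex$patients, shuffled, ex$catalog)
  expect_identical(p1, p2)
  # single-patient extraction agrees with the vectorised path
  pid <- ex$patients$patient_id[7]
  expect_equal(p1$condition_code[p1$patient_id == pid],
               extract_comorbidities(ex$patients[7, ], ex$diagnoses,
                                     ex$catalog))
})

test_that("prevalence filter keeps the inclusive 1% boundary per cohort", {
  n <- 200
  patients <- data.frame(
    patient_id = c(sprintf("t1-%03d", 1:n), sprintf("t2-%03d", 1:n)),
    diabetes_type = rep(c("T1DM", "T2DM"), each = n),
    stringsAsFactors = FALSE
  )
  # HTN: exactly 1% of T1DM (2/200), 0.5% of T2DM (1/200)
  profiles <- data.frame(
    patient_id = c("t1-001", "t1-002", "t2-001",
                   sprintf("t1-%03d", 1:50), sprintf("t2-%03d", 1:50)),
    condition_code = c("HTN", "HTN", "HTN", rep("DLP", 100)),
    stringsAsFactors = FALSE
  )
  filt <- prevalence_filter(profiles, patients, threshold = 0.01)
  expect_true("HTN" %in% filt$retained$T1DM)   # exactly 1% retained
  expect_false("HTN" %in% filt$retained$T2DM)  # 0.5% dropped
  expect_true(all(c("DLP") %in% filt$retained$T1DM))
  # rewritten profiles contain only retained codes per cohort
  t2_rows <- grepl("^t2", filt$profiles$patient_id)
  expect_false(any(filt$profiles$condition_code[t2_rows] == "HTN"))
  # brute-force recheck: every retained code's prevalence >= threshold
  for (co in c("T1DM", "T2DM")) {
    for (code in filt$retained[[co]]) {
      ids <- patients$patient_id[patients$diabetes_type == co]
      cnt <- length(unique(profiles$patient_id[
        profiles$condition_code == code & profiles$patient_id %in% ids]))
      expect_gte(cnt / n, 0.01)
    }
  }
  # a 10,000-patient cohort with a code in 99 patients drops it (0.99%)
  big <- data.frame(patient_id = sprintf("p%05d", 1:10000),
                    diabetes_type = "T1DM", stringsAsFactors = FALSE)
  prof99 <- data.frame(patient_id = sprintf("p%05d", 1:99),
                       condition_code = "RARE", stringsAsFactors = FALSE)
  expect_false("RARE" %in%
                 prevalence_filter(prof99, big, 0.01)$retained$T1DM)
})

test_that("multimorbidity needs at least two retained conditions", {
  expect_false(flag_multimorbidity(character(0)))
  expect_false(flag_multimorbidity("HTN"))
  expect_true(flag_multimorbidity(c("HTN", "DLP")))
  expect_false(flag_multimorbidity(c("HTN", "HTN")))
})
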