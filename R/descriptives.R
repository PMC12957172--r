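#' Summary of one variable
#'
#' Approximately normal variables are summarised as mean and SD, skewed ones
#' as median and quartiles (linear-interpolation quantiles), categorical ones
#' as counts and percentages per level.
#'
#' @param values numeric vector (or factor/character for `categorical`).
#' @param kind one of `"continuous_normal"`, `"continuous_skewed"`,
#'   `"categorical"`.
#' @return a list: normal -> `mean`, `sd`; skewed -> `median`, `q1`, `q3`;
#'   categorical -> data.frame `level`, `count`, `percent`.
#' @export
summarize_variable <- function(values,
                               kind = c("continuous_normal",
                                        "continuous_skewed", "categorical")) {
  kind <- match.arg(kind)
  if (!length(values)) stopf("summarize_variable: empty input")
  switch(kind,
    continuous_normal = list(
      mean = mean(values),
      sd = if (length(values) > 1) stats::sd(values) else 0
    ),
    continuous_skewed = {
      q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      list(median = q[2], q1 = q[1], q3 = q[3])
    },
    categorical = {
      tab <- table(values)
      data.frame(level = names(tab), count = as.integer(tab),
                 percent = 100 * as.integer(tab) / length(values),
                 stringsAsFactors = FALSE)
    }
  )
}

pooled_sd <- function(sd_a, sd_b) sqrt((sd_a^2 + sd_b^2) / 2)

#' Standardized mean difference of a continuous variable
#'
#' `SMD = (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2)/2)`. Skewed variables
#' are first transformed by natural log, or by `log(x+1)` when either group
#' contains zeros.
#'
#' @param group_a,group_b numeric vectors.
#' @param kind `"continuous_normal"` (no transform) or
#'   `"continuous_skewed"`.
#' @return list with `smd`, `transform_used` (`"none"`, `"log"`, `"log1p"`)
#'   and `group_ns`.
#' @export
smd_continuous <- function(group_a, group_b,
                           kind = c("continuous_normal", "continuous_skewed")) {
  kind <- match.arg(kind)
  if (!length(group_a) || !length(group_b))
    stopf("smd_continuous: both groups must be nonempty")
  transform_used <- "none"
  if (kind == "continuous_skewed") {
    if (any(c(group_a, group_b) < 0))
      stopf("smd_continuous: negative values under log transform")
    if (any(c(group_a, group_b) == 0)) {
      group_a <- log1p(group_a); group_b <- log1p(group_b)
      transform_used <- "log1p"
    } else {
      group_a <- log(group_a); group_b <- log(group_b)
      transform_used <- "log"
    }
  }
  sda <- if (length(group_a) > 1) stats::sd(group_a) else 0
  sdb <- if (length(group_b) > 1) stats::sd(group_b) else 0
  ps <- pooled_sd(sda, sdb)
  delta <- mean(group_a) - mean(group_b)
  smd <- if (ps == 0) {
    if (delta == 0) 0 else sign(delta) * Inf
  } else delta / ps
  list(smd = smd, transform_used = transform_used,
       group_ns = c(length(group_a), length(group_b)))
}

#' Standardized mean difference of a binary variable
#'
#' `(p_a - p_b) / sqrt((p_a(1-p_a) + p_b(1-p_b))/2)`, with 0 returned for
#' equal proportions (including the degenerate 0/0 and 1/1 cases).
#'
#' @param p_a,p_b proportions in `[0,1]`.
#' @param n_a,n_b group sizes (recorded only).
#' @return numeric SMD.
#' @export
smd_binary <- function(p_a, n_a, p_b, n_b) {
  if (p_a < 0 || p_a > 1 || p_b < 0 || p_b > 1)
    stopf("smd_binary: proportions must lie in [0,1]")
  if (p_a == p_b) return(0)
  (p_a - p_b) / sqrt((p_a * (1 - p_a) + p_b * (1 - p_b)) / 2)
}

#' NGSP (%) from IFCC (mmol/mol) HbA1c
#'
#' Display-layer master-equation conversion: `NGSP% = 0.09148 * IFCC + 2.152`.
#' @param ifcc HbA1c in mmol/mol.
#' @return HbA1c in NGSP percent.
#' @export
hba1c_ngsp <- function(ifcc) 0.09148 * ifcc + 2.152

#' Default variable kinds for the descriptive table
#'
#' Index age and the lipid/HbA1c labs are treated as approximately normal;
#' follow-up and the liver/renal labs as skewed (log-transformed for SMDs).
#' @return data.frame `name`, `kind`.
#' @export
default_variable_kinds <- function() {
  data.frame(
    name = c("index_age_years", "followup_years",
             "hba1c", "tc", "ldlc", "hdlc",
             "tg", "alt", "ast", "alp", "ggt", "ua", "uma"),
    kind = c("continuous_normal", "continuous_skewed",
             rep("continuous_normal", 4), rep("continuous_skewed", 7)),
    stringsAsFactors = FALSE
  )
}

#' Descriptive comparison table with SMDs
#'
#' Builds a long-format table-one: for each stratum (overall, male, female)
#' and variable, the T1DM and T2DM summaries plus the standardized mean
#' difference. Age bands and sex are reported as per-level binary SMDs;
#' continuous variables follow [smd_continuous()]'s transform rules. Rows
#' with a missing value are dropped per variable and the drop count recorded.
#'
#' @param patients patient table including `followup_years` and lab columns.
#' @param variable_kinds data.frame `name`, `kind`
#'   (default [default_variable_kinds()]), restricted to columns present.
#' @return data.frame with one row per stratum x variable (x level for
#'   categorical): `stratum`, `variable`, `level`, `summary_t1dm`,
#'   `summary_t2dm`, `smd`, `transform`, `n_dropped`.
#' @export
describe_cohorts <- function(patients, variable_kinds = default_variable_kinds()) {
  variable_kinds <- variable_kinds[variable_kinds$name %in% names(patients), ]
  strata <- list(overall = rep(TRUE, nrow(patients)),
                 male = patients$sex == "male",
                 female = patients$sex == "female")
  fmt_normal <- function(s) sprintf("%.2f ± %.2f", s$mean, s$sd)
  fmt_skewed <- function(s) sprintf("%.2f (%.2f, %.2f)", s$median, s$q1, s$q3)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  for (st in names(strata)) {
    sel <- strata[[st]]
    a_all <- patients[sel & patients$diabetes_type == "T1DM", ]
    b_all <- patients[sel & patients$diabetes_type == "T2DM", ]

    # age bands: per-band binary SMDs
    band_of <- function(age) AGE_BANDS$band[
      findInterval(age, AGE_BANDS$lower)]
    ba <- band_of(a_all$index_age_years)
    bb <- band_of(b_all$index_age_years)
    for (bd in AGE_BANDS$band) {
      pa <- mean(ba == bd); pb <- mean(bb == bd)
      add(stratum = st, variable = "age_band", level = bd,
          summary_t1dm = sprintf("%d (%.1f)", sum(ba == bd), 100 * pa),
          summary_t2dm = sprintf("%d (%.1f)", sum(bb == bd), 100 * pb),
          smd = smd_binary(pa, nrow(a_all), pb, nrow(b_all)),
          transform = "none", n_dropped = 0L)
    }
    if (st == "overall") {
      pa <- mean(a_all$sex == "female"); pb <- mean(b_all$sex == "female")
      add(stratum = st, variable = "sex_female", level = "female",
          summary_t1dm = sprintf("%d (%.1f)", sum(a_all$sex == "female"), 100 * pa),
          summary_t2dm = sprintf("%d (%.1f)", sum(b_all$sex == "female"), 100 * pb),
          smd = smd_binary(pa, nrow(a_all), pb, nrow(b_all)),
          transform = "none", n_dropped = 0L)
    }

    for (i in seq_len(nrow(variable_kinds))) {
      v <- variable_kinds$name[i]
      kind <- variable_kinds$kind[i]
      a <- a_all[[v]]; b <- b_all[[v]]
      n_drop <- sum(is.na(a)) + sum(is.na(b))
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      res <- smd_continuous(a, b, kind)
      fmt <- if (kind == "continuous_normal") fmt_normal else fmt_skewed
      add(stratum = st, variable = v, level = "",
          summary_t1dm = fmt(summarize_variable(a, kind)),
          summary_t2dm = fmt(summarize_variable(b, kind)),
          smd = res$smd, transform = res$transform_used,
          n_dropped = n_drop)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
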