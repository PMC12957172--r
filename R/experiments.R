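#' Planted-pair recovery scenario configuration
#'
#' A calibration scenario for end-to-end validation: 10,000 patients per
#' cohort (about 5,000 per diabetes-type x sex subgroup at a 50% sex split),
#' twelve independent background conditions with prevalences between 5% and
#' 15%, and one subgroup-unique planted pair per subgroup with 10% marginals
#' and odds ratio 8. Laboratory distributions are identical across diabetes
#' types (no planted shift), so any between-type lab SMD is sampling noise.
#'
#' The settings come from an explicit power computation (see the methods
#' vignette): at these margins the planted joint cell is about 0.0374, so a
#' planted pair's expected SCI (about 0.37) clearly exceeds the chance-level
#' SCI of the most prevalent background pair (about 0.13, roughly
#' `sqrt(p_i p_j)` under independence), and the expected t of about 4.3
#' (sampling SD about 0.25) clears the 1.96 significance screen with a wide
#' margin, while recovery through the top-`e` SCI ranking remains
#' informative rather than trivially saturated.
#'
#' @param seed root seed.
#' @param n_per_cohort patients per cohort (default 10000).
#' @return a [synthetic_config()].
#' @export
recovery_scenario_config <- function(seed = 1L, n_per_cohort = 10000L) {
  k <- 12L
  prev <- c(rep(0.10, 8), 0.05, 0.08, 0.12, 0.15)
  conds <- data.frame(
    code = sprintf("C%02d", seq_len(k)),
    label = sprintf("Condition %02d", seq_len(k)),
    chapter = roman_chapters(rep(1:14, length.out = k)),
    prevalence = prev,
    rr_female = 1, rr_t2dm = 1,
    stringsAsFactors = FALSE
  )
  planted <- data.frame(
    code_i = c("C01", "C03", "C05", "C07"),
    code_j = c("C02", "C04", "C06", "C08"),
    subgroups = subgroup_labels(),
    odds_ratio = 8,
    stringsAsFactors = FALSE
  )
  labs <- default_lab_specs()
  # no planted type shift: give T2DM rows the T1DM parameters
  for (lab in unique(labs$lab)) for (sx in c("male", "female")) {
    src <- labs$lab == lab & labs$diabetes_type == "T1DM" & labs$sex == sx
    dst <- labs$lab == lab & labs$diabetes_type == "T2DM" & labs$sex == sx
    labs$location[dst] <- labs$location[src]
    labs$scale[dst] <- labs$scale[src]
  }
  fu <- default_followup_spec()
  fu$meanlog <- mean(fu$meanlog)
  fu$sdlog <- mean(fu$sdlog)
  synthetic_config(
    n_per_cohort = n_per_cohort,
    sex_fraction_female = 0.5,
    condition_specs = conds,
    planted_pairs = planted,
    lab_specs = labs,
    followup_spec = fu,
    seed = seed
  )
}

#' Planted-structure recovery experiment
#'
#' Runs the full pipeline (generate -> cohort -> associate -> contrast) on
#' `n_reps` seeded replicates of a scenario and checks, per replicate,
#' whether every planted pair is recovered as a significant edge in its
#' target subgroup, whether every subgroup-unique planted pair surfaces in
#' the unique-pair report, and (when the scenario plants no lab shift)
#' whether all between-type lab SMDs stay below 0.10 in absolute value.
#'
#' @param n_reps number of replicates (default 20).
#' @param seed root seed; replicate r uses a substream of it.
#' @param scenario function(seed) returning a [synthetic_config()]
#'   (default [recovery_scenario_config()]).
#' @param t_threshold significance threshold (default 1.96).
#' @return data.frame, one row per replicate: `rep`, `n_planted`,
#'   `n_recovered`, `all_recovered`, `n_unique_expected`,
#'   `n_unique_found`, `all_unique`, `max_abs_smd`, `smd_ok`.
#' @export
recovery_experiment <- function(n_reps = 20L, seed = 1L,
                                scenario = recovery_scenario_config,
                                t_threshold = 1.96) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- scenario(substream_seed(seed, paste0("recovery.rep.", r)))
    truth <- planted_truth(cfg)
    res <- run_pipeline(cfg, t_threshold = t_threshold)

    n_planted <- 0L; n_recovered <- 0L
    n_unique_expected <- 0L; n_unique_found <- 0L
    up <- res$contrast$unique_pairs
    up_keys <- paste(up$subgroup, pair_key(up$code_i, up$code_j))
    for (sg in subgroup_labels()) {
      tp <- truth$pairs[[sg]]
      if (!nrow(tp)) next
      edges <- res$assoc[[sg]]$edges
      edge_keys <- pair_key(edges$code_i, edges$code_j)
      planted_keys <- pair_key(tp$code_i, tp$code_j)
      n_planted <- n_planted + length(planted_keys)
      n_recovered <- n_recovered + sum(planted_keys %in% edge_keys)
      # planted pairs targeting only this subgroup should be unique to it
      other <- do.call(rbind, truth$pairs[setdiff(subgroup_labels(), sg)])
      only_here <- !(planted_keys %in%
                       if (nrow(other)) pair_key(other$code_i, other$code_j)
                       else character(0))
      n_unique_expected <- n_unique_expected + sum(only_here)
      n_unique_found <- n_unique_found +
        sum(paste(sg, planted_keys[only_here]) %in% up_keys)
    }

    no_shift <- all(truth$lab_shift_direction$direction == 0)
    max_smd <- NA_real_
    if (no_shift) {
      t1 <- res$table1
      labs <- unique(cfg$lab_specs$lab)
      max_smd <- max(abs(t1$smd[t1$stratum == "overall" &
                                  t1$variable %in% labs]))
    }
    rows[[r]] <- data.frame(
      rep = r, n_planted = n_planted, n_recovered = n_recovered,
      all_recovered = n_recovered == n_planted,
      n_unique_expected = n_unique_expected,
      n_unique_found = n_unique_found,
      all_unique = n_unique_found == n_unique_expected,
      max_abs_smd = max_smd,
      smd_ok = if (no_shift) max_smd < 0.10 else NA
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
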