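#' Cohort-building stage
#'
#' From a raw extract: recompute index dates from index-disease diagnosis
#' records (patients with no qualifying record are excluded with a reason),
#' compute observed follow-up, 1:1 exact-match T1DM cases to T2DM
#' comparators on sex and index age, restrict to matched patients, extract
#' chapter-restricted comorbidity profiles and apply the per-cohort
#' prevalence filter.
#'
#' @param extract list with `patients`, `diagnoses`, `catalog` (see
#'   [generate_cohort()] / [read_extract_csv()]).
#' @param prevalence_threshold retention threshold (default 0.01).
#' @param chapters ICD chapter whitelist (default I-XIV).
#' @param seed seed for the matching draws.
#' @return list with `patients` (matched patients + `followup_years`),
#'   `matched` (pairs/unmatched), `profiles` (long, retained codes),
#'   `retained`, `prevalence`, `excluded`, `catalog`, `multimorbidity`
#'   (data.frame `patient_id`, `n_conditions`, `is_multimorbid`).
#' @export
stage_cohort <- function(extract, prevalence_threshold = 0.01,
                         chapters = roman_chapters(1:14), seed = 1L) {
  patients <- extract$patients
  diagnoses <- extract$diagnoses
  catalog <- extract$catalog
  index_codes <- catalog$condition_code[catalog$is_index_disease == 1L]

  idx <- assign_index_dates(diagnoses, index_codes)
  missing_idx <- setdiff(patients$patient_id, idx$patient_id)
  excluded <- data.frame(patient_id = missing_idx,
                         reason = rep("no_index_diagnosis",
                                      length(missing_idx)),
                         stringsAsFactors = FALSE)
  patients <- patients[patients$patient_id %in% idx$patient_id, ]
  patients$index_date <- idx$index_date[match(patients$patient_id,
                                              idx$patient_id)]
  patients$followup_years <- observed_followup(patients$index_date,
                                               patients$last_visit_date)

  matched <- match_cohorts(
    patients[patients$diabetes_type == "T1DM", ],
    patients[patients$diabetes_type == "T2DM", ],
    seed = seed
  )
  keep_ids <- c(matched$pairs$case_id, matched$pairs$comparator_id)
  patients <- patients[patients$patient_id %in% keep_ids, ]

  profiles_raw <- build_profiles(patients, diagnoses, catalog, chapters)
  filt <- prevalence_filter(profiles_raw, patients, prevalence_threshold)

  n_cond <- table(filt$profiles$patient_id)
  mm <- data.frame(
    patient_id = patients$patient_id,
    n_conditions = as.integer(n_cond[patients$patient_id]),
    stringsAsFactors = FALSE
  )
  mm$n_conditions[is.na(mm$n_conditions)] <- 0L
  mm$is_multimorbid = mm$n_conditions >= 2L

  list(patients = patients, matched = matched, profiles = filt$profiles,
       retained = filt$retained, prevalence = filt$prevalence,
       excluded = excluded, catalog = catalog, multimorbidity = mm)
}

#' Descriptive stage
#'
#' Table-one-style summaries and SMDs for the matched cohorts.
#' @param cohort result of [stage_cohort()].
#' @return data.frame from [describe_cohorts()].
#' @export
stage_describe <- function(cohort) {
  describe_cohorts(cohort$patients)
}

#' Pair-association stage
#'
#' For each of the four diabetes-type x sex subgroups: contingency counts,
#' SCI/phi/t, the SCI cut-off derivation and the significant edge set.
#'
#' @param cohort result of [stage_cohort()].
#' @param t_threshold significance threshold on t (default 1.96).
#' @return named list per subgroup: `pairs`, `cutoff`, `edges`, `N`,
#'   `codes`.
#' @export
stage_associate <- function(cohort, t_threshold = 1.96) {
  out <- list()
  for (sg in subgroup_labels()) {
    parts <- strsplit(sg, "_")[[1]]
    sel <- cohort$patients$diabetes_type == parts[1] &
      cohort$patients$sex == parts[2]
    ids <- cohort$patients$patient_id[sel]
    codes <- cohort$retained[[parts[1]]]
    pairs <- pair_statistics(count_pairs(cohort$profiles, ids, codes))
    cutoff <- derive_cutoff(pairs, t_threshold)
    edges <- significant_edges(pairs, cutoff)
    out[[sg]] <- list(pairs = pairs, cutoff = cutoff, edges = edges,
                      N = length(ids), codes = codes)
  }
  out
}

#' Network stage
#'
#' Builds the four subgroup networks and computes node metrics, summaries,
#' PageRank hubs and chapter-level aggregates.
#'
#' @param assoc result of [stage_associate()].
#' @param catalog condition catalog.
#' @param damping PageRank damping (default 0.85).
#' @param hub_k number of hubs (default 10).
#' @return list with `networks` (named list of `mm_network`),
#'   `node_metrics`, `summary` (one row per subgroup), `hubs`, `systems`.
#' @export
stage_network <- function(assoc, catalog, damping = 0.85, hub_k = 10) {
  networks <- list()
  nm_list <- list()
  sum_list <- list()
  hub_list <- list()
  sys_list <- list()
  for (sg in names(assoc)) {
    nw <- build_network(assoc[[sg]]$codes, assoc[[sg]]$edges, label = sg)
    networks[[sg]] <- nw
    nm <- node_metrics(nw, damping)
    nm_list[[sg]] <- data.frame(subgroup = sg, nm, stringsAsFactors = FALSE)
    sum_list[[sg]] <- summarize_network(nw)
    hub_list[[sg]] <- data.frame(subgroup = sg,
                                 pagerank_hubs(nw, hub_k, damping),
                                 stringsAsFactors = FALSE)
    sys_list[[sg]] <- data.frame(subgroup = sg,
                                 system_aggregates(nw, catalog),
                                 stringsAsFactors = FALSE)
  }
  list(networks = networks,
       node_metrics = do.call(rbind, c(nm_list, make.row.names = FALSE)),
       summary = do.call(rbind, c(sum_list, make.row.names = FALSE)),
       hubs = do.call(rbind, c(hub_list, make.row.names = FALSE)),
       systems = do.call(rbind, c(sys_list, make.row.names = FALSE)))
}

#' Contrast stage
#'
#' All 12 ordered A-not-in-B difference networks and the subgroup-unique
#' pair report.
#'
#' @param networks named list of the four subgroup `mm_network`s.
#' @return list with `differences` (named list `A_not_B`) and
#'   `unique_pairs`.
#' @export
stage_contrast <- function(networks) {
  diffs <- list()
  for (a in names(networks)) for (b in names(networks)) {
    if (a == b) next
    diffs[[paste0(a, "_not_", b)]] <- difference_network(networks[[a]],
                                                         networks[[b]])
  }
  list(differences = diffs, unique_pairs = unique_pairs(networks))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> cohort -> describe -> associate -> network ->
#' contrast. With `out_dir` set, every stage's tables are written as plain
#' CSV (ISO-8601 dates), networks additionally as GraphML, and a JSON run
#' manifest records configuration, seed, package version and per-stage
#' counts. Re-running with the same configuration and seed reproduces
#' byte-identical outputs.
#'
#' @param config a [synthetic_config()] (used when `input` is `NULL`).
#' @param input optional extract (list or directory path of CSVs) to use
#'   instead of simulating.
#' @param prevalence_threshold retention threshold (default 0.01).
#' @param t_threshold significance threshold on t (default 1.96).
#' @param chapters ICD chapter whitelist (default I-XIV).
#' @param damping PageRank damping (default 0.85).
#' @param hub_k hubs per subgroup (default 10).
#' @param seed seed for the matching stage (default: the config's seed).
#' @param out_dir optional output directory.
#' @return list with `extract`, `cohort`, `table1`, `assoc`, `network`,
#'   `contrast`, `manifest`.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         input = NULL,
                         prevalence_threshold = 0.01,
                         t_threshold = 1.96,
                         chapters = roman_chapters(1:14),
                         damping = 0.85,
                         hub_k = 10,
                         seed = NULL,
                         out_dir = NULL) {
  seed <- seed %||% config$seed
  extract <- if (is.null(input)) generate_cohort(config)
             else if (is.character(input)) read_extract_csv(input)
             else input
  cohort <- stage_cohort(extract, prevalence_threshold, chapters, seed)
  table1 <- stage_describe(cohort)
  assoc <- stage_associate(cohort, t_threshold)
  network <- stage_network(assoc, cohort$catalog, damping, hub_k)
  contrast <- stage_contrast(network$networks)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mmnet")),
    seed = seed,
    synthetic = is.null(input),
    parameters = list(prevalence_threshold = prevalence_threshold,
                      t_threshold = t_threshold,
                      chapters = chapters, damping = damping, hub_k = hub_k),
    config = if (is.null(input)) unclass_config(config) else NULL,
    counts = list(
      n_patients = nrow(extract$patients),
      n_diagnoses = nrow(extract$diagnoses),
      n_matched_pairs = nrow(cohort$matched$pairs),
      n_unmatched = nrow(cohort$matched$unmatched),
      retained_conditions = lapply(cohort$retained, length),
      edges_per_subgroup = lapply(assoc, function(a) a$cutoff$n_edges)
    )
  )

  res <- list(extract = extract, cohort = cohort, table1 = table1,
              assoc = assoc, network = network, contrast = contrast,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

# Serialise a synthetic_config for the manifest (data.frames -> lists).
unclass_config <- function(config) {
  out <- unclass(config)
  out$index_window <- as.character(out$index_window)
  out
}

#' Write all pipeline outputs
#'
#' Emits, under `out_dir`: `matched_pairs.csv`, `unmatched.csv`,
#' `profiles.csv` (semicolon-joined retained codes), `prevalence.csv`,
#' `table1.csv`, per-subgroup `pairs_<subgroup>.csv` and
#' `cutoff_<subgroup>.json`, `network_<subgroup>.graphml`,
#' `node_metrics_<subgroup>.csv`, `hubs_<subgroup>.csv`, `summary_all.csv`,
#' `system_aggregates.csv`, `difference_<A>_not_<B>.csv` for all 12 ordered
#' contrasts, `unique_pairs.csv` and `manifest.json`. Report files round
#' network metrics to 3 decimals and SMDs to 2; machine-readable pair and
#' node tables keep full precision.
#'
#' @param res result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)

  wcsv(res$cohort$matched$pairs, "matched_pairs.csv")
  wcsv(res$cohort$matched$unmatched, "unmatched.csv")
  prof <- res$cohort$profiles
  joined <- vapply(split(prof$condition_code, prof$patient_id),
                   paste, character(1), collapse = ";")
  all_ids <- sort(res$cohort$patients$patient_id)
  wcsv(data.frame(patient_id = all_ids,
                  conditions = unname(joined[all_ids]),
                  stringsAsFactors = FALSE) |>
         transform(conditions = ifelse(is.na(conditions), "", conditions)),
       "profiles.csv")
  wcsv(res$cohort$prevalence, "prevalence.csv")

  t1 <- res$table1
  t1$smd <- round(t1$smd, 2)
  wcsv(t1, "table1.csv")

  for (sg in names(res$assoc)) {
    a <- res$assoc[[sg]]
    pairs <- a$pairs
    pairs$passes <- !is.na(pairs$t) & pairs$t > res$manifest$parameters$t_threshold
    wcsv(pairs, paste0("pairs_", sg, ".csv"))
    jsonlite::write_json(a$cutoff[c("q", "e", "sci_cutoff")],
                         file.path(out_dir, paste0("cutoff_", sg, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write_network_graphml(res$network$networks[[sg]], res$cohort$catalog,
                          file.path(out_dir, paste0("network_", sg, ".graphml")))
    nm <- res$network$node_metrics
    wcsv(nm[nm$subgroup == sg, ], paste0("node_metrics_", sg, ".csv"))
    hb <- res$network$hubs
    wcsv(hb[hb$subgroup == sg, ], paste0("hubs_", sg, ".csv"))
  }
  summ <- res$network$summary
  for (col in c("density", "avg_degree", "avg_weighted_degree",
                "avg_harmonic_centrality"))
    summ[[col]] <- round(summ[[col]], 3)
  wcsv(summ, "summary_all.csv")
  wcsv(res$network$systems, "system_aggregates.csv")

  for (nm in names(res$contrast$differences))
    wcsv(res$contrast$differences[[nm]]$edges,
         paste0("difference_", nm, ".csv"))
  wcsv(res$contrast$unique_pairs, "unique_pairs.csv")

  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
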