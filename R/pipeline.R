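# Pipeline entry points tying the stages together on disk: simulate a
# cohort directory, then preprocess -> window -> featurize -> train ->
# evaluate with stage outputs cached under the results directory. Every
# cached stage output carries the hash of the configuration that produced
# it, and is reused only when that hash matches.

#' Simulate a cohort to disk
#'
#' @param out_dir Output directory for the ACC CSV files and manifest.
#' @param n_stroke,n_control Subject counts.
#' @param cfg A [sim_config()].
#' @return The manifest data frame, invisibly.
#' @export
cmd_simulate <- function(out_dir, n_stroke = 84L, n_control = 101L,
                         cfg = sim_config()) {
  recs <- simulate_cohort(n_stroke, n_control, cfg)
  manifest <- write_cohort(recs, out_dir)
  message(sprintf("simulated %d stroke + %d control subjects (seed %d) -> %s",
                  n_stroke, n_control, cfg$seed, out_dir))
  invisible(manifest)
}

stage_fresh <- function(stamp_file, hash) {
  file.exists(stamp_file) &&
    identical(readLines(stamp_file, warn = FALSE)[1], hash)
}

#' Run the analysis pipeline over a cohort directory
#'
#' Reads the cohort manifest, preprocesses every recording (cached as
#' processed-pair CSVs), extracts windows and features per window length
#' (cached as feature CSVs), and runs the model-comparison experiment.
#' Stage caches are keyed by a hash of the stage configuration; removing a
#' cache file simply recomputes that stage.
#'
#' @param cohort_dir Directory written by [cmd_simulate()] (or laid out the
#'   same way).
#' @param out_dir Results directory.
#' @param families,window_min,grids,n_parts,alpha,seed See
#'   [run_experiment()].
#' @param pcfg A [preprocess_config()].
#' @return The `paresis_experiment`, invisibly; results tables and the
#'   diagram structure are written under `out_dir`.
#' @export
cmd_run <- function(cohort_dir, out_dir, families = c("svm", "knn", "rf"),
                    window_min = c(15, 60), grids = default_grids(),
                    n_parts = 5L, alpha = 0.05, seed = 1L,
                    pcfg = preprocess_config()) {
  mf <- file.path(cohort_dir, "manifest.csv")
  if (!file.exists(mf)) stopf("missing manifest: %s", mf)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: preprocessing, cached per subject
  pp_dir <- file.path(out_dir, "processed")
  dir.create(pp_dir, showWarnings = FALSE)
  pp_hash <- hash_config(pcfg)
  pairs <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$subject_id[i]
    csv <- file.path(pp_dir, paste0(sid, ".csv"))
    stamp <- file.path(pp_dir, paste0(sid, ".hash"))
    if (stage_fresh(stamp, pp_hash) && file.exists(csv)) {
      return(read_processed_pair(csv))
    }
    rec <- read_recording(sid, cohort_dir, manifest$group[i],
                          manifest$paresis_grade[i],
                          manifest$affected_side[i])
    pair <- preprocess_recording(rec, pcfg)
    write_processed_pair(pair, csv)
    writeLines(pp_hash, stamp)
    pair
  })

  # stage 2: features per window length, cached
  ft_hash <- hash_config(list(pcfg = pp_hash, window_min = window_min))
  for (L in window_min) {
    csv <- file.path(out_dir, sprintf("features_%dmin.csv", L))
    stamp <- file.path(out_dir, sprintf("features_%dmin.hash", L))
    if (stage_fresh(stamp, ft_hash) && file.exists(csv)) next
    wf <- windows_for_length(pairs, L)
    utils::write.csv(wf$feats, csv, row.names = FALSE)
    writeLines(ft_hash, stamp)
  }

  # stage 3: experiment
  exp <- run_experiment(pairs, families = families, window_min = window_min,
                        grids = grids, n_parts = n_parts, alpha = alpha,
                        seed = seed)
  run_hash <- hash_config(list(ft = ft_hash, families = families,
                               n_parts = n_parts, alpha = alpha,
                               seed = seed))
  ov <- exp$overall
  ov$config_hash <- run_hash
  pt <- exp$parts
  pt$config_hash <- run_hash
  utils::write.csv(ov, file.path(out_dir, "results_overall.csv"),
                   row.names = FALSE)
  utils::write.csv(pt, file.path(out_dir, "results_parts.csv"),
                   row.names = FALSE)
  if (!is.null(exp$diagram)) {
    jsonlite::write_json(
      list(models = exp$diagram$models, avg_ranks = exp$diagram$avg_ranks,
           cd = exp$diagram$cd, groups = exp$diagram$groups,
           friedman_statistic = exp$friedman$statistic,
           friedman_p = exp$friedman$p.value, config_hash = run_hash),
      file.path(out_dir, "cd_diagram.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(exp)
}
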