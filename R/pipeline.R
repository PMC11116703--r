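#' Default pipeline configuration
#'
#' The full configuration the pipeline runs from, with every stage's
#' parameters and seeds explicit. Values can be overridden by a (possibly
#' partial) YAML file or list; unknown fields are rejected by the schema
#' check in [run_pipeline()].
#'
#' @return Nested list of stage settings.
#' @export
default_config <- function() {
  list(
    simulate = list(n_subjects = 3L, sessions_per_subject = 2L,
                    height = 64L, width = 64L, fps = 40, dur_per_state = 300,
                    noise_sd = 1, f0 = 100, seed = 1L),
    preprocess = list(cutoff = 0.1),
    gica = list(k = 8L, n_runs = 10L, mode = "both", seed = 1L),
    annotate = list(midline_frac = 0.5, elongation = 4),
    activations = list(k_sigma = 3, n_per_state = 5000L, seed = 1L),
    output = list(write_movies = FALSE)
  )
}

validate_config <- function(config) {
  ref <- default_config()
  for (stage in names(config)) {
    if (!stage %in% names(ref)) stop("unknown config stage: ", stage)
    for (f in names(config[[stage]])) {
      if (!f %in% names(ref[[stage]])) {
        stop("unknown config field: ", stage, "$", f)
      }
      ref[[stage]][[f]] <- config[[stage]][[f]]
    }
  }
  st <- ref$simulate
  if (st$n_subjects < 1 || st$sessions_per_subject < 1 ||
      st$dur_per_state <= 0 || st$fps <= 0) {
    stop("invalid simulate config (n_subjects, sessions_per_subject, fps ",
         "and dur_per_state must be positive)")
  }
  ref
}

#' Run the synthetic pipeline end to end and write all stage outputs
#'
#' Orchestrates simulate -> preprocess -> group ICA -> annotate ->
#' activations -> statistics from a single validated configuration, writing
#' every stage product plus a manifest (configuration, its hash, seeds,
#' package version) to the output directory. Rerunning with the same
#' configuration reproduces all outputs exactly.
#'
#' @param config configuration list, path to a YAML file, or `NULL` for
#'   [default_config()]; partial configs are filled with defaults and
#'   validated against the schema.
#' @param out_dir output directory (created if needed).
#' @return The `wf_analysis` result, invisibly. Files written: `atlas.tif`
#'   (+ legend JSON), `labels.csv`, `occurrence.csv`,
#'   `occurrence_summary.csv`, `cooccurrence_<state>.csv` (per-state mean
#'   co-occurrence matrices), `group_cooccurrence.csv`, `expected_null.json`,
#'   `prominent.csv`, `anova.csv`, `posthoc.csv`, `rindex.csv` (when order
#'   selection ran), `manifest.json`, and per-session movies when
#'   `output$write_movies` is set.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- config$simulate
  study <- simulate_study(n_subjects = sim$n_subjects,
                          sessions_per_subject = sim$sessions_per_subject,
                          height = sim$height, width = sim$width,
                          fps = sim$fps, dur_per_state = sim$dur_per_state,
                          seed = sim$seed, noise_sd = sim$noise_sd,
                          f0 = sim$f0)
  write_atlas(study$atlas, file.path(out_dir, "atlas.tif"))
  if (isTRUE(config$output$write_movies)) {
    for (i in seq_len(study$n_sessions)) {
      write_movie(study_session(study, i),
                  file.path(out_dir, paste0(study$session_id[i], ".tif")))
    }
  }

  res <- analyze_study(study, k = config$gica$k,
                       n_runs = config$gica$n_runs,
                       mode = config$gica$mode, seed = config$gica$seed,
                       cutoff = config$preprocess$cutoff,
                       k_sigma = config$activations$k_sigma,
                       n_per_state = config$activations$n_per_state,
                       null_seed = config$activations$seed,
                       midline_frac = config$annotate$midline_frac,
                       elongation = config$annotate$elongation)

  utils::write.csv(res$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(res$occurrence$per_subject,
                   file.path(out_dir, "occurrence.csv"), row.names = FALSE)
  utils::write.csv(res$occurrence$summary,
                   file.path(out_dir, "occurrence_summary.csv"),
                   row.names = FALSE)
  for (st in names(res$global_phi)) {
    R <- Reduce(`+`, lapply(res$records, function(r) {
      state_matrices(r$binaries, r$segments)[[st]]
    })) / length(res$records)
    utils::write.csv(round(R, 4),
                     file.path(out_dir, paste0("cooccurrence_",
                                               gsub("[^A-Za-z0-9.]", "_", st),
                                               ".csv")))
  }
  cooc_long <- do.call(rbind, lapply(names(res$cooccurrence), function(g) {
    cbind(group = g, res$cooccurrence[[g]])
  }))
  utils::write.csv(cooc_long, file.path(out_dir, "group_cooccurrence.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(expected = res$null$expected,
                            n_sim = res$null$n_sim,
                            n_per_state = res$null$n_per_state,
                            seed = res$null$seed),
                       file.path(out_dir, "expected_null.json"),
                       auto_unbox = TRUE, digits = NA)
  prom <- do.call(rbind, lapply(names(res$prominent), function(st) {
    cbind(state = st, res$prominent[[st]])
  }))
  utils::write.csv(prom, file.path(out_dir, "prominent.csv"),
                   row.names = FALSE)
  an <- do.call(rbind, lapply(c(occurrence = "anova_occurrence",
                                cooccurrence = "anova_cooccurrence"),
                              function(f) {
    a <- res[[f]]
    if (is.null(a)) return(NULL)
    data.frame(measure = sub("anova_", "", f), F = a$F, df1 = a$df1,
               df2 = a$df2, p = a$p)
  }))
  utils::write.csv(an, file.path(out_dir, "anova.csv"), row.names = FALSE)
  ph <- rbind(cbind(measure = "occurrence", res$posthoc_occurrence),
              cbind(measure = "cooccurrence", res$posthoc_cooccurrence))
  utils::write.csv(ph, file.path(out_dir, "posthoc.csv"), row.names = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "wfgica",
    version = as.character(utils::packageVersion("wfgica")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seeds = list(simulate = sim$seed, gica = config$gica$seed,
                 activations = config$activations$seed),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
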