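# End-to-end orchestration over synthetic cohorts: simulate -> NES -> Cox
# screen -> stratify -> single-cell CNV -> assignment -> report. Every stage
# derives its seed deterministically from the master seed, logs what it
# dropped, and records its outputs in a run manifest so a rerun with the
# same config reproduces identical results.

stage_seed <- function(master, k) (as.integer(master) + 1000L * k) %% 2147483647L

#' Run the full synthetic-data analysis pipeline
#'
#' Executes, in dependency order: `simulate` (gene universe, signature
#' registry, bulk cohorts, single-cell samples), `nes` (per-cohort NES
#' matrices), `cox` (per-cohort prognostic screen plus pooled cell-type
#' consistency), `stratify` (two-cluster PIR/NIR stratification with
#' log-rank test per cohort), `cnv` (transformed-cell calls per sc sample),
#' `assign` (fold-change assignment plus cell typing and composition), and
#' `report` (per-cohort summary table). A failing stage aborts the run
#' with the stage named.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param alpha Prognostic screening cut-off (default 0.05).
#' @param sc_samples_per_profile Single-cell samples simulated per profile
#'   (default 2 NIR-like + 2 PIR-like).
#' @param out_dir Optional directory: when given, per-stage TSV outputs and
#'   a JSON manifest are written there.
#' @return List of class `run_manifest`: `config`, `config_hash`, `seed`,
#'   `stages` (`data.frame` of stage/status), and `results` holding every
#'   stage's in-memory outputs.
#' @export
run_pipeline <- function(config = sim_config(), alpha = 0.05,
                         sc_samples_per_profile = 2L, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  stages <- c("simulate", "nes", "cox", "stratify", "cnv", "assign", "report")
  status <- stats::setNames(rep("pending", length(stages)), stages)
  results <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    status[[name]] <<- "ok"
    results[[name]] <<- res
    res
  }

  sim <- run_stage("simulate", function() {
    universe <- make_universe_and_signatures(config)
    cohorts <- lapply(seq_len(config$n_cohorts), function(c_i) {
      simulate_bulk_cohort(config, universe,
                           seed = stage_seed(config$seed, c_i))
    })
    names(cohorts) <- paste0("cohort", seq_len(config$n_cohorts))
    profiles <- rep(c("NIR-like", "PIR-like"), each = sc_samples_per_profile)
    sc_samples <- lapply(seq_along(profiles), function(s_i) {
      simulate_sc_sample(config, universe, profile = profiles[s_i],
                         seed = stage_seed(config$seed, 100L + s_i))
    })
    names(sc_samples) <- sprintf("sc%02d_%s", seq_along(profiles),
                                 sub("-like", "", profiles))
    list(universe = universe, cohorts = cohorts, sc_samples = sc_samples)
  })

  nes_list <- run_stage("nes", function() {
    lapply(sim$cohorts, function(coh) {
      compute_nes_matrix(coh$expr, sim$universe$signatures)
    })
  })

  cox <- run_stage("cox", function() {
    records <- lapply(names(nes_list), function(cn) {
      screen_signatures(nes_list[[cn]], sim$cohorts[[cn]]$survival,
                        alpha = alpha, cohort_id = cn)
    })
    names(records) <- names(nes_list)
    all_records <- do.call(rbind, records)
    list(records = records,
         consistency = consistency_by_cell_type(all_records,
                                                sim$universe$signatures))
  })

  strat <- run_stage("stratify", function() {
    cd8_ids <- names(sim$universe$signatures)[
      signature_cell_types(sim$universe$signatures) == "CD8_T_cell"]
    out <- lapply(names(nes_list), function(cn) {
      prog <- cox$records[[cn]]
      prog_ids <- prog$signature_id[prog$prognostic]
      if (length(prog_ids) < 2L)
        stop("no prognostic signatures in ", cn)
      stratify_cohort(nes_list[[cn]], prog_ids, sim$cohorts[[cn]]$survival,
                      cd8_signature_ids = cd8_ids)
    })
    names(out) <- names(nes_list)
    out
  })

  cnv <- run_stage("cnv", function() {
    lapply(sim$sc_samples, function(s) {
      identify_transformed_cells(s$counts, sim$universe$annotation)
    })
  })

  assign <- run_stage("assign", function() {
    bulk_labels <- lapply(strat, function(r) r$labels)
    bulk_expr <- lapply(sim$cohorts, function(coh) coh$expr)
    assignments <- lapply(names(sim$sc_samples), function(sn) {
      assign_sc_sample(sim$sc_samples[[sn]]$counts,
                       sim$universe$signatures,
                       bulk_labels_list = bulk_labels,
                       sc_sample_id = sn,
                       space = "genes", bulk_expr_list = bulk_expr)
    })
    names(assignments) <- names(sim$sc_samples)
    compositions <- lapply(names(sim$sc_samples), function(sn) {
      labels <- assign_cell_types_by_signature(
        sim$sc_samples[[sn]]$counts, sim$universe$signatures)
      composition_summary(labels, sample_id = sn)
    })
    names(compositions) <- names(sim$sc_samples)
    list(assignments = assignments, compositions = compositions)
  })

  report <- run_stage("report", function() {
    rows <- lapply(names(strat), function(cn) {
      prog <- cox$records[[cn]]
      prog_ids <- prog$signature_id[prog$prognostic]
      types <- signature_cell_types(sim$universe$signatures)[
        match(prog_ids, names(sim$universe$signatures))]
      data.frame(cohort = cn,
                 n_samples = ncol(nes_scores(nes_list[[cn]])),
                 n_prognostic_signatures = length(prog_ids),
                 n_cell_types = length(unique(types)),
                 n_pir = sum(strat[[cn]]$labels == "PIR"),
                 n_nir = sum(strat[[cn]]$labels == "NIR"),
                 logrank_p = strat[[cn]]$logrank_p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  manifest <- structure(
    list(config = config,
         config_hash = config_hash(config),
         seed = config$seed,
         stages = data.frame(stage = stages,
                             status = unname(status[stages]),
                             stringsAsFactors = FALSE),
         results = results),
    class = "run_manifest")

  if (!is.null(out_dir)) write_manifest_outputs(manifest, out_dir)
  manifest
}

write_manifest_outputs <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- manifest$results
  for (cn in names(res$nes)) {
    write_nes_matrix(res$nes[[cn]],
                     file.path(out_dir, paste0("nes_", cn, ".tsv")))
    data.table::fwrite(res$cox$records[[cn]],
                       file.path(out_dir, paste0("cox_", cn, ".tsv")),
                       sep = "\t")
    strat <- res$stratify[[cn]]
    data.table::fwrite(
      data.frame(sample = names(strat$labels),
                 cluster = unname(strat$cluster_assignment[names(strat$labels)]),
                 label = unname(strat$labels)),
      file.path(out_dir, paste0("stratification_", cn, ".tsv")), sep = "\t")
  }
  data.table::fwrite(res$cox$consistency,
                     file.path(out_dir, "consistency.tsv"), sep = "\t")
  data.table::fwrite(res$report, file.path(out_dir, "report.tsv"), sep = "\t")
  for (sn in names(res$cnv)) {
    data.table::fwrite(res$cnv[[sn]],
                       file.path(out_dir, paste0("cnv_", sn, ".tsv")),
                       sep = "\t")
  }
  assign_df <- do.call(rbind, lapply(res$assign$assignments, function(a) {
    data.frame(sc_sample = a$sc_sample_id,
               total_fc = a$total_fc,
               n_usable_cohorts = a$n_usable_cohorts,
               label = a$label, stringsAsFactors = FALSE)
  }))
  data.table::fwrite(assign_df, file.path(out_dir, "sc_assignments.tsv"),
                     sep = "\t")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, seed = manifest$seed,
         stages = manifest$stages),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @exportS3Method base::print
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "hash", x$config_hash, "\n")
  print(x$stages)
  invisible(x)
}

#' Per-cohort summary table of a pipeline run
#'
#' One row per cohort: sample count, prognostic signature and cell-type
#' counts, PIR/NIR sizes and the log-rank p-value of the split (PIR + NIR
#' always equals the cohort's sample count).
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @return The report `data.frame`.
#' @export
report_summary <- function(manifest) {
  if (is.null(manifest$results$report))
    stop("manifest has no report stage output")
  manifest$results$report
}
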