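# End-to-end orchestration: generate every synthetic input, push it
# through all analysis stages and write the artifact bundle with a
# manifest, so a run is reproducible from its manifest alone.

#' Run the full synthetic analysis pipeline
#'
#' Generates promoters, occupancies, PBM probes, a noise table, turnover
#' values and cytometry events from one master seed, runs every analysis
#' stage (TBS scanning, co-activator classification, DM, PBM class
#' comparisons, turnover binning, the cytometry chain, and both promoter
#' archetype simulations), and writes all tables plus a `manifest.yaml`
#' recording the configuration, seed and package version.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param config A [synth_config()].
#' @param n_cells,n_steps Simulation size for the archetype runs.
#' @param include_sweep Also run a small phase-diagram sweep
#'   (default FALSE; the full sweep is the expensive stage).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = synth_config(),
                         n_cells = 500, n_steps = 150,
                         include_sweep = FALSE, quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()
  out <- function(f) file.path(out_dir, f)
  tsv <- function(x, f) {
    readr::write_tsv(x, out(f))
    paths[[sub("\\..*$", "", f)]] <<- out(f)
  }

  say("[synth] generating inputs (n_genes = %d)", config$n_genes)
  promoters <- gen_promoters(config, seed = derive_seed(seed, 1))
  write_promoters(stats::setNames(promoters$sequence, promoters$gene_id),
                  out("promoters.fasta"))
  paths$promoters_fasta <- out("promoters.fasta")
  tsv(dplyr::select(promoters, -"sequence"), "promoter_truth.tsv")

  occ <- gen_occupancy(config, promoters, seed = derive_seed(seed, 2))
  tsv(occ$occupancy, "occupancy.tsv")
  tsv(occ$truth, "occupancy_truth.tsv")
  probes <- gen_pbm(config, seed = derive_seed(seed, 3))
  tsv(probes, "pbm_probes.tsv")
  noise_tbl <- gen_noise_table(config, promoters, seed = derive_seed(seed, 4))
  turn <- gen_turnover(config, promoters, seed = derive_seed(seed, 5))
  events <- gen_cytometry(config, seed = derive_seed(seed, 6))
  readr::write_csv(events, out("cytometry_events.csv"))
  paths$cytometry_events <- out("cytometry_events.csv")

  say("[classify] scanning %d promoters", nrow(promoters))
  calls <- scan_promoter(stats::setNames(promoters$sequence,
                                         promoters$gene_id))
  tsv(calls, "tbs_calls.tsv")
  coact <- classify_coactivator(occ$occupancy)
  tsv(coact, "coactivator_classes.tsv")

  say("[noise] DM over %d genes", nrow(noise_tbl))
  dm_tbl <- compute_dm(noise_tbl)
  tsv(dm_tbl, "noise_table.tsv")
  tsv(bin_turnover(turn), "turnover_bins.tsv")

  say("[pbm] aggregating %d probes", nrow(probes))
  medians <- aggregate_probe_signal(probes)
  tsv(medians, "pbm_motif_medians.tsv")
  pbm_sum <- class_signal_summary(probes)
  tsv(pbm_sum$comparisons, "pbm_class_comparisons.tsv")

  say("[cytometry] processing %d events", nrow(events))
  cyto <- cytometry_pipeline(events, method = "ratio")
  tsv(cyto$noise$replicates, "cytometry_replicates.tsv")
  tsv(cyto$stage_counts, "cytometry_stage_counts.tsv")

  say("[simulate] archetypes (%d cells x %d steps)", n_cells, n_steps)
  sims <- list(tata_box = params_tata_box(), tata_like = params_tata_like())
  sim_summary <- purrr::map(names(sims), function(nm) {
    sim <- simulate_population(sims[[nm]], n_cells = n_cells,
                               n_steps = n_steps,
                               seed = derive_seed(seed, 7))
    tsv(tidy(sim), paste0("simulation_", nm, ".tsv"))
    glance(sim)
  }) |> dplyr::bind_rows()
  tsv(sim_summary, "simulation_summary.tsv")

  if (include_sweep) {
    say("[sweep] phase diagram")
    pd <- sweep_phase_diagram(n_cells = n_cells, n_steps = n_steps,
                              seed = derive_seed(seed, 8))
    tsv(tibble::as_tibble(pd), "phase_diagram.tsv")
  }

  manifest <- list(
    package = "tbpnoise",
    version = as.character(utils::packageVersion("tbpnoise")),
    seed = as.integer(seed),
    n_cells = as.integer(n_cells),
    n_steps = as.integer(n_steps),
    include_sweep = include_sweep,
    config = unclass(rapply(config, function(x) x, how = "replace")),
    files = vapply(paths, basename, character(1))
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  paths$manifest <- out("manifest.yaml")
  say("[done] %d artifacts in %s", length(paths), out_dir)
  invisible(paths)
}
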