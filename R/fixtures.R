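#' Write a complete synthetic fixture set to disk
#'
#' Emits the OTU table (TSV), metadata (TSV), spectra (CSV), ground truth
#' (JSON) and run configuration (YAML) for one simulated study, plus a
#' manifest of paths and MD5 checksums. Two runs with the same design and
#' seed produce byte-identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Data frame with columns `file` and `md5`, invisibly.
#' @export
write_fixture_set <- function(out_dir, design = simulation_design(),
                              seed = 1L, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite)
    abort("directory '%s' is not empty (use overwrite = TRUE)", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_otu_study(design, seed)
  sp <- simulate_spectra(design, sim$otu, sim$metadata, seed,
                         log_abundance = sim$truth$log_abundance)
  paths <- file.path(out_dir, c("otu.tsv", "metadata.tsv", "spectra.csv",
                                "ground_truth.json", "config.yaml"))
  write_otu_table(sim$otu, paths[1L])
  write_metadata(sim$metadata, paths[2L])
  write_spectra_csv(sp$spectra, paths[3L])
  truth <- c(sim$truth[c("affected_taxa", "metabolite_effects", "coupling",
                         "library_sizes")],
             sp$truth[c("dilution", "shift_ppm")])
  jsonlite::write_json(truth, paths[4L], digits = NA, auto_unbox = TRUE)
  write_run_config(run_config(seed = seed), paths[5L])
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
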