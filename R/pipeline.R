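# End-to-end pipeline wiring: simulate a clonal cohort, render and segment
# probe signals, and score aneuploidy relative to the parental clone.

#' Simulate a clonal cohort of copy-number profiles
#'
#' Generates a parental (event-free) clone plus `n_samples` derived clones
#' with karyotype events, renders probe signals and segments them.
#'
#' @param genome A `genome_model`.
#' @param grid A `bin_grid`.
#' @param n_samples Number of derived clones.
#' @param config A `sim_config`.
#' @param seed Integer seed; per-sample seeds are derived from it.
#' @param params A `segmentation_params`.
#' @param burden_grades If TRUE, sample `i` receives exactly `i - 1`
#'   events (graded burden, no WGD) instead of Poisson counts — useful for
#'   recovery experiments with known ordering.
#' @return List with `parental` and `samples` (lists holding `track`,
#'   `events`, `signal`, `seg` per sample).
#' @export
simulate_cohort <- function(genome, grid, n_samples = 10,
                            config = sim_config(), seed = 1,
                            params = segmentation_params(),
                            burden_grades = FALSE) {
  seeds <- seed + seq_len(n_samples + 1) * 101
  par_sim <- simulate_karyotype(genome, grid, config, seed = seeds[1],
                                events = list(), sample_id = "P0")
  parental <- list(
    track = par_sim$track, events = par_sim$events,
    signal = render_probe_signal(par_sim$track, genome,
                                 config$probe_density, config$noise_sd,
                                 seed = seeds[1]))
  parental$seg <- segment_probes(parental$signal, params, genome)
  cfg_i <- config
  samples <- lapply(seq_len(n_samples), function(i) {
    if (burden_grades) cfg_i$p_wgd <- 0
    sim <- simulate_karyotype(genome, grid, cfg_i, seed = seeds[i + 1],
                              sample_id = sprintf("S%02d", i),
                              n_events = if (burden_grades) i - 1 else NULL)
    sig <- render_probe_signal(sim$track, genome, config$probe_density,
                               config$noise_sd, seed = seeds[i + 1])
    list(track = sim$track, events = sim$events, signal = sig,
         seg = segment_probes(sig, params, genome))
  })
  names(samples) <- sprintf("S%02d", seq_len(n_samples))
  list(parental = parental, samples = samples)
}

#' Ground-truth alteration burden of a copy-number track
#'
#' Mb-weighted total deviation of copy number from the baseline ploidy —
#' the quantity the aneuploidy score is expected to rank-order.
#'
#' @param track A `cn_track`.
#' @return Non-negative numeric burden (copy-Mb).
#' @export
true_burden <- function(track) {
  stopifnot(inherits(track, "cn_track"))
  sum(abs(track$cn - attr(track, "baseline_ploidy")) * track$width) / 1e6
}

#' Run the full simulate-segment-score pipeline
#'
#' @param n_samples Cohort size.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param scale Genome scale factor (1 = full hg38-like lengths).
#' @param bin_width Bin width in bp.
#' @param out_dir Optional output directory; when given, writes the SEG
#'   file, per-sample metrics TSV and a run manifest there.
#' @return The `aneuploidy_result` for the cohort (invisibly when writing
#'   files).
#' @export
run_pipeline <- function(n_samples = 10, config = sim_config(), seed = 1,
                         scale = 0.1, bin_width = 1e6, out_dir = NULL) {
  genome <- build_genome(scale = scale)
  grid <- make_bins(genome, bin_width)
  cohort <- simulate_cohort(genome, grid, n_samples, config, seed)
  segs <- lapply(cohort$samples, `[[`, "seg")
  res <- score_aneuploidy(segs, cohort$parental$seg, grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    seg_path <- file.path(out_dir, "segments.seg")
    met_path <- file.path(out_dir, "metrics.tsv")
    write_seg(c(list(cohort$parental$seg), unname(segs)), seg_path)
    write_tsv(res, met_path)
    write_manifest(file.path(out_dir, "manifest.json"),
                   config = unclass(config), seed = seed,
                   files = c(seg_path, met_path))
    return(invisible(res))
  }
  res
}
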