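# Synthetic-data generators: karyotypes, probe signals, expression,
# mutation tables, survival cohorts, growth curves. Every generator is
# deterministic for a fixed seed and returns its ground truth so downstream
# stages can be tested without external data.

#' Simulation configuration
#'
#' Bundles the knobs shared by the generators. Defaults describe a clonal
#' cell-line cohort: a handful of whole-chromosome/arm events per sample on
#' a near-diploid background, occasional whole-genome doubling and rare
#' chromothripsis, CytoScan-like probe noise, and a proportional
#' gene-dosage effect on expression.
#'
#' @param n_events_lambda Poisson mean of the per-sample event count.
#' @param p_wgd Probability a sample undergoes whole-genome doubling first.
#' @param event_weights Named weights over event kinds
#'   `whole_chrom`, `arm`, `focal`, `chromothripsis`.
#' @param copies Magnitude of the copy change per (non-chromothripsis) event.
#' @param probe_density Probes per Mb.
#' @param noise_sd Gaussian probe noise standard deviation (logR units).
#' @param dosage_slope Exponent of the (CN/2) gene-dosage factor on mean
#'   expression; 1 means expression proportional to copy number.
#' @param dispersion Negative-binomial dispersion of expression counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson.
#' @param base_mean,base_sdlog Baseline gene mean and lognormal spread of
#'   per-gene baselines (0 = identical baselines).
#' @param hazard_ratio Hazard ratio of the aneuploid-high (FGA Q4) group
#'   versus the rest in the survival generator.
#' @param baseline_hazard Baseline exponential event hazard (per day).
#' @param censor_rate Exponential censoring hazard (per day).
#' @param class_mix Named proportions over TP53 classes
#'   `WT`, `missense`, `truncating`, `multi`, `inframe` (must sum to 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_events_lambda = 3, p_wgd = 0.2,
                       event_weights = c(whole_chrom = 0.40, arm = 0.30,
                                         focal = 0.25, chromothripsis = 0.05),
                       copies = 1L,
                       probe_density = 20, noise_sd = 0.1,
                       dosage_slope = 1, dispersion = 0.1,
                       base_mean = 100, base_sdlog = 0,
                       hazard_ratio = 2, baseline_hazard = 1 / 1500,
                       censor_rate = 1 / 3000,
                       class_mix = c(WT = 0.50, missense = 0.30,
                                     truncating = 0.15, multi = 0.03,
                                     inframe = 0.02)) {
  cfg <- list(n_events_lambda = n_events_lambda, p_wgd = p_wgd,
              event_weights = event_weights, copies = as.integer(copies),
              probe_density = probe_density, noise_sd = noise_sd,
              dosage_slope = dosage_slope, dispersion = dispersion,
              base_mean = base_mean, base_sdlog = base_sdlog,
              hazard_ratio = hazard_ratio, baseline_hazard = baseline_hazard,
              censor_rate = censor_rate, class_mix = class_mix)
  rates <- c(n_events_lambda, p_wgd, probe_density, noise_sd, dosage_slope,
             dispersion, base_mean, base_sdlog, baseline_hazard, censor_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates and standard deviations must be finite and >= 0")
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  structure(cfg, class = "sim_config")
}

#' Construct a karyotype event
#'
#' @param kind One of `whole_chrom_gain`, `whole_chrom_loss`, `arm_gain`,
#'   `arm_loss`, `focal_gain`, `focal_loss`, `WGD`, `chromothripsis`.
#' @param chrom Target chromosome (all kinds but WGD).
#' @param arm Target arm for arm events ("p"/"q").
#' @param start,end Interval for focal events (bp).
#' @param copies Integer copy change (ignored for WGD/chromothripsis).
#' @param n_switches Number of state changes for chromothripsis (>= 2).
#' @param states Two copy-number states for chromothripsis, low then high.
#' @export
karyotype_event <- function(kind, chrom = NA, arm = NA, start = NA, end = NA,
                            copies = 1L, n_switches = NA, states = NULL) {
  kinds <- c("whole_chrom_gain", "whole_chrom_loss", "arm_gain", "arm_loss",
             "focal_gain", "focal_loss", "WGD", "chromothripsis")
  kind <- match.arg(kind, kinds)
  if (kind != "WGD" && kind != "chromothripsis" && copies == 0)
    stop("copies must be nonzero")
  if (kind == "chromothripsis") {
    if (is.na(n_switches) || n_switches < 2)
      stop("chromothripsis requires n_switches >= 2")
    if (is.null(states) || length(states) != 2 || states[1] == states[2])
      stop("chromothripsis requires two distinct copy states")
  }
  structure(list(kind = kind, chrom = as.character(chrom), arm = arm,
                 start = start, end = end, copies = as.integer(copies),
                 n_switches = n_switches, states = states),
            class = "karyotype_event")
}

# Apply one event to an integer CN vector over the grid (in place semantics).
apply_event <- function(cn, grid, ev) {
  if (ev$kind == "WGD") return(cn * 2L)
  idx <- which(grid$chrom == ev$chrom)
  if (length(idx) == 0) stop("event targets unknown chromosome ", ev$chrom)
  if (ev$kind %in% c("arm_gain", "arm_loss"))
    idx <- idx[grid$arm[idx] == ev$arm]
  if (ev$kind %in% c("focal_gain", "focal_loss"))
    idx <- idx[grid$start[idx] < ev$end & grid$end[idx] > ev$start]
  if (ev$kind == "chromothripsis") {
    nb <- length(idx)
    if (nb < ev$n_switches + 1)
      stop("chromosome too small for requested n_switches")
    # n_switches internal breakpoints -> n_switches + 1 alternating runs
    cuts <- sort(sample(seq_len(nb - 1), ev$n_switches))
    run_id <- findInterval(seq_len(nb) - 1, cuts) # 0..n_switches
    state <- ev$states[(run_id %% 2) + 1]
    cn[idx] <- as.integer(state)
    return(cn)
  }
  delta <- if (grepl("loss", ev$kind)) -abs(ev$copies) else abs(ev$copies)
  cn[idx] <- cn[idx] + delta
  cn
}

#' Simulate a karyotype
#'
#' Starts from CN = 2 on every bin. If whole-genome doubling is drawn (or
#' supplied) it is applied first and sets the baseline ploidy to 4;
#' subsequent events add or subtract copies on whole chromosomes, arms, or
#' focal intervals, and chromothripsis rewrites one chromosome as runs
#' alternating between two copy states with exactly `n_switches` changes.
#' Copy numbers driven below 0 are clamped at 0 with a warning.
#'
#' @param genome A `genome_model`.
#' @param grid A `bin_grid` over `genome`.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param events Optional list of `karyotype_event` objects applied
#'   deterministically instead of drawing events from `config`.
#' @param sample_id Sample identifier stored on the track.
#' @param n_events Optional fixed event count overriding the Poisson draw.
#' @return A list with `track` (a `cn_track`: grid columns plus integer `cn`)
#'   and `events` (ground truth list of `karyotype_event`).
#' @export
simulate_karyotype <- function(genome, grid, config = sim_config(), seed = 1,
                               events = NULL, sample_id = "S1",
                               n_events = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  set.seed(seed)
  cn <- rep(2L, nrow(grid))
  baseline <- 2L
  if (is.null(events)) {
    events <- list()
    if (stats::runif(1) < config$p_wgd)
      events <- c(events, list(karyotype_event("WGD")))
    k <- if (is.null(n_events)) stats::rpois(1, config$n_events_lambda)
         else n_events
    chroms <- unique(grid$chrom)
    for (i in seq_len(k)) {
      w <- config$event_weights
      cls <- sample(names(w), 1, prob = w)
      ch <- sample(chroms, 1)
      gain <- stats::runif(1) < 0.5
      ev <- switch(cls,
        whole_chrom = karyotype_event(
          if (gain) "whole_chrom_gain" else "whole_chrom_loss",
          chrom = ch, copies = config$copies),
        arm = karyotype_event(
          if (gain) "arm_gain" else "arm_loss", chrom = ch,
          arm = sample(c("p", "q"), 1), copies = config$copies),
        focal = {
          len <- genome$length[genome$chrom == ch]
          w0 <- stats::runif(1, 0.05, 0.25) * len
          s0 <- stats::runif(1, 0, len - w0)
          karyotype_event(if (gain) "focal_gain" else "focal_loss",
                          chrom = ch, start = s0, end = s0 + w0,
                          copies = config$copies)
        },
        chromothripsis = {
          base <- if (any(vapply(events, function(e) e$kind == "WGD",
                                 logical(1)))) 4L else 2L
          nb <- sum(grid$chrom == ch)
          if (nb < 3) # chromosome too coarse to shatter: gain instead
            karyotype_event("whole_chrom_gain", chrom = ch,
                            copies = config$copies)
          else
            karyotype_event("chromothripsis", chrom = ch,
                            n_switches = min(sample(4:10, 1), nb - 1),
                            states = c(max(0L, base - 1L), base + 1L))
        })
      events <- c(events, list(ev))
    }
  }
  # WGD always applies first
  is_wgd <- vapply(events, function(e) e$kind == "WGD", logical(1))
  for (ev in c(events[is_wgd], events[!is_wgd])) {
    cn <- apply_event(cn, grid, ev)
    if (ev$kind == "WGD") baseline <- 4L
  }
  if (any(cn < 0)) {
    warning("events drove copy number below 0; clamped at 0")
    cn[cn < 0] <- 0L
  }
  track <- as.data.frame(grid)
  track$cn <- cn
  track <- structure(track, class = c("cn_track", "data.frame"),
                     sample_id = sample_id, baseline_ploidy = baseline,
                     seed = seed)
  list(track = track, events = events)
}

#' @export
print.cn_track <- function(x, ...) {
  cat(sprintf("Copy-number track '%s': baseline ploidy %d, %d/%d bins altered\n",
              attr(x, "sample_id"), attr(x, "baseline_ploidy"),
              sum(x$cn != attr(x, "baseline_ploidy")), nrow(x)))
  invisible(x)
}

#' Render a probe-level logR signal from a copy-number track
#'
#' Probes are placed uniformly at the given density; each probe reads
#' `log2(CN/2)` of its bin plus Gaussian noise, and the whole sample is then
#' median-centered (genome-wide median subtracted), emulating array
#' normalization. A pure whole-genome-doubled sample therefore renders as
#' logR ~ 0 everywhere. `log2(CN/2)` is floored at CN = 0.25 so
#' homozygous-deleted bins stay finite.
#'
#' @param track A `cn_track`.
#' @param genome The `genome_model` the track's grid was built on.
#' @param density Probes per Mb.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A `probe_signal`.
#' @export
render_probe_signal <- function(track, genome, density = 20, noise_sd = 0.1,
                                seed = 1) {
  stopifnot(inherits(track, "cn_track"))
  if (density <= 0) stop("probe density must be positive")
  set.seed(seed)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    len <- genome$length[i]
    np <- max(1L, round(len / 1e6 * density))
    pos <- sort(stats::runif(np, 0, len))
    bins <- track[track$chrom == ch, ]
    bi <- findInterval(pos, bins$start)
    raw <- log2(pmax(bins$cn[bi], 0.25) / 2)
    data.frame(chrom = ch, pos = pos,
               logR = raw + stats::rnorm(np, 0, noise_sd),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$logR <- df$logR - stats::median(df$logR)
  probe_signal(attr(track, "sample_id"), df$chrom, df$pos, df$logR,
               genome = genome)
}

#' Simulate a gene-by-sample expression matrix under a dosage model
#'
#' Gene `g` on a bin with copy number CN has mean
#' `mu_g * (CN/2)^dosage_slope`; counts are negative-binomial with the
#' configured dispersion (Poisson at dispersion 0). With `dosage_slope = 1`
#' expected expression is proportional to copy number.
#'
#' @param tracks A `cn_track` or list of them (one per sample).
#' @param gene_map Data frame with columns `gene`, `chrom`, `pos` mapping
#'   each gene to a genomic position.
#' @param dosage_slope,dispersion,base_mean,base_sdlog See [sim_config()].
#' @param seed Integer seed.
#' @return A genes x samples numeric matrix with a `gene_map` attribute.
#' @export
simulate_expression <- function(tracks, gene_map, dosage_slope = 1,
                                dispersion = 0.1, base_mean = 100,
                                base_sdlog = 0, seed = 1) {
  if (inherits(tracks, "cn_track")) tracks <- list(tracks)
  if (nrow(gene_map) == 0) stop("empty gene map")
  stopifnot(all(c("gene", "chrom", "pos") %in% names(gene_map)))
  if (dosage_slope < 0) stop("dosage_slope must be >= 0")
  grid <- tracks[[1]]
  bad <- !(gene_map$chrom %in% unique(grid$chrom))
  if (any(bad))
    stop("genes mapped to chromosomes absent from the grid: ",
         paste(utils::head(gene_map$gene[bad], 5), collapse = ", "))
  set.seed(seed)
  mu_g <- if (base_sdlog > 0)
    stats::rlnorm(nrow(gene_map), log(base_mean), base_sdlog)
  else rep(base_mean, nrow(gene_map))
  # gene -> bin index per track (grids are shared)
  bin_of_gene <- vapply(seq_len(nrow(gene_map)), function(j) {
    idx <- which(grid$chrom == gene_map$chrom[j])
    k <- idx[findInterval(gene_map$pos[j], grid$start[idx])]
    if (length(k) != 1 || is.na(k)) stop("gene ", gene_map$gene[j],
                                         " maps outside the bin grid")
    k
  }, numeric(1))
  mat <- sapply(tracks, function(tr) {
    mu <- mu_g * (tr$cn[bin_of_gene] / 2)^dosage_slope
    if (dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
  })
  mat <- matrix(as.numeric(mat), nrow = nrow(gene_map))
  rownames(mat) <- gene_map$gene
  colnames(mat) <- vapply(tracks, function(tr) attr(tr, "sample_id"),
                          character(1))
  attr(mat, "gene_map") <- gene_map
  mat
}

#' Draw a random gene map over a genome
#'
#' @param genome A `genome_model`.
#' @param genes_per_chrom Number of genes placed uniformly on each chromosome.
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `chrom`, `pos`.
#' @export
random_gene_map <- function(genome, genes_per_chrom = 100, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    data.frame(gene = sprintf("g%s_%03d", genome$chrom[i],
                              seq_len(genes_per_chrom)),
               chrom = genome$chrom[i],
               pos = sort(stats::runif(genes_per_chrom, 0,
                                       genome$length[i])),
               stringsAsFactors = FALSE)
  }))
}

# Hotspot / representative TP53 protein changes used by the generator.
.tp53_missense <- c("R175H", "R273H", "R248Q", "R282W", "G245S", "Y220C")
.tp53_truncating <- data.frame(
  class = c("nonsense", "frameshift", "frameshift", "splice_site"),
  protein = c("R196*", "P98fs", "K120fs", "X126_splice"),
  stringsAsFactors = FALSE
)

#' Simulate a MAF-like TP53 mutation table
#'
#' Each sample is assigned a ground-truth class drawn from `class_mix` and
#' receives TP53 records realizing it: missense samples get a single hotspot
#' missense record; truncating samples a nonsense/frameshift/splice-site
#' record; `multi` samples two or more non-silent alterations; `inframe`
#' samples an in-frame deletion; WT samples none or a silent record only.
#'
#' @param class_mix Named proportions over `WT`, `missense`, `truncating`,
#'   `multi`, `inframe`; must sum to 1 (tolerance 1e-6).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param cohort Optional cohort label added to every record.
#' @return A list with `records` (data frame: `sample`, `gene`,
#'   `variant_class`, `protein_change`, `cohort`) and `truth` (named vector
#'   of generating classes; samples with no TP53 rows still appear here).
#' @export
simulate_mutation_table <- function(class_mix = c(WT = 0.5, missense = 0.3,
                                                  truncating = 0.2),
                                    n_samples = 100, seed = 1,
                                    cohort = "SYN") {
  full <- c(WT = 0, missense = 0, truncating = 0, multi = 0, inframe = 0)
  if (!all(names(class_mix) %in% names(full)))
    stop("unknown class in mix: ",
         paste(setdiff(names(class_mix), names(full)), collapse = ", "))
  full[names(class_mix)] <- class_mix
  if (abs(sum(full) - 1) > 1e-6) stop("class proportions must sum to 1")
  set.seed(seed)
  truth <- sample(names(full), n_samples, replace = TRUE, prob = full)
  names(truth) <- sprintf("S%05d", seq_len(n_samples))
  rec <- list()
  for (i in seq_len(n_samples)) {
    sid <- names(truth)[i]
    rows <- switch(truth[i],
      WT = if (stats::runif(1) < 0.3)
        data.frame(variant_class = "silent", protein_change = "P36P")
      else NULL,
      missense = data.frame(variant_class = "missense",
                            protein_change = sample(.tp53_missense, 1)),
      truncating = {
        k <- sample(nrow(.tp53_truncating), 1)
        data.frame(variant_class = .tp53_truncating$class[k],
                   protein_change = .tp53_truncating$protein[k])
      },
      multi = {
        k <- sample(nrow(.tp53_truncating), 1)
        data.frame(variant_class = c("missense", .tp53_truncating$class[k]),
                   protein_change = c(sample(.tp53_missense, 1),
                                      .tp53_truncating$protein[k]))
      },
      inframe = data.frame(variant_class = "in_frame_indel",
                           protein_change = "I255del"))
    if (!is.null(rows)) {
      rows$sample <- sid
      rec[[length(rec) + 1]] <- rows
    }
  }
  records <- if (length(rec)) do.call(rbind, rec)
             else data.frame(variant_class = character(),
                             protein_change = character(),
                             sample = character())
  records$gene <- "TP53"
  records$cohort <- cohort
  records <- records[, c("sample", "gene", "variant_class",
                         "protein_change", "cohort")]
  rownames(records) <- NULL
  list(records = records, truth = truth)
}

#' Simulate survival records for a cohort with an aneuploid-high hazard
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hazard_ratio^[sample in upper FGA quartile]`
#' (intermediate quartiles at baseline), with independent exponential
#' censoring.
#'
#' @param fga Named per-sample FGA values (names become sample ids).
#' @param hazard_ratio Hazard ratio of the upper FGA quartile vs the rest.
#' @param baseline_hazard Baseline hazard per day.
#' @param censor_rate Exponential censoring hazard per day (0 = none).
#' @param seed Integer seed.
#' @return Data frame with `sample`, `time` (days), `event` (1 =
#'   event observed, 0 = censored) and the FGA quartile `group`.
#' @export
simulate_cohort_survival <- function(fga, hazard_ratio = 2,
                                     baseline_hazard = 1 / 1500,
                                     censor_rate = 1 / 3000, seed = 1) {
  if (length(fga) == 0) stop("empty cohort")
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (is.null(names(fga))) names(fga) <- sprintf("S%05d", seq_along(fga))
  set.seed(seed)
  cls <- classify_by_quantile(fga)
  hz <- ifelse(cls == "aneuploid_high",
               baseline_hazard * hazard_ratio, baseline_hazard)
  t_event <- stats::rexp(length(fga), hz)
  t_cens <- if (censor_rate > 0) stats::rexp(length(fga), censor_rate)
            else rep(Inf, length(fga))
  data.frame(sample = names(fga),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             group = as.character(cls),
             stringsAsFactors = FALSE)
}

#' Simulate an exponential growth curve
#'
#' Counts follow `N0 * 2^(t / Td)` with multiplicative lognormal noise of
#' coefficient of variation `noise_cv`.
#'
#' @param true_doubling_time Doubling time in hours (> 0).
#' @param duration Total duration in hours.
#' @param n_timepoints Number of equally spaced timepoints (first at t = 0).
#' @param noise_cv Lognormal noise CV (0 = noiseless).
#' @param n0 Initial count.
#' @param seed Integer seed.
#' @return A `growth_curve` data frame with columns `time` (h), `count`.
#' @export
simulate_growth_curve <- function(true_doubling_time, duration = 120,
                                  n_timepoints = 6, noise_cv = 0, n0 = 1500,
                                  seed = 1) {
  if (true_doubling_time <= 0) stop("doubling time must be positive")
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  t <- seq(0, duration, length.out = n_timepoints)
  mu <- n0 * 2^(t / true_doubling_time)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mu <- mu * stats::rlnorm(length(t), -sdlog^2 / 2, sdlog)
  }
  growth_curve("sim", t, mu)
}

#' Construct a growth curve
#' @param sample_id Sample identifier.
#' @param time Timepoints in hours, strictly increasing.
#' @param count Cell counts (> 0).
#' @export
growth_curve <- function(sample_id, time, count) {
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(count <= 0)) stop("counts must be positive")
  structure(data.frame(time = time, count = count),
            class = c("growth_curve", "data.frame"), sample_id = sample_id)
}
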