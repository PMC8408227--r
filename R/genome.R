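# Chromosome/arm coordinate system and the shared bin grid.
# Internal coordinates are 0-based half-open throughout; SEG I/O converts.

# Embedded hg38-like chromosome lengths and centromere positions (bp,
# rounded to 0.01 Mb). 22 autosomes + X.
.hg38_table <- data.frame(
  chrom = c(as.character(1:22), "X"),
  length = c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35,
             145.14, 138.39, 133.80, 135.09, 133.28, 114.36, 107.04,
             101.99, 90.34, 83.26, 80.37, 58.62, 64.44, 46.71, 50.82,
             156.04) * 1e6,
  centromere = c(123.40, 93.90, 90.90, 50.00, 48.80, 59.80, 60.10,
                 45.20, 43.00, 39.80, 53.40, 35.50, 17.70, 17.20,
                 19.00, 36.80, 25.10, 18.50, 26.20, 28.10, 12.00,
                 15.00, 60.60) * 1e6,
  stringsAsFactors = FALSE
)

#' Build a genome model
#'
#' Defines the coordinate system every other stage works on: an ordered set
#' of chromosomes with lengths and centromere positions splitting each into a
#' p (before the centromere) and q (after) arm.
#'
#' @param n Number of chromosomes for a custom genome (ignored when `lengths`
#'   or `preset` is given).
#' @param lengths Chromosome lengths in bp. Default: embedded hg38-like
#'   autosome lengths.
#' @param centromere_frac Centromere position as a fraction of chromosome
#'   length, recycled across chromosomes. Ignored when the embedded table is
#'   used (its real centromere positions apply).
#' @param preset `"hg38-like"` for the embedded 22-autosome + X table.
#' @param scale Multiplies all lengths and centromere positions; `scale = 0.1`
#'   gives a ~240 Mb genome convenient for fast simulation.
#' @param include_x Include the X chromosome (only with the embedded table).
#' @return A `genome_model` data frame with columns `chrom`, `length`,
#'   `centromere`.
#' @examples
#' g <- build_genome(lengths = c(100e6, 80e6), centromere_frac = 0.4)
#' build_genome(preset = "hg38-like")
#' @export
build_genome <- function(n = NULL, lengths = NULL, centromere_frac = NULL,
                         preset = NULL, scale = 1, include_x = FALSE) {
  if (!is.null(preset)) {
    if (!identical(preset, "hg38-like"))
      stop("unknown preset: ", preset)
    tab <- .hg38_table
  } else if (!is.null(lengths)) {
    if (any(!is.finite(lengths)) || any(lengths <= 0))
      stop("chromosome lengths must be positive and finite")
    cf <- if (is.null(centromere_frac)) 0.4 else centromere_frac
    if (any(cf <= 0) || any(cf >= 1))
      stop("centromere fraction must lie strictly inside (0, 1)")
    tab <- data.frame(chrom = as.character(seq_along(lengths)),
                      length = as.numeric(lengths),
                      centromere = as.numeric(lengths) * rep_len(cf, length(lengths)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- .hg38_table
    if (!include_x) tab <- tab[tab$chrom != "X", ]
    if (!is.null(n)) tab <- tab[seq_len(n), ]
  }
  if (scale <= 0) stop("scale must be positive")
  tab$length <- tab$length * scale
  tab$centromere <- tab$centromere * scale
  if (anyDuplicated(tab$chrom)) stop("chromosome names must be unique")
  stopifnot(all(tab$centromere > 0), all(tab$centromere < tab$length))
  rownames(tab) <- NULL
  structure(tab, class = c("genome_model", "data.frame"))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Genome model: %d chromosomes, %.1f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Tile a genome with fixed-width bins
#'
#' Bins are half-open `[start, end)` intervals tiling each arm; bins never
#' span a centromere, so arm-level statistics are exact sums of bins. The
#' last bin of each arm may be short.
#'
#' @param genome A `genome_model`.
#' @param width Bin width in bp (default 1 Mb).
#' @return A `bin_grid` data frame with columns `chrom`, `start`, `end`,
#'   `arm` ("p"/"q") and `width`.
#' @export
make_bins <- function(genome, width = 1e6) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.finite(width) || width <= 0) stop("bin width must be positive")
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    len <- genome$length[i]
    cen <- genome$centromere[i]
    arm_bins <- function(a0, a1, arm) {
      nb <- max(1L, ceiling((a1 - a0) / width - 1e-9))
      starts <- a0 + (seq_len(nb) - 1) * width
      ends <- pmin(starts + width, a1)
      data.frame(chrom = chrom, start = starts, end = ends, arm = arm,
                 stringsAsFactors = FALSE)
    }
    rbind(arm_bins(0, cen, "p"), arm_bins(cen, len, "q"))
  })
  grid <- do.call(rbind, pieces)
  grid$width <- grid$end - grid$start
  rownames(grid) <- NULL
  structure(grid, class = c("bin_grid", "data.frame"),
            genome = genome, bin_width = width)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("Bin grid: %d bins (nominal width %.2f Mb) over %d chromosomes\n",
              nrow(x), attr(x, "bin_width") / 1e6, length(unique(x$chrom))))
  invisible(x)
}

# Two grids describe the same coordinate system?
same_grid <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    isTRUE(all.equal(a$start, b$start)) && isTRUE(all.equal(a$end, b$end))
}

#' Construct a probe-level signal container
#'
#' @param sample_id Sample identifier.
#' @param chrom,pos,logR Per-probe chromosome, position (bp) and log2 ratio.
#' @param genome Optional `genome_model` used to validate positions.
#' @return A `probe_signal` data frame sorted by (chromosome, position).
#' @export
probe_signal <- function(sample_id, chrom, pos, logR, genome = NULL) {
  if (length(chrom) != length(pos) || length(pos) != length(logR))
    stop("chrom, pos and logR must have equal length")
  if (any(!is.finite(logR))) stop("logR values must be finite")
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   logR = as.numeric(logR), stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    m <- match(df$chrom, genome$chrom)
    if (anyNA(m)) stop("probe chromosome absent from genome")
    if (any(df$pos < 0 | df$pos > genome$length[m]))
      stop("probe position outside chromosome bounds")
    df <- df[order(m, df$pos), ]
  } else {
    df <- df[order(chrom_order(df$chrom), df$pos), ]
  }
  rownames(df) <- NULL
  structure(df, class = c("probe_signal", "data.frame"), sample_id = sample_id)
}

#' @export
print.probe_signal <- function(x, ...) {
  cat(sprintf("Probe signal '%s': %d probes on %d chromosomes\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  invisible(x)
}

# Natural chromosome sort key: 1..22 before X before Y before anything else.
chrom_order <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(!is.na(num), num,
         ifelse(chrom == "X", 100, ifelse(chrom == "Y", 101, 102)))
}

#' Construct a segment profile
#'
#' Segmented representation of one sample: non-overlapping, sorted, half-open
#' segments with a mean log2 ratio and supporting probe count.
#'
#' @param sample_id Sample identifier.
#' @param chrom,start,end Segment coordinates (bp, 0-based half-open).
#' @param seg_mean Mean log2 ratio of each segment.
#' @param n_probes Number of probes supporting each segment.
#' @return A `segment_profile` data frame.
#' @export
segment_profile <- function(sample_id, chrom, start, end, seg_mean,
                            n_probes = NA_integer_) {
  if (length(chrom) == 0) stop("empty segment profile")
  n_probes <- rep_len(as.integer(n_probes), length(chrom))
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), n_probes = as.integer(n_probes),
                   seg_mean = as.numeric(seg_mean), stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty segment profile")
  if (any(df$end <= df$start)) stop("segment end must exceed start")
  df <- df[order(chrom_order(df$chrom), df$start), ]
  for (ch in unique(df$chrom)) {
    s <- df[df$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)] - 1e-9))
      stop("overlapping segments on chromosome ", ch)
  }
  rownames(df) <- NULL
  structure(df, class = c("segment_profile", "data.frame"),
            sample_id = sample_id)
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("Segment profile '%s': %d segments on %d chromosomes\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Project a segment profile onto a bin grid
#'
#' Each bin receives the length-weighted mean log2 ratio of the segments
#' overlapping it. Bins not covered by any segment are set to 0 with a
#' warning; profiles must cover at least `min_coverage` of the grid span.
#'
#' @param seg A `segment_profile`.
#' @param grid A `bin_grid`.
#' @param min_coverage Minimum fraction of the grid length that must be
#'   covered by segments (default 0.99).
#' @return A `binned_profile` data frame: the grid columns plus `logR`.
#' @export
bin_profile <- function(seg, grid, min_coverage = 0.99) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!inherits(seg, "segment_profile")) stop("seg must be a segment_profile")
  if (nrow(seg) == 0) stop("empty segment profile")
  if (!all(seg$chrom %in% grid$chrom))
    stop("segment chromosomes absent from grid: mismatched genome")
  logR <- numeric(nrow(grid))
  cover <- numeric(nrow(grid))
  for (ch in unique(seg$chrom)) {
    bi <- which(grid$chrom == ch)
    s <- seg[seg$chrom == ch, ]
    for (k in seq_len(nrow(s))) {
      ov <- pmin(grid$end[bi], s$end[k]) - pmax(grid$start[bi], s$start[k])
      hit <- ov > 0
      logR[bi][hit] <- logR[bi][hit] + ov[hit] * s$seg_mean[k]
      cover[bi][hit] <- cover[bi][hit] + ov[hit]
    }
  }
  covered_frac <- sum(cover) / sum(grid$width)
  if (covered_frac < min_coverage)
    stop(sprintf("segments cover only %.1f%% of the grid (need %.0f%%)",
                 100 * covered_frac, 100 * min_coverage))
  uncovered <- cover == 0
  if (any(uncovered))
    warning(sprintf("%d bins uncovered by any segment; set to 0",
                    sum(uncovered)))
  logR[!uncovered] <- logR[!uncovered] / cover[!uncovered]
  out <- as.data.frame(grid)
  out$logR <- logR
  structure(out, class = c("binned_profile", "data.frame"),
            sample_id = attr(seg, "sample_id"), grid = grid)
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("Binned profile '%s': %d bins, mean |logR| = %.3f\n",
              attr(x, "sample_id"), nrow(x), mean(abs(x$logR))))
  invisible(x)
}
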