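# Aneuploidy statistics: parental-relative profiles, aneuploidy score,
# fraction of genome altered, quartile classification, alteration-frequency
# tracks, and per-arm group comparisons.

#' Parental-relative profile
#'
#' Bin-wise difference `sample - parental`, so alterations shared with the
#' parental clone (ancestral gains/losses) cancel before scoring.
#'
#' @param sample,parental `binned_profile`s on the same bin grid.
#' @return A `binned_profile` of differences.
#' @export
relative_profile <- function(sample, parental) {
  stopifnot(inherits(sample, "binned_profile"),
            inherits(parental, "binned_profile"))
  if (!same_grid(sample, parental)) stop("profiles are on different bin grids")
  out <- sample
  out$logR <- sample$logR - parental$logR
  attr(out, "sample_id") <- paste0(attr(sample, "sample_id"), "-rel")
  out
}

#' Aneuploidy score
#'
#' The sum of absolute segmented log2 ratios of a (parental-relative)
#' profile. Because the unit of the published statistic is not fixed, three
#' weighting modes are offered: `per_Mb` (default; each bin's |logR| is
#' weighted by its length in Mb, so the score is invariant to bin width),
#' `per_bin` (unweighted sum over bins), and `per_segment` (sum of |segment
#' mean| over segments of a `segment_profile`).
#'
#' @param rel A `binned_profile` (modes `per_Mb`, `per_bin`) or
#'   `segment_profile` (mode `per_segment`).
#' @param mode Weighting mode.
#' @return Non-negative numeric score.
#' @export
aneuploidy_score <- function(rel, mode = c("per_Mb", "per_bin",
                                           "per_segment")) {
  mode <- match.arg(mode)
  if (mode == "per_segment") {
    stopifnot(inherits(rel, "segment_profile"))
    return(sum(abs(rel$seg_mean)))
  }
  stopifnot(inherits(rel, "binned_profile"))
  if (mode == "per_bin") sum(abs(rel$logR))
  else sum(abs(rel$logR) * rel$width) / 1e6
}

#' Fraction of genome altered
#'
#' The summed length of segments whose |mean log2 ratio| strictly exceeds
#' `threshold`, divided by the total segmented length.
#'
#' @param seg A `segment_profile` (or `binned_profile`; bins act as
#'   segments).
#' @param threshold Alteration threshold on |logR| (default 0.2, strict
#'   inequality).
#' @return FGA in \[0, 1\].
#' @export
fraction_genome_altered <- function(seg, threshold = 0.2) {
  if (inherits(seg, "segment_profile")) {
    len <- seg$end - seg$start
    val <- seg$seg_mean
  } else if (inherits(seg, "binned_profile")) {
    len <- seg$width
    val <- seg$logR
  } else stop("seg must be a segment_profile or binned_profile")
  if (length(len) == 0) stop("empty profile")
  sum(len[abs(val) > threshold]) / sum(len)
}

#' Classify samples into aneuploid-low / intermediate / aneuploid-high
#'
#' Quartile boundaries come from the empirical distribution (linear
#' interpolation, `stats::quantile` type 7). Values at or below the first
#' quartile are `aneuploid_low`, at or above the third quartile
#' `aneuploid_high`, the rest `intermediate`.
#'
#' @param values Numeric per-sample statistic (AS or FGA), optionally named.
#' @return Factor of class labels with a `boundaries` attribute (Q1, Q3).
#' @export
classify_by_quantile <- function(values) {
  if (length(values) < 4) stop("need at least 4 samples to form quartiles")
  if (all(values == values[1])) {
    warning("all values identical; every sample classified intermediate")
    out <- factor(rep("intermediate", length(values)),
                  levels = c("aneuploid_low", "intermediate",
                             "aneuploid_high"))
    names(out) <- names(values)
    return(out)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  lab <- ifelse(values <= q[1], "aneuploid_low",
                ifelse(values >= q[2], "aneuploid_high", "intermediate"))
  out <- factor(lab, levels = c("aneuploid_low", "intermediate",
                                "aneuploid_high"))
  names(out) <- names(values)
  attr(out, "boundaries") <- c(Q1 = q[1], Q3 = q[2])
  out
}

#' Gain/loss frequency track for a group of profiles
#'
#' A bin is called gained in a sample when its (parental-relative) logR
#' exceeds `+call_threshold`, lost below `-call_threshold`; fractions are
#' calls over group size.
#'
#' @param group List of `binned_profile`s, already parental-relative.
#' @param call_threshold Call threshold on logR (default 0.2).
#' @param label Group label stored on the result.
#' @return A `frequency_track` data frame: grid columns plus `gain_frac`,
#'   `loss_frac`.
#' @export
alteration_frequency <- function(group, call_threshold = 0.2,
                                 label = "group") {
  if (length(group) == 0) stop("empty group")
  stopifnot(all(vapply(group, inherits, logical(1), "binned_profile")))
  n <- length(group)
  gains <- Reduce(`+`, lapply(group, function(p) p$logR > call_threshold))
  losses <- Reduce(`+`, lapply(group, function(p) p$logR < -call_threshold))
  out <- as.data.frame(group[[1]][, c("chrom", "start", "end", "arm",
                                      "width")])
  out$gain_frac <- gains / n
  out$loss_frac <- losses / n
  structure(out, class = c("frequency_track", "data.frame"),
            group = label, n = n)
}

# Bin-length-weighted mean logR of one profile over an index set.
weighted_arm_mean <- function(profile, idx) {
  sum(profile$logR[idx] * profile$width[idx]) / sum(profile$width[idx])
}

#' Compare chromosome arms between two groups of profiles
#'
#' For each arm, the per-sample bin-length-weighted mean logR is compared
#' between groups with a two-sided two-sample t-test (Welch by default),
#' and p-values are Benjamini-Hochberg adjusted across arms. Arms with
#' adjusted p below `fdr_q` are flagged.
#'
#' @param groupA,groupB Lists of `binned_profile`s (each of length >= 2) on
#'   a shared grid.
#' @param fdr_q FDR threshold for flagging (default 0.1).
#' @param var_equal Use the pooled-variance (classical Student) test
#'   instead of Welch.
#' @return An `arm_comparison` data frame: `chrom`, `arm`, group means,
#'   `t`, `p`, `p_adj`, `flagged`.
#' @export
compare_arms <- function(groupA, groupB, fdr_q = 0.1, var_equal = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 samples")
  g <- groupA[[1]]
  arms <- unique(g[, c("chrom", "arm")])
  res <- lapply(seq_len(nrow(arms)), function(i) {
    idx <- which(g$chrom == arms$chrom[i] & g$arm == arms$arm[i])
    if (length(idx) == 0) stop("arm with zero bins")
    a <- vapply(groupA, weighted_arm_mean, numeric(1), idx = idx)
    b <- vapply(groupB, weighted_arm_mean, numeric(1), idx = idx)
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
      same <- abs(mean(a) - mean(b)) < 1e-12
      tt <- list(statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                 p.value = if (same) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
    }
    data.frame(chrom = arms$chrom[i], arm = arms$arm[i],
               mean_A = mean(a), mean_B = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj < fdr_q
  structure(out, class = c("arm_comparison", "data.frame"), fdr_q = fdr_q)
}

#' Average copy number of a chromosome
#'
#' The length-weighted mean logR `m` over the chromosome is converted to an
#' average copy number `2 * 2^m` (diploid reference).
#'
#' @param profile A `binned_profile` or `segment_profile`.
#' @param chromosome Chromosome name.
#' @return Average copy number (numeric).
#' @export
chromosome_mean_copy <- function(profile, chromosome) {
  if (inherits(profile, "binned_profile")) {
    idx <- profile$chrom == chromosome
    if (!any(idx)) stop("unknown chromosome: ", chromosome)
    m <- sum(profile$logR[idx] * profile$width[idx]) /
      sum(profile$width[idx])
  } else if (inherits(profile, "segment_profile")) {
    idx <- profile$chrom == chromosome
    if (!any(idx)) stop("unknown chromosome: ", chromosome)
    len <- profile$end[idx] - profile$start[idx]
    m <- sum(profile$seg_mean[idx] * len) / sum(len)
  } else stop("profile must be a binned_profile or segment_profile")
  2 * 2^m
}

#' Score a cohort of segment profiles against a parental clone
#'
#' Convenience wrapper running the scoring stage end to end: bins every
#' profile, subtracts the parental profile, and computes AS, FGA and the
#' cohort quartile class per sample.
#'
#' @param profiles Named list of `segment_profile`s.
#' @param parental The parental clone's `segment_profile`.
#' @param grid A `bin_grid`.
#' @param as_mode Aneuploidy-score weighting mode (see
#'   [aneuploidy_score()]).
#' @param fga_threshold FGA threshold (default 0.2).
#' @return An `aneuploidy_result` data frame: `sample`, `AS`, `FGA`,
#'   `class`.
#' @export
score_aneuploidy <- function(profiles, parental, grid, as_mode = "per_Mb",
                             fga_threshold = 0.2) {
  par_bin <- bin_profile(parental, grid)
  rels <- lapply(profiles, function(p)
    relative_profile(bin_profile(p, grid), par_bin))
  AS <- vapply(rels, aneuploidy_score, numeric(1), mode = as_mode)
  FGA <- vapply(profiles, fraction_genome_altered, numeric(1),
                threshold = fga_threshold)
  cls <- classify_by_quantile(AS)
  out <- data.frame(sample = vapply(profiles, attr, character(1),
                                    "sample_id"),
                    AS = unname(AS), FGA = unname(FGA),
                    class = as.character(cls), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("aneuploidy_result", "data.frame"),
            boundaries = attr(cls, "boundaries"), relative = rels)
}

#' @export
print.aneuploidy_result <- function(x, ...) {
  b <- attr(x, "boundaries")
  cat(sprintf("Aneuploidy scores for %d samples (Q1 = %.2f, Q3 = %.2f)\n",
              nrow(x), b[1], b[2]))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' @export
summary.aneuploidy_result <- function(object, ...) {
  cat(sprintf("%d samples: %d aneuploid_low, %d intermediate, %d aneuploid_high\n",
              nrow(object), sum(object$class == "aneuploid_low"),
              sum(object$class == "intermediate"),
              sum(object$class == "aneuploid_high")))
  cat(sprintf("AS: median %.2f, range [%.2f, %.2f]; FGA: median %.3f\n",
              stats::median(object$AS), min(object$AS), max(object$AS),
              stats::median(object$FGA)))
  invisible(object)
}
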