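# TP53 genotype classification from MAF-style mutation records, with the
# cohort-level exclusion rules used for TCGA-style analyses.

# Canonical variant-class vocabulary and accepted synonyms (MAF dialects).
.variant_vocab <- c(
  missense = "missense", missense_mutation = "missense",
  nonsense = "nonsense", nonsense_mutation = "nonsense",
  stop_gain = "nonsense", stopgain = "nonsense",
  frameshift = "frameshift", frame_shift_del = "frameshift",
  frame_shift_ins = "frameshift", frameshift_del = "frameshift",
  frameshift_ins = "frameshift",
  splice_site = "splice_site",
  silent = "silent", synonymous = "silent",
  in_frame_indel = "in_frame_indel", in_frame_del = "in_frame_indel",
  in_frame_ins = "in_frame_indel", inframe = "in_frame_indel",
  noncoding = "noncoding", intron = "noncoding", rna = "noncoding",
  `3'utr` = "noncoding", `5'utr` = "noncoding", `3'flank` = "noncoding",
  `5'flank` = "noncoding", igr = "noncoding",
  other = "other", translation_start_site = "other",
  nonstop_mutation = "other", splice_region = "other"
)

canonical_variant_class <- function(x) {
  key <- tolower(gsub(" ", "_", as.character(x)))
  out <- .variant_vocab[key]
  if (anyNA(out))
    stop("unknown variant classification: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Classify one sample's TP53 status
#'
#' Applies the rules used for tumor cohorts: a sample with sequencing data
#' but no TP53 calls beyond silent/noncoding is WT; a single missense
#' record is missense; a single nonsense/frameshift/splice-site (or
#' stop-gain, folded into nonsense) record is truncating; any in-frame
#' indel, or more than one non-silent alteration of any mix, is excluded
#' with the corresponding reason. In `cell_line` mode WT requires
#' silent-or-none (noncoding records are likewise ignored) and
#' not-assayed is not used.
#'
#' @param records Data frame of this sample's TP53 records with a
#'   `variant_class` column (MAF dialect synonyms accepted); zero rows mean
#'   no mutation calls. Records for other genes (column `gene`) are
#'   ignored.
#' @param mode `"tumor"` or `"cell_line"`.
#' @param assayed Whether the sample has sequencing data (tumor mode).
#' @return A `tp53_call` list: `call` (one of `WT`, `missense`,
#'   `truncating`, `excluded`, `not_assayed`) and `reason`.
#' @export
classify_tp53 <- function(records, mode = c("tumor", "cell_line"),
                          assayed = TRUE) {
  mode <- match.arg(mode)
  if (mode == "tumor" && !assayed)
    return(structure(list(call = "not_assayed", reason = "no sequencing data"),
                     class = "tp53_call"))
  if (!is.null(records$gene))
    records <- records[toupper(records$gene) == "TP53", , drop = FALSE]
  cls <- if (nrow(records)) canonical_variant_class(records$variant_class)
         else character(0)
  # silent, noncoding and unclassifiable records never count as alterations
  cls <- cls[!cls %in% c("silent", "noncoding", "other")]
  if (length(cls) == 0)
    return(structure(list(call = "WT", reason = ""), class = "tp53_call"))
  if (any(cls == "in_frame_indel"))
    return(structure(list(call = "excluded", reason = "in-frame"),
                     class = "tp53_call"))
  if (length(cls) > 1)
    return(structure(list(call = "excluded", reason = "multiple alterations"),
                     class = "tp53_call"))
  call <- if (cls == "missense") "missense"
          else if (cls %in% c("nonsense", "frameshift", "splice_site"))
            "truncating"
          else "excluded"
  reason <- if (call == "excluded") "multiple alterations" else ""
  structure(list(call = call, reason = reason), class = "tp53_call")
}

#' @export
print.tp53_call <- function(x, ...) {
  cat("TP53 call:", x$call,
      if (nzchar(x$reason)) paste0("(", x$reason, ")") else "", "\n")
  invisible(x)
}

#' Classify every sample in a mutation table
#'
#' @param records Data frame with columns `sample`, `gene`,
#'   `variant_class` (extra columns ignored).
#' @param samples Optional character vector of all assayed sample ids;
#'   samples absent from `records` are then called WT. Defaults to the
#'   samples present in `records`.
#' @param mode See [classify_tp53()].
#' @return Data frame with `sample`, `call`, `reason`.
#' @export
classify_tp53_table <- function(records, samples = NULL,
                                mode = c("tumor", "cell_line")) {
  mode <- match.arg(mode)
  if (is.null(samples)) samples <- unique(records$sample)
  calls <- lapply(samples, function(s) {
    classify_tp53(records[records$sample == s, , drop = FALSE], mode = mode)
  })
  data.frame(sample = samples,
             call = vapply(calls, `[[`, character(1), "call"),
             reason = vapply(calls, `[[`, character(1), "reason"),
             stringsAsFactors = FALSE)
}

#' Apply cohort-level exclusion rules
#'
#' Drops individuals with multiple tumor samples, then drops whole cohorts
#' in which fewer than 20 individuals, or fewer than 10% of classified
#' samples, carry a missense call. Every exclusion is reported with its
#' rule.
#'
#' @param calls Data frame from [classify_tp53_table()] with an added
#'   `cohort` column (and optionally `individual`; defaults to `sample`).
#' @param min_missense Minimum missense individuals per cohort (default
#'   20).
#' @param min_missense_frac Minimum missense fraction per cohort (default
#'   0.10).
#' @return List with `kept` (filtered calls) and `report` (data frame
#'   `sample`, `rule`).
#' @export
apply_cohort_filters <- function(calls, min_missense = 20,
                                 min_missense_frac = 0.10) {
  if (is.null(calls$cohort)) stop("calls must carry a cohort column")
  if (is.null(calls$individual)) calls$individual <- calls$sample
  report <- list()
  dup <- names(which(table(calls$individual) > 1))
  if (length(dup)) {
    drop <- calls$individual %in% dup
    report[[length(report) + 1]] <- data.frame(
      sample = calls$sample[drop], rule = "multiple tumors per individual",
      stringsAsFactors = FALSE)
    calls <- calls[!drop, , drop = FALSE]
  }
  for (co in unique(calls$cohort)) {
    idx <- calls$cohort == co
    n_mis <- sum(calls$call[idx] == "missense")
    frac <- n_mis / sum(idx)
    rule <- if (n_mis < min_missense)
      sprintf("cohort with fewer than %d missense individuals", min_missense)
    else if (frac < min_missense_frac)
      sprintf("cohort below %.0f%% missense frequency",
              100 * min_missense_frac)
    else NA_character_
    if (!is.na(rule)) {
      report[[length(report) + 1]] <- data.frame(
        sample = calls$sample[idx], rule = rule, stringsAsFactors = FALSE)
      calls <- calls[!idx, , drop = FALSE]
    }
  }
  report <- if (length(report)) do.call(rbind, report)
            else data.frame(sample = character(), rule = character(),
                            stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(kept = calls, report = report)
}

#' Tabulate TP53 calls per cohort
#'
#' @param calls Data frame with `call` and optionally `cohort` columns.
#' @return Contingency table of counts (cohort x call, or a named vector
#'   when no cohort column is present). All call levels always appear.
#' @export
summarize_genotypes <- function(calls) {
  lev <- c("WT", "missense", "truncating", "excluded", "not_assayed")
  f <- factor(calls$call, levels = lev)
  if (is.null(calls$cohort)) table(call = f)
  else table(cohort = calls$cohort, call = f)
}
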