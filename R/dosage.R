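# Gene-dosage analysis: per-chromosome average expression versus average
# chromosomal copy number, with Pearson correlation and a least-squares
# line for plotting.

#' Average expression of a chromosome's genes per sample
#'
#' Genes with zero counts in every sample are excluded before averaging
#' (unexpressed genes dilute the dosage signal). Expression is
#' log2(x + 1)-transformed by default.
#'
#' @param expr Genes x samples numeric matrix (non-negative, no missing
#'   values).
#' @param gene_map Data frame with columns `gene`, `chrom` (a `pos` column
#'   is allowed and ignored here).
#' @param chromosome Chromosome name.
#' @param transform `"log2"` (default, log2(x + 1)) or `"raw"`.
#' @return Named per-sample mean expression vector.
#' @export
chromosome_mean_expression <- function(expr, gene_map, chromosome,
                                       transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (any(expr < 0)) stop("expression values must be non-negative")
  genes <- gene_map$gene[gene_map$chrom == chromosome]
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0) stop("no genes mapped to chromosome ", chromosome)
  sub <- expr[genes, , drop = FALSE]
  expressed <- rowSums(sub) > 0
  if (!all(expressed))
    message(sum(!expressed), " unexpressed gene(s) excluded on chromosome ",
            chromosome)
  sub <- sub[expressed, , drop = FALSE]
  if (nrow(sub) == 0) stop("no expressed genes on chromosome ", chromosome)
  if (transform == "log2") sub <- log2(sub + 1)
  colMeans(sub)
}

#' Correlate per-sample mean expression with mean copy number
#'
#' Pearson correlation with a two-sided p-value from the t transform, plus
#' the least-squares line (slope, intercept) and a 95% confidence band
#' half-width function for plotting. Zero variance in either vector yields
#' a flagged result (`undefined = TRUE`) rather than NaN propagation.
#'
#' @param mean_expr,mean_cn Paired per-sample vectors (length >= 3).
#' @param chromosome Optional chromosome label stored on the result.
#' @return A `dosage_correlation` list: `r`, `p`, `n`, `slope`,
#'   `intercept`, `undefined`, `chromosome`, and the paired data.
#' @export
dosage_correlation <- function(mean_expr, mean_cn, chromosome = NA) {
  if (length(mean_expr) != length(mean_cn))
    stop("mean_expr and mean_cn must be paired")
  n <- length(mean_expr)
  if (n < 3) stop("need at least 3 paired samples")
  if (stats::sd(mean_cn) == 0 || stats::sd(mean_expr) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          slope = NA_real_, intercept = NA_real_,
                          undefined = TRUE, chromosome = chromosome,
                          mean_expr = mean_expr, mean_cn = mean_cn),
                     class = "dosage_correlation"))
  }
  ct <- stats::cor.test(mean_cn, mean_expr, method = "pearson")
  fit <- stats::lm(mean_expr ~ mean_cn)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 undefined = FALSE, chromosome = chromosome,
                 mean_expr = mean_expr, mean_cn = mean_cn, fit = fit),
            class = "dosage_correlation")
}

#' @export
print.dosage_correlation <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Dosage correlation (%s): undefined (zero variance), n = %d\n",
                x$chromosome, x$n))
  } else {
    cat(sprintf("Dosage correlation (%s): r = %.3f, p = %.3g, n = %d\n",
                x$chromosome, x$r, x$p, x$n))
  }
  invisible(x)
}

#' @export
plot.dosage_correlation <- function(x, ...) {
  if (x$undefined) stop("correlation undefined; nothing to plot")
  graphics::plot(x$mean_cn, x$mean_expr,
                 xlab = "average chromosomal copy number",
                 ylab = "average expression (log2)",
                 main = sprintf("%s: r = %.2f", x$chromosome, x$r), ...)
  graphics::abline(x$intercept, x$slope, col = "blue")
  nd <- data.frame(mean_cn = seq(min(x$mean_cn), max(x$mean_cn),
                                 length.out = 50))
  ci <- stats::predict(x$fit, nd, interval = "confidence")
  graphics::lines(nd$mean_cn, ci[, "lwr"], lty = 2, col = "grey40")
  graphics::lines(nd$mean_cn, ci[, "upr"], lty = 2, col = "grey40")
  invisible(x)
}
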