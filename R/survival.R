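# Kaplan-Meier estimation and log-rank testing, plus the stratified
# comparison of aneuploid-high vs aneuploid-low FGA quartiles within TP53
# classes. Estimation is delegated to the survival package; this module
# defines the containers and the stratification logic.

#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator via [survival::survfit()]; at tied times events
#' precede censorings (the standard convention).
#'
#' @param time Event/censoring times (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return A `km_curve` list: `time`, `surv`, `n_risk`, `n_event`,
#'   `median` (first time the curve reaches <= 0.5, or NA), `n`.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("empty group")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median survival %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  t <- c(0, rep(x$time, each = 2))
  s <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  graphics::plot(t, s, type = "l", ylim = c(0, 1), xlab = "time",
                 ylab = "survival probability", ...)
  invisible(x)
}

#' Log-rank test between two or more groups
#'
#' Standard (unweighted) log-rank test via [survival::survdiff()]:
#' observed-minus-expected events over distinct event times with
#' hypergeometric variance, chi-square with k - 1 degrees of freedom.
#'
#' @param time,event As in [km_curve()].
#' @param group Group labels (>= 2 non-empty groups).
#' @return A `logrank_result` list: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2) stop("need at least 2 groups")
  if (any(table(group) == 0)) stop("a group has zero records")
  if (any(time <= 0)) stop("times must be positive")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(unique(group)) - 1
  structure(list(chisq = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f on %d df, p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Stratified aneuploidy-survival comparison
#'
#' Within each TP53 class, samples are split into FGA quartiles (via
#' [classify_by_quantile()], computed within the class by default or over
#' the pooled cohort), the intermediate quartiles are dropped, and the
#' aneuploid-high (Q4) and aneuploid-low (Q1) groups are compared with
#' Kaplan-Meier curves and a log-rank test. A genotype-level comparison
#' across all TP53 classes is also returned.
#'
#' @param data Data frame with columns `sample`, `time`, `event`, `fga`,
#'   `tp53_call` (classes other than WT/missense/truncating are dropped).
#' @param quartile_scope `"per_class"` (default) or `"pooled"`.
#' @return A `survival_strata` list: per-class `curves` (Q1/Q4
#'   `km_curve`s) and `test` (`logrank_result`), plus `genotype_test`.
#' @export
stratify_and_compare <- function(data, quartile_scope = c("per_class",
                                                          "pooled")) {
  quartile_scope <- match.arg(quartile_scope)
  need <- c("sample", "time", "event", "fga", "tp53_call")
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)),
                                    collapse = ", "))
  if (anyNA(data[need])) stop("FGA and TP53 call must be present for every record")
  data <- data[data$tp53_call %in% c("WT", "missense", "truncating"), ]
  if (quartile_scope == "pooled") {
    if (nrow(data) < 4) stop("fewer than 4 samples; quartiles undefined")
    data$quart <- as.character(classify_by_quantile(
      stats::setNames(data$fga, data$sample)))
  }
  strata <- list()
  for (cls in intersect(c("WT", "missense", "truncating"),
                        unique(data$tp53_call))) {
    d <- data[data$tp53_call == cls, ]
    if (quartile_scope == "per_class") {
      if (nrow(d) < 4)
        stop("stratum ", cls, " has fewer than 4 samples; quartiles undefined")
      d$quart <- as.character(classify_by_quantile(
        stats::setNames(d$fga, d$sample)))
    }
    lo <- d[d$quart == "aneuploid_low", ]
    hi <- d[d$quart == "aneuploid_high", ]
    if (nrow(lo) == 0 || nrow(hi) == 0)
      stop("stratum ", cls, " has an empty quartile group")
    dd <- rbind(lo, hi)
    strata[[cls]] <- list(
      curves = list(aneuploid_low = km_curve(lo$time, lo$event),
                    aneuploid_high = km_curve(hi$time, hi$event)),
      test = logrank_test(dd$time, dd$event, dd$quart),
      n = c(aneuploid_low = nrow(lo), aneuploid_high = nrow(hi)))
  }
  genotype_test <- if (length(unique(data$tp53_call)) >= 2)
    logrank_test(data$time, data$event, data$tp53_call) else NULL
  structure(list(strata = strata, genotype_test = genotype_test,
                 quartile_scope = quartile_scope),
            class = "survival_strata")
}

#' @export
print.survival_strata <- function(x, ...) {
  cat("Aneuploidy-stratified survival (FGA quartiles,",
      x$quartile_scope, "scope)\n")
  for (cls in names(x$strata)) {
    s <- x$strata[[cls]]
    cat(sprintf("  %s: Q1 n = %d, Q4 n = %d, log-rank p = %.3g\n", cls,
                s$n["aneuploid_low"], s$n["aneuploid_high"], s$test$p))
  }
  if (!is.null(x$genotype_test))
    cat(sprintf("  genotype comparison: p = %.3g\n", x$genotype_test$p))
  invisible(x)
}
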