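# Group-comparison statistics used throughout the study: one-sample z
# test (signal ratios against 1), paired t test (tip vs back), the
# Kruskal-Wallis rank test (length comparisons across treatments), fold
# changes and between-timepoint growth rates. Sample standard deviations
# use the n-1 denominator throughout; no multiple-testing correction is
# applied by default, matching how such panels are conventionally
# reported, and the output flags this.

#' One-sample z test
#'
#' z = (mean - mu0) / (sd / sqrt(n)) with the sample standard deviation;
#' the p-value comes from the standard normal. One-tailed tests use the
#' "greater" direction (mean > mu0), so the two-tailed p equals
#' 2 * min(p1, 1 - p1).
#'
#' @param values numeric sample (n >= 2)
#' @param mu0 null mean (default 1, the no-enrichment ratio)
#' @param tails 1 or 2
#' @return a \linkS4class{GroupComparison}
#' @export
oneSampleZTest <- function(values, mu0 = 1, tails = 2) {
  check(length(values) >= 2, "need n >= 2")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero standard deviation", call. = FALSE)
  n <- length(values)
  z <- (mean(values) - mu0) / (s / sqrt(n))
  p <- if (tails == 2) 2 * stats::pnorm(-abs(z)) else 1 - stats::pnorm(z)
  GroupComparison("one_sample_z", z, p, tails, n,
                  effect = mean(values) - mu0, effect_name = "mean_minus_mu0")
}

#' Paired t test
#'
#' t on the pairwise differences d = a - b, df = n - 1. One-tailed tests
#' use the "greater" direction (mean difference > 0).
#'
#' @param a,b paired numeric samples of equal length (n >= 2)
#' @param tails 1 or 2
#' @return a \linkS4class{GroupComparison}
#' @export
pairedTTest <- function(a, b, tails = 2) {
  if (length(a) != length(b))
    stop("unequal lengths: paired samples must match", call. = FALSE)
  check(length(a) >= 2, "need n >= 2")
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate sample: zero-variance differences", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE,
                      alternative = if (tails == 2) "two.sided" else "greater")
  GroupComparison("paired_t", unname(ht$statistic), ht$p.value, tails,
                  length(a), effect = mean(d), effect_name = "mean_difference",
                  df = unname(ht$parameter))
}

#' Kruskal-Wallis rank test across groups
#'
#' Mid-ranks over the pooled data with tie correction; p from the
#' chi-square approximation on k - 1 degrees of freedom. The
#' approximation is documented for group sizes >= 5; a warning is issued
#' below that.
#'
#' @param groups list of numeric vectors (>= 2 groups, total N >= 3)
#' @return a \linkS4class{GroupComparison} (statistic = H)
#' @export
kruskalWallis <- function(groups) {
  check(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  ns <- lengths(groups)
  check(all(ns >= 1) && sum(ns) >= 3, "need total N >= 3")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1)
    stop("no variation: all values identical", call. = FALSE)
  if (any(ns < 5))
    warning("group size < 5: chi-square approximation is crude",
            call. = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  ht <- stats::kruskal.test(pooled, g)
  GroupComparison("kruskal_wallis", unname(ht$statistic), ht$p.value, 2,
                  ns, df = unname(ht$parameter))
}

#' Fold change between two groups of measurements
#'
#' mean(a) / mean(b).
#'
#' @param group_a_values,group_b_values non-empty numeric vectors
#' @return the ratio of means
#' @export
foldChange <- function(group_a_values, group_b_values) {
  check(length(group_a_values) >= 1 && length(group_b_values) >= 1,
        "both groups must be non-empty")
  mb <- mean(group_b_values)
  if (mb == 0) stop("zero denominator mean", call. = FALSE)
  mean(group_a_values) / mb
}

#' Growth rate of a measurement between two timepoints
#'
#' (mean at t2 - mean at t1) / (t2 - t1), in field units per hour.
#'
#' @param records data.frame in the morphometric record schema
#' @param condition condition label to subset
#' @param t1_hpf,t2_hpf the two timepoints (t2 > t1), hours post
#'   fertilization
#' @param field measured column, default "volume_um3"
#' @return rate in field units per hour
#' @export
growthRate <- function(records, condition, t1_hpf, t2_hpf,
                       field = "volume_um3") {
  check(t2_hpf > t1_hpf, "t2_hpf must exceed t1_hpf")
  check(field %in% names(records), paste0("missing field: ", field))
  pick <- function(tp) {
    v <- records[records$condition == condition &
                   records$timepoint_hpf == tp, field]
    if (!length(v))
      stop(sprintf("missing group: condition '%s' at %g hpf", condition, tp),
           call. = FALSE)
    v
  }
  (mean(pick(t2_hpf)) - mean(pick(t1_hpf))) / (t2_hpf - t1_hpf)
}

#' Run a comparison plan over a cohort records table
#'
#' Each plan entry names a test and its grouping; supported tests are
#' "kruskal_wallis" (conditions at one timepoint), "fold_change"
#' (condition a over condition b at one timepoint) and "growth_rate"
#' (one condition between two timepoints). No multiple-testing correction
#' is applied unless `correct = "bonferroni"`; the output carries the
#' choice in its attributes.
#'
#' @param records data.frame in the morphometric record schema
#' @param plan list of entries: list(test =, field =, conditions =,
#'   timepoint = | timepoints =)
#' @param correct "none" (default) or "bonferroni"
#' @return data.frame with one row per comparison; attributes
#'   `p_correction` records the correction used
#' @export
compareCohorts <- function(records, plan, correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  check(all(c("condition", "timepoint_hpf") %in% names(records)),
        "records must carry condition and timepoint_hpf columns")
  rows <- lapply(seq_along(plan), function(i) {
    e <- plan[[i]]
    label <- if (!is.null(e$name)) e$name else paste0("entry_", i)
    fail <- function(msg) stop(sprintf("plan entry '%s': %s", label, msg),
                               call. = FALSE)
    if (is.null(e$test) || is.null(e$field)) fail("needs test and field")
    if (!e$field %in% names(records)) fail(paste0("missing field ", e$field))
    grab <- function(cond, tp) {
      v <- records[records$condition == cond &
                     records$timepoint_hpf == tp, e$field]
      if (!length(v)) fail(sprintf("missing group '%s' at %g hpf", cond, tp))
      v
    }
    if (e$test == "kruskal_wallis") {
      gs <- lapply(e$conditions, grab, tp = e[["timepoint"]])
      gc <- suppressWarnings(kruskalWallis(gs))
      df <- as.data.frame(gc)
    } else if (e$test == "fold_change") {
      a <- grab(e$conditions[1], e[["timepoint"]])
      b <- grab(e$conditions[2], e[["timepoint"]])
      df <- data.frame(test_name = "fold_change", statistic = NA_real_,
                       p_value = NA_real_, tails = NA_real_, df = NA_real_,
                       group_sizes = paste(c(length(a), length(b)),
                                           collapse = "/"),
                       effect = foldChange(a, b),
                       effect_name = "fold_change",
                       stringsAsFactors = FALSE)
    } else if (e$test == "growth_rate") {
      r <- growthRate(records, e$conditions[1], e$timepoints[1],
                      e$timepoints[2], e$field)
      n1 <- sum(records$condition == e$conditions[1] &
                  records$timepoint_hpf == e$timepoints[1])
      n2 <- sum(records$condition == e$conditions[1] &
                  records$timepoint_hpf == e$timepoints[2])
      df <- data.frame(test_name = "growth_rate", statistic = NA_real_,
                       p_value = NA_real_, tails = NA_real_, df = NA_real_,
                       group_sizes = paste(c(n1, n2), collapse = "/"),
                       effect = r, effect_name = paste0(e$field, "_per_hr"),
                       stringsAsFactors = FALSE)
    } else fail(paste0("unknown test ", e$test))
    cbind(data.frame(name = label, field = e$field,
                     timepoint_hpf = if (!is.null(e[["timepoint"]]))
                       e[["timepoint"]] else NA_real_,
                     stringsAsFactors = FALSE), df)
  })
  out <- do.call(rbind, rows)
  if (correct == "bonferroni") {
    k <- sum(!is.na(out$p_value))
    out$p_adjusted <- pmin(out$p_value * k, 1)
  }
  attr(out, "p_correction") <- correct
  out
}
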