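# Cohort-level arithmetic: treatment-change tables (percent change, effect
# size, tests), classification transition tables and correlation summaries.
# The hypothesis tests are thin wrappers over the standard stats routines.

#' Percent change of a measure following treatment
#'
#' `100 * (before - after) / before`; positive when the score improves
#' (falls).
#'
#' @param before_mean,after_mean Group means before and after treatment.
#' @return Percent change.
#' @export
#' @examples
#' delta_percent(38, 32.7) # UPDRS III, ~13.9
delta_percent <- function(before_mean, after_mean) {
  100 * (before_mean - after_mean) / before_mean
}

#' Standardized effect size of a treatment change
#'
#' Standardized mean difference `(before - after) / s`. The default
#' standardizer is the pooled SD `sqrt((sd1^2 + sd2^2) / 2)`; `"baseline"`
#' uses the before-treatment SD and `"paired"` standardizes the mean paired
#' difference by the SD of the differences (requires per-subject vectors).
#'
#' @param before_mean,after_mean,before_sd,after_sd Group summaries.
#' @param method `"pooled"` (default), `"baseline"` or `"paired"`.
#' @param before,after Per-subject vectors, required for `method = "paired"`.
#' @return Standardized difference.
#' @export
effect_size <- function(before_mean, before_sd, after_mean, after_sd,
                        method = c("pooled", "baseline", "paired"),
                        before = NULL, after = NULL) {
  method <- match.arg(method)
  switch(method,
    pooled = (before_mean - after_mean) /
      sqrt((before_sd^2 + after_sd^2) / 2),
    baseline = (before_mean - after_mean) / before_sd,
    paired = {
      if (is.null(before) || is.null(after)) {
        stop("'paired' effect size needs per-subject 'before'/'after' vectors",
             call. = FALSE)
      }
      d <- before - after
      mean(d) / sd(d)
    }
  )
}

#' Welch's t-test (wrapper)
#'
#' @param before,after Numeric vectors.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(before, after) {
  ht <- t.test(before, after, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Mann-Whitney (Wilcoxon rank-sum) test (wrapper)
#'
#' @inheritParams welch_t
#' @return List with `statistic`, `p_value`.
#' @export
mann_whitney <- function(before, after) {
  ht <- wilcox.test(before, after, exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Chi-square test of proportions (wrapper)
#'
#' @param counts A contingency table or matrix of counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(counts) {
  ht <- chisq.test(counts)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Pearson correlation with Fisher-z 95% confidence interval
#'
#' @param x,y Numeric vectors.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `r`, `ci` (length-2), `p_value`, `n`.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  ok <- complete.cases(x, y)
  ht <- cor.test(x[ok], y[ok], method = "pearson", conf.level = conf_level)
  list(r = unname(ht$estimate), ci = as.numeric(ht$conf.int),
       p_value = ht$p.value, n = sum(ok))
}

#' One-way ANOVA with Sidak-adjusted pairwise contrasts
#'
#' Fits `aov(value ~ group)` and adjusts the unpaired pairwise Welch p-values
#' with the Sidak correction `1 - (1 - p)^m` over the m contrasts.
#'
#' @param value Numeric response.
#' @param group Factor (or coercible) of group labels.
#' @return List with `anova_p` (overall F-test p), and `pairwise` (data
#'   frame: `group1`, `group2`, `p_raw`, `p_sidak`).
#' @export
anova_sidak <- function(value, group) {
  group <- factor(group)
  fit <- aov(value ~ group)
  overall <- summary(fit)[[1]][["Pr(>F)"]][1]
  levs <- levels(group)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  p_raw <- vapply(seq_len(m), function(i) {
    t.test(value[group == pairs[1, i]], value[group == pairs[2, i]],
           var.equal = FALSE)$p.value
  }, numeric(1))
  data_pairs <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           p_raw = p_raw,
                           p_sidak = pmin(1, 1 - (1 - p_raw)^m))
  list(anova_p = overall, pairwise = data_pairs)
}

#' Fluctuator-class transition table
#'
#' Cross-tabulates paired before/after class labels over the eight class
#' values, with the marginal shifts the cohort summaries report.
#'
#' @param classes_before,classes_after Character vectors of fluctuator
#'   classes, paired by subject.
#' @return List with `table` (8 x 8 count matrix), `n`, `pct_unchanged`, and
#'   `marginals` (data frame of before/after counts per class).
#' @export
transition_table <- function(classes_before, classes_after) {
  if (length(classes_before) != length(classes_after)) {
    stop("before/after class vectors must be paired", call. = FALSE)
  }
  fb <- factor(classes_before, levels = FLUCT_CLASSES)
  fa <- factor(classes_after, levels = FLUCT_CLASSES)
  if (anyNA(fb) || anyNA(fa)) {
    stop("unknown class label; expected one of: ",
         paste(FLUCT_CLASSES, collapse = ", "), call. = FALSE)
  }
  tab <- table(before = fb, after = fa)
  n <- length(fb)
  list(
    table = tab,
    n = n,
    pct_unchanged = 100 * sum(diag(tab)) / n,
    marginals = data.frame(class = FLUCT_CLASSES,
                           before = as.integer(rowSums(tab)),
                           after = as.integer(colSums(tab)))
  )
}

#' Treatment-change summary for paired cohorts
#'
#' Builds one row per measure with before/after mean (SD), percent change,
#' effect size and Welch p-value.
#'
#' @param before,after Data frames of per-subject measures (shared columns,
#'   paired rows).
#' @param measures Character vector of column names to summarize; defaults
#'   to all shared numeric columns.
#' @param es_method Effect-size method passed to [effect_size()].
#' @return Data frame with columns `measure`, `before_mean`, `before_sd`,
#'   `after_mean`, `after_sd`, `delta_pct`, `effect_size`, `p_value`, `n`.
#' @export
treatment_change_table <- function(before, after, measures = NULL,
                                   es_method = "pooled") {
  shared <- intersect(names(before), names(after))
  if (is.null(measures)) {
    measures <- shared[vapply(before[shared], is.numeric, logical(1))]
  }
  rows <- lapply(measures, function(m) {
    b <- before[[m]]
    a <- after[[m]]
    ok_b <- !is.na(b)
    ok_a <- !is.na(a)
    es <- if (es_method == "paired") {
      ok <- ok_b & ok_a
      effect_size(mean(b[ok]), sd(b[ok]), mean(a[ok]), sd(a[ok]),
                  method = "paired", before = b[ok], after = a[ok])
    } else {
      effect_size(mean(b[ok_b]), sd(b[ok_b]), mean(a[ok_a]), sd(a[ok_a]),
                  method = es_method)
    }
    data.frame(
      measure = m,
      before_mean = mean(b[ok_b]), before_sd = sd(b[ok_b]),
      after_mean = mean(a[ok_a]), after_sd = sd(a[ok_a]),
      delta_pct = delta_percent(mean(b[ok_b]), mean(a[ok_a])),
      effect_size = es,
      p_value = tryCatch(welch_t(b[ok_b], a[ok_a])$p_value,
                         error = function(e) NA_real_),
      n = sum(ok_b & ok_a),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
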