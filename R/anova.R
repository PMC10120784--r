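#' Two-way fixed-effects ANOVA for one metric
#'
#' Fits `value ~ treatment * sex` on complete cases with sum-to-zero factor
#' coding and Type III sums of squares, the decomposition appropriate for the
#' mildly unbalanced cell counts that arise here (and the one matched by
#' GraphPad-style two-way ANOVA). For each of the two main effects and the
#' interaction it returns F, numerator and denominator df, and the p-value
#' from the F distribution. With a full 2 x 2 design and complete cases the
#' denominator df is `n - 4`.
#'
#' @param values Numeric per-bird metric values (NAs dropped as incomplete
#'   cases).
#' @param sex,treatment Factors (or coercible) of the same length.
#' @return A `data.frame` with rows `treatment`, `sex`, `interaction` and
#'   columns `effect`, `F`, `df1`, `df2`, `p`, plus attribute `n_used`.
#' @export
fit_two_way_anova <- function(values, sex, treatment) {
  stopifnot(length(values) == length(sex), length(values) == length(treatment))
  d <- data.frame(value = as.numeric(values),
                  sex = factor(sex), treatment = factor(treatment))
  d <- d[complete.cases(d), , drop = FALSE]
  tab <- table(d$treatment, d$sex)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: treatment '%s' x sex '%s'",
                 rownames(tab)[empty[1L]], colnames(tab)[empty[2L]]), call. = FALSE)
  }
  fit <- stats::lm(value ~ treatment * sex, data = d,
                   contrasts = list(treatment = "contr.sum", sex = "contr.sum"))
  if (stats::sigma(fit) < sqrt(.Machine$double.eps) * max(1, abs(mean(d$value))))
    stop("zero residual variance: ANOVA F is undefined", call. = FALSE)
  a3 <- car::Anova(fit, type = 3)
  rn <- rownames(a3)
  pick <- function(term) {
    i <- which(rn == term)
    df2 <- a3[rn == "Residuals", "Df"]
    data.frame(effect = switch(term, "treatment:sex" = "interaction", term),
               F = a3[i, "F value"], df1 = a3[i, "Df"], df2 = df2,
               p = a3[i, "Pr(>F)"], stringsAsFactors = FALSE)
  }
  out <- rbind(pick("treatment"), pick("sex"), pick("treatment:sex"))
  rownames(out) <- NULL
  attr(out, "n_used") <- nrow(d)
  out
}

.metric_columns <- c("syllable_type_repertoire", "song_type_repertoire",
                     "syllables_per_song", "syllable_types_per_song",
                     "svi", "syllables_per_sec", "syllable_types_per_sec",
                     "levenshtein_mean", "network_path", "network_density")

#' ANOVA table across all metrics
#'
#' Runs [fit_two_way_anova()] for each metric column of a per-bird metric
#' table, producing the familiar three-effects-per-metric summary. Birds with
#' a missing value for a metric (e.g. excluded small networks) are dropped
#' from that metric's fit only, so the denominator df reflects each metric's
#' own complete cases.
#'
#' @param metrics A [metric_table()] result (needs `sex` and `treatment`
#'   columns).
#' @param metric_cols Metric columns to analyse; defaults to the eight
#'   diversity metrics plus the two network metrics, in display order.
#' @return Long `data.frame` `metric,effect,F,df1,df2,p,n_used`.
#' @export
anova_table <- function(metrics, metric_cols = intersect(.metric_columns, names(metrics))) {
  rows <- lapply(metric_cols, function(mc) {
    a <- fit_two_way_anova(metrics[[mc]], metrics$sex, metrics$treatment)
    cbind(metric = mc, a, n_used = attr(a, "n_used"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell means and standard errors
#'
#' Mean and SEM (sd / sqrt(n)) of each metric in each sex x treatment cell —
#' the table behind mean-and-error-bar plots. SEM is `NA` for singleton
#' cells.
#'
#' @inheritParams anova_table
#' @return Long `data.frame` `metric,sex,treatment,n,mean,sem`.
#' @export
summarize_cells <- function(metrics, metric_cols = intersect(.metric_columns, names(metrics))) {
  cells <- unique(metrics[, c("sex", "treatment")])
  cells <- cells[order(cells$sex, cells$treatment), , drop = FALSE]
  rows <- lapply(metric_cols, function(mc) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      v <- metrics[metrics$sex == cells$sex[i] & metrics$treatment == cells$treatment[i], mc]
      v <- v[!is.na(v)]
      data.frame(metric = mc, sex = cells$sex[i], treatment = cells$treatment[i],
                 n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
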