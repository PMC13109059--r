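#' Row-wise Z-score transform of an expression matrix
#'
#' Each gene row is centered and scaled to `(x - mean) / sd` with the sample
#' standard deviation (n - 1 denominator), so every row has mean 0 and SD 1
#' across samples. A zero-variance row is an error naming the gene, since
#' its Z-score is undefined.
#'
#' @param m Numeric genes-by-samples matrix (>= 2 samples).
#' @return Matrix of the same shape, dimensionless.
#' @export
zscore_rows <- function(m) {
  if (!is.matrix(m) || ncol(m) < 2)
    stop("expression matrix must have >= 2 samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero))
    stop("zero-variance row(s): ",
         paste(rownames(m)[zero] %||% zero, collapse = ", "))
  (m - mu) / sdv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Composite TF-activity score
#'
#' Per-sample unweighted mean of the Z-scored rows of a gene set, e.g. the
#' seven major AP-1 subunits (JUN, JUNB, JUND, FOS, FOSB, FOSL1, FOSL2).
#' Averaging a subunit family into one composite sidesteps the
#' subunit-level compensation that blurs single-gene comparisons.
#'
#' @param z Z-scored expression matrix (see [zscore_rows()]).
#' @param subunits Character vector of gene ids; all must be rows of `z`.
#' @return Named numeric vector, one score per sample.
#' @export
activity_score <- function(z, subunits) {
  miss <- setdiff(subunits, rownames(z))
  if (length(miss))
    stop("subunit(s) absent from matrix: ", paste(miss, collapse = ", "))
  colMeans(z[subunits, , drop = FALSE])
}

#' Median split of activity scores
#'
#' Samples with score strictly above the cohort median are `high`; scores
#' at or below the median (including exact ties) are `low`. With all scores
#' equal the whole cohort is `low` and a warning is emitted.
#'
#' @param scores Named numeric vector (>= 2 samples).
#' @return Named character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("median split needs >= 2 samples")
  med <- stats::median(scores)
  out <- ifelse(scores > med, "high", "low")
  if (all(out == "low"))
    warning("all scores at or below the median; every sample labelled 'low'")
  stats::setNames(out, names(scores))
}

#' Rank-based quantile groups
#'
#' Sorts scores ascending and cuts at ranks `ceiling(n * j / k)`, j = 1..k,
#' so groups are equal-count (within 1 when k divides n) regardless of the
#' score distribution; `Qk` always holds the highest scores. Ties are broken
#' by stable sample order.
#'
#' @param scores Named numeric vector (>= k samples).
#' @param k Number of groups; default 4 (quartiles Q1-Q4).
#' @return Named factor with levels `Q1..Qk`.
#' @export
quantile_groups <- function(scores, k = 4) {
  if (k < 2) stop("k must be >= 2")
  n <- length(scores)
  if (n < k) stop("need at least k samples")
  ord <- order(scores)  # stable: ties keep original sample order
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  cuts <- ceiling(n * seq_len(k) / k)
  grp <- vapply(rank_of, function(r) which(r <= cuts)[1], integer(1))
  stats::setNames(factor(paste0("Q", grp), levels = paste0("Q", seq_len(k))),
                  names(scores))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' distinct event times, with subjects censored at `t` counted at risk at
#' `t` (the standard convention). Computed via the `survival` package.
#'
#' @param cohort Data.frame with `survival_time` (> 0) and `event` (0/1).
#' @return Data.frame `time`, `n_risk`, `n_event`, `survival`, restricted
#'   to distinct observed event times; `S` is 1 before the first event.
#' @export
km_estimate <- function(cohort) {
  validate_cohort(cohort)
  if (nrow(cohort) < 1) stop("cohort must have >= 1 subject")
  fit <- survival::survfit(
    survival::Surv(cohort$survival_time, cohort$event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], survival = fit$surv[keep])
}

#' Survival probability at given times
#'
#' Step-function evaluation of a [km_estimate()] curve (right-continuous;
#' `S = 1` before the first event).
#'
#' @param curve A `km_estimate` result.
#' @param times Numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two right-censored cohorts:
#' `statistic = (sum(O - E))^2 / sum(V)` over distinct event times, with
#' the p-value from the upper tail of the 1-df chi-square distribution.
#' Computed via `survival::survdiff`. The statistic is invariant to
#' swapping the group labels.
#'
#' @param cohort_a,cohort_b Data.frames with `survival_time` and `event`.
#' @return List with `statistic` and `p_value`.
#' @export
logrank_test <- function(cohort_a, cohort_b) {
  validate_cohort(cohort_a); validate_cohort(cohort_b)
  if (nrow(cohort_a) == 0 || nrow(cohort_b) == 0)
    stop("both cohorts must be non-empty")
  time <- c(cohort_a$survival_time, cohort_b$survival_time)
  event <- c(cohort_a$event, cohort_b$event)
  if (sum(event) == 0) stop("log-rank test requires at least one event")
  group <- rep(c("a", "b"), c(nrow(cohort_a), nrow(cohort_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = as.numeric(sd$chisq),
       p_value = stats::pchisq(as.numeric(sd$chisq), df = 1,
                               lower.tail = FALSE))
}

#' Spearman correlation of loop strength with expression
#'
#' Rank correlation (average-rank ties) between per-gene promoter-loop
#' strength (CPM units) and per-gene expression, on the genes present in
#' both vectors; the p-value uses the large-sample t approximation. This is
#' the statistic relating 3D contact strength to transcriptional output.
#'
#' @param loop_strength Named numeric vector, gene -> loop strength.
#' @param expression Named numeric vector, gene -> expression level.
#' @return List with `rho`, `p_value` and `n` (genes used).
#' @export
loop_expression_correlation <- function(loop_strength, expression) {
  genes <- intersect(names(loop_strength), names(expression))
  if (length(genes) < 3)
    stop("need >= 3 genes shared between loop strengths and expression")
  ct <- suppressWarnings(
    stats::cor.test(loop_strength[genes], expression[genes],
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(genes))
}
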