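# Small-cohort biomarker statistics: logit + BH method comparison, exact
# Mann-Whitney / rank-biserial effect sizes, ROC/Youden, MCC, clustering, PCA.

#' Logit transform of a proportion
#'
#' ln(p / (1 - p)). Proportions exactly 0 or 1 are clamped to eps and 1 - eps
#' with a warning so gel-band and complement percentages can be modelled on
#' the logit scale.
#'
#' @param p Proportions in \[0, 1\] (vectorized).
#' @param eps Clamping bound for boundary values (default 1e-6).
#' @return Logit values.
#' @export
logit_transform <- function(p, eps = 1e-6) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 0 | p == 1)) {
    warning("boundary proportion(s) clamped to eps / 1 - eps", call. = FALSE)
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  log(p / (1 - p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()] with
#' `method = "BH"`); input order is preserved and values are validated.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare two measurement methods on logit-transformed percentages
#'
#' For every (cell line, band) contrast, the percentages from the two methods
#' (e.g. PRM vs SDS-PAGE densitometry) are logit-transformed and compared by
#' a pooled two-sample t test on the method factor; p-values are then
#' Benjamini-Hochberg adjusted across all contrasts. Significance labels use
#' the usual stars, "n.s." above 0.05.
#'
#' @param data data.frame with columns `percent` (0-100), `method` (exactly
#'   two levels), `cell`, `band`; several replicate rows per combination.
#' @return data.frame with one row per (cell, band): `cell`, `band`,
#'   `estimate` (logit difference method2 - method1), `p`, `p_adj`, `label`.
#' @export
method_comparison <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("percent", "method", "cell", "band") %in% names(data)))
  methods <- sort(unique(as.character(data$method)))
  if (length(methods) != 2L) stop("exactly two methods are required", call. = FALSE)
  combos <- unique(data[, c("cell", "band")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- data[data$cell == combos$cell[i] & data$band == combos$band[i], ,
                drop = FALSE]
    n_per <- table(factor(sub$method, levels = methods))
    if (any(n_per < 2L)) {
      stop(sprintf("fewer than 2 replicates for %s / %s",
                   combos$cell[i], combos$band[i]), call. = FALSE)
    }
    y <- logit_transform(sub$percent / 100)
    g <- factor(sub$method, levels = methods)
    tt <- stats::t.test(y ~ g, var.equal = TRUE)
    data.frame(cell = combos$cell[i], band = combos$band[i],
               estimate = unname(tt$estimate[2] - tt$estimate[1]),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$label <- cut(out$p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "n.s."))
  out$label <- as.character(out$label)
  rownames(out) <- NULL
  out
}

#' Confusion matrix
#'
#' @param tp,tn,fp,fn Non-negative integer counts, total > 0.
#' @return A `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) == 0) {
    stop("counts must be non-negative integers with a positive total",
         call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the balanced
#' binary-classification metric recommended for small, unbalanced cohorts.
#' When any denominator factor is zero the value is 0 by convention. The
#' customary heuristic benchmark for a "good" classifier is 0.5.
#'
#' @param cm A [confusion_matrix()].
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  num <- cm$tp * cm$tn - cm$fp * cm$fn
  fac <- c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)
  if (any(fac == 0)) return(0)
  num / sqrt(prod(fac))
}

#' Mann-Whitney U statistic
#'
#' U counted as the number of (x1, x2) pairs in which the group-2 value ranks
#' above the group-1 value, with ties contributing 1/2. Complete separation
#' with group 2 below group 1 gives U = 0; complete reversal gives n1 * n2.
#'
#' @param group1,group2 Non-empty numeric vectors.
#' @return U (possibly half-integer under ties).
#' @export
mann_whitney_u <- function(group1, group2) {
  if (length(group1) == 0L || length(group2) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  cmp <- outer(group2, group1, function(a, b) (a > b) + 0.5 * (a == b))
  sum(cmp)
}

#' Rank-biserial correlation (Wendt) from U
#'
#' r = 1 - 2U / (n1 * n2), the matched-pairs effect size of the Mann-Whitney
#' test for small cohorts. U = 0 gives r = 1; U = n1*n2/2 gives r = 0.
#'
#' @param U Mann-Whitney statistic, in \[0, n1*n2\].
#' @param n1,n2 Group sizes (>= 1).
#' @return r in \[-1, 1\].
#' @export
brcc <- function(U, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (U < 0 || U > n1 * n2) stop("U must lie in [0, n1*n2]", call. = FALSE)
  1 - 2 * U / (n1 * n2)
}

# Exact null distribution of U for group sizes (n1, n2), no ties: counts of
# each U value over all choose(n1+n2, n2) equally likely rank arrangements.
.u_null_counts <- function(n1, n2) {
  N <- n1 + n2
  arrangements <- utils::combn(N, n2)
  U <- colSums(arrangements) - n2 * (n2 + 1) / 2
  table(factor(U, levels = 0:(n1 * n2)))
}

#' Minimal significant rank-biserial correlation by exact enumeration
#'
#' Enumerates the full Mann-Whitney null distribution over all
#' choose(n1+n2, n2) rank arrangements, finds the largest U whose one-sided
#' exact lower-tail probability is at most `alpha`, and converts it with
#' Wendt's formula. For group sizes 8 and 2 at alpha = 0.05 the critical U is
#' 1 (P(U <= 1) = 2/45), giving r = 0.875.
#'
#' @param n1,n2 Group sizes (enumeration is exact; intended for small n).
#' @param alpha One-sided significance level in (0, 1).
#' @return List with `critical_r`, `critical_u` and `p_at_critical`. If even
#'   U = 0 is not significant, `critical_u` is `NA` and `critical_r` is
#'   `NA`.
#' @export
brcc_critical <- function(n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  counts <- .u_null_counts(n1, n2)
  cum <- cumsum(as.numeric(counts)) / sum(counts)
  ok <- which(cum <= alpha)      # index i corresponds to U = i - 1
  if (length(ok) == 0L) {
    return(list(critical_r = NA_real_, critical_u = NA_real_,
                p_at_critical = NA_real_))
  }
  u_crit <- max(ok) - 1L
  list(critical_r = brcc(u_crit, n1, n2),
       critical_u = u_crit,
       p_at_critical = cum[max(ok)])
}

#' Rank test summary for two groups
#'
#' Convenience wrapper computing U, Wendt's r (in both the directional and
#' the min-direction convention) and the exact critical r for the observed
#' group sizes.
#'
#' @inheritParams mann_whitney_u
#' @param alpha Significance level passed to [brcc_critical()].
#' @return List with `U`, `U_min`, `n1`, `n2`, `r` (directional), `r_min`
#'   (from the min-direction U, always >= 0), `critical_r`, `significant`
#'   (is `r_min >= critical_r`).
#' @export
rank_test <- function(group1, group2, alpha = 0.05) {
  U <- mann_whitney_u(group1, group2)
  n1 <- length(group1); n2 <- length(group2)
  U_min <- min(U, n1 * n2 - U)
  crit <- brcc_critical(n1, n2, alpha)
  r_min <- brcc(U_min, n1, n2)
  list(U = U, U_min = U_min, n1 = n1, n2 = n2,
       r = brcc(U, n1, n2), r_min = r_min,
       critical_r = crit$critical_r,
       significant = !is.na(crit$critical_r) && r_min >= crit$critical_r)
}

#' Empirical ROC curve, AUC and Youden-optimal operating point
#'
#' Thresholds are placed at midpoints between consecutive distinct scores
#' (plus sentinels below and above all scores). The AUC is computed by
#' concordance-pair counting with ties credited 1/2, so it obeys the
#' Mann-Whitney identity AUC = U' / (n_pos * n_neg) where U' counts positive
#' scores ranked above negative ones. Youden's J = sensitivity +
#' specificity - 1 is maximized over thresholds; among ties the highest
#' specificity (then the lower threshold) wins.
#'
#' @param scores Numeric predictor per subject.
#' @param labels Binary labels (logical, 0/1, or a two-level factor where the
#'   *second* sorted level is taken as positive unless `positive` is given).
#' @param positive Value of `labels` treated as the positive class.
#' @param direction `">"` if positives score higher (default), `"<"`
#'   otherwise.
#' @return A `roc_result` list: `points` (data.frame threshold, sensitivity,
#'   specificity), `auc`, `youden_j`, `best_threshold`, `sensitivity`,
#'   `specificity` (at the J-optimal threshold).
#' @export
roc_curve <- function(scores, labels, positive = NULL, direction = c(">", "<")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  if (is.null(positive)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) stop("labels must have exactly two classes", call. = FALSE)
    positive <- lv[2L]
  }
  is_pos <- as.character(labels) == as.character(positive)
  if (!any(is_pos) || all(is_pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  s <- if (direction == ">") scores else -scores
  pos <- s[is_pos]; neg <- s[!is_pos]
  auc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  su <- sort(unique(s))
  thr <- c(su[1L] - 1, (su[-length(su)] + su[-1L]) / 2, su[length(su)] + 1)
  pts <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg < t), numeric(1)))
  j <- pts$sensitivity + pts$specificity - 1
  best <- order(-j, -pts$specificity, pts$threshold)[1L]
  structure(list(points = pts, auc = auc,
                 youden_j = j[best],
                 best_threshold = if (direction == ">") pts$threshold[best]
                                  else -pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 direction = direction, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4g, Youden J = %.4g at threshold %.4g (sens %.4g, spec %.4g)\n",
              x$auc, x$youden_j, x$best_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Classify at a threshold and tabulate the confusion matrix
#'
#' @inheritParams roc_curve
#' @param threshold Scores at/above it (direction `">"`) are called positive.
#' @return A [confusion_matrix()].
#' @export
classify_at <- function(scores, labels, threshold, positive = NULL,
                        direction = c(">", "<")) {
  direction <- match.arg(direction)
  if (is.null(positive)) {
    lv <- sort(unique(as.character(labels)))
    positive <- lv[2L]
  }
  is_pos <- as.character(labels) == as.character(positive)
  called <- if (direction == ">") scores >= threshold else scores <= threshold
  confusion_matrix(tp = sum(called & is_pos), tn = sum(!called & !is_pos),
                   fp = sum(called & !is_pos), fn = sum(!called & is_pos))
}

#' Hierarchical clustering of subject profiles on correlation distance
#'
#' Distance between two subjects is 1 - Pearson correlation of their feature
#' vectors (0 for identical shape, 2 for perfect anticorrelation), clustered
#' with average linkage via [stats::hclust()]. A zero-variance profile has no
#' defined correlation and is rejected.
#'
#' @param profiles Numeric matrix or data.frame, subjects in rows, features
#'   (e.g. subtype percentages) in columns; row names label subjects.
#' @param k Number of flat clusters to cut (default 2).
#' @return List with `hclust` (the merge tree), `distance` (dist object) and
#'   `clusters` (named integer vector from [stats::cutree()]).
#' @export
hierarchical_cluster <- function(profiles, k = 2L) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 subjects and 2 features", call. = FALSE)
  }
  vars <- apply(m, 1L, stats::var)
  if (any(vars == 0)) {
    stop("zero-variance profile(s): ",
         paste(rownames(m)[vars == 0], collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, distance = d,
       clusters = stats::cutree(hc, k = min(k, nrow(m))))
}

#' PCA of subject profiles
#'
#' Column-centered (and by default unit-variance-scaled) principal component
#' analysis via [stats::prcomp()]. Percentages of explained variance sum to
#' 100. Component signs are fixed so that the loading largest in magnitude on
#' each component is positive, making scores reproducible across platforms.
#'
#' @param profiles Numeric matrix or data.frame, subjects in rows.
#' @param scale. Scale columns to unit variance (default `TRUE`); constant
#'   columns are an error when scaling.
#' @return List with `scores` (subjects x components), `loadings`,
#'   `percent_variance` (sums to 100).
#' @export
pca_profiles <- function(profiles, scale. = TRUE) {
  m <- as.matrix(profiles)
  if (nrow(m) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (scale. && any(apply(m, 2L, stats::var) == 0)) {
    stop("constant column(s) cannot be unit-variance scaled", call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, percent_variance = pv)
}
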