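# Cohort-comparison statistics: Pearson chi-square contingency tests for
# qualitative features, Shapiro-Wilk-gated two-group tests for quantitative
# ones (pooled-variance t when both groups pass normality, tie-corrected
# Mann-Whitney Z otherwise), and Benjamini-Hochberg correction applied per
# table family.

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction, which is
#' required to regenerate the reference cohort statistics even for small
#' expected counts): `sum((O-E)^2/E)` with `E` from the margins, upper-tail
#' p-value.
#'
#' @param table matrix of nonnegative counts (e.g. 2x2 or 2x3, rows SF/NSF).
#' @return A list `statistic`, `df`, `p`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) < 1)
    stop("`table` must contain nonnegative counts with a positive total")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined: a row or column total is zero")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Tie-corrected Mann-Whitney U test (normal approximation)
#'
#' The U statistic with midranks for ties and the tie-corrected normal
#' approximation Z (no continuity correction), signed so that a negative Z
#' means the first group tends to be smaller.
#'
#' @param x,y numeric samples for the two groups.
#' @return A list `U`, `Z`, `p` (two-sided).
#' @export
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  list(U = U, Z = z, p = if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1)
}

#' Normality-gated two-group comparison
#'
#' Runs a Shapiro-Wilk test on each group; when both are compatible with
#' normality (p > 0.05) the groups are compared by a pooled-variance
#' two-sample t-test, otherwise by the tie-corrected Mann-Whitney Z. The
#' returned record says which path was taken and carries the matching
#' group summaries (mean/sd on the normal path, median/IQR otherwise).
#'
#' @param values_sf,values_nsf numeric samples (each of length >= 3).
#' @return A list `test` ("t" or "mann-whitney"), `statistic`, `p`,
#'   `normal` (both-groups normality flag), and per-group `summary`.
#' @export
two_group_quantitative <- function(values_sf, values_nsf) {
  if (length(values_sf) < 3 || length(values_nsf) < 3)
    stop("each group needs at least 3 observations")
  swp <- function(v) if (var(v) == 0) 0 else shapiro.test(v)$p.value
  normal <- swp(values_sf) > 0.05 && swp(values_nsf) > 0.05
  if (normal) {
    tt <- t.test(values_sf, values_nsf, var.equal = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value; test <- "t"
    summ <- function(v) c(n = length(v), mean = mean(v), sd = sd(v))
  } else {
    mw <- mann_whitney_z(values_sf, values_nsf)
    stat <- mw$Z; p <- mw$p; test <- "mann-whitney"
    summ <- function(v) c(n = length(v), median = median(v),
                          iqr = unname(diff(quantile(v, c(0.25, 0.75)))))
  }
  list(test = test, statistic = stat, p = p, normal = normal,
       summary = list(SF = summ(values_sf), NSF = summ(values_nsf)))
}

#' Pooled-variance t statistic from group summaries
#'
#' The classical two-sample pooled t computed from group summary
#' statistics alone, which lets the reference cohort's t value be
#' regenerated from its group means, SDs and sizes. Degrees of freedom: `n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return A list `statistic`, `df`, `p`. Equal means give statistic 0; zero
#'   variances with differing means give signed `Inf`.
#' @export
pooled_t_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be nonnegative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- if (se > 0) (mean1 - mean2) / se
  else if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  list(statistic = stat, df = df,
       p = if (is.finite(stat)) 2 * pt(-abs(stat), df) else 0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; input order is
#' preserved, adjusted values are monotone in the order statistics, never
#' below the raw p, and capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Cohort demographic/clinical comparison table
#'
#' Builds the descriptive comparison of the SF and NSF groups from a
#' clinical table: chi-square tests for the categorical features (observed
#' counts per class), normality-gated two-group tests for the quantitative
#' ones.
#'
#' @param clinical clinical data frame with `label` and the 15 features.
#' @return A data frame with one row per feature: `feature`, `type`,
#'   `test`, `statistic`, `p`.
#' @export
clinical_comparison_table <- function(clinical) {
  sf <- clinical[clinical$label == "SF", ]
  nsf <- clinical[clinical$label == "NSF", ]
  rows <- list()
  for (f in c("sex", "age", "age_at_onset", "follow_up",
              "seizure_freq_before_oxc", "circadian_rhythm", "comorbidity",
              "inducement", "perinatal_injury", "physical_development",
              "family_history", "mri", "tle", "cns_infection", "head_injury")) {
    if (is.numeric(clinical[[f]])) {
      r <- two_group_quantitative(sf[[f]], nsf[[f]])
      rows[[f]] <- data.frame(feature = f, type = "quantitative",
                              test = r$test, statistic = r$statistic, p = r$p,
                              stringsAsFactors = FALSE)
    } else {
      lv <- sort(unique(clinical[[f]]))
      tab <- rbind(SF = table(factor(sf[[f]], levels = lv)),
                   NSF = table(factor(nsf[[f]], levels = lv)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      r <- tryCatch(chi_square(tab), error = function(e)
        list(statistic = NA_real_, p = NA_real_))
      rows[[f]] <- data.frame(feature = f, type = "categorical",
                              test = "chi-square", statistic = r$statistic,
                              p = r$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-feature two-group comparison of EEG complexity features
#'
#' Compares every complexity feature column between the SF and NSF groups
#' with the normality-gated two-group test, then applies Benjamini-Hochberg
#' correction across the feature family.
#'
#' @param fm a [assemble_features()] feature matrix.
#' @param features optional subset of feature names (default: all complexity
#'   band-channel features).
#' @return A data frame `feature`, `test`, `statistic`, `p`, `p_adjusted`,
#'   ordered as given.
#' @export
feature_comparison_table <- function(fm, features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(features)) {
    bands <- default_bands()$name
    features <- fm$feature_names[sub("-.*", "", fm$feature_names) %in% bands]
  }
  sf <- fm$labels == "SF"
  rows <- lapply(features, function(f) {
    r <- two_group_quantitative(fm$values[sf, f], fm$values[!sf, f])
    data.frame(feature = f, test = r$test, statistic = r$statistic, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
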