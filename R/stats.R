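#' @importFrom stats cor.test t.test lm confint pf aov coef anova var
NULL

stat_result <- function(statistic, value, df, p, n, grouping = NA_character_,
                        extra = list()) {
  structure(c(list(statistic = statistic, value = value, df = df, p = p,
                   n = n, grouping = grouping), extra),
            class = "stat_result")
}

#' @exportS3Method print stat_result
print.stat_result <- function(x, ...) {
  dfs <- if (length(x$df) == 2) sprintf("(%g,%g)", x$df[1], x$df[2])
         else sprintf("(df=%g)", x$df)
  cat(sprintf("<stat_result> %s%s = %.4g, p = %.4g, n = %d\n",
              x$statistic, dfs, x$value, x$p, x$n))
  invisible(x)
}

#' Percentage of volume variation
#'
#' The spread statistic used to summarize inter-individual variability of a
#' volume distribution: `(max - min) * 100 / max`. Lies in `[0, 100)` and is
#' invariant to positive rescaling of the values.
#'
#' @param values numeric vector of at least 2 positive volumes.
#' @return percentage.
#' @export
percent_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("percent_variation: need at least 2 values")
  if (any(values < 0) || max(values) == 0)
    stop("percent_variation: values must be positive")
  (max(values) - min(values)) * 100 / max(values)
}

#' Pearson correlation with t-distributed p-value
#'
#' @param x,y numeric vectors (pairwise complete, n >= 3, non-constant).
#' @return a `stat_result` with `r`, df = n - 2 and a two-sided p-value.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson: need n >= 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("pearson: constant vector")
  ct <- cor.test(x, y, method = "pearson")
  stat_result("r", unname(ct$estimate), unname(ct$parameter), ct$p.value,
              length(x))
}

#' Allometric slope of a neuropil against total brain volume
#'
#' Least-squares slope of `log(part)` on `log(total)`; a slope of 1 means
#' isometric scaling (the part keeps a constant share of the whole). The
#' isometry flag reports whether the 95% confidence interval contains 1.
#'
#' @param total,part positive volume vectors.
#' @return list with `slope`, `ci` (95%), `isometric`, `n` and the fitted lm.
#' @export
allometric_slope <- function(total, part) {
  ok <- !is.na(total) & !is.na(part)
  total <- total[ok]; part <- part[ok]
  if (any(total <= 0) || any(part <= 0))
    stop("allometric_slope: volumes must be positive")
  fit <- lm(log(part) ~ log(total))
  ci <- confint(fit)[2, ]
  list(slope = unname(coef(fit)[2]), ci = unname(ci),
       isometric = ci[1] <= 1 && ci[2] >= 1, n = length(total), fit = fit)
}

#' Test for colony (hive) effects on a volume
#'
#' Fits a linear mixed model of the response with hive as a fixed
#' categorical effect and population as a random intercept, followed by an
#' F-test of the hive term with containment denominator degrees of freedom
#' `n - n_hives` (numerator `n_hives - 1`). With a single population the
#' model reduces to a plain one-way ANOVA, which has the same degrees of
#' freedom. For the honey-bee design (110 specimens, 9 hives, 2 populations)
#' this yields F(8, 101).
#'
#' @param t a specimen table (data.frame) with `hive`, `population` and the
#'   response column.
#' @param response name of the response column.
#' @return a `stat_result` with the F statistic, df pair and p-value.
#' @export
colony_effect_test <- function(t, response = "total") {
  if (!response %in% names(t))
    stop("colony_effect_test: response column '", response, "' not found")
  d <- t[!is.na(t[[response]]), , drop = FALSE]
  d$hive <- factor(d$hive)
  n <- nrow(d)
  nh <- nlevels(d$hive)
  if (nh < 2) stop("colony_effect_test: need at least 2 hives")
  df1 <- nh - 1
  df2 <- n - nh
  if (length(unique(d$population)) > 1) {
    d$population <- factor(d$population)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(d[[response]] ~ hive + (1 | population), data = d,
                 REML = TRUE)))
    Fv <- anova(fit)["hive", "F value"]
  } else {
    fit <- aov(d[[response]] ~ hive, data = d)
    sm <- summary(fit)[[1]]
    Fv <- sm["hive", "F value"]
  }
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  stat_result("F", Fv, c(df1, df2), p, n, grouping = "hive|population",
              extra = list(response = response))
}

#' Paired left/right lateralization test
#'
#' Student's paired-samples t-test of left minus right volumes of a paired
#' neuropil, plus the percentage of specimens whose left side is strictly
#' smaller than the right. Rows with missing sides (non-separable
#' segmentations, e.g. midline-merged mushroom bodies) are excluded and
#' counted; exact ties are reported separately.
#'
#' @param t specimen table with `<neuropil>_left` / `<neuropil>_right`.
#' @param neuropil one of AL, MB, ME, LO, OL.
#' @return a `stat_result` with `t`, df, p and extras `pct_smaller_left`,
#'   `n_used`, `n_excluded`, `n_ties`.
#' @export
lateralization_test <- function(t, neuropil = "OL") {
  lc <- paste0(neuropil, "_left"); rc <- paste0(neuropil, "_right")
  if (!all(c(lc, rc) %in% names(t)))
    stop("lateralization_test: columns ", lc, "/", rc, " not found")
  L <- t[[lc]]; R <- t[[rc]]
  ok <- !is.na(L) & !is.na(R)
  n_excl <- sum(!ok)
  L <- L[ok]; R <- R[ok]
  if (length(L) < 3)
    stop("lateralization_test: fewer than 3 usable left/right pairs")
  if (all(L == R)) {
    tt <- list(statistic = 0, parameter = length(L) - 1, p.value = 1)
  } else {
    tt <- t.test(L, R, paired = TRUE)
  }
  ties <- sum(L == R)
  pct <- 100 * sum(L < R) / length(L)
  stat_result("t", unname(tt$statistic), unname(tt$parameter), tt$p.value,
              length(L),
              extra = list(neuropil = neuropil, pct_smaller_left = pct,
                           n_used = length(L), n_excluded = n_excl,
                           n_ties = ties))
}

#' Whole-brain asymmetry quadrants
#'
#' Classifies each specimen by the sign of (right - left) for two paired
#' neuropils into four categories (larger right A & B, larger right A only,
#' larger right B only, smaller right A & B), using strict inequalities.
#' Specimens tied on either pair, or with missing sides, are excluded and
#' reported. Percentages are over the classified rows and sum to 100%.
#'
#' @param t specimen table.
#' @param pairA,pairB paired neuropil names (defaults AL and OL).
#' @return list with `percent` (named numeric, 4 categories), `counts`,
#'   `n_classified`, `n_ties`, `n_missing`.
#' @export
asymmetry_quadrants <- function(t, pairA = "AL", pairB = "OL") {
  dA <- t[[paste0(pairA, "_right")]] - t[[paste0(pairA, "_left")]]
  dB <- t[[paste0(pairB, "_right")]] - t[[paste0(pairB, "_left")]]
  missing <- is.na(dA) | is.na(dB)
  tie <- !missing & (dA == 0 | dB == 0)
  use <- !missing & !tie
  cats <- c(
    sprintf("larger right %s and %s", pairA, pairB),
    sprintf("larger right %s, smaller right %s", pairA, pairB),
    sprintf("smaller right %s, larger right %s", pairA, pairB),
    sprintf("smaller right %s and %s", pairA, pairB)
  )
  cls <- ifelse(dA[use] > 0,
                ifelse(dB[use] > 0, cats[1], cats[2]),
                ifelse(dB[use] > 0, cats[3], cats[4]))
  counts <- table(factor(cls, levels = cats))
  if (sum(use) == 0)
    warning("asymmetry_quadrants: no classifiable rows (all ties or missing)")
  pct <- if (sum(use) == 0) setNames(rep(NA_real_, 4), cats)
         else 100 * as.numeric(counts) / sum(use)
  names(pct) <- cats
  list(percent = pct, counts = counts, n_classified = sum(use),
       n_ties = sum(tie), n_missing = sum(missing))
}

#' Operating characteristics of the cohort tests by simulation
#'
#' Repeatedly draws cohorts from the generator (volumes only, no voxel
#' rendering), applies the lateralization and/or colony-effect test, and
#' returns rejection frequencies with binomial standard errors. With all
#' lateral deficits at zero this estimates the type-I error rate; with a
#' non-zero deficit it estimates power.
#'
#' @param params a [phantom_params()] describing the generator conditions.
#' @param hive_plan hive plan (see [sample_cohort()]).
#' @param n_reps number of simulated cohorts (>= 50; use more for stable
#'   estimates).
#' @param alpha significance level.
#' @param seed base RNG seed; rep r uses `seed + r`.
#' @param tests subset of `c("lateralization", "colony")`.
#' @param neuropil paired neuropil for the lateralization test.
#' @param response response column for the colony test.
#' @return data.frame with one row per test: rejection rate, binomial se, n_reps.
#' @export
simulate_operating_characteristics <- function(params,
                                               hive_plan = bumblebee_hive_plan(),
                                               n_reps = 200, alpha = 0.05,
                                               seed = 1L,
                                               tests = c("lateralization"),
                                               neuropil = "OL",
                                               response = "total") {
  if (n_reps < 50)
    stop("simulate_operating_characteristics: n_reps must be >= 50")
  if (alpha <= 0 || alpha >= 1)
    stop("simulate_operating_characteristics: alpha must be in (0, 1)")
  rej <- sapply(tests, function(x) 0)
  for (r in seq_len(n_reps)) {
    cohort <- sample_cohort(params, hive_plan = hive_plan,
                            seed = seed + r)
    tab <- cohort_to_table(cohort)
    if ("lateralization" %in% tests) {
      p <- lateralization_test(tab, neuropil)$p
      rej["lateralization"] <- rej["lateralization"] + (p < alpha)
    }
    if ("colony" %in% tests) {
      p <- colony_effect_test(tab, response)$p
      rej["colony"] <- rej["colony"] + (p < alpha)
    }
  }
  rate <- rej / n_reps
  data.frame(test = tests, rate = as.numeric(rate),
             se = sqrt(rate * (1 - rate) / n_reps), n_reps = n_reps,
             alpha = alpha, stringsAsFactors = FALSE, row.names = NULL)
}
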