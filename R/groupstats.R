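#' Head-size residualization of VOI volumes
#'
#' Fits the linear volume~TIV relationship on the healthy controls only
#' (the "normal" head-size relationship), computes every subject's residual
#' with respect to that prediction, and standardizes the residuals by the
#' standard deviation of the whole sample's residuals (sample sd, n - 1).
#' Standardized residuals are the head-size-corrected volume estimates.
#'
#' @param volumes Numeric vector of VOI volumes (mm^3).
#' @param tivs Numeric vector of total intracranial volumes (any consistent
#'   unit; results are invariant to affine rescaling of the TIV unit).
#' @param is_control Logical vector: TRUE for healthy controls.
#' @return List with `z` (standardized residuals), `residuals`, and `model`
#'   (intercept, slope, slope 95% CI, whole-sample residual sd).
#' @export
residualize <- function(volumes, tivs, is_control) {
  n <- length(volumes)
  if (length(tivs) != n || length(is_control) != n)
    stop("volumes, tivs and is_control must have equal length")
  if (all(is_control) || !any(is_control))
    stop("need both controls and patients")
  if (sum(is_control) < 3) stop("need >= 3 controls for the TIV fit")
  if (stats::var(tivs[is_control]) <= 0)
    stop("TIV variance among controls must be > 0")
  fit <- stats::lm(v ~ t, data = data.frame(v = volumes[is_control],
                                            t = tivs[is_control]))
  pred <- coef(fit)[1] + coef(fit)[2] * tivs
  res <- volumes - pred
  s <- stats::sd(res)
  if (s <= 1e-10 * max(abs(volumes), 1))
    stop("residual sd is zero; volumes are exactly linear in TIV")
  ci <- stats::confint(fit)["t", ]
  list(z = res / s, residuals = res,
       model = list(intercept = unname(coef(fit)[1]),
                    slope = unname(coef(fit)[2]),
                    slope_ci95 = unname(ci), sd = s))
}

#' ANCOVA with partial eta squared
#'
#' Linear model `dep ~ group + age (+ extras)` with type-III (marginal)
#' F tests per term: each term's sum of squares is the increase in residual
#' sum of squares when that term alone is dropped from the full model.
#' Partial eta squared is `SS_term / (SS_term + SS_error)`.
#'
#' @param dep Numeric response.
#' @param group Factor (or coercible) with >= 2 levels, each n >= 2.
#' @param age Numeric covariate.
#' @param extra_covariates Optional data frame of further numeric covariates.
#' @return Data frame with one row per term: `term`, `F`, `df_effect`,
#'   `df_error`, `p`, `partial_eta_squared`.
#' @export
ancova <- function(dep, group, age, extra_covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("each group needs n >= 2")
  df <- data.frame(dep = dep, group = group, age = age)
  terms <- c("group", "age")
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.data.frame(extra_covariates)
    df <- cbind(df, extra_covariates)
    terms <- c(terms, names(extra_covariates))
  }
  full <- stats::lm(stats::reformulate(terms, response = "dep"), data = df)
  qrf <- qr(stats::model.matrix(full))
  if (qrf$rank < ncol(stats::model.matrix(full))) {
    al <- colnames(stats::model.matrix(full))[-seq_len(qrf$rank)]
    stop("rank-deficient design; collinear columns: ",
         paste(al, collapse = ", "))
  }
  rss_full <- sum(resid(full)^2)
  df_err <- full$df.residual
  mse <- rss_full / df_err
  out <- do.call(rbind, lapply(terms, function(tm) {
    red <- stats::lm(stats::reformulate(setdiff(terms, tm),
                                        response = "dep",
                                        intercept = TRUE), data = df)
    ss <- sum(resid(red)^2) - rss_full
    df1 <- red$df.residual - df_err
    Fv <- (ss / df1) / mse
    data.frame(term = tm, F = Fv, df_effect = df1, df_error = df_err,
               p = stats::pf(Fv, df1, df_err, lower.tail = FALSE),
               partial_eta_squared = ss / (ss + rss_full))
  }))
  rownames(out) <- NULL
  out
}

#' Sidak adjustment of p-values
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`; monotone in both `p` and
#' `m`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param m Number of comparisons in the family (>= number of p-values).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  if (m < length(p_values))
    stop("m must be at least the number of comparisons supplied")
  pmin(1, pmax(0, 1 - (1 - p_values)^m))
}

#' Pairwise group comparisons with Sidak-adjusted p-values
#'
#' Post hoc pairwise Welch comparisons of group means (applied after a
#' significant ANCOVA omnibus test), Sidak-adjusted over the number of
#' pairs.
#'
#' @param dep Numeric response.
#' @param group Factor of group membership.
#' @return List with matrices `p_raw`, `p_sidak`, `direction` (sign of the
#'   row-minus-column mean difference), and `m` (family size).
#' @export
posthoc_sidak <- function(dep, group) {
  group <- factor(group)
  lev <- levels(group)
  k <- length(lev)
  m <- k * (k - 1) / 2
  p_raw <- p_adj <- dir <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tt <- stats::t.test(dep[group == lev[i]], dep[group == lev[j]])
    p_raw[i, j] <- p_raw[j, i] <- tt$p.value
    d <- mean(dep[group == lev[i]]) - mean(dep[group == lev[j]])
    dir[i, j] <- sign(d)
    dir[j, i] <- -sign(d)
  }
  ut <- upper.tri(p_raw)
  p_adj[ut] <- sidak_adjust(p_raw[ut], m = m)
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(p_raw = p_raw, p_sidak = p_adj, direction = dir, m = m)
}

#' Partial Spearman correlation (rank-based, covariate-controlled)
#'
#' Rank-transforms `x`, `y` and the covariate, then computes the partial
#' Pearson correlation of the ranks controlling for the covariate ranks;
#' the p-value uses the t approximation with n - 3 degrees of freedom.
#' A constant covariate degenerates to the plain Spearman correlation.
#'
#' @param x,y Numeric vectors (n >= 5, finite, non-constant).
#' @param covariate Numeric covariate (e.g. age).
#' @return List with `r`, `p`, `n`, `method`, `covariates`.
#' @export
partial_spearman <- function(x, y, covariate) {
  n <- length(x)
  if (n < 5) stop("need n >= 5")
  if (any(!is.finite(c(x, y, covariate)))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(covariate) == 0) {
    r <- stats::cor(rx, ry)
  } else {
    rc <- rank(covariate)
    ex <- resid(stats::lm(rx ~ rc))
    ey <- resid(stats::lm(ry ~ rc))
    r <- stats::cor(ex, ey)
  }
  df <- n - 3
  tstat <- r * sqrt(df / max(1 - r^2, 1e-15))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(r = r, p = p, n = n, method = "partial Spearman",
       covariates = "covariate (ranked)")
}

#' Two-way mixed-effects intraclass correlation
#'
#' ICC(3,1): single-rater consistency form of the two-way mixed-effects
#' model, `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`
#' from the two-way ANOVA mean squares (subjects x raters, no replicates).
#' The absolute-agreement variant ICC(A,1) adds the rater variance to the
#' denominator.
#'
#' @param ratings Numeric matrix, subjects in rows (>= 3), raters in
#'   columns (>= 2), no missing cells.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return List with `icc`, `model`, `n_subjects`, `n_raters`.
#' @export
icc_two_way_mixed <- function(ratings, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3) stop("need >= 3 subjects")
  if (k < 2) stop("need >= 2 raters")
  if (any(!is.finite(ratings))) stop("missing cells are not allowed")
  grand <- mean(ratings)
  ms_r <- k * sum((rowMeans(ratings) - grand)^2) / (n - 1)     # subjects
  ms_c <- n * sum((colMeans(ratings) - grand)^2) / (k - 1)     # raters
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - (n - 1) * ms_r / k * k - (k - 1) * ms_c / n * n
  ms_e <- ss_err / ((n - 1) * (k - 1))
  icc <- if (type == "consistency") {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  } else {
    (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k / n * (ms_c - ms_e))
  }
  list(icc = icc,
       model = sprintf("two-way mixed, single rater, %s", type),
       n_subjects = n, n_raters = k)
}

#' Descriptive cohort summary with unpaired t-tests
#'
#' Per variable: group means, sds and ranges, and the Welch (unequal
#' variance) two-sample t-test between patients and controls.
#'
#' @param table Data frame with a `group` column (values `patient` /
#'   `control`) and numeric variables.
#' @param variables Character vector of columns to summarize (default: all
#'   numeric columns).
#' @return Data frame with one row per variable.
#' @export
cohort_summary <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  gp <- table$group == "patient"
  gc <- table$group == "control"
  if (sum(gp) < 2 || sum(gc) < 2) stop("both groups need n >= 2")
  do.call(rbind, lapply(variables, function(v) {
    xp <- table[[v]][gp]; xc <- table[[v]][gc]
    tt <- stats::t.test(xp, xc)
    data.frame(variable = v,
               patient_mean = mean(xp), patient_sd = stats::sd(xp),
               patient_min = min(xp), patient_max = max(xp),
               control_mean = mean(xc), control_sd = stats::sd(xc),
               control_min = min(xc), control_max = max(xc),
               t = unname(tt$statistic), p = tt$p.value)
  }))
}
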