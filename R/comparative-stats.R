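#' Fit the comparative linear mixed model for a physiological response
#'
#' Fits, by REML, `response ~ habitat * activity + mass + (1 | species)`:
#' fixed effects for habitat, daily activity and their interaction, body mass
#' as a covariate, and a random intercept per species (individuals of a
#' species share habitat and activity, so species is the grouping unit).
#' Factors are coded with sum-to-zero contrasts so that downstream type-III
#' Wald tests are meaningful. Endothermy is log-transformed in the published
#' analysis (`log_transform = TRUE`); non-positive response values are then
#' dropped with a message.
#'
#' @param data Data frame with columns `species`, `habitat`, `activity`,
#'   `mass` and the response.
#' @param response Response column name (e.g. `"endothermy"`, `"slope_th"`,
#'   `"slope_abd"`, `"slope_diff"`).
#' @param log_transform Log-transform the response first?
#' @return An object of class `thermo_lmm` wrapping the `lme4` fit, with
#'   `$fit`, `$response`, `$log_transform`, `$singular` (TRUE when the
#'   random-intercept variance collapsed to zero; reported with a warning,
#'   not an error) and `$n_dropped`.
#' @export
fit_thermal_lmm <- function(data, response, log_transform = FALSE) {
  need <- c("species", "habitat", "activity", "mass", response)
  if (!all(need %in% names(data))) {
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "))
  }
  data <- as.data.frame(data)
  if (any(is.na(data[c("species", "habitat", "activity")]))) {
    stop("species/habitat/activity must not contain missing values")
  }
  data$.y <- data[[response]]
  n_dropped <- 0L
  if (log_transform) {
    bad <- !is.na(data$.y) & data$.y <= 0
    n_dropped <- sum(bad)
    if (n_dropped > 0) {
      message(n_dropped, " non-positive response values dropped before log transform")
      data <- data[!bad, ]
    }
    data$.y <- log(data$.y)
  }
  data$habitat <- factor(data$habitat)
  data$activity <- factor(data$activity)
  data$species <- factor(data$species)
  if (nlevels(data$habitat) < 2 || nlevels(data$activity) < 2) {
    stop("habitat and activity need at least 2 observed levels")
  }
  if (nlevels(data$species) < 2) stop("at least 2 species required")
  contrasts(data$habitat) <- stats::contr.sum(nlevels(data$habitat))
  contrasts(data$activity) <- stats::contr.sum(nlevels(data$activity))
  fit <- lme4::lmer(.y ~ habitat * activity + mass + (1 | species),
                    data = data, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("random-intercept variance estimated at zero (singular fit)")
  }
  structure(list(fit = fit, response = response,
                 log_transform = log_transform, singular = singular,
                 n_dropped = n_dropped, data = data),
            class = "thermo_lmm")
}

#' @method print thermo_lmm
#' @export
print.thermo_lmm <- function(x, ...) {
  cat(sprintf("<thermo_lmm> %s%s ~ habitat * activity + mass + (1 | species)\n",
              if (x$log_transform) "log " else "", x$response))
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  cat(sprintf("  %d obs, %d species; species sd %.4g, residual sd %.4g%s\n",
              stats::nobs(x$fit), nlevels(x$data$species),
              vc$sdcor[vc$grp == "species"], vc$sdcor[vc$grp == "Residual"],
              if (x$singular) " (singular)" else ""))
  invisible(x)
}

#' Type-III Wald chi-square ANOVA of a fitted mixed model
#'
#' Per-term Wald chi-square tests of the fixed effects (habitat, activity,
#' their interaction, mass) under the sum-to-zero coding set at fit time;
#' each term's statistic is `b' V^-1 b` over its coefficients with the
#' corresponding block of the fixed-effect covariance.
#'
#' @param model A [fit_thermal_lmm()] object (or a bare `lmerMod`).
#' @return A data frame `term`, `Chisq`, `df`, `P`.
#' @export
anova_type3 <- function(model) {
  fit <- if (inherits(model, "thermo_lmm")) model$fit else model
  a <- car::Anova(fit, type = 3, test.statistic = "Chisq")
  out <- data.frame(term = rownames(a), Chisq = a$Chisq, df = a$Df,
                    P = a[["Pr(>Chisq)"]], stringsAsFactors = FALSE)
  out <- out[out$term != "(Intercept)", ]
  rownames(out) <- NULL
  out
}

#' Tukey-adjusted pairwise contrasts of estimated marginal means
#'
#' Estimated marginal means per habitat-by-activity cell at the mean of the
#' mass covariate, compared pairwise either between habitats within each
#' activity class or between activity classes within each habitat, with
#' Tukey (studentized-range) adjustment. Tests use the large-sample normal
#' approximation (z statistics), since denominator degrees of freedom in
#' mixed models are approximation-dependent.
#'
#' @param model A [fit_thermal_lmm()] object.
#' @param within `"activity"`: habitat contrasts within each activity class;
#'   `"habitat"`: activity contrasts within each habitat.
#' @return A data frame `group`, `contrast`, `E` (estimate), `t` (statistic),
#'   `P` (Tukey-adjusted).
#' @export
tukey_contrasts <- function(model, within = c("activity", "habitat")) {
  within <- match.arg(within)
  stopifnot(inherits(model, "thermo_lmm"))
  spec <- if (within == "activity") ~ habitat | activity else ~ activity | habitat
  emm <- emmeans::emmeans(model$fit, spec, lmer.df = "asymptotic")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  grp_col <- if (within == "activity") "activity" else "habitat"
  data.frame(group = as.character(prs[[grp_col]]),
             contrast = as.character(prs$contrast),
             E = prs$estimate,
             t = prs$z.ratio,
             P = prs$p.value, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test with Conover-Iman pairwise post hocs
#'
#' Tie-corrected Kruskal-Wallis H across k groups, followed by Conover-Iman
#' pairwise comparisons: t statistics on mean ranks with the pooled
#' tie-corrected rank variance,
#' `t = (Rbar_i - Rbar_j) / sqrt(S2 * (N - 1 - H) / (N - k) * (1/n_i + 1/n_j))`
#' on `N - k` degrees of freedom. P-values are two-sided and unadjusted by
#' default (the published analysis applies no multiple-testing correction);
#' set `p_adjust = "holm"` (or any [p.adjust()] method) to adjust.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 values).
#' @param p_adjust P-adjustment method for the pairwise table (default
#'   `"none"`).
#' @return A list of class `kw_conover`: `H`, `df`, `P`, and `pairwise`, a
#'   data frame `group_1`, `group_2`, `t`, `df`, `P`.
#' @export
kruskal_conover <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups required")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  if (length(unique(values)) == 1L) stop("all values identical; rank tests undefined")
  kw <- stats::kruskal.test(values, groups)
  H <- unname(kw$statistic)
  N <- length(values)
  k <- nlevels(groups)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n_g <- as.vector(table(groups))
  # pooled tie-corrected rank variance
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  pairs <- utils::combn(levels(groups), 2)
  tstat <- apply(pairs, 2, function(p) {
    i <- match(p[1], levels(groups)); j <- match(p[2], levels(groups))
    (rbar[i] - rbar[j]) /
      sqrt(s2 * (N - 1 - H) / (N - k) * (1 / n_g[i] + 1 / n_g[j]))
  })
  pv <- 2 * stats::pt(abs(tstat), df = N - k, lower.tail = FALSE)
  pv <- stats::p.adjust(pv, method = p_adjust)
  res <- list(H = H, df = unname(kw$parameter), P = kw$p.value,
              pairwise = data.frame(group_1 = pairs[1, ],
                                    group_2 = pairs[2, ],
                                    t = unname(tstat), df = N - k,
                                    P = pv, stringsAsFactors = FALSE))
  class(res) <- "kw_conover"
  res
}

#' @method print kw_conover
#' @export
print.kw_conover <- function(x, ...) {
  cat(sprintf("<kw_conover> H = %.4g (df = %d), P = %.4g\n", x$H, x$df, x$P))
  print.data.frame(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pearson correlations among physiological variables
#'
#' @param data Data frame of per-individual physiology.
#' @param pairs List of 2-element character vectors of column names; defaults
#'   to the three pairs reported alongside the multiple-testing discussion
#'   (thorax slope vs abdomen slope, each vs their difference).
#' @return Data frame `var_1`, `var_2`, `r`, `n`.
#' @export
correlate_physiology <- function(data,
                                 pairs = list(c("slope_th", "slope_abd"),
                                              c("slope_th", "slope_diff"),
                                              c("slope_abd", "slope_diff"))) {
  out <- lapply(pairs, function(p) {
    x <- data[[p[1]]]; y <- data[[p[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) stop("need at least 3 paired observations for ", p[1],
                          " vs ", p[2])
    data.frame(var_1 = p[1], var_2 = p[2],
               r = stats::cor(x[ok], y[ok]), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
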