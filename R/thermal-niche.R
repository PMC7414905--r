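#' Endothermy (excess temperature) of one flight
#'
#' Endothermy is the mean thorax-minus-environment temperature difference over
#' the flight window: the individual's ability to hold its flight motor above
#' ambient. It is invariant to any constant shift applied to both traces.
#'
#' @param t_th,t_env Thorax and environment [temp_trace()]s on a common time
#'   base.
#' @param window A qualifying [flight_window()].
#' @return Endothermy in degrees C (scalar).
#' @examples
#' tt <- temp_trace(0:40, rep(30, 41), "thorax")
#' te <- temp_trace(0:40, rep(25, 41), "environment")
#' compute_endothermy(tt, te, flight_window(0, 40))
#' @export
compute_endothermy <- function(t_th, t_env, window) {
  stopifnot(inherits(t_th, "temp_trace"), inherits(t_env, "temp_trace"),
            inherits(window, "flight_window"))
  if (!isTRUE(all.equal(t_th$times, t_env$times))) {
    stop("thorax and environment traces must share a time base")
  }
  if (!window$qualifies) stop("flight window does not qualify (< minimum duration)")
  sel <- t_th$times >= window$takeoff_time & t_th$times <= window$end_time
  if (!any(sel)) stop("no samples inside the flight window")
  mean(t_th$values[sel] - t_env$values[sel])
}

#' Least-squares temperature slope over the flight window
#'
#' Ordinary least-squares slope of temperature versus time from take-off to
#' `slope_window` seconds into continuous flight (default 40 s, the analysis
#' window), or to the window end if the trace is shorter.
#'
#' @param trace A [temp_trace()].
#' @param window A [flight_window()].
#' @param slope_window Length of the slope-fitting window after take-off (s).
#' @return Slope in degrees C per second.
#' @export
fit_slope <- function(trace, window, slope_window = 40) {
  stopifnot(inherits(trace, "temp_trace"), inherits(window, "flight_window"))
  hi <- min(window$takeoff_time + slope_window, window$end_time)
  sel <- trace$times >= window$takeoff_time & trace$times <= hi
  if (sum(sel) < 3) stop("need at least 3 samples in the slope window")
  tt <- trace$times[sel]
  if (diff(range(tt)) == 0) stop("degenerate time axis in slope window")
  unname(stats::coef(stats::lm(trace$values[sel] ~ tt))[2])
}

#' Physiology of one individual flight
#'
#' Computes the per-individual physiological variables from an aligned trace
#' triplet: endothermy, the three least-squares slopes, and their difference
#' (thorax slope minus abdomen slope, an inverse proxy of thorax-to-abdomen
#' heat transfer).
#'
#' @param t_th,t_abd,t_env Aligned [temp_trace()]s.
#' @param window A qualifying [flight_window()].
#' @param individual_id,species,mass,activity,habitat Individual metadata
#'   carried into the result.
#' @param slope_window Slope-fitting window length (s), see [fit_slope()].
#' @return A one-row data frame (class `individual_physiology`) with columns
#'   `individual_id`, `species`, `mass`, `activity`, `habitat`, `endothermy`,
#'   `slope_th`, `slope_abd`, `slope_env`, `slope_diff`, and `takeoff_temp`
#'   (the thorax temperature at take-off, the tethered-flight analogue of the
#'   minimum take-off temperature).
#' @export
individual_physiology <- function(t_th, t_abd, t_env, window,
                                  individual_id = NA_character_,
                                  species = NA_character_, mass = NA_real_,
                                  activity = NA_character_,
                                  habitat = NA_character_,
                                  slope_window = 40) {
  s_th <- fit_slope(t_th, window, slope_window)
  s_abd <- fit_slope(t_abd, window, slope_window)
  s_env <- fit_slope(t_env, window, slope_window)
  out <- data.frame(
    individual_id = individual_id, species = species, mass = mass,
    activity = activity, habitat = habitat,
    endothermy = compute_endothermy(t_th, t_env, window),
    slope_th = s_th, slope_abd = s_abd, slope_env = s_env,
    slope_diff = s_th - s_abd,
    takeoff_temp = t_th$values[which(t_th$times >= window$takeoff_time)[1]],
    stringsAsFactors = FALSE)
  class(out) <- c("individual_physiology", class(out))
  out
}

#' Thorax-minus-abdomen slope difference
#'
#' The difference between the thorax and abdomen temperature slopes estimates
#' (inversely) the heat transferred from thorax to abdomen during flight: a
#' greater difference indicates less transfer.
#'
#' @param slope_th,slope_abd Slopes in degrees C per second.
#' @return `slope_th - slope_abd`.
#' @export
slope_difference <- function(slope_th, slope_abd) slope_th - slope_abd

#' Kruskal-Wallis comparison of two slope samples
#'
#' Tie-corrected Kruskal-Wallis H test (df = 1 for two groups) used to decide
#' whether two sets of per-individual slopes are "similar" (P >= alpha) or
#' "different" (P < alpha). When every value in both groups is identical the
#' statistic is undefined; by convention H = 0, P = 1 (similar) is returned
#' with a warning.
#'
#' @param group_a,group_b Numeric vectors of per-individual slopes (n >= 2
#'   each).
#' @param alpha Significance level for the similarity call.
#' @param pair Label of the compared pair (carried into the result).
#' @return A list of class `slope_comparison` with `H`, `df`, `P`, `similar`.
#' @export
compare_slope_pair <- function(group_a, group_b, alpha = 0.05,
                               pair = "th_vs_abd") {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; H set to 0, similar = TRUE")
    res <- list(pair = pair, H = 0, df = 1L, P = 1, similar = TRUE,
                alpha = alpha)
    class(res) <- "slope_comparison"
    return(res)
  }
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  kw <- stats::kruskal.test(pooled, g)
  res <- list(pair = pair, H = unname(kw$statistic),
              df = unname(kw$parameter), P = kw$p.value,
              similar = kw$p.value >= alpha, alpha = alpha)
  class(res) <- "slope_comparison"
  res
}

#' @method print slope_comparison
#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison> %s: H = %.4g (df = %d), P = %.4g -> %s at alpha = %g\n",
              x$pair, x$H, x$df, x$P,
              if (x$similar) "similar" else "different", x$alpha))
  invisible(x)
}

#' Thermoregulation-mechanism rule table
#'
#' Applies the classification rule to precomputed species-level summaries:
#' abdominal passive heat transfer (APHT) requires the thorax and abdomen
#' slopes to differ, a positive mean thorax slope, and similar abdomen and
#' environment slopes; abdominal active heat transfer (AAHT) requires similar
#' thorax and abdomen slopes, positive mean thorax and abdomen slopes, and
#' different abdomen and environment slopes. Anything else is UNDEFINED.
#' "Similar" means Kruskal-Wallis P >= alpha; slope sign is the sign of the
#' species mean with threshold exactly 0.
#'
#' @param mean_slope_th,mean_slope_abd Species mean slopes (degrees C/s).
#' @param p_th_abd,p_abd_env Kruskal-Wallis p-values of the two slope-pair
#'   comparisons.
#' @param alpha Significance level.
#' @return `"APHT"`, `"AAHT"` or `"UNDEFINED"`.
#' @examples
#' mechanism_rule(0.0026, -0.0049, p_th_abd = 0.0345, p_abd_env = 0.0595)
#' @export
mechanism_rule <- function(mean_slope_th, mean_slope_abd, p_th_abd, p_abd_env,
                           alpha = 0.05) {
  similar_th_abd <- p_th_abd >= alpha
  similar_abd_env <- p_abd_env >= alpha
  th_pos <- mean_slope_th > 0
  abd_pos <- mean_slope_abd > 0
  if (!similar_th_abd && th_pos && similar_abd_env) {
    "APHT"
  } else if (similar_th_abd && th_pos && abd_pos && !similar_abd_env) {
    "AAHT"
  } else {
    "UNDEFINED"
  }
}

#' Classify a species' physiological thermoregulation mechanism
#'
#' From the per-individual thorax, abdomen and environment slopes of one
#' species, runs the two Kruskal-Wallis slope-pair comparisons (thorax vs
#' abdomen, abdomen vs environment) and applies the [mechanism_rule()]. All
#' intermediate quantities (means, signs, both comparisons) are reported, so
#' the call can be re-derived from the stored fields.
#'
#' @param slope_th,slope_abd,slope_env Numeric vectors of per-individual
#'   slopes (same length, >= 2 individuals).
#' @param species Species label.
#' @param alpha Significance level for "similar" (default 0.05).
#' @return A list of class `mechanism_call` with fields `species`, `n`,
#'   `mean_slope_th`, `mean_slope_abd`, `sign_th`, `sign_abd`, `cmp_th_abd`,
#'   `cmp_abd_env`, `mechanism`, `alpha`.
#' @export
classify_mechanism <- function(slope_th, slope_abd, slope_env,
                               species = NA_character_, alpha = 0.05) {
  n <- length(slope_th)
  if (n < 2 || length(slope_abd) != n || length(slope_env) != n) {
    stop("need aligned slope vectors for at least 2 individuals")
  }
  cmp1 <- compare_slope_pair(slope_th, slope_abd, alpha, pair = "th_vs_abd")
  cmp2 <- compare_slope_pair(slope_abd, slope_env, alpha, pair = "abd_vs_env")
  m_th <- mean(slope_th)
  m_abd <- mean(slope_abd)
  res <- list(
    species = species, n = n,
    mean_slope_th = m_th, mean_slope_abd = m_abd,
    sign_th = if (m_th > 0) "+" else "-",
    sign_abd = if (m_abd > 0) "+" else "-",
    cmp_th_abd = cmp1, cmp_abd_env = cmp2,
    mechanism = mechanism_rule(m_th, m_abd, cmp1$P, cmp2$P, alpha),
    alpha = alpha)
  class(res) <- "mechanism_call"
  res
}

#' @method print mechanism_call
#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (n = %d): %s\n", x$species, x$n,
              x$mechanism))
  cat(sprintf("  mean slopes: thorax %+.4f, abdomen %+.4f degC/s\n",
              x$mean_slope_th, x$mean_slope_abd))
  cat(sprintf("  th vs abd:  H = %.3g, P = %.4g (%s)\n", x$cmp_th_abd$H,
              x$cmp_th_abd$P, if (x$cmp_th_abd$similar) "similar" else "different"))
  cat(sprintf("  abd vs env: H = %.3g, P = %.4g (%s)\n", x$cmp_abd_env$H,
              x$cmp_abd_env$P, if (x$cmp_abd_env$similar) "similar" else "different"))
  invisible(x)
}

#' Per-species mechanism calls from an individual-physiology table
#'
#' @param physiology A data frame with columns `species`, `slope_th`,
#'   `slope_abd`, `slope_env` (one row per individual), e.g. rows bound from
#'   [individual_physiology()].
#' @param alpha Significance level.
#' @return A data frame with one row per species (species with < 2
#'   individuals are dropped with a message): mean slopes, the two H/P pairs,
#'   and the mechanism call.
#' @export
classify_mechanisms <- function(physiology, alpha = 0.05) {
  need <- c("species", "slope_th", "slope_abd", "slope_env")
  stopifnot(all(need %in% names(physiology)))
  out <- lapply(split(physiology, physiology$species), function(d) {
    if (nrow(d) < 2) {
      message("species '", d$species[1], "' has < 2 individuals; skipped")
      return(NULL)
    }
    mc <- classify_mechanism(d$slope_th, d$slope_abd, d$slope_env,
                             species = d$species[1], alpha = alpha)
    data.frame(species = mc$species, n = mc$n,
               mean_slope_th = mc$mean_slope_th,
               mean_slope_abd = mc$mean_slope_abd,
               sign_th = mc$sign_th, sign_abd = mc$sign_abd,
               H_th_abd = mc$cmp_th_abd$H, P_th_abd = mc$cmp_th_abd$P,
               H_abd_env = mc$cmp_abd_env$H, P_abd_env = mc$cmp_abd_env$P,
               mechanism = mc$mechanism, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
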