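# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Closed-form OLS slope: sum((t - tbar)(y - ybar)) / sum((t - tbar)^2)
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# Kruskal-Wallis H from first principles (tie-corrected), two groups.
kw_oracle <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  n <- length(x)
  ra <- r[seq_along(a)]
  rb <- r[-seq_along(a)]
  h <- 12 / (n * (n + 1)) *
    (length(a) * (mean(ra) - (n + 1) / 2)^2 +
       length(b) * (mean(rb) - (n + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Conover-Iman pairwise t statistics from first principles.
conover_oracle <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  k <- nlevels(groups)
  r <- rank(values)
  # tie-corrected H, generic k groups
  ssq <- sum(tapply(r, groups, function(z) length(z) * mean(z)^2))
  h <- (12 / (n * (n + 1))) * (ssq - n * (n + 1)^2 / 4) /
    (1 - sum(sapply(unique(values), function(v) {
      tt <- sum(values == v); tt^3 - tt
    })) / (n^3 - n))
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  lv <- levels(groups)
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ri <- mean(r[groups == lv[i]]); rj <- mean(r[groups == lv[j]])
    ni <- sum(groups == lv[i]); nj <- sum(groups == lv[j])
    tstat <- (ri - rj) / sqrt(s2 * (n - 1 - h) / (n - k) * (1 / ni + 1 / nj))
    out[[paste(lv[i], lv[j], sep = "-")]] <- tstat
  }
  unlist(out)
}

# Greybody forward model evaluated by direct arithmetic (degrees C in/out).
apparent_oracle <- function(t_true, emissivity, reflected, tau = 1,
                            air = reflected) {
  w <- function(tc) (tc + 273.15)^4
  (emissivity * tau * w(t_true) + (1 - emissivity) * tau * w(reflected) +
      (1 - tau) * w(air))^0.25 - 273.15
}

# Small standard trace fixture: constant environment, linear thorax.
make_linear_trace <- function(n = 101, dt = 0.5, intercept = 25, slope = 0.01,
                              roi = "thorax") {
  t <- (seq_len(n) - 1) * dt
  temp_trace(t, intercept + slope * t, roi = roi)
}
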