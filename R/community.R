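#' Indicator value (IndVal) analysis with permutation inference
#'
#' For each species i and habitat j computes the Dufrene-Legendre indicator
#' value `IndVal_ij = A_ij * B_ij * 100`, where specificity `A_ij` is the mean
#' abundance of i over the sites of habitat j divided by the sum of those
#' habitat means, and fidelity `B_ij` is the fraction of habitat-j sites where
#' i occurs. Significance is assessed by permuting the site-to-habitat
#' assignment: for each species the null statistic is the maximum IndVal over
#' habitats, and the add-one p-value is
#' `(1 + #permuted max >= observed max) / (1 + n_permutations)`, reported on
#' every row of that species. The indicator/detector category is assigned at
#' the species' best habitat (see [categorize_indval()]).
#'
#' @param counts Site-by-species matrix or data frame of non-negative integer
#'   abundances (rows = sites).
#' @param habitat Habitat label per site (length `nrow(counts)`); at least 2
#'   habitats, each with at least 1 site.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A data frame of class `indval_result`, one row per
#'   species-by-habitat: `species`, `habitat`, `A`, `B`, `indval`, `P_perm`,
#'   `is_max`, `category`. Species with zero total abundance get `A = NA`,
#'   `indval = 0`, `category = "none"` (with a message).
#' @examples
#' counts <- rbind(matrix(c(5, 6, 7), 3, 1), matrix(0, 6, 1))
#' colnames(counts) <- "sp1"
#' indval(counts, rep(c("A", "B", "C"), each = 3), n_permutations = 99,
#'        seed = 1)
#' @export
indval <- function(counts, habitat, n_permutations = 999, seed = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("abundances must be non-negative")
  habitat <- as.character(habitat)
  if (length(habitat) != nrow(counts)) {
    stop("one habitat label per site (row) required")
  }
  habs <- sort(unique(habitat))
  if (length(habs) < 2) stop("at least 2 habitats required")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sp", seq_len(ncol(counts)))
  }
  spp <- colnames(counts)
  zero_total <- colSums(counts) == 0
  if (any(zero_total)) {
    message(sum(zero_total), " species with zero total abundance: indval = 0, category = none")
  }

  iv_matrix <- function(lab) {
    g <- factor(lab, levels = habs)
    n_j <- as.vector(table(g))
    m <- rowsum(counts, g) / n_j              # habitat x species group means
    tot <- colSums(m)
    a <- sweep(m, 2, tot, "/")                # specificity
    b <- rowsum((counts > 0) + 0, g) / n_j    # fidelity
    iv <- a * b * 100
    iv[, tot == 0] <- 0
    list(a = a, b = b, iv = iv)
  }

  obs <- iv_matrix(habitat)
  obs_max <- apply(obs$iv, 2, max)

  exceed <- integer(length(spp))
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      pm <- iv_matrix(sample(habitat))
      exceed <- exceed + (apply(pm$iv, 2, max) >= obs_max)
    }
  })
  p_perm <- (1 + exceed) / (1 + n_permutations)

  out <- do.call(rbind, lapply(seq_along(spp), function(i) {
    best <- which.max(obs$iv[, i])
    data.frame(
      species = spp[i], habitat = habs,
      A = if (zero_total[i]) NA_real_ else obs$a[, i],
      B = obs$b[, i], indval = obs$iv[, i],
      P_perm = p_perm[i],
      is_max = seq_along(habs) == best,
      stringsAsFactors = FALSE)
  }))
  out$category <- ifelse(
    out$is_max & !rep(zero_total, each = length(habs)),
    mapply(categorize_indval, out$indval, out$P_perm),
    "none")
  rownames(out) <- NULL
  class(out) <- c("indval_result", class(out))
  out
}

#' @method print indval_result
#' @export
print.indval_result <- function(x, ...) {
  cat("<indval_result>", length(unique(x$species)), "species x",
      length(unique(x$habitat)), "habitats\n")
  best <- x[x$is_max & x$category != "none", ]
  if (nrow(best)) {
    cat("flagged species:\n")
    print.data.frame(best[, c("species", "habitat", "indval", "P_perm",
                              "category")], row.names = FALSE, digits = 4)
  } else {
    cat("no indicator or detector species\n")
  }
  invisible(x)
}

#' Categorise an indicator value
#'
#' Indicator species: IndVal strictly above 70% with permutation P < 0.05.
#' Detector species: IndVal in the closed band 45-70% with P < 0.05.
#' Everything else: none.
#'
#' @param indval Indicator value in percent, 0-100.
#' @param p Permutation p-value.
#' @param alpha Significance level (default 0.05).
#' @return `"indicator"`, `"detector"` or `"none"`.
#' @export
categorize_indval <- function(indval, p, alpha = 0.05) {
  if (is.na(indval) || is.na(p)) return("none")
  if (p >= alpha) return("none")
  if (indval > 70) "indicator" else if (indval >= 45) "detector" else "none"
}

#' Assign capture timestamps to diel periods
#'
#' Period 1 is the half-open daytime interval (default 7:00-18:00 local
#' clock); period 2 (18:00-7:00) spans midnight. Binning uses clock time
#' only.
#'
#' @param timestamps `POSIXct` vector, or strings parseable by
#'   [as.POSIXct()].
#' @param day_start,day_end Daytime window bounds in hours (default 7 and 18).
#' @return Character vector of `"P1"` / `"P2"`.
#' @export
bin_capture_periods <- function(timestamps, day_start = 7, day_end = 18) {
  ts <- as.POSIXct(timestamps, tz = "UTC")
  lt <- as.POSIXlt(ts)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  ifelse(h >= day_start & h < day_end, "P1", "P2")
}

#' Classify a species' daily activity from period capture counts
#'
#' A species is diurnal when at least 60% of its captures fall in period 1
#' (7:00-18:00) and evening/nocturnal/crepuscular (ENC) when at least 60%
#' fall in period 2. When the total is below `min_captures`, or neither
#' period reaches 60%, a literature label is used if available (source
#' `"literature"`), otherwise the call is `"unresolved"`.
#'
#' @param p1,p2 Capture counts in periods 1 and 2.
#' @param min_captures Minimum total captures to trust the sampling (default
#'   25).
#' @param literature Optional fallback label (`"diurnal"` or `"ENC"`).
#' @param threshold Dominance threshold (default 0.60, inclusive).
#' @return A list of class `activity_call`: `fraction_P1`, `call`, `source`.
#' @examples
#' classify_activity(70, 30)                      # diurnal by sampling
#' classify_activity(11, 9, literature = "ENC")   # too few captures
#' @export
classify_activity <- function(p1, p2, min_captures = 25, literature = NULL,
                              threshold = 0.60) {
  total <- p1 + p2
  frac <- if (total > 0) p1 / total else NA_real_
  fallback <- function() {
    if (!is.null(literature) && !is.na(literature)) {
      list(fraction_P1 = frac, call = literature, source = "literature")
    } else {
      list(fraction_P1 = frac, call = "unresolved", source = "sampling")
    }
  }
  res <- if (total < min_captures) {
    fallback()
  } else if (frac >= threshold) {
    list(fraction_P1 = frac, call = "diurnal", source = "sampling")
  } else if ((1 - frac) >= threshold) {
    list(fraction_P1 = frac, call = "ENC", source = "sampling")
  } else {
    fallback()
  }
  class(res) <- "activity_call"
  res
}

#' @method print activity_call
#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf("<activity_call> %s (source: %s, P1 share %s)\n", x$call,
              x$source,
              if (is.na(x$fraction_P1)) "NA" else sprintf("%.0f%%", 100 * x$fraction_P1)))
  invisible(x)
}

#' Classify daily activity for every species in a capture table
#'
#' @param captures Data frame with columns `species` and `timestamp`.
#' @param min_captures,threshold See [classify_activity()].
#' @param literature Optional named vector/list mapping species to fallback
#'   labels.
#' @param day_start,day_end Daytime window (hours).
#' @return Data frame with one row per species: `species`, `p1`, `p2`,
#'   `fraction_P1`, `call`, `source`.
#' @export
classify_activities <- function(captures, min_captures = 25,
                                literature = NULL, threshold = 0.60,
                                day_start = 7, day_end = 18) {
  stopifnot(all(c("species", "timestamp") %in% names(captures)))
  per <- bin_capture_periods(captures$timestamp, day_start, day_end)
  out <- lapply(split(per, captures$species), function(pp) {
    data.frame(p1 = sum(pp == "P1"), p2 = sum(pp == "P2"))
  })
  sp <- names(out)
  out <- do.call(rbind, out)
  calls <- lapply(seq_along(sp), function(i) {
    classify_activity(out$p1[i], out$p2[i], min_captures,
                      literature = if (is.null(literature)) NULL else literature[[sp[i]]],
                      threshold = threshold)
  })
  data.frame(species = sp, p1 = out$p1, p2 = out$p2,
             fraction_P1 = vapply(calls, function(z) z$fraction_P1, numeric(1)),
             call = vapply(calls, function(z) z$call, character(1)),
             source = vapply(calls, function(z) z$source, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
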