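#' Single-measure absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way ANOVA decomposition with subjects as rows and sessions as columns:
#' with `MSR`, `MSC`, `MSE` the mean squares for rows, columns and error,
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + (k/n)(MSC - MSE)}.}
#' The 95 percent confidence interval uses the F-distribution method of
#' McGraw and Wong for absolute-agreement single-measure ICC:
#' with `a = k*ICC/(n*(1-ICC))`, `b = 1 + k*ICC*(n-1)/(n*(1-ICC))`,
#' Satterthwaite degrees of freedom
#' `v = (a*MSC + b*MSE)^2 / ((a*MSC)^2/(k-1) + (b*MSE)^2/((n-1)(k-1)))`,
#' and `FL = qf(1-alpha/2, n-1, v)`, `FU = qf(1-alpha/2, v, n-1)`:
#' `lower = n(MSR - FL*MSE) / (FL(k*MSC + (kn-k-n)MSE) + n*MSR)` and
#' `upper = n(FU*MSR - MSE) / (k*MSC + (kn-k-n)MSE + n*FU*MSR)`.
#'
#' @param values n x k numeric matrix (subjects by sessions), complete.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `icc`, `lower`, `upper`, `ms` (the three mean squares),
#'   `n`, `k`. A matrix with zero total variance yields `NA` estimates with
#'   a warning.
#' @export
icc_absolute_single <- function(values, conf_level = 0.95) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("values must be a complete finite matrix")
  n <- nrow(values); k <- ncol(values)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 sessions")
  gm <- mean(values)
  rm_ <- rowMeans(values); cm <- colMeans(values)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((values - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  ms <- c(MSR = MSR, MSC = MSC, MSE = MSE)
  if (SST <= .Machine$double.eps * max(1, abs(gm))^2) {
    warning("constant matrix: ICC undefined", call. = FALSE)
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                ms = ms, n = n, k = k))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  if (MSE == 0) {
    # perfect agreement: interval degenerates at 1
    return(list(icc = icc, lower = 1, upper = 1, ms = ms, n = n, k = k))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, lower = lower, upper = upper, ms = ms, n = n, k = k)
}

#' Within-subject coefficient of variation for two sessions
#'
#' `sw = sqrt(sum(d_i^2) / (2n))` with `d_i` the session-2 minus session-1
#' difference, and `wsCoV = 100 * sw / grand mean` over all `2n` values. The
#' 95 percent interval uses the root-formula approximation
#' `wsCoV * (1 +/- 1.96 / sqrt(2 n (k-1)))` with `k = 2`; it is approximate
#' and reported as such.
#'
#' @param value_s1,value_s2 Paired session values (same units).
#' @return List: `wscov_pct`, `lower`, `upper`, `sw`, `grand_mean`, `n`.
#' @export
within_subject_cov <- function(value_s1, value_s2) {
  stopifnot(length(value_s1) == length(value_s2))
  ok <- is.finite(value_s1) & is.finite(value_s2)
  if (!all(ok)) stop("missing values within retained pairs are not allowed")
  n <- length(value_s1)
  if (n < 3) stop("need at least 3 pairs")
  d <- value_s2 - value_s1
  sw <- sqrt(sum(d^2) / (2 * n))
  gmean <- mean(c(value_s1, value_s2))
  if (gmean <= 0) {
    warning("non-positive grand mean: wsCoV undefined", call. = FALSE)
    return(list(wscov_pct = NA_real_, lower = NA_real_, upper = NA_real_,
                sw = sw, grand_mean = gmean, n = n))
  }
  wscov <- 100 * sw / gmean
  half <- 1.96 / sqrt(2 * n * (2 - 1))
  list(wscov_pct = wscov, lower = wscov * (1 - half),
       upper = wscov * (1 + half), sw = sw, grand_mean = gmean, n = n)
}

#' Bland-Altman repeatability summaries
#'
#' Mean interscan difference, Pearson correlation (with two-sided p) between
#' the interscan differences and interscan means, and the repeatability
#' coefficient `1.96 * SD(d)` — the span expected to contain 95 percent of
#' test-retest differences.
#'
#' @param value_s1,value_s2 Paired session values.
#' @return List: `mean_diff`, `r`, `p`, `repeatability_coeff`, `n`.
#' @export
bland_altman <- function(value_s1, value_s2) {
  stopifnot(length(value_s1) == length(value_s2))
  n <- length(value_s1)
  if (n < 3) stop("need at least 3 pairs")
  d <- value_s2 - value_s1
  avg <- (value_s1 + value_s2) / 2
  if (stats::sd(d) == 0) {
    warning("zero variance of differences: correlation undefined",
            call. = FALSE)
    return(list(mean_diff = mean(d), r = NA_real_, p = NA_real_,
                repeatability_coeff = 0, n = n))
  }
  ct <- stats::cor.test(d, avg)
  list(mean_diff = mean(d), r = unname(ct$estimate), p = ct$p.value,
       repeatability_coeff = 1.96 * stats::sd(d), n = n)
}

#' Test-retest reliability report over a two-session metrics table
#'
#' Applies [icc_absolute_single()], [within_subject_cov()] and
#' [bland_altman()] to mean CBF and sCoV, globally and per lobe, from a
#' two-session [roi_metrics()] table.
#'
#' @param metrics Data frame in the `roi_metrics` schema covering exactly two
#'   sessions per subject.
#' @param regions Regions to report (default global plus the four lobes;
#'   regions absent from the table are skipped).
#' @return Data frame, one row per region x metric: `region`, `metric`, `n`,
#'   `icc`, `icc_lower`, `icc_upper`, `wscov_pct`, `wscov_lower`,
#'   `wscov_upper`, `mean_diff`, `r_diff_mean`, `p_diff_mean`,
#'   `repeatability_coeff`.
#' @export
reliability_report <- function(metrics,
                               regions = c("global_gm", "frontal",
                                           "occipital", "parietal",
                                           "temporal")) {
  req <- c("subject_id", "session_id", "region", "mean_cbf", "scov_pct")
  miss <- setdiff(req, names(metrics))
  if (length(miss))
    stop("metrics table lacks required column(s): ",
         paste(miss, collapse = ", "))
  sessions <- sort(unique(metrics$session_id))
  if (length(sessions) != 2)
    stop("reliability analysis needs exactly 2 sessions, got ",
         length(sessions))
  rows <- list()
  for (reg in intersect(regions, unique(metrics$region))) {
    sub <- metrics[metrics$region == reg, ]
    w1 <- sub[sub$session_id == sessions[1], ]
    w2 <- sub[sub$session_id == sessions[2], ]
    common <- intersect(w1$subject_id, w2$subject_id)
    off <- setdiff(union(w1$subject_id, w2$subject_id), common)
    if (length(off))
      stop("unmatched sessions for subject(s): ",
           paste(sort(off), collapse = ", "))
    w1 <- w1[match(common, w1$subject_id), ]
    w2 <- w2[match(common, w2$subject_id), ]
    for (metric in c("mean_cbf", "scov_pct")) {
      v1 <- w1[[metric]]; v2 <- w2[[metric]]
      if (any(!is.finite(v1)) || any(!is.finite(v2))) next
      icc <- icc_absolute_single(cbind(v1, v2))
      ws <- within_subject_cov(v1, v2)
      ba <- bland_altman(v1, v2)
      rows[[length(rows) + 1]] <- data.frame(
        region = reg,
        metric = if (metric == "mean_cbf") "cbf" else "scov",
        n = length(v1),
        icc = icc$icc, icc_lower = icc$lower, icc_upper = icc$upper,
        wscov_pct = ws$wscov_pct, wscov_lower = ws$lower,
        wscov_upper = ws$upper,
        mean_diff = ba$mean_diff, r_diff_mean = ba$r,
        p_diff_mean = ba$p, repeatability_coeff = ba$repeatability_coeff,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
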