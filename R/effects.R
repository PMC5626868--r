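#' Paired t-test
#'
#' Classical paired t on the within-subject differences, df = n - 1,
#' two-sided p. Degenerate inputs are handled explicitly: all-zero
#' differences give t = 0, p = 1; zero-variance nonzero differences give an
#' infinite t with a zero-limit p and a warning.
#'
#' @param values0,values1 Numeric vectors of equal length (n >= 2);
#'   differences are `values1 - values0`.
#' @return List: `t`, `df`, `p`, `mean_diff`, `sd_diff`, `n`.
#' @export
paired_t <- function(values0, values1) {
  stopifnot(length(values0) == length(values1))
  n <- length(values0)
  if (n < 2) stop("need at least 2 pairs")
  d <- values1 - values0
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, sd_diff = 0,
                  n = n))
    warning("zero variance of differences with nonzero mean: p -> 0",
            call. = FALSE)
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), sd_diff = 0, n = n))
  }
  tt <- stats::t.test(values1, values0, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), sd_diff = sdd, n = n)
}

# Validate and order a long subject x timepoint x region table.
check_long_grid <- function(table) {
  req <- c("subject_id", "timepoint", "region", "value")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("long table lacks required column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(table$value))) stop("values must be finite")
  table$timepoint <- factor(table$timepoint)
  table$region <- factor(table$region)
  table$subject_id <- factor(table$subject_id)
  cnt <- table(table$subject_id, table$timepoint, table$region)
  if (any(cnt != 1)) {
    bad <- which(cnt != 1, arr.ind = TRUE)
    lab <- apply(bad, 1, function(i)
      paste(dimnames(cnt)[[1]][i[1]], dimnames(cnt)[[2]][i[2]],
            dimnames(cnt)[[3]][i[3]], sep = "/"))
    stop("incomplete subject x timepoint x region grid; offending cells: ",
         paste(utils::head(lab, 5), collapse = ", "))
  }
  table
}

#' Two-way within-subject repeated-measures ANOVA
#'
#' Univariate RM-ANOVA of a complete subject x timepoint x region grid, with
#' each within-subject effect tested against its own subject-interaction
#' error stratum (no sphericity correction by default; time has two levels in
#' the designs this package targets, and the interaction stratum is reported
#' as used). For 2 timepoints and 4 regions the interaction has df1 = 3 and
#' df2 = 3(n - 1).
#'
#' @param table Long data frame: `subject_id`, `timepoint`, `region`,
#'   `value`, one row per cell.
#' @param gg_correction Apply a Greenhouse-Geisser epsilon correction to the
#'   interaction p-value (estimated from the interaction covariance).
#' @return List with elements `interaction`, `time`, `region`, each a list
#'   `(F, df1, df2, p)`; the interaction carries `epsilon` when corrected.
#'   A single-region table yields the time main effect only (for two
#'   timepoints its F equals the squared paired t).
#' @export
rm_anova_interaction <- function(table, gg_correction = FALSE) {
  table <- check_long_grid(table)
  one_region <- nlevels(table$region) == 1
  fit <- if (one_region)
    stats::aov(value ~ timepoint + Error(subject_id / timepoint),
               data = table)
  else
    stats::aov(value ~ timepoint * region +
                 Error(subject_id / (timepoint * region)),
               data = table)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tab)))
    j <- grep("^Residuals", trimws(rownames(tab)))
    list(F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[j, "Df"],
         p = tab[i, "Pr(>F)"], ss = tab[i, "Sum Sq"],
         ss_error = tab[j, "Sum Sq"])
  }
  if (one_region)
    return(list(time = pull("Error: subject_id:timepoint", "timepoint"),
                region = NULL, interaction = NULL))
  res <- list(
    time = pull("Error: subject_id:timepoint", "timepoint"),
    region = pull("Error: subject_id:region", "region"),
    interaction = pull("Error: subject_id:timepoint:region",
                       "timepoint:region"))
  if (gg_correction) {
    eps <- gg_epsilon(table)
    it <- res$interaction
    it$epsilon <- eps
    it$p <- stats::pf(it$F, eps * it$df1, eps * it$df2, lower.tail = FALSE)
    res$interaction <- it
  }
  res
}

# Greenhouse-Geisser epsilon for the time x region interaction, from the
# covariance of the per-subject time-difference scores across regions.
gg_epsilon <- function(table) {
  tps <- levels(table$timepoint)
  D <- sapply(levels(table$region), function(reg) {
    sub <- table[table$region == reg, ]
    sub <- sub[order(sub$subject_id), ]
    sub$value[sub$timepoint == tps[2]] - sub$value[sub$timepoint == tps[1]]
  })
  S <- stats::cov(D)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  SC <- C %*% S %*% C
  ev <- Re(eigen(SC, only.values = TRUE)$values)
  ev <- ev[ev > 1e-12]
  sum(ev)^2 / (length(ev) * sum(ev^2))
}

#' Per-lobe baseline vs follow-up post hocs with Bonferroni adjustment
#'
#' Paired t-test within each of the four lobes; adjusted p-values are
#' `min(1, 4 * p)`.
#'
#' @param table Long data frame as in [rm_anova_interaction()], with the four
#'   lobes as regions and two timepoints.
#' @return Data frame: `region`, `t`, `df`, `p`, `p_bonferroni`,
#'   `mean_diff`.
#' @export
posthoc_lobes <- function(table) {
  table <- check_long_grid(table)
  tps <- levels(table$timepoint)
  if (length(tps) != 2) stop("post hocs need exactly 2 timepoints")
  regs <- levels(table$region)
  rows <- lapply(regs, function(reg) {
    sub <- table[table$region == reg, ]
    sub <- sub[order(sub$subject_id), ]
    v0 <- sub$value[sub$timepoint == tps[1]]
    v1 <- sub$value[sub$timepoint == tps[2]]
    pt <- paired_t(v0, v1)
    data.frame(region = reg, t = pt$t, df = pt$df, p = pt$p,
               mean_diff = pt$mean_diff, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out[, c("region", "t", "df", "p", "p_bonferroni", "mean_diff")]
}

#' Hedges' g for paired samples
#'
#' Standardized mean change with small-sample correction:
#' `g = J * mean(d) / SD(d)`, `d = values1 - values0`,
#' `J = 1 - 3 / (4(n-1) - 1)`. The 95 percent CI uses the normal
#' approximation `Var(g) ~ 1/n + g^2/(2n)` (documented as approximate).
#' Positive g means an increase. The alternative standardizer — the average
#' of the two occasion SDs — is available via `standardizer = "average"`.
#'
#' @param values0,values1 Paired samples, n >= 3.
#' @param standardizer `"diff"` (SD of difference scores, default) or
#'   `"average"` (mean of the two occasion SDs).
#' @return List: `g`, `lower`, `upper`, `n`, `standardizer`.
#' @export
hedges_g_paired <- function(values0, values1,
                            standardizer = c("diff", "average")) {
  standardizer <- match.arg(standardizer)
  stopifnot(length(values0) == length(values1))
  n <- length(values0)
  if (n < 3) stop("need at least 3 pairs")
  d <- values1 - values0
  s <- if (standardizer == "diff") stats::sd(d)
       else (stats::sd(values0) + stats::sd(values1)) / 2
  if (s == 0) {
    warning("zero standardizer: Hedges' g undefined", call. = FALSE)
    return(list(g = NA_real_, lower = NA_real_, upper = NA_real_, n = n,
                standardizer = standardizer))
  }
  J <- 1 - 3 / (4 * (n - 1) - 1)
  g <- J * mean(d) / s
  se <- sqrt(1 / n + g^2 / (2 * n))
  list(g = g, lower = g - 1.96 * se, upper = g + 1.96 * se, n = n,
       standardizer = standardizer)
}

#' Random-intercept-and-slope model for aerobic fitness
#'
#' Linear mixed model
#' `vo2 = b0 + b_3m I(t=3) + b_6m I(t=6) + u0_i + u1_i t + e`, fitted by
#' maximum likelihood with lme4, using every available row (no listwise
#' deletion), which is how missing follow-up assessments are accommodated.
#' Inference on the timepoint contrasts is by Wald z — the simplest
#' defensible choice at these sample sizes, reported as approximate. A
#' singular random-effects covariance triggers a refit with a random
#' intercept only (recorded in the result).
#'
#' @param fitness Long data frame: `subject_id`, `months` (0/3/6),
#'   `vo2peak`; follow-up rows may be missing.
#' @return List: `fixed` (data frame with `term`, `estimate`, `se`, `z`,
#'   `p`), `random_structure`, `converged`, `fit` (the lme4 object).
#' @export
fit_fitness_lmm <- function(fitness) {
  req <- c("subject_id", "months", "vo2peak")
  miss <- setdiff(req, names(fitness))
  if (length(miss))
    stop("fitness table lacks required column(s): ",
         paste(miss, collapse = ", "))
  tab <- fitness
  tab$tp3 <- as.numeric(tab$months == 3)
  tab$tp6 <- as.numeric(tab$months == 6)
  nobs <- table(tab$subject_id)
  if (sum(nobs >= 2) < 3)
    stop("need at least 3 subjects with 2 or more timepoints")
  structure_used <- "intercept+slope"
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(vo2peak ~ tp3 + tp6 + (1 + months | subject_id), data = tab,
               REML = FALSE,
               control = lme4::lmerControl(check.nobs.vs.nRE = "ignore",
                                           check.conv.singular = "ignore"))))
  if (lme4::isSingular(fit, tol = 1e-4)) {
    structure_used <- "intercept-only (singular slope refit)"
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(vo2peak ~ tp3 + tp6 + (1 | subject_id), data = tab,
                 REML = FALSE)))
  }
  co <- summary(fit)$coefficients
  z <- co[, "Estimate"] / co[, "Std. Error"]
  fixed <- data.frame(term = c("(Intercept)", "3-month", "6-month"),
                      estimate = co[, "Estimate"], se = co[, "Std. Error"],
                      z = z, p = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  rownames(fixed) <- NULL
  conv <- length(fit@optinfo$conv$lme4) == 0
  list(fixed = fixed, random_structure = structure_used, converged = conv,
       fit = fit)
}

#' Sample size for a within-subject repeated-measures ANOVA
#'
#' Smallest n such that the noncentral-F test with `df1 = m - 1`,
#' `df2 = (n - 1)(m - 1)`, noncentrality
#' `lambda = f^2 * m * n / (1 - rho)` and central-F critical value at level
#' `alpha` reaches the requested power. `f` follows the G*Power repeated-
#' measures convention in which the paired standardized effect magnitude is
#' used directly as the effect size f (not halved); under this convention
#' the printed design pairs f = 0.27 -> n = 29 and f = 0.15 -> n = 90 are
#' reproduced at alpha = 0.05, power = 0.8, rho = 0.5, m = 2.
#'
#' @param effect_f Effect size f (> 0), taken as the magnitude of the paired
#'   Hedges' g.
#' @param alpha Significance level. @param power Target power.
#' @param rho Correlation among repeated measures in [0, 1).
#' @param m Number of repeated measurements (>= 2).
#' @param n_max Search ceiling.
#' @return List: `n` (smallest sample size) and `power` achieved at that n.
#' @export
sample_size_rm_anova <- function(effect_f, alpha = 0.05, power = 0.8,
                                 rho = 0.5, m = 2, n_max = 100000L) {
  if (effect_f <= 0) stop("effect_f must be > 0: no finite n otherwise")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (m < 2) stop("m must be >= 2")
  df1 <- m - 1
  for (n in 2:n_max) {
    df2 <- (n - 1) * (m - 1)
    lambda <- effect_f^2 * m * n / (1 - rho)
    crit <- stats::qf(1 - alpha, df1, df2)
    pw <- stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
    if (pw >= power) return(list(n = n, power = pw))
  }
  stop("no n <= ", n_max, " reaches the requested power")
}

#' Percent change between two means
#'
#' @param baseline_mean Baseline mean (> 0).
#' @param followup_mean Follow-up mean.
#' @return `100 * (followup - baseline) / baseline`.
#' @export
pct_change <- function(baseline_mean, followup_mean) {
  if (any(baseline_mean <= 0)) stop("baseline mean must be > 0")
  100 * (followup_mean - baseline_mean) / baseline_mean
}

#' Full training-effect report
#'
#' Assembles the effect analysis over a baseline/follow-up metrics table:
#' paired t-tests and paired Hedges' g for global GM CBF and sCoV, the
#' time-by-region RM-ANOVA interaction over the four lobes, Bonferroni-
#' adjusted per-lobe post hocs, per-region percent change (mean and SD
#' across subjects), the fitness mixed model when a fitness table is given,
#' and RM-ANOVA sample-size suggestions seeded by the |g| magnitudes.
#'
#' @param metrics Two-session [roi_metrics()]-schema data frame (session 1 =
#'   baseline, session 2 = follow-up).
#' @param fitness Optional fitness table for [fit_fitness_lmm()].
#' @return List of class `effect_report`: `paired` (per endpoint),
#'   `interaction_cbf`, `interaction_scov`, `posthoc`, `hedges`,
#'   `pct_change`, `fitness`, `sample_size`.
#' @export
effect_report <- function(metrics, fitness = NULL) {
  sessions <- sort(unique(metrics$session_id))
  if (length(sessions) != 2) stop("effect analysis needs exactly 2 sessions")
  lobes <- c("frontal", "occipital", "parietal", "temporal")

  wide <- function(region, metric) {
    sub <- metrics[metrics$region == region, ]
    w1 <- sub[sub$session_id == sessions[1], ]
    w2 <- sub[sub$session_id == sessions[2], ]
    common <- intersect(w1$subject_id, w2$subject_id)
    list(v0 = w1[[metric]][match(common, w1$subject_id)],
         v1 = w2[[metric]][match(common, w2$subject_id)])
  }

  g_cbf <- wide("global_gm", "mean_cbf")
  g_scov <- wide("global_gm", "scov_pct")
  paired <- list(global_cbf = paired_t(g_cbf$v0, g_cbf$v1),
                 global_scov = paired_t(g_scov$v0, g_scov$v1))
  hedges <- list(global_cbf = hedges_g_paired(g_cbf$v0, g_cbf$v1),
                 global_scov = hedges_g_paired(g_scov$v0, g_scov$v1))

  long <- function(metric) {
    sub <- metrics[metrics$region %in% lobes, ]
    data.frame(subject_id = sub$subject_id,
               timepoint = ifelse(sub$session_id == sessions[1],
                                  "baseline", "followup"),
               region = sub$region, value = sub[[metric]],
               stringsAsFactors = FALSE)
  }
  long_cbf <- long("mean_cbf")
  interaction_cbf <- rm_anova_interaction(long_cbf)
  interaction_scov <- rm_anova_interaction(long("scov_pct"))
  posthoc <- posthoc_lobes(long_cbf)

  pc <- lapply(c(global_gm = "global_gm", stats::setNames(lobes, lobes)),
               function(reg) {
                 w <- wide(reg, "mean_cbf")
                 ch <- pct_change(w$v0, w$v1)
                 c(mean = mean(ch), sd = stats::sd(ch))
               })

  fit <- if (!is.null(fitness)) fit_fitness_lmm(fitness) else NULL

  ss <- list(
    global_cbf = sample_size_rm_anova(abs(hedges$global_cbf$g))$n,
    global_scov = sample_size_rm_anova(abs(hedges$global_scov$g))$n)

  structure(list(paired = paired, interaction_cbf = interaction_cbf,
                 interaction_scov = interaction_scov, posthoc = posthoc,
                 hedges = hedges, pct_change = pc, fitness = fit,
                 sample_size = ss),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat("Training-effect report\n")
  p <- x$paired$global_cbf
  cat(sprintf("  global GM CBF: t(%d) = %.2f, p = %.3f; g = %.2f (%.2f, %.2f)\n",
              p$df, p$t, p$p, x$hedges$global_cbf$g,
              x$hedges$global_cbf$lower, x$hedges$global_cbf$upper))
  p <- x$paired$global_scov
  cat(sprintf("  global GM sCoV: t(%d) = %.2f, p = %.3f; g = %.2f (%.2f, %.2f)\n",
              p$df, p$t, p$p, x$hedges$global_scov$g,
              x$hedges$global_scov$lower, x$hedges$global_scov$upper))
  it <- x$interaction_cbf$interaction
  cat(sprintf("  time x region (CBF): F(%d, %d) = %.2f, p = %.3f\n",
              it$df1, it$df2, it$F, it$p))
  cat("  per-lobe post hocs (Bonferroni):\n")
  for (i in seq_len(nrow(x$posthoc)))
    cat(sprintf("    %-9s p = %.4f, p_adj = %.4f\n", x$posthoc$region[i],
                x$posthoc$p[i], x$posthoc$p_bonferroni[i]))
  cat(sprintf("  suggested n: CBF %d, sCoV %d\n",
              x$sample_size$global_cbf, x$sample_size$global_scov))
  invisible(x)
}
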