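# Independent brute-force oracles for the statistical machinery.

# Two-way ANOVA mean squares from raw sums over cells (no lm/aov machinery).
brute_icc_a1 <- function(X) {
  n <- nrow(X); k <- ncol(X)
  gm <- sum(X) / (n * k)
  ssr <- ssc <- sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ri <- sum(X[i, ]) / k
    cj <- sum(X[, j]) / n
    sse <- sse + (X[i, j] - ri - cj + gm)^2
  }
  for (i in seq_len(n)) ssr <- ssr + k * (sum(X[i, ]) / k - gm)^2
  for (j in seq_len(k)) ssc <- ssc + n * (sum(X[, j]) / n - gm)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force sums-of-squares decomposition of a balanced two-way
# within-subject design; returns the interaction (and main-effect) F ratios.
brute_rm_anova <- function(table) {
  subj <- unique(as.character(table$subject_id))
  tps <- unique(as.character(table$timepoint))
  regs <- unique(as.character(table$region))
  n <- length(subj); a <- length(tps); b <- length(regs)
  val <- function(s, t, r)
    table$value[table$subject_id == s & table$timepoint == t &
                  table$region == r]
  Y <- array(0, c(n, a, b))
  for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(b))
    Y[i, j, l] <- val(subj[i], tps[j], regs[l])
  gm <- mean(Y)
  mi <- apply(Y, 1, mean); mj <- apply(Y, 2, mean); ml <- apply(Y, 3, mean)
  mij <- apply(Y, c(1, 2), mean); mil <- apply(Y, c(1, 3), mean)
  mjl <- apply(Y, c(2, 3), mean)
  ss_t <- n * b * sum((mj - gm)^2)
  ss_r <- n * a * sum((ml - gm)^2)
  ss_tr <- n * sum((sweep(sweep(mjl, 1, mj), 2, ml) + gm)^2)
  ss_st <- b * sum((sweep(sweep(mij, 1, mi), 2, mj) + gm)^2)
  ss_sr <- a * sum((sweep(sweep(mil, 1, mi), 2, ml) + gm)^2)
  ss_str <- 0
  for (i in seq_len(n)) for (j in seq_len(a)) for (l in seq_len(b))
    ss_str <- ss_str + (Y[i, j, l] - mij[i, j] - mil[i, l] - mjl[j, l] +
                          mi[i] + mj[j] + ml[l] - gm)^2
  list(
    F_time = (ss_t / (a - 1)) / (ss_st / ((n - 1) * (a - 1))),
    F_region = (ss_r / (b - 1)) / (ss_sr / ((n - 1) * (b - 1))),
    F_inter = (ss_tr / ((a - 1) * (b - 1))) /
      (ss_str / ((n - 1) * (a - 1) * (b - 1))))
}
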