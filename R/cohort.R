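# Cohort-level diagnostic statistics: the 11-patient clinical reference
# table, Pearson correlation with case-resampling bootstrap, predictive
# values, subgroup comparisons, and a Monte-Carlo power check.

TABLE1_MD5 <- "228ccdb5b55c4bd6b5586cedb21a9b5c"

#' Load the packaged 11-patient clinical reference table
#'
#' Eleven consecutive patients with suspected lower-grade diffuse glioma:
#' IDH genotype (R132H / R132C / R132S / WT), histology and location, the
#' in vivo MRS percentage elevation, the ex vivo 2-HG tissue concentration
#' (mmoles/kg, by GC-MS), their ratio, and the predictive-value label
#' (TP/TN/FP/FN). The file's md5 checksum is verified on load so that a
#' silently edited fixture cannot masquerade as the published cohort.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @param verify verify the md5 checksum (only for the default fixture).
#' @return data frame of 11 patient records.
#' @export
load_table1 <- function(path = NULL, verify = TRUE) {
  packaged <- is.null(path)
  if (packaged)
    path <- system.file("extdata", "table1.csv", package = "hgmrs",
                        mustWork = TRUE)
  if (packaged && verify) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, TABLE1_MD5))
      stop("table1.csv checksum mismatch: expected ", TABLE1_MD5,
           ", found ", md5)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "idh", "mrs_elevation_pct", "exvivo_hg",
            "exvivo_over_mrs", "pv_label")
  if (!all(need %in% names(df)))
    stop("clinical table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return the sample correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Case-resampling bootstrap of the Pearson correlation
#'
#' Draws `n_resamples` bootstrap samples of the (x, y) pairs, recomputes
#' the correlation on each, and reports the point estimate with a
#' percentile confidence interval. Degenerate resamples (a constant
#' vector) are skipped and counted.
#'
#' @param x,y paired observations.
#' @param n_resamples number of bootstrap resamples.
#' @param seed integer RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return list with `r` (point estimate on the original data), `ci`
#'   (percentile interval), `n_resamples`, `n_skipped`, `conf`.
#' @export
bootstrap_r <- function(x, y, n_resamples = 10000, seed = 1234,
                        conf = 0.95) {
  r0 <- pearson(x, y)
  set.seed(as.integer(seed))
  n <- length(x)
  rs <- vapply(seq_len(n_resamples), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
    stats::cor(x[idx], y[idx])
  }, numeric(1))
  skipped <- sum(is.na(rs))
  rs <- rs[!is.na(rs)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(rs, c(alpha, 1 - alpha)))
  list(r = r0, ci = ci, n_resamples = n_resamples, n_skipped = skipped,
       conf = conf)
}

#' Positive and negative predictive value of the MRS call
#'
#' A patient is called positive when the MRS elevation is strictly above
#' 0%; disease truth is IDH-mutant (any genotype other than WT).
#' PPV = 100 * TP / (TP + FP); NPV = 100 * TN / (TN + FN). A predictive
#' value whose denominator is zero is returned as `NA` with a flag.
#'
#' @param records data frame with columns `mrs_elevation_pct` and `idh`.
#' @return list with `ppv_pct`, `npv_pct`, the 2x2 `counts`
#'   (TP, FP, TN, FN), `n_positive`, and `undefined` flags.
#' @export
predictive_values <- function(records) {
  call_pos <- records$mrs_elevation_pct > 0
  mutant <- records$idh != "WT"
  tp <- sum(call_pos & mutant); fp <- sum(call_pos & !mutant)
  tn <- sum(!call_pos & !mutant); fn <- sum(!call_pos & mutant)
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
  list(ppv_pct = ppv, npv_pct = npv,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       n_positive = tp + fp,
       undefined = c(ppv = is.na(ppv), npv = is.na(npv)))
}

#' Ex vivo 2-HG by IDH1 mutation subtype
#'
#' Mean ex vivo 2-HG concentration in IDH1-mutant patients split by R132H
#' versus non-R132H genotype (wild-type records are excluded), with a
#' two-sample comparison. Welch's t-test is the default; Student's
#' equal-variance test is available.
#'
#' @param records data frame with columns `idh` and `exvivo_hg`.
#' @param test `"welch"` or `"student"`.
#' @return list with `mean_nonR132H`, `mean_R132H`, group sizes, and `p`.
#' @export
subgroup_means <- function(records, test = c("welch", "student")) {
  test <- match.arg(test)
  mut <- records[records$idh != "WT", ]
  r132h <- mut$exvivo_hg[mut$idh == "R132H"]
  other <- mut$exvivo_hg[mut$idh != "R132H"]
  if (length(r132h) == 0 || length(other) == 0)
    stop("both genotype subgroups must be non-empty")
  p <- stats::t.test(other, r132h, var.equal = (test == "student"))$p.value
  list(mean_nonR132H = mean(other), mean_R132H = mean(r132h),
       n_nonR132H = length(other), n_R132H = length(r132h), p = p)
}

#' Median and interquartile range
#'
#' @param values numeric vector, non-empty.
#' @return list with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) stop("empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75)))
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Full cohort analysis of the packaged clinical table
#'
#' Recomputes every headline statistic from the 11-patient reference
#' table: the Pearson correlation between the MRS percentage elevations
#' and the ex vivo 2-HG concentrations (with bootstrap interval), the
#' predictive values of the >0% call against IDH genotype, the subgroup
#' means by mutation subtype, and the median/IQR of the ex vivo
#' concentrations.
#'
#' @param records patient table; defaults to [load_table1()].
#' @param n_boot bootstrap resample count.
#' @param seed bootstrap RNG seed.
#' @return a `cohort_stats` list: `n`, `pearson_r`, `r_ci`, `cor_p`,
#'   `ppv_pct`, `npv_pct`, `counts`, `n_positive`, `mean_nonR132H`,
#'   `mean_R132H`, `group_p`, `median_exvivo`, `iqr_exvivo`, `records`.
#' @export
run_cohort_analysis <- function(records = load_table1(), n_boot = 10000,
                               seed = 1234) {
  x <- records$mrs_elevation_pct
  y <- records$exvivo_hg
  boot <- bootstrap_r(x, y, n_resamples = n_boot, seed = seed)
  pv <- predictive_values(records)
  sg <- subgroup_means(records)
  mi <- median_iqr(y)
  structure(
    list(n = nrow(records), pearson_r = boot$r, r_ci = boot$ci,
         cor_p = stats::cor.test(x, y)$p.value,
         ppv_pct = pv$ppv_pct, npv_pct = pv$npv_pct, counts = pv$counts,
         n_positive = pv$n_positive,
         mean_nonR132H = sg$mean_nonR132H, mean_R132H = sg$mean_R132H,
         group_p = sg$p,
         median_exvivo = mi$median, iqr_exvivo = c(mi$q1, mi$q3),
         records = records),
    class = "cohort_stats"
  )
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("Cohort analysis (n = %d)\n", x$n))
  cat(sprintf("  Pearson r (MRS %% vs ex vivo 2-HG): %.2f (p = %.3f), 95%% CI %.2f..%.2f\n",
              x$pearson_r, x$cor_p, x$r_ci[1], x$r_ci[2]))
  cat(sprintf("  Positive calls: %d; PPV %.0f%%, NPV %.0f%% (TP %d, FP %d, TN %d, FN %d)\n",
              x$n_positive, x$ppv_pct, round(x$npv_pct),
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  cat(sprintf("  Ex vivo 2-HG: non-R132H mean %.2f vs R132H mean %.2f mmoles/kg (p = %.3f)\n",
              x$mean_nonR132H, x$mean_R132H, x$group_p))
  cat(sprintf("  Ex vivo median %.2f mmoles/kg (IQR %.2f-%.2f)\n",
              x$median_exvivo, x$iqr_exvivo[1], x$iqr_exvivo[2]))
  invisible(x)
}

#' Monte-Carlo power of the Pearson correlation test
#'
#' Simulates bivariate-normal samples of size `n` with true correlation
#' `r_true`, tests each with `cor.test`, and reports the rejection rate at
#' level `alpha` with its Monte-Carlo standard error. At `r_true = 0` the
#' power equals the nominal alpha (null calibration).
#'
#' @param r_true true correlation in (-1, 1).
#' @param n sample size per simulation (>= 4).
#' @param alpha two-sided significance level.
#' @param n_sims number of simulated datasets.
#' @param seed integer RNG seed.
#' @return list with `power`, `mc_se`, `n_sims`.
#' @export
power_check <- function(r_true, n, alpha = 0.05, n_sims = 4000, seed = 1) {
  if (n < 4) stop("n must be >= 4")
  if (abs(r_true) >= 1) stop("r_true must be in (-1, 1)")
  set.seed(as.integer(seed))
  reject <- vapply(seq_len(n_sims), function(i) {
    x <- stats::rnorm(n)
    y <- r_true * x + sqrt(1 - r_true^2) * stats::rnorm(n)
    stats::cor.test(x, y)$p.value < alpha
  }, logical(1))
  p <- mean(reject)
  list(power = p, mc_se = sqrt(p * (1 - p) / n_sims), n_sims = n_sims)
}
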