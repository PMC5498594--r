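#' Paired per-joint measurement table
#'
#' Two measurements (methods A and B) of one metric over the same joints,
#' the input to the joint-level agreement statistics.
#'
#' @param a,b numeric vectors of equal length (n >= 2), one value per joint.
#' @return A data frame with columns `A` and `B`, class `cg_joint_table`.
#' @export
paired_joint_table <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  if (length(a) < 2) stop("need at least 2 joints")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  structure(data.frame(A = as.numeric(a), B = as.numeric(b)),
            class = c("cg_joint_table", "data.frame"))
}

as_joint_table <- function(x) {
  if (inherits(x, "cg_joint_table")) return(x)
  if ((is.data.frame(x) || is.matrix(x)) && ncol(x) == 2)
    return(paired_joint_table(as.numeric(x[, 1]), as.numeric(x[, 2])))
  stop("expected a paired_joint_table or a 2-column table")
}

#' Single-measure ICC, two-way random effects, absolute agreement
#'
#' ICC(2,1) in the Shrout--Fleiss taxonomy (ICC(A,1) in McGraw--Wong):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`
#' raters/methods, where MSR, MSC, MSE are the rows (joints), columns
#' (methods) and residual mean squares of the two-way ANOVA. The confidence
#' interval uses the standard F-distribution bounds with a
#' Satterthwaite-approximated denominator df.
#'
#' @param table a [paired_joint_table()] (or any 2-column numeric table).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return A list: `icc`, `ci_low`, `ci_high`, `label` (Landis--Koch
#'   qualitative annotation), `n`, and the ANOVA mean squares.
#' @export
icc_two_way_random_absolute <- function(table, conf_level = 0.95) {
  tab <- as_joint_table(table)
  x <- as.matrix(tab)
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - mu)^2)
  ssc <- n * sum((col_m - mu)^2)
  sse <- sum((x - outer(row_m, col_m, `+`) + mu)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (ssr <= 0 || denom <= 0) {
    warning("zero between-joint variance: ICC undefined", call. = FALSE)
    return(list(icc = NaN, ci_low = NaN, ci_high = NaN, label = NA_character_,
                n = n, msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(icc, icc)          # degenerate: columns identical
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], label = icc_label(icc),
       n = n, msr = msr, msc = msc, mse = mse)
}

# Landis--Koch qualitative agreement labels (presentation only).
icc_label <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc >= 0.81) "almost perfect" else if (icc >= 0.61) "substantial"
  else if (icc >= 0.41) "moderate" else if (icc >= 0.21) "fair"
  else "slight"
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (with `p = 1` and a warning when nothing remains). For up to
#' `exact_limit` informative pairs the exact null distribution of the
#' positive-rank sum is computed by dynamic programming over the (doubled,
#' so tied midranks stay integral) ranks — equivalent to full enumeration of
#' the 2^n sign assignments; above the limit a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @inheritParams icc_two_way_random_absolute
#' @param method `"auto"` (exact up to `exact_limit`, default),
#'   `"exact"`, or `"asymptotic"`.
#' @param exact_limit largest number of informative pairs for the exact
#'   null distribution (default 25).
#' @return The two-sided p-value, with attributes `statistic` (positive-rank
#'   sum W), `n_informative` and `method`.
#' @export
wilcoxon_signed_rank <- function(table, method = c("auto", "exact",
                                                   "asymptotic"),
                                 exact_limit = 25L) {
  tab <- as_joint_table(table)
  method <- match.arg(method)
  d <- tab$A - tab$B
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero", call. = FALSE)
    return(structure(1, statistic = 0, n_informative = 0L, method = "none"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  use_exact <- switch(method, exact = TRUE, asymptotic = FALSE,
                      auto = n <= exact_limit)
  if (use_exact && n > 30)
    stop("exact method is limited to 30 informative pairs")
  if (use_exact) {
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2)))      # counts[s+1] = #subsets with sum s
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[seq(w2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    meth <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    meth <- "asymptotic"
  }
  structure(p, statistic = w, n_informative = n, method = meth)
}

#' Lesion-level positive predictive value
#'
#' `100 * matched / n_detected_A`: the percentage of interruptions detected
#' by the test modality (A) that are confirmed by an overlapping reference
#' interruption.
#'
#' @param matched number of matched test-side interruptions.
#' @param n_detected_A total interruptions detected by the test modality.
#' @return Percent in \[0, 100\].
#' @export
ppv <- function(matched, n_detected_A) {
  if (n_detected_A < 1) stop("undefined metric: zero detections in A")
  if (matched < 0 || matched > n_detected_A)
    stop("matched must lie in [0, n_detected_A]")
  100 * matched / n_detected_A
}

#' Lesion-level sensitivity
#'
#' `100 * matched / n_detected_B`: the percentage of reference (B)
#' interruptions recovered by the test modality.
#'
#' @param matched number of matched reference-side interruptions.
#' @param n_detected_B total interruptions in the reference set.
#' @return Percent in \[0, 100\].
#' @export
sensitivity <- function(matched, n_detected_B) {
  if (n_detected_B < 1) stop("undefined metric: zero detections in B")
  if (matched < 0 || matched > n_detected_B)
    stop("matched must lie in [0, n_detected_B]")
  100 * matched / n_detected_B
}

#' Joint- and lesion-level reliability report
#'
#' Assembles the full reliability summary for a set of joints measured by
#' two methods: per metric the mean (SD) of each method, the Wilcoxon
#' signed-rank p and the ICC(2,1) with 95% CI; plus, per match report, the
#' lesion-level PPV (matched A over all A) and sensitivity (matched B over
#' all B). The PPV numerator counts on the test side and the sensitivity
#' numerator on the reference side, so one-to-many matches are handled
#' consistently with each denominator.
#'
#' @param tables named list of [paired_joint_table()]s (e.g.
#'   `list(count = ..., surface_mm2 = ...)`).
#' @param matches optional named list of `cg_match_report`s.
#' @param conf_level CI level for the ICC (default 0.95).
#' @return A `cg_reliability_report` with data frames `joint` and `lesion`.
#' @export
reliability_report <- function(tables, matches = list(), conf_level = 0.95) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  joint <- do.call(rbind, lapply(names(tables), function(nm) {
    tab <- as_joint_table(tables[[nm]])
    ic <- icc_two_way_random_absolute(tab, conf_level)
    data.frame(metric = nm,
               mean_A = mean(tab$A), sd_A = stats::sd(tab$A),
               mean_B = mean(tab$B), sd_B = stats::sd(tab$B),
               wilcoxon_p = as.numeric(wilcoxon_signed_rank(tab)),
               icc = ic$icc, icc_ci_low = ic$ci_low,
               icc_ci_high = ic$ci_high, icc_label = ic$label)
  }))
  lesion <- if (length(matches)) {
    do.call(rbind, lapply(names(matches), function(nm) {
      m <- matches[[nm]]
      stopifnot(inherits(m, "cg_match_report"))
      data.frame(comparison = nm, mode = m$mode,
                 n_A = m$n_A, n_B = m$n_B,
                 matched_A = m$matched_A, matched_B = m$matched_B,
                 ppv_percent = if (m$n_A >= 1) ppv(m$matched_A, m$n_A)
                               else NA_real_,
                 sensitivity_percent = if (m$n_B >= 1)
                   sensitivity(m$matched_B, m$n_B) else NA_real_)
    }))
  } else {
    data.frame()
  }
  structure(list(joint = joint, lesion = lesion, conf_level = conf_level),
            class = "cg_reliability_report")
}

#' @export
print.cg_reliability_report <- function(x, ...) {
  cat("<cg_reliability_report>\n\nJoint level:\n")
  j <- x$joint
  for (i in seq_len(nrow(j)))
    cat(sprintf(
      "  %-12s A %.1f (%.1f)  B %.1f (%.1f)  p = %.3g  ICC %.2f (%.2f to %.2f) [%s]\n",
      j$metric[i], j$mean_A[i], j$sd_A[i], j$mean_B[i], j$sd_B[i],
      j$wilcoxon_p[i], j$icc[i], j$icc_ci_low[i], j$icc_ci_high[i],
      j$icc_label[i]))
  if (nrow(x$lesion)) {
    cat("\nLesion level:\n")
    l <- x$lesion
    for (i in seq_len(nrow(l)))
      cat(sprintf("  %-16s PPV %5.1f%% (%d/%d)  sensitivity %5.1f%% (%d/%d)\n",
                  l$comparison[i], l$ppv_percent[i], l$matched_A[i], l$n_A[i],
                  l$sensitivity_percent[i], l$matched_B[i], l$n_B[i]))
  }
  invisible(x)
}
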