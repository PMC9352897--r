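# Pairwise method-agreement statistics: Pearson correlation with the
# non-correlation test, Lin's concordance correlation coefficient, and
# Bland-Altman limits of agreement.
#
# Lin's coefficient measures agreement with the identity line,
#
#   rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2),
#
# with n-denominator (biased) moments as in the original definition. It
# combines precision (Pearson's r) with accuracy (location/scale shift), so
# |rho_c| <= |r| always, with equality iff the means and variances agree.

paired_sample <- function(x, y, labels = c("x", "y"), min_n = 3L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    validation_error("paired sample vectors must have equal length")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n) {
    degenerate_sample_error(sprintf(
      "need at least %d complete pairs, got %d", min_n, length(x)))
  }
  list(x = x, y = y, labels = labels, n = length(x))
}

check_nonconstant <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    degenerate_sample_error("correlation undefined for a constant vector")
  }
}

#' Pearson correlation with non-correlation test
#'
#' Product-moment correlation and the two-sided p-value of the t-based
#' non-correlation test (which assumes bivariate normality).
#'
#' @param x,y Equal-length numeric vectors; pairs with a missing value are
#'   dropped.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  s <- paired_sample(x, y)
  check_nonconstant(s$x, s$y)
  ct <- stats::cor.test(s$x, s$y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = s$n)
}

#' Lin's concordance correlation coefficient
#'
#' Point estimate with n-denominator moments, and a confidence interval via
#' the Fisher z-transform with the asymptotic standard error of the original
#' derivation.
#'
#' @param x,y Equal-length numeric vectors; incomplete pairs dropped.
#' @param ci_level Confidence level (default 0.95); `NULL` skips the CI.
#' @return List with `ccc`, `ci` (length-2 or NULL) and `n`.
#' @export
lin_ccc <- function(x, y, ci_level = 0.95) {
  s <- paired_sample(x, y)
  check_nonconstant(s$x, s$y)
  n <- s$n
  mx <- mean(s$x); my <- mean(s$y)
  # n-denominator moments per the original definition
  sx2 <- mean((s$x - mx)^2); sy2 <- mean((s$y - my)^2)
  sxy <- mean((s$x - mx) * (s$y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)

  ci <- NULL
  if (!is.null(ci_level)) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)  # location shift relative to scale
    if (abs(ccc) < 1 && abs(r) > 0 && n > 2) {
      se_z2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                  2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                  ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
      se_z2 <- max(se_z2, 0)
      z <- atanh(ccc)
      q <- stats::qnorm(1 - (1 - ci_level) / 2)
      ci <- tanh(z + c(-1, 1) * q * sqrt(se_z2))
    } else {
      ci <- c(ccc, ccc)
    }
  }
  list(ccc = ccc, ci = ci, n = n)
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken first-minus-second (`x - y`). Limits of agreement
#' are `mean(d) +/- 1.96 sd(d)` with the sample (n-1) SD; the CI of the mean
#' difference uses the t distribution, and each limit's CI uses the
#' classical standard error `sd * sqrt(3/n)`.
#'
#' @param x,y Equal-length numeric vectors; incomplete pairs dropped.
#' @param ci_level Confidence level for the intervals.
#' @param labels Method names, in difference order.
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, their confidence intervals, `n`, and the
#'   per-point `(mean, difference)` pairs for plotting.
#' @export
bland_altman <- function(x, y, ci_level = 0.95, labels = c("x", "y")) {
  s <- paired_sample(x, y, labels = labels)
  d <- s$x - s$y
  n <- s$n
  md <- mean(d)
  sd_d <- stats::sd(d)
  loa <- md + c(-1, 1) * 1.96 * sd_d
  tq <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  se_mean <- sd_d / sqrt(n)
  se_loa <- sd_d * sqrt(3 / n)
  structure(
    list(
      labels = labels, n = n,
      mean_diff = md, sd_diff = sd_d,
      loa_low = loa[1], loa_high = loa[2],
      ci_mean = md + c(-1, 1) * tq * se_mean,
      ci_loa_low = loa[1] + c(-1, 1) * tq * se_loa,
      ci_loa_high = loa[2] + c(-1, 1) * tq * se_loa,
      ci_level = ci_level,
      points = data.frame(mean = (s$x + s$y) / 2, difference = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman: %s - %s (n = %d)\n",
              x$labels[1], x$labels[2], x$n))
  cat(sprintf("  mean difference: %.*f  [%.*f, %.*f]\n",
              digits, x$mean_diff, digits, x$ci_mean[1], digits, x$ci_mean[2]))
  cat(sprintf("  limits of agreement: [%.*f, %.*f]\n",
              digits, x$loa_low, digits, x$loa_high))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Royston algorithm with the sample-size
#' contract made explicit.
#'
#' @param v Numeric vector, 3 <= n <= 5000 after NA removal.
#' @return List with `W`, `p` and `n`.
#' @export
shapiro_wilk <- function(v) {
  v <- as.numeric(v[!is.na(v)])
  n <- length(v)
  if (n < 3 || n > 5000) {
    unsupported_size_error(sprintf("Shapiro-Wilk requires 3 <= n <= 5000, got %d", n))
  }
  if (stats::var(v) == 0) {
    degenerate_sample_error("Shapiro-Wilk undefined for a constant sample")
  }
  sw <- stats::shapiro.test(v)
  list(W = unname(sw$statistic), p = sw$p.value, n = n)
}

#' Pairwise method comparison, optionally stratified
#'
#' For one metric (`bfr` or `smr`) and one ordered method pair, computes the
#' full agreement bundle — Pearson r with p, Lin's concordance coefficient,
#' and Bland-Altman statistics — overall and per stratum. Differences are
#' first-listed minus second-listed method. Pairs with a missing reading are
#' dropped per comparison (pairwise-complete); strata with fewer than 3
#' complete pairs are skipped with a warning.
#'
#' @param table Measurement data.frame (see [validate_measurements]).
#' @param metric `"bfr"` or `"smr"`.
#' @param pair Character vector of two method names among `bca`, `dxa`,
#'   `bia` (the metric/method combination must exist as a column).
#' @param stratify `"none"`, `"bmi"` or `"sex"`.
#' @param config A [bca_config] (CI level, BMI cut points, CCC CI switch).
#' @return Object of class `method_comparison`: list with `metric`, `pair`
#'   and `strata`, each stratum holding `agreement` (r, p, ccc, ccc_ci, n)
#'   and `bland_altman`.
#' @export
compare_methods <- function(table, metric = c("bfr", "smr"),
                            pair = c("bca", "dxa"),
                            stratify = c("none", "bmi", "sex"),
                            config = bca_config()) {
  metric <- match.arg(metric)
  stratify <- match.arg(stratify)
  table <- validate_measurements(table)
  cols <- paste(metric, pair, sep = "_")
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0) {
    validation_error(sprintf("column(s) %s not in table", paste(miss, collapse = ", ")))
  }

  strata <- list(overall = rep(TRUE, nrow(table)))
  if (stratify == "bmi") {
    grp <- assign_bmi_group(table$bmi, cut_points = config$bmi_cut_points)
    for (g in levels(grp)) {
      if (any(grp == g, na.rm = TRUE)) strata[[g]] <- !is.na(grp) & grp == g
    }
  } else if (stratify == "sex") {
    for (g in c("male", "female")) {
      if (any(table$sex == g, na.rm = TRUE)) {
        strata[[g]] <- !is.na(table$sex) & table$sex == g
      }
    }
  }

  out <- list()
  for (nm in names(strata)) {
    x <- table[[cols[1]]][strata[[nm]]]
    y <- table[[cols[2]]][strata[[nm]]]
    res <- tryCatch({
      pr <- pearson_with_p(x, y)
      cc <- lin_ccc(x, y, ci_level = if (config$ccc_ci) config$ci_level else NULL)
      ba <- bland_altman(x, y, ci_level = config$ci_level,
                         labels = paste(pair, metric, sep = "_"))
      list(
        stratum = nm,
        agreement = list(r = pr$r, p = pr$p, ccc = cc$ccc, ccc_ci = cc$ci,
                         n = pr$n),
        bland_altman = ba
      )
    }, ctbca_degenerate_sample_error = function(e) {
      warning(sprintf("stratum '%s' skipped: %s", nm, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) out[[nm]] <- res
  }
  structure(
    list(metric = metric, pair = pair, stratify = stratify, strata = out),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Method comparison: %s, %s vs %s (difference = %s - %s)\n",
              toupper(x$metric), x$pair[1], x$pair[2], x$pair[1], x$pair[2]))
  for (s in x$strata) {
    a <- s$agreement; b <- s$bland_altman
    cat(sprintf(
      "  %-10s n=%3d  r=%.*f (p=%.2g)  ccc=%.*f  mean diff=%.*f  LoA=[%.*f, %.*f]\n",
      s$stratum, a$n, digits, a$r, a$p, digits, a$ccc,
      digits, b$mean_diff, digits, b$loa_low, digits, b$loa_high))
  }
  invisible(x)
}

#' @export
summary.method_comparison <- function(object, ...) {
  rows <- lapply(object$strata, function(s) {
    data.frame(
      metric = object$metric,
      pair = paste(object$pair, collapse = "-"),
      stratum = s$stratum, n = s$agreement$n,
      r = s$agreement$r, p = s$agreement$p, ccc = s$agreement$ccc,
      mean_diff = s$bland_altman$mean_diff,
      loa_low = s$bland_altman$loa_low,
      loa_high = s$bland_altman$loa_high,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman plot for a method comparison stratum
#'
#' Mean-difference plot with the mean difference (blue) and limits of
#' agreement (red), each with its confidence band.
#'
#' @param x A `bland_altman` object or a `method_comparison` (in which case
#'   `stratum` selects which stratum to draw).
#' @param stratum Stratum name, default `"overall"`.
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, the `bland_altman` object drawn.
#' @export
plot.method_comparison <- function(x, stratum = "overall", ...) {
  if (!stratum %in% names(x$strata)) {
    validation_error(sprintf("no stratum '%s' in comparison", stratum))
  }
  plot(x$strata[[stratum]]$bland_altman, ...)
}

#' @export
plot.bland_altman <- function(x, ...) {
  pts <- x$points
  ylim <- range(pts$difference, x$ci_loa_low, x$ci_loa_high)
  graphics::plot(pts$mean, pts$difference,
                 xlab = sprintf("mean of %s and %s", x$labels[1], x$labels[2]),
                 ylab = sprintf("%s - %s", x$labels[1], x$labels[2]),
                 ylim = ylim, pch = 19, col = "grey30", ...)
  graphics::abline(h = x$mean_diff, col = "blue", lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lwd = 2)
  graphics::abline(h = c(x$ci_mean, x$ci_loa_low, x$ci_loa_high),
                   col = c("blue", "blue", "red", "red", "red", "red"),
                   lty = 3)
  invisible(x)
}
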