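#' Agreement statistics between automated and reference measurements
#'
#' Compares two paired series of relative pneumothorax sizes (percentages):
#' per-case absolute errors and their mean, the Pearson product-moment
#' correlation, a two-sided paired t-test on the differences (auto - ref,
#' n - 1 degrees of freedom), and the ordinary least-squares trendline of
#' auto on ref (with intercept).
#'
#' If either series has zero variance the correlation is undefined and
#' reported as `NA` with a warning; a paired t on identical series is 0/0 and
#' reported as 0, also with a warning.
#'
#' @param auto_pct,ref_pct numeric vectors of percentages, equal length >= 2.
#' @param case_ids optional identifiers (default `case 1..n`).
#' @return Object of class `method_comparison` with fields `case_ids`,
#'   `auto_pct`, `ref_pct`, `abs_errors`, `mean_abs_error`, `pearson_r`,
#'   `t_statistic`, `t_pvalue`, `slope`, `intercept`, `r_squared`.
#' @examples
#' cmp <- compare_methods(c(10.2, 5.1, 20.3), c(10.0, 5.5, 19.8))
#' cmp$mean_abs_error
#' @export
compare_methods <- function(auto_pct, ref_pct, case_ids = NULL) {
  auto_pct <- as.numeric(auto_pct)
  ref_pct <- as.numeric(ref_pct)
  n <- length(auto_pct)
  if (n < 2L || length(ref_pct) != n) {
    stop("need two series of equal length >= 2")
  }
  if (any(!is.finite(auto_pct)) || any(!is.finite(ref_pct))) {
    stop("percentages must be finite")
  }
  if (is.null(case_ids)) case_ids <- paste("case", seq_len(n))

  abs_errors <- abs(auto_pct - ref_pct)
  mean_abs_error <- mean(abs_errors)

  if (stats::var(auto_pct) == 0 || stats::var(ref_pct) == 0) {
    warning("zero variance in a series: Pearson correlation undefined")
    pearson_r <- NA_real_
  } else {
    pearson_r <- stats::cor(auto_pct, ref_pct)
  }

  d <- auto_pct - ref_pct
  if (stats::sd(d) == 0) {
    warning("zero variance in paired differences: t statistic reported as 0")
    t_statistic <- 0
    t_pvalue <- 1
  } else {
    tt <- stats::t.test(auto_pct, ref_pct, paired = TRUE)
    t_statistic <- unname(tt$statistic)
    t_pvalue <- tt$p.value
  }

  if (stats::var(ref_pct) == 0) {
    slope <- NA_real_; intercept <- NA_real_; r_squared <- NA_real_
  } else {
    fit <- stats::lm(auto_pct ~ ref_pct)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    ss_tot <- sum((auto_pct - mean(auto_pct))^2)
    r_squared <- if (ss_tot == 0) NA_real_ else
      1 - sum(stats::residuals(fit)^2) / ss_tot
  }

  structure(list(case_ids = case_ids, auto_pct = auto_pct, ref_pct = ref_pct,
                 abs_errors = abs_errors, mean_abs_error = mean_abs_error,
                 pearson_r = pearson_r, t_statistic = t_statistic,
                 t_pvalue = t_pvalue, slope = slope, intercept = intercept,
                 r_squared = r_squared),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("method_comparison over", length(x$case_ids), "cases\n")
  cat(sprintf("  mean absolute error: %.2f%%\n", x$mean_abs_error))
  cat(sprintf("  Pearson r: %.3f\n", x$pearson_r))
  cat(sprintf("  paired t: t = %.2f, p = %.4f\n", x$t_statistic, x$t_pvalue))
  cat(sprintf("  trendline: auto = %.3f * ref + %.3f (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
summary.method_comparison <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot automated against reference sizes with the OLS trendline
#'
#' @param x a `method_comparison`.
#' @param ... passed to [plot()].
#' @export
plot.method_comparison <- function(x, ...) {
  plot(x$ref_pct, x$auto_pct, xlab = "reference PTX size (%)",
       ylab = "automated PTX size (%)", pch = 19, ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  if (is.finite(x$slope)) graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Render a comparison as a per-case table
#'
#' One column per case: automated %, reference %, absolute error, all at
#' 2 decimals, plus a summary column carrying the mean absolute error.
#'
#' @param mc a `method_comparison`.
#' @param path optional CSV path to write.
#' @return A data.frame (rows: auto, ref, absolute error; columns: cases +
#'   `average`), invisibly if written to file.
#' @export
tabulate_comparison <- function(mc, path = NULL) {
  if (!inherits(mc, "method_comparison")) {
    stop("'mc' must be a method_comparison (see compare_methods)")
  }
  tab <- rbind(
    auto_pct = round(mc$auto_pct, 2),
    ref_pct = round(mc$ref_pct, 2),
    abs_error = round(mc$abs_errors, 2)
  )
  colnames(tab) <- mc$case_ids
  df <- as.data.frame(tab)
  df$average <- c(round(mean(mc$auto_pct), 2), round(mean(mc$ref_pct), 2),
                  round(mc$mean_abs_error, 2))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = TRUE)
    return(invisible(df))
  }
  df
}

#' Published eight-case benchmark: automated vs manual PTX size
#'
#' The per-case relative pneumothorax sizes (percent of the pleural space)
#' measured by the automated CT method and by expert manual segmentation on
#' the original eight-patient cohort. Useful as a worked example and as the
#' reference input for the agreement statistics.
#'
#' @return data.frame with `case_id`, `auto_pct`, `ref_pct`.
#' @export
table1_preset <- function() {
  data.frame(
    case_id = paste0("case", 1:8),
    auto_pct = c(8.10, 0.38, 19.73, 17.29, 5.34, 38.54, 3.04, 19.92),
    ref_pct = c(7.93, 0.00, 20.11, 18.44, 6.52, 35.26, 3.97, 19.45),
    stringsAsFactors = FALSE
  )
}
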