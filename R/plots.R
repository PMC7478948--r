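#' Diagnostic plots for an evaluation report
#'
#' Base-graphics summaries of a cohort evaluation: Dice versus reference
#' WML volume, CT-vs-reference volume scatter with the fitted line,
#' Bland-Altman plot, and per-group volume distributions.
#'
#' @param report An `evaluation_report` from [evaluate_cohort()].
#' @param which Subset of `c("dice", "scatter", "bland_altman", "groups")`.
#' @return Invisibly, the report.
#' @export
plot_evaluation <- function(report,
                            which = c("dice", "scatter", "bland_altman",
                                      "groups")) {
  per <- report$per_subject
  which <- match.arg(which, several.ok = TRUE)
  if ("dice" %in% which) {
    graphics::plot(per$vol_flair_ml, per$dice, xlab = "reference WML volume (mL)",
                   ylab = "Dice", main = "Overlap vs lesion load",
                   pch = 19, col = "grey30", ylim = c(0, 1))
  }
  if ("scatter" %in% which) {
    graphics::plot(per$vol_flair_ml, per$vol_ct_ml,
                   xlab = "reference volume (mL)", ylab = "CT volume (mL)",
                   main = sprintf("r = %.3f, slope = %.3f",
                                  report$correlation$pearson_r,
                                  report$correlation$slope), pch = 19)
    graphics::abline(report$correlation$intercept, report$correlation$slope,
                     col = "red3")
    graphics::abline(0, 1, lty = 3)
  }
  if ("bland_altman" %in% which) {
    ba <- report$bland_altman
    graphics::plot(ba$points$mean, ba$points$difference,
                   xlab = "mean of CT and reference volume (mL)",
                   ylab = "CT - reference (mL)", main = "Bland-Altman",
                   pch = 19)
    graphics::abline(h = c(ba$mean_difference, ba$loa_lower, ba$loa_upper),
                     lty = c(1, 2, 2), col = "red3")
  }
  if ("groups" %in% which) {
    graphics::boxplot(vol_ct_ml ~ fazekas_label, data = per,
                      xlab = "Fazekas group", ylab = "CT WML volume (mL)",
                      main = "Volume by severity group")
  }
  invisible(report)
}
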