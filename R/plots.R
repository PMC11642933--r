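#' Plot a prediction's activation maps
#'
#' One panel per modality: the preprocessed input trace with the activation
#' map as a color band behind it (pink = evidence for an upcoming adverse
#' event, light blue = evidence for control), plus the additive
#' contribution in the panel title.
#'
#' @param pred A `namts_nam_prediction` from [nam_forward()].
#' @param input The `namts_model_input` that produced it.
#' @param modalities Which modalities to draw.
#' @export
plot_activation_maps <- function(pred, input,
                                 modalities = names(pred$activation_maps)) {
  stopifnot(inherits(pred, "namts_nam_prediction"))
  old <- graphics::par(mfrow = c(length(modalities), 1),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in modalities) {
    map <- pred$activation_maps[[m]]
    x <- input[[m]]
    t_s <- seq(0, 30, length.out = length(x) + 1)[-1]
    amax <- max(abs(map), 1e-12)
    cols <- grDevices::rgb(
      ifelse(map > 0, 1, 0.55 + 0.45 * pmax(1 + map / amax, 0)),
      ifelse(map > 0, pmax(1 - map / amax, 0) * 0.75, 0.85),
      ifelse(map > 0, pmax(1 - map / amax, 0), 1),
      alpha = 0.6)
    plot(t_s, x, type = "n", xlab = "", ylab = m,
         main = sprintf("%s  (contribution %+.3f)", m,
                        pred$contributions[[m]]))
    graphics::rect(t_s - diff(t_s[1:2]), min(x), t_s, max(x),
                   col = cols, border = NA)
    graphics::lines(t_s, x, lwd = 1.2)
  }
  invisible(NULL)
}

#' Plot the averaged ROC curve of a cross-validation report
#'
#' Vertically averaged ROC over patients with a pointwise +/- 1 sd band.
#'
#' @param report A `namts_cv_report` from [loocv()].
#' @export
plot_roc <- function(report) {
  stopifnot(inherits(report, "namts_cv_report"))
  r <- report$roc
  plot(r$fpr, r$tpr_mean, type = "l", lwd = 2, xlim = c(0, 1),
       ylim = c(0, 1), xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("%s: mean AuROC %.3f (sd %.3f)", report$kind,
                      report$aggregate$mean_auroc,
                      report$aggregate$sd_auroc))
  graphics::polygon(c(r$fpr, rev(r$fpr)),
                    c(pmin(r$tpr_mean + r$tpr_sd, 1),
                      rev(pmax(r$tpr_mean - r$tpr_sd, 0))),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::abline(0, 1, lty = 2, col = "darkgreen")
  invisible(NULL)
}
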