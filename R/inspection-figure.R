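# Five-row augmented visual inspection figure.

#' @describeIn inspect_carotid Draw the five-row inspection figure:
#'   original signal; cardiac pulse train; rolling-ball-sifted bruits
#'   (display-magnified); high-pass-filtered bruits (display-magnified);
#'   overlaid autocorrelation curves with the heart-rate peak annotated.
#'   Magnification affects the display only, never the stored traces.
#' @param magnify display magnification of the bruit traces (default 100).
#' @param ... ignored.
#' @export
plot.carotid_inspection <- function(x, magnify = 100, ...) {
  sig <- x$signal
  t <- (seq_along(sig$samples) - 1) / sig$fs
  op <- par(mfrow = c(5, 1), mar = c(2.2, 4, 1.2, 1), mgp = c(2.2, 0.7, 0))
  on.exit(par(op))
  plot(t, sig$samples, type = "l", col = "black", xlab = "", ylab = "signal",
       main = "Augmented visual inspection")
  plot(t, x$case$pulse_train, type = "l", col = "red", xlab = "",
       ylab = "pulse train")
  plot(t, magnify * x$case$rbs_bruits, type = "l", col = "blue", xlab = "",
       ylab = sprintf("RBS x%g", magnify))
  plot(t, magnify * x$case$hpf_bruits, type = "l", col = "darkgreen",
       xlab = "time (s)", ylab = sprintf("HPF x%g", magnify))
  draw_acf_panel(x)
  invisible(x)
}

draw_acf_panel <- function(x) {
  fs <- x$signal$fs
  curves <- list(HR = x$hr$periodicity, RBS = x$rbs$periodicity,
                 HPF = x$hpf$periodicity)
  cols <- c(HR = "red", RBS = "blue", HPF = "darkgreen")
  have <- vapply(curves, function(p) length(p$acf) > 0, logical(1))
  if (!any(have)) {
    plot.new()
    title(main = "autocorrelation unavailable")
    return(invisible(NULL))
  }
  first <- TRUE
  for (nm in names(curves)[have]) {
    p <- curves[[nm]]
    lag_s <- (seq_along(p$acf) - 1) / fs
    if (first) {
      plot(lag_s, p$acf, type = "l", col = cols[[nm]], ylim = c(-1, 1),
           xlab = "lag (s)", ylab = "autocorrelation")
      first <- FALSE
    } else lines(lag_s, p$acf, col = cols[[nm]])
  }
  legend("topright", legend = names(curves)[have], col = cols[have],
         lty = 1, bty = "n", cex = 0.8)
  if (x$case$hr_positive) {
    p <- x$hr$periodicity
    abline(v = p$peak_lag / fs, lty = 3)
    text(p$peak_lag / fs, 0.95,
         sprintf("%.0f beats/min", p$rate_bpm), pos = 4, cex = 0.9)
  } else {
    text(mean(par("usr")[1:2]), 0.9, "HR undetectable", cex = 0.9)
  }
  invisible(NULL)
}

#' Render the inspection figure to an image file
#'
#' Writes the five-row figure of [plot.carotid_inspection()] as PNG or
#' SVG.
#'
#' @param report a `carotid_inspection`.
#' @param path output file path; the format is taken from its extension
#'   (`.png` or `.svg`).
#' @param width,height device size in pixels (PNG) or inches (SVG).
#' @param magnify display magnification of the bruit traces.
#' @return `path`, invisibly.
#' @export
render_inspection_figure <- function(report, path, width = NULL,
                                     height = NULL, magnify = 100) {
  stopifnot(inherits(report, "carotid_inspection"))
  for (stage in c("pulse_train", "rbs_bruits", "hpf_bruits")) {
    if (!length(report$case[[stage]]))
      stop("missing trace for stage: ", stage, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = if (is.null(width)) 900 else width,
                   height = if (is.null(height)) 1100 else height)
  } else if (ext == "svg") {
    grDevices::svg(path, width = if (is.null(width)) 9 else width,
                   height = if (is.null(height)) 11 else height)
  } else stop("unsupported figure format: .", ext, call. = FALSE)
  on.exit(grDevices::dev.off())
  plot(report, magnify = magnify)
  invisible(path)
}
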