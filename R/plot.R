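#' Plot data and fitted dose-response curves
#'
#' Observed responses and the fitted curve per covariate level, on log10
#' axes (the control group is drawn at a small positive pseudo-dose so
#' it stays visible on the log scale).
#'
#' @param dataset an [mn_dataset] in individual form.
#' @param fit an [mn_fit] for that dataset.
#' @param ces optional critical effect size; when given, the per-level
#'   benchmark doses are marked with vertical dashed lines.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(dataset, fit, ces = NULL) {
  stopifnot(inherits(dataset, "mn_dataset"), inherits(fit, "mn_fit"))
  df <- dataset$data
  pos <- df$dose[df$dose > 0]
  x0 <- min(pos) / 4
  pts <- data.frame(dose = pmax(df$dose, x0),
                    response = if (dataset$form == "individual")
                      df$response else df$mean,
                    level = df$covariate_level)
  grid <- exp(seq(log(x0), log(max(df$dose)), length.out = 200))
  curves <- do.call(rbind, lapply(dataset$levels, function(l)
    data.frame(dose = grid,
               response = predict_response(fit$params, l,
                                           c(0, grid[-1])),
               level = l)))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$dose,
                                         y = .data$response,
                                         colour = .data$level)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0("dose (", dataset$units, ")"),
                  y = dataset$endpoint, colour = "level")
  if (!is.null(ces)) {
    bmds <- data.frame(
      level = dataset$levels,
      bmd = vapply(dataset$levels, function(l)
        compute_bmd(fit$params, l, ces), 0))
    bmds <- bmds[is.finite(bmds$bmd), , drop = FALSE]
    if (nrow(bmds))
      p <- p + ggplot2::geom_vline(
        data = bmds,
        ggplot2::aes(xintercept = .data$bmd, colour = .data$level),
        linetype = "dashed", show.legend = FALSE)
  }
  p
}

#' BMDL-BMDU interval plot
#'
#' One horizontal segment per family and covariate level from BMDL to
#' BMDU on a log10 dose axis — the at-a-glance comparison of BMD
#' precision across families and subgroups.
#'
#' @param estimates list of [mn_bmd] objects (e.g.
#'   `report$estimates` from [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_bmd_intervals <- function(estimates) {
  tab <- do.call(rbind, lapply(unname(estimates), function(e)
    data.frame(family = e$family, level = e$level, bmd = e$bmd,
               bmdl = e$bmdl, bmdu = e$bmdu)))
  tab$row <- paste(tab$family, tab$level, sep = " / ")
  tab$bmdu_plot <- ifelse(is.finite(tab$bmdu), tab$bmdu,
                          max(tab$bmdl, na.rm = TRUE) * 100)
  ggplot2::ggplot(tab, ggplot2::aes(y = .data$row)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$bmdl,
                                       xend = .data$bmdu_plot,
                                       yend = .data$row)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$bmd)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (mg/kg)", y = NULL)
}
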