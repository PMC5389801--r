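#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_histogram
#'   geom_vline geom_density labs theme_minimal after_stat
#' @export
ggplot2::autoplot

#' Plot a niche analysis
#'
#' Four standard views of the inequality chain: `"fundamental_existing"` —
#' existing vs fundamental measures with the identity line (the gap below the
#' line is unused fundamental niche); `"standardized"` — histogram of
#' occurrence temperatures on the common fundamental-niche scale with the
#' interval edges at -0.5 and +0.5; `"realized_existing"` — realized vs
#' existing measures with the identity line; `"volumes"` — densities of the
#' decimal log of observed fundamental-niche volumes and of the
#' random-interval null.
#'
#' @param object a `niche_analysis`.
#' @param type which view; default `"fundamental_existing"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot niche_analysis
#' @export
autoplot.niche_analysis <- function(object,
                                    type = c("fundamental_existing",
                                             "standardized",
                                             "realized_existing", "volumes"),
                                    ...) {
  type <- match.arg(type)
  switch(type,
    fundamental_existing = {
      d <- figure_data(object, "fundamental_existing")
      ggplot(d, aes(x = .data$nf_measure, y = .data$existing_measure)) +
        geom_point(alpha = 0.6) +
        geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
        labs(x = "|N_F| (°C)", y = "|N*(t, G)| (°C)",
             title = "Existing vs fundamental niche measures") +
        theme_minimal()
    },
    standardized = {
      d <- figure_data(object, "standardized")
      ggplot(d, aes(x = .data$standardized)) +
        geom_histogram(aes(y = after_stat(.data$density)), bins = 40,
                       fill = "grey70", colour = "grey40") +
        geom_density(colour = "black") +
        geom_vline(xintercept = c(-0.5, 0.5), colour = "red") +
        labs(x = "standardized temperature",
             y = "density",
             title = "Occurrence temperatures on the common niche scale") +
        theme_minimal()
    },
    realized_existing = {
      d <- figure_data(object, "realized_existing")
      ggplot(d, aes(x = .data$existing_measure, y = .data$realized_measure)) +
        geom_point(alpha = 0.6) +
        geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
        labs(x = "|N*(t, G)| (°C)", y = "|N_R(t, G)| (°C)",
             title = "Realized vs existing niche measures") +
        theme_minimal()
    },
    volumes = {
      d <- figure_data(object, "volumes")
      ggplot(d, aes(x = .data$log10_volume, colour = .data$source)) +
        geom_density() +
        labs(x = "log10 niche volume (°C)", y = "density",
             title = "Observed vs random-interval niche volumes") +
        theme_minimal()
    }
  )
}
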