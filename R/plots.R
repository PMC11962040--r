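# Quick-look track figures.

#' Plot GPS tracks
#'
#' Draws fix paths per individual, optionally coloured by trip number or
#' decoded behavioural label when those columns are present, with the colony
#' marked.
#'
#' @param fixes A fix tibble; columns `trip` or `label` are used for colour
#'   when present (in that order of preference, overridable via `colour_by`).
#' @param colony Optional colony coordinates `c(lat, lon)`.
#' @param colour_by Optional column name to colour by.
#' @return A ggplot object.
#' @export
plot_track <- function(fixes, colony = NULL, colour_by = NULL) {
  fixes <- as_tibble(fixes)
  if (is.null(colour_by)) {
    colour_by <- intersect(c("label", "trip"), names(fixes))[1]
  }
  p <- ggplot(fixes, aes(x = .data$lon, y = .data$lat, group = .data$individual_id))
  if (!is.null(colour_by) && !is.na(colour_by)) {
    p <- p + geom_path(aes(colour = factor(.data[[colour_by]])), linewidth = 0.3) +
      labs(colour = colour_by)
  } else {
    p <- p + geom_path(linewidth = 0.3, colour = "steelblue")
  }
  if (!is.null(colony)) {
    colony <- .as_colony(colony)
    p <- p + annotate("point", x = colony[2], y = colony[1],
                      shape = 17, size = 3, colour = "black")
  }
  p + coord_quickmap() + labs(x = "longitude", y = "latitude") + theme_minimal()
}
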