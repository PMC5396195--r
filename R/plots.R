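#' Site-level risk bars with levels of concern
#'
#' Percent-of-LD50 bars per site for one exposure route, partitioned
#' into hazard from compounds sprayed during bloom versus not sprayed,
#' with the relevant regulatory levels of concern drawn as horizontal
#' lines (EPA 40% and EFSA 20% of contact LD50; EFSA 3% of oral LD50).
#'
#' @param risk Site risk tibble from [site_risk()].
#' @param route `"contact"` or `"oral"`.
#' @param thresholds A [loc_thresholds()] object.
#' @return A ggplot object.
#' @export
plot_site_risk <- function(risk, route = c("contact", "oral"),
                           thresholds = loc_thresholds()) {
  route <- match.arg(route)
  pct_col <- paste0("pct_ld50_", route)
  frac_col <- paste0("nonspray_fraction_", route)
  d <- risk |>
    transmute(.data$site_id,
              `not sprayed during bloom` =
                .data[[pct_col]] * .data[[frac_col]],
              `sprayed during bloom` =
                .data[[pct_col]] * (1 - .data[[frac_col]])) |>
    tidyr::pivot_longer(-"site_id", names_to = "source",
                        values_to = "pct")
  locs <- if (route == "contact") {
    tibble(agency = c("EPA acute contact", "EFSA acute contact"),
           pct = 100 * c(thresholds$epa_acute_contact,
                         thresholds$efsa_acute_contact))
  } else {
    tibble(agency = "EFSA chronic oral",
           pct = 100 * thresholds$efsa_chronic_oral)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site_id, y = .data$pct,
                                  fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = locs,
                        ggplot2::aes(yintercept = .data$pct,
                                     colour = .data$agency),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(
      `sprayed during bloom` = "grey75",
      `not sprayed during bloom` = "grey35")) +
    ggplot2::labs(x = NULL, y = sprintf("%% of %s LD50", route),
                  fill = NULL, colour = "level of concern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Stacked pollen composition bars
#'
#' @param abundance Long abundance tibble from [pollen_abundance()].
#' @return A ggplot object.
#' @export
plot_pollen_composition <- function(abundance) {
  ggplot2::ggplot(abundance,
                  ggplot2::aes(x = .data$site_id,
                               y = .data$rel_abundance,
                               fill = .data$morphotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
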