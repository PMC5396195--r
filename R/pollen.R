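#' Morphotypes retained under the sporadic-pollen rule
#'
#' A morphotype is retained iff its relative abundance reaches the
#' threshold (default 3%) on at least one site's slide; everything else
#' is sporadic and pooled into the `"other"` category. The comparison is
#' `>=`, so a morphotype at exactly 3% on one slide is retained
#' everywhere. A threshold of 0 retains every morphotype observed with a
#' positive count.
#'
#' @param pollen Pollen count tibble as from [read_pollen()].
#' @param threshold Relative-abundance cutoff as a fraction (default
#'   0.03).
#' @return Character vector of retained morphotype names.
#' @export
classify_sporadic <- function(pollen, threshold = 0.03) {
  if (nrow(pollen) == 0) abort("Pollen table is empty.")
  totals <- pollen_totals(pollen)
  if (any(totals$total_counted == 0)) {
    abort("Every site must have a positive grain total.")
  }
  pollen |>
    left_join(totals, by = "site_id") |>
    mutate(rel = .data$count / .data$total_counted) |>
    group_by(.data$morphotype) |>
    summarise(retained = any(.data$rel >= .env$threshold &
                               .data$count > 0),
              .groups = "drop") |>
    filter(.data$retained) |>
    pull("morphotype") |>
    sort()
}

#' Relative abundance of retained morphotypes, with sporadic pooling
#'
#' @param pollen Pollen count tibble as from [read_pollen()].
#' @param retained Retained morphotypes; computed with
#'   [classify_sporadic()] at `threshold` when `NULL`.
#' @param threshold Passed to [classify_sporadic()] when `retained` is
#'   `NULL`.
#' @return Long tibble `site_id`, `morphotype` (retained names plus
#'   `"other"`), `rel_abundance`; fractions sum to 1 within each site.
#' @export
pollen_abundance <- function(pollen, retained = NULL, threshold = 0.03) {
  if (is.null(retained)) retained <- classify_sporadic(pollen, threshold)
  pollen |>
    mutate(morphotype = ifelse(.data$morphotype %in% retained,
                               .data$morphotype, "other")) |>
    group_by(.data$site_id, .data$morphotype) |>
    summarise(count = sum(.data$count), .groups = "drop_last") |>
    mutate(rel_abundance = .data$count / sum(.data$count)) |>
    ungroup() |>
    select("site_id", "morphotype", "rel_abundance")
}

#' Per-site pollen composition metrics
#'
#' Normalises morphotype counts to relative abundances and derives the
#' focal-crop pollen fraction (the focal morphotype's share of all
#' grains, whether or not it is retained), the pooled sporadic
#' (`"other"`) fraction, and pollen richness — the number of retained
#' morphotypes present with a positive count at the site. The sporadic
#' pool never counts toward richness.
#'
#' @param pollen Pollen count tibble as from [read_pollen()].
#' @param retained Retained morphotypes; computed with
#'   [classify_sporadic()] at `threshold` when `NULL`.
#' @param focal Focal-crop morphotype name (default `"Malus"`).
#' @param threshold Passed to [classify_sporadic()] when `retained` is
#'   `NULL`.
#' @return A tibble `site_id`, `total_counted`, `richness`,
#'   `focal_fraction`, `other_fraction`.
#' @export
#' @examples
#' pollen <- tibble::tibble(
#'   site_id = "S1", morphotype = c("Malus", "Rhamnus"),
#'   count = c(150L, 150L))
#' pollen_composition(pollen)
pollen_composition <- function(pollen, retained = NULL, focal = "Malus",
                               threshold = 0.03) {
  if (is.null(retained)) retained <- classify_sporadic(pollen, threshold)
  totals <- pollen_totals(pollen)
  if (any(totals$total_counted == 0)) {
    abort("Every site must have a positive grain total.")
  }
  pollen |>
    group_by(.data$site_id) |>
    summarise(
      total_counted = sum(.data$count),
      richness = sum(.data$count > 0 &
                       .data$morphotype %in% retained),
      focal_fraction = sum(.data$count[.data$morphotype == .env$focal]) /
        sum(.data$count),
      other_fraction = sum(.data$count[!.data$morphotype %in% retained]) /
        sum(.data$count),
      .groups = "drop"
    )
}
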