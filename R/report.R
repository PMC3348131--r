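#' Per-site property distributions across an ensemble
#'
#' For every reference-site label, collects one value per conformer of
#' each pocket property (SiteScore, Dscore, volume, balance) and computes
#' the five-number boxplot summary. When a conformer holds several pockets
#' with the same label, its highest-SiteScore pocket supplies the values.
#' Only automatic assignments contribute; ambiguous ones are excluded.
#'
#' @param assignments Assignment table from [track_ensemble()].
#' @param pockets Ensemble pocket tibble from [detect_ensemble_pockets()].
#' @param properties Property columns to summarise.
#' @return Tibble (label, property, n_conformers, min, q1, median, q3,
#'   max, values list-column). Quartiles use linear interpolation between
#'   order statistics (type 7).
#' @export
property_distributions <- function(assignments, pockets,
                                   properties = c("site_score", "d_score",
                                                  "volume", "balance")) {
  joined <- dplyr::inner_join(
    dplyr::filter(assignments, .data$status == "assigned"),
    pockets,
    by = c("conformer_id", "pocket_rank" = "rank"))
  if (nrow(joined) == 0) {
    return(tibble::tibble(label = character(0), property = character(0),
                          n_conformers = integer(0), min = numeric(0),
                          q1 = numeric(0), median = numeric(0),
                          q3 = numeric(0), max = numeric(0),
                          values = list()))
  }
  best <- joined |>
    dplyr::group_by(.data$label, .data$conformer_id) |>
    dplyr::slice_max(.data$site_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  long <- tidyr::pivot_longer(
    best[, c("label", "conformer_id", properties)],
    cols = dplyr::all_of(properties), names_to = "property",
    values_to = "value")
  long |>
    dplyr::group_by(.data$label, .data$property) |>
    dplyr::summarise(
      n_conformers = dplyr::n(),
      min = min(.data$value),
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = quantile(.data$value, 0.50, type = 7, names = FALSE),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      max = max(.data$value),
      values = list(setNames(.data$value, .data$conformer_id)),
      .groups = "drop")
}

#' Select the conformer to dock against for a site
#'
#' Among the (up to) five conformers with the highest
#' SiteScores for the label, pick the one whose pocket has the largest
#' volume — a bigger cavity compensates for the lack of side-chain
#' flexibility in rigid docking. Score ties at rank five admit all tied
#' candidates before the volume test; remaining volume ties go to the
#' lowest conformer id.
#'
#' @param label Reference-site label.
#' @param assignments Assignment table from [track_ensemble()].
#' @param pockets Ensemble pocket tibble.
#' @return One-row tibble: `label`, `conformer_id`, `site_score`, `volume`.
#' @export
select_docking_conformer <- function(label, assignments, pockets) {
  cand <- dplyr::inner_join(
    dplyr::filter(assignments, .data$status == "assigned",
                  .data$label == !!label),
    pockets,
    by = c("conformer_id", "pocket_rank" = "rank"))
  if (nrow(cand) == 0) stop("label not found in any conformer: ", label)
  best <- cand |>
    dplyr::group_by(.data$conformer_id) |>
    dplyr::slice_max(.data$site_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  scores <- sort(best$site_score, decreasing = TRUE)
  cut <- scores[min(5, length(scores))]
  top <- best[best$site_score >= cut, , drop = FALSE]
  top <- top[order(-top$volume, top$conformer_id), , drop = FALSE]
  tibble::tibble(label = label, conformer_id = top$conformer_id[1],
                 site_score = top$site_score[1], volume = top$volume[1])
}

#' Overlay crystal-structure properties on ensemble distributions
#'
#' Joins externally supplied per-structure property values (e.g. from
#' crystal structures) to the ensemble summaries and flags each value as
#' within, below or above the ensemble's observed range.
#'
#' @param reference_values Tibble with `structure_id`, `label`,
#'   `property`, `value`.
#' @param distributions Output of [property_distributions()].
#' @return Overlay tibble with a `flag` column (`within` / `below` /
#'   `above`); rows with labels absent from the distributions are dropped
#'   with a warning.
#' @export
crystal_compare <- function(reference_values, distributions) {
  known <- unique(distributions$label)
  unknown <- setdiff(unique(reference_values$label), known)
  if (length(unknown) > 0) {
    warning("skipping unknown label(s): ", paste(unknown, collapse = ", "))
    reference_values <-
      reference_values[reference_values$label %in% known, , drop = FALSE]
  }
  out <- dplyr::inner_join(
    reference_values,
    distributions[, c("label", "property", "min", "max")],
    by = c("label", "property"))
  dplyr::mutate(out, flag = dplyr::case_when(
    .data$value < .data$min ~ "below",
    .data$value > .data$max ~ "above",
    TRUE ~ "within"))
}
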