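#' Build a reference site catalog
#'
#' Maps single-letter (or other unique) labels to the geometric centres of
#' the pockets of a reference structure, in the common superposed frame.
#' All later conformer pockets are identified against these centres.
#'
#' @param pockets Pocket tibble (needs `center_x`, `center_y`, `center_z`),
#'   or a data frame with `label`, `x`, `y`, `z` columns.
#' @param labels Labels for the pockets, one per row (ignored when the
#'   input already has a `label` column).
#' @return A `site_catalog` tibble: `label`, `x`, `y`, `z`.
#' @export
build_catalog <- function(pockets, labels = NULL) {
  if (all(c("label", "x", "y", "z") %in% names(pockets))) {
    out <- tibble::as_tibble(pockets[, c("label", "x", "y", "z")])
  } else {
    stopifnot(!is.null(labels), length(labels) == nrow(pockets))
    out <- tibble::tibble(label = as.character(labels),
                          x = pockets$center_x, y = pockets$center_y,
                          z = pockets$center_z)
  }
  if (anyDuplicated(out$label)) {
    stop("duplicate catalog label(s): ",
         paste(unique(out$label[duplicated(out$label)]), collapse = ", "))
  }
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop("catalog centres must be finite")
  }
  class(out) <- c("site_catalog", class(out))
  out
}

#' Assign a pocket to a reference site
#'
#' Geometric-centre matching: the pocket centre is compared with every
#' catalog centre. Nearest distance at most `auto_cutoff` assigns the
#' label automatically (if two or more reference centres fall inside the
#' cutoff the pocket straddles them and gets a merged label joining them
#' alphabetically with `_`, e.g. `"C_E"`). A nearest distance in
#' `(auto_cutoff, new_cutoff]` is flagged `ambiguous` with the nearest
#' label as a suggestion for human review — automation never silently
#' guesses in this band. Beyond `new_cutoff` everywhere, the pocket is
#' `NEW`. Both boundaries are inclusive on the lower-status side.
#'
#' @param center Numeric 3-vector, the pocket's geometric centre in the
#'   catalog's superposed frame.
#' @param catalog A [build_catalog()] table.
#' @param auto_cutoff Automatic-assignment distance (Angstrom).
#' @param new_cutoff Distance beyond which a site is new (Angstrom).
#' @return One-row tibble: `label`, `status` (`assigned` / `ambiguous` /
#'   `new`), `match_distance` (NA for new).
#' @export
assign_site <- function(center, catalog, auto_cutoff = 3.75,
                        new_cutoff = 10) {
  if (nrow(catalog) == 0) stop("empty site catalog")
  stopifnot(length(center) == 3, all(is.finite(center)))
  d <- sqrt((catalog$x - center[1])^2 + (catalog$y - center[2])^2 +
              (catalog$z - center[3])^2)
  within <- which(d <= auto_cutoff)
  if (length(within) >= 1) {
    lab <- if (length(within) >= 2) {
      paste(sort(catalog$label[within]), collapse = "_")
    } else {
      catalog$label[within]
    }
    return(tibble::tibble(label = lab, status = "assigned",
                          match_distance = min(d)))
  }
  dmin <- min(d)
  if (dmin <= new_cutoff) {
    nearest <- catalog$label[which.min(d)]
    return(tibble::tibble(label = nearest, status = "ambiguous",
                          match_distance = dmin))
  }
  tibble::tibble(label = "NEW", status = "new", match_distance = NA_real_)
}

#' Track pocket identity across an ensemble
#'
#' Assigns every pocket of every conformer against the reference catalog
#' and tabulates per-label persistence: the fraction of conformers that
#' contain at least one automatically assigned pocket with that label.
#' Ambiguous assignments are reported but never counted as assigned; a
#' conformer contributing two pockets with the same label counts once.
#'
#' @param pockets Tibble of ensemble pockets with `conformer_id`, `rank`,
#'   `center_x/y/z` (from [detect_ensemble_pockets()]).
#' @param catalog A [build_catalog()] table in the same superposed frame.
#' @param n_conformers Ensemble size (the persistence denominator —
#'   conformers without pockets still count).
#' @param auto_cutoff,new_cutoff See [assign_site()].
#' @param superposed Set `FALSE` if the pockets are not in the catalog
#'   frame; this is an error.
#' @return List with `assignments` (conformer_id, pocket_rank, label,
#'   status, match_distance) and `persistence` (label, n_present,
#'   persistence; catalog labels always present, merged labels as observed;
#'   ensemble size as attribute `ensemble_size`).
#' @export
track_ensemble <- function(pockets, catalog, n_conformers,
                           auto_cutoff = 3.75, new_cutoff = 10,
                           superposed = TRUE) {
  if (!superposed) {
    stop("pockets must be in the catalog's superposed frame")
  }
  stopifnot(n_conformers >= 1)
  assignments <- purrr::map_dfr(seq_len(nrow(pockets)), function(k) {
    a <- assign_site(c(pockets$center_x[k], pockets$center_y[k],
                       pockets$center_z[k]),
                     catalog, auto_cutoff, new_cutoff)
    dplyr::mutate(a, conformer_id = pockets$conformer_id[k],
                  pocket_rank = pockets$rank[k], .before = 1)
  })
  if (nrow(assignments) == 0) {
    assignments <- tibble::tibble(conformer_id = integer(0),
                                  pocket_rank = integer(0),
                                  label = character(0), status = character(0),
                                  match_distance = numeric(0))
  }
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  labels <- union(catalog$label, sort(unique(assigned$label)))
  n_present <- vapply(labels, function(lb) {
    length(unique(assigned$conformer_id[assigned$label == lb]))
  }, integer(1))
  persistence <- tibble::tibble(label = labels,
                                n_present = unname(n_present),
                                persistence = unname(n_present) / n_conformers)
  attr(persistence, "ensemble_size") <- n_conformers
  list(assignments = assignments, persistence = persistence)
}
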