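#' Pocket-lining mask of one conformer
#'
#' Flags each residue 1 when any of its atoms lies within `cutoff`
#' (inclusive) of any pocket sphere centre, 0 otherwise. Distances are
#' atom-to-sphere-centre; sphere radii are not subtracted.
#'
#' @param s The reference `mol_structure` (defines the residue set).
#' @param spheres Numeric matrix of sphere centres (rows; may have zero
#'   rows), or a data frame with `x`, `y`, `z` columns.
#' @param cutoff Lining distance in Angstrom.
#' @return Tibble `key`, `lining` (integer 0/1), one row per residue in
#'   structure order.
#' @export
lining_mask <- function(s, spheres, cutoff = 3.75) {
  if (is.data.frame(spheres)) spheres <- as.matrix(spheres[, c("x", "y", "z")])
  keys <- residue_table(s)$key
  if (is.null(spheres) || nrow(spheres) == 0) {
    return(tibble::tibble(key = keys, lining = 0L))
  }
  d <- cpp_surface_distance(coords(s), spheres, rep(0, nrow(spheres)))
  hit <- unique(atom_residue_keys(s)[d <= cutoff])
  tibble::tibble(key = keys, lining = as.integer(keys %in% hit))
}

#' Per-residue pocket-lining propensity (Provar)
#'
#' Elementwise mean of per-conformer lining masks: each residue's
#' probability of bordering a predicted pocket across the ensemble,
#' computed as the mask sum divided by the number of conformers.
#'
#' @param masks List of [lining_mask()] tibbles over an identical residue
#'   set (order included).
#' @param cutoff The lining cutoff the masks were built with (metadata).
#' @return A `provar_profile` tibble: `key`, `probability`; attributes
#'   `ensemble_size` and `distance_threshold`.
#' @export
propensity <- function(masks, cutoff = 3.75) {
  stopifnot(length(masks) >= 1)
  keys <- masks[[1]]$key
  for (m in masks) {
    if (!identical(m$key, keys)) {
      stop("masks cover inconsistent residue sets")
    }
  }
  prob <- Reduce(`+`, lapply(masks, function(m) m$lining)) / length(masks)
  out <- tibble::tibble(key = keys, probability = prob)
  attr(out, "ensemble_size") <- length(masks)
  attr(out, "distance_threshold") <- cutoff
  class(out) <- c("provar_profile", class(out))
  out
}

#' Colour-scale limits of a Provar profile
#'
#' First and third quartiles of the per-residue probability distribution
#' (linear interpolation between order statistics, the common "type 7"
#' convention), used as the white and red limits of the visualisation
#' spectrum.
#'
#' @param profile A `provar_profile`.
#' @return Named numeric vector `c(low = Q1, high = Q3)`.
#' @export
scale_limits <- function(profile) {
  stopifnot(nrow(profile) > 0)
  q <- quantile(profile$probability, c(0.25, 0.75), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Annotate a structure with Provar probabilities
#'
#' Writes each residue's pocket-lining probability into the B-factor
#' column of every one of its atoms (two decimals), for rendering on a
#' white-to-red spectrum between the [scale_limits()] quartiles.
#'
#' @param s The reference `mol_structure`; every residue must appear in
#'   `profile`.
#' @param profile A `provar_profile`.
#' @param file Optional output path.
#' @return PDB-format text with annotated B-factors; the colour limits are
#'   attached as attribute `limits`.
#' @export
annotate_structure <- function(s, profile, file = NULL) {
  keys <- residue_table(s)$key
  missing <- setdiff(keys, profile$key)
  if (length(missing) > 0) {
    stop("profile does not cover residue(s): ",
         paste(head(missing, 5), collapse = ", "))
  }
  vals <- setNames(profile$probability, profile$key)[keys]
  out <- write_pdb(s, residue_values = vals, file = file)
  attr(out, "limits") <- scale_limits(profile)
  out
}
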