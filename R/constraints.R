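#' Default constraint tolerance policy
#'
#' Per-category half-widths (Angstrom) added either side of the observed
#' template distance, and the detection cutoffs. Categories from tightest
#' to loosest: covalent bonds, 1-3 (angle) pairs, hydrogen bonds, nonbonded
#' contacts — stronger interactions get tighter constraints.
#'
#' @param covalent,angle_1_3,hbond,contact Tolerances in Angstrom.
#' @param contact_cutoff Nonbonded-contact detection cutoff (Angstrom).
#' @param hbond_cutoff Donor-acceptor N/O distance cutoff (Angstrom).
#' @param bond_scale Two heavy atoms are bonded when their distance is below
#'   `bond_scale` times the sum of their covalent radii.
#' @return A named list usable as the `policy` of [build_constraints()].
#' @export
constraint_policy <- function(covalent = 0.05, angle_1_3 = 0.10, hbond = 0.30,
                              contact = 1.5, contact_cutoff = 6.0,
                              hbond_cutoff = 3.5, bond_scale = 1.2) {
  list(covalent = covalent, angle_1_3 = angle_1_3, hbond = hbond,
       contact = contact, contact_cutoff = contact_cutoff,
       hbond_cutoff = hbond_cutoff, bond_scale = bond_scale)
}

#' Build a distance-constraint library from a template structure
#'
#' Enumerates atom pairs of the template and brackets each observed distance
#' with category-dependent tolerances: covalent pairs (within bonding
#' distance by element covalent radii) tightest, then 1-3 pairs sharing a
#' bonded neighbour, then N/O hydrogen-bond pairs, then all remaining
#' nonbonded contacts within the cutoff.
#'
#' @param s A `mol_structure` with at least 2 atoms.
#' @param policy Tolerance table from [constraint_policy()].
#' @return A `constraint_set`: list with `template`, `constraints` (tibble
#'   `i`, `j`, `observed`, `lower`, `upper`, `category`) and `policy`.
#' @export
build_constraints <- function(s, policy = constraint_policy()) {
  if (n_atoms(s) < 2) stop("need at least 2 atoms to build constraints")
  xyz <- coords(s)
  n <- nrow(xyz)
  dmat <- as.matrix(stats::dist(xyz))
  el <- s$atoms$element
  rcov <- cov_radius(el)

  pair_idx <- which(upper.tri(dmat) & dmat <= policy$contact_cutoff,
                    arr.ind = TRUE)
  i <- pair_idx[, 1]
  j <- pair_idx[, 2]
  d <- dmat[pair_idx]

  bond_cut <- policy$bond_scale * (rcov[i] + rcov[j])
  is_cov <- d <= bond_cut & d > 0.4

  # adjacency for 1-3 detection
  adj <- vector("list", n)
  ci <- i[is_cov]; cj <- j[is_cov]
  for (k in seq_along(ci)) {
    adj[[ci[k]]] <- c(adj[[ci[k]]], cj[k])
    adj[[cj[k]]] <- c(adj[[cj[k]]], ci[k])
  }
  pk <- paste(i, j)
  one_three <- character(0)
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      one_three <- c(one_three, paste(cmb[1, ], cmb[2, ]))
    }
  }
  is_13 <- !is_cov & pk %in% one_three

  no <- el %in% c("N", "O")
  is_hb <- !is_cov & !is_13 & no[i] & no[j] & d <= policy$hbond_cutoff

  category <- rep("nonbonded-contact", length(d))
  category[is_hb] <- "hbond"
  category[is_13] <- "angle-1-3"
  category[is_cov] <- "covalent"

  tol <- c(covalent = policy$covalent, `angle-1-3` = policy$angle_1_3,
           hbond = policy$hbond, `nonbonded-contact` = policy$contact)[category]

  constraints <- tibble::tibble(
    i = as.integer(i), j = as.integer(j), observed = d,
    lower = pmax(d - unname(tol), 0.1), upper = d + unname(tol),
    category = category
  )
  structure(list(template = s, constraints = constraints, policy = policy),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  tab <- table(x$constraints$category)
  cat(sprintf("<constraint_set> %d constraints over %d atoms (%s)\n",
              nrow(x$constraints), n_atoms(x$template),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Total distance-constraint violation of a coordinate set
#'
#' Sum over all constraints of the distance by which the pair separation
#' falls outside its `[lower, upper]` bounds; the quantity against which
#' candidate conformers are accepted or rejected.
#'
#' @param xyz Numeric n-by-3 coordinate matrix in template atom order.
#' @param cs A `constraint_set`.
#' @return Total violation in Angstrom (0 when all bounds hold).
#' @export
total_violation <- function(xyz, cs) {
  if (nrow(xyz) != n_atoms(cs$template)) {
    stop("coordinate count does not match the constraint template")
  }
  cn <- cs$constraints
  dx <- xyz[cn$j, , drop = FALSE] - xyz[cn$i, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  sum(pmax(0, cn$lower - d) + pmax(0, d - cn$upper))
}
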