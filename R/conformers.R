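#' Chirality signs of the C-alpha centres
#'
#' Sign of the improper determinant det[N-CA, C-CA, CB-CA] for every residue
#' carrying all four atoms; used as a post-hoc guard that constraint
#' correction has not mirrored side chains.
#'
#' @param s A `mol_structure` (atom order defines the residues checked).
#' @param xyz Optional replacement coordinates in the structure's atom order.
#' @return Named numeric vector of +/-1 per checkable residue (may be empty).
#' @export
chirality_signs <- function(s, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(s)
  a <- s$atoms
  key <- atom_residue_keys(s)
  need <- c("N", "CA", "C", "CB")
  sel <- a$atom_name %in% need
  if (!any(sel)) return(setNames(numeric(0), character(0)))
  sp <- split(which(sel), key[sel])
  out <- vapply(sp, function(idx) {
    nm <- a$atom_name[idx]
    if (!all(need %in% nm)) return(NA_real_)
    p <- xyz[idx[match(need, nm)], , drop = FALSE]
    m <- rbind(p[1, ] - p[2, ], p[3, ] - p[2, ], p[4, ] - p[2, ])
    sign(det(m))
  }, numeric(1))
  out[!is.na(out)]
}

# Reflect the CB atoms of residues whose C-alpha improper sign flipped
# across their own N-CA-C plane. The reflection preserves CB's distances
# to those three atoms exactly, so it restores handedness while staying
# close to the constraint-feasible set.
restore_chirality <- function(s, xyz, ref_signs) {
  sgn <- chirality_signs(s, xyz)
  flipped <- names(sgn)[sgn != ref_signs[names(sgn)]]
  if (length(flipped) == 0) return(list(xyz = xyz, n_flipped = 0L))
  a <- s$atoms
  key <- atom_residue_keys(s)
  for (rk in flipped) {
    idx <- which(key == rk)
    nm <- a$atom_name[idx]
    pN <- xyz[idx[nm == "N"][1], ]
    pCA <- xyz[idx[nm == "CA"][1], ]
    pC <- xyz[idx[nm == "C"][1], ]
    iCB <- idx[nm == "CB"][1]
    nrm <- c((pN - pCA)[2] * (pC - pCA)[3] - (pN - pCA)[3] * (pC - pCA)[2],
             (pN - pCA)[3] * (pC - pCA)[1] - (pN - pCA)[1] * (pC - pCA)[3],
             (pN - pCA)[1] * (pC - pCA)[2] - (pN - pCA)[2] * (pC - pCA)[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    xyz[iCB, ] <- xyz[iCB, ] - 2 * sum((xyz[iCB, ] - pCA) * nrm) * nrm
  }
  list(xyz = xyz, n_flipped = length(flipped))
}

#' Generate one conformer by constrained perturbation
#'
#' Displaces every template atom by an isotropic Gaussian of scale
#' `start_magnitude`, then runs randomized-order pairwise-projection
#' correction sweeps until the summed constraint violation reaches
#' `converge_tol` or `max_iter` sweeps have run. Distance constraints are
#' blind to handedness, so after correction any residue whose C-alpha
#' improper sign flipped has its CB reflected back across the N-CA-C plane
#' and correction resumes (a few rounds). The result is accepted when its
#' total violation is at most `reject_threshold`.
#'
#' @param cs A `constraint_set`.
#' @param seed Integer seed; identical seeds give identical conformers.
#' @param start_magnitude Gaussian displacement scale in Angstrom.
#' @param max_iter Maximum correction sweeps.
#' @param reject_threshold Total-violation acceptance bound (Angstrom).
#' @param converge_tol Total violation at which correction stops early.
#' @return A `conformer`: list with `coordinates`, `seed`,
#'   `iterations_used`, `total_violation`, `accepted`.
#' @export
generate_conformer <- function(cs, seed, start_magnitude = 0.75,
                               max_iter = 1000, reject_threshold = 30,
                               converge_tol = 1e-3) {
  stopifnot(max_iter >= 1, start_magnitude >= 0)
  xyz0 <- coords(cs$template)
  cn <- cs$constraints
  ref_signs <- chirality_signs(cs$template)
  res <- with_seed(seed, {
    start <- xyz0 + matrix(rnorm(length(xyz0), sd = start_magnitude),
                           ncol = 3)
    out <- cpp_correct_sweeps(start, cn$i - 1L, cn$j - 1L, cn$lower,
                              cn$upper, as.integer(max_iter), converge_tol)
    iters <- out$iterations
    if (length(ref_signs) > 0) {
      for (round in 1:3) {
        budget <- max_iter - iters
        if (budget < 1) break
        fix <- restore_chirality(cs$template, out$coords, ref_signs)
        if (fix$n_flipped == 0) break
        out <- cpp_correct_sweeps(fix$xyz, cn$i - 1L, cn$j - 1L, cn$lower,
                                  cn$upper, as.integer(budget), converge_tol)
        iters <- iters + out$iterations
      }
    }
    out$iterations <- iters
    out
  })
  structure(list(coordinates = res$coords, seed = seed,
                 iterations_used = res$iterations,
                 total_violation = res$total_violation,
                 accepted = res$total_violation <= reject_threshold),
            class = "conformer")
}

#' Generate a native-like conformational ensemble
#'
#' Repeats [generate_conformer()] with per-member sub-seeds (drawn
#' deterministically from the master seed) until exactly `n` members pass
#' both the total-violation bound and the chirality guard, rejections being
#' regenerated with fresh sub-seeds. Every accepted member is rigidly
#' superposed onto the template before return and its C-alpha RMSD to the
#' template recorded.
#'
#' @param s Template `mol_structure` (cleaned, single chain).
#' @param n Number of conformers to return.
#' @param seed Master integer seed; fully determines the ensemble.
#' @param start_magnitude,max_iter,reject_threshold,converge_tol Passed to
#'   [generate_conformer()].
#' @param policy Constraint tolerances, see [constraint_policy()].
#' @param chirality_min Minimum fraction of residues whose C-alpha improper
#'   sign must match the template (conformers below it are resampled).
#' @param max_attempts Attempt cap before a generation-failure error.
#' @return A `conformer_ensemble`: `template`, `coords` (atoms x 3 x n
#'   array), `info` tibble (conformer_id, seed, iterations, total_violation,
#'   chirality_fraction, ca_rmsd), `superposed = TRUE`.
#' @export
generate_ensemble <- function(s, n = 100, seed = 1, start_magnitude = 0.75,
                              max_iter = 1000, reject_threshold = 30,
                              converge_tol = 1e-3,
                              policy = constraint_policy(),
                              chirality_min = 0.95, max_attempts = 20 * n) {
  stopifnot(n >= 1)
  cs <- build_constraints(s, policy)
  ref_signs <- chirality_signs(s)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                          max_attempts))
  sel <- if (any(s$atoms$atom_name == "CA")) "CA" else NULL

  xyz_list <- vector("list", n)
  info <- vector("list", n)
  got <- 0L
  attempt <- 0L
  while (got < n) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      stop(sprintf(paste0("ensemble generation failed: %d/%d accepted after ",
                          "%d attempts (last total_violation %.3f)"),
                   got, n, max_attempts, conf$total_violation))
    }
    conf <- generate_conformer(cs, sub_seeds[attempt], start_magnitude,
                               max_iter, reject_threshold, converge_tol)
    if (!conf$accepted) next
    chir <- 1.0
    if (length(ref_signs) > 0) {
      sgn <- chirality_signs(s, conf$coordinates)
      chir <- mean(sgn == ref_signs[names(sgn)])
      if (chir < chirality_min) next
    }
    fitted <- superpose(set_coords(s, conf$coordinates), s, selection = sel)
    got <- got + 1L
    xyz_list[[got]] <- coords(fitted$structure)
    info[[got]] <- tibble::tibble(
      conformer_id = got, seed = conf$seed,
      iterations = conf$iterations_used,
      total_violation = conf$total_violation,
      chirality_fraction = chir, ca_rmsd = fitted$rmsd
    )
  }
  arr <- array(unlist(xyz_list), dim = c(n_atoms(s), 3, n))
  structure(list(template = s, coords = arr,
                 info = dplyr::bind_rows(info), superposed = TRUE,
                 params = list(n = n, seed = seed,
                               start_magnitude = start_magnitude,
                               max_iter = max_iter,
                               reject_threshold = reject_threshold,
                               attempts = attempt)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<conformer_ensemble> %d conformers of %s ",
                     "(%d atoms); Ca RMSD to template %.2f-%.2f A\n"),
              dim(x$coords)[3], x$template$source_id, n_atoms(x$template),
              min(x$info$ca_rmsd), max(x$info$ca_rmsd)))
  invisible(x)
}

#' Extract one conformer as a structure
#' @param ensemble A `conformer_ensemble`.
#' @param i Conformer index.
#' @return A `mol_structure` with the conformer's coordinates.
#' @export
conformer_structure <- function(ensemble, i) {
  stopifnot(i >= 1, i <= dim(ensemble$coords)[3])
  s <- set_coords(ensemble$template, ensemble$coords[, , i])
  s$source_id <- sprintf("%s_conf%03d", ensemble$template$source_id, i)
  s
}

#' Per-conformer diagnostics of an ensemble
#' @param x A `conformer_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per conformer: seed, correction iterations,
#'   total violation, chirality fraction and C-alpha RMSD to the template.
#' @export
tidy.conformer_ensemble <- function(x, ...) x$info

#' One-row ensemble summary
#' @param x A `conformer_ensemble`.
#' @param ... Unused.
#' @return Tibble with ensemble size, acceptance-attempt count, and RMSD /
#'   violation summaries.
#' @export
glance.conformer_ensemble <- function(x, ...) {
  tibble::tibble(
    n_conformers = dim(x$coords)[3],
    n_attempts = x$params$attempts,
    max_total_violation = max(x$info$total_violation),
    mean_ca_rmsd = mean(x$info$ca_rmsd),
    max_ca_rmsd = max(x$info$ca_rmsd)
  )
}

#' Write an ensemble as a multi-model PDB
#'
#' @param ensemble A `conformer_ensemble`.
#' @param file Optional output path.
#' @return The multi-model PDB text (MODEL/ENDMDL framing), invisibly when
#'   `file` is given.
#' @export
write_ensemble_pdb <- function(ensemble, file = NULL) {
  n <- dim(ensemble$coords)[3]
  blocks <- vapply(seq_len(n), function(i) {
    txt <- write_pdb(conformer_structure(ensemble, i))
    lines <- strsplit(txt, "\n")[[1]]
    lines <- lines[!grepl("^END\\s*$", lines)]
    paste0(sprintf("MODEL     %4d\n", i),
           paste(lines, collapse = "\n"), "\nENDMDL")
  }, character(1))
  out <- paste0(paste(blocks, collapse = "\n"), "\nEND\n")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", out), file)
    return(invisible(out))
  }
  out
}
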