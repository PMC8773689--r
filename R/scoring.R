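# NOE-consistency scoring and ranking of docked models.
#
# The primary criterion is the mean, over a set of protein probe protons
# known to contact the 2-O-sulfated uronate protons, of the distance from
# each probe to its nearest uronate proton (IdoA2S.H2 / dUA2S.H3). A
# secondary score uses the glucosamine H3/H5 protons and is reported as a
# consistency check (uronate score < glucosamine score for NOE-consistent
# models). Probe ambiguity groups (e.g. the K68/91 lysine pair) contribute a
# single value: the minimum over the whole group.

#' Probe and acceptor selector tables
#'
#' `ctd_probes()` / `ntd_probes()` return the probe protons of the two
#' binding sites; `uronate_acceptors()` and `glucosamine_acceptors()` return
#' the ligand proton selectors of the primary and secondary NOE scores.
#' Selector columns are globs matched against residue/atom names; `group`
#' merges rows into one ambiguity group (scored by the group minimum).
#'
#' @return tibble with columns `group`, `protein_res`, `protein_atom` (probe
#'   tables) or `ligand_res`, `ligand_atom` (acceptor tables).
#' @export
ctd_probes <- function() {
  tibble(group = c("W59.HE1", "W74.HE1", "K68/91.HZ", "K68/91.HZ", "K111.HN"),
         protein_res = c(59, 74, 68, 91, 111),
         protein_atom = c("HE1", "HE1", "HZ*", "HZ*", "H"))
}

#' @rdname ctd_probes
#' @export
ntd_probes <- function() {
  tibble(group = c("W18.HE1", "W20.HE1", "R52.HE", "K54.HZ"),
         protein_res = c(18, 20, 52, 54),
         protein_atom = c("HE1", "HE1", "HE", "HZ*"))
}

#' @rdname ctd_probes
#' @export
uronate_acceptors <- function() {
  tibble(ligand_res = c("IdoA2S", "dUA2S"), ligand_atom = c("H2", "H3"))
}

#' @rdname ctd_probes
#' @export
glucosamine_acceptors <- function() {
  tibble(ligand_res = c("GlcNS6S", "GlcNS6S"), ligand_atom = c("H3", "H5"))
}

resolve_acceptors <- function(ligand, acceptors) {
  lat <- ligand$atoms
  idx <- unique(unlist(purrr::map(seq_len(nrow(acceptors)), function(k)
    which(glob_match(acceptors$ligand_res[k], lat$res_name) &
            glob_match(acceptors$ligand_atom[k], lat$atom)))))
  if (length(idx) == 0) abort("acceptor selectors match no ligand atom")
  sort(idx)
}

#' NOE-consistency score of a pose
#'
#' For each probe group, the minimum distance from any of its protons to any
#' acceptor proton; the score is the arithmetic mean over probe groups.
#' Probes that resolve to no atom are excluded with a warning and reported.
#'
#' @param xyz_protein,xyz_ligand pose coordinates.
#' @param protein protein atom tibble (for probe resolution).
#' @param ligand `glycan_chain` (for acceptor resolution).
#' @param probes probe tibble (see [ctd_probes()]).
#' @param acceptors acceptor tibble (see [uronate_acceptors()]).
#' @return list: `score` (A), `per_probe` tibble (`group`, `distance`),
#'   `n_unresolved`.
#' @export
noe_score <- function(xyz_protein, xyz_ligand, protein, ligand,
                      probes = ctd_probes(), acceptors = uronate_acceptors()) {
  xyz_protein <- as.matrix(xyz_protein); xyz_ligand <- as.matrix(xyz_ligand)
  acc <- resolve_acceptors(ligand, acceptors)
  accx <- xyz_ligand[acc, , drop = FALSE]
  groups <- unique(probes$group)
  dists <- numeric(0); labs <- character(0); unresolved <- 0L
  for (g in groups) {
    rows <- probes[probes$group == g, ]
    idx <- unique(unlist(purrr::map(seq_len(nrow(rows)), function(k)
      which(protein$res_id == rows$protein_res[k] &
              glob_match(rows$protein_atom[k], protein$atom)))))
    if (length(idx) == 0) {
      warn(paste0("probe '", g, "' resolves to no protein atom; excluded"))
      unresolved <- unresolved + 1L
      next
    }
    d <- cpp_min_dist(xyz_protein[idx, , drop = FALSE], accx)
    dists <- c(dists, d); labs <- c(labs, g)
  }
  if (length(dists) == 0) abort("no probe resolved; cannot score")
  list(score = mean(dists), per_probe = tibble(group = labs, distance = dists),
       n_unresolved = unresolved)
}

#' Score every pose of a docking run
#'
#' Computes, per pose: the primary uronate-proton NOE-consistency score
#' (optionally augmented with named special distances such as the
#' K45 Hz - dUA2S H4 contact of the NTD site, averaged in with equal
#' weight), the secondary glucosamine score, the surrogate binding energy,
#' and the backbone RMSD to the starting protein structure.
#'
#' @param result a `docking_result` from [dock()].
#' @param probes probe table, default [ctd_probes()].
#' @param special optional contact-style tibble (columns `protein_res`,
#'   `protein_atom`, `ligand_res`, `ligand_atom`): each row adds one
#'   min-distance term to the primary score.
#' @return tibble of class `pose_scores`: `pose_id`, `noe_uronate_A`,
#'   `noe_gluc_A`, special distance columns, `energy`, `backbone_rmsd_A`,
#'   `uronate_lt_gluc` flag.
#' @export
score_poses <- function(result, probes = ctd_probes(), special = NULL) {
  protein <- attr(result, "protein")
  ligand <- attr(result, "ligand")
  xyzP0 <- as.matrix(protein[, c("x", "y", "z")])
  bb <- which(protein$backbone %||% (protein$atom %in% BACKBONE_ATOMS))
  rows <- purrr::map(seq_len(nrow(result)), function(i) {
    pose <- result$pose[[i]]
    ur <- noe_score(pose$xyz_protein, pose$xyz, protein, ligand,
                    probes, uronate_acceptors())
    gl <- noe_score(pose$xyz_protein, pose$xyz, protein, ligand,
                    probes, glucosamine_acceptors())
    prim <- ur$per_probe$distance
    sp <- numeric(0)
    if (!is.null(special)) {
      for (k in seq_len(nrow(special))) {
        ip <- which(protein$res_id == as.integer(special$protein_res[k]) &
                      glob_match(special$protein_atom[k], protein$atom))
        il <- which(glob_match(special$ligand_res[k], ligand$atoms$res_name) &
                      glob_match(special$ligand_atom[k], ligand$atoms$atom))
        if (length(ip) == 0 || length(il) == 0)
          abort(paste0("special distance ", k, " resolves to no atom pair"))
        sp[k] <- cpp_min_dist(pose$xyz_protein[ip, , drop = FALSE],
                              pose$xyz[il, , drop = FALSE])
      }
      names(sp) <- paste0(special$protein_res, ".", special$protein_atom,
                          "-", special$ligand_res, ".", special$ligand_atom)
    }
    e <- surrogate_binding_energy(protein, pose$xyz_protein, ligand, pose$xyz)
    out <- tibble(pose_id = result$start[i],
                  noe_uronate_A = mean(c(prim, sp)),
                  noe_gluc_A = gl$score,
                  energy = e$energy,
                  backbone_rmsd_A = backbone_deviation(
                    pose$xyz_protein[bb, , drop = FALSE], xyzP0[bb, , drop = FALSE]),
                  uronate_lt_gluc = mean(c(prim, sp)) < gl$score,
                  clash = e$clash)
    for (nm in names(sp)) out[[nm]] <- sp[[nm]]
    out
  })
  out <- bind_rows(rows)
  class(out) <- c("pose_scores", class(out))
  out
}

#' Select and rank the top fraction of models
#'
#' Sorts by the primary NOE-consistency score (ascending), retains
#' `ceiling(top_fraction * N)` models, then orders the retained set by
#' surrogate binding energy (most favorable first). Ties are broken by pose
#' id, making the ranking stable under input shuffling.
#'
#' @param scores a `pose_scores` tibble (or any tibble with `pose_id`,
#'   `noe_uronate_A`, `energy`).
#' @param top_fraction fraction in (0, 1], default 0.10.
#' @return the full table with `selected` flag and `rank` (NA for unselected
#'   models), selected rows first in energy order.
#' @export
rank_models <- function(scores, top_fraction = 0.10) {
  if (nrow(scores) == 0) abort("no scores to rank")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    abort("top_fraction must be in (0, 1]")
  n_keep <- ceiling(top_fraction * nrow(scores))
  ord <- order(scores$noe_uronate_A, scores$pose_id)
  keep_ids <- scores$pose_id[ord][seq_len(n_keep)]
  scores$selected <- scores$pose_id %in% keep_ids
  sel <- scores[scores$selected, ]
  sel <- sel[order(sel$energy, sel$pose_id), ]
  sel$rank <- seq_len(nrow(sel))
  rest <- scores[!scores$selected, ]
  if (nrow(rest) > 0) rest$rank <- NA_integer_
  out <- bind_rows(sel, rest)
  class(out) <- unique(c("pose_scores", class(out)))
  out
}

#' Backbone deviation after optimal superposition
#'
#' RMSD between matched coordinate sets after Kabsch superposition; zero for
#' identical structures and invariant under rigid motion.
#'
#' @param xyz,xyz_ref matched n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
backbone_deviation <- function(xyz, xyz_ref) {
  kabsch(as.matrix(xyz), as.matrix(xyz_ref))$rmsd
}

#' Surrogate binding energy of a pose
#'
#' `E(complex) - E(protein) - E(ligand)` under the surrogate nonbonded
#' energy; because the surrogate has no intramolecular terms this reduces to
#' the intermolecular Coulomb + repulsion energy, zero for infinitely
#' separated molecules and more negative for more favorable poses. Not
#' comparable in absolute value with forcefield end-point energies. Atom
#' pairs closer than 0.5 A trigger a clash flag.
#'
#' @param protein protein atom tibble (charges assigned).
#' @param xyz_protein,xyz_ligand pose coordinates.
#' @param ligand `glycan_chain`.
#' @param ... passed to [nonbonded_energy()] (e.g. `coul_k`).
#' @return list: `energy`, `coulomb`, `repulsion`, `min_dist`, `clash`.
#' @export
surrogate_binding_energy <- function(protein, xyz_protein, ligand, xyz_ligand,
                                     ...) {
  v <- nonbonded_energy(xyz_protein, protein$charge, protein$element != "H",
                        xyz_ligand, ligand$atoms$charge,
                        ligand$atoms$element != "H", ...)
  clash <- v[["min_dist"]] < 0.5
  if (clash) warn(sprintf("atoms closer than 0.5 A (%.2f A): clash penalty path",
                          v[["min_dist"]]))
  list(energy = v[["total"]], coulomb = v[["coulomb"]],
       repulsion = v[["repulsion"]], min_dist = v[["min_dist"]],
       clash = clash)
}

#' Ligand RMSD between two poses (protein frame)
#'
#' Direct (non-superposed) RMSD between two sets of ligand coordinates in
#' the fixed protein frame - the pose-recovery metric.
#'
#' @param xyz,xyz_ref matched ligand coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(xyz, xyz_ref) rmsd_raw(xyz, xyz_ref)

#' @method autoplot pose_scores
#' @export
autoplot.pose_scores <- function(object, ...) {
  d <- object
  d$selected <- d$selected %||% FALSE
  ggplot2::ggplot(d, ggplot2::aes(x = .data$noe_uronate_A, y = .data$energy,
                                  color = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "uronate-proton NOE score (A)",
                  y = "surrogate binding energy",
                  color = "top fraction") +
    ggplot2::theme_minimal()
}
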