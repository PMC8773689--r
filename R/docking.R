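# Restrained rigid-body + torsion docking by two-stage seeded simulated
# annealing. Stage 1 minimizes ambiguous-restraint energy plus a surrogate
# nonbonded energy with the ligand's glycosidic torsions harmonically
# restrained to their targets and the protein held fixed; stage 2 drops the
# distance restraints (torsion restraints stay active) and additionally frees
# the side-chain chi1 rotations of the restrained protein residues. The MD
# refinement this stands in for is replaced by annealing for determinism:
# identical seeds give identical output.

#' Assign surrogate formal charges to a protein atom tibble
#'
#' Places +1 on lysine NZ and arginine CZ (the guanidinium carbon); all other
#' atoms are neutral. These are the charge centers of the surrogate Coulomb
#' energy.
#'
#' @param protein atom tibble.
#' @return the tibble with its `charge` column filled in.
#' @export
assign_charges <- function(protein) {
  protein$charge <- 0
  protein$charge[protein$res_name == "LYS" & protein$atom == "NZ"] <- 1
  protein$charge[protein$res_name == "ARG" & protein$atom == "CZ"] <- 1
  protein
}

#' Surrogate intermolecular nonbonded energy
#'
#' Coulomb energy with distance-dependent dielectric `eps(r) = 4r` over
#' formal-charge centers (with the distance soft-floored at `sigma` so the
#' contact attraction stays bounded) plus capped soft-sphere repulsion
#' `(sigma/r)^12` over heavy-atom pairs. The absolute scale is arbitrary (it replaces a
#' forcefield end-point energy); only comparisons between poses of the same
#' system are meaningful.
#'
#' @param xyz_protein,xyz_ligand coordinate matrices.
#' @param q_protein,q_ligand formal charges per atom.
#' @param heavy_protein,heavy_ligand logical, non-hydrogen atoms.
#' @param coul_k Coulomb prefactor (332.06/4 by default, absorbing the 1/4r
#'   dielectric into a 1/r^2 law).
#' @param sigma,cap soft-sphere radius (A) and per-pair repulsion cap.
#' @return named vector: `total`, `coulomb`, `repulsion`, `min_dist`.
#' @export
nonbonded_energy <- function(xyz_protein, q_protein, heavy_protein,
                             xyz_ligand, q_ligand, heavy_ligand,
                             coul_k = 332.06 / 4, sigma = 2.8, cap = 100) {
  v <- cpp_nonbonded(as.matrix(xyz_protein), q_protein, heavy_protein,
                     as.matrix(xyz_ligand), q_ligand, heavy_ligand,
                     coul_k, sigma, cap)
  setNames(v, c("total", "coulomb", "repulsion", "min_dist"))
}

#' The 64-orientation start grid
#'
#' All rotations by 0, 90, 180, 270 degrees about X, then Y, then Z, in
#' lexicographic order of the angle triple: 64 start orientations for ligand
#' placement (24 of the rotation matrices are unique - the proper octahedral
#' group - but the printed protocol enumerates all 64).
#'
#' @return tibble with `start`, `rx`, `ry`, `rz` (degrees) and a list-column
#'   `R` of 3x3 rotation matrices.
#' @export
orientation_grid <- function() {
  g <- expand.grid(rz = c(0, 90, 180, 270), ry = c(0, 90, 180, 270),
                   rx = c(0, 90, 180, 270))[, c("rx", "ry", "rz")]
  g <- g[order(g$rx, g$ry, g$rz), ]
  rot <- purrr::pmap(g, function(rx, ry, rz) rot_z(rz) %*% rot_y(ry) %*% rot_x(rx))
  tibble(start = seq_len(64), rx = g$rx, ry = g$ry, rz = g$rz, R = rot)
}

ligand_xyz_of <- function(ligand) chain_xyz(ligand)

#' Place a ligand at a standoff distance from the binding face
#'
#' Rotates the ligand about its centroid by `rotation`, then positions it
#' along the binding-face axis (centroid of the restrained protein atoms,
#' displaced outward from the protein centroid) so that the minimum
#' protein-ligand atom distance lies within `standoff +/- 2` A. Protein
#' coordinates are untouched.
#'
#' @param protein atom tibble.
#' @param ligand a `glycan_chain`.
#' @param rotation 3x3 rotation matrix (e.g. one entry of
#'   [orientation_grid()]).
#' @param standoff target minimum separation in Angstrom (default 30).
#' @param face_atoms integer rows of `protein` defining the binding face;
#'   defaults to all atoms of charged residues, or supply the protein atoms of
#'   a compiled restraint set.
#' @return list of class `pose`: `q` (unit quaternion), `t` (translation of
#'   the ligand centroid), `xyz` (placed ligand coordinates), `chain` (the
#'   ligand), `torsions` (its linkage torsions).
#' @export
place_ligand <- function(protein, ligand, rotation = diag(3), standoff = 30,
                         face_atoms = NULL) {
  if (standoff <= 0) abort("standoff must be positive")
  xyzP <- as.matrix(protein[, c("x", "y", "z")])
  if (is.null(face_atoms)) {
    face_atoms <- which(protein$res_id %in%
                          unique(protein$res_id[protein$charge != 0]))
    if (length(face_atoms) == 0) face_atoms <- seq_len(nrow(protein))
  }
  face_c <- colMeans(xyzP[face_atoms, , drop = FALSE])
  prot_c <- colMeans(xyzP)
  u <- face_c - prot_c
  if (vnorm(u) < 1e-6) u <- c(0, 0, 1)
  u <- unitv(u)
  X0 <- ligand_xyz_of(ligand)
  c0 <- colMeans(X0)
  Xr <- sweep(sweep(X0, 2, c0) %*% t(rotation), 2, c0, `+`)
  # walk the centroid out along u until the closest approach hits standoff
  d <- standoff + max(sqrt(rowSums(sweep(Xr, 2, colMeans(Xr))^2)))
  f <- function(d) {
    Xc <- sweep(Xr, 2, face_c + d * u - colMeans(Xr), `+`)
    cpp_min_dist(xyzP, Xc)
  }
  for (it in 1:12) {
    err <- standoff - f(d)
    if (abs(err) <= 1.5) break
    d <- d + err
    if (d < 0) d <- 0.1
  }
  if (f(d) < standoff - 2) {
    warn("requested standoff not reachable; increasing separation")
    while (f(d) < standoff - 2) d <- d + 1
  }
  t_c <- face_c + d * u
  xyz <- sweep(Xr, 2, t_c - colMeans(Xr), `+`)
  structure(list(q = matrix_to_quat(rotation), t = t_c - c0, xyz = xyz,
                 chain = ligand, torsions = ligand$linkages[, c("phi", "psi")]),
            class = "pose")
}

#' Annealing configuration for the docking stages
#'
#' @param stage1_levels,stage2_levels temperature levels per stage.
#' @param n_prop proposals per level.
#' @param cool geometric cooling factor per level.
#' @param t0 starting temperature (energy units).
#' @param w_rot,w_trans,w_tor,w_chi proposal widths: rotation (rad),
#'   translation (A), glycosidic torsion (deg), side-chain chi (deg).
#' @param p_tor probability that a proposal perturbs a glycosidic torsion.
#' @param torsion_k harmonic torsion-restraint constant (energy/deg^2).
#' @param force_constant distance-restraint force constant (energy/A^2).
#' @param coul_k,sigma,cap surrogate nonbonded parameters
#'   (see [nonbonded_energy()]).
#' @param prescreen_top refine only the best N starts after a short
#'   restraint-driven prescreen of all starts (`Inf` refines every start).
#' @param prescreen_levels,prescreen_prop schedule of the prescreen.
#' @return named list of class `dock_config`.
#' @export
dock_config <- function(stage1_levels = 40, stage2_levels = 20, n_prop = 200,
                        cool = 0.93, t0 = 10,
                        w_rot = 0.15, w_trans = 1.0, w_tor = 10, w_chi = 20,
                        p_tor = 0.2, torsion_k = 0.2, force_constant = 10,
                        coul_k = 332.06 / 4, sigma = 2.8, cap = 100,
                        prescreen_top = Inf, prescreen_levels = 8,
                        prescreen_prop = 40) {
  structure(as.list(environment()), class = "dock_config")
}

# pose coordinates from base chain coords + rigid parameters
pose_coords <- function(X0, c0, q, t) {
  sweep(sweep(X0, 2, c0) %*% t(quat_to_matrix(q)), 2, c0 + t, `+`)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "H")

# rotate the side chain (beyond CB) of residue `res` about its CA-CB axis
rotate_sidechain <- function(protein, xyzP, res, angle_deg) {
  ica <- which(protein$res_id == res & protein$atom == "CA")
  icb <- which(protein$res_id == res & protein$atom == "CB")
  if (length(ica) != 1 || length(icb) != 1) return(xyzP)
  mov <- which(protein$res_id == res &
                 !protein$atom %in% c(BACKBONE_ATOMS, "CB"))
  if (length(mov) == 0) return(xyzP)
  R <- rotation_about_axis(xyzP[icb, ] - xyzP[ica, ], angle_deg)
  p0 <- xyzP[ica, ]
  xyzP[mov, ] <- sweep(sweep(xyzP[mov, , drop = FALSE], 2, p0) %*% t(R), 2,
                       p0, `+`)
  xyzP
}

#' Dock a glycan ligand onto a protein with ambiguous restraints
#'
#' Two-stage seeded simulated annealing from a grid of start orientations.
#' Each start is placed at `standoff` from the binding face and refined:
#' stage 1 anneals rotation, translation and glycosidic torsions against
#' `restraint energy + surrogate nonbonded energy + torsion restraints` with
#' the whole protein fixed; stage 2 continues without the distance-restraint
#' term (torsion restraints stay active) and also frees the side-chain chi1
#' angles of the restrained residues. Backbone atoms never move. The run is
#' fully determined by `seed`.
#'
#' With `config$prescreen_top < nrow(starts)` a short restraint-driven
#' prescreen of every start selects the most promising orientations for full
#' refinement (the remaining starts are reported unrefined with their
#' prescreen energies), mirroring the rigid-body-then-refine structure of
#' data-driven docking protocols.
#'
#' @param protein atom tibble with charges assigned ([assign_charges()]) and
#'   a logical `backbone` column (created if absent).
#' @param ligand a `glycan_chain` at its target torsions.
#' @param restraints `restraint_set` compiled against `protein` and `ligand`.
#' @param seed integer seed; fully determines the run.
#' @param standoff initial placement distance (A), default 30.
#' @param starts start-orientation tibble, default [orientation_grid()].
#' @param config a [dock_config()].
#' @return tibble of class `docking_result`, one row per start: angles,
#'   `refined`, energy breakdown (`e_restraint`, `e_nonbonded`, `score` =
#'   their sum, `satisfied_frac`), and a `pose` list-column (each pose holds
#'   final ligand coordinates `xyz`, protein coordinates `xyz_protein`,
#'   rigid parameters and torsions, plus the best-energy trace of each
#'   stage). Attribute `"protein"`, `"ligand"`, `"restraints"`, `"config"`.
#' @export
dock <- function(protein, ligand, restraints, seed, standoff = 30,
                 starts = orientation_grid(), config = dock_config()) {
  stopifnot(inherits(ligand, "glycan_chain"))
  if (!"backbone" %in% names(protein))
    protein$backbone <- protein$atom %in% BACKBONE_ATOMS
  set.seed(seed)
  xyzP0 <- as.matrix(protein[, c("x", "y", "z")])
  qP <- protein$charge
  heavyP <- protein$element != "H"
  qL <- ligand$atoms$charge
  heavyL <- ligand$atoms$element != "H"
  tor0 <- as.matrix(ligand$linkages[, c("phi", "psi")])
  n_link <- nrow(tor0)
  face <- unique(unlist(lapply(restraints$pairs, function(p) p[, "ip"])))
  restrained_res <- unique(protein$res_id[face])
  ridx <- if (nrow(restraints) > 0) restraint_index(restraints) else NULL

  # fast inline energy (no tibble construction in the hot loop)
  energy_of <- function(xyzL, xyzP, tor, with_restraints) {
    nb <- cpp_nonbonded(xyzP, qP, heavyP, xyzL, qL, heavyL,
                        config$coul_k, config$sigma, config$cap)[1]
    et <- config$torsion_k * sum(normalize_angle(tor - tor0)^2)
    er <- 0
    if (with_restraints && !is.null(ridx)) {
      deff <- cpp_group_deff(xyzP, xyzL, ridx$ip, ridx$il, ridx$grp,
                             ridx$ngroups)
      viol <- pmax(0, deff - restraints$upper, restraints$lower - deff)
      er <- config$force_constant * sum(restraints$weight * viol^2)
    }
    nb + et + er
  }

  # precomputed glycosidic-bond rotation machinery: axis atom indices and
  # downstream atom masks per linkage
  lat <- ligand$atoms
  link_geom <- purrr::map(seq_len(n_link), function(i) {
    list(ic1 = which(lat$res_idx == i & lat$atom == "C1"),
         io1 = which(lat$res_idx == i & lat$atom == "O1"),
         ic4 = which(lat$res_idx == i + 1 & lat$atom == "C4"),
         down = which(lat$res_idx > i))
  })
  rotate_link <- function(X0, lk, which_t, delta) {
    g <- link_geom[[lk]]
    if (which_t == 1) { p0 <- X0[g$ic1, ]; axis <- X0[g$io1, ] - p0 }
    else { p0 <- X0[g$io1, ]; axis <- X0[g$ic4, ] - p0 }
    R <- rotation_about_axis(axis, -delta)
    X0[g$down, ] <- sweep(sweep(X0[g$down, , drop = FALSE], 2, p0) %*% t(R),
                          2, p0, `+`)
    X0
  }

  anneal_stage <- function(state, levels, n_prop, with_restraints,
                           free_sidechains) {
    e <- energy_of(state$xyz, state$xyzP, state$tor, with_restraints)
    best <- state; ebest <- e; trace <- e
    temp <- config$t0
    n_rejected_nonfinite <- 0L
    for (lev in seq_len(levels)) {
      for (pp in seq_len(n_prop)) {
        cand <- state
        u <- runif(1)
        p_chi <- if (free_sidechains && length(restrained_res) > 0) 0.15 else 0
        if (u < p_chi) {
          res <- restrained_res[sample.int(length(restrained_res), 1)]
          cand$xyzP <- rotate_sidechain(protein, state$xyzP, res,
                                        rnorm(1, 0, config$w_chi))
        } else if (u < p_chi + config$p_tor && n_link > 0) {
          lk <- sample.int(n_link, 1)
          which_t <- sample.int(2, 1)
          delta <- rnorm(1, 0, config$w_tor)
          cand$tor[lk, which_t] <- normalize_angle(cand$tor[lk, which_t] + delta)
          cand$X0 <- rotate_link(state$X0, lk, which_t, delta)
        } else if (u < p_chi + config$p_tor + (1 - p_chi - config$p_tor) / 2) {
          dq <- quat_from_axis_angle(rnorm(3), abs(rnorm(1, 0, config$w_rot)))
          cand$q <- quat_normalize(quat_multiply(dq, state$q))
        } else {
          cand$t <- state$t + rnorm(3, 0, config$w_trans)
        }
        cand$xyz <- pose_coords(cand$X0, cand$c0, cand$q, cand$t)
        ec <- energy_of(cand$xyz, cand$xyzP, cand$tor, with_restraints)
        if (!is.finite(ec)) {
          n_rejected_nonfinite <- n_rejected_nonfinite + 1L
          next
        }
        if (ec <= e || runif(1) < exp(-(ec - e) / temp)) {
          state <- cand; e <- ec
          if (e < ebest) { best <- state; ebest <- e; trace <- c(trace, ebest) }
        }
      }
      temp <- temp * config$cool
    }
    if (n_rejected_nonfinite > 0)
      inform(paste0("annealing rejected ", n_rejected_nonfinite,
                    " non-finite energy step(s)"))
    if (n_rejected_nonfinite >= levels * n_prop)
      abort("all annealing proposals of a stage were rejected as non-finite")
    list(state = best, energy = ebest, trace = trace)
  }

  init_state <- function(R) {
    p <- place_ligand(protein, ligand, R, standoff,
                      face_atoms = face)
    list(q = p$q, t = p$t, tor = tor0,
         X0 = chain_xyz(ligand), c0 = colMeans(chain_xyz(ligand)),
         xyz = p$xyz, xyzP = xyzP0)
  }

  n_starts <- nrow(starts)
  # prescreen: short restraint-driven anneal of every start
  pres <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    st <- init_state(starts$R[[s]])
    pres[[s]] <- anneal_stage(st, config$prescreen_levels,
                              config$prescreen_prop,
                              with_restraints = TRUE, free_sidechains = FALSE)
  }
  pre_e <- vapply(pres, `[[`, numeric(1), "energy")
  refine_idx <- if (is.finite(config$prescreen_top) &&
                    config$prescreen_top < n_starts) {
    order(pre_e, seq_len(n_starts))[seq_len(config$prescreen_top)]
  } else seq_len(n_starts)

  rows <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    refined <- s %in% refine_idx
    if (refined) {
      s1 <- anneal_stage(pres[[s]]$state, config$stage1_levels, config$n_prop,
                         with_restraints = TRUE, free_sidechains = FALSE)
      s2 <- anneal_stage(s1$state, config$stage2_levels, config$n_prop,
                         with_restraints = FALSE, free_sidechains = TRUE)
      fin <- s2$state
      trace1 <- s1$trace; trace2 <- s2$trace
    } else {
      fin <- pres[[s]]$state
      trace1 <- pres[[s]]$trace; trace2 <- numeric(0)
    }
    re <- restraint_energy(restraints, fin$xyzP, fin$xyz,
                           config$force_constant)
    nb <- cpp_nonbonded(fin$xyzP, qP, heavyP, fin$xyz, qL, heavyL,
                        config$coul_k, config$sigma, config$cap)[1]
    rows[[s]] <- tibble(
      start = starts$start[s], rx = starts$rx[s], ry = starts$ry[s],
      rz = starts$rz[s], refined = refined,
      e_restraint = re$total, e_nonbonded = nb, score = re$total + nb,
      satisfied_frac = if (nrow(re$table) > 0) mean(re$table$satisfied) else NA_real_,
      pose = list(structure(list(
        q = fin$q, t = fin$t, torsions = fin$tor, xyz = fin$xyz,
        xyz_protein = fin$xyzP, trace_stage1 = trace1, trace_stage2 = trace2),
        class = "pose")))
  }
  out <- bind_rows(rows)
  class(out) <- c("docking_result", class(out))
  attr(out, "protein") <- protein
  attr(out, "ligand") <- ligand
  attr(out, "restraints") <- restraints
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Best pose of a docking run
#'
#' Refined poses are ranked restraint-consistency first: highest fraction of
#' satisfied restraints, then lowest total score (restraint + surrogate
#' nonbonded energy recomputed on the final coordinates), ties broken by the
#' lowest start index - the same primary/secondary logic as the
#' NOE-consistency model ranking.
#'
#' @param result a `docking_result`.
#' @return one-row tibble.
#' @export
best_pose <- function(result) {
  r <- result[result$refined, ]
  r[order(-r$satisfied_frac, r$score, r$start), ][1, ]
}
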