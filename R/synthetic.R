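# Synthetic fixtures: everything needed to exercise the pipeline without any
# external data. Titration fixtures carry their ground-truth parameters;
# mini-receptors stand in for the GAG-binding domains (schematic poly-alanine
# scaffolds presenting Lys/Arg/Trp side chains as one or two basic patches);
# bound-pose fixtures hand-dock the ligand onto the patch and derive the
# contact table from the actual pose geometry, enabling closed-loop
# pose-recovery experiments.

#' Generate a synthetic titration peak list with known parameters
#'
#' One- or two-site fast-exchange titration tracks at the standard schedule
#' (ligand at 0.1, 0.2, 0.3, 0.4, 0.6, 0.8 and 1.0 mM), with optional
#' Gaussian shift noise. Ground-truth parameters are attached as the
#' `"ground_truth"` attribute and written as `#` header comments when `path`
#' is given, so parameter-recovery tests are self-describing.
#'
#' @param kind `"one_site"` or `"two_site"`.
#' @param kd one-site dissociation constant, mM (`kind = "one_site"`).
#' @param kd1,kd2 two-site dissociation constants, mM (`kind = "two_site"`).
#' @param protein_conc total protein, mM.
#' @param shift1,shift2 per-site saturation shift vectors `(dH, dN)` in ppm.
#' @param schedule increasing ligand concentrations, mM.
#' @param noise_sd Gaussian shift noise (ppm); requires `seed` when > 0.
#' @param seed RNG seed for the noise.
#' @param include_apo prepend the 0 mM apo reference point (needed to see a
#'   direction change at ratio 1:1 when the schedule starts at one protein
#'   equivalent).
#' @param residue_id,atom_label identifiers for the generated track.
#' @param path optional CSV output path.
#' @return peak-list tibble (invisibly returns `path` if written).
#' @export
make_titration_fixture <- function(kind = c("one_site", "two_site"),
                                   kd = 0.05, kd1 = 0.001, kd2 = 0.15,
                                   protein_conc = 0.1,
                                   shift1 = c(0.15, 0.5),
                                   shift2 = c(-0.15, -0.25),
                                   schedule = c(0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1.0),
                                   noise_sd = 0, seed = NULL,
                                   include_apo = FALSE,
                                   residue_id = 1L, atom_label = "HN",
                                   path = NULL) {
  kind <- match.arg(kind)
  if (any(diff(schedule) <= 0)) abort("schedule must be strictly increasing")
  if (include_apo && schedule[1] > 0) schedule <- c(0, schedule)
  sys <- if (kind == "one_site") {
    two_site_system(kd, Inf, protein_conc, shift1 = shift1, shift2 = c(0, 0))
  } else {
    two_site_system(kd1, kd2, protein_conc, shift1 = shift1, shift2 = shift2)
  }
  peaks <- simulate_titration(sys, schedule, noise_sd = noise_sd, seed = seed,
                              residue_id = residue_id, atom_label = atom_label)
  gt <- list(kind = kind, protein_conc = protein_conc, noise_sd = noise_sd,
             seed = seed, shift1 = shift1, shift2 = shift2)
  gt <- c(gt, if (kind == "one_site") list(kd = kd) else
    list(kd1 = kd1, kd2 = kd2))
  attr(peaks, "ground_truth") <- gt
  if (!is.null(path)) {
    cm <- vapply(names(gt), function(n)
      paste0(n, "=", paste(gt[[n]], collapse = ",")), character(1))
    write_peaks(peaks, path, comments = c("synthetic titration fixture", cm))
    return(invisible(path))
  }
  peaks
}

AA3 <- c(A = "ALA", K = "LYS", R = "ARG", W = "TRP")

#' Default mini-receptor layouts
#'
#' Residue layouts of the synthetic GAG-binding mini-receptors. The CTD-like
#' layout presents two cationic/aromatic patches about 15 A apart
#' (W59/K68/K91 and W74/K111); the NTD-like layout presents the more diffuse
#' W18/W20 ... K45/K49/R52/K54 arrangement. Residue ids follow the probe and
#' contact tables.
#'
#' @return tibble with `res_id` and `aa` (one-letter).
#' @export
ctd_like_layout <- function() {
  tibble(res_id = c(55L, 59L, 68L, 91L, 80L, 81L, 74L, 111L, 112L),
         aa = c("A", "W", "K", "K", "A", "A", "W", "K", "A"))
}

#' @rdname ctd_like_layout
#' @export
ntd_like_layout <- function() {
  tibble(res_id = c(18L, 20L, 30L, 45L, 49L, 52L, 54L, 55L),
         aa = c("W", "W", "A", "K", "K", "R", "K", "A"))
}

sidechain_atoms <- function(aa) {
  zig <- function(k) {  # zig-zag chain offsets from CA, bond ~1.53 A
    dz <- 1.34 * seq_len(k)
    dy <- 0.73 * (seq_len(k) %% 2)
    cbind(0, dy, 0.19 + dz)
  }
  switch(aa,
    ALA = tibble(atom = "CB", element = "C",
                 dx = 0, dy = 0, dz = 1.53, charge = 0),
    LYS = {
      ch <- zig(4)
      nz <- c(0, 0.73 * (5 %% 2), 0.19 + 1.34 * 5)
      hz <- rbind(nz + c(0.94, 0, 0.34), nz + c(-0.47, 0.82, 0.34),
                  nz + c(-0.47, -0.82, 0.34))
      tibble(atom = c("CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
             element = c("C", "C", "C", "C", "N", "H", "H", "H"),
             dx = c(ch[, 1], nz[1], hz[, 1]),
             dy = c(ch[, 2], nz[2], hz[, 2]),
             dz = c(ch[, 3], nz[3], hz[, 3]),
             charge = c(0, 0, 0, 0, 1, 0, 0, 0))
    },
    ARG = {
      ch <- zig(3)
      ne <- c(0, 0.73 * (4 %% 2), 0.19 + 1.34 * 4)
      he <- ne + c(0.94, 0, 0.33)
      cz <- ne + c(-0.44, 0, 1.26)
      nh1 <- cz + c(-1.2, 0, 0.55); nh2 <- cz + c(0.74, 0, 1.1)
      tibble(atom = c("CB", "CG", "CD", "NE", "HE", "CZ", "NH1", "NH2"),
             element = c("C", "C", "C", "N", "H", "C", "N", "N"),
             dx = c(ch[, 1], ne[1], he[1], cz[1], nh1[1], nh2[1]),
             dy = c(ch[, 2], ne[2], he[2], cz[2], nh1[2], nh2[2]),
             dz = c(ch[, 3], ne[3], he[3], cz[3], nh1[3], nh2[3]),
             charge = c(0, 0, 0, 0, 0, 1, 0, 0))
    },
    TRP = {
      cb <- c(0, 0, 1.53); cg <- c(0, 0.73, 2.87)
      cd1 <- cg + c(1.05, 0.45, 0.55); ne1 <- cd1 + c(0.35, 0.25, 1.3)
      he1 <- ne1 + c(0.85, 0.15, 0.5); ce2 <- cg + c(-0.6, 0.5, 1.3)
      m <- rbind(cb, cg, cd1, ne1, he1, ce2)
      tibble(atom = c("CB", "CG", "CD1", "NE1", "HE1", "CE2"),
             element = c("C", "C", "C", "N", "H", "C"),
             dx = m[, 1], dy = m[, 2], dz = m[, 3], charge = 0)
    },
    abort(paste0("unsupported residue type '", aa, "'")))
}

#' Build a synthetic GAG-binding mini-receptor
#'
#' A rigid, schematic poly-alanine scaffold (CA spacing `spacing` along x)
#' presenting Lys/Arg/Trp side chains on the +z binding face. Deterministic
#' for a given layout and seed; overlapping side-chain placements (which the
#' default layouts do not produce) are rebuilt with a small seeded jitter.
#'
#' @param layout tibble with `res_id`, `aa` (one-letter A/K/R/W), at most 30
#'   residues; see [ctd_like_layout()].
#' @param seed RNG seed for the overlap jitter.
#' @param spacing CA-CA spacing along the scaffold axis, A.
#' @return atom tibble (`res_id`, `res_name`, `atom`, `element`, `x`, `y`,
#'   `z`, `charge`, `backbone`) with a `"params"` attribute echoing the
#'   layout.
#' @export
make_mini_receptor <- function(layout = ctd_like_layout(), seed = 1,
                               spacing = 3.8) {
  if (nrow(layout) > 30) abort("mini-receptor layouts are limited to 30 residues")
  if (!all(layout$aa %in% names(AA3)))
    abort("layout residue types must be A, K, R or W")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  rows <- purrr::map(seq_len(nrow(layout)), function(i) {
    ca <- c((i - 1) * spacing, 0, 0)
    aa3 <- AA3[[layout$aa[i]]]
    bb <- tibble(atom = c("N", "CA", "C", "O", "H"),
                 element = c("N", "C", "C", "O", "H"),
                 dx = c(-0.9, 0, 0.9, 0.9, -0.9),
                 dy = c(-1.0, 0, -1.0, -2.2, -0.6),
                 dz = c(0, 0, 0, 0, 0.95),
                 charge = 0)
    sc <- sidechain_atoms(aa3)
    at <- bind_rows(bb, sc)
    tibble(res_id = layout$res_id[i], res_name = aa3, atom = at$atom,
           element = at$element, x = unname(ca[1] + at$dx),
           y = unname(ca[2] + at$dy), z = unname(ca[3] + at$dz),
           charge = at$charge,
           backbone = at$atom %in% c("N", "CA", "C", "O", "H"))
  })
  prot <- bind_rows(rows)
  # overlap guard: jitter clashing side chains (deterministic via seed)
  for (tries in 1:5) {
    xyz <- as.matrix(prot[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    diff_res <- outer(prot$res_id, prot$res_id, `!=`)
    bad <- which(upper.tri(d) & d < 1.5 & diff_res, arr.ind = TRUE)
    if (nrow(bad) == 0) break
    inform(paste0("mini-receptor: ", nrow(bad),
                  " overlapping placements; applying jitter"))
    res_fix <- unique(prot$res_id[bad[, 1]])
    sel <- prot$res_id %in% res_fix & !prot$backbone
    prot$y[sel] <- prot$y[sel] + runif(sum(sel), -0.3, 0.3)
  }
  attr(prot, "params") <- list(layout = layout, seed = seed, spacing = spacing)
  prot
}

#' Construct a bound-pose docking fixture
#'
#' Hand-docks a glycan onto the mini-receptor's basic patch: the ligand's
#' long axis is aligned with the scaffold, then rotations about the axis,
#' axial offsets and the standoff height are searched for the placement with
#' the most favorable surrogate energy subject to sulfate-cation contact
#' range (closest sulfate sulfur 3.5-5 A from a cationic center, no
#' protein-ligand atoms closer than 2.5 A). The intermolecular contact table
#' is then derived from the actual pose geometry (probe protons and sulfate
#' terminal oxygens / ring protons within `contact_cutoff`), so restraints
#' compiled from it are exactly satisfiable by construction. The manifest
#' stores the true pose for recovery checks.
#'
#' @param receptor atom tibble from [make_mini_receptor()].
#' @param ligand a `glycan_chain` (default [dp6c()]).
#' @param seed seed recorded in the manifest (placement itself is exhaustive
#'   and deterministic).
#' @param contact_cutoff distance cutoff (A) for deriving contacts, default 6
#'   (inside the 4-7 A restraint well).
#' @return list: `protein`, `ligand` (chain at the bound pose), `contacts`
#'   tibble, `manifest` (list with `true_xyz`, placement parameters, seed).
#' @export
make_bound_pose_fixture <- function(receptor = make_mini_receptor(),
                                    ligand = dp6c(), seed = 11,
                                    contact_cutoff = 6) {
  xyzP <- as.matrix(receptor[, c("x", "y", "z")])
  qP <- receptor$charge; heavyP <- receptor$element != "H"
  qL <- ligand$atoms$charge; heavyL <- ligand$atoms$element != "H"
  X0 <- chain_xyz(ligand)
  c0 <- colMeans(X0)
  # align ligand principal axis with x
  sv <- svd(sweep(X0, 2, c0))
  ax <- sv$v[, 1]
  R0 <- rotation_between(ax, c(1, 0, 0))
  Xa <- sweep(sweep(X0, 2, c0) %*% t(R0), 2, c0, `+`)
  cations <- which(receptor$charge > 0)
  patch <- colMeans(xyzP[cations, , drop = FALSE])
  s_idx <- which(ligand$atoms$element == "S")
  best <- NULL
  for (flip in c(0, 180)) for (rot in seq(0, 345, by = 15)) {
    Rr <- rot_x(rot) %*% rot_z(flip)
    Xr <- sweep(sweep(Xa, 2, c0) %*% t(Rr), 2, c0, `+`)
    for (dx in c(-4, -2, 0, 2, 4)) {
      target <- c(patch[1] + dx, patch[2], patch[3])
      for (gap in seq(1.0, 6, by = 0.5)) {
        Xc <- sweep(Xr, 2, target + c(0, 0, gap) - colMeans(Xr), `+`)
        mind <- cpp_min_dist(xyzP, Xc)
        if (mind < 2.5) next
        s_cat <- cpp_min_dist(Xc[s_idx, , drop = FALSE],
                              xyzP[cations, , drop = FALSE])
        if (s_cat < 3.5 || s_cat > 5.0) next
        e <- cpp_nonbonded(xyzP, qP, heavyP, Xc, qL, heavyL,
                           332.06 / 4, 2.8, 100)[1]
        if (is.null(best) || e < best$e)
          best <- list(e = e, X = Xc, flip = flip, rot = rot, dx = dx,
                       gap = gap)
      }
    }
  }
  if (is.null(best))
    abort("no clash-free bound placement with sulfates in contact range; adjust parameters")

  # settle the coarse placement into the nearest local minimum of the
  # surrogate energy (deterministic rigid-body Nelder-Mead with soft walls
  # keeping the pose clash-free and the sulfates in contact range), so the
  # recorded true pose is a stationary point of the docking objective
  Xb <- best$X
  cb <- colMeans(Xb)
  relax_obj <- function(p) {
    R <- rot_z(p[3]) %*% rot_y(p[2]) %*% rot_x(p[1])
    Xp <- sweep(sweep(Xb, 2, cb) %*% t(R), 2, cb + p[4:6], `+`)
    e <- cpp_nonbonded(xyzP, qP, heavyP, Xp, qL, heavyL, 332.06 / 4, 2.8,
                       100)[1]
    mind <- cpp_min_dist(xyzP, Xp)
    s_cat <- cpp_min_dist(Xp[s_idx, , drop = FALSE],
                          xyzP[cations, , drop = FALSE])
    e + 100 * max(0, 2.6 - mind)^2 + 20 * max(0, s_cat - 5)^2 +
      20 * max(0, 3.4 - s_cat)^2
  }
  opt <- optim(rep(0, 6), relax_obj, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-10))
  opt <- optim(opt$par, relax_obj, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-10))
  Rr <- rot_z(opt$par[3]) %*% rot_y(opt$par[2]) %*% rot_x(opt$par[1])
  best$X <- sweep(sweep(Xb, 2, cb) %*% t(Rr), 2, cb + opt$par[4:6], `+`)
  best$e <- cpp_nonbonded(xyzP, qP, heavyP, best$X, qL, heavyL,
                          332.06 / 4, 2.8, 100)[1]
  placed <- set_chain_xyz(ligand, best$X)

  # derive the contact table from the actual pose geometry; probes are the
  # side-chain protons of the basic/aromatic residues plus their backbone
  # amide protons (the same proton types the NOESY experiments report)
  probe_def <- tibble(
    res_name = c("TRP", "LYS", "ARG", "TRP", "LYS", "ARG"),
    atom_glob = c("HE1", "HZ*", "HE", "H", "H", "H"))
  lig_targets <- tibble(
    atom_glob = c("O2S*", "ON*", "O6S*", "H2", "H3", "H4", "H5"))
  contacts <- list()
  lat <- placed$atoms
  for (ri in unique(receptor$res_id)) {
    rn <- receptor$res_name[receptor$res_id == ri][1]
    pd <- probe_def[probe_def$res_name == rn, ]
    if (nrow(pd) == 0) next
    for (pk in seq_len(nrow(pd))) {
      ip <- which(receptor$res_id == ri &
                    glob_match(pd$atom_glob[pk], receptor$atom))
      if (length(ip) == 0) next
      for (lres in unique(lat$res_idx)) for (g in lig_targets$atom_glob) {
        il <- which(lat$res_idx == lres & glob_match(g, lat$atom))
        if (length(il) == 0) next
        d <- cpp_min_dist(xyzP[ip, , drop = FALSE],
                          best$X[il, , drop = FALSE])
        if (d < contact_cutoff)
          contacts[[length(contacts) + 1]] <- tibble(
            protein_res = as.character(ri), protein_atom = pd$atom_glob[pk],
            ligand_res = lat$res_name[il[1]], ligand_atom = g,
            distance_A = d)
      }
    }
  }
  contacts <- bind_rows(contacts) |>
    dplyr::distinct(.data$protein_res, .data$protein_atom, .data$ligand_res,
                    .data$ligand_atom, .keep_all = TRUE)
  # keep only contacts whose compiled (r^-6-pooled) effective distance lies
  # strictly inside the flat-bottom well, so the true pose has zero
  # restraint energy by construction
  rset <- compile_restraints(contacts, receptor, placed)
  deff <- restraint_energy(rset, xyzP, best$X)$table$d_eff
  keep <- deff > 4.05 & deff < 6.9
  contacts <- contacts[keep, ]
  if (nrow(contacts) < 3)
    abort("bound-pose fixture yielded fewer than 3 usable contacts")
  # calibrated bounds: the generator knows the pose, so each contact gets an
  # upper bound just above its pooled effective distance (capped at the
  # default 7 A well), sharpening register discrimination in recovery runs
  contacts$lower_A <- 4
  contacts$upper_A <- pmin(7, deff[keep] + 1)
  manifest <- list(seed = seed, contact_cutoff = contact_cutoff,
                   placement = list(flip = best$flip, rot = best$rot,
                                    dx = best$dx, gap = best$gap,
                                    energy = best$e),
                   receptor_params = attr(receptor, "params"),
                   sequence = format_glycan_sequence(ligand),
                   true_xyz = best$X)
  list(protein = receptor, ligand = placed, contacts = contacts,
       manifest = manifest)
}

# rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b); c_ <- sum(a * b)
  if (vnorm(v) < 1e-9) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about_axis(p, 180))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Write / read a fixture manifest (JSON)
#'
#' Manifests record every parameter and the true pose of a bound-pose
#' fixture; coordinates are serialized at full precision so the pose
#' round-trips exactly.
#'
#' @param manifest manifest list from [make_bound_pose_fixture()].
#' @param path JSON file path.
#' @return `read_manifest()` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required to write manifests")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required to read manifests")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(m$true_xyz)) m$true_xyz <- as.matrix(m$true_xyz)
  m
}
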