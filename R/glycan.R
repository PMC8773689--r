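# Oligosaccharide chain construction, measurement and modification.
#
# Glycosidic torsion convention (heavy-atom convention, used consistently by
# the builder and the measurer and recorded in PDB output headers):
#   phi = O5(i) - C1(i) - O1(i) - C4(i+1)
#   psi = C1(i) - O1(i) - C4(i+1) - C3(i+1)
# for alpha-1,4 linkages, residues ordered non-reducing -> reducing.

default_linkage_torsions <- function(donor) {
  # minimum-energy alpha-1,4 geometries: glucosamine -> 2-O-sulfo-iduronate
  # at 80/-170; uronate -> glucosamine at -80/-140
  if (grepl("^Glc", donor)) c(phi = 80, psi = -170) else c(phi = -80, psi = -140)
}

#' Parse / format a glycan sequence specification
#'
#' Text form: residue names joined by `-`, non-reducing to reducing end, with
#' optional per-linkage `[phi,psi]` suffixes on the donor residue, e.g.
#' `"dUA2S-GlcNS6S[80,-170]-IdoA2S"`.
#'
#' @param text sequence specification string.
#' @return list with `sequence` (character vector) and `torsions` (tibble with
#'   `phi`, `psi`; `NA` where unspecified).
#' @export
parse_glycan_sequence <- function(text) {
  parts <- strsplit(trimws(text), "-(?=[A-Za-z])", perl = TRUE)[[1]]
  seqs <- character(0); phis <- numeric(0); psis <- numeric(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([A-Za-z0-9]+)(\\[([-0-9.]+),([-0-9.]+)\\])?$", p))[[1]]
    if (length(m) == 0) abort(paste0("cannot parse sequence element '", p, "'"))
    seqs <- c(seqs, m[2])
    phis <- c(phis, if (m[3] == "") NA_real_ else as.numeric(m[4]))
    psis <- c(psis, if (m[3] == "") NA_real_ else as.numeric(m[5]))
  }
  n <- length(seqs)
  torsions <- if (n > 1) tibble(phi = phis[seq_len(n - 1)],
                                psi = psis[seq_len(n - 1)])
              else tibble(phi = numeric(0), psi = numeric(0))
  list(sequence = seqs, torsions = torsions)
}

#' @rdname parse_glycan_sequence
#' @param chain a `glycan_chain`.
#' @export
format_glycan_sequence <- function(chain) {
  paste(chain$sequence, collapse = "-")
}

normalize_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

#' Build a 3D heparin-family oligosaccharide
#'
#' Constructs Cartesian coordinates for a 1,4-linked chain of heparin-family
#' monosaccharides from idealized residue templates, placing each glycosidic
#' linkage at requested `phi`/`psi` torsions (heavy-atom convention, see
#' Details). Ring puckers come from the templates (4C1 glucosamines, 1C4
#' iduronates, half-chair unsaturated uronate). Steric clashes between
#' non-bonded atoms closer than 1.8 A trigger a warning, not a failure.
#'
#' @details The torsion convention is `phi = O5-C1-O1-C4'`,
#'   `psi = C1-O1-C4'-C3'`; measured torsions of the built chain reproduce the
#'   requested values to well under 0.5 degrees ([measure_torsions()]).
#'   Unspecified torsions default to the minimum-energy values for the linkage
#'   type: 80/-170 for glucosamine -> iduronate and -80/-140 for uronate ->
#'   glucosamine.
#'
#' @param sequence character vector of residue names (non-reducing to
#'   reducing), or a single sequence string for [parse_glycan_sequence()].
#' @param torsions optional tibble/data.frame with columns `phi`, `psi`, one
#'   row per linkage; `NA` entries fall back to the defaults.
#' @return object of class `glycan_chain`: list with `atoms` (tibble:
#'   `res_idx`, `res_name`, `atom`, `element`, `x`, `y`, `z`, `charge`,
#'   `group`), `sequence`, and `linkages` (tibble: `linkage`, `donor`,
#'   `acceptor`, `phi`, `psi`, `linkage_type`).
#' @examples
#' dp6 <- build_glycan("dUA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S")
#' measure_torsions(dp6)
#' @export
build_glycan <- function(sequence, torsions = NULL) {
  if (length(sequence) == 1 && grepl("-", sequence)) {
    parsed <- parse_glycan_sequence(sequence)
    sequence <- parsed$sequence
    if (is.null(torsions)) torsions <- parsed$torsions
  }
  n <- length(sequence)
  n_link <- max(n - 1, 0)
  defaults <- if (n_link > 0) {
    t(vapply(sequence[seq_len(n_link)], default_linkage_torsions, numeric(2)))
  } else matrix(numeric(0), 0, 2)
  if (is.null(torsions)) {
    torsions <- tibble(phi = unname(defaults[, 1]), psi = unname(defaults[, 2]))
  } else {
    torsions <- as_tibble(torsions)
    if (nrow(torsions) != n_link)
      abort(paste0("torsion list has ", nrow(torsions), " rows; expected ",
                   n_link, " (one per linkage)"))
    if (n_link > 0) {
      torsions$phi <- unname(ifelse(is.na(torsions$phi), defaults[, 1],
                                    torsions$phi))
      torsions$psi <- unname(ifelse(is.na(torsions$psi), defaults[, 2],
                                    torsions$psi))
    }
  }

  res_atoms <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- glycan_template(sequence[i]) |>
      mutate(res_idx = i, res_name = sequence[i], .before = 1)
    if (i < n)  # O1 becomes the glycosidic oxygen
      tmpl <- filter(tmpl, .data$atom != "HO1")
    if (i > 1)  # C4 hydroxyl replaced by the incoming glycosidic bond
      tmpl <- filter(tmpl, !.data$atom %in% c("O4", "HO4"))
    res_atoms[[i]] <- tmpl
  }

  get_pos <- function(tbl, a) {
    r <- tbl[tbl$atom == a, , drop = FALSE]
    if (nrow(r) != 1) abort(paste0("internal: atom ", a, " not found"))
    c(r$x, r$y, r$z)
  }

  for (i in seq_len(n_link)) {
    donor <- res_atoms[[i]]
    acc <- res_atoms[[i + 1]]
    phi <- torsions$phi[i]; psi <- torsions$psi[i]
    o5 <- get_pos(donor, "O5"); c1 <- get_pos(donor, "C1")
    o1 <- get_pos(donor, "O1")
    # target C4' from phi, then a virtual C3' from psi; rigid-fit the
    # acceptor template so its C4 lands on the target with the old C4-O4 bond
    # direction pointing back along the glycosidic oxygen
    c4t <- place_atom_zmat(o5, c1, o1, 1.43, 113, phi)
    tmpl_full <- glycan_template(sequence[i + 1])
    c4s <- get_pos(tmpl_full, "C4"); c3s <- get_pos(tmpl_full, "C3")
    o4s <- get_pos(tmpl_full, "O4")
    d_c43 <- vnorm(c3s - c4s)
    c3t <- place_atom_zmat(c1, o1, c4t, d_c43, 109.47, psi)

    frame <- function(origin, p_main, p_plane) {
      e1 <- unitv(p_main - origin)
      v <- p_plane - origin
      e2 <- unitv(v - sum(v * e1) * e1)
      rbind(e1, e2, cross3(e1, e2))
    }
    Fs <- frame(c4s, o4s, c3s)          # source frame (template)
    Ft <- frame(c4t, o1, c3t)           # target frame (placed)
    R <- t(Ft) %*% Fs
    xyz <- as.matrix(acc[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, c4s) %*% t(R)
    xyz <- sweep(xyz, 2, c4t, `+`)
    acc$x <- xyz[, 1]; acc$y <- xyz[, 2]; acc$z <- xyz[, 3]
    res_atoms[[i + 1]] <- acc
  }

  atoms <- bind_rows(res_atoms)
  chain <- structure(list(
    atoms = atoms, sequence = sequence,
    linkages = tibble(linkage = seq_len(n_link),
                      donor = sequence[seq_len(n_link)],
                      acceptor = if (n_link > 0) sequence[2:n] else character(0),
                      phi = torsions$phi, psi = torsions$psi,
                      linkage_type = rep("alpha1-4", n_link))),
    class = "glycan_chain")

  cl <- chain_clashes(chain)
  if (nrow(cl) > 0)
    warn(paste0("built chain has ", nrow(cl),
                " non-bonded atom pair(s) closer than 1.8 A (closest ",
                sprintf("%.2f", min(cl$dist)), " A)"))
  chain
}

# Inter-residue non-bonded heavy-atom contacts below 1.8 A (linkage-bonded
# neighbourhood excluded). 1.8 A is a heavy-atom overlap criterion; idealized
# hydrogen positions are not screened.
chain_clashes <- function(chain, cutoff = 1.8) {
  at <- chain$atoms[chain$atoms$element != "H", ]
  n <- length(chain$sequence)
  if (n < 2) return(tibble(dist = numeric(0)))
  # vectorized over all inter-residue pairs
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  same_res <- outer(at$res_idx, at$res_idx, `==`)
  # atoms chemically bonded across a linkage: donor O1 to acceptor C4/H4
  linked <- matrix(FALSE, nrow(at), nrow(at))
  for (i in seq_len(max(n - 1, 0))) {
    io1 <- which(at$res_idx == i & at$atom == "O1")
    inb <- which(at$res_idx == i + 1 & at$atom %in% c("C4", "H4", "C3", "C5"))
    linked[io1, inb] <- TRUE
    linked[inb, io1] <- TRUE
  }
  hit <- which(upper.tri(d) & d < cutoff & !same_res & !linked, arr.ind = TRUE)
  if (nrow(hit) == 0) return(tibble(dist = numeric(0)))
  tibble(i = hit[, 1], j = hit[, 2], dist = d[hit])
}

#' @export
print.glycan_chain <- function(x, ...) {
  cat("Glycan chain:", format_glycan_sequence(x), "\n")
  cat(" ", nrow(x$atoms), "atoms,", length(x$sequence), "residues,",
      "formal charge", chain_charge(x), "\n")
  invisible(x)
}

#' Total formal charge of a glycan chain
#' @param chain a `glycan_chain`.
#' @return integer formal charge (each sulfate and carboxylate contributes -1).
#' @export
chain_charge <- function(chain) sum(chain$atoms$charge)

chain_xyz <- function(chain) as.matrix(chain$atoms[, c("x", "y", "z")])

set_chain_xyz <- function(chain, xyz) {
  chain$atoms$x <- xyz[, 1]; chain$atoms$y <- xyz[, 2]; chain$atoms$z <- xyz[, 3]
  chain
}

#' Measure glycosidic torsions from chain coordinates
#'
#' Inverse of [build_glycan()]: recomputes `phi`/`psi` for every linkage from
#' the Cartesian coordinates using the same heavy-atom convention
#' (`phi = O5-C1-O1-C4'`, `psi = C1-O1-C4'-C3'`). Degenerate geometry
#' (collinear atoms) or missing convention atoms yield `NA` for that linkage
#' with a message.
#'
#' @param chain a `glycan_chain`.
#' @return tibble with `linkage`, `donor`, `acceptor`, `phi`, `psi` (degrees).
#' @export
measure_torsions <- function(chain) {
  at <- chain$atoms
  n <- length(chain$sequence)
  if (n < 2)
    return(tibble(linkage = integer(0), donor = character(0),
                  acceptor = character(0), phi = numeric(0), psi = numeric(0)))
  grab <- function(i, a) {
    r <- at[at$res_idx == i & at$atom == a, ]
    if (nrow(r) != 1) return(NULL)
    c(r$x, r$y, r$z)
  }
  out <- purrr::map(seq_len(n - 1), function(i) {
    o5 <- grab(i, "O5"); c1 <- grab(i, "C1"); o1 <- grab(i, "O1")
    c4 <- grab(i + 1, "C4"); c3 <- grab(i + 1, "C3")
    if (any(vapply(list(o5, c1, o1, c4, c3), is.null, logical(1)))) {
      inform(paste0("linkage ", i, ": convention atoms missing; torsions undefined"))
      return(tibble(linkage = i, donor = chain$sequence[i],
                    acceptor = chain$sequence[i + 1],
                    phi = NA_real_, psi = NA_real_))
    }
    phi <- dihedral_angle(o5, c1, o1, c4)
    psi <- dihedral_angle(c1, o1, c4, c3)
    if (any(is.na(c(phi, psi))))
      inform(paste0("linkage ", i, ": degenerate (collinear) dihedral; flagged NA"))
    tibble(linkage = i, donor = chain$sequence[i],
           acceptor = chain$sequence[i + 1], phi = phi, psi = psi)
  })
  bind_rows(out)
}

#' Rotate glycosidic torsions of a built chain in place
#'
#' Applies rigid rotations of all downstream residues about the glycosidic
#' bond axes so that linkage `linkage` takes the requested `phi` and/or `psi`.
#' Used by the docking stage to explore ligand internal flexibility without
#' rebuilding the chain.
#'
#' @param chain a `glycan_chain`.
#' @param linkage linkage index (1-based, as in `chain$linkages`).
#' @param phi,psi target torsions in degrees (`NULL` leaves one unchanged).
#' @return the modified `glycan_chain`.
#' @export
set_linkage_torsion <- function(chain, linkage, phi = NULL, psi = NULL) {
  at <- chain$atoms
  i <- linkage
  grab <- function(ri, a) {
    r <- at[at$res_idx == ri & at$atom == a, ]
    c(r$x, r$y, r$z)
  }
  down <- at$res_idx > i
  cur <- measure_torsions(chain)[i, ]
  rotate_about <- function(p0, axis, delta) {
    R <- rotation_about_axis(axis, delta)
    xyz <- as.matrix(at[down, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, p0) %*% t(R), 2, p0, `+`)
    at$x[down] <<- xyz[, 1]; at$y[down] <<- xyz[, 2]; at$z[down] <<- xyz[, 3]
  }
  if (!is.null(phi)) {
    c1 <- grab(i, "C1"); o1 <- grab(i, "O1")
    rotate_about(c1, o1 - c1, cur$phi - phi)
    chain$atoms <- at
  }
  if (!is.null(psi)) {
    o1 <- grab(i, "O1")
    c4 <- grab(i + 1, "C4")
    rotate_about(o1, c4 - o1, measure_torsions(chain)[i, ]$psi - psi)
    chain$atoms <- at
  }
  chain$linkages$phi[i] <- if (is.null(phi)) chain$linkages$phi[i] else phi
  chain$linkages$psi[i] <- if (is.null(psi)) chain$linkages$psi[i] else psi
  chain
}

#' Selectively desulfate a glycan chain
#'
#' Emulates chemical selective desulfation: `"2-O"` replaces every uronate
#' 2-O-sulfate with a hydroxyl, `"6-O"` replaces every glucosamine
#' 6-O-sulfate with a hydroxyl, and `"N-to-NAc"` replaces N-sulfates with
#' N-acetyl groups. Backbone (ring) coordinates are unchanged; the total
#' formal charge increases by exactly the number of sulfates removed. A mode
#' that matches no group returns the chain unchanged with a warning.
#'
#' @param chain a `glycan_chain`.
#' @param mode one of `"2-O"`, `"6-O"`, `"N-to-NAc"`.
#' @return the modified `glycan_chain` (residue names updated accordingly).
#' @export
desulfate <- function(chain, mode = c("2-O", "6-O", "N-to-NAc")) {
  mode <- match.arg(mode)
  at <- chain$atoms
  target_group <- switch(mode, "2-O" = "2-O-sulfate", "6-O" = "6-O-sulfate",
                         "N-to-NAc" = "N-sulfate")
  hit_res <- unique(at$res_idx[at$group == target_group])
  if (length(hit_res) == 0) {
    warn(paste0("desulfate mode '", mode, "' matches no group; chain unchanged"))
    return(chain)
  }
  grab <- function(ri, a) {
    r <- at[at$res_idx == ri & at$atom == a, ]
    c(r$x, r$y, r$z)
  }
  new_rows <- list()
  for (ri in hit_res) {
    if (mode == "2-O") {
      h <- place_atom_zmat(grab(ri, "C1"), grab(ri, "C2"), grab(ri, "O2"),
                           0.96, 108, 180)
      new_rows[[length(new_rows) + 1]] <- tibble(
        res_idx = ri, res_name = NA_character_, atom = "HO2", element = "H",
        x = h[1], y = h[2], z = h[3], charge = 0, group = "hydroxyl")
    } else if (mode == "6-O") {
      h <- place_atom_zmat(grab(ri, "C5"), grab(ri, "C6"), grab(ri, "O6"),
                           0.96, 108, 180)
      new_rows[[length(new_rows) + 1]] <- tibble(
        res_idx = ri, res_name = NA_character_, atom = "HO6", element = "H",
        x = h[1], y = h[2], z = h[3], charge = 0, group = "hydroxyl")
    } else {
      c2 <- grab(ri, "C2"); n2 <- grab(ri, "N2"); c3 <- grab(ri, "C3")
      c7 <- place_atom_zmat(c3, c2, n2, 1.33, 122, 180)
      o7 <- place_atom_zmat(c2, n2, c7, 1.23, 122, 0)
      c8 <- place_atom_zmat(c2, n2, c7, 1.50, 116, 180)
      hs <- lapply(c(60, 180, 300), function(chi)
        place_atom_zmat(n2, c7, c8, 1.09, 109.5, chi))
      pos <- rbind(c7, o7, c8, hs[[1]], hs[[2]], hs[[3]])
      new_rows[[length(new_rows) + 1]] <- tibble(
        res_idx = ri, res_name = NA_character_,
        atom = c("C7", "O7", "C8", "H81", "H82", "H83"),
        element = c("C", "O", "C", "H", "H", "H"),
        x = pos[, 1], y = pos[, 2], z = pos[, 3], charge = 0,
        group = "N-acetyl")
    }
  }
  at <- filter(at, !(.data$res_idx %in% hit_res & .data$group == target_group))
  # residue renaming after modification
  rename_map <- switch(mode,
    "2-O" = c(IdoA2S = "IdoA", dUA2S = "dUA"),
    "6-O" = c(GlcNS6S = "GlcNS", GlcNAc6S = "GlcNAc"),
    "N-to-NAc" = c(GlcNS6S = "GlcNAc6S", GlcNS = "GlcNAc"))
  seq_new <- chain$sequence
  for (ri in hit_res) {
    old <- seq_new[ri]
    if (old %in% names(rename_map)) seq_new[ri] <- rename_map[[old]]
  }
  newat <- bind_rows(new_rows)
  newat$res_name <- seq_new[newat$res_idx]
  at <- bind_rows(at, newat) |> arrange(.data$res_idx)
  at$res_name <- seq_new[at$res_idx]
  chain$atoms <- at
  chain$sequence <- seq_new
  chain$linkages$donor <- seq_new[chain$linkages$linkage]
  chain$linkages$acceptor <- seq_new[chain$linkages$linkage + 1]
  chain
}

#' Inter-sulfate sulfur-sulfur distances
#'
#' Enumerates all S...S distances between sulfate sulfurs (2-O-, 6-O- and
#' N-sulfates) within a distance cap, sorted ascending. Highlights the
#' high-density sulfate clusters (e.g. the N-sulfate / 2-O-sulfate pair across
#' a glucosamine -> iduronate linkage) that basic protein side chains target.
#'
#' @param chain a `glycan_chain`.
#' @param cap report only pairs within this distance (A), default 12.
#' @return tibble with `res1`, `group1`, `res2`, `group2`, `dist_A`, sorted by
#'   distance.
#' @export
sulfate_distances <- function(chain, cap = 12) {
  s <- filter(chain$atoms, .data$element == "S")
  if (nrow(s) < 2)
    return(tibble(res1 = integer(0), group1 = character(0), res2 = integer(0),
                  group2 = character(0), dist_A = numeric(0)))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cap, arr.ind = TRUE)
  tibble(res1 = s$res_idx[idx[, 1]], group1 = s$group[idx[, 1]],
         res2 = s$res_idx[idx[, 2]], group2 = s$group[idx[, 2]],
         dist_A = d[idx]) |>
    arrange(.data$dist_A)
}

#' Cremer-Pople puckering parameters of each ring
#'
#' Computes the Cremer-Pople amplitude `Q`, polar angle `theta` and phase
#' `phi2` for every six-membered ring of the chain, with atoms ordered
#' O5, C1...C5. `theta` near 0 deg is the 4C1 chair, near 180 deg the 1C4
#' chair, and mid-range values are boats/skew-boats/half-chairs.
#'
#' @param chain a `glycan_chain`.
#' @return tibble with `res_idx`, `res_name`, `Q`, `theta`, `phi2` (degrees).
#' @export
cremer_pople <- function(chain) {
  at <- chain$atoms
  out <- purrr::map(seq_along(chain$sequence), function(ri) {
    ring <- at[at$res_idx == ri & at$atom %in% RING_ATOMS, ]
    ring <- ring[match(RING_ATOMS, ring$atom), ]
    xyz <- as.matrix(ring[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, colMeans(xyz))
    j <- 0:5
    Rp <- colSums(xyz * sin(2 * pi * j / 6))
    Rpp <- colSums(xyz * cos(2 * pi * j / 6))
    nvec <- unitv(cross3(Rp, Rpp))
    z <- as.vector(xyz %*% nvec)
    q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
    q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
    q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
    q2 <- sqrt(q2c^2 + q2s^2)
    Q <- sqrt(q2^2 + q3^2)
    theta <- atan2(q2, q3) / DEG
    phi2 <- (atan2(q2s, q2c) / DEG) %% 360
    tibble(res_idx = ri, res_name = chain$sequence[ri],
           Q = Q, theta = theta, phi2 = phi2)
  })
  bind_rows(out)
}

#' Build the conformation-controlled heparin hexasaccharide DP6-C
#'
#' Convenience constructor for the hexasaccharide
#' dUA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S with iduronates in the 1C4
#' chair, glucosamines in 4C1, and the minimum-energy glycosidic torsions
#' (glucosamine -> iduronate 80/-170, uronate -> glucosamine -80/-140).
#'
#' @return a `glycan_chain` with 6 residues and total formal charge -12
#'   (9 sulfates + 3 carboxylates).
#' @export
dp6c <- function() {
  build_glycan(c("dUA2S", "GlcNS6S", "IdoA2S", "GlcNS6S", "IdoA2S", "GlcNS6S"))
}
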