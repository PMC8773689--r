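# Monosaccharide templates for heparin-family residues.
#
# Templates are built in a local frame from idealized internal coordinates
# (tetrahedral carbons, C-C 1.52 A, C-O 1.43 A, C-N 1.47 A, S-O ester 1.58 A,
# S-O terminal 1.45 A, C-H 1.09 A). Ring geometry is an ideal chair whose
# Cremer-Pople theta is ~0 deg (4C1) or ~180 deg (1C4); the 4,5-unsaturated
# uronate uses a half-chair with the C3-C4=C5-O5 region planar. Hydrogens are
# explicit because NOE scoring and restraints operate on named protons
# (e.g. IdoA2S.H2, dUA2S.H4). Sulfates and carboxylates are fully ionized
# (formal charge -1 placed on the sulfur / carboxylate carbon).

RING_ATOMS <- c("O5", "C1", "C2", "C3", "C4", "C5")

#' Residue-name / PDB 3-letter code mapping for glycan residues
#'
#' Sidecar table mapping the full residue names used throughout the package to
#' the 3-letter codes written into PDB output. No claim of PDB
#' chemical-component fidelity is made.
#'
#' @format tibble with columns `name` and `code`.
#' @export
glycan_codes <- tibble::tibble(
  name = c("GlcNS6S", "GlcNS", "GlcNAc6S", "GlcNAc",
           "IdoA2S", "IdoA", "dUA2S", "dUA"),
  code = c("SGN", "GNS", "NA6", "NAG", "IDS", "IDR", "SUA", "DUA")
)

# Heavy-substituent slot (axial/equatorial) per ring carbon, by residue
# family. The templates are an idealized diastereomer, not a forcefield
# geometry: slots are fixed so that (a) the 1C4 iduronate presents its
# 2-O-sulfate on the linkage face next to the glucosamine N-sulfate (the
# high-density sulfate cluster), and (b) the hexasaccharide built at the
# minimum-energy glycosidic torsions is extended and free of heavy-atom
# steric overlap.
family_slots <- function(base) {
  switch(base,
    Glc = c(C1 = "eq", C2 = "eq", C3 = "eq", C4 = "eq", C5 = "eq"),
    Ido = c(C1 = "eq", C2 = "ax", C3 = "ax", C4 = "ax", C5 = "eq"),
    dUA = c(C1 = "eq", C2 = "eq", C3 = "eq"))
}

# Exocyclic rotamer choices (dihedral chi, degrees) for the rotatable
# template groups. One rotamer per group is fixed at template level (no
# conformational ensembles); values chosen so the hexasaccharide at the
# minimum-energy glycosidic torsions is free of steric overlap.
template_chis <- function() {
  list(glc_o6 = 320,   # O6 about C5-C6 (gg/gt/tg rotamer)
       glc_s6 = 180,   # S6 about C6-O6
       glc_sn = 60,    # SN about C2-N2
       ido_s2 = 180,   # S2 about C2-O2
       carbox = 300)   # carboxylate plane about C5-C6
}

# Parse a residue name into its structural features.
parse_residue_name <- function(name) {
  known <- glycan_codes$name
  if (!name %in% known)
    abort(paste0("unknown residue name '", name, "'; known residues: ",
                 paste(known, collapse = ", ")))
  if (grepl("^Glc", name)) {
    list(base = "Glc", pucker = "4C1",
         n_group = if (grepl("NAc", name)) "NAc" else "NS",
         sulf6 = grepl("6S$", name), sulf2 = FALSE, unsaturated = FALSE)
  } else if (grepl("^IdoA", name)) {
    list(base = "Ido", pucker = "1C4", n_group = NA,
         sulf6 = FALSE, sulf2 = grepl("2S$", name), unsaturated = FALSE)
  } else {
    list(base = "dUA", pucker = "half-chair", n_group = NA,
         sulf6 = FALSE, sulf2 = grepl("2S$", name), unsaturated = TRUE)
  }
}

# Ideal ring coordinates (6 x 3, rows O5,C1,C2,C3,C4,C5).
ring_coords <- function(pucker) {
  R <- sqrt(1.52^2 - 4 * 0.25^2)   # in-plane radius giving 1.52 A ring bonds
  ang <- (0:5) * 60 * DEG
  xy <- cbind(R * cos(ang), R * sin(ang))
  z <- switch(pucker,
    "4C1"  = -0.25 * c(1, -1, 1, -1, 1, -1),
    "1C4"  = 0.25 * c(1, -1, 1, -1, 1, -1),
    "half-chair" = c(0, 0.35, -0.35, 0, 0, 0),
    abort(paste0("unknown ring pucker '", pucker, "'")))
  m <- cbind(xy, z)
  rownames(m) <- RING_ATOMS
  m
}

# Axial/equatorial exocyclic slots at ring carbon `j` (name in RING_ATOMS).
# Returns list(ax = unit vector, eq = unit vector).
ring_slots <- function(ring, j) {
  i <- match(j, RING_ATOMS)
  nb <- RING_ATOMS[c((i - 2) %% 6 + 1, i %% 6 + 1)]
  u1 <- unitv(ring[nb[1], ] - ring[j, ])
  u2 <- unitv(ring[nb[2], ] - ring[j, ])
  d <- tetrahedral_directions(u1, u2)
  # ring lies in the xy plane of the local frame, so the ring normal is z
  if (abs(d[1, 3]) >= abs(d[2, 3])) list(ax = d[1, ], eq = d[2, ])
  else list(ax = d[2, ], eq = d[1, ])
}

# In-plane direction for an sp2 ring carbon (half-chair C4/C5).
sp2_slot <- function(ring, j) {
  i <- match(j, RING_ATOMS)
  nb <- RING_ATOMS[c((i - 2) %% 6 + 1, i %% 6 + 1)]
  u1 <- unitv(ring[nb[1], ] - ring[j, ])
  u2 <- unitv(ring[nb[2], ] - ring[j, ])
  -unitv(u1 + u2)
}

#' Monosaccharide template geometry
#'
#' Builds the idealized local-frame geometry of a heparin-family
#' monosaccharide, with controlled ring pucker, explicit hydrogens, sulfation
#' pattern and formal charges.
#'
#' @param name residue name (one of `glycan_codes$name`, e.g. `"GlcNS6S"`,
#'   `"IdoA2S"`, `"dUA2S"`).
#' @return tibble of atom records: `atom`, `element`, `x`, `y`, `z`, `charge`,
#'   `group` (functional-group label used by [desulfate()] and restraint
#'   selectors).
#' @export
glycan_template <- function(name) {
  cached <- .template_cache[[name]]
  if (!is.null(cached)) return(cached)
  out <- build_template(name)
  .template_cache[[name]] <- out
  out
}

.template_cache <- new.env(parent = emptyenv())

build_template <- function(name) {
  feat <- parse_residue_name(name)
  ring <- ring_coords(feat$pucker)
  chis <- template_chis()

  atoms <- list()
  add <- function(atom, element, pos, charge = 0, group = "ring") {
    pos <- unname(pos)
    atoms[[length(atoms) + 1]] <<- tibble(
      atom = atom, element = element,
      x = pos[1], y = pos[2], z = pos[3], charge = charge, group = group)
  }
  for (a in RING_ATOMS)
    add(a, if (a == "O5") "O" else "C", ring[a, ], group = "ring")

  pos <- function(a) {
    for (rec in atoms) if (rec$atom == a) return(c(rec$x, rec$y, rec$z))
    abort(paste0("internal: atom ", a, " not yet placed"))
  }

  heavy_slot <- family_slots(feat$base)

  place_pair <- function(cj, heavy_name, heavy_el, heavy_len, h_name,
                         heavy_group) {
    s <- ring_slots(ring, cj)
    hv <- if (heavy_slot[[cj]] == "ax") s$ax else s$eq
    hy <- if (heavy_slot[[cj]] == "ax") s$eq else s$ax
    add(heavy_name, heavy_el, ring[cj, ] + heavy_len * hv, group = heavy_group)
    add(h_name, "H", ring[cj, ] + 1.09 * hy, group = "H")
  }

  # sulfate ester: S on oxygen `o` (placed), three terminal oxygens
  add_o_sulfate <- function(o, c_of_o, a_ref, s_name, term_prefix, group,
                            s_chi = 180) {
    s_pos <- place_atom_zmat(pos(a_ref), pos(c_of_o), pos(o), 1.58, 118, s_chi)
    add(s_name, "S", s_pos, charge = -1, group = group)
    for (k in 1:3) {
      op <- place_atom_zmat(pos(c_of_o), pos(o), s_pos, 1.45, 106,
                            c(60, 180, 300)[k])
      add(paste0(term_prefix, k), "O", op, group = group)
    }
  }

  hydroxyl_h <- function(o, c_of_o, a_ref, h_name) {
    add(h_name, "H", place_atom_zmat(pos(a_ref), pos(c_of_o), pos(o),
                                     0.96, 108, 180), group = "hydroxyl")
  }

  # --- C1: anomeric O1 (+ HO1, stripped on linking) and H1
  place_pair("C1", "O1", "O", 1.43, "H1", "anomeric")
  add("HO1", "H", place_atom_zmat(pos("O5"), pos("C1"), pos("O1"),
                                  0.96, 108, 60), group = "anomeric")

  # --- C2: amine (Glc) or O2 (uronates)
  if (feat$base == "Glc") {
    place_pair("C2", "N2", "N", 1.47, "H2", "amine")
    if (feat$n_group == "NS") {
      add("HN2", "H", place_atom_zmat(pos("C1"), pos("C2"), pos("N2"),
                                      1.01, 112, 60), group = "amine")
      sn <- place_atom_zmat(pos("C3"), pos("C2"), pos("N2"), 1.60, 116,
                            chis$glc_sn)
      add("SN", "S", sn, charge = -1, group = "N-sulfate")
      for (k in 1:3)
        add(paste0("ON", k), "O",
            place_atom_zmat(pos("C2"), pos("N2"), sn, 1.45, 106,
                            c(60, 180, 300)[k]), group = "N-sulfate")
    } else { # N-acetyl
      add("HN2", "H", place_atom_zmat(pos("C1"), pos("C2"), pos("N2"),
                                      1.01, 112, 60), group = "amine")
      c7 <- place_atom_zmat(pos("C3"), pos("C2"), pos("N2"), 1.33, 122, 180)
      add("C7", "C", c7, group = "N-acetyl")
      add("O7", "O", place_atom_zmat(pos("C2"), pos("N2"), c7, 1.23, 122, 0),
          group = "N-acetyl")
      c8 <- place_atom_zmat(pos("C2"), pos("N2"), c7, 1.50, 116, 180)
      add("C8", "C", c8, group = "N-acetyl")
      for (k in 1:3)
        add(paste0("H8", k), "H",
            place_atom_zmat(pos("N2"), pos("C7"), c8, 1.09, 109.5,
                            c(60, 180, 300)[k]), group = "N-acetyl")
    }
  } else {
    place_pair("C2", "O2", "O", 1.43, "H2",
               if (feat$sulf2) "O2-ester" else "O2-ester")
    if (feat$sulf2) {
      add_o_sulfate("O2", "C2", "C1", "S2", "O2S", "2-O-sulfate",
                    s_chi = chis$ido_s2)
    } else {
      hydroxyl_h("O2", "C2", "C1", "HO2")
    }
  }

  # --- C3: hydroxyl
  place_pair("C3", "O3", "O", 1.43, "H3", "O3")
  hydroxyl_h("O3", "C3", "C2", "HO3")

  # --- C4
  if (feat$unsaturated) {
    # sp2 vinyl carbon of the 4,5-unsaturated uronate: single in-plane H4
    add("H4", "H", ring["C4", ] + 1.08 * sp2_slot(ring, "C4"), group = "H")
  } else {
    place_pair("C4", "O4", "O", 1.43, "H4", "O4")
    add("HO4", "H", place_atom_zmat(pos("C3"), pos("C4"), pos("O4"),
                                    0.96, 108, 180), group = "O4")
  }

  # --- C5 / C6 branch
  if (feat$base == "Glc") {
    place_pair("C5", "C6", "C", 1.52, "H5", "C6")
    o6 <- place_atom_zmat(pos("O5"), pos("C5"), pos("C6"), 1.43, 109.5,
                          chis$glc_o6)
    add("O6", "O", o6, group = "O6")
    for (k in 1:2)
      add(paste0("H6", k), "H",
          place_atom_zmat(pos("O5"), pos("C5"), pos("C6"), 1.09, 109.5,
                          chis$glc_o6 + c(120, 240)[k]), group = "H")
    if (feat$sulf6) {
      add_o_sulfate("O6", "C6", "C5", "S6", "O6S", "6-O-sulfate",
                    s_chi = chis$glc_s6)
    } else {
      hydroxyl_h("O6", "C6", "C5", "HO6")
    }
  } else {
    # uronate carboxylate at C5
    if (feat$unsaturated) {
      c6 <- ring["C5", ] + 1.50 * sp2_slot(ring, "C5")
      add("C6", "C", c6, charge = -1, group = "carboxylate")
    } else {
      s <- ring_slots(ring, "C5")
      hv <- if (heavy_slot[["C5"]] == "ax") s$ax else s$eq
      hy <- if (heavy_slot[["C5"]] == "ax") s$eq else s$ax
      c6 <- ring["C5", ] + 1.52 * hv
      add("C6", "C", c6, charge = -1, group = "carboxylate")
      add("H5", "H", ring["C5", ] + 1.09 * hy, group = "H")
    }
    add("O6A", "O", place_atom_zmat(pos("C4"), pos("C5"), c6, 1.25, 118,
                                    chis$carbox), group = "carboxylate")
    add("O6B", "O", place_atom_zmat(pos("C4"), pos("C5"), c6, 1.25, 118,
                                    chis$carbox + 180), group = "carboxylate")
  }

  bind_rows(atoms)
}
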