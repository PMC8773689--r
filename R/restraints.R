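# Ambiguous NOE-derived distance restraints with r^-6 averaging.
#
# A restraint is a group of protein-proton / ligand-atom pairs combined into
# one effective distance d_eff = (sum_i d_i^-6)^(-1/6): the shortest pair
# dominates, so the restraint is satisfied if ANY of the pairs is in contact.
# The default flat-bottom well is [4, 7] A: the intermolecular NOEs are weak
# (lower bound 4 A) and no calibrated upper bound exists, so 7 A keeps the
# restrained groups in contact range without over-constraining.

glob_match <- function(pattern, x) {
  grepl(utils::glob2rx(pattern), x)
}

#' Compile ambiguous distance restraints from a contact table
#'
#' Resolves each contact row against a protein structure and a ligand chain:
#' protein ambiguity groups (`"68/91"`) expand across both residues into a
#' single restraint; atom globs (`"HZ*"`, `"O2S*"`) expand to all matching
#' atoms; ligand residue globs expand across all matching residues. Every
#' contact therefore becomes one restraint holding all its atom pairs.
#'
#' @param contacts contact tibble (see [read_contacts()]); optional columns
#'   `lower_A`, `upper_A`, `weight` override the defaults per contact.
#' @param protein atom tibble (e.g. from [read_structure()] or
#'   [make_mini_receptor()]).
#' @param ligand a `glycan_chain`.
#' @param lower,upper flat-bottom bounds in Angstrom (defaults 4 and 7).
#' @param weight default restraint weight.
#' @return tibble of class `restraint_set`: `id`, `label`, `n_pairs`,
#'   `lower`, `upper`, `weight` and a `pairs` list-column of 2-column matrices
#'   (protein atom row, ligand atom row).
#' @export
compile_restraints <- function(contacts, protein, ligand,
                               lower = 4, upper = 7, weight = 1) {
  stopifnot(inherits(ligand, "glycan_chain"))
  contacts <- as_tibble(contacts)
  if (nrow(contacts) == 0) {
    out <- tibble(id = integer(0), label = character(0), n_pairs = integer(0),
                  lower = numeric(0), upper = numeric(0), weight = numeric(0),
                  pairs = list())
    class(out) <- c("restraint_set", class(out))
    return(out)
  }
  lat <- ligand$atoms
  rows <- purrr::map(seq_len(nrow(contacts)), function(k) {
    ct <- contacts[k, ]
    res_ids <- as.integer(strsplit(as.character(ct$protein_res), "/")[[1]])
    isel <- which(protein$res_id %in% res_ids &
                    glob_match(ct$protein_atom, protein$atom))
    if (length(isel) == 0)
      abort(paste0("contact ", k, ": no protein atom matches residue(s) ",
                   ct$protein_res, " atom '", ct$protein_atom,
                   "'; atoms present there: ",
                   paste(unique(protein$atom[protein$res_id %in% res_ids]),
                         collapse = " ")))
    jsel <- which(glob_match(ct$ligand_res, lat$res_name) &
                    glob_match(ct$ligand_atom, lat$atom))
    if (length(jsel) == 0)
      abort(paste0("contact ", k, ": no ligand atom matches residue '",
                   ct$ligand_res, "' atom '", ct$ligand_atom,
                   "'; candidate atoms: ",
                   paste(unique(lat$atom[glob_match(ct$ligand_res, lat$res_name)]),
                         collapse = " ")))
    pairs <- as.matrix(expand.grid(ip = isel, il = jsel))
    tibble(id = k,
           label = paste0(ct$protein_res, ".", ct$protein_atom, " <-> ",
                          ct$ligand_res, ".", ct$ligand_atom),
           n_pairs = nrow(pairs),
           lower = if ("lower_A" %in% names(ct) && !is.na(ct$lower_A))
             as.numeric(ct$lower_A) else lower,
           upper = if ("upper_A" %in% names(ct) && !is.na(ct$upper_A))
             as.numeric(ct$upper_A) else upper,
           weight = if ("weight" %in% names(ct) && !is.na(ct$weight))
             as.numeric(ct$weight) else weight,
           pairs = list(pairs))
  })
  out <- bind_rows(rows)
  bad <- out$lower >= out$upper
  if (any(bad)) abort("restraint lower bound must be below the upper bound")
  class(out) <- c("restraint_set", class(out))
  out
}

# Flatten a restraint set into parallel index vectors for the C++ kernel.
restraint_index <- function(restraints) {
  ip <- unlist(lapply(restraints$pairs, function(p) p[, "ip"]))
  il <- unlist(lapply(restraints$pairs, function(p) p[, "il"]))
  grp <- rep(seq_len(nrow(restraints)), restraints$n_pairs)
  list(ip = as.integer(ip), il = as.integer(il), grp = as.integer(grp),
       ngroups = nrow(restraints))
}

#' r^-6-averaged effective distance
#'
#' `d_eff = (sum_i d_i^-6)^(-1/6)` over a set of pair distances. Always
#' bounded above by the minimum pair distance (with equality only for a
#' single pair), so the shortest contact dominates - the physical rationale
#' for ambiguous NOE restraints.
#'
#' @param d numeric vector of pair distances (Angstrom), all > 0.
#' @return effective distance in Angstrom.
#' @examples
#' effective_distance(5)              # 5
#' effective_distance(c(4, 8))        # ~3.99
#' @export
effective_distance <- function(d) {
  if (length(d) == 0) abort("effective_distance() needs at least one distance")
  if (any(d <= 0)) abort("coincident atoms in restraint (distance 0)")
  sum(d^-6)^(-1 / 6)
}

#' Evaluate restraint effective distances and flat-bottom energy
#'
#' For each restraint, computes the r^-6-averaged effective distance between
#' protein and ligand coordinates and the flat-bottom quadratic energy:
#' zero inside `[lower, upper]`, `force_constant * weight * (d_eff - bound)^2`
#' outside.
#'
#' @param restraints a `restraint_set` from [compile_restraints()].
#' @param xyz_protein,xyz_ligand coordinate matrices the restraint indices
#'   refer to (rows = atoms of the structures used at compile time).
#' @param force_constant harmonic force constant (energy/A^2), default 10.
#' @return list with `total` energy, and `table`: per-restraint `id`, `label`,
#'   `d_eff`, `violation` (A, 0 when satisfied), `energy`, `satisfied`.
#' @export
restraint_energy <- function(restraints, xyz_protein, xyz_ligand,
                             force_constant = 10) {
  if (nrow(restraints) == 0)
    return(list(total = 0,
                table = tibble(id = integer(0), label = character(0),
                               d_eff = numeric(0), violation = numeric(0),
                               energy = numeric(0), satisfied = logical(0))))
  idx <- restraint_index(restraints)
  deff <- cpp_group_deff(as.matrix(xyz_protein), as.matrix(xyz_ligand),
                         idx$ip, idx$il, idx$grp, idx$ngroups)
  viol <- pmax(0, deff - restraints$upper, restraints$lower - deff)
  en <- force_constant * restraints$weight * viol^2
  list(total = sum(en),
       table = tibble(id = restraints$id, label = restraints$label,
                      d_eff = deff, violation = viol, energy = en,
                      satisfied = deff <= restraints$upper))
}

#' Analytic gradient of the restraint energy w.r.t. ligand coordinates
#'
#' Chain-rule gradient of the flat-bottom r^-6-averaged restraint energy,
#' used to verify the energy implementation against finite differences.
#'
#' @inheritParams restraint_energy
#' @return matrix of the same shape as `xyz_ligand`.
#' @export
restraint_gradient <- function(restraints, xyz_protein, xyz_ligand,
                               force_constant = 10) {
  xyz_protein <- as.matrix(xyz_protein)
  xyz_ligand <- as.matrix(xyz_ligand)
  grad <- matrix(0, nrow(xyz_ligand), 3)
  for (k in seq_len(nrow(restraints))) {
    p <- restraints$pairs[[k]]
    dvec <- xyz_ligand[p[, "il"], , drop = FALSE] -
      xyz_protein[p[, "ip"], , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    if (any(d <= 0)) abort("coincident atoms in restraint (distance 0)")
    deff <- sum(d^-6)^(-1 / 6)
    bound <- if (deff > restraints$upper[k]) restraints$upper[k]
             else if (deff < restraints$lower[k]) restraints$lower[k]
             else NA_real_
    if (is.na(bound)) next
    dE_ddeff <- 2 * force_constant * restraints$weight[k] * (deff - bound)
    # d(deff)/d(d_i) = deff^7 * d_i^-7
    ddeff_dd <- deff^7 * d^-7
    contrib <- dE_ddeff * ddeff_dd / d   # per pair, times dvec
    for (r in seq_len(nrow(p)))
      grad[p[r, "il"], ] <- grad[p[r, "il"], ] + contrib[r] * dvec[r, ]
  }
  grad
}
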