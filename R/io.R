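# Structure and table I/O. PDB parsing/writing goes through bio3d; the
# package-level containers are plain tibbles of atom records.

guess_element <- function(atom) {
  a <- sub("^[0-9]+", "", atom)
  first <- substr(a, 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H", "P"), first, "C")
}

#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records (HETATM covers glycan residues) into an
#' atom-record tibble. Coordinates are Angstrom, residue numbering 1-based as
#' in the file; insertion codes are preserved. Malformed coordinate records
#' raise an error naming the offending line.
#'
#' @param path PDB file path.
#' @return tibble with columns `res_id`, `res_name`, `chain`, `atom`,
#'   `element`, `x`, `y`, `z`, `charge`, `insert`, `record`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  is_at <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_at)) {
    l <- lines[i]
    if (nchar(l) < 54)
      abort(paste0("malformed (truncated) atom record at line ", i, " of ", path))
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (any(is.na(xyz)))
      abort(paste0("malformed coordinates in atom record at line ", i, " of ", path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  el <- ifelse(!is.na(a$elesy) & a$elesy != "", trimws(a$elesy),
               guess_element(a$elety))
  tibble(res_id = a$resno, res_name = trimws(a$resid), chain = a$chain,
         atom = trimws(a$elety), element = el,
         x = a$x, y = a$y, z = a$z, charge = 0,
         insert = ifelse(is.na(a$insert), "", a$insert), record = a$type)
}

#' Write a structure (atom tibble or glycan chain) to a PDB file
#'
#' Glycan chains are written as HETATM records using the 3-letter codes of
#' [glycan_codes], and the glycosidic torsion convention is recorded in REMARK
#' header lines. Occupancy/B-factor are written as 1.00/0.00; coordinates are
#' rounded to the format's 3 decimals.
#'
#' @param x a `glycan_chain` or an atom-record tibble (as from
#'   [read_structure()] or [make_mini_receptor()]).
#' @param path output file path.
#' @param remarks extra character lines to include as REMARK records.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, remarks = character(0)) {
  if (inherits(x, "glycan_chain")) {
    at <- x$atoms
    code <- setNames(glycan_codes$code, glycan_codes$name)
    df <- tibble(res_id = at$res_idx, res_name = code[at$res_name],
                 chain = "X", atom = at$atom, element = at$element,
                 x = at$x, y = at$y, z = at$z, record = "HETATM")
    remarks <- c(remarks,
                 paste0("glycan sequence ", format_glycan_sequence(x)),
                 "glycosidic torsion convention: phi = O5-C1-O1-C4', psi = C1-O1-C4'-C3'")
  } else {
    df <- x
    if (!"record" %in% names(df)) df$record <- "ATOM"
    if (!"chain" %in% names(df)) df$chain <- "A"
  }
  pdb_lines <- sprintf(
    "%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    df$record, seq_len(nrow(df)),
    ifelse(nchar(df$atom) < 4, paste0(" ", df$atom), df$atom),
    substr(df$res_name, 1, 3), df$chain, df$res_id,
    df$x, df$y, df$z, 1.00, 0.00, df$element)
  out <- c(if (length(remarks) > 0) paste("REMARK  ", remarks),
           pdb_lines, "END")
  tmp <- paste0(path, ".tmp")
  writeLines(out, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Reconstruct a glycan chain from an atom tibble
#'
#' Inverse of writing a chain to PDB: maps 3-letter codes back to residue
#' names, reassigns functional groups and formal charges from the template
#' definitions, and re-measures linkage torsions from the coordinates.
#'
#' @param atoms atom tibble from [read_structure()] containing glycan residues.
#' @return a `glycan_chain`.
#' @export
as_glycan_chain <- function(atoms) {
  name_of <- setNames(glycan_codes$name, glycan_codes$code)
  if (!all(atoms$res_name %in% glycan_codes$code))
    abort(paste0("unknown glycan residue code(s): ",
                 paste(setdiff(unique(atoms$res_name), glycan_codes$code),
                       collapse = ", ")))
  res_ids <- unique(atoms$res_id)
  seqs <- name_of[atoms$res_name[match(res_ids, atoms$res_id)]]
  at <- tibble(res_idx = match(atoms$res_id, res_ids),
               res_name = unname(name_of[atoms$res_name]),
               atom = atoms$atom, element = atoms$element,
               x = atoms$x, y = atoms$y, z = atoms$z,
               charge = 0, group = NA_character_)
  # recover charges/groups from the residue templates
  for (i in seq_along(res_ids)) {
    tmpl <- glycan_template(seqs[i])
    sel <- at$res_idx == i
    m <- match(at$atom[sel], tmpl$atom)
    at$charge[sel] <- ifelse(is.na(m), 0, tmpl$charge[m])
    at$group[sel] <- ifelse(is.na(m), "ring", tmpl$group[m])
  }
  n <- length(res_ids)
  chain <- structure(list(
    atoms = at, sequence = unname(seqs),
    linkages = tibble(linkage = seq_len(max(n - 1, 0)),
                      donor = unname(seqs[seq_len(max(n - 1, 0))]),
                      acceptor = if (n > 1) unname(seqs[2:n]) else character(0),
                      phi = NA_real_, psi = NA_real_,
                      linkage_type = rep("alpha1-4", max(n - 1, 0)))),
    class = "glycan_chain")
  if (n > 1) {
    mt <- measure_torsions(chain)
    chain$linkages$phi <- mt$phi
    chain$linkages$psi <- mt$psi
  }
  chain
}

#' Read / write peak-list CSV files
#'
#' Peak-list layout: columns `residue_id`, `atom_label`, `ligand_conc_mM`,
#' `dH_ppm`, `dN_ppm`, one row per (residue, titration point); `#`-prefixed
#' lines are comments (used by fixture generators to embed ground truth).
#'
#' @param path CSV file path.
#' @return tibble of peaks (validated).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  validate_peaks(utils::read.csv(path, comment.char = "#"))
}

#' @rdname read_peaks
#' @param peaks peak-list tibble.
#' @param comments character vector written as `#` header lines (fixture
#'   ground truth / provenance).
#' @export
write_peaks <- function(peaks, path, comments = character(0)) {
  peaks <- validate_peaks(peaks)
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(close(con), add = TRUE)
  if (length(comments) > 0) writeLines(paste("#", comments), con)
  utils::write.csv(peaks, con, row.names = FALSE, quote = FALSE)
  close(con)
  on.exit(NULL)
  file.rename(tmp, path)
  invisible(path)
}

#' Read an intermolecular contact table
#'
#' Contact tables list NOE-derived protein-ligand contacts, one row each:
#' `protein_res` (residue id, or an ambiguity group like `"68/91"`),
#' `protein_atom` (glob pattern, e.g. `"HZ*"` for the lysine zeta protons),
#' `ligand_res` (residue-name glob, `"*"` for any), `ligand_atom` (glob;
#' `"O2S*"` selects the 2-O-sulfate terminal oxygens). The packaged CTD/NTD
#' tables are available via [example_contacts()].
#'
#' @param path CSV file path.
#' @return contact tibble.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  d <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  need <- c("protein_res", "protein_atom", "ligand_res", "ligand_atom")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    abort(paste0("contact table missing column(s): ",
                 paste(missing, collapse = ", ")))
  as_tibble(d)
}

#' Packaged NOE contact tables for the CTD / NTD binding sites
#'
#' The ambiguous-contact tables used for docking the heparin hexasaccharide
#' onto the two structured domains: the CTD set restrains the 2-O-sulfate
#' terminal oxygens to the indole protons of W59/W74, the zeta amines of the
#' K68/91 ambiguity pair, and the K111 backbone amide; the NTD set restrains
#' them to R52 Hε, K49/K54 Hζ and W18/W20 Hε1, plus one unambiguous
#' K45 Hζ - dUA2S H4 contact.
#'
#' @param domain `"ctd"` or `"ntd"`.
#' @return contact tibble (see [read_contacts()]).
#' @export
example_contacts <- function(domain = c("ctd", "ntd")) {
  domain <- match.arg(domain)
  read_contacts(system.file("extdata", paste0(domain, "_contacts.csv"),
                            package = "hepnmr", mustWork = TRUE))
}
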