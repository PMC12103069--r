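#' Structure data model and file input/output
#'
#' A `structure_model` is the package's in-memory representation of a
#' multi-chain protein structure: a table of heavy atoms belonging to polymer
#' residues, a per-residue summary carrying the mean B-factor as a confidence
#' proxy (pLDDT for AlphaFold-style models), and single-atom hetero entities
#' (typically zinc ions) kept apart from the polymer chains. Hydrogens are
#' removed at parse time and alternate locations are resolved to the highest
#' occupancy, so every distance computed downstream is a heavy-atom distance.
#'
#' @name structure_model
NULL

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

.normalize_element <- function(x) {
  x <- toupper(trimws(x))
  paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x))))
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and the synthetic complex
#' generator. Atoms are sorted deterministically (chains in order of first
#' appearance, residues by number, atoms by name) so that two files with
#' permuted records within a residue yield identical models.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `elety`
#'   (atom name), `elesy` (element symbol), `x`, `y`, `z`, `b`.
#' @param hetero_ions data.frame with columns `element`, `x`, `y`, `z`
#'   (may be empty).
#' @param source list with `path` and `format`, or NULL for in-memory models.
#' @return An object of class `structure_model` with components `atoms`,
#'   `residues` (chain, resno, resname, plddt, masked, standard),
#'   `hetero_ions` and `source`.
#' @export
new_structure_model <- function(atoms, hetero_ions = NULL, source = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resname", "elety", "elesy", "x", "y", "z", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure has zero polymer atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$elesy))) stop("empty element symbol in atom table")

  chain_order <- unique(atoms$chain)
  ord <- order(match(atoms$chain, chain_order), atoms$resno,
               atoms$elety, method = "radix")
  atoms <- atoms[ord, need, drop = FALSE]
  rownames(atoms) <- NULL
  atoms$is_backbone <- atoms$elety %in% c("N", "CA", "C", "O")

  key <- paste(atoms$chain, atoms$resno, sep = "\r")
  first <- !duplicated(key)
  residues <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    resname = atoms$resname[first],
    plddt = as.numeric(tapply(atoms$b, factor(key, levels = key[first]),
                              mean, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  residues$plddt[is.nan(residues$plddt)] <- NA_real_
  residues$masked <- FALSE
  residues$standard <- residues$resname %in% .STANDARD_AA3
  rownames(residues) <- NULL

  if (is.null(hetero_ions) || nrow(hetero_ions) == 0L) {
    hetero_ions <- data.frame(element = character(), x = numeric(),
                              y = numeric(), z = numeric(),
                              stringsAsFactors = FALSE)
  }

  structure(list(atoms = atoms, residues = residues,
                 hetero_ions = hetero_ions, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$residues$chain)[unique(x$residues$chain)]
  cat("structure_model:", length(ch), "chain(s),",
      nrow(x$residues), "residues,", nrow(x$atoms), "heavy atoms\n")
  for (cn in names(ch)) cat("  chain", cn, ":", ch[[cn]], "residues\n")
  if (nrow(x$hetero_ions))
    cat("  hetero ions:", paste(x$hetero_ions$element, collapse = ", "), "\n")
  nm <- sum(x$residues$masked)
  if (nm) cat("  masked residues:", nm, "\n")
  invisible(x)
}

#' Chain identifiers of a structure model
#' @param model a `structure_model`.
#' @return character vector of chain ids in order of first appearance.
#' @export
model_chains <- function(model) unique(model$residues$chain)

#' Read a PDB or mmCIF structure file
#'
#' Parses a structure file into a [structure_model]. Hydrogens (and deuterium)
#' are dropped, alternate locations are resolved to the highest-occupancy copy
#' (ties broken by file order), and single-atom HETATM entities other than
#' water are routed to `hetero_ions`. Author chain ids and residue numbers are
#' kept as-is. Per-residue confidence (pLDDT for AlphaFold models) is the mean
#' of the atom B-factors.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (default; decided by file
#'   extension, `.cif`/`.mmcif` meaning mmCIF).
#' @return a [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  raw <- tryCatch(
    suppressWarnings(
      if (format == "pdb") {
        bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
      } else {
        bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
      }
    ),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- raw$atom
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- NA_real_
  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""

  # resolve altlocs: highest occupancy wins, ties go to the first record
  akey <- paste(at$chain, at$resno, ins, at$elety, sep = "\r")
  keep <- !logical(nrow(at))
  if (anyDuplicated(akey)) {
    best <- tapply(seq_len(nrow(at)), akey, function(i) {
      i[which.max(at$o[i])]
    })
    keep <- seq_len(nrow(at)) %in% unlist(best)
  }
  at <- at[keep, , drop = FALSE]

  # element symbol: prefer the element column, fall back to the atom name
  elesy <- if ("elesy" %in% names(at)) trimws(as.character(at$elesy)) else ""
  fallback <- !nzchar(elesy) | is.na(elesy)
  if (any(fallback)) {
    guess <- sub("^[0-9]+", "", trimws(at$elety[fallback]))
    elesy[fallback] <- substr(guess, 1, 1)
  }
  at$elesy <- .normalize_element(elesy)
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms in '", path, "'")

  # single-atom non-water hetero entities are ions, never chain members
  rkey <- paste(at$chain, at$resno, sep = "\r")
  n_in_res <- ave(seq_along(rkey), rkey, FUN = length)
  is_ion <- at$type == "HETATM" & n_in_res == 1L & !(at$resid %in% .WATER_CODES)
  ions <- data.frame(element = at$elesy[is_ion], x = at$x[is_ion],
                     y = at$y[is_ion], z = at$z[is_ion],
                     stringsAsFactors = FALSE)
  at <- at[!is_ion & !(at$resid %in% .WATER_CODES), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("structure '", path, "' contains zero polymer chains")

  atoms <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                      elety = at$elety, elesy = at$elesy,
                      x = at$x, y = at$y, z = at$z, b = at$b,
                      stringsAsFactors = FALSE)
  new_structure_model(atoms, ions, source = list(path = path, format = format))
}

#' Write a structure model to PDB or mmCIF
#'
#' Minimal writer used by the synthetic-complex generator and for round-trip
#' testing. Coordinates are written with 3 decimals and B-factors with 2, the
#' same quantisation both formats use, so a written model re-reads identically
#' in either dialect. Hetero ions are emitted as HETATM records on an unused
#' chain id.
#'
#' @param model a [structure_model].
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (extension-based).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  a <- model$atoms
  ions <- model$hetero_ions
  ion_chain <- setdiff(c(LETTERS, letters, 0:9), model_chains(model))[1]

  if (format == "pdb") {
    name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                    sprintf(" %-3s", a$elety))
    lines <- sprintf(
      "%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      "ATOM", seq_len(nrow(a)), name4, a$resname, a$chain, a$resno,
      a$x, a$y, a$z, 1, ifelse(is.na(a$b), 0, a$b), toupper(a$elesy))
    if (nrow(ions)) {
      el <- toupper(ions$element)
      lines <- c(lines, sprintf(
        "%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        "HETATM", nrow(a) + seq_len(nrow(ions)), sprintf(" %-3s", el),
        substr(el, 1, 3), ion_chain, seq_len(nrow(ions)),
        ions$x, ions$y, ions$z, 1, 0, el))
    }
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_ringsel", "#", "loop_",
             paste0("_atom_site.", c(
               "group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z",
               "occupancy", "B_iso_or_equiv", "auth_seq_id",
               "auth_comp_id", "auth_asym_id", "auth_atom_id",
               "pdbx_PDB_model_num")))
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      seq_len(nrow(a)), toupper(a$elesy), a$elety, a$resname, a$chain,
      a$resno, a$x, a$y, a$z, 1, ifelse(is.na(a$b), 0, a$b),
      a$resno, a$resname, a$chain, a$elety)
    if (nrow(ions)) {
      el <- toupper(ions$element)
      rows <- c(rows, sprintf(
        "HETATM %d %s %s . %s %s 2 . ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
        nrow(a) + seq_len(nrow(ions)), el, el, substr(el, 1, 3), ion_chain,
        ions$x, ions$y, ions$z, 1, 0,
        seq_len(nrow(ions)), substr(el, 1, 3), ion_chain, el))
    }
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Mask low-confidence residues
#'
#' Flags residues whose per-residue confidence (mean B-factor, i.e. pLDDT for
#' AlphaFold models) is strictly below `threshold`. Masked residues are
#' excluded from contact detection and superposition but keep their numbering.
#' The masked set is recomputed from scratch, so the operation is idempotent
#' and monotone in the threshold. Residues without a confidence value are
#' never masked.
#'
#' @param model a [structure_model].
#' @param threshold confidence cutoff in \[0, 100\]; the conventional
#'   AlphaFold confident/low boundary of 70 is the pipeline default
#'   (see [run_config()]).
#' @return a copy of `model` with the `masked` flag updated.
#' @export
mask_low_confidence <- function(model, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 100)
  model$residues$masked <- !is.na(model$residues$plddt) &
    model$residues$plddt < threshold
  model
}

#' Read a FASTA file of protein sequences
#'
#' @param path FASTA file.
#' @return named character vector of uppercase, ungapped sequences; names are
#'   the record ids (first whitespace-delimited token). Positions are 1-based
#'   throughout the package.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("failed to parse FASTA '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (length(ss) == 0L) stop("no records in FASTA file: ", path)
  seqs <- toupper(gsub("[-.* ]", "", as.character(ss)))
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(seqs)))
    stop("empty FASTA record: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  setNames(seqs, ids)
}

#' Packaged E3/E2 working sequences
#'
#' Returns the six working construct sequences used throughout the package
#' examples and tests: the MuRF1 RING+MFC construct (`MuRF1_RM`, residues
#' 1-115), full-length MuRF1 (`MuRF1_FL`), and the four E2 enzymes `UBE2E1`,
#' `UBE2J1`, `UBE2J2`, `UBE2L3`.
#'
#' @return named character vector of sequences.
#' @export
working_sequences <- function() {
  read_fasta(system.file("extdata", "murf_e2_sequences.fasta",
                         package = "ringsel", mustWork = TRUE))
}
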