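#' Canonical / common / selective contact classification
#'
#' The central inference of the pipeline: given interface contact maps for a
#' panel of complexes that share one E3 chain but carry homologous E2
#' partners, every contact is projected onto equivalence keys
#' `(E3 position, E2 reference position)` through an alignment-derived
#' [position_map], and each key is classified:
#'
#' 1. **canonical** - both sides of the key lie on positions catalogued for
#'    the generic RING-E3/E2 interface (zinc-centre motif, conserved Pro,
#'    linchpin Arg on the E3; alpha-1 basic pair, L4 bulky hydrophobic,
#'    SPA and pre-SPA motifs on the E2, in reference numbering);
#' 2. else **common** - present in every complex of the panel;
#' 3. else **selective** - present in exactly one complex (tagged with it);
#' 4. else **other** - present in a strict subset larger than one.
#'
#' Presence is binary on equivalence keys: a pair at 3.9 A in one complex
#' and 4.2 A in another is absent in the second; the cutoff is sharp by
#' design.
#'
#' @name selectivity
NULL

#' Canonical RING-E3/E2 interface reference positions
#'
#' Reads a reference table of canonical interface positions (editable data,
#' not code, so other E3 systems can supply their own). The packaged default
#' lists, on the E3 side, the zinc-centre pentapeptide (PICLE, 24-28), the
#' conserved Pro76 and the linchpin Arg79; on the E2 side (reference
#' numbering), the alpha-1 basic pair 51/54, the L4 bulky hydrophobic 108,
#' the pre-SPA triplet 137-139 and the SPA motif 140-142.
#'
#' @param path TSV with columns `side` (`e3` or `e2_ref`), `position`,
#'   `role`; default: the packaged reference file.
#' @return object of class `canonical_reference` with `e3_positions`,
#'   `e2_reference_positions` (named integer vectors, names = roles) and
#'   `table`.
#' @export
canonical_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "canonical_reference.tsv",
                                package = "ringsel", mustWork = TRUE)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("side", "position", "role")
  if (!all(need %in% names(tab)))
    stop("canonical reference must have columns: ",
         paste(need, collapse = ", "))
  if (!all(tab$side %in% c("e3", "e2_ref")))
    stop("canonical reference side must be 'e3' or 'e2_ref'")
  if (any(tab$position <= 0)) stop("canonical positions must be positive")
  e3 <- tab[tab$side == "e3", ]
  e2 <- tab[tab$side == "e2_ref", ]
  structure(list(
    e3_positions = setNames(as.integer(e3$position), e3$role),
    e2_reference_positions = setNames(as.integer(e2$position), e2$role),
    table = tab), class = "canonical_reference")
}

#' Project a contact map onto reference equivalence keys
#'
#' Each contact `(E3 residue, E2 residue)` becomes the key
#' `(E3 position, E2 reference position)` by inverting the position map for
#' the complex's E2. E2 residues with no reference equivalent (insertions
#' relative to the reference) are collected in `unprojected`, never silently
#' dropped. The E3 side is kept in its own numbering: all complexes of a
#' panel share the same E3 chain.
#'
#' @param cmap a `contact_map` whose chain A is the E3 and chain B the E2.
#' @param pmap a [position_map] in the panel's reference numbering.
#' @param target id of this complex's E2 in `pmap` (use the reference id
#'   itself when the E2 is the reference sequence; the map is then the
#'   identity).
#' @return list with `keys` (data.frame `e3_pos`, `e2_ref_pos`, plus the raw
#'   residue annotation) and `unprojected` (contacts at unmapped E2
#'   positions).
#' @export
project_contacts <- function(cmap, pmap, target) {
  cc <- cmap$contacts
  if (target == pmap$reference_id) {
    tgt2ref <- function(p) p
  } else {
    m <- pmap$maps[[target]]
    if (is.null(m))
      stop("position map does not cover target '", target, "'")
    tgt2ref <- function(p) m$ref_pos[match(p, m$target_pos)]
  }
  ref_pos <- tgt2ref(cc$resno_b)
  ok <- !is.na(ref_pos)
  keys <- data.frame(e3_pos = cc$resno_a[ok], e2_ref_pos = ref_pos[ok],
                     e3_resname = cc$resname_a[ok],
                     e2_resname = cc$resname_b[ok],
                     e2_pos = cc$resno_b[ok],
                     min_dist = cc$min_dist[ok],
                     stringsAsFactors = FALSE)
  keys <- keys[order(keys$e3_pos, keys$e2_ref_pos), , drop = FALSE]
  keys <- keys[!duplicated(keys[c("e3_pos", "e2_ref_pos")]), , drop = FALSE]
  rownames(keys) <- NULL
  list(keys = keys, unprojected = cc[!ok, , drop = FALSE])
}

#' Classify contacts across a panel of complexes
#'
#' Applies the four classification rules (canonical, common, selective,
#' other; see [selectivity]) to the union of projected equivalence keys of
#' all complexes.
#'
#' @param cmaps named list of >= 2 `contact_map`s (names = complex ids).
#' @param pmap a [position_map].
#' @param canon a [canonical_reference()].
#' @param targets named character vector mapping complex id -> E2 sequence
#'   id in `pmap`; defaults to the complex ids themselves.
#' @return object of class `contact_classification`: data.frame `keys` with
#'   `e3_pos`, `e2_ref_pos`, one presence column `present.<complex>` per
#'   complex, `n_present`, `class`, `selective_for`; plus `unprojected`,
#'   a per-complex list.
#' @export
classify_panel <- function(cmaps, pmap, canon, targets = NULL) {
  if (length(cmaps) < 2L)
    stop("a panel needs at least 2 complexes; classes are undefined for one")
  ids <- names(cmaps) %||% paste0("complex", seq_along(cmaps))
  names(cmaps) <- ids
  targets <- targets %||% setNames(ids, ids)

  proj <- lapply(ids, function(id) {
    project_contacts(cmaps[[id]], pmap, target = targets[[id]])
  })
  names(proj) <- ids

  all_keys <- unique(do.call(rbind, lapply(proj, function(p)
    p$keys[c("e3_pos", "e2_ref_pos")])))
  all_keys <- all_keys[order(all_keys$e3_pos, all_keys$e2_ref_pos), ,
                       drop = FALSE]
  rownames(all_keys) <- NULL

  kid <- function(df) paste(df$e3_pos, df$e2_ref_pos, sep = ":")
  universe <- kid(all_keys)
  pres <- vapply(ids, function(id) universe %in% kid(proj[[id]]$keys),
                 logical(length(universe)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = length(universe))
  colnames(pres) <- ids

  n_present <- rowSums(pres)
  is_canon <- all_keys$e3_pos %in% canon$e3_positions &
    all_keys$e2_ref_pos %in% canon$e2_reference_positions
  cls <- ifelse(is_canon, "canonical",
                ifelse(n_present == length(ids), "common",
                       ifelse(n_present == 1L, "selective", "other")))
  selective_for <- rep(NA_character_, length(universe))
  sel <- which(cls == "selective")
  if (length(sel))
    selective_for[sel] <- ids[apply(pres[sel, , drop = FALSE], 1, which)]

  keys <- cbind(all_keys,
                as.data.frame(pres)[, ids, drop = FALSE],
                n_present = n_present, class = cls,
                selective_for = selective_for,
                stringsAsFactors = FALSE)
  names(keys)[match(ids, names(keys))] <- paste0("present.", ids)
  structure(list(keys = keys, complexes = ids,
                 unprojected = lapply(proj, `[[`, "unprojected"),
                 projections = lapply(proj, `[[`, "keys")),
            class = "contact_classification")
}

#' @export
print.contact_classification <- function(x, ...) {
  cat("contact_classification over", length(x$complexes), "complexes:",
      nrow(x$keys), "equivalence keys\n")
  print(table(x$keys$class))
  invisible(x)
}

#' Per-complex selectivity report
#'
#' Resolves each classified key back to the residues of every complex in
#' which it is present and lists, per complex, its canonical, common and
#' selective contacts (plus the `other` bucket for keys shared by a strict
#' subset). Ordering is deterministic: complex, class, then key.
#'
#' @param classification a [classify_panel()] result.
#' @return data.frame with columns `complex_id`, `class`, `e3_pos`,
#'   `e3_resname`, `e2_ref_pos`, `e2_pos`, `e2_resname`, `min_dist`.
#' @export
selectivity_report <- function(classification) {
  keys <- classification$keys
  out <- list()
  for (id in classification$complexes) {
    pk <- classification$projections[[id]]
    present <- keys[keys[[paste0("present.", id)]], , drop = FALSE]
    if (nrow(present) == 0L) next
    m <- match(paste(present$e3_pos, present$e2_ref_pos),
               paste(pk$e3_pos, pk$e2_ref_pos))
    out[[id]] <- data.frame(
      complex_id = id, class = present$class,
      e3_pos = present$e3_pos, e3_resname = pk$e3_resname[m],
      e2_ref_pos = present$e2_ref_pos, e2_pos = pk$e2_pos[m],
      e2_resname = pk$e2_resname[m], min_dist = pk$min_dist[m],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(complex_id = character(), class = character(),
                      e3_pos = integer(), e3_resname = character(),
                      e2_ref_pos = integer(), e2_pos = integer(),
                      e2_resname = character(), min_dist = numeric(),
                      stringsAsFactors = FALSE))
  }
  rep <- do.call(rbind, out)
  cls_order <- c("canonical", "common", "selective", "other")
  rep <- rep[order(match(rep$complex_id, classification$complexes),
                   match(rep$class, cls_order),
                   rep$e3_pos, rep$e2_ref_pos), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Write a classification as TSV
#'
#' One row per equivalence key with per-complex presence flags.
#'
#' @param classification a [classify_panel()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(classification, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# equivalence keys (E3 position x E2 reference",
                   "position); presence per complex; 1-based numbering"),
             con)
  suppressWarnings(write.table(classification$keys, con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}
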