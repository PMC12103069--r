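#' Synthetic complexes, panels and titrations
#'
#' Generators for every input the pipeline consumes, with machine-readable
#' ground truth, so all stages are testable without external data: toy
#' two-chain complexes with engineered cross-chain contact geometry, zinc
#' sites and per-residue confidence profiles; panels of homologous complexes
#' with planted canonical/common/selective contacts; and simulated
#' serial-dilution fluorescence titrations. Toy residues are geometrically
#' valid but not stereochemically refined: the contact engine consumes
#' coordinates only.
#'
#' @name synthetic_data
NULL

# 4-atom residue template (CA at origin); max radius ~2.1 A
.RES_TEMPLATE <- data.frame(
  elety = c("C", "CA", "N", "O"),
  elesy = c("C", "C", "N", "O"),
  dx = c(1.2, 0, -1.2, 1.9), dy = c(0.8, 0, 0.8, 1.8), dz = c(0, 0, 0, 0),
  stringsAsFactors = FALSE)

#' Specify a synthetic two-chain complex
#'
#' @param chain_a_len,chain_b_len residue counts of chains A and B.
#' @param planted_contacts data.frame with columns `pos_a`, `pos_b`,
#'   `dist` (target minimum heavy-atom distance, Angstrom); may be empty.
#' @param zinc_sites list of `list(anchors = <chain-A positions>,
#'   dist = <coordination distance>)`; anchors become CYS with an SG ligand.
#' @param plddt_a,plddt_b per-residue confidence profiles (length 1 or
#'   chain length; default 90).
#' @param inter_chain_floor minimum distance guaranteed for all non-planted
#'   cross-chain residue pairs (default 6).
#' @param seq_a,seq_b optional sequences giving residue names (default
#'   poly-ALA).
#' @param seed RNG seed for the sub-Angstrom placement jitter.
#' @return object of class `synthetic_complex_spec`.
#' @export
synthetic_complex_spec <- function(chain_a_len, chain_b_len,
                                   planted_contacts = NULL,
                                   zinc_sites = list(),
                                   plddt_a = 90, plddt_b = 90,
                                   inter_chain_floor = 6,
                                   seq_a = NULL, seq_b = NULL, seed = 1) {
  pc <- planted_contacts %||%
    data.frame(pos_a = integer(), pos_b = integer(), dist = numeric())
  stopifnot(all(c("pos_a", "pos_b", "dist") %in% names(pc)))
  if (any(pc$dist >= inter_chain_floor))
    stop("planted distances must be below the inter-chain floor")
  if (any(pc$dist <= 0.5))
    stop("planted distances below 0.5 A are not representable")
  if (any(pc$pos_a < 1 | pc$pos_a > chain_a_len) ||
      any(pc$pos_b < 1 | pc$pos_b > chain_b_len))
    stop("planted positions outside chain lengths")
  if (anyDuplicated(pc[c("pos_a", "pos_b")]))
    stop("duplicate planted pair")
  if (any(tapply(pc$pos_a, pc$pos_b, function(x) length(unique(x))) > 1))
    stop("infeasible geometry: one chain-B residue planted against ",
         "two different chain-A residues")
  for (z in zinc_sites) {
    stopifnot(!is.null(z$anchors), !is.null(z$dist))
    if (any(z$anchors < 1 | z$anchors > chain_a_len))
      stop("zinc anchor outside chain A")
  }
  expand <- function(p, len) if (length(p) == 1L) rep(p, len) else p
  plddt_a <- expand(plddt_a, chain_a_len)
  plddt_b <- expand(plddt_b, chain_b_len)
  stopifnot(length(plddt_a) == chain_a_len, length(plddt_b) == chain_b_len,
            all(plddt_a >= 0 & plddt_a <= 100),
            all(plddt_b >= 0 & plddt_b <= 100))
  structure(list(chain_a_len = chain_a_len, chain_b_len = chain_b_len,
                 planted_contacts = pc, zinc_sites = zinc_sites,
                 plddt_a = plddt_a, plddt_b = plddt_b,
                 inter_chain_floor = inter_chain_floor,
                 seq_a = seq_a, seq_b = seq_b, seed = seed),
            class = "synthetic_complex_spec")
}

.res_names <- function(seq, len) {
  if (is.null(seq)) return(rep("ALA", len))
  s <- strsplit(toupper(seq), "")[[1]]
  stopifnot(length(s) == len)
  out <- unname(.AA3[s])
  out[is.na(out)] <- "UNK"
  out
}

.place_residue <- function(center, elety = NULL) {
  t <- .RES_TEMPLATE
  data.frame(elety = t$elety, elesy = t$elesy,
             x = center[1] + t$dx, y = center[2] + t$dy, z = center[3] + t$dz,
             stringsAsFactors = FALSE)
}

.min_dist_tables <- function(a, b) {
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
    outer(a$z, b$z, "-")^2
  sqrt(min(d2))
}

#' Build a synthetic two-chain complex
#'
#' Arranges 4-atom toy residues so that every planted cross-chain pair
#' achieves its target minimum heavy-atom distance to within 0.05 A (exact
#' 1-D root finding on the separation) while every non-planted cross-chain
#' pair stays beyond the floor; the construction is verified by a naive
#' all-pairs scan before returning and errors if any constraint fails.
#' Confidence profiles are written into the B-factor column so parsing
#' exercises the same path as real predicted-model files. Deterministic
#' under `spec$seed`.
#'
#' @param spec a [synthetic_complex_spec()].
#' @return list with `model` (a [structure_model], chains `A` and `B`) and
#'   `ledger` (planted pairs, zinc ligand bookkeeping, confidence profiles).
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_complex_spec"))
  pc <- spec$planted_contacts
  set.seed(spec$seed)
  jit <- function(n) runif(n, -0.3, 0.3)

  names_a <- .res_names(spec$seq_a, spec$chain_a_len)
  names_b <- .res_names(spec$seq_b, spec$chain_b_len)

  centers_a <- cbind(6 * seq_len(spec$chain_a_len) + jit(spec$chain_a_len),
                     jit(spec$chain_a_len),
                     -500 + jit(spec$chain_a_len))
  centers_b <- cbind(6 * seq_len(spec$chain_b_len) + jit(spec$chain_b_len),
                     jit(spec$chain_b_len),
                     500 + jit(spec$chain_b_len))

  # planted pairs live in isolated cells at z = 0, grouped by A-residue
  if (nrow(pc)) {
    groups <- split(seq_len(nrow(pc)), pc$pos_a)
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      ia <- pc$pos_a[rows[1]]
      cell <- c(150 * g, 0, 0)
      centers_a[ia, ] <- cell
      a_res <- .place_residue(cell)
      for (m in seq_along(rows)) {
        ib <- pc$pos_b[rows[m]]
        d <- pc$dist[rows[m]]
        th <- 2 * pi * (m - 1) / length(rows)
        u <- c(sin(th), cos(th), 0)
        f <- function(t) {
          .min_dist_tables(a_res, .place_residue(cell + t * u)) - d
        }
        t_star <- stats::uniroot(f, c(0.05, 80), tol = 1e-9)$root
        centers_b[ib, ] <- cell + t_star * u
      }
    }
  }

  build_chain <- function(chain, centers, rnames, plddt) {
    n <- nrow(centers)
    t <- .RES_TEMPLATE
    k <- nrow(t)
    idx <- rep(seq_len(n), each = k)
    data.frame(chain = chain, resno = idx, resname = rnames[idx],
               elety = rep(t$elety, n), elesy = rep(t$elesy, n),
               x = centers[idx, 1] + rep(t$dx, n),
               y = centers[idx, 2] + rep(t$dy, n),
               z = centers[idx, 3] + rep(t$dz, n),
               b = plddt[idx], stringsAsFactors = FALSE)
  }
  atoms_a <- build_chain("A", centers_a, names_a, spec$plddt_a)
  atoms_b <- build_chain("B", centers_b, names_b, spec$plddt_b)

  # zinc sites: anchors become CYS and gain an SG at the coordination radius
  ions <- NULL
  zinc_ledger <- list()
  for (s in seq_along(spec$zinc_sites)) {
    zs <- spec$zinc_sites[[s]]
    anchor_ca <- centers_a[zs$anchors, , drop = FALSE]
    zn <- colMeans(anchor_ca) + c(0, -12, -8 * s)
    sg <- do.call(rbind, lapply(seq_along(zs$anchors), function(k) {
      u <- anchor_ca[k, ] - zn
      u <- u / sqrt(sum(u^2))
      p <- zn + zs$dist * u
      data.frame(chain = "A", resno = zs$anchors[k], resname = "CYS",
                 elety = "SG", elesy = "S", x = p[1], y = p[2], z = p[3],
                 b = spec$plddt_a[zs$anchors[k]], stringsAsFactors = FALSE)
    }))
    atoms_a$resname[atoms_a$resno %in% zs$anchors] <- "CYS"
    atoms_a <- rbind(atoms_a, sg)
    ions <- rbind(ions, data.frame(element = "Zn", x = zn[1], y = zn[2],
                                   z = zn[3], stringsAsFactors = FALSE))
    zinc_ledger[[s]] <- list(anchors = zs$anchors, dist = zs$dist,
                             coords = zn)
  }

  model <- new_structure_model(rbind(atoms_a, atoms_b), ions,
                               source = list(path = NA_character_,
                                             format = "synthetic"))

  # verify the construction against its own ledger: every cross-chain atom
  # pair within the floor must belong to a planted residue pair, and every
  # planted pair must realise its target distance
  aa <- model$atoms[model$atoms$chain == "A", ]
  ab <- model$atoms[model$atoms$chain == "B", ]
  D2 <- outer(aa$x, ab$x, "-")^2 + outer(aa$y, ab$y, "-")^2 +
    outer(aa$z, ab$z, "-")^2
  planted_key <- paste(pc$pos_a, pc$pos_b)
  hits <- which(D2 <= spec$inter_chain_floor^2, arr.ind = TRUE)
  if (nrow(hits)) {
    hit_key <- unique(paste(aa$resno[hits[, 1]], ab$resno[hits[, 2]]))
    stray <- setdiff(hit_key, planted_key)
    if (length(stray))
      stop("infeasible geometry: non-planted pair(s) ",
           paste(stray, collapse = ", "), " violate the floor")
  }
  for (r in seq_len(nrow(pc))) {
    d <- sqrt(min(D2[aa$resno == pc$pos_a[r], ab$resno == pc$pos_b[r]]))
    if (abs(d - pc$dist[r]) > 0.05)
      stop("infeasible geometry: planted pair ", pc$pos_a[r], "-",
           pc$pos_b[r], " realised at ", round(d, 3),
           " instead of ", pc$dist[r])
  }

  list(model = model,
       ledger = list(planted = pc, zinc = zinc_ledger,
                     plddt_a = spec$plddt_a, plddt_b = spec$plddt_b,
                     inter_chain_floor = spec$inter_chain_floor,
                     chain_a = "A", chain_b = "B"))
}

#' Build a panel of homologous synthetic complexes with planted classes
#'
#' One complex per E2 sequence, all sharing the E3 chain. Contacts are
#' planted so that [classify_panel()] must recover the intended class of
#' every planted key: `canonical` and `common` keys are planted in every
#' complex, `selective` keys in exactly one, `other` keys in the first two
#' complexes (needs a panel of >= 3). The plan is validated up front: a key
#' whose positions would be classified differently from its intended class
#' (e.g. a `common` key sitting on canonical positions) is a plan conflict.
#'
#' @param plan data.frame with columns `e3_pos`, `e2_ref_pos`, `class`
#'   (canonical/common/selective/other) and `selective_for` (complex id,
#'   required for selective keys).
#' @param e2_sequences named character vector of E2 sequences; the default
#'   is the packaged E2 set ([working_sequences()]), so the position map in
#'   play is the real one while coordinates remain synthetic.
#' @param reference_id reference E2 for position mapping (default the first
#'   sequence).
#' @param e3_sequence E3 sequence (default the packaged RING+MFC construct).
#' @param canon a [canonical_reference()] used for plan validation.
#' @param pmap optional pre-built [position_map] (rebuilt otherwise).
#' @param planted_dist target distance for planted contacts (default 3.5).
#' @param seed RNG seed.
#' @return list with `models` (named list of [structure_model]s), `cmaps`
#'   convenience extraction left to the caller, `pmap`, and `ledger`
#'   (data.frame of planted keys with intended classes, same schema as the
#'   classification output).
#' @export
make_panel <- function(plan, e2_sequences = NULL, reference_id = NULL,
                       e3_sequence = NULL, canon = canonical_reference(),
                       pmap = NULL, planted_dist = 3.5, seed = 1) {
  if (is.null(e2_sequences)) {
    ws <- working_sequences()
    e2_sequences <- ws[c("UBE2E1", "UBE2J1", "UBE2J2", "UBE2L3")]
  }
  e3_sequence <- e3_sequence %||% working_sequences()[["MuRF1_RM"]]
  ids <- names(e2_sequences)
  if (length(ids) < 2L) stop("a panel needs at least 2 complexes")
  reference_id <- reference_id %||% ids[1]
  stopifnot(all(c("e3_pos", "e2_ref_pos", "class") %in% names(plan)))
  if (!"selective_for" %in% names(plan)) plan$selective_for <- NA_character_
  if (anyDuplicated(plan[c("e3_pos", "e2_ref_pos")]))
    stop("plan conflict: duplicate key")
  if (!all(plan$class %in% c("canonical", "common", "selective", "other")))
    stop("unknown intended class")
  sel <- plan$class == "selective"
  if (any(sel & (is.na(plan$selective_for) |
                 !plan$selective_for %in% ids)))
    stop("selective keys need a valid selective_for complex id")
  if (any(plan$class == "other") && length(ids) < 3L)
    stop("'other' keys need a panel of at least 3 complexes")

  # intended class must match what the rules would produce
  is_canon_key <- plan$e3_pos %in% canon$e3_positions &
    plan$e2_ref_pos %in% canon$e2_reference_positions
  expected <- ifelse(is_canon_key, "canonical",
                     ifelse(plan$class %in% c("canonical", "common"),
                            "common",
                            ifelse(plan$class == "selective", "selective",
                                   "other")))
  bad <- expected != plan$class
  if (any(bad))
    stop("plan conflict: key(s) ",
         paste(plan$e3_pos[bad], plan$e2_ref_pos[bad], sep = ":",
               collapse = ", "),
         " would classify as ", paste(unique(expected[bad]), collapse = "/"),
         " not ", paste(unique(plan$class[bad]), collapse = "/"))

  if (is.null(pmap)) {
    pmap <- build_position_map(e2_sequences[reference_id],
                               e2_sequences[setdiff(ids, reference_id)])
  }

  present_in <- function(row) {
    switch(row$class,
           canonical = ids, common = ids,
           selective = row$selective_for,
           other = ids[1:2])
  }

  models <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    rows <- plan[vapply(seq_len(nrow(plan)),
                        function(i) id %in% present_in(plan[i, ]),
                        logical(1)), , drop = FALSE]
    if (nrow(rows)) {
      tgt <- if (id == reference_id) rows$e2_ref_pos
             else map_position(pmap, id, rows$e2_ref_pos)
      if (any(is.na(tgt)))
        stop("plan not realizable: reference position(s) ",
             paste(rows$e2_ref_pos[is.na(tgt)], collapse = ", "),
             " have no equivalent in ", id)
      pc <- data.frame(pos_a = rows$e3_pos, pos_b = tgt,
                       dist = planted_dist)
    } else {
      pc <- NULL
    }
    spec <- synthetic_complex_spec(
      chain_a_len = nchar(e3_sequence),
      chain_b_len = nchar(e2_sequences[[id]]),
      planted_contacts = pc,
      seq_a = e3_sequence, seq_b = e2_sequences[[id]],
      seed = seed + k)
    models[[id]] <- make_complex(spec)$model
  }

  ledger <- plan[order(plan$e3_pos, plan$e2_ref_pos), , drop = FALSE]
  rownames(ledger) <- NULL
  list(models = models, pmap = pmap, ledger = ledger,
       reference_id = reference_id)
}

#' Simulate a fluorescence titration series
#'
#' Generates `signal = baseline + amplitude * fraction_bound + noise` over a
#' geometric dilution series, emulating an initial-fluorescence binding
#' assay with constant labeled receptor: 16 points of 2-fold dilution,
#' receptor at 10 nM, additive Gaussian noise with standard deviation
#' expressed as a percentage of the amplitude (2% by default).
#'
#' @param kd true dissociation constant (molar).
#' @param receptor_conc molar (default 1e-8).
#' @param c_max top ligand concentration (default `50 * kd`, comfortably
#'   above the transition).
#' @param n points (default 16).
#' @param factor dilution factor (default 2).
#' @param noise_pct Gaussian noise sd as a fraction of |amplitude|
#'   (default 0.02).
#' @param baseline,amplitude signal model (defaults 1000 and 300; the
#'   amplitude sign is free, fluorescence may rise or fall on binding).
#' @param seed RNG seed (deterministic series for equal seeds).
#' @param replicate_id label.
#' @return a [titration_series]; the generating truth is attached as
#'   attribute `truth`.
#' @export
simulate_titration <- function(kd, receptor_conc = 1e-8, c_max = 50 * kd,
                               n = 16, factor = 2, noise_pct = 0.02,
                               baseline = 1000, amplitude = 300,
                               seed = 1, replicate_id = "sim") {
  stopifnot(kd > 0, receptor_conc > 0)
  l <- serial_dilution(c_max, n, factor)
  f <- fraction_bound(l, receptor_conc, kd)
  set.seed(seed)
  noise <- rnorm(n, 0, noise_pct * abs(amplitude))
  ts <- titration_series(l, baseline + amplitude * f + noise,
                         receptor_conc = receptor_conc,
                         replicate_id = replicate_id)
  attr(ts, "truth") <- list(kd = kd, baseline = baseline,
                            amplitude = amplitude, noise_pct = noise_pct,
                            c_max = c_max, factor = factor)
  ts
}

#' Synthetic MuRF3-like RING domain surrogate
#'
#' Returns the RING-domain subsequence of the packaged MuRF1 construct
#' (residues 22-86, 65 residues) together with a *synthetic* MuRF3-like
#' counterpart. The surrogate is constructed, not a database sequence: it
#' applies to the MuRF1 RING the divergence pattern reported for the
#' MuRF1/MuRF3 RING pair - 5 substitutions to positively-scoring (similar)
#' residues and 5 to non-positive (dissimilar) ones out of 65 positions,
#' sparing the zinc-coordinating residues, the conserved Pro/linchpin-Arg
#' pair and the E2-interaction positions, which are conserved between the
#' two ligases. Use it where the analysis needs a MuRF3-like RING and no
#' sequence database is available; it is not the real TRIM54 sequence.
#'
#' @param start,end 1-based RING boundaries on the MuRF1 construct
#'   (defaults 22 and 86).
#' @return named character vector with `murf1_ring` and
#'   `murf3_like_ring_synthetic`.
#' @export
murf3_like_ring <- function(start = 22, end = 86) {
  rm1 <- working_sequences()[["MuRF1_RM"]]
  chars <- strsplit(rm1, "")[[1]]
  similar <- c("29" = "L", "34" = "I", "60" = "S", "62" = "K", "81" = "D")
  dissimilar <- c("30" = "S", "42" = "P", "58" = "G", "63" = "R", "68" = "P")
  for (p in names(similar)) chars[as.integer(p)] <- similar[[p]]
  for (p in names(dissimilar)) chars[as.integer(p)] <- dissimilar[[p]]
  c(murf1_ring = substr(rm1, start, end),
    murf3_like_ring_synthetic = paste(chars[start:end], collapse = ""))
}
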