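#' Global pairwise alignment and position equivalence maps
#'
#' Affine-gap global alignment (Needleman-Wunsch / Gotoh) with the EMBOSS
#' needle conventions: BLOSUM62 scoring, gap_open 10 / gap_extend 0.5 where a
#' gap of length L costs `gap_open + gap_extend * (L - 1)`, end gaps free by
#' default, and identity/similarity percentages computed over all alignment
#' columns including gap columns. Similarity counts columns whose
#' substitution score is strictly positive.
#'
#' @name seqalign
NULL

#' BLOSUM62 substitution matrix used by the aligner
#'
#' The Biostrings BLOSUM62 restricted to the 20 amino acids plus X, with X
#' scored 0 against everything (unknown residues are neutral).
#'
#' @return integer-valued substitution matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c(sort(unname(.AA1)), "X")
  m <- m[keep, keep]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

.check_protein <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " must be a non-empty protein sequence")
  toupper(seq)
}

#' Global pairwise alignment with affine gaps
#'
#' Returns one optimal global alignment of two protein sequences under
#' affine gap penalties, with a fixed traceback tie-break (diagonal, then
#' vertical = gap in `seq_b`, then horizontal = gap in `seq_a`) so results
#' are deterministic.
#'
#' @param seq_a,seq_b protein sequences (single strings; X tolerated and
#'   scored 0).
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open penalty for the first residue of a gap (default 10).
#' @param gap_extend penalty per additional gap residue (default 0.5).
#' @param endweight if FALSE (default, the needle convention) terminal gaps
#'   are not penalised.
#' @return object of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `score`, `pct_identity`,
#'   `pct_similarity` (percent over all alignment columns), `n_columns`.
#' @export
needleman_wunsch <- function(seq_a, seq_b, matrix = blosum62(),
                             gap_open = 10, gap_extend = 0.5,
                             endweight = FALSE) {
  seq_a <- .check_protein(seq_a, "seq_a")
  seq_b <- .check_protein(seq_b, "seq_b")
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  bad <- setdiff(unique(c(a, b)), rownames(matrix))
  if (length(bad))
    stop("residues not covered by the substitution matrix: ",
         paste(bad, collapse = ", "))
  n <- length(a)
  m <- length(b)
  NEG <- -1e18
  sub <- matrix[a, b, drop = FALSE]          # n x m substitution scores

  # three-state Gotoh; state X consumes seq_a (gap in b), Y consumes seq_b
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  lead <- function(k) if (endweight) -(gap_open + gap_extend * (k - 1)) else 0
  if (m > 0) Y[1, 2:(m + 1)] <- vapply(1:m, lead, numeric(1))
  if (n > 0) X[2:(n + 1), 1] <- vapply(1:n, lead, numeric(1))

  for (i in 1:n) {
    prevM <- M[i, ]; prevX <- X[i, ]; prevY <- Y[i, ]
    if (m > 0) {
      M[i + 1, 2:(m + 1)] <- sub[i, ] +
        pmax(prevM[1:m], prevX[1:m], prevY[1:m])
      X[i + 1, 2:(m + 1)] <- pmax(pmax(prevM[2:(m + 1)], prevY[2:(m + 1)]) -
                                    gap_open,
                                  prevX[2:(m + 1)] - gap_extend)
    }
    # horizontal state via running maximum of gap entry points in this row
    g <- pmax(M[i + 1, ], X[i + 1, ]) + gap_extend * (0:m)
    cg <- cummax(g)
    if (m > 0)
      Y[i + 1, 2:(m + 1)] <- pmax(Y[i + 1, 2:(m + 1)],
                                  cg[1:m] - gap_open - gap_extend * (0:(m - 1)))
  }

  tol <- 1e-9
  states <- list(M = M, X = X, Y = Y)
  if (endweight) {
    ends <- data.frame(i = n, j = m, state = c("M", "X", "Y"),
                       score = c(M[n + 1, m + 1], X[n + 1, m + 1],
                                 Y[n + 1, m + 1]), stringsAsFactors = FALSE)
  } else {
    # free trailing gaps: end anywhere on the last row or column
    ends <- rbind(
      data.frame(i = n, j = 0:m, state = "M", score = M[n + 1, ]),
      data.frame(i = n, j = 0:m, state = "X", score = X[n + 1, ]),
      data.frame(i = n, j = 0:m, state = "Y", score = Y[n + 1, ]),
      data.frame(i = 0:n, j = m, state = "M", score = M[, m + 1]),
      data.frame(i = 0:n, j = m, state = "X", score = X[, m + 1]),
      data.frame(i = 0:n, j = m, state = "Y", score = Y[, m + 1]))
  }
  best <- max(ends$score)
  # deterministic start: most-consumed cell first, then state order M > X > Y
  cand <- ends[ends$score >= best - tol, , drop = FALSE]
  cand <- cand[order(-(cand$i + cand$j), match(cand$state, c("M", "X", "Y"))), ]
  i <- cand$i[1]; j <- cand$j[1]; st <- cand$state[1]

  out_a <- character(0)
  out_b <- character(0)
  if (i < n) { out_a <- a[n:(i + 1)]; out_b <- rep("-", n - i) }
  if (j < m) { out_a <- c(rep("-", m - j), out_a); out_b <- c(b[m:(j + 1)], out_b) }

  near <- function(x, y) abs(x - y) <= tol
  while (i > 0 || j > 0) {
    if (st == "M") {
      if (i == 0 || j == 0) break
      out_a <- c(out_a, a[i]); out_b <- c(out_b, b[j])
      want <- M[i + 1, j + 1] - sub[i, j]
      st <- if (near(M[i, j], want)) "M" else if (near(X[i, j], want)) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (st == "X") {
      out_a <- c(out_a, a[i]); out_b <- c(out_b, "-")
      if (i == 1 && !endweight) { i <- 0; st <- "M"; next }
      v <- X[i + 1, j + 1]
      st <- if (near(M[i, j + 1] - gap_open, v)) "M"
            else if (near(X[i, j + 1] - gap_extend, v)) "X" else "Y"
      i <- i - 1
    } else {
      out_a <- c(out_a, "-"); out_b <- c(out_b, b[j])
      if (j == 1 && !endweight) { j <- 0; st <- "M"; next }
      v <- Y[i + 1, j + 1]
      st <- if (near(M[i + 1, j] - gap_open, v)) "M"
            else if (near(Y[i + 1, j] - gap_extend, v)) "Y" else "X"
      j <- j - 1
    }
    if (i == 0 && j == 0) break
    if (i == 0 && st != "Y") st <- "Y"
    if (j == 0 && st != "X") st <- "X"
  }
  if (i > 0) { out_a <- c(out_a, a[i:1]); out_b <- c(out_b, rep("-", i)) }
  if (j > 0) { out_a <- c(out_a, rep("-", j)); out_b <- c(out_b, b[j:1]) }

  aligned_a <- paste(rev(out_a), collapse = "")
  aligned_b <- paste(rev(out_b), collapse = "")
  stats <- .alignment_stats(aligned_a, aligned_b, matrix)
  structure(c(list(aligned_a = aligned_a, aligned_b = aligned_b,
                   score = best), stats),
            class = "alignment_result")
}

.alignment_stats <- function(aligned_a, aligned_b, matrix = blosum62()) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  ncol_ <- length(ca)
  both <- ca != "-" & cb != "-"
  ident <- sum(both & ca == cb)
  simil <- sum(matrix[cbind(ca[both], cb[both])] > 0)
  list(pct_identity = 100 * ident / ncol_,
       pct_similarity = 100 * simil / ncol_,
       n_columns = ncol_)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment: %d columns, score %.1f, identity %.1f%%, similarity %.1f%%\n",
              x$n_columns, x$score, x$pct_identity, x$pct_similarity))
  w <- 60
  for (k in seq(1, x$n_columns, by = w)) {
    cat(substr(x$aligned_a, k, min(k + w - 1, x$n_columns)), "\n")
    cat(substr(x$aligned_b, k, min(k + w - 1, x$n_columns)), "\n\n")
  }
  invisible(x)
}

#' Identity and similarity of two RING-domain sequences
#'
#' Aligns two RING-domain subsequences globally with EMBOSS-default
#' parameters and reports percent identity and percent similarity (positive
#' BLOSUM62 score) over all alignment columns. The RING-domain boundaries
#' are an input: pass the delimited subsequences, not full-length proteins.
#'
#' @param ring_a,ring_b RING-domain subsequences.
#' @return list with `pct_identity`, `pct_similarity` and the full
#'   `alignment`.
#' @export
rings_identity <- function(ring_a, ring_b) {
  aln <- needleman_wunsch(ring_a, ring_b)
  list(pct_identity = aln$pct_identity,
       pct_similarity = aln$pct_similarity,
       alignment = aln)
}

#' Alignment-derived residue position equivalence map
#'
#' Aligns each target sequence to the reference (star topology) and records
#' 1-based position correspondences for match/mismatch columns only; gap
#' columns never create entries, so each map is strictly monotone in both
#' coordinates. Equivalence statements across homologous E2 enzymes are
#' expressed in the reference numbering.
#'
#' @param reference named length-1 character vector (name = id).
#' @param targets named character vector of target sequences.
#' @param ... passed to [needleman_wunsch()].
#' @return object of class `position_map`: `reference_id` and `maps`, a list
#'   per target of data.frames (`ref_pos`, `ref_aa`, `target_pos`,
#'   `target_aa`).
#' @export
build_position_map <- function(reference, targets, ...) {
  stopifnot(length(reference) == 1L, !is.null(names(reference)),
            length(targets) >= 1L, !is.null(names(targets)))
  ref_id <- names(reference)
  maps <- lapply(seq_along(targets), function(k) {
    aln <- needleman_wunsch(reference[[1]], targets[[k]], ...)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    ref_pos <- cumsum(ca != "-")
    tgt_pos <- cumsum(cb != "-")
    keep <- ca != "-" & cb != "-"
    data.frame(ref_pos = ref_pos[keep], ref_aa = ca[keep],
               target_pos = tgt_pos[keep], target_aa = cb[keep],
               stringsAsFactors = FALSE)
  })
  names(maps) <- names(targets)
  structure(list(reference_id = ref_id, maps = maps), class = "position_map")
}

#' @export
print.position_map <- function(x, ...) {
  cat("position_map: reference", x$reference_id, "->",
      paste(names(x$maps), collapse = ", "), "\n")
  for (id in names(x$maps))
    cat(sprintf("  %s: %d mapped positions\n", id, nrow(x$maps[[id]])))
  invisible(x)
}

#' Map one reference position through a position map
#'
#' @param pmap a [position_map].
#' @param target target id.
#' @param ref_pos 1-based reference position(s).
#' @return integer target positions (NA where unmapped).
#' @export
map_position <- function(pmap, target, ref_pos) {
  m <- pmap$maps[[target]]
  if (is.null(m)) stop("no map for target '", target, "'")
  m$target_pos[match(ref_pos, m$ref_pos)]
}

#' Write a position map as TSV
#'
#' Columns: ref_pos, ref_aa, target_id, target_pos, target_aa (1-based).
#' @param pmap a [position_map].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_position_map_tsv <- function(pmap, path) {
  rows <- do.call(rbind, lapply(names(pmap$maps), function(id) {
    m <- pmap$maps[[id]]
    data.frame(ref_pos = m$ref_pos, ref_aa = m$ref_aa, target_id = id,
               target_pos = m$target_pos, target_aa = m$target_aa,
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference %s; positions 1-based", pmap$reference_id),
             con)
  suppressWarnings(write.table(rows, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Locate a motif in a sequence
#'
#' @param sequence protein sequence.
#' @param motif exact motif to find (non-empty).
#' @return 1-based start of the first occurrence, or `NA_integer_` when the
#'   motif is absent.
#' @export
motif_locate <- function(sequence, motif) {
  sequence <- .check_protein(sequence, "sequence")
  if (!is.character(motif) || !nzchar(motif)) stop("motif must be non-empty")
  pos <- regexpr(toupper(motif), sequence, fixed = TRUE)[1]
  if (pos < 0) NA_integer_ else as.integer(pos)
}
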