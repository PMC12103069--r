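#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of paired coordinate sets via SVD with
#' explicit reflection correction, and pairwise RMSD comparison of
#' alternative models of the same complex.
#'
#' @name superposition
NULL

#' Kabsch superposition of paired coordinate sets
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `coords_mov` and `coords_ref` over all rigid motions. Reflections are
#' rejected by sign-correcting the smallest singular vector, so the returned
#' rotation always has determinant +1.
#'
#' @param coords_ref,coords_mov N x 3 matrices (Angstrom), N >= 3, paired
#'   row-by-row.
#' @return list of class `superposition_result` with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n_atoms`. The fitted
#'   moving set is `coords_mov %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  if (ncol(coords_ref) != 3L || ncol(coords_mov) != 3L)
    stop("coordinate sets must be N x 3")
  n <- nrow(coords_ref)
  if (nrow(coords_mov) != n) stop("coordinate sets must have equal size")
  if (n < 3L) stop("at least 3 paired atoms are required")

  cr <- colMeans(coords_ref)
  cm <- colMeans(coords_mov)
  p <- sweep(coords_ref, 2, cr)
  q <- sweep(coords_mov, 2, cm)
  if (max(svd(q)$d) < 1e-12 || svd(q)$d[2] < 1e-9 * max(svd(q)$d, 1))
    stop("degenerate (collinear or coincident) moving coordinates")

  h <- crossprod(q, p)                 # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- q %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - p)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - rot %*% cm),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: %d paired atoms, RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Pair CA coordinates of two models for superposition
#'
#' Matches residues 1:1 between two models, either by identical residue
#' numbers (`mapping = NULL`) or through an alignment-derived
#' [position_map] when the chains carry homologous but different sequences.
#' Masked residues and residues missing a CA in either model are skipped.
#'
#' @param model_a,model_b [structure_model]s.
#' @param chain_a,chain_b chain to pair in each model (defaults: first
#'   chain).
#' @param mapping NULL for identity pairing on residue numbers, or a
#'   [position_map] whose reference numbering applies to `model_a` and with
#'   `target` naming the map to use for `model_b`.
#' @param target target id in `mapping` (required when mapping is given).
#' @return list with `ref`, `mov` (N x 3 CA coordinate matrices) and
#'   `residues` (data.frame of paired residue numbers).
#' @export
pair_by_alignment <- function(model_a, model_b,
                              chain_a = model_chains(model_a)[1],
                              chain_b = model_chains(model_b)[1],
                              mapping = NULL, target = NULL) {
  ca_tab <- function(model, chain) {
    a <- .atoms_of(model, chain, unmasked_only = TRUE)
    a <- a[a$elety == "CA", , drop = FALSE]
    a[order(a$resno), , drop = FALSE]
  }
  ca_a <- ca_tab(model_a, chain_a)
  ca_b <- ca_tab(model_b, chain_b)

  if (is.null(mapping)) {
    common <- intersect(ca_a$resno, ca_b$resno)
    pos_a <- common
    pos_b <- common
  } else {
    if (!inherits(mapping, "position_map")) stop("mapping must be a position_map")
    if (is.null(target)) stop("a target id is required with a position_map")
    m <- mapping$maps[[target]]
    if (is.null(m)) stop("no map for target '", target, "'")
    keep <- m$ref_pos %in% ca_a$resno & m$target_pos %in% ca_b$resno
    pos_a <- m$ref_pos[keep]
    pos_b <- m$target_pos[keep]
  }
  if (length(pos_a) < 3L) stop("fewer than 3 matched residues with CA")
  ia <- match(pos_a, ca_a$resno)
  ib <- match(pos_b, ca_b$resno)
  list(ref = as.matrix(ca_a[ia, c("x", "y", "z")]),
       mov = as.matrix(ca_b[ib, c("x", "y", "z")]),
       residues = data.frame(resno_a = pos_a, resno_b = pos_b))
}

#' Pairwise RMSD matrix over alternative models of one complex
#'
#' Superposes every pair of models on matched CA atoms (identity pairing on
#' residue numbers; the models are assumed to share chain sequences, as
#' independent predictions of the same complex do).
#'
#' @param models list of >= 2 [structure_model]s.
#' @param chain chain to compare (default: first chain of the first model).
#' @return symmetric matrix of RMSDs (Angstrom) with zero diagonal.
#' @export
compare_predictions <- function(models, chain = NULL) {
  if (length(models) < 2L) stop("need at least 2 models")
  chain <- chain %||% model_chains(models[[1]])[1]
  n <- length(models)
  out <- matrix(0, n, n)
  labs <- names(models) %||% paste0("model", seq_len(n))
  dimnames(out) <- list(labs, labs)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pr <- pair_by_alignment(models[[i]], models[[j]],
                              chain_a = chain, chain_b = chain)
      out[i, j] <- out[j, i] <- kabsch_superpose(pr$ref, pr$mov)$rmsd
    }
  }
  out
}
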