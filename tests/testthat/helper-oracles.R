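# Independent oracles and small fixture builders shared across tests.
# Each oracle is deliberately naive (enumeration, brute force, generic
# optimisation) and stays independent of the implementation it checks.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# brute-force minimum distance over all atom pairs of two atom tables
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(b$x[j], b$y[j], b$z[j]))^2))
      if (d < best) best <- d
    }
  }
  best
}

# exhaustive enumeration of all global alignments (as column paths) and
# their affine-gap scores; returns the maximum score
enum_align_score <- function(seq_a, seq_b, mat = blosum62(),
                             gap_open = 10, gap_extend = 0.5,
                             endweight = FALSE) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a)
  m <- length(b)
  best <- -Inf
  score_path <- function(moves) {
    # moves: vector over columns, "D" (aligned), "U" (gap in b), "L" (gap in a)
    i <- 0; j <- 0; s <- 0
    runs <- rle(moves)
    col_start <- cumsum(c(1, runs$lengths))[seq_along(runs$lengths)]
    for (r in seq_along(runs$values)) {
      v <- runs$values[r]; len <- runs$lengths[r]
      if (v == "D") {
        for (k in seq_len(len)) {
          i <- i + 1; j <- j + 1
          s <- s + mat[a[i], b[j]]
        }
      } else {
        if (v == "U") i <- i + len else j <- j + len
        touches_end <- col_start[r] == 1 ||
          (col_start[r] + len - 1) == length(moves)
        if (!(endweight == FALSE && touches_end))
          s <- s - (gap_open + gap_extend * (len - 1))
      }
    }
    s
  }
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      best <<- max(best, score_path(moves))
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(moves, "D"))
    if (i < n) rec(i + 1, j, c(moves, "U"))
    if (j < m) rec(i, j + 1, c(moves, "L"))
  }
  rec(0, 0, character(0))
  best
}

# quaternion-parameterised numeric minimisation of RMSD over rotations
quaternion_rmsd <- function(ref, mov) {
  p <- sweep(ref, 2, colMeans(ref))
  q <- sweep(mov, 2, colMeans(mov))
  rot_of <- function(v) {
    v <- v / sqrt(sum(v^2))
    w <- v[1]; x <- v[2]; y <- v[3]; z <- v[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(v) sqrt(mean(rowSums((q %*% t(rot_of(v)) - p)^2)))
  best <- Inf
  for (s in 1:20) {
    v0 <- rnorm(4)
    o <- optim(v0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# presence-matrix re-evaluation of the four classification rules
oracle_classes <- function(pres, e3_pos, e2_ref_pos, canon) {
  n_complex <- ncol(pres)
  vapply(seq_len(nrow(pres)), function(k) {
    if (e3_pos[k] %in% canon$e3_positions &&
        e2_ref_pos[k] %in% canon$e2_reference_positions) return("canonical")
    np <- sum(pres[k, ])
    if (np == n_complex) return("common")
    if (np == 1) return("selective")
    "other"
  }, character(1))
}

# bisection solve of the 1:1 equilibrium kd*B = (r-B)(l-B) for bound B
bisect_fraction_bound <- function(l, r, kd, tol = 1e-14) {
  g <- function(B) kd * B - (r - B) * (l - B)
  lo <- 0
  hi <- min(l, r)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  ((lo + hi) / 2) / r
}

# quick synthetic complex with k planted contacts at given distance
quick_complex <- function(k = 3, dist = 3.5, seed = 1, len_a = 15,
                          len_b = 12, ...) {
  pos_a <- sample(seq_len(len_a), k, replace = TRUE)
  pos_b <- sample(seq_len(len_b), k, replace = FALSE)
  pc <- unique(data.frame(pos_a = pos_a, pos_b = pos_b,
                          dist = rep(dist, k)))
  make_complex(synthetic_complex_spec(len_a, len_b, planted_contacts = pc,
                                      seed = seed, ...))
}

# build a bare contact_map directly from key rows (for rule-level tests)
fake_cmap <- function(id, e3_pos, e2_pos) {
  n <- length(e3_pos)
  structure(list(
    complex_id = id, chain_a = "A", chain_b = "B", cutoff = 4,
    masked_policy = list(n_masked = 0),
    contacts = data.frame(
      resno_a = e3_pos, resname_a = rep("ALA", n),
      resno_b = e2_pos, resname_b = rep("GLY", n),
      min_dist = rep(3.5, n), atom_a = rep("CA", n), atom_b = rep("CA", n),
      a_backbone = rep(TRUE, n), b_backbone = rep(TRUE, n),
      stringsAsFactors = FALSE)),
    class = "contact_map")
}

# canonical reference confined to small position sets, for rule tests
toy_canon <- function(e3 = c(5, 6), e2 = c(50, 51)) {
  structure(list(e3_positions = setNames(e3, paste0("r", seq_along(e3))),
                 e2_reference_positions = setNames(e2, paste0("s", seq_along(e2))),
                 table = NULL), class = "canonical_reference")
}

# identity position map covering 1..n for a set of targets
identity_pmap <- function(reference_id, targets, n = 200) {
  maps <- lapply(targets, function(t)
    data.frame(ref_pos = 1:n, ref_aa = "A", target_pos = 1:n,
               target_aa = "A", stringsAsFactors = FALSE))
  names(maps) <- targets
  structure(list(reference_id = reference_id, maps = maps),
            class = "position_map")
}
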