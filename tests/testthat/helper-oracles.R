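# Independent oracles and small fixtures shared across the test files.

# Brute-force Delaunay: enumerate all 4-subsets and keep those whose
# circumsphere is empty of all other sites. Only for n <= ~30.
brute_force_delaunay <- function(pts) {
  n <- nrow(pts)
  keep <- NULL
  combs <- combn(n, 4)
  for (k in seq_len(ncol(combs))) {
    id <- combs[, k]
    A <- pts[id, , drop = FALSE]
    M <- 2 * (A[2:4, ] - matrix(A[1, ], 3, 3, byrow = TRUE))
    b <- rowSums(A[2:4, ]^2) - sum(A[1, ]^2)
    cc <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(cc)) next
    r2 <- sum((A[1, ] - cc)^2)
    d2 <- colSums((t(pts) - cc)^2)
    if (all(d2[-id] > r2 * (1 + 1e-9))) keep <- rbind(keep, sort(id))
  }
  keep
}

simplex_keys <- function(m) apply(m, 1, paste, collapse = "-")

# Cayley-Menger determinant volume of a tetrahedron
cayley_menger_volume <- function(coords) {
  d2 <- as.matrix(dist(coords))^2
  B <- rbind(c(0, 1, 1, 1, 1), cbind(1, d2))
  sqrt(max(0, det(B) / 288))
}

# exhaustive pair-counting AUC (ties half)
pair_count_auc <- function(truth_pos, score) {
  pos <- score[truth_pos]
  neg <- score[!truth_pos]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Pearson chi-square by direct O/E evaluation
brute_force_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# a tiny all-purpose potential: every quadruplet scored, deterministic
toy_potential <- function(score_fun = NULL) {
  keys <- enumerate_quadruplets()
  s <- if (is.null(score_fun)) {
    # reproducible pseudo-scores in [-1, 1]
    set.seed(99)
    runif(length(keys), -1, 1)
  } else {
    vapply(keys, score_fun, numeric(1))
  }
  pot <- data.frame(quad = keys, count = NA_integer_, f = NA_real_,
                    p = NA_real_, s = s, observed = TRUE)
  class(pot) <- c("four_body_potential", "data.frame")
  pot
}

# single regular-ish tetrahedron structure (4 residues)
tetra_structure <- function(aa = c("G", "A", "L", "W"), scale = 3.8) {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3))) * scale
  calpha_structure(1:4, aa, xyz)
}

# cached small synthetic benchmark shared by the slower test files
small_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthetic_benchmark(n_structures = 6, n_residues = 30,
                                    seed = 42)
    cache
  }
})

# minimal PDB ATOM line in standard fixed columns
pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          alt = " ", occ = 1.00, icode = " ", elety = " CA ") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, elety, alt, resname, chain, resno, icode, x, y, z, occ, 0)
}

# minimal PDB text for a set of residues (CA only)
pdb_text_fixture <- function(resno, resname, xyz, chain = "A") {
  lines <- vapply(seq_along(resno), function(i)
    pdb_atom_line(i, resname[i], chain, resno[i],
                  xyz[i, 1], xyz[i, 2], xyz[i, 3]), character(1))
  paste(c(lines, "END"), collapse = "\n")
}
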