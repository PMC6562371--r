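## Synthetic protein-like C-alpha chains and planted-signal fitness tables.
## These emulate, at desk scale, the two external inputs of the workflow: a
## training corpus of tessellatable structures and a per-variant phenotype
## table whose fitness depends monotonically on the residual score.

#' Generate a compact self-avoiding C-alpha chain
#'
#' A collapsed random walk: successive sites at the canonical C-alpha
#' virtual-bond spacing (3.8 A), all non-successive pairs farther apart
#' than a clash distance (3.6 A), with each step biased toward the current
#' centroid so the chain stays globular and its 12 A-filtered tessellation
#' well connected. The generator backtracks a few residues when it paints
#' itself into a corner and errors after a bounded number of attempts.
#' Residue types are drawn from a configurable composition and secondary
#' labels at random (they exercise the feature pipeline; no structural
#' realism is implied).
#'
#' @param n_residues Chain length (>= 10).
#' @param seed Integer seed; fully determines the chain.
#' @param bond_length Successive C-alpha spacing in Angstrom (default 3.8).
#' @param clash_distance Minimum non-successive distance (default 3.6).
#' @param compactness Strength of the centroid bias in `[0, 1]` (default
#'   0.5); higher is more collapsed but harder to place.
#' @param composition Named sampling weights over the 20 amino acids
#'   (default uniform).
#' @param chain Chain identifier.
#' @return A [calpha_structure()].
#' @export
generate_chain <- function(n_residues, seed = 1, bond_length = 3.8,
                           clash_distance = 3.6, compactness = 0.5,
                           composition = NULL, chain = "A") {
  if (n_residues < 10) stop("n_residues must be at least 10")
  if (bond_length <= 0.9 * clash_distance)
    stop("bond_length must exceed 0.9 * clash_distance")
  set.seed(seed)
  pts <- matrix(NA_real_, n_residues, 3)
  pts[1, ] <- 0
  i <- 2L
  budget <- 400L * n_residues
  while (i <= n_residues) {
    placed <- FALSE
    for (try in 1:300) {
      budget <- budget - 1L
      if (budget <= 0L)
        stop("failed to place residue ", i,
             " after bounded retries; lower compactness")
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cen <- colMeans(pts[1:(i - 1L), , drop = FALSE])
      pull <- cen - pts[i - 1L, ]
      if (sum(pull^2) > 1e-9)
        dir <- dir + compactness * pull / sqrt(sum(pull^2))
      dir <- dir / sqrt(sum(dir^2)) * bond_length
      cand <- pts[i - 1L, ] + dir
      d <- sqrt(colSums((t(pts[1:(i - 1L), , drop = FALSE]) - cand)^2))
      if (length(d) < 2L || all(d[-(i - 1L)] > clash_distance)) {
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    i <- if (placed) i + 1L else max(2L, i - 3L)  # backtrack when stuck
  }
  if (is.null(composition)) composition <- setNames(rep(1, 20), AA20)
  aa <- sample(names(composition), n_residues, replace = TRUE,
               prob = composition)
  secondary <- sample(c("helix", "strand", "coil"), n_residues,
                      replace = TRUE, prob = c(0.35, 0.25, 0.40))
  calpha_structure(seq_len(n_residues), aa, pts, chain = chain,
                   secondary = secondary)
}

#' Generate a training set of synthetic structures
#'
#' Independent chains with varied lengths (uniform over `length_range`) and
#' the given composition; a desk-scale stand-in for a diverse structure
#' corpus, suitable input to [train_potential()].
#'
#' @param n_structures Number of chains (>= 1).
#' @param length_range Inclusive range of chain lengths (default 30-60).
#' @param seed Integer seed; chain `i` uses `seed + i`.
#' @param ... Passed to [generate_chain()].
#' @return List of [calpha_structure()] objects.
#' @export
generate_structure_set <- function(n_structures = 10,
                                   length_range = c(30, 60), seed = 1, ...) {
  if (n_structures < 1) stop("n_structures must be at least 1")
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n_structures,
                 replace = TRUE)
  lapply(seq_len(n_structures), function(i)
    generate_chain(lens[i], seed = seed + i, ...))
}

#' Generate fitness values with a planted dependence on residual score
#'
#' `fitness = link(residual_score) + Gaussian noise`. The default link is
#' the identity, i.e. monotone increasing: variants that perturb the
#' structural environment downward (negative residual scores) receive lower
#' fitness, matching the empirical direction of the structure-function
#' relationship the workflow is designed to recover.
#'
#' @param residual_scores Numeric residual scores, one per variant.
#' @param link Monotone link function (default identity).
#' @param noise_sd Gaussian noise standard deviation, in fitness units
#'   (default 0.75).
#' @param seed Integer seed.
#' @return Numeric fitness vector.
#' @export
generate_fitness <- function(residual_scores, link = identity,
                             noise_sd = 0.75, seed = 1) {
  if (anyNA(residual_scores)) stop("residual scores must be available")
  set.seed(seed)
  link(residual_scores) + rnorm(length(residual_scores), sd = noise_sd)
}

#' End-to-end synthetic benchmark data
#'
#' Convenience composition for tests and examples: trains a four-body
#' potential on a synthetic structure set, performs saturation mutagenesis
#' on a held-out chain, plants fitness on the residual scores, and
#' assembles both feature designs.
#'
#' @param n_structures Training structures (default 10).
#' @param n_residues Held-out chain length (default 50).
#' @param noise_sd Fitness noise (default 0.75).
#' @param seed Integer seed.
#' @param cutoff Edge-length cutoff in Angstrom (default 12).
#' @return List with `potential`, `tess` (filtered tessellation of the
#'   held-out chain), `variants` (saturation table with `residual_score`
#'   and `fitness`), and feature tables `residual_features` /
#'   `local_features`.
#' @export
synthetic_benchmark <- function(n_structures = 10, n_residues = 50,
                                noise_sd = 0.75, seed = 1, cutoff = 12) {
  train <- generate_structure_set(n_structures, seed = seed)
  pot <- train_potential(train, cutoff = cutoff)
  target <- generate_chain(n_residues, seed = seed + 10000L)
  tess <- filter_long_edges(tessellate(target), cutoff = cutoff)
  variants <- saturation_variants(target)
  variants$residual_score <- vapply(seq_len(nrow(variants)), function(i)
    residual_profile(tess, pot, variants$position[i],
                     variants$replacement[i])$residual_score, numeric(1))
  variants$fitness <- generate_fitness(variants$residual_score,
                                       noise_sd = noise_sd, seed = seed + 1L)
  rf <- feature_table(tess, pot, variants, design = "residual")
  lf <- feature_table(tess, pot, variants, design = "local")
  list(potential = pot, tess = tess, variants = variants,
       residual_features = rf, local_features = lf)
}
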