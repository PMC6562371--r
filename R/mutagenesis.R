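#' Total four-body potential of a sequence-structure pair
#'
#' Sum of the quadruplet scores over all retained simplices of a filtered
#' tessellation, with the residue labels taken from `sequence`.
#'
#' @param tess A filtered `delaunay_tessellation`.
#' @param sequence One-letter residue vector over the tessellation sites;
#'   defaults to the structure's own sequence.
#' @param potential A `four_body_potential`.
#' @return Scalar total potential.
#' @export
total_potential <- function(tess, potential, sequence = NULL) {
  if (is.null(sequence)) sequence <- tess$structure$aa
  if (length(sequence) != length(tess$structure$position))
    stop("sequence length must equal the site count")
  lk <- score_lookup(potential)
  keys <- quad_key(matrix(sequence[tess$simplices], ncol = 4))
  sc <- lk[keys]
  sc[is.na(sc)] <- 0
  sum(sc)
}

#' Residue environment scores (3D-1D potential profile)
#'
#' The residue environment score (RES) of a position is the sum of the
#' scores of all retained simplices sharing its C-alpha vertex; the ordered
#' RES vector over all positions is the 3D-1D potential profile. Since every
#' simplex touches 4 positions, `sum(RES) = 4 * total potential`.
#'
#' @inheritParams total_potential
#' @return List with `res` (named by author position) and `total`.
#' @export
potential_profile <- function(tess, potential, sequence = NULL) {
  if (is.null(sequence)) sequence <- tess$structure$aa
  n <- length(tess$structure$position)
  if (length(sequence) != n)
    stop("sequence length must equal the site count")
  lk <- score_lookup(potential)
  s <- tess$simplices
  res <- numeric(n)
  if (nrow(s)) {
    keys <- quad_key(matrix(sequence[s], ncol = 4))
    sc <- lk[keys]
    sc[is.na(sc)] <- 0
    for (k in 1:4) {
      acc <- tapply(sc, s[, k], sum)
      res[as.integer(names(acc))] <- res[as.integer(names(acc))] + acc
    }
  } else {
    sc <- numeric(0)
  }
  list(res = setNames(res, tess$structure$position), total = sum(sc))
}

#' Residual profile of a single-residue variant
#'
#' Relabels the mutated vertex with the replacement residue, rescores only
#' the simplices incident to it, and reports the environmental-perturbation
#' (EP) score at every position: `EP(q) = RES_mutant(q) - RES_native(q)`.
#' The residual score (mutant total potential minus native total potential)
#' equals the EP score at the mutated position, and EP is zero at every
#' position that shares no retained simplex with it.
#'
#' @param tess A filtered `delaunay_tessellation`.
#' @param potential A `four_body_potential`.
#' @param position Author residue number of the mutated site.
#' @param replacement One-letter code of the replacement residue. Equal to
#'   the native residue is allowed and yields an all-zero profile.
#' @param sequence Optional native sequence override.
#' @return An object of class `residual_profile`: list with `position`,
#'   `native`, `replacement`, `ep` (named by author position) and
#'   `residual_score`.
#' @export
residual_profile <- function(tess, potential, position, replacement,
                             sequence = NULL) {
  if (is.null(sequence)) sequence <- tess$structure$aa
  n <- length(tess$structure$position)
  if (length(sequence) != n)
    stop("sequence length must equal the site count")
  if (!replacement %in% AA20)
    stop("replacement must be a standard one-letter code, got '",
         replacement, "'")
  idx <- site_index(tess, position)
  native <- sequence[idx]
  ep <- setNames(numeric(n), tess$structure$position)
  inc <- simplices_at(tess, position)
  if (nrow(inc) && replacement != native) {
    lk <- score_lookup(potential)
    mut_seq <- sequence
    mut_seq[idx] <- replacement
    k_old <- quad_key(matrix(sequence[inc], ncol = 4))
    k_new <- quad_key(matrix(mut_seq[inc], ncol = 4))
    ds <- lk[k_new] - lk[k_old]
    ds[is.na(ds)] <- 0
    for (k in 1:4) {
      acc <- tapply(ds, inc[, k], sum)
      ep[as.integer(names(acc))] <- ep[as.integer(names(acc))] + acc
    }
  }
  base::structure(
    list(position = position, native = native, replacement = replacement,
         ep = ep, residual_score = unname(ep[as.character(position)])),
    class = "residual_profile")
}

#' @export
print.residual_profile <- function(x, ...) {
  cat(sprintf("Residual profile %s%d%s: residual score %.4f, %d non-zero EP\n",
              x$native, x$position, x$replacement, x$residual_score,
              sum(x$ep != 0)))
  invisible(x)
}

#' All single-residue variants of a structure
#'
#' @param structure A [calpha_structure()].
#' @param positions Positions to mutate (default all).
#' @return Data frame with columns `position`, `native`, `replacement`
#'   (19 rows per position).
#' @export
saturation_variants <- function(structure, positions = NULL) {
  if (is.null(positions)) positions <- structure$position
  idx <- match(positions, structure$position)
  do.call(rbind, lapply(seq_along(positions), function(i) {
    nat <- structure$aa[idx[i]]
    data.frame(position = positions[i], native = nat,
               replacement = setdiff(AA20, nat))
  }))
}

#' Comprehensive mutational profile (CMP) scores
#'
#' Per position, the mean residual score over the 19 possible substitutions,
#' together with the sub-means over conservative (C) and non-conservative
#' (NC) replacements; `19 * CMP = sum(C residuals) + sum(NC residuals)`.
#'
#' @inheritParams residual_profile
#' @param positions Positions to profile (default all).
#' @return Data frame with columns `position`, `native`, `cmp`, `cmp_c`,
#'   `cmp_nc`, `n_c`, `n_nc`.
#' @export
cmp_scores <- function(tess, potential, positions = NULL, sequence = NULL) {
  if (is.null(sequence)) sequence <- tess$structure$aa
  if (is.null(positions)) positions <- tess$structure$position
  rows <- lapply(positions, function(p) {
    nat <- sequence[site_index(tess, p)]
    reps <- setdiff(AA20, nat)
    rs <- vapply(reps, function(r)
      residual_profile(tess, potential, p, r, sequence)$residual_score,
      numeric(1))
    cls <- vapply(reps, substitution_class, character(1), native = nat)
    data.frame(position = p, native = nat, cmp = mean(rs),
               cmp_c = if (any(cls == "C")) mean(rs[cls == "C"]) else NA_real_,
               cmp_nc = if (any(cls == "NC")) mean(rs[cls == "NC"]) else NA_real_,
               n_c = sum(cls == "C"), n_nc = sum(cls == "NC"))
  })
  do.call(rbind, rows)
}

# six physicochemical residue classes
AA_SIX_CLASSES <- list(c("A", "S", "T", "G", "P"),
                       c("D", "E", "N", "Q"),
                       c("R", "K", "H"),
                       c("F", "Y", "W"),
                       c("V", "L", "I", "M"),
                       c("C"))

#' Conservative vs non-conservative substitution
#'
#' Substitutions within one of the six physicochemical residue classes
#' `(A,S,T,G,P), (D,E,N,Q), (R,K,H), (F,Y,W), (V,L,I,M), (C)` are
#' conservative (`"C"`); all inter-class replacements are non-conservative
#' (`"NC"`).
#'
#' @param native,replacement Distinct one-letter residue codes.
#' @return `"C"` or `"NC"`.
#' @export
substitution_class <- function(native, replacement) {
  if (!native %in% AA20 || !replacement %in% AA20)
    stop("residues must be standard one-letter codes")
  if (native == replacement)
    stop("native and replacement are identical: not a variant")
  cl_n <- which(vapply(AA_SIX_CLASSES, function(s) native %in% s, logical(1)))
  cl_r <- which(vapply(AA_SIX_CLASSES, function(s) replacement %in% s,
                       logical(1)))
  if (cl_n == cl_r) "C" else "NC"
}

AA_POLARITY <- c(
  setNames(rep("polar", 9), c("C", "G", "H", "N", "Q", "S", "T", "W", "Y")),
  setNames(rep("apolar", 7), c("A", "F", "I", "L", "M", "P", "V")),
  setNames(rep("charged", 4), c("D", "E", "K", "R")))

#' Side-chain polarity class of a residue
#'
#' Partition of the 20 standard residues into polar
#' (C, G, H, N, Q, S, T, W, Y), apolar (A, F, I, L, M, P, V) and charged
#' (D, E, K, R).
#'
#' @param aa One-letter residue code(s).
#' @return Character vector in `{polar, apolar, charged}`.
#' @export
polarity_class <- function(aa) {
  out <- unname(AA_POLARITY[aa])
  if (anyNA(out))
    stop("unknown residue code(s): ", paste(unique(aa[is.na(out)]),
                                            collapse = ", "))
  out
}

#' Group means of per-variant or per-position scores
#'
#' @param values Numeric vector.
#' @param groups Vector of group labels, same length as `values`.
#' @param levels Optional label set to report (empty groups get count 0 and
#'   mean `NA`).
#' @return Data frame with columns `label`, `mean`, `n`.
#' @export
group_mean_scores <- function(values, groups, levels = NULL) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length")
  if (is.null(levels)) levels <- unique(groups)
  rows <- lapply(levels, function(l) {
    v <- values[groups == l]
    data.frame(label = l, mean = if (length(v)) mean(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}
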