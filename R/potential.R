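#' Canonical key of an unordered residue quadruplet
#'
#' @param aas Character vector of 4 one-letter codes (or a matrix with 4
#'   columns, one quadruplet per row).
#' @return Canonical (sorted) 4-letter key(s).
#' @export
quad_key <- function(aas) {
  if (is.matrix(aas)) {
    return(apply(aas, 1, function(r) paste(sort(r), collapse = "")))
  }
  stopifnot(length(aas) == 4L)
  paste(sort(aas), collapse = "")
}

#' Enumerate all unordered residue quadruplets
#'
#' Size-4 multisets over an alphabet of `m` letters; there are
#' `choose(m + 3, 4)` of them (8855 for the 20 standard amino acids).
#'
#' @param alphabet Character vector of one-letter codes (default the 20
#'   standard amino acids).
#' @return Character vector of canonical keys, lexicographically sorted.
#' @export
enumerate_quadruplets <- function(alphabet = AA20) {
  if (!length(alphabet)) stop("alphabet must be non-empty")
  a <- sort(unique(alphabet))
  m <- length(a)
  idx <- combn(m + 3L, 4L)           # 4-subsets of 1..m+3
  idx <- idx - 0:3                    # standard bijection to multisets
  keys <- apply(idx, 2, function(k) paste(a[k], collapse = ""))
  sort(keys)
}

#' Observed quadruplet statistics of filtered tessellations
#'
#' Tallies the residue quadruplet at the vertices of every retained simplex
#' across a set of tessellations, the relative frequency `f` of each
#' quadruplet type, and the background amino-acid composition `a_n` over all
#' residues of the input structures.
#'
#' @param tessellations A filtered `delaunay_tessellation`, or a list of them.
#' @return List with `counts` (named integer vector over observed keys),
#'   `f` (counts / total simplices) and `background` (named composition over
#'   the 20 amino acids, summing to 1).
#' @export
observed_statistics <- function(tessellations) {
  if (inherits(tessellations, "delaunay_tessellation"))
    tessellations <- list(tessellations)
  total <- sum(vapply(tessellations, function(t) nrow(t$simplices), integer(1)))
  if (total == 0L) stop("no retained simplices in the input tessellations")
  keys <- unlist(lapply(tessellations, function(t) {
    aa <- t$structure$aa
    quad_key(matrix(aa[t$simplices], ncol = 4))
  }))
  counts <- table(keys)
  counts <- setNames(as.integer(counts), names(counts))
  allaa <- unlist(lapply(tessellations, function(t) t$structure$aa))
  bg <- table(factor(allaa, levels = AA20))
  background <- setNames(as.numeric(bg) / length(allaa), AA20)
  list(counts = counts, f = counts / total, background = background,
       n_simplices = total)
}

#' Multinomial chance rate of a residue quadruplet
#'
#' The probability of drawing the unordered quadruplet from a background
#' composition: `p = 4!/prod(t_n!) * prod(a_n^t_n)`, with `t_n` the
#' multiplicity of residue type `n` in the quadruplet.
#'
#' @param key Canonical quadruplet key(s) (4-letter strings).
#' @param background Named composition over the alphabet, summing to 1
#'   (tolerance 1e-9).
#' @return Numeric vector of rates; they sum to 1 over all quadruplets.
#' @export
multinomial_rate <- function(key, background) {
  if (abs(sum(background) - 1) > 1e-9)
    stop("background composition must sum to 1")
  vapply(key, function(k) {
    aas <- strsplit(k, "")[[1]]
    if (length(aas) != 4L) stop("quadruplet key must have 4 letters: ", k)
    t_n <- table(aas)
    a <- background[names(t_n)]
    if (anyNA(a)) stop("key '", k, "' contains letters outside the background")
    factorial(4) / prod(factorial(t_n)) * prod(a^as.integer(t_n))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Log-likelihood score of a quadruplet
#'
#' Inverted-Boltzmann score `s = log(f/p)` comparing the observed frequency
#' of a quadruplet against its multinomial chance rate. Base-10 logarithm by
#' default. Unobserved quadruplets (`f = 0`) receive a sentinel score
#' (default 0) rather than `-Inf`, so total potentials stay finite.
#'
#' @param f Observed relative frequency (vector).
#' @param p Chance rate (vector, must be positive).
#' @param log_base Logarithm base (default 10).
#' @param unobserved_score Score assigned where `f == 0`.
#' @return Numeric scores.
#' @export
quad_score <- function(f, p, log_base = 10, unobserved_score = 0) {
  if (any(p <= 0)) stop("chance rate p must be positive")
  s <- ifelse(f > 0, log(f / p, base = log_base), unobserved_score)
  as.numeric(s)
}

#' Train a four-body statistical potential
#'
#' Composes tessellation, long-edge filtering, quadruplet tallying and
#' multinomial scoring over a set of C-alpha structures into the full table
#' over all `choose(m+3, 4)` quadruplet types.
#'
#' @param structures A list of [calpha_structure()] objects.
#' @param cutoff Edge-length cutoff in Angstrom (default 12).
#' @param log_base Logarithm base for the scores (default 10).
#' @param unobserved_score Sentinel score for never-observed quadruplets.
#' @return A `four_body_potential`: data frame with columns `quad`, `count`,
#'   `f`, `p`, `s`, `observed`, with the background composition, cutoff and
#'   training-set size as attributes.
#' @export
train_potential <- function(structures, cutoff = 12, log_base = 10,
                            unobserved_score = 0) {
  if (inherits(structures, "calpha_structure")) structures <- list(structures)
  if (!length(structures)) stop("need at least one training structure")
  tessellations <- lapply(structures, function(s)
    filter_long_edges(tessellate(s), cutoff = cutoff))
  stats <- observed_statistics(tessellations)
  keys <- enumerate_quadruplets(AA20)
  count <- setNames(integer(length(keys)), keys)
  count[names(stats$counts)] <- stats$counts
  f <- count / stats$n_simplices
  p <- multinomial_rate(keys, stats$background)
  # residue types absent from the training set give p = 0 for every
  # quadruplet containing them; those quadruplets are necessarily
  # unobserved and take the sentinel score
  s <- rep(unobserved_score, length(keys))
  pos <- p > 0
  s[pos] <- quad_score(f[pos], p[pos], log_base = log_base,
                       unobserved_score = unobserved_score)
  pot <- data.frame(quad = keys, count = as.integer(count),
                    f = as.numeric(f), p = p, s = s,
                    observed = count > 0L, row.names = NULL)
  attr(pot, "background") <- stats$background
  attr(pot, "log_base") <- log_base
  attr(pot, "cutoff") <- cutoff
  attr(pot, "n_structures") <- length(structures)
  attr(pot, "n_simplices") <- stats$n_simplices
  class(pot) <- c("four_body_potential", "data.frame")
  pot
}

# fast named score lookup vector for a potential
score_lookup <- function(potential) {
  setNames(potential$s, potential$quad)
}

#' Write a four-body potential as a whitespace-delimited text table
#'
#' @param potential A `four_body_potential`.
#' @param file Optional path; when `NULL` the lines are returned.
#' @return The text lines, invisibly.
#' @export
write_potential <- function(potential, file = NULL) {
  stopifnot(inherits(potential, "four_body_potential"))
  lines <- c("# four-body potential: QUAD SCORE F P COUNT",
             sprintf("%s %.10g %.10g %.10g %d", potential$quad, potential$s,
                     potential$f, potential$p, potential$count))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a four-body potential from text
#'
#' Tolerant whitespace-delimited reader: each row carries a 4-letter
#' quadruplet and its score, optionally followed by `f`, `p` and a count.
#' Lines starting with `#` are comments.
#'
#' @param text Path to a file, or the text itself (single string with
#'   newlines, or a character vector of lines).
#' @param log_base Logarithm base recorded on the returned object.
#' @return A `four_body_potential` data frame (background composition is
#'   `NA` when the file does not carry counts).
#' @export
read_potential <- function(text, log_base = 10) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else text <- unlist(strsplit(text, "\n", fixed = TRUE))
  keep <- which(!grepl("^\\s*(#|$)", text))
  quads <- character(0); s <- numeric(0)
  f <- numeric(0); p <- numeric(0); count <- integer(0)
  for (ln in keep) {
    tok <- strsplit(trimws(text[ln]), "\\s+")[[1]]
    if (length(tok) < 2L)
      stop("line ", ln, ": expected at least a quadruplet and a score")
    q <- toupper(tok[1])
    if (nchar(q) != 4L || !all(strsplit(q, "")[[1]] %in% AA20))
      stop("line ", ln, ": '", tok[1], "' is not a 4-letter residue quadruplet")
    v <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(v)) stop("line ", ln, ": score '", tok[2], "' is not numeric")
    quads <- c(quads, quad_key(strsplit(q, "")[[1]]))
    s <- c(s, v)
    f <- c(f, if (length(tok) >= 3) as.numeric(tok[3]) else NA_real_)
    p <- c(p, if (length(tok) >= 4) as.numeric(tok[4]) else NA_real_)
    count <- c(count, if (length(tok) >= 5) as.integer(tok[5]) else NA_integer_)
  }
  if (anyDuplicated(quads)) stop("duplicate quadruplet keys in potential file")
  pot <- data.frame(quad = quads, count = count, f = f, p = p, s = s,
                    observed = is.na(f) | f > 0, row.names = NULL)
  attr(pot, "log_base") <- log_base
  class(pot) <- c("four_body_potential", "data.frame")
  pot
}
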