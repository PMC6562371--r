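#' Delaunay tessellation of a C-alpha structure
#'
#' Partitions the convex hull of the site coordinates into tetrahedra whose
#' circumspheres contain no other site (empty-circumsphere property), using
#' an incremental Bowyer-Watson construction with an infinite vertex.
#'
#' @param structure A [calpha_structure()] object, or a numeric matrix of
#'   coordinates (one row per site).
#' @return An object of class `delaunay_tessellation` holding the simplices
#'   (rows of 4 site indices), the edge table with Euclidean lengths, and a
#'   reference to the structure. Degenerate input (fewer than 4 sites,
#'   coplanar or duplicated sites) is an error.
#' @seealso [filter_long_edges()], [simplices_at()], [tess_neighbors()]
#' @export
tessellate <- function(structure) {
  if (is.matrix(structure)) {
    structure <- calpha_structure(seq_len(nrow(structure)),
                                  rep("G", nrow(structure)), structure)
  }
  stopifnot(inherits(structure, "calpha_structure"))
  simplices <- .delaunay_tetrahedra(unname(structure$xyz))
  tess <- base::structure(
    list(structure = structure, simplices = simplices,
         filtered = FALSE, cutoff = Inf),
    class = "delaunay_tessellation")
  tess$edges <- simplex_edge_table(tess)
  tess
}

# unique edges (index pairs i < j) of the retained simplices, with lengths
simplex_edge_table <- function(tess) {
  s <- tess$simplices
  if (!nrow(s)) {
    return(data.frame(i = integer(), j = integer(), length = numeric()))
  }
  pairs <- rbind(s[, c(1, 2)], s[, c(1, 3)], s[, c(1, 4)],
                 s[, c(2, 3)], s[, c(2, 4)], s[, c(3, 4)])
  pairs <- unique(pairs)
  xyz <- tess$structure$xyz
  len <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                         xyz[pairs[, 2], , drop = FALSE])^2))
  out <- data.frame(i = pairs[, 1], j = pairs[, 2], length = len)
  out[order(out$i, out$j), , drop = FALSE]
}

# max edge length of each simplex
simplex_max_edge <- function(tess) {
  s <- tess$simplices
  xyz <- tess$structure$xyz
  d <- function(a, b) sqrt(rowSums((xyz[s[, a], , drop = FALSE] -
                                      xyz[s[, b], , drop = FALSE])^2))
  pmax(d(1, 2), d(1, 3), d(1, 4), d(2, 3), d(2, 4), d(3, 4))
}

#' Discard simplices containing a long edge
#'
#' Convexity forces tetrahedra whose long edges connect surface residues
#' that do not physically interact; any simplex with an edge longer than the
#' cutoff is removed, so every retained quadruplet is a plausible four-body
#' interaction.
#'
#' @param tess An unfiltered `delaunay_tessellation`.
#' @param cutoff Edge-length cutoff in Angstrom (default 12).
#' @return A filtered `delaunay_tessellation`; all subsequent incidence,
#'   neighbor and depth queries use only the retained simplices.
#' @export
filter_long_edges <- function(tess, cutoff = 12) {
  stopifnot(inherits(tess, "delaunay_tessellation"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive length in Angstrom")
  if (tess$filtered) stop("tessellation is already filtered")
  keep <- simplex_max_edge(tess) <= cutoff
  tess$simplices <- tess$simplices[keep, , drop = FALSE]
  tess$filtered <- TRUE
  tess$cutoff <- cutoff
  tess$edges <- simplex_edge_table(tess)
  tess
}

#' @export
print.delaunay_tessellation <- function(x, ...) {
  cat(sprintf("Delaunay tessellation: %d sites, %d tetrahedra%s\n",
              length(x$structure$position), nrow(x$simplices),
              if (x$filtered) sprintf(" (edges <= %g A)", x$cutoff) else ""))
  invisible(x)
}

# author position -> site index
site_index <- function(tess, position) {
  idx <- match(position, tess$structure$position)
  if (anyNA(idx))
    stop("unknown residue position(s): ",
         paste(position[is.na(idx)], collapse = ", "))
  idx
}

#' Simplices incident to a residue position
#'
#' @param tess A `delaunay_tessellation`.
#' @param position Author residue number of one site.
#' @return Integer matrix of simplices (rows of 4 site indices) that share
#'   the site as a vertex.
#' @export
simplices_at <- function(tess, position) {
  idx <- site_index(tess, position)
  stopifnot(length(idx) == 1L)
  s <- tess$simplices
  s[s[, 1] == idx | s[, 2] == idx | s[, 3] == idx | s[, 4] == idx, ,
    drop = FALSE]
}

#' Tessellation neighbors of a residue position
#'
#' Sites that share a retained tessellation edge with the query position,
#' in ascending order of Euclidean distance (ties broken by residue number).
#'
#' @param tess A filtered `delaunay_tessellation`.
#' @param position Author residue number of one site.
#' @return A data frame with columns `position`, `aa` and `distance`.
#' @export
tess_neighbors <- function(tess, position) {
  idx <- site_index(tess, position)
  stopifnot(length(idx) == 1L)
  e <- tess$edges
  other <- c(e$j[e$i == idx], e$i[e$j == idx])
  len <- c(e$length[e$i == idx], e$length[e$j == idx])
  pos <- tess$structure$position[other]
  ord <- order(len, pos)
  data.frame(position = pos[ord],
             aa = tess$structure$aa[other][ord],
             distance = len[ord])
}

#' Volume of a tetrahedron
#'
#' @param coords Numeric 4 x 3 matrix of vertex coordinates.
#' @return Volume in cubic Angstrom (`|det|/6`); degenerate input gives 0.
#' @export
tetra_volume <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4L, ncol(coords) == 3L)
  m <- coords[2:4, , drop = FALSE] -
    matrix(coords[1, ], 3, 3, byrow = TRUE)
  abs(det(m)) / 6
}

#' Tetrahedrality (irregularity) of a tetrahedron
#'
#' A dimensionless measure of the departure from a regular tetrahedron:
#' `T = sum_{i<j} (l_i - l_j)^2 / (15 * mean(l)^2)` over the 6 edge lengths
#' `l`. A regular tetrahedron scores 0, and the score is invariant under
#' uniform scaling.
#'
#' @param coords Numeric 4 x 3 matrix of vertex coordinates.
#' @return Non-negative irregularity score.
#' @export
tetrahedrality <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4L, ncol(coords) == 3L)
  pr <- combn(4, 2)
  l <- sqrt(colSums((t(coords[pr[1, ], ]) - t(coords[pr[2, ], ]))^2))
  lbar <- mean(l)
  if (lbar <= 0) stop("zero mean edge length")
  dif <- outer(l, l, "-")
  sum(dif[upper.tri(dif)]^2) / (15 * lbar^2)
}

# mean volume and mean tetrahedrality of the simplices incident to a position
incident_geometry <- function(tess, position) {
  s <- simplices_at(tess, position)
  if (!nrow(s)) return(c(mean_volume = NA_real_, mean_tetrahedrality = NA_real_))
  xyz <- tess$structure$xyz
  vols <- apply(s, 1, function(v) tetra_volume(xyz[v, , drop = FALSE]))
  tets <- apply(s, 1, function(v) tetrahedrality(xyz[v, , drop = FALSE]))
  c(mean_volume = mean(vols), mean_tetrahedrality = mean(tets))
}

#' Tessellation-derived residue depth classes
#'
#' A position is `surface` if it touches a boundary triangular face (a face
#' belonging to exactly one retained simplex), `undersurface` if it is not
#' on the surface but has at least one surface neighbor, and `buried`
#' otherwise. The surface-contact count is the number of tessellation
#' neighbors classified as surface, reported for every position.
#'
#' @param tess A filtered `delaunay_tessellation`.
#' @return A data frame with columns `position`, `depth` and
#'   `surface_contacts`.
#' @export
classify_depth <- function(tess) {
  stopifnot(inherits(tess, "delaunay_tessellation"))
  s <- tess$simplices
  n <- length(tess$structure$position)
  if (!nrow(s)) {
    return(data.frame(position = tess$structure$position,
                      depth = rep(NA_character_, n),
                      surface_contacts = rep(0L, n)))
  }
  faces <- rbind(s[, c(2, 3, 4)], s[, c(1, 3, 4)],
                 s[, c(1, 2, 4)], s[, c(1, 2, 3)])
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  boundary <- faces[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  surface_idx <- unique(as.vector(boundary))
  # adjacency from the retained edge set
  adj <- vector("list", n)
  e <- tess$edges
  for (k in seq_len(nrow(e))) {
    adj[[e$i[k]]] <- c(adj[[e$i[k]]], e$j[k])
    adj[[e$j[k]]] <- c(adj[[e$j[k]]], e$i[k])
  }
  depth <- rep(NA_character_, n)
  depth[surface_idx] <- "surface"
  in_tess <- unique(as.vector(s))
  for (i in setdiff(in_tess, surface_idx)) {
    depth[i] <- if (any(adj[[i]] %in% surface_idx)) "undersurface" else "buried"
  }
  contacts <- vapply(seq_len(n), function(i)
    sum(adj[[i]] %in% surface_idx), integer(1))
  data.frame(position = tess$structure$position, depth = depth,
             surface_contacts = contacts)
}
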