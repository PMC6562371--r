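#' Residual-profile feature vector of a variant
#'
#' The variant identity (mutated position, native and replacement residues)
#' appended to the left of its full EP profile, with the fitness value as
#' the final (output) column: `3 + n_positions + 1` columns, 170 for a
#' 166-site structure.
#'
#' @param profile A [residual_profile()].
#' @param fitness Fitness value of the variant (`NA` when unknown).
#' @return One-row data frame: `position`, `native`, `replacement`,
#'   `ep_<position>` for every structure position, `fitness`.
#' @export
build_residual_profile_vector <- function(profile, fitness = NA_real_) {
  stopifnot(inherits(profile, "residual_profile"))
  ep <- as.data.frame(as.list(profile$ep))
  names(ep) <- paste0("ep_", names(profile$ep))
  cbind(data.frame(position = profile$position, native = profile$native,
                   replacement = profile$replacement,
                   stringsAsFactors = FALSE),
        ep, data.frame(fitness = fitness))
}

#' Local-profile feature vector of a variant
#'
#' Focuses on the mutated position and its six nearest tessellation
#' neighbors. The 27 input attributes, in order: position, native and
#' replacement residues; residual score; EP scores at the six nearest
#' neighbors (by distance); the six neighbor residue identities (same
#' order); the six signed sequence separations (neighbor position minus
#' mutated position); mean volume and mean tetrahedrality of the incident
#' simplices; tessellation depth class and surface-contact count; secondary
#' structure at the mutated position. Fitness is the 28th (output) column.
#'
#' @param profile A [residual_profile()].
#' @param tess The filtered `delaunay_tessellation` the profile came from.
#' @param depth Optional precomputed [classify_depth()] table.
#' @param fitness Fitness value of the variant.
#' @return One-row data frame with 28 columns, or a `variant_exclusion`
#'   object (carrying the reason) when the mutated position has fewer than
#'   six tessellation neighbors.
#' @export
build_local_profile_vector <- function(profile, tess, depth = NULL,
                                       fitness = NA_real_) {
  stopifnot(inherits(profile, "residual_profile"))
  nb <- tess_neighbors(tess, profile$position)
  if (nrow(nb) < 6L) {
    return(base::structure(
      list(reason = sprintf(
        "position %d has only %d tessellation neighbors (6 required)",
        profile$position, nrow(nb))),
      class = "variant_exclusion"))
  }
  nb <- nb[1:6, , drop = FALSE]
  geom <- incident_geometry(tess, profile$position)
  if (is.null(depth)) depth <- classify_depth(tess)
  drow <- depth[depth$position == profile$position, ]
  row <- data.frame(position = profile$position, native = profile$native,
                    replacement = profile$replacement,
                    residual_score = profile$residual_score,
                    stringsAsFactors = FALSE)
  for (k in 1:6)
    row[[paste0("nn", k, "_ep")]] <- unname(profile$ep[as.character(nb$position[k])])
  for (k in 1:6) row[[paste0("nn", k, "_aa")]] <- nb$aa[k]
  for (k in 1:6)
    row[[paste0("nn", k, "_sep")]] <- nb$position[k] - profile$position
  row$mean_volume <- unname(geom["mean_volume"])
  row$mean_tetrahedrality <- unname(geom["mean_tetrahedrality"])
  row$depth <- drow$depth
  row$surface_contacts <- drow$surface_contacts
  row$secondary <- unname(tess$structure$secondary[as.character(profile$position)])
  row$fitness <- fitness
  row
}

#' Assemble feature tables for a variant set
#'
#' Convenience wrapper: computes the residual profile of every variant and
#' stacks either design's feature vectors.
#'
#' @param tess A filtered `delaunay_tessellation`.
#' @param potential A `four_body_potential`.
#' @param variants Data frame with columns `position`, `replacement`, and
#'   optionally `fitness`.
#' @param design `"residual"` (full-profile vectors) or `"local"`
#'   (28-column local vectors; variants at positions with fewer than six
#'   neighbors are dropped, with the reasons in attribute `exclusions`).
#' @return Feature data frame, one row per (retained) variant.
#' @export
feature_table <- function(tess, potential, variants,
                          design = c("residual", "local")) {
  design <- match.arg(design)
  fitness <- if ("fitness" %in% names(variants)) variants$fitness
             else rep(NA_real_, nrow(variants))
  depth <- if (design == "local") classify_depth(tess) else NULL
  rows <- vector("list", nrow(variants))
  excl <- character(0)
  for (i in seq_len(nrow(variants))) {
    pr <- residual_profile(tess, potential, variants$position[i],
                           variants$replacement[i])
    if (design == "residual") {
      rows[[i]] <- build_residual_profile_vector(pr, fitness[i])
    } else {
      v <- build_local_profile_vector(pr, tess, depth, fitness[i])
      if (inherits(v, "variant_exclusion")) {
        excl <- c(excl, sprintf("%s%d%s: %s", pr$native, pr$position,
                                pr$replacement, v$reason))
        v <- NULL
      }
      rows[[i]] <- v
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "exclusions") <- excl
  out
}

#' Dichotomize fitness values at a threshold
#'
#' Values above the threshold are `increased`, below are `decreased`.
#' Values exactly at the threshold are assigned alternately (starting with
#' `decreased`, in input order) so the two classes stay balanced when the
#' threshold is the median.
#'
#' @param values Numeric fitness values (at least 2, not all identical).
#' @param threshold Class boundary; defaults to the median of `values`.
#' @return Factor with levels `decreased`, `increased`.
#' @export
categorize_fitness <- function(values, threshold = stats::median(values)) {
  if (length(values) < 2L) stop("need at least 2 fitness values")
  if (length(unique(values)) == 1L)
    stop("all fitness values identical: no class split possible")
  cls <- ifelse(values > threshold, "increased",
                ifelse(values < threshold, "decreased", NA))
  ties <- which(is.na(cls))
  if (length(ties))
    cls[ties] <- rep(c("decreased", "increased"),
                     length.out = length(ties))
  factor(cls, levels = c("decreased", "increased"))
}

#' Write a feature table as CSV
#'
#' @param vectors Feature data frame (either design).
#' @param file Optional path; when `NULL` the CSV lines are returned.
#' @return The CSV lines, invisibly.
#' @export
write_feature_csv <- function(vectors, file = NULL) {
  if (is.null(file)) {
    return(invisible(utils::capture.output(
      write.csv(vectors, row.names = FALSE, quote = FALSE))))
  }
  write.csv(vectors, file, row.names = FALSE, quote = FALSE)
  invisible(readLines(file))
}

#' Read a feature table from CSV
#'
#' Header-sniffing reader for both feature designs; ragged rows are an
#' error with their line number.
#'
#' @param text Path to a CSV file, or CSV text.
#' @return Feature data frame.
#' @export
read_feature_csv <- function(text) {
  path <- text
  if (length(text) > 1L || grepl("\n", text[1]) || !file.exists(text[1])) {
    path <- tempfile(fileext = ".csv")
    writeLines(unlist(strsplit(text, "\n", fixed = TRUE)), path)
    on.exit(unlink(path))
  }
  nf <- count.fields(path, sep = ",", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged CSV: line ", bad, " has ", nf[bad], " fields, expected ",
         nf[1])
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("position", "native", "replacement") %in% names(df)))
    stop("feature CSV must name position, native and replacement columns")
  df
}
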