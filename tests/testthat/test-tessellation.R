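test_that("four non-coplanar points give exactly one tetrahedron", {
  tess <- tessellate(tetra_structure())
  expect_equal(nrow(tess$simplices), 1L)
  expect_equal(sort(tess$simplices[1, ]), 1:4)
})

test_that("simplices match the brute-force empty-circumsphere oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:25, 1)
    pts <- matrix(runif(3 * n, 0, 20), ncol = 3)
    tess <- tessellate(pts)
    oracle <- brute_force_delaunay(pts)
    expect_setequal(simplex_keys(tess$simplices), simplex_keys(oracle))
  }
})

test_that("degenerate inputs are rejected with a description", {
  expect_error(tessellate(matrix(rnorm(9), 3, 3)), "4 sites")
  flat <- cbind(matrix(runif(12), 6, 2), 0)
  expect_error(tessellate(flat), "coplanar")
  dup <- rbind(diag(3) * 5, c(5, 0, 0), c(1, 1, 1))
  expect_error(tessellate(dup), "duplicate")
})

test_that("edge filtering drops exactly the simplices with a long edge", {
  # a tetrahedron stretched so one edge exceeds 12 A
  s <- calpha_structure(1:4, rep("G", 4),
                        rbind(c(0, 0, 0), c(13, 0, 0), c(6, 5, 0),
                              c(6, 2, 5)))
  expect_equal(nrow(filter_long_edges(tessellate(s), 12)$simplices), 0L)
  expect_equal(nrow(filter_long_edges(tessellate(s), Inf)$simplices), 1L)

  set.seed(4)
  ch <- generate_chain(40, seed = 4)
  full <- tessellate(ch)
  f12 <- filter_long_edges(full, 12)
  # only whole simplices are discarded, and only those with a long edge
  maxe <- tessmut:::simplex_max_edge(full)
  expect_equal(nrow(f12$simplices), sum(maxe <= 12))
  expect_true(all(f12$edges$length <= 12))
  expect_error(filter_long_edges(f12, 12), "already")
  expect_error(filter_long_edges(full, -1), "positive")
})

test_that("filtering is monotone in the cutoff", {
  set.seed(9)
  ch <- generate_chain(35, seed = 9)
  full <- tessellate(ch)
  k8 <- simplex_keys(filter_long_edges(full, 8)$simplices)
  k12 <- simplex_keys(filter_long_edges(full, 12)$simplices)
  kinf <- simplex_keys(filter_long_edges(full, Inf)$simplices)
  expect_true(all(k8 %in% k12))
  expect_true(all(k12 %in% kinf))
  expect_setequal(kinf, simplex_keys(full$simplices))
})

test_that("incidence queries satisfy the counting identity", {
  set.seed(2)
  ch <- generate_chain(30, seed = 2)
  tess <- filter_long_edges(tessellate(ch), 12)
  counts <- vapply(ch$position, function(p) nrow(simplices_at(tess, p)),
                   integer(1))
  expect_equal(sum(counts), 4L * nrow(tess$simplices))
  expect_error(simplices_at(tess, 999), "999")

  single <- tessellate(tetra_structure())
  for (p in 1:4) expect_equal(nrow(simplices_at(single, p)), 1L)
})

test_that("neighbors are distance-sorted, symmetric, tie-broken by position", {
  single <- tessellate(tetra_structure())
  for (p in 1:4) expect_equal(nrow(tess_neighbors(single, p)), 3L)

  set.seed(5)
  ch <- generate_chain(30, seed = 5)
  tess <- filter_long_edges(tessellate(ch), 12)
  xyz <- ch$xyz
  for (p in c(1, 10, 25)) {
    nb <- tess_neighbors(tess, p)
    # brute-force: collect edge-connected sites, sort by distance then number
    e <- tess$edges
    idx <- match(p, ch$position)
    oth <- c(e$j[e$i == idx], e$i[e$j == idx])
    d <- sqrt(colSums((t(xyz[oth, , drop = FALSE]) - xyz[idx, ])^2))
    ord <- order(d, ch$position[oth])
    expect_equal(nb$position, ch$position[oth][ord])
    expect_equal(nb$distance, unname(d[ord]), tolerance = 1e-9)
    # symmetry
    for (q in nb$position)
      expect_true(p %in% tess_neighbors(tess, q)$position)
  }
})

test_that("tetrahedron volume matches the Cayley-Menger oracle", {
  unit <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(tetra_volume(unit), 1 / 6)
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(tetra_volume(flat), 0)
  for (seed in 1:5) {
    set.seed(seed)
    coords <- matrix(rnorm(12, sd = 4), 4, 3)
    expect_equal(tetra_volume(coords), cayley_menger_volume(coords),
                 tolerance = 1e-9)
  }
})

test_that("tetrahedrality is zero for regular, scale-free, equals pair sum", {
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(tetrahedrality(reg), 0, tolerance = 1e-12)
  set.seed(8)
  coords <- matrix(rnorm(12, sd = 3), 4, 3)
  expect_equal(tetrahedrality(coords), tetrahedrality(coords * 7.3),
               tolerance = 1e-12)
  # direct double-loop oracle over the 15 edge pairs
  pr <- combn(4, 2)
  l <- sqrt(colSums((t(coords[pr[1, ], ]) - t(coords[pr[2, ], ]))^2))
  acc <- 0
  for (i in 1:5) for (j in (i + 1):6) acc <- acc + (l[i] - l[j])^2
  expect_equal(tetrahedrality(coords), acc / (15 * mean(l)^2),
               tolerance = 1e-12)
})

test_that("depth classes respect their definitions", {
  single <- tessellate(tetra_structure())
  d <- classify_depth(single)
  expect_equal(d$depth, rep("surface", 4))

  set.seed(13)
  ch <- generate_chain(60, seed = 13)
  tess <- filter_long_edges(tessellate(ch), 12)
  d <- classify_depth(tess)
  # boundary-face oracle: surface positions touch a face used by 1 simplex
  s <- tess$simplices
  faces <- rbind(s[, c(2, 3, 4)], s[, c(1, 3, 4)], s[, c(1, 2, 4)],
                 s[, c(1, 2, 3)])
  key <- paste(faces[, 1], faces[, 2], faces[, 3])
  surf <- sort(unique(as.vector(faces[key %in% names(which(table(key) == 1)), ])))
  expect_equal(which(d$depth == "surface"), surf)
  for (i in which(d$depth == "undersurface")) {
    nb <- tess_neighbors(tess, d$position[i])$position
    expect_true(any(d$depth[match(nb, d$position)] == "surface"))
  }
  for (i in which(d$depth == "buried")) {
    nb <- tess_neighbors(tess, d$position[i])$position
    expect_false(any(d$depth[match(nb, d$position)] == "surface"))
    expect_equal(d$surface_contacts[i], 0L)
  }
  # surface-contact count equals neighbors classified surface
  for (i in seq_len(nrow(d))) {
    nb <- tess_neighbors(tess, d$position[i])$position
    expect_equal(d$surface_contacts[i],
                 sum(d$depth[match(nb, d$position)] == "surface"))
  }
})
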