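test_that("total potential sums simplex scores", {
  s <- tetra_structure(aa = c("G", "A", "L", "W"))
  tess <- filter_long_edges(tessellate(s), Inf)
  pot <- toy_potential(function(k) if (k == quad_key(c("G", "A", "L", "W"))) 0.5 else 0)
  expect_equal(total_potential(tess, pot), 0.5)
  zero <- toy_potential(function(k) 0)
  expect_equal(total_potential(tess, zero), 0)
  expect_error(total_potential(tess, pot, sequence = c("G", "A")), "length")
})

test_that("potential profile distributes each simplex score to 4 vertices", {
  s <- tetra_structure()
  tess <- filter_long_edges(tessellate(s), Inf)
  pot <- toy_potential(function(k) 0.25)
  pp <- potential_profile(tess, pot)
  expect_equal(unname(pp$res), rep(0.25, 4))
  expect_equal(pp$total, 0.25)

  ch <- generate_chain(20, seed = 61)
  tess <- filter_long_edges(tessellate(ch), 12)
  pot <- toy_potential()
  pp <- potential_profile(tess, pot)
  expect_equal(sum(pp$res), 4 * pp$total, tolerance = 1e-9)
  # brute-force per-position sums
  lk <- setNames(pot$s, pot$quad)
  for (p in c(1, 7, 20)) {
    inc <- simplices_at(tess, p)
    keys <- apply(inc, 1, function(v) paste(sort(ch$aa[v]), collapse = ""))
    expect_equal(unname(pp$res[as.character(p)]), sum(lk[keys]),
                 tolerance = 1e-9)
  }
})

test_that("residual profiles obey the EP identities", {
  ch <- generate_chain(25, seed = 71)
  tess <- filter_long_edges(tessellate(ch), 12)
  pot <- toy_potential()

  idn <- residual_profile(tess, pot, 5, ch$aa[5])
  expect_true(all(idn$ep == 0))
  expect_equal(idn$residual_score, 0)

  set.seed(72)
  for (i in 1:20) {
    p <- sample(ch$position, 1)
    r <- sample(setdiff(tessmut:::AA20, ch$aa[match(p, ch$position)]), 1)
    pr <- residual_profile(tess, pot, p, r)
    # residual score is the EP entry at the mutated position
    expect_equal(pr$residual_score, unname(pr$ep[as.character(p)]))
    # each incident simplex contributes its delta at 4 vertices
    expect_equal(sum(pr$ep), 4 * pr$residual_score, tolerance = 1e-9)
    # EP support within the mutated position and its neighbors
    supp <- as.integer(names(pr$ep)[pr$ep != 0])
    expect_true(all(supp %in% c(p, tess_neighbors(tess, p)$position)))
    # locality optimization equals naive full recomputation
    mut_seq <- ch$aa
    mut_seq[match(p, ch$position)] <- r
    nat <- potential_profile(tess, pot)
    mut <- potential_profile(tess, pot, sequence = mut_seq)
    expect_equal(unname(pr$ep), unname(mut$res - nat$res), tolerance = 1e-9)
    expect_equal(pr$residual_score, mut$total - nat$total, tolerance = 1e-9)
  }
  expect_error(residual_profile(tess, pot, 999, "A"), "999")
})

test_that("CMP scores average the 19 substitutions and split by class", {
  ch <- generate_chain(15, seed = 81)
  tess <- filter_long_edges(tessellate(ch), 12)
  pot <- toy_potential()
  cmp <- cmp_scores(tess, pot, positions = c(3, 8))
  for (i in 1:2) {
    p <- cmp$position[i]
    nat <- ch$aa[match(p, ch$position)]
    reps <- setdiff(tessmut:::AA20, nat)
    rs <- vapply(reps, function(r)
      residual_profile(tess, pot, p, r)$residual_score, numeric(1))
    expect_equal(cmp$cmp[i], mean(rs), tolerance = 1e-12)
    # partition identity: 19 * CMP = C-sum + NC-sum
    expect_equal(19 * cmp$cmp[i],
                 cmp$n_c[i] * cmp$cmp_c[i] + cmp$n_nc[i] * cmp$cmp_nc[i],
                 tolerance = 1e-9)
    expect_equal(cmp$n_c[i] + cmp$n_nc[i], 19L)
  }
})

test_that("substitution classes follow the six physicochemical groups", {
  expect_equal(substitution_class("A", "S"), "C")
  expect_equal(substitution_class("A", "D"), "NC")
  expect_equal(substitution_class("C", "W"), "NC")  # cysteine is a singleton
  expect_equal(substitution_class("V", "M"), "C")
  expect_equal(substitution_class("R", "H"), "C")
  expect_error(substitution_class("A", "A"), "identical")
})

test_that("polarity classes partition the 20 residues as 9 + 7 + 4", {
  cls <- polarity_class(tessmut:::AA20)
  expect_equal(unname(table(cls)[c("polar", "apolar", "charged")]),
               c(9L, 7L, 4L), ignore_attr = TRUE)
  expect_equal(polarity_class("H"), "polar")
  expect_equal(polarity_class("K"), "charged")
  expect_equal(polarity_class("A"), "apolar")
  expect_error(polarity_class("X"), "X")
})

test_that("group means recombine to the global mean", {
  set.seed(91)
  v <- rnorm(50)
  g <- sample(c("a", "b", "c"), 50, replace = TRUE)
  gm <- group_mean_scores(v, g)
  expect_equal(sum(gm$mean * gm$n) / sum(gm$n), mean(v), tolerance = 1e-12)
  for (l in unique(g))
    expect_equal(gm$mean[gm$label == l], mean(v[g == l]), tolerance = 1e-12)
  one <- group_mean_scores(v, rep("all", 50))
  expect_equal(one$mean, mean(v))
  withempty <- group_mean_scores(v, g, levels = c("a", "b", "c", "d"))
  expect_equal(withempty$n[withempty$label == "d"], 0L)
  expect_true(is.na(withempty$mean[withempty$label == "d"]))
})
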