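test_that("CDR concatenation is VL CDR1-3 then VH CDR1-3 and framework-independent", {
  vl <- toy_kappa_chain("c1_VL", cdr1 = "RASQDVNTAVA", cdr2 = "SASFLYS", cdr3 = "QQHYTTPPT")
  vh <- toy_heavy_chain("c1_VH", cdr1 = "GFNIKDTYIH", cdr3 = "WGGDGFYA")
  expect_identical(
    concat_cdrs(vl, vh),
    paste0("RASQDVNTAVA", "SASFLYS", "QQHYTTPPT", "GFNIKDTYIH", "AISGSGGSTYYADSVK", "WGGDGFYA")
  )
  # same CDRs on a mutated framework: identical concatenation
  vl2 <- toy_kappa_chain("c2_VL",
    cdr1 = "RASQDVNTAVA", cdr2 = "SASFLYS", cdr3 = "QQHYTTPPT",
    fw_mut = c(3, 17, 40)
  )
  expect_identical(concat_cdrs(vl2, vh), concat_cdrs(vl, vh))
})

test_that("pairwise difference is zero iff identical and symmetric", {
  expect_equal(pairwise_cdr_difference("RASQSIS", "RASQSIS"), 0)
  set.seed(9)
  for (k in 1:8) {
    a <- paste(sample(c("A", "G", "S", "T", "W", "R"), 12, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "G", "S", "T", "W", "R"), 12, replace = TRUE), collapse = "")
    expect_equal(pairwise_cdr_difference(a, b), pairwise_cdr_difference(b, a))
    if (a != b) expect_gt(pairwise_cdr_difference(a, b), 0)
  }
  expect_error(pairwise_cdr_difference("", "AAA"), "empty")
})

test_that("one conservative mismatch in 20 ungapped columns is 5 percent", {
  # S->T scores positive under BLOSUM62, so no gap is favoured
  a <- paste0(strrep("A", 10), "S", strrep("G", 9))
  b <- paste0(strrep("A", 10), "T", strrep("G", 9))
  expect_equal(pairwise_cdr_difference(a, b), 5.0)
})

test_that("disjoint equal-length strings are 100 percent different", {
  expect_equal(pairwise_cdr_difference(strrep("A", 10), strrep("G", 10)), 100)
  expect_equal(pairwise_cdr_difference(strrep("A", 4), strrep("W", 4)), 100)
})

test_that("implementation matches the exhaustive alignment oracle on tiny strings", {
  set.seed(31)
  for (k in 1:12) {
    a <- paste(sample(c("A", "S", "T", "W", "G"), sample(3:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "S", "T", "W", "G"), sample(3:6, 1), replace = TRUE), collapse = "")
    diffs <- bf_align_diffs(a, b)
    got <- round(pairwise_cdr_difference(a, b), 8)
    expect_true(got %in% diffs, info = sprintf("a=%s b=%s got=%g oracle={%s}",
      a, b, got, paste(diffs, collapse = ",")
    ))
  }
})

test_that("distance matrix is symmetric, zero-diagonal and permutation-equivariant", {
  strings <- c(x = "RASQSISSYLN", y = "RASQDVNTAVA", z = "RASQSISSYLN")
  d <- build_distance_matrix(strings)
  expect_equal(diag(d), c(x = 0, y = 0, z = 0))
  expect_equal(d, t(d))
  expect_equal(d["x", "z"], 0) # identical strings
  dh <- pairwise_cdr_difference(strings["x"], strings["y"])
  expect_equal(d["x", "y"], dh)
  perm <- c("z", "x", "y")
  d2 <- build_distance_matrix(strings[perm])
  expect_equal(d2, d[perm, perm])
  expect_error(build_distance_matrix(c(a = "AA", a = "GG")), "duplicate")
  expect_error(build_distance_matrix(c(a = "AA")), "at least two")
})

test_that("dedupe clusters by single linkage with first-in-order representatives", {
  same <- setNames(rep("RASQSISSYLNAASSLQS", 4), paste0("c", 1:4))
  dd <- dedupe_clones(same)
  expect_equal(dd$n_unique, 1)
  expect_identical(dd$representatives, "c1")
  expect_equal(dd$uniqueness_pct, 25)

  # threshold 0: every distinct string its own cluster
  mix <- c(a = strrep("A", 20), b = strrep("A", 20), c = strrep("G", 20))
  dd0 <- dedupe_clones(mix, threshold_pct = 0)
  expect_equal(dd0$n_unique, 2)
  expect_identical(dd0$representatives, c("a", "c"))
})

test_that("dedupe is idempotent and non-increasing in threshold", {
  rep_ <- simulate_clone_repertoire(seed = 13, n_lineages = 8, n_clones = 12)
  d <- build_distance_matrix(rep_$clones)
  dd <- dedupe_clones(rep_$clones, distance = d)
  reps <- d[dd$representatives, dd$representatives]
  dd2 <- dedupe_clones(setNames(
    vapply(rep_$clones, `[[`, character(1), "cdr_concat"),
    vapply(rep_$clones, `[[`, character(1), "clone_id")
  )[dd$representatives], distance = reps)
  expect_equal(dd2$n_unique, dd$n_unique)
  expect_identical(dd2$representatives, dd$representatives)

  counts <- vapply(
    c(0, 5, 10, 30, 100),
    function(th) dedupe_clones(rep_$clones, threshold_pct = th, distance = d)$n_unique,
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1) # threshold 100 merges everything
})

test_that("a planted 34-clone 24-lineage repertoire dedupes to 24 unique (71%)", {
  rep_ <- simulate_clone_repertoire(seed = 101)
  dd <- dedupe_clones(rep_$clones)
  expect_equal(dd$n_unique, 24)
  expect_equal(dd$uniqueness_pct, 71)
  # recovered clusters coincide with the planted lineages
  lineages <- rep_$truth$lineage[names(dd$cluster)]
  expect_equal(
    unname(vapply(split(lineages, dd$cluster), function(x) length(unique(x)), numeric(1))),
    rep(1, dd$n_unique)
  )
  expect_equal(length(unique(lineages)), dd$n_unique)
})
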