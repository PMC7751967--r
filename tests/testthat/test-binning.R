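named_matrix <- function(x, ids) {
  matrix(x, length(ids), length(ids), byrow = TRUE, dimnames = list(ids, ids))
}

test_that("competition normalization divides each column by its expected response", {
  ids <- c("a", "b")
  raw <- named_matrix(c(200, 100, 50, 100), ids)
  norm <- normalize_competition(raw, c(a = 200, b = 100))
  expect_equal(norm, named_matrix(c(1, 1, 0.25, 1), ids))
  expect_equal(
    normalize_competition(named_matrix(rep(0, 4), ids), c(a = 200, b = 100)),
    named_matrix(rep(0, 4), ids)
  )
  expect_error(normalize_competition(raw, c(a = 0, b = 100)), "positive")
})

test_that("blocked calls use a strict threshold with a forced diagonal", {
  ids <- c("a", "b")
  norm <- named_matrix(c(0.9, 0.05, 0.2, 0.9), ids)
  blocked <- call_blocked(norm, threshold = 0.2)
  expect_true(blocked["a", "b"])    # 0.05 < 0.2
  expect_false(blocked["b", "a"])   # 0.2 is not < 0.2
  expect_true(all(diag(blocked)))
})

test_that("bins group identical blocking profiles", {
  ids <- paste0("c", 1:4)
  # all rows identical -> one bin
  all_same <- named_matrix(rep(TRUE, 16), ids)
  expect_length(assign_bins(all_same)$bins, 1)
  # self-block only -> every clone its own bin
  solo <- diag(4) == 1
  dimnames(solo) <- list(ids, ids)
  expect_length(assign_bins(solo)$bins, 4)
  expect_error(assign_bins(matrix(TRUE, 2, 3)), "square")
})

test_that("a bridging clone creates a third bin between two profiles", {
  # A1,A2 share an epitope; B1,B2 share another; X bridges both
  ids <- c("A1", "A2", "B1", "B2", "X")
  blocked <- named_matrix(c(
    TRUE,  TRUE,  FALSE, FALSE, TRUE,
    TRUE,  TRUE,  FALSE, FALSE, TRUE,
    FALSE, FALSE, TRUE,  TRUE,  TRUE,
    FALSE, FALSE, TRUE,  TRUE,  TRUE,
    TRUE,  TRUE,  TRUE,  TRUE,  TRUE
  ), ids)
  bins <- assign_bins(blocked)
  expect_length(bins$bins, 3)
  expect_equal(bins$assignment[["A1"]], bins$assignment[["A2"]])
  expect_equal(bins$assignment[["B1"]], bins$assignment[["B2"]])
  expect_false(bins$assignment[["X"]] %in%
    c(bins$assignment[["A1"]], bins$assignment[["B1"]]))
  # the bridging clone is connected to everything in the network
  net <- build_network(blocked)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_equal(unname(deg[["X"]]), 4)
  # A-B pairs can sandwich; nothing can pair with the bridge
  pairs <- sandwich_compatible_pairs(blocked)
  expect_equal(nrow(pairs), 4)
  expect_false("X" %in% c(pairs$a, pairs$b))
})

test_that("network edges count competing pairs; compatible pairs are the complement", {
  ids <- paste0("c", 1:4)
  none <- diag(4) == 1
  dimnames(none) <- list(ids, ids)
  expect_equal(nrow(build_network(none)$edges), 0)
  expect_equal(nrow(sandwich_compatible_pairs(none)), 6)
  full <- named_matrix(rep(TRUE, 16), ids)
  expect_equal(nrow(build_network(full)$edges), 6) # n(n-1)/2
  expect_equal(nrow(sandwich_compatible_pairs(full)), 0)
  single <- matrix(TRUE, 1, 1, dimnames = list("c1", "c1"))
  expect_equal(nrow(sandwich_compatible_pairs(single)), 0)
})

test_that("bins partition the clones; permutation preserves the partition", {
  sim <- simulate_competition(seed = 21, bin_sizes = c(3, 2, 4), bridge = TRUE)
  blocked <- call_blocked(normalize_competition(sim$raw, sim$expected))
  bins <- assign_bins(blocked)
  expect_setequal(unlist(bins$bins), rownames(blocked))
  expect_equal(sum(lengths(bins$bins)), nrow(blocked))
  perm <- sample(rownames(blocked))
  bins_p <- assign_bins(blocked[perm, perm])
  part <- function(b) unname(lapply(b$bins, sort)[order(vapply(b$bins, function(x) sort(x)[1], character(1)))])
  expect_equal(part(bins_p), part(bins))
  # same-bin clones have identical network neighbourhoods
  net <- build_network(blocked)
  nbhd <- function(id) sort(c(net$edges$to[net$edges$from == id], net$edges$from[net$edges$to == id]))
  for (b in bins$bins) {
    if (length(b) < 2) next
    ref <- setdiff(nbhd(b[1]), b)
    for (m in b[-1]) expect_equal(setdiff(nbhd(m), b), ref)
  }
  # sandwich-compatible pairs never share a bin
  pairs <- sandwich_compatible_pairs(blocked)
  if (nrow(pairs) > 0) {
    expect_true(all(bins$assignment[pairs$a] != bins$assignment[pairs$b]))
  }
})

test_that("latent-interval fixtures are recovered exactly at zero noise", {
  sim <- simulate_competition(seed = 2, bin_sizes = c(3, 3, 3), noise_sd = 0)
  blocked <- call_blocked(normalize_competition(sim$raw, sim$expected))
  bins <- assign_bins(blocked)
  expect_length(bins$bins, 3)
  # recovered bins coincide with the distinct-interval classes
  truth_split <- split(names(sim$truth$bins), sim$truth$bins)
  expect_setequal(
    unname(lapply(bins$bins, sort)),
    unname(lapply(truth_split, sort))
  )
  # all clones on one interval -> one bin; disjoint intervals -> cliques
  one <- simulate_competition(seed = 3, bin_sizes = 5)
  blocked1 <- call_blocked(normalize_competition(one$raw, one$expected))
  expect_length(assign_bins(blocked1)$bins, 1)
  net <- build_network(blocked)
  expect_equal(nrow(net$edges), 3 * choose(3, 2)) # three 3-cliques
})
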