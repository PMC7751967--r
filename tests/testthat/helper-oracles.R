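# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: exhaustive enumeration for alignments
# and tree topologies, numerical ODE integration for binding curves.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Enumerate every global alignment of a and b under zero gap penalties and
# return the set of percent differences attained by score-optimal
# alignments. Exponential; keep strings short (<= 8).
bf_align_diffs <- function(a, b, mat = blosum62) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$diffs <- numeric(0)
  rec <- function(i, j, score, len, diff) {
    if (i > length(A) && j > length(B)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$diffs <- numeric(0)
      }
      if (score >= best$score - 1e-9) {
        best$diffs <- union(best$diffs, round(100 * diff / len, 8))
      }
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, score + mat[A[i], B[j]], len + 1, diff + (A[i] != B[j]))
    }
    if (i <= length(A)) rec(i + 1, j, score, len + 1, diff + 1)
    if (j <= length(B)) rec(i, j + 1, score, len + 1, diff + 1)
  }
  rec(1L, 1L, 0, 0L, 0L)
  best$diffs
}

# Least-squares branch-length fit of all three unrooted 4-taxon topologies;
# returns the split with minimal residual sum of squares and its fitted
# edge lengths (a, b = cherry leaves; c, d = other leaves; m = internal).
bf_nj4 <- function(d) {
  labs <- rownames(d)
  splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  fits <- lapply(splits, function(sp) {
    i <- sp[1]; j <- sp[2]; k <- sp[3]; l <- sp[4]
    X <- rbind(
      c(1, 1, 0, 0, 0), # d(i,j) = a + b
      c(1, 0, 1, 0, 1), # d(i,k) = a + m + c
      c(1, 0, 0, 1, 1), # d(i,l) = a + m + d
      c(0, 1, 1, 0, 1), # d(j,k) = b + m + c
      c(0, 1, 0, 1, 1), # d(j,l) = b + m + d
      c(0, 0, 1, 1, 0)  # d(k,l) = c + d
    )
    y <- c(d[i, j], d[i, k], d[i, l], d[j, k], d[j, l], d[k, l])
    beta <- qr.solve(X, y)
    rss <- sum((X %*% beta - y)^2)
    list(cherry = sort(labs[c(i, j)]), lengths = beta, rss = rss)
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}

# Cherry (sister-leaf pair containing labs[1]) of an unrooted 4-taxon tree,
# by the four-point condition on its path-length matrix.
tree_cherry4 <- function(path_lengths) {
  labs <- rownames(path_lengths)
  stopifnot(length(labs) == 4)
  sums <- c(
    path_lengths[labs[1], labs[2]] + path_lengths[labs[3], labs[4]],
    path_lengths[labs[1], labs[3]] + path_lengths[labs[2], labs[4]],
    path_lengths[labs[1], labs[4]] + path_lengths[labs[2], labs[3]]
  )
  partner <- labs[c(2, 3, 4)][which.min(sums)]
  sort(c(labs[1], partner))
}

# Integrate dR/dt = kon*C*(rmax - R) - koff*R numerically.
ode_langmuir <- function(times, kon, koff, rmax, conc, r0 = 0, dissociation = FALSE) {
  deriv <- function(t, y, parms) {
    cc <- if (dissociation) 0 else conc
    list(kon * cc * (rmax - y[1]) - koff * y[1])
  }
  out <- deSolve::lsoda(
    y = c(R = r0), times = times, func = deriv, parms = NULL,
    rtol = 1e-12, atol = 1e-12
  )
  out[, "R"]
}

# Random additive distance matrix from a random tree with positive branch
# lengths; returns the matrix (the generating tree's path lengths).
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, br = function(k) runif(k, 0.5, 5))
  d <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(d))
  d[labs, labs]
}

# Toy numbered chains built directly from region strings at template
# positions; used where alignment-based numbering is not under test.
toy_kappa_chain <- function(id = "toy", cdr1 = "RASQSISSYLN", cdr2 = "AASSLQS",
                            cdr3 = "QQSYSTPLT", fw_mut = integer(0)) {
  tpl <- builtin_templates("kappa_light")[[1]]
  stopifnot(nchar(cdr1) == 11, nchar(cdr2) == 7, nchar(cdr3) == 9)
  res <- tpl$residues
  res[tpl$regions == "CDR1"] <- strsplit(cdr1, "")[[1]]
  res[tpl$regions == "CDR2"] <- strsplit(cdr2, "")[[1]]
  res[tpl$regions == "CDR3"] <- strsplit(cdr3, "")[[1]]
  for (i in fw_mut) {
    idx <- which(startsWith(tpl$regions, "FR"))[i]
    res[idx] <- if (res[idx] == "A") "V" else "A"
  }
  numbered_chain(id, "kappa_light", tpl$positions, res)
}

toy_heavy_chain <- function(id = "toy_vh", cdr1 = "GFTFSSYAMS",
                            cdr2 = "AISGSGGSTYYADSVK", cdr3 = "DGGYYFDY") {
  tpl <- builtin_templates("heavy")[[1]]
  stopifnot(nchar(cdr1) == 10, nchar(cdr2) == 16, nchar(cdr3) == 8)
  res <- tpl$residues
  res[tpl$regions == "CDR1"] <- strsplit(cdr1, "")[[1]]
  res[tpl$regions == "CDR2"] <- strsplit(cdr2, "")[[1]]
  res[tpl$regions == "CDR3"] <- strsplit(cdr3, "")[[1]]
  numbered_chain(id, "heavy", tpl$positions, res)
}
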