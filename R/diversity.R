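# Clone CDR-diversity analysis: concatenated CDR strings, pairwise percent
# differences under zero-gap-penalty global alignment, single-linkage
# deduplication at the >10%-difference uniqueness rule, and distance
# matrices feeding the neighbor-joining tree.

#' Create a clone record
#'
#' @param clone_id Clone identifier (e.g. `"14F9"`).
#' @param vl,vh Numbered light and heavy chains of the clone.
#' @return Object of class `clone_record` carrying the chains and the
#'   concatenated CDR string (VL CDR1..3 then VH CDR1..3).
#' @export
clone_record <- function(clone_id, vl, vh) {
  stopifnot(inherits(vl, "numbered_chain"), inherits(vh, "numbered_chain"))
  if (vl$chain_type != "kappa_light" || vh$chain_type != "heavy") {
    stop("clone ", clone_id, ": vl must be kappa_light and vh heavy")
  }
  structure(
    list(clone_id = clone_id, vl = vl, vh = vh, cdr_concat = concat_cdrs(vl, vh)),
    class = "clone_record"
  )
}

#' @export
print.clone_record <- function(x, ...) {
  cat(sprintf("<clone_record> %s, CDR concat %s\n", x$clone_id, x$cdr_concat))
  invisible(x)
}

#' Concatenate the six CDRs of a clone into one residue string
#'
#' Deterministic order: VL CDR1, CDR2, CDR3, then VH CDR1, CDR2, CDR3. The
#' framework plays no part, so clones differing only in framework residues
#' have identical concatenated strings.
#'
#' @param vl,vh Numbered chains (or a single `clone_record` as `vl`).
#' @return Single residue string.
#' @export
concat_cdrs <- function(vl, vh = NULL) {
  if (inherits(vl, "clone_record")) {
    vh <- vl$vh
    vl <- vl$vl
  }
  part <- function(chain) {
    cd <- extract_regions(chain)$cdrs
    paste0(cd$cdr1$sequence, cd$cdr2$sequence, cd$cdr3$sequence)
  }
  paste0(part(vl), part(vh))
}

#' Pairwise percent difference between CDR strings
#'
#' Globally aligns the two strings by dynamic programming with the given
#' substitution matrix and gap penalties (both zero by default, the setting
#' used for CDR-string comparison) and reports
#' `100 * (mismatched columns + gap columns) / alignment length`. For
#' equal-length comparisons where no gap is favoured this reduces to the
#' Hamming fraction. Symmetric; 0 iff the strings are identical.
#'
#' @param a,b Non-empty residue strings.
#' @param substitution_matrix Matrix name or numeric matrix for
#'   [Biostrings::pairwiseAlignment()] (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (default 0, 0).
#' @return Percent difference in \[0, 100\].
#' @export
pairwise_cdr_difference <- function(a, b, substitution_matrix = "BLOSUM62",
                                    gap_open = 0, gap_extend = 0) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty CDR string")
  if (a == b) return(0)
  # several alignments can share the optimal score; fix the orientation so
  # the reported difference is exactly symmetric
  if (a > b) {
    tmp <- a
    a <- b
    b <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  ca <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * mean(ca != cb | ca == "-" | cb == "-")
}

#' Distance matrix of pairwise CDR differences
#'
#' @param clones List of `clone_record` (or a named character vector of CDR
#'   strings).
#' @param ... Passed to [pairwise_cdr_difference()].
#' @return Symmetric numeric matrix (percent differences, zero diagonal)
#'   with clone ids as dimnames.
#' @export
build_distance_matrix <- function(clones, ...) {
  strings <- cdr_strings(clones)
  if (length(strings) < 2) stop("need at least two clones")
  if (anyDuplicated(names(strings))) stop("duplicate clone ids")
  n <- length(strings)
  d <- matrix(0, n, n, dimnames = list(names(strings), names(strings)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- pairwise_cdr_difference(strings[i], strings[j], ...)
    }
  }
  d
}

cdr_strings <- function(clones) {
  if (is.character(clones)) {
    if (is.null(names(clones))) names(clones) <- paste0("clone_", seq_along(clones))
    return(clones)
  }
  setNames(
    vapply(clones, `[[`, character(1), "cdr_concat"),
    vapply(clones, `[[`, character(1), "clone_id")
  )
}

#' Deduplicate clones by CDR-difference threshold
#'
#' A clone is unique when its concatenated CDR string differs by more than
#' `threshold_pct` percent from every other unique clone; operationally,
#' clones are single-linkage clustered at the threshold (any chain of
#' pairwise differences `<= threshold_pct` shares a cluster) and the first
#' clone of each cluster in input order is its representative.
#'
#' @param clones List of `clone_record` or named CDR strings.
#' @param threshold_pct Percent-difference threshold (default 10).
#' @param distance Optional precomputed distance matrix (ids as dimnames);
#'   computed with defaults when missing.
#' @return List with `cluster` (integer assignment named by clone id, in
#'   input order), `representatives` (one id per cluster), `n_unique`, and
#'   `uniqueness_pct = round(100 * n_unique / n)`.
#' @export
dedupe_clones <- function(clones, threshold_pct = 10, distance = NULL) {
  ids <- names(cdr_strings(clones))
  n <- length(ids)
  if (n < 1) stop("need at least one clone")
  if (n == 1) {
    return(list(
      cluster = setNames(1L, ids), representatives = ids,
      n_unique = 1L, uniqueness_pct = 100
    ))
  }
  if (is.null(distance)) distance <- build_distance_matrix(clones)
  d <- distance[ids, ids, drop = FALSE]
  # union-find over edges d <= threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (d[i, j] <= threshold_pct) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster <- match(roots, unique(roots)) # numbered by first appearance
  reps <- ids[!duplicated(cluster)]
  list(
    cluster = setNames(cluster, ids),
    representatives = reps,
    n_unique = length(reps),
    uniqueness_pct = round(100 * length(reps) / n)
  )
}
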