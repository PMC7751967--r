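# Scheme positions and region (framework/CDR) bookkeeping.
#
# A scheme position is a text label: an integer part plus an optional
# insertion letter ("52", "52A", "100B"). Insertion letters follow the
# convention of lettered positions for residues inserted relative to the
# numbering template. Ordering is by integer part, then letter (no letter
# sorts before "A").

REGION_ORDER <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

position_num <- function(positions) {
  as.integer(sub("[A-Z]*$", "", positions))
}

position_ins <- function(positions) {
  sub("^[0-9]+", "", positions)
}

#' Order scheme position labels
#'
#' Returns the permutation that sorts position labels by integer part and
#' then by insertion letter (unlettered first).
#'
#' @param positions Character vector of scheme position labels.
#' @return Integer permutation suitable for subsetting.
#' @export
position_order <- function(positions) {
  order(position_num(positions), position_ins(positions))
}

#' Default CDR boundary table
#'
#' One row per CDR giving its scheme-position span on each chain type. The
#' default implements the union of the Kabat and Chothia loop definitions
#' (the wider of the two at each end), which is the conservative choice when
#' the goal is to keep every hypervariable residue out of the framework.
#' Users with an exact convention can pass their own table anywhere a
#' `boundary_table` argument appears.
#'
#' @return A data.frame with columns `chain_type`, `region`, `start`, `end`
#'   (integer scheme positions, inclusive).
#' @export
default_boundary_table <- function() {
  data.frame(
    chain_type = c(rep("kappa_light", 3), rep("heavy", 3)),
    region = rep(c("CDR1", "CDR2", "CDR3"), 2),
    start = c(24L, 50L, 89L, 26L, 50L, 95L),
    end = c(34L, 56L, 97L, 35L, 65L, 102L),
    stringsAsFactors = FALSE
  )
}

#' Map scheme positions to regions
#'
#' @param positions Character vector of scheme position labels.
#' @param chain_type `"kappa_light"` or `"heavy"`.
#' @param boundary_table CDR boundary table; see [default_boundary_table()].
#' @return Character vector of region labels (`FR1`..`FR4`, `CDR1`..`CDR3`).
#' @export
region_for_position <- function(positions, chain_type,
                                boundary_table = default_boundary_table()) {
  bt <- boundary_table[boundary_table$chain_type == chain_type, ]
  if (nrow(bt) != 3L) {
    stop("boundary table must define CDR1-3 for chain type ", chain_type)
  }
  bt <- bt[order(bt$start), ]
  num <- position_num(positions)
  region <- character(length(num))
  region[num < bt$start[1]] <- "FR1"
  region[num >= bt$start[1] & num <= bt$end[1]] <- "CDR1"
  region[num > bt$end[1] & num < bt$start[2]] <- "FR2"
  region[num >= bt$start[2] & num <= bt$end[2]] <- "CDR2"
  region[num > bt$end[2] & num < bt$start[3]] <- "FR3"
  region[num >= bt$start[3] & num <= bt$end[3]] <- "CDR3"
  region[num > bt$end[3]] <- "FR4"
  region
}

#' Construct a numbered antibody chain
#'
#' Low-level constructor used by [number_chain()] and the simulators; checks
#' the structural invariants (unique positions, one region per residue,
#' regions in FR1..FR4 order with no interleaving).
#'
#' @param chain_id Identifier.
#' @param chain_type `"kappa_light"` or `"heavy"`.
#' @param positions Character vector of scheme position labels.
#' @param residues Character vector of 1-letter residues, same length.
#' @param boundary_table CDR boundary table.
#' @return An object of class `numbered_chain`.
#' @export
numbered_chain <- function(chain_id, chain_type, positions, residues,
                           boundary_table = default_boundary_table()) {
  chain_type <- match.arg(chain_type, c("kappa_light", "heavy"))
  stopifnot(length(positions) == length(residues))
  if (anyDuplicated(positions)) {
    stop("duplicated scheme positions in chain ", chain_id)
  }
  ord <- position_order(positions)
  positions <- positions[ord]
  residues <- residues[ord]
  aa_check(paste(residues, collapse = ""), paste("chain", chain_id))
  regions <- region_for_position(positions, chain_type, boundary_table)
  ridx <- match(regions, REGION_ORDER)
  if (any(diff(ridx) < 0)) {
    stop("regions interleave along chain ", chain_id)
  }
  structure(
    list(
      chain_id = chain_id, chain_type = chain_type,
      positions = positions, residues = residues, regions = regions
    ),
    class = "numbered_chain"
  )
}

#' @export
print.numbered_chain <- function(x, ...) {
  cat(sprintf(
    "<numbered_chain> %s (%s), %d residues\n  %s\n",
    x$chain_id, x$chain_type, length(x$residues), chain_sequence(x)
  ))
  invisible(x)
}

#' Plain sequence of a numbered chain
#'
#' @param chain A `numbered_chain`.
#' @return Single string of 1-letter residues in scheme order.
#' @export
chain_sequence <- function(chain) {
  paste(chain$residues, collapse = "")
}

#' Framework residues as a position-named vector
#'
#' @param chain A `numbered_chain`.
#' @return Named character vector (names are scheme positions) restricted to
#'   framework (FR) positions.
#' @export
framework_vector <- function(chain) {
  keep <- startsWith(chain$regions, "FR")
  setNames(chain$residues[keep], chain$positions[keep])
}
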