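# Framework-control design: germline consensus frameworks, closest-framework
# selection against a candidate therapeutic antibody (Ab1), and CDR grafting
# of an irrelevant donor onto the chosen consensus acceptor. The grafted
# control Fab carries the closest human framework but decoy CDRs, so that in
# screening it soaks up framework-reactive binders and leaves only
# CDR-specific anti-idiotypic clones.

#' Build a germline panel
#'
#' @param family_label Family short label, e.g. `"K1"` or `"H3"`.
#' @param members List of `numbered_chain`, all of the same chain type.
#' @return Object of class `germline_panel`.
#' @export
germline_panel <- function(family_label, members) {
  if (length(members) < 1) stop("germline panel needs at least one member")
  types <- unique(vapply(members, `[[`, character(1), "chain_type"))
  if (length(types) != 1) stop("panel members mix chain types")
  structure(
    list(family_label = family_label, chain_type = types, members = members),
    class = "germline_panel"
  )
}

#' Consensus framework of a germline panel
#'
#' At every framework scheme position carried by the panel, the consensus
#' residue is the most prevalent residue among members carrying that
#' position; ties go to the alphabetically smallest residue (deterministic).
#' Positions absent from more than half of the members are dropped.
#'
#' @param panel A `germline_panel`.
#' @return Object of class `consensus_framework` with `family_label`,
#'   `chain_type`, `positions`, `residues` and `per_position_frequencies`.
#' @export
build_consensus_framework <- function(panel) {
  stopifnot(inherits(panel, "germline_panel"))
  fws <- lapply(panel$members, framework_vector)
  all_pos <- unique(unlist(lapply(fws, names)))
  all_pos <- all_pos[position_order(all_pos)]
  n <- length(fws)
  freqs <- list()
  residues <- character(0)
  positions <- character(0)
  for (p in all_pos) {
    obs <- unlist(lapply(fws, function(f) unname(f[p])))
    obs <- obs[!is.na(obs)]
    if (length(obs) < n / 2) next # absent from >50% of members
    tab <- table(obs)
    winners <- names(tab)[tab == max(tab)]
    positions <- c(positions, p)
    residues <- c(residues, sort(winners)[1])
    freqs[[p]] <- tab
  }
  structure(
    list(
      family_label = panel$family_label,
      chain_type = panel$chain_type,
      positions = positions,
      residues = residues,
      per_position_frequencies = freqs
    ),
    class = "consensus_framework"
  )
}

#' @export
print.consensus_framework <- function(x, ...) {
  cat(sprintf(
    "<consensus_framework> %s (%s), %d framework positions\n",
    x$family_label, x$chain_type, length(x$positions)
  ))
  invisible(x)
}

consensus_vector <- function(consensus) {
  setNames(consensus$residues, consensus$positions)
}

as_framework_vector <- function(x) {
  if (inherits(x, "numbered_chain")) return(framework_vector(x))
  if (inherits(x, "consensus_framework")) return(consensus_vector(x))
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("expected a numbered_chain, consensus_framework or position-named vector")
}

#' Percent identity between two scheme-aligned frameworks
#'
#' Identity is computed over the union of framework positions present in
#' either chain: positions present in only one chain (indels) count as
#' mismatches. The raw percentage is returned; reporting rounds to the
#' nearest integer.
#'
#' @param fw_a,fw_b Frameworks: `numbered_chain`, `consensus_framework`, or
#'   position-named residue vectors on the same numbering scheme.
#' @return Percentage in \[0, 100\] (unrounded); symmetric in its arguments.
#' @export
percent_identity <- function(fw_a, fw_b) {
  a <- as_framework_vector(fw_a)
  b <- as_framework_vector(fw_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop("no shared scheme positions; identity undefined")
  union_n <- length(union(names(a), names(b)))
  matches <- sum(a[shared] == b[shared])
  100 * matches / union_n
}

#' Select the closest framework control for a given Ab1
#'
#' Scores the Ab1 light- and heavy-chain frameworks against every available
#' consensus framework (independently per chain), picks the
#' maximum-identity family on each side (ties broken by panel order) and
#' assembles the control label (e.g. `"K1H3"`).
#'
#' @param ab1_vl,ab1_vh Numbered Ab1 chains.
#' @param lc_panels,hc_panels Lists of `consensus_framework` candidates.
#' @return Object of class `control_design`: chosen families, integer
#'   identities, label, and (after [graft_cdrs()]) the grafted sequences.
#' @export
select_closest_control <- function(ab1_vl, ab1_vh, lc_panels, hc_panels) {
  if (length(lc_panels) < 1 || length(hc_panels) < 1) {
    stop("need at least one light- and one heavy-chain consensus framework")
  }
  pick <- function(chain, panels) {
    ids <- vapply(panels, function(p) percent_identity(chain, p), numeric(1))
    best <- which.max(ids) # which.max takes the first on ties (panel order)
    list(
      family = panels[[best]]$family_label,
      identity = ids[best],
      consensus = panels[[best]],
      all_identities = setNames(ids, vapply(panels, `[[`, character(1), "family_label"))
    )
  }
  lc <- pick(ab1_vl, lc_panels)
  hc <- pick(ab1_vh, hc_panels)
  structure(
    list(
      lc_choice = lc$family, hc_choice = hc$family,
      lc_identity_pct = round(lc$identity), hc_identity_pct = round(hc$identity),
      control_label = paste0(lc$family, hc$family),
      lc_consensus = lc$consensus, hc_consensus = hc$consensus,
      lc_all_identities = lc$all_identities, hc_all_identities = hc$all_identities,
      grafted_vl = NULL, grafted_vh = NULL
    ),
    class = "control_design"
  )
}

#' @export
print.control_design <- function(x, ...) {
  cat(sprintf(
    "<control_design> %s (LC %s: %d%%, HC %s: %d%%)\n",
    x$control_label, x$lc_choice, x$lc_identity_pct, x$hc_choice, x$hc_identity_pct
  ))
  invisible(x)
}

graft_chain <- function(cdrs, acceptor, chain_id) {
  stopifnot(inherits(cdrs, "cdr_set"), inherits(acceptor, "consensus_framework"))
  if (cdrs$chain_type != acceptor$chain_type) {
    stop(sprintf(
      "donor CDRs are %s but acceptor framework is %s",
      cdrs$chain_type, acceptor$chain_type
    ))
  }
  positions <- c(
    acceptor$positions,
    cdrs$cdr1$positions, cdrs$cdr2$positions, cdrs$cdr3$positions
  )
  residues <- c(
    acceptor$residues,
    strsplit(cdrs$cdr1$sequence, "")[[1]],
    strsplit(cdrs$cdr2$sequence, "")[[1]],
    strsplit(cdrs$cdr3$sequence, "")[[1]]
  )
  numbered_chain(chain_id, acceptor$chain_type, positions, residues)
}

#' Graft donor CDRs onto acceptor consensus frameworks
#'
#' Builds the framework-control variable domains by combining the acceptor
#' framework residues with the donor CDR residues at their own scheme
#' positions. Round-trip guarantee: [extract_regions()] of a grafted chain
#' returns the donor CDRs and the acceptor framework verbatim.
#'
#' @param donor List with elements `vl` and `vh`, each a `cdr_set` (e.g. from
#'   [extract_regions()] of an irrelevant donor antibody).
#' @param acceptor_lc,acceptor_hc `consensus_framework` acceptors.
#' @param label Prefix for the grafted chain ids.
#' @return List with `vl` and `vh` grafted `numbered_chain`s.
#' @export
graft_cdrs <- function(donor, acceptor_lc, acceptor_hc, label = "ctrl") {
  list(
    vl = graft_chain(donor$vl, acceptor_lc, paste0(label, "_VL")),
    vh = graft_chain(donor$vh, acceptor_hc, paste0(label, "_VH"))
  )
}

#' Read protein chains from FASTA
#'
#' @param path FASTA file of variable-domain protein sequences.
#' @return Named character vector of sequences.
#' @export
read_chain_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write protein chains to FASTA
#'
#' @param sequences Named character vector or list of `numbered_chain`.
#' @param path Output file.
#' @export
write_chain_fasta <- function(sequences, path) {
  if (is.list(sequences) && all(vapply(sequences, inherits, logical(1), "numbered_chain"))) {
    sequences <- setNames(
      vapply(sequences, chain_sequence, character(1)),
      vapply(sequences, `[[`, character(1), "chain_id")
    )
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
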