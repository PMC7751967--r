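# Epitope-type classification of anti-ID clones from SPR summary responses:
# antigen blocking vs non-blocking (sign of the actual antigen-binding Rmax
# percentage) and antigen-drug-complex specificity (complex/Fab-only Rmax
# ratio), combined into the three reagent groups used for assay selection:
#   Group 1: Ag non-blocking, complex-specific
#   Group 2: Ag non-blocking, not complex-specific
#   Group 3: Ag blocking

#' Theoretical antigen-binding Rmax
#'
#' The response expected if every drug Fab held by the captured anti-ID
#' bound one antigen: `(mw_ag / mw_fab) * fab_response * fab_stoichiometry`
#' (SPR responses scale with bound mass).
#'
#' @param mw_ag,mw_fab Molecular weights (kDa), positive.
#' @param fab_response Drug-Fab binding response (RU).
#' @param fab_stoichiometry Antigen sites per Fab (default 1, monovalent).
#' @return Theoretical Rmax in RU.
#' @export
theoretical_ag_rmax <- function(mw_ag, mw_fab, fab_response, fab_stoichiometry = 1) {
  if (any(mw_fab <= 0) || any(mw_ag <= 0)) stop("molecular weights must be positive")
  (mw_ag / mw_fab) * fab_response * fab_stoichiometry
}

#' Classify antigen blocking vs non-blocking
#'
#' The actual antigen-binding Rmax percentage is
#' `100 * (post_ag_response - fab_response) / theoretical_ag_rmax`; a clone
#' is antigen-blocking when the percentage is `<= 0` (no antigen signal over
#' the drug-Fab baseline) and non-blocking when it is `> 0`.
#'
#' @param fab_response Drug-Fab saturation response (RU).
#' @param post_ag_response Cumulative response after the antigen injection (RU).
#' @param mw_ag,mw_fab,fab_stoichiometry See [theoretical_ag_rmax()].
#' @return data.frame with `actual_ag_rmax_pct` and logical `blocking`.
#' @export
classify_blocking <- function(fab_response, post_ag_response, mw_ag, mw_fab,
                              fab_stoichiometry = 1) {
  theo <- theoretical_ag_rmax(mw_ag, mw_fab, fab_response, fab_stoichiometry)
  if (any(theo == 0)) stop("theoretical Rmax is zero; classification undefined")
  pct <- 100 * (post_ag_response - fab_response) / theo
  data.frame(actual_ag_rmax_pct = pct, blocking = pct <= 0)
}

#' Classify antigen-drug-complex specificity
#'
#' Compares the binding Rmax of premixed antigen + drug-Fab complex with the
#' drug-Fab-only Rmax on matched capture levels; a clone is
#' complex-specific when the ratio exceeds `threshold_pct` percent
#' (strictly).
#'
#' @param complex_rmax Rmax against the antigen + drug-Fab premix (RU).
#' @param fab_only_rmax Rmax against drug Fab alone (RU), positive.
#' @param threshold_pct Ratio threshold in percent (default 10).
#' @param capture_complex,capture_fab Optional protein-A capture responses;
#'   when given, each Rmax is normalized by its capture level before the
#'   ratio (otherwise matched capture is assumed).
#' @return data.frame with `complex_ratio_pct` and logical `complex_specific`.
#' @export
classify_complex <- function(complex_rmax, fab_only_rmax, threshold_pct = 10,
                             capture_complex = NULL, capture_fab = NULL) {
  if (!is.null(capture_complex) && !is.null(capture_fab)) {
    if (any(capture_complex <= 0) || any(capture_fab <= 0)) {
      stop("capture responses must be positive")
    }
    complex_rmax <- complex_rmax / capture_complex
    fab_only_rmax <- fab_only_rmax / capture_fab
  }
  if (any(fab_only_rmax <= 0)) stop("fab_only_rmax must be positive")
  ratio <- 100 * complex_rmax / fab_only_rmax
  data.frame(complex_ratio_pct = ratio, complex_specific = ratio > threshold_pct)
}

#' Assign the reagent group from the two epitope flags
#'
#' @param blocking Logical: antigen blocking.
#' @param complex_specific Logical: antigen-drug-complex specific.
#' @return Integer group: 1 (non-blocking, complex-specific), 2
#'   (non-blocking, not complex-specific), 3 (blocking). Vectorized; a
#'   total function of the two flags.
#' @export
assign_group <- function(blocking, complex_specific) {
  stopifnot(length(blocking) == length(complex_specific))
  ifelse(blocking, 3L, ifelse(complex_specific, 1L, 2L))
}

#' Classify a table of epitope assay records
#'
#' @param records data.frame with columns `clone_id`, `fab_response`,
#'   `post_ag_response`, `mw_ag`, `mw_fab`, `complex_rmax`, `fab_only_rmax`
#'   and optional `fab_stoichiometry` (default 1).
#' @param complex_threshold_pct Complex-ratio threshold (default 10).
#' @return data.frame of epitope calls: `clone_id`, `actual_ag_rmax_pct`,
#'   `blocking`, `complex_ratio_pct`, `complex_specific`, `group`.
#' @export
classify_epitopes <- function(records, complex_threshold_pct = 10) {
  stoich <- records$fab_stoichiometry %||% rep(1, nrow(records))
  bl <- classify_blocking(
    records$fab_response, records$post_ag_response,
    records$mw_ag, records$mw_fab, stoich
  )
  cx <- classify_complex(
    records$complex_rmax, records$fab_only_rmax, complex_threshold_pct
  )
  data.frame(
    clone_id = records$clone_id,
    actual_ag_rmax_pct = bl$actual_ag_rmax_pct,
    blocking = bl$blocking,
    complex_ratio_pct = cx$complex_ratio_pct,
    complex_specific = cx$complex_specific,
    group = assign_group(bl$blocking, cx$complex_specific),
    stringsAsFactors = FALSE
  )
}

#' Summarize epitope groups and affinities
#'
#' @param calls data.frame with `clone_id` and `group` (e.g. from
#'   [classify_epitopes()], or flags passed through [assign_group()]).
#' @param kd_nM Optional named (by clone id) or positionally matched vector
#'   of affinities in nM; clones with missing KD are excluded from the
#'   affinity aggregates with a warning.
#' @return List with `counts` (named vector, groups 1-3, summing to the
#'   clone count), and when affinities are given, `kd_overall` and
#'   `kd_by_group` (min/median/max in nM).
#' @export
summarize_groups <- function(calls, kd_nM = NULL) {
  counts <- table(factor(calls$group, levels = 1:3))
  counts <- setNames(as.integer(counts), c("group1", "group2", "group3"))
  out <- list(counts = counts, n = nrow(calls))
  if (!is.null(kd_nM)) {
    if (!is.null(names(kd_nM))) kd_nM <- kd_nM[calls$clone_id]
    miss <- is.na(kd_nM)
    if (any(miss)) {
      warning(
        sum(miss), " clone(s) missing KD excluded from affinity aggregates: ",
        paste(calls$clone_id[miss], collapse = ", ")
      )
    }
    rng <- function(x) {
      if (length(x) == 0) {
        c(min = NA_real_, median = NA_real_, max = NA_real_)
      } else {
        c(min = min(x), median = stats::median(x), max = max(x))
      }
    }
    out$kd_overall <- rng(kd_nM[!miss])
    out$kd_by_group <- lapply(setNames(1:3, c("group1", "group2", "group3")),
      function(g) rng(kd_nM[!miss & calls$group == g])
    )
  }
  out
}

#' Worked-example anti-ID panel (24 clones)
#'
#' Loads the packaged characterization summary of an example anti-ID
#' discovery campaign: 24 unique clones with their measured affinity (nM)
#' and per-clone antigen-blocking / non-blocking / complex-specificity
#' flags, as produced by SPR epitope typing.
#'
#' @return data.frame with columns `clone_id`, `kd_nM`, `ag_blocking`,
#'   `ag_non_blocking`, `ag_ab1_complex` (flags as `"Yes"`/`"No"`).
#' @export
example_epitope_panel <- function() {
  path <- system.file("extdata", "example_panel_epitopes.csv", package = "idiokit")
  read.csv(path, stringsAsFactors = FALSE)
}
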