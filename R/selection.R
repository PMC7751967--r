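# Reagent selection for assay development: score capture/detect sandwich
# pairs for PK assays and single-clone bridging positive controls for ADA
# assays by signal-to-noise from titration curves, under epitope-bin
# compatibility constraints.

#' Signal-to-noise ratio of a titration curve
#'
#' Top-dose signal over the zero-analyte blank, with the blank floored to
#' avoid division by zero.
#'
#' @param conc Analyte concentrations (one must be 0, the blank).
#' @param od Matching OD reads.
#' @param floor Blank floor (default 0.001).
#' @return The ratio.
#' @export
signal_to_noise <- function(conc, od, floor = 0.001) {
  stopifnot(length(conc) == length(od))
  if (!any(conc == 0)) stop("titration curve has no zero-analyte blank")
  blank <- mean(od[conc == 0])
  top <- mean(od[conc == max(conc)])
  top / max(blank, floor)
}

# Non-strict monotonicity with a small relative tolerance for plate noise:
# each step up in concentration may drop the OD by at most tol (fraction).
curve_monotone <- function(conc, od, tol = 0.02) {
  ord <- order(conc)
  o <- od[ord]
  all(diff(o) >= -tol * pmax(o[-length(o)], 1e-9))
}

#' Select PK sandwich capture/detect pairs
#'
#' A pair is suitable when the two clones sit in different epitope bins with
#' no mutual competition, the curve's signal-to-noise is at least `min_sn`,
#' and the OD increases monotonically with analyte concentration (within a
#' small noise tolerance). Results are ranked by signal-to-noise.
#'
#' @param curves data.frame of titrations: `capture_id`, `detect_id`,
#'   `conc`, `od` (one blank row with `conc == 0` per pair).
#' @param bins Bin assignment from [assign_bins()] (or a named vector of
#'   bin labels).
#' @param blocked Logical competition matrix (ids as dimnames) used for the
#'   no-mutual-competition check; when missing, different bins suffice.
#' @param min_sn Minimum signal-to-noise (default 10).
#' @param monotone_tol Relative tolerance of the monotonicity check
#'   (default 0.02).
#' @return data.frame `capture_id`, `detect_id`, `signal_to_noise`,
#'   `monotone`, `compatible_bins`, `suitable`, ranked by decreasing
#'   signal-to-noise.
#' @export
select_pk_pairs <- function(curves, bins, blocked = NULL, min_sn = 10,
                            monotone_tol = 0.02) {
  assignment <- if (is.list(bins) && !is.null(bins$assignment)) bins$assignment else bins
  keys <- unique(curves[, c("capture_id", "detect_id")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    cap <- keys$capture_id[k]
    det <- keys$detect_id[k]
    cc <- curves[curves$capture_id == cap & curves$detect_id == det, ]
    if (!(cap %in% names(assignment)) || !(det %in% names(assignment))) {
      warning("no bin assignment for pair ", cap, "/", det, "; skipped")
      return(NULL)
    }
    sn <- tryCatch(signal_to_noise(cc$conc, cc$od), error = function(e) {
      warning("pair ", cap, "/", det, ": ", conditionMessage(e), "; skipped")
      NA_real_
    })
    if (is.na(sn)) return(NULL)
    compatible <- assignment[[cap]] != assignment[[det]]
    if (compatible && !is.null(blocked)) {
      compatible <- !blocked[cap, det] && !blocked[det, cap]
    }
    mono <- curve_monotone(cc$conc, cc$od, monotone_tol)
    data.frame(
      capture_id = cap, detect_id = det,
      signal_to_noise = sn, monotone = mono, compatible_bins = compatible,
      suitable = compatible && mono && sn >= min_sn,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      capture_id = character(0), detect_id = character(0),
      signal_to_noise = numeric(0), monotone = logical(0),
      compatible_bins = logical(0), suitable = logical(0)
    ))
  }
  out <- out[order(-out$signal_to_noise, out$capture_id, out$detect_id), ]
  rownames(out) <- NULL
  out
}

#' Rank ADA bridging positive-control candidates
#'
#' Ranks single clones by the signal-to-noise of their bridging titration
#' curve (descending; ties by clone id). Clones without a blank are skipped
#' with a warning.
#'
#' @param curves data.frame `clone_id`, `conc`, `od` (blank row with
#'   `conc == 0` per clone).
#' @return data.frame `clone_id`, `signal_to_noise`, ranked.
#' @export
rank_ada_controls <- function(curves) {
  ids <- unique(curves$clone_id)
  rows <- lapply(ids, function(id) {
    cc <- curves[curves$clone_id == id, ]
    sn <- tryCatch(signal_to_noise(cc$conc, cc$od), error = function(e) {
      warning("clone ", id, ": ", conditionMessage(e), "; skipped")
      NA_real_
    })
    if (is.na(sn)) return(NULL)
    data.frame(clone_id = id, signal_to_noise = sn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(clone_id = character(0), signal_to_noise = numeric(0)))
  }
  out <- out[order(-out$signal_to_noise, out$clone_id), ]
  rownames(out) <- NULL
  out
}
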