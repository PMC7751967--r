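# ELISA screening: hit calling on culture-supernatant plates, top-clone
# selection for molecular cloning, recombinant-IgG confirmation, and serum
# titers. All threshold comparisons are strict (> / <) exactly as the assay
# cutoffs are stated; boundary values fail.

ANTIGENS <- c("Ab1_Fab", "Ab1ctrl_Fab", "Huctrl_Fab", "blank")

# Average replicate wells and pivot a long plate read into one row per
# sample with one OD column per antigen.
pivot_plate <- function(plate, antigens) {
  stopifnot(all(c("sample_id", "antigen", "od") %in% names(plate)))
  if (any(plate$od < 0, na.rm = TRUE)) stop("negative OD in plate read")
  agg <- stats::aggregate(od ~ sample_id + antigen, data = plate, FUN = mean)
  samples <- unique(plate$sample_id)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (ag in antigens) {
    v <- agg$od[agg$antigen == ag][match(samples, agg$sample_id[agg$antigen == ag])]
    out[[paste0("od_", ag)]] <- v
  }
  out
}

#' Call primary ELISA hits
#'
#' A supernatant is a hit when it binds the drug Fab (`od_ab1 >
#' pos_threshold`) but not the framework-control Fab (`od_ctrl <
#' ctrl_threshold`). Samples reactive against the control (`od_ctrl >=
#' ctrl_threshold`) are excluded as framework binders; everything else is
#' negative. Samples missing either antigen read get status `"error"`
#' rather than aborting the plate.
#'
#' @param plate Long-format data.frame with columns `sample_id`, `antigen`
#'   (`"Ab1_Fab"`, `"Ab1ctrl_Fab"`, ...), `od`; replicate wells are averaged.
#' @param pos_threshold OD cutoff on the drug Fab (default 0.25).
#' @param ctrl_threshold OD cutoff on the control Fab (default 0.1).
#' @return data.frame `sample_id`, `od_ab1`, `od_ctrl`, `status` in
#'   `{hit, negative, excluded, error}`.
#' @export
call_primary_hits <- function(plate, pos_threshold = 0.25, ctrl_threshold = 0.1) {
  wide <- pivot_plate(plate, c("Ab1_Fab", "Ab1ctrl_Fab"))
  out <- data.frame(
    sample_id = wide$sample_id,
    od_ab1 = wide$od_Ab1_Fab,
    od_ctrl = wide$od_Ab1ctrl_Fab,
    stringsAsFactors = FALSE
  )
  status <- rep("negative", nrow(out))
  status[is.na(out$od_ab1) | is.na(out$od_ctrl)] <- "error"
  ok <- status != "error"
  status[ok & out$od_ctrl >= ctrl_threshold] <- "excluded"
  status[ok & out$od_ab1 > pos_threshold & out$od_ctrl < ctrl_threshold] <- "hit"
  out$status <- status
  out
}

#' Select top clones for molecular cloning
#'
#' Among primary hits, keeps those with a strong drug-Fab signal (`od_ab1 >
#' top_threshold`) and a clean control (`od_ctrl < ctrl_threshold`), ranked
#' by `od_ab1` descending with ties broken by sample id.
#'
#' @param hits Output of [call_primary_hits()].
#' @param top_threshold OD cutoff for a strong signal (default 1.0).
#' @param ctrl_threshold Control OD cutoff (default 0.1).
#' @return Ranked data.frame of top clones with status `"top_hit"`.
#' @export
select_top_clones <- function(hits, top_threshold = 1.0, ctrl_threshold = 0.1) {
  top <- hits[hits$status == "hit" &
    hits$od_ab1 > top_threshold &
    hits$od_ctrl < ctrl_threshold, , drop = FALSE]
  top <- top[order(-top$od_ab1, top$sample_id), , drop = FALSE]
  if (nrow(top)) top$status <- "top_hit"
  rownames(top) <- NULL
  top
}

#' Confirm recombinant IgG specificity
#'
#' A recombinant clone is confirmed when it binds the drug Fab (`od_ab1 >
#' pos_threshold`) with near-undetectable signal on both the designed
#' framework control and the native human-Fab control (`max(od) <
#' neg_threshold`).
#'
#' @param plate Long-format plate with antigens `"Ab1_Fab"`, `"Ab1ctrl_Fab"`
#'   and `"Huctrl_Fab"`.
#' @param pos_threshold Positive cutoff (default 0.3).
#' @param neg_threshold Control cutoff (default 0.05).
#' @return data.frame `sample_id`, `od_ab1`, `od_ctrl`, `od_huctrl`,
#'   `status` in `{confirmed, negative, error}`.
#' @export
confirm_recombinant <- function(plate, pos_threshold = 0.3, neg_threshold = 0.05) {
  wide <- pivot_plate(plate, c("Ab1_Fab", "Ab1ctrl_Fab", "Huctrl_Fab"))
  out <- data.frame(
    sample_id = wide$sample_id,
    od_ab1 = wide$od_Ab1_Fab,
    od_ctrl = wide$od_Ab1ctrl_Fab,
    od_huctrl = wide$od_Huctrl_Fab,
    stringsAsFactors = FALSE
  )
  status <- rep("negative", nrow(out))
  status[is.na(out$od_ab1) | is.na(out$od_ctrl) | is.na(out$od_huctrl)] <- "error"
  ok <- status != "error"
  ctrl_max <- pmax(out$od_ctrl, out$od_huctrl)
  status[ok & out$od_ab1 > pos_threshold & ctrl_max < neg_threshold] <- "confirmed"
  out$status <- status
  out
}

#' Serum titer from a dilution series
#'
#' The titer is the largest dilution factor whose OD is still above the
#' cutoff; 0 when no point is positive.
#'
#' @param dilution_factor Strictly increasing positive dilution factors
#'   (e.g. 100, 1000, ..., 1e6), at least two.
#' @param od Matching OD reads.
#' @param cutoff Positivity OD cutoff.
#' @return The titer (a dilution factor, or 0).
#' @export
compute_titer <- function(dilution_factor, od, cutoff) {
  if (length(dilution_factor) < 2) stop("need at least two dilution points")
  if (length(dilution_factor) != length(od)) stop("dilution/od length mismatch")
  if (any(diff(dilution_factor) <= 0)) {
    stop("dilution factors must be strictly increasing")
  }
  pos <- dilution_factor[od > cutoff]
  if (length(pos) == 0) 0 else max(pos)
}

#' Summarize screening statuses
#'
#' @param calls Output of a hit-calling function.
#' @return List with per-status counts and the positivity rate (fraction of
#'   non-error samples called `hit` or `confirmed`).
#' @export
summarize_screen <- function(calls) {
  counts <- table(factor(calls$status,
    levels = c("hit", "top_hit", "confirmed", "negative", "excluded", "error")
  ))
  n_ok <- sum(calls$status != "error")
  pos <- sum(calls$status %in% c("hit", "top_hit", "confirmed"))
  list(
    counts = as.list(counts),
    n = nrow(calls),
    positivity_rate = if (n_ok > 0) pos / n_ok else NA_real_
  )
}
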