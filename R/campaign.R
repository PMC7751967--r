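# End-to-end campaign orchestration: run every computational stage of an
# anti-ID discovery campaign (on synthetic inputs or user-supplied tables),
# collect the per-stage artifacts, and emit a campaign report in the style
# of a project summary row plus a per-clone characterization table.

#' Default campaign configuration
#'
#' Returns the nested per-stage parameter list consumed by
#' [run_campaign()]. Each block can be overridden; `NULL`-ing a block skips
#' that stage. `epitope_flags` may carry a user-supplied typing table
#' (columns `clone_id`, `blocking`, `complex_specific`, optional `kd_nM`),
#' in which case epitope grouping uses it instead of simulated assays.
#'
#' @param project_id Campaign label.
#' @return Named list of stage blocks.
#' @export
campaign_config <- function(project_id = "synthetic_campaign") {
  list(
    project_id = project_id,
    germline = list(n_families = 4, members_per_family = 5,
                    family_rate = 0.08, member_rate = 0.02,
                    ab1_lc_family = "K1", ab1_hc_family = "H3"),
    repertoire = list(n_lineages = 24, n_clones = 34),
    plates = list(n_clones = 2000, hit_fraction = 0.45, excluded_fraction = 0.05),
    kinetics = list(n_clones = 6, noise_sd = 1),
    epitopes = list(n = 24, proportions = c(5, 14, 5) / 24, noise_frac = 0),
    competition = list(bin_sizes = c(3, 3, 3), bridge = TRUE),
    titrations = list(min_sn = 10),
    epitope_flags = NULL
  )
}

run_stage <- function(report, name, fn) {
  res <- tryCatch(fn(), error = function(e) e)
  if (inherits(res, "error")) {
    warning("stage '", name, "' failed: ", conditionMessage(res))
    report$stages[[name]] <- list(ok = FALSE, error = conditionMessage(res))
  } else {
    report$stages[[name]] <- c(list(ok = TRUE), res)
  }
  report
}

#' Run a full anti-ID discovery campaign
#'
#' Orchestrates the computational stages — framework-control design, clone
#' diversity, ELISA screening, 1:1 kinetics, epitope typing, epitope
#' binning and reagent selection — on synthetic inputs generated from
#' per-stage substreams of `seed` (or on tables supplied in `config`).
#' A failing stage is isolated: it is recorded as absent in the report and
#' the remaining stages still run.
#'
#' @param seed Campaign seed; fans out per stage via [substream_seed()].
#' @param config Stage configuration, see [campaign_config()].
#' @param outdir Optional directory: per-stage artifacts are written there
#'   as CSV/JSON/FASTA/Newick files.
#' @return Object of class `campaign_report`.
#' @export
run_campaign <- function(seed = 1, config = campaign_config(), outdir = NULL) {
  report <- structure(
    list(project_id = config$project_id, seed = seed, stages = list()),
    class = "campaign_report"
  )

  # --- framework-control design ------------------------------------------
  if (!is.null(config$germline)) {
    report <- run_stage(report, "control_design", function() {
      g <- config$germline
      sim <- simulate_germline_panel(
        substream_seed(seed, "germline"),
        n_families = g$n_families, members_per_family = g$members_per_family,
        family_rate = g$family_rate, member_rate = g$member_rate
      )
      lc_cons <- lapply(sim$lc_panels, build_consensus_framework)
      hc_cons <- lapply(sim$hc_panels, build_consensus_framework)
      # synthetic Ab1: framework drawn from the configured families with a
      # little extra divergence, CDRs mutated away from the donor's
      set.seed(substream_seed(seed, "germline") + 1L)
      ab1_vl <- perturbed_chain(sim$truth$lc_founders[[g$ab1_lc_family]],
                                "kappa_light", "ab1_VL")
      ab1_vh <- perturbed_chain(sim$truth$hc_founders[[g$ab1_hc_family]],
                                "heavy", "ab1_VH")
      design <- select_closest_control(ab1_vl, ab1_vh, unname(lc_cons), unname(hc_cons))
      donor <- list(
        vl = extract_regions(builtin_templates("kappa_light")[[1]])$cdrs,
        vh = extract_regions(builtin_templates("heavy")[[1]])$cdrs
      )
      grafted <- graft_cdrs(
        donor, design$lc_consensus, design$hc_consensus,
        label = design$control_label
      )
      design$grafted_vl <- grafted$vl
      design$grafted_vh <- grafted$vh
      list(design = design,
           truth = list(lc_family = g$ab1_lc_family, hc_family = g$ab1_hc_family))
    })
  }

  # --- clone diversity ----------------------------------------------------
  if (!is.null(config$repertoire)) {
    report <- run_stage(report, "diversity", function() {
      r <- config$repertoire
      sim <- simulate_clone_repertoire(
        substream_seed(seed, "repertoire"),
        n_lineages = r$n_lineages, n_clones = r$n_clones
      )
      d <- build_distance_matrix(sim$clones)
      dd <- dedupe_clones(sim$clones, threshold_pct = 10, distance = d)
      reps <- d[dd$representatives, dd$representatives, drop = FALSE]
      tree <- if (nrow(reps) >= 3) neighbor_joining(reps) else NULL
      list(
        n_cloned = length(sim$clones), dedupe = dd, distance = d,
        tree = tree, truth = sim$truth
      )
    })
  }

  # --- ELISA screening ----------------------------------------------------
  if (!is.null(config$plates)) {
    report <- run_stage(report, "screening", function() {
      p <- config$plates
      sim <- simulate_plates(
        substream_seed(seed, "plates"),
        n_clones = p$n_clones, hit_fraction = p$hit_fraction,
        excluded_fraction = p$excluded_fraction
      )
      calls <- call_primary_hits(sim$plate)
      top <- select_top_clones(calls)
      list(
        calls = calls, top = top, summary = summarize_screen(calls),
        truth = sim$truth
      )
    })
  }

  # --- kinetics -----------------------------------------------------------
  if (!is.null(config$kinetics)) {
    report <- run_stage(report, "kinetics", function() {
      k <- config$kinetics
      sim <- simulate_sensorgrams(
        substream_seed(seed, "sensorgrams"),
        n_clones = k$n_clones, noise_sd = k$noise_sd
      )
      fits <- fit_kinetics_table(sim$sensorgrams)
      list(fits = fits, truth = sim$truth)
    })
  }

  # --- epitope typing -----------------------------------------------------
  if (!is.null(config$epitopes) || !is.null(config$epitope_flags)) {
    report <- run_stage(report, "epitope_typing", function() {
      if (!is.null(config$epitope_flags)) {
        fl <- config$epitope_flags
        calls <- data.frame(
          clone_id = fl$clone_id,
          blocking = fl$blocking,
          complex_specific = fl$complex_specific,
          group = assign_group(fl$blocking, fl$complex_specific),
          stringsAsFactors = FALSE
        )
        kd <- if ("kd_nM" %in% names(fl)) setNames(fl$kd_nM, fl$clone_id) else NULL
        list(calls = calls, summary = summarize_groups(calls, kd), truth = NULL)
      } else {
        e <- config$epitopes
        sim <- simulate_epitope_assays(
          substream_seed(seed, "epitopes"),
          n = e$n, proportions = e$proportions, noise_frac = e$noise_frac
        )
        calls <- classify_epitopes(sim$records)
        kd <- NULL
        kin <- report$stages$kinetics
        if (!is.null(kin) && isTRUE(kin$ok)) {
          kd <- setNames(kin$fits$kd_nM, kin$fits$clone_id)[calls$clone_id]
          names(kd) <- calls$clone_id
        }
        list(calls = calls, summary = summarize_groups(calls, kd), truth = sim$truth)
      }
    })
  }

  # --- epitope binning ----------------------------------------------------
  if (!is.null(config$competition)) {
    report <- run_stage(report, "binning", function() {
      cb <- config$competition
      sim <- simulate_competition(
        substream_seed(seed, "competition"),
        bin_sizes = cb$bin_sizes, bridge = isTRUE(cb$bridge)
      )
      normalized <- normalize_competition(sim$raw, sim$expected)
      blocked <- call_blocked(normalized)
      bins <- assign_bins(blocked)
      list(
        blocked = blocked, bins = bins,
        network = build_network(blocked),
        compatible = sandwich_compatible_pairs(blocked),
        truth = sim$truth
      )
    })
  }

  # --- reagent selection --------------------------------------------------
  if (!is.null(config$titrations)) {
    report <- run_stage(report, "selection", function() {
      bn <- report$stages$binning
      if (is.null(bn) || !isTRUE(bn$ok)) stop("binning stage unavailable")
      tseed <- substream_seed(seed, "titrations")
      pk_curves <- simulate_pk_curves(bn$blocked, seed = tseed)
      pk <- select_pk_pairs(pk_curves, bn$bins, blocked = bn$blocked,
                            min_sn = config$titrations$min_sn)
      ids <- rownames(bn$blocked)
      good <- if (nrow(bn$compatible) > 0) unlist(bn$compatible[1, ]) else character(0)
      ada_curves <- simulate_ada_curves(ids, good, seed = tseed + 1L)
      ada <- rank_ada_controls(ada_curves)
      list(pk_pairs = pk, ada_ranking = ada)
    })
  }

  report <- finalize_report(report)
  if (!is.null(outdir)) write_campaign_artifacts(report, outdir)
  report
}

perturbed_chain <- function(framework, chain_type, chain_id, n_fw_mut = 1) {
  cdrs <- extract_regions(builtin_templates(chain_type)[[1]])$cdrs
  fw <- framework
  idx <- sample(length(fw), n_fw_mut)
  fw[idx] <- mutate_residues(unname(fw), idx)[idx]
  positions <- c(names(fw), cdrs$cdr1$positions, cdrs$cdr2$positions, cdrs$cdr3$positions)
  residues <- c(
    unname(fw),
    strsplit(mutate_string(cdrs$cdr1$sequence, rate = 0.5), "")[[1]],
    strsplit(mutate_string(cdrs$cdr2$sequence, rate = 0.5), "")[[1]],
    strsplit(mutate_string(cdrs$cdr3$sequence, rate = 0.5), "")[[1]]
  )
  numbered_chain(chain_id, chain_type, positions, residues)
}

# Assemble the top-level summary fields and check the report invariants.
finalize_report <- function(report) {
  s <- report$stages
  summary <- list()
  if (isTRUE(s$control_design$ok)) {
    d <- s$control_design$design
    summary$control <- list(
      label = d$control_label,
      lc_choice = d$lc_choice, lc_identity_pct = d$lc_identity_pct,
      hc_choice = d$hc_choice, hc_identity_pct = d$hc_identity_pct
    )
  }
  if (isTRUE(s$diversity$ok)) {
    dd <- s$diversity$dedupe
    stopifnot(dd$uniqueness_pct == round(100 * dd$n_unique / s$diversity$n_cloned))
    summary$counts <- list(
      cloned = s$diversity$n_cloned,
      unique = dd$n_unique,
      uniqueness_pct = dd$uniqueness_pct
    )
  }
  if (isTRUE(s$screening$ok)) {
    summary$screening <- list(
      n = s$screening$summary$n,
      positivity_rate = s$screening$summary$positivity_rate,
      n_top = nrow(s$screening$top)
    )
  }
  if (isTRUE(s$kinetics$ok)) {
    kd <- s$kinetics$fits$kd_nM
    stopifnot(min(kd) <= max(kd))
    summary$affinity_nM <- c(min = min(kd), max = max(kd))
  }
  if (isTRUE(s$epitope_typing$ok)) {
    counts <- s$epitope_typing$summary$counts
    stopifnot(sum(counts) == nrow(s$epitope_typing$calls))
    summary$group_counts <- counts
    if (!is.null(s$epitope_typing$summary$kd_overall)) {
      summary$affinity_nM <- c(
        min = unname(s$epitope_typing$summary$kd_overall["min"]),
        max = unname(s$epitope_typing$summary$kd_overall["max"])
      )
    }
  }
  if (isTRUE(s$binning$ok)) {
    summary$n_bins <- length(s$binning$bins$bins)
  }
  if (isTRUE(s$selection$ok)) {
    pk <- s$selection$pk_pairs
    summary$pk_pairs <- pk[pk$suitable, c("capture_id", "detect_id"), drop = FALSE]
    summary$ada_top <- utils::head(s$selection$ada_ranking$clone_id, 2)
  }
  report$summary <- summary
  report
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(sprintf("<campaign_report> %s (seed %d)\n", x$project_id, x$seed))
  for (line in render_report(x)$markdown) cat(line, "\n")
  invisible(x)
}

#' Render a campaign report as deterministic tables
#'
#' @param report A `campaign_report`.
#' @return List with `markdown` (character lines), `campaign_row`
#'   (one-row data.frame in project-summary style: control families,
#'   integer identities, clone counts, uniqueness, affinity range) and
#'   `clone_table` (per-clone typing table when available, KD printed to 3
#'   decimals). Rendering the same report twice is byte-identical.
#' @export
render_report <- function(report) {
  s <- report$summary
  fmt_kd <- function(x) sprintf("%.3f", x)
  row <- data.frame(
    project = report$project_id,
    lc_control = s$control$lc_choice %||% NA_character_,
    lc_identity_pct = s$control$lc_identity_pct %||% NA_integer_,
    hc_control = s$control$hc_choice %||% NA_character_,
    hc_identity_pct = s$control$hc_identity_pct %||% NA_integer_,
    control_label = s$control$label %||% NA_character_,
    cloned = s$counts$cloned %||% NA_integer_,
    unique = s$counts$unique %||% NA_integer_,
    uniqueness_pct = s$counts$uniqueness_pct %||% NA_integer_,
    kd_min_nM = if (is.null(s$affinity_nM)) NA_character_ else fmt_kd(s$affinity_nM[["min"]]),
    kd_max_nM = if (is.null(s$affinity_nM)) NA_character_ else fmt_kd(s$affinity_nM[["max"]]),
    stringsAsFactors = FALSE
  )
  md <- c(
    sprintf("# Campaign %s", report$project_id),
    if (!is.null(s$control)) {
      sprintf(
        "- framework control: %s (LC %s %d%%, HC %s %d%%)",
        s$control$label, s$control$lc_choice, s$control$lc_identity_pct,
        s$control$hc_choice, s$control$hc_identity_pct
      )
    },
    if (!is.null(s$counts)) {
      sprintf(
        "- clones: %d cloned, %d unique (%d%%)",
        s$counts$cloned, s$counts$unique, s$counts$uniqueness_pct
      )
    },
    if (!is.null(s$screening)) {
      sprintf(
        "- screening: %d supernatants, positivity %.1f%%, %d top clones",
        s$screening$n, 100 * s$screening$positivity_rate, s$screening$n_top
      )
    },
    if (!is.null(s$affinity_nM)) {
      sprintf(
        "- affinity range: %s-%s nM",
        fmt_kd(s$affinity_nM[["min"]]), fmt_kd(s$affinity_nM[["max"]])
      )
    },
    if (!is.null(s$group_counts)) {
      sprintf(
        "- epitope groups: %d / %d / %d (groups 1/2/3)",
        s$group_counts[["group1"]], s$group_counts[["group2"]], s$group_counts[["group3"]]
      )
    },
    if (!is.null(s$n_bins)) sprintf("- epitope bins: %d", s$n_bins),
    if (!is.null(s$pk_pairs) && nrow(s$pk_pairs) > 0) {
      shown <- utils::head(paste(s$pk_pairs$capture_id, s$pk_pairs$detect_id, sep = "/"), 4)
      more <- nrow(s$pk_pairs) - length(shown)
      sprintf(
        "- suitable PK pairs (%d): %s%s",
        nrow(s$pk_pairs), paste(shown, collapse = ", "),
        if (more > 0) sprintf(" and %d more", more) else ""
      )
    },
    if (!is.null(s$ada_top) && length(s$ada_top) > 0) {
      sprintf("- top ADA controls: %s", paste(s$ada_top, collapse = ", "))
    }
  )
  clone_table <- NULL
  et <- report$stages$epitope_typing
  if (!is.null(et) && isTRUE(et$ok)) clone_table <- et$calls
  list(markdown = md, campaign_row = row, clone_table = clone_table)
}

write_campaign_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- report$stages
  r <- render_report(report)
  write.csv(r$campaign_row, file.path(outdir, "campaign_summary.csv"), row.names = FALSE)
  writeLines(r$markdown, file.path(outdir, "campaign_report.md"))
  if (isTRUE(s$control_design$ok)) {
    write_chain_fasta(
      list(s$control_design$design$grafted_vl, s$control_design$design$grafted_vh),
      file.path(outdir, "control_fab.fasta")
    )
  }
  if (isTRUE(s$diversity$ok)) {
    write.csv(s$diversity$distance, file.path(outdir, "cdr_distance_matrix.csv"))
    if (!is.null(s$diversity$tree)) {
      write_newick(s$diversity$tree, file.path(outdir, "unique_clones_nj.nwk"))
    }
    jsonlite::write_json(
      list(
        representatives = s$diversity$dedupe$representatives,
        n_unique = s$diversity$dedupe$n_unique,
        uniqueness_pct = s$diversity$dedupe$uniqueness_pct
      ),
      file.path(outdir, "dedupe_report.json"),
      auto_unbox = TRUE
    )
  }
  if (isTRUE(s$screening$ok)) {
    write.csv(s$screening$calls, file.path(outdir, "hit_calls.csv"), row.names = FALSE)
  }
  if (isTRUE(s$kinetics$ok)) {
    write.csv(s$kinetics$fits, file.path(outdir, "kinetic_fits.csv"), row.names = FALSE)
  }
  if (!is.null(r$clone_table)) {
    write.csv(r$clone_table, file.path(outdir, "epitope_calls.csv"), row.names = FALSE)
  }
  if (isTRUE(s$binning$ok)) {
    write.csv(s$binning$blocked, file.path(outdir, "blocked_matrix.csv"))
    write.csv(s$binning$network$edges, file.path(outdir, "competition_edges.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(s$binning$bins$bins, file.path(outdir, "bins.json"))
  }
  if (isTRUE(s$selection$ok)) {
    write.csv(s$selection$pk_pairs, file.path(outdir, "pk_pairs.csv"), row.names = FALSE)
    write.csv(s$selection$ada_ranking, file.path(outdir, "ada_ranking.csv"), row.names = FALSE)
  }
  invisible(outdir)
}
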