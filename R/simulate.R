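# Synthetic-data generators: every wet-lab input the pipeline consumes can
# be simulated with recorded ground truth, so each analysis stage has a
# recovery test and the whole campaign runs without instrument exports.
#
# Seeding: each generator takes an explicit integer seed and is bit-for-bit
# reproducible. A campaign-level seed fans out to per-stage substreams via
# substream_seed() so stages can be regenerated independently.

STREAM_OFFSETS <- c(
  germline = 101L, repertoire = 211L, sensorgrams = 307L,
  plates = 401L, epitopes = 503L, competition = 601L, titrations = 701L
)

#' Derive a per-stage substream seed
#'
#' Deterministic fan-out of one campaign seed into independent per-stage
#' seeds (kept below 2^31).
#'
#' @param seed Campaign seed (integer).
#' @param stream One of `names(STREAM_OFFSETS)`:
#'   germline, repertoire, sensorgrams, plates, epitopes, competition,
#'   titrations.
#' @return Integer seed.
#' @export
substream_seed <- function(seed, stream) {
  off <- STREAM_OFFSETS[[stream]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

mutate_residues <- function(residues, idx) {
  for (i in idx) {
    residues[i] <- sample(setdiff(AA_ALPHABET, residues[i]), 1)
  }
  residues
}

mutate_string <- function(s, n_mut = NULL, rate = NULL) {
  chars <- strsplit(s, "")[[1]]
  if (is.null(n_mut)) {
    idx <- which(runif(length(chars)) < rate)
  } else {
    idx <- sample(length(chars), min(n_mut, length(chars)))
  }
  paste(mutate_residues(chars, idx), collapse = "")
}

#' Simulate germline framework panels
#'
#' Builds `n_families` light- and heavy-chain families by mutating the
#' packaged base framework at family-specific positions, then adds
#' per-member noise. The recorded truth (each family's founder framework)
#' lets the framework-design stage be checked for consensus and
#' closest-family recovery.
#'
#' @param seed Integer seed.
#' @param n_families Families per chain type (default 4: K1..K4 / H1..H4).
#' @param members_per_family Members per family (default 5).
#' @param family_rate Per-position mutation rate separating family founders
#'   from the base framework (default 0.08).
#' @param member_rate Per-position mutation rate of members around their
#'   founder (default 0.02); a warning is issued at rates >= 0.5 (families
#'   may collide).
#' @return List with `lc_panels`, `hc_panels` (lists of `germline_panel`)
#'   and `truth` (founder framework vectors per family).
#' @export
simulate_germline_panel <- function(seed = 1, n_families = 4,
                                    members_per_family = 5,
                                    family_rate = 0.08, member_rate = 0.02) {
  if (member_rate >= 0.5 || family_rate >= 0.5) {
    warning("mutation rate >= 0.5: families may collide")
  }
  set.seed(seed)
  make_side <- function(chain_type, prefix) {
    template <- builtin_templates(chain_type)[[1]]
    fw <- framework_vector(template)
    cdrs <- extract_regions(template)$cdrs
    panels <- list()
    truth <- list()
    for (f in seq_len(n_families)) {
      founder <- fw
      idx <- which(runif(length(founder)) < family_rate)
      founder[idx] <- mutate_residues(unname(founder), idx)[idx]
      label <- paste0(prefix, f)
      truth[[label]] <- founder
      members <- lapply(seq_len(members_per_family), function(m) {
        mem <- founder
        midx <- which(runif(length(mem)) < member_rate)
        mem[midx] <- mutate_residues(unname(mem), midx)[midx]
        positions <- c(
          names(mem),
          cdrs$cdr1$positions, cdrs$cdr2$positions, cdrs$cdr3$positions
        )
        residues <- c(
          unname(mem),
          strsplit(cdrs$cdr1$sequence, "")[[1]],
          strsplit(cdrs$cdr2$sequence, "")[[1]],
          strsplit(cdrs$cdr3$sequence, "")[[1]]
        )
        numbered_chain(sprintf("%s_m%d", label, m), chain_type, positions, residues)
      })
      panels[[label]] <- germline_panel(label, members)
    }
    list(panels = panels, truth = truth)
  }
  lc <- make_side("kappa_light", "K")
  hc <- make_side("heavy", "H")
  list(
    lc_panels = lc$panels, hc_panels = hc$panels,
    truth = list(lc_founders = lc$truth, hc_founders = hc$truth)
  )
}

CDR_WIDTHS <- c(11L, 7L, 9L, 10L, 16L, 8L) # VL 1-3 then VH 1-3 (template spans)

split_concat <- function(concat) {
  stopifnot(nchar(concat) == sum(CDR_WIDTHS))
  ends <- cumsum(CDR_WIDTHS)
  starts <- c(1L, ends[-6] + 1L)
  vapply(1:6, function(i) substr(concat, starts[i], ends[i]), character(1))
}

clone_from_concat <- function(clone_id, concat) {
  parts <- split_concat(concat)
  build <- function(chain_type, cdr_seqs) {
    template <- builtin_templates(chain_type)[[1]]
    keep <- startsWith(template$regions, "FR")
    positions <- template$positions
    residues <- template$residues
    for (k in 1:3) {
      idx <- which(template$regions == paste0("CDR", k))
      residues[idx] <- strsplit(cdr_seqs[k], "")[[1]]
    }
    numbered_chain(
      paste0(clone_id, if (chain_type == "kappa_light") "_VL" else "_VH"),
      chain_type, positions, residues
    )
  }
  clone_record(clone_id, build("kappa_light", parts[1:3]), build("heavy", parts[4:6]))
}

#' Simulate a clonal repertoire of anti-ID candidates
#'
#' Generates `n_lineages` founder CDR-concatenation strings far apart in
#' percent difference (inter-lineage) and expands some lineages with close
#' variants (at most `intra_max_mut` substitutions from the founder, which
#' keeps the alignment-based difference under the 10% uniqueness rule),
#' mirroring affinity-matured variants of common ancestral clones. The
#' lineage labels are the recorded truth: deduplication at the default
#' threshold must recover exactly the planted lineage count.
#'
#' @param seed Integer seed.
#' @param n_lineages Planted lineages (default 24).
#' @param n_clones Total clones (default 34); the first
#'   `n_clones - n_lineages` lineages contribute one extra variant each.
#' @param inter_rate Per-position mutation rate of founders from the base
#'   CDR string (default 0.3).
#' @param intra_max_mut Maximum substitutions of a variant from its founder
#'   (default 3).
#' @param min_founder_diff_pct Minimum accepted pairwise founder difference
#'   (default 18); founders are resampled until satisfied.
#' @return List with `clones` (list of `clone_record`) and `truth`
#'   (`lineage` label per clone id, `founders` strings).
#' @export
simulate_clone_repertoire <- function(seed = 1, n_lineages = 24, n_clones = 34,
                                      inter_rate = 0.3, intra_max_mut = 3,
                                      min_founder_diff_pct = 18) {
  if (n_clones < n_lineages) stop("n_clones must be >= n_lineages")
  n_extra <- n_clones - n_lineages
  if (n_extra > n_lineages) stop("at most one extra variant per lineage supported")
  set.seed(seed)
  base <- {
    vk <- extract_regions(builtin_templates("kappa_light")[[1]])$cdrs
    vh <- extract_regions(builtin_templates("heavy")[[1]])$cdrs
    paste0(
      vk$cdr1$sequence, vk$cdr2$sequence, vk$cdr3$sequence,
      vh$cdr1$sequence, vh$cdr2$sequence, vh$cdr3$sequence
    )
  }
  founders <- character(0)
  tries <- 0
  while (length(founders) < n_lineages) {
    cand <- mutate_string(base, rate = inter_rate)
    ok <- all(vapply(
      founders,
      function(f) pairwise_cdr_difference(cand, f) > min_founder_diff_pct,
      logical(1)
    ))
    if (ok) founders <- c(founders, cand)
    tries <- tries + 1
    if (tries > 200 * n_lineages) {
      stop("could not place founders at the requested separation; ",
           "lower min_founder_diff_pct or n_lineages")
    }
  }
  clones <- list()
  lineage <- character(0)
  idx <- 0L
  for (l in seq_len(n_lineages)) {
    idx <- idx + 1L
    id <- sprintf("clone_%02d", idx)
    clones[[id]] <- clone_from_concat(id, founders[l])
    lineage[id] <- paste0("lineage_", l)
    if (l <= n_extra) {
      idx <- idx + 1L
      id <- sprintf("clone_%02d", idx)
      k <- sample(intra_max_mut, 1)
      clones[[id]] <- clone_from_concat(id, mutate_string(founders[l], n_mut = k))
      lineage[id] <- paste0("lineage_", l)
    }
  }
  list(
    clones = unname(clones),
    truth = list(lineage = lineage, founders = founders)
  )
}

#' Simulate 1:1 Langmuir sensorgram sets
#'
#' Closed-form 1:1 binding curves over a serial-dilution concentration
#' series with additive i.i.d. Gaussian noise; the generating (kon, koff,
#' rmax) per clone is the recorded truth for parameter-recovery tests.
#'
#' @param seed Integer seed.
#' @param n_clones Clones to simulate (default 4).
#' @param kon_range,koff_range Log-uniform sampling ranges (defaults
#'   `[1e5, 1e7]` 1/(M*s), `[1e-5, 1e-2]` 1/s).
#' @param rmax Maximal response (default 100 RU).
#' @param concentrations_nM Analyte series (default five-fold dilutions
#'   100 nM down to 0.032 nM).
#' @param assoc_duration,diss_duration Phase lengths in seconds (defaults
#'   180 and 420).
#' @param dt Sampling interval (default 3 s).
#' @param noise_sd Gaussian noise sd in RU (default 0).
#' @return List with `sensorgrams` (data.frame `clone_id`, `conc_M`,
#'   `phase`, `time_s`, `ru`) and `truth` (per-clone kon/koff/rmax/kd).
#' @export
simulate_sensorgrams <- function(seed = 1, n_clones = 4,
                                 kon_range = c(1e5, 1e7),
                                 koff_range = c(1e-5, 1e-2),
                                 rmax = 100,
                                 concentrations_nM = 100 / 5^(0:5),
                                 assoc_duration = 180, diss_duration = 420,
                                 dt = 3, noise_sd = 0) {
  set.seed(seed)
  truth <- data.frame(
    clone_id = sprintf("clone_%02d", seq_len(n_clones)),
    kon = 10^runif(n_clones, log10(kon_range[1]), log10(kon_range[2])),
    koff = 10^runif(n_clones, log10(koff_range[1]), log10(koff_range[2])),
    rmax = rmax,
    stringsAsFactors = FALSE
  )
  truth$kd <- truth$koff / truth$kon
  t_assoc <- seq(0, assoc_duration, by = dt)
  t_diss <- seq(0, diss_duration, by = dt)
  rows <- list()
  for (i in seq_len(n_clones)) {
    for (conc in concentrations_nM * 1e-9) {
      ra <- langmuir_response(
        t_assoc, truth$kon[i], truth$koff[i], truth$rmax[i], conc, "association"
      )
      rd <- langmuir_response(
        t_diss, truth$kon[i], truth$koff[i], truth$rmax[i], conc,
        "dissociation", assoc_duration = assoc_duration
      )
      rows[[length(rows) + 1]] <- data.frame(
        clone_id = truth$clone_id[i], conc_M = conc,
        phase = rep(c("association", "dissociation"), c(length(t_assoc), length(t_diss))),
        time_s = c(t_assoc, t_diss),
        ru = c(ra, rd) + rnorm(length(ra) + length(rd), 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }
  }
  list(sensorgrams = do.call(rbind, rows), truth = truth)
}

largest_remainder_counts <- function(n, proportions) {
  raw <- n * proportions / sum(proportions)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate epitope-typing assay records
#'
#' Plants a reagent group per clone and generates the SPR summary responses
#' consistent with it: blocking clones gain no response after the antigen
#' injection; complex-specific clones show a large complex/Fab-only Rmax
#' ratio. Multiplicative Gaussian noise perturbs every response.
#'
#' @param seed Integer seed.
#' @param n Clones (default 24).
#' @param proportions Group 1/2/3 proportions (default `c(5, 14, 5)/24`),
#'   realized exactly by largest-remainder rounding; must sum to 1 (up to
#'   scaling).
#' @param noise_frac Relative response noise (default 0; e.g. 0.02 = 2%).
#' @param fab_response Baseline drug-Fab response (default 100 RU).
#' @param mw_ag,mw_fab Molecular weights in kDa (defaults 50, 50).
#' @return List with `records` (data.frame of assay fields) and `truth`
#'   (planted group per clone).
#' @export
simulate_epitope_assays <- function(seed = 1, n = 24,
                                    proportions = c(5, 14, 5) / 24,
                                    noise_frac = 0,
                                    fab_response = 100, mw_ag = 50, mw_fab = 50) {
  set.seed(seed)
  counts <- largest_remainder_counts(n, proportions)
  group <- rep(1:3, counts)
  noisy <- function(x) x * (1 + rnorm(length(x), 0, noise_frac))
  blocking <- group == 3
  complex_specific <- group == 1
  # margins: blocking clones sit 5 RU below the Fab baseline after the Ag
  # injection; non-blocking gain 40 RU; complex ratio 60% vs 2%
  post_ag <- ifelse(blocking, fab_response - 5, fab_response + 40)
  fab_only <- rep(100, n)
  complex_rmax <- ifelse(complex_specific, 60, 2)
  records <- data.frame(
    clone_id = sprintf("clone_%02d", seq_len(n)),
    fab_response = noisy(rep(fab_response, n)),
    post_ag_response = noisy(post_ag),
    mw_ag = mw_ag, mw_fab = mw_fab, fab_stoichiometry = 1,
    complex_rmax = noisy(complex_rmax),
    fab_only_rmax = noisy(fab_only),
    stringsAsFactors = FALSE
  )
  list(
    records = records,
    truth = setNames(group, records$clone_id)
  )
}

#' Simulate a primary ELISA screening plate
#'
#' Draws hits, negatives and framework-reactive (excluded) supernatants
#' with non-overlapping OD distributions around the calling thresholds, so
#' the hit caller recovers the planted labels exactly.
#'
#' @param seed Integer seed.
#' @param n_clones Supernatants (default 2000).
#' @param hit_fraction Fraction of hits (default 0.45).
#' @param excluded_fraction Fraction of framework-reactive supernatants
#'   (default 0.05).
#' @return List with `plate` (long data.frame `sample_id`, `antigen`, `od`)
#'   and `truth` (planted status per sample).
#' @export
simulate_plates <- function(seed = 1, n_clones = 2000, hit_fraction = 0.45,
                            excluded_fraction = 0.05) {
  stopifnot(hit_fraction >= 0, hit_fraction <= 1,
            hit_fraction + excluded_fraction <= 1)
  set.seed(seed)
  status <- sample(c(
    rep("hit", round(n_clones * hit_fraction)),
    rep("excluded", round(n_clones * excluded_fraction)),
    rep("negative", n_clones - round(n_clones * hit_fraction) -
      round(n_clones * excluded_fraction))
  ))
  ids <- sprintf("S%04d", seq_len(n_clones))
  od_ab1 <- ifelse(status == "hit", runif(n_clones, 0.5, 3.5),
    ifelse(status == "excluded", runif(n_clones, 0.3, 2.0),
      runif(n_clones, 0, 0.2)
    )
  )
  od_ctrl <- ifelse(status == "excluded", runif(n_clones, 0.15, 1.0),
    runif(n_clones, 0, 0.08)
  )
  plate <- rbind(
    data.frame(sample_id = ids, antigen = "Ab1_Fab", od = od_ab1),
    data.frame(sample_id = ids, antigen = "Ab1ctrl_Fab", od = od_ctrl)
  )
  list(plate = plate, truth = setNames(status, ids))
}

intervals_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Simulate a pairwise competition matrix from latent epitopes
#'
#' Each clone occupies a latent 1-D epitope interval on \[0, 1\]; two clones
#' compete (low secondary response) iff their intervals overlap. Clones
#' sharing an identical interval form the planted bins. An optional
#' bridging clone spans the first two sites.
#'
#' @param seed Integer seed.
#' @param bin_sizes Clones per latent site (default `c(3, 3, 3)`).
#' @param width Interval width (default 0.12; sites are evenly spaced and
#'   disjoint for defaults).
#' @param bridge Add one clone spanning sites 1 and 2 (default `FALSE`).
#' @param expected Expected uncompeted response per clone (default 200 RU).
#' @param competed_frac Fractional response when competed (default 0.02).
#' @param noise_sd Additive RU noise (default 0).
#' @return List with `raw` (response matrix), `expected` (named vector),
#'   `truth` (`intervals` per clone, `bins` planted partition).
#' @export
simulate_competition <- function(seed = 1, bin_sizes = c(3, 3, 3), width = 0.12,
                                 bridge = FALSE, expected = 200,
                                 competed_frac = 0.02, noise_sd = 0) {
  set.seed(seed)
  n_sites <- length(bin_sizes)
  centers <- (seq_len(n_sites) - 0.5) / n_sites
  sites <- lapply(centers, function(c) c(c - width / 2, c + width / 2))
  intervals <- list()
  bin_truth <- character(0)
  for (s in seq_len(n_sites)) {
    for (k in seq_len(bin_sizes[s])) {
      id <- sprintf("clone_%02d", length(intervals) + 1L)
      intervals[[id]] <- sites[[s]]
      bin_truth[id] <- paste0("site_", s)
    }
  }
  if (bridge) {
    id <- sprintf("clone_%02d", length(intervals) + 1L)
    intervals[[id]] <- c(sites[[1]][1], sites[[2]][2])
    bin_truth[id] <- "bridge"
  }
  ids <- names(intervals)
  n <- length(ids)
  exp_vec <- setNames(rep(expected, n), ids)
  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      compete <- intervals_overlap(intervals[[i]], intervals[[j]])
      raw[i, j] <- exp_vec[j] * (if (compete) competed_frac else 1)
    }
  }
  raw <- raw + matrix(rnorm(n * n, 0, noise_sd), n, n)
  list(
    raw = raw, expected = exp_vec,
    truth = list(intervals = intervals, bins = bin_truth)
  )
}

saturating_od <- function(conc, top = 2, ec50 = 2, background = 0.05) {
  background + top * conc / (conc + ec50)
}

#' Simulate PK pair titration curves
#'
#' For every ordered capture/detect pair, sandwich-compatible pairs (no
#' competition in either direction) produce a saturating dose-response
#' curve; competing pairs stay at background. Used to exercise
#' [select_pk_pairs()].
#'
#' @param blocked Logical competition matrix (ids as dimnames).
#' @param seed Integer seed.
#' @param conc Analyte series in ng/mL (default two-fold 20 down to 0.3125
#'   plus a 0 blank).
#' @param noise_sd Additive OD noise (default 0).
#' @return data.frame `capture_id`, `detect_id`, `conc`, `od`.
#' @export
simulate_pk_curves <- function(blocked, seed = 1,
                               conc = c(20 / 2^(0:6), 0), noise_sd = 0) {
  set.seed(seed)
  ids <- rownames(blocked)
  rows <- list()
  for (cap in ids) {
    for (det in setdiff(ids, cap)) {
      works <- !blocked[cap, det] && !blocked[det, cap]
      od <- if (works) saturating_od(conc) else rep(0.05, length(conc))
      od <- pmax(od + rnorm(length(conc), 0, noise_sd), 0)
      rows[[length(rows) + 1]] <- data.frame(
        capture_id = cap, detect_id = det, conc = conc, od = od,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate ADA bridging titration curves
#'
#' Planted good clones bridge the labelled drug reagents and titrate with a
#' strong saturating curve; the rest stay near background.
#'
#' @param clone_ids Clones to titrate.
#' @param good_clones Subset with strong bridging signal.
#' @param seed Integer seed.
#' @param conc Series in ng/mL (default two-fold 1000 down to 7.8125 plus a
#'   0 blank).
#' @param noise_sd Additive OD noise (default 0).
#' @return data.frame `clone_id`, `conc`, `od`.
#' @export
simulate_ada_curves <- function(clone_ids, good_clones, seed = 1,
                                conc = c(1000 / 2^(0:7), 0), noise_sd = 0) {
  set.seed(seed)
  rows <- lapply(clone_ids, function(id) {
    od <- if (id %in% good_clones) {
      saturating_od(conc, top = 2.5, ec50 = 100)
    } else {
      saturating_od(conc, top = 0.15, ec50 = 100)
    }
    od <- pmax(od + rnorm(length(conc), 0, noise_sd), 0)
    data.frame(clone_id = id, conc = conc, od = od, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
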