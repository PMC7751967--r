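# Template-based chain numbering.
#
# Numbering is implemented as global alignment against packaged pre-numbered
# template chains rather than a rule-based engine: the query inherits the
# template position of every aligned template residue, insertions relative to
# the template receive lettered positions (100A, 100B, ...) and template
# positions deleted in the query are simply absent. This is behaviourally
# equivalent to scheme numbering for variable domains of ordinary geometry
# and is directly testable against hand-aligned fixtures.

# Synthetic consensus-like variable-domain templates (kappa light and heavy),
# written for this package; they are NOT germline database entries. Positions
# run 1..N with the default boundary table's CDR spans.
TEMPLATE_VK <- paste0(
  "DIQMTQSPSSLSASVGDRVTITC", # FR1   1-23
  "RASQSISSYLN",             # CDR1 24-34
  "WYQQKPGKAPKLLIY",         # FR2  35-49
  "AASSLQS",                 # CDR2 50-56
  "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", # FR3 57-88
  "QQSYSTPLT",               # CDR3 89-97
  "FGQGTKVEIK"               # FR4  98-107
)
TEMPLATE_VH <- paste0(
  "EVQLLESGGGLVQPGGSLRLSCAAS", # FR1   1-25
  "GFTFSSYAMS",               # CDR1 26-35
  "WVRQAPGKGLEWVS",           # FR2  36-49
  "AISGSGGSTYYADSVK",         # CDR2 50-65
  "RFTISRDNSKNTLYLQMNSLRAEDTAVYY", # FR3 66-94
  "DGGYYFDY",                 # CDR3 95-102
  "WGQGTLVTVSS"               # FR4 103-113
)

#' Packaged numbering templates
#'
#' Returns the built-in pre-numbered template chains for a chain type. The
#' templates are synthetic human-consensus-like sequences bundled with the
#' package (no germline database entries are shipped); user-supplied
#' templates, e.g. numbered germline panels, can be passed to
#' [number_chain()] instead.
#'
#' @param chain_type `"kappa_light"` or `"heavy"`.
#' @param boundary_table CDR boundary table.
#' @return List of `numbered_chain` templates.
#' @export
builtin_templates <- function(chain_type,
                              boundary_table = default_boundary_table()) {
  chain_type <- match.arg(chain_type, c("kappa_light", "heavy"))
  seq <- if (chain_type == "kappa_light") TEMPLATE_VK else TEMPLATE_VH
  res <- strsplit(seq, "")[[1]]
  list(numbered_chain(
    chain_id = paste0("template_", chain_type),
    chain_type = chain_type,
    positions = as.character(seq_along(res)),
    residues = res,
    boundary_table = boundary_table
  ))
}

align_global <- function(query, template, gap_opening = 10, gap_extension = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = template,
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global"
  )
  list(
    score = Biostrings::score(aln),
    pattern = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
    subject = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  )
}

#' Number an antibody variable-domain sequence
#'
#' Assigns a scheme position and a region label (FR1..FR4, CDR1..CDR3) to
#' every residue by global alignment against a set of pre-numbered template
#' chains; the best-scoring template is used. Residues inserted relative to
#' the template receive lettered positions appended to the preceding
#' position (e.g. `100A`, `100B`).
#'
#' @param sequence Protein string (1-letter codes), length 90-140.
#' @param chain_type `"kappa_light"` or `"heavy"`.
#' @param templates List of pre-numbered `numbered_chain` templates; defaults
#'   to the packaged template for `chain_type`.
#' @param chain_id Identifier for the output chain.
#' @param boundary_table CDR boundary table.
#' @param min_coverage Minimum fraction of template framework positions the
#'   query must align to (default 0.7); below it numbering fails.
#' @return A `numbered_chain`.
#' @export
number_chain <- function(sequence, chain_type,
                         templates = builtin_templates(chain_type, boundary_table),
                         chain_id = "query",
                         boundary_table = default_boundary_table(),
                         min_coverage = 0.7) {
  chain_type <- match.arg(chain_type, c("kappa_light", "heavy"))
  if (nchar(sequence) < 90 || nchar(sequence) > 140) {
    stop("sequence length must be 90-140 residues, got ", nchar(sequence))
  }
  aa_check(sequence, "query sequence")
  if (length(templates) == 0) stop("template set is empty")
  wrong <- vapply(templates, function(t) t$chain_type != chain_type, logical(1))
  if (any(wrong)) stop("template chain types do not all match ", chain_type)

  alns <- lapply(templates, function(t) align_global(sequence, chain_sequence(t)))
  best <- which.max(vapply(alns, `[[`, numeric(1), "score"))
  template <- templates[[best]]
  aln <- alns[[best]]

  positions <- character(0)
  residues <- character(0)
  ti <- 0L          # index into template residues
  prev_label <- "0" # last assigned/seen template position
  ins <- 0L
  for (k in seq_along(aln$pattern)) {
    q <- aln$pattern[k]
    s <- aln$subject[k]
    if (s != "-") {
      ti <- ti + 1L
      prev_label <- template$positions[ti]
      ins <- 0L
      if (q != "-") {
        positions <- c(positions, prev_label)
        residues <- c(residues, q)
      }
    } else if (q != "-") {
      ins <- ins + 1L
      if (ins > 26L) stop("more than 26 consecutive insertions; not a variable domain?")
      positions <- c(positions, paste0(prev_label, LETTERS[ins]))
      residues <- c(residues, q)
    }
  }

  fw_template <- template$positions[startsWith(template$regions, "FR")]
  covered <- mean(fw_template %in% positions)
  if (covered < min_coverage) {
    stop(sprintf(
      "numbering failure: query aligns to %.0f%% of template framework positions (< %.0f%%)",
      100 * covered, 100 * min_coverage
    ))
  }
  numbered_chain(chain_id, chain_type, positions, residues, boundary_table)
}

#' Split a numbered chain into framework and CDR regions
#'
#' @param chain A `numbered_chain`.
#' @return A list with `framework` (concatenated FR1-FR4 string), `cdrs`
#'   (class `cdr_set`: per-CDR sequence and positions), `by_region` (named
#'   list of all seven region strings in order) and `chain_type`.
#'   Concatenating the regions in FR1,CDR1,...,FR4 order reproduces the
#'   input sequence exactly.
#' @export
extract_regions <- function(chain) {
  stopifnot(inherits(chain, "numbered_chain"))
  if (any(is.na(chain$regions)) || any(chain$regions == "")) {
    stop("internal consistency error: residue without a region label")
  }
  by_region <- lapply(setNames(REGION_ORDER, REGION_ORDER), function(r) {
    idx <- chain$regions == r
    list(
      sequence = paste(chain$residues[idx], collapse = ""),
      positions = chain$positions[idx]
    )
  })
  for (r in c("CDR1", "CDR2", "CDR3")) {
    if (nchar(by_region[[r]]$sequence) == 0) {
      stop("empty ", r, " in chain ", chain$chain_id)
    }
  }
  cdrs <- structure(
    list(
      chain_type = chain$chain_type,
      cdr1 = by_region$CDR1, cdr2 = by_region$CDR2, cdr3 = by_region$CDR3
    ),
    class = "cdr_set"
  )
  framework <- paste(
    vapply(by_region[c("FR1", "FR2", "FR3", "FR4")], `[[`, character(1), "sequence"),
    collapse = ""
  )
  list(
    framework = framework,
    cdrs = cdrs,
    by_region = lapply(by_region, `[[`, "sequence"),
    chain_type = chain$chain_type
  )
}

#' @export
print.cdr_set <- function(x, ...) {
  cat(sprintf(
    "<cdr_set> %s: CDR1=%s CDR2=%s CDR3=%s\n",
    x$chain_type, x$cdr1$sequence, x$cdr2$sequence, x$cdr3$sequence
  ))
  invisible(x)
}
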