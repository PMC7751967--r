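make_member <- function(id, residues, chain_type = "kappa_light") {
  tpl <- builtin_templates(chain_type)[[1]]
  numbered_chain(id, chain_type, tpl$positions, residues)
}

consensus_residue <- function(cons, position) {
  setNames(cons$residues, cons$positions)[position]
}

consensus_vector_public <- function(cons) setNames(cons$residues, cons$positions)

graft_chain_public <- function(cdrs, cons) {
  idiokit:::graft_chain(cdrs, cons, "regraft")
}

test_that("consensus of a single-member panel equals that member's framework", {
  tpl <- builtin_templates("kappa_light")[[1]]
  cons <- build_consensus_framework(germline_panel("K1", list(tpl)))
  expect_identical(
    setNames(cons$residues, cons$positions),
    framework_vector(tpl)
  )
})

test_that("consensus takes the majority residue and breaks ties alphabetically", {
  tpl <- builtin_templates("kappa_light")[[1]]
  fw_idx <- which(startsWith(tpl$regions, "FR"))[5]
  res_a <- tpl$residues
  res_s <- tpl$residues
  res_a[fw_idx] <- "A"
  res_s[fw_idx] <- "S"
  pos <- tpl$positions[fw_idx]
  # majority {A, A, S} -> A
  maj <- build_consensus_framework(germline_panel("K1", list(
    make_member("m1", res_a), make_member("m2", res_a), make_member("m3", res_s)
  )))
  expect_identical(unname(consensus_residue(maj, pos)), "A")
  # 2-2 tie {A, A, S, S} -> alphabetically smaller (A)
  tie <- build_consensus_framework(germline_panel("K1", list(
    make_member("m1", res_a), make_member("m2", res_a),
    make_member("m3", res_s), make_member("m4", res_s)
  )))
  expect_identical(unname(consensus_residue(tie, pos)), "A")
})

test_that("positions absent from more than half of the members are dropped", {
  tpl <- builtin_templates("kappa_light")[[1]]
  full <- tpl
  drop_idx <- which(startsWith(tpl$regions, "FR"))[3]
  pos_dropped <- tpl$positions[drop_idx]
  partial <- numbered_chain(
    "p", "kappa_light", tpl$positions[-drop_idx], tpl$residues[-drop_idx]
  )
  cons <- build_consensus_framework(
    germline_panel("K1", list(partial, partial, full))
  )
  expect_false(pos_dropped %in% cons$positions)
  # present in half the members: kept
  cons2 <- build_consensus_framework(germline_panel("K1", list(partial, full)))
  expect_true(pos_dropped %in% cons2$positions)
})

test_that("consensus of N copies of one sequence equals that sequence for all N", {
  tpl <- builtin_templates("heavy")[[1]]
  for (n in c(1, 2, 5)) {
    cons <- build_consensus_framework(
      germline_panel("H1", rep(list(tpl), n))
    )
    expect_identical(setNames(cons$residues, cons$positions), framework_vector(tpl))
  }
})

test_that("percent identity counts matches over the position union", {
  a <- setNames(rep("A", 100), as.character(1:100))
  expect_equal(percent_identity(a, a), 100)
  b <- a
  b[c("10", "20")] <- "G"
  expect_equal(percent_identity(a, b), 98) # 98 of 100 shared, no indels
  # an indel counts against the union denominator
  c_ <- a[as.character(1:99)]
  expect_equal(percent_identity(a, c_), 99)
  expect_error(
    percent_identity(a, setNames("A", "200")),
    "no shared scheme positions"
  )
})

test_that("percent identity is symmetric, bounded and 100 iff identical on shared positions", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(20:80, 1)
    a <- setNames(sample(c("A", "G", "S", "T"), n, replace = TRUE), as.character(1:n))
    b <- a
    nm <- sample(n, sample(0:n, 1))
    for (i in nm) b[i] <- sample(setdiff(c("A", "G", "S", "T", "W"), b[i]), 1)
    expect_equal(percent_identity(a, b), percent_identity(b, a))
    expect_gte(percent_identity(a, b), 0)
    expect_lte(percent_identity(a, b), 100)
    expect_equal(percent_identity(a, b) == 100, all(a == b))
  }
})

mutated_consensus <- function(cons, n_mut, label = cons$family_label) {
  res <- cons$residues
  idx <- seq_len(n_mut)
  res[idx] <- vapply(res[idx], function(r) if (r == "G") "A" else "G", character(1))
  structure(
    list(
      family_label = label, chain_type = cons$chain_type,
      positions = cons$positions, residues = res,
      per_position_frequencies = list()
    ),
    class = "consensus_framework"
  )
}

test_that("closest-control selection finds a planted optimum and ranks by identity", {
  sim <- simulate_germline_panel(seed = 11)
  lc <- lapply(sim$lc_panels, build_consensus_framework)
  hc <- lapply(sim$hc_panels, build_consensus_framework)

  # Ab1 framework = exact copy of K2 / H4 consensus => identities 100/100
  ab1_vl <- graft_cdrs(
    list(
      vl = extract_regions(builtin_templates("kappa_light")[[1]])$cdrs,
      vh = extract_regions(builtin_templates("heavy")[[1]])$cdrs
    ),
    lc$K2, hc$H4
  )
  design <- select_closest_control(ab1_vl$vl, ab1_vl$vh, unname(lc), unname(hc))
  expect_identical(design$control_label, "K2H4")
  expect_equal(design$lc_identity_pct, 100)
  expect_equal(design$hc_identity_pct, 100)

  # planted graded identities: fewer mutations => closer family
  lc_graded <- list(
    mutated_consensus(lc$K1, 2), mutated_consensus(lc$K2, 7),
    mutated_consensus(lc$K3, 10), mutated_consensus(lc$K4, 12)
  )
  hc_graded <- list(
    mutated_consensus(hc$H1, 8), mutated_consensus(hc$H2, 10),
    mutated_consensus(hc$H3, 3), mutated_consensus(hc$H4, 9)
  )
  design2 <- select_closest_control(ab1_vl$vl, ab1_vl$vh, lc_graded, hc_graded)
  # exhaustive oracle: argmax over all panels
  lc_ids <- vapply(lc_graded, function(p) percent_identity(ab1_vl$vl, p), numeric(1))
  hc_ids <- vapply(hc_graded, function(p) percent_identity(ab1_vl$vh, p), numeric(1))
  expect_identical(design2$lc_choice, lc_graded[[which.max(lc_ids)]]$family_label)
  expect_identical(design2$hc_choice, hc_graded[[which.max(hc_ids)]]$family_label)

  # permutation of panel order leaves the choice unchanged (identities differ)
  perm <- c(3, 1, 4, 2)
  design3 <- select_closest_control(ab1_vl$vl, ab1_vl$vh, lc_graded[perm], hc_graded[perm])
  expect_identical(design3$control_label, design2$control_label)
})

test_that("grafting round-trips donor CDRs and acceptor framework verbatim", {
  sim <- simulate_germline_panel(seed = 5)
  lc <- build_consensus_framework(sim$lc_panels$K3)
  hc <- build_consensus_framework(sim$hc_panels$H2)
  donor <- list(
    vl = extract_regions(toy_kappa_chain("donor", cdr3 = "QQWDSSPPT"))$cdrs,
    vh = extract_regions(toy_heavy_chain("donor_vh", cdr3 = "ARWFDYWG"))$cdrs
  )
  grafted <- graft_cdrs(donor, lc, hc)
  er_vl <- extract_regions(grafted$vl)
  er_vh <- extract_regions(grafted$vh)
  expect_identical(er_vl$cdrs$cdr3$sequence, "QQWDSSPPT")
  expect_identical(er_vh$cdrs$cdr3$sequence, "ARWFDYWG")
  expect_identical(framework_vector(grafted$vl), consensus_vector_public(lc))
  expect_identical(framework_vector(grafted$vh), consensus_vector_public(hc))
})

test_that("grafting the acceptor's own CDRs reconstructs the parent exactly", {
  tpl <- builtin_templates("kappa_light")[[1]]
  cons <- build_consensus_framework(germline_panel("K1", list(tpl)))
  donor_cdrs <- extract_regions(tpl)$cdrs
  g <- graft_chain_public(donor_cdrs, cons)
  expect_identical(chain_sequence(g), chain_sequence(tpl))
})

test_that("a longer donor CDR lengthens the graft by exactly the extra residues", {
  tpl <- builtin_templates("heavy")[[1]]
  cons <- build_consensus_framework(germline_panel("H1", list(tpl)))
  long_cdr3 <- list(
    sequence = "DGGYYFDYWF",
    positions = c(as.character(95:102), "102A", "102B")
  )
  cdrs <- extract_regions(tpl)$cdrs
  cdrs$cdr3 <- long_cdr3
  g <- graft_chain_public(cdrs, cons)
  expect_equal(
    nchar(chain_sequence(g)),
    length(cons$positions) + nchar(cdrs$cdr1$sequence) +
      nchar(cdrs$cdr2$sequence) + nchar(long_cdr3$sequence)
  )
})

test_that("4 LC x 4 HC acceptors yield 16 distinct control designs", {
  sim <- simulate_germline_panel(seed = 23)
  lc <- lapply(sim$lc_panels, build_consensus_framework)
  hc <- lapply(sim$hc_panels, build_consensus_framework)
  donor <- list(
    vl = extract_regions(builtin_templates("kappa_light")[[1]])$cdrs,
    vh = extract_regions(builtin_templates("heavy")[[1]])$cdrs
  )
  designs <- character(0)
  for (l in names(lc)) {
    for (h in names(hc)) {
      g <- graft_cdrs(donor, lc[[l]], hc[[h]], label = paste0(l, h))
      designs <- c(designs, paste(chain_sequence(g$vl), chain_sequence(g$vh)))
    }
  }
  expect_length(designs, 16)
  expect_length(unique(designs), 16)
})

test_that("chain-type mismatch in grafting is an input error", {
  tplk <- builtin_templates("kappa_light")[[1]]
  tplh <- builtin_templates("heavy")[[1]]
  consh <- build_consensus_framework(germline_panel("H1", list(tplh)))
  expect_error(
    graft_chain_public(extract_regions(tplk)$cdrs, consh),
    "kappa_light.*heavy|heavy.*kappa_light"
  )
})

test_that("FASTA round trip preserves sequences", {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  chains <- list(builtin_templates("kappa_light")[[1]], builtin_templates("heavy")[[1]])
  write_chain_fasta(chains, tmp)
  back <- read_chain_fasta(tmp)
  expect_identical(
    unname(back),
    vapply(chains, chain_sequence, character(1))
  )
})
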