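random_helix <- function(n, letters = names(fauchere_pliska())) {
  helix_sequence(paste(sample(letters, n, replace = TRUE),
                       collapse = ""))
}

test_that("turn partition tiles the sequence under the 3.6-residue rule", {
  tp <- partition_turns(alps_native())
  expect_equal(nrow(tp), 11)
  expect_equal(c(tp$start[1], tp$end[1]), c(1, 3))
  expect_equal(c(tp$start[11], tp$end[11]), c(37, 38))
  expect_equal(nrow(partition_turns(helix_sequence("ASD"))), 1)
  tp36 <- partition_turns(random_helix(36))
  expect_equal(nrow(tp36), 10)
  expect_equal(c(tp36$start[10], tp36$end[10]), c(33, 36))
  # tiling: every position covered exactly once, all lengths 1..100
  for (n in c(1:15, 36:40, 100)) {
    tp <- partition_turns(random_helix(n))
    covered <- unlist(mapply(seq, tp$start, tp$end, SIMPLIFY = FALSE))
    expect_identical(sort(covered), 1:n)
  }
})

test_that("single-hydrophobic turn statistic separates sparse helices", {
  expect_equal(count_single_hydrophobic_turns(alps_native()), 9)
  expect_equal(count_single_hydrophobic_turns(helix_sequence("SSSSSS")), 0)
  expect_equal(count_single_hydrophobic_turns(helix_sequence("LLSS")), 0)
})

test_that("hydrophobic moment follows the phasor sum and vanishes for
          uniform full-wheel sequences", {
  expect_equal(hydrophobic_moment(
    helix_sequence(strrep("L", 18)))$mu_h, 0, tolerance = 1e-12)
  expect_equal(hydrophobic_moment(
    helix_sequence(strrep("L", 36)))$mu_h, 0, tolerance = 1e-12)
  # independent trig-sum oracle on an arbitrary sequence
  s <- helix_sequence("WLSSGLQNVTKDMLAFIP")
  h <- unname(fauchere_pliska()[s$residues])
  ang <- (seq_along(h) - 1) * 100 * pi / 180
  oracle <- sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
  expect_equal(hydrophobic_moment(s)$mu_h, oracle, tolerance = 1e-12)
  expect_error(hydrophobic_moment(helix_sequence("A")), "length")
  expect_error(helix_sequence("ABZ"), "nonstandard")
})

test_that("inversion preserves muH and <H> to machine precision", {
  set.seed(77)
  for (i in 1:50) {
    s <- random_helix(sample(5:60, 1))
    w <- hydrophobic_moment(s)
    wi <- hydrophobic_moment(invert(s))
    expect_equal(wi$mu_h, w$mu_h, tolerance = 1e-12)
    expect_equal(wi$mean_h, w$mean_h, tolerance = 1e-12)
  }
  s <- alps_peptide()
  expect_identical(invert(invert(s))$residues, s$residues)
  expect_identical(invert(s)$residues[1],
                   s$residues[length(s$residues)])
  expect_identical(sort(invert(s)$residues), sort(s$residues))
})

test_that("spacing classifier separates sparse and paired patterns", {
  sp <- spacing_profile(pattern_sparse())
  expect_equal(sp$paired_fraction, 0)
  expect_equal(sp$classification, "sparse")
  pp <- spacing_profile(pattern_paired())
  expect_equal(pp$paired_fraction, 1)
  expect_equal(pp$classification, "paired")
  expect_equal(spacing_profile(cond_alps_peptide())$classification,
               "paired")
  expect_equal(spacing_profile(helix_sequence("SSSS"))$status,
               "undefined")
})

test_that("inserting a polar spacer never increases the paired fraction", {
  set.seed(99)
  for (i in 1:40) {
    s <- random_helix(sample(8:40, 1))
    pf <- spacing_profile(s)
    if (pf$status != "ok") next
    pos <- pf$hydrophobic_positions
    adj <- pos[which(diff(pos) == 1)]
    if (length(adj) == 0) next
    at <- adj[1]
    s2 <- mutate_helix(s, sprintf("Ins%dS", at))
    pf2 <- spacing_profile(s2)
    expect_lte(pf2$paired_fraction, pf$paired_fraction)
  }
})

test_that("condensation reproduces condALPS and guards hydrophobics", {
  cond <- condense(alps_peptide(), alps_condensation_deletions())
  expect_identical(as.character(cond),
                   as.character(cond_alps_peptide()))
  expect_length(cond$residues, 24)
  expect_true(attr(cond, "condense_report")$all_paired)
  expect_identical(condense(alps_peptide(), integer(0))$residues,
                   alps_peptide()$residues)
  expect_error(condense(alps_peptide(), 12), "hydrophobic")
  # conservation: the ordered hydrophobic subsequence survives
  set.seed(5)
  for (i in 1:20) {
    s <- random_helix(30)
    polar <- which(!s$residues %in% s$hydrophobic_set)
    if (length(polar) < 3) next
    del <- sample(polar, 3)
    out <- condense(s, del)
    hyd <- function(x) x$residues[x$residues %in% x$hydrophobic_set]
    expect_identical(hyd(out), hyd(s))
  }
})

test_that("edits apply with wild-type guards and invert cleanly", {
  alps <- alps_peptide()
  m <- mutate_helix(alps, "L12D")
  expect_identical(m$residues[12], "D")
  expect_identical(mutate_helix(alps, "G11P")$residues[11], "P")
  expect_error(mutate_helix(alps, "A12D"), "position 12")
  ins <- mutate_helix(alps, "Ins20AA")
  expect_length(ins$residues, 40)
  expect_identical(ins$residues[21:22], c("A", "A"))
  tr <- truncate_helix(alps, list(c(1, 6), c(29, 38)))
  expect_length(tr$residues, 16)
  expect_identical(paste(tr$residues[1:6], collapse = ""), "CSSWLG")
  # round trip through a composite edit list
  edited <- mutate_helix(alps, c("L12D", "Ins20AA", "Del3-5", "G8P"))
  undo <- invert_edit_log(attr(edited, "edit_log"))
  restored <- mutate_helix(edited, undo)
  expect_identical(restored$residues, alps$residues)
})

test_that("positional identity is strict and alignment-free", {
  a <- alps_peptide()
  expect_equal(positional_identity(a, a)$identity, 1)
  expect_equal(positional_identity(helix_sequence("AAAA"),
                                   helix_sequence("GGGG"))$identity, 0)
  expect_error(positional_identity(a, helix_sequence("AA")), "length")
  pid <- positional_identity(a, invert(a))
  oracle <- sum(a$residues == rev(a$residues))
  expect_equal(pid$matches, oracle)
  expect_equal(pid$mismatches, 38 - oracle)
})

test_that("sequences round-trip through FASTA", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_helix_fasta(list(alps_peptide(), cond_alps_peptide()), path)
  back <- read_helix_fasta(path)
  expect_length(back, 2)
  expect_identical(as.character(back[[1]]),
                   as.character(alps_peptide()))
  expect_identical(as.character(back[[2]]),
                   as.character(cond_alps_peptide()))
})
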