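test_that("fork assembly derives the published geometry", {
  f <- fork_ac90()
  expect_identical(f$duplex_bp, 108L)
  expect_identical(f$overhang5_nt, 37L)
  expect_identical(f$nicks, 1L)
  expect_identical(f$unwindable_bp, 90L)
  expect_identical(f$ss_nt, 37L)
})

test_that("mimicked-unwound assembly has a 37 bp duplex and 71 nt ss tail", {
  m <- mimic_unwound()
  expect_identical(m$duplex_bp, 37L)
  expect_identical(m$nicks, 1L)
  # the bead strand (C, 90 nt) keeps only 19 nt paired
  cc <- Filter(function(p) p$name == "C", m$partners)[[1]]
  paired <- cc$anneal_end - cc$anneal_start + 1L
  expect_identical(cc$length - paired, 71L)
  expect_identical(m$ss_nt, 71L)
})

test_that("a bare scaffold has no duplex and a full-length overhang", {
  s <- anneal(oligo("A", 145), list())
  expect_identical(s$duplex_bp, 0L)
  expect_identical(s$overhang5_nt, 145L)
  expect_identical(s$nicks, 0L)
})

test_that("anneal rejects overlapping and out-of-range intervals", {
  a <- oligo("A", 100)
  expect_error(
    anneal(a, list(oligo("P", 30, anneal_start = 10, anneal_end = 39),
                   oligo("Q", 30, anneal_start = 35, anneal_end = 64))),
    "overlap")
  expect_error(
    anneal(a, list(oligo("P", 30, anneal_start = 90, anneal_end = 119))),
    "outside")
  expect_error(
    anneal(a, list(oligo("P", 30))), "no annealing coordinates")
})

test_that("anneal is order-independent in its partner list", {
  a <- oligo("A", 145)
  b <- oligo("B", 18, anneal_start = 128, anneal_end = 145)
  cc <- oligo("C", 90, anneal_start = 38, anneal_end = 127)
  s1 <- anneal(a, list(b, cc))
  s2 <- anneal(a, list(cc, b))
  expect_identical(s1$duplex_bp, s2$duplex_bp)
  expect_identical(s1$nicks, s2$nicks)
  expect_identical(s1$overhang5_nt, s2$overhang5_nt)
})

test_that("non-adjacent partners leave a gap, not a nick", {
  a <- oligo("A", 100)
  s <- anneal(a, list(oligo("P", 20, anneal_start = 11, anneal_end = 30),
                      oligo("Q", 20, anneal_start = 41, anneal_end = 60)))
  expect_identical(s$nicks, 0L)
  expect_identical(s$duplex_bp, 40L)
})

test_that("sequence complementarity is verified when sequences are given", {
  scf <- oligo("S", sequence = "ACGTACGTAC")
  ok <- oligo("P", sequence = "ACGT", anneal_start = 5, anneal_end = 8)
  # scaffold[5:8] = ACGT, reverse complement ACGT -> pairs
  expect_silent(anneal(scf, list(ok)))
  bad <- oligo("Q", sequence = "AAAA", anneal_start = 5, anneal_end = 8)
  expect_error(anneal(scf, list(bad)), "reverse complement")
})

test_that("composition follows the one-duplex-two-ss rule per unwound bp", {
  f <- fork_ac90()
  c0 <- composition_at(f, 0)
  expect_identical(c0$duplex_bp, 108L)
  expect_identical(c0$ss_nt, 37L)
  expect_true(c0$bead_attached)
  c45 <- composition_at(f, 45)
  expect_identical(c45$duplex_bp, 63L)
  expect_identical(c45$ss_nt, 127L)
  expect_true(c45$bead_attached)
  c90 <- composition_at(f, 90)
  expect_false(c90$bead_attached)
  expect_error(composition_at(f, 91), "unwound")
  expect_error(composition_at(f, -1), "unwound")
})

test_that("tether nucleotide content is conserved and monotone in unwinding", {
  f <- fork_ac90()
  comps <- lapply(0:90, composition_at, substrate = f)
  total <- vapply(comps, function(x) 2L * x$duplex_bp + x$ss_nt, integer(1))
  expect_true(all(total == total[1]))
  ss <- vapply(comps, `[[`, integer(1), "ss_nt")
  dx <- vapply(comps, `[[`, integer(1), "duplex_bp")
  expect_true(all(diff(ss) > 0))
  expect_true(all(diff(dx) < 0))
})

test_that("FASTA round trip preserves labels and anneal registers", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">A",
    paste(rep("ACGTA", 29), collapse = ""),
    ">B label5=dig anneal=128-145",
    "TACGTACGTACGTACGTA",
    ">C label3=biotin anneal=38-127",
    paste(rep("GTACG", 18), collapse = "")), fa)
  oligos <- read_oligo_fasta(fa)
  expect_named(oligos, c("A", "B", "C"))
  expect_identical(oligos$A$length, 145L)
  expect_identical(oligos$B$label5, "dig")
  expect_identical(oligos$C$anneal_start, 38L)
  expect_identical(oligos$C$anneal_end, 127L)
  s <- anneal(oligos$A, list(oligos$B, oligos$C), check_sequences = FALSE)
  expect_identical(s$duplex_bp, 108L)
  rep_path <- tempfile(fileext = ".tsv")
  df <- write_substrate_report(list(fork = s), rep_path)
  back <- read.delim(rep_path)
  expect_identical(back$duplex_bp, 108L)
  expect_identical(back$unwindable_bp, 90L)
})

test_that("oligo validation catches inconsistent fields", {
  expect_error(oligo("X", 10, sequence = "ACGT"), "does not match")
  expect_error(oligo("X", 3, anneal_start = 1, anneal_end = 5), "longer")
  expect_error(oligo("X", 0), "length")
})
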