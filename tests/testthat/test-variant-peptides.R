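test_that("translation follows the standard code and stops at the first stop codon", {
  expect_identical(translate_cds("ATGAAATAA"), "MK")
  expect_identical(translate_cds("ATGGCCAAATAA"), "MAK")
  expect_identical(translate_cds("ATGGCCGGGAAATAA"), "MAGK")
  expect_identical(translate_cds("ATGAAA"), "MK")    # no stop: all complete codons
  expect_identical(translate_cds("ATGAAAC"), "MK")   # trailing partial codon ignored
  expect_identical(translate_cds("atgaaa"), "MK")    # case-insensitive input
  expect_error(translate_cds("ATGNAA"), class = "invalid_sequence")
  expect_error(translate_cds("AT"), class = "invalid_sequence")
})

test_that("transcript records reject internal stops and derive the protein", {
  t <- transcript_record("T1", "ATGGCCAAACTGTAA")
  expect_identical(t$protein, "MAKL")
  expect_error(transcript_record("T2", "ATGTAAAAATAA"), class = "invalid_sequence")
  expect_error(transcript_record("", "ATGAAATAA"), class = "invalid_input")
})

test_that("missense application substitutes exactly one residue", {
  t <- transcript_record("T1", "ATGGCCAAACTGTAA")  # MAKL
  expect_identical(apply_missense(t, missense_variant("T1", 2, "A", "V")), "MVKL")
  expect_error(apply_missense(t, missense_variant("T1", 2, "G", "V")),
               class = "reference_mismatch")
  expect_error(apply_missense(t, missense_variant("T1", 9, "A", "V")),
               class = "invalid_input")
  expect_error(missense_variant("T1", 2, "A", "A"), class = "invalid_input")

  set.seed(11)
  prot <- random_protein(500)
  pos <- 250L
  ref <- substr(prot, pos, pos)
  alt <- setdiff(AA20, ref)[1L]
  mut <- apply_missense(prot, missense_variant("T1", pos, ref, alt))
  expect_identical(nchar(mut), 500L)
  expect_identical(sum(utf8ToInt(mut) != utf8ToInt(prot)), 1L)
  expect_identical(substr(mut, pos, pos), alt)
})

test_that("in-frame CDS edits are applied and translated; frameshifts rejected", {
  t <- transcript_record("T1", "ATGGCCAAATAA")  # MAK
  expect_identical(apply_cds_indel(t, inframe_indel("T1", 7, inserted = "GGG")),
                   "MAGK")
  expect_identical(apply_cds_indel(t, inframe_indel("T1", 4, deleted = "GCC")),
                   "MK")
  expect_error(inframe_indel("T1", 7, inserted = "GG"),
               class = "unsupported_variant")
  expect_error(apply_cds_indel(t, inframe_indel("T1", 4, deleted = "AAA")),
               class = "reference_mismatch")
  # prefix before the edited codon is unchanged (position stability)
  t2 <- transcript_record("T2", paste0("ATG", strrep("GCC", 30), "TAA"))
  mut <- apply_cds_indel(t2, inframe_indel("T2", 31, inserted = "AAA"))
  expect_identical(substr(mut, 1, 10), substr(t2$protein, 1, 10))
})

test_that("an interior mutation yields exactly 38 windows of lengths 8-11", {
  prot <- strrep("Q", 500)
  w <- enumerate_mutant_windows(prot, 50)
  expect_identical(nrow(w), 38L)
  expect_identical(as.integer(table(w$length)), c(8L, 9L, 10L, 11L))
})

test_that("terminal mutations yield only the windows that exist", {
  prot <- random_protein(60)
  expect_identical(nrow(enumerate_mutant_windows(prot, 1)), 4L)
  expect_identical(nrow(enumerate_mutant_windows(prot, 60)), 4L)
  p9 <- random_protein(9)
  w <- enumerate_mutant_windows(p9, 5)
  expect_identical(nrow(w), 3L)
  expect_identical(sort(w$length), c(8L, 8L, 9L))
  expect_error(enumerate_mutant_windows("", 1), class = "invalid_input")
  expect_error(enumerate_mutant_windows(prot, 61), class = "invalid_input")
})

test_that("window enumeration matches the closed-form count exhaustively (N <= 30)", {
  set.seed(3)
  for (N in 8:30) {
    prot <- random_protein(N)
    for (p in seq_len(N)) {
      w <- enumerate_mutant_windows(prot, p)
      for (L in 8:11) {
        expected <- if (L > N) 0L else {
          cnt <- min(p, N - L + 1L) - max(1L, p - L + 1L) + 1L
          max(cnt, 0L)
        }
        expect_identical(sum(w$length == L), expected,
                         info = sprintf("N=%d p=%d L=%d", N, p, L))
      }
      # every window is a substring at its start and covers the position
      expect_true(all(substring(prot, w$start, w$start + w$length - 1L) == w$peptide))
      expect_true(all(w$start <= p & p <= w$start + w$length - 1L))
    }
  }
})

test_that("interior window total is 38 whenever both flanks are long enough", {
  set.seed(4)
  for (N in c(21, 40, 75)) {
    prot <- random_protein(N)
    for (p in seq(11, N - 10)) {
      expect_identical(nrow(enumerate_mutant_windows(prot, p)), 38L)
    }
  }
})

test_that("novelty filtering removes wild-type substrings and is idempotent", {
  wt <- "MAKLTTTTTTTT"
  mut <- "MAGKLTTTTTTTT"  # G inserted at protein position 3
  cand <- enumerate_mutant_windows(mut, seq_len(nchar(mut)))
  nov <- novel_peptides(cand, wt)
  expect_gt(nrow(nov), 0L)
  expect_true(all(grepl("G", nov$peptide)))          # wild type has no G
  expect_true(!any(vapply(nov$peptide, grepl, logical(1), x = wt, fixed = TRUE)))
  expect_identical(novel_peptides(nov, wt), nov)     # idempotent

  # mutant == wildtype: nothing is novel
  same <- enumerate_mutant_windows(wt, 3)
  expect_identical(nrow(novel_peptides(same, wt)), 0L)

  # anti-monotone: a longer wild type can only shrink the result
  set.seed(5)
  for (i in 1:20) {
    w0 <- random_protein(30)
    m0 <- random_protein(30)
    cand0 <- enumerate_mutant_windows(m0, sample(30, 1))
    n1 <- novel_peptides(cand0, w0)
    n2 <- novel_peptides(cand0, paste0(w0, random_protein(15)))
    expect_true(all(n2$peptide %in% n1$peptide))
  }
})

test_that("the mutated span is located for substitutions, insertions and deletions", {
  expect_identical(mutated_span("MAKLTTTTTTTT", "MAGKLTTTTTTTT"), 3L)
  expect_identical(mutated_span("MAKL", "MVKL"), 2L)
  # clean one-residue deletion: junction positions returned
  span <- mutated_span("MAAK", "MAK")
  expect_true(length(span) >= 1L && all(span >= 1L & span <= 3L))
})

test_that("per-variant peptide sets respect the missense/indel rules", {
  set.seed(6)
  codons <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                                    c("A","C","G","T"), paste0)),
                    c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(codons, 60, TRUE), collapse = ""), "TAA")
  t <- transcript_record("TX1", cds)
  pos <- 30L
  ref <- substr(t$protein, pos, pos)
  v <- missense_variant("TX1", pos, ref, setdiff(AA20, ref)[1L])
  pep <- mutant_peptides(t, v)
  expect_identical(nrow(pep), 38L)  # interior missense
  ins <- inframe_indel("TX1", 31, inserted = "GAC")
  pepi <- mutant_peptides(t, ins)
  mut <- apply_cds_indel(t, ins)
  expect_true(all(substring(mut, pepi$start, pepi$start + pepi$length - 1L) == pepi$peptide))
  expect_true(!any(vapply(pepi$peptide, grepl, logical(1), x = t$protein, fixed = TRUE)))
})

test_that("notation parsers accept the documented forms and reject others", {
  pc <- parse_protein_change("A2V")
  expect_identical(pc, list(ref_aa = "A", protein_position = 2L, alt_aa = "V"))
  expect_error(parse_protein_change("A2fs"), class = "parse_error")

  ins <- parse_cds_effect("6_7insGGG")
  expect_identical(ins$cds_position, 7L)
  expect_identical(ins$inserted, "GGG")
  del <- parse_cds_effect("4_6del")
  expect_identical(del$cds_position, 4L)
  expect_identical(del$deleted_length, 3L)
  delb <- parse_cds_effect("4_6delGCC")
  expect_identical(delb$deleted, "GCC")
  expect_error(parse_cds_effect("6_9insGGG"), class = "parse_error")
  expect_error(parse_cds_effect("4_6delGC"), class = "parse_error")
  expect_error(parse_cds_effect("banana"), class = "parse_error")
})
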