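mk_ref <- function(patterns, threshold = 0.95) {
  reference_barcode("test-ref",
                    tibble::tibble(segment = paste0("seg", seq_along(patterns)),
                                   pattern = patterns),
                    identity_threshold = threshold, target_species = "tgt")
}

test_that("case encoding defines the essential mask", {
  ref <- mk_ref("AAgTA")
  expect_equal(ref$segments$essential_mask[[1]], c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ref$segments$pattern[[1]], "AAGTA")
  # lowercase ambiguity: essential position accepting A or G
  ref_r <- mk_ref("AArTA")
  expect_true(ref_r$segments$essential_mask[[1]][3])
  expect_true(match_reference("AAATA", ref_r, try_revcomp = FALSE)$passed)
  expect_true(match_reference("AAGTA", ref_r, try_revcomp = FALSE)$passed)
  expect_false(match_reference("AACTA", ref_r, try_revcomp = FALSE)$passed)
  expect_error(mk_ref("AAZTA"), "non-IUPAC")
  expect_error(mk_ref("AATTA"), "essential")
})

test_that("reference files round trip", {
  ref <- mk_ref(c("ACGTacgtACGTACGTACGT", "TTTTggggTTTTTTTTTTTT"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_reference_barcode(ref, path)
  back <- parse_reference_barcode(path)
  expect_equal(back$segments$pattern, ref$segments$pattern)
  expect_equal(back$segments$essential_mask, ref$segments$essential_mask)
  expect_equal(back$identity_threshold, ref$identity_threshold)
})

test_that("semi-global alignment handles identity, deletions and overhangs", {
  al <- align_to_reference("ACGTACGT", "ACGTACGT")
  expect_equal(al$aligned_pattern, "ACGTACGT")
  expect_equal(al$aligned_test, "ACGTACGT")
  # one internal deletion in the test -> exactly one gap, verified against
  # the DP optimum on a short string
  al <- align_to_reference("ACGTCGTACG", "ACGTACGTACG")
  expect_equal(sum(strsplit(al$aligned_test, "")[[1]] == "-"), 1)
  expect_equal(sum(strsplit(al$aligned_pattern, "")[[1]] == "-"), 0)
  # test overhangs are free
  al <- align_to_reference("TTTTACGTACGTTTTT", "ACGTACGT")
  expect_equal(al$score, 8)
  expect_error(align_to_reference("", "ACGT"), "empty")
})

test_that("inclusive 95% boundary: 19/20 with intact essentials passes", {
  pattern <- paste0("aA", strrep("C", 17), "g")  # 20 columns, essentials at 1,20
  ref <- mk_ref(pattern, threshold = 0.95)
  test <- paste0("AT", strrep("C", 17), "G")     # one non-essential mismatch
  res <- match_reference(test, ref, try_revcomp = FALSE)
  expect_equal(res$overall_identity, 19 / 20)
  expect_true(res$passed)
  # same identity but an essential violated: veto dominates
  test_e <- paste0("CA", strrep("C", 17), "G")
  res_e <- match_reference(test_e, ref, try_revcomp = FALSE)
  expect_false(res_e$passed)
  expect_equal(res_e$essential_failures$position, 1L)
})

test_that("essential-base veto holds at every essential position", {
  pattern <- "acGTACgtACGTACGTacgA"
  ref <- mk_ref(pattern, threshold = 0.5)  # permissive threshold: only the veto can fail it
  clean <- toupper(pattern)
  expect_true(match_reference(clean, ref, try_revcomp = FALSE)$passed)
  mask <- ref$segments$essential_mask[[1]]
  for (p in which(mask)) {
    ch <- strsplit(clean, "")[[1]]
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    res <- match_reference(paste(ch, collapse = ""), ref, try_revcomp = FALSE)
    expect_false(res$passed)
    expect_true(p %in% res$essential_failures$position)
  }
})

test_that("mismatches and thresholds are monotone", {
  set.seed(31)
  pattern <- random_dna(60)
  ch <- strsplit(pattern, "")[[1]]
  ess <- sort(sample(60, 5))
  ch[ess] <- tolower(ch[ess])
  ref <- mk_ref(paste(ch, collapse = ""))
  test <- toupper(pattern)
  prev_passed <- TRUE
  non_ess <- setdiff(seq_len(60), ess)
  for (k in seq_len(20)) {
    tch <- strsplit(test, "")[[1]]
    tch[non_ess[k]] <- setdiff(c("A", "C", "G", "T"), tch[non_ess[k]])[1]
    test <- paste(tch, collapse = "")
    res <- match_reference(test, ref, try_revcomp = FALSE)
    # extra mismatches never convert failed -> passed
    expect_true(prev_passed || !res$passed)
    prev_passed <- res$passed
    # passing at t implies passing at any weaker t'
    if (res$passed) {
      weaker <- mk_ref(paste(ch, collapse = ""), threshold = 0.80)
      expect_true(match_reference(test, weaker, try_revcomp = FALSE)$passed)
    }
  }
})

test_that("reverse-complemented material matches in the logged orientation", {
  ref <- its_reference()
  tgt <- match_reference(herbarcode:::expand_reference(ref), ref)
  expect_true(tgt$passed)
  expect_equal(tgt$orientation, "forward")
  rc <- match_reference(herbarcode:::revcomp(herbarcode:::expand_reference(ref)), ref)
  expect_true(rc$passed)
  expect_equal(rc$orientation, "reverse")
})

test_that("segment combination modes both work", {
  ref_w <- mk_ref(c(paste0("a", strrep("A", 9)), paste0("c", strrep("C", 29))))
  test1 <- strrep("A", 10); test2 <- strrep("C", 30)
  joined <- paste0(test1, "ACGTACGT", test2)
  res <- match_reference(joined, ref_w, try_revcomp = FALSE)
  expect_equal(res$overall_identity, 1)
  res_min <- match_reference(joined, ref_w, combine = "min", try_revcomp = FALSE)
  expect_equal(res_min$overall_identity, 1)
})

test_that("the packaged reference separates target from adulterant material", {
  ref <- its_reference()
  expect_true(match_reference(herbarcode:::expand_reference(ref), ref)$passed)
  res <- match_reference(herbarcode:::mutate_essentials(ref, n = 2), ref)
  expect_false(res$passed)
  expect_equal(nrow(res$essential_failures), 4)  # 2 per segment
})
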