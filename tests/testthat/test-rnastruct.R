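test_that("folding recovers the canonical toy hairpin and degenerate cases", {
  ss <- fold_hairpin("GGGAAACCC")
  expect_equal(ss$structure, "(((...)))")
  expect_equal(sum(!is.na(ss$pair_map)) / 2, 3)
  expect_equal(fold_hairpin("AAAAA")$structure, ".....")
  expect_error(fold_hairpin("ACG"), "shorter")
  expect_error(fold_hairpin("ACGRYACGT"), "unambiguous")
})

test_that("fold pair counts equal the exhaustive-enumeration maximum", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(5:14, 1)
    s <- random_dna(n)
    folded <- fold_hairpin(s)
    expect_equal(sum(!is.na(folded$pair_map)) / 2, oracle_max_pairs(s),
                 info = s)
  }
})

test_that("structure validation enforces the documented invariants", {
  expect_error(structured_sequence("ACGU", "(().."), "lengths differ")
  expect_error(structured_sequence("ACGUA", "(()))"), "unbalanced")
  expect_error(structured_sequence("ACGUA", "(()()"), "unbalanced")
  expect_error(structured_sequence("AAAAAACUU", "(((...)))"), "non-canonical")
  expect_error(structured_sequence("GAAC", "(..)"), "loop shorter")
  expect_silent(structured_sequence("GGGAAACCC", "(((...)))"))
})

test_that("the 12-letter encoding is positionwise and invertible", {
  ss <- structured_sequence("GGGAAACCC", "(((...)))")
  enc <- encode_structure_alphabet(ss)
  expect_equal(nchar(enc), 9)
  # 3 opening-class, 3 unpaired-class, 3 closing-class letters
  expect_equal(enc, "FFFAAALLL")
  expect_equal(encode_structure_alphabet(structured_sequence("A", ".")), "A")
  set.seed(5)
  for (i in 1:25) {
    s <- random_dna(sample(8:25, 1))
    ss <- fold_hairpin(s)
    dec <- decode_structure_alphabet(encode_structure_alphabet(ss))
    expect_identical(dec$sequence, ss$sequence)
    expect_identical(dec$structure, ss$structure)
  }
})

test_that("CBC counting: identity, constructed examples, brute-force check", {
  a <- structured_sequence("GGAAACC", "((...))")
  expect_equal(count_cbc(a, a), list(cbc = 0L, hemi_cbc = 0L, shared_pairs = 2L))
  # inner pair G-C flipped to C-G: one full CBC, outer pair untouched
  b <- structured_sequence("GCAAAGC", "((...))")
  res <- count_cbc(a, b)
  expect_equal(res$cbc, 1L)
  expect_equal(res$hemi_cbc, 0L)
  expect_equal(res$shared_pairs, 2L)
  # brute-force over the 2 shared pairs confirms the counts
  ca <- strsplit(a$sequence, "")[[1]]; cb <- strsplit(b$sequence, "")[[1]]
  manual <- table(vapply(c(1, 2), function(i) {
    j <- a$pair_map[i]
    sum(ca[i] != cb[i], ca[j] != cb[j])
  }, numeric(1)))
  expect_equal(unname(manual[["2"]]), 1)
  # hemi: GC -> GU changes one side only
  h <- structured_sequence("GGAAAUC", "((...))")
  res_h <- count_cbc(a, h)
  expect_equal(res_h$cbc, 0L)
  expect_equal(res_h$hemi_cbc, 1L)
  expect_error(count_cbc(a, structured_sequence("GGGAAACCC", "(((...)))")),
               "frame")
})

test_that("CBC counts are symmetric and bounded by shared pairs", {
  set.seed(23)
  for (i in 1:200) {
    hp <- random_helix_pair(stem_bp = sample(3:8, 1), loop_len = sample(3:5, 1))
    ab <- count_cbc(hp$a, hp$b)
    ba <- count_cbc(hp$b, hp$a)
    expect_identical(ab, ba)
    expect_lte(ab$cbc + ab$hemi_cbc, ab$shared_pairs)
    expect_identical(count_cbc(hp$a, hp$a)$cbc, 0L)
  }
})

test_that("the clade-gradient fixture reproduces its planted CBC counts", {
  demo <- cbc_demo_panel()
  got <- vapply(demo$panel$ss, function(s) count_cbc(demo$target, s)$cbc, integer(1))
  expect_equal(got, as.integer(demo$panel$cbc_planted))
  # qualitative gradient: same-clade-as-target species show none, and the
  # counts never decrease along the E -> D -> C -> B ladder of minima
  by_clade <- split(got, demo$panel$meseguer_clade)
  expect_true(all(by_clade$E == 0))
  expect_true(min(by_clade$D) >= 1)
  expect_true(min(by_clade$C) >= 2)
  expect_true(min(by_clade$B) >= 4)
})

test_that("stem-loop extraction classifies archetypes and tolerates apex changes", {
  anchors <- psba_anchors()
  arch <- psba_archetypes()
  flank <- "TTTAAATTTTAAA"
  spacer <- function(region) paste0(flank, anchors$five_prime, region,
                                    gsub("W", "A", anchors$three_prime), flank)
  short <- extract_stem_loop(spacer(arch$sequence[arch$id == "short"]))
  expect_equal(short$class, "SHORT")
  expect_equal(short$loop_seq, "AAA")
  expect_equal(short$archetype_match, "short")
  long <- extract_stem_loop(spacer(arch$sequence[arch$id == "long"]))
  expect_equal(long$class, "LONG")
  expect_true(long$stem_bp > short$stem_bp)
  # apex AAA -> UUU: loop label changes, class must not
  mut <- sub("AAA", "TTT", arch$sequence[arch$id == "short"], fixed = TRUE)
  short_u <- extract_stem_loop(spacer(mut))
  expect_equal(short_u$class, "SHORT")
  expect_equal(short_u$loop_seq, "UUU")
  expect_equal(short_u$stem_bp, short$stem_bp)
})

test_that("anchor failures are reported with match positions", {
  expect_error(extract_stem_loop("AAAATTTTAAAA"), "not found")
  anchors <- psba_anchors()
  arch <- psba_archetypes()
  dbl <- paste0(anchors$five_prime, "TTTT", anchors$five_prime,
                arch$sequence[1], "CCGGATAAGC")
  expect_error(extract_stem_loop(dbl), "2 times")
})
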