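mutate_at_positions <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  paste(ch, collapse = "")
}

test_that("outlier filter discards unsupported singletons only", {
  base <- strrep("ACGTG", 20)
  ident <- sequence_records(paste0("r", 1:5), rep(base, 5))
  fo <- filter_outliers(ident)
  expect_equal(nrow(fo$kept), 5)

  # expected outcome frozen from an exhaustive pairwise identity matrix:
  # r5 differs at 10/100 columns -> 0.90 to everything else, below 0.95
  far <- mutate_at_positions(base, seq(3, 93, by = 10))
  recs <- sequence_records(paste0("r", 1:5), c(rep(base, 4), far))
  idm <- outer(recs$sequence, recs$sequence,
               Vectorize(function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])))
  diag(idm) <- NA
  expect_true(max(idm[5, ], na.rm = TRUE) < 0.95)
  fo <- filter_outliers(recs, 0.95)
  expect_equal(fo$discarded$id, "r5")

  # two mutually distant records with no supported core: both kept
  pair <- sequence_records(c("a", "b"), c(base, far))
  expect_equal(nrow(filter_outliers(pair, 0.95)$kept), 2)

  expect_error(filter_outliers(ident[0, ]), "empty")
})

test_that("outlier filter is idempotent", {
  set.seed(11)
  base <- random_dna(120)
  seqs <- c(replicate(4, mutate_at_positions(base, sample(120, 2))),
            mutate_at_positions(base, seq(1, 110, by = 8)))
  recs <- sequence_records(paste0("r", 1:5), seqs)
  once <- filter_outliers(recs, 0.95)
  twice <- filter_outliers(once$kept, 0.95)
  expect_identical(twice$kept$id, once$kept$id)
  expect_equal(nrow(twice$discarded), 0)
})

test_that("consensus construction follows the frequency / ambiguity rules", {
  mk <- function(seqs) sequence_records(paste0("r", seq_along(seqs)), seqs,
                                        species = "sp", gapped = TRUE)
  expect_equal(build_consensus(mk(c("ACGT", "ACGT")))$consensus, "ACGT")
  # W = A/T from the IUPAC table
  cons <- build_consensus(mk(c("ACGT", "ACGA")), ambiguity_floor = 0.25)
  expect_equal(cons$consensus, "ACGW")
  expect_equal(cons$polymorphic_columns[[1]], 4L)
  # T at 0.25 below the 0.3 floor: majority base emitted plain
  expect_equal(build_consensus(mk(c("ACGT", "ACGA", "ACGA", "ACGA")),
                               ambiguity_floor = 0.3)$consensus, "ACGA")
  # majority-gap column dropped, with a coordinate map
  cons_gap <- build_consensus(mk(c("A-GT", "A-GT", "ACGT")))
  expect_equal(cons_gap$consensus, "AGT")
  expect_equal(attr(cons_gap, "column_map"), c(1L, 3L, 4L))
  expect_error(build_consensus(mk(character(0))[0, ]), "empty")
})

test_that("consensus covers every member base when the floor is zero", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    len <- 30
    seqs <- replicate(n, random_dna(len))
    recs <- sequence_records(paste0("r", 1:n), seqs, species = "sp", gapped = TRUE)
    cons <- strsplit(build_consensus(recs, ambiguity_floor = 0)$consensus, "")[[1]]
    for (s in seqs) {
      ch <- strsplit(s, "")[[1]]
      compat <- iupac_compatible(ch, cons)
      expect_true(all(compat))
    }
  }
})

test_that("subtype detection recovers planted templates and ignores row order", {
  cfg <- sim_config(seed = 42, n_species = 4, n_accessions = 10, sites = 300)
  pan <- generate_panel(cfg)
  tgt <- pan$alignment[pan$alignment$species == "H. perforatum", ]
  subs <- detect_subtypes(tgt, link_identity = 0.985)
  expect_equal(nrow(subs), 3)
  templates <- sort(pan$truth$templates$sequence[
    pan$truth$templates$species == "H. perforatum"])
  expect_equal(sort(subs$consensus), templates)

  perm <- tgt[sample(nrow(tgt)), ]
  subs_perm <- detect_subtypes(perm, link_identity = 0.985)
  expect_equal(subs_perm$consensus, subs$consensus)
  expect_equal(subs_perm$subtype_label, subs$subtype_label)

  ident <- sequence_records(paste0("r", 1:10), rep(strrep("ACGT", 10), 10),
                            species = "sp", gapped = TRUE)
  expect_equal(nrow(detect_subtypes(ident)), 1)

  two <- sequence_records(c("a", "b"),
                          c(strrep("ACGT", 10), strrep("TGCA", 10)),
                          species = "sp", gapped = TRUE)
  expect_equal(nrow(detect_subtypes(two, link_identity = 0.9)), 2)
})

test_that("discriminating sites: unique vs pairwise semantics", {
  mk_aln <- function(ids, species, seqs) {
    new_alignment(sequence_records(ids, seqs, species = species, gapped = TRUE))
  }
  # all rows identical -> empty report
  aln <- mk_aln(c("a", "b", "c"), c("t", "u", "v"), rep("ACGTACGT", 3))
  rep0 <- find_discriminating_sites(aln, "t")
  expect_length(rep0$unique_sites, 0)
  expect_equal(nrow(rep0$pairwise_sites), 0)

  # brute-force toy: target state at column 2 differs from both others
  aln <- mk_aln(c("a", "b", "c"), c("tgt", "sp2", "sp3"),
                c("AAAA", "AGAA", "ATAA"))
  expect_equal(find_discriminating_sites(aln, "tgt")$unique_sites, 2L)

  # a column where target subtypes disagree is never unique
  aln <- mk_aln(c("a1", "a2", "b"), c("tgt", "tgt", "sp2"),
                c("AAAA", "ACAA", "AGAA"))
  expect_length(find_discriminating_sites(aln, "tgt")$unique_sites, 0)

  expect_error(find_discriminating_sites(aln, "nope"), "absent")
})

test_that("panel-style fixture shows unique, adulterant-unique and pairwise-only sites", {
  # four species; col 2 unique to target, col 4 unique to the adulterant,
  # col 6 separates target from adulterant but each of its states recurs in
  # one of the outgroup species, so it is never unique
  aln <- new_alignment(sequence_records(
    c("t1", "t2", "m1", "m2", "o1", "p1"),
    species = c("tgt", "tgt", "adu", "adu", "out", "oth"),
    c("ACAAGTAA",
      "ACAAGTAA",
      "AAATGCAA",
      "AAATGCAA",
      "AAAAGTAA",
      "AAAAGCAA"),
    gapped = TRUE
  ))
  rep_t <- find_discriminating_sites(aln, "tgt")
  expect_equal(rep_t$unique_sites, 2L)
  rep_a <- find_discriminating_sites(aln, "adu")
  expect_equal(rep_a$unique_sites, 4L)
  pw <- rep_t$pairwise_sites
  ta <- pw$position[(pw$species_a == "tgt" & pw$species_b == "adu") |
                      (pw$species_a == "adu" & pw$species_b == "tgt")]
  expect_true(6L %in% ta)        # discriminates the pair ...
  expect_false(6L %in% rep_t$unique_sites)  # ... without being unique
  expect_false(6L %in% rep_a$unique_sites)
})

test_that("planted species-specific SNPs are recovered exactly at zero noise", {
  cfg <- sim_config(seed = 9, n_species = 8, sites = 240, noise_rate = 0)
  pan <- generate_panel(cfg)
  for (sp in c("H. perforatum", "H. maculatum")) {
    planted <- sort(pan$truth$sites$position[pan$truth$sites$species == sp])
    found <- find_discriminating_sites(pan$alignment, sp)$unique_sites
    expect_equal(found, planted)
  }
})

test_that("hotspot scan flags packed variable regions", {
  ident <- new_alignment(sequence_records(
    c("a", "b"), rep(strrep("ACGT", 10), 2), species = c("x", "y"),
    gapped = TRUE))
  hs <- scan_hotspots(ident, window = 10, step = 5)
  expect_true(all(hs$score == 0))
  expect_false(any(hs$flagged))

  s1 <- strrep("A", 40)
  ch <- strsplit(s1, "")[[1]]; ch[c(10, 12, 14, 17, 20)] <- "G"
  aln <- new_alignment(sequence_records(c("a", "b"), c(s1, paste(ch, collapse = "")),
                                        species = c("x", "y"), gapped = TRUE))
  hs <- scan_hotspots(aln, window = 10, step = 1)
  best <- hs[which.max(hs$score), ]
  expect_true(best$start <= 20 && best$end >= 10)
  # 5 variable columns span positions 10-20; a 10-wide window holds 4
  expect_equal(max(hs$score), 0.4)
  expect_error(scan_hotspots(aln, window = 100), "larger")
  expect_error(scan_hotspots(aln, window = 0), "positive")
})
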