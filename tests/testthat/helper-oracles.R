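# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: plain recursion instead of the DP
# fold, a hard-coded rule transcription instead of the data-driven
# haplotype key.

# exhaustive-enumeration maximum base-pair count over all nested structures
oracle_max_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  ch <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  ok <- c("AU", "UA", "GC", "CG", if (allow_gu) c("GU", "UG"))
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (paste0(ch[i], ch[k]) %in% ok) {
        cand <- 1L + rec(i + 1, k - 1) + if (k < j) rec(k + 1, j) else 0L
        if (cand > best) best <- cand
      }
    }
    best
  }
  if (length(ch) < min_loop + 2) return(0L)
  rec(1L, length(ch))
}

# hard-coded truth-table transcription of the rbcL haplotype rules
oracle_rbcl_label <- function(s66, s180, s263, s300, s372, s378, s492) {
  markers <- (s66 == "T") + (s263 == "T")
  if (s300 == "G" && s372 == "C") {
    c("1", "1(p)", "1p")[markers + 1]
  } else if (s378 == "G" && s492 == "T") {
    "2"
  } else if (s180 == "C" && s300 == "A" && s372 == "A" &&
             s378 == "A" && s492 == "A") {
    "1-2"
  } else {
    "novel"
  }
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# random perfect hairpin (stem_bp pairs, loop_len apex) plus an independent
# same-structure partner; used for CBC property tests
random_helix_pair <- function(stem_bp = 6, loop_len = 4) {
  canon <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                c("G", "U"), c("U", "G"))
  draw <- function() {
    pairs <- canon[sample(length(canon), stem_bp, replace = TRUE)]
    left <- vapply(pairs, `[`, "", 1)
    right <- rev(vapply(pairs, `[`, "", 2))
    loop <- sample(c("A", "C"), loop_len, replace = TRUE)
    paste(c(left, loop, right), collapse = "")
  }
  db <- paste0(strrep("(", stem_bp), strrep(".", loop_len), strrep(")", stem_bp))
  list(a = structured_sequence(draw(), db),
       b = structured_sequence(draw(), db))
}

states_from_vector <- function(v) {
  stats::setNames(v, c("66", "180", "263", "300", "372", "378", "492"))
}

table5_path <- function() {
  system.file("extdata", "test_collection_characters.tsv",
              package = "herbarcode", mustWork = TRUE)
}
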