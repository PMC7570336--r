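# Pairwise alignment engine. Small Needleman-Wunsch with IUPAC-aware
# scoring; the semi-global mode leaves both ends of the *test* sequence
# unpenalised while the pattern must be consumed in full (the geometry the
# reference-barcode matcher needs). Traceback is deterministic: at ties the
# high road diagonal > up (gap in test) > left (gap in pattern), starting
# from the leftmost best cell, so results are reproducible across platforms.

iupac_bits <- function(chars) {
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(toupper(chars), function(ch) {
    if (ch == "U") ch <- "T"
    if (ch %in% c("-", ".")) return(0L)
    ex <- IUPAC_EXPANSION[[ch]]
    if (is.null(ex)) abort(paste0("not an IUPAC nucleotide code: '", ch, "'"))
    sum(bit[ex])
  }, integer(1), USE.NAMES = FALSE)
}

#' Align a test sequence to a pattern
#'
#' Global or semi-global (free end gaps on the test side) alignment with
#' IUPAC-compatibility scoring: columns whose codes share at least one base
#' score `match`, others `mismatch`, indels `gap` per position (linear).
#'
#' @param pattern,test Nucleotide strings (IUPAC codes allowed in both).
#' @param type `"semiglobal"` (pattern consumed in full, test overhangs free)
#'   or `"global"`.
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `aligned_pattern`, `aligned_test` (equal-length gapped
#'   strings), `score`, and `pattern_cols`: for each pattern position, the
#'   aligned column index.
#' @export
align_pair <- function(pattern, test, type = c("semiglobal", "global"),
                       match = 1, mismatch = -1, gap = -2) {
  type <- match.arg(type)
  if (!nzchar(pattern)) abort("empty pattern")
  if (!nzchar(test)) abort("empty test sequence")
  p <- seq_chars(pattern)
  q <- seq_chars(test)
  m <- length(p); n <- length(q)
  pb <- iupac_bits(p); qb <- iupac_bits(q)
  # substitution score matrix m x n
  S <- matrix(mismatch, m, n)
  for (i in seq_len(m)) {
    S[i, ] <- ifelse(bitwAnd(pb[i], qb) > 0L, match, mismatch)
  }
  M <- matrix(0, m + 1, n + 1)
  M[, 1] <- gap * (0:m)                    # pattern aligned to gaps: charged
  M[1, ] <- if (type == "global") gap * (0:n) else 0
  for (i in 2:(m + 1)) {
    row_prev <- M[i - 1, ]
    cur <- M[i, ]
    for (j in 2:(n + 1)) {
      cur[j] <- max(row_prev[j - 1] + S[i - 1, j - 1],
                    row_prev[j] + gap,
                    cur[j - 1] + gap)
    }
    M[i, ] <- cur
  }
  if (type == "global") {
    end_j <- n + 1
    score <- M[m + 1, n + 1]
  } else {
    score <- max(M[m + 1, ])
    end_j <- which(M[m + 1, ] == score)[1]  # leftmost best end
  }
  # traceback
  ap <- character(0); at <- character(0)
  i <- m + 1; j <- end_j
  while (i > 1 || j > 1) {
    if (i == 1) {
      ap <- c("-", ap); at <- c(q[j - 1], at); j <- j - 1
    } else if (j == 1) {
      ap <- c(p[i - 1], ap); at <- c("-", at); i <- i - 1
    } else if (M[i, j] == M[i - 1, j] + gap) {
      # high road: at ties the up move wins, which (walking back from the
      # end) defers test-residue consumption and places residues 5'-most
      ap <- c(p[i - 1], ap); at <- c("-", at); i <- i - 1
    } else if (M[i, j] == M[i - 1, j - 1] + S[i - 1, j - 1]) {
      ap <- c(p[i - 1], ap); at <- c(q[j - 1], at); i <- i - 1; j <- j - 1
    } else {
      ap <- c("-", ap); at <- c(q[j - 1], at); j <- j - 1
    }
  }
  # trailing test overhang (semiglobal): append unaligned tail
  if (type == "semiglobal" && end_j <= n) {
    ap <- c(ap, rep("-", n + 1 - end_j))
    at <- c(at, q[end_j:n])
  }
  pattern_cols <- which(ap != "-")
  list(
    aligned_pattern = paste(ap, collapse = ""),
    aligned_test = paste(at, collapse = ""),
    score = score,
    pattern_cols = pattern_cols
  )
}

#' Pairwise identity between two sequences
#'
#' Identity = compatible columns / aligned columns (gap-gap pairs cannot
#' occur in a pairwise alignment), computed on a global alignment with
#' match +1, mismatch 0, gap -1 — the conventional curation scoring.
#'
#' @param a,b Nucleotide strings.
#' @param aligned If `TRUE`, `a` and `b` are already gapped rows of a common
#'   frame; columns where both have a gap are dropped.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, aligned = FALSE) {
  if (aligned) {
    ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
    if (length(ca) != length(cb)) abort("aligned rows differ in length")
    keep <- !(ca == "-" & cb == "-")
    ca <- ca[keep]; cb <- cb[keep]
    if (length(ca) == 0) return(NA_real_)
    comp <- iupac_compatible(ca, cb)
    comp[is.na(comp)] <- FALSE
    return(sum(comp) / length(ca))
  }
  al <- align_pair(a, b, type = "global", match = 1, mismatch = 0, gap = -1)
  pairwise_identity(al$aligned_pattern, al$aligned_test, aligned = TRUE)
}
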