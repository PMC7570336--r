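# RNA secondary-structure characters. The in-repo folding method is
# base-pair maximisation (Nussinov-style dynamic programming) over canonical
# pairs (AU/UA, GC/CG and the GU/UG wobble) with a minimum hairpin loop,
# plus a deterministic traceback; thermodynamic folding is deliberately out
# of scope, with externally computed dot-brackets accepted as input for
# parity checks.

CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

can_pair <- function(a, b, allow_gu = TRUE) {
  p <- paste0(a, b)
  p %in% (if (allow_gu) CANONICAL_PAIRS else CANONICAL_PAIRS[1:4])
}

# dot-bracket -> pair vector (pm[i] = partner index or NA)
parse_dotbracket <- function(structure) {
  ch <- seq_chars(structure)
  pm <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) abort(paste0("unbalanced ')' at position ", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pm[j] <- i; pm[i] <- j
    } else if (!ch[i] %in% c(".", "-")) {
      abort(paste0("invalid structure character '", ch[i], "' at position ", i))
    }
  }
  if (length(stack) > 0) {
    abort(paste0("unbalanced '(' at position ", stack[1]))
  }
  pm
}

#' Construct a sequence + secondary structure pair
#'
#' Validates that the dot-bracket is balanced, only canonical pairs are
#' closed, and every hairpin loop has at least `min_loop` unpaired bases.
#' DNA input (`T`) is mapped to RNA (`U`).
#'
#' @param sequence RNA (or DNA) string; may contain `-` in gapped frames.
#' @param structure Dot-bracket string of equal length.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @param allow_gu Accept GU wobble pairs (default `TRUE`).
#' @return Object of class `"structured_sequence"` with fields `sequence`,
#'   `structure`, `pair_map`.
#' @export
structured_sequence <- function(sequence, structure, min_loop = 3,
                                allow_gu = TRUE) {
  sequence <- gsub("T", "U", toupper(sequence), fixed = TRUE)
  if (nchar(sequence) != nchar(structure)) {
    abort("sequence and structure lengths differ")
  }
  pm <- parse_dotbracket(structure)
  ch <- seq_chars(sequence)
  for (i in which(!is.na(pm))) {
    j <- pm[i]
    if (i < j) {
      if (!can_pair(ch[i], ch[j], allow_gu)) {
        abort(paste0("non-canonical pair ", ch[i], "-", ch[j],
                     " at positions ", i, ",", j))
      }
      between <- if (j - i - 1 > 0) pm[(i + 1):(j - 1)] else integer(0)
      if (j - i - 1 < min_loop && all(is.na(between))) {
        abort(paste0("hairpin loop shorter than ", min_loop,
                     " at positions ", i, "-", j))
      }
    }
  }
  structure(list(sequence = sequence, structure = structure, pair_map = pm),
            class = "structured_sequence")
}

#' @export
print.structured_sequence <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "  (",
      sum(!is.na(x$pair_map)) / 2, " pairs)\n", sep = "")
  invisible(x)
}

#' Fold a short RNA into its maximum-base-pair hairpin structure
#'
#' Nussinov-style base-pair maximisation over canonical pairs with a
#' minimum hairpin loop. Among co-optimal structures the traceback is
#' deterministic: a 5' base is paired whenever pairing is optimal, and its
#' partner is the 3'-most optimal one, which stacks helices under the
#' enclosing pair.
#'
#' @param seq RNA string (`T` accepted and mapped to `U`).
#' @param min_loop Minimum unpaired bases in a hairpin loop (default 3).
#' @param allow_gu Allow GU wobble pairs.
#' @return `"structured_sequence"`.
#' @export
fold_hairpin <- function(seq, min_loop = 3, allow_gu = TRUE) {
  s <- gsub("T", "U", toupper(seq), fixed = TRUE)
  ch <- seq_chars(s)
  n <- length(ch)
  if (n < min_loop + 2) abort(paste0("sequence shorter than min_loop + 2 (", n, " nt)"))
  if (!all(ch %in% c("A", "C", "G", "U", "N"))) {
    abort("fold_hairpin expects an unambiguous RNA/DNA sequence")
  }
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1):(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- N[i + 1, j]                     # i unpaired
      for (k in (i + min_loop + 1):j) {
        if (can_pair(ch[i], ch[k], allow_gu)) {
          inner <- if (k - i - 1 >= min_loop + 2) N[i + 1, k - 1] else 0L
          rest <- if (k < j) N[k + 1, j] else 0L
          cand <- 1L + inner + rest
          if (cand > best) best <- cand
        }
      }
      N[i, j] <- best
    }
  }
  pm <- rep(NA_integer_, n)
  trace <- function(i, j) {
    while (i < j) {
      if (j - i < min_loop + 1) return(invisible())
      target <- N[i, j]
      if (target == N[i + 1, j]) {
        # check whether pairing i is also optimal; prefer it (3'-most k)
        paired <- FALSE
        for (k in j:(i + min_loop + 1)) {
          if (can_pair(ch[i], ch[k], allow_gu)) {
            inner <- if (k - i - 1 >= min_loop + 2) N[i + 1, k - 1] else 0L
            rest <- if (k < j) N[k + 1, j] else 0L
            if (1L + inner + rest == target) {
              pm[i] <<- k; pm[k] <<- i
              if (k < j) trace(k + 1, j)
              i <- i + 1; j <- k - 1
              paired <- TRUE
              break
            }
          }
        }
        if (!paired) { i <- i + 1 }
      } else {
        for (k in j:(i + min_loop + 1)) {
          if (can_pair(ch[i], ch[k], allow_gu)) {
            inner <- if (k - i - 1 >= min_loop + 2) N[i + 1, k - 1] else 0L
            rest <- if (k < j) N[k + 1, j] else 0L
            if (1L + inner + rest == target) {
              pm[i] <<- k; pm[k] <<- i
              if (k < j) trace(k + 1, j)
              i <- i + 1; j <- k - 1
              break
            }
          }
        }
      }
    }
  }
  if (n >= min_loop + 2) trace(1, n)
  db <- rep(".", n)
  db[!is.na(pm) & seq_len(n) < pm] <- "("
  db[!is.na(pm) & seq_len(n) > pm] <- ")"
  structured_sequence(s, paste(db, collapse = ""), min_loop = min_loop,
                      allow_gu = allow_gu)
}

# apex hairpin loop(s) of a structure: runs of unpaired bases directly
# closed by a pair
hairpin_loops <- function(ss) {
  pm <- ss$pair_map
  loops <- list()
  for (i in which(!is.na(pm))) {
    j <- pm[i]
    if (i < j && j - i > 1 && all(is.na(pm[(i + 1):(j - 1)]))) {
      loops[[length(loops) + 1]] <- list(start = i + 1, end = j - 1,
                                         closed_by = c(i, j))
    }
  }
  loops
}

# number of pairs enclosing a span (interior loops allowed)
enclosing_pairs <- function(pm, start, end) {
  sum(vapply(which(!is.na(pm)), function(i) {
    j <- pm[i]
    i < j && i < start && j > end
  }, logical(1)))
}

#' Extract and classify the psbA 3' UTR stem-loop
#'
#' Locates the variable region between two conserved anchor motifs (IUPAC
#' motifs, each required to occur exactly once), folds it with
#' [fold_hairpin()], measures the terminal helix (base pairs enclosing the
#' apex loop; interior loops allowed) and classifies the hairpin as SHORT
#' iff `stem_bp <= short_max_bp`. If archetype sequences are supplied (or
#' the packaged synthetic long/short archetypes are used), the closer
#' archetype by pairwise identity is reported as cross-check evidence;
#' classification itself uses the fold.
#'
#' @param seq psbA-trnH spacer sequence (DNA or RNA).
#' @param anchors List with `five_prime` and `three_prime` IUPAC motifs.
#' @param short_max_bp SHORT iff the terminal helix has at most this many
#'   pairs; default 8.
#' @param min_loop Minimum apex loop (default 3).
#' @param archetypes Optional sequence-record tibble with ids `long` and
#'   `short`; `NULL` for the packaged synthetic archetypes, `NA` to skip.
#' @return Object of class `"stem_loop"`: `region_start`, `region_end`
#'   (1-based in `seq`), `structure`, `stem_bp`, `loop_seq`, `loop_label`,
#'   `class` (`"LONG"`/`"SHORT"`), `archetype_match`, `archetype_agrees`.
#' @export
extract_stem_loop <- function(seq, anchors = psba_anchors(),
                              short_max_bp = 8, min_loop = 3,
                              archetypes = NULL) {
  s <- gsub("U", "T", toupper(seq), fixed = TRUE)
  find_anchor <- function(motif, name) {
    rx <- iupac_regex(motif)
    hits <- gregexpr(rx, s)[[1]]
    if (hits[1] == -1) abort(paste0(name, " anchor '", motif, "' not found"))
    if (length(hits) > 1) {
      abort(paste0(name, " anchor '", motif, "' matches ", length(hits),
                   " times (positions ", paste(hits, collapse = ", "), ")"))
    }
    c(start = hits[1], end = hits[1] + nchar(motif) - 1)
  }
  a5 <- find_anchor(anchors$five_prime, "five_prime")
  a3 <- find_anchor(anchors$three_prime, "three_prime")
  if (a5["end"] >= a3["start"]) abort("anchors out of order or overlapping")
  region_start <- unname(a5["end"] + 1)
  region_end <- unname(a3["start"] - 1)
  region <- substr(s, region_start, region_end)
  ss <- fold_hairpin(region, min_loop = min_loop)
  loops <- hairpin_loops(ss)
  if (length(loops) == 0) {
    abort("no hairpin found between anchors")
  }
  depth <- vapply(loops, function(l) enclosing_pairs(ss$pair_map, l$start, l$end),
                  numeric(1))
  apex <- loops[[which.max(depth)]]
  stem_bp <- max(depth)
  loop_seq <- substr(ss$sequence, apex$start, apex$end)
  cls <- if (stem_bp <= short_max_bp) "SHORT" else "LONG"

  archetype_match <- NA_character_
  if (is.null(archetypes)) archetypes <- psba_archetypes()
  if (is.data.frame(archetypes)) {
    ids <- vapply(archetypes$sequence, function(a) {
      pairwise_identity(region, gsub("U", "T", toupper(a), fixed = TRUE))
    }, numeric(1))
    archetype_match <- archetypes$id[which.max(ids)]
  }
  structure(
    list(region_start = region_start, region_end = region_end,
         sequence = ss$sequence, structure = ss$structure,
         stem_bp = stem_bp, loop_seq = loop_seq, loop_label = loop_seq,
         class = cls, short_max_bp = short_max_bp,
         archetype_match = archetype_match,
         archetype_agrees = if (is.na(archetype_match)) NA else
           identical(toupper(archetype_match), cls)),
    class = "stem_loop"
  )
}

#' @export
print.stem_loop <- function(x, ...) {
  cat("<stem-loop>", x$class, "| stem", x$stem_bp, "bp | apex loop",
      x$loop_seq, "\n")
  cat("region", x$region_start, "-", x$region_end, "(1-based)\n")
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' The packaged conserved anchor motifs flanking the psbA stem-loop
#' @return List with `five_prime` and `three_prime` IUPAC motifs.
#' @export
psba_anchors <- function() {
  list(five_prime = "ACGCATCCGG", three_prime = "CCGGATWAGC")
}

#' The packaged synthetic psbA stem-loop archetypes
#'
#' Synthetic long (extended stem) and short (stem truncated by the
#' diagnostic deletion, three-base apex) archetype regions; see the
#' packaged FASTA fixture.
#'
#' @return Sequence-record tibble with ids `long` and `short`.
#' @export
psba_archetypes <- function() {
  read_sequences(system.file("extdata", "psba_archetypes_synthetic.fasta",
                             package = "herbarcode", mustWork = TRUE))
}

iupac_regex <- function(motif) {
  ch <- seq_chars(toupper(motif))
  paste(vapply(ch, function(c) {
    ex <- iupac_expand(c)
    if (length(ex) == 1) ex else paste0("[", paste(ex, collapse = ""), "]")
  }, ""), collapse = "")
}

# 12-letter sequence+structure alphabet: each (base, pairing state) maps to
# one letter. Documented, internally consistent mapping:
#   state      A  C  G  U
#   unpaired   A  C  G  U
#   opening    D  E  F  I
#   closing    K  L  M  P
SS_ALPHABET <- local({
  tab <- expand.grid(base = c("A", "C", "G", "U"),
                     state = c("unpaired", "opening", "closing"),
                     stringsAsFactors = FALSE)
  tab$letter <- c("A", "C", "G", "U", "D", "E", "F", "I", "K", "L", "M", "P")
  tab
})

#' Encode a structured sequence in the single-letter sequence+structure alphabet
#'
#' Each (base, pairing-state) combination maps to one of 12 letters
#' (unpaired A/C/G/U keep their base letter; opening-strand bases map to
#' D/E/F/I; closing-strand bases to K/L/M/P). The encoding is invertible:
#' [decode_structure_alphabet()] recovers both sequence and dot-bracket.
#' Gap characters pass through as `-`.
#'
#' @param ss `"structured_sequence"`.
#' @return Single encoded string.
#' @export
encode_structure_alphabet <- function(ss) {
  ch <- seq_chars(ss$sequence)
  st <- seq_chars(ss$structure)
  state <- ifelse(st == "(", "opening", ifelse(st == ")", "closing", "unpaired"))
  out <- vapply(seq_along(ch), function(i) {
    if (ch[i] == "-") return("-")
    hit <- SS_ALPHABET$letter[SS_ALPHABET$base == ch[i] &
                                SS_ALPHABET$state == state[i]]
    if (length(hit) != 1) abort(paste0("cannot encode base '", ch[i],
                                       "' at position ", i))
    hit
  }, "")
  paste(out, collapse = "")
}

#' @rdname encode_structure_alphabet
#' @param encoded String produced by [encode_structure_alphabet()].
#' @export
decode_structure_alphabet <- function(encoded) {
  ch <- seq_chars(encoded)
  idx <- match(ch, SS_ALPHABET$letter)
  if (any(is.na(idx) & ch != "-")) {
    abort(paste0("unknown encoded letter '", ch[which(is.na(idx) & ch != "-")[1]], "'"))
  }
  base <- ifelse(ch == "-", "-", SS_ALPHABET$base[idx])
  st <- ifelse(ch == "-", "-",
               c(unpaired = ".", opening = "(", closing = ")")[SS_ALPHABET$state[idx]])
  structured_sequence(paste(base, collapse = ""), paste(st, collapse = ""))
}

#' Count compensatory base changes between two structured sequences
#'
#' Both inputs must live in a common gapped frame (equal length; gaps as
#' `-` with `.`/`-` structure). Over aligned position pairs `(i, j)` that
#' are base-paired in BOTH structures: a CBC is counted when the two
#' sequences differ at `i` AND at `j`; a hemi-CBC when they differ at
#' exactly one side. Symmetric in its arguments.
#'
#' @param a,b `"structured_sequence"` objects in a common frame.
#' @return List with `cbc`, `hemi_cbc`, `shared_pairs`.
#' @export
count_cbc <- function(a, b) {
  if (nchar(a$sequence) != nchar(b$sequence)) {
    abort("structured sequences are not in a common frame (length mismatch)")
  }
  pa <- a$pair_map; pb <- b$pair_map
  ca <- seq_chars(a$sequence); cb <- seq_chars(b$sequence)
  shared <- which(!is.na(pa) & !is.na(pb) & pa == pb & seq_along(pa) < pa)
  cbc <- 0L; hemi <- 0L
  for (i in shared) {
    j <- pa[i]
    d1 <- ca[i] != cb[i]
    d2 <- ca[j] != cb[j]
    if (d1 && d2) cbc <- cbc + 1L
    else if (d1 || d2) hemi <- hemi + 1L
  }
  list(cbc = cbc, hemi_cbc = hemi, shared_pairs = length(shared))
}
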