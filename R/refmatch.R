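# Reference-barcode matching: a pharmacopoeia-style quality standard where
# a curated pattern carries *essential* bases (lowercase in the file format;
# exact, ambiguity-code-aware match required) embedded in context sequence
# (uppercase; contributes to an overall identity threshold, default 95%).
# A test sequence passes iff every essential base matches AND overall
# identity meets the threshold (inclusive).

#' Construct a reference barcode
#'
#' @param name Barcode name.
#' @param segments Tibble with columns `segment` (name) and `pattern`
#'   (case-encoded IUPAC string: lowercase = essential).
#' @param identity_threshold Overall identity required, in `(0, 1]`.
#' @param target_species Binomial the standard certifies.
#' @return Object of class `"reference_barcode"`.
#' @export
reference_barcode <- function(name, segments, identity_threshold = 0.95,
                              target_species = "unknown") {
  stopifnot(is.data.frame(segments), all(c("segment", "pattern") %in% names(segments)))
  if (!(identity_threshold > 0 && identity_threshold <= 1)) {
    abort("identity_threshold must be in (0, 1]")
  }
  segs <- segments %>%
    mutate(
      essential_mask = map(.data$pattern, function(p) {
        ch <- seq_chars(p)
        bad <- which(!is_iupac(ch))
        if (length(bad) > 0) {
          abort(paste0("non-IUPAC character '", ch[bad[1]], "' at position ",
                       bad[1], " of segment pattern"))
        }
        grepl("[a-z]", ch)
      }),
      pattern = toupper(.data$pattern),
      length = nchar(.data$pattern)
    )
  if (sum(map_int(segs$essential_mask, sum)) == 0) {
    abort("reference barcode must define at least one essential base")
  }
  structure(
    list(name = name, segments = segs,
         identity_threshold = identity_threshold,
         target_species = target_species),
    class = "reference_barcode"
  )
}

#' @export
print.reference_barcode <- function(x, ...) {
  cat("<reference barcode>", x$name, "for", x$target_species, "\n")
  cat("segments:", paste0(x$segments$segment, " (", x$segments$length, " nt, ",
                          map_int(x$segments$essential_mask, sum),
                          " essential)", collapse = "; "), "\n")
  cat("overall identity threshold:", x$identity_threshold, "(inclusive)\n")
  invisible(x)
}

#' Parse a reference-barcode file
#'
#' FASTA-like text: each record header
#' `>name segment=<s> threshold=<t> species=<binomial>` is followed by a
#' case-encoded IUPAC pattern (lowercase = essential base, exact match
#' required; uppercase = context; ambiguity codes allowed in either case).
#' Records sharing a name become segments of one barcode.
#'
#' @param path File path.
#' @return `"reference_barcode"` object.
#' @export
parse_reference_barcode <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) abort(paste0("no records in ", path))
  ends <- c(hdr[-1] - 1, length(lines))
  name <- NULL; threshold <- 0.95; species <- "unknown"
  segs <- purrr::map2(hdr, ends, function(h, e) {
    info <- parse_fasta_header(lines[h])
    toks <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    kv <- function(key, default) {
      hit <- grep(paste0("^", key, "="), toks, value = TRUE)
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else default
    }
    pattern <- paste(gsub("\\s", "", lines[(h + 1):e]), collapse = "")
    tibble(name = toks[1], segment = kv("segment", toks[1]),
           threshold = as.numeric(kv("threshold", "0.95")),
           species = gsub("_", " ", kv("species", "unknown")),
           pattern = pattern)
  }) %>% bind_rows()
  reference_barcode(
    name = segs$name[1],
    segments = segs[, c("segment", "pattern")],
    identity_threshold = segs$threshold[1],
    target_species = segs$species[1]
  )
}

#' Write a reference barcode to its file format
#' @param ref `"reference_barcode"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_barcode <- function(ref, path) {
  out <- unlist(pmap(ref$segments, function(segment, pattern, essential_mask, length) {
    ch <- seq_chars(pattern)
    ch[essential_mask] <- tolower(ch[essential_mask])
    c(paste0(">", ref$name, " segment=", segment,
             " threshold=", format(ref$identity_threshold),
             " species=", gsub(" ", "_", ref$target_species)),
      paste(ch, collapse = ""))
  }))
  readr::write_lines(out, path)
  invisible(path)
}

#' Align a test sequence to a reference segment
#'
#' Semi-global alignment (the pattern is consumed in full; the test
#' sequence's ends are free), IUPAC-compatibility scoring (+1/-1, gap -2),
#' deterministic leftmost high-road traceback. Exposed mostly for
#' inspection; [match_reference()] drives it.
#'
#' @param test Test sequence string.
#' @param pattern Segment pattern (uppercase IUPAC).
#' @return See [align_pair()].
#' @export
align_to_reference <- function(test, pattern) {
  align_pair(pattern, test, type = "semiglobal")
}

segment_match <- function(pattern, mask, test) {
  al <- align_to_reference(test, pattern)
  pch <- seq_chars(pattern)
  tch <- seq_chars(al$aligned_test)[al$pattern_cols]
  comp <- iupac_compatible(tch, pch)
  comp[is.na(comp) | tch == "-"] <- FALSE
  failures <- which(mask & !comp)
  list(
    identity = sum(comp) / length(pch),
    essential_failures = tibble(
      position = failures,
      expected = pch[failures],
      observed = tch[failures]
    ),
    alignment = al
  )
}

#' Match a test sequence against a reference barcode
#'
#' Each segment is aligned and scored independently. An essential position
#' fails iff the aligned test base is a gap or incompatible with the
#' (possibly ambiguous) essential code. Segment identity = compatible
#' columns / pattern length; the overall identity combines segments by
#' length-weighted mean (`combine = "weighted"`) or by the per-segment
#' minimum (`combine = "min"`). The verdict passes iff there are no
#' essential failures and overall identity is at or above the threshold
#' (inclusive). Both orientations of the test sequence are tried and the
#' better-scoring one used.
#'
#' @param test Test sequence string (or one-row sequence-record tibble).
#' @param ref `"reference_barcode"`.
#' @param combine `"weighted"` or `"min"`.
#' @param try_revcomp Try the reverse complement too (default `TRUE`).
#' @return Object of class `"match_result"`: `passed`, `overall_identity`,
#'   `orientation`, `per_segment` tibble (`segment`, `identity`,
#'   `n_essential`, `n_failures`), `essential_failures` tibble with
#'   segment-qualified positions.
#' @export
match_reference <- function(test, ref, combine = c("weighted", "min"),
                            try_revcomp = TRUE) {
  combine <- match.arg(combine)
  if (is.data.frame(test)) test <- test$sequence[1]
  if (!nzchar(test)) abort("empty test sequence")
  run <- function(seqstr) {
    res <- pmap(ref$segments, function(segment, pattern, essential_mask, length) {
      sm <- segment_match(pattern, essential_mask, seqstr)
      list(segment = segment, len = length,
           n_essential = sum(essential_mask), sm = sm)
    })
    ids <- map_dbl(res, ~ .x$sm$identity)
    lens <- map_dbl(res, "len")
    overall <- if (combine == "weighted") sum(ids * lens) / sum(lens) else min(ids)
    list(res = res, overall = overall)
  }
  fwd <- run(test)
  use <- fwd; orientation <- "forward"
  if (isTRUE(try_revcomp)) {
    rev <- run(revcomp(test))
    if (rev$overall > fwd$overall) { use <- rev; orientation <- "reverse" }
  }
  per_segment <- map(use$res, function(r) {
    tibble(segment = r$segment, identity = r$sm$identity,
           n_essential = r$n_essential,
           n_failures = nrow(r$sm$essential_failures))
  }) %>% bind_rows()
  failures <- map(use$res, function(r) {
    f <- r$sm$essential_failures
    if (nrow(f)) f$segment <- r$segment
    f
  }) %>% bind_rows()
  passed <- nrow(failures) == 0 && use$overall >= ref$identity_threshold
  structure(
    list(passed = passed, overall_identity = use$overall,
         orientation = orientation, threshold = ref$identity_threshold,
         combine = combine, reference = ref$name,
         target_species = ref$target_species,
         per_segment = per_segment, essential_failures = failures),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match result>", x$reference, "->",
      if (x$passed) "PASS" else "FAIL", "\n")
  cat(sprintf("overall identity %.4f (threshold %.2f, %s), orientation %s\n",
              x$overall_identity, x$threshold, x$combine, x$orientation))
  if (nrow(x$essential_failures)) {
    cat("essential-base failures:\n")
    print(as.data.frame(x$essential_failures))
  }
  invisible(x)
}
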