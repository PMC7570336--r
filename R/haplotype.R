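# Chloroplast haplotype assignment from a small coordinate-mapped SNP key.
# The key names a handful of 1-based positions in a fixed coordinate system,
# a consensus base for each, a prioritised list of core haplotype patterns,
# and species-marker SNPs that are layered on top of the core call (the
# rbcL case: core types 1 / 2 / intermediate "1-2", with two target-species
# marker SNPs turning a type-1 call into "1(p)" or "1p").

#' Construct a haplotype key
#'
#' @param coordinate_name Name of the 1-based coordinate system.
#' @param positions Integer vector of mapped sites (strictly increasing).
#' @param consensus Named character vector, consensus base per position.
#' @param core_types List of `list(label=, priority=, required_states=)`
#'   entries; `required_states` is a named base vector keyed on positions.
#'   Evaluated in increasing priority; the first fully satisfied wins.
#' @param marker_snps Tibble with `position`, `state`, `label` for the
#'   species-marker SNPs (counted independently of the core call).
#' @param core_positions Positions a call requires data at; defaults to the
#'   union of core-type positions.
#' @param reference Optional reference sequence realising the coordinate
#'   system (consensus states at the mapped sites), used by
#'   [extract_states()] for unaligned samples.
#' @return Object of class `"haplotype_key"`.
#' @export
haplotype_key <- function(coordinate_name, positions, consensus, core_types,
                          marker_snps, core_positions = NULL,
                          reference = NULL) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("key positions must be strictly increasing")
  }
  if (!all(names(consensus) %in% as.character(positions))) {
    abort("consensus keyed on unlisted positions")
  }
  pr <- map_dbl(core_types, "priority")
  if (anyDuplicated(pr)) abort("core type priorities must be unique")
  for (ct in core_types) {
    if (!all(names(ct$required_states) %in% as.character(positions))) {
      abort(paste0("core type '", ct$label, "' keyed on unlisted positions"))
    }
  }
  if (!all(marker_snps$position %in% positions)) {
    abort("marker SNPs keyed on unlisted positions")
  }
  if (is.null(core_positions)) {
    core_positions <- sort(unique(as.integer(
      unlist(map(core_types, ~ names(.x$required_states)))
    )))
  }
  structure(
    list(coordinate_name = coordinate_name, positions = positions,
         consensus = consensus,
         core_types = core_types[order(pr)],
         marker_snps = marker_snps,
         core_positions = as.integer(core_positions),
         reference = reference),
    class = "haplotype_key"
  )
}

#' @export
print.haplotype_key <- function(x, ...) {
  cat("<haplotype key>", x$coordinate_name, "(1-based)\n")
  cat("positions:", paste(x$positions, collapse = ", "), "\n")
  cat("core types:", paste(map_chr(x$core_types, "label"), collapse = " > "), "\n")
  cat("marker SNPs:", paste0(x$marker_snps$position, "=", x$marker_snps$state,
                             collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a haplotype key (JSON)
#'
#' Plain-text JSON with fields `coordinate_name`, `positions`, `consensus`
#' (position-keyed object), `core_types` (array of `{label, priority,
#' required_states}`), `marker_snps` (array of `{position, state, label}`),
#' optional `core_positions` and `reference`.
#'
#' @param path JSON file.
#' @return `"haplotype_key"`.
#' @export
read_haplotype_key <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  haplotype_key(
    coordinate_name = j$coordinate_name,
    positions = unlist(j$positions),
    consensus = unlist(j$consensus),
    core_types = map(j$core_types, function(ct) {
      list(label = ct$label, priority = ct$priority,
           required_states = unlist(ct$required_states))
    }),
    marker_snps = bind_rows(map(j$marker_snps, as_tibble)),
    core_positions = if (!is.null(j$core_positions)) unlist(j$core_positions),
    reference = j$reference
  )
}

#' @rdname read_haplotype_key
#' @param key `"haplotype_key"` to serialise.
#' @export
write_haplotype_key <- function(key, path) {
  jsonlite::write_json(
    list(coordinate_name = key$coordinate_name,
         positions = key$positions,
         consensus = as.list(key$consensus),
         core_types = map(key$core_types, function(ct) {
           list(label = ct$label, priority = ct$priority,
                required_states = as.list(ct$required_states))
         }),
         marker_snps = key$marker_snps,
         core_positions = key$core_positions,
         reference = key$reference),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' The packaged rbcL haplotype key
#'
#' Seven mapped positions (66, 180, 263, 300, 372, 378, 492) over an
#' all-consensus background C,C,A,A,A,A,A. Core type `1` is keyed on
#' 300=G & 372=C (180=T co-occurs in most but not all type-1 panel species,
#' so it is mapped but not required); core type `2` on 378=G & 492=T; the
#' intermediate `1-2` is the all-consensus pattern at the five core sites.
#' Marker SNPs 66=T and 263=T are the target-species (H. perforatum)
#' markers. Type 1 takes priority over type 2 when both patterns co-occur.
#'
#' @return `"haplotype_key"`.
#' @export
rbcl_key <- function() {
  read_haplotype_key(system.file("extdata", "rbcl_haplotype_key.json",
                                 package = "herbarcode", mustWork = TRUE))
}

#' The published rbcL haplotype reference rows
#'
#' Panel haplotype map plus reference-sample assignments: 23 rows of
#' per-position states (dots already resolved against the consensus) and
#' the printed type label — the regression surface for [assign_haplotype()].
#'
#' @return Tibble with `row_id`, `source`, `type_label` and state columns
#'   `s66` ... `s492`.
#' @export
rbcl_reference_rows <- function() {
  readr::read_tsv(
    system.file("extdata", "rbcl_reference_rows.tsv", package = "herbarcode",
                mustWork = TRUE),
    comment = "#", col_types = readr::cols(.default = "c")
  )
}

#' Extract key-position states from a sample sequence
#'
#' For unaligned samples the sequence is aligned to the key's reference
#' (semi-global, free test ends); positions outside the aligned span are
#' reported as missing (`NA`), interior deletions as `"-"`.
#'
#' @param sample Sequence string, or a gapped row already in key
#'   coordinates (`aligned = TRUE`).
#' @param key `"haplotype_key"`.
#' @param aligned Is `sample` already in the key's coordinate frame?
#' @return Named character vector of states, one per key position.
#' @export
extract_states <- function(sample, key, aligned = FALSE) {
  if (is.data.frame(sample)) sample <- sample$sequence[1]
  if (aligned) {
    ch <- seq_chars(toupper(sample))
    if (max(key$positions) > length(ch)) {
      abort("aligned sample shorter than key coordinate span")
    }
    states <- ch[key$positions]
  } else {
    if (is.null(key$reference)) {
      abort("key has no reference sequence; supply an aligned sample")
    }
    al <- align_pair(key$reference, sample, type = "semiglobal")
    tch <- seq_chars(al$aligned_test)
    covered <- range(which(tch != "-"))
    cols <- al$pattern_cols[key$positions]
    states <- tch[cols]
    states[cols < covered[1] | cols > covered[2]] <- NA_character_
  }
  setNames(states, as.character(key$positions))
}

#' Assign a haplotype call from key-position states
#'
#' Core types are evaluated in priority order and the first whose required
#' states all match wins; a state vector matching no pattern is `"novel"`.
#' Marker SNPs are counted independently and layered onto a type-1 core:
#' two markers display `"1p"`, one `"1(p)"`, none `"1"`. Missing data
#' (`NA`, gap or `N`) at any core position degrades the call to
#' `"insufficient data"`.
#'
#' @param states Named state vector from [extract_states()].
#' @param key `"haplotype_key"`.
#' @return One-row tibble: `core_label`, `marker_count`, `display_label`,
#'   `states` (collapsed string).
#' @export
assign_haplotype <- function(states, key) {
  pos <- as.character(key$positions)
  states <- toupper(states[pos])
  names(states) <- pos
  core_pos <- as.character(key$core_positions)
  missing_core <- is.na(states[core_pos]) | states[core_pos] %in% c("-", "N", "")
  state_str <- paste0(pos, "=", ifelse(is.na(states), "?", states), collapse = ",")
  marker_count <- sum(!is.na(states[as.character(key$marker_snps$position)]) &
                        states[as.character(key$marker_snps$position)] ==
                          key$marker_snps$state)
  if (any(missing_core)) {
    return(tibble(core_label = "insufficient data", marker_count = marker_count,
                  display_label = "insufficient data", states = state_str))
  }
  core_label <- "novel"
  for (ct in key$core_types) {
    req <- ct$required_states
    if (all(states[names(req)] == req)) { core_label <- ct$label; break }
  }
  display <- if (core_label == "1") {
    c("1", "1(p)", "1p")[min(marker_count, 2) + 1]
  } else if (core_label == "novel") {
    paste0("novel:", state_str)
  } else {
    core_label
  }
  tibble(core_label = core_label, marker_count = marker_count,
         display_label = display, states = state_str)
}

#' Haplotype-call a tibble of samples
#'
#' Tidy wrapper: aligns each sequence to the key reference, extracts states
#' and assigns calls.
#'
#' @param samples Sequence-record tibble.
#' @param key `"haplotype_key"`.
#' @param aligned Passed to [extract_states()].
#' @return `samples` with call columns appended.
#' @export
call_haplotypes <- function(samples, key = rbcl_key(), aligned = FALSE) {
  calls <- map(samples$sequence, function(s) {
    assign_haplotype(extract_states(s, key, aligned = aligned), key)
  }) %>% bind_rows()
  bind_cols(samples[, setdiff(names(samples), names(calls))], calls)
}
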