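#' Filter singleton outlier accessions from a conspecific set
#'
#' Screens a set of accessions attributed to one species and discards
#' obvious outliers: a record is discarded iff its best pairwise identity to
#' any other conspecific record falls below `identity_threshold` — i.e. it
#' is a singleton with no near neighbour. Two records that are close to
#' each other but far from everything else are both kept (they corroborate
#' one another). This is the local, offline replacement for screening
#' accessions on a distance tree.
#'
#' Records are linked at the identity threshold (single linkage); a record
#' is discarded iff it forms a singleton cluster while at least one
#' multi-member (mutually supported) cluster exists. With no supported core
#' — e.g. just two distant records — nothing is discarded: there is no
#' basis to call either one the outlier. The filter is idempotent.
#'
#' @param records Sequence-record tibble (one species).
#' @param identity_threshold Minimum pairwise identity to any other record,
#'   default 0.95.
#' @param aligned Set `TRUE` if the sequences are gapped rows of a common
#'   frame (identity is then computed column-wise).
#' @return List with `kept` and `discarded` record tibbles.
#' @export
filter_outliers <- function(records, identity_threshold = 0.95, aligned = FALSE) {
  n <- nrow(records)
  if (is.null(n) || n == 0) abort("filter_outliers: empty input")
  if (n == 1) return(list(kept = records, discarded = records[0, ]))
  idm <- identity_matrix(records$sequence, aligned = aligned)
  hc <- hclust(as.dist(1 - idm), method = "single")
  grp <- cutree(hc, h = 1 - identity_threshold)
  sizes <- table(grp)
  keep <- if (any(sizes >= 2)) sizes[as.character(grp)] >= 2 else rep(TRUE, n)
  list(kept = records[keep, ], discarded = records[!keep, ])
}

identity_matrix <- function(seqs, aligned = FALSE) {
  n <- length(seqs)
  idm <- matrix(1, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        idm[i, j] <- idm[j, i] <- pairwise_identity(seqs[i], seqs[j],
                                                    aligned = aligned)
      }
    }
  }
  idm
}

#' Build an IUPAC consensus for aligned conspecific rows
#'
#' Per column: if one base reaches frequency `>= 1 - ambiguity_floor` it is
#' emitted directly; otherwise the minimal IUPAC code covering every base at
#' frequency `>= ambiguity_floor` is emitted (all observed bases if none
#' reach the floor). Gaps are ignored in the frequency counts; a column
#' whose gap frequency exceeds 0.5 is dropped from the consensus, with the
#' retained alignment columns recorded in the `column_map` attribute.
#'
#' @param records Sequence-record tibble with equal-length gapped rows, or a
#'   `"mult_alignment"`.
#' @param ambiguity_floor Frequency below which a variant base is not folded
#'   into the ambiguity code; default 0.25.
#' @param species,subtype_label Labels carried into the result.
#' @return A one-row tibble with columns `species`, `subtype_label`,
#'   `consensus`, `n_members`, `member_ids` (list), `polymorphic_columns`
#'   (list of 1-based alignment positions); attribute `column_map` gives the
#'   alignment column behind each consensus position.
#' @export
build_consensus <- function(records, ambiguity_floor = 0.25,
                            species = records$species[1],
                            subtype_label = "I") {
  if (nrow(records) == 0) abort("build_consensus: empty alignment")
  m <- alignment_matrix(new_alignment(records))
  ncol_aln <- ncol(m)
  keep <- colMeans(m == "-") <= 0.5
  cons <- character(0)
  poly <- integer(0)
  for (j in which(keep)) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) == 0) { cons <- c(cons, "N"); next }
    # expand any ambiguity codes in the rows themselves
    freq <- table(unlist(lapply(col, iupac_expand))) / length(col)
    freq <- sort(freq, decreasing = TRUE)
    if (freq[1] >= 1 - ambiguity_floor) {
      code <- names(freq)[1]
    } else {
      bases <- names(freq)[freq >= ambiguity_floor]
      if (length(bases) == 0) bases <- names(freq)
      code <- iupac_code(bases)
      poly <- c(poly, j)
    }
    cons <- c(cons, code)
  }
  out <- tibble(
    species = species,
    subtype_label = subtype_label,
    consensus = paste(cons, collapse = ""),
    n_members = nrow(records),
    member_ids = list(records$id),
    polymorphic_columns = list(poly)
  )
  attr(out, "column_map") <- which(keep)
  out
}

#' Detect within-species subtypes by single-linkage clustering
#'
#' Clusters aligned conspecific rows at `link_identity` (single linkage on
#' pairwise identity) and summarises each cluster with [build_consensus()].
#' Clusters are ordered by size (descending) then consensus string, and
#' labelled with Roman numerals, so the result is invariant to input row
#' order.
#'
#' @param records Aligned conspecific sequence-record tibble.
#' @param link_identity Identity at or above which two rows are linked;
#'   default 0.985.
#' @param ambiguity_floor Passed to [build_consensus()].
#' @return Tibble with one row per subtype (columns as [build_consensus()]).
#' @export
detect_subtypes <- function(records, link_identity = 0.985,
                            ambiguity_floor = 0.25) {
  if (nrow(records) == 0) abort("detect_subtypes: empty input")
  if (nrow(records) == 1) {
    return(build_consensus(records, ambiguity_floor, subtype_label = "I"))
  }
  idm <- identity_matrix(records$sequence, aligned = TRUE)
  hc <- hclust(as.dist(1 - idm), method = "single")
  grp <- cutree(hc, h = 1 - link_identity)
  subs <- map(sort(unique(grp)), function(g) {
    build_consensus(records[grp == g, , drop = FALSE], ambiguity_floor)
  })
  subs <- bind_rows(subs)
  ord <- order(-subs$n_members, subs$consensus)
  subs <- subs[ord, ]
  subs$subtype_label <- as.character(utils::as.roman(seq_len(nrow(subs))))
  subs
}

# per-column state set (intersection of row expansions); NULL if rows
# conflict or any gap present
column_state <- function(col) {
  if (any(col == "-")) return(NULL)
  sets <- lapply(col, iupac_expand)
  s <- Reduce(intersect, sets)
  if (length(s) == 0) NULL else s
}

#' Find species-discriminating alignment columns
#'
#' Scans a panel alignment for (i) `unique_sites`: columns where every row
#' of the target species shares a state (IUPAC-compatible across rows,
#' subtypes included) and every non-target row is incompatible with that
#' state; and (ii) `pairwise_sites`: for each species pair, the columns that
#' discriminate that pair. Columns containing a gap in any relevant row are
#' excluded by default, and coordinates are 1-based alignment columns.
#'
#' @param aln A `"mult_alignment"` whose `species` column labels the rows.
#' @param target Target species name (must be present).
#' @return List of class `"site_report"`: `unique_sites` (integer vector),
#'   `pairwise_sites` (tibble `species_a`, `species_b`, `position`),
#'   `target`, `coordinate_name`.
#' @export
find_discriminating_sites <- function(aln, target) {
  if (!target %in% aln$species) {
    abort(paste0("target species '", target, "' absent from alignment"))
  }
  if (all(aln$species == target)) abort("alignment has no non-target rows")
  m <- alignment_matrix(aln)
  nc <- ncol(m)
  sp <- aln$species
  species_list <- unique(sp)
  # per species x column consolidated state sets
  states <- lapply(species_list, function(s) {
    rows <- m[sp == s, , drop = FALSE]
    lapply(seq_len(nc), function(j) column_state(rows[, j]))
  })
  names(states) <- species_list

  unique_sites <- integer(0)
  tgt <- states[[target]]
  others <- setdiff(species_list, target)
  for (j in seq_len(nc)) {
    s_t <- tgt[[j]]
    if (is.null(s_t)) next
    incompat <- vapply(others, function(o) {
      rows <- m[sp == o, j]
      if (any(rows == "-")) return(FALSE)
      all(vapply(rows, function(b) length(intersect(iupac_expand(b), s_t)) == 0,
                 logical(1)))
    }, logical(1))
    if (all(incompat)) unique_sites <- c(unique_sites, j)
  }

  pairs <- utils::combn(species_list, 2, simplify = FALSE)
  pairwise <- map(pairs, function(pr) {
    sa <- states[[pr[1]]]; sb <- states[[pr[2]]]
    pos <- which(vapply(seq_len(nc), function(j) {
      !is.null(sa[[j]]) && !is.null(sb[[j]]) &&
        length(intersect(sa[[j]], sb[[j]])) == 0
    }, logical(1)))
    if (length(pos) == 0) return(NULL)
    tibble(species_a = pr[1], species_b = pr[2], position = pos)
  })
  pairwise <- bind_rows(pairwise)
  if (nrow(pairwise) == 0) {
    pairwise <- tibble(species_a = character(), species_b = character(),
                       position = integer())
  }
  structure(
    list(unique_sites = unique_sites, pairwise_sites = pairwise,
         target = target, coordinate_name = attr(aln, "coordinate_name")),
    class = "site_report"
  )
}

#' @export
print.site_report <- function(x, ...) {
  cat("<site report> target:", x$target,
      "| coordinates:", x$coordinate_name, "(1-based)\n")
  cat("unique sites:",
      if (length(x$unique_sites)) paste(x$unique_sites, collapse = ", ")
      else "none", "\n")
  cat("pairwise discriminating positions:", nrow(x$pairwise_sites), "\n")
  invisible(x)
}

#' Scan an alignment for variability hotspots
#'
#' Slides a window over the alignment and scores each window by the
#' fraction of its columns that are variable (more than one incompatible
#' non-gap state across rows). Windows scoring at or above the given
#' quantile of positive scores are flagged.
#'
#' @param aln A `"mult_alignment"`.
#' @param window Window width (columns), must be positive and no larger
#'   than the alignment.
#' @param step Step between window starts.
#' @param flag_quantile Quantile of nonzero scores above which a window is
#'   flagged; default 0.9.
#' @return Tibble of class `"hotspot_scan"`: `start`, `end` (1-based
#'   inclusive), `score`, `flagged`.
#' @export
scan_hotspots <- function(aln, window = 20, step = 5, flag_quantile = 0.9) {
  nc <- alignment_columns(aln)
  if (window <= 0) abort("window must be positive")
  if (window > nc) abort("window larger than alignment")
  m <- alignment_matrix(aln)
  variable <- vapply(seq_len(nc), function(j) {
    col <- m[, j][m[, j] != "-"]
    if (length(col) < 2) return(FALSE)
    is.null(column_state(m[, j])) || length(unique(col)) > 1
  }, logical(1))
  starts <- seq(1, nc - window + 1, by = step)
  scores <- vapply(starts, function(s) mean(variable[s:(s + window - 1)]),
                   numeric(1))
  thr <- if (any(scores > 0)) quantile(scores[scores > 0], flag_quantile) else Inf
  out <- tibble(start = starts, end = starts + window - 1L, score = scores,
                flagged = scores >= thr & scores > 0)
  class(out) <- c("hotspot_scan", class(out))
  out
}
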