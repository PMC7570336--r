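#' Sequence records as a tibble
#'
#' The package's working representation of barcode sequences is a tibble with
#' one row per sequence and columns `id`, `species`, `region`, `sequence`,
#' `source`. Gapped alignments additionally carry the S3 class
#' `"mult_alignment"` plus `column_count` and `coordinate_name` attributes;
#' all coordinates are 1-based inclusive.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of IUPAC nucleotide strings.
#' @param species Binomials (or `"unknown"`).
#' @param region Barcode region label, one of `"ITS"`, `"ITS1"`, `"ITS2"`,
#'   `"rbcL"`, `"psbA-trnH"`, `"matK"`, `"other"`.
#' @param source Free-text provenance (voucher/accession).
#' @param gapped Allow `-` characters (alignment rows).
#' @return A tibble of sequence records.
#' @export
sequence_records <- function(id, sequence, species = "unknown",
                             region = "other", source = "",
                             gapped = FALSE) {
  region_levels <- c("ITS", "ITS1", "ITS2", "rbcL", "psbA-trnH", "matK", "other")
  if (!all(region %in% region_levels)) {
    abort(paste0("unknown region label: ",
                 paste(setdiff(region, region_levels), collapse = ", ")))
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate sequence id: ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (any(!nzchar(sequence))) abort("empty sequence not allowed")
  ok <- vapply(sequence, function(s) {
    ch <- seq_chars(s)
    all(is_iupac(ch) | (gapped & ch == "-"))
  }, logical(1))
  if (!all(ok)) {
    bad <- id[!ok][1]
    abort(paste0("sequence '", bad, "' contains non-IUPAC characters"))
  }
  tibble(
    id = as.character(id),
    species = rep_len(as.character(species), length(id)),
    region = rep_len(as.character(region), length(id)),
    sequence = toupper(sequence),
    source = rep_len(as.character(source), length(id))
  )
}

#' Construct a multiple alignment from gapped sequence records
#'
#' @param records A sequence-record tibble (see [sequence_records()]) whose
#'   sequences are gapped and of equal length.
#' @param coordinate_name Name of the 1-based coordinate system the columns
#'   live in, e.g. `"rbcLa-panel-v1"`.
#' @return The records tibble with class `"mult_alignment"` and attributes
#'   `column_count`, `coordinate_name`.
#' @export
new_alignment <- function(records, coordinate_name = "unnamed") {
  if (nrow(records) < 1) abort("alignment needs at least one row")
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1) {
    abort(paste0("ragged alignment: row lengths ",
                 paste(sort(unique(lens)), collapse = ", ")))
  }
  structure(
    records,
    class = c("mult_alignment", class(tibble())),
    column_count = lens[1],
    coordinate_name = coordinate_name
  )
}

#' @export
print.mult_alignment <- function(x, ...) {
  cat("<multiple alignment> ", nrow(x), " rows x ",
      attr(x, "column_count"), " columns (coordinates: ",
      attr(x, "coordinate_name"), ", 1-based)\n", sep = "")
  NextMethod()
}

alignment_columns <- function(aln) attr(aln, "column_count")

# alignment as a character matrix, rows = records
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

parse_fasta_header <- function(header) {
  header <- sub("^>", "", header)
  toks <- strsplit(trimws(header), "\\s+")[[1]]
  id <- toks[1]
  kv <- toks[-1][grepl("=", toks[-1])]
  vals <- list(species = "unknown", region = "other", source = "")
  for (t in kv) {
    key <- sub("=.*", "", t)
    val <- gsub("_", " ", sub("^[^=]*=", "", t))
    if (key %in% names(vals)) vals[[key]] <- val
  }
  c(list(id = id), vals)
}

#' Read barcode sequences or a multiple alignment
#'
#' Supported formats: plain FASTA (`"fasta"`), gapped FASTA
#' (`"aligned_fasta"`) and Clustal (`"clustal"`, read-only). Records are
#' normalised to uppercase and, for DNA regions, `U` is mapped to `T`
#' (`rna_as_dna = FALSE` disables this). FASTA headers may carry
#' `species=`, `region=` and `source=` tokens (underscores stand for
#' spaces); the first word is the record id.
#'
#' @param path Input file.
#' @param fmt One of `"fasta"`, `"aligned_fasta"`, `"clustal"`.
#' @param rna_as_dna Map `U` to `T` on input.
#' @param coordinate_name Coordinate-system label for alignment formats.
#' @return A sequence-record tibble, or a `"mult_alignment"` for the
#'   alignment formats.
#' @export
read_sequences <- function(path, fmt = c("fasta", "aligned_fasta", "clustal"),
                           rna_as_dna = TRUE, coordinate_name = basename(path)) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (fmt == "clustal") {
    m <- ape::read.dna(path, format = "clustal", as.character = TRUE)
    ids <- rownames(m)
    seqs <- unname(toupper(apply(m, 1, paste, collapse = "")))
    meta <- list(id = ids, species = "unknown", region = "other", source = "")
  } else {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0) abort(paste0("no FASTA records in ", path))
    meta <- purrr::map(names(set), parse_fasta_header)
    seqs <- unname(toupper(as.character(set)))
    meta <- list(
      id = map_chr(meta, "id"),
      species = map_chr(meta, "species"),
      region = map_chr(meta, "region"),
      source = map_chr(meta, "source")
    )
  }
  if (rna_as_dna) seqs <- gsub("U", "T", seqs, fixed = TRUE)
  gapped <- fmt %in% c("aligned_fasta", "clustal")
  if (!gapped && any(grepl("-", seqs, fixed = TRUE))) {
    abort("gap characters found; use fmt = \"aligned_fasta\" for alignments")
  }
  rec <- sequence_records(meta$id, seqs, species = meta$species,
                          region = meta$region, source = meta$source,
                          gapped = gapped)
  if (gapped) new_alignment(rec, coordinate_name = coordinate_name) else rec
}

#' Write sequence records (or an alignment) as FASTA
#'
#' Headers carry `species=`, `region=` and `source=` tokens so that
#' read/write round trips are identity.
#'
#' @param records Sequence-record tibble or `"mult_alignment"`.
#' @param path Output file.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, width = 70) {
  hdr <- paste0(
    ">", records$id,
    ifelse(records$species != "unknown",
           paste0(" species=", gsub(" ", "_", records$species)), ""),
    ifelse(records$region != "other", paste0(" region=", records$region), ""),
    ifelse(nzchar(records$source),
           paste0(" source=", gsub(" ", "_", records$source)), "")
  )
  body <- map(records$sequence, function(s) {
    starts <- seq(1, nchar(s), by = width)
    substring(s, starts, pmin(starts + width - 1, nchar(s)))
  })
  out <- unlist(map2(hdr, body, function(h, b) c(h, b)))
  readr::write_lines(out, path)
  invisible(path)
}

its_levels <- c("PASS", "MATCH_ADULTERANT", "FAIL", "NO_DATA")
stem_levels <- c("LONG", "SHORT", "SHORT_AAA", "NO_DATA")

#' Read a per-sample character table
#'
#' Reads the TSV dialect used for recording per-sample barcode characters:
#' columns `sample_id`, `nominal_species`, `its_result` (tokens `Yes`, `No`,
#' blank), optional `its_closest` (binomial the failed ITS sequence was most
#' similar to), `stem_class` (tokens `L`, `S`, `Sa`, and lowercase `s`,
#' normalised to `SHORT`), `rbcl_label` (e.g. `1`, `1p`, `1(p)`, `1-2`, `2`;
#' blank for no data). A `No` ITS token maps to `MATCH_ADULTERANT` when
#' `its_closest` names a species, and to `FAIL` otherwise. Extra columns are
#' passed through untouched. Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return Tibble with `its_result` and `stem_class` as enum strings and
#'   `rbcl_label` with `NA` for missing data.
#' @export
read_character_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         na = character())
  need <- c("sample_id", "nominal_species", "its_result", "stem_class", "rbcl_label")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("character table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"its_closest" %in% names(raw)) raw$its_closest <- ""
  if (anyDuplicated(raw$sample_id)) abort("duplicate sample_id in character table")

  map_its <- function(tok, closest, row) {
    tok <- trimws(tok)
    if (tok == "Yes") return("PASS")
    if (tok == "") return("NO_DATA")
    if (tok == "No") {
      return(if (nzchar(trimws(closest))) "MATCH_ADULTERANT" else "FAIL")
    }
    abort(paste0("row ", row, ": unknown ITS token '", tok, "'"))
  }
  map_stem <- function(tok, row) {
    tok <- trimws(tok)
    if (tok == "L") return("LONG")
    if (tok %in% c("S", "s")) return("SHORT")
    if (tok == "Sa") return("SHORT_AAA")
    if (tok == "") return("NO_DATA")
    abort(paste0("row ", row, ": unknown stem-loop token '", tok, "'"))
  }
  n_row <- nrow(raw)
  its <- vapply(seq_len(n_row),
                function(i) map_its(raw$its_result[i], raw$its_closest[i], i), "")
  stem <- vapply(seq_len(n_row), function(i) map_stem(raw$stem_class[i], i), "")
  raw %>%
    mutate(
      its_result = its,
      its_closest = ifelse(nzchar(trimws(.data$its_closest)),
                           trimws(.data$its_closest), NA_character_),
      stem_class = stem,
      rbcl_label = ifelse(nzchar(trimws(.data$rbcl_label)),
                          trimws(.data$rbcl_label), NA_character_)
    )
}

#' Write a verdict report
#'
#' Writes the verdict table as TSV (deterministic column order, `#` header
#' stating the coordinate convention) plus a human-readable summary with
#' per-code tallies alongside (`<path>` with extension replaced by
#' `_summary.txt`). Re-running on the same input is byte-identical.
#'
#' @param verdicts Tibble from [decide_identity()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_verdict_report <- function(verdicts, path) {
  lead <- c("sample_id", "nominal_species", "its_result", "stem_class",
            "rbcl_label", "code", "rationale")
  cols <- c(intersect(lead, names(verdicts)), setdiff(names(verdicts), lead))
  out <- verdicts[, cols]
  hdr <- c("# herbarcode verdict report",
           "# coordinates: 1-based inclusive")
  readr::write_lines(hdr, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)

  tal <- if (nrow(verdicts) > 0) {
    verdicts %>% count(.data$nominal_species, .data$code) %>%
      arrange(.data$nominal_species, .data$code)
  } else {
    tibble(nominal_species = character(), code = character(), n = integer())
  }
  sum_path <- sub("\\.[^.]*$", "", path)
  sum_path <- paste0(sum_path, "_summary.txt")
  lines <- c("herbarcode verdict summary",
             paste0("samples: ", nrow(verdicts)),
             "code tallies (nominal species / code / n):",
             sprintf("  %-24s %-4s %d", tal$nominal_species, tal$code, tal$n))
  readr::write_lines(lines, sum_path)
  invisible(path)
}
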