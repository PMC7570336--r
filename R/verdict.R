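# Multi-locus identification verdicts. Primary evidence is the ITS match
# against the target-species reference barcode; the psbA stem-loop class and
# rbcL haplotype corroborate. Codes: M = confirmed adulterant, m = possible
# adulterant, P = confirmed target, p = possible target, U = undetermined.

#' The verdict rule cascade
#'
#' Returns the active rules, in firing order, as a tibble — the audit
#' surface behind [decide_identity()] (`--rules` in the command-line tool).
#'
#' @return Tibble with `rule`, `condition`, `code`.
#' @export
verdict_rules <- function() {
  tibble::tribble(
    ~rule, ~condition, ~code,
    "R1", "ITS matches the target reference barcode", "P",
    "R2a", "ITS matched an adulterant reference; long stem; rbcL not the anomalous intermediate (1-2)", "M",
    "R2b", "ITS matched an adulterant reference; short stem or intermediate rbcL", "m",
    "R3", "ITS sequenced but matched no reference (failed criteria)", "U",
    "R4a", "no ITS data; short stem (deletion present)", "p",
    "R4b", "no ITS data; long stem; nominally the adulterant", "m",
    "R4c", "no ITS data; long stem; nominally the target", "U",
    "R4d", "no ITS data; no stem data", "U"
  )
}

decide_one <- function(its_result, stem_class, rbcl_label, nominal_is_target) {
  short <- stem_class %in% c("SHORT", "SHORT_AAA")
  if (its_result == "PASS") {
    return(c("P", "R1: ITS matches the target reference barcode"))
  }
  if (its_result == "MATCH_ADULTERANT") {
    if (stem_class == "LONG" && (is.na(rbcl_label) || rbcl_label != "1-2")) {
      return(c("M", "R2a: adulterant ITS match corroborated by long stem"))
    }
    return(c("m", paste0("R2b: adulterant ITS match, but ",
                         if (stem_class != "LONG") "stem not long"
                         else "anomalous intermediate rbcL haplotype")))
  }
  if (its_result == "FAIL") {
    return(c("U", "R3: ITS sequence met no reference criteria"))
  }
  # NO_DATA
  if (short) {
    return(c("p", "R4a: no ITS data; short stem consistent with target"))
  }
  if (stem_class == "LONG") {
    if (!nominal_is_target) {
      return(c("m", "R4b: no ITS data; long stem consistent with nominal adulterant"))
    }
    return(c("U", "R4c: no ITS data; long stem contradicts nominal target"))
  }
  c("U", "R4d: no evidence")
}

#' Decide sample identity from the multi-locus characters
#'
#' Applies the rule cascade (see [verdict_rules()]) to each row of a
#' character table: ITS result first, then the stem-loop class, with the
#' rbcL haplotype acting only as the corroborating character that downgrades
#' a confirmed adulterant call to "possible" when the anomalous intermediate
#' (`1-2`) haplotype is seen. Rows with no ITS data are resolved on the stem
#' class, asymmetrically by nominal identity: a long stem confirms a nominal
#' adulterant as "possible adulterant" but leaves a nominal target
#' undetermined. This asymmetric no-ITS rule is reconstructed from observed
#' test-collection outcomes rather than stated methodology.
#'
#' @param chars Character-table tibble (see [read_character_table()]).
#' @param target Binomial (or label) counted as the target species in
#'   `nominal_species`; everything else is treated as a nominal adulterant.
#' @return `chars` with `code` and `rationale` columns appended.
#' @export
decide_identity <- function(chars, target = "H. perforatum") {
  need <- c("its_result", "stem_class", "rbcl_label", "nominal_species")
  missing_cols <- setdiff(need, names(chars))
  if (length(missing_cols)) {
    abort(paste0("character table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(chars$its_result, its_levels)
  if (length(bad)) abort(paste0("invalid its_result value: ", bad[1]))
  bad <- setdiff(chars$stem_class, stem_levels)
  if (length(bad)) abort(paste0("invalid stem_class value: ", bad[1]))
  if (nrow(chars) == 0) {
    chars$code <- character(0)
    chars$rationale <- character(0)
    return(chars)
  }
  out <- t(mapply(decide_one, chars$its_result, chars$stem_class,
                  chars$rbcl_label, chars$nominal_species == target))
  chars$code <- unname(out[, 1])
  chars$rationale <- unname(out[, 2])
  chars
}

#' Tally verdicts and supporting characters
#'
#' @param verdicts Output of [decide_identity()].
#' @return Object of class `"verdict_tally"`: a list of tibbles `by_code`
#'   (per nominal species and code), `stem` (stem-class tallies per nominal
#'   species), `its` (ITS-result tallies), and `n` (samples).
#' @export
tally_verdicts <- function(verdicts) {
  empty <- function(...) tibble(nominal_species = character(), ...)
  structure(
    list(
      by_code = if (nrow(verdicts)) count(verdicts, .data$nominal_species, .data$code)
                else empty(code = character(), n = integer()),
      stem = if (nrow(verdicts)) count(verdicts, .data$nominal_species, .data$stem_class)
             else empty(stem_class = character(), n = integer()),
      its = if (nrow(verdicts)) count(verdicts, .data$nominal_species, .data$its_result)
            else empty(its_result = character(), n = integer()),
      n = nrow(verdicts)
    ),
    class = "verdict_tally"
  )
}

#' @export
print.verdict_tally <- function(x, ...) {
  cat("<verdict tally>", x$n, "samples\n")
  print(as.data.frame(x$by_code))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a verdict tally
#'
#' @param x `"verdict_tally"`.
#' @param ... Unused.
#' @return Long tibble `nominal_species`, `code`, `n`.
#' @export
tidy.verdict_tally <- function(x, ...) x$by_code

#' One-row summary of a verdict tally
#'
#' @param x `"verdict_tally"`.
#' @param ... Unused.
#' @return One-row tibble with totals per code and `n_samples`.
#' @export
glance.verdict_tally <- function(x, ...) {
  wide <- x$by_code %>%
    group_by(.data$code) %>% summarise(n = sum(.data$n)) %>%
    tidyr::pivot_wider(names_from = "code", values_from = "n")
  bind_cols(tibble(n_samples = x$n), wide)
}

#' Tidy a match result
#'
#' @param x `"match_result"`.
#' @param ... Unused.
#' @return Per-segment tibble with pass/identity columns.
#' @export
tidy.match_result <- function(x, ...) {
  x$per_segment %>%
    mutate(reference = x$reference, orientation = x$orientation)
}

#' One-row summary of a match result
#' @param x `"match_result"`.
#' @param ... Unused.
#' @export
glance.match_result <- function(x, ...) {
  tibble(reference = x$reference, passed = x$passed,
         overall_identity = x$overall_identity, threshold = x$threshold,
         n_essential_failures = nrow(x$essential_failures),
         orientation = x$orientation)
}
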