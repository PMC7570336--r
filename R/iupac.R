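# IUPAC nucleotide ambiguity handling. Comparisons throughout the package are
# "compatibility" checks: two codes are compatible iff their expansions share
# at least one base. Gaps ("-") expand to nothing and are never compatible.

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# reverse lookup: sorted base set -> minimal single code
IUPAC_CODE_FOR <- local({
  m <- vapply(IUPAC_EXPANSION, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(m), m)
})

#' Expand an IUPAC nucleotide code to the set of bases it covers
#'
#' @param code Single-character IUPAC code (case-insensitive). `"U"` is
#'   treated as `"T"`; `"-"` expands to an empty set.
#' @return Character vector of bases from `A`, `C`, `G`, `T`.
#' @export
#' @examples
#' iupac_expand("R")
iupac_expand <- function(code) {
  code <- toupper(code)
  if (code == "U") code <- "T"
  if (code == "-" || code == ".") return(character(0))
  out <- IUPAC_EXPANSION[[code]]
  if (is.null(out)) abort(paste0("not an IUPAC nucleotide code: '", code, "'"))
  out
}

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases Character vector over `A`, `C`, `G`, `T` (duplicates allowed).
#' @return Single IUPAC letter.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  bases[bases == "U"] <- "T"
  key <- paste(bases, collapse = "")
  out <- IUPAC_CODE_FOR[[key]]
  if (is.null(out)) abort(paste0("no IUPAC code for base set {", key, "}"))
  out
}

#' Are two IUPAC codes compatible?
#'
#' Compatibility means the expansions intersect; a gap is compatible with
#' nothing. Vectorised over equal-length inputs.
#'
#' @param a,b Character vectors of single IUPAC codes.
#' @return Logical vector.
#' @export
iupac_compatible <- function(a, b) {
  stopifnot(length(a) == length(b))
  mapply(function(x, y) {
    ex <- tryCatch(iupac_expand(x), error = function(e) NULL)
    ey <- tryCatch(iupac_expand(y), error = function(e) NULL)
    if (is.null(ex) || is.null(ey)) return(NA)
    length(intersect(ex, ey)) > 0
  }, a, b, USE.NAMES = FALSE)
}

is_iupac <- function(chars) {
  toupper(chars) %in% c(names(IUPAC_EXPANSION), "U")
}

# split a sequence string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(x) {
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", U = "A",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
  )
  ch <- rev(seq_chars(toupper(x)))
  paste(comp[ch], collapse = "")
}
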