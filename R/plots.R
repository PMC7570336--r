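#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a hotspot scan
#'
#' Window variability scores along the alignment, flagged hotspot windows
#' highlighted.
#'
#' @param object `"hotspot_scan"` from [scan_hotspots()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hotspot_scan <- function(object, ...) {
  ggplot(object, aes(x = (.data$start + .data$end) / 2, y = .data$score)) +
    geom_line(colour = "grey40") +
    geom_point(aes(colour = .data$flagged), size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "hotspot") +
    labs(x = "alignment position (1-based)", y = "variable-column fraction") +
    theme_minimal()
}

#' Plot a verdict tally
#'
#' Identification-code counts per nominal species.
#'
#' @param object `"verdict_tally"` from [tally_verdicts()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.verdict_tally <- function(object, ...) {
  ggplot(object$by_code, aes(x = .data$code, y = .data$n)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~nominal_species) +
    labs(x = "identification code", y = "samples") +
    theme_minimal()
}

#' Plot a reference-barcode match result
#'
#' Per-segment identity against the overall threshold; essential-base
#' failures annotated in the subtitle.
#'
#' @param object `"match_result"` from [match_reference()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.match_result <- function(object, ...) {
  ggplot(object$per_segment, aes(x = .data$segment, y = .data$identity)) +
    geom_col(fill = if (object$passed) "seagreen" else "firebrick") +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    labs(
      title = paste0(object$reference, ": ",
                     if (object$passed) "PASS" else "FAIL"),
      subtitle = paste0("overall identity ",
                        sprintf("%.3f", object$overall_identity),
                        "; essential failures: ",
                        nrow(object$essential_failures)),
      x = NULL, y = "segment identity"
    ) +
    theme_minimal()
}

#' Plot a folded stem-loop
#'
#' Simple base-pair arc rendering of the extracted hairpin: positions along
#' the x axis, pairs as arcs, apex loop marked.
#'
#' @param object `"stem_loop"` from [extract_stem_loop()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stem_loop <- function(object, ...) {
  pm <- parse_dotbracket(object$structure)
  pairs <- tibble(i = which(!is.na(pm) & seq_along(pm) < pm),
                  j = pm[which(!is.na(pm) & seq_along(pm) < pm)])
  arc <- purrr::pmap(pairs, function(i, j) {
    t <- seq(0, pi, length.out = 30)
    tibble(x = (i + j) / 2 + (j - i) / 2 * cos(t),
           y = (j - i) / 2 * sin(t), grp = paste(i, j))
  }) %>% bind_rows()
  bases <- tibble(x = seq_len(nchar(object$sequence)), y = 0,
                  base = seq_chars(object$sequence))
  ggplot() +
    geom_line(data = arc, aes(x = .data$x, y = .data$y, group = .data$grp),
              colour = "grey50") +
    geom_point(data = bases, aes(x = .data$x, y = .data$y), size = 0.8) +
    labs(title = paste0(object$class, " stem-loop (", object$stem_bp,
                        " bp stem, apex ", object$loop_seq, ")"),
         x = "position in extracted region", y = NULL) +
    theme_minimal()
}
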