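# Synthetic panel and test-collection generator. Emulates the statistical
# structure the authentication methods assume — a panel of congeneric
# species carrying species-specific SNPs on a shared backbone, intraspecific
# subtypes, core + marker chloroplast haplotypes, and a psbA spacer whose
# diagnostic deletion truncates the hairpin stem — so every module is
# testable offline with exact planted truth. Randomness uses R's
# Mersenne-Twister via a single seed; substitution noise is kept off the
# planted columns so truth bookkeeping stays exact, and indels occur only in
# the psbA flanks, where the emulated region is known for them.

#' Configuration for the synthetic generator
#'
#' Defaults emulate the case-study panel: 20 congeneric species, 2
#' accessions each, a ~300-column ITS-like alignment, 2 planted
#' species-specific SNPs per species, 3 subtypes for the target and 2 for
#' the adulterant (subtype templates differing at 7 planted columns), and
#' zero substitution noise.
#'
#' @param seed Integer seed (all randomness flows from it).
#' @param n_species Panel size.
#' @param n_accessions Accessions per species (per subtype for the species
#'   with subtypes).
#' @param sites Alignment columns.
#' @param species_snp_count Planted species-specific SNPs per species.
#' @param subtype_counts Named integer vector: subtypes per species (others
#'   get 1).
#' @param subtype_cols Columns at which subtype templates differ.
#' @param noise_rate Expected random substitutions per sequence (applied
#'   off the planted columns).
#' @param its_dropout Fraction of test samples with no ITS sequence
#'   (emulating the ~70% sequencing success rate of the test collection).
#' @param n_test_target,n_test_adulterant Test-collection sizes.
#' @param target,adulterant Species names used for test collections.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_species = 20, n_accessions = 2,
                       sites = 300, species_snp_count = 2,
                       subtype_counts = c("H. perforatum" = 3,
                                          "H. maculatum" = 2),
                       subtype_cols = 7, noise_rate = 0,
                       its_dropout = 0.3,
                       n_test_target = 22, n_test_adulterant = 16,
                       target = "H. perforatum",
                       adulterant = "H. maculatum") {
  if (n_species < 2) abort("panel needs at least two species")
  cfg <- list(seed = as.integer(seed), n_species = n_species,
              n_accessions = n_accessions, sites = sites,
              species_snp_count = species_snp_count,
              subtype_counts = subtype_counts, subtype_cols = subtype_cols,
              noise_rate = noise_rate, its_dropout = its_dropout,
              n_test_target = n_test_target,
              n_test_adulterant = n_test_adulterant,
              target = target, adulterant = adulterant)
  class(cfg) <- "sim_config"
  cfg
}

sim_rng <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

#' Generate a synthetic panel alignment with planted truth
#'
#' Builds an ancestral sequence, plants `species_snp_count` species-specific
#' SNPs per species at disjoint columns (each species' diagnostic state
#' differs from the shared ancestral state carried by everyone else),
#' derives subtype templates for the species configured to have them
#' (differing at `subtype_cols` planted columns), and emits `n_accessions`
#' rows per subtype with optional off-plant substitution noise.
#'
#' @param cfg `"sim_config"`.
#' @return List: `alignment` (`"mult_alignment"` with species labels),
#'   `truth` with `sites` (tibble `species`, `position`, `state`),
#'   `subtypes` (tibble `id`, `species`, `subtype`), `templates` (tibble
#'   `species`, `subtype`, `sequence`).
#' @export
generate_panel <- function(cfg) {
  sim_rng(cfg$seed)
  n_sub_total <- sum(pmax(cfg$subtype_counts - 1, 0))
  need <- cfg$n_species * cfg$species_snp_count +
    length(cfg$subtype_counts) * cfg$subtype_cols
  if (need > cfg$sites) abort("infeasible config: more planted columns than sites")
  species <- panel_species_names(cfg$n_species, cfg$target, cfg$adulterant)
  ancestral <- sample(c("A", "C", "G", "T"), cfg$sites, replace = TRUE)
  free_cols <- sample(cfg$sites)         # random order, consumed left to right
  take <- function(k) {
    out <- free_cols[seq_len(k)]
    free_cols <<- free_cols[-seq_len(k)]
    sort(out)
  }

  sites_truth <- list()
  templates <- list()
  rows <- list()
  for (sp in species) {
    snp_pos <- take(cfg$species_snp_count)
    snp_state <- vapply(snp_pos, function(p) sample(other_bases(ancestral[p]), 1), "")
    sites_truth[[sp]] <- tibble(species = sp, position = snp_pos,
                                state = snp_state)
    base_seq <- ancestral
    base_seq[snp_pos] <- snp_state
    n_sub <- if (sp %in% names(cfg$subtype_counts)) cfg$subtype_counts[[sp]] else 1
    sub_pos <- if (n_sub > 1) take(cfg$subtype_cols) else integer(0)
    for (k in seq_len(n_sub)) {
      tmpl <- base_seq
      if (n_sub > 1 && k > 1) {
        # each non-first subtype carries its own planted pattern at sub_pos
        tmpl[sub_pos] <- vapply(sub_pos, function(p) {
          other_bases(ancestral[p])[(k - 1 + p) %% 3 + 1]
        }, "")
      }
      lab <- as.character(utils::as.roman(k))
      templates[[paste(sp, k)]] <- tibble(species = sp, subtype = lab,
                                          sequence = paste(tmpl, collapse = ""))
      for (a in seq_len(cfg$n_accessions)) {
        acc <- tmpl
        if (cfg$noise_rate > 0) {
          n_mut <- stats::rpois(1, cfg$noise_rate)
          if (n_mut > 0) {
            protected <- c(unlist(map(sites_truth, "position")), sub_pos)
            cand <- setdiff(seq_len(cfg$sites), protected)
            mut <- sample(cand, min(n_mut, length(cand)))
            acc[mut] <- vapply(mut, function(p) sample(other_bases(acc[p]), 1), "")
          }
        }
        rows[[paste(sp, k, a)]] <- tibble(
          id = paste0(gsub("[^A-Za-z]", "", sp), "_", k, "_", a),
          species = sp, subtype = lab,
          sequence = paste(acc, collapse = "")
        )
      }
    }
  }
  rows <- bind_rows(rows)
  aln <- new_alignment(
    sequence_records(rows$id, rows$sequence, species = rows$species,
                     region = "ITS", source = "synthetic", gapped = TRUE),
    coordinate_name = "synthetic-panel-v1"
  )
  list(
    alignment = aln,
    truth = list(
      sites = bind_rows(sites_truth),
      subtypes = rows[, c("id", "species", "subtype")],
      templates = bind_rows(templates)
    )
  )
}

panel_species_names <- function(n, target, adulterant) {
  tbl <- tryCatch(panel_species(), error = function(e) NULL)
  pool <- if (!is.null(tbl)) tbl$species else character(0)
  pool <- unique(c(target, adulterant, pool,
                   paste0("Synthetic species ", seq_len(max(0, n)))))
  pool[seq_len(n)]
}

#' The packaged adulterant-panel metadata table
#'
#' The 20-species restricted panel: attribution, section, Robson and
#' Meseguer clades, selection flags (close relative / medicinal listing /
#' horticultural / reported adulterant) and the published CBC count of each
#' species' ITS2 structure relative to the target (NA where no structure
#' was modelled).
#'
#' @return Tibble, one row per panel species.
#' @export
panel_species <- function() {
  path <- system.file("extdata", "panel_species.tsv", package = "herbarcode",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    species = "c", attribution = "c", section = "c", robson_clade = "c",
    meseguer_clade = "c", rel = "l", mpns = "l", cult = "l", adult = "l",
    cbc_vs_target = "i"
  ))
}

#' The packaged test-collection character table (38 samples)
#'
#' Transcription of the published test-collection character table: 22
#' nominal target and 16 nominal adulterant samples with their ITS match
#' outcome, stem-loop class token and rbcL label, plus the printed final
#' identification code in `reported_id`. Ships as a checked-in fixture
#' because it is the regression surface for the verdict engine.
#'
#' @param raw Return the raw token TSV instead of the parsed table.
#' @return Parsed character-table tibble (see [read_character_table()]).
#' @export
table5_samples <- function(raw = FALSE) {
  path <- system.file("extdata", "test_collection_characters.tsv",
                      package = "herbarcode", mustWork = TRUE)
  if (raw) {
    return(readr::read_tsv(path, comment = "#",
                           col_types = readr::cols(.default = "c"),
                           na = character()))
  }
  read_character_table(path)
}

#' Canonical key states for a printed haplotype label
#'
#' Inverse of [assign_haplotype()] for the labels the haplotype key can
#' print: returns the representative state vector that carries exactly the
#' core pattern and marker SNPs the label encodes.
#'
#' @param label One of `"1"`, `"1(p)"`, `"1p"`, `"2"`, `"1-2"`.
#' @param key `"haplotype_key"`.
#' @return Named state vector over the key positions.
#' @export
haplotype_states_for_label <- function(label, key = rbcl_key()) {
  states <- key$consensus[as.character(key$positions)]
  set_states <- function(req) { states[names(req)] <<- req; states }
  core1 <- key$core_types[[which(map_chr(key$core_types, "label") == "1")]]
  core2 <- key$core_types[[which(map_chr(key$core_types, "label") == "2")]]
  # the representative type-1 pattern carries the common 180=T as well
  full1 <- c(core1$required_states, "180" = "T")
  markers <- setNames(key$marker_snps$state, as.character(key$marker_snps$position))
  switch(label,
    "1" = set_states(full1),
    "1(p)" = set_states(c(full1, markers[1])),
    "1p" = set_states(c(full1, markers)),
    "2" = set_states(core2$required_states),
    "1-2" = states,
    abort(paste0("no canonical states for label '", label, "'"))
  )
}

# deterministic A/T-rich flank with homopolymer stretches
at_flank <- function(n_runs) {
  runs <- map_chr(seq_len(n_runs), function(i) {
    strrep(sample(c("A", "T"), 1), sample(3:8, 1))
  })
  paste(runs, collapse = "")
}

#' Generate synthetic psbA-trnH spacer variants
#'
#' Emits full spacer sequences: A/T-rich flanks with homopolymer-length
#' jitter and optional random long insertions (the region's characteristic
#' noise), conserved anchor motifs, and between them either the long
#' (extended-stem) or short (deletion-truncated, three-base apex) stem-loop
#' archetype. The apex of short variants is `AAA` or `UUU`.
#'
#' @param n_long,n_short Number of variants of each class.
#' @param seed Integer seed.
#' @param apex Apex options for short variants.
#' @param insertion_rate Probability of a random long insertion in a flank.
#' @return Sequence-record tibble with a `truth` attribute (tibble `id`,
#'   `class`, `apex`).
#' @export
generate_stem_variants <- function(n_long = 5, n_short = 5, seed = 1,
                                   apex = c("AAA", "TTT"),
                                   insertion_rate = 0.3) {
  sim_rng(seed)
  arch <- psba_archetypes()
  anchors <- psba_anchors()
  a3 <- gsub("W", "A", anchors$three_prime)
  mk <- function(i, class) {
    ap <- if (class == "short") sample(apex, 1) else "AAA"
    region <- arch$sequence[arch$id == class]
    if (class == "short") region <- sub("AAA", ap, region, fixed = TRUE)
    ins <- function() {
      if (stats::runif(1) < insertion_rate) strrep(sample(c("A", "T"), 1), sample(10:20, 1)) else ""
    }
    seqstr <- paste0(at_flank(sample(2:4, 1)), ins(), anchors$five_prime,
                     region, a3, at_flank(sample(2:4, 1)), ins())
    tibble(id = paste0(class, "_", i), class = toupper(class), apex = ap,
           sequence = seqstr)
  }
  out <- bind_rows(
    map(seq_len(n_long), ~ mk(.x, "long")),
    map(seq_len(n_short), ~ mk(.x, "short"))
  )
  rec <- sequence_records(out$id, out$sequence, species = "synthetic",
                          region = "psbA-trnH", source = "synthetic")
  attr(rec, "truth") <- out[, c("id", "class", "apex")]
  rec
}

#' Generate a synthetic test collection
#'
#' Emits a per-sample character table (and, in sequence mode, synthetic
#' ITS / rbcL / psbA sequences consistent with the planted characters).
#' Nominal-target samples are planted as true targets (ITS passes unless
#' dropped out, short stem, `1p` haplotype); nominal-adulterant samples as
#' true adulterants (ITS matches the adulterant reference when sequenced,
#' long stem, type `1` haplotype). ITS dropout follows `cfg$its_dropout`.
#'
#' @param cfg `"sim_config"`.
#' @param sequences Also generate per-sample sequences.
#' @param ref Reference barcode used to expand target ITS sequences
#'   (default: the packaged synthetic standard).
#' @param key Haplotype key (default [rbcl_key()]).
#' @return List: `characters` (character-table tibble) and, in sequence
#'   mode, `its`, `rbcl`, `psba` sequence-record tibbles.
#' @export
generate_test_collection <- function(cfg, sequences = FALSE,
                                     ref = NULL, key = rbcl_key()) {
  sim_rng(cfg$seed + 1L)
  if (is.null(ref)) ref <- its_reference()
  n_t <- cfg$n_test_target; n_a <- cfg$n_test_adulterant
  samples <- tibble(
    sample_id = c(sprintf("target%02d", seq_len(n_t)),
                  sprintf("adult%02d", seq_len(n_a))),
    nominal_species = c(rep(cfg$target, n_t), rep(cfg$adulterant, n_a)),
    is_target = c(rep(TRUE, n_t), rep(FALSE, n_a))
  )
  dropout <- stats::runif(nrow(samples)) < cfg$its_dropout
  samples <- samples %>%
    mutate(
      its_result = dplyr::case_when(
        dropout ~ "NO_DATA",
        .data$is_target ~ "PASS",
        TRUE ~ "MATCH_ADULTERANT"
      ),
      its_closest = ifelse(.data$its_result == "MATCH_ADULTERANT",
                           cfg$adulterant, NA_character_),
      stem_class = ifelse(.data$is_target, "SHORT", "LONG"),
      rbcl_label = ifelse(.data$is_target, "1p", "1")
    )
  out <- list(characters = select(samples, -"is_target"))
  if (sequences) {
    tgt_seq <- expand_reference(ref)
    adu_seq <- mutate_essentials(ref, n = 2)
    its <- samples %>% filter(.data$its_result != "NO_DATA")
    out$its <- sequence_records(
      its$sample_id,
      ifelse(its$its_result == "PASS", tgt_seq, adu_seq),
      species = its$nominal_species, region = "ITS", source = "synthetic"
    )
    rbcl_seqs <- map_chr(samples$rbcl_label, function(lab) {
      states <- haplotype_states_for_label(lab, key)
      ch <- seq_chars(key$reference)
      ch[key$positions] <- states
      paste(ch, collapse = "")
    })
    out$rbcl <- sequence_records(samples$sample_id, rbcl_seqs,
                                 species = samples$nominal_species,
                                 region = "rbcL", source = "synthetic")
    stems <- generate_stem_variants(n_long = sum(!samples$is_target),
                                    n_short = sum(samples$is_target),
                                    seed = cfg$seed + 2L)
    truth <- attr(stems, "truth")
    ord <- c(which(truth$class == "SHORT"), which(truth$class == "LONG"))
    psba <- stems[ord, ][seq_len(nrow(samples)), ]
    psba$id <- c(samples$sample_id[samples$is_target],
                 samples$sample_id[!samples$is_target])
    out$psba <- psba
  }
  out
}

#' Synthetic clade-gradient ITS2 structure panel for CBC counting
#'
#' Builds structured sequences in a common ungapped frame sharing one
#' hairpin (8-pair stem, 4-base loop): the target structure plus one
#' structure per panel species with a published CBC count, carrying exactly
#' that many planted compensatory changes (G-C pairs flipped to C-G) so the
#' clade gradient of the published counts is reproduced qualitatively.
#' Species without a modelled structure are omitted.
#'
#' @return List: `target` (`"structured_sequence"`), `panel` (tibble
#'   `species`, `meseguer_clade`, `cbc_planted`, `ss` list-column).
#' @export
cbc_demo_panel <- function() {
  pan <- panel_species()
  pan <- pan[!is.na(pan$cbc_vs_target) & pan$species != "H. perforatum", ]
  left <- "GGGGGGGG"; loop <- "AUCA"; right <- "CCCCCCCC"
  db <- "((((((((....))))))))"
  base_seq <- paste0(left, loop, right)
  target <- structured_sequence(base_seq, db)
  mk <- function(k) {
    ch <- seq_chars(gsub("T", "U", base_seq))
    n <- nchar(base_seq)
    for (i in seq_len(k)) {          # flip pair i: G-C -> C-G
      j <- n - i + 1
      ch[i] <- "C"; ch[j] <- "G"
    }
    structured_sequence(paste(ch, collapse = ""), db)
  }
  panel <- pan %>%
    mutate(cbc_planted = .data$cbc_vs_target,
           ss = map(.data$cbc_vs_target, mk)) %>%
    select("species", "meseguer_clade", "cbc_planted", "ss")
  list(target = target, panel = panel)
}

#' The packaged synthetic ITS reference barcode
#'
#' A two-segment case-encoded reference standard with the structural
#' properties of a pharmacopoeial barcode (lowercase essential bases,
#' ambiguity codes for intraspecific polymorphism, 95% overall threshold).
#' The base string is synthetic: the published figure is not
#' machine-readable.
#'
#' @return `"reference_barcode"`.
#' @export
its_reference <- function() {
  parse_reference_barcode(system.file("extdata", "its_reference_synthetic.txt",
                                      package = "herbarcode", mustWork = TRUE))
}

# one concrete expansion of a reference barcode (first base of each
# ambiguity code), segments joined by a short linker
expand_reference <- function(ref, linker = "ACGTACGT") {
  segs <- map_chr(ref$segments$pattern, function(p) {
    paste(vapply(seq_chars(p), function(c) iupac_expand(c)[1], ""), collapse = "")
  })
  paste(segs, collapse = linker)
}

# expansion with n essential bases per segment mutated to incompatible states
mutate_essentials <- function(ref, n = 2, linker = "ACGTACGT") {
  segs <- map2_chr(ref$segments$pattern, ref$segments$essential_mask,
                   function(p, mask) {
    ch <- vapply(seq_chars(p), function(c) iupac_expand(c)[1], "")
    ess <- which(mask)[seq_len(min(n, sum(mask)))]
    for (i in ess) {
      ch[i] <- setdiff(c("A", "C", "G", "T"),
                       iupac_expand(substr(p, i, i)))[1]
    }
    paste(ch, collapse = "")
  })
  paste(segs, collapse = linker)
}
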