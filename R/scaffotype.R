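#' Assemble a cross-species orthology table
#'
#' Turns per-species segment maps (each species aligned to the same
#' reference) into a scaffotype table: for every reference chromosome, the
#' ordered list of orthologous target-scaffold fragments per species.
#' Fragment letters are assigned with [name_fragments()]. Overlapping claims
#' by one species on a reference interval are an error — assignments are
#' required to be unambiguous.
#'
#' @param segment_maps Named list (species -> segment tibble from
#'   [build_segment_map()]) or one tibble with a `species` column.
#' @param similarities Optional per-segment similarity tibble from
#'   [segment_similarity()] with a `species` column; joined on
#'   `(species, segment_id)`.
#' @param warn_threshold Segments with `eig_similarity` below this are
#'   flagged (`low_similarity = TRUE`), never removed (default 0.5).
#' @param species_meta Optional tibble (`species`, `family`, `diploid_2n`).
#' @return An object of class `scaffotype_table`: list with `fragments`
#'   (long tibble) and `species_meta`.
#' @export
assign_orthology <- function(segment_maps, similarities = NULL,
                             warn_threshold = 0.5, species_meta = NULL) {
  if (is.data.frame(segment_maps)) {
    if (!"species" %in% names(segment_maps)) {
      abort("segment_maps must carry a species column or be a named list")
    }
    segment_maps <- split(segment_maps, segment_maps$species)
  }
  frags <- purrr::imap(segment_maps, function(seg, sp) {
    seg <- as_tibble(seg)
    seg$species <- sp
    seg
  }) |> bind_rows()

  # unambiguity: within one species + ref chromosome, intervals must not overlap
  conflicts <- frags |>
    group_by(.data$species, .data$ref_chrom) |>
    arrange(.data$ref_start, .by_group = TRUE) |>
    filter(dplyr::lag(.data$ref_end, default = -Inf) > .data$ref_start) |>
    ungroup()
  if (nrow(conflicts) > 0) {
    c1 <- conflicts[1, ]
    abort(sprintf(
      "conflicting orthology claims: species %s has overlapping segments on %s near %g",
      c1$species, c1$ref_chrom, c1$ref_start))
  }

  frags <- frags |>
    group_by(.data$species, .data$ref_chrom) |>
    arrange(.data$ref_start, .by_group = TRUE) |>
    mutate(order_on_ref = row_number()) |>
    ungroup()

  if (!is.null(similarities)) {
    frags <- left_join(frags,
                       select(similarities, "species", "segment_id",
                              eig_similarity = "r"),
                       by = c("species", "segment_id"))
  } else {
    frags$eig_similarity <- NA_real_
  }
  frags$low_similarity <- is.finite(frags$eig_similarity) &
    frags$eig_similarity < warn_threshold

  tab <- structure(list(fragments = frags, species_meta = species_meta,
                        species_order = names(segment_maps)),
                   class = "scaffotype_table")
  name_fragments(tab)
}

#' Assign fragment letters
#'
#' Scaffolds mapping to a single segment get no letter; scaffolds split into
#' `k >= 2` segments get letters `a..` in order of ascending target start
#' (so the letter encodes position along the scaffold, independently of any
#' table ordering). Beyond 26 fragments, double letters (`aa`, `ab`, ...)
#' are used.
#'
#' @param table A `scaffotype_table`.
#' @return The table with `fragment_letter` and `fragment_name` columns
#'   recomputed.
#' @export
name_fragments <- function(table) {
  stopifnot(inherits(table, "scaffotype_table"))
  frags <- table$fragments |>
    group_by(.data$species, .data$tgt_scaffold) |>
    arrange(.data$tgt_start, .by_group = TRUE) |>
    mutate(.k = n(),
           fragment_letter = ifelse(.data$.k == 1, "",
                                    index_to_letters(row_number()))) |>
    ungroup() |>
    mutate(fragment_name = paste0(.data$tgt_scaffold,
                                  .data$fragment_letter)) |>
    select(-".k") |>
    arrange(.data$species, .data$ref_chrom, .data$order_on_ref)
  table$fragments <- frags
  table
}

#' @export
print.scaffotype_table <- function(x, ...) {
  cat("<scaffotype_table>",
      dplyr::n_distinct(x$fragments$species), "species x",
      dplyr::n_distinct(x$fragments$ref_chrom), "reference chromosomes,",
      nrow(x$fragments), "fragments\n")
  invisible(x)
}

#' @rdname assign_orthology
#' @param x A `scaffotype_table`.
#' @param ... Unused.
#' @method tidy scaffotype_table
#' @export
tidy.scaffotype_table <- function(x, ...) x$fragments

#' Render a scaffotype table in the one-row-per-reference-chromosome format
#'
#' One column per species; each cell joins that species' fragments on the
#' chromosome with `+`, in reference-coordinate order.
#'
#' @param table A `scaffotype_table`.
#' @param path Optional output path; when given the TSV is written there.
#' @return The wide tibble (invisibly when `path` is given).
#' @export
emit_table1 <- function(table, path = NULL) {
  stopifnot(inherits(table, "scaffotype_table"))
  wide <- table$fragments |>
    arrange(.data$species, .data$ref_chrom, .data$order_on_ref) |>
    group_by(.data$ref_chrom, .data$species) |>
    summarise(entry = paste(.data$fragment_name, collapse = "+"),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "entry",
                       values_fill = "")
  wide <- arrange(wide, order_chrom(.data$ref_chrom))
  sp_order <- intersect(table$species_order %||% names(wide), names(wide))
  wide <- wide[c("ref_chrom", sp_order)]
  if (!is.null(path)) {
    readr::write_tsv(wide, path)
    return(invisible(wide))
  }
  wide
}

# cat-style chromosome labels (A1..F2, X) sort by letter group then number;
# anything else sorts naturally
order_chrom <- function(ch) {
  m <- regmatches(ch, regexec("^([A-Za-z]*)([0-9]*)$", ch))
  grp <- vapply(m, function(x) if (length(x) == 3) x[2] else "", character(1))
  num <- suppressWarnings(vapply(m, function(x)
    if (length(x) == 3 && x[3] != "") as.numeric(x[3]) else Inf, double(1)))
  order(order(grp == "X", grp, num, ch))
}

#' Parse a scaffotype table from its printed form
#'
#' Reads the one-row-per-reference-chromosome TSV (first column the
#' reference chromosome, one column per species), splitting `+`-joined
#' fragment names into scaffold and letter. Whitespace around `+` is
#' tolerated. Round-trips through [emit_table1()] losslessly modulo
#' whitespace.
#'
#' @param path Path to the TSV (or a character vector of lines via `text`).
#' @param text Optional character vector of lines instead of `path`.
#' @param species_meta Optional species metadata tibble.
#' @return A `scaffotype_table`. Coordinates are unknown from the printed
#'   form, so `ref_start`/`tgt_start` columns encode only ordering.
#' @export
parse_table1 <- function(path = NULL, text = NULL, species_meta = NULL) {
  if (is.null(text)) {
    if (is.null(path)) abort("supply path or text")
    text <- readLines(path)
  }
  text <- text[!grepl("^\\s*(#|$)", text)]
  if (length(text) < 2) abort("table must have a header row and data rows")
  header <- strsplit(text[1], "\t")[[1]]
  species <- header[-1]
  rows <- strsplit(text[-1], "\t")
  frags <- list()
  for (r in seq_along(rows)) {
    f <- rows[[r]]
    ch <- trimws(f[1])
    for (s in seq_along(species)) {
      cell <- if (s + 1 <= length(f)) trimws(f[s + 1]) else ""
      if (cell == "") next
      toks <- trimws(strsplit(cell, "\\+")[[1]])
      toks <- toks[toks != ""]
      for (k in seq_along(toks)) {
        m <- regmatches(toks[k], regexec("^([0-9A-Za-z_.]*?)([a-z]*)$",
                                         toks[k]))[[1]]
        if (length(m) != 3 || m[2] == "") {
          abort(sprintf("malformed fragment token '%s' at row %d, column %d",
                        toks[k], r + 1, s + 1))
        }
        frags[[length(frags) + 1L]] <- tibble(
          species = species[s], ref_chrom = ch, order_on_ref = k,
          tgt_scaffold = m[2], fragment_letter = m[3],
          fragment_name = toks[k])
      }
    }
  }
  if (length(frags) == 0) abort("no fragments found in table")
  frags <- bind_rows(frags)
  # ordering surrogates for coordinates the printed table does not carry:
  # position along the reference follows column order; position along the
  # scaffold follows the fragment letter.
  frags <- frags |>
    mutate(ref_start = .data$order_on_ref - 1,
           ref_end = .data$order_on_ref,
           tgt_start = ifelse(.data$fragment_letter == "", 0,
                              letters_to_index(.data$fragment_letter) - 1),
           tgt_end = .data$tgt_start + 1,
           segment_id = row_number(),
           eig_similarity = NA_real_, low_similarity = FALSE)
  structure(list(fragments = frags, species_meta = species_meta,
                 species_order = species),
            class = "scaffotype_table")
}

letters_to_index <- function(s) {
  vapply(s, function(x) {
    if (x == "") return(0)
    ch <- strsplit(x, "")[[1]]
    sum((match(ch, letters)) * 26^(rev(seq_along(ch)) - 1))
  }, double(1), USE.NAMES = FALSE)
}

#' Summary statistics of a scaffotype table
#'
#' Per species group: the number of reference autosomes with a single whole
#' (unlettered) scaffold in every group member, the range of fragments per
#' reference chromosome, and per-species scaffold counts.
#'
#' @param table A `scaffotype_table`.
#' @param groups Optional named list (group -> character vector of species);
#'   defaults to one group per species, plus groups from
#'   `species_meta$family` when present.
#' @param sex_chroms Reference chromosomes treated as sex chromosomes
#'   (default `"X"`), excluded from the autosome 1:1 count.
#' @return A list with `by_group` (tibble: group, `n_autosomes_one_to_one`,
#'   `min_fragments`, `max_fragments`) and `by_species` (tibble: species,
#'   `n_scaffolds`, `n_fragments`).
#' @export
summarize_table <- function(table, groups = NULL, sex_chroms = "X") {
  stopifnot(inherits(table, "scaffotype_table"))
  frags <- table$fragments
  if (is.null(groups)) {
    if (!is.null(table$species_meta) &&
        "family" %in% names(table$species_meta)) {
      groups <- split(table$species_meta$species, table$species_meta$family)
    } else {
      groups <- as.list(setNames(unique(frags$species),
                                 unique(frags$species)))
    }
  }
  per_cell <- frags |>
    group_by(.data$species, .data$ref_chrom) |>
    summarise(n_frag = n(),
              one_to_one = n() == 1 && all(.data$fragment_letter == ""),
              .groups = "drop")
  by_group <- purrr::imap(groups, function(sp, g) {
    sub <- filter(per_cell, .data$species %in% sp,
                  !(.data$ref_chrom %in% sex_chroms))
    counts <- sub |>
      group_by(.data$ref_chrom) |>
      summarise(all_one = all(.data$one_to_one) &&
                  n() == length(sp), .groups = "drop")
    tibble(group = g,
           n_autosomes_one_to_one = sum(counts$all_one),
           min_fragments = min(sub$n_frag),
           max_fragments = max(sub$n_frag))
  }) |> bind_rows()
  by_species <- frags |>
    group_by(.data$species) |>
    summarise(n_scaffolds = dplyr::n_distinct(.data$tgt_scaffold),
              n_fragments = n(), .groups = "drop")
  list(by_group = by_group, by_species = by_species)
}

#' Recommend a scaffold naming scheme
#'
#' Encodes the published naming rules: the reference should be the most
#' ancestral karyotype in the clade and must have more than 90% of its
#' sequence anchored to chromosomes; reference-name adoption is only
#' appropriate when every reference chromosome is a 1:1 whole-scaffold
#' ortholog in every species, otherwise scaffolds should be named by size
#' rank with the orthology table as the lookup.
#'
#' @param table A `scaffotype_table`.
#' @param reference_anchored_fraction Fraction of the reference assembly
#'   anchored to chromosomes, in `[0, 1]`.
#' @param sex_chroms Sex chromosomes excluded from the 1:1 gate.
#' @return A list: `accepted` (logical), `scheme`
#'   (`"reference-name-adoption"`, `"size-rank"`, or `NA`), `message`.
#' @export
recommend_naming <- function(table, reference_anchored_fraction,
                             sex_chroms = "X") {
  if (reference_anchored_fraction <= 0.9) {
    return(list(accepted = FALSE, scheme = NA_character_,
                message = paste("reference rejected: requires > 90% of the",
                                "sequence anchored to chromosomes")))
  }
  per_cell <- table$fragments |>
    filter(!(.data$ref_chrom %in% sex_chroms)) |>
    group_by(.data$species, .data$ref_chrom) |>
    summarise(one_to_one = n() == 1 && all(.data$fragment_letter == ""),
              .groups = "drop")
  all_one <- nrow(per_cell) > 0 && all(per_cell$one_to_one)
  if (all_one) {
    list(accepted = TRUE, scheme = "reference-name-adoption",
         message = paste("full complement of 1:1 chromosome orthologs;",
                         "adopt reference chromosome names"))
  } else {
    list(accepted = TRUE, scheme = "size-rank",
         message = paste("1:1 complement violated; name scaffolds by size",
                         "rank and keep the orthology table as lookup"))
  }
}

#' Read the packaged carnivore orthology table
#'
#' The cross-species orthology table for 11 carnivores against the cat
#' reference, as published, transcribed as a plain TSV fixture, with species
#' family and diploid-number metadata.
#'
#' @return A `scaffotype_table` with `species_meta` populated.
#' @export
read_carnivore_table <- function() {
  tab <- system.file("extdata", "table1_3dcs.tsv", package = "scaffotyper")
  meta <- system.file("extdata", "table1_species.tsv", package = "scaffotyper")
  parse_table1(tab,
               species_meta = readr::read_tsv(meta, col_types = "ccd",
                                              progress = FALSE))
}
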