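# FASTA-based genome composition: base and dyad counting, count-based skews,
# and per-kingdom tolerance boxes estimated from genome cohorts.

#' Count bases and dyads in a FASTA file
#'
#' Counts A/C/G/T (case-insensitive; soft-masked lowercase counted
#' identically) and the 16 dyads on the forward strand of every record.
#' Ambiguity symbols (N etc.) are skipped and tallied; dyads spanning a
#' skipped symbol are not counted, so dyad counting restarts after each
#' ambiguous position (contiguous-segment rule). `dyad_mode = "sliding"`
#' counts all overlapping dimers; `"segmentation"` counts non-overlapping
#' dimers from position 1.
#'
#' @param fasta Path to a FASTA file (plain or gzip), or a
#'   `Biostrings::DNAStringSet`.
#' @param dyad_mode `"sliding"` or `"segmentation"`.
#' @param pooled Also append a pooled whole-file row (id `".pooled"`).
#' @return A tibble with columns `id`, `length`, `skipped`, `A`, `C`, `G`,
#'   `T`, and the 16 dyad columns.
#' @export
count_genome <- function(fasta, dyad_mode = c("sliding", "segmentation"),
                         pooled = TRUE) {
  dyad_mode <- match.arg(dyad_mode)
  if (inherits(fasta, "DNAStringSet")) {
    seqs <- fasta
  } else {
    if (!file.exists(fasta)) rlang::abort(paste0("cannot read FASTA: ", fasta))
    seqs <- Biostrings::readDNAStringSet(fasta)
    if (length(seqs) == 0) rlang::abort("FASTA file contains no records")
  }
  step <- if (dyad_mode == "sliding") 1L else 2L
  af <- Biostrings::alphabetFrequency(seqs)
  dy <- Biostrings::oligonucleotideFrequency(seqs, width = 2, step = step)
  base_counts <- af[, base_order(), drop = FALSE]
  lens <- Biostrings::width(seqs)
  skipped <- lens - rowSums(base_counts)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- dplyr::bind_cols(
    tibble::tibble(id = ids, length = lens, skipped = skipped),
    tibble::as_tibble(base_counts),
    tibble::as_tibble(dy[, dyad_labels(), drop = FALSE])
  )
  if (any(lens == 0)) {
    rlang::warn("FASTA contains empty record(s); zero counts reported")
  }
  if (pooled && nrow(out) > 1) {
    pool <- dplyr::summarise(out, dplyr::across(-"id", sum))
    pool$id <- ".pooled"
    out <- dplyr::bind_rows(out, pool[names(out)])
  }
  out
}

#' Count-based skews of genome counts
#'
#' Computes (G - C)/(G + C) and (A - T)/(A + T) from integer counts (exact up
#' to float precision). Zero denominators are flagged as degenerate with skew
#' 0, as in [skews()].
#'
#' @param counts A tibble from [count_genome()] (or any table with columns
#'   `A`, `C`, `G`, `T`).
#' @return The input with `gc_skew`, `at_skew`, `skew_degenerate` and
#'   `gc_content` columns appended.
#' @export
genome_skews <- function(counts) {
  sk <- skews(counts)
  counts$gc_skew <- sk$gc_skew
  counts$at_skew <- sk$at_skew
  counts$skew_degenerate <- sk$skew_degenerate
  tot <- counts$A + counts$C + counts$G + counts$T
  counts$gc_content <- ifelse(tot > 0, (counts$G + counts$C) / tot, NA_real_)
  counts
}

#' Estimate per-kingdom tolerance boxes from a genome cohort
#'
#' Groups genomes by a kingdom label and packages the mean and standard
#' deviation of each skew as a tolerance box (mean +/- 1 sd compliance
#' region per axis).
#'
#' @param counts Table with `gc_skew` and `at_skew` columns (see
#'   [genome_skews()]).
#' @param labels Kingdom label per row.
#' @return A tolerance-box tibble (`kingdom`, `gc_mean`, `gc_sd`, `at_mean`,
#'   `at_sd`).
#' @export
kingdom_tolerance <- function(counts, labels) {
  if (length(labels) != nrow(counts)) {
    rlang::abort("`labels` must have one entry per genome")
  }
  sizes <- table(labels)
  if (any(sizes < 2)) {
    rlang::abort(paste0("need >= 2 genomes per label; singleton label(s): ",
                        paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  out <- tibble::tibble(kingdom = labels,
                        gc_skew = counts$gc_skew,
                        at_skew = counts$at_skew) |>
    dplyr::group_by(.data$kingdom) |>
    dplyr::summarise(
      gc_mean = mean(.data$gc_skew), gc_sd = stats::sd(.data$gc_skew),
      at_mean = mean(.data$at_skew), at_sd = stats::sd(.data$at_skew),
      .groups = "drop"
    )
  if (any(out$gc_sd == 0 | out$at_sd == 0)) {
    rlang::warn("degenerate tolerance box: zero skew sd within a label")
  }
  out
}

#' De-duplicate a species metadata table
#'
#' Keeps the first occurring row of each species name — the cohort-filtering
#' rule used when assemblies of the same species appear many times in a
#' download manifest.
#'
#' @param metadata A data frame.
#' @param species_col Name of the species column.
#' @return The filtered tibble.
#' @export
dedupe_species <- function(metadata, species_col = "species") {
  if (!species_col %in% names(metadata)) {
    rlang::abort(paste0("no column `", species_col, "` in metadata"))
  }
  tibble::as_tibble(metadata) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(species_col)),
                    .keep_all = TRUE)
}
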