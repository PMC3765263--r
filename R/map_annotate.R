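# Annotation classes in priority order: a tag overlapping several feature
# classes is assigned the highest-priority one. Housekeeping ncRNA first
# (GenBank-sourced records outrank Rfam-sourced ones within a class), then
# known miRNA, repeat, exon, intron.
ANNOTATION_PRIORITY <- c("rRNA", "scRNA", "snRNA", "snoRNA", "srpRNA", "tRNA",
                         "miRNA", "repeat", "exon", "intron")

#' Map unique tags to the genome by exact full-length matching
#'
#' Finds every exact occurrence of each tag on both strands of the genome
#' (no mismatches: deterministic, oracle-checkable behaviour; a mismatch
#' budget is not supported). Tags with non-ACGT characters are skipped
#' with a warning.
#'
#' @param library A `clean_library` or any data frame with `tag` and
#'   `count` columns.
#' @param genome Named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param max_loci Tags hitting more than this many loci are flagged
#'   (`multi_locus`), matching the copy-number cap used downstream.
#' @return A tibble of hits: `tag`, `count`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `n_loci`, `multi_locus`. Tags with no
#'   hit are absent (they flow to the `unan` class at annotation).
#' @export
map_tags <- function(library, genome, max_loci = 20) {
  stopifnot(all(c("tag", "count") %in% names(library)))
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  tags <- library$tag
  counts <- setNames(library$count, tags)
  ok <- grepl("^[ACGT]+$", tags)
  if (any(!ok)) {
    warn(sprintf("%d tag(s) with non-ACGT characters skipped", sum(!ok)))
    tags <- tags[ok]
  }
  if (length(tags) == 0) return(empty_hits())

  hit_one_strand <- function(patterns, strand) {
    res <- list()
    for (w in unique(nchar(patterns))) {
      grp <- patterns[nchar(patterns) == w]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(grp)))
      for (chrom in names(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[chrom]])
        nh <- S4Vectors::elementNROWS(m)
        if (sum(nh) == 0) next
        ir <- unlist(m)
        res[[length(res) + 1]] <- tibble(
          tag = rep(names(grp), nh),
          chrom = chrom,
          start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir),
          strand = strand)
      }
    }
    bind_rows(res)
  }

  plus <- hit_one_strand(setNames(tags, tags), "+")
  rc <- reverse_complement(tags)
  minus <- hit_one_strand(setNames(rc, tags), "-")
  hits <- bind_rows(plus, minus)
  if (nrow(hits) == 0) return(empty_hits())
  hits <- hits %>%
    group_by(.data$tag) %>%
    mutate(n_loci = dplyr::n()) %>%
    ungroup() %>%
    mutate(count = unname(counts[.data$tag]),
           multi_locus = .data$n_loci > max_loci) %>%
    select("tag", "count", "chrom", "start", "end", "strand", "n_loci",
           "multi_locus") %>%
    arrange(.data$tag, .data$chrom, .data$start, .data$strand)
  hits
}

empty_hits <- function() {
  tibble(tag = character(), count = numeric(), chrom = character(),
         start = integer(), end = integer(), strand = character(),
         n_loci = integer(), multi_locus = logical())
}

#' Assign every tag exactly one annotation class
#'
#' Each mapped tag is compared (>= 1 base of overlap) against the feature
#' annotation across all of its loci, and assigned the single
#' highest-priority class: housekeeping ncRNA (GenBank-sourced before
#' Rfam-sourced within a class) > miRNA > repeat > exon > intron. Exon and
#' intron assignments are split into sense/antisense by strand agreement
#' between the tag locus and the feature. Unmapped or featureless tags
#' get class `unan`.
#'
#' @param hits Mapped tags from [map_tags()].
#' @param features Feature annotation tibble (`chrom`, `start`, `end`,
#'   `class`, `source`, `strand`), e.g. from [read_bed()].
#' @param library The full `clean_library` (so unmapped tags are included);
#'   optional — when omitted only mapped tags are classified.
#' @param priority Character vector ordering the feature classes.
#' @return A tibble `tag`, `count`, `class` (one row per unique tag).
#' @export
annotate_tags <- function(hits, features, library = NULL,
                          priority = ANNOTATION_PRIORITY) {
  stopifnot(all(c("chrom", "start", "end", "class", "strand") %in% names(features)))
  unknown <- setdiff(unique(features$class), priority)
  if (length(unknown) > 0) {
    abort(paste0("unknown feature class label(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (!"source" %in% names(features)) features$source <- NA_character_

  per_tag <- if (nrow(hits) == 0) {
    tibble(tag = character(), count = numeric(), class = character())
  } else {
    fgr <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(features$start + 1L, features$end),
      strand = features$strand)
    hgr <- GenomicRanges::GRanges(
      hits$chrom, IRanges::IRanges(hits$start + 1L, hits$end),
      strand = hits$strand)
    ov <- GenomicRanges::findOverlaps(hgr, fgr, minoverlap = 1L,
                                      ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    cls <- features$class[s]
    src_rank <- ifelse(is.na(features$source[s]), 3L,
                       ifelse(features$source[s] == "GenBank", 1L, 2L))
    sense <- hits$strand[q] == features$strand[s]
    eff_class <- ifelse(cls %in% c("exon", "intron"),
                        paste0(cls, ifelse(sense, "_sense", "_antisense")),
                        cls)
    ovl <- tibble(tag = hits$tag[q],
                  rank = match(cls, priority),
                  src_rank = src_rank,
                  eff_class = eff_class) %>%
      arrange(.data$tag, .data$rank, .data$src_rank) %>%
      distinct(.data$tag, .keep_all = TRUE)
    mapped <- distinct(hits, .data$tag, .data$count)
    mapped %>%
      left_join(ovl, by = "tag") %>%
      mutate(class = ifelse(is.na(.data$eff_class), "unan", .data$eff_class)) %>%
      select("tag", "count", "class")
  }
  if (!is.null(library)) {
    missing <- library[!library$tag %in% per_tag$tag, c("tag", "count")]
    per_tag <- bind_rows(per_tag,
                         mutate(as_tibble(missing), class = "unan"))
  }
  arrange(per_tag, .data$tag)
}

#' Summarise an annotation into per-class counts
#'
#' @param per_tag Output of [annotate_tags()].
#' @return An `annotation_summary` tibble with one row per class:
#'   `class`, `unique_tags`, `total_reads` and their percentages; the
#'   abundance-weighted rRNA percentage is attached as attribute
#'   `rrna_fraction`.
#' @export
annotation_summary <- function(per_tag) {
  smry <- per_tag %>%
    group_by(.data$class) %>%
    summarise(unique_tags = dplyr::n(), total_reads = sum(.data$count),
              .groups = "drop") %>%
    mutate(unique_percent = 100 * .data$unique_tags / sum(.data$unique_tags),
           total_percent = 100 * .data$total_reads / sum(.data$total_reads)) %>%
    arrange(.data$class)
  rrna <- smry$total_percent[smry$class == "rRNA"]
  attr(smry, "rrna_fraction") <- if (length(rrna) == 0) 0 else rrna
  class(smry) <- c("annotation_summary", class(smry))
  smry
}

#' rRNA-fraction sample quality check
#'
#' The abundance-weighted rRNA proportion is a sample-quality indicator:
#' in animal samples it should stay below 40% (60% is the corresponding
#' plant threshold). Returns `PASS` when strictly below the threshold,
#' otherwise `WARN` with the fraction.
#'
#' @param x An `annotation_summary`, or a numeric rRNA percentage.
#' @param threshold Percent threshold (default 40, the animal-sample rule).
#' @return A one-row tibble `verdict`, `rrna_fraction`, `threshold`.
#' @export
rrna_quality_check <- function(x, threshold = 40) {
  frac <- if (is.numeric(x)) x else attr(x, "rrna_fraction")
  if (is.null(frac) || length(frac) == 0) frac <- 0
  tibble(verdict = ifelse(frac < threshold, "PASS", "WARN"),
         rrna_fraction = frac, threshold = threshold)
}
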