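#' Filter raw small-RNA reads into a clean tag library
#'
#' Classifies every high-quality read into exactly one category, in fixed
#' precedence order, and collapses the surviving inserts into unique tags:
#'
#' 1. low quality (dropped from `high_quality`): more than `max_n` N bases
#'    or more than 20% of bases below Phred 10;
#' 2. `adapter3_null`: the first `adapter_seed` bases of the 3' adapter are
#'    not found in the read (the adapter may be truncated at the read end);
#' 3. `insert_null`: the 3' adapter starts at position 1, leaving an empty
#'    insert;
#' 4. `adapter5_contaminants`: the last `adapter_seed` bases of the 5'
#'    adapter occur in the insert;
#' 5. `polyA`: at least 90% of insert bases are adenine;
#' 6. `smaller_than_18nt`: insert shorter than `min_len` (or, when a finite
#'    `max_len` is set, longer than `max_len`);
#' 7. clean: the insert becomes a tag.
#'
#' A read failing several rules is counted once, at the first failing rule.
#'
#' @param reads A data frame with columns `sequence` and `quality`
#'   (Phred+33), e.g. from [read_fastq()], or a path to a FASTQ file.
#' @param adapter3,adapter5 Adapter sequences (non-empty).
#' @param stage Optional stage label attached to the library.
#' @param min_len,max_len Insert length bounds for clean tags. The default
#'   upper bound is `Inf`: no explicit post-trim upper filter is applied,
#'   the read geometry already bounds insert length.
#' @param max_n Maximum tolerated N bases before a read is low quality.
#' @param low_qual_frac Fraction of sub-Phred-10 bases above which a read
#'   is low quality.
#' @param polya_frac Minimum adenine fraction that marks a polyA insert.
#' @param adapter_seed Number of adapter bases used for detection.
#' @return A `clean_library`: a tibble of unique tags (`tag`, `count`,
#'   lexicographic order) with attributes `stats` (the per-category
#'   accounting tibble, see [filter_stats()]), `stage` and `total_clean`.
#' @export
filter_reads <- function(reads, adapter3, adapter5, stage = NA_character_,
                         min_len = 18, max_len = Inf, max_n = 2,
                         low_qual_frac = 0.2, polya_frac = 0.9,
                         adapter_seed = 6) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  stopifnot(all(c("sequence", "quality") %in% names(reads)))
  if (!nzchar(adapter3) || !nzchar(adapter5)) abort("adapters must be non-empty")
  seqs <- toupper(reads$sequence)
  quals <- reads$quality
  total <- length(seqs)

  n_len <- nchar(seqs)
  n_count <- n_len - nchar(gsub("N", "", seqs, fixed = TRUE))
  # Phred+33: scores below 10 are ASCII 33..42, i.e. the class [!-*].
  lowq <- nchar(quals) - nchar(gsub("[!-*]", "", quals))
  is_lowqual <- n_count > max_n | (n_len > 0 & lowq / pmax(n_len, 1) > low_qual_frac)

  hq_seq <- seqs[!is_lowqual]
  high_quality <- length(hq_seq)

  seed3 <- substr(adapter3, 1, adapter_seed)
  pos3 <- regexpr(seed3, hq_seq, fixed = TRUE)
  insert <- ifelse(pos3 > 0, substr(hq_seq, 1, pos3 - 1), hq_seq)

  seed5 <- substr(adapter5, max(1, nchar(adapter5) - adapter_seed + 1),
                  nchar(adapter5))
  has5 <- regexpr(seed5, insert, fixed = TRUE) > 0
  polya <- nchar(insert) > 0 & base_fraction(insert, "A") >= polya_frac
  short <- nchar(insert) < min_len | nchar(insert) > max_len

  category <- rep("clean_reads", high_quality)
  category[short] <- "smaller_than_18nt"
  category[polya] <- "polyA"
  category[has5] <- "adapter5_contaminants"
  category[pos3 == 1] <- "insert_null"
  category[pos3 < 0] <- "adapter3_null"

  counts <- c(
    total_reads = total,
    high_quality = high_quality,
    setNames(vapply(FILTER_CATEGORIES, function(k) sum(category == k), 0L),
             FILTER_CATEGORIES),
    clean_reads = sum(category == "clean_reads")
  )
  stats <- filter_stats(counts)
  tags <- collapse_tags(tibble(sequence = insert[category == "clean_reads"]))
  new_clean_library(tags, stats = stats, stage = stage)
}

new_clean_library <- function(tags, stats, stage) {
  structure(tags,
            stats = stats, stage = stage, total_clean = sum(tags$count),
            class = c("clean_library", class(tibble())))
}

#' Per-category filtering accounting
#'
#' Turns named category counts into the standard accounting tibble:
#' one row per category with its count and its percentage of the
#' high-quality reads (two decimals are conventional in reports; the
#' column is not rounded).
#'
#' @param counts Named numeric vector with entries `total_reads`,
#'   `high_quality`, the five contamination categories, and (optionally)
#'   `clean_reads`, which is derived when absent.
#' @return A tibble `category`, `count`, `percent` with the partition
#'   invariant `sum(categories) + clean_reads == high_quality` enforced.
#' @export
filter_stats <- function(counts) {
  required <- c("total_reads", "high_quality", FILTER_CATEGORIES)
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort(paste0("missing filter categories: ", paste(missing, collapse = ", ")))
  }
  if (!"clean_reads" %in% names(counts)) {
    counts["clean_reads"] <- counts["high_quality"] -
      sum(counts[FILTER_CATEGORIES])
  }
  if (counts["high_quality"] > counts["total_reads"]) {
    abort("high_quality cannot exceed total_reads")
  }
  if (sum(counts[FILTER_CATEGORIES]) + counts["clean_reads"] !=
      counts["high_quality"]) {
    abort("category counts do not partition the high-quality reads")
  }
  cat_order <- c("total_reads", "high_quality", FILTER_CATEGORIES, "clean_reads")
  hq <- counts[["high_quality"]]
  tibble(category = cat_order,
         count = unname(as.numeric(counts[cat_order])),
         percent = unname(c(NA, if (hq > 0) 100 * counts[cat_order[-1]] / hq
                            else rep(0, length(cat_order) - 1))))
}

#' Recompute a multi-library filtering accounting table
#'
#' Given per-library raw category counts (for example the counts printed
#' in a sequencing report), derives the clean-read counts, the per-library
#' percentages of high-quality reads, and the across-library totals —
#' useful to audit published accounting tables.
#'
#' @param counts A data frame with a `library` column and numeric columns
#'   `total_reads`, `high_quality`, `adapter3_null`, `insert_null`,
#'   `adapter5_contaminants`, `smaller_than_18nt`, `polyA` (and optionally
#'   `clean_reads`, rederived when absent).
#' @return A tibble in long form: `library`, `category`, `count`,
#'   `percent`, with an extra `Total` library summing counts.
#' @export
filter_accounting <- function(counts) {
  stopifnot("library" %in% names(counts))
  per_lib <- purrr::map(seq_len(nrow(counts)), function(i) {
    row <- counts[i, setdiff(names(counts), "library")]
    filter_stats(unlist(row)) %>%
      mutate(library = counts$library[i], .before = 1)
  })
  long <- bind_rows(per_lib)
  totals <- long %>%
    group_by(.data$category) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(library = "Total", percent = NA_real_)
  bind_rows(long, totals[, names(long)])
}

#' Collapse clean reads into unique tags
#'
#' Merges identical insert sequences, sums their counts, and orders tags
#' lexicographically. Accepts either raw clean reads (column `sequence`)
#' or an already-collapsed table (columns `tag`, `count`) to merge.
#'
#' @param reads A data frame with a `sequence` column (one row per read)
#'   or `tag`/`count` columns.
#' @return A tibble `tag`, `count` in lexicographic tag order.
#' @export
collapse_tags <- function(reads) {
  if (all(c("tag", "count") %in% names(reads))) {
    tb <- reads %>% group_by(.data$tag) %>%
      summarise(count = sum(.data$count), .groups = "drop")
  } else {
    stopifnot("sequence" %in% names(reads))
    tb <- tibble(tag = reads$sequence) %>% count(.data$tag, name = "count")
  }
  arrange(tb, .data$tag)
}

#' Accessors for clean libraries
#'
#' @param x A `clean_library` from [filter_reads()].
#' @return `filter_stats_of()`: the accounting tibble; `clean_total()`:
#'   the number of clean reads; `library_stage()`: the stage label.
#' @export
filter_stats_of <- function(x) attr(x, "stats")

#' @rdname filter_stats_of
#' @export
clean_total <- function(x) attr(x, "total_clean")

#' @rdname filter_stats_of
#' @export
library_stage <- function(x) attr(x, "stage")

#' Tag length distribution of clean libraries
#'
#' Two histograms per library: total (abundance-weighted) and distinct
#' (unique tags) counts per insert length.
#'
#' @param libraries A single `clean_library` (or `tag`/`count` tibble) or
#'   a named list of them.
#' @return A tibble `stage`, `length`, `total`, `distinct`, spanning the
#'   observed length range of each library.
#' @export
length_distribution <- function(libraries) {
  if (is.data.frame(libraries)) libraries <- list(libraries)
  if (is.null(names(libraries))) {
    names(libraries) <- vapply(libraries, function(l) {
      s <- attr(l, "stage"); if (is.null(s) || is.na(s)) "" else s
    }, "")
  }
  out <- purrr::imap(libraries, function(lib, nm) {
    if (nrow(lib) == 0) {
      return(tibble(stage = character(), length = integer(),
                    total = numeric(), distinct = integer()))
    }
    tibble(tag = lib$tag, count = lib$count, length = nchar(lib$tag)) %>%
      group_by(.data$length) %>%
      summarise(total = sum(.data$count), distinct = dplyr::n(),
                .groups = "drop") %>%
      mutate(stage = nm, .before = 1)
  })
  bind_rows(out)
}
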