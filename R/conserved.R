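#' Credit clean tags to known (conserved) miRNAs
#'
#' A tag is credited to a reference mature miRNA when it aligns within the
#' miRNA's precursor with at most `max_mismatches` mismatches and its 5'
#' end lies within `offset_window` nt of the mature 5' end — the common
#' small-RNA quantification tolerance. Each tag is credited to at most one
#' miRNA: the best (fewest-mismatch) match, ties broken lexicographically
#' by miRNA id.
#'
#' @param library A `clean_library` (or `tag`/`count` tibble).
#' @param precursors Named character vector of precursor sequences (DNA or
#'   RNA alphabet), e.g. from [read_fasta()].
#' @param matures Named character vector of mature sequences; every mature
#'   must be a subsequence of at least one precursor.
#' @param max_mismatches Maximum mismatches between tag and precursor.
#' @param offset_window Maximum distance between tag and mature 5' ends.
#' @return A tibble `mirna_id`, `count` of credited read counts (only
#'   detected miRNAs appear; see [mirna_expression()] for the full
#'   matrix).
#' @export
match_known_mirnas <- function(library, precursors, matures,
                               max_mismatches = 2, offset_window = 4) {
  stopifnot(all(c("tag", "count") %in% names(library)))
  precursors <- toupper(rna_to_dna(precursors))
  matures <- toupper(rna_to_dna(matures))

  # locate each mature inside its precursor
  loc <- purrr::imap(matures, function(mseq, mid) {
    pos <- vapply(precursors, function(p) regexpr(mseq, p, fixed = TRUE), 0L)
    hit <- which(pos > 0)
    if (length(hit) == 0) {
      abort(sprintf("mature miRNA '%s' is not a subsequence of any precursor", mid))
    }
    tibble(mirna_id = mid, precursor = names(precursors)[hit[1]],
           mstart = pos[hit[1]])
  })
  loc <- bind_rows(loc)

  if (nrow(library) == 0) return(tibble(mirna_id = character(), count = numeric()))

  best <- rep(NA_character_, nrow(library))
  best_mm <- rep(Inf, nrow(library))
  lens <- nchar(library$tag)
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    tag_mat <- do.call(rbind, strsplit(library$tag[sel], ""))
    for (k in seq_len(nrow(loc))) {
      prec <- precursors[[loc$precursor[k]]]
      for (d in -offset_window:offset_window) {
        p <- loc$mstart[k] + d
        if (p < 1 || p + L - 1 > nchar(prec)) next
        w <- strsplit(substr(prec, p, p + L - 1), "")[[1]]
        mm <- rowSums(tag_mat != matrix(w, nrow = length(sel), ncol = L,
                                        byrow = TRUE))
        ok <- mm <= max_mismatches
        if (!any(ok)) next
        strictly <- ok & mm < best_mm[sel]
        tie <- ok & mm == best_mm[sel] &
          (is.na(best[sel]) | loc$mirna_id[k] < best[sel])
        upd <- strictly | (tie & !is.na(tie))
        if (any(upd)) {
          best[sel[upd]] <- loc$mirna_id[k]
          best_mm[sel[upd]] <- mm[upd]
        }
      }
    }
  }
  credited <- tibble(mirna_id = best, count = library$count) %>%
    filter(!is.na(.data$mirna_id)) %>%
    group_by(.data$mirna_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$mirna_id)
  credited
}

#' Conserved miRNA expression across the three stages
#'
#' Runs [match_known_mirnas()] per stage library and assembles the long
#' expression table with raw counts and TPM (count / clean total * 1e6).
#' miRNAs detected in any stage get explicit zero rows in the others.
#'
#' @param libraries Named list of `clean_library` objects (names = stages).
#' @param precursors,matures Reference sequences, as in
#'   [match_known_mirnas()].
#' @param clean_totals Optional named vector of clean totals; defaults to
#'   each library's own total.
#' @param ... Passed to [match_known_mirnas()].
#' @return A tibble `mirna_id`, `stage`, `count`, `tpm`.
#' @export
mirna_expression <- function(libraries, precursors, matures,
                             clean_totals = NULL, ...) {
  stopifnot(!is.null(names(libraries)))
  if (is.null(clean_totals)) {
    clean_totals <- vapply(libraries, function(l) {
      tt <- attr(l, "total_clean"); if (is.null(tt)) sum(l$count) else tt
    }, 0)
  }
  per_stage <- purrr::imap(libraries, function(lib, stage) {
    match_known_mirnas(lib, precursors, matures, ...) %>%
      mutate(stage = stage, .after = 1)
  })
  long <- bind_rows(per_stage)
  if (nrow(long) == 0) {
    return(tibble(mirna_id = character(), stage = character(),
                  count = numeric(), tpm = numeric()))
  }
  tidyr::complete(long, mirna_id = unique(long$mirna_id),
                  stage = names(libraries), fill = list(count = 0)) %>%
    filter(.data$stage %in% names(libraries)) %>%
    mutate(tpm = tpm_normalize(.data$count,
                               unname(clean_totals[.data$stage]))) %>%
    arrange(.data$mirna_id, .data$stage)
}

#' Stage membership and Venn partition of detected miRNAs
#'
#' A miRNA is present in a stage when its raw count reaches `min_count`
#' (default 1: detection by presence). The Venn region label partitions
#' the detected set.
#'
#' @param expr Long expression tibble from [mirna_expression()].
#' @param min_count Presence threshold on the raw count.
#' @return A tibble `mirna_id`, one logical column per stage, and
#'   `region` (e.g. `"anagen"`, `"anagen&catagen"`, `"all"`).
#' @export
stage_membership <- function(expr, min_count = 1) {
  stopifnot(all(c("mirna_id", "stage", "count") %in% names(expr)))
  stages <- sort(unique(expr$stage))
  wide <- expr %>%
    mutate(present = .data$count >= min_count) %>%
    tidyr::pivot_wider(id_cols = "mirna_id", names_from = "stage",
                       values_from = "present", values_fill = FALSE)
  pres <- as.matrix(wide[, stages, drop = FALSE])
  region <- apply(pres, 1, function(r) {
    if (all(r)) "all" else paste(stages[r], collapse = "&")
  })
  out <- wide %>%
    mutate(region = region) %>%
    filter(.data$region != "")
  out
}

#' @rdname stage_membership
#' @param membership Output of `stage_membership()`.
#' @return `venn_counts()`: a tibble `region`, `n` partitioning the
#'   detected miRNAs.
#' @export
venn_counts <- function(membership) {
  membership %>% count(.data$region, name = "n") %>% arrange(.data$region)
}

#' Top expressed miRNAs per stage
#'
#' Ranks miRNAs per stage by descending raw count, breaking ties
#' lexicographically by id, and keeps the top `n` (all, if fewer).
#'
#' @param expr Long expression tibble from [mirna_expression()].
#' @param n Number of miRNAs to keep per stage.
#' @return A tibble `stage`, `rank`, `mirna_id`, `count`, `tpm`.
#' @export
top_expressed <- function(expr, n = 10) {
  stopifnot(n >= 1)
  expr %>%
    arrange(.data$stage, desc(.data$count), .data$mirna_id) %>%
    group_by(.data$stage) %>%
    slice_head(n = n) %>%
    mutate(rank = row_number(), .after = "stage") %>%
    ungroup()
}
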