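#' Mireap-style novel miRNA prediction parameters
#'
#' The twelve thresholds governing hairpin candidate acceptance: mature
#' length bounds, genomic copy (reference) length bounds, minimum read
#' depth at the Drosha/Dicer cut site (reads sharing the mature 5' end),
#' maximum genomic copy number, maximum precursor free energy, maximum
#' space between miRNA and miRNA*, minimum miRNA/miRNA* base pairs,
#' maximum bulge, maximum duplex asymmetry, and the precursor flank
#' length.
#'
#' @param min_mirna_len,max_mirna_len Mature length bounds (nt).
#' @param min_ref_len,max_ref_len Bounds on the mature's genomic match
#'   span (nt).
#' @param min_cut_depth Minimum reads whose 5' end coincides with the
#'   mature 5' end.
#' @param max_copy_number Maximum genomic loci for a contributing tag.
#' @param max_precursor_mfe Maximum (most positive) precursor MFE,
#'   kcal/mol.
#' @param max_mirna_star_space Maximum nt between miRNA and miRNA*.
#' @param min_pairs_mirna_star Minimum base pairs between the two arms.
#' @param max_bulge Maximum contiguous unpaired run within the mature arm.
#' @param max_asymmetry Maximum |unpaired(mature) - unpaired(star)|.
#' @param flank_len Flank added beyond the candidate duplex (nt).
#' @return A `novel_params` list.
#' @export
novel_params <- function(min_mirna_len = 18, max_mirna_len = 26,
                         min_ref_len = 20, max_ref_len = 24,
                         min_cut_depth = 3, max_copy_number = 20,
                         max_precursor_mfe = -18,
                         max_mirna_star_space = 35,
                         min_pairs_mirna_star = 14,
                         max_bulge = 4, max_asymmetry = 5,
                         flank_len = 10) {
  stopifnot(max_precursor_mfe < 0, min_mirna_len <= max_mirna_len,
            min_ref_len <= max_ref_len, min_cut_depth > 0,
            max_copy_number > 0, max_mirna_star_space > 0,
            min_pairs_mirna_star > 0, max_bulge >= 0, max_asymmetry >= 0,
            flank_len >= 0)
  structure(as.list(environment()), class = "novel_params")
}

#' Excise hairpin candidate windows around unannotated tag clusters
#'
#' Tags are clustered per contig and strand when their loci overlap or
#' lie within `max_mirna_star_space` of each other; the deepest tag of a
#' cluster (ties: 5'-most) is the putative mature. Two genomic windows
#' are excised per cluster — one allowing the star upstream, one
#' downstream — each extending `flank_len` beyond the putative
#' miRNA/miRNA* duplex. Tags mapping to more than `max_copy_number` loci
#' are excluded. Windows running past a contig end are truncated and
#' flagged.
#'
#' @param hits Unannotated tag hits (a subset of [map_tags()] output;
#'   typically tags classified `unan` by [annotate_tags()]).
#' @param genome Named character vector of contigs or `DNAStringSet`.
#' @param params A [novel_params()] object.
#' @return A tibble of candidate windows: `cluster`, `chrom`, `strand`,
#'   `window_start`, `window_end` (0-based half-open), `precursor_seq`
#'   (transcript orientation), `mature_seq`, `mature_offset` (1-based in
#'   the precursor), `mature_len`, `cut_depth`, `truncated`.
#' @export
build_hairpin_candidates <- function(hits, genome, params = novel_params()) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  hits <- filter(hits, .data$n_loci <= params$max_copy_number)
  if (nrow(hits) == 0) return(empty_candidates())

  hits <- hits %>% arrange(.data$chrom, .data$strand, .data$start)
  grp <- hits %>%
    group_by(.data$chrom, .data$strand) %>%
    mutate(new_cluster = .data$start >
             dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf) +
             params$max_mirna_star_space,
           cluster_local = cumsum(.data$new_cluster)) %>%
    ungroup() %>%
    mutate(cluster = paste(.data$chrom, .data$strand, .data$cluster_local,
                           sep = ":"))

  clusters <- split(grp, grp$cluster)
  out <- purrr::map(clusters, function(cl) {
    # deepest tag, tie-break 5'-most start (transcript 5': start on +, end on -)
    ord <- if (cl$strand[1] == "+") order(-cl$count, cl$start, cl$tag)
           else order(-cl$count, -cl$end, cl$tag)
    m <- cl[ord[1], ]
    cut_depth <- if (m$strand == "+") {
      sum(cl$count[cl$start == m$start])
    } else {
      sum(cl$count[cl$end == m$end])
    }
    L <- m$end - m$start
    contig_len <- nchar(as.character(genome[[m$chrom]]))
    ext <- params$max_mirna_star_space + L + params$flank_len
    windows <- list(c(m$start - params$flank_len, m$end + ext),
                    c(m$start - ext, m$end + params$flank_len))
    purrr::map(windows, function(w) {
      ws <- max(0, w[1]); we <- min(contig_len, w[2])
      seq_plus <- substr(as.character(genome[[m$chrom]]), ws + 1, we)
      prec <- if (m$strand == "+") seq_plus else reverse_complement(seq_plus)
      offset <- if (m$strand == "+") m$start - ws + 1 else we - m$end + 1
      tibble(cluster = cl$cluster[1], chrom = m$chrom, strand = m$strand,
             window_start = ws, window_end = we,
             precursor_seq = prec, mature_seq = m$tag,
             mature_offset = as.integer(offset), mature_len = as.integer(L),
             cut_depth = cut_depth,
             truncated = ws > w[1] || we < w[2])
    }) %>% bind_rows()
  })
  bind_rows(out) %>% arrange(.data$cluster, .data$window_start)
}

empty_candidates <- function() {
  tibble(cluster = character(), chrom = character(), strand = character(),
         window_start = integer(), window_end = integer(),
         precursor_seq = character(), mature_seq = character(),
         mature_offset = integer(), mature_len = integer(),
         cut_depth = numeric(), truncated = logical())
}

#' Evaluate hairpin candidates against the prediction criteria
#'
#' Folds each candidate window with the active energy model and records a
#' verdict per criterion: mature and reference length bounds, precursor
#' MFE, miRNA/miRNA* on opposite arms within the allowed space, minimum
#' arm base pairs, maximum bulge within the mature arm, duplex asymmetry,
#' and cut-site depth. A candidate is accepted iff every criterion
#' passes; rejections are data, not errors.
#'
#' @param candidates Output of [build_hairpin_candidates()].
#' @param params A [novel_params()] object.
#' @param model An [energy_model()].
#' @return The candidate tibble augmented with `mfe`, `structure`,
#'   `n_pairs`, `star_offset`, `star_len`, one `pass_*` column per
#'   criterion, and `accepted`.
#' @export
evaluate_candidates <- function(candidates, params = novel_params(),
                                model = energy_model()) {
  if (nrow(candidates) == 0) {
    return(mutate(candidates, mfe = numeric(0), structure = character(0),
                  n_pairs = integer(0), star_offset = integer(0),
                  star_len = integer(0), accepted = logical(0)))
  }
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    fr <- fold_mfe(cand$precursor_seq, model)
    a <- cand$mature_offset
    b <- a + cand$mature_len - 1L
    pt <- fr$pair_table
    partners <- pt[a:b]
    outside <- partners[partners > 0 & (partners < a | partners > b)]
    n_pairs <- length(outside)
    one_side <- n_pairs > 0 && (all(outside > b) || all(outside < a))
    if (n_pairs > 0) {
      ss <- min(outside); se <- max(outside)
      space <- if (ss > b) ss - b - 1L else if (se < a) a - se - 1L else Inf
      star_unpaired <- sum(pt[ss:se] == 0)
      star_offset <- ss; star_len <- se - ss + 1L
    } else {
      space <- Inf; star_unpaired <- NA_integer_
      star_offset <- NA_integer_; star_len <- NA_integer_
    }
    in_mature <- pt[a:b] == 0
    runs <- rle(in_mature)
    bulge <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    mature_unpaired <- sum(in_mature)
    asym <- if (is.na(star_unpaired)) Inf else abs(mature_unpaired - star_unpaired)

    tibble(
      mfe = fr$mfe, structure = fr$structure, n_pairs = n_pairs,
      star_offset = star_offset, star_len = star_len,
      pass_mirna_len = cand$mature_len >= params$min_mirna_len &
        cand$mature_len <= params$max_mirna_len,
      pass_ref_len = cand$mature_len >= params$min_ref_len &
        cand$mature_len <= params$max_ref_len,
      pass_mfe = fr$mfe <= params$max_precursor_mfe,
      pass_space = one_side && space <= params$max_mirna_star_space,
      pass_min_pairs = n_pairs >= params$min_pairs_mirna_star,
      pass_bulge = bulge <= params$max_bulge,
      pass_asymmetry = asym <= params$max_asymmetry,
      pass_cut_depth = cand$cut_depth >= params$min_cut_depth
    )
  })
  res <- bind_cols(candidates, bind_rows(rows))
  res %>%
    mutate(accepted = .data$pass_mirna_len & .data$pass_ref_len &
             .data$pass_mfe & .data$pass_space & .data$pass_min_pairs &
             .data$pass_bulge & .data$pass_asymmetry & .data$pass_cut_depth)
}

#' Predict novel miRNAs from unannotated tags
#'
#' Builds candidate windows, evaluates every criterion, and keeps one
#' accepted prediction per tag cluster (the lowest-MFE window when both
#' orientations pass).
#'
#' @inheritParams build_hairpin_candidates
#' @param model An [energy_model()].
#' @return A tibble of accepted predictions (one row per cluster), with
#'   the full evaluated candidate table in attribute `candidates`.
#' @export
predict_novel_mirnas <- function(hits, genome, params = novel_params(),
                                 model = energy_model()) {
  cands <- build_hairpin_candidates(hits, genome, params)
  ev <- evaluate_candidates(cands, params, model)
  acc <- ev %>%
    filter(.data$accepted) %>%
    arrange(.data$cluster, .data$mfe, .data$window_start) %>%
    distinct(.data$cluster, .keep_all = TRUE)
  # a hairpin is its own reverse complement's hairpin: collapse accepted
  # windows that overlap on the genome regardless of strand, keeping the
  # deepest-supported (then lowest-energy) one
  if (nrow(acc) > 1) {
    acc <- arrange(acc, desc(.data$cut_depth), .data$mfe, .data$window_start)
    keep <- rep(TRUE, nrow(acc))
    for (i in seq_len(nrow(acc))[-1]) {
      prior <- which(keep[seq_len(i - 1)])
      ov <- acc$chrom[prior] == acc$chrom[i] &
        acc$window_start[prior] < acc$window_end[i] &
        acc$window_end[prior] > acc$window_start[i]
      if (any(ov)) keep[i] <- FALSE
    }
    acc <- acc[keep, ]
  }
  acc <- acc %>%
    arrange(.data$chrom, .data$window_start) %>%
    mutate(novel_id = sprintf("novel-m%04d", row_number()), .before = 1)
  attr(acc, "candidates") <- ev
  acc
}

#' Per-stage expression of predicted novel miRNAs
#'
#' Counts, in each stage library, the reads whose tag equals the
#' predicted mature sequence exactly.
#'
#' @param predictions Output of [predict_novel_mirnas()].
#' @param libraries Named list of `clean_library` objects.
#' @return A long tibble `mirna_id`, `stage`, `count`, `tpm`.
#' @export
novel_expression <- function(predictions, libraries) {
  stopifnot(!is.null(names(libraries)))
  out <- purrr::imap(libraries, function(lib, stage) {
    idx <- match(predictions$mature_seq, lib$tag)
    tibble(mirna_id = predictions$novel_id, stage = stage,
           count = ifelse(is.na(idx), 0, lib$count[idx]),
           tpm = tpm_normalize(ifelse(is.na(idx), 0, lib$count[idx]),
                               max(attr(lib, "total_clean"), 1)))
  })
  bind_rows(out) %>% arrange(.data$mirna_id, .data$stage)
}

#' 5' first-nucleotide composition of predictions by mature length
#'
#' Novel miRNAs characteristically begin with uridine; this tabulates the
#' first base (RNA alphabet) per mature length and reports the overall U
#' fraction as attribute `u_fraction`.
#'
#' @param predictions A data frame with a `mature_seq` column.
#' @return A tibble `length`, `first_base`, `n`; empty input gives an
#'   empty table.
#' @export
first_base_stats <- function(predictions) {
  if (nrow(predictions) == 0) {
    out <- tibble(length = integer(), first_base = character(), n = integer())
    attr(out, "u_fraction") <- NA_real_
    return(out)
  }
  fb <- dna_to_rna(toupper(substr(predictions$mature_seq, 1, 1)))
  out <- tibble(length = nchar(predictions$mature_seq), first_base = fb) %>%
    count(.data$length, .data$first_base, name = "n") %>%
    arrange(.data$length, .data$first_base)
  attr(out, "u_fraction") <- mean(fb == "U")
  out
}
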