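#' Rules for miRNA target-site acceptance
#'
#' Positional mismatch and duplex-stability criteria for calling a miRNA
#' binding site in a 3'UTR. Positions are 1-based from the miRNA 5' end.
#' G:U wobble pairs count 0.5 towards the weighted mismatch totals, but
#' count as full mismatch positions for the adjacency and positional
#' exclusion rules.
#'
#' @param max_mismatches Maximum weighted mismatches over the whole duplex.
#' @param max_adjacent_mm Longest tolerated run of consecutive mismatch
#'   positions anywhere in the duplex.
#' @param no_adjacent_mm_region Two positions delimiting the region (from
#'   the miRNA 5' end) in which no two adjacent mismatch positions are
#'   allowed.
#' @param no_mm_positions Positions that must be paired (no mismatch, no
#'   wobble).
#' @param max_mm_1_12 Maximum weighted mismatches over positions 1-12.
#' @param min_mfe_ratio Minimum ratio of duplex energy to the energy of the
#'   miRNA bound to its perfect complement (absolute values).
#' @return A `target_rules` list.
#' @export
target_rules <- function(max_mismatches = 4, max_adjacent_mm = 2,
                         no_adjacent_mm_region = c(2, 12),
                         no_mm_positions = c(10, 11),
                         max_mm_1_12 = 2.5, min_mfe_ratio = 0.75) {
  stopifnot(max_mismatches >= 0, max_adjacent_mm >= 0, max_mm_1_12 >= 0,
            min_mfe_ratio >= 0, length(no_adjacent_mm_region) == 2,
            length(no_mm_positions) == 2)
  structure(list(max_mismatches = max_mismatches,
                 max_adjacent_mm = max_adjacent_mm,
                 no_adjacent_mm_region = as.integer(no_adjacent_mm_region),
                 no_mm_positions = as.integer(no_mm_positions),
                 max_mm_1_12 = max_mm_1_12,
                 min_mfe_ratio = min_mfe_ratio),
            class = "target_rules")
}

# Pair class of one miRNA base against one target base (both RNA, the
# target base being the one physically opposite in the antiparallel duplex).
classify_pair <- function(m, u) {
  code <- paste0(m, u)
  ifelse(code %in% c("AU", "UA", "GC", "CG"), "WC",
         ifelse(code %in% c("GU", "UG"), "GU", "mismatch"))
}

#' Classify a miRNA against one ungapped target window
#'
#' Aligns the miRNA (5'->3') antiparallel against a same-length UTR window
#' (given 5'->3'), so miRNA position 1 faces the window's last base, and
#' classifies every position as Watson-Crick pair, G:U wobble, or mismatch.
#'
#' @param mirna,utr_window Same-length RNA (or DNA) sequences.
#' @return A tibble with columns `position` (1-based from the miRNA 5'
#'   end), `mirna_base`, `target_base`, `pair`.
#' @examples
#' align_site("AUGGC", "GCCAU") # perfect complement
#' @export
align_site <- function(mirna, utr_window) {
  stopifnot(is.character(mirna), is.character(utr_window))
  mirna <- toupper(dna_to_rna(mirna)); utr_window <- toupper(dna_to_rna(utr_window))
  if (nchar(mirna) != nchar(utr_window)) {
    abort("miRNA and target window must have equal length for ungapped alignment")
  }
  m <- strsplit(mirna, "")[[1]]
  u <- rev(strsplit(utr_window, "")[[1]])
  tibble(position = seq_along(m), mirna_base = m, target_base = u,
         pair = classify_pair(m, u))
}

#' Evaluate the target-site rules on one classified duplex
#'
#' @param classification A tibble from [align_site()].
#' @param rules A [target_rules()] object.
#' @param model An [energy_model()] for the duplex-stability rule.
#' @return A one-row tibble with the weighted `mismatch_score`, duplex
#'   `mfe`, `mfe_ratio`, one logical column per rule, and `accepted`.
#' @export
check_target_rules <- function(classification, rules = target_rules(),
                               model = energy_model()) {
  cls <- classification
  L <- nrow(cls)
  w <- ifelse(cls$pair == "mismatch", 1, ifelse(cls$pair == "GU", 0.5, 0))
  mmpos <- cls$pair != "WC"
  score <- sum(w)

  runs <- rle(mmpos)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L

  reg <- rules$no_adjacent_mm_region
  idx <- seq(reg[1], min(reg[2], L))
  adj_in_region <- any(mmpos[idx[-length(idx)]] & mmpos[idx[-1]])

  ex <- rules$no_mm_positions
  ex <- ex[ex <= L]
  mm_excl <- any(mmpos[ex])

  upto <- seq_len(min(12L, L))
  score_1_12 <- sum(w[upto])

  mfe <- pair_class_energy(cls, model)
  perfect <- sum(wc_energy(cls$mirna_base, model))
  ratio <- if (perfect == 0) 0 else abs(mfe) / abs(perfect)

  tibble(
    mismatch_score = score,
    mfe = mfe,
    mfe_ratio = ratio,
    pass_max_mismatches = score <= rules$max_mismatches,
    pass_adjacent_mm = max_run <= rules$max_adjacent_mm,
    pass_region_adjacency = !adj_in_region,
    pass_no_mm_10_11 = !mm_excl,
    pass_mm_1_12 = score_1_12 <= rules$max_mm_1_12,
    pass_mfe_ratio = ratio >= rules$min_mfe_ratio
  ) %>%
    mutate(accepted = .data$pass_max_mismatches & .data$pass_adjacent_mm &
             .data$pass_region_adjacency & .data$pass_no_mm_10_11 &
             .data$pass_mm_1_12 & .data$pass_mfe_ratio)
}

#' Scan 3'UTR sequences for miRNA target sites
#'
#' Slides every miRNA along every UTR in ungapped antiparallel register and
#' keeps the windows passing all [target_rules()]. The scan is a vectorised
#' matrix evaluation; [align_site()] plus [check_target_rules()] give the
#' same verdict window by window.
#'
#' @param mirnas A data frame with columns `mirna_id` and `sequence`, or a
#'   named character vector of mature sequences.
#' @param utrs A data frame with columns `gene_id` and `sequence`, a named
#'   character vector, or a `Biostrings::DNAStringSet`.
#' @param rules A [target_rules()] object.
#' @param model An [energy_model()].
#' @param keep_rejected If `TRUE`, return every window with its verdicts.
#' @return A tibble of sites: `mirna_id`, `gene_id`, `start`, `end`
#'   (0-based half-open on the UTR), `mismatch_score`, `mfe`, `mfe_ratio`,
#'   rule verdict columns and `accepted`, deduplicated per
#'   (miRNA, gene, position) and sorted.
#' @export
predict_targets <- function(mirnas, utrs, rules = target_rules(),
                            model = energy_model(), keep_rejected = FALSE) {
  mirnas <- as_seq_table(mirnas, "mirna_id")
  utrs <- as_seq_table(utrs, "gene_id")
  if (nrow(mirnas) == 0 || nrow(utrs) == 0) return(empty_sites())

  res <- purrr::map(seq_len(nrow(mirnas)), function(mi) {
    m_seq <- toupper(dna_to_rna(mirnas$sequence[mi]))
    L <- nchar(m_seq)
    m <- strsplit(m_seq, "")[[1]]
    purrr::map(seq_len(nrow(utrs)), function(gi) {
      u_seq <- toupper(dna_to_rna(utrs$sequence[gi]))
      n <- nchar(u_seq)
      if (n < L) {
        warn(sprintf("UTR '%s' shorter than miRNA '%s'; skipped",
                     utrs$gene_id[gi], mirnas$mirna_id[mi]))
        return(NULL)
      }
      scan_one(mirnas$mirna_id[mi], m, utrs$gene_id[gi],
               strsplit(u_seq, "")[[1]], rules, model)
    })
  })
  out <- bind_rows(purrr::flatten(res))
  if (nrow(out) == 0) return(empty_sites())
  out <- distinct(out, .data$mirna_id, .data$gene_id, .data$start,
                  .keep_all = TRUE) %>%
    arrange(.data$mirna_id, .data$gene_id, .data$start)
  if (!keep_rejected) out <- filter(out, .data$accepted)
  out
}

# Matrix scan of one miRNA over one UTR; windows are columns.
scan_one <- function(mirna_id, m, gene_id, u, rules, model) {
  L <- length(m); n <- length(u)
  W <- n - L + 1
  # column s = window starting at s (1-based); miRNA position i faces
  # UTR base s + L - i.
  idx <- outer(L - seq_len(L), seq_len(W), "+") # L x W matrix of indices
  U <- matrix(u[idx], nrow = L)
  M <- matrix(m, nrow = L, ncol = W)
  code <- matrix(paste0(M, U), nrow = L)
  is_wc <- code %in% c("AU", "UA", "GC", "CG")
  is_gu <- code %in% c("GU", "UG")
  wc <- matrix(is_wc, nrow = L); gum <- matrix(is_gu, nrow = L)
  mm <- !(wc | gum)                 # full mismatches
  mmpos <- !wc                      # mismatch positions (wobble included)
  wts <- mm * 1 + gum * 0.5

  score <- colSums(wts)
  # longest run of mismatch positions > max_adjacent_mm?
  k <- rules$max_adjacent_mm + 1L
  run_fail <- rep(FALSE, W)
  if (k <= L) {
    for (i in seq_len(L - k + 1L)) {
      block <- colSums(mmpos[i:(i + k - 1L), , drop = FALSE]) == k
      run_fail <- run_fail | block
    }
  }
  reg <- seq(rules$no_adjacent_mm_region[1], min(rules$no_adjacent_mm_region[2], L))
  adj_fail <- rep(FALSE, W)
  for (i in reg[-length(reg)]) {
    adj_fail <- adj_fail | (mmpos[i, ] & mmpos[i + 1L, ])
  }
  ex <- rules$no_mm_positions[rules$no_mm_positions <= L]
  excl_fail <- colSums(mmpos[ex, , drop = FALSE]) > 0
  upto <- seq_len(min(12L, L))
  score12 <- colSums(wts[upto, , drop = FALSE])

  wc_e <- wc_energy(m, model)
  E <- wc * wc_e + gum * model$gu
  mfe <- colSums(E)
  perfect <- sum(wc_e)
  ratio <- abs(mfe) / abs(perfect)

  tibble(
    mirna_id = mirna_id, gene_id = gene_id,
    start = seq_len(W) - 1L, end = seq_len(W) - 1L + L,
    mismatch_score = score, mfe = mfe, mfe_ratio = ratio,
    pass_max_mismatches = score <= rules$max_mismatches,
    pass_adjacent_mm = !run_fail,
    pass_region_adjacency = !adj_fail,
    pass_no_mm_10_11 = !excl_fail,
    pass_mm_1_12 = score12 <= rules$max_mm_1_12,
    pass_mfe_ratio = ratio >= rules$min_mfe_ratio
  ) %>%
    mutate(accepted = .data$pass_max_mismatches & .data$pass_adjacent_mm &
             .data$pass_region_adjacency & .data$pass_no_mm_10_11 &
             .data$pass_mm_1_12 & .data$pass_mfe_ratio)
}

empty_sites <- function() {
  tibble(mirna_id = character(), gene_id = character(),
         start = integer(), end = integer(), mismatch_score = numeric(),
         mfe = numeric(), mfe_ratio = numeric(),
         pass_max_mismatches = logical(), pass_adjacent_mm = logical(),
         pass_region_adjacency = logical(), pass_no_mm_10_11 = logical(),
         pass_mm_1_12 = logical(), pass_mfe_ratio = logical(),
         accepted = logical())
}

# Coerce the accepted sequence-set inputs to a two-column tibble.
as_seq_table <- function(x, id_col) {
  if (inherits(x, "DNAStringSet") || inherits(x, "RNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) abort("sequence vectors must be named")
    out <- tibble(id = names(x), sequence = unname(x))
    names(out)[1] <- id_col
    return(out)
  }
  if (is.data.frame(x)) {
    if (!all(c(id_col, "sequence") %in% names(x))) {
      abort(sprintf("data frame must have columns '%s' and 'sequence'", id_col))
    }
    return(as_tibble(x[, c(id_col, "sequence")]))
  }
  abort("unsupported sequence input")
}
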