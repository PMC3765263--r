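#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that at least `m` of the `n` candidate genes
#' fall in a term of size `M` drawn from a universe of `N` annotated
#' genes:
#' `P = 1 - sum_{i=0}^{m-1} C(M, i) C(N-M, n-i) / C(N, n)`.
#' Terms with impossible arguments contribute zero; evaluation is in log
#' space so large gene universes are handled exactly.
#'
#' @param N Number of annotated genes in the universe.
#' @param n Number of candidate genes (drawn from the universe).
#' @param M Number of universe genes annotated to the term.
#' @param m Observed overlap between candidates and the term.
#' @return Upper-tail probability `P(overlap >= m)`.
#' @examples
#' hypergeom_p(N = 10, n = 4, M = 5, m = 3) # 55/210
#' @export
hypergeom_p <- function(N, n, M, m) {
  stopifnot(N >= 0, n >= 0, M >= 0, m >= 0)
  if (M > N || n > N) abort("M and n must not exceed N")
  if (m > min(n, M)) abort("overlap m cannot exceed min(n, M)")
  if (m == 0) return(1)
  # evaluate 1 - sum_{i<m} as the normalised complement sum_{i>=m}: the
  # two tails add to exactly 1 analytically, and the ratio form avoids the
  # cancellation of subtracting a near-1 partial sum
  lt <- function(i) lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  lo <- lt(0:(m - 1))
  hi <- lt(m:min(n, M))
  lo <- lo[is.finite(lo)]; hi <- hi[is.finite(hi)]
  if (length(hi) == 0) return(0)
  if (length(lo) == 0) return(1)
  s_lo <- logsumexp(lo); s_hi <- logsumexp(hi)
  1 / (1 + exp(s_lo - s_hi))
}

#' Multiple-testing corrections for enrichment p-values
#'
#' `bonferroni()` multiplies each p-value by the number of tested terms
#' (capped at 1); `bh_fdr()` computes Benjamini-Hochberg step-up q-values.
#' Both delegate to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "bonferroni")
}

#' @rdname bonferroni
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Term enrichment of candidate target genes
#'
#' Tests every term with at least one candidate overlap by the
#' hypergeometric upper tail, then corrects for multiple testing:
#' Bonferroni with a 0.05 cut-off in GO mode, Benjamini-Hochberg FDR with
#' a 0.05 cut-off in pathway mode. The universe `N` is the number of
#' genes carrying any annotation in `gene2term`, so it is specific to the
#' mapping supplied (GO-annotated vs pathway-annotated genes). Candidate
#' genes absent from the universe are dropped from `n` with a warning.
#'
#' @param candidates Character vector of candidate gene ids (e.g. the
#'   distinct `gene_id`s of [predict_targets()] output).
#' @param gene2term A data frame with columns `gene` and `term` (one row
#'   per annotation), e.g. read from a two-column TSV.
#' @param mode `"GO"` (Bonferroni) or `"pathway"` (BH FDR).
#' @param alpha Significance cut-off on the corrected p-value.
#' @return An `enrichment_result` tibble sorted by adjusted then raw
#'   p-value: `term`, `N`, `n`, `M`, `m`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
run_enrichment <- function(candidates, gene2term, mode = c("GO", "pathway"),
                           alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "term") %in% names(gene2term)))
  candidates <- unique(candidates)
  universe <- unique(gene2term$gene)
  N_univ <- length(universe)
  dropped <- setdiff(candidates, universe)
  if (length(dropped) > 0) {
    warn(sprintf("%d candidate gene(s) absent from the annotation universe; dropped",
                 length(dropped)))
  }
  cand <- intersect(candidates, universe)
  n_cand <- length(cand)
  if (n_cand == 0) {
    return(structure(tibble(term = character(), N = integer(), n = integer(),
                            M = integer(), m = integer(), p_raw = numeric(),
                            p_adjusted = numeric(), significant = logical()),
                     class = c("enrichment_result", class(tibble()))))
  }
  by_term <- gene2term %>%
    distinct(.data$gene, .data$term) %>%
    group_by(.data$term) %>%
    summarise(M = dplyr::n_distinct(.data$gene),
              m = sum(unique(.data$gene) %in% cand), .groups = "drop") %>%
    filter(.data$m >= 1)
  res <- by_term %>%
    mutate(N = N_univ, n = n_cand,
           p_raw = purrr::map2_dbl(.data$M, .data$m,
                                   ~ hypergeom_p(N_univ, n_cand, .x, .y))) %>%
    mutate(p_adjusted = if (mode == "GO") bonferroni(.data$p_raw)
           else bh_fdr(.data$p_raw),
           significant = .data$p_adjusted <= alpha) %>%
    select("term", "N", "n", "M", "m", "p_raw", "p_adjusted", "significant") %>%
    arrange(.data$p_adjusted, .data$p_raw, .data$term)
  class(res) <- c("enrichment_result", class(res))
  attr(res, "mode") <- mode
  res
}
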