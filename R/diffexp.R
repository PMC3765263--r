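#' Transcripts-per-million normalisation
#'
#' `TPM = 1e6 * count / clean_total`, where `clean_total` is the library's
#' clean-read total. No rounding is applied.
#'
#' @param count Raw count(s), non-negative.
#' @param clean_total Clean-read total of the library (> 0).
#' @return Numeric TPM value(s).
#' @examples
#' tpm_normalize(500, 1e6)
#' @export
tpm_normalize <- function(count, clean_total) {
  if (any(clean_total <= 0)) abort("clean_total must be positive")
  if (any(count < 0)) abort("counts must be non-negative")
  1e6 * count / clean_total
}

#' Low-expression revision rule for a two-library comparison
#'
#' Zero normalised values are revised to 0.01 so ratios stay defined; a
#' miRNA whose revised TPM is below 1 in both libraries is flagged as
#' excluded from the differential analysis. With
#' `revise_when_both_zero = TRUE` the 0.01 revision is only applied when
#' both values are zero (the stricter alternative reading).
#'
#' @param tpm_control,tpm_treatment Non-negative normalised expressions.
#' @param floor Revision value for zeros (default 0.01).
#' @param revise_when_both_zero Apply the floor only when both TPMs are 0.
#' @return A tibble with `tpm_control`, `tpm_treatment` (revised) and
#'   `excluded`.
#' @export
revise_low_expression <- function(tpm_control, tpm_treatment, floor = 0.01,
                                  revise_when_both_zero = FALSE) {
  stopifnot(all(tpm_control >= 0), all(tpm_treatment >= 0))
  if (revise_when_both_zero) {
    both0 <- tpm_control == 0 & tpm_treatment == 0
    tpm_control <- ifelse(both0, floor, tpm_control)
    tpm_treatment <- ifelse(both0, floor, tpm_treatment)
  } else {
    tpm_control <- ifelse(tpm_control == 0, floor, tpm_control)
    tpm_treatment <- ifelse(tpm_treatment == 0, floor, tpm_treatment)
  }
  tibble(tpm_control = tpm_control, tpm_treatment = tpm_treatment,
         excluded = tpm_control < 1 & tpm_treatment < 1)
}

#' Log2 fold change of normalised expression
#'
#' `log2(treatment / control)`; inputs must be positive (apply
#' [revise_low_expression()] first).
#'
#' @param tpm_treatment,tpm_control Positive normalised expressions.
#' @return log2 ratio(s).
#' @export
log2_fold_change <- function(tpm_treatment, tpm_control) {
  if (any(tpm_treatment <= 0) || any(tpm_control <= 0)) {
    abort("fold change requires positive normalised expression; revise zeros first")
  }
  log2(tpm_treatment / tpm_control)
}

# Log-probability of observing y treatment counts given x control counts
# in libraries of totals n1, n2: the Audic-Claverie sampling distribution
# p(y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)), r = n2/n1, evaluated
# through log-gamma for stability.
ac_log_prob <- function(yv, x, log_r, log_1pr) {
  yv * log_r + lgamma(x + yv + 1) - lgamma(x + 1) - lgamma(yv + 1) -
    (x + yv + 1) * log_1pr
}

#' Audic-Claverie exact test for two-library digital expression
#'
#' Tests whether a feature's counts `x` (control, library total `n1`) and
#' `y` (treatment, library total `n2`) are compatible with equal
#' expression. The lower tail P(Y <= y | x) and the upper tail
#' P(Y >= y | x) are obtained by summing the conditional distribution in
#' log space (the infinite upper tail via the complement of the finite
#' lower sum); the two-sided p-value is twice the smaller tail, capped
#' at 1. Vectorised over `x`, `y`.
#'
#' @param x,y Non-negative integer counts.
#' @param n1,n2 Clean-read totals of the control and treatment libraries.
#' @return Two-sided p-value(s) in (0, 1].
#' @examples
#' ac_pvalue(5, 50, 1e6, 1e6)
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) abort("counts must be non-negative")
  if (any(x != round(x)) || any(y != round(y))) abort("counts must be integers")
  stopifnot(n1 > 0, n2 > 0)
  r <- n2 / n1
  log_r <- log(r); log_1pr <- log1p(r)
  # Beyond mu + 10 sd the conditional distribution has decayed; `extra`
  # covers the geometric tail down to ~1e-19 of its leading term.
  extra <- ceiling(45 / (log_1pr - log_r)) + 20
  purrr::map2_dbl(x, y, function(xi, yi) {
    lp <- ac_log_prob(0:yi, xi, log_r, log_1pr)
    lower <- min(exp(logsumexp(lp)), 1)
    mu <- (xi + 1) * r
    sd <- sqrt((xi + 1) * r * (1 + r))
    ymax <- max(yi, ceiling(mu + 10 * sd)) + extra
    lp_up <- ac_log_prob(yi:ymax, xi, log_r, log_1pr)
    upper <- min(exp(logsumexp(lp_up)), 1)
    min(1, 2 * min(lower, upper))
  })
}

#' Classify differential-expression results into significance and ratio bands
#'
#' Significance bands follow the printed cut-offs (`p < 0.01`,
#' `0.01 <= p < 0.05`, not significant); expression-ratio bands follow the
#' scatter-plot convention: ratio > 2, 1/2 < ratio <= 2, ratio <= 1/2,
#' with ratio = normalised treatment / normalised control.
#'
#' @param pvalue Numeric p-values.
#' @param ratio Numeric expression ratios (treatment / control TPM).
#' @return A tibble with `sig_class` and `ratio_class` factors.
#' @export
classify_de <- function(pvalue, ratio) {
  sig <- ifelse(pvalue < 0.01, "p<0.01",
                ifelse(pvalue < 0.05, "0.01<=p<0.05", "NS"))
  rat <- ifelse(ratio > 2, "ratio>2",
                ifelse(ratio > 0.5, "1/2<ratio<=2", "ratio<=1/2"))
  tibble(
    sig_class = factor(sig, levels = c("p<0.01", "0.01<=p<0.05", "NS")),
    ratio_class = factor(rat, levels = c("ratio>2", "1/2<ratio<=2", "ratio<=1/2"))
  )
}

#' Pairwise differential expression across the hair-cycle stages
#'
#' For each stage pair, normalises counts to TPM by the library clean
#' totals, applies the low-expression revision/exclusion rule, computes
#' the log2 fold change and the Audic-Claverie two-sided p-value on the
#' raw counts, and assigns significance and ratio classes.
#'
#' @param expr A data frame with columns `mirna_id`, `stage`, `count`
#'   (long format, one row per miRNA and stage), e.g. from
#'   [mirna_expression()].
#' @param clean_totals Named numeric vector of library clean-read totals,
#'   names matching the stages in `expr`.
#' @param pairs A two-column data frame (`control`, `treatment`) of stage
#'   pairs; defaults to the three ordered hair-cycle comparisons
#'   (catagen-anagen, telogen-anagen, telogen-catagen).
#' @param revise_when_both_zero Passed to [revise_low_expression()].
#' @return A `de_result` tibble: one row per miRNA and pair with counts,
#'   revised TPMs, `log2fc`, `pvalue`, `sig_class`, `ratio_class`,
#'   `excluded`.
#' @export
diff_expression <- function(expr, clean_totals, pairs = NULL,
                            revise_when_both_zero = FALSE) {
  stopifnot(all(c("mirna_id", "stage", "count") %in% names(expr)))
  if (is.null(pairs)) {
    pairs <- tibble(control = c("anagen", "anagen", "catagen"),
                    treatment = c("catagen", "telogen", "telogen"))
  }
  missing_stage <- setdiff(unique(c(pairs$control, pairs$treatment)),
                           names(clean_totals))
  if (length(missing_stage) > 0) {
    abort(paste0("clean_totals missing stages: ",
                 paste(missing_stage, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(expr, id_cols = "mirna_id",
                             names_from = "stage", values_from = "count",
                             values_fill = 0)
  out <- purrr::pmap(pairs, function(control, treatment) {
    x <- wide[[control]] %||% rep(0, nrow(wide))
    y <- wide[[treatment]] %||% rep(0, nrow(wide))
    n1 <- clean_totals[[control]]; n2 <- clean_totals[[treatment]]
    rev <- revise_low_expression(tpm_normalize(x, n1), tpm_normalize(y, n2),
                                 revise_when_both_zero = revise_when_both_zero)
    p <- ac_pvalue(x, y, n1, n2)
    cls <- classify_de(p, rev$tpm_treatment / rev$tpm_control)
    tibble(mirna_id = wide$mirna_id, control = control, treatment = treatment,
           x = x, y = y,
           tpm_control = rev$tpm_control, tpm_treatment = rev$tpm_treatment,
           log2fc = log2_fold_change(rev$tpm_treatment, rev$tpm_control),
           pvalue = p, sig_class = cls$sig_class, ratio_class = cls$ratio_class,
           excluded = rev$excluded)
  })
  res <- bind_rows(out)
  class(res) <- c("de_result", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster miRNA fold-change profiles across stage pairs
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of per-miRNA log2 fold-change vectors over the stage pairs,
#' cut into `k` clusters. Deterministic given the input.
#'
#' @param de A `de_result` tibble from [diff_expression()] (or any data
#'   frame with `mirna_id`, `control`, `treatment`, `log2fc`).
#' @param k Number of clusters (default 5 expression patterns).
#' @return A tibble `mirna_id`, `cluster` (integer). If there are fewer
#'   miRNAs than `k`, each gets its own cluster.
#' @export
cluster_profiles <- function(de, k = 5) {
  stopifnot(all(c("mirna_id", "control", "treatment", "log2fc") %in% names(de)))
  m <- de %>%
    mutate(pair = paste(.data$treatment, .data$control, sep = "/")) %>%
    tidyr::pivot_wider(id_cols = "mirna_id", names_from = "pair",
                       values_from = "log2fc")
  ids <- m$mirna_id
  mat <- as.matrix(m[, -1, drop = FALSE])
  if (nrow(mat) <= k) {
    return(tibble(mirna_id = ids, cluster = seq_along(ids)))
  }
  hc <- hclust(dist(mat), method = "average")
  tibble(mirna_id = ids, cluster = unname(cutree(hc, k = k)))
}
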