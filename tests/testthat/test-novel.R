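# Helpers shared by the novel-miRNA tests: map a tiny simulated study and
# keep only the unannotated hits, as the pipeline does.
unannotated_hits <- function(sim, cfg, stages = names(sim$libraries)) {
  libs <- purrr::map(stages, function(s) {
    filter_reads(sim$libraries[[s]], cfg$adapter3, cfg$adapter5, stage = s)
  })
  combined <- collapse_tags(dplyr::bind_rows(purrr::map(libs, tibble::as_tibble)))
  hits <- map_tags(combined, sim$genome)
  feats <- dplyr::filter(sim$truth$features, class != "intergenic")
  ann <- annotate_tags(hits, feats, combined)
  dplyr::filter(hits, tag %in% ann$tag[ann$class == "unan"])
}

test_that("noise-free planted precursors are all recovered", {
  ts <- tiny_sim()
  hits <- unannotated_hits(ts$sim, ts$cfg)
  pred <- predict_novel_mirnas(hits, ts$sim$genome)
  truth <- dplyr::filter(ts$sim$truth$mirnas, kind == "novel")
  recalled <- vapply(seq_len(nrow(truth)), function(i) {
    any(pred$chrom == truth$chrom[i] &
          pred$window_start < truth$end[i] &
          pred$window_end > truth$start[i])
  }, TRUE)
  expect_equal(mean(recalled), 1.0)
  # every accepted prediction passes every recorded criterion
  expect_true(all(pred$accepted))
  expect_true(all(pred$mfe <= -18))
  expect_true(all(pred$n_pairs >= 14))
  expect_true(all(pred$cut_depth >= 3))
})

test_that("candidate windows cover the mature plus flanks", {
  ts <- tiny_sim()
  truth1 <- dplyr::filter(ts$sim$truth$mirnas, kind == "novel")[1, ]
  hits <- tibble::tibble(tag = truth1$mature_seq, count = 10,
                         chrom = truth1$chrom,
                         start = truth1$mature_start, end = truth1$mature_end,
                         strand = truth1$strand, n_loci = 1L,
                         multi_locus = FALSE)
  cands <- build_hairpin_candidates(hits, ts$sim$genome)
  expect_equal(nrow(cands), 2)  # star allowed on either side
  expect_true(all(cands$window_start <= truth1$mature_start - 10 |
                    cands$window_start == 0))
  expect_true(all(cands$window_end >= truth1$mature_end + 10))
  expect_true(all(cands$cut_depth == 10))
})

test_that("copy-number cap and empty input are honoured", {
  ts <- tiny_sim()
  hits <- unannotated_hits(ts$sim, ts$cfg)
  capped <- dplyr::mutate(hits, n_loci = 21L)
  expect_equal(nrow(build_hairpin_candidates(capped, ts$sim$genome)), 0)
  expect_equal(nrow(build_hairpin_candidates(hits[0, ], ts$sim$genome)), 0)
  expect_equal(nrow(predict_novel_mirnas(hits[0, ], ts$sim$genome)), 0)
})

test_that("a 13-pair duplex fails the minimum-pair criterion", {
  # mature of 22 C; only its first 13 positions have G partners
  mature <- strrep("C", 22)
  prec <- paste0(strrep("A", 10), mature, strrep("A", 8),
                 strrep("G", 13), strrep("A", 10))
  cand <- tibble::tibble(cluster = "c:+:1", chrom = "c", strand = "+",
                         window_start = 0L, window_end = nchar(prec),
                         precursor_seq = prec, mature_seq = mature,
                         mature_offset = 11L, mature_len = 22L,
                         cut_depth = 10, truncated = FALSE)
  ev <- evaluate_candidates(cand)
  expect_equal(ev$n_pairs, 13)
  expect_false(ev$pass_min_pairs)
  expect_false(ev$accepted)
})

test_that("insufficient cut-site depth rejects a perfect hairpin", {
  ts <- tiny_sim()
  truth1 <- dplyr::filter(ts$sim$truth$mirnas, kind == "novel")[1, ]
  hits <- tibble::tibble(tag = truth1$mature_seq, count = 2,
                         chrom = truth1$chrom,
                         start = truth1$mature_start, end = truth1$mature_end,
                         strand = truth1$strand, n_loci = 1L,
                         multi_locus = FALSE)
  ev <- evaluate_candidates(build_hairpin_candidates(hits, ts$sim$genome))
  expect_true(all(!ev$pass_cut_depth))
  expect_true(all(!ev$accepted))
  hits$count <- 3
  ev3 <- evaluate_candidates(build_hairpin_candidates(hits, ts$sim$genome))
  expect_true(any(ev3$accepted))
})

test_that("acceptance is monotone when thresholds are loosened", {
  ts <- tiny_sim()
  hits <- unannotated_hits(ts$sim, ts$cfg)
  cands <- build_hairpin_candidates(hits, ts$sim$genome)
  strict <- evaluate_candidates(cands, novel_params())
  for (loose_params in list(novel_params(min_pairs_mirna_star = 10),
                            novel_params(max_precursor_mfe = -10),
                            novel_params(max_bulge = 8),
                            novel_params(min_cut_depth = 1))) {
    loose <- evaluate_candidates(cands, loose_params)
    expect_true(all(!strict$accepted | loose$accepted))
  }
})

test_that("no accepted prediction overlaps an annotated feature", {
  ts <- tiny_sim()
  hits <- unannotated_hits(ts$sim, ts$cfg)
  pred <- predict_novel_mirnas(hits, ts$sim$genome)
  feats <- dplyr::filter(ts$sim$truth$features, class != "intergenic")
  pred_lib <- tibble::tibble(tag = unique(pred$mature_seq), count = 1)
  ann <- annotate_tags(map_tags(pred_lib, ts$sim$genome), feats, pred_lib)
  expect_true(all(ann$class == "unan"))
})

test_that("reads mapped to a shuffled genome yield no predictions", {
  ts <- tiny_sim()
  set.seed(123)
  shuffled <- paste(sample(strsplit(ts$sim$genome, "")[[1]]), collapse = "")
  libs <- purrr::imap(ts$sim$libraries, function(r, s) {
    filter_reads(r, ts$cfg$adapter3, ts$cfg$adapter5, stage = s)
  })
  combined <- collapse_tags(dplyr::bind_rows(purrr::map(libs, tibble::as_tibble)))
  hits <- map_tags(combined, c(shuf = shuffled))
  pred <- predict_novel_mirnas(hits, c(shuf = shuffled))
  expect_lte(nrow(pred), 1)
})

test_that("first-base statistics report the uridine fraction", {
  all_u <- tibble::tibble(mature_seq = c("TACG", "TGGA", "TTTA"))
  expect_equal(attr(first_base_stats(all_u), "u_fraction"), 1)
  mixed <- tibble::tibble(mature_seq = c("TAAA", "AAAA", "TCCC", "GCCC"))
  expect_equal(attr(first_base_stats(mixed), "u_fraction"), 0.5)
  empty <- first_base_stats(tibble::tibble(mature_seq = character()))
  expect_equal(nrow(empty), 0)
  # planted 70% uridine starts are recovered within binomial error
  set.seed(99)
  n <- 400
  first <- ifelse(stats::runif(n) < 0.7, "T", sample(c("A", "C", "G"), n, TRUE))
  seqs <- paste0(first, strrep("ACG", 7))
  frac <- attr(first_base_stats(tibble::tibble(mature_seq = seqs)), "u_fraction")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})
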