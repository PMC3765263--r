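test_that("configuration invariants are enforced", {
  expect_error(sim_config(contamination_rates = c(low_quality = 0.5,
                                                  adapter3_null = 0.3,
                                                  insert_null = 0.3,
                                                  adapter5_contaminants = 0,
                                                  smaller_than_18nt = 0,
                                                  polyA = 0)),
               "sum below 1")
  expect_error(sim_config(contamination_rates = c(low_quality = 0.1)),
               "missing")
  expect_error(generate_genome(sim_config(genome_length = 2000)),
               "genome too small")
})

test_that("the generator is a deterministic function of the seed", {
  cfg <- sim_config(seed = 5, reads_per_library = 1500,
                    n_conserved_precursors = 6, n_novel_precursors = 2,
                    genome_length = 40000)
  s1 <- simulate_srna_study(cfg)
  s2 <- simulate_srna_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth$mirnas, s2$truth$mirnas)
  expect_identical(s1$libraries, s2$libraries)
  s3 <- simulate_srna_study(sim_config(seed = 6, reads_per_library = 1500,
                                       n_conserved_precursors = 6,
                                       n_novel_precursors = 2,
                                       genome_length = 40000))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("planted precursors are genuine stem-loops in the genome", {
  ts <- tiny_sim()
  tm <- ts$sim$truth$mirnas
  g <- ts$sim$genome
  for (i in seq_len(nrow(tm))) {
    span <- unname(substr(g, tm$start[i] + 1, tm$end[i]))
    if (tm$strand[i] == "-") span <- reverse_complement(span)
    expect_equal(span, tm$precursor_seq[i])
    expect_equal(substr(tm$precursor_seq[i], 1, nchar(tm$mature_seq[i])),
                 tm$mature_seq[i])
    f <- fold_mfe(tm$precursor_seq[i])
    expect_lte(f$mfe, -18)
    expect_gte(sum(f$pair_table > 0) / 2, 14)
  }
})

test_that("contamination injection matches the recovered accounting exactly", {
  ts <- tiny_sim()
  for (stage in names(ts$sim$libraries)) {
    lib <- filter_reads(ts$sim$libraries[[stage]], ts$cfg$adapter3,
                        ts$cfg$adapter5, stage = stage)
    st <- filter_stats_of(lib)
    counts <- setNames(st$count, st$category)
    manifest <- ts$sim$truth$contamination %>%
      dplyr::filter(stage == !!stage)
    man <- setNames(manifest$count, manifest$category)
    for (cat in c("adapter3_null", "insert_null", "adapter5_contaminants",
                  "smaller_than_18nt", "polyA")) {
      expect_equal(counts[[cat]], man[[cat]], info = paste(stage, cat))
    }
    expect_equal(counts[["total_reads"]] - counts[["high_quality"]],
                 man[["low_quality"]])
    expect_equal(counts[["clean_reads"]],
                 unname(ts$sim$truth$clean_totals[stage]))
  }
})

test_that("zero contamination means clean equals high quality", {
  rates <- c(low_quality = 0, adapter3_null = 0, insert_null = 0,
             adapter5_contaminants = 0, smaller_than_18nt = 0, polyA = 0)
  cfg <- sim_config(seed = 3, reads_per_library = 1200,
                    n_conserved_precursors = 6, n_novel_precursors = 2,
                    genome_length = 40000, contamination_rates = rates)
  sim <- simulate_srna_study(cfg)
  lib <- filter_reads(sim$libraries$anagen, cfg$adapter3, cfg$adapter5)
  st <- filter_stats_of(lib)
  counts <- setNames(st$count, st$category)
  expect_equal(counts[["clean_reads"]], counts[["high_quality"]])
  expect_equal(counts[["high_quality"]], counts[["total_reads"]])
})

test_that("a genome without precursors yields no conserved miRNAs", {
  cfg <- sim_config(seed = 4, reads_per_library = 800,
                    n_conserved_precursors = 0, n_novel_precursors = 0,
                    genome_length = 40000,
                    stage_profiles = tibble::tibble(mirna_id = character(),
                                                    stage = character(),
                                                    expected = numeric()),
                    de_spec = tibble::tibble(mirna_id = character(),
                                             control = character(),
                                             treatment = character(),
                                             fold = numeric()))
  sim <- simulate_srna_study(cfg)
  expect_equal(nrow(sim$truth$mirnas), 0)
  lib <- filter_reads(sim$libraries$anagen, cfg$adapter3, cfg$adapter5)
  out <- match_known_mirnas(lib, character(0), character(0))
  expect_equal(nrow(out), 0)
})

test_that("unknown miRNAs in stage profiles are rejected by name", {
  cfg <- sim_config(seed = 5, reads_per_library = 800,
                    n_conserved_precursors = 4, n_novel_precursors = 1,
                    genome_length = 40000,
                    stage_profiles = tibble::tibble(mirna_id = "ghost-mir",
                                                    stage = "anagen",
                                                    expected = 10))
  expect_error(simulate_srna_study(cfg), "ghost-mir")
})

test_that("written artifacts round-trip through the readers", {
  ts <- tiny_sim()
  dir <- withr::local_tempdir()
  write_simulation(ts$sim, dir)
  g <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(unname(g), unname(ts$sim$genome))
  bed <- read_bed(file.path(dir, "annotation.bed"))
  feats <- dplyr::filter(ts$sim$truth$features, class != "intergenic")
  expect_equal(nrow(bed), nrow(feats))
  expect_setequal(unique(bed$class), unique(feats$class))
  fq <- read_fastq(file.path(dir, "anagen.fastq"))
  expect_equal(nrow(fq), nrow(ts$sim$libraries$anagen))
  expect_equal(fq$sequence, ts$sim$libraries$anagen$sequence)
  mat <- read_fasta(file.path(dir, "reference_matures.fa"))
  cons <- dplyr::filter(ts$sim$truth$mirnas, kind == "conserved")
  expect_equal(unname(mat[cons$mirna_id]), cons$mature_seq)
  g2t <- read_gene2term(file.path(dir, "gene2go.tsv"))
  expect_true(all(c("gene", "term") %in% names(g2t)))
})
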