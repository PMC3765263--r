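ad3 <- "TCGTATGCCGTCTTCTGCTTG"
ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
seed5 <- substr(ad5, nchar(ad5) - 5, nchar(ad5))

test_that("reads are classified once each, in precedence order", {
  insert22 <- "ACGTGCATCGTAGCTAGCTAGC"
  insert16 <- "ACGTGCATCGTAGCTA"
  reads <- dplyr::bind_rows(
    reads_from_inserts(insert22, ad3),                       # clean
    reads_from_inserts(strrep("A", 22), ad3),                # polyA
    reads_from_inserts(insert16, ad3),                       # < 18 nt
    reads_from_inserts(paste0(seed5, "ACGTACGTACGTACGT"), ad3),  # 5' adapter
    reads_from_inserts("", ad3),                             # empty insert
    tibble::tibble(id = "noad", sequence = strrep("C", 36),
                   quality = strrep("I", 36)),               # no 3' adapter
    tibble::tibble(id = "lowq", sequence = paste0("NNN", strrep("C", 33)),
                   quality = strrep("I", 36)))               # low quality
  lib <- filter_reads(reads, ad3, ad5, stage = "anagen")
  st <- filter_stats_of(lib)
  counts <- setNames(st$count, st$category)
  expect_equal(counts[["total_reads"]], 7)
  expect_equal(counts[["high_quality"]], 6)
  expect_equal(counts[["adapter3_null"]], 1)
  expect_equal(counts[["insert_null"]], 1)
  expect_equal(counts[["adapter5_contaminants"]], 1)
  expect_equal(counts[["smaller_than_18nt"]], 1)
  expect_equal(counts[["polyA"]], 1)
  expect_equal(counts[["clean_reads"]], 1)
  expect_equal(lib$tag, insert22)
  expect_equal(clean_total(lib), 1)
  expect_equal(library_stage(lib), "anagen")
  # a read failing several rules counts at the first failing rule:
  # polyA insert shorter than 18 nt is polyA, not smaller_than_18nt
  lib2 <- filter_reads(reads_from_inserts(strrep("A", 16), ad3), ad3, ad5)
  st2 <- filter_stats_of(lib2)
  expect_equal(st2$count[st2$category == "polyA"], 1)
  expect_equal(st2$count[st2$category == "smaller_than_18nt"], 0)
})

test_that("the category partition holds on random fuzzed input", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 300
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), 36, TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = "")
    }, "")
    quals <- vapply(seq_len(n), function(i) {
      paste(sample(c("I", "#", "5"), 36, TRUE, prob = c(.8, .1, .1)),
            collapse = "")
    }, "")
    lib <- filter_reads(tibble::tibble(id = as.character(1:n),
                                       sequence = seqs, quality = quals),
                        ad3, ad5)
    st <- filter_stats_of(lib)
    counts <- setNames(st$count, st$category)
    expect_equal(sum(counts[c("adapter3_null", "insert_null",
                              "adapter5_contaminants", "smaller_than_18nt",
                              "polyA", "clean_reads")]),
                 counts[["high_quality"]])
    expect_lte(counts[["high_quality"]], counts[["total_reads"]])
    expect_equal(sum(lib$count), counts[["clean_reads"]])
  }
})

test_that("filtering is idempotent on its own clean output", {
  sim <- tiny_sim()
  lib <- filter_reads(sim$sim$libraries$anagen, sim$cfg$adapter3,
                      sim$cfg$adapter5)
  again <- filter_reads(reads_from_inserts(rep(lib$tag, lib$count),
                                           sim$cfg$adapter3),
                        sim$cfg$adapter3, sim$cfg$adapter5)
  st <- filter_stats_of(again)
  expect_equal(st$count[st$category == "clean_reads"], clean_total(lib))
  expect_equal(again$tag, lib$tag)
  expect_equal(again$count, lib$count)
})

test_that("malformed and empty FASTQ are handled per contract", {
  tf <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), tf)   # quality too short
  expect_error(read_fastq(tf), "record 1")
  writeLines(c("r1", "ACGT", "+", "IIII"), tf)
  expect_error(read_fastq(tf), "header")
  writeLines(character(0), tf)
  lib <- filter_reads(tf, ad3, ad5)
  st <- filter_stats_of(lib)
  expect_true(all(st$count == 0))
  expect_equal(nrow(lib), 0)
})

test_that("collapse_tags merges duplicates deterministically", {
  reads <- tibble::tibble(sequence = c(rep("ACGTACGTACGTACGTAA", 3),
                                       rep("TTGACCGTACGTACGTAC", 2)))
  tags <- collapse_tags(reads)
  expect_equal(tags$tag, sort(unique(reads$sequence)))
  expect_equal(tags$count[match("ACGTACGTACGTACGTAA", tags$tag)], 3)
  expect_equal(tags$count[match("TTGACCGTACGTACGTAC", tags$tag)], 2)
  # all distinct: one tag per read
  distinct_reads <- tibble::tibble(
    sequence = vapply(1:10, function(i) paste0(strrep("A", 17), LETTERS[i]), ""))
  expect_equal(nrow(collapse_tags(tibble::tibble(
    sequence = replicate(10, paste(sample(c("A","C","G","T"), 20, TRUE),
                                   collapse = ""))))), 10)
})

test_that("length distribution reports total and distinct histograms", {
  lib <- tibble::tibble(tag = strrep("A", 22), count = 10)
  ld <- length_distribution(list(x = lib))
  expect_equal(ld$length, 22)
  expect_equal(ld$total, 10)
  expect_equal(ld$distinct, 1)
  expect_equal(nrow(length_distribution(list(x = lib[0, ]))), 0)
})

test_that("simulated libraries peak at 22 nt", {
  sim <- tiny_sim()
  lib <- filter_reads(sim$sim$libraries$anagen, sim$cfg$adapter3,
                      sim$cfg$adapter5)
  ld <- length_distribution(list(anagen = lib))
  expect_equal(ld$length[which.max(ld$total)], 22)
})

test_that("filter_stats enforces the accounting invariants", {
  good <- c(total_reads = 100, high_quality = 95, adapter3_null = 5,
            insert_null = 5, adapter5_contaminants = 5,
            smaller_than_18nt = 5, polyA = 5)
  st <- filter_stats(good)
  expect_equal(st$count[st$category == "clean_reads"], 70)
  expect_equal(st$percent[st$category == "clean_reads"], 100 * 70 / 95)
  bad <- good; bad["high_quality"] <- 120
  expect_error(filter_stats(bad), "exceed")
  bad2 <- c(good, clean_reads = 60)
  expect_error(filter_stats(bad2), "partition")
})
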