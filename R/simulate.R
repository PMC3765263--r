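NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA")

#' Configuration for the synthetic small-RNA study generator
#'
#' Defines the study conditions emulated by the generator: a toy genome
#' carrying planted miRNA precursors (perfect stem-loops: mature arm,
#' 8-20 nt loop, reverse-complement star arm) and non-overlapping ncRNA /
#' repeat / exon / intron features; three stage-labelled read libraries
#' whose per-miRNA counts are Poisson draws around the stage profiles;
#' adapter chemistry; and contaminant reads injected at fixed per-category
#' rates.
#'
#' @param genome_length Genome size in bases.
#' @param n_conserved_precursors,n_novel_precursors Numbers of planted
#'   miRNA precursors with (conserved) and without (novel) reference
#'   records.
#' @param n_ncrna_loci_per_class Loci planted for each of rRNA, tRNA,
#'   snRNA, snoRNA, scRNA, srpRNA.
#' @param n_repeats,n_exons,n_introns Numbers of repeat/exon/intron loci.
#' @param stage_profiles Optional tibble `mirna_id`, `stage`, `expected`
#'   of Poisson mean counts; by default built at generation time (a
#'   lognormal abundance spread, three stage-specific miRNAs per stage,
#'   and the `de_spec` fold changes).
#' @param de_spec Optional tibble `mirna_id`, `control`, `treatment`,
#'   `fold` of planted fold changes; by default four conserved miRNAs
#'   carry a 4-fold anagen/telogen difference at deep (>= 500) counts.
#' @param adapter3,adapter5 Adapter sequences ligated 3' and 5' of the
#'   insert.
#' @param contamination_rates Named fractions of `reads_per_library` for
#'   `low_quality`, `adapter3_null`, `insert_null`,
#'   `adapter5_contaminants`, `smaller_than_18nt`, `polyA`. Each in
#'   [0, 1], summing below 1.
#' @param reads_per_library Total reads per stage library.
#' @param read_length Read length in cycles; inserts are 18-30 nt with a
#'   22 nt mode, followed by the 3' adapter, truncated to this length.
#' @param n_genes,utr_length 3'UTR set written for target prediction.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000,
                       n_conserved_precursors = 30,
                       n_novel_precursors = 8,
                       n_ncrna_loci_per_class = 4,
                       n_repeats = 6, n_exons = 8, n_introns = 8,
                       stage_profiles = NULL, de_spec = NULL,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       contamination_rates = c(low_quality = 0.006,
                                               adapter3_null = 0.003,
                                               insert_null = 0.004,
                                               adapter5_contaminants = 0.002,
                                               smaller_than_18nt = 0.02,
                                               polyA = 0.001),
                       reads_per_library = 50000,
                       read_length = 36,
                       n_genes = 40, utr_length = 300,
                       seed = 1) {
  stopifnot(reads_per_library > 0, genome_length > 0, read_length >= 30,
            n_genes >= 14)
  if (any(contamination_rates < 0 | contamination_rates > 1) ||
      sum(contamination_rates) >= 1) {
    abort("contamination rates must each lie in [0,1] and sum below 1")
  }
  needed <- c("low_quality", "adapter3_null", "insert_null",
              "adapter5_contaminants", "smaller_than_18nt", "polyA")
  missing <- setdiff(needed, names(contamination_rates))
  if (length(missing) > 0) {
    abort(paste0("contamination_rates missing: ", paste(missing, collapse = ", ")))
  }
  structure(as.list(environment()), class = "sim_config")
}

# An insert is unambiguous for the read classifier when it contains no 3'
# adapter seed (also not across the insert/adapter boundary), no 5' adapter
# seed, and is not polyA-like.
insert_is_unambiguous <- function(s, cfg) {
  seed3 <- substr(cfg$adapter3, 1, 6)
  seed5 <- substr(cfg$adapter5, nchar(cfg$adapter5) - 5, nchar(cfg$adapter5))
  !grepl(seed5, s, fixed = TRUE) &
    base_fraction(s, "A") < 0.85 &
    regexpr(seed3, paste0(s, cfg$adapter3), fixed = TRUE) == nchar(s) + 1
}

# Draw a random sequence avoiding adapter seeds, N runs and polyA so a
# clean insert can never be misclassified.
random_clean_insert <- function(len, cfg, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (insert_is_unambiguous(s, cfg)) return(s)
  }
  abort("could not draw a clean insert; adapters too repetitive?")
}

#' Generate the toy genome and its ground truth
#'
#' Builds a random genome and plants, without overlap: conserved and
#' novel miRNA precursors (each a perfect stem-loop whose excised window
#' is verified to pass every candidate criterion under the default
#' folding model), ncRNA loci of six classes, repeats, exons, introns,
#' and unannotated intergenic pools that later source background reads.
#' Also lays out stage expression profiles, planted fold changes, a 3'UTR
#' gene set with planted perfect-complement target sites, and GO/pathway
#' gene-term mappings with one deliberately enriched term.
#'
#' Sets the RNG from `config$seed`: the same configuration always yields
#' a byte-identical genome and truth.
#'
#' @param config A [sim_config()].
#' @return A list `genome` (named character vector of one contig) and
#'   `truth` (list of tibbles: `mirnas`, `features`, `profiles`, `de`,
#'   `utrs`, `gene2go`, `gene2pathway`, `target_sites`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  # --- feature layout ---------------------------------------------------
  n_cons <- cfg$n_conserved_precursors
  n_nov <- cfg$n_novel_precursors
  feat <- list()
  add <- function(class, len, source = NA_character_) {
    feat[[length(feat) + 1]] <<- list(class = class, len = len, source = source)
  }
  for (i in seq_len(n_cons)) add("miRNA", NA)          # length set when built
  for (i in seq_len(n_nov)) add("novel", NA)
  for (cl in NCRNA_CLASSES) {
    for (i in seq_len(cfg$n_ncrna_loci_per_class)) {
      add(cl, sample(80:300, 1), source = if (i %% 2 == 1) "GenBank" else "Rfam")
    }
  }
  for (i in seq_len(cfg$n_repeats)) add("repeat", sample(100:200, 1))
  for (i in seq_len(cfg$n_exons)) add("exon", sample(150:300, 1))
  for (i in seq_len(cfg$n_introns)) add("intron", sample(200:400, 1))
  for (i in seq_len(6)) add("intergenic", 400)

  # plant precursors: mature arm + loop + reverse complement of the arm;
  # the geometry is stored with the feature so it survives the shuffle
  for (k in seq_along(feat)) {
    if (feat[[k]]$class %in% c("miRNA", "novel")) {
      # mature lengths mirror the sharp 22-nt mode of real miRNomes
      feat[[k]]$mlen <- sample(20:24, 1, prob = c(.05, .15, .55, .18, .07))
      feat[[k]]$loop <- sample(8:20, 1)
      feat[[k]]$len <- feat[[k]]$mlen * 2 + feat[[k]]$loop
    }
  }

  feat <- feat[sample(length(feat))]           # shuffle order on the genome
  lens <- vapply(feat, function(f) f$len, 0)
  min_gap <- 80
  need <- sum(lens) + (length(feat) + 1) * min_gap
  if (need > cfg$genome_length) {
    abort(sprintf("genome too small to host features: need >= %d bases, have %d",
                  need, cfg$genome_length))
  }
  slack <- cfg$genome_length - need
  extra <- as.vector(stats::rmultinom(1, slack, rep(1, length(feat) + 1)))
  gaps <- min_gap + extra
  n_f <- length(lens)
  starts <- cumsum(c(gaps[1], head(lens, -1) + gaps[2:n_f]))  # 0-based starts

  genome_chars <- sample(DNA_BASES, cfg$genome_length, replace = TRUE)
  chrom <- "chr_sim1"

  # embed a hairpin core at a 0-based start; returns its description
  embed_hairpin <- function(start0, mlen, loop, strand) {
    repeat {
      # matures start with U (T in DNA) 70% of the time, the hallmark
      # 5'-uridine bias of Dicer products
      repeat {
        mature <- random_clean_insert(mlen, cfg)
        if (runif(1) < 0.7) substr(mature, 1, 1) <- "T"
        if (insert_is_unambiguous(mature, cfg)) break
      }
      core <- paste0(mature, random_dna(loop), reverse_complement(mature))
      placed <- if (strand == "+") core else reverse_complement(core)
      genome_chars[(start0 + 1):(start0 + nchar(core))] <<-
        strsplit(placed, "")[[1]]
      if (strand == "+") {
        ms <- start0; me <- start0 + mlen
      } else {
        ms <- start0 + nchar(core) - mlen; me <- start0 + nchar(core)
      }
      ok <- hairpin_passes(genome_chars, chrom, ms, me, strand)
      if (ok) {
        return(list(mature = mature, star = reverse_complement(mature),
                    core = core, mstart = ms, mend = me))
      }
    }
  }

  mirna_rows <- list()
  feature_rows <- list()
  hp_i <- 0
  for (k in seq_along(feat)) {
    f <- feat[[k]]
    s0 <- starts[k]
    if (f$class %in% c("miRNA", "novel")) {
      hp_i <- hp_i + 1
      strand <- sample(c("+", "-"), 1)
      emb <- embed_hairpin(s0, f$mlen, f$loop, strand)
      kind <- if (f$class == "miRNA") "conserved" else "novel"
      id <- if (kind == "conserved") sprintf("bta-miR-s%03d", hp_i)
            else sprintf("novel-true-%03d", hp_i)
      mirna_rows[[length(mirna_rows) + 1]] <- tibble(
        mirna_id = id, kind = kind, chrom = chrom,
        start = s0, end = s0 + f$len, strand = strand,
        precursor_seq = emb$core, mature_seq = emb$mature,
        star_seq = emb$star, mature_start = emb$mstart,
        mature_end = emb$mend)
      if (kind == "conserved") {
        feature_rows[[length(feature_rows) + 1]] <- tibble(
          chrom = chrom, start = s0, end = s0 + f$len, class = "miRNA",
          source = NA_character_, strand = strand)
      }
    } else if (f$class != "intergenic") {
      feature_rows[[length(feature_rows) + 1]] <- tibble(
        chrom = chrom, start = s0, end = s0 + f$len, class = f$class,
        source = f$source, strand = sample(c("+", "-"), 1))
    } else {
      feature_rows[[length(feature_rows) + 1]] <- tibble(
        chrom = chrom, start = s0, end = s0 + f$len, class = "intergenic",
        source = NA_character_, strand = "+")
    }
  }
  mirnas <- if (length(mirna_rows) == 0) {
    tibble(mirna_id = character(), kind = character(), chrom = character(),
           start = numeric(), end = numeric(), strand = character(),
           precursor_seq = character(), mature_seq = character(),
           star_seq = character(), mature_start = numeric(),
           mature_end = numeric())
  } else bind_rows(mirna_rows)
  features <- bind_rows(feature_rows)

  # --- stage profiles and planted differential expression ---------------
  cons_ids <- mirnas$mirna_id[mirnas$kind == "conserved"]
  nov_ids <- mirnas$mirna_id[mirnas$kind == "novel"]
  de_spec <- cfg$de_spec
  profiles <- cfg$stage_profiles
  if (is.null(profiles)) {
    de_ids <- head(cons_ids, 4)
    pool <- setdiff(cons_ids, de_ids)
    spec <- head(pool, min(9, length(pool)))
    grp <- rep(HF_STAGES, each = 3)[seq_along(spec)]
    spec_anagen <- spec[grp == "anagen"]
    spec_catagen <- spec[grp == "catagen"]
    spec_telogen <- spec[grp == "telogen"]
    rest <- setdiff(pool, spec)
    base <- round(exp(stats::rnorm(length(rest), log(250), 0.7)))
    base <- pmax(base, 30)
    rows <- list(
      tidyr::expand_grid(mirna_id = de_ids, stage = HF_STAGES) %>%
        mutate(expected = dplyr::case_when(stage == "anagen" ~ 2000,
                                           stage == "catagen" ~ 1000,
                                           TRUE ~ 500)),
      tidyr::expand_grid(mirna_id = spec_anagen, stage = HF_STAGES) %>%
        mutate(expected = ifelse(.data$stage == "anagen", 300, 0)),
      tidyr::expand_grid(mirna_id = spec_catagen, stage = HF_STAGES) %>%
        mutate(expected = ifelse(.data$stage == "catagen", 300, 0)),
      tidyr::expand_grid(mirna_id = spec_telogen, stage = HF_STAGES) %>%
        mutate(expected = ifelse(.data$stage == "telogen", 300, 0)),
      tidyr::expand_grid(mirna_id = rest, stage = HF_STAGES) %>%
        left_join(tibble(mirna_id = rest, base = base), by = "mirna_id") %>%
        mutate(expected = .data$base) %>% select(-"base"),
      tidyr::expand_grid(mirna_id = nov_ids, stage = HF_STAGES) %>%
        mutate(expected = dplyr::case_when(
          .data$mirna_id %in% head(nov_ids, 2) & .data$stage != "anagen" ~ 0,
          TRUE ~ 150))
    )
    profiles <- bind_rows(rows)
    if (is.null(de_spec)) {
      de_spec <- tibble(mirna_id = de_ids, control = "anagen",
                        treatment = "telogen", fold = 4)
    }
  }
  if (is.null(de_spec)) {
    de_spec <- tibble(mirna_id = character(), control = character(),
                      treatment = character(), fold = numeric())
  }
  unknown <- setdiff(profiles$mirna_id, mirnas$mirna_id)
  if (length(unknown) > 0) {
    abort(paste0("stage profile references unknown miRNA(s): ",
                 paste(unknown, collapse = ", ")))
  }

  # --- UTRs, planted target sites, term mappings ------------------------
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  utrs <- setNames(vapply(genes, function(g) random_dna(cfg$utr_length), ""),
                   genes)
  target_mirnas <- head(cons_ids, min(5, length(cons_ids)))
  target_genes <- if (length(target_mirnas) > 0) {
    head(genes, min(10, length(genes)))
  } else character(0)
  site_rows <- list()
  for (g in target_genes) {
    mid <- target_mirnas[1 + (match(g, target_genes) - 1) %% length(target_mirnas)]
    mseq <- mirnas$mature_seq[mirnas$mirna_id == mid]
    site <- reverse_complement(mseq)
    pos <- sample(seq_len(cfg$utr_length - nchar(site) - 10), 1) + 5
    substr(utrs[[g]], pos, pos + nchar(site) - 1) <- site
    site_rows[[length(site_rows) + 1]] <- tibble(
      gene_id = g, mirna_id = mid, start = pos - 1L,
      end = pos - 1L + nchar(site))
  }
  target_sites <- bind_rows(site_rows)

  # every gene carries the root term, so the annotation universe is the
  # whole gene set (as in curated ontologies); one term is deliberately
  # concentrated on the planted target genes
  go_terms <- sprintf("GO:%07d", seq_len(12))
  gene2go <- bind_rows(
    tibble(gene = genes, term = "GO:0000099"),
    tibble(gene = c(target_genes, genes[11:12]), term = "GO:0000001"),
    purrr::map(go_terms[-1], function(tm) {
      tibble(gene = sample(genes, sample(6:14, 1)), term = tm)
    })) %>% distinct() %>% arrange(.data$term, .data$gene)
  path_terms <- sprintf("path:sim%05d", seq_len(8))
  gene2pathway <- bind_rows(
    tibble(gene = genes, term = "path:sim00099"),
    tibble(gene = c(head(target_genes, 8), genes[13:14]),
           term = "path:sim00001"),
    purrr::map(path_terms[-1], function(tm) {
      tibble(gene = sample(genes, sample(6:14, 1)), term = tm)
    })) %>% distinct() %>% arrange(.data$term, .data$gene)

  truth <- list(mirnas = mirnas, features = features, profiles = profiles,
                de = de_spec, utrs = utrs, target_sites = target_sites,
                gene2go = gene2go, gene2pathway = gene2pathway,
                enriched_go = "GO:0000001", enriched_pathway = "path:sim00001")
  list(genome = setNames(paste(genome_chars, collapse = ""), chrom),
       truth = truth)
}

# Check that the planted hairpin, excised exactly as the candidate
# builder will excise it, passes every criterion at default parameters.
hairpin_passes <- function(genome_chars, chrom, ms, me, strand) {
  genome <- setNames(paste(genome_chars, collapse = ""), chrom)
  hits <- tibble(tag = "x", count = 10, chrom = chrom,
                 start = ms, end = me, strand = strand,
                 n_loci = 1L, multi_locus = FALSE)
  hits$tag <- if (strand == "+") substr(genome, ms + 1, me) else
    reverse_complement(substr(genome, ms + 1, me))
  cand <- build_hairpin_candidates(hits, genome, novel_params())
  ev <- evaluate_candidates(cand, novel_params(), energy_model())
  any(ev$accepted)
}

#' Simulate the three stage-labelled read libraries
#'
#' Clean reads are planted mature miRNAs (counts Poisson around the stage
#' profile) and 18-30 nt fragments (modal 22 nt) sampled from the ncRNA,
#' repeat, exon, intron and intergenic loci, each followed by the 3'
#' adapter and truncated to the read length. Contaminant reads of the six
#' categories are injected at the configured per-library rates and are
#' constructed to be unambiguous, so the filtering accounting can be
#' compared to the manifest exactly. Quality strings are constant high
#' quality; low-quality reads carry N bases instead.
#'
#' Sets the RNG from `config$seed + 1` (offset so it does not replay the
#' genome stream); identical config and genome give byte-identical reads.
#'
#' @param genome,truth Output of [generate_genome()].
#' @param config The same [sim_config()].
#' @return A list `libraries` (named list of read tibbles `id`,
#'   `sequence`, `quality`), `abundance` (realized per-stage mature
#'   counts), `contamination` (realized per-category injection counts),
#'   `clean_totals`.
#' @export
simulate_reads <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  unknown <- setdiff(truth$profiles$mirna_id, truth$mirnas$mirna_id)
  if (length(unknown) > 0) {
    abort(paste0("stage profile references unknown miRNA(s): ",
                 paste(unknown, collapse = ", ")))
  }
  set.seed(cfg$seed + 1)
  qual <- function(n) strrep("I", n)
  seed3 <- substr(cfg$adapter3, 1, 6)
  seed5 <- substr(cfg$adapter5, nchar(cfg$adapter5) - 5, nchar(cfg$adapter5))
  finish_read <- function(insert) {
    substr(paste0(insert, cfg$adapter3, strrep("A", cfg$read_length)),
           1, cfg$read_length)
  }

  pools <- filter(truth$features,
                  !.data$class %in% c("miRNA"))
  pool_seq <- substr(rep(genome, nrow(pools)), pools$start + 1, pools$end)
  # rRNA dominates the non-miRNA background of animal small-RNA samples;
  # oversample it so the mapped rRNA share lands near the 30-40% regime
  # the quality check is designed for.
  pool_w <- ifelse(pools$class == "rRNA", 10, 1)

  frag_from_pool <- function(n) {
    if (n <= 0) return(character(0))
    idx <- sample(nrow(pools), n, replace = TRUE, prob = pool_w)
    lens <- pmin(30, pmax(18, round(stats::rnorm(n, 22, 2.2))))
    starts <- floor(runif(n) * (nchar(pool_seq[idx]) - lens)) + 1
    frags <- substr(pool_seq[idx], starts, starts + lens - 1)
    bad <- !insert_is_unambiguous(frags, cfg)
    while (any(bad)) {
      m <- sum(bad)
      idx2 <- sample(nrow(pools), m, replace = TRUE, prob = pool_w)
      lens2 <- pmin(30, pmax(18, round(stats::rnorm(m, 22, 2.2))))
      starts2 <- floor(runif(m) * (nchar(pool_seq[idx2]) - lens2)) + 1
      frags[bad] <- substr(pool_seq[idx2], starts2, starts2 + lens2 - 1)
      bad <- !insert_is_unambiguous(frags, cfg)
    }
    frags
  }

  n_cat <- round(cfg$contamination_rates * cfg$reads_per_library)
  libraries <- list()
  abund_rows <- list()
  contam_rows <- list()
  clean_totals <- numeric(0)

  for (stage in HF_STAGES) {
    prof <- filter(truth$profiles, .data$stage == !!stage)
    realized <- stats::rpois(nrow(prof), prof$expected)
    abund_rows[[stage]] <- tibble(mirna_id = prof$mirna_id, stage = stage,
                                  expected = prof$expected, count = realized)
    mat <- truth$mirnas$mature_seq[match(prof$mirna_id, truth$mirnas$mirna_id)]
    mirna_inserts <- rep(mat, realized)

    n_clean_target <- cfg$reads_per_library - sum(n_cat)
    n_frag <- max(0, n_clean_target - length(mirna_inserts))
    frag_inserts <- frag_from_pool(n_frag)
    clean_inserts <- c(mirna_inserts, frag_inserts)

    # contaminants, each unambiguous for the classifier
    lowq <- vapply(seq_len(n_cat[["low_quality"]]), function(i) {
      ins <- random_clean_insert(22, cfg)
      substr(ins, 5, 7) <- "NNN"
      finish_read(ins)
    }, "")
    a3null <- vapply(seq_len(n_cat[["adapter3_null"]]), function(i) {
      repeat {
        s <- random_dna(cfg$read_length)
        if (!grepl(seed3, s, fixed = TRUE)) return(s)
      }
    }, "")
    insnull <- vapply(seq_len(n_cat[["insert_null"]]), function(i) {
      finish_read("")
    }, "")
    a5cont <- vapply(seq_len(n_cat[["adapter5_contaminants"]]), function(i) {
      repeat {
        ins <- paste0(seed5, random_dna(16))
        # must carry the 5' adapter seed but stay clean of the 3' seed
        # and the polyA rule so it is classified at the 5'-adapter step
        if (base_fraction(ins, "A") < 0.85 &&
            regexpr(seed3, paste0(ins, cfg$adapter3), fixed = TRUE) ==
              nchar(ins) + 1) {
          return(finish_read(ins))
        }
      }
    }, "")
    short <- vapply(seq_len(n_cat[["smaller_than_18nt"]]), function(i) {
      finish_read(random_clean_insert(sample(15:17, 1), cfg))
    }, "")
    polya <- vapply(seq_len(n_cat[["polyA"]]), function(i) {
      finish_read(strrep("A", 22))
    }, "")

    seqs <- c(finish_read(clean_inserts), lowq, a3null, insnull, a5cont,
              short, polya)
    categories <- c(rep("clean", length(clean_inserts)),
                    rep("low_quality", length(lowq)),
                    rep("adapter3_null", length(a3null)),
                    rep("insert_null", length(insnull)),
                    rep("adapter5_contaminants", length(a5cont)),
                    rep("smaller_than_18nt", length(short)),
                    rep("polyA", length(polya)))
    ord <- sample(length(seqs))
    reads <- tibble(
      id = sprintf("%s_%07d", stage, seq_along(seqs)),
      sequence = seqs[ord],
      quality = qual(nchar(seqs[ord])))
    libraries[[stage]] <- reads
    contam_rows[[stage]] <- tibble(stage = stage,
                                   category = names(n_cat),
                                   count = as.numeric(n_cat))
    clean_totals[stage] <- length(clean_inserts)
  }

  list(libraries = libraries,
       abundance = bind_rows(abund_rows),
       contamination = bind_rows(contam_rows),
       clean_totals = clean_totals)
}

#' Run the whole generator: genome, truth, reads, manifest
#'
#' Convenience wrapper calling [generate_genome()] then
#' [simulate_reads()] and assembling the complete ground-truth manifest
#' (planted loci, realized abundances, contamination counts, stage
#' membership and differential-expression flags).
#'
#' @param config A [sim_config()].
#' @return A list `genome`, `truth`, `libraries`, `manifest`.
#' @export
simulate_srna_study <- function(config = sim_config()) {
  gen <- generate_genome(config)
  reads <- simulate_reads(gen$genome, gen$truth, config)
  truth <- gen$truth
  truth$abundance <- reads$abundance
  truth$contamination <- reads$contamination
  truth$clean_totals <- reads$clean_totals
  membership <- truth$abundance %>%
    filter(.data$count >= 1) %>%
    group_by(.data$mirna_id) %>%
    summarise(region = if (dplyr::n() == 3) "all"
              else paste(sort(.data$stage), collapse = "&"),
              .groups = "drop")
  truth$membership <- left_join(
    membership,
    truth$mirnas[, c("mirna_id", "kind")], by = "mirna_id")
  list(genome = gen$genome, truth = truth, libraries = reads$libraries,
       manifest = truth)
}

#' Write a simulated study to disk in interchange formats
#'
#' Writes the genome FASTA, feature-annotation BED, synthetic reference
#' precursor and mature FASTA (conserved miRNAs only), 3'UTR FASTA,
#' gene-to-GO and gene-to-pathway TSVs, one FASTQ per stage, and the
#' ground-truth manifest JSON.
#'
#' @param sim Output of [simulate_srna_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fasta(sim$genome, p("genome.fa"))
  feats <- filter(sim$truth$features, .data$class != "intergenic")
  write_bed(feats, p("annotation.bed"))
  cons <- filter(sim$truth$mirnas, .data$kind == "conserved")
  write_fasta(setNames(cons$precursor_seq, paste0(cons$mirna_id, "-pre")),
              p("reference_precursors.fa"))
  write_fasta(setNames(cons$mature_seq, cons$mirna_id),
              p("reference_matures.fa"))
  write_fasta(sim$truth$utrs, p("utrs.fa"))
  write.table(sim$truth$gene2go, p("gene2go.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$truth$gene2pathway, p("gene2pathway.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (stage in names(sim$libraries)) {
    write_fastq(sim$libraries[[stage]], p(paste0(stage, ".fastq")))
  }
  manifest <- sim$truth
  manifest$utrs <- as.list(manifest$utrs)
  jsonlite::write_json(manifest, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
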