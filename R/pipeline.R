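#' Assemble a pipeline configuration
#'
#' Collects the input paths and module parameters for [run_pipeline()].
#' `pipeline_config()` builds the list in code;
#' `read_pipeline_config()` loads the same structure from a YAML file.
#' For a directory written by [write_simulation()],
#' [simulation_paths()] fills the paths automatically.
#'
#' @param fastq Named character vector of FASTQ paths (names are stage
#'   labels, e.g. anagen/catagen/telogen).
#' @param genome,annotation,precursors,matures,utrs,gene2go,gene2pathway
#'   Paths to the genome FASTA, feature BED, reference precursor and
#'   mature FASTA, 3'UTR FASTA, and the gene-to-term TSVs.
#' @param adapter3,adapter5 Adapter sequences used at filtering.
#' @param params A [novel_params()] object.
#' @param rules A [target_rules()] object.
#' @param model An [energy_model()] object.
#' @param out_dir Optional directory for TSV/FASTA/JSON artifacts.
#' @param k_clusters Clusters for the fold-change profile clustering.
#' @param seed Seed stored with the run (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fastq, genome, annotation, precursors, matures,
                            utrs = NULL, gene2go = NULL, gene2pathway = NULL,
                            adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                            params = novel_params(), rules = target_rules(),
                            model = energy_model(), out_dir = NULL,
                            k_clusters = 5, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with fields matching the `pipeline_config()`
#'   arguments (`fastq` as a stage->path mapping).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$fastq <- unlist(y$fastq)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' @rdname pipeline_config
#' @param dir Directory written by [write_simulation()].
#' @param ... Overrides passed on to `pipeline_config()`.
#' @export
simulation_paths <- function(dir, ...) {
  fq <- setNames(file.path(dir, paste0(HF_STAGES, ".fastq")), HF_STAGES)
  pipeline_config(
    fastq = fq,
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.bed"),
    precursors = file.path(dir, "reference_precursors.fa"),
    matures = file.path(dir, "reference_matures.fa"),
    utrs = file.path(dir, "utrs.fa"),
    gene2go = file.path(dir, "gene2go.tsv"),
    gene2pathway = file.path(dir, "gene2pathway.tsv"),
    ...)
}

validate_pipeline_config <- function(config) {
  req <- c(config$fastq, config$genome, config$annotation,
           config$precursors, config$matures)
  opt <- c(config$utrs, config$gene2go, config$gene2pathway)
  missing <- c(req, opt)[!file.exists(c(req, opt))]
  if (length(missing) > 0) {
    abort(paste0("pipeline input file(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(config$fastq) < 2 || is.null(names(config$fastq))) {
    abort("need at least two named stage FASTQ files")
  }
  invisible(config)
}

#' Run the full small-RNA analysis
#'
#' Executes the stages in dependency order: read filtering and tag
#' collapsing per library; genome mapping and priority annotation;
#' conserved miRNA quantification with stage membership and top tables;
#' novel miRNA prediction from the unannotated tags; target prediction of
#' the detected conserved miRNAs against the UTR set; pairwise
#' differential expression with classification and profile clustering;
#' and GO/pathway enrichment of the predicted target genes. When
#' `config$out_dir` is set, every stage writes its TSV/FASTA artifacts
#' plus a machine-readable `summary.json`.
#'
#' @param config A `pipeline_config` (or path to its YAML form).
#' @return A list with one element per stage (`libraries`, `stats`,
#'   `annotation`, `conserved`, `novel`, `targets`, `diffexp`,
#'   `enrichment`) and `summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  genome <- read_fasta(config$genome)
  features <- read_bed(config$annotation)
  precursors <- read_fasta(config$precursors)
  matures <- read_fasta(config$matures)

  libraries <- run_stage("preprocess", {
    purrr::imap(as.list(config$fastq), function(fq, stage) {
      filter_reads(fq, config$adapter3, config$adapter5, stage = stage)
    })
  })
  stats <- purrr::imap(libraries, function(l, s) {
    mutate(filter_stats_of(l), library = s, .before = 1)
  }) %>% bind_rows()
  lengths <- length_distribution(libraries)

  combined <- run_stage("collapse", {
    collapse_tags(bind_rows(purrr::map(libraries, as_tibble)))
  })
  hits <- run_stage("map", map_tags(combined, genome,
                                    max_loci = config$params$max_copy_number))
  per_tag <- run_stage("annotate", annotate_tags(hits, features, combined))
  ann_summary <- annotation_summary(per_tag)
  rrna <- rrna_quality_check(ann_summary)

  expr <- run_stage("conserved", {
    mirna_expression(libraries, precursors, matures)
  })
  membership <- stage_membership(expr)
  venn <- venn_counts(membership)
  top10 <- top_expressed(expr, 10)

  unan_tags <- per_tag$tag[per_tag$class == "unan"]
  novel <- run_stage("novel", {
    predict_novel_mirnas(filter(hits, .data$tag %in% unan_tags), genome,
                         config$params, config$model)
  })
  novel_expr <- novel_expression(novel, libraries)
  novel_venn <- if (nrow(novel) > 0) {
    venn_counts(stage_membership(novel_expr))
  } else tibble(region = character(), n = integer())
  fb <- first_base_stats(novel)

  clean_totals <- vapply(libraries, clean_total, 0)
  de <- run_stage("diffexp", diff_expression(expr, clean_totals))
  de_kept <- filter(de, !.data$excluded)
  clusters <- if (length(unique(de$mirna_id)) > 0) {
    cluster_profiles(de, k = config$k_clusters)
  } else tibble(mirna_id = character(), cluster = integer())

  targets <- NULL; enr_go <- NULL; enr_path <- NULL
  if (!is.null(config$utrs)) {
    detected <- unique(expr$mirna_id[expr$count > 0])
    targets <- run_stage("targets", {
      predict_targets(matures[names(matures) %in% detected],
                      read_fasta(config$utrs), config$rules, config$model)
    })
    target_genes <- unique(targets$gene_id)
    if (!is.null(config$gene2go)) {
      enr_go <- run_stage("enrich", {
        run_enrichment(target_genes, read_gene2term(config$gene2go), "GO")
      })
    }
    if (!is.null(config$gene2pathway)) {
      enr_path <- run_stage("enrich", {
        run_enrichment(target_genes, read_gene2term(config$gene2pathway),
                       "pathway")
      })
    }
  }

  de_frac <- de_kept %>%
    group_by(.data$control, .data$treatment, .data$sig_class) %>%
    summarise(n = dplyr::n(), .groups = "drop_last") %>%
    mutate(fraction = .data$n / sum(.data$n)) %>% ungroup()

  summary <- list(
    schema_version = 1,
    stages = names(config$fastq),
    clean_reads = as.list(clean_totals),
    filter_stats = stats,
    rrna_check = rrna,
    n_conserved_detected = length(unique(expr$mirna_id[expr$count > 0])),
    venn = venn,
    n_novel_predicted = nrow(novel),
    novel_venn = novel_venn,
    novel_u_fraction = attr(fb, "u_fraction"),
    de_class_fractions = de_frac,
    n_target_sites = if (is.null(targets)) NA_integer_ else nrow(targets),
    n_target_genes = if (is.null(targets)) NA_integer_
                     else length(unique(targets$gene_id)),
    n_go_significant = if (is.null(enr_go)) NA_integer_
                       else sum(enr_go$significant),
    n_pathway_significant = if (is.null(enr_path)) NA_integer_
                            else sum(enr_path$significant))

  result <- list(libraries = libraries, stats = stats, lengths = lengths,
                 hits = hits, annotation = per_tag,
                 annotation_summary = ann_summary, rrna = rrna,
                 conserved = expr, membership = membership, venn = venn,
                 top10 = top10, novel = novel, novel_expr = novel_expr,
                 novel_venn = novel_venn,
                 first_base = fb, diffexp = de, clusters = clusters,
                 targets = targets, enrichment_go = enr_go,
                 enrichment_pathway = enr_path, summary = summary)

  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_tsv_artifact(result$stats, p("filter_stats.tsv"))
  write_tsv_artifact(result$lengths, p("length_distribution.tsv"))
  write_tsv_artifact(result$annotation, p("tag_annotation.tsv"))
  write_tsv_artifact(as_tibble(result$annotation_summary),
                     p("annotation_summary.tsv"))
  write_tsv_artifact(result$conserved, p("conserved_expression.tsv"))
  write_tsv_artifact(result$venn, p("venn_regions.tsv"))
  write_tsv_artifact(result$top10, p("top_expressed.tsv"))
  if (nrow(result$novel) > 0) {
    write_fasta(setNames(c(result$novel$precursor_seq, result$novel$mature_seq),
                         c(paste0(result$novel$novel_id, "-pre"),
                           result$novel$novel_id)),
                p("novel_mirnas.fa"))
    write_bed(tibble(chrom = result$novel$chrom,
                     start = result$novel$window_start,
                     end = result$novel$window_end,
                     class = result$novel$novel_id,
                     source = NA_character_,
                     strand = result$novel$strand),
              p("novel_loci.bed"))
  }
  cand <- attr(result$novel, "candidates")
  if (!is.null(cand) && nrow(cand) > 0) {
    write_tsv_artifact(select(cand, -"precursor_seq", -"structure"),
                       p("novel_candidate_verdicts.tsv"))
  }
  write_tsv_artifact(result$diffexp, p("diffexp.tsv"))
  write_tsv_artifact(result$clusters, p("clusters.tsv"))
  if (!is.null(result$targets)) {
    write_tsv_artifact(result$targets, p("target_sites.tsv"))
  }
  if (!is.null(result$enrichment_go)) {
    write_tsv_artifact(result$enrichment_go, p("enrichment_go.tsv"))
  }
  if (!is.null(result$enrichment_pathway)) {
    write_tsv_artifact(result$enrichment_pathway, p("enrichment_pathway.tsv"))
  }
  s <- result$summary
  jsonlite::write_json(s, p("summary.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
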