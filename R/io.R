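# Readers and writers for the interchange formats: FASTQ (Phred+33),
# FASTA, BED, two-column TSV mappings. FASTA goes through Biostrings; the
# FASTQ reader is a thin validating wrapper so malformed records can be
# reported by index, as the filtering contract requires.

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an uncompressed FASTQ file (Phred+33 qualities).
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(id = character(), sequence = character(), quality = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                  path, length(lines)))
  }
  idx <- seq(1, length(lines), by = 4)
  rec <- (idx - 1) / 4 + 1
  bad <- which(substr(lines[idx], 1, 1) != "@")
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d in '%s': header does not start with '@'",
                  rec[bad[1]], path))
  }
  bad <- which(substr(lines[idx + 2], 1, 1) != "+")
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d in '%s': separator line missing '+'",
                  rec[bad[1]], path))
  }
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d in '%s': sequence and quality lengths differ",
                  rec[bad[1]], path))
  }
  tibble(id = sub("^@", "", lines[idx]), sequence = seqs, quality = quals)
}

#' Write reads to a FASTQ file
#'
#' @param reads A data frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality))
  writeLines(out, path)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings returning/accepting named character
#' vectors so the tabular modules stay string-based.
#'
#' @param path FASTA path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a BED feature annotation
#'
#' Minimal six-column BED (0-based, half-open): chrom, start, end, name,
#' score, strand. The name column carries `class` or `class:source`
#' (source distinguishes e.g. GenBank- from Rfam-derived ncRNA records).
#'
#' @param path BED path.
#' @return A tibble `chrom`, `start`, `end`, `class`, `source`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 6)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  parts <- strsplit(df$name, ":", fixed = TRUE)
  tibble(chrom = df$chrom, start = as.integer(df$start), end = as.integer(df$end),
         class = vapply(parts, `[`, "", 1),
         source = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
         strand = df$strand)
}

#' @rdname read_bed
#' @param features A tibble as returned by `read_bed()` (the `source`
#'   column may be absent).
#' @export
write_bed <- function(features, path) {
  name <- if ("source" %in% names(features) && any(!is.na(features$source))) {
    ifelse(is.na(features$source), features$class,
           paste(features$class, features$source, sep = ":"))
  } else features$class
  df <- data.frame(features$chrom, features$start, features$end, name, 0,
                   features$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term mapping TSV
#'
#' Two or three tab-separated columns: gene, term, optional namespace.
#'
#' @param path TSV path (no header).
#' @return A tibble `gene`, `term` (and `namespace` when present).
#' @export
read_gene2term <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", "term", "namespace")[seq_len(ncol(df))]
  as_tibble(df)
}

#' Write a tibble as a TSV artifact
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_tsv_artifact <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
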