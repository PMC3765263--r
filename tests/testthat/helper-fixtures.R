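# Shared fixtures, built once per test run.

tiny_sim_cache <- new.env(parent = emptyenv())

# A small but complete simulated study (deterministic, seed 11).
tiny_sim <- function() {
  if (is.null(tiny_sim_cache$sim)) {
    cfg <- sim_config(seed = 11, reads_per_library = 6000,
                      n_conserved_precursors = 12, n_novel_precursors = 4,
                      genome_length = 60000)
    tiny_sim_cache$cfg <- cfg
    tiny_sim_cache$sim <- simulate_srna_study(cfg)
  }
  list(cfg = tiny_sim_cache$cfg, sim = tiny_sim_cache$sim)
}

# FASTQ tibble from insert sequences plus adapters at constant quality.
reads_from_inserts <- function(inserts, adapter3, read_length = 36) {
  seqs <- substr(paste0(inserts, adapter3, strrep("A", read_length)),
                 1, read_length)
  tibble::tibble(id = sprintf("r%04d", seq_along(seqs)),
                 sequence = seqs, quality = strrep("I", nchar(seqs)))
}

# Build a UTR window opposite a miRNA with chosen per-position pair
# classes ("WC", "GU", "mm"), 1-based from the miRNA 5' end. The window
# is returned 5'->3' (so the miRNA's position 1 faces its last base).
make_window <- function(mirna, classes = rep("WC", nchar(mirna))) {
  m <- strsplit(toupper(chartr("T", "U", mirna)), "")[[1]]
  stopifnot(length(classes) == length(m))
  partner <- vapply(seq_along(m), function(i) {
    b <- m[i]
    switch(classes[i],
           WC = c(A = "U", U = "A", G = "C", C = "G")[[b]],
           GU = switch(b, G = "U", U = "G",
                       stop("GU impossible for base ", b)),
           mm = switch(b, A = "C", C = "A", G = "A", U = "C"))
  }, "")
  paste(rev(partner), collapse = "")
}
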