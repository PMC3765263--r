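#' Simplified RNA pairing energy model
#'
#' The folding and duplex routines score structures with a per-base-pair
#' energy model: each Watson-Crick or wobble pair contributes a fixed
#' negative energy and loops cost nothing. This deliberately replaces the
#' full nearest-neighbour tables of thermodynamic folding engines with a
#' self-contained model whose optima can be verified by exhaustive
#' enumeration; the precursor energy threshold is applied within whichever
#' backend is active.
#'
#' @param gc,au,gu Pair energies in kcal/mol (must be negative).
#' @param min_hairpin_loop Minimum number of unpaired bases closing a
#'   hairpin loop (at least 3).
#' @param backend `"internal"` for the built-in dynamic program, or
#'   `"vienna"` to delegate folding to the ViennaRNA `RNAfold` executable
#'   (nearest-neighbour energies; must be on the PATH).
#' @return An object of class `energy_model`.
#' @examples
#' energy_model()
#' @export
energy_model <- function(gc = -3, au = -2, gu = -1, min_hairpin_loop = 3,
                         backend = c("internal", "vienna")) {
  backend <- match.arg(backend)
  if (any(c(gc, au, gu) >= 0)) abort("pair energies must be negative")
  if (min_hairpin_loop < 3) abort("min_hairpin_loop must be >= 3")
  structure(list(gc = gc, au = au, gu = gu,
                 min_hairpin_loop = as.integer(min_hairpin_loop),
                 backend = backend),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> GC %.1f, AU %.1f, GU %.1f kcal/mol; min loop %d; backend %s\n",
              x$gc, x$au, x$gu, x$min_hairpin_loop, x$backend))
  invisible(x)
}

# Per-position Watson-Crick pair energy (for perfect-complement scoring).
wc_energy <- function(base, model) {
  unname(c(A = model$au, U = model$au, T = model$au,
           G = model$gc, C = model$gc)[base])
}

#' Fold an RNA sequence to its minimum free energy structure
#'
#' Finds the pseudoknot-free secondary structure minimising total pair
#' energy under the model, by interval dynamic programming. Ties are broken
#' deterministically: prefer the structure with more pairs, then 5'-most
#' pairing. DNA input (T) is converted to RNA (U) first.
#'
#' @param seq A single RNA (or DNA) sequence, length >= 10.
#' @param model An [energy_model()].
#' @return A `fold_result` list: `structure` (dot-bracket), `mfe`
#'   (kcal/mol), `pair_table` (integer vector, 1-based pairing partner or 0).
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(seq, model = energy_model()) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(dna_to_rna(seq))
  check_alphabet(seq, c("A", "C", "G", "U"), "RNA sequence")
  if (nchar(seq) < 10) abort("sequence must be at least 10 nt to fold")
  res <- if (model$backend == "vienna") {
    fold_vienna(seq)
  } else {
    nussinov_fold_cpp(seq, model$gc, model$au, model$gu, model$min_hairpin_loop)
  }
  structure(list(seq = seq, structure = res$structure, mfe = res$mfe,
                 pair_table = as.integer(res$pair_table),
                 backend = model$backend),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, sprintf(" (%.2f kcal/mol, %s backend)\n",
                                        x$mfe, x$backend), sep = "")
  invisible(x)
}

# Fold through the ViennaRNA RNAfold CLI and parse dot-bracket + energy.
fold_vienna <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) abort("RNAfold executable not found on PATH")
  out <- system2(exe, args = c("--noPS"), input = seq, stdout = TRUE)
  line <- out[2]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3) abort("could not parse RNAfold output")
  db <- m[2]
  pt <- integer(nchar(db))
  stack <- integer(0)
  ch <- strsplit(db, "")[[1]]
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") { j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i }
  }
  list(structure = db, mfe = as.numeric(m[3]), pair_table = pt)
}

#' Hybridisation energy of an aligned miRNA/target duplex
#'
#' Sums pair energies over positions classified as Watson-Crick or G:U
#' wobble pairs in an ungapped antiparallel alignment; mismatched positions
#' contribute zero.
#'
#' @param mirna RNA sequence of the miRNA (5'->3').
#' @param target_site RNA sequence of the target window, given 5'->3'; it is
#'   read antiparallel so miRNA position 1 faces the window's last base.
#' @param model An [energy_model()].
#' @return Duplex energy in kcal/mol (<= 0).
#' @seealso [align_site()] for the position-wise classification.
#' @export
duplex_energy <- function(mirna, target_site, model = energy_model()) {
  cls <- align_site(mirna, target_site)
  pair_class_energy(cls, model)
}

# Energy from an align_site() classification tibble.
pair_class_energy <- function(cls, model = energy_model()) {
  e <- c(WC = NA_real_, GU = model$gu, mismatch = 0)
  wc <- cls$pair == "WC"
  total <- sum(wc_energy(cls$mirna_base[wc], model)) +
    model$gu * sum(cls$pair == "GU")
  total
}

#' Energy of a miRNA bound to its perfect complement
#'
#' Every position pairs Watson-Crick, so the energy is the sum of the
#' per-base Watson-Crick pair energies. Used as the denominator of the
#' duplex-stability ratio in target prediction.
#'
#' @inheritParams duplex_energy
#' @return Energy in kcal/mol; 0 for an empty sequence (with a warning).
#' @examples
#' perfect_complement_energy("GGGG") # 4 GC pairs
#' @export
perfect_complement_energy <- function(mirna, model = energy_model()) {
  stopifnot(is.character(mirna), length(mirna) == 1)
  mirna <- toupper(dna_to_rna(mirna))
  if (nchar(mirna) == 0) {
    warn("empty miRNA sequence; perfect-complement energy is 0")
    return(0)
  }
  check_alphabet(mirna, c("A", "C", "G", "U"), "miRNA")
  sum(wc_energy(strsplit(mirna, "")[[1]], model))
}
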