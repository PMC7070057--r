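#' k-mer composition specification
#'
#' Defines the alphabet and word length used to turn a sequence into a
#' normalized k-mer frequency vector. The vector has `length(alphabet)^k`
#' entries indexed lexicographically (first alphabet symbol varying
#' slowest), so the default 4-letter alphabet with `k = 3` gives the
#' 64-dimensional composition used for both ncRNA and (reduced-alphabet)
#' protein sequences.
#'
#' @param alphabet ordered character vector of single symbols.
#' @param k word length (default 3).
#' @return A `kmer_spec` list with `alphabet`, `k` and the lexicographic
#'   k-mer ordering in `$kmers`.
#' @export
kmer_spec <- function(alphabet = c("A", "C", "G", "U"), k = 3L) {
  stopifnot(k >= 1L, length(alphabet) >= 2L, !anyDuplicated(alphabet))
  grids <- rev(lapply(seq_len(k), function(i) alphabet))
  g <- expand.grid(grids, stringsAsFactors = FALSE)
  kmers <- apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
  structure(list(alphabet = alphabet, k = as.integer(k), kmers = kmers),
            class = "kmer_spec")
}

# Core windowed k-mer counter over an integer-coded sequence; codes are
# 1-based positions in the alphabet, NA marks an invalid symbol. Windows
# containing any invalid symbol are skipped; the result is normalized by
# the number of valid windows.
.kmer_profile <- function(codes, spec) {
  k <- spec$k
  A <- length(spec$alphabet)
  v <- numeric(A^k)
  n <- length(codes)
  if (n < k) return(v)
  # index of window starting at p: sum (code-1) * A^(k - offset)
  idx <- rep(1, n - k + 1L)
  valid <- rep(TRUE, n - k + 1L)
  for (off in seq_len(k)) {
    c_off <- codes[off:(n - k + off)]
    valid <- valid & !is.na(c_off)
    idx <- idx + ifelse(is.na(c_off), 0, (c_off - 1)) * A^(k - off)
  }
  if (!any(valid)) return(v)
  tab <- tabulate(idx[valid], nbins = A^k)
  tab / sum(valid)
}

#' Encode an RNA/DNA sequence as a normalized 3-mer vector
#'
#' Each entry is the frequency of one k-mer among the valid length-k
#' windows of the sequence. `T` is read as `U`; windows containing any
#' other symbol outside `{A, C, G, U}` are skipped and do not count in the
#' denominator, so the vector sums to 1 whenever at least one valid window
#' exists.
#'
#' @param sequence nucleotide string.
#' @param spec a [kmer_spec()]; default 4-letter RNA alphabet, k = 3.
#' @return named numeric vector of length `length(alphabet)^k` (64 by
#'   default), summing to 1 (or all zero, with a warning, when the
#'   sequence has no valid window).
#' @export
encode_rna_kmer <- function(sequence, spec = kmer_spec()) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a non-empty string")
  }
  chars <- toupper(strsplit(sequence, "", fixed = TRUE)[[1L]])
  chars[chars == "T"] <- "U"
  codes <- match(chars, spec$alphabet)
  v <- .kmer_profile(codes, spec)
  if (sum(v) == 0) {
    warning("sequence has no valid ", spec$k, "-mer window; returning zeros")
  }
  names(v) <- spec$kmers
  v
}

#' Reduced amino-acid alphabet by side-chain polarity
#'
#' The 20 standard amino acids fall into four groups:
#' `G1 = {A,V,L,I,M,F,W,P}`, `G2 = {G,S,T,C,N,Q,Y}`, `G3 = {R,K,H}`,
#' `G4 = {D,E}`. Non-standard residues (X, B, Z, U, O, ...) map to `NA`
#' and invalidate the windows they fall in.
#'
#' @return named character vector mapping one-letter residues to group
#'   symbols `"1".."4"`.
#' @export
polarity_groups <- function() {
  c(A = "1", V = "1", L = "1", I = "1", M = "1", F = "1", W = "1", P = "1",
    G = "2", S = "2", T = "2", C = "2", N = "2", Q = "2", Y = "2",
    R = "3", K = "3", H = "3",
    D = "4", E = "4")
}

#' Encode a protein sequence as a reduced-alphabet 3-mer vector
#'
#' The sequence is first translated to the 4-letter side-chain-polarity
#' alphabet of [polarity_groups()], then encoded exactly as
#' [encode_rna_kmer()] encodes nucleotides, giving a 64-dimensional
#' normalized 3-mer composition. Windows containing residues outside the
#' 20 standard amino acids are skipped.
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param spec a [kmer_spec()] over the group alphabet; default groups
#'   `"1".."4"`, k = 3.
#' @return named numeric vector of length 64 (by default) summing to 1.
#' @export
encode_protein_kmer <- function(sequence,
                                spec = kmer_spec(alphabet = c("1", "2", "3", "4"))) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a non-empty string")
  }
  chars <- toupper(strsplit(sequence, "", fixed = TRUE)[[1L]])
  grp <- unname(polarity_groups()[chars])
  codes <- match(grp, spec$alphabet)
  v <- .kmer_profile(codes, spec)
  if (sum(v) == 0) {
    warning("sequence has no valid ", spec$k, "-mer window; returning zeros")
  }
  names(v) <- spec$kmers
  v
}

#' k-mer attribute matrix for a FASTA file
#'
#' Reads sequences (record ids must equal node ids) and encodes each with
#' [encode_rna_kmer()] or [encode_protein_kmer()] according to
#' `node_type`.
#'
#' @param path FASTA file path.
#' @param node_type `"miRNA"`, `"lncRNA"` (nucleotide) or `"protein"`.
#' @return numeric matrix, one row per record, 64 columns, rownames = ids.
#' @export
encode_fasta <- function(path, node_type = c("miRNA", "lncRNA", "protein")) {
  node_type <- match.arg(node_type)
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  enc <- if (node_type == "protein") encode_protein_kmer else encode_rna_kmer
  spec <- if (node_type == "protein") {
    kmer_spec(alphabet = c("1", "2", "3", "4"))
  } else {
    kmer_spec()
  }
  out <- t(vapply(as.character(seqs), enc, numeric(64), USE.NAMES = FALSE))
  dimnames(out) <- list(ids, spec$kmers)
  out
}
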