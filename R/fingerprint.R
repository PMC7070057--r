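#' Drug structural fingerprint
#'
#' Returns the binary substructure fingerprint of a drug, either parsed
#' from a precomputed 0/1 bitstring or computed from a SMILES string when
#' the optional chemistry back-end (\pkg{ChemmineR}/\pkg{ChemmineOB}) is
#' installed. Precomputed bitstrings keep the chemistry stack optional;
#' the raw fingerprint is later compressed to 64 dimensions by the sparse
#' autoencoder.
#'
#' @param payload either a 0/1 bitstring of length `n_bits` or a SMILES
#'   string.
#' @param n_bits fingerprint length (default 1024).
#' @return integer 0/1 vector of length `n_bits`.
#' @export
drug_fingerprint <- function(payload, n_bits = 1024L) {
  payload <- as.character(payload)
  if (length(payload) != 1L || is.na(payload) || !nzchar(payload)) {
    stop("payload must be a non-empty string")
  }
  if (grepl("^[01]+$", payload)) {
    if (nchar(payload) != n_bits) {
      stop("bitstring length ", nchar(payload), " != n_bits ", n_bits)
    }
    return(as.integer(strsplit(payload, "", fixed = TRUE)[[1L]]))
  }
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES input requires the ChemmineR/ChemmineOB chemistry ",
         "back-end; supply a precomputed 0/1 bitstring instead")
  }
  sdf <- tryCatch(ChemmineR::smiles2sdf(payload),
                  error = function(e) stop("unparsable SMILES: ", payload))
  fp <- ChemmineR::fingerprintOB(sdf, "FP2")
  bits <- as.numeric(as.matrix(fp)[1L, ])
  out <- integer(n_bits)
  out[seq_len(min(n_bits, length(bits)))] <-
    as.integer(bits[seq_len(min(n_bits, length(bits)))] > 0)
  out
}

#' Read a drug fingerprint table
#'
#' TSV with columns `node_id`, `payload` where the payload is a 0/1
#' bitstring (or SMILES, with the optional chemistry back-end).
#'
#' @param path file path.
#' @param n_bits fingerprint length.
#' @return 0/1 matrix, one row per drug, rownames = ids.
#' @export
read_fingerprint_table <- function(path, n_bits = 1024L) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    colClasses = "character")
  out <- t(vapply(tab[[2L]], drug_fingerprint, integer(n_bits),
                  n_bits = n_bits, USE.NAMES = FALSE))
  rownames(out) <- tab[[1L]]
  out[.radix_order(rownames(out)), , drop = FALSE]
}
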