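#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequences
#'
#' @param n number of sequences
#' @param len length of each sequence
#' @return character vector of `n` sequences of `len` bases
#' @keywords internal
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- character(length(x))
  nonempty <- nzchar(x)
  out[nonempty] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nonempty]))
  )
  out
}

#' Hamming distance of equal-length strings against one reference
#'
#' Vectorised over `x`; all elements of `x` must have the same number of
#' characters as `ref`.
#'
#' @param x character vector
#' @param ref single reference string
#' @return integer vector of mismatch counts (NA where lengths differ)
#' @export
hamming_to_ref <- function(x, ref) {
  L <- nchar(ref)
  n <- length(x)
  if (n == 0) return(integer(0))
  out <- rep(NA_integer_, n)
  ok <- nchar(x) == L
  if (any(ok)) {
    m <- matrix(charToRaw(paste(x[ok], collapse = "")), nrow = L)
    out[ok] <- as.integer(colSums(m != charToRaw(ref)))
  }
  out
}

#' Inject random substitution errors into DNA strings
#'
#' Each base is independently replaced, with probability `rate`, by one of
#' the three other bases chosen uniformly.  All input strings must have the
#' same length.
#'
#' @param seqs character vector of equal-length DNA strings
#' @param rate per-base substitution probability
#' @return character vector with errors applied
#' @export
inject_substitutions <- function(seqs, rate) {
  stopifnot(rate >= 0, rate <= 1)
  n <- length(seqs)
  if (n == 0 || rate == 0) return(seqs)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  m <- matrix(strsplit(paste(seqs, collapse = ""), "")[[1]], nrow = L)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit)) {
    # replacement drawn from the three non-matching bases
    cur <- m[hit]
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1), USE.NAMES = FALSE)
    m[hit] <- repl
  }
  apply(m, 2, paste, collapse = "")
}

# mutate exactly the given positions of one sequence to different bases
mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# generate n unique barcodes of given length with pairwise Hamming >= min_dist.
# Sphere-packing makes large sets at distance >= 3 infeasible for 8-mers, so
# above 200 barcodes the requirement degrades to plain uniqueness (real
# dual-index sets are small; large simulated cohorts only need unique pairs).
generate_barcodes <- function(n, len = 8, min_dist = 3, max_tries = 10000L) {
  if (n > 200) min_dist <- 1
  pool <- character(0)
  tries <- 0L
  while (length(pool) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not generate ", n, " barcodes of length ", len,
           " at minimum distance ", min_dist)
    }
    cand <- random_dna(1, len)
    ok <- if (length(pool) == 0) TRUE
          else if (min_dist <= 1) !(cand %in% pool)
          else all(hamming_to_ref(pool, cand) >= min_dist)
    if (ok) pool <- c(pool, cand)
  }
  pool
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible 31-bit sub-seed from a base seed and stage offset
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
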