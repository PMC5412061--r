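#' Synthetic assay manifest for a competitive multiplex amplicon panel
#'
#' Builds a manifest of target assays plus one ACTB reference assay.  Every
#' assay amplifies a fixed-length region (`amplicon_len`, primers included);
#' the internal standard (IS) captured sequence differs from the native
#' template (NT) captured sequence at exactly six positions, which is what
#' allows NT and IS reads to be told apart after sequencing.  IS molecules
#' are spiked at a known copy number per reaction: 600 copies for each
#' target assay and 6000 copies for the ACTB reference.
#'
#' Assays are distributed over genes so that some genes carry more than one
#' assay (alternative-transcript assays), mirroring real targeted panels.
#'
#' @param n_assays number of target assays (ACTB reference excluded)
#' @param n_genes number of distinct target genes; must be <= n_assays
#' @param primer_len length of each primer (forward and reverse)
#' @param amplicon_len total amplicon length including both primers
#' @param is_input_copies IS copies spiked per target assay reaction
#' @param actb_is_copies IS copies spiked for the ACTB reference assay
#' @param n_is_diff number of bases at which IS differs from NT
#' @param seed RNG seed
#' @return data.frame with one row per assay (targets first, ACTB last) and
#'   columns `assay_id`, `gene`, `primer_f`, `primer_r`, `nt_captured`,
#'   `is_captured`, `is_input_copies`, `is_reference_assay`
#' @export
synthetic_assay_design <- function(n_assays = 68, n_genes = 33,
                                   primer_len = 20, amplicon_len = 101,
                                   is_input_copies = 600,
                                   actb_is_copies = 6000,
                                   n_is_diff = 6,
                                   seed = 1) {
  stopifnot(n_assays >= 1, n_genes >= 1, n_genes <= n_assays)
  captured_len <- amplicon_len - 2 * primer_len
  stopifnot(captured_len > n_is_diff + 2)
  set.seed(seed)

  # assign assays to genes: every gene gets one, extras go to random genes
  genes <- sprintf("GM%02d", seq_len(n_genes))
  gene_of <- c(genes, sample(genes, n_assays - n_genes, replace = TRUE))
  gene_of <- sort(gene_of)
  assay_id <- stats::ave(gene_of, gene_of, FUN = function(g) {
    if (length(g) == 1) g else paste0(g, ".", seq_along(g))
  })

  n_total <- n_assays + 1L  # plus ACTB reference

  # primers: enforce pairwise distance so locus assignment at mismatch <= 2
  # is unambiguous even on error-containing reads
  primer_f <- generate_barcodes(n_total, primer_len, min_dist = 6,
                                max_tries = 50 * n_total)
  primer_r <- generate_barcodes(n_total, primer_len, min_dist = 6,
                                max_tries = 50 * n_total)

  nt_captured <- random_dna(n_total, captured_len)
  # IS differs at n_is_diff evenly spaced interior positions
  diff_pos <- unique(round(seq(3, captured_len - 2, length.out = n_is_diff)))
  stopifnot(length(diff_pos) == n_is_diff)
  is_captured <- vapply(nt_captured, mutate_positions, character(1),
                        positions = diff_pos, USE.NAMES = FALSE)

  design <- data.frame(
    assay_id = c(assay_id, "ACTB"),
    gene = c(gene_of, "ACTB"),
    primer_f = primer_f,
    primer_r = primer_r,
    nt_captured = nt_captured,
    is_captured = is_captured,
    is_input_copies = c(rep(is_input_copies, n_assays), actb_is_copies),
    is_reference_assay = c(rep(FALSE, n_assays), TRUE),
    stringsAsFactors = FALSE
  )
  validate_assay_design(design)
  design
}

#' Validate an assay manifest
#'
#' Checks the structural invariants: required columns, NT/IS captured
#' sequences of equal length differing at exactly six bases, positive IS
#' input copies, exactly one reference assay, unique assay ids.
#'
#' @param design assay manifest data.frame
#' @param n_is_diff required NT/IS Hamming distance
#' @return the design, invisibly; stops on violation
#' @export
validate_assay_design <- function(design, n_is_diff = 6) {
  req <- c("assay_id", "gene", "primer_f", "primer_r", "nt_captured",
           "is_captured", "is_input_copies", "is_reference_assay")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    stop("assay design is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(design$assay_id)) stop("duplicate assay_id in design")
  if (sum(design$is_reference_assay) != 1) {
    stop("design must flag exactly one reference (ACTB) assay")
  }
  if (any(design$is_input_copies <= 0)) stop("is_input_copies must be > 0")
  if (any(nchar(design$nt_captured) != nchar(design$is_captured))) {
    stop("nt_captured and is_captured must have equal length per assay")
  }
  d <- mapply(function(a, b) hamming_to_ref(a, b),
              design$nt_captured, design$is_captured)
  if (any(d != n_is_diff)) {
    stop("NT and IS captured sequences must differ at exactly ",
         n_is_diff, " positions")
  }
  if (length(unique(nchar(design$primer_f))) != 1 ||
      length(unique(nchar(design$primer_r))) != 1) {
    stop("all primers must have a common length")
  }
  invisible(design)
}

#' Write / read an assay manifest as tab-delimited text
#'
#' @param design assay manifest
#' @param path file path
#' @return `read_assay_design` returns the validated manifest
#' @export
write_assay_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_design
#' @export
read_assay_design <- function(path) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  design$is_reference_assay <- as.logical(design$is_reference_assay)
  validate_assay_design(design)
  design
}
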