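#' Join paired reads into full amplicon sequences
#'
#' For the fixed non-overlapping simulated layout, the joined sequence is
#' read 1 followed by the reverse complement of read 2.  Pairs whose joined
#' length falls below `min_len` (it must at least hold both barcodes and
#' both primers), or with an empty mate, are flagged unjoinable.
#'
#' @param r1,r2 character vectors of read sequences (equal length vectors)
#' @param min_len minimum acceptable joined length
#' @return list with `joined` (character) and `ok` (logical)
#' @export
join_reads <- function(r1, r2, min_len = 1) {
  stopifnot(length(r1) == length(r2))
  joined <- paste0(r1, revcomp(r2))
  ok <- nzchar(r1) & nzchar(r2) & nchar(joined) >= min_len
  list(joined = joined, ok = ok)
}

# nearest-candidate resolution shared by barcode and primer matching:
# both component distances must be <= max_mismatch; among such candidates
# the smallest total distance wins, ties -> unassigned (NA)
resolve_nearest <- function(dist_f, dist_r, max_mismatch) {
  ok <- !is.na(dist_f) & !is.na(dist_r) &
    dist_f <= max_mismatch & dist_r <= max_mismatch
  total <- dist_f + dist_r
  total[!ok] <- NA_integer_
  n_reads <- nrow(total)
  out <- rep(NA_integer_, n_reads)
  has <- which(rowSums(ok) > 0)
  for (i in has) {
    ti <- total[i, ]
    m <- min(ti, na.rm = TRUE)
    hit <- which(!is.na(ti) & ti == m)
    if (length(hit) == 1) out[i] <- hit
  }
  out
}

#' Demultiplex joined reads by dual barcodes
#'
#' The forward barcode is the first `barcode_len` bases of the joined read
#' and the reverse barcode is the reverse complement of its last
#' `barcode_len` bases.  A read is assigned to the unique subject whose two
#' barcodes both lie within `max_mismatch` substitutions; ties and
#' non-matches are unassigned.
#'
#' @param joined character vector of joined reads
#' @param sample_sheet data.frame with subject_id, barcode_f, barcode_r
#' @param max_mismatch maximum per-barcode mismatches (default 1)
#' @param barcode_len barcode length in bases
#' @return integer vector of row indices into `sample_sheet` (NA when
#'   unassigned)
#' @export
demultiplex <- function(joined, sample_sheet, max_mismatch = 1,
                        barcode_len = 8) {
  key <- paste(sample_sheet$barcode_f, sample_sheet$barcode_r)
  if (anyDuplicated(key)) {
    stop("duplicate barcode pair in sample sheet")
  }
  n <- length(joined)
  if (n == 0) return(integer(0))
  L <- nchar(joined)
  long_enough <- L >= 2 * barcode_len
  bf <- substr(joined, 1, barcode_len)
  br <- revcomp(substring(joined, L - barcode_len + 1, L))

  out <- rep(NA_integer_, n)
  # fast path: exact pair match
  out[long_enough] <- match(paste(bf, br)[long_enough], key)
  todo <- which(is.na(out) & long_enough)
  if (length(todo) && max_mismatch > 0) {
    dist_f <- vapply(sample_sheet$barcode_f,
                     function(b) hamming_to_ref(bf[todo], b),
                     integer(length(todo)))
    dist_r <- vapply(sample_sheet$barcode_r,
                     function(b) hamming_to_ref(br[todo], b),
                     integer(length(todo)))
    dist_f <- matrix(dist_f, nrow = length(todo))
    dist_r <- matrix(dist_r, nrow = length(todo))
    out[todo] <- resolve_nearest(dist_f, dist_r, max_mismatch)
  }
  out
}

#' Assign each joined read to an assay by its primer sequences
#'
#' The forward primer is expected directly after the forward barcode and
#' the reverse-complemented reverse primer directly before the trailing
#' barcode.  A read is assigned to the unique assay whose two primers both
#' match within `max_mismatch` substitutions at those fixed offsets.
#'
#' @param joined character vector of joined reads
#' @param design assay manifest
#' @param max_mismatch maximum per-primer mismatches (default 2)
#' @param barcode_len barcode length in bases
#' @return integer vector of row indices into `design` (NA when unassigned)
#' @export
assign_locus <- function(joined, design, max_mismatch = 2,
                         barcode_len = 8) {
  plen <- nchar(design$primer_f[1])
  n <- length(joined)
  if (n == 0) return(integer(0))
  L <- nchar(joined)
  min_len <- 2 * barcode_len + 2 * plen
  ok_len <- L >= min_len
  pf_obs <- substr(joined, barcode_len + 1, barcode_len + plen)
  pr_obs <- substring(joined, L - barcode_len - plen + 1, L - barcode_len)

  out <- rep(NA_integer_, n)
  idx <- which(ok_len)
  if (!length(idx)) return(out)
  pr_ref <- revcomp(design$primer_r)
  dist_f <- vapply(design$primer_f,
                   function(p) hamming_to_ref(pf_obs[idx], p),
                   integer(length(idx)))
  dist_r <- vapply(pr_ref,
                   function(p) hamming_to_ref(pr_obs[idx], p),
                   integer(length(idx)))
  dist_f <- matrix(dist_f, nrow = length(idx))
  dist_r <- matrix(dist_r, nrow = length(idx))
  out[idx] <- resolve_nearest(dist_f, dist_r, max_mismatch)
  out
}

#' Classify a captured region as native template or internal standard
#'
#' Computes the Levenshtein edit distance from the captured sequence to the
#' assay's NT and IS reference sequences (which differ at six positions).
#' The nearer allele is returned when the smaller distance is at most
#' `max_distance` and the two distances differ by at least `min_margin`;
#' otherwise the read is ambiguous.
#'
#' @param captured character vector of captured-region sequences
#' @param nt_ref,is_ref the assay's NT and IS reference sequences
#' @param max_distance maximum accepted edit distance to the nearer allele
#' @param min_margin minimum difference between the two distances
#' @return character vector of "NT", "IS" or "ambiguous"
#' @export
classify_allele <- function(captured, nt_ref, is_ref,
                            max_distance = 2, min_margin = 1) {
  if (length(captured) == 0) return(character(0))
  d_nt <- as.integer(utils::adist(captured, nt_ref))
  d_is <- as.integer(utils::adist(captured, is_ref))
  out <- rep("ambiguous", length(captured))
  confident <- pmin(d_nt, d_is) <= max_distance &
    abs(d_nt - d_is) >= min_margin
  out[confident & d_nt < d_is] <- "NT"
  out[confident & d_is < d_nt] <- "IS"
  out
}

#' Count NT and IS reads per subject and assay from paired FASTQ
#'
#' Composes read joining, dual-barcode demultiplexing, primer-based locus
#' assignment and approximate-string allele classification.  Every input
#' read pair is counted exactly once: as NT, IS or ambiguous in its
#' subject x assay cell, as locus-unassigned under its subject, or in the
#' global unassigned bucket (join or barcode failure).
#'
#' @param r1_path,r2_path paired FASTQ files (gzip accepted)
#' @param sample_sheet data.frame with subject_id, barcode_f, barcode_r
#' @param design assay manifest
#' @param max_barcode_mismatch,max_primer_mismatch,max_allele_distance,min_allele_margin
#'   stage tolerances
#' @param barcode_len barcode length in bases
#' @return object of class `read_counts`: list with `counts` (long
#'   data.frame over the full subject x assay grid) and `summary`
#'   (per-stage read accounting; conservation holds exactly)
#' @export
count_reads <- function(r1_path, r2_path, sample_sheet, design,
                        max_barcode_mismatch = 1, max_primer_mismatch = 2,
                        max_allele_distance = 2, min_allele_margin = 1,
                        barcode_len = 8) {
  r1 <- tryCatch(read_fastq_seqs(r1_path), error = function(e) {
    stop("failed to read FASTQ '", r1_path, "': ", conditionMessage(e))
  })
  r2 <- tryCatch(read_fastq_seqs(r2_path), error = function(e) {
    stop("failed to read FASTQ '", r2_path, "': ", conditionMessage(e))
  })
  if (length(r1) != length(r2)) {
    stop("paired FASTQ files differ in record count (",
         length(r1), " vs ", length(r2), ")")
  }
  plen <- nchar(design$primer_f[1])
  min_len <- 2 * barcode_len + 2 * plen

  jr <- join_reads(r1, r2, min_len = min_len)
  joined <- jr$joined
  n_pairs <- length(joined)

  subj_idx <- rep(NA_integer_, n_pairs)
  assay_idx <- rep(NA_integer_, n_pairs)
  allele <- rep(NA_character_, n_pairs)

  ok <- which(jr$ok)
  if (length(ok)) {
    subj_idx[ok] <- demultiplex(joined[ok], sample_sheet,
                                max_mismatch = max_barcode_mismatch,
                                barcode_len = barcode_len)
    with_subj <- ok[!is.na(subj_idx[ok])]
    if (length(with_subj)) {
      assay_idx[with_subj] <- assign_locus(joined[with_subj], design,
                                           max_mismatch = max_primer_mismatch,
                                           barcode_len = barcode_len)
      with_assay <- with_subj[!is.na(assay_idx[with_subj])]
      if (length(with_assay)) {
        L <- nchar(joined[with_assay])
        capt <- substring(joined[with_assay], barcode_len + plen + 1,
                          L - barcode_len - plen)
        for (a in unique(assay_idx[with_assay])) {
          sel <- with_assay[assay_idx[with_assay] == a]
          allele[sel] <- classify_allele(
            capt[match(sel, with_assay)],
            design$nt_captured[a], design$is_captured[a],
            max_distance = max_allele_distance,
            min_margin = min_allele_margin
          )
        }
      }
    }
  }

  # tabulate over full grid
  n_s <- nrow(sample_sheet)
  n_a <- nrow(design)
  grid_count <- function(sel) {
    tab <- table(factor(subj_idx[sel], levels = seq_len(n_s)),
                 factor(assay_idx[sel], levels = seq_len(n_a)))
    as.integer(tab)
  }
  nt_sel <- !is.na(allele) & allele == "NT"
  is_sel <- !is.na(allele) & allele == "IS"
  amb_sel <- !is.na(allele) & allele == "ambiguous"

  counts <- data.frame(
    subject_id = rep(sample_sheet$subject_id, times = n_a),
    assay_id = rep(design$assay_id, each = n_s),
    nt_reads = grid_count(nt_sel),
    is_reads = grid_count(is_sel),
    ambiguous_reads = grid_count(amb_sel),
    unassigned_reads = 0L,
    stringsAsFactors = FALSE
  )

  # locus-unassigned reads, attributed to their subject
  locus_un <- !is.na(subj_idx) & is.na(assay_idx)
  per_subj_un <- as.integer(table(factor(subj_idx[locus_un],
                                         levels = seq_len(n_s))))
  # fold into the table on the subject's first assay row for conservation
  first_rows <- match(sample_sheet$subject_id, counts$subject_id)
  counts$unassigned_reads[first_rows] <- per_subj_un

  global_unassigned <- sum(is.na(subj_idx))
  summary <- list(
    n_pairs = n_pairs,
    n_join_failed = sum(!jr$ok),
    n_barcode_unassigned = sum(jr$ok & is.na(subj_idx)),
    n_locus_unassigned = sum(locus_un),
    n_ambiguous = sum(amb_sel),
    n_nt = sum(nt_sel),
    n_is = sum(is_sel),
    global_unassigned = global_unassigned,
    per_subject_unassigned = stats::setNames(per_subj_un,
                                             sample_sheet$subject_id)
  )
  structure(list(counts = counts, summary = summary),
            class = "read_counts")
}

#' Write a demultiplexing run to disk
#'
#' Counts go to a tab-delimited file and the stage accounting to JSON.
#'
#' @param x a `read_counts` object
#' @param counts_path TSV output path
#' @param summary_path JSON output path (optional)
#' @export
write_read_counts <- function(x, counts_path, summary_path = NULL) {
  stopifnot(inherits(x, "read_counts"))
  write_counts(x$counts, counts_path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(x$summary, summary_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(counts_path)
}
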