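#' ORFeome reference for exact k-mer read assignment
#'
#' The prey library reference: a set of uniquely named ORF nucleotide
#' sequences plus the k-mer length used for assignment. Reads are
#' assigned by exact k-mer matching on the forward strand (the prey
#' cassette is amplified with fixed-orientation cassette primers), a
#' deterministic stand-in for a spliced aligner.
#'
#' @param orf_ids Character vector of unique ORF identifiers.
#' @param sequences Character vector of A/C/G/T sequences, one per ORF,
#'   each at least `k` bases long.
#' @param k K-mer length in bases (default 31, a standard
#'   pseudo-alignment choice long enough for uniqueness at ORF scale).
#' @return An object of class `orf_reference`.
#' @seealso [read_orf_reference()], [index_reference()], [assign_reads()]
#' @export
orf_reference <- function(orf_ids, sequences, k = 31) {
  orf_ids <- as.character(orf_ids)
  sequences <- toupper(as.character(sequences))
  if (anyDuplicated(orf_ids)) stop("duplicate orf_id in reference")
  if (length(orf_ids) != length(sequences)) stop("orf_ids and sequences differ in length")
  if (any(grepl("[^ACGT]", sequences))) stop("sequences must be over {A,C,G,T}")
  stop_if_not_count(k, "k")
  if (k < 1) stop("k must be >= 1")
  if (any(nchar(sequences) < k)) stop("every ORF must be at least k bases long")
  structure(list(orf_ids = orf_ids, sequences = sequences, k = as.integer(k)),
            class = "orf_reference")
}

#' Read an ORF reference from FASTA
#'
#' @param path FASTA file of ORF sequences (record names are the ORF ids).
#' @inheritParams orf_reference
#' @return An `orf_reference`.
#' @export
read_orf_reference <- function(path, k = 31) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  orf_reference(ids, as.character(seqs), k = k)
}

#' Write an ORF reference to FASTA
#'
#' @param ref An [orf_reference()].
#' @param path Output FASTA path.
#' @export
write_orf_reference <- function(ref, path) {
  stopifnot(inherits(ref, "orf_reference"))
  x <- Biostrings::DNAStringSet(ref$sequences)
  names(x) <- ref$orf_ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# marker value for k-mers occurring in >= 2 ORFs
AMBIGUOUS <- "__AMBIGUOUS__"

# all k-mers of one sequence, in order
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

#' Build the k-mer index of an ORF reference
#'
#' Every k-mer occurring in exactly one ORF maps to that ORF; k-mers
#' shared by two or more ORFs map to the ambiguous marker. A k-mer
#' repeated within a single ORF is still unique to it.
#'
#' @param ref An [orf_reference()].
#' @return An object of class `kmer_index`: a named character vector
#'   (k-mer -> orf_id or ambiguous marker) with attributes `k` and
#'   `orf_ids` (reference order, used for count-column layout).
#' @export
index_reference <- function(ref) {
  stopifnot(inherits(ref, "orf_reference"))
  k <- ref$k
  km <- lapply(ref$sequences, function(s) unique(seq_kmers(s, k)))
  all_km <- unlist(km, use.names = FALSE)
  owner <- rep(ref$orf_ids, lengths(km))
  dup <- all_km %in% all_km[duplicated(all_km)]
  owner[dup] <- AMBIGUOUS
  keep <- !duplicated(all_km)
  idx <- owner[keep]
  names(idx) <- all_km[keep]
  structure(idx, k = k, orf_ids = ref$orf_ids, class = "kmer_index")
}

#' Assign reads to ORFs by exact k-mer lookup
#'
#' A read is counted for ORF X iff all of its k-mers that map
#' unambiguously map to X and at least one k-mer is unambiguous. Reads
#' whose unambiguous k-mers disagree (`conflict`), whose matching k-mers
#' are all shared between ORFs (`ambiguous`), that match nothing
#' (`unmatched`) or that are shorter than k (`short`) are discarded and
#' tallied. The result is independent of read order.
#'
#' @param reads Character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param index A [index_reference()] k-mer index.
#' @return A list with `counts` (named integer vector in reference ORF
#'   order), `discarded` (named tally: ambiguous, conflict, unmatched,
#'   short) and `n_reads`. `counts` plus `discarded` always sums to
#'   `n_reads`.
#' @export
assign_reads <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(as.character(reads))
  k <- attr(index, "k")
  orf_ids <- attr(index, "orf_ids")
  counts <- stats::setNames(integer(length(orf_ids)), orf_ids)
  discarded <- c(ambiguous = 0L, conflict = 0L, unmatched = 0L, short = 0L)
  short <- nchar(reads) < k
  discarded["short"] <- sum(short)
  long <- reads[!short]
  if (length(long) > 0L) {
    km <- lapply(long, function(rd) unique(seq_kmers(rd, k)))
    read_of <- rep(seq_along(long), lengths(km))
    # one hash lookup for all reads' k-mers at once
    hit <- index[match(unlist(km, use.names = FALSE), names(index))]
    fate <- vapply(split(hit, read_of), function(h) {
      h <- h[!is.na(h)]
      if (length(h) == 0L) return("unmatched")
      unamb <- unique(h[h != AMBIGUOUS])
      if (length(unamb) == 0L) return("ambiguous")
      if (length(unamb) > 1L) return("conflict")
      unamb
    }, character(1))
    assigned <- table(fate[fate %in% orf_ids])
    counts[names(assigned)] <- counts[names(assigned)] + as.integer(assigned)
    for (why in c("ambiguous", "conflict", "unmatched")) {
      discarded[why] <- discarded[why] + sum(fate == why)
    }
  }
  list(counts = counts, discarded = discarded, n_reads = length(reads))
}

#' Quantify FASTQ replicates against an ORF reference
#'
#' Convenience wrapper: reads one FASTQ per replicate, assigns reads with
#' [assign_reads()] and returns a [count_table()] with CPM filled.
#'
#' @param ref An [orf_reference()].
#' @param fastq_paths Character vector of FASTQ files, one per replicate
#'   (plain or gzipped).
#' @param replicate_labels Column labels (default `rep1, rep2, ...`).
#' @return A list with `table` (a [count_table()] with CPM) and
#'   `discarded` (per-replicate discard tallies).
#' @export
quantify_screen <- function(ref, fastq_paths,
                            replicate_labels = paste0("rep", seq_along(fastq_paths))) {
  idx <- index_reference(ref)
  asn <- lapply(fastq_paths, function(p) {
    assign_reads(Biostrings::readDNAStringSet(p, format = "fastq"), idx)
  })
  m <- do.call(cbind, lapply(asn, `[[`, "counts"))
  colnames(m) <- replicate_labels
  list(table = counts_to_cpm(count_table(m)),
       discarded = stats::setNames(lapply(asn, `[[`, "discarded"), replicate_labels))
}
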