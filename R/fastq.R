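# FASTQ and truth-table I/O. Sequence parsing is delegated to Biostrings;
# the wrappers add pair bookkeeping and the validation the pipeline relies on.

#' Write a paired FASTQ file set
#'
#' Read ids carry the pair id with `/1` and `/2` suffixes. Qualities are a
#' constant Q30 symbol unless per-read qualities are supplied: the assembly
#' never consumes input qualities.
#'
#' @param pairs a `ps_library` or a data frame with columns `pair_id`,
#'   `seq1`, `seq2`.
#' @param path_r1,path_r2 output paths.
#' @param quality_char constant Phred+33 quality symbol.
#' @return invisibly, the two paths.
#' @export
write_fastq_pair <- function(pairs, path_r1, path_r2, quality_char = "?") {
  if (inherits(pairs, "ps_library")) pairs <- pairs$pairs
  stopifnot(all(c("pair_id", "seq1", "seq2") %in% names(pairs)))
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  write_one(pairs$seq1, paste0(pairs$pair_id, "/1"), path_r1)
  write_one(pairs$seq2, paste0(pairs$pair_id, "/2"), path_r2)
  invisible(c(path_r1, path_r2))
}

read_fastq_one <- function(path) {
  if (file.exists(path) && file.size(path) == 0)
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  # short quality lines come back NUL-padded, surfacing only on conversion
  qc <- tryCatch(as.character(q), error = function(e)
    stop("malformed FASTQ in ", path,
         ": quality length != sequence length", call. = FALSE))
  bad <- which(nchar(qc) != Biostrings::width(x))
  if (length(bad) > 0)
    stop("malformed FASTQ in ", path, ": quality length != sequence length ",
         "for record ", bad[1])
  data.frame(id = names(x), seq = as.character(x), stringsAsFactors = FALSE)
}

#' Read a paired FASTQ file set
#'
#' Inverse of [write_fastq_pair()]: `/1` and `/2` suffixes are stripped and
#' the two files are matched record by record. Malformed records (quality
#' and sequence lengths differing, truncated entries) are an error; a pair
#' of empty files yields zero pairs.
#'
#' @param path_r1,path_r2 the two FASTQ paths.
#' @return data frame with columns `pair_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(path_r1, path_r2) {
  a <- read_fastq_one(path_r1)
  b <- read_fastq_one(path_r2)
  if (nrow(a) != nrow(b))
    stop("paired FASTQ files hold different record counts")
  strip <- function(ids) sub("/[12]$", "", sub(" .*$", "", ids))
  ia <- strip(a$id); ib <- strip(b$id)
  if (nrow(a) > 0 && any(ia != ib))
    stop("read ids of the two files do not pair up")
  data.frame(pair_id = ia, seq1 = a$seq, seq2 = b$seq, stringsAsFactors = FALSE)
}

#' Write / read simulator truth records
#'
#' Truth is a tab-separated table with header columns `pair_id`,
#' `haplotype`, `start`, `end` (0-based half-open fragment coordinates on
#' the haplotype), `strand` (of read 1), `err_r1`, `err_r2` (comma-separated
#' 0-based read offsets of injected errors).
#'
#' @param truth truth data frame (or a `ps_library`).
#' @param path file path.
#' @return `write_truth_tsv` returns the path invisibly;
#'   `read_truth_tsv` the data frame.
#' @export
write_truth_tsv <- function(truth, path) {
  if (inherits(truth, "ps_library")) truth <- truth$truth
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = c("character", "character", "integer", "integer",
                            "character", "character", "character"))
}

#' Write a reference FASTA (both haplotypes)
#'
#' @param reference a `ps_diploid`.
#' @param path output path.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(c(hap_a = reference$hap_a,
                                  hap_b = reference$hap_b))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write pseudo-Sanger reads to FASTQ
#'
#' @param ps data frame of pseudo-Sanger reads (`id`, `seq`, `qual`), as in
#'   the `ps` element of a [run_pipeline()] result.
#' @param path output path.
#' @export
write_ps_fastq <- function(ps, path) {
  x <- Biostrings::DNAStringSet(ps$seq)
  names(x) <- ps$id
  q <- Biostrings::BStringSet(ps$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
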