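# Blocked spaced-seed indexing of supporting reads, anchor scanning,
# overlap verification and per-anchor clustering.

#' Default blocked spaced-seed pattern
#'
#' Two care-blocks of 7 bases separated by a 2-base don't-care gap (span 16,
#' weight 14). The span is kept well below the minimum overlap so that a
#' single sequencing error inside a minimum-length overlap still leaves
#' clean seed windows; the pattern only affects candidate sensitivity, as
#' every candidate is verified by alignment.
#'
#' @return the pattern as a `0`/`1` mask string.
#' @export
default_seed_pattern <- function() {
  paste0(strrep("1", 7), strrep("0", 2), strrep("1", 7))
}

#' Tuning parameters of the pseudo-Sanger assembly
#'
#' @param seed_pattern blocked spaced-seed mask (`1` = care).
#' @param sr_stride indexing stride over supporting reads (anchors are
#'   always scanned base by base).
#' @param min_overlap minimum read overlap `O` in bp.
#' @param max_mismatch_rate mismatch fraction above which a gapless
#'   extension is deemed failed and Smith-Waterman is tried.
#' @param sw_scores Smith-Waterman scores: match, mismatch, gap open,
#'   gap extend (a gap of length k scores `gap_open + k * gap_extend`).
#' @param sw_min_identity minimum identity for accepting a gapped alignment.
#' @param repeat_factor multiple of the expected supporting-read count above
#'   which an anchor read is flagged repetitive.
#' @param insert_range_mult the anchor library's insert range is its mean
#'   plus/minus this many standard deviations.
#' @return a `ps_params` list.
#' @export
ps_params <- function(seed_pattern = default_seed_pattern(),
                      sr_stride = 2L,
                      min_overlap = 30L,
                      max_mismatch_rate = 0.08,
                      sw_scores = c(match = 1, mismatch = -2,
                                    gap_open = -3, gap_extend = -1),
                      sw_min_identity = 0.92,
                      repeat_factor = 1.5,
                      insert_range_mult = 3) {
  stopifnot(min_overlap >= 1, max_mismatch_rate >= 0, max_mismatch_rate < 1,
            length(sw_scores) == 4, repeat_factor > 0, insert_range_mult > 0)
  structure(list(seed_pattern = seed_pattern, sr_stride = as.integer(sr_stride),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 sw_scores = unname(sw_scores),
                 sw_min_identity = sw_min_identity,
                 repeat_factor = repeat_factor,
                 insert_range_mult = insert_range_mult),
            class = "ps_params")
}

#' Extract spaced-seed keys from a sequence
#'
#' Applies the mask at every stride-spaced position; windows containing a
#' non-`ACGT` base yield `NA` (such positions are never indexed).
#'
#' @param seq a DNA string.
#' @param pattern mask string.
#' @param step stride between window starts.
#' @return character vector of keys with a `positions` attribute (0-based
#'   window starts).
#' @export
#' @examples
#' spaced_seed_keys("AACGT", "11011", step = 1)  # "AAGT"
spaced_seed_keys <- function(seq, pattern = default_seed_pattern(), step = 1L) {
  cpp_seed_keys(seq, pattern, as.integer(step))
}

#' Pool the supporting-read libraries of one pass
#'
#' Interleaves the read pairs of the given libraries (read `2i - 1` is pair
#' `i`'s first read, read `2i` its second) and keeps per-pair library
#' metadata for recruitment windows.
#'
#' @param libraries list of `ps_library` objects.
#' @return a `ps_srpool`: `pairs` (with `pair_id`, `seq1`, `seq2`, `lib`),
#'   `reads` (interleaved character vector), `lib_specs` (insert mean/sd and
#'   depth per library).
#' @export
sr_pool <- function(libraries) {
  if (inherits(libraries, "ps_library")) libraries <- list(libraries)
  stopifnot(length(libraries) >= 1,
            all(vapply(libraries, inherits, TRUE, "ps_library")))
  pairs <- do.call(rbind, lapply(seq_along(libraries), function(i) {
    p <- libraries[[i]]$pairs
    p$lib <- i
    p
  }))
  n <- nrow(pairs)
  reads <- character(2 * n)
  reads[seq(1, 2 * n, by = 2)] <- pairs$seq1
  reads[seq(2, 2 * n, by = 2)] <- pairs$seq2
  specs <- data.frame(
    name = vapply(libraries, function(l) l$spec$name, ""),
    insert_mean = vapply(libraries, function(l) l$spec$insert_mean, 0),
    insert_sd = vapply(libraries, function(l) l$spec$insert_sd, 0),
    depth = vapply(libraries, function(l) l$spec$depth, 0),
    read_length = vapply(libraries, function(l) l$spec$read_length, 0L),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, reads = reads, lib_specs = specs),
            class = "ps_srpool")
}

#' Build a blocked spaced-seed index over supporting reads
#'
#' Every stride-spaced position of every read (on its stored strand) is
#' entered under its masked key. Reads shorter than the seed span are
#' skipped and counted, not an error.
#'
#' @param reads a character vector of reads or a [sr_pool()] result.
#' @param pattern mask string.
#' @param step indexing stride.
#' @return a `ps_index` wrapping the native index; `info(index)$n_entries`
#'   style metadata is available via the `info` element.
#' @export
build_spaced_index <- function(reads, pattern = default_seed_pattern(),
                               step = 2L) {
  pool <- NULL
  if (inherits(reads, "ps_srpool")) {
    pool <- reads
    reads <- pool$reads
  }
  ptr <- cpp_index_build(as.character(reads), pattern, as.integer(step))
  structure(list(ptr = ptr, reads = as.character(reads), pattern = pattern,
                 step = as.integer(step), pool = pool,
                 info = cpp_index_info(ptr)),
            class = "ps_index")
}

#' Scan an anchor read against the index
#'
#' The anchor is scanned base by base on the given strand and, optionally,
#' its reverse complement; key-sharing reads are returned one row per
#' (read, diagonal), where the diagonal is the supporting-read start in
#' anchor coordinates. Rows with `strand == "-"` report coordinates on the
#' reverse-complemented anchor.
#'
#' @param ar_read anchor read sequence.
#' @param index a `ps_index`.
#' @param both_strands scan the reverse complement as well?
#' @return data frame with `sr_id`, `diagonal`, `strand`.
#' @export
scan_anchor <- function(ar_read, index, both_strands = TRUE) {
  stopifnot(inherits(index, "ps_index"))
  cpp_index_scan(index$ptr, ar_read, both_strands)
}

#' Gapless overlap verification on a fixed diagonal
#'
#' Extends across the full overlap implied by the diagonal and counts
#' mismatches (`N` never matches). The extension fails when the overlap is
#' shorter than `min_overlap` or the mismatch fraction exceeds
#' `max_mismatch_rate`; the caller then falls back to [sw_align()].
#'
#' @param ar_read,sr_read the two reads.
#' @param diagonal supporting-read start in anchor coordinates (signed).
#' @param min_overlap minimum acceptable overlap in bp.
#' @param max_mismatch_rate maximum mismatch fraction.
#' @return list with `ok`, `overlap_len`, `mismatches` (`NA` on failure).
#' @export
gapless_extend <- function(ar_read, sr_read, diagonal, min_overlap = 30L,
                           max_mismatch_rate = 0.08) {
  cpp_gapless_extend(ar_read, sr_read, as.integer(diagonal),
                     as.integer(min_overlap), max_mismatch_rate)
}

#' Smith-Waterman local alignment
#'
#' Affine-gap local alignment with deterministic tie-breaking (smallest end
#' coordinate in `a`, then in `b`). Returns the no-alignment signal
#' (`found = FALSE`) when no cell scores above zero.
#'
#' @param a,b sequences.
#' @param scoring numeric vector: match, mismatch, gap open, gap extend.
#' @return list with `found`, `score`, half-open aligned intervals
#'   `a_start`/`a_end`/`b_start`/`b_end` (0-based), `cigar` (`M`/`I`/`D`
#'   relative to `a`), and column counts.
#' @export
sw_align <- function(a, b, scoring = c(1, -2, -3, -1)) {
  stopifnot(nchar(a) > 0, nchar(b) > 0, length(scoring) == 4)
  cpp_sw_align(a, b, as.integer(scoring[1]), as.integer(scoring[2]),
               as.integer(scoring[3]), as.integer(scoring[4]))
}

#' Expected number of supporting reads overlapping an anchor read
#'
#' Under uniform coverage at depth `D`, the expected count of reads whose
#' start lies within `(L - O)` bp of an anchor read's start is
#' `D * (2 * (L - O) + 1) / L`.
#'
#' @param L read length (bp).
#' @param O minimum overlap (bp).
#' @param D summed depth of the supporting libraries (fold-coverage).
#' @return the expectation (numeric scalar).
#' @export
#' @examples
#' expected_sr_count(100, 30, 45)  # 63.45
expected_sr_count <- function(L, O, D) {
  if (O >= L) stop("`O` must be smaller than the read length `L`")
  if (O <= 0 || D <= 0) stop("`O` and `D` must be positive")
  D * (2 * (L - O) + 1) / L
}

params_list <- function(params) {
  stopifnot(inherits(params, "ps_params"))
  params[c("seed_pattern", "min_overlap", "max_mismatch_rate", "sw_scores",
           "sw_min_identity", "repeat_factor")]
}

#' Cluster supporting-read pairs around one anchor pair
#'
#' The anchor is normalised to fragment-forward orientation: read 1 is the
#' left anchor and the reverse complement of read 2 the right anchor. Every
#' supporting read that forward-overlaps an anchor read by at least `O`
#' (gapless verification, Smith-Waterman fallback) admits its pair; the
#' partner is re-oriented to fragment-forward and admitted untested, since
#' it falls inside the anchor span. Reverse-strand overlaps are discarded.
#'
#' @param ar_pair character vector `c(read1, read2)` of the anchor pair.
#' @param index a `ps_index` built over a [sr_pool()].
#' @param params a [ps_params()].
#' @return a `ps_cluster`: `left`/`right` anchor sequences
#'   (fragment-forward), verified hit counts `hitsL`/`hitsR`, and `members`
#'   (one row per admitted pair: matched read, partner, anchor side,
#'   diagonal, overlap, mismatches).
#' @export
cluster_for_anchor <- function(ar_pair, index, params = ps_params()) {
  stopifnot(inherits(index, "ps_index"), !is.null(index$pool))
  cl <- cpp_cluster_one(index$ptr, ar_pair[[1]], ar_pair[[2]],
                        params_list(params))
  m <- cl$members
  m$pair_id <- index$pool$pairs$pair_id[m$pair]
  structure(list(left = cl$left, right = cl$right,
                 hitsL = cl$hitsL, hitsR = cl$hitsR,
                 members = m, params = params),
            class = "ps_cluster")
}

#' Repeat gate for an anchor
#'
#' An anchor is repetitive when the verified forward-overlap hit count on
#' either of its reads exceeds `factor * E` (strictly), where `E` comes
#' from [expected_sr_count()]. No pseudo-Sanger sequence is built from
#' repetitive anchors.
#'
#' @param cluster a `ps_cluster`.
#' @param E expected supporting-read count.
#' @param factor gate multiplier.
#' @return logical flag.
#' @export
is_repetitive <- function(cluster, E, factor = 1.5) {
  stopifnot(E > 0)
  cluster$hitsL > factor * E || cluster$hitsR > factor * E
}
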