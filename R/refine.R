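# Inner-SR recruitment and the final consensus producing the pseudo-Sanger
# read.

#' Recruit inner supporting-read pairs onto a primitive sequence
#'
#' First pass: the primitive is queried against the index by seed match and
#' gapless verification only, keeping reads that lie entirely inside it.
#' For each pair with exactly one placed end, the partner is placed (as
#' reverse complement) inside the window implied by the pair's library
#' insert range — gapless first, Smith-Waterman on failure. Pairs whose
#' partner cannot be placed inside the primitive are dropped entirely.
#'
#' @param primitive a `ps_primitive`, or a plain sequence string.
#' @param index a `ps_index` built over a [sr_pool()] (library metadata is
#'   taken from the pool).
#' @param params a [ps_params()].
#' @return data frame of placements: `read`, `pair`, `pair_id`, `offset`,
#'   `rc` (placed as reverse complement), `cigar` (non-empty for gapped
#'   placements, relative to the primitive), `via_sw`, `b_start`/`b_end`
#'   (read interval placed).
#' @export
recruit_inner_srs <- function(primitive, index, params = ps_params()) {
  stopifnot(inherits(index, "ps_index"), !is.null(index$pool))
  seq <- if (inherits(primitive, "ps_primitive")) primitive$seq else primitive
  pool <- index$pool
  df <- cpp_recruit(index$ptr, as.integer(pool$pairs$lib),
                    pool$lib_specs$insert_mean, pool$lib_specs$insert_sd,
                    seq, params_list(params))
  df$pair_id <- pool$pairs$pair_id[df$pair]
  df
}

#' Final consensus: the pseudo-Sanger read
#'
#' Re-votes every column of the primitive over its layout contributors plus
#' the recruited inner pairs (each read votes once; recruited placements of
#' reads already in the layout are skipped). Tie rules match
#' [layout_consensus()]. The per-column quality is the Phred-scaled
#' consensus confidence `min(40, -10 log10(1 - f))` for winning vote
#' fraction `f`.
#'
#' @param primitive a `ps_primitive`.
#' @param placements recruitment table from [recruit_inner_srs()].
#' @param index the `ps_index` the placements refer to.
#' @param id read id to assign.
#' @return a `ps_read`: `id`, `seq`, `qual`, `depth`, and `flags` with
#'   `primitive_only` (no pair recruited) and `refined`.
#' @export
final_consensus <- function(primitive, placements, index, id = "PS") {
  stopifnot(inherits(primitive, "ps_primitive"), inherits(index, "ps_index"))
  graph <- primitive$graph
  lay <- primitive$layout
  seqs <- graph$seqs[lay$path]
  offs <- lay$offsets
  pri <- ifelse(lay$path <= 2L, 0L, 1L)
  cig <- character(length(seqs))
  path_reads <- stats::na.omit(graph$node_read[lay$path])
  if (nrow(placements) > 0) {
    for (i in seq_len(nrow(placements))) {
      r <- placements$read[i]
      if (r %in% path_reads) next  # already votes via the layout
      s <- index$reads[r]
      if (placements$rc[i]) s <- revcomp_dna(s)
      if (nzchar(placements$cigar[i]))
        s <- substr(s, placements$b_start[i] + 1L, placements$b_end[i])
      seqs <- c(seqs, s)
      offs <- c(offs, placements$offset[i])
      pri <- c(pri, 2L)
      cig <- c(cig, placements$cigar[i])
    }
  }
  # anchor-verified member reads vote too: they may cross the primitive's
  # ends and correct anchor errors in the otherwise thin terminal columns
  mem <- graph$members
  voting <- c(path_reads, if (nrow(placements)) placements$read)
  if (!is.null(mem) && nrow(mem) > 0) {
    for (i in seq_len(nrow(mem))) {
      if (mem$gapped[i] || mem$m_read[i] %in% voting) next
      node <- 2L + 2L * i - 1L  # member i's matched read node
      off <- if (mem$anchor[i] == 1L) mem$diag[i] else
        primitive$span - nchar(graph$seqs[2L]) + mem$diag[i]
      seqs <- c(seqs, graph$seqs[node])
      offs <- c(offs, off)
      pri <- c(pri, 2L)
      cig <- c(cig, "")
    }
  }
  cons <- cpp_consensus(seqs, as.integer(offs), as.integer(pri), cig,
                        primitive$span)
  structure(list(id = id, seq = cons$seq, qual = cons$qual,
                 depth = cons$depth,
                 flags = list(primitive_only = nrow(placements) == 0,
                              refined = nrow(placements) > 0)),
            class = "ps_read")
}
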