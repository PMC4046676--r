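# Constrained local overlap-layout-consensus: overlap graph over a cluster,
# anchored traversal, and the primitive consensus.

#' Build the overlap graph of a local cluster
#'
#' Nodes are the two anchor reads (fragment-forward) followed by each
#' member pair's matched read and re-oriented partner. Suffix-prefix
#' overlaps of at least `O` bp passing the identity threshold become
#' directed edges; candidate shifts come from seeds shared within the
#' cluster and are verified gapless. A read lying entirely inside another
#' is recorded as a containment, not an edge, so duplicates never create
#' cycles.
#'
#' @param cluster a `ps_cluster` from [cluster_for_anchor()].
#' @param index the `ps_index` the cluster was built against.
#' @param params a [ps_params()].
#' @return a `ps_ograph`: `seqs`, `node_read` (global read index per node,
#'   `NA` for anchors), `edges` (`from`, `to`, `shift`, `overlap_len`,
#'   `mismatches`), `containments`.
#' @export
build_overlap_graph <- function(cluster, index, params = ps_params()) {
  stopifnot(inherits(cluster, "ps_cluster"), inherits(index, "ps_index"))
  m <- cluster$members
  seqs <- c(cluster$left, cluster$right)
  node_read <- c(NA_integer_, NA_integer_)
  if (nrow(m) > 0) {
    for (i in seq_len(nrow(m))) {
      mseq <- index$reads[m$m_read[i]]
      pseq <- index$reads[m$p_read[i]]
      # right-anchor members sit reverse-complemented on the fragment-forward
      # strand; their partners are then already forward
      if (m$m_rc[i]) mseq <- revcomp_dna(mseq) else pseq <- revcomp_dna(pseq)
      seqs <- c(seqs, mseq, pseq)
      node_read <- c(node_read, m$m_read[i], m$p_read[i])
    }
  }
  g <- cpp_build_graph(seqs, params_list(params))
  structure(list(seqs = seqs, node_read = node_read,
                 edges = g$edges, containments = g$containments,
                 left = 1L, right = 2L, members = m),
            class = "ps_ograph")
}

#' Find the anchored layout with the most overlapped bases
#'
#' Heap-driven search over (node, offset) states from the left anchor.
#' Every edge advances the offset by at least one base, so states expand in
#' strictly increasing offset order and the maximum-cumulative-overlap
#' layout reaching the right anchor is found exactly. Arrivals whose span
#' (right-anchor offset plus its length) falls outside `insert_range` are
#' infeasible. Ties resolve to the larger overlap total, then the smaller
#' span, then the lexicographically smallest node sequence.
#'
#' @param graph a `ps_ograph`, or a plain list with elements `node_len`,
#'   `edges` (`from`, `to`, `shift`, `overlap_len`), `left`, `right`
#'   (useful for testing the search on abstract graphs).
#' @param insert_range numeric `c(min, max)` span constraint in bp.
#' @return a `ps_layout` (`path` node indices, `offsets`, `span`, `score`),
#'   or `NULL` when no feasible path exists.
#' @export
traverse <- function(graph, insert_range) {
  stopifnot(length(insert_range) == 2, insert_range[1] <= insert_range[2])
  if (inherits(graph, "ps_ograph")) {
    node_len <- nchar(graph$seqs)
    edges <- graph$edges
    left <- graph$left; right <- graph$right
  } else {
    node_len <- graph$node_len
    edges <- graph$edges
    left <- graph$left; right <- graph$right
  }
  t <- cpp_traverse(as.integer(node_len), edges, as.integer(left),
                    as.integer(right), as.integer(round(insert_range[1])),
                    as.integer(round(insert_range[2])))
  if (!t$found) return(NULL)
  structure(list(path = t$path, offsets = t$offsets,
                 span = t$span, score = t$score),
            class = "ps_layout")
}

#' Primitive consensus of a layout
#'
#' Majority vote per column over the placed layout reads. Ties go to the
#' base of the covering read with the smallest offset, anchor reads
#' outranking supporting reads at equal offsets. Per-column depth is
#' recorded.
#'
#' @param layout a `ps_layout`.
#' @param graph the `ps_ograph` the layout was found in.
#' @return a `ps_primitive`: `seq`, `qual`, `depth` (integer per column),
#'   `placements` (node, offset, anchor flag), `span`.
#' @export
layout_consensus <- function(layout, graph) {
  stopifnot(inherits(layout, "ps_layout"), inherits(graph, "ps_ograph"))
  seqs <- graph$seqs[layout$path]
  pri <- ifelse(layout$path <= 2L, 0L, 1L)
  cons <- cpp_consensus(seqs, as.integer(layout$offsets), pri,
                        character(length(seqs)), layout$span)
  structure(list(seq = cons$seq, qual = cons$qual, depth = cons$depth,
                 placements = data.frame(node = layout$path,
                                         offset = layout$offsets,
                                         anchor = layout$path <= 2L),
                 span = layout$span, layout = layout, graph = graph),
            class = "ps_primitive")
}
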