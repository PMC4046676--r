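# Independent oracles and fixture builders. The oracles are deliberately
# naive plain-R implementations, kept separate from the package's code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Brute-force affine-gap local alignment (score only). A gap of length k
# scores gap_open + k * gap_extend; full three-matrix dynamic program over
# every cell, best local score = max over all cells (0 floor).
sw_oracle <- function(a, b, match = 1, mismatch = -2,
                      gap_open = -3, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend, F[i - 1, j] + gap_extend)
      sub <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive enumeration of simple paths from `left` to `right` in an
# overlap graph, honouring the span constraint. Returns the best layout by
# (max total overlap, min span, lexicographically smallest node sequence),
# or NULL. Edges: data.frame(from, to, shift, overlap_len), 1-based nodes.
traverse_oracle <- function(node_len, edges, left, right, imin, imax) {
  best <- NULL
  better_than <- function(cand, cur) {
    if (is.null(cur)) return(TRUE)
    if (cand$score != cur$score) return(cand$score > cur$score)
    if (cand$span != cur$span) return(cand$span < cur$span)
    pa <- cand$path; pb <- cur$path
    for (t in seq_len(min(length(pa), length(pb))))
      if (pa[t] != pb[t]) return(pa[t] < pb[t])
    length(pa) < length(pb)
  }
  consider <- function(path, score, span) {
    if (span < imin || span > imax) return()
    cand <- list(path = path, score = score, span = span)
    if (better_than(cand, best)) best <<- cand
  }
  walk <- function(node, offset, score, path) {
    if (node == right) { consider(path, score, offset + node_len[right]); return() }
    sel <- which(edges$from == node)
    for (e in sel) {
      v <- edges$to[e]
      if (v %in% path || v == left) next
      o2 <- offset + edges$shift[e]
      if (o2 > imax) next
      walk(v, o2, score + edges$overlap_len[e], c(path, v))
    }
  }
  walk(left, 0, 0, left)
  best
}

# Random layered overlap graph (a DAG, as real repeat-free clusters are):
# nodes ordered left .. interior .. right, edges only forward in that order.
random_overlap_graph <- function(n_nodes, p_edge = 0.5) {
  node_len <- sample(40:120, n_nodes, replace = TRUE)
  from <- c(); to <- c(); shift <- c(); ov <- c()
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) > p_edge) next
      s <- sample.int(node_len[i] - 1, 1)
      if (s + node_len[j] <= node_len[i]) next  # containment, not an edge
      from <- c(from, i); to <- c(to, j)
      shift <- c(shift, s); ov <- c(ov, node_len[i] - s)
    }
  }
  list(node_len = node_len,
       edges = data.frame(from = from %||% integer(0), to = to %||% integer(0),
                          shift = shift %||% integer(0),
                          overlap_len = ov %||% integer(0)),
       left = 1L, right = n_nodes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hand-built supporting-read pool: pairs cut from a fragment-forward genome
# at given (start, insert) rows, optionally strand-flipped, one library.
manual_pool <- function(genome, layout, insert_mean, insert_sd = 0.1 * insert_mean,
                        read_length = 50L, name = "manual") {
  seq1 <- character(nrow(layout)); seq2 <- character(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    frag <- substr(genome, layout$start[i] + 1, layout$start[i] + layout$insert[i])
    if (!is.null(layout$strand) && layout$strand[i] == "-")
      frag <- revcomp_dna(frag)
    seq1[i] <- substr(frag, 1, read_length)
    seq2[i] <- revcomp_dna(substr(frag, layout$insert[i] - read_length + 1,
                                  layout$insert[i]))
  }
  lib <- structure(list(
    spec = library_spec(insert_mean, depth = 1, read_length = read_length,
                        error_rate = 0, insert_sd = insert_sd, name = name),
    pairs = data.frame(pair_id = sprintf("%s_%03d", name, seq_len(nrow(layout))),
                       seq1 = seq1, seq2 = seq2, stringsAsFactors = FALSE),
    truth = NULL), class = "ps_library")
  sr_pool(list(lib))
}

# Session-wide cache for expensive simulated runs shared across test files.
ps_cache <- local({
  env <- new.env(parent = emptyenv())
  function(name, expr) {
    if (!exists(name, envir = env)) assign(name, force(expr), envir = env)
    get(name, envir = env)
  }
})

# The study conditions: repeat-free 100 kb genome, four nested libraries.
headline_dataset <- function(seed = 101L)
  simulate_ps_dataset(genome_length = 1e5, seed = seed)

repeat_dataset <- function(seed = 202L)
  simulate_ps_dataset(genome_length = 2e5, seed = seed,
                      repeats = list(unit_length = 400, copies = 50))
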