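# Morphometry operates on *logical* segments: the stretches of neurite
# between topological nodes (root, branch points, tips), reconstructed from
# the piecewise-linear representation so that the statistics are invariant to
# how finely the pieces are discretized.

# Decompose a tree into logical segments.
# Returns a data.frame: one row per segment with its distal node, length,
# centrifugal order and whether it is terminal.
logical_segments <- function(tree) {
  stopifnot(inherits(tree, "neurite_tree"))
  n <- nrow(tree$pos)
  kids <- child_count(tree)
  if (n < 2) {
    return(data.frame(distal = integer(), length = numeric(),
                      order = integer(), terminal = logical()))
  }
  is_branch <- kids >= 2
  parent <- tree$parent
  root <- which(parent == 0L)[1]
  is_branch[root] <- FALSE  # the root is never a branch point
  # segment id per node: new segment after the root or a branch point
  seg <- integer(n)
  ord <- integer(n)   # branch points on the path root -> node (node excluded)
  nseg <- 0L
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p == 0L) next
    ord[i] <- ord[p] + as.integer(is_branch[p])
    if (p == root || is_branch[p]) {
      nseg <- nseg + 1L
      seg[i] <- nseg
    } else {
      seg[i] <- seg[p]
    }
  }
  plen <- piece_lengths(tree)
  seg_len <- as.numeric(tapply(plen[seg > 0],
                               factor(seg[seg > 0], levels = seq_len(nseg)),
                               sum))
  distal <- integer(nseg)
  terminal <- logical(nseg)
  sord <- integer(nseg)
  for (i in seq_len(n)) {
    s <- seg[i]
    if (s == 0L) next
    if (kids[i] != 1L) {        # tip (0 children) or branch point (2): distal end
      distal[s] <- i
      terminal[s] <- kids[i] == 0L
      sord[s] <- ord[i]
    }
  }
  data.frame(distal = distal, length = seg_len, order = sord,
             terminal = terminal)
}

#' Degree of a neuritic tree
#'
#' The number of terminal tips of the tree.
#' @param tree a `neurite_tree`.
#' @return integer count.
#' @export
tree_degree <- function(tree) {
  stopifnot(inherits(tree, "neurite_tree"))
  if (nrow(tree$pos) < 2) return(0L)
  sum(child_count(tree) == 0L)
}

#' Centrifugal orders of all segments
#'
#' The centrifugal order of a segment is the number of branch points along
#' the path from the root to the distal end of the segment; the tree's mean
#' centrifugal order averages over all terminal and intermediate segments.
#' @param tree a `neurite_tree`.
#' @return integer vector, one order per logical segment.
#' @export
centrifugal_orders <- function(tree) logical_segments(tree)$order

#' Segment and path lengths of a tree
#'
#' @param tree a `neurite_tree`.
#' @return list with `intermediate` (lengths of segments ending in a branch
#'   point), `terminal` (lengths of segments ending in a tip) and `path`
#'   (root-to-tip path length per terminal tip), all in um.
#' @export
segment_and_path_lengths <- function(tree) {
  segs <- logical_segments(tree)
  cp <- cum_path(tree)
  list(intermediate = segs$length[!segs$terminal],
       terminal = segs$length[segs$terminal],
       path = cp[segs$distal[segs$terminal]])
}

#' Population shape statistics
#'
#' Computes the six morphological shape characteristics over a population of
#' trees with the standard counting rules: for degree and total tree length
#' `n` is the number of trees; for centrifugal order `n` is the total number
#' of segments (intermediate and terminal, pooled); for intermediate segment
#' length the pooled intermediate segments; for terminal segment length and
#' path length the pooled terminal segments.
#'
#' @param trees a list of `neurite_tree` objects (or a single tree).
#' @return a data.frame with columns `characteristic`, `mean`, `sd`, `n`.
#' @examples
#' set.seed(1)
#' trees <- replicate(5, grow_tree(growth_params("basal", total_time = 86400)),
#'                    simplify = FALSE)
#' population_stats(trees)
#' @export
population_stats <- function(trees) {
  if (inherits(trees, "neurite_tree")) trees <- list(trees)
  stopifnot(length(trees) > 0, all(vapply(trees, inherits, TRUE, "neurite_tree")))
  per <- lapply(trees, function(tr) {
    sl <- segment_and_path_lengths(tr)
    list(degree = tree_degree(tr),
         total = sum(sl$intermediate) + sum(sl$terminal),
         order = centrifugal_orders(tr),
         inter = sl$intermediate, term = sl$terminal, path = sl$path)
  })
  pull <- function(f) unlist(lapply(per, `[[`, f), use.names = FALSE)
  row <- function(name, x) data.frame(
    characteristic = name, mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else NA_real_, n = length(x))
  out <- rbind(
    row("degree", pull("degree")),
    row("centrifugal_order", pull("order")),
    row("total_length", pull("total")),
    row("intermediate_segment_length", pull("inter")),
    row("terminal_segment_length", pull("term")),
    row("path_length", pull("path")))
  rownames(out) <- NULL
  out
}

#' Refine the piecewise discretization of a tree
#'
#' Splits every line piece in two equal halves. Shape characteristics operate
#' on logical segments and must be invariant under this operation; exposed
#' mainly for testing that invariance.
#' @param tree a `neurite_tree`.
#' @return a `neurite_tree` with twice as many pieces.
#' @export
refine_pieces <- function(tree) {
  n <- nrow(tree$pos)
  idx <- which(tree$parent > 0)
  mid <- (tree$pos[idx, , drop = FALSE] + tree$pos[tree$parent[idx], , drop = FALSE]) / 2
  pos <- rbind(tree$pos, mid)
  parent <- tree$parent
  newpar <- parent
  for (k in seq_along(idx)) {
    i <- idx[k]
    m <- n + k
    newpar[i] <- m
  }
  parent <- c(newpar, parent[idx]) # midpoint's parent = old parent of i
  # reorder so parents precede children
  tr <- new_neurite_tree(pos, parent, tree$arbor_type)
  reorder_tree(tr)
}

# topological sort of nodes so that parent < child
reorder_tree <- function(tree) {
  n <- nrow(tree$pos)
  ord <- integer(n)
  pos_new <- matrix(0, n, 3)
  par_new <- integer(n)
  map <- integer(n)
  queue <- which(tree$parent == 0L)
  k <- 0L
  kids <- split(seq_len(n), factor(tree$parent, levels = 0:n))
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    k <- k + 1L
    map[i] <- k
    pos_new[k, ] <- tree$pos[i, ]
    par_new[k] <- if (tree$parent[i] == 0L) 0L else map[tree$parent[i]]
    ch <- kids[[as.character(i)]]
    if (length(ch)) queue <- c(ch, queue)
  }
  new_neurite_tree(pos_new, par_new, tree$arbor_type)
}
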