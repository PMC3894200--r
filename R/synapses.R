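#' Closest approach of two 3D line pieces
#'
#' Tests whether an axonal and a dendritic line piece "cross": the common
#' perpendicular of their carrier lines must touch both pieces strictly in
#' their interiors. Parallel pieces and pairs whose closest approach lies at
#' or beyond an endpoint never cross (they are not synapse candidates, no
#' matter how close). The synapse location is the midpoint of the orthogonal
#' connector.
#'
#' @param a1,a2 endpoints of the axonal piece (numeric length 3, um).
#' @param d1,d2 endpoints of the dendritic piece.
#' @return list with `crossing` (logical), `distance` (length of the common
#'   perpendicular, um; `NA` if not crossing), `midpoint` (connector
#'   midpoint), and the line parameters `s`, `t` in `(0, 1)`.
#' @examples
#' segment_pair_crossing(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 3), c(0, 1, 3))
#' @export
segment_pair_crossing <- function(a1, a2, d1, d2) {
  stopifnot(length(a1) == 3, length(a2) == 3, length(d1) == 3, length(d2) == 3)
  if (sum((a2 - a1)^2) == 0 || sum((d2 - d1)^2) == 0) {
    warning("zero-length line piece; skipped")
    return(list(crossing = FALSE, distance = NA_real_,
                midpoint = rep(NA_real_, 3), s = NA_real_, t = NA_real_))
  }
  .segment_pair_crossing_cpp(as.numeric(a1), as.numeric(a2),
                             as.numeric(d1), as.numeric(d2))
}

# Assemble the line-piece tables of a network: one row per piece with
# endpoints, owning neuron, cumulative path length at the proximal end and a
# global piece id. Axonal and dendritic pieces are kept separate; dendritic
# pieces carry their kind (1 = basal, 2 = apical).
network_pieces <- function(network) {
  stopifnot(inherits(network, "neuron_network"))
  ax <- list(); de <- list()
  next_id <- 1L
  tree_pieces <- function(tree, neuron, kind) {
    idx <- which(tree$parent > 0)
    if (!length(idx)) return(NULL)
    cp <- cum_path(tree)
    m <- cbind(tree$pos[tree$parent[idx], , drop = FALSE],
               tree$pos[idx, , drop = FALSE])
    list(seg = m, neuron = rep.int(neuron, length(idx)),
         path0 = cp[tree$parent[idx]], kind = rep.int(kind, length(idx)))
  }
  for (nr in network$neurons) {
    ax[[length(ax) + 1L]] <- tree_pieces(nr$axon, nr$id, 0L)
    for (b in nr$basal) de[[length(de) + 1L]] <- tree_pieces(b, nr$id, 1L)
    de[[length(de) + 1L]] <- tree_pieces(nr$apical, nr$id, 2L)
  }
  bind <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    list(seg = do.call(rbind, lapply(lst, `[[`, "seg")),
         neuron = unlist(lapply(lst, `[[`, "neuron")),
         path0 = unlist(lapply(lst, `[[`, "path0")),
         kind = unlist(lapply(lst, `[[`, "kind")))
  }
  axb <- bind(ax); deb <- bind(de)
  axb$id <- seq_len(if (is.null(axb$seg)) 0L else nrow(axb$seg))
  deb$id <- seq_len(if (is.null(deb$seg)) 0L else nrow(deb$seg))
  list(axonal = axb, dendritic = deb)
}

#' Detect candidate synapses in a grown network
#'
#' Scans all (axonal piece, dendritic piece) pairs of distinct neurons and
#' records one candidate synapse for every crossing pair whose orthogonal
#' distance is below `threshold` (default 4 um). Axo-axonic and axo-somatic
#' contacts are never formed, and autapses are excluded. The default
#' `method = "grid"` uses a uniform spatial grid (cell size = threshold +
#' longest piece); `method = "exhaustive"` is the all-pairs reference scan,
#' guaranteed to return the identical set.
#'
#' @param network a `neuron_network` from [grow_network()].
#' @param threshold crossing-distance threshold, um.
#' @param method `"grid"` (spatial index) or `"exhaustive"` (O(n^2) oracle).
#' @return a data.frame of class `synapse_table`, one row per synapse:
#'   `pre`, `post` (neuron ids), `axonal_piece`, `dendritic_piece` (global
#'   piece ids), `x`, `y`, `z` (connector midpoint), `orth_dist`,
#'   `post_kind` (`"basal"`/`"apical"`), and the four synapse-to-soma
#'   distance measures `post_path_dist`, `post_eucl_dist`, `pre_path_dist`,
#'   `pre_eucl_dist` (um).
#' @examples
#' \donttest{
#' net <- grow_network(network_config(n_neurons = 4), seed = 1)
#' syn <- detect_synapses(net, threshold = 4)
#' }
#' @export
detect_synapses <- function(network, threshold = 4,
                            method = c("grid", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(threshold > 0)
  pieces <- network_pieces(network)
  empty <- is.null(pieces$axonal$seg) || is.null(pieces$dendritic$seg)
  if (empty) {
    syn <- data.frame(pre = integer(), post = integer(),
                      axonal_piece = integer(), dendritic_piece = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      orth_dist = numeric(), kind = integer(),
                      pre_path_dist = numeric(), post_path_dist = numeric())
  } else if (method == "grid") {
    syn <- .detect_synapses_cpp(pieces$axonal$seg, pieces$axonal$neuron,
                                pieces$axonal$path0, pieces$axonal$id,
                                pieces$dendritic$seg, pieces$dendritic$neuron,
                                pieces$dendritic$path0, pieces$dendritic$id,
                                pieces$dendritic$kind, threshold)
  } else {
    syn <- detect_synapses_exhaustive(pieces, threshold)
  }
  soma <- network$soma
  syn$post_kind <- c("basal", "apical")[syn$kind]
  syn$kind <- NULL
  if (nrow(syn)) {
    # Euclidean distances measured from the contact points on the axonal and
    # dendritic centre lines (the feet of the orthogonal connector), the same
    # points the path distances refer to; this keeps Euclidean <= path exact.
    foot <- function(tab, ids, path_dist, path0) {
      seg <- tab$seg[ids, , drop = FALSE]
      v <- seg[, 4:6, drop = FALSE] - seg[, 1:3, drop = FALSE]
      len <- sqrt(rowSums(v^2))
      tpar <- (path_dist - path0[ids]) / len
      seg[, 1:3, drop = FALSE] + v * tpar
    }
    fa <- foot(pieces$axonal, syn$axonal_piece, syn$pre_path_dist,
               pieces$axonal$path0)
    fd <- foot(pieces$dendritic, syn$dendritic_piece, syn$post_path_dist,
               pieces$dendritic$path0)
    syn$pre_eucl_dist <- sqrt(rowSums((fa - soma[syn$pre, , drop = FALSE])^2))
    syn$post_eucl_dist <- sqrt(rowSums((fd - soma[syn$post, , drop = FALSE])^2))
  } else {
    syn$pre_eucl_dist <- numeric(0)
    syn$post_eucl_dist <- numeric(0)
  }
  # canonical order, so grid and exhaustive results are directly comparable
  syn <- syn[order(syn$axonal_piece, syn$dendritic_piece), ]
  rownames(syn) <- NULL
  attr(syn, "threshold") <- threshold
  attr(syn, "n_neurons") <- network$config$n_neurons
  class(syn) <- c("synapse_table", "data.frame")
  syn
}

# all-pairs reference implementation (R loop over axonal pieces, vectorized
# over dendritic pieces); used as the correctness oracle for the grid
detect_synapses_exhaustive <- function(pieces, threshold) {
  A <- pieces$axonal; D <- pieces$dendritic
  out <- list()
  d1 <- D$seg[, 1:3, drop = FALSE]
  v <- D$seg[, 4:6, drop = FALSE] - d1
  c_ <- rowSums(v * v)
  for (i in seq_len(nrow(A$seg))) {
    a1 <- A$seg[i, 1:3]; a2 <- A$seg[i, 4:6]
    u <- a2 - a1
    a <- sum(u * u)
    if (a < 1e-18) next
    w0 <- matrix(rep(a1, each = nrow(d1)), ncol = 3) - d1
    b <- as.numeric(v %*% u)
    d <- as.numeric(w0 %*% u)
    e <- rowSums(v * w0)
    denom <- a * c_ - b^2
    ok <- c_ > 1e-18 & denom > 1e-12 * a * c_
    s <- ifelse(ok, (b * e - c_ * d) / denom, NA)
    t <- ifelse(ok, (a * e - b * d) / denom, NA)
    ok <- ok & !is.na(s) & s > 0 & s < 1 & t > 0 & t < 1 &
      D$neuron != A$neuron[i]
    if (!any(ok)) next
    j <- which(ok)
    P <- matrix(rep(a1, each = length(j)), ncol = 3) +
      s[j] * matrix(rep(u, each = length(j)), ncol = 3)
    Q <- d1[j, , drop = FALSE] + v[j, , drop = FALSE] * t[j]
    dist <- sqrt(rowSums((P - Q)^2))
    keep <- which(dist < threshold)
    if (!length(keep)) next
    jk <- j[keep]
    mid <- (P[keep, , drop = FALSE] + Q[keep, , drop = FALSE]) / 2
    out[[length(out) + 1L]] <- data.frame(
      pre = A$neuron[i], post = D$neuron[jk],
      axonal_piece = A$id[i], dendritic_piece = D$id[jk],
      x = mid[, 1], y = mid[, 2], z = mid[, 3],
      orth_dist = dist[keep], kind = D$kind[jk],
      pre_path_dist = A$path0[i] + s[jk] * sqrt(a),
      post_path_dist = D$path0[jk] + t[jk] * sqrt(c_[jk]))
  }
  if (!length(out))
    return(data.frame(pre = integer(), post = integer(),
                      axonal_piece = integer(), dendritic_piece = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      orth_dist = numeric(), kind = integer(),
                      pre_path_dist = numeric(), post_path_dist = numeric()))
  do.call(rbind, out)
}

#' @export
print.synapse_table <- function(x, ...) {
  cat(sprintf("<synapse_table> %d candidate synapses (threshold %g um)\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x)) {
    tb <- table(x$post_kind)
    cat("  on basal:", if ("basal" %in% names(tb)) tb[["basal"]] else 0,
        " on apical:", if ("apical" %in% names(tb)) tb[["apical"]] else 0, "\n")
  }
  invisible(x)
}

#' Write a synapse table to TSV
#' @param syn a `synapse_table`.
#' @param path output file.
#' @export
write_synapses <- function(syn, path) {
  utils::write.table(as.data.frame(syn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
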