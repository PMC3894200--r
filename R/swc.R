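# Standard SWC morphology format: whitespace-separated columns
#   id type x y z radius parent
# with '#' comments, 1-indexed ids and parent -1 for the root sample.
# Type codes: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite.

swc_type_code <- c(axon = 2L, basal = 3L, apical = 4L)

#' Write a neuron to an SWC file
#'
#' Emits one soma sample (type 1) followed by all trees of the neuron (axon
#' type 2, basal dendrites type 3, apical dendrite type 4), each rooted at
#' the soma sample. Radii are constant (1 um; neurite diameters are not
#' modelled) except for the soma, which uses half the soma diameter.
#'
#' @param neuron one element of `neuron_network$neurons`, or a single
#'   `neurite_tree`.
#' @param path output file.
#' @param soma_position,soma_radius soma sample; defaults to the tree root.
#' @param radius neurite radius written for every sample, um.
#' @return the path, invisibly.
#' @export
write_swc <- function(neuron, path, soma_position = NULL, soma_radius = 5,
                      radius = 1) {
  trees <- if (inherits(neuron, "neurite_tree")) list(neuron)
           else c(list(neuron$axon), neuron$basal, list(neuron$apical))
  if (is.null(soma_position)) soma_position <- trees[[1]]$pos[1, ]
  lines <- sprintf("%d 1 %.6f %.6f %.6f %.6f -1", 1L,
                   soma_position[1], soma_position[2], soma_position[3],
                   soma_radius)
  offset <- 1L
  for (tr in trees) {
    type <- swc_type_code[[sub("_.*", "", tr$arbor_type)]]
    n <- nrow(tr$pos)
    if (n < 2) next
    # tree node 1 (the root, at the soma) maps to the soma sample
    ids <- offset + seq_len(n - 1L)
    par <- tr$parent[-1L]
    par_ids <- ifelse(par == 1L, 1L, offset + par - 1L)
    lines <- c(lines, sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                              ids, type,
                              tr$pos[-1L, 1], tr$pos[-1L, 2], tr$pos[-1L, 3],
                              radius, par_ids))
    offset <- offset + n - 1L
  }
  writeLines(c("# SWC generated by arborsim", lines), path)
  invisible(path)
}

#' Read neurite trees from an SWC file
#'
#' Parses a standard SWC file and splits it into one `neurite_tree` per
#' neurite type (samples of type 2 become the axon, 3 the basal dendrites --
#' one tree per root sample attached to the soma -- and 4 the apical
#' dendrite). Soma samples become tree roots.
#'
#' @param path SWC file.
#' @return list of `neurite_tree` objects with an `swc_type` attribute.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  raw <- trimws(sub("#.*", "", raw))
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("no samples in SWC file: ", path)
  fields <- strsplit(raw, "[[:space:]]+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop("malformed SWC line ", bad[1], ": expected 7 columns")
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in SWC file: ", path)
  ids <- as.integer(m[, 1])
  parent <- as.integer(m[, 7])
  idx <- match(parent, ids)
  orphan <- which(parent != -1 & is.na(idx))
  if (length(orphan))
    stop("malformed parent reference on SWC line ", orphan[1],
         " (sample id ", ids[orphan[1]], " refers to missing parent ",
         parent[orphan[1]], ")")
  type <- as.integer(m[, 2])
  nsamp <- nrow(m)
  kids <- vector("list", nsamp)
  for (i in seq_len(nsamp)) {
    p <- idx[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  # a neurite tree starts at every non-soma sample whose parent is a soma
  # sample or absent (-1)
  tree_roots <- which(type != 1L & (is.na(idx) | type[idx] == 1L))
  out <- list()
  for (r in tree_roots) {
    sel <- integer(0)
    queue <- r
    while (length(queue)) {               # depth-first subtree collection
      i <- queue[1]; queue <- queue[-1]
      sel <- c(sel, i)
      queue <- c(kids[[i]], queue)
    }
    has_soma <- !is.na(idx[r])
    if (has_soma) {                       # soma position becomes the root node
      pos <- rbind(m[idx[r], 3:5, drop = FALSE], m[sel, 3:5, drop = FALSE])
      local <- match(idx[sel], sel) + 1L  # parent position within this tree
      local[sel == r] <- 1L
      pos_par <- c(0L, local)
    } else {
      pos <- m[sel, 3:5, drop = FALSE]
      pos_par <- match(idx[sel], sel)
      pos_par[is.na(pos_par)] <- 0L
    }
    arbor <- names(swc_type_code)[match(type[r], swc_type_code)]
    if (is.na(arbor)) arbor <- "basal"
    tr <- new_neurite_tree(pos, as.integer(pos_par), arbor)
    attr(tr, "swc_type") <- type[r]
    out[[length(out) + 1L]] <- tr
  }
  out
}
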