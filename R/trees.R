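#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (m - 2) d(i,j) - R(i) - R(j)` is joined, branch lengths are
#' assigned from the row sums, and the matrix is reduced with the usual
#' average update. Ties in the Q matrix are broken deterministically by the
#' lowest (row, column) index pair in the current ordering, so the result is
#' invariant to the order in which ties happen to be stored. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sibling
#' edge (the convention used by common distance-tree software); raw values
#' are kept in the `"clamp_log"` attribute.
#'
#' On an additive (tree-like) matrix the output reproduces the generating
#' tree exactly, topology and branch lengths.
#'
#' @param dm a `k2p_matrix`, `dist`, or square symmetric matrix with
#'   dimnames; at least 3 labels, no undefined entries
#' @return an unrooted `phylo` tree (ape)
#' @export
nj_tree <- function(dm) {
  D <- .as_dmatrix(dm)
  labs <- rownames(D)
  n <- length(labs)
  if (n < 3L) stop("neighbour-joining needs at least 3 labels")
  if (any(is.na(D[upper.tri(D)]))) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distances for pairs: ",
         paste(paste(labs[bad[, 1]], labs[bad[, 2]], sep = "/"),
               collapse = ", "))
  }
  # node ids: tips 1..n; internal nodes created n+1, n+2, ...; the last
  # internal node created (the final trifurcation) becomes the phylo root.
  node_id <- seq_len(n)
  next_node <- n + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  clamp_log <- list()
  Dcur <- D
  add_edge <- function(p, c, l) {
    parent <<- c(parent, p); child <<- c(child, c); elen <<- c(elen, l)
  }
  note_clamp <- function(node, raw) {
    clamp_log[[length(clamp_log) + 1L]] <<-
      data.frame(node = node, raw_length = raw)
  }
  while (length(node_id) > 3L) {
    m <- length(node_id)
    R <- rowSums(Dcur)
    Qm <- (m - 2) * Dcur - outer(R, R, "+")
    Qm[lower.tri(Qm, diag = TRUE)] <- Inf
    cand <- which(Qm == min(Qm), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- Dcur[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { note_clamp(node_id[i], li); lj <- lj + li; li <- 0 }
    if (lj < 0) { note_clamp(node_id[j], lj); li <- max(0, li + lj); lj <- 0 }
    new <- next_node; next_node <- next_node + 1L
    add_edge(new, node_id[i], li)
    add_edge(new, node_id[j], lj)
    dnew <- (Dcur[i, ] + Dcur[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dcur <- rbind(cbind(Dcur[keep, keep, drop = FALSE], dnew[keep]),
                  c(dnew[keep], 0))
    node_id <- c(node_id[keep], new)
  }
  d12 <- Dcur[1, 2]; d13 <- Dcur[1, 3]; d23 <- Dcur[2, 3]
  lens <- c((d12 + d13 - d23) / 2,
            (d12 + d23 - d13) / 2,
            (d13 + d23 - d12) / 2)
  root <- next_node
  for (k in 1:3) {
    l <- lens[k]
    if (l < 0) { note_clamp(node_id[k], l); l <- 0 }
    add_edge(root, node_id[k], l)
  }
  # renumber internal nodes to ape convention: root = n + 1
  remap <- function(v) ifelse(v == root, n + 1L,
                              ifelse(v > n, v + 1L, v))
  tr <- structure(list(edge = cbind(remap(parent), remap(child)),
                       edge.length = elen,
                       tip.label = labs,
                       Nnode = n - 2L),
                  class = "phylo")
  tr <- stats::reorder(tr, "cladewise")
  attr(tr, "clamp_log") <- if (length(clamp_log) > 0L)
    do.call(rbind, clamp_log) else
    data.frame(node = integer(), raw_length = numeric())
  tr
}

#' Bootstrap supports for a neighbour-joining K2P tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P distance
#' matrix (pairwise deletion is re-applied per replicate) and the NJ tree,
#' and scores each internal bipartition of the reference tree by the percent
#' of replicate trees containing it. A replicate whose resampled matrix
#' contains an undefined distance is redrawn (up to `10 * replicates`
#' redraws, after which an error is raised); the redraw count is recorded in
#' the `"n_redrawn"` attribute.
#'
#' @param lib a `barcode_library`
#' @param replicates number of bootstrap replicates
#' @param seed integer seed (results are reproducible)
#' @param tree optional reference tree; defaults to the NJ tree of the full
#'   alignment
#' @return the reference `phylo` tree with integer percent supports in
#'   `node.label`
#' @export
bootstrap_supports <- function(lib, replicates = 100, seed = 1, tree = NULL) {
  stopifnot(replicates >= 1)
  m <- .as_seqmat(lib)
  if (is.null(tree)) tree <- nj_tree(distance_matrix(m))
  set.seed(seed)
  L <- ncol(m)
  reps <- vector("list", replicates)
  got <- 0L
  redrawn <- 0L
  while (got < replicates) {
    cols <- sample.int(L, L, replace = TRUE)
    dmb <- distance_matrix(m[, cols, drop = FALSE])
    if (any(dmb$flag[upper.tri(dmb$flag)] == "undefined")) {
      redrawn <- redrawn + 1L
      if (redrawn > 10L * replicates) {
        stop("too many bootstrap replicates with undefined distances")
      }
      next
    }
    # saturated pairs are tolerated by substituting the largest defined
    # distance; they are rare and only perturb deep branches
    if (anyNA(dmb$d)) {
      dmb$d[is.na(dmb$d)] <- max(dmb$d, na.rm = TRUE)
    }
    got <- got + 1L
    reps[[got]] <- nj_tree(dmb)
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.integer(round(100 * counts / replicates))
  attr(tree, "n_redrawn") <- redrawn
  tree
}

# Root a tree at an outgroup tip if given, else midpoint.
.root_tree <- function(tree, outgroup = NULL) {
  if (ape::is.rooted(tree) && is.null(outgroup)) return(tree)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a tip of the tree")
    }
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
}

#' Test whether a set of tips is monophyletic
#'
#' The tree is rooted at the designated outgroup when one is supplied,
#' otherwise at the midpoint of the longest path. The set is monophyletic
#' when some edge bipartition isolates exactly the set on the non-root side.
#'
#' @param tree a `phylo` tree
#' @param label_set character vector of tip labels
#' @param outgroup optional outgroup tip label used for rooting
#' @return logical
#' @export
is_monophyletic <- function(tree, label_set, outgroup = NULL) {
  unknown <- setdiff(label_set, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown labels: ", paste(unknown, collapse = ", "))
  }
  rooted <- .root_tree(tree, outgroup)
  ape::is.monophyletic(rooted, tips = label_set)
}

#' Species-differentiation report
#'
#' Applies the two-part barcoding differentiation criterion: a species with
#' two or more sampled individuals is successfully differentiated when its
#' barcodes form a monophyletic cluster on the tree and none of its
#' haplotypes is shared with another species; for a species with a single
#' representative only the haplotype-sharing criterion applies.
#'
#' @param tree a `phylo` tree whose tips are record ids
#' @param haplotypes a `haplotype_set` from [collapse_haplotypes()]
#' @param species_of id -> species mapping covering the tree tips
#' @param outgroup optional outgroup tip id; excluded from the tally and used
#'   to root the tree (midpoint rooting otherwise)
#' @return data frame of class `differentiation_report` with columns
#'   `species`, `n`, `status` (`monophyletic` / `non-monophyletic` /
#'   `singleton`), `shared_haplotype`, `success`; attributes
#'   `n_success`, `n_species`, `success_fraction`
#' @export
differentiation_report <- function(tree, haplotypes, species_of,
                                   outgroup = NULL) {
  tips <- setdiff(tree$tip.label, outgroup)
  sp <- species_of[tips]
  if (any(is.na(sp))) {
    stop("species_of must cover every tree tip")
  }
  shared_sp <- shared_haplotype_species(haplotypes)
  rooted <- .root_tree(tree, outgroup)
  species <- sort(unique(unname(sp)))
  rows <- lapply(species, function(s) {
    ids <- tips[sp == s]
    shared <- s %in% shared_sp
    if (length(ids) == 1L) {
      status <- "singleton"
      success <- !shared
    } else {
      mono <- ape::is.monophyletic(rooted, tips = ids)
      status <- if (mono) "monophyletic" else "non-monophyletic"
      success <- mono && !shared
    }
    data.frame(species = s, n = length(ids), status = status,
               shared_haplotype = shared, success = success,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_success") <- sum(out$success)
  attr(out, "n_species") <- nrow(out)
  attr(out, "success_fraction") <- sum(out$success) / nrow(out)
  class(out) <- c("differentiation_report", class(out))
  out
}

#' @export
print.differentiation_report <- function(x, ...) {
  cat(sprintf("species differentiation: %d of %d (%.1f%%)\n",
              attr(x, "n_success"), attr(x, "n_species"),
              100 * attr(x, "success_fraction")))
  print.data.frame(x, ...)
  invisible(x)
}
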