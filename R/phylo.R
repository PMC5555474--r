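#' @name phylo
#' @title Distances, neighbor-joining and clade-purity statistics
#' @description
#' Distance computation (p-distance and Kimura two-parameter), canonical
#' Saitou-Nei neighbor-joining with deterministic tie-breaking, bootstrap
#' supports by column resampling, and a statistic for whether functional
#' and pseudogenic paralogs separate into two clades.
NULL

.aln_matrix <- function(alignment) {
  width <- unique(nchar(alignment))
  if (length(width) != 1L)
    stop("alignment rows must have equal gapped length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

.pair_stats <- function(a_chars, b_chars) {
  ok <- a_chars %in% DNA_BASES & b_chars %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L)
    return(list(n = 0L, diffs = 0L, P = NA_real_, Q = NA_real_))
  a <- a_chars[ok]; b <- b_chars[ok]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  list(n = n, diffs = sum(diff),
       P = sum(transition) / n, Q = sum(diff & !transition) / n)
}

#' Proportion of differing sites between two aligned sequences
#'
#' p-distance with pairwise deletion: columns carrying a gap or ambiguity
#' code in either sequence are excluded.
#'
#' @param a,b equal-length gapped strings.
#' @return List with `distance` and `comparable_sites`; `distance` is `NA`
#'   (flagged undefined) when no site is comparable.
#' @examples
#' p_distance("ACGT", "ACGA")$distance  # 0.25
#' @export
p_distance <- function(a, b) {
  ca <- seq_to_chars(toupper(a)); cb <- seq_to_chars(toupper(b))
  if (length(ca) != length(cb))
    stop("gapped sequences have unequal lengths", call. = FALSE)
  st <- .pair_stats(ca, cb)
  list(distance = if (st$n > 0) st$diffs / st$n else NA_real_,
       comparable_sites = st$n)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over comparable (pairwise
#' deletion) sites. When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the distance is
#' undefined (saturation) and flagged.
#'
#' @inheritParams p_distance
#' @return List with `distance` (`NA` when saturated or no comparable
#'   sites), `P`, `Q`, `comparable_sites`, `saturated`.
#' @export
k2p_distance <- function(a, b) {
  ca <- seq_to_chars(toupper(a)); cb <- seq_to_chars(toupper(b))
  if (length(ca) != length(cb))
    stop("gapped sequences have unequal lengths", call. = FALSE)
  st <- .pair_stats(ca, cb)
  if (st$n == 0L)
    return(list(distance = NA_real_, P = NA_real_, Q = NA_real_,
                comparable_sites = 0L, saturated = FALSE))
  w1 <- 1 - 2 * st$P - st$Q
  w2 <- 1 - 2 * st$Q
  if (w1 <= 0 || w2 <= 0)
    return(list(distance = NA_real_, P = st$P, Q = st$Q,
                comparable_sites = st$n, saturated = TRUE))
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), P = st$P, Q = st$Q,
       comparable_sites = st$n, saturated = FALSE)
}

#' Distance matrix over an alignment
#'
#' @param alignment named character vector of equal-length gapped
#'   sequences.
#' @param model `"p"` or `"k2p"`.
#' @param deletion `"pairwise"` (drop columns gapped/ambiguous in the pair
#'   at hand) or `"complete"` (drop columns gapped/ambiguous in any
#'   sequence of the alignment).
#' @return Symmetric numeric matrix with `NA` for undefined (saturated or
#'   zero-site) pairs; attributes `model`, `deletion`, and `sites` (matrix
#'   of comparable-site counts).
#' @export
dist_rdna <- function(alignment, model = c("k2p", "p"),
                      deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- .aln_matrix(alignment)
  if (deletion == "complete") {
    keep <- apply(m, 2L, function(col) all(col %in% DNA_BASES))
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sites <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      st <- .pair_stats(m[i, ], m[j, ])
      sites[i, j] <- sites[j, i] <- st$n
      val <- if (st$n == 0L) {
        NA_real_
      } else if (model == "p") {
        st$diffs / st$n
      } else {
        w1 <- 1 - 2 * st$P - st$Q; w2 <- 1 - 2 * st$Q
        if (w1 <= 0 || w2 <= 0) NA_real_
        else -0.5 * log(w1) - 0.25 * log(w2)
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  attr(d, "model") <- model
  attr(d, "deletion") <- deletion
  attr(d, "sites") <- sites
  d
}

#' Average p-distance of a sequence set
#'
#' Arithmetic mean of pairwise p-distances over all unordered pairs;
#' undefined pairs (no comparable sites) are skipped.
#'
#' @inheritParams dist_rdna
#' @return Numeric mean distance; `NA` when fewer than two sequences or no
#'   defined pair.
#' @export
average_p_distance <- function(alignment, deletion = c("pairwise",
                                                       "complete")) {
  if (length(alignment) < 2L) return(NA_real_)
  d <- dist_rdna(alignment, model = "p", deletion = match.arg(deletion))
  vals <- d[upper.tri(d)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

# -- neighbor joining ---------------------------------------------------------

.fmt_bl <- function(x) sprintf("%.10g", max(0, x))

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined; ties are broken by the lexicographically smallest
#' pair of representative ids (an internal node is represented by the
#' smallest leaf id it contains), so the topology is fully deterministic.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sister branch, preserving path lengths.
#'
#' @param d symmetric numeric distance matrix with ids as dimnames (e.g.
#'   from [dist_rdna()]).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs dimnames", call. = FALSE)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined/saturated distances for pairs: ",
         paste(paste(ids[bad[, 1]], ids[bad[, 2]], sep = "-"),
               collapse = ", "), call. = FALSE)
  }
  nwk <- ids
  rep_id <- ids
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Qc <- (m - 2) * D - outer(r, r, "+")
    diag(Qc) <- Inf
    qmin <- min(Qc)
    cand <- which(Qc - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_id[ij[1]], rep_id[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    dij <- D[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_nwk <- paste0("(", nwk[i], ":", .fmt_bl(bi), ",",
                      nwk[j], ":", .fmt_bl(bj), ")")
    new_rep <- min(rep_id[i], rep_id[j])
    others <- setdiff(seq_len(m), c(i, j))
    new_d <- (D[i, others] + D[j, others] - dij) / 2
    new_d[new_d < 0] <- 0
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, new_d), c(new_d, 0))
    nwk <- c(nwk[others], new_nwk)
    rep_id <- c(rep_id[others], new_rep)
    rownames(D) <- colnames(D) <- rep_id
  }
  if (nrow(D) == 3L) {
    b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    txt <- paste0("(", nwk[1], ":", .fmt_bl(b1), ",",
                  nwk[2], ":", .fmt_bl(b2), ",",
                  nwk[3], ":", .fmt_bl(b3), ");")
  } else {
    txt <- paste0("(", nwk[1], ":", .fmt_bl(D[1, 2] / 2), ",",
                  nwk[2], ":", .fmt_bl(D[1, 2] / 2), ");")
  }
  ape::read.tree(text = txt)
}

# Tip-label sets below each edge's child node, in one postorder pass.
.node_tipsets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  desc <- vector("list", nt + nn)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; c_ <- tr$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[c_]])
  }
  desc
}

# Canonical keys of the non-trivial bipartitions induced by internal edges.
# The side not containing the alphabetically smallest label is the key.
.tree_splits <- function(tree, all_labels = sort(tree$tip.label)) {
  nt <- length(tree$tip.label)
  desc <- .node_tipsets(tree)
  anchor <- all_labels[1L]
  internal_children <- tree$edge[tree$edge[, 2] > nt, 2]
  keys <- character(0); nodes <- integer(0)
  for (node in internal_children) {
    side <- desc[[node]]
    if (length(side) < 2L || length(side) > nt - 2L) next
    if (anchor %in% side) side <- setdiff(all_labels, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for every internal edge of the original tree the
#' percentage of replicates containing the same bipartition. Replicates in
#' which some pairwise distance is undefined (saturated) are dropped and
#' counted; a warning is raised when more than 5% are dropped.
#'
#' @inheritParams dist_rdna
#' @param n_replicates number of bootstrap pseudoreplicates (>= 1).
#' @param seed integer RNG seed; fixed seed gives identical supports.
#' @return List with `tree` (the original NJ tree, supports as integer
#'   0-100 node labels; the root label is empty), `splits` (data frame of
#'   bipartition keys and supports), and `dropped_replicates`.
#' @export
bootstrap_support <- function(alignment, model = c("k2p", "p"),
                              n_replicates = 100L, seed = 1L,
                              deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  m <- .aln_matrix(alignment)
  d0 <- dist_rdna(alignment, model = model, deletion = deletion)
  tree <- nj_tree(d0)
  labels <- sort(rownames(m))
  orig <- .tree_splits(tree, labels)
  counts <- setNames(rep(0L, nrow(orig)), orig$key)
  dropped <- 0L
  width <- ncol(m)
  with_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      cols <- sample.int(width, width, replace = TRUE)
      res <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      names(res) <- rownames(m)
      db <- dist_rdna(res, model = model, deletion = deletion)
      if (any(!is.finite(db))) { dropped <- dropped + 1L; next }
      keys_b <- .tree_splits(nj_tree(db), labels)$key
      hit <- orig$key %in% keys_b
      counts[hit] <- counts[hit] + 1L
    }
  })
  used <- n_replicates - dropped
  if (dropped > 0.05 * n_replicates)
    warning(dropped, " of ", n_replicates,
            " bootstrap replicates dropped (undefined distances)")
  supports <- if (used > 0) as.integer(round(100 * counts / used)) else
    rep(NA_integer_, length(counts))
  node_label <- rep("", tree$Nnode)
  nt <- length(tree$tip.label)
  node_label[orig$node - nt] <- as.character(supports)
  tree$node.label <- node_label
  list(tree = tree,
       splits = data.frame(key = orig$key, support = supports,
                           stringsAsFactors = FALSE),
       dropped_replicates = dropped)
}

#' Does the tree separate functional genes from pseudogenes?
#'
#' Scans every edge of the tree for the bipartition that exactly splits the
#' leaves by label; when no edge induces it, reports the minimum number of
#' leaves that would have to be moved (over all edges) to make the split
#' class-pure.
#'
#' @param tree an `ape::phylo` tree.
#' @param labels named character vector mapping every leaf to
#'   `"functional"` or `"pseudogene"`.
#' @return List with `is_bipartition_separating` (logical) and
#'   `best_split_impurity` (integer; 0 when separating).
#' @export
clade_purity <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("unlabeled leaves: ",
         paste(setdiff(tips, names(labels)), collapse = ", "),
         call. = FALSE)
  lab <- labels[tips]
  if (!all(lab %in% c("functional", "pseudogene")))
    stop("labels must be 'functional' or 'pseudogene'", call. = FALSE)
  desc <- .node_tipsets(tree)
  n_fun <- sum(lab == "functional")
  n_pse <- sum(lab == "pseudogene")
  best <- Inf
  for (k in seq_len(nrow(tree$edge))) {
    side <- desc[[tree$edge[k, 2]]]
    f_in <- sum(lab[side] == "functional")
    p_in <- sum(lab[side] == "pseudogene")
    # side taken as the pseudogene clade, or as the functional clade
    imp <- min(f_in + (n_pse - p_in), p_in + (n_fun - f_in))
    if (imp < best) best <- imp
  }
  list(is_bipartition_separating = best == 0,
       best_split_impurity = as.integer(best))
}
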