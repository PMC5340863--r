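# Run-integration metrics: technical-replicate stability curves, UPGMA
# trees on Hamming distances, and unweighted UniFrac.

#' Technical-replicate stability overlap curve
#'
#' For each minimum-frequency threshold `f`, the fraction of features with
#' total count `>= f` in one table that are present (count >= 1) in the
#' other. Reported in both directions.
#'
#' @param t1,t2 `feature_table`s from the two replicates (feature totals
#'   across samples are used).
#' @param thresholds Integer vector of minimum-frequency thresholds.
#' @return A data frame with columns `threshold`, `overlap_12` (fraction of
#'   thresholded `t1` features found in `t2`) and `overlap_21`. A threshold
#'   that leaves no features yields `NaN`.
#' @export
stability_overlap <- function(t1, t2, thresholds = c(1, 2, 5, 10, 20, 50)) {
  tot1 <- colSums(as_plain_matrix(t1))
  tot2 <- colSums(as_plain_matrix(t2))
  one_way <- function(a, b) {
    vapply(thresholds, function(f) {
      sel <- names(a)[a >= f]
      if (length(sel) == 0L) return(NaN)
      mean(sel %in% names(b)[b >= 1])
    }, numeric(1))
  }
  data.frame(threshold = thresholds,
             overlap_12 = one_way(tot1, tot2),
             overlap_21 = one_way(tot2, tot1))
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic beta diversity: for two samples, the sum of
#' branch lengths leading only to leaves present in exactly one of them,
#' divided by the sum of branch lengths leading to leaves present in either.
#' Presence means count >= 1. Implemented by a single postorder pass that
#' propagates per-sample presence up the tree, marking each branch as
#' observed in a sample when any leaf below it is present.
#'
#' @param t A `feature_table`; every feature with a nonzero count must be a
#'   tip label of `tree`.
#' @param tree A rooted `ape::phylo` with branch lengths.
#' @return A symmetric numeric matrix (zero diagonal) with sample ids as
#'   dimnames. Sample pairs observing no branches at all get distance 0.
#' @export
unweighted_unifrac <- function(t, tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!ape::is.rooted(tree)) stop("unweighted UniFrac requires a rooted tree")
  m <- as_plain_matrix(t)
  present_feats <- colnames(m)[colSums(m) > 0L]
  missing <- setdiff(present_feats, tree$tip.label)
  if (length(missing) > 0L) {
    stop("feature not found as a tree leaf: ", missing[1L])
  }
  n_samp <- nrow(m)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # pres[node, sample]: any tip below `node` present in `sample`
  pres <- matrix(FALSE, n_node, n_samp)
  idx <- match(tree$tip.label, colnames(m))
  has <- !is.na(idx)
  pres[which(has), ] <- t(m[, idx[has], drop = FALSE] >= 1L)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    pres[pa, ] <- pres[pa, ] | pres[ch, ]
  }
  # branch e observed in sample s iff its child subtree has a present tip
  obs <- pres[tree$edge[, 2L], , drop = FALSE]
  len <- tree$edge.length
  d <- matrix(0, n_samp, n_samp,
              dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n_samp)) {
    for (j in seq_len(n_samp)) {
      if (j <= i) next
      union_len <- sum(len[obs[, i] | obs[, j]])
      uniq_len <- sum(len[xor(obs[, i], obs[, j])])
      d[i, j] <- d[j, i] <- if (union_len == 0) 0 else uniq_len / union_len
    }
  }
  d
}

#' UPGMA tree from pairwise Hamming distances
#'
#' Average-linkage hierarchical clustering on the pairwise Hamming distance
#' matrix, returned as a rooted ultrametric `ape::phylo` whose tip labels
#' are the sequences themselves. At every step the pair at minimal distance
#' is merged; ties are broken by merging the pair whose (lexicographically
#' smallest member, then second member) sorts first, so the topology is
#' deterministic.
#'
#' @param seqs Character vector of >= 2 unique equal-length sequences.
#' @return A rooted `phylo` with ultrametric branch lengths (leaf depth =
#'   half the root-height cophenetic distance).
#' @export
hamming_upgma <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !anyDuplicated(seqs))
  n <- length(seqs)
  cm <- seq_char_matrix(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- sum(cm[i, ] != cm[j, ])
    }
  }
  # active clusters: newick fragment, size, height, smallest member sequence
  cl <- lapply(seq_len(n), function(i) {
    list(nwk = seqs[i], size = 1L, height = 0, label = seqs[i])
  })
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL
    for (ai in seq_along(active)) {
      for (aj in seq_along(active)) {
        if (aj <= ai) next
        i <- active[ai]; j <- active[aj]
        key <- sort(c(cl[[i]]$label, cl[[j]]$label))
        if (is.null(best) || D[i, j] < best$d - 1e-12 ||
            (abs(D[i, j] - best$d) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, d = D[i, j], key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    # child order by label keeps the written tree input-order invariant
    if (cl[[j]]$label < cl[[i]]$label) { tmp <- i; i <- j; j <- tmp }
    h <- best$d / 2
    merged <- list(
      nwk = sprintf("(%s:%.10g,%s:%.10g)",
                    cl[[i]]$nwk, h - cl[[i]]$height,
                    cl[[j]]$nwk, h - cl[[j]]$height),
      size = cl[[i]]$size + cl[[j]]$size,
      height = h,
      label = min(cl[[i]]$label, cl[[j]]$label))
    cl[[length(cl) + 1L]] <- merged
    k <- length(cl)
    D <- rbind(cbind(D, 0), 0)
    for (o in seq_len(k - 1L)) {
      D[k, o] <- D[o, k] <-
        (cl[[i]]$size * D[i, o] + cl[[j]]$size * D[j, o]) / merged$size
    }
    active <- c(setdiff(active, c(i, j)), k)
  }
  ape::read.tree(text = paste0(cl[[active]]$nwk, ";"))
}

#' Read a rooted tree from a Newick file
#'
#' Standard Newick with branch lengths. Before parsing, the text is scanned
#' for unbalanced parentheses so malformed input fails with the offending
#' character offset.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such Newick file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars))
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
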