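# Independent reference implementations used as oracles. Deliberately
# written in plain scalar style, sharing no code with the package internals.

oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

oracle_pair_dist <- function(ga, gb) {
  va <- strsplit(ga, "")[[1]]
  vb <- strsplit(gb, "")[[1]]
  subs <- 0L
  ind <- 0L
  for (col in seq_along(va)) {
    a <- va[col]
    b <- vb[col]
    if (a == "-" && b == "-") next
    if (a == "-" || b == "-") {
      ind <- ind + 1L
    } else if (a != b) {
      subs <- subs + 1L
    }
  }
  list(h = subs, g = ind)
}

# Exhaustive global-alignment score by recursion over all alignments.
oracle_align_score <- function(a, b, match = 1, mismatch = -1.5, gap = -3) {
  if (nchar(a) == 0L) return(gap * nchar(b))
  if (nchar(b) == 0L) return(gap * nchar(a))
  s <- if (substr(a, 1, 1) == substr(b, 1, 1)) match else mismatch
  max(oracle_align_score(substring(a, 2), substring(b, 2),
                         match, mismatch, gap) + s,
      oracle_align_score(substring(a, 2), b, match, mismatch, gap) + gap,
      oracle_align_score(a, substring(b, 2), match, mismatch, gap) + gap)
}

# Brute-force greedy subtraction on an aligned workspace: one pass in
# descending-count order (ties lexicographic on the ungapped sequence),
# per-pair distances rescanned from scratch, removal at residual <= 0.
oracle_deblur <- function(gapped, counts, profile_vec,
                          mean_error, indel_prob, indel_max, read_length) {
  M <- (1 - mean_error)^read_length
  H <- length(profile_vec) - 1L
  seqs <- gsub("-", "", gapped)
  k <- length(gapped)
  r <- as.numeric(counts)
  removed <- rep(FALSE, k)
  ord <- order(-counts, seqs, method = "radix")
  for (i in ord) {
    if (removed[i]) next
    for (j in seq_len(k)) {
      if (j == i) next
      d <- oracle_pair_dist(gapped[i], gapped[j])
      if (d$g > indel_max) next
      pen <- r[i] * profile_vec[min(d$h, H) + 1L] / M
      if (d$g >= 1L) pen <- pen * indel_prob
      r[j] <- r[j] - pen
    }
    removed <- removed | (r <= 0)
  }
  rounded <- floor(r + 0.5)
  keep <- !removed & rounded >= 1
  o <- order(seqs[keep])
  list(sequences = seqs[keep][o], counts = as.integer(rounded[keep][o]))
}

# Brute-force two-parent chimera scan over every (P1, P2, x).
oracle_chimeras <- function(seqs, counts, skew = 2, min_parent_diffs = 3L,
                            max_model_diffs = 0L) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  flagged <- rep(FALSE, n)
  for (q in order(counts, seqs, method = "radix")) {
    pool <- order(-counts, seqs, method = "radix")
    pool <- pool[!flagged[pool] & counts[pool] >= skew * counts[q]]
    pool <- setdiff(pool, q)
    found <- FALSE
    for (p1 in pool) {
      for (p2 in pool) {
        if (p2 == p1 || found) next
        for (x in seq_len(L - 1L)) {
          model <- paste0(substr(seqs[p1], 1, x), substr(seqs[p2], x + 1, L))
          if (oracle_hamming(model, seqs[q]) <= max_model_diffs &&
              oracle_hamming(substr(seqs[p1], x + 1, L),
                             substr(seqs[q], x + 1, L)) >= min_parent_diffs &&
              oracle_hamming(substr(seqs[p2], 1, x),
                             substr(seqs[q], 1, x)) >= min_parent_diffs) {
            flagged[q] <- TRUE
            found <- TRUE
            break
          }
        }
      }
    }
  }
  flagged
}

# Unweighted UniFrac by explicit per-sample branch-set construction: each
# sample's branch set is the union of root-to-leaf edge paths of its
# present features.
oracle_unifrac <- function(tab, tree) {
  m <- unclass(tab)
  root <- length(tree$tip.label) + 1L
  branch_set <- function(feats) {
    edges <- integer(0)
    for (f in feats) {
      np <- ape::nodepath(tree, root, match(f, tree$tip.label))
      for (s in seq_len(length(np) - 1L)) {
        e <- which(tree$edge[, 1] == np[s] & tree$edge[, 2] == np[s + 1L])
        edges <- union(edges, e)
      }
    }
    edges
  }
  sets <- lapply(seq_len(nrow(m)),
                 function(i) branch_set(colnames(m)[m[i, ] >= 1L]))
  d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (j <= i) next
      uni <- union(sets[[i]], sets[[j]])
      uniq <- c(setdiff(sets[[i]], sets[[j]]), setdiff(sets[[j]], sets[[i]]))
      d[i, j] <- d[j, i] <- if (length(uni) == 0L) 0 else
        sum(tree$edge.length[uniq]) / sum(tree$edge.length[uni])
    }
  }
  d
}
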