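# Independent brute-force oracles and small random-instance generators.
# These deliberately take different code paths than the package
# implementations they check.

# Single-linkage clonotype oracle: full pairwise distance matrix +
# stats::hclust/cutree. Clones with different V, J or CDRH3 length get an
# effectively infinite distance; linked clones have normalized Hamming
# distance strictly below 1 - threshold.
oracle_clonotypes <- function(v, j, cdrh3, threshold = 0.9) {
  n <- length(cdrh3)
  if (n == 1) return(1L)
  d <- matrix(10, n, n)
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      if (v[a] == v[b] && j[a] == j[b] &&
          nchar(cdrh3[a]) == nchar(cdrh3[b])) {
        ca <- strsplit(cdrh3[a], "")[[1]]
        cb <- strsplit(cdrh3[b], "")[[1]]
        d[a, b] <- d[b, a] <- sum(ca != cb) / length(ca)
      }
    }
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  stats::cutree(hc, h = (1 - threshold) - 1e-9)
}

# Partitions agree up to relabeling.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Hamming-distance-1 adjacency by explicit per-pair character loops.
oracle_hamming1_pairs <- function(seqs) {
  n <- length(seqs)
  out <- NULL
  for (a in seq_len(max(n - 1, 0))) {
    for (b in seq(a + 1, n)) {
      if (nchar(seqs[a]) != nchar(seqs[b])) next
      ca <- strsplit(seqs[a], "")[[1]]
      cb <- strsplit(seqs[b], "")[[1]]
      if (sum(ca != cb) == 1) out <- rbind(out, c(a, b))
    }
  }
  out
}

# Exhaustive maximum-parsimony oracle: minimum number of state changes
# over all internal labelings of a rooted tree.
oracle_parsimony_changes <- function(tree, tip_states, nstates) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  edge <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(seq_len(nstates)), nint)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tip_states, grid[r, ])
    ch <- sum(lab[edge[, 1]] != lab[edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# Random clone instances with collision-prone CDRH3s (small alphabet,
# mutated copies) to exercise clustering boundaries.
random_clone_instance <- function(n, n_base = max(2L, n %/% 5L)) {
  alph <- c("A", "R", "D", "G")
  lens <- sample(c(10L, 12L), n_base, replace = TRUE)
  base <- vapply(lens, function(L) {
    paste(sample(alph, L, replace = TRUE), collapse = "")
  }, character(1))
  pick <- sample(n_base, n, replace = TRUE)
  cdrh3 <- vapply(pick, function(i) {
    s <- strsplit(base[i], "")[[1]]
    nm <- sample(0:3, 1)
    if (nm > 0) {
      pos <- sample(length(s), nm)
      s[pos] <- sample(alph, nm, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  df <- data.frame(
    v_gene = sample(c("IGHV1-1", "IGHV1-2"), n, replace = TRUE),
    j_gene = sample(c("IGHJ1", "IGHJ2"), n, replace = TRUE),
    cdrh3_aa = cdrh3,
    stringsAsFactors = FALSE
  )
  df[!duplicated(paste(df$v_gene, df$j_gene, df$cdrh3_aa)), , drop = FALSE]
}

# Minimal clone_table builder for tests.
make_clone_table <- function(v, j, cdrh3, organ = "BM", count = 1L,
                             mouse = "m1") {
  rec <- data.frame(
    sequence_id = sprintf("s%03d", seq_along(cdrh3)),
    mouse_id = mouse, organ = organ, v_call = v, j_call = j,
    cdrh3_aa = cdrh3, count = count, stringsAsFactors = FALSE
  )
  assign_clones(rec)
}

# Per-clone sequence sets for the tree-input filter tests.
make_tree_seqs <- function(clone_id, n, organs, counts = NULL) {
  data.frame(
    clone_id = clone_id,
    sequence_id = sprintf("%s_%03d", clone_id, seq_len(n)),
    organ = rep_len(organs, n),
    count = if (is.null(counts)) rep(10L, n) else rep_len(counts, n),
    stringsAsFactors = FALSE
  )
}

# Random organ-labeled lineage tree (iid labels).
random_labeled_tree <- function(ntip, organs) {
  tr <- ape::rtree(ntip)
  lineage_tree(tr, setNames(sample(organs, ntip, replace = TRUE),
                            tr$tip.label))
}
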