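# Directional organ-transition analysis on B-cell lineage trees:
# maximum-parsimony ancestral organ reconstruction, polytomy reordering,
# the switch-proportion (SP) statistic, and its permutation test.

#' Filter clonal sequence sets before tree building
#'
#' Applies the input filters used ahead of lineage-tree analysis:
#' sequences with fewer than `min_reads` associated reads are discarded
#' (when a `count` column is present); clones with fewer than
#' `min_clone_size` sequences or with sequences from only one organ are
#' removed; clones larger than `max_clone_size` are down-sampled
#' uniformly at random to `max_clone_size` sequences.
#'
#' @param sequences Data frame with columns `clone_id`, `sequence_id`,
#'   `organ` and optionally `count`.
#' @param max_clone_size Down-sampling cap (default 100 sequences).
#' @param min_clone_size Minimum sequences per clone (default 10).
#' @param min_reads Minimum reads per sequence (default 3).
#' @return List with `sequences` (the filtered data frame) and `report`
#'   (named counts: `dropped_low_reads`, `removed_small_clones`,
#'   `removed_single_organ`, `downsampled_clones`).
#' @export
filter_trees_input <- function(sequences, max_clone_size = 100L,
                               min_clone_size = 10L, min_reads = 3L) {
  df <- as.data.frame(sequences)
  stopifnot(all(c("clone_id", "sequence_id", "organ") %in% names(df)))

  dropped_low_reads <- 0L
  if ("count" %in% names(df)) {
    keep <- df$count >= min_reads
    dropped_low_reads <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }

  removed_small <- 0L
  removed_single <- 0L
  downsampled <- 0L
  out <- list()
  for (cl in lex_sort(unique(df$clone_id))) {
    g <- df[df$clone_id == cl, , drop = FALSE]
    if (length(unique(g$organ)) < 2) {
      removed_single <- removed_single + 1L
      next
    }
    if (nrow(g) < min_clone_size) {
      removed_small <- removed_small + 1L
      next
    }
    if (nrow(g) > max_clone_size) {
      g <- g[sample(nrow(g), max_clone_size), , drop = FALSE]
      downsampled <- downsampled + 1L
    }
    out[[length(out) + 1]] <- g
  }
  res <- if (length(out) > 0) do.call(rbind, out) else df[0, , drop = FALSE]
  rownames(res) <- NULL
  list(
    sequences = res,
    report = c(dropped_low_reads = dropped_low_reads,
               removed_small_clones = removed_small,
               removed_single_organ = removed_single,
               downsampled_clones = downsampled)
  )
}

# Internal: postorder edge matrix + 0-based tip states for the Sankoff
# kernel. `organs` is the global lexicographic state alphabet.
prepare_tree <- function(lt, organs) {
  lt <- strip_germline(lt)
  tr <- ape::reorder.phylo(lt$tree, "postorder")
  states <- match(lt$organs[tr$tip.label], organs) - 1L
  if (anyNA(states)) stop("tip with organ outside the state alphabet")
  list(edge = tr$edge, ntip = ape::Ntip(tr), nnode = tr$Nnode,
       states = states, tree = tr, mouse_id = lt$mouse_id)
}

sp_organs <- function(trees) {
  lex_sort(unique(unlist(lapply(trees, function(lt) organ_labels(lt)))))
}

#' Maximum-parsimony reconstruction of internal organ states
#'
#' Sankoff dynamic programming with unit transition costs over the organ
#' states at the tips. Ambiguous most-parsimonious labelings are resolved
#' by preferring the parent's state during the top-down pass (delaying
#' transitions toward the tips), then lexicographic organ order; the
#' `"enumerate"` strategy instead averages the directional transition
#' counts over all most-parsimonious labelings (small trees only). A tip
#' labeled `"germline"` anchors the root and is excluded: the root takes
#' the reconstructed state of the observed sequences and no transition
#' out of the germline is counted.
#'
#' @param lt A [lineage_tree()].
#' @param strategy `"parent"` (deterministic single labeling, default) or
#'   `"enumerate"` (average over all most-parsimonious labelings).
#' @return List with `changes` (minimum number of organ changes),
#'   `transitions` (organ x organ directional change counts; fractional
#'   under `"enumerate"`), `node_states` (reconstructed state per node;
#'   `"parent"` strategy only) and `organs`.
#' @export
parsimony_reconstruct <- function(lt, strategy = c("parent", "enumerate")) {
  strategy <- match.arg(strategy)
  organs <- lex_sort(unique(organ_labels(lt)))
  pt <- prepare_tree(lt, organs)
  if (!ape::is.rooted(pt$tree)) stop("tree must be rooted")
  k <- length(organs)
  res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode,
                       matrix(pt$states, ncol = 1), k)
  trans <- matrix(as.numeric(res$transitions[, 1]), k, k, byrow = TRUE,
                  dimnames = list(organs, organs))
  changes <- res$changes[1]

  if (strategy == "enumerate") {
    if (pt$nnode > 12) stop("enumerate strategy limited to <= 12 internal nodes")
    trans <- enumerate_mp_transitions(pt, organs, changes)
  }

  states <- setNames(organs[res$node_states[, 1] + 1L],
                     c(pt$tree$tip.label,
                       paste0("node", seq_len(pt$nnode) + pt$ntip)))
  list(changes = changes,
       transitions = trans,
       node_states = if (strategy == "parent") states else NULL,
       organs = organs)
}

# Average directional transition counts over all most-parsimonious
# internal labelings (exhaustive; small trees).
enumerate_mp_transitions <- function(pt, organs, min_changes) {
  k <- length(organs)
  nint <- pt$nnode
  ntip <- pt$ntip
  grid <- as.matrix(expand.grid(rep(list(seq_len(k) - 1L), nint)))
  acc <- matrix(0, k, k, dimnames = list(organs, organs))
  n_mp <- 0L
  for (r in seq_len(nrow(grid))) {
    lab <- c(pt$states, grid[r, ])
    ch <- lab[pt$edge[, 1]] != lab[pt$edge[, 2]]
    if (sum(ch) != min_changes) next
    n_mp <- n_mp + 1L
    for (e in which(ch)) {
      from <- lab[pt$edge[e, 1]] + 1L
      to <- lab[pt$edge[e, 2]] + 1L
      acc[from, to] <- acc[from, to] + 1
    }
  }
  acc / n_mp
}

#' Reorder polytomies to minimize parsimony changes
#'
#' Internal nodes separated by (near) zero-length branches represent
#' polytomies whose arbitrary binary resolution can inflate the inferred
#' number of organ changes. Within each zero-length cluster,
#' nearest-neighbor-interchange moves are applied greedily (deterministic
#' edge order, first improving move taken) while they strictly reduce the
#' parsimony change count. The result's change count is never larger than
#' the input's, and the operation is idempotent.
#'
#' @param lt A [lineage_tree()] (a germline tip, if present, is removed).
#' @param tol Branch lengths below `tol` count as zero.
#' @return The rearranged [lineage_tree()].
#' @export
reorder_polytomies <- function(lt, tol = 1e-8) {
  lt <- strip_germline(lt)
  organs <- lex_sort(unique(organ_labels(lt)))
  k <- length(organs)
  score <- function(tree) {
    tr <- ape::reorder.phylo(tree, "postorder")
    st <- match(lt$organs[tr$tip.label], organs) - 1L
    sankoff_batch(tr$edge, ape::Ntip(tr), tr$Nnode,
                  matrix(st, ncol = 1), k)$changes[1]
  }
  tree <- ape::reorder.phylo(lt$tree, "postorder")
  if (is.null(tree$edge.length)) return(lt)
  current <- score(tree)
  ntip <- ape::Ntip(tree)

  repeat {
    improved <- FALSE
    zero <- which(tree$edge[, 2] > ntip & tree$edge.length < tol)
    for (e in zero) {
      u <- tree$edge[e, 1]
      v <- tree$edge[e, 2]
      vkids <- tree$edge[tree$edge[, 1] == v, 2]
      ukids <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
      for (w in ukids) {
        for (cc in vkids) {
          cand <- tree
          cand$edge[cand$edge[, 2] == cc & cand$edge[, 1] == v, 1] <- u
          cand$edge[cand$edge[, 2] == w & cand$edge[, 1] == u, 1] <- v
          # the stale "order" attribute would make reorder.phylo a no-op
          attr(cand, "order") <- NULL
          cand <- ape::reorder.phylo(cand, "postorder")
          sc <- score(cand)
          if (sc < current) {
            tree <- cand
            current <- sc
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (improved) break
    }
    if (!improved) break
  }
  out <- lineage_tree(tree, lt$organs, lt$mouse_id, lt$clone_id)
  out$true_transitions <- lt$true_transitions
  out
}

#' Observed switch-proportion (SP) matrix
#'
#' For every ordered organ pair (x, y), the SP statistic is the number of
#' parsimony-inferred parent-to-child organ changes x -> y, summed over
#' all trees, divided by the total number of changes; the entries of the
#' matrix sum to 1.
#'
#' @param trees List of [lineage_tree()] objects.
#' @return Organ x organ matrix of switch proportions (attribute
#'   `total_changes`); all-`NA` with a warning when no transitions exist.
#' @export
sp_statistic <- function(trees) {
  organs <- sp_organs(trees)
  k <- length(organs)
  counts <- matrix(0, k, k, dimnames = list(organs, organs))
  for (lt in trees) {
    pt <- prepare_tree(lt, organs)
    res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode,
                         matrix(pt$states, ncol = 1), k)
    counts <- counts + matrix(as.numeric(res$transitions[, 1]), k, k,
                              byrow = TRUE)
  }
  total <- sum(counts)
  if (total == 0) {
    warning("no organ transitions observed; SP matrix undefined")
    counts[] <- NA_real_
    return(structure(counts, total_changes = 0))
  }
  structure(counts / total, total_changes = total)
}

# transitions vector (length k*k, row-major from C++) -> k x k matrix
trans_matrix <- function(v, k) matrix(as.numeric(v), k, k, byrow = TRUE)

#' Switch-proportion permutation test for directional migration
#'
#' Tests, per organ pair, whether lineage trees show more directional
#' organ transitions than expected by chance. Per replicate: (i) every
#' tree whose tip-to-change ratio exceeds `ratio_cap` is down-sampled
#' uniformly at random to `ratio_cap` times its change count (topology
#' pruned, not re-estimated); (ii) tip organ labels are permuted — within
#' each tree (`within_tree`), or pooled and reshuffled across all trees
#' of a mouse (`among_trees`); (iii) parsimony and SP are recomputed;
#' (iv) the difference delta = observed SP - permuted SP is recorded per
#' pair. The p-value for enrichment (delta > 0) is the proportion of
#' replicates with delta <= 0. In `among_trees` mode transitions are
#' summed over both directions and pairs are unordered.
#'
#' @param trees List of [lineage_tree()] objects (already filtered, see
#'   [filter_trees_input()]); `mouse_id` groups trees for `among_trees`
#'   permutations.
#' @param replicates Number of permutation replicates (default 1000).
#' @param mode `"within_tree"` (directional test) or `"among_trees"`
#'   (association test, undirected).
#' @param ratio_cap Maximum tip-to-change ratio before down-sampling
#'   (default 20); must be positive.
#' @param seed Optional integer seed.
#' @param reorder Apply [reorder_polytomies()] to each tree first.
#' @return An object of class `sp_result`: list with `observed_sp`
#'   (full-tree SP matrix), `p_values` (organ x organ; upper triangle
#'   only in `among_trees` mode), `delta` (replicates x pairs matrix),
#'   `replicates`, `mode`, `organs`, `seed`.
#' @export
sp_test <- function(trees, replicates = 1000L,
                    mode = c("within_tree", "among_trees"),
                    ratio_cap = 20, seed = NULL, reorder = TRUE) {
  mode <- match.arg(mode)
  if (ratio_cap <= 0) stop("ratio_cap must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (reorder) trees <- lapply(trees, reorder_polytomies)

  organs <- sp_organs(trees)
  k <- length(organs)
  B <- as.integer(replicates)
  pts <- lapply(trees, prepare_tree, organs = organs)

  # observed full-tree counts and per-tree down-sampling requirement
  obs_counts <- matrix(0, k, k, dimnames = list(organs, organs))
  tree_changes <- numeric(length(pts))
  tree_counts <- vector("list", length(pts))
  for (i in seq_along(pts)) {
    pt <- pts[[i]]
    res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode,
                         matrix(pt$states, ncol = 1), k)
    tree_counts[[i]] <- trans_matrix(res$transitions[, 1], k)
    tree_changes[i] <- res$changes[1]
    obs_counts <- obs_counts + tree_counts[[i]]
  }
  total_obs <- sum(obs_counts)
  observed_sp <- if (total_obs > 0) obs_counts / total_obs else {
    warning("no organ transitions observed; SP test degenerate")
    m <- obs_counts
    m[] <- NA_real_
    m
  }

  needs_ds <- tree_changes > 0 &
    vapply(pts, function(p) p$ntip, numeric(1)) / pmax(tree_changes, 1) >
      ratio_cap
  active <- tree_changes > 0  # constant-labeled trees contribute nothing

  # per-replicate observed and permuted transition counts, k*k x B
  obs_rep <- matrix(0, k * k, B)
  perm_rep <- matrix(0, k * k, B)

  if (!any(needs_ds)) {
    # fast path: observed counts constant across replicates; all
    # permutations of a tree evaluated in one batched kernel call
    for (i in which(active)) {
      obs_rep <- obs_rep + as.vector(t(tree_counts[[i]]))
    }
    if (mode == "within_tree") {
      for (i in which(active)) {
        pt <- pts[[i]]
        perm <- vapply(seq_len(B), function(b) sample(pt$states),
                       integer(pt$ntip))
        res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode, perm, k)
        perm_rep <- perm_rep + res$transitions
      }
    } else {
      mice <- vapply(pts, function(p) as.character(p$mouse_id), character(1))
      for (m in unique(mice)) {
        idx <- which(mice == m & active)
        if (length(idx) == 0) next
        pool <- unlist(lapply(pts[idx], function(p) p$states))
        sizes <- vapply(pts[idx], function(p) p$ntip, integer(1))
        offs <- cumsum(c(0L, sizes))
        perm_pool <- vapply(seq_len(B), function(b) sample(pool),
                            integer(length(pool)))
        for (ii in seq_along(idx)) {
          pt <- pts[[idx[ii]]]
          rows <- (offs[ii] + 1):offs[ii + 1]
          res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode,
                               perm_pool[rows, , drop = FALSE], k)
          perm_rep <- perm_rep + res$transitions
        }
      }
    }
  } else {
    # general path: re-draw the down-sampled tip set each replicate
    mice <- vapply(pts, function(p) as.character(p$mouse_id), character(1))
    for (b in seq_len(B)) {
      reps <- vector("list", length(pts))
      for (i in which(active)) {
        pt <- pts[[i]]
        if (needs_ds[i]) {
          keep_n <- max(2L, as.integer(floor(ratio_cap * tree_changes[i])))
          if (keep_n < pt$ntip) {
            keep <- sample(pt$tree$tip.label, keep_n)
            sub <- ape::keep.tip(pt$tree, keep)
            lt_sub <- lineage_tree(
              sub, setNames(organs[pt$states + 1L],
                            pt$tree$tip.label)[sub$tip.label])
            pt <- prepare_tree(lt_sub, organs)
            pt$mouse_id <- pts[[i]]$mouse_id
          }
        }
        res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode,
                             matrix(pt$states, ncol = 1), k)
        obs_rep[, b] <- obs_rep[, b] + as.numeric(res$transitions[, 1])
        reps[[i]] <- pt
      }
      if (mode == "within_tree") {
        for (i in which(active)) {
          pt <- reps[[i]]
          res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode,
                               matrix(sample(pt$states), ncol = 1), k)
          perm_rep[, b] <- perm_rep[, b] + as.numeric(res$transitions[, 1])
        }
      } else {
        for (m in unique(mice)) {
          idx <- which(mice == m & active)
          if (length(idx) == 0) next
          pool <- sample(unlist(lapply(reps[idx], function(p) p$states)))
          off <- 0L
          for (i in idx) {
            pt <- reps[[i]]
            st <- pool[(off + 1):(off + pt$ntip)]
            off <- off + pt$ntip
            res <- sankoff_batch(pt$edge, pt$ntip, pt$nnode,
                                 matrix(st, ncol = 1), k)
            perm_rep[, b] <- perm_rep[, b] + as.numeric(res$transitions[, 1])
          }
        }
      }
    }
  }

  # normalize counts to SP per replicate; 0/0 -> 0
  norm_sp <- function(mat) {
    tot <- colSums(mat)
    sweep(mat, 2, pmax(tot, 1), "/")
  }
  obs_sp_rep <- norm_sp(obs_rep)
  perm_sp_rep <- norm_sp(perm_rep)

  if (mode == "among_trees") {
    # fold to unordered pairs: index (i,j), i < j
    pair_idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    fold <- function(spmat) {
      apply(spmat, 2, function(v) {
        m <- matrix(v, k, k, byrow = TRUE)
        m[pair_idx] + t(m)[pair_idx]
      })
    }
    obs_f <- fold(obs_sp_rep)
    perm_f <- fold(perm_sp_rep)
    if (nrow(pair_idx) == 1) {
      obs_f <- matrix(obs_f, nrow = 1)
      perm_f <- matrix(perm_f, nrow = 1)
    }
    delta <- t(obs_f - perm_f)
    pair_names <- paste(organs[pair_idx[, 1]], organs[pair_idx[, 2]],
                        sep = "<->")
    colnames(delta) <- pair_names
    p <- matrix(NA_real_, k, k, dimnames = list(organs, organs))
    for (r in seq_len(nrow(pair_idx))) {
      p[pair_idx[r, 1], pair_idx[r, 2]] <- mean(delta[, r] <= 0)
    }
  } else {
    delta <- t(obs_sp_rep - perm_sp_rep)
    pair_names <- as.vector(t(outer(organs, organs, paste, sep = "->")))
    colnames(delta) <- pair_names
    keep_pairs <- as.vector(t(outer(seq_len(k), seq_len(k), "!=")))
    delta <- delta[, keep_pairs, drop = FALSE]
    pvec <- colMeans(delta <= 0)
    p <- matrix(NA_real_, k, k, dimnames = list(organs, organs))
    nm <- colnames(delta)
    for (j in seq_along(nm)) {
      parts <- strsplit(nm[j], "->", fixed = TRUE)[[1]]
      p[parts[1], parts[2]] <- pvec[j]
    }
  }
  if (total_obs == 0) p[] <- NA_real_

  structure(
    list(observed_sp = observed_sp, p_values = p, delta = delta,
         replicates = B, mode = mode, organs = organs, seed = seed,
         total_changes = total_obs),
    class = "sp_result"
  )
}

#' @export
print.sp_result <- function(x, ...) {
  cat("Switch-proportion permutation test (", x$mode, ", ",
      x$replicates, " replicates)\n", sep = "")
  cat("Total observed organ changes:", x$total_changes, "\n")
  cat("Observed SP matrix (rows: from, cols: to):\n")
  print(round(x$observed_sp, 3))
  cat("p-values (delta > 0 enrichment):\n")
  print(round(x$p_values, 4))
  invisible(x)
}
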