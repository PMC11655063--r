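# CDRH3 sequence-similarity networks within clonotypes.

#' Build a CDRH3 similarity network for one clonotype
#'
#' Each node is a unique clone of the clonotype; an edge connects two
#' clones whose CDRH3 amino-acid sequences have equal length and Hamming
#' distance exactly 1. Node attributes carry the clone's organ-occupancy
#' set, its summed frequency, and a display size proportional to
#' log10(frequency) rescaled into `size_range`.
#'
#' @param members Rows of a `clone_table` belonging to one clonotype
#'   (several organ rows per clone allowed).
#' @param size_range Numeric range the log-frequencies are rescaled into
#'   (display attribute only).
#' @param size_reference Optional `c(min, max)` log10-frequency range used
#'   for rescaling, so that node sizes are comparable across the networks
#'   of one mouse; defaults to the network's own range.
#' @return An [igraph::graph] with vertex attributes `name` (clone key),
#'   `cdrh3`, `organs`, `frequency` and `size`.
#' @export
build_similarity_network <- function(members, size_range = c(1, 10),
                                     size_reference = NULL) {
  df <- as.data.frame(members)
  if ("clonotype_id" %in% names(df) &&
      length(unique(df$clonotype_id)) > 1) {
    stop("members must belong to a single clonotype")
  }
  agg <- stats::aggregate(list(frequency = df$frequency),
                          by = list(clone_key = df$clone_key), FUN = sum)
  agg$cdrh3 <- df$cdrh3_aa[match(agg$clone_key, df$clone_key)]
  agg$organs <- vapply(split(df$organ, df$clone_key)[agg$clone_key],
                       function(o) paste(lex_sort(unique(o)), collapse = "+"),
                       character(1))
  agg <- agg[lex_order(agg$clone_key), ]

  n <- nrow(agg)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    len <- nchar(agg$cdrh3)
    elist <- list()
    for (L in unique(len)) {
      idx <- which(len == L)
      if (length(idx) < 2) next
      d <- hamming_matrix(agg$cdrh3[idx])
      pr <- which(upper.tri(d) & d == 1L, arr.ind = TRUE)
      if (nrow(pr) > 0) {
        elist[[length(elist) + 1]] <- cbind(idx[pr[, 1]], idx[pr[, 2]])
      }
    }
    if (length(elist) > 0) edges <- do.call(rbind, elist)
  }

  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- agg$clone_key
  igraph::V(g)$cdrh3 <- agg$cdrh3
  igraph::V(g)$organs <- agg$organs
  igraph::V(g)$frequency <- agg$frequency
  lf <- log10(agg$frequency)
  ref <- size_reference %||% range(lf)
  span <- ref[2] - ref[1]
  igraph::V(g)$size <- if (span > 0) {
    size_range[1] + (lf - ref[1]) / span * diff(size_range)
  } else rep(mean(size_range), n)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  g
}

#' Pooled node-degree distribution of clone networks
#'
#' Connectivity summary: the fraction of clones (nodes) at each degree,
#' pooled over a list of networks.
#'
#' @param networks List of [igraph::graph] objects (or a single graph).
#' @return Data frame with `degree` and `fraction` (sums to 1).
#' @export
degree_distribution <- function(networks) {
  if (inherits(networks, "igraph")) networks <- list(networks)
  degs <- unlist(lapply(networks, function(g) igraph::degree(g)))
  if (length(degs) == 0) {
    return(data.frame(degree = integer(0), fraction = numeric(0)))
  }
  tab <- table(factor(degs, levels = seq(0, max(degs))))
  out <- data.frame(degree = as.integer(names(tab)),
                    fraction = as.numeric(tab) / length(degs))
  out[out$fraction > 0, , drop = FALSE]
}

#' Select the most diverse clonotypes per organ
#'
#' Ranks clonotypes within each mouse x organ by the number of unique
#' member clones observed in that organ (clonal diversification), with
#' ties broken by summed clonal frequency, then lexicographic clonotype
#' id, and returns the top `k`.
#'
#' @param clones A `clone_table` with `clonotype_id` (from
#'   [cluster_clonotypes()]).
#' @param k Number of clonotypes per organ (all are returned when fewer
#'   exist).
#' @return Data frame with `mouse_id`, `organ`, `clonotype_id`,
#'   `n_clones`, `total_frequency` and `rank`.
#' @export
select_top_diverse_clonotypes <- function(clones, k = 5L) {
  df <- as.data.frame(clones)
  if (!"clonotype_id" %in% names(df)) {
    stop("clones must carry clonotype_id; run cluster_clonotypes() first")
  }
  res <- do.call(rbind, lapply(
    split(df, paste(df$mouse_id, df$organ, sep = "\r")),
    function(g) {
      s <- do.call(rbind, lapply(split(g, g$clonotype_id), function(ct) {
        data.frame(mouse_id = ct$mouse_id[1], organ = ct$organ[1],
                   clonotype_id = ct$clonotype_id[1],
                   n_clones = length(unique(ct$clone_key)),
                   total_frequency = sum(ct$frequency),
                   stringsAsFactors = FALSE)
      }))
      s <- s[lex_order(-s$n_clones, -s$total_frequency, s$clonotype_id), ]
      s <- head(s, k)
      s$rank <- seq_len(nrow(s))
      s
    }))
  rownames(res) <- NULL
  res
}

#' Export a clone network as GraphML
#'
#' @param network An [igraph::graph] from [build_similarity_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
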