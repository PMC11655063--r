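# Clone and clonotype assignment, clonal-expansion profiles, Hill-number
# diversity/evenness, and somatic-hypermutation load.

#' Assign clones from sequence records
#'
#' A clone is the set of sequences with identical CDRH3 amino-acid
#' sequence and matching germline V and J genes (allele suffixes after
#' `*` are ignored); in paired mode the CDRL3 is part of the key as well.
#' Records are aggregated per mouse, and read counts are normalized to
#' clonal frequencies within each organ.
#'
#' @param records Sequence-record data frame (from [read_airr_table()] or
#'   [simulate_repertoire()]); must contain `organ`, `v_call`, `j_call`,
#'   `cdrh3_aa` and `count` (and `cdrl3_aa` in paired mode). A missing
#'   `mouse_id` column is treated as a single mouse.
#' @param mode `"heavy"` keys clones on (V, J, CDRH3); `"paired"` on
#'   (V, J, CDRH3, CDRL3).
#' @return A clone table (class `clone_table`): one row per clone per
#'   organ per mouse with columns `mouse_id`, `organ`, `v_gene`,
#'   `j_gene`, `cdrh3_aa` (`cdrl3_aa` in paired mode), `clone_key`,
#'   `clone_id`, `count` and `frequency`. Within each mouse x organ the
#'   frequencies sum to 1; clones absent from an organ have no row there.
#' @export
assign_clones <- function(records, mode = c("heavy", "paired")) {
  mode <- match.arg(mode)
  if (is.null(records) || nrow(records) == 0) {
    stop("assign_clones: no input records")
  }
  needed <- c("organ", "v_call", "j_call", "cdrh3_aa", "count")
  if (mode == "paired") needed <- c(needed, "cdrl3_aa")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) {
    stop("assign_clones: missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"mouse_id" %in% names(records)) records$mouse_id <- "mouse-1"

  v_gene <- strip_allele(records$v_call)
  j_gene <- strip_allele(records$j_call)
  key <- paste(v_gene, j_gene, records$cdrh3_aa, sep = "|")
  if (mode == "paired") key <- paste(key, records$cdrl3_aa, sep = "|")

  agg <- stats::aggregate(
    list(count = records$count),
    by = list(mouse_id = records$mouse_id, organ = records$organ,
              clone_key = key),
    FUN = sum
  )
  meta_idx <- match(paste(agg$mouse_id, agg$organ, agg$clone_key),
                    paste(records$mouse_id, records$organ, key))
  agg$v_gene <- v_gene[meta_idx]
  agg$j_gene <- j_gene[meta_idx]
  agg$cdrh3_aa <- records$cdrh3_aa[meta_idx]
  if (mode == "paired") agg$cdrl3_aa <- records$cdrl3_aa[meta_idx]

  # deterministic ordering, then per-mouse dense clone ids
  agg <- agg[lex_order(agg$mouse_id, agg$organ, agg$clone_key), ]
  agg$clone_id <- stats::ave(agg$clone_key, agg$mouse_id, FUN = function(k) {
    match(k, lex_sort(unique(k)))
  })
  agg$clone_id <- as.integer(agg$clone_id)

  total <- stats::ave(agg$count, agg$mouse_id, agg$organ, FUN = sum)
  agg$frequency <- agg$count / total

  cols <- c("mouse_id", "organ", "v_gene", "j_gene", "cdrh3_aa",
            if (mode == "paired") "cdrl3_aa", "clone_key", "clone_id",
            "count", "frequency")
  out <- agg[, cols]
  rownames(out) <- NULL
  class(out) <- c("clone_table", "data.frame")
  attr(out, "clone_key_mode") <- mode
  out
}

#' Cluster clones into clonotypes
#'
#' Single-linkage clustering of clones sharing V gene, J gene and CDRH3
#' length: two clones are linked when their CDRH3 amino-acid identity is
#' strictly greater than `identity_threshold` (or at least the threshold
#' when `inclusive = TRUE`); connected components of the link graph are
#' clonotypes. Clustering is performed within each mouse; ids are stable
#' under a deterministic (lexicographic) ordering of clones.
#'
#' @param clones A `clone_table` from [assign_clones()].
#' @param identity_threshold Identity fraction in (0, 1]; default 0.90.
#' @param inclusive Link clones at identity exactly equal to the
#'   threshold (normalized Hamming distance `<= 1 - threshold`) as well.
#' @return The clone table with an added `clonotype_id` column
#'   (`<mouse>_t<k>`), identical across all organ rows of a clone.
#' @export
cluster_clonotypes <- function(clones, identity_threshold = 0.90,
                               inclusive = FALSE) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  uq <- unique(as.data.frame(clones)[, c("mouse_id", "clone_key", "v_gene",
                                         "j_gene", "cdrh3_aa")])
  uq$len <- nchar(uq$cdrh3_aa)
  uq <- uq[lex_order(uq$mouse_id, uq$clone_key), ]
  uq$idx <- seq_len(nrow(uq))

  uq$component <- uq$idx  # singleton default
  groups <- split(uq, paste(uq$mouse_id, uq$v_gene, uq$j_gene, uq$len,
                            sep = "\r"))
  edges_from <- integer(0)
  edges_to <- integer(0)
  max_dist <- function(L) {
    # link iff hamming/L < 1 - thr (strict) or <= (inclusive)
    if (inclusive) floor(L * (1 - identity_threshold) + 1e-9)
    else ceiling(L * (1 - identity_threshold) - 1e-9) - 1L
  }
  for (g in groups) {
    if (nrow(g) < 2) next
    d <- hamming_matrix(g$cdrh3_aa)
    lim <- max_dist(g$len[1])
    pairs <- which(upper.tri(d) & d <= lim, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      edges_from <- c(edges_from, g$idx[pairs[, 1]])
      edges_to <- c(edges_to, g$idx[pairs[, 2]])
    }
  }
  if (length(edges_from) > 0) {
    gr <- igraph::graph_from_edgelist(
      cbind(edges_from, edges_to), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, nrow(uq) - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership[seq_len(nrow(uq))]
    # stable ids: component labeled by its lexicographically first clone
    uq$component <- stats::ave(uq$idx, comp, FUN = min)
  }
  uq$clonotype_id <- paste0(
    uq$mouse_id, "_t",
    stats::ave(uq$component, uq$mouse_id, FUN = function(x) {
      match(x, unique(x[order(x)]))
    })
  )

  out <- as.data.frame(clones)
  out$clonotype_id <- uq$clonotype_id[
    match(paste(out$mouse_id, out$clone_key),
          paste(uq$mouse_id, uq$clone_key))]
  class(out) <- c("clone_table", "data.frame")
  attr(out, "clone_key_mode") <- attr(clones, "clone_key_mode")
  out
}

#' Clonal expansion profile over frequency ranks
#'
#' Sorts clones by descending frequency (ties broken lexicographically on
#' CDRH3 for determinism) and reports the summed frequency in each rank
#' bin, e.g. the fraction of the repertoire occupied by the top 3 clones.
#'
#' @param frequencies Numeric vector of normalized clone frequencies.
#' @param rank_cutoffs Ascending upper rank bounds of the bins; a final
#'   bin up to the last rank is appended if the cutoffs do not cover all
#'   clones. E.g. `c(3, 10)` gives bins ranks 1-3, 4-10, 11-n.
#' @param cdrh3 Optional CDRH3 strings used for deterministic tie-breaks
#'   (defaults to `names(frequencies)`).
#' @return Data frame with `rank_from`, `rank_to` and `fraction`; the
#'   fractions sum to 1. Empty input gives a zero-row profile.
#' @export
expansion_profile <- function(frequencies, rank_cutoffs,
                              cdrh3 = names(frequencies)) {
  n <- length(frequencies)
  if (n == 0) {
    return(data.frame(rank_from = integer(0), rank_to = integer(0),
                      fraction = numeric(0)))
  }
  if (is.null(cdrh3)) cdrh3 <- as.character(seq_len(n))
  ord <- lex_order(-frequencies, cdrh3)
  f <- frequencies[ord]

  cuts <- sort(unique(as.integer(pmin(rank_cutoffs, n))))
  if (length(cuts) == 0 || cuts[length(cuts)] < n) cuts <- c(cuts, n)
  from <- c(1L, head(cuts, -1) + 1L)
  data.frame(
    rank_from = from,
    rank_to = cuts,
    fraction = vapply(seq_along(cuts),
                      function(b) sum(f[from[b]:cuts[b]]), numeric(1))
  )
}

#' Hill-number diversity
#'
#' The Hill number of order `alpha` of a clonal frequency distribution
#' `f`: \eqn{{}^{\alpha}D = (\sum_i f_i^\alpha)^{1/(1-\alpha)}}. At
#' `alpha = 0` this is the species richness (number of clones); at
#' `alpha = 1` the analytic (Shannon) limit \eqn{\exp(-\sum f_i \log
#' f_i)} is returned. Larger `alpha` weights high-frequency clones more.
#'
#' @param f Numeric probability vector (must sum to 1 within `1e-6`);
#'   zero-frequency entries are dropped.
#' @param alpha Non-negative order(s); vectorized.
#' @return Numeric vector of Hill numbers, one per `alpha`.
#' @export
hill_diversity <- function(f, alpha) {
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-6) {
    stop("frequencies must sum to 1 (tolerance 1e-6); got ", sum(f))
  }
  if (any(alpha < 0)) stop("alpha must be non-negative")
  f <- f[f > 0]
  vapply(alpha, function(a) {
    if (a == 0) {
      length(f)
    } else if (abs(a - 1) < 1e-9) {
      exp(-sum(f * log(f)))
    } else {
      sum(f^a)^(1 / (1 - a))
    }
  }, numeric(1))
}

#' Hill-based diversity and evenness profile
#'
#' Computes the Hill diversity \eqn{{}^{\alpha}D} and evenness
#' \eqn{{}^{\alpha}E = {}^{\alpha}D / SR} (species richness SR = number
#' of clones) over a grid of orders. Evenness ranges over (0, 1]: values
#' near 1 indicate a uniform clonal frequency distribution, values near 0
#' a repertoire dominated by one or few expanded clones; the `alpha = 1`
#' point is the Shannon evenness commonly reported for immune
#' repertoires.
#'
#' @param f Normalized clone frequency vector (zero entries dropped).
#' @param alpha_grid Ascending grid of non-negative orders; the default
#'   covers \[0, 10\] in steps of 0.2 (including the `alpha = 1` Shannon
#'   limit).
#' @return Data frame with columns `alpha`, `diversity`, `evenness`;
#'   attribute `species_richness`.
#' @export
evenness_profile <- function(f, alpha_grid = seq(0, 10, by = 0.2)) {
  D <- hill_diversity(f, alpha_grid)
  sr <- sum(f > 0)
  out <- data.frame(alpha = alpha_grid, diversity = D, evenness = D / sr)
  attr(out, "species_richness") <- sr
  out
}

#' Shannon evenness
#'
#' Convenience accessor for the `alpha = 1` evenness
#' \eqn{{}^{1}E = \exp(H)/SR}.
#'
#' @param f Normalized clone frequency vector.
#' @return Scalar Shannon evenness.
#' @export
shannon_evenness <- function(f) {
  hill_diversity(f, 1) / sum(f > 0)
}

#' Somatic hypermutation load
#'
#' Length-normalized Hamming distance between an observed V-region
#' nucleotide sequence and its inferred germline over IMGT positions
#' 1..`region_end` (default 312, the IGHV region). Positions where either
#' sequence carries an ambiguous base (`N`), a gap (`-`, `.`), or no base
#' at all are excluded from both numerator and denominator.
#'
#' @param v_region_nt,germline_nt Aligned nucleotide strings in the same
#'   IMGT coordinate frame.
#' @param region_end Last IMGT position compared (default 312).
#' @return Mismatch fraction, or `NA` when no comparable positions exist.
#' @export
shm_load <- function(v_region_nt, germline_nt, region_end = 312L) {
  a <- strsplit(toupper(v_region_nt), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(germline_nt), "", fixed = TRUE)[[1]]
  n <- min(length(a), length(b), region_end)
  if (n == 0) return(NA_real_)
  a <- a[seq_len(n)]
  b <- b[seq_len(n)]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}
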