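# Clone sharing and repertoire similarity across organs: Jaccard and
# cosine similarity, occupancy/Venn statistics, V-gene usage correlation,
# and binder-annotated overlap tables.

#' Jaccard index between two clone sets
#'
#' Size of the intersection of two repertoires divided by the size of
#' their union: \eqn{J(A,B) = |A \cap B| / (|A| + |B| - |A \cap B|)}.
#'
#' @param repA,repB Character vectors of clone keys (duplicates ignored).
#' @return Jaccard index in \[0, 1\]; `NA` when both sets are empty.
#' @export
jaccard_index <- function(repA, repB) {
  a <- unique(repA)
  b <- unique(repB)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Cosine similarity between two clone frequency distributions
#'
#' Repertoires are embedded in the vector space spanned by the union of
#' their clones (clones absent from a repertoire contribute 0), and the
#' standard cosine \eqn{\sum_i A_i B_i / (\sqrt{\sum_i A_i^2}
#' \sqrt{\sum_i B_i^2})} is returned, weighting overlap by clonal
#' frequency. Disjoint repertoires score 0, identical ones 1.
#'
#' @param freqA,freqB Named numeric vectors of clone frequencies (names
#'   are clone keys).
#' @return Cosine similarity in \[0, 1\]; `NA` if either vector is zero.
#' @export
cosine_similarity <- function(freqA, freqB) {
  keys <- union(names(freqA), names(freqB))
  a <- setNames(numeric(length(keys)), keys)
  b <- a
  a[names(freqA)] <- freqA
  b[names(freqB)] <- freqB
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Pairwise repertoire similarity matrix
#'
#' Computes all pairwise Jaccard or cosine similarities between the organ
#' repertoires of a clone table. With several mice, samples are
#' `mouse:organ` pairs (set `per_mouse = FALSE` to pool organs across
#' mice).
#'
#' @param clones A `clone_table` from [assign_clones()].
#' @param metric `"jaccard"` (presence/absence) or `"cosine"`
#'   (frequency-weighted).
#' @param per_mouse Treat each mouse x organ as its own sample.
#' @return A symmetric similarity matrix of class `similarity_matrix`
#'   with attribute `metric`.
#' @export
repertoire_similarity <- function(clones, metric = c("jaccard", "cosine"),
                                  per_mouse = TRUE) {
  metric <- match.arg(metric)
  df <- as.data.frame(clones)
  df$sample <- if (per_mouse && length(unique(df$mouse_id)) > 1) {
    paste(df$mouse_id, df$organ, sep = ":")
  } else df$organ
  samples <- lex_sort(unique(df$sample))
  reps <- split(df, df$sample)
  m <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_along(samples)) {
    for (j in seq(i, length(samples))) {
      A <- reps[[samples[i]]]
      B <- reps[[samples[j]]]
      v <- if (metric == "jaccard") {
        jaccard_index(A$clone_key, B$clone_key)
      } else {
        cosine_similarity(setNames(A$frequency, A$clone_key),
                          setNames(B$frequency, B$clone_key))
      }
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, metric = metric, class = c("similarity_matrix", "matrix"))
}

#' Organ-occupancy degrees and Venn partition of clones
#'
#' Annotates every clone with the set of organs it occupies within its
#' mouse and the occupancy degree (number of organs), and tabulates the
#' degree histogram and the full Venn partition (counts of clones in each
#' non-empty organ subset). The Venn partition is refused above 16 organs
#' (2^k cells); degrees are still computed.
#'
#' @param clones A `clone_table` covering at least 2 organs.
#' @return List with `clone_degrees` (mouse, clone_key, organ set,
#'   degree), `degree_histogram` (mouse, degree, n) and `venn` (mouse,
#'   organ_set, n; `NULL` when refused).
#' @export
organ_overlap_counts <- function(clones) {
  df <- as.data.frame(clones)
  organs <- lex_sort(unique(df$organ))
  if (length(organs) < 2) stop("organ_overlap_counts needs >= 2 organs")

  key <- paste(df$mouse_id, df$clone_key, sep = "\r")
  occ <- lapply(split(df$organ, key), function(o) lex_sort(unique(o)))
  first <- !duplicated(key)
  deg <- data.frame(
    mouse_id = df$mouse_id[first],
    clone_key = df$clone_key[first],
    organs = vapply(occ[key[first]], paste, character(1), collapse = "+"),
    degree = vapply(occ[key[first]], length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(deg) <- NULL
  deg <- deg[lex_order(deg$mouse_id, deg$clone_key), ]

  hist <- as.data.frame(table(mouse_id = deg$mouse_id, degree = deg$degree),
                        stringsAsFactors = FALSE)
  names(hist)[3] <- "n"
  hist$degree <- as.integer(hist$degree)
  hist <- hist[hist$n > 0, ]
  rownames(hist) <- NULL

  venn <- NULL
  if (length(organs) <= 16) {
    venn <- as.data.frame(table(mouse_id = deg$mouse_id,
                                organ_set = deg$organs),
                          stringsAsFactors = FALSE)
    names(venn)[3] <- "n"
    venn <- venn[venn$n > 0, ]
    rownames(venn) <- NULL
  } else {
    warning("more than 16 organs: full Venn partition refused; ",
            "degrees still computed")
  }
  list(clone_degrees = deg, degree_histogram = hist, venn = venn)
}

#' Germline V-gene usage correlation
#'
#' Counts unique clones per germline V gene in each sample (ignoring
#' clonal frequency), computes all pairwise Pearson correlation
#' coefficients over the union of V genes (absent genes count 0), and
#' orders the samples by average-linkage hierarchical clustering on the
#' `1 - r` distance.
#'
#' @param clones A `clone_table` with at least 2 samples (mouse x organ).
#' @return List with `correlation` (`similarity_matrix`, may contain `NA`
#'   for constant count vectors), `counts` (V gene x sample matrix) and
#'   `order` (leaf order of the clustering; input order if any
#'   correlation is undefined).
#' @export
vgene_usage_correlation <- function(clones) {
  df <- as.data.frame(clones)
  df$sample <- if (length(unique(df$mouse_id)) > 1) {
    paste(df$mouse_id, df$organ, sep = ":")
  } else df$organ
  uq <- unique(df[, c("sample", "clone_key", "v_gene")])
  if (length(unique(uq$sample)) < 2) {
    stop("vgene_usage_correlation needs >= 2 samples")
  }
  counts <- table(uq$v_gene, uq$sample)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  r <- suppressWarnings(cor(counts, method = "pearson"))
  ord <- colnames(r)
  if (!anyNA(r) && ncol(r) > 2) {
    hc <- hclust(as.dist(1 - r), method = "average")
    ord <- colnames(r)[hc$order]
  }
  list(
    correlation = structure(r, metric = "pearson_vgene",
                            class = c("similarity_matrix", "matrix")),
    counts = counts,
    order = ord
  )
}

#' Annotate clones with antigen-binder status by CDRH3 matching
#'
#' Flags clones whose CDRH3 occurs in a set of known binder CDRH3s
#' (matching on CDRH3 alone by default, as binder sequences typically
#' come without V/J context; `by_vj = TRUE` additionally requires a
#' matching V and J gene against binder keys `"V|J|CDRH3"`), and relates
#' binding to the degree of organ overlap: the ratio of binding clones to
#' all clones at each occupancy degree, and per-clone frequency summaries
#' for frequency-vs-overlap analyses.
#'
#' @param binder_cdrh3 Non-empty character vector of binder CDRH3s (or
#'   `"V|J|CDRH3"` keys when `by_vj = TRUE`).
#' @param clones A `clone_table`.
#' @param by_vj Require matching V/J genes as well.
#' @return List with `clones` (per mouse x clone: degree, `is_binder`,
#'   mean and max frequency across occupied organs) and
#'   `ratio_by_degree` (per mouse and occupancy degree: clone counts,
#'   binder counts, binder ratio, mean frequencies of binding and of all
#'   clones).
#' @export
match_binders <- function(binder_cdrh3, clones, by_vj = FALSE) {
  if (length(binder_cdrh3) == 0) stop("binder set must be non-empty")
  df <- as.data.frame(clones)
  ov <- organ_overlap_counts(df)$clone_degrees

  fr <- stats::aggregate(
    list(mean_frequency = df$frequency, max_frequency = df$frequency),
    by = list(mouse_id = df$mouse_id, clone_key = df$clone_key),
    FUN = mean
  )
  fr$max_frequency <- stats::aggregate(
    df$frequency, by = list(df$mouse_id, df$clone_key), FUN = max)$x

  ann <- merge(ov, fr, by = c("mouse_id", "clone_key"), sort = FALSE)
  cdrh3_of <- vapply(strsplit(ann$clone_key, "|", fixed = TRUE),
                     function(p) p[3], character(1))
  ann$is_binder <- if (by_vj) {
    vapply(strsplit(ann$clone_key, "|", fixed = TRUE), function(p) {
      paste(p[1:3], collapse = "|") %in% binder_cdrh3
    }, logical(1))
  } else {
    cdrh3_of %in% binder_cdrh3
  }
  ann <- ann[lex_order(ann$mouse_id, ann$clone_key), ]
  rownames(ann) <- NULL

  ratio <- do.call(rbind, lapply(
    split(ann, paste(ann$mouse_id, ann$degree, sep = "\r")),
    function(g) {
      data.frame(
        mouse_id = g$mouse_id[1], degree = g$degree[1],
        n_clones = nrow(g), n_binders = sum(g$is_binder),
        binder_ratio = sum(g$is_binder) / nrow(g),
        mean_frequency_all = mean(g$mean_frequency),
        mean_frequency_binders =
          if (any(g$is_binder)) mean(g$mean_frequency[g$is_binder])
          else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  ratio <- ratio[lex_order(ratio$mouse_id, ratio$degree), ]
  rownames(ratio) <- NULL
  list(clones = ann, ratio_by_degree = ratio)
}
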