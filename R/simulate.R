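# Synthetic multi-organ repertoire and lineage-tree generator.
#
# The generator emulates the structure of an IgG VH deep-sequencing study
# of murine lymphoid organs: six organs per mouse (bone marrow, spleen and
# four lymph nodes), three mice per cohort, heavy-tailed clone-frequency
# distributions, partial clone sharing between organs, SHM-derived clonal
# variants, and lineage trees whose tips acquire organ labels under a
# Markov migration process.

CANONICAL_ORGANS <- c("BM", "spleen", "aLN-L", "aLN-R", "iLN-L", "iLN-R")

#' Simulation configuration
#'
#' Parameters of the synthetic repertoire and lineage-tree generator.
#' Defaults describe a polyclonal post-immunization repertoire: a few
#' hundred founder clones under a discrete power-law (Zipf) frequency
#' distribution, moderate organ sharing, and point-mutated CDRH3 variants
#' attached to each founder.
#'
#' @param organs Character vector of organ labels.
#' @param n_founder_clones Number of founder clones per mouse.
#' @param p_share Probability that a clone seeded in its home organ also
#'   appears in each other organ. Scalar, or a square matrix indexed by
#'   organ (`p_share[home, other]`).
#' @param expansion_exponent Exponent `s` of the Zipf clone-frequency law
#'   `w_r = r^-s` (0 = uniform). Scalar, or a named vector per organ.
#' @param frequency_noise Standard deviation of the per-organ lognormal
#'   perturbation of clone weights; 0 makes shared clones have identical
#'   frequencies in every organ.
#' @param shm_rate Expected substitutions per CDRH3 position per variant
#'   generation; every variant carries at least one substitution.
#' @param variants_per_clone Mean of the Poisson number of SHM variants
#'   attached to each founder clone.
#' @param v_gene_pool,j_gene_pool Germline gene names to sample from
#'   (Zipf-weighted).
#' @param cdrh3_length_range Inclusive range of CDRH3 lengths; lengths are
#'   drawn with a peaked (binomial-shaped) distribution over the range.
#' @param reads_per_organ Sequencing depth used to convert clone weights
#'   to integer read counts.
#' @param migration_matrix Row-stochastic organ transition matrix applied
#'   along lineage-tree branches, or `NULL` for a default with strong
#'   self-transition (0.9) and uniform off-diagonal mass.
#' @param migration_mode `"per_branch"` applies the matrix once per
#'   branch; `"per_length"` applies it a Poisson(branch length) number of
#'   times.
#' @param founder_organ Organ state at the germline root of simulated
#'   trees, or `NULL` to draw uniformly per tree.
#' @param n_trees,tree_tips_mean,tree_tips_min Number of simulated lineage
#'   trees and the Poisson mean / lower bound of their tip counts.
#' @param paired If `TRUE`, founders also receive a CDRL3 (paired-chain
#'   clone keys).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(organs = CANONICAL_ORGANS,
                              n_founder_clones = 300L,
                              p_share = 0.15,
                              expansion_exponent = 1.3,
                              frequency_noise = 0.5,
                              shm_rate = 0.08,
                              variants_per_clone = 2,
                              v_gene_pool = sprintf("IGHV1-%d", 1:15),
                              j_gene_pool = sprintf("IGHJ%d", 1:4),
                              cdrh3_length_range = c(10L, 20L),
                              reads_per_organ = 10000L,
                              migration_matrix = NULL,
                              migration_mode = c("per_branch", "per_length"),
                              founder_organ = NULL,
                              n_trees = 50L,
                              tree_tips_mean = 15,
                              tree_tips_min = 4L,
                              paired = FALSE,
                              seed = NULL) {
  migration_mode <- match.arg(migration_mode)
  if (length(organs) < 1) stop_config("at least one organ is required")
  if (n_founder_clones < 1) stop_config("n_founder_clones must be >= 1")
  if (any(p_share < 0) || any(p_share > 1)) {
    stop_config("p_share must lie in [0, 1]")
  }
  if (is.matrix(p_share) &&
      !identical(dim(p_share), c(length(organs), length(organs)))) {
    stop_config("p_share matrix must be organs x organs")
  }
  if (frequency_noise < 0 || shm_rate < 0 || variants_per_clone < 0) {
    stop_config("noise/SHM parameters must be non-negative")
  }
  if (is.null(migration_matrix)) {
    k <- length(organs)
    migration_matrix <- matrix(if (k > 1) 0.1 / (k - 1) else 0, k, k,
                               dimnames = list(organs, organs))
    diag(migration_matrix) <- if (k > 1) 0.9 else 1
  }
  validate_migration_matrix(migration_matrix, organs)
  if (!is.null(founder_organ) && !founder_organ %in% organs) {
    stop_config("founder_organ must be one of the configured organs")
  }
  structure(
    list(organs = organs, n_founder_clones = as.integer(n_founder_clones),
         p_share = p_share, expansion_exponent = expansion_exponent,
         frequency_noise = frequency_noise, shm_rate = shm_rate,
         variants_per_clone = variants_per_clone,
         v_gene_pool = v_gene_pool, j_gene_pool = j_gene_pool,
         cdrh3_length_range = as.integer(cdrh3_length_range),
         reads_per_organ = as.integer(reads_per_organ),
         migration_matrix = migration_matrix,
         migration_mode = migration_mode,
         founder_organ = founder_organ,
         n_trees = as.integer(n_trees), tree_tips_mean = tree_tips_mean,
         tree_tips_min = as.integer(tree_tips_min),
         paired = paired, seed = seed),
    class = "simulation_config"
  )
}

validate_migration_matrix <- function(Q, organs) {
  if (!is.matrix(Q) || nrow(Q) != length(organs) ||
      ncol(Q) != length(organs)) {
    stop_config("migration_matrix must be a square organs x organs matrix")
  }
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-8)) {
    stop_config("migration_matrix rows must be probability distributions")
  }
  invisible(Q)
}

random_cdrh3 <- function(len) {
  # junctions start with the invariant Cys and end with the Trp of the
  # J-region motif
  core <- sample(AA_ALPHABET, len - 4L, replace = TRUE)
  paste0("CAR", paste(core, collapse = ""), "W")
}

mutate_cdrh3 <- function(seq, shm_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- max(1L, rpois(1, shm_rate * length(chars)))
  n_mut <- min(n_mut, length(chars))
  pos <- sample(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

zipf_weights <- function(n, s) (seq_len(n))^(-s)

#' Simulate a multi-organ antibody repertoire
#'
#' Generates sequence records for one mouse. Each founder clone receives a
#' V gene, J gene and CDRH3; it is seeded in a uniformly drawn home organ
#' and appears in each other organ with probability `p_share`. Per-organ
#' clone frequencies follow a Zipf law (exponent `expansion_exponent`),
#' perturbed per organ by lognormal noise, and are converted to read
#' counts at depth `reads_per_organ`. Each founder additionally spawns a
#' Poisson number of SHM variants: point-mutated CDRH3 copies (Hamming
#' distance >= 1 from the founder) sharing the founder's V/J genes, placed
#' in one of the founder's organs with a small read count.
#'
#' Generation is fully reproducible for a fixed `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param mouse_id Identifier stored in the records.
#' @return A sequence-record data frame (as from [read_airr_table()]),
#'   with extra columns `founder_id` and `is_variant`.
#' @export
simulate_repertoire <- function(config, mouse_id = "mouse-1") {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  organs <- config$organs
  n <- config$n_founder_clones
  k <- length(organs)

  v <- sample(config$v_gene_pool, n, replace = TRUE,
              prob = zipf_weights(length(config$v_gene_pool), 1))
  j <- sample(config$j_gene_pool, n, replace = TRUE,
              prob = zipf_weights(length(config$j_gene_pool), 1))
  lr <- config$cdrh3_length_range
  len <- lr[1] + rbinom(n, lr[2] - lr[1], 0.4)
  cdrh3 <- vapply(len, random_cdrh3, character(1))
  # founders are distinct clones by construction
  while (anyDuplicated(cdrh3)) {
    dup <- which(duplicated(cdrh3))
    cdrh3[dup] <- vapply(len[dup], random_cdrh3, character(1))
  }
  cdrl3 <- if (config$paired) {
    vapply(rep(9L, n), function(l) {
      paste0("CQ", paste(sample(AA_ALPHABET, l - 3, replace = TRUE),
                         collapse = ""), "F")
    }, character(1))
  } else NULL

  home <- sample(organs, n, replace = TRUE)
  presence <- matrix(FALSE, n, k, dimnames = list(NULL, organs))
  for (i in seq_len(n)) {
    for (o in seq_len(k)) {
      p <- if (is.matrix(config$p_share)) {
        config$p_share[home[i], organs[o]]
      } else config$p_share
      presence[i, o] <- organs[o] == home[i] || runif(1) < p
    }
  }

  exponent <- config$expansion_exponent
  if (!is.null(names(exponent))) exponent <- exponent[organs]
  if (length(exponent) == 1) exponent <- rep(exponent, k)
  # Zipf ranks assigned by a single random permutation of the founders so
  # that a clone keeps its rank across organs (frequency_noise = 0 then
  # yields identical frequencies for shared clones)
  rank_of <- sample(n)

  rows <- vector("list", k)
  for (o in seq_len(k)) {
    idx <- which(presence[, o])
    if (length(idx) == 0) next
    w <- rank_of[idx]^(-exponent[o])
    if (config$frequency_noise > 0) {
      w <- w * exp(rnorm(length(w), 0, config$frequency_noise))
    }
    counts <- pmax(1L, as.integer(round(w / sum(w) * config$reads_per_organ)))
    rows[[o]] <- data.frame(
      organ = organs[o], founder_id = idx, v_call = v[idx], j_call = j[idx],
      cdrh3_aa = cdrh3[idx], count = counts, is_variant = FALSE,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  # SHM variants: new clones (mutated CDRH3, same V/J) in one of the
  # founder's organs, entering the same clonotype downstream
  n_var <- rpois(n, config$variants_per_clone)
  var_rows <- vector("list", sum(n_var > 0))
  vi <- 0
  for (i in which(n_var > 0)) {
    orgs_i <- organs[presence[i, ]]
    for (m in seq_len(n_var[i])) {
      vi <- vi + 1
      var_rows[[vi]] <- data.frame(
        organ = sample(orgs_i, 1), founder_id = i, v_call = v[i],
        j_call = j[i], cdrh3_aa = mutate_cdrh3(cdrh3[i], config$shm_rate),
        count = 1L + rpois(1, 1), is_variant = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (vi > 0) records <- rbind(records, do.call(rbind, var_rows[seq_len(vi)]))

  records$mouse_id <- mouse_id
  records$sequence_id <- sprintf("%s_seq%06d", mouse_id, seq_len(nrow(records)))
  if (config$paired) records$cdrl3_aa <- cdrl3[records$founder_id]
  rownames(records) <- NULL
  cols <- c("sequence_id", "mouse_id", "organ", "v_call", "j_call",
            "cdrh3_aa", if (config$paired) "cdrl3_aa", "count",
            "founder_id", "is_variant")
  records[, cols]
}

#' Simulate organ-labeled B-cell lineage trees
#'
#' Random bifurcating (Yule) topologies rooted at a germline node. The
#' root carries the founder organ; each branch applies the migration
#' matrix once (default) or a Poisson(branch length) number of times, and
#' the resulting tip organ labels are recorded. The true number and
#' direction of simulated transitions along every branch are stored in
#' each tree's `true_transitions` matrix for oracle comparison.
#'
#' @param config A [simulation_config()]; `migration_matrix` rows must be
#'   probability distributions.
#' @param mouse_id Identifier stored on the trees.
#' @return List of [lineage_tree()] objects, each with elements
#'   `true_transitions` (organ x organ count matrix) and `founder_organ`.
#' @export
simulate_lineage_trees <- function(config, mouse_id = "mouse-1") {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  organs <- config$organs
  Q <- validate_migration_matrix(config$migration_matrix, organs)

  lapply(seq_len(config$n_trees), function(t) {
    ntip <- max(config$tree_tips_min, rpois(1, config$tree_tips_mean))
    tree <- ape::rphylo(ntip, birth = 1, death = 0)
    tree$tip.label <- sprintf("c%03d_t%02d", t, seq_len(ntip))
    # branch lengths on a mutations-per-site-like scale
    tree$edge.length <- tree$edge.length * 0.02

    founder <- config$founder_organ %||% sample(organs, 1)
    n_nodes <- ape::Ntip(tree) + tree$Nnode
    state <- integer(n_nodes)
    root <- ape::Ntip(tree) + 1L
    state[root] <- match(founder, organs)
    trans <- matrix(0L, length(organs), length(organs),
                    dimnames = list(organs, organs))
    # walk edges parent-first
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(pre$edge))) {
      par <- pre$edge[e, 1]
      child <- pre$edge[e, 2]
      s <- state[par]
      steps <- if (config$migration_mode == "per_branch") 1L else {
        rpois(1, pre$edge.length[e])
      }
      for (st in seq_len(steps)) {
        s_new <- sample.int(length(organs), 1, prob = Q[s, ])
        if (s_new != s) trans[s, s_new] <- trans[s, s_new] + 1L
        s <- s_new
      }
      state[child] <- s
    }
    lt <- lineage_tree(tree,
                       setNames(organs[state[seq_len(ntip)]], tree$tip.label),
                       mouse_id, sprintf("clone%03d", t))
    lt$true_transitions <- trans
    lt$founder_organ <- founder
    lt
  })
}

#' Simulate a two-cohort, multi-mouse study
#'
#' Generates repertoires for a study of two immunization cohorts with
#' three mice each. Cohort defaults emulate a single-immunization cohort
#' (low organ sharing, strongly polarized lymph-node repertoires) and a
#' triple-immunization cohort (high organ sharing, uniformly expanded
#' repertoires).
#'
#' @param n_mice Mice per cohort.
#' @param config_1x,config_3x [simulation_config()] objects for the two
#'   cohorts; defaults as described above.
#' @param seed Integer seed driving the whole study.
#' @return A sequence-record data frame with an additional `cohort`
#'   column; mouse ids are `1x-A` ... `3x-C`.
#' @export
simulate_study <- function(n_mice = 3L,
                           config_1x = NULL, config_3x = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config_1x)) {
    config_1x <- simulation_config(
      p_share = 0.05,
      expansion_exponent = c(
        "BM" = 1.0, "spleen" = 1.3,
        "aLN-L" = 1.8, "aLN-R" = 1.8, "iLN-L" = 1.8, "iLN-R" = 1.8
      )
    )
  }
  if (is.null(config_3x)) {
    config_3x <- simulation_config(p_share = 0.45, expansion_exponent = 1.6)
  }
  out <- list()
  for (cohort in c("1x", "3x")) {
    cfg <- if (cohort == "1x") config_1x else config_3x
    cfg$seed <- NULL  # one RNG stream for the whole study
    for (m in seq_len(n_mice)) {
      mouse <- paste0(cohort, "-", LETTERS[m])
      rec <- simulate_repertoire(cfg, mouse_id = mouse)
      rec$cohort <- paste0("cohort-", cohort)
      out[[length(out) + 1]] <- rec
    }
  }
  do.call(rbind, out)
}
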