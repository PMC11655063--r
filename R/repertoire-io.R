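# Reading and writing the external formats used by the pipeline:
# AIRR-style rearrangement TSVs, Newick trees with tip->organ label tables,
# and the analysis configuration.

# Default column mapping, following the AIRR Rearrangement standard.
# Internal canonical names are on the left, file column names on the right.
default_airr_columns <- function() {
  list(
    sequence_id = "sequence_id",
    organ       = "organ",
    mouse_id    = "mouse_id",
    v_call      = "v_call",
    j_call      = "j_call",
    cdrh3_aa    = "junction_aa",
    count       = "duplicate_count",
    v_region_nt = "sequence_alignment",
    germline_nt = "germline_alignment",
    cdrl3_aa    = "cdrl3_aa"
  )
}

#' Read an AIRR-style rearrangement table
#'
#' Reads a tab-separated rearrangement table with a header row into a
#' sequence-record data frame. Rows with an empty CDRH3, a stop codon
#' (`*`) in the CDRH3, or a missing/zero count are dropped; the numbers of
#' rows dropped for each reason are returned in a filter report, so that
#' `sum(report) + nrow(records)` always equals the input row count.
#'
#' Column names follow the AIRR Rearrangement standard (`sequence_id`,
#' `v_call`, `j_call`, `junction_aa`, `duplicate_count`) and can be
#' overridden through `columns`, `organ_column` and `count_column`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param organ_column Name of the column holding the organ/sample label.
#' @param count_column Name of the column holding the read/duplicate count.
#' @param columns Named list overriding the default AIRR column mapping;
#'   names are the canonical internal fields (see
#'   [default_airr_columns()]), values the file's column names.
#' @return A list with `records`, a data frame with canonical columns
#'   (`sequence_id`, `organ`, `mouse_id`, `v_call`, `j_call`, `cdrh3_aa`,
#'   `count`, plus `v_region_nt`/`germline_nt`/`cdrl3_aa` when present),
#'   and `report`, a named integer vector of dropped-row counts
#'   (`dropped_empty_cdr3`, `dropped_stop_codon`, `dropped_zero_count`).
#' @seealso [write_airr_table()]
#' @export
read_airr_table <- function(path, organ_column = "organ",
                            count_column = "duplicate_count",
                            columns = list()) {
  if (!file.exists(path)) {
    stop("cannot read AIRR table: no such file: ", path)
  }
  map <- default_airr_columns()
  map[names(columns)] <- columns
  map$organ <- organ_column
  map$count <- count_column

  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL)

  required <- c("sequence_id", "organ", "v_call", "j_call", "cdrh3_aa",
                "count")
  for (field in required) {
    if (!map[[field]] %in% names(tab)) {
      stop_config("required column '", map[[field]],
                  "' (field ", field, ") not found in ", path)
    }
  }

  records <- data.frame(
    sequence_id = tab[[map$sequence_id]],
    organ       = tab[[map$organ]],
    mouse_id    = if (map$mouse_id %in% names(tab)) tab[[map$mouse_id]]
                  else "mouse-1",
    v_call      = tab[[map$v_call]],
    j_call      = tab[[map$j_call]],
    cdrh3_aa    = tab[[map$cdrh3_aa]],
    count       = suppressWarnings(as.integer(tab[[map$count]])),
    stringsAsFactors = FALSE
  )
  for (opt in c("v_region_nt", "germline_nt", "cdrl3_aa")) {
    if (map[[opt]] %in% names(tab)) records[[opt]] <- tab[[map[[opt]]]]
  }

  empty_cdr3 <- is.na(records$cdrh3_aa) | records$cdrh3_aa == ""
  stop_codon <- !empty_cdr3 & grepl("*", records$cdrh3_aa, fixed = TRUE)
  zero_count <- !empty_cdr3 & !stop_codon &
    (is.na(records$count) | records$count <= 0L)
  keep <- !(empty_cdr3 | stop_codon | zero_count)

  list(
    records = records[keep, , drop = FALSE],
    report = c(
      dropped_empty_cdr3 = sum(empty_cdr3),
      dropped_stop_codon = sum(stop_codon),
      dropped_zero_count = sum(zero_count)
    )
  )
}

#' Write sequence records as an AIRR-style TSV
#'
#' Inverse of [read_airr_table()]: canonical record columns are written
#' under their AIRR names so that a write/read round trip preserves all
#' fields.
#'
#' @param records Sequence-record data frame as returned by
#'   [read_airr_table()] or [simulate_repertoire()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr_table <- function(records, path) {
  map <- default_airr_columns()
  out <- records
  canon <- intersect(names(map), names(out))
  names(out)[match(canon, names(out))] <- unlist(map[canon])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an organ-labeled lineage tree
#'
#' Bundles a rooted `phylo` topology with the organ label of every tip.
#' A tip labeled `"germline"` marks the unmutated ancestor; it anchors the
#' root and is excluded from organ-transition counting.
#'
#' @param tree An [ape::read.tree()] `phylo` object.
#' @param organs Named character vector mapping every tip label of `tree`
#'   to an organ (the name `"germline"` is reserved for the root).
#' @param mouse_id,clone_id Optional identifiers carried through to the
#'   migration test.
#' @return An object of class `lineage_tree`.
#' @export
lineage_tree <- function(tree, organs, mouse_id = NA_character_,
                         clone_id = NA_character_) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  missing <- setdiff(tree$tip.label, names(organs))
  if (length(missing) > 0) {
    stop("tips without an organ label: ", paste(missing, collapse = ", "))
  }
  structure(
    list(tree = tree, organs = organs[tree$tip.label],
         mouse_id = mouse_id, clone_id = clone_id),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  org <- organ_labels(x)
  cat("lineage_tree: ", length(org), " organ-labeled tips (",
      paste(lex_sort(unique(org)), collapse = ", "), ")",
      if (!is.na(x$mouse_id)) paste0("; mouse ", x$mouse_id),
      if (!is.na(x$clone_id)) paste0("; clone ", x$clone_id),
      "\n", sep = "")
  invisible(x)
}

#' Organ labels of the non-germline tips of a lineage tree
#'
#' @param lt A [lineage_tree()].
#' @return Named character vector of tip organ labels, excluding any
#'   `"germline"` tip.
#' @export
organ_labels <- function(lt) {
  orgs <- lt$organs
  orgs[orgs != "germline"]
}

# Drop the germline tip (if any); the root of the returned phylo takes the
# maximum-parsimony state of its descendants, so no transition is counted
# out of the germline.
strip_germline <- function(lt) {
  idx <- which(lt$organs == "germline")
  if (length(idx) == 0) return(lt)
  tips <- names(lt$organs)[idx]
  tree <- ape::drop.tip(lt$tree, tips)
  lineage_tree(tree, lt$organs[setdiff(names(lt$organs), tips)],
               lt$mouse_id, lt$clone_id)
}

#' Read organ-labeled lineage trees
#'
#' Reads one or more Newick trees and a two-column tab-separated table
#' (`tip`, `organ`) assigning an organ to every tip. A tip labeled
#' `"germline"` is used as outgroup to root the tree and is excluded from
#' transition counting downstream.
#'
#' @param newick_path Path to a Newick file (may contain several trees).
#' @param labels_path Path to a TSV with header columns `tip` and `organ`,
#'   covering every tip name occurring in the Newick file. Optional
#'   columns `mouse_id` and `clone_id` are carried onto the trees.
#' @return A list of [lineage_tree()] objects.
#' @seealso [write_labeled_trees()]
#' @export
read_labeled_trees <- function(newick_path, labels_path) {
  trees <- ape::read.tree(newick_path)
  if (is.null(trees)) stop("could not parse Newick file: ", newick_path)
  if (inherits(trees, "phylo")) trees <- list(trees)

  lab <- read.delim(labels_path, sep = "\t", header = TRUE,
                    colClasses = "character")
  if (!all(c("tip", "organ") %in% names(lab))) {
    stop_config("labels table must have columns 'tip' and 'organ'")
  }
  organs <- setNames(lab$organ, lab$tip)

  lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (is.null(tr$edge)) stop("unparseable tree at index ", i)
    missing <- setdiff(tr$tip.label, names(organs))
    if (length(missing) > 0) {
      stop("tree ", i, ": tips without an organ label: ",
           paste(missing, collapse = ", "))
    }
    tip_org <- organs[tr$tip.label]
    germ <- tr$tip.label[tip_org == "germline"]
    if (length(germ) == 1) {
      tr <- ape::root(tr, outgroup = germ, resolve.root = TRUE)
    }
    mouse <- if ("mouse_id" %in% names(lab)) {
      unique(lab$mouse_id[lab$tip %in% tr$tip.label])[1]
    } else NA_character_
    clone <- if ("clone_id" %in% names(lab)) {
      unique(lab$clone_id[lab$tip %in% tr$tip.label])[1]
    } else NA_character_
    lineage_tree(tr, tip_org, mouse, clone)
  })
}

#' Write organ-labeled lineage trees
#'
#' @param trees List of [lineage_tree()] objects.
#' @param newick_path,labels_path Output paths for the Newick file and the
#'   tip/organ label TSV.
#' @return `newick_path`, invisibly.
#' @export
write_labeled_trees <- function(trees, newick_path, labels_path) {
  phy <- lapply(trees, function(lt) lt$tree)
  class(phy) <- "multiPhylo"
  ape::write.tree(phy, file = newick_path)
  lab <- do.call(rbind, lapply(trees, function(lt) {
    data.frame(tip = names(lt$organs), organ = unname(lt$organs),
               mouse_id = lt$mouse_id, clone_id = lt$clone_id,
               stringsAsFactors = FALSE)
  }))
  write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(newick_path)
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline with the defaults used
#' throughout: clones are exact-key groups, clonotypes single-linkage
#' clusters at >90% CDRH3 amino-acid identity, diversity profiles run over
#' alpha in \[0, 10\], and the migration test uses 1000 permutation
#' replicates with a tip-to-change ratio cap of 20.
#'
#' @param clone_identity Identity fraction defining a clone (1 = exact
#'   CDRH3 match).
#' @param clonotype_identity Identity threshold for clonotype clustering;
#'   clones are linked when identity is strictly greater (see
#'   `inclusive`).
#' @param inclusive Logical; if `TRUE` clones at identity exactly equal to
#'   the threshold are also linked (normalized Hamming distance \eqn{\le}
#'   `1 - clonotype_identity`).
#' @param alpha_grid Ascending grid of non-negative alpha values for
#'   diversity/evenness profiles.
#' @param sp_replicates Number of permutation replicates for the SP test.
#' @param sp_ratio_cap Maximum tip-to-change ratio before per-replicate
#'   tree down-sampling.
#' @param seed Integer seed, or `NULL` to leave the RNG state alone.
#' @param clone_key_mode `"heavy"` (V, J, CDRH3) or `"paired"`
#'   (V, J, CDRH3, CDRL3).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(clone_identity = 1.0,
                            clonotype_identity = 0.90,
                            inclusive = FALSE,
                            alpha_grid = seq(0, 10, by = 0.2),
                            sp_replicates = 1000L,
                            sp_ratio_cap = 20,
                            seed = NULL,
                            clone_key_mode = c("heavy", "paired")) {
  clone_key_mode <- match.arg(clone_key_mode)
  if (clone_identity <= 0 || clone_identity > 1) {
    stop_config("clone_identity must be in (0, 1]")
  }
  if (clonotype_identity <= 0 || clonotype_identity > 1) {
    stop_config("clonotype_identity must be in (0, 1]")
  }
  if (is.unsorted(alpha_grid) || any(alpha_grid < 0)) {
    stop_config("alpha_grid must be non-negative and ascending")
  }
  if (sp_replicates < 1) stop_config("sp_replicates must be >= 1")
  if (sp_ratio_cap <= 0) stop_config("sp_ratio_cap must be positive")
  structure(
    list(clone_identity = clone_identity,
         clonotype_identity = clonotype_identity,
         inclusive = inclusive,
         alpha_grid = alpha_grid,
         sp_replicates = as.integer(sp_replicates),
         sp_ratio_cap = sp_ratio_cap,
         seed = seed,
         clone_key_mode = clone_key_mode),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys match
#'   the arguments of [analysis_config()].
#' @return A list of class `analysis_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading JSON configs requires the 'jsonlite' package")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_config("unsupported config format: ", ext)
  }
  do.call(analysis_config, vals)
}
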