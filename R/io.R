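#' Read an annotated feature table
#'
#' Reads a delimited table of annotated ORF observations, one row per
#' predicted ORF per sample, as produced by a gene-centric metagenomic
#' annotation workflow.  Mandatory columns are `orf_id`, `gene`, `taxon`,
#' `sample_id` and `raw_count`; any further columns are carried along
#' untouched.
#'
#' @param path Path to a delimited text file with a header line.
#' @param sep Field separator; tab by default, use `","` for CSV.
#' @return A data.frame of feature records in file order.
#' @export
read_feature_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  validate_feature_table(df)
}

#' Validate a feature table
#'
#' Checks the column contract and invariants of a feature table: mandatory
#' columns present, non-empty gene symbols, non-negative counts, and
#' (orf_id, sample_id) unique.
#'
#' @param df A data.frame of feature records.
#' @return `df`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_feature_table <- function(df) {
  needed <- c("orf_id", "gene", "taxon", "sample_id", "raw_count")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("feature table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$raw_count <- as.numeric(df$raw_count)
  bad <- which(!is.finite(df$raw_count) | df$raw_count < 0)
  if (length(bad) > 0L)
    stop("negative or non-numeric raw_count at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (any(!nzchar(df$gene)))
    stop("empty gene symbol in feature table", call. = FALSE)
  key <- paste(df$orf_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (orf_id, sample_id) pair(s), first at row ",
         which(duplicated(key))[1L], call. = FALSE)
  df
}

#' Read sample metadata
#'
#' Reads station/depth/nutrient metadata for each sample and derives the
#' depth-stratum label with [assign_layer()].  Mandatory columns:
#' `sample_id`, `station_id`, `depth_m`, `nox_um`, `po4_um`.  An `oxygen`
#' column (or any other) is kept as-is.
#'
#' @inheritParams read_feature_table
#' @return A data.frame with an added (or refreshed) `layer` column.
#' @export
read_sample_metadata <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  needed <- c("sample_id", "station_id", "depth_m", "nox_um", "po4_um")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("sample metadata is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(df$nox_um < 0, na.rm = TRUE) || any(df$po4_um < 0, na.rm = TRUE))
    stop("negative nutrient concentration in metadata", call. = FALSE)
  df$layer <- assign_layer(df$depth_m)
  df
}

#' Assign an ocean depth stratum
#'
#' Classifies depths into the three standard pelagic strata: epipelagic
#' (0--200 m), mesopelagic (200--1000 m) and bathypelagic (1000--4000 m).
#' Boundaries are upper-inclusive: 200 m is epipelagic and 1000 m is
#' mesopelagic.  This is a fixed convention of the package; any consistent
#' one yields the same three-way split for realistic bottle depths, which do
#' not sit exactly on the stratum boundaries.
#'
#' @param depth_m Numeric vector of depths in metres, in [0, 4000].
#' @return Character vector of layer labels.
#' @examples
#' assign_layer(c(3, 200, 210, 1000, 4000))
#' @export
assign_layer <- function(depth_m) {
  if (any(!is.finite(depth_m)) || any(depth_m < 0) || any(depth_m > 4000))
    stop("depth_m must lie in [0, 4000] metres", call. = FALSE)
  cut(depth_m, breaks = c(-Inf, 200, 1000, 4000),
      labels = c("epipelagic", "mesopelagic", "bathypelagic"),
      right = TRUE) |> as.character()
}

#' Ordered layer labels
#' @return The three stratum labels, shallowest first.
#' @export
layer_levels <- function() c("epipelagic", "mesopelagic", "bathypelagic")

# ---- reference trees and placements ----------------------------------------

#' Build a clade-labelled reference tree
#'
#' Wraps an `ape::phylo` tree whose internal-node labels name curated clades
#' (clusters), together with a map from clade name to functional status.
#' Such trees act as classifiers for metagenomic query sequences: queries
#' placed inside a clade of known non-functional paralogs are purged.
#'
#' @param tree An `ape::phylo` object with `node.label`s on the labelled
#'   clades (unlabelled internal nodes are allowed and are transparent).
#' @param clade_labels Named character vector mapping clade name to
#'   `"functional"` or `"non_functional"`.
#' @param gene Marker-gene symbol the tree classifies.
#' @return An object of class `reference_tree`.
#' @export
reference_tree <- function(tree, clade_labels, gene) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(clade_labels)) || any(!nzchar(names(clade_labels))))
    stop("clade_labels must be a named vector", call. = FALSE)
  if (!all(clade_labels %in% c("functional", "non_functional")))
    stop("clade status must be 'functional' or 'non_functional'",
         call. = FALSE)
  present <- names(clade_labels) %in% c(tree$node.label, tree$tip.label)
  if (!all(present))
    stop("clade label(s) not found in tree: ",
         paste(names(clade_labels)[!present], collapse = ", "),
         call. = FALSE)
  obj <- structure(list(tree = tree, clade_labels = clade_labels,
                        gene = gene),
                   class = "reference_tree")
  uncovered <- vapply(seq_along(tree$tip.label), function(i) {
    is.na(.smallest_labelled_clade(obj, tree$tip.label[i]))
  }, logical(1L))
  if (any(uncovered))
    stop("tip(s) not covered by any labelled clade: ",
         paste(tree$tip.label[uncovered], collapse = ", "), call. = FALSE)
  obj
}

#' @export
print.reference_tree <- function(x, ...) {
  cat("Reference tree for", x$gene, "-", length(x$tree$tip.label),
      "tips,", length(x$clade_labels), "labelled clades\n")
  st <- table(x$clade_labels)
  cat("  clades:", paste(names(x$clade_labels), unname(x$clade_labels),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a reference tree from newick plus a clade-status table
#'
#' @param newick_path Newick file; labelled internal nodes name the clades.
#' @param labels_path Tab-separated file with columns `clade` and `status`
#'   (`functional`/`non_functional`).
#' @param gene Marker-gene symbol.
#' @return A `reference_tree`.
#' @export
read_reference_tree <- function(newick_path, labels_path, gene) {
  tree <- ape::read.tree(newick_path)
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  reference_tree(tree, stats::setNames(lab$status, lab$clade), gene)
}

#' Construct a placement set
#'
#' A placement set records, for one marker gene, where candidate query
#' sequences fall on the companion reference tree.  Each placement points at
#' a node of the tree (a tip label or an internal clade label, standing for
#' the edge leading to that node) with a likelihood weight ratio in [0, 1].
#' A query may carry several placements.
#'
#' @param gene Marker-gene symbol.
#' @param placements data.frame with columns `query_id`, `node`,
#'   `like_weight_ratio`.
#' @return An object of class `placement_set`.
#' @export
placement_set <- function(gene, placements) {
  if (nrow(placements) > 0L) {
    stopifnot(all(c("query_id", "node", "like_weight_ratio") %in%
                    names(placements)))
    lwr <- placements$like_weight_ratio
    if (any(!is.finite(lwr)) || any(lwr < 0) || any(lwr > 1))
      stop("like_weight_ratio must lie in [0, 1]", call. = FALSE)
  }
  structure(list(gene = gene, placements = placements),
            class = "placement_set")
}

#' Read a jplace-style placement file
#'
#' Reads placements from a lightweight jplace-style JSON document with
#' top-level fields `gene`, `fields` (column names, including `node` and
#' `like_weight_ratio`) and `placements` (a list of `{n: [names],
#' p: [[values...]]}` records, as in jplace).
#'
#' @param path Path to the JSON file.
#' @return A `placement_set`.
#' @export
read_placements <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$gene) || is.null(doc$fields))
    stop("placement file lacks 'gene' or 'fields'", call. = FALSE)
  fields <- unlist(doc$fields)
  rows <- list()
  for (pl in doc$placements) {
    nms <- unlist(pl$n)
    for (p in pl$p) {
      vals <- stats::setNames(as.list(unlist(p)), fields)
      for (nm in nms) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = nm, node = as.character(vals$node),
          like_weight_ratio = as.numeric(vals$like_weight_ratio),
          stringsAsFactors = FALSE)
      }
    }
  }
  placements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), node = character(),
               like_weight_ratio = numeric())
  placement_set(doc$gene, placements)
}

#' Write a placement set as jplace-style JSON
#'
#' @param x A `placement_set`.
#' @param path Output path.
#' @export
write_placements <- function(x, path) {
  stopifnot(inherits(x, "placement_set"))
  pl <- x$placements
  recs <- lapply(seq_len(nrow(pl)), function(i) {
    list(n = list(pl$query_id[i]),
         p = list(list(pl$node[i], pl$like_weight_ratio[i])))
  })
  doc <- list(version = 3, gene = x$gene,
              fields = list("node", "like_weight_ratio"),
              placements = recs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- result export ----------------------------------------------------------

#' Write an analysis result table
#'
#' Exports guild scores, density curves or contrast tables as tab-separated
#' text with full numeric precision, so that reading the file back
#' reproduces every numeric column bit-identically.
#'
#' @param x A data.frame of results (e.g. from [score_strata()],
#'   [delta_density()] grids, or [one_vs_rest_rotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (!is.data.frame(x) || nrow(x) == 0L)
    stop("refusing to write an empty result collection", call. = FALSE)
  num <- vapply(x, is.numeric, logical(1L))
  for (j in which(num)) {
    bad <- !is.finite(x[[j]])
    if (any(bad)) {
      where <- if ("gene" %in% names(x))
        paste0(" (", x$gene[which(bad)[1L]],
               if ("taxon" %in% names(x))
                 paste0("/", x$taxon[which(bad)[1L]]) else "", ")")
      else ""
      stop("non-finite value in column '", names(x)[j], "' at row ",
           which(bad)[1L], where, call. = FALSE)
    }
  }
  out <- x
  for (j in which(num)) out[[j]] <- sprintf("%.17g", x[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame; columns that parse as numbers become numeric.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  df
}
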