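# Purging of non-functional paralogs by placement on labelled reference trees.
#
# A query inherits the verdict of the smallest labelled clade that contains
# its best placement; placements below the confidence threshold are discarded
# outright.  This reproduces curator-driven purges such as dropping anammox
# candidates that fall in a hydrazine-synthase paralog cluster, or nitrogenase
# candidates falling in the non-functional cluster IV of the nifH tree.

# Parent node of each node in an ape phylo tree; 0 for the root.
.parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# Node number for a tip or internal-node label; NA if absent.
.node_number <- function(tree, label) {
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (!is.na(j)) return(length(tree$tip.label) + j)
  NA_integer_
}

# Name of the smallest labelled clade containing `node_ref` (a tip or clade
# label), walking rootward; NA if no labelled ancestor exists.
.smallest_labelled_clade <- function(rtree, node_ref) {
  tree <- rtree$tree
  node <- .node_number(tree, node_ref)
  if (is.na(node)) return(NA_character_)
  ntip <- length(tree$tip.label)
  parents <- .parents(tree)
  labelled <- names(rtree$clade_labels)
  cur <- node
  while (cur != 0L) {
    lab <- if (cur > ntip) tree$node.label[cur - ntip] else
      tree$tip.label[cur]
    if (!is.null(lab) && !is.na(lab) && nzchar(lab) && lab %in% labelled)
      return(lab)
    cur <- parents[cur]
  }
  NA_character_
}

#' Default filter rules derived from a reference tree
#'
#' Clades labelled `functional` map to verdict `retain`, clades labelled
#' `non_functional` to `discard`.  Returned in the rules-table format so a
#' curator can override individual clades.
#'
#' @param rtree A [reference_tree()].
#' @return data.frame with columns `gene`, `clade`, `verdict`.
#' @export
default_filter_rules <- function(rtree) {
  data.frame(gene = rtree$gene, clade = names(rtree$clade_labels),
             verdict = ifelse(rtree$clade_labels == "functional",
                              "retain", "discard"),
             stringsAsFactors = FALSE)
}

#' Read a filter-rules table
#'
#' @param path TSV file with columns `gene`, `clade`, `verdict`
#'   (`retain`/`discard`).
#' @return data.frame of rules.
#' @export
read_filter_rules <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "clade", "verdict") %in% names(df)),
            all(df$verdict %in% c("retain", "discard")))
  df
}

#' Classify one query from its placements
#'
#' The placement with the largest likelihood weight ratio wins; ties break
#' toward `discard` (the conservative choice for a purging step).  A best
#' placement below `weight_threshold` is discarded with reason
#' `"low_confidence"`.  Otherwise the query inherits the verdict of the
#' smallest labelled clade containing the placement node.
#'
#' @param placements data.frame of this query's placements (`node`,
#'   `like_weight_ratio`).
#' @param rtree The gene's [reference_tree()].
#' @param rules Rules table for the gene (see [default_filter_rules()]).
#' @param weight_threshold Minimum likelihood weight ratio in (0, 1];
#'   default 0.5.
#' @return list with `verdict` (`"retain"`/`"discard"`), `clade`, `reason`.
#' @export
classify_query <- function(placements, rtree, rules, weight_threshold = 0.5) {
  stopifnot(weight_threshold > 0, weight_threshold <= 1,
            nrow(placements) >= 1L)
  clades <- vapply(placements$node, function(nd) {
    cl <- .smallest_labelled_clade(rtree, nd)
    if (is.na(cl))
      stop("placement node '", nd, "' does not resolve in the ", rtree$gene,
           " reference tree", call. = FALSE)
    cl
  }, character(1L), USE.NAMES = FALSE)
  verdicts <- rules$verdict[match(clades, rules$clade)]
  if (anyNA(verdicts))
    stop("no filter rule for clade '", clades[which(is.na(verdicts))[1L]],
         "' of gene ", rtree$gene, call. = FALSE)
  w <- placements$like_weight_ratio
  best <- which(w == max(w))
  if (length(best) > 1L) {    # tie: prefer a discarding placement
    disc <- best[verdicts[best] == "discard"]
    best <- if (length(disc)) disc[1L] else best[1L]
  }
  if (w[best] < weight_threshold)
    return(list(verdict = "discard", clade = clades[best],
                reason = "low_confidence"))
  list(verdict = verdicts[best], clade = clades[best], reason = "clade_rule")
}

#' Purge a feature table of non-functional paralogs
#'
#' Applies [classify_query()] to every placed ORF and removes records whose
#' query is discarded.  Records of genes that have no reference tree are
#' retained with reason `"no_tree"`; records with a tree but no placement are
#' discarded (a candidate that could not be placed cannot be confirmed
#' functional).
#'
#' @param records Feature table (see [read_feature_table()]).
#' @param placement_sets list of [placement_set()] objects.
#' @param trees list of [reference_tree()] objects.
#' @param rules Rules table covering every labelled clade of every tree;
#'   defaults to rules derived from the trees' own clade labels.
#' @param weight_threshold Passed to [classify_query()].
#' @return list with `retained` (the surviving records) and `report`, a
#'   per-gene data.frame of input/retained/discarded tallies whose counts
#'   always conserve (`n_retained + n_discarded == n_input`).
#' @export
filter_feature_table <- function(records, placement_sets = list(),
                                 trees = list(), rules = NULL,
                                 weight_threshold = 0.5) {
  validate_feature_table(records)
  trees <- if (inherits(trees, "reference_tree")) list(trees) else trees
  placement_sets <- if (inherits(placement_sets, "placement_set"))
    list(placement_sets) else placement_sets
  tree_genes <- vapply(trees, `[[`, character(1L), "gene")
  names(trees) <- tree_genes
  for (ps in placement_sets) {
    if (!ps$gene %in% tree_genes)
      stop("placements reference gene '", ps$gene,
           "' which has no reference tree", call. = FALSE)
  }
  if (is.null(rules) && length(trees))
    rules <- do.call(rbind, lapply(trees, default_filter_rules))

  # verdict per (gene, query)
  verdict_of <- new.env(parent = emptyenv())
  for (ps in placement_sets) {
    pl <- ps$placements
    if (nrow(pl) == 0L) next
    grules <- rules[rules$gene == ps$gene, , drop = FALSE]
    for (qid in unique(pl$query_id)) {
      cls <- classify_query(pl[pl$query_id == qid, , drop = FALSE],
                            trees[[ps$gene]], grules, weight_threshold)
      assign(paste(ps$gene, qid, sep = "\r"), cls, envir = verdict_of)
    }
  }

  n <- nrow(records)
  keep <- logical(n)
  clade <- rep(NA_character_, n)
  reason <- character(n)
  for (i in seq_len(n)) {
    g <- records$gene[i]
    if (!g %in% tree_genes) {
      keep[i] <- TRUE; reason[i] <- "no_tree"
    } else {
      key <- paste(g, records$orf_id[i], sep = "\r")
      cls <- if (exists(key, envir = verdict_of, inherits = FALSE))
        get(key, envir = verdict_of) else
        list(verdict = "discard", clade = NA_character_,
             reason = "unplaced")
      keep[i] <- cls$verdict == "retain"
      clade[i] <- cls$clade
      reason[i] <- cls$reason
    }
  }

  genes <- sort(unique(records$gene))
  report <- do.call(rbind, lapply(genes, function(g) {
    sel <- records$gene == g
    data.frame(gene = g, n_input = sum(sel),
               n_retained = sum(sel & keep),
               n_discarded = sum(sel & !keep),
               stringsAsFactors = FALSE)
  }))
  clade_tally <- stats::aggregate(
    list(n = rep(1L, n)),
    by = list(gene = records$gene,
              clade = ifelse(is.na(clade), "(none)", clade),
              verdict = ifelse(keep, "retain", "discard")),
    FUN = sum)
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, report = report, clade_tally = clade_tally,
       reasons = reason)
}
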