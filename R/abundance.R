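# Global FPM normalization and aggregation to (gene, taxon, context) strata.

#' Normalize raw counts to features per million (FPM)
#'
#' FPM is a globally scaled abundance: each record's raw read count divided
#' by the grand total of raw reads over the whole dataset (all samples
#' together), times 1e6.  The sum of FPM over all records is therefore
#' exactly one million, and doubling every raw count leaves every FPM
#' unchanged.  Normalization is global -- across samples, not per sample --
#' so FPM values are comparable between samples and layers.
#'
#' @param records Feature table (see [read_feature_table()]).  Normalization
#'   is intended to run after paralog purging, so that the one-million total
#'   is carried by retained, truly functional features.
#' @return `records` with an `fpm` column added (or recomputed).
#' @examples
#' tab <- data.frame(orf_id = c("a", "b", "c"), gene = "amt",
#'                   taxon = "t", sample_id = "s1", raw_count = c(10, 30, 60))
#' normalize_fpm(tab)$fpm   # 1e5, 3e5, 6e5
#' @export
normalize_fpm <- function(records) {
  validate_feature_table(records)
  total <- sum(records$raw_count)
  if (total <= 0)
    stop("cannot normalize: total raw_count is zero", call. = FALSE)
  records$fpm <- records$raw_count / total * 1e6
  records
}

#' Aggregate feature records to (gene, taxon, context) strata
#'
#' A stratum is the unit on which expected richness, delta and k are
#' computed: one marker gene, one taxon, one environmental context (station
#' class crossed with depth layer).  Its abundance `A` is the summed FPM of
#' its records and its observed richness `d_obs` the number of distinct
#' ORF ids (each predicted ORF counts as one unique sequence; an ORF seen in
#' several samples of the same context counts once).
#'
#' @param records Feature table with an `fpm` column (see
#'   [normalize_fpm()]).
#' @param metadata Sample metadata with `sample_id`, `station_id`, `layer`.
#' @param context_map data.frame mapping `station_id` to `station_class`
#'   (e.g. `"OMZ"`, `"NAtl"`, `"SAtl"`, `"average_ocean"`).
#' @return data.frame of strata: `gene`, `taxon`, `station_class`, `layer`,
#'   `context`, `A`, `d_obs`.  Strata with zero abundance are omitted.
#' @export
aggregate_strata <- function(records, metadata, context_map) {
  if (is.null(records$fpm))
    stop("records lack an 'fpm' column; run normalize_fpm() first",
         call. = FALSE)
  orphan <- setdiff(unique(records$sample_id), metadata$sample_id)
  if (length(orphan) > 0L)
    stop("sample_id(s) without metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  m <- match(records$sample_id, metadata$sample_id)
  station <- metadata$station_id[m]
  cls <- context_map$station_class[match(station, context_map$station_id)]
  if (anyNA(cls))
    stop("station_id(s) without a context class: ",
         paste(unique(station[is.na(cls)]), collapse = ", "),
         call. = FALSE)
  layer <- metadata$layer[m]
  key <- paste(records$gene, records$taxon, cls, layer, sep = "\r")
  A <- tapply(records$fpm, key, sum)
  d_obs <- tapply(records$orf_id, key, function(x) length(unique(x)))
  parts <- strsplit(names(A), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[[`, character(1L), 1L),
    taxon = vapply(parts, `[[`, character(1L), 2L),
    station_class = vapply(parts, `[[`, character(1L), 3L),
    layer = vapply(parts, `[[`, character(1L), 4L),
    A = as.numeric(A),
    d_obs = as.integer(d_obs),
    stringsAsFactors = FALSE)
  out$context <- paste(out$station_class, out$layer, sep = ".")
  out <- out[out$A > 0, , drop = FALSE]
  out <- out[order(out$gene, out$taxon, out$station_class, out$layer), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool minor taxa into an "Others" entry
#'
#' Within each displayed cell (gene x context), taxa are ranked by their
#' summed k-value; taxa beyond the top `n` are pooled into a single
#' `"Others"` row whose k is the sum of its members, so total k is
#' conserved.  Ties in k break lexicographically by taxon name for
#' reproducibility.
#'
#' @param scores Guild-score data.frame (see [score_strata()]) with at least
#'   `gene`, `taxon`, `context`, `k`.
#' @param n Number of taxa to keep per cell; default 25.
#' @return Scores with minor taxa replaced by pooled `"Others"` rows
#'   (columns `gene`, `taxon`, `station_class`, `layer`, `context`, `A`,
#'   `k`).
#' @export
top_taxa <- function(scores, n = 25L) {
  stopifnot(n >= 1L)
  cells <- unique(scores[, c("gene", "context")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- scores[scores$gene == cells$gene[i] &
                    scores$context == cells$context[i], , drop = FALSE]
    ksum <- tapply(sub$k, sub$taxon, sum)
    ord <- order(-ksum, names(ksum))
    keep_taxa <- names(ksum)[utils::head(ord, n)]
    keep <- sub[sub$taxon %in% keep_taxa, , drop = FALSE]
    rest <- sub[!sub$taxon %in% keep_taxa, , drop = FALSE]
    if (nrow(rest) > 0L) {
      pooled <- rest[1L, , drop = FALSE]   # template row: gene/context fields
      pooled$taxon <- "Others"
      pooled$A <- sum(rest$A)
      pooled$k <- sum(rest$k)
      # per-stratum statistics do not pool; only abundance-like columns do
      for (col in intersect(names(pooled),
                            c("d_obs", "d_exp", "delta", "log_delta")))
        pooled[[col]] <- NA
      if ("log_k" %in% names(pooled)) pooled$log_k <- log(pooled$k)
      keep <- rbind(keep, pooled)
    }
    out[[i]] <- keep
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
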