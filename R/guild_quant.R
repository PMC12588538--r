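# The quantitative heart of the package: expected sequence richness as a
# power law of abundance, the delta diversification statistic, and k-values.
#
# Within a marker gene, the number of distinct sequence variants observed in
# a stratum grows with the stratum's abundance approximately as
#     d_exp = c * A^gamma ,
# with A in FPM.  delta = d_obs / d_exp measures the departure of observed
# richness from that expectation: 1 means exactly as diverse as expected
# from abundance alone, below 1 under-diversified, above 1 over-diversified.
# k = delta * A combines incidence and unexpected diversity into a single
# guild-importance score; logs are natural throughout.

#' Fit the richness-abundance power law for one gene
#'
#' Least squares of log(d_obs) on log(A) across the gene's strata, pooled
#' over taxa and environments.  On log-log axes the power law is linear and
#' the multiplicative richness noise the generator emulates is
#' homoscedastic, which is why the fit is done there rather than on raw
#' axes.
#'
#' @param strata data.frame of one gene's strata with columns `A` (> 0) and
#'   `d_obs` (>= 1); see [aggregate_strata()].
#' @param gene Gene symbol recorded in the fit (defaults to the `gene`
#'   column of `strata` when unique).
#' @return data.frame of class `diversity_fit` with one row: `gene`, `c`,
#'   `gamma`, `se_log_c`, `se_gamma`, `n`, `r2`, `sigma` (residual sd on the
#'   log scale).
#' @export
fit_diversity_model <- function(strata, gene = NULL) {
  usable <- strata$A > 0 & strata$d_obs >= 1
  strata <- strata[usable, , drop = FALSE]
  if (is.null(gene))
    gene <- if (length(unique(strata$gene)) == 1L) strata$gene[1L] else
      stop("strata span several genes; fit one gene at a time",
           call. = FALSE)
  if (nrow(strata) < 3L)
    stop("need at least 3 usable strata to fit the power law for ", gene,
         call. = FALSE)
  x <- log(strata$A)
  y <- log(strata$d_obs)
  if (stats::sd(x) == 0)
    stop("zero variance in log(A): power-law fit is degenerate for ", gene,
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  res <- fit$residuals
  n <- length(y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / max(n - 2L, 1L)
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, x))))
  se <- sqrt(diag(xtx_inv) * sigma2)
  out <- data.frame(gene = gene, c = exp(beta[1L]), gamma = beta[2L],
                    se_log_c = se[1L], se_gamma = se[2L], n = n,
                    r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                    sigma = sqrt(sigma2),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("diversity_fit", "data.frame")
  out
}

#' Fit the power law for every gene in a strata table
#'
#' @param strata Strata table covering one or more genes.
#' @param min_strata Groups with fewer usable strata are skipped with a
#'   warning rather than an error; default 3.
#' @param per_taxon If `TRUE`, fit a separate power law for every
#'   (gene, taxon) pair instead of pooling taxa within a gene.  The pooled
#'   per-gene fit is the default: it is the reading that keeps the
#'   regression well-posed when many strata contribute a single point each.
#' @return A `diversity_fit` data.frame with one row per fitted group (a
#'   `taxon` column is present when `per_taxon = TRUE`).
#' @export
fit_diversity_models <- function(strata, min_strata = 3L,
                                 per_taxon = FALSE) {
  keys <- if (per_taxon) unique(strata[, c("gene", "taxon")]) else
    data.frame(gene = sort(unique(strata$gene)))
  fits <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- strata$gene == keys$gene[i] & strata$A > 0 & strata$d_obs >= 1
    if (per_taxon) sel <- sel & strata$taxon == keys$taxon[i]
    sub <- strata[sel, , drop = FALSE]
    if (nrow(sub) < min_strata || stats::sd(log(sub$A)) == 0) {
      warning("skipping ", keys$gene[i],
              if (per_taxon) paste0("/", keys$taxon[i]) else "",
              ": too few strata or degenerate A", call. = FALSE)
      next
    }
    f <- fit_diversity_model(sub, gene = keys$gene[i])
    if (per_taxon) f$taxon <- keys$taxon[i]
    fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L)
    stop("no group had enough strata to fit", call. = FALSE)
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("diversity_fit", "data.frame")
  out
}

#' Score strata with delta and k
#'
#' Attaches to every stratum its expected richness `d_exp = c * A^gamma`
#' from the gene's fitted power law, the diversification statistic
#' `delta = d_obs / d_exp`, the guild-importance score `k = delta * A`, and
#' their natural logarithms.
#'
#' @param strata Strata table (see [aggregate_strata()]).
#' @param fits `diversity_fit` table covering every gene present in
#'   `strata`.
#' @return data.frame of guild scores: the stratum key columns plus `d_exp`,
#'   `delta`, `k`, `log_delta`, `log_k`.
#' @examples
#' strata <- data.frame(gene = "amt", taxon = "t1", station_class = "OMZ",
#'                      layer = "epipelagic", context = "OMZ.epipelagic",
#'                      A = 100, d_obs = 20L)
#' fits <- data.frame(gene = "amt", c = 2, gamma = 0.5)
#' score_strata(strata, fits)   # delta = 1, k = 100
#' @export
score_strata <- function(strata, fits) {
  m <- if ("taxon" %in% names(fits))
    match(paste(strata$gene, strata$taxon),
          paste(fits$gene, fits$taxon))
  else match(strata$gene, fits$gene)
  if (anyNA(m))
    stop("no diversity fit for gene(s): ",
         paste(unique(strata$gene[is.na(m)]), collapse = ", "),
         call. = FALSE)
  out <- strata
  out$d_exp <- fits$c[m] * strata$A^fits$gamma[m]
  out$delta <- strata$d_obs / out$d_exp
  out$k <- out$delta * strata$A
  out$log_delta <- log(out$delta)
  out$log_k <- log(out$k)
  out
}

#' Export radial-plot-ready log-k summaries
#'
#' For each analysis cell (station class x layer), taxa are pooled to the
#' top `top_n` contributors per gene via [top_taxa()] and rows are ordered
#' by the guild grouping of the marker registry (acquisition genes first,
#' then redox genes), ready to be drawn as one radial plot per cell.
#'
#' @param scores Guild scores from [score_strata()].
#' @param top_n Taxa kept per gene-cell before pooling into `"Others"`;
#'   default 25.
#' @param guilds Marker registry data.frame (`gene`, `guild_class`);
#'   defaults to [n_cycle_markers()].
#' @return data.frame `context`, `guild_class`, `gene`, `taxon`, `k`,
#'   `log_k`.
#' @export
radial_export <- function(scores, top_n = 25L, guilds = n_cycle_markers()) {
  if (nrow(scores) == 0L) stop("no scores to export", call. = FALSE)
  unknown <- setdiff(unique(scores$gene), guilds$gene)
  if (length(unknown) > 0L)
    stop("gene(s) without a guild grouping: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pooled <- top_taxa(scores, n = top_n)
  pooled$guild_class <- guild_class_of(pooled$gene, guilds)
  gene_order <- match(pooled$gene, guilds$gene)
  pooled <- pooled[order(pooled$context, gene_order, -pooled$k,
                         pooled$taxon), , drop = FALSE]
  rownames(pooled) <- NULL
  pooled[, c("context", "guild_class", "gene", "taxon", "k", "log_k")]
}
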