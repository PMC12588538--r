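# Synthetic oceanic survey generator.
#
# Emulates the statistical structure the guild analysis assumes, with known
# ground truth at every stage: a cruise of stations sampled down the water
# column; N:P profiles with an oxygen-minimum-zone-like (low, shallow
# mesopelagic maximum) and a North-Atlantic-like (high maximum) anomaly;
# gene x taxon x sample feature tables whose unique-sequence richness
# follows d = c * A^gamma with multiplicative lognormal noise; depth-
# dependent taxon turnover; and per-context multiplicative shifts injectable
# into the richness law so that downstream delta estimates can be checked
# against truth.

.round_half_up <- function(x) floor(x + 0.5)

#' Simulation configuration
#'
#' Defaults describe a cruise of the size and shape the package's analyses
#' are designed for: 11 stations spanning the three pelagic strata (7
#' bottle depths each, 77 samples), one oxygen-minimum-zone-like station,
#' one high-N:P station, one further station singled out as its own
#' context, and the 18 nitrogen-cycle marker genes with per-gene power-law
#' richness constants.
#'
#' @param n_stations Number of stations; the first three are the OMZ-like,
#'   NAtl-like and SAtl stations, the rest average ocean.
#' @param depths Bottle depths (m) sampled at every station.
#' @param genes data.frame `gene`, `c`, `gamma` of true richness-law
#'   constants per marker.  Defaults to the 18-marker registry with `c`
#'   between 1.6 and 3.0 and `gamma` between 0.30 and 0.60.
#' @param taxa_per_layer Taxon pool size per depth layer.
#' @param turnover_shared Fraction of a layer's taxa shared with the layer
#'   above, `c(epi_meso, meso_bathy)`.  Default `c(0.3, 0.8)`: strong
#'   turnover at the epi/mesopelagic transition, similar meso- and
#'   bathypelagic communities.
#' @param occupancy Probability that a (gene, taxon, context) stratum is
#'   realized at all.
#' @param fpm_meanlog,fpm_sdlog Lognormal law of stratum abundance weights
#'   (order-of-magnitude spread across strata).
#' @param total_reads Total mapped reads across the whole dataset.
#' @param noise_sd Lognormal sd of the multiplicative richness noise
#'   (unit median).
#' @param delta_multipliers Named numeric vector of injected richness
#'   multipliers; names are `"<station_class>.<layer>"`, a bare station
#'   class, or a bare layer.  Unnamed contexts multiply by 1.
#' @param abundance_law `"lognormal"` (default) or `"fixed"`.
#' @param fpm_values For `abundance_law = "fixed"`: FPM per stratum,
#'   recycled; realized FPM equals these values exactly when they sum to
#'   1e6 and `total_reads` is 1e6.
#' @param np Shape parameters of the N:P profiles; see
#'   [simulate_np_profiles()].
#' @param seed Integer seed fixing the full output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_stations = 11L,
                       depths = c(3, 100, 210, 500, 1000, 2500, 4000),
                       genes = NULL,
                       taxa_per_layer = 40L,
                       turnover_shared = c(epi_meso = 0.3, meso_bathy = 0.8),
                       occupancy = 0.25,
                       fpm_meanlog = log(80), fpm_sdlog = 1.5,
                       total_reads = 5e6,
                       noise_sd = 0.2,
                       delta_multipliers = numeric(),
                       abundance_law = c("lognormal", "fixed"),
                       fpm_values = NULL,
                       np = NULL,
                       seed = 1L) {
  if (is.null(genes)) {
    reg <- n_cycle_markers()
    ng <- nrow(reg)
    genes <- data.frame(gene = reg$gene,
                        c = seq(1.6, 3.0, length.out = ng),
                        gamma = seq(0.30, 0.60, length.out = ng),
                        stringsAsFactors = FALSE)
  }
  if (is.null(np))
    np <- list(
      average  = list(surface = 2, peak = 16.3, peak_depth = 500,
                      asym = 15.3, tau = 800, jitter_sd = 0.1),
      omz_like = list(surface = 2, peak = 12.4, peak_depth = 210,
                      asym = 11.3, tau = 800, jitter_sd = 0),
      natl_like = list(surface = 2, peak = 18.96, peak_depth = 500,
                       asym = 16.4, tau = 800, jitter_sd = 0))
  cfg <- list(n_stations = as.integer(n_stations), depths = depths,
              genes = genes, taxa_per_layer = as.integer(taxa_per_layer),
              turnover_shared = turnover_shared, occupancy = occupancy,
              fpm_meanlog = fpm_meanlog, fpm_sdlog = fpm_sdlog,
              total_reads = total_reads, noise_sd = noise_sd,
              delta_multipliers = delta_multipliers,
              abundance_law = match.arg(abundance_law),
              fpm_values = fpm_values, np = np, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Validate a simulation configuration
#' @param cfg A `sim_config` (or plain list with the same fields).
#' @return `cfg` invisibly, or an error.
#' @export
validate_sim_config <- function(cfg) {
  if (any(cfg$genes$c <= 0))
    stop("true richness constants c must be positive", call. = FALSE)
  if (any(cfg$genes$gamma <= 0 | cfg$genes$gamma > 1.5))
    stop("true exponents gamma must lie in (0, 1.5]", call. = FALSE)
  if (any(cfg$delta_multipliers <= 0))
    stop("delta multipliers must be positive", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("noise_sd must be non-negative", call. = FALSE)
  if (cfg$occupancy <= 0 || cfg$occupancy > 1)
    stop("occupancy must lie in (0, 1]", call. = FALSE)
  if (cfg$n_stations < 3L)
    stop("need at least 3 stations", call. = FALSE)
  if (any(cfg$turnover_shared < 0 | cfg$turnover_shared > 1))
    stop("turnover fractions must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields map directly onto [sim_config()] arguments; `genes` may be
#' a list of `{gene, c, gamma}` records and `delta_multipliers` a mapping
#' from context name to multiplier.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$genes))
    raw$genes <- do.call(rbind, lapply(raw$genes, as.data.frame))
  if (!is.null(raw$delta_multipliers))
    raw$delta_multipliers <- unlist(raw$delta_multipliers)
  do.call(sim_config, raw)
}

# station table: ids, shapes, context classes
.sim_stations <- function(cfg) {
  n <- cfg$n_stations
  ids <- sprintf("st%02d", seq_len(n))
  shape <- c("omz_like", "natl_like", rep("average", n - 2L))
  cls <- c("OMZ", "NAtl", "SAtl", rep("average_ocean", n - 3L))
  data.frame(station_id = ids, shape = shape, station_class = cls,
             stringsAsFactors = FALSE)
}

# N:P ratio of a parametric vertical profile: linear rise from the surface
# value to the peak, then exponential relaxation to the deep asymptote
.np_curve <- function(depth, p) {
  ifelse(depth <= p$peak_depth,
         p$surface + (p$peak - p$surface) * depth / p$peak_depth,
         p$asym + (p$peak - p$asym) * exp(-(depth - p$peak_depth) / p$tau))
}

#' Simulate sample metadata with N:P vertical profiles
#'
#' Each station follows one of three profile shapes.  `average` stations
#' relax to a deep asymptote just under the Redfield ratio, with small
#' per-station jitter on the peak and asymptote; `omz_like` has a low
#' mesopelagic maximum reached shallow (default 12.4 at 210 m) and stays
#' below all average stations at depth; `natl_like` peaks high (default
#' 18.96) and stays above them.  Phosphate increases smoothly with depth and
#' NOx is derived as ratio x phosphate.
#'
#' @param cfg A [sim_config()].
#' @return list: `metadata` (sample_id, station_id, depth_m, nox_um,
#'   po4_um, oxygen, layer) and `stations` (station_id, shape,
#'   station_class).
#' @export
simulate_np_profiles <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  stations <- .sim_stations(cfg)
  rows <- list()
  for (i in seq_len(nrow(stations))) {
    p <- cfg$np[[stations$shape[i]]]
    if (p$jitter_sd > 0) {
      p$peak <- p$peak + stats::rnorm(1L, 0, p$jitter_sd)
      p$asym <- p$asym + stats::rnorm(1L, 0, p$jitter_sd)
    }
    d <- cfg$depths
    ratio <- .np_curve(d, p)
    po4 <- 0.3 + 2.0 * d / (d + 300)        # monotone, saturating
    oxy <- if (stations$shape[i] == "omz_like")
      200 - 180 * exp(-((d - p$peak_depth) / 300)^2) else
      rep(200, length(d))
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_d%04d", stations$station_id[i], round(d)),
      station_id = stations$station_id[i],
      depth_m = d, nox_um = ratio * po4, po4_um = po4,
      oxygen = oxy, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, rows)
  metadata$layer <- assign_layer(metadata$depth_m)
  rownames(metadata) <- NULL
  list(metadata = metadata, stations = stations)
}

# taxon pools per layer with configured sharing between adjacent layers
.sim_taxa <- function(cfg) {
  n <- cfg$taxa_per_layer
  fresh <- local({
    counter <- 0L
    function(k) {
      ids <- sprintf("tax%04d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
  })
  epi <- fresh(n)
  n_shared1 <- round(cfg$turnover_shared[[1L]] * n)
  meso <- c(sample(epi, n_shared1), fresh(n - n_shared1))
  n_shared2 <- round(cfg$turnover_shared[[2L]] * n)
  bathy <- c(sample(meso, n_shared2), fresh(n - n_shared2))
  list(epipelagic = epi, mesopelagic = meso, bathypelagic = bathy)
}

# multiplier for a context: exact "class.layer" name wins, then bare class,
# then bare layer, then 1
.context_multiplier <- function(mult, station_class, layer) {
  key <- paste(station_class, layer, sep = ".")
  out <- rep(1, length(key))
  if (length(mult) == 0L) return(out)
  for (i in seq_along(key)) {
    if (key[i] %in% names(mult)) out[i] <- mult[[key[i]]]
    else if (station_class[i] %in% names(mult))
      out[i] <- mult[[station_class[i]]]
    else if (layer[i] %in% names(mult)) out[i] <- mult[[layer[i]]]
  }
  out
}

#' Simulate a full annotated feature dataset
#'
#' Draws the cruise metadata, realizes the (gene, taxon, context) strata,
#' gives each stratum a heavy-tailed abundance and an on- or off-curve
#' unique-sequence richness `d = max(1, round(c * A^gamma * m * eps))` --
#' `m` the context's injected delta multiplier, `eps` lognormal noise with
#' unit median, rounding half away from zero -- and expands every stratum
#' into that many distinct ORF records whose raw counts sum to the
#' stratum's reads, scattered over the context's samples.  Identical seeds
#' give identical output.
#'
#' @param cfg A [sim_config()].
#' @return list: `records` (feature table), `metadata`, `stations`,
#'   `context_map` (station_id -> station_class), and `truth` -- one row
#'   per emitted stratum with the realized `A` (FPM), `d_true`, the
#'   multiplier applied, and the true `c`/`gamma`.
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  md <- simulate_np_profiles(cfg)
  set.seed(cfg$seed + 2L)
  metadata <- md$metadata
  stations <- md$stations
  taxa <- .sim_taxa(cfg)

  # enumerate candidate strata: context = station_class x layer
  contexts <- unique(data.frame(
    station_class = stations$station_class[
      match(metadata$station_id, stations$station_id)],
    layer = metadata$layer, stringsAsFactors = FALSE))
  cand <- list()
  for (i in seq_len(nrow(contexts))) {
    lay <- contexts$layer[i]
    grid <- expand.grid(gene = cfg$genes$gene, taxon = taxa[[lay]],
                        stringsAsFactors = FALSE)
    grid$station_class <- contexts$station_class[i]
    grid$layer <- lay
    cand[[i]] <- grid
  }
  strata <- do.call(rbind, cand)
  strata <- strata[stats::runif(nrow(strata)) < cfg$occupancy, ,
                   drop = FALSE]
  ns <- nrow(strata)
  if (ns == 0L) stop("occupancy too low: no strata realized", call. = FALSE)

  # stratum raw reads
  raw <- if (cfg$abundance_law == "lognormal") {
    w <- stats::rlnorm(ns, cfg$fpm_meanlog, cfg$fpm_sdlog)
    .round_half_up(w / sum(w) * cfg$total_reads)
  } else {
    fpm <- rep_len(cfg$fpm_values, ns)
    .round_half_up(fpm * cfg$total_reads / 1e6)
  }
  keep <- raw >= 1
  strata <- strata[keep, , drop = FALSE]
  raw <- raw[keep]
  ns <- nrow(strata)
  total <- sum(raw)
  A <- raw / total * 1e6

  gi <- match(strata$gene, cfg$genes$gene)
  m <- .context_multiplier(cfg$delta_multipliers, strata$station_class,
                           strata$layer)
  eps <- if (cfg$noise_sd > 0) exp(stats::rnorm(ns, 0, cfg$noise_sd))
    else rep(1, ns)
  d <- .round_half_up(cfg$genes$c[gi] * A^cfg$genes$gamma[gi] * m * eps)
  d <- pmin(pmax(d, 1L), raw)   # at least 1 ORF, at most 1 read per ORF

  truth <- data.frame(strata, A = A, raw_reads = raw, d_true = as.integer(d),
                      multiplier = m, c_true = cfg$genes$c[gi],
                      gamma_true = cfg$genes$gamma[gi],
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  # expand strata into ORF-level records
  station_class_of_sample <- stations$station_class[
    match(metadata$station_id, stations$station_id)]
  sample_pool <- split(metadata$sample_id,
                       paste(station_class_of_sample, metadata$layer,
                             sep = "."))
  orf_counter <- 0L
  recs <- vector("list", ns)
  for (i in seq_len(ns)) {
    di <- d[i]
    counts <- rep(1L, di)
    extra <- raw[i] - di
    if (extra > 0L)
      counts <- counts + drop(stats::rmultinom(1L, extra, rep(1, di)))
    pool <- sample_pool[[paste(strata$station_class[i], strata$layer[i],
                               sep = ".")]]
    smp <- if (length(pool) == 1L) rep(pool, di) else
      sample(pool, di, replace = TRUE)
    recs[[i]] <- data.frame(
      orf_id = sprintf("orf%07d", orf_counter + seq_len(di)),
      gene = strata$gene[i], taxon = strata$taxon[i],
      sample_id = smp, raw_count = counts, stringsAsFactors = FALSE)
    orf_counter <- orf_counter + di
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  list(records = records, metadata = metadata, stations = stations,
       context_map = stations[, c("station_id", "station_class")],
       truth = truth)
}

#' Simulate strata directly on the richness law
#'
#' Lightweight stratum-level generator for validating the power-law fit and
#' the delta machinery without expanding to ORF records: abundances are
#' lognormal (or supplied), richness is
#' `max(1, round(c * A^gamma * multiplier * eps))` with lognormal noise of
#' unit median, rounding half away from zero.
#'
#' @param n Number of strata.
#' @param c_s,gamma_s True power-law constants.
#' @param noise_sd Lognormal sd of the richness noise; 0 for on-curve data.
#' @param fpm_meanlog,fpm_sdlog Abundance law.
#' @param multiplier Per-stratum richness multiplier, recycled.
#' @param A Optional explicit abundances (overrides the lognormal draw).
#' @param round_richness Set `FALSE` to keep `d_obs` continuous (exactly on
#'   the curve when `noise_sd = 0`).
#' @param gene Gene label stamped on the output.
#' @param seed Optional seed.
#' @return data.frame `gene`, `A`, `d_obs`, `multiplier`.
#' @export
simulate_strata <- function(n, c_s = 3, gamma_s = 0.4, noise_sd = 0.2,
                            fpm_meanlog = log(80), fpm_sdlog = 1.5,
                            multiplier = 1, A = NULL,
                            round_richness = TRUE, gene = "g1",
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(A)) A <- stats::rlnorm(n, fpm_meanlog, fpm_sdlog)
  A <- rep_len(A, n)
  m <- rep_len(multiplier, n)
  eps <- if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else rep(1, n)
  d <- c_s * A^gamma_s * m * eps
  if (round_richness) d <- pmax(.round_half_up(d), 1)
  data.frame(gene = gene, A = A, d_obs = d, multiplier = m,
             stringsAsFactors = FALSE)
}

#' Simulate a labelled reference tree with query placements
#'
#' Builds a reference tree for one marker with functional and
#' non-functional (paralog) clades, then draws query sequences from chosen
#' clades and places each on a tip of its true clade with a configurable
#' likelihood weight ratio, returning the truth labels alongside.
#'
#' @param gene Marker symbol (used in tip/clade names).
#' @param n_functional,n_non_functional Query counts drawn from the
#'   functional clade(s) and from the paralog clade.
#' @param tips_per_clade Reference tips per clade.
#' @param like_weight Likelihood weight ratio given to each query's true
#'   placement; either a single value (default 1, unambiguous) or a range
#'   `c(lo, hi)` sampled uniformly.
#' @param seed Optional seed.
#' @return list: `tree` (a [reference_tree()]; clades `<gene>-I`,
#'   `<gene>-II` functional, `<gene>-III` non-functional), `placements` (a
#'   [placement_set()]), and `truth` (query_id, clade, status).
#' @export
simulate_placements <- function(gene = "hzsA", n_functional = 10L,
                                n_non_functional = 5L, tips_per_clade = 4L,
                                like_weight = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clades <- paste0(gene, "-", c("I", "II", "III"))
  status <- stats::setNames(c("functional", "functional", "non_functional"),
                            clades)
  tip_sets <- lapply(seq_along(clades), function(i)
    sprintf("%s_ref%s%02d", gene, c("I", "II", "III")[i],
            seq_len(tips_per_clade)))
  nwk <- paste0("(",
    paste(vapply(seq_along(clades), function(i)
      paste0("(", paste(tip_sets[[i]], collapse = ","), ")", clades[i]),
      character(1L)), collapse = ","),
    ")root;")
  tree <- reference_tree(ape::read.tree(text = nwk), status, gene)

  src <- c(rep.int(1:2, c(ceiling(n_functional / 2), floor(n_functional / 2))),
           rep.int(3L, n_non_functional))
  if (length(src) == 0L) {
    return(list(tree = tree,
                placements = placement_set(gene, data.frame(
                  query_id = character(), node = character(),
                  like_weight_ratio = numeric())),
                truth = data.frame(query_id = character(),
                                   clade = character(),
                                   status = character())))
  }
  qid <- sprintf("%s_q%03d", gene, seq_along(src))
  node <- vapply(src, function(i) sample(tip_sets[[i]], 1L), character(1L))
  lwr <- if (length(like_weight) == 2L)
    stats::runif(length(src), like_weight[1L], like_weight[2L]) else
    rep(like_weight, length(src))
  placements <- placement_set(gene, data.frame(
    query_id = qid, node = node, like_weight_ratio = lwr,
    stringsAsFactors = FALSE))
  truth <- data.frame(query_id = qid, clade = clades[src],
                      status = unname(status[clades[src]]),
                      stringsAsFactors = FALSE)
  list(tree = tree, placements = placements, truth = truth)
}
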