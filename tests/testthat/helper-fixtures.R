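# Shared fixtures, built in code.

# minimal well-formed feature table
tiny_feature_table <- function() {
  data.frame(
    orf_id = c("o1", "o2", "o3"),
    gene = c("amt", "nirK", "amt"),
    taxon = c("taxA", "taxB", "taxA"),
    sample_id = c("s1", "s1", "s2"),
    raw_count = c(10, 30, 60),
    stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# strata lying exactly on d = c * A^gamma (A chosen so richness is integer)
on_curve_strata <- function(c_s = 2, gamma_s = 0.5,
                            A = (1:20)^2, gene = "amt") {
  data.frame(gene = gene, taxon = "t", station_class = "average_ocean",
             layer = "epipelagic", context = "average_ocean.epipelagic",
             A = A, d_obs = c_s * A^gamma_s, stringsAsFactors = FALSE)
}

# small cruise configuration: quick to simulate, all layers populated
small_cruise <- function(seed = 42L, ...) {
  sim_config(n_stations = 5L,
             taxa_per_layer = 15L,
             occupancy = 0.5,
             genes = data.frame(gene = c("amt", "nirK", "ureC", "nrtA"),
                                c = c(2, 2.5, 1.8, 2.2),
                                gamma = c(0.45, 0.5, 0.4, 0.35)),
             seed = seed, ...)
}
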