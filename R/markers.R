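#' Nitrogen-cycle marker gene registry
#'
#' The 18 marker genes used to profile nitrogen-cycle guilds, together with
#' their guild class and the process each gene is a marker for.  Guild classes
#' split the cycle into nitrogen acquisition (`N_uptake`: transporters and the
#' branched-amino-acid synthesis marker) and redox transformation of nitrogen
#' species (`N_redox`).  The nitrogen-fixation marker \emph{nifH} is grouped
#' with acquisition, since fixation is the route by which N2 enters the cell's
#' nitrogen pool.
#'
#' @return A data.frame with columns `gene`, `guild_class`
#'   (`"N_uptake"`/`"N_redox"`) and `process`.
#' @examples
#' n_cycle_markers()
#' @export
n_cycle_markers <- function() {
  data.frame(
    gene = c("amt", "nrtA", "nifH", "tauA", "potF", "livJ", "bztA", "ilvC",
             "amoA", "nirK", "ureC", "uca", "nxrA", "nirS", "nasA", "narG",
             "nosZ", "hzsA"),
    guild_class = c(rep("N_uptake", 8L), rep("N_redox", 10L)),
    process = c("ammonium uptake", "nitrate uptake", "nitrogen fixation",
                "taurine uptake", "polyamine uptake",
                "branched-chain amino acid uptake",
                "carboxylated amino acid uptake",
                "branched-chain amino acid synthesis",
                "ammonia oxidation (nitrification)",
                "nitrite reduction (Cu-type, denitrification)",
                "urea hydrolysis", "urea carboxylation",
                "nitrite oxidation", "nitrite reduction (cd1-type)",
                "assimilatory nitrate reduction",
                "dissimilatory nitrate reduction", "nitrous oxide reduction",
                "hydrazine synthase (anammox)"),
    stringsAsFactors = FALSE
  )
}

#' Map genes to guild classes
#'
#' @param genes Character vector of marker symbols.
#' @param guilds Registry data.frame with columns `gene` and `guild_class`;
#'   defaults to [n_cycle_markers()].  Genes absent from the registry map to
#'   `NA`.
#' @return Character vector of guild classes, same length as `genes`.
#' @export
guild_class_of <- function(genes, guilds = n_cycle_markers()) {
  guilds$guild_class[match(genes, guilds$gene)]
}
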