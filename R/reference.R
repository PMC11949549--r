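#' Published summary counts of the three reference connectome datasets
#'
#' Node and edge counts (with printed degree summaries, soma sizes and
#' contact thresholds) for the synaptic and contact layers of the three
#' public volumetric reconstructions the modelling framework targets: the
#' fly hemibrain, the mouse visual-cortex volume and the human temporal-lobe
#' sample. These are summary constants of published datasets, shipped so
#' that in-table arithmetic (mean degree `2E/N`, contact-to-synaptic edge
#' ratios) can be checked without downloading the volumes; the package does
#' not ship the networks themselves.
#'
#' @return data frame with one row per organism x layer.
#' @examples
#' ref <- reference_networks()
#' with(ref[ref$organism == "mouse" & ref$layer == "synaptic", ],
#'      2 * n_edges / n_nodes)  # reproduces the printed mean degree
#' @export
reference_networks <- function() {
  utils::read.csv(system.file("extdata", "reference_networks.csv",
                              package = "neuromaxent"),
                  stringsAsFactors = FALSE)
}
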