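## Bundled example dataset: the published summary tables of a rat model
## of capsaicin-induced sensory neuropathy affecting cardiac miRNA
## expression -- array-level calls for eight selected miRNAs, their
## qRT-PCR validation, the curated miRNA-target interactions of the four
## selected hub targets, and the primer/efficiency registry of the mRNA
## assays.

examplePath <- function(name) {
    p <- system.file("extdata", name, package = "mirTarNet", mustWork = TRUE)
    p
}

#' Example array differential-expression calls
#'
#' Array-level log2 changes (neuropathy vs control), SDs, significance
#' and selection tier for the eight selected miRNAs of the bundled
#' cardiac sensory-neuropathy dataset.
#'
#' @return data.frame with columns \code{mirna}, \code{mean_log2_ratio},
#'   \code{sd_log2}, \code{significant}, \code{direction}, \code{tier}.
#' @export
exampleArrayCalls <- function() {
    read.delim(examplePath("example_array_de.tsv"), stringsAsFactors = FALSE)
}

#' Example qRT-PCR validation results
#'
#' qRT-PCR log2 changes, signed fold changes, significance and detection
#' status for the same eight miRNAs (miR-344b did not amplify: "n.d.").
#'
#' @return data.frame with columns \code{mirna},
#'   \code{mean_log2_change}, \code{sd_log2}, \code{fold_change},
#'   \code{significant}, \code{detected}, \code{direction}.
#' @export
exampleQpcrValidation <- function() {
    read.delim(examplePath("example_qpcr_validation.tsv"),
               stringsAsFactors = FALSE)
}

#' Example curated miRNA-target interactions
#'
#' The twelve interactions linking six down-regulated miRNAs to the four
#' selected hub target genes (IGF-1, SLC2a-12, EIF-4e, ULK-2).
#'
#' @return data.frame with columns \code{mirna}, \code{target}.
#' @export
exampleMtiEdges <- function() {
    read.delim(examplePath("example_mti_edges.tsv"), stringsAsFactors = FALSE)
}

#' Example primer/assay registry
#'
#' Primer pairs, amplification efficiencies and product sizes for the
#' four target genes and the GAPDH reference.
#'
#' @return data.frame (see [readPrimerAssays()]).
#' @export
examplePrimerAssays <- function() {
    readPrimerAssays(examplePath("example_primer_assays.tsv"))
}
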