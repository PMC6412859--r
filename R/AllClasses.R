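#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats approx dnorm integrate lowess median optim pnorm pt
#'   qexp quantile rexp rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Two-color miRNA array container
#'
#' An extension of \linkS4class{SummarizedExperiment} holding per-probe
#' foreground intensities of a two-color miRNA array experiment: one
#' \code{"sample"} assay (Hy3-labelled sample channel) and one
#' \code{"reference"} assay (Hy5-labelled common-reference channel), both
#' probe x array matrices.  \code{colData} must carry a \code{group} column
#' with values \code{"control"} or \code{"neuropathy"}.  Background
#' correction and normalization add further assays (\code{sampleBg},
#' \code{referenceBg}, \code{M}, \code{A}, \code{Mnorm}).
#'
#' @slot .  See \linkS4class{SummarizedExperiment}.
#' @seealso [MirArrayExperiment()], [readArrayTable()],
#'   [backgroundCorrectArrays()], [normalizeArrays()]
#' @export
setClass("MirArrayExperiment", contains = "SummarizedExperiment")

setValidity("MirArrayExperiment", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("sample", "reference") %in% an))
        msg <- c(msg, "assays 'sample' and 'reference' are required")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else if (!all(cd$group %in% c("control", "neuropathy"))) {
        msg <- c(msg, "group values must be 'control' or 'neuropathy'")
    }
    if (all(c("sample", "reference") %in% an)) {
        raw <- cbind(SummarizedExperiment::assay(object, "sample"),
                     SummarizedExperiment::assay(object, "reference"))
        if (any(raw < 0, na.rm = TRUE))
            msg <- c(msg, "foreground intensities must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MirArrayExperiment
#'
#' @param sample,reference probe x array matrices of foreground intensities
#'   for the sample (Hy3) and common-reference (Hy5) channels; identical
#'   dimnames required.
#' @param group character/factor of length \code{ncol(sample)} with values
#'   \code{"control"} or \code{"neuropathy"}.
#' @return A \linkS4class{MirArrayExperiment}.
#' @examples
#' s <- matrix(rexp(20, 1/500) + 100, 10, 2,
#'             dimnames = list(paste0("mir-", 1:10), c("a1", "a2")))
#' mae <- MirArrayExperiment(s, s, group = c("control", "neuropathy"))
#' @export
MirArrayExperiment <- function(sample, reference, group) {
    stopifnot(is.matrix(sample), is.matrix(reference),
              identical(dim(sample), dim(reference)))
    group <- as.character(group)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(sample = sample, reference = reference),
        colData = S4Vectors::DataFrame(
            array_id = colnames(sample), group = group,
            row.names = colnames(sample)))
    new("MirArrayExperiment", se)
}

#' @describeIn MirArrayExperiment group assignment of each array
#' @param x a \code{MirArrayExperiment}
#' @export
arrayGroups <- function(x) {
    stopifnot(is(x, "SummarizedExperiment"))
    setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x))
}

setMethod("show", "MirArrayExperiment", function(object) {
    callNextMethod()
    g <- table(arrayGroups(object))
    cat("arrays per group:",
        paste(names(g), g, sep = "=", collapse = ", "), "\n")
})

#' Bipartite miRNA-target network
#'
#' Edges connect miRNA nodes to target-gene nodes; each (miRNA, target)
#' pair appears once regardless of how many interaction sources support
#' it, with the supporting sources kept as provenance.  miRNA nodes carry
#' a regulation direction (\code{"up"}/\code{"down"}) from the expression
#' analysis.
#'
#' @slot edges data.frame with columns \code{mirna}, \code{target},
#'   \code{sources} (";"-collapsed supporting source tags) and
#'   \code{scores} (";"-collapsed retained scores, \code{NA} for validated
#'   records).
#' @slot mirnaDirections named character vector, direction per miRNA node.
#' @seealso [buildNetwork()], [findHubs()], [exportNetwork()]
#' @export
setClass("BipartiteNetwork",
         representation(edges = "data.frame",
                        mirnaDirections = "character"))

setValidity("BipartiteNetwork", function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("mirna", "target", "sources", "scores") %in% colnames(e)))
        msg <- c(msg, "edges need columns mirna, target, sources, scores")
    if (nrow(e) && anyDuplicated(paste(e$mirna, e$target, sep = "\r")))
        msg <- c(msg, "duplicate (mirna, target) edges")
    if (nrow(e) && length(intersect(e$mirna, e$target)))
        msg <- c(msg, "network not bipartite: shared mirna/target names")
    if (nrow(e) && !all(e$mirna %in% names(object@mirnaDirections)))
        msg <- c(msg, "every edge miRNA needs a direction")
    if (length(object@mirnaDirections) &&
        !all(object@mirnaDirections %in% c("up", "down")))
        msg <- c(msg, "directions must be 'up' or 'down'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BipartiteNetwork", function(object) {
    cat("BipartiteNetwork:", length(mirnaNodes(object)), "miRNAs,",
        length(targetNodes(object)), "targets,",
        nrow(object@edges), "edges\n")
})

#' @describeIn BipartiteNetwork edge table (one row per unique pair)
#' @param x a \code{BipartiteNetwork}
#' @export
networkEdges <- function(x) x@edges

#' @describeIn BipartiteNetwork miRNA node names
#' @export
mirnaNodes <- function(x) sort(unique(x@edges$mirna))

#' @describeIn BipartiteNetwork target node names
#' @export
targetNodes <- function(x) sort(unique(x@edges$target))

#' @describeIn BipartiteNetwork direction attached to each miRNA node
#' @export
mirnaDirections <- function(x) x@mirnaDirections

#' @describeIn BipartiteNetwork number of distinct regulating miRNAs per
#'   target (named integer, decreasing)
#' @export
targetDegree <- function(x) {
    if (!nrow(x@edges)) return(setNames(integer(0), character(0)))
    d <- vapply(split(x@edges$mirna, x@edges$target),
                function(m) length(unique(m)), integer(1))
    d[order(-d, names(d))]
}
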