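## miRNA-target interaction (MTI) integration: source dialects, score
## filters, bipartite network construction, hub-target selection and
## predicted direction of target mRNA change.

.DIALECTS <- c("predicted_high_good", "predicted_low_good", "validated")

#' Read one MTI source table
#'
#' TSV with columns \code{mirna}, \code{target} and, for predicted
#' dialects, \code{score}.  Three dialects are supported, mirroring the
#' three classes of public MTI databases: \code{"predicted_high_good"}
#' (confidence score, higher is better, miRDB-style),
#' \code{"predicted_low_good"} (regression score, more negative is
#' stronger, mirSVR-style) and \code{"validated"} (experimentally
#' supported, no score required, miRTarBase-style).  Malformed rows
#' (missing miRNA/target, or a predicted row without a score) are
#' skipped; the number skipped is attached as attribute
#' \code{"n_rejected"}.
#'
#' @param path TSV path.
#' @param dialect one of the three dialect tags.
#' @param species optional species tag attached to every record.
#' @return data.frame with columns \code{mirna}, \code{target},
#'   \code{source}, \code{score}, \code{species}.
#' @export
readMtiTable <- function(path, dialect, species = NA_character_) {
    if (!dialect %in% .DIALECTS)
        stop("unknown dialect '", dialect, "'; expected one of: ",
             paste(.DIALECTS, collapse = ", "))
    tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if (!all(c("mirna", "target") %in% colnames(tab)))
        stop("MTI table needs columns mirna, target")
    if (!"score" %in% colnames(tab)) tab$score <- NA_real_
    tab$score <- suppressWarnings(as.numeric(tab$score))
    bad <- is.na(tab$mirna) | tab$mirna == "" |
           is.na(tab$target) | tab$target == ""
    if (dialect != "validated") bad <- bad | is.na(tab$score)
    if (any(bad))
        message(sum(bad), " malformed row(s) rejected from ", basename(path))
    out <- data.frame(mirna = tab$mirna[!bad], target = tab$target[!bad],
                      source = rep(dialect, sum(!bad)),
                      score = tab$score[!bad],
                      species = rep(species, sum(!bad)),
                      stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- sum(bad)
    out
}

#' Load several MTI sources
#'
#' @param paths character vector of TSV paths.
#' @param dialects dialect tag per file (recycled names allowed).
#' @param species optional species tag.
#' @return Combined record data.frame; attribute \code{"n_rejected"}
#'   totals skipped rows.
#' @export
loadMtiSources <- function(paths, dialects, species = NA_character_) {
    stopifnot(length(paths) == length(dialects))
    tabs <- Map(readMtiTable, paths, dialects,
                MoreArgs = list(species = species))
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    attr(out, "n_rejected") <- as.integer(
        sum(vapply(tabs, attr, 0, "n_rejected")))
    out
}

#' Filter MTI records by score thresholds
#'
#' Removes poor predictions: high-good records are kept only with score
#' strictly above \code{highGoodMin} (default 80.0, i.e. scores <= 80.0
#' removed) and low-good records only with score strictly below
#' \code{lowGoodMax} (default -1.2, i.e. scores >= -1.2 removed).
#' Validated records are exempt from score thresholds.
#'
#' @param records MTI record data.frame (see [readMtiTable()]).
#' @param highGoodMin exclusive lower bound for high-good scores.
#' @param lowGoodMax exclusive upper bound for low-good scores.
#' @return The retained records.
#' @export
filterMti <- function(records, highGoodMin = 80.0, lowGoodMax = -1.2) {
    keep <- rep(TRUE, nrow(records))
    hg <- records$source == "predicted_high_good"
    lg <- records$source == "predicted_low_good"
    keep[hg] <- records$score[hg] > highGoodMin
    keep[lg] <- records$score[lg] < lowGoodMax
    records[keep, , drop = FALSE]
}

## case-insensitive miRNA name matching; mature-arm suffix must match as
## typed (lower-cased along with the rest)
.mirKey <- function(x) tolower(x)

#' Build the bipartite miRNA-target network
#'
#' Union semantics across sources: one edge per distinct (miRNA, target)
#' pair, with provenance listing every supporting source and its
#' retained score.  Records whose miRNA has no entry in
#' \code{directions} are dropped with a message.  miRNA matching is
#' case-insensitive.
#'
#' @param records retained MTI records (see [filterMti()]).
#' @param directions named character vector, \code{"up"}/\code{"down"}
#'   per differentially expressed miRNA.
#' @return A \linkS4class{BipartiteNetwork}.
#' @export
buildNetwork <- function(records, directions) {
    stopifnot(all(directions %in% c("up", "down")))
    names(directions) <- names(directions)
    dirKey <- setNames(as.character(directions), .mirKey(names(directions)))
    canonical <- setNames(names(directions), .mirKey(names(directions)))
    known <- .mirKey(records$mirna) %in% names(dirKey)
    if (any(!known))
        message(sum(!known), " record(s) dropped: miRNA not in direction map")
    rec <- records[known, , drop = FALSE]
    if (!nrow(rec)) {
        return(new("BipartiteNetwork",
                   edges = data.frame(mirna = character(), target = character(),
                                      sources = character(), scores = character(),
                                      stringsAsFactors = FALSE),
                   mirnaDirections = setNames(character(0), character(0))))
    }
    rec$mirna <- canonical[.mirKey(rec$mirna)]
    key <- paste(rec$mirna, rec$target, sep = "\r")
    agg <- lapply(split(seq_len(nrow(rec)), key), function(i) {
        o <- order(rec$source[i])
        data.frame(mirna = rec$mirna[i][1], target = rec$target[i][1],
                   sources = paste(unique(rec$source[i][o]), collapse = ";"),
                   scores = paste(rec$score[i][o], collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, agg)
    edges <- edges[order(edges$mirna, edges$target), ]
    rownames(edges) <- NULL
    dirs <- setNames(dirKey[.mirKey(unique(edges$mirna))],
                     unique(edges$mirna))
    new("BipartiteNetwork", edges = edges, mirnaDirections = dirs)
}

#' Find hub targets and predict their direction of change
#'
#' A hub is a target gene regulated by at least \code{minDegree}
#' distinct differentially expressed miRNAs (default 3).  Since miRNAs
#' repress their targets, a hub whose regulators are all down-regulated
#' is predicted up-regulated and vice versa; mixed regulator directions
#' give \code{"ambiguous"} under the default unanimity rule, or follow
#' the majority when \code{rule = "majority"} and the majority fraction
#' reaches \code{majorityFraction}.
#'
#' @param network a \linkS4class{BipartiteNetwork}.
#' @param minDegree minimum number of distinct regulating miRNAs.
#' @param rule \code{"unanimity"} (default) or \code{"majority"}.
#' @param majorityFraction required fraction for the majority rule.
#' @return data.frame sorted by degree (decreasing) then name:
#'   \code{target}, \code{degree}, \code{regulators} (";"-collapsed),
#'   \code{predicted_direction}.
#' @export
findHubs <- function(network, minDegree = 3,
                     rule = c("unanimity", "majority"),
                     majorityFraction = 0.5) {
    rule <- match.arg(rule)
    stopifnot(is(network, "BipartiteNetwork"), minDegree >= 1)
    deg <- targetDegree(network)
    hubs <- names(deg)[deg >= minDegree]
    if (!length(hubs))
        return(data.frame(target = character(), degree = integer(),
                          regulators = character(),
                          predicted_direction = character(),
                          stringsAsFactors = FALSE))
    e <- networkEdges(network)
    dirs <- mirnaDirections(network)
    out <- do.call(rbind, lapply(hubs, function(h) {
        regs <- sort(unique(e$mirna[e$target == h]))
        rd <- dirs[regs]
        if (any(is.na(rd)))
            stop("regulator without direction for target '", h, "'")
        data.frame(target = h, degree = length(regs),
                   regulators = paste(regs, collapse = ";"),
                   predicted_direction =
                       predictTargetDirection(rd, rule, majorityFraction),
                   stringsAsFactors = FALSE)
    }))
    out <- out[order(-out$degree, out$target), ]
    rownames(out) <- NULL
    out
}

#' Predict a target's direction of change from its regulators
#'
#' @param regulatorDirections character vector of \code{"up"}/\code{"down"}
#'   regulator directions.
#' @param rule,majorityFraction see [findHubs()].
#' @return \code{"up"}, \code{"down"} or \code{"ambiguous"}.
#' @export
predictTargetDirection <- function(regulatorDirections,
                                   rule = c("unanimity", "majority"),
                                   majorityFraction = 0.5) {
    rule <- match.arg(rule)
    d <- regulatorDirections
    if (!length(d) || any(is.na(d)) || !all(d %in% c("up", "down")))
        stop("every regulator needs an 'up' or 'down' direction")
    fracDown <- mean(d == "down")
    if (rule == "unanimity") {
        if (fracDown == 1) "up" else if (fracDown == 0) "down"
        else "ambiguous"
    } else {
        if (fracDown > majorityFraction) "up"
        else if (1 - fracDown > majorityFraction) "down"
        else "ambiguous"
    }
}

#' Export a bipartite network (node/edge TSV, SIF, GraphML)
#'
#' Writes Cytoscape-ready files: a node table (id, kind, direction,
#' degree, is_hub), an edge table (mirna, target, provenance, scores), a
#' SIF file with relation \code{targets}, and GraphML.  A GraphML
#' round-trip through [readNetworkGraphml()] reproduces the network.
#'
#' @param network a \linkS4class{BipartiteNetwork}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"network"}).
#' @param hubs optional hub table from [findHubs()] to flag hub nodes.
#' @param header optional comment line for the TSVs.
#' @return Invisibly, named vector of written paths.
#' @export
exportNetwork <- function(network, dir, prefix = "network", hubs = NULL,
                          header = NULL) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    e <- networkEdges(network)
    deg <- targetDegree(network)
    dirs <- mirnaDirections(network)
    mns <- mirnaNodes(network)
    tns <- targetNodes(network)
    mirnaDeg <- if (nrow(e))
        vapply(split(e$target, e$mirna), function(t) length(unique(t)),
               integer(1)) else setNames(integer(0), character(0))
    nodes <- data.frame(
        id = c(mns, tns),
        kind = rep(c("mirna", "target"), c(length(mns), length(tns))),
        direction = c(unname(dirs[mns]), rep(NA_character_, length(tns))),
        degree = c(unname(mirnaDeg[mns]), unname(deg[tns])),
        is_hub = c(rep(FALSE, length(mns)),
                   if (is.null(hubs)) rep(FALSE, length(tns))
                   else tns %in% hubs$target),
        stringsAsFactors = FALSE)
    paths <- c(nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
               edges = file.path(dir, paste0(prefix, "_edges.tsv")),
               sif = file.path(dir, paste0(prefix, ".sif")),
               graphml = file.path(dir, paste0(prefix, ".graphml")))
    writeTsv(nodes, paths["nodes"], header)
    writeTsv(e, paths["edges"], header)
    writeLines(if (nrow(e)) paste(e$mirna, "targets", e$target, sep = "\t")
               else character(0), paths["sif"])
    igraph::write_graph(asIgraph(network), paths["graphml"],
                        format = "graphml")
    invisible(paths)
}

#' Convert a BipartiteNetwork to an igraph graph
#'
#' Vertices carry \code{kind} and \code{direction} attributes, edges
#' carry \code{sources} and \code{scores}.
#'
#' @param network a \linkS4class{BipartiteNetwork}.
#' @return An \code{igraph} graph.
#' @export
asIgraph <- function(network) {
    e <- networkEdges(network)
    mns <- mirnaNodes(network)
    tns <- targetNodes(network)
    verts <- data.frame(
        name = c(mns, tns),
        kind = rep(c("mirna", "target"), c(length(mns), length(tns))),
        direction = c(unname(mirnaDirections(network)[mns]),
                      rep("", length(tns))),
        stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(
        e[, c("mirna", "target", "sources", "scores")],
        directed = FALSE, vertices = verts)
}

#' Read a network back from GraphML
#'
#' @param path GraphML file written by [exportNetwork()].
#' @return A \linkS4class{BipartiteNetwork}.
#' @export
readNetworkGraphml <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    vd <- igraph::as_data_frame(g, what = "vertices")
    if (!nrow(ed)) {
        return(new("BipartiteNetwork",
                   edges = data.frame(mirna = character(), target = character(),
                                      sources = character(), scores = character(),
                                      stringsAsFactors = FALSE),
                   mirnaDirections = setNames(character(0), character(0))))
    }
    mirs <- vd$name[vd$kind == "mirna"]
    flip <- !(ed$from %in% mirs)
    edges <- data.frame(mirna = ifelse(flip, ed$to, ed$from),
                        target = ifelse(flip, ed$from, ed$to),
                        sources = ed$sources, scores = ed$scores,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$mirna, edges$target), ]
    rownames(edges) <- NULL
    dirs <- setNames(vd$direction[vd$kind == "mirna"], mirs)
    new("BipartiteNetwork", edges = edges,
        mirnaDirections = dirs[sort(unique(edges$mirna))])
}
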