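## I/O for two-color array intensity tables (long TSV) and array metadata.

.CHANNELS <- c(sample = "sample_Hy3", reference = "reference_Hy5")

#' Read a two-color array intensity table
#'
#' Reads a long-format intensity TSV (columns \code{probe_id},
#' \code{array_id}, \code{channel}, \code{foreground}; channel values
#' \code{sample_Hy3} / \code{reference_Hy5}) together with an array
#' metadata TSV (columns \code{array_id}, \code{group}) into a
#' \linkS4class{MirArrayExperiment}.  Every (probe, array, channel)
#' combination may appear at most once.
#'
#' @param intensityFile path to the intensity TSV.
#' @param metadataFile path to the array metadata TSV.
#' @return A \linkS4class{MirArrayExperiment}.
#' @export
readArrayTable <- function(intensityFile, metadataFile) {
    tab <- read.delim(intensityFile, stringsAsFactors = FALSE,
                      comment.char = "#")
    meta <- read.delim(metadataFile, stringsAsFactors = FALSE,
                       comment.char = "#")
    need <- c("probe_id", "array_id", "channel", "foreground")
    if (!all(need %in% colnames(tab)))
        stop("intensity table needs columns: ", paste(need, collapse = ", "))
    if (!all(c("array_id", "group") %in% colnames(meta)))
        stop("metadata needs columns array_id, group")
    if (!all(tab$channel %in% .CHANNELS))
        stop("unknown channel values; expected ",
             paste(.CHANNELS, collapse = ", "))
    key <- paste(tab$probe_id, tab$array_id, tab$channel, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicated (probe, array, channel) rows in intensity table")
    arrays <- meta$array_id
    probes <- sort(unique(tab$probe_id))
    mk <- function(chan) {
        sub <- tab[tab$channel == chan, ]
        m <- matrix(NA_real_, length(probes), length(arrays),
                    dimnames = list(probes, arrays))
        m[cbind(match(sub$probe_id, probes), match(sub$array_id, arrays))] <-
            sub$foreground
        m
    }
    MirArrayExperiment(mk(.CHANNELS["sample"]), mk(.CHANNELS["reference"]),
                       group = meta$group)
}

#' Write a MirArrayExperiment back to long intensity + metadata TSVs
#'
#' @param mae a \linkS4class{MirArrayExperiment}.
#' @param intensityFile,metadataFile output paths.
#' @param header optional comment line (e.g. a config hash) written atop
#'   each file.
#' @return Invisibly, the two paths.
#' @export
writeArrayTable <- function(mae, intensityFile, metadataFile, header = NULL) {
    long <- do.call(rbind, lapply(names(.CHANNELS), function(ch) {
        m <- SummarizedExperiment::assay(mae, ch)
        data.frame(probe_id = rep(rownames(m), ncol(m)),
                   array_id = rep(colnames(m), each = nrow(m)),
                   channel = .CHANNELS[[ch]],
                   foreground = as.vector(m))
    }))
    meta <- data.frame(array_id = colnames(mae), group = arrayGroups(mae))
    writeTsv(long, intensityFile, header)
    writeTsv(meta, metadataFile, header)
    invisible(c(intensityFile, metadataFile))
}

## shared TSV writer; optional "# ..." header comment line
writeTsv <- function(df, path, header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
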