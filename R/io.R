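#' Write intervals and values as bedGraph
#'
#' Writes one record per interval (chrom, 0-based start, end, value).
#' Integer-valued scores are written without a decimal point, so repeated
#' runs produce byte-identical files.
#'
#' @param gr `GRanges` of intervals.
#' @param values Numeric vector, one per interval.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeBedGraph <- function(gr, values, file) {
    stopifnot(length(gr) == length(values))
    val <- ifelse(values == round(values), format(values, trim = TRUE,
                                                  scientific = FALSE),
                  formatC(values, digits = 6, format = "g"))
    lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   val, sep = "\t")
    writeLines(lines, file)
    invisible(file)
}

#' Write intervals as BED6
#'
#' @param gr `GRanges`; optional `mcols()` columns `name` and `score` are
#'   used for the corresponding BED fields (names(gr) serve as a fallback
#'   for `name`).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeBed <- function(gr, file) {
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
          else if (!is.null(names(gr))) names(gr)
          else rep(".", length(gr))
    sc <- if (!is.null(mcols(gr)$score))
              formatC(mcols(gr)$score, digits = 4, format = "g")
          else rep("0", length(gr))
    lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   nm, sc, rep(".", length(gr)), sep = "\t")
    writeLines(lines, file)
    invisible(file)
}

#' Read a BED file as GRanges
#'
#' Thin wrapper over [rtracklayer::import()]; BED name fields carrying
#' comma-separated gene identifiers land in `mcols()$name`.
#'
#' @param file Path to a BED file.
#' @return A `GRanges`.
#' @export
readBed <- function(file) {
    rtracklayer::import(file, format = "BED")
}

#' Write a gene set, one identifier per line
#'
#' @param ids Character vector.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeGeneSet <- function(ids, file) {
    writeLines(as.character(ids), file)
    invisible(file)
}

#' Write a binned-signal matrix as TSV
#'
#' Columns: `chrom`, `start` (0-based), `end`, then one column per sample.
#'
#' @param x A [BinnedSignal].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeBinMatrix <- function(x, file) {
    bins <- rowRanges(x)
    df <- data.frame(chrom = as.character(seqnames(bins)),
                     start = start(bins) - 1L, end = end(bins),
                     assay(x, "values"), check.names = FALSE)
    colnames(df)[-(1:3)] <- colData(x)$sample_id
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a sample sheet TSV
#'
#' Expects columns `sample_id`, `condition`, `replicate`, `role`, and
#' optionally `file` (track path, resolved relative to the sheet's
#' directory).
#'
#' @param file Path to a TSV.
#' @return A `data.frame`.
#' @export
readSampleSheet <- function(file) {
    sheet <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "replicate", "role")
    if (!all(need %in% colnames(sheet)))
        stop("sample sheet must contain columns: ",
             paste(need, collapse = ", "))
    if ("file" %in% colnames(sheet)) {
        rel <- !file.exists(sheet$file)
        sheet$file[rel] <- file.path(dirname(file), sheet$file[rel])
    }
    sheet
}
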