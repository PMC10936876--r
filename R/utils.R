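#' Derive a stage-specific seed from a global seed
#'
#' Each pipeline stage draws its random numbers under a seed derived
#' deterministically from the global seed and the stage name, so a stage can
#' be rerun in isolation and reproduce exactly what it did inside the full
#' pipeline.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @examples
#' stageSeed(1L, "coverage")
#' @export
stageSeed <- function(seed, stage) {
    stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
    h <- as.numeric(seed) %% 2147483647
    for (code in utf8ToInt(stage))
        h <- (h * 131 + code) %% 2147483647
    as.integer(h)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                          openLower = FALSE, openUpper = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
        (if (openLower) x > lower else x >= lower) &&
        (if (openUpper) x < upper else x <= upper)
    if (!ok)
        stop(sprintf("'%s' must be a single number in %s%s, %s%s", name,
                     if (openLower) "(" else "[", format(lower),
                     format(upper), if (openUpper) ")" else "]"),
             call. = FALSE)
    invisible(x)
}

# sort a GRanges by (seqlevel order, start); keeps mcols
.sortGR <- function(gr) {
    gr[order(as.integer(seqnames(gr)), start(gr))]
}

# row variances with one delta degree of freedom, no extra deps
.rowVars <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (n - 1L)
}

.splitGeneIds <- function(x) {
    strsplit(as.character(x), ",", fixed = TRUE)
}
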