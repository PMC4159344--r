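## Internal helpers shared across modules.

## Deterministic child seed: splits one user seed into independent streams so
## that e.g. adding a fourth co-culture replicate leaves replicates 1-3
## bit-identical. Values stay below 2^31.
childSeed <- function(seed, stream) {
    as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(stream) * 8191 + 1) %% 2147483647)
}

## Validate a probes x samples expression matrix.
checkExpressionMatrix <- function(x, what = "expression matrix") {
    if (!is.matrix(x) || !is.numeric(x))
        stop(what, " must be a numeric matrix", call. = FALSE)
    if (is.null(rownames(x)))
        stop(what, " must have probe identifiers as rownames", call. = FALSE)
    dup <- rownames(x)[duplicated(rownames(x))]
    if (length(dup))
        stop(what, " has duplicate probe identifiers: ",
             paste(unique(dup), collapse = ", "), call. = FALSE)
    if (!all(is.finite(x)))
        stop(what, " contains non-finite values", call. = FALSE)
    if (any(x < 0))
        stop(what, " contains negative intensities", call. = FALSE)
    invisible(x)
}

## Coerce a single-sample profile (named vector or 1-column matrix) to a
## named numeric vector.
asProfile <- function(x, what = "profile") {
    if (is.matrix(x)) {
        if (ncol(x) != 1L)
            stop(what, " must be a single-sample profile", call. = FALSE)
        v <- x[, 1L]
        names(v) <- rownames(x)
        x <- v
    }
    if (!is.numeric(x) || is.null(names(x)))
        stop(what, " must be a named numeric vector or 1-column matrix",
             call. = FALSE)
    x
}

## Error if two profiles/matrices do not share the identical probe set,
## listing offending probes.
checkSharedProbes <- function(a, b, whatA = "A", whatB = "B") {
    pa <- if (is.matrix(a)) rownames(a) else names(a)
    pb <- if (is.matrix(b)) rownames(b) else names(b)
    if (identical(pa, pb)) return(invisible(TRUE))
    offending <- c(setdiff(pa, pb), setdiff(pb, pa))
    if (length(offending))
        stop("probe-set mismatch between ", whatA, " and ", whatB, ": ",
             paste(utils::head(offending, 10L), collapse = ", "),
             if (length(offending) > 10L) ", ...", call. = FALSE)
    stop("probes of ", whatA, " and ", whatB,
         " are in different orders; reorder to a shared probe order",
         call. = FALSE)
}

probeIds <- function(n) sprintf("P%05d", seq_len(n))

## FNV-1a hash of a character scalar; plumbing for output provenance headers.
configHash <- function(x) {
    bytes <- utf8ToInt(paste(x, collapse = "\n"))
    h <- 2166136261
    for (b in bytes) {
        h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
        h <- (h * 16777619) %% 2^31
    }
    sprintf("%08x", as.integer(h))
}
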