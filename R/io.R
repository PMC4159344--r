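## File formats: TSV expression matrices (first column = probe ID, header row
## of sample IDs, '.' decimal mark, full double precision), GEO series-matrix
## text, ELDA CSV (dose,tested,negative[,group]) and Ct CSV (sample,gene,ct).
## Lines starting with '#' are provenance comments and are skipped on read.

#' Read an expression matrix from TSV
#'
#' First column: probe identifiers; header row: sample identifiers; body:
#' numeric linear-scale intensities. Ragged rows, duplicate probe identifiers
#' and non-numeric cells are rejected with their location.
#'
#' @param path file path.
#' @return probes x samples numeric matrix.
#' @export
readExpressionTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                              quote = "\"")
    nf <- nf[!is.na(nf)]
    if (length(unique(nf)) > 1L)
        stop("ragged rows in ", path, ": rows have ",
             paste(unique(nf), collapse = ", "), " fields")
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            colClasses = "character", quote = "\"")
    if (ncol(df) < 2L)
        stop("expected a probe column plus at least one sample column in ",
             path)
    probes <- df[[1L]]
    dup <- which(duplicated(probes))
    if (length(dup))
        stop("duplicate probe identifier '", probes[dup[1L]],
             "' at data row ", dup[1L], " of ", path)
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                   dimnames = list(probes, colnames(vals))))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric value '", vals[bad[1L, 1L], bad[1L, 2L]],
             "' at data row ", bad[1L, 1L], ", column '",
             colnames(vals)[bad[1L, 2L]], "' of ", path)
    checkExpressionMatrix(num, paste0("matrix read from ", path))
    num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionTsv()]; doubles are written with 17 significant
#' digits so a write/read round trip is bit-exact.
#'
#' @param x probes x samples numeric matrix.
#' @param path output path.
#' @param probeColumn header label of the probe column (default
#'   \code{"probe"}).
#' @param comments optional character vector written as leading \code{"# "}
#'   comment lines (provenance headers).
#' @return \code{path}, invisibly.
#' @export
writeExpressionTsv <- function(x, path, probeColumn = "probe",
                               comments = NULL) {
    checkExpressionMatrix(x, "x")
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments))
        writeLines(paste0("# ", comments), con)
    writeLines(paste(c(probeColumn, colnames(x)), collapse = "\t"), con)
    body <- apply(x, 1L, function(row)
        paste(sprintf("%.17g", row), collapse = "\t"))
    writeLines(paste(rownames(x), body, sep = "\t"), con)
    invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the table between the \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end} markers into an expression matrix and
#' preserves the \code{!}-prefixed metadata lines as a named sidecar map.
#'
#' @param path path to a series-matrix text file.
#' @return list with \code{matrix} (probes x samples) and \code{metadata}
#'   (named list of character vectors, one element per metadata key).
#' @export
readGeoSeriesMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
        stop("missing or malformed series-matrix table markers in ", path)
    metaLines <- grep("^!", lines[-(begin:end)], value = TRUE)
    metadata <- list()
    for (ln in metaLines) {
        parts <- strsplit(sub("^!", "", ln), "\t", fixed = TRUE)[[1L]]
        key <- parts[1L]
        val <- gsub('^"|"$', "", parts[-1L])
        metadata[[key]] <- c(metadata[[key]], val)
    }
    tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                             header = TRUE, sep = "\t", quote = "\"",
                             check.names = FALSE, colClasses = "character")
    probes <- tab[[1L]]
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                   dimnames = list(probes, colnames(vals))))
    if (anyNA(num))
        stop("non-numeric value inside the series-matrix table of ", path)
    checkExpressionMatrix(num, paste0("series matrix from ", path))
    list(matrix = num, metadata = metadata)
}

#' Read/write ELDA plate CSV
#'
#' CSV with columns \code{dose,tested,negative} and an optional \code{group}
#' column; on read, one \linkS4class{EldaPlate} per group.
#'
#' @param path file path.
#' @return for \code{readEldaCsv}, a list of \linkS4class{EldaPlate} (one per
#'   group, single-element list when no group column is present).
#' @export
readEldaCsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    need <- c("dose", "tested", "negative")
    if (!all(need %in% names(df)))
        stop("ELDA CSV must have columns dose,tested,negative: ", path)
    if (!"group" %in% names(df)) df$group <- ""
    lapply(split(df, df$group), function(g)
        eldaPlate(g$dose, g$tested, g$negative, groupLabel = g$group[1L]))
}

#' @rdname readEldaCsv
#' @param plates an \linkS4class{EldaPlate} or list of them.
#' @param comments optional leading \code{"# "} comment lines.
#' @export
writeEldaCsv <- function(plates, path, comments = NULL) {
    if (is(plates, "EldaPlate")) plates <- list(plates)
    rows <- do.call(rbind, lapply(plates, function(p)
        data.frame(dose = p@doses, tested = p@tested, negative = p@negative,
                   group = p@groupLabel)))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read/write Ct CSV
#'
#' CSV with columns \code{sample,gene,ct}.
#'
#' @param path file path.
#' @param refGene,scaleUnits,collapse passed to [ctTable()].
#' @return for \code{readCtCsv}, a \linkS4class{CtTable}.
#' @export
readCtCsv <- function(path, refGene = "GAPDH", scaleUnits = 10000,
                      collapse = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("sample", "gene", "ct") %in% names(df)))
        stop("Ct CSV must have columns sample,gene,ct: ", path)
    ctTable(df, refGene = refGene, scaleUnits = scaleUnits,
            collapse = collapse)
}

#' @rdname readCtCsv
#' @param ct a \linkS4class{CtTable}.
#' @param comments optional leading \code{"# "} comment lines.
#' @export
writeCtCsv <- function(ct, path, comments = NULL) {
    stopifnot(is(ct, "CtTable"))
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    utils::write.csv(ct@data, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write ground truth of a simulation
#'
#' TSV of (probe, effect_log2) for the interaction genes plus a flat
#' key-value metadata sidecar recording alpha, noise, replicate count and
#' seed.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output TSV path; the sidecar goes to \code{<path>.meta}.
#' @return \code{path}, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
    stopifnot(is(truth, "SimTruth"))
    df <- data.frame(probe = truth@interactionGenes,
                     effect_log2 = unname(
                         truth@perGeneEffect[truth@interactionGenes]))
    con <- file(path, "w")
    writeLines("probe\teffect_log2", con)
    if (nrow(df))
        writeLines(paste(df$probe, sprintf("%.17g", df$effect_log2),
                         sep = "\t"), con)
    close(con)
    cfg <- truth@config
    meta <- c(alpha_true = sprintf("%.17g", truth@alphaTrue),
              n_genes = cfg@nGenes, baseline_log_mean = cfg@baselineLogMean,
              baseline_log_sd = cfg@baselineLogSd,
              between_celltype_sd = cfg@betweenCelltypeSd,
              noise_log_sd = cfg@noiseLogSd, n_replicates = cfg@nReplicates,
              seed = cfg@seed)
    writeLines(paste(names(meta), meta, sep = " = "), paste0(path, ".meta"))
    invisible(path)
}

#' Read simulation ground truth written by [writeSimTruth()]
#'
#' @param path TSV path (sidecar expected at \code{<path>.meta}).
#' @return list with \code{effects} (named numeric vector) and \code{meta}
#'   (named character vector).
#' @export
readSimTruth <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    effects <- df$effect_log2
    names(effects) <- df$probe
    meta <- character(0)
    metaPath <- paste0(path, ".meta")
    if (file.exists(metaPath)) {
        kv <- strsplit(readLines(metaPath), " = ", fixed = TRUE)
        meta <- vapply(kv, `[`, character(1), 2L)
        names(meta) <- vapply(kv, `[`, character(1), 1L)
    }
    list(effects = effects, meta = meta)
}

formatExportP <- function(p) {
    ifelse(is.na(p), "NA",
           ifelse(p < 1e-3, toupper(sprintf("%.2E", p)),
                  sub("0+$", "", sprintf("%.3f", p))))
}

#' Write an interaction-gene table
#'
#' \code{layout = "long"} writes the full per-gene table as TSV.
#' \code{layout = "sideBySide"} writes only the called genes, sorted by
#' adjusted p-value then absolute fold change, with up-regulated genes in the
#' left column block and down-regulated genes in the right (the conventional
#' published layout); p-values below 1e-3 are exported in scientific
#' notation.
#'
#' @param table data.frame from [callInteractionGenes()].
#' @param path output path.
#' @param layout \code{"long"} (default) or \code{"sideBySide"}.
#' @param comments optional leading \code{"# "} comment lines.
#' @return \code{path}, invisibly.
#' @export
writeInteractionTable <- function(table, path,
                                  layout = c("long", "sideBySide"),
                                  comments = NULL) {
    layout <- match.arg(layout)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    if (layout == "long") {
        out <- table
        out$pRaw <- formatExportP(out$pRaw)
        out$pBH <- formatExportP(out$pBH)
        utils::write.table(out, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(path))
    }
    called <- table[table$called, , drop = FALSE]
    called <- called[order(called$pBH, -abs(called$foldChange)), ,
                     drop = FALSE]
    up <- called[called$foldChange > 0, , drop = FALSE]
    down <- called[called$foldChange < 0, , drop = FALSE]
    n <- max(nrow(up), nrow(down))
    pad <- function(x, n) c(x, rep("", n - length(x)))
    out <- data.frame(
        probe_up = pad(up$probe, n),
        p_up = pad(formatExportP(up$pBH), n),
        fold_change_up = pad(sprintf("%.2f", up$foldChange), n),
        probe_down = pad(down$probe, n),
        p_down = pad(formatExportP(down$pBH), n),
        fold_change_down = pad(sprintf("%.2f", down$foldChange), n))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
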