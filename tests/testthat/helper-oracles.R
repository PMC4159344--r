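## Independent oracles, coded from the closed forms, never calling the
## package functions they check.

## Benjamini-Hochberg step-up, coded directly from the definition.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

## Two-sided one-sample t p-value from the t CDF.
oracleOneSampleP <- function(x) {
    n <- length(x)
    tt <- mean(x) / (sd(x) / sqrt(n))
    2 * stats::pt(-abs(tt), df = n - 1)
}

## Two-sided Welch two-sample t p-value from the closed form.
oracleWelchP <- function(a, b) {
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    tt <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    2 * stats::pt(-abs(tt), df = df)
}

## Single-hit Poisson log-likelihood, written out independently.
oracleEldaLogLik <- function(doses, tested, negative, f) {
    sum(negative * doses * log(1 - f) +
        (tested - negative) * log(1 - (1 - f)^doses))
}

## Brute-force 1-D grid maximizer of the ELDA likelihood.
oracleEldaGridMLE <- function(doses, tested, negative, res = 1e-6) {
    f <- seq(res, 1 - res, by = res)
    ll <- numeric(length(f))
    for (i in seq_along(doses)) {
        pneg <- (1 - f)^doses[i]
        term <- (tested[i] - negative[i]) * log1p(-pneg)
        term[pneg == 1 & tested[i] > negative[i]] <- -Inf
        ll <- ll + negative[i] * doses[i] * log1p(-f) + term
    }
    f[which.max(ll)]
}

## Exhaustive mixing-fraction search coded independently of scanAlpha.
oracleAlphaSearch <- function(A, B, obs, grid, pseudocount = 1) {
    lo <- log2(obs + pseudocount)
    r <- vapply(grid, function(a) {
        stats::cor(log2(a * A + (1 - a) * B + pseudocount), lo)
    }, numeric(1))
    grid[which.max(r)]
}

## Minimal GEO series-matrix writer for fixtures.
writeGeoFixture <- function(mat, path, series = "GSE00000") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        paste0("!Series_geo_accession\t\"", series, "\""),
        paste0("!Sample_title\t",
               paste(sprintf("\"sample %s, mixed\"", colnames(mat)),
                     collapse = "\t")),
        "!series_matrix_table_begin",
        paste(c("\"ID_REF\"", sprintf("\"%s\"", colnames(mat))),
              collapse = "\t")), con)
    body <- apply(mat, 1L, function(row)
        paste(sprintf("%.17g", row), collapse = "\t"))
    writeLines(paste(sprintf("\"%s\"", rownames(mat)), body, sep = "\t"), con)
    writeLines("!series_matrix_table_end", con)
    invisible(path)
}
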