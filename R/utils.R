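# Internal helpers.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. Assumes R >= 3.6 defaults (Mersenne-Twister, inversion normals,
# rejection sampling), which set.seed() re-selects here explicitly so
# results are stable across sessions whatever the caller changed.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
                    rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    force(code)
}

# write.table wrapper with the package's TSV dialect.
writeTsv <- function(df, path, col.names = TRUE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
    invisible(path)
}

stopIf <- function(cond, fmt, ...) if (cond) stop(sprintf(fmt, ...), call. = FALSE)
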