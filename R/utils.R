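# Internal helpers: error conditions, scoped RNG, natural file ordering.

# Classed conditions so batch drivers (and the CLI) can distinguish bad
# input (exit 2) from the biologically meaningful no-motion case (exit 3).
inputError <- function(msg, call = sys.call(-1L)) {
    structure(class = c("inputError", "error", "condition"),
              list(message = msg, call = call))
}

noMotionError <- function(msg, call = sys.call(-1L)) {
    structure(class = c("noMotionError", "error", "condition"),
              list(message = msg, call = call))
}

# Evaluate expr under a given seed without disturbing the caller's RNG
# stream.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Order of file names with embedded counters: img_2 sorts before img_10.
# Digit runs are left-padded to a fixed width, then ordered lexically.
naturalOrder <- function(x) {
    pad <- vapply(x, function(s) {
        loc <- gregexpr("[0-9]+", s)
        if (loc[[1L]][1L] == -1L) return(s)
        runs <- regmatches(s, loc)[[1L]]
        runs <- sub("^0+(?=[0-9])", "", runs, perl = TRUE)
        wide <- paste0(strrep("0", pmax(0L, 12L - nchar(runs))), runs)
        regmatches(s, loc) <- list(wide)
        s
    }, character(1L), USE.NAMES = FALSE)
    order(pad, x)
}
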