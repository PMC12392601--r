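# Internal helpers shared across modules.

# Named substreams derived from one root seed, so each generator stage is
# reproducible on its own. Offsets are fixed; the combination stays < 2^31.
.SUBSTREAMS <- c(cohort = 11L, annotation = 23L, counts = 37L,
                 se_events = 53L, domain_hits = 71L, isoform_chains = 89L,
                 sequences = 101L)

.substreamSeed <- function(seed, name) {
    if (!name %in% names(.SUBSTREAMS))
        stop("unknown substream: ", name)
    (as.integer(seed) %% 1000000L) * 1009L + .SUBSTREAMS[[name]]
}

.withSubstream <- function(seed, name, expr) {
    set.seed(.substreamSeed(seed, name))
    expr
}

.checkFraction <- function(x, what) {
    if (any(x < 0 | x > 1))
        stop(what, " must lie in [0, 1]")
    invisible(x)
}
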