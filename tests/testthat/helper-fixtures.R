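## Shared fixture builders (all in code; no data files).

UM <- "−"   # Unicode minus as emitted by the formatter

## tiny RTDB from (class, chains, rt) triples
makeDB <- function(chains, rts, classes = "PC", span = c(0.5, 32),
                   batches = "b1", evidence = "SIL-experiment") {
    RTDB(data.frame(lipid_class = rep_len(classes, length(chains)),
                    chains = chains, reference_rt_min = rts,
                    batches = rep_len(batches, length(chains)),
                    evidence = rep_len(evidence, length(chains)),
                    flags = "", stringsAsFactors = FALSE),
         gradientSpan = span, methodId = "fixture")
}

## random registry-valid chain table, reproducible
randomChains <- function(n, seed, labeled = FALSE) {
    set.seed(seed)
    reg <- silLabelRegistry()
    out <- list()
    for (i in seq_len(n)) {
        carbons <- sample(seq(12L, 24L, 2L), 1L)
        dbs <- sample(0:min(6L, (carbons - 1L) %/% 2L), 1L)
        linkage <- sample(c("acyl", "alkyl", "alkenyl"), 1L,
                          prob = c(0.8, 0.1, 0.1))
        label <- NA_character_
        omega <- NA_integer_
        if (dbs >= 1L) {
            if (labeled && runif(1) < 0.5 && linkage == "acyl") {
                j <- sample(nrow(reg), 1L)
                ## labels must fit the substitutable atoms of the chain
                avail <- if (reg$element[j] == "13C") carbons
                         else 2L * carbons - 2L - 2L * dbs
                if (reg$atom_count[j] <= avail) {
                    label <- reg$code[j]
                    omega <- reg$omega[j]
                }
            }
            if (is.na(label) && runif(1) < 0.7)
                omega <- sample(c(3L, 6L, 7L, 9L, 10L), 1L)
        }
        out[[i]] <- data.frame(carbons = carbons, double_bonds = dbs,
                               omega = omega, linkage = linkage,
                               label = label, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

## brute-force enumeration oracle: all ordered tuples, deduplicated by key
bruteEnumerate <- function(lipidClass, pool, k) {
    idx <- do.call(expand.grid, rep(list(seq_along(pool)), k))
    keys <- apply(idx, 1L, function(ii) {
        ch <- omegaRT:::.sortChains(parseChain(pool[ii]))
        paste(lipidClass, paste(formatChain(ch), collapse = "_"))
    })
    sort(unique(keys))
}

## brute-force knot-merge oracle: pool bins left to right until the knot
## sources are strictly increasing
bruteKnots <- function(src, tgt, width) {
    groups <- split(seq_along(src), floor(src / width))
    groups <- groups[order(vapply(groups, function(i) median(src[i]),
                                  numeric(1)))]
    repeat {
        s <- vapply(groups, function(i) median(src[i]), numeric(1))
        bad <- which(diff(s) <= 0)
        if (!length(bad) || length(groups) < 2L) break
        i <- bad[1L]
        groups[[i]] <- c(groups[[i]], groups[[i + 1L]])
        groups[[i + 1L]] <- NULL
    }
    data.frame(source = vapply(groups, function(i) median(src[i]),
                               numeric(1)),
               target = vapply(groups, function(i) median(tgt[i]),
                               numeric(1)),
               row.names = NULL)
}
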