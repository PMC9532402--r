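#' Rank-position increment vector of a gene set
#'
#' For a ranked list of N genes and a set with G members present in the list,
#' the increment at rank i is sqrt((N-G)/G) when gene i is a member and
#' -sqrt(G/(N-G)) otherwise, so the increments sum to zero over the list and
#' the running sum returns to 0 at rank N.
#'
#' @slot x numeric increments in rank order (length N).
#' @slot member logical membership mask per rank position.
#' @slot G,N integer set size (after universe intersection) and list length.
#' @export
setClass("IncrementVector", slots = c(
    x = "numeric", member = "logical", G = "integer", N = "integer"))

setValidity("IncrementVector", function(object) {
    msg <- character()
    G <- object@G; N <- object@N
    if (length(object@x) != N || length(object@member) != N)
        msg <- c(msg, "x and member must have length N")
    if (sum(object@member) != G)
        msg <- c(msg, "membership mask must have exactly G TRUE entries")
    if (G <= 0L || G >= N)
        msg <- c(msg, "0 < G < N is required")
    else {
        a <- sqrt((N - G) / G); b <- sqrt(G / (N - G))
        if (any(object@x[object@member] != a))
            msg <- c(msg, "member increments must all equal sqrt((N-G)/G)")
        if (any(object@x[!object@member] != -b))
            msg <- c(msg, "non-member increments must all equal -sqrt(G/(N-G))")
        if (abs(sum(object@x)) > 1e-9)
            msg <- c(msg, "increments must sum to 0 (conservation)")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "IncrementVector", function(object) {
    cat(sprintf("IncrementVector: N = %d, G = %d, step +%.4g / -%.4g\n",
                object@N, object@G,
                sqrt((object@N - object@G) / object@G),
                sqrt(object@G / (object@N - object@G))))
})

#' Compute the increment vector of a gene set over a ranked list
#'
#' Set members absent from the ranked universe are dropped before computing
#' G.  Degenerate sets (no overlap, or covering the whole universe) raise an
#' error; \code{\link{enrichCollection}} converts those into skipped results.
#'
#' @param ranked a \linkS4class{RankedGeneList} (defines the universe and N).
#' @param set character vector of member gene ids (or one set extracted from a
#'   \linkS4class{GeneSetCollection}).
#' @return An \linkS4class{IncrementVector}.
#' @examples
#' r <- rankGenes(c(a = 3, b = 2, c = 1, d = 0))
#' xiIncrements(r, c("a", "b"))  # +1 at ranks 1,2; -1 at ranks 3,4
#' @export
xiIncrements <- function(ranked, set) {
    stopifnot(is(ranked, "RankedGeneList"))
    N <- length(ranked)
    member <- ranked@geneIds %in% set
    G <- sum(member)
    if (G == 0L)
        stop("degenerate set: no members in the ranked universe (G = 0)")
    if (G == N)
        stop("degenerate set: members cover the whole universe (G = N)")
    a <- sqrt((N - G) / G); b <- sqrt(G / (N - G))
    x <- ifelse(member, a, -b)
    new("IncrementVector", x = x, member = member,
        G = as.integer(G), N = as.integer(N))
}

#' Maximum Estimate Score of an increment vector
#'
#' Let S_j be the running sum of the increments up to rank j.  In
#' \code{literal_max} mode the score is max_j S_j (never negative, because
#' S_N = 0).  In the default \code{signed_extremum} mode the score is the
#' running-sum deviation of largest magnitude, keeping its sign -- the
#' convention that makes a negative score mean depletion (members concentrated
#' at the bottom of the ranking); magnitude ties resolve to the positive value.
#'
#' @param increments an \linkS4class{IncrementVector}.
#' @param mode "signed_extremum" (default) or "literal_max".
#' @return Signed numeric score.
#' @examples
#' r <- rankGenes(c(a = 3, b = 2, c = 1, d = 0))
#' mesStatistic(xiIncrements(r, c("a", "b")))  # +2: members fill the top block
#' mesStatistic(xiIncrements(r, c("c", "d")))  # -2: members fill the bottom
#' @export
mesStatistic <- function(increments, mode = c("signed_extremum", "literal_max")) {
    mode <- match.arg(mode)
    stopifnot(is(increments, "IncrementVector"))
    if (!length(increments@x)) stop("empty increment vector")
    s <- cumsum(increments@x)
    mx <- max(s)
    if (mode == "literal_max") return(mx)
    mn <- min(s)
    if (mx >= -mn) mx else mn
}

## B null scores: membership labels placed uniformly at random over the N rank
## positions.  Vectorized over permutations (columns of a G x B matrix of
## sorted member positions): the running sum only increases at member
## positions, so its maxima sit right after a member (S = k*a - (p_k - k)*b)
## and its minima right before one (or at rank N, where the sum is 0 by
## conservation) -- O(G) per permutation instead of O(N).
.mesNullSample <- function(N, G, B, mode = "signed_extremum") {
    a <- sqrt((N - G) / G); b <- sqrt(G / (N - G))
    k <- seq_len(G)
    P <- vapply(seq_len(B),
                function(i) sort.int(sample.int(N, G), method = "quick"),
                integer(G))
    P <- matrix(P, nrow = G)
    peaks <- k * a - (P - k) * b                 # k recycles down columns
    rows <- lapply(seq_len(G), function(i) peaks[i, ])
    maxS <- if (G == 1L) rows[[1L]] else do.call(pmax, rows)
    if (mode == "literal_max") return(maxS)
    dips <- peaks - a                            # (k-1)*a - (p_k - k)*b
    rows <- lapply(seq_len(G), function(i) dips[i, ])
    minS <- pmin(if (G == 1L) rows[[1L]] else do.call(pmin, rows), 0)
    ifelse(maxS >= -minS, maxS, minS)
}

#' Permutation p-value of a set's MES
#'
#' Each of the B permutations places the G membership labels uniformly at
#' random among the N rank positions and recomputes the score; the two-sided
#' p-value is (1 + #\{b : |MES_b| >= |MES_obs|\}) / (B + 1), so p >= 1/(B+1)
#' always.  Deterministic for a given seed.
#'
#' @param ranked a \linkS4class{RankedGeneList}.
#' @param set character vector of member gene ids.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param mode score mode, see \code{\link{mesStatistic}}.
#' @return list: \code{mes} (observed), \code{p} (two-sided permutation p),
#'   \code{null} (the B null scores), \code{G}, \code{N}.
#' @export
permutationPvalue <- function(ranked, set, B = 1000L, seed = 1L,
                              mode = c("signed_extremum", "literal_max")) {
    mode <- match.arg(mode)
    stopifnot(B >= 1)
    inc <- xiIncrements(ranked, set)
    obs <- mesStatistic(inc, mode)
    null <- .withSeed(seed, .mesNullSample(inc@N, inc@G, B, mode))
    p <- (1 + sum(abs(null) >= abs(obs))) / (B + 1)
    list(mes = obs, p = p, null = null, G = inc@G, N = inc@N)
}

#' MES enrichment of a gene-set collection over a ranked list
#'
#' Scores every set against the ranked list, attaches two-sided permutation
#' p-values (per-set RNG substreams derived from \code{seed} and the set id,
#' so results do not depend on collection order) and Benjamini-Hochberg q
#' across all tested sets.  Sets with fewer than \code{min_size} members in
#' the universe, no members, or all members are returned as skipped with a
#' reason.  A set is called significant when p < \code{p_threshold} and
#' q < \code{fdr_threshold} (defaults 0.05 and 0.1).
#'
#' @param ranked a \linkS4class{RankedGeneList}.
#' @param sets a \linkS4class{GeneSetCollection} (or named list of character
#'   vectors).
#' @param B permutations per set (default 1000).
#' @param min_size minimum in-universe set size to test (default 5).
#' @param seed integer seed.
#' @param mode score mode, see \code{\link{mesStatistic}}.
#' @param p_threshold,fdr_threshold significance thresholds.
#' @return data.frame sorted by (skipped, p, -|MES|): set_id, G, N, MES,
#'   p_perm, q_BH, direction, significant, n_permutations, skipped, reason.
#' @export
enrichCollection <- function(ranked, sets, B = 1000L, min_size = 5L,
                             seed = 1L,
                             mode = c("signed_extremum", "literal_max"),
                             p_threshold = 0.05, fdr_threshold = 0.1) {
    mode <- match.arg(mode)
    stopifnot(is(ranked, "RankedGeneList"))
    if (is(sets, "GeneSetCollection")) sets <- sets@sets
    if (!length(sets)) stop("empty gene-set collection")
    if (is.null(names(sets))) stop("sets must be named")
    N <- length(ranked)
    universe <- ranked@geneIds
    rows <- lapply(names(sets), function(id) {
        G <- sum(universe %in% sets[[id]])
        reason <- if (G == 0L) "no overlap with universe"
            else if (G == N) "covers entire universe"
            else if (G < min_size) "below min_size"
            else ""
        if (nzchar(reason))
            return(data.frame(set_id = id, G = G, N = N, MES = NA_real_,
                              p_perm = NA_real_, skipped = TRUE,
                              reason = reason, stringsAsFactors = FALSE))
        pv <- permutationPvalue(ranked, sets[[id]], B = B,
                                seed = .substreamSeed(seed, paste0("mes:", id)),
                                mode = mode)
        data.frame(set_id = id, G = G, N = N, MES = pv$mes, p_perm = pv$p,
                   skipped = FALSE, reason = "", stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$q_BH <- NA_real_
    tested <- !res$skipped
    if (any(tested)) res$q_BH[tested] <- bhFdr(res$p_perm[tested])
    res$direction <- ifelse(!tested, NA_character_,
                            ifelse(res$MES > 0, "up", "down"))
    res$significant <- tested & res$p_perm < p_threshold &
        res$q_BH < fdr_threshold
    res$n_permutations <- ifelse(tested, as.integer(B), NA_integer_)
    res <- res[order(res$skipped, res$p_perm, -abs(res$MES),
                     res$set_id, method = "radix", na.last = TRUE), ]
    rownames(res) <- NULL
    res[, c("set_id", "G", "N", "MES", "p_perm", "q_BH", "direction",
            "significant", "n_permutations", "skipped", "reason")]
}

#' Write enrichment results as TSV
#' @param res data.frame from \code{\link{enrichCollection}}.
#' @param path output file.
#' @param provenance optional character lines written '#'-prefixed on top.
#' @return \code{path}, invisibly.
#' @export
writeEnrichmentResults <- function(res, path, provenance = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
    utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
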