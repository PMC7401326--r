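# Independent reference implementations used as oracles. These are
# deliberately written as different algorithms from the package code:
# the aligner oracle enumerates monotone matchings, the folding oracle
# enumerates all nested structures, and the tree-distance oracle is the
# plain recursive forest edit distance.

ORACLE_GO <- -2
ORACLE_GE <- -1

oracle_gapcost <- function(k, go = ORACLE_GO, ge = ORACLE_GE) {
    if (k > 0) go + k * ge else 0
}

# Optimal anchored alignment score (window overhangs free, query global)
# by recursion over monotone matchings (memoized on the last matched
# pair and the index of the next required anchor column).
oracle_align_score <- function(q, w, anchors = NULL,
                               match = 1, mismatch = -1,
                               go = ORACLE_GO, ge = ORACLE_GE) {
    qc <- strsplit(chartr("Tt", "Uu", toupper(q)), "")[[1]]
    wc <- strsplit(chartr("Tt", "Uu", toupper(w)), "")[[1]]
    n <- length(qc); m <- length(wc)
    req <- matrix(integer(0), ncol = 2)
    if (!is.null(anchors) && nrow(anchors)) {
        for (a in seq_len(nrow(anchors))) {
            req <- rbind(req, cbind(anchors$q_start[a] + 0:(anchors$length[a] - 1L),
                                    anchors$w_start[a] + 0:(anchors$length[a] - 1L)))
        }
        req <- req[order(req[, 1]), , drop = FALSE]
    }
    nreq <- nrow(req)
    memo <- new.env(parent = emptyenv())
    colscore <- function(a, b) if (qc[a] == wc[b]) match else mismatch
    # best score of the remaining matching after last matched pair (i, j);
    # terminal runs: unmatched window residues are free, unmatched query
    # residues cost an affine gap (query aligned globally)
    best_from <- function(i, j, r) {
        key <- paste(i, j, r)
        if (!is.null(memo[[key]])) return(memo[[key]])
        # stopping is allowed only once all required columns are matched;
        # the remaining query suffix is charged as a gap run
        best <- if (r > nreq) oracle_gapcost(n - i, go, ge) else -Inf
        lim_q <- if (r <= nreq) req[r, 1] else n
        lim_w <- if (r <= nreq) req[r, 2] else m
        for (a in (i + 1):n) {
            if (i + 1 > n || a > lim_q) break
            for (b in (j + 1):m) {
                if (j + 1 > m || b > lim_w) break
                is_req <- r <= nreq && a == req[r, 1] && b == req[r, 2]
                if (r <= nreq && (a == lim_q || b == lim_w) && !is_req) next
                gap <- if (i == 0 && j == 0)
                    oracle_gapcost(a - 1, go, ge) # query prefix costs, window free
                else
                    oracle_gapcost(a - i - 1, go, ge) + oracle_gapcost(b - j - 1, go, ge)
                v <- gap + colscore(a, b) + best_from(a, b, if (is_req) r + 1L else r)
                if (v > best) best <- v
            }
        }
        memo[[key]] <- best
        best
    }
    if (n == 0 || m == 0)
        return(if (n > 0) oracle_gapcost(n, go, ge) else 0)
    best_from(0L, 0L, 1L)
}

# All nested structures (as lists of pair matrices) of a canonical RNA
# string, honoring min_loop and optional forced-unpaired positions.
oracle_all_structures <- function(seq, min_loop = 3, unpaired = integer(0)) {
    ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
    n <- length(ch)
    canp <- function(a, b) {
        x <- paste0(ch[a], ch[b])
        x %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    }
    rec <- function(i, j) {
        if (i > j) return(list(matrix(integer(0), ncol = 2)))
        out <- list()
        for (s in rec(i + 1, j)) out[[length(out) + 1L]] <- s # i unpaired
        for (k in (i + min_loop + 1):j) {
            if (i + min_loop + 1 > j) break
            if (!canp(i, k) || i %in% unpaired || k %in% unpaired) next
            for (inner in rec(i + 1, k - 1)) {
                for (right in rec(k + 1, j)) {
                    out[[length(out) + 1L]] <- rbind(c(i, k), inner, right)
                }
            }
        }
        out
    }
    rec(1L, n)
}

oracle_max_pairs <- function(seq, min_loop = 3, unpaired = integer(0)) {
    max(vapply(oracle_all_structures(seq, min_loop, unpaired), nrow, integer(1)))
}

# number of nodes of a dot-bracket forest
oracle_forest_size <- function(f) {
    sum(strsplit(f, "")[[1]] %in% c(".", "("))
}

# plain recursive forest edit distance (unit costs), memoized on the
# forest strings; independent of the keyroot-based implementation
oracle_tree_dist <- local({
    memo <- new.env(parent = emptyenv())
    split_rightmost <- function(f) {
        ch <- strsplit(f, "")[[1]]
        n <- length(ch)
        if (ch[n] == ".") {
            list(rest = substr(f, 1, n - 1), children = "", label = ".")
        } else {
            depth <- 0
            p <- n
            repeat {
                if (ch[p] == ")") depth <- depth + 1
                if (ch[p] == "(") depth <- depth - 1
                if (depth == 0) break
                p <- p - 1
            }
            list(rest = substr(f, 1, p - 1),
                 children = substr(f, p + 1, n - 1), label = "(")
        }
    }
    fd <- function(f, g) {
        if (!nchar(f)) return(oracle_forest_size(g))
        if (!nchar(g)) return(oracle_forest_size(f))
        key <- paste(f, g, sep = "|")
        if (!is.null(memo[[key]])) return(memo[[key]])
        sf <- split_rightmost(f)
        sg <- split_rightmost(g)
        del <- fd(paste0(sf$rest, sf$children), g) + 1
        ins <- fd(f, paste0(sg$rest, sg$children)) + 1
        sub <- fd(sf$rest, sg$rest) + fd(sf$children, sg$children) +
            (if (sf$label == sg$label) 0 else 1)
        out <- min(del, ins, sub)
        memo[[key]] <- out
        out
    }
    fd
})

# enumerate all dot-bracket strings of length n (min_loop 3)
oracle_all_dotbrackets <- function(n) {
    if (n == 0) return("")
    seq <- strrep("G", n) # irrelevant; use a string where any (i,j) pairs
    # generate directly over bracket placements
    rec <- function(i, j) {
        if (i > j) return("")
        out <- character(0)
        for (rest in rec(i + 1, j)) out <- c(out, paste0(".", rest))
        for (k in (i + 4):j) {
            if (i + 4 > j) break
            for (inner in rec(i + 1, k - 1)) {
                for (right in rec(k + 1, j)) {
                    out <- c(out, paste0("(", inner, ")", right))
                }
            }
        }
        out
    }
    rec(1L, n)
}

# random nucleotide string under the local RNG
rand_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random but valid HSP with aligned strings, plus consistent lengths
rand_hsp <- function(query_length = 40L, subject_length = 120L) {
    repeat {
        len <- sample(5:15, 1)
        ops <- sample(c("M", "Q", "W"), len, replace = TRUE, prob = c(0.8, 0.1, 0.1))
        ops[1] <- "M"; ops[len] <- "M"
        nq <- sum(ops != "W"); ns <- sum(ops != "Q")
        if (nq < 1 || ns < 1) next
        q_start <- sample.int(query_length - nq + 1L, 1)
        s_start <- sample.int(subject_length - ns + 1L, 1)
        qres <- sample(c("A", "C", "G", "U"), nq, replace = TRUE)
        sres <- sample(c("A", "C", "G", "U"), ns, replace = TRUE)
        q_aln <- character(len); s_aln <- character(len)
        qi <- 0L; si <- 0L
        for (k in seq_len(len)) {
            if (ops[k] != "W") { qi <- qi + 1L; q_aln[k] <- qres[qi] } else q_aln[k] <- "-"
            if (ops[k] != "Q") { si <- si + 1L; s_aln[k] <- sres[si] } else s_aln[k] <- "-"
        }
        return(hsp(q_start, q_start + nq - 1L, s_start, s_start + ns - 1L,
                   sample(c("plus", "minus"), 1),
                   paste(q_aln, collapse = ""), paste(s_aln, collapse = ""),
                   bit_score = round(runif(1, 10, 90), 1),
                   e_value = 10^(-sample(1:20, 1)), raw_score = sample(5:50, 1)))
    }
}

# random search result list for round-trip testing
rand_search_results <- function(n_queries = 2L) {
    lapply(seq_len(n_queries), function(qi) {
        qlen <- sample(25:45, 1)
        hits <- lapply(seq_len(sample(0:2, 1)), function(hi) {
            slen <- sample(80:150, 1)
            hsps <- lapply(seq_len(sample(1:3, 1)), function(k) rand_hsp(qlen, slen))
            blast_hit(sprintf("subj%d_%d", qi, hi), slen, hsps,
                      sprintf("subj%d_%d description words", qi, hi))
        })
        search_result(sprintf("query%d", qi), qlen, hits)
    })
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
    p <- strsplit(s, "")[[1]]
    table(paste0(p[-length(p)], p[-1]))
}

# a small shared hairpin-rich consensus used by family fixtures
FIXTURE_STRUCT <- "..(((((....(((....)))...(((....))).....)))))..."

fixture_families <- function(k, seed0 = 100, n = 6, sub_rate = 0.08,
                             indel_rate = 0.03, ...) {
    lapply(seq_len(k), function(i)
        generate_synthetic_family(FIXTURE_STRUCT, n = n, sub_rate = sub_rate,
                                  indel_rate = indel_rate, seed = seed0 + i,
                                  family_id = paste0("fam", i), ...))
}
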