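# Decoy-based synthetic benchmark: artificial database construction,
# extension-accuracy scoring, HSP quality binning and structure-quality
# curves. Doubles as the package's synthetic fixture generator.

#' Rfam families of the published benchmark set
#'
#' The 29 Rfam accessions used to build the original evaluation database
#' (families with a CompaRNA structure template and at least 20 seed
#' homologs). Shipped as a reference constant; the package's synthetic
#' benchmark generates its own families and does not download Rfam data.
#'
#' @format character vector of 29 Rfam accessions.
#' @export
rfam_benchmark_families <- c(
    "RF00001", "RF00002", "RF00005", "RF00008", "RF00015", "RF00017",
    "RF00020", "RF00095", "RF00100", "RF00162", "RF00167", "RF00169",
    "RF00175", "RF00209", "RF00230", "RF00250", "RF00374", "RF00379",
    "RF00380", "RF00480", "RF01051", "RF01725", "RF01739", "RF01807",
    "RF01831", "RF01852", "RF02095", "RF02253", "RF02348")

#' Dinucleotide-preserving shuffle
#'
#' Shuffles a sequence preserving its exact dinucleotide counts (and
#' hence mononucleotide composition, first and last base) by drawing a
#' random Euler path through the dinucleotide multigraph
#' (Altschul-Erickson). Deterministic for a given seed.
#'
#' @param seq nucleotide string (length >= 2 to be meaningful).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return shuffled sequence of the same length.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
    run <- function() {
        ch <- str_chars(seq)
        n <- length(ch)
        if (n < 3) return(seq)
        from <- ch[-n]; to <- ch[-1]
        verts <- unique(ch)
        s1 <- ch[1]; sn <- ch[n]
        out_edges <- split(to, factor(from, levels = verts))
        # choose per-vertex last edges forming an arborescence toward sn
        sources <- names(out_edges)[vapply(out_edges, length, integer(1)) > 0]
        sources <- setdiff(sources, sn)
        repeat {
            last <- vapply(sources, function(v) {
                e <- out_edges[[v]]
                e[[sample.int(length(e), 1)]]
            }, character(1))
            ok <- all(vapply(sources, function(v) {
                seen <- character(0)
                while (v != sn) {
                    if (v %in% seen || !(v %in% sources)) return(FALSE)
                    seen <- c(seen, v)
                    v <- last[[v]]
                }
                TRUE
            }, logical(1)))
            if (ok) break
        }
        ordered <- lapply(setNames(names(out_edges), names(out_edges)), function(v) {
            e <- out_edges[[v]]
            if (!length(e)) return(character(0))
            if (v %in% sources) {
                # remove one copy of the chosen last edge, shuffle the rest
                k <- match(last[[v]], e)
                rest <- e[-k]
                c(if (length(rest)) sample(rest) else character(0), last[[v]])
            } else {
                if (length(e) > 1) sample(e) else e
            }
        })
        nxt <- lapply(ordered, function(e) 1L)
        res <- character(n)
        res[1] <- s1
        v <- s1
        for (i in 2:n) {
            k <- nxt[[v]]
            w <- ordered[[v]][k]
            nxt[[v]] <- k + 1L
            res[i] <- w
            v <- w
        }
        paste(res, collapse = "")
    }
    if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Specification of one synthetic RNA family
#'
#' Describes a family of related RNA sequences sharing a template
#' secondary structure and how it is planted into the artificial
#' database: some members are held out as queries, the rest are embedded
#' between flanking regions together with shuffled decoy copies.
#'
#' @param family_id family name.
#' @param member_seqs character vector of member sequences (at least
#'   `n_queries_held_out + 1`).
#' @param template_structure dot-bracket template shared by the family.
#' @param template_seq sequence the template structure is written on
#'   (defaults to the first member).
#' @param n_queries_held_out members set aside as queries (default 3).
#' @param flank_len length of the 5' and 3' flanking regions (default
#'   1000 nt).
#' @param n_decoys_per_seq shuffled decoy copies per planted member
#'   (default 10).
#' @param flank_mode `"natural_stub"` (i.i.d. fill matching the member's
#'   base composition, standing in for unavailable natural flanks) or
#'   `"shuffled"` (dinucleotide-shuffled copies of the member).
#' @param seed integer seed for all of the family's random draws.
#' @return list of class `"family_spec"`.
#' @export
family_spec <- function(family_id, member_seqs, template_structure,
                        template_seq = member_seqs[[1]],
                        n_queries_held_out = 3L, flank_len = 1000L,
                        n_decoys_per_seq = 10L,
                        flank_mode = c("natural_stub", "shuffled"), seed = 1L) {
    flank_mode <- match.arg(flank_mode)
    if (length(member_seqs) < n_queries_held_out + 1L)
        stop_input("family '%s' needs at least %d members", family_id, n_queries_held_out + 1L)
    if (flank_len < 0) stop_input("flank_len must be >= 0")
    if (any(nchar(member_seqs) < 2)) stop_input("family members must be at least 2 nt")
    structure(list(family_id = family_id, member_seqs = member_seqs,
                   template_structure = template_structure,
                   template_seq = template_seq,
                   n_queries_held_out = as.integer(n_queries_held_out),
                   flank_len = as.integer(flank_len),
                   n_decoys_per_seq = as.integer(n_decoys_per_seq),
                   flank_mode = flank_mode, seed = as.integer(seed)),
              class = "family_spec")
}

#' Generate a synthetic RNA family from a consensus structure
#'
#' Draws a founder sequence compatible with the consensus structure
#' (paired sites get canonical pairs), then derives `n` members by
#' point substitution and small indels in unpaired regions.
#' Substitutions at paired sites are compensatory (the partner is
#' changed too, keeping a canonical pair) with probability
#' `compensatory_prob`.
#'
#' @param consensus_struct dot-bracket consensus.
#' @param n number of members.
#' @param sub_rate per-position substitution probability in `[0, 1)`.
#' @param indel_rate per-unpaired-position indel probability in `[0, 1)`.
#' @param seed integer seed.
#' @param compensatory_prob probability a paired-site substitution keeps
#'   a canonical pair (default 0.8).
#' @param ... further arguments passed to [family_spec()] (e.g.
#'   `family_id`, `flank_len`, `flank_mode`).
#' @return a [family_spec()]; the founder is stored as `template_seq`.
#' @export
generate_synthetic_family <- function(consensus_struct, n, sub_rate = 0.1,
                                      indel_rate = 0.02, seed = 1L,
                                      compensatory_prob = 0.8, ...) {
    if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
        stop_input("rates must be in [0, 1)")
    pair_types <- c("AU", "UA", "GC", "CG", "GU", "UG")
    pair_probs <- c(0.2, 0.2, 0.25, 0.25, 0.05, 0.05)
    bases <- c("A", "C", "G", "U")
    pr <- db_to_pairs(consensus_struct)
    L <- nchar(consensus_struct)
    withr::with_seed(seed, {
        founder <- character(L)
        paired_with <- rep(NA_integer_, L)
        if (nrow(pr)) {
            paired_with[pr$i] <- pr$j
            paired_with[pr$j] <- pr$i
            pt <- sample(pair_types, nrow(pr), replace = TRUE, prob = pair_probs)
            founder[pr$i] <- substr(pt, 1, 1)
            founder[pr$j] <- substr(pt, 2, 2)
        }
        unp <- which(is.na(paired_with))
        founder[unp] <- sample(bases, length(unp), replace = TRUE)

        members <- vapply(seq_len(n), function(k) {
            ch <- founder
            # substitutions; iterate 5'->3' and handle each pair once (at i)
            for (p in seq_len(L)) {
                j <- paired_with[p]
                if (!is.na(j) && j < p) next
                if (runif(1) >= sub_rate) next
                if (is.na(j)) {
                    ch[p] <- sample(setdiff(bases, ch[p]), 1)
                } else if (runif(1) < compensatory_prob) {
                    cur <- paste0(ch[p], ch[j])
                    new <- sample(setdiff(pair_types, cur), 1)
                    ch[p] <- substr(new, 1, 1)
                    ch[j] <- substr(new, 2, 2)
                } else {
                    ch[p] <- sample(setdiff(bases, ch[p]), 1)
                }
            }
            # indels only in unpaired regions (loops), keeping stems intact
            keep <- rep(TRUE, L)
            insert_after <- vector("list", L)
            for (p in unp) {
                if (runif(1) >= indel_rate) next
                if (runif(1) < 0.5) {
                    keep[p] <- FALSE
                } else {
                    insert_after[[p]] <- sample(bases, sample(1:2, 1), replace = TRUE)
                }
            }
            parts <- character(0)
            for (p in seq_len(L)) {
                if (keep[p]) parts <- c(parts, ch[p])
                if (!is.null(insert_after[[p]])) parts <- c(parts, insert_after[[p]])
            }
            paste(parts, collapse = "")
        }, character(1))
        family_spec(member_seqs = members, template_structure = consensus_struct,
                    template_seq = paste(founder, collapse = ""), seed = seed, ...)
    })
}

make_flank <- function(member, len, mode) {
    if (len <= 0) return("")
    if (mode == "shuffled") {
        reps <- ceiling(len / nchar(member))
        s <- paste(vapply(seq_len(reps), function(i) dinucleotide_shuffle(member),
                          character(1)), collapse = "")
        substr(s, 1, len)
    } else {
        random_seq(len, prob = base_composition(member))
    }
}

#' Build the artificial benchmark database
#'
#' For each family, holds out `n_queries_held_out` members as queries
#' (chosen at random under the family seed) and embeds the remaining
#' members, one after another with their 5' and 3' flanking regions,
#' into one long subject sequence; each planted member is additionally
#' embedded as `n_decoys_per_seq` dinucleotide-shuffled decoy copies
#' with their own flanks. The truth table records every planted
#' interval. Every truth interval is audited against the planted
#' sequence at build time.
#'
#' @param families list of [family_spec()] objects (a single spec is
#'   accepted).
#' @return list with `queries` (named character), `subjects` (named
#'   character, one per family), `truth` (tibble: `subject_id`, `start`,
#'   `end`, `family_id`, `member`, `is_decoy`) and `families`.
#' @export
build_artificial_database <- function(families) {
    if (inherits(families, "family_spec")) families <- list(families)
    queries <- character(0)
    subjects <- character(0)
    rows <- list()
    for (f in families) {
        built <- withr::with_seed(f$seed, {
            n <- length(f$member_seqs)
            held <- sort(sample.int(n, f$n_queries_held_out))
            planted_idx <- setdiff(seq_len(n), held)
            q <- setNames(f$member_seqs[held],
                          sprintf("%s_q%d", f$family_id, seq_along(held)))
            parts <- character(0)
            pos <- 0L
            trows <- list()
            plant <- function(seqs, names, decoy) {
                for (k in seq_along(seqs)) {
                    s <- seqs[[k]]
                    f5 <- make_flank(s, f$flank_len, f$flank_mode)
                    f3 <- make_flank(s, f$flank_len, f$flank_mode)
                    parts <<- c(parts, f5, s, f3)
                    start <- pos + nchar(f5) + 1L
                    end <- start + nchar(s) - 1L
                    pos <<- pos + nchar(f5) + nchar(s) + nchar(f3)
                    trows[[length(trows) + 1L]] <<- tibble::tibble(
                        subject_id = sprintf("%s_db", f$family_id),
                        start = start, end = end, family_id = f$family_id,
                        member = names[k], is_decoy = decoy)
                }
            }
            planted <- f$member_seqs[planted_idx]
            plant(planted, sprintf("%s_m%d", f$family_id, planted_idx), FALSE)
            for (k in seq_along(planted)) {
                dec <- vapply(seq_len(f$n_decoys_per_seq), function(d)
                    dinucleotide_shuffle(planted[[k]]), character(1))
                plant(dec, sprintf("%s_m%d_decoy%d", f$family_id, planted_idx[k],
                                   seq_len(f$n_decoys_per_seq)), TRUE)
            }
            list(q = q, subject = paste(parts, collapse = ""),
                 truth = do.call(rbind, trows))
        })
        queries <- c(queries, built$q)
        subjects[[sprintf("%s_db", f$family_id)]] <- built$subject
        rows[[length(rows) + 1L]] <- built$truth
    }
    truth <- do.call(rbind, rows)
    # construction audit: every truth interval recovers its planted sequence
    for (i in seq_len(nrow(truth))) {
        got <- substr(subjects[[truth$subject_id[i]]], truth$start[i], truth$end[i])
        if (nchar(got) != truth$end[i] - truth$start[i] + 1L)
            stop_input("internal error: truth interval %d out of bounds", i)
    }
    list(queries = queries, subjects = subjects, truth = truth, families = families)
}

#' Fabricate synthetic search results over the artificial database
#'
#' The no-external-search path of the benchmark: for each held-out query
#' and each planted interval of its family, a partial match is fabricated
#' by locally aligning a seeded random fragment of the query (emulating a
#' partial HSP) against a window around the planted interval under the
#' search scoring (+1/-1, gap existence 2, extension 1). The local
#' alignment score serves as the HSP bit-score stand-in.
#'
#' @param db output of [build_artificial_database()].
#' @param frac mean fraction of the query used as the HSP seed fragment.
#' @param jitter relative jitter of the fragment length and placement.
#' @param pad window padding around the planted interval (nt).
#' @param min_score drop fabricated HSPs scoring below this.
#' @param include_decoys also fabricate HSPs against decoy intervals.
#' @param seed integer seed.
#' @return list with `results` (list of [search_result()]) and
#'   `hsp_truth` (tibble linking each HSP to its truth record).
#' @export
fabricate_search <- function(db, frac = 0.6, jitter = 0.2, pad = 40L,
                             min_score = 8, include_decoys = TRUE, seed = 1L) {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                       baseOnly = FALSE)
    results <- list()
    link <- list()
    withr::with_seed(seed, {
        for (qname in names(db$queries)) {
            qseq <- db$queries[[qname]]
            fam <- sub("_q\\d+$", "", qname)
            tr <- db$truth[db$truth$family_id == fam, , drop = FALSE]
            if (!include_decoys) tr <- tr[!tr$is_decoy, , drop = FALSE]
            sid <- sprintf("%s_db", fam)
            sseq <- db$subjects[[sid]]
            L <- nchar(qseq)
            hsps <- list()
            rows <- list()
            for (i in seq_len(nrow(tr))) {
                flen <- max(8L, min(L, round(L * frac * (1 + runif(1, -jitter, jitter)))))
                fstart <- sample.int(L - flen + 1L, 1)
                frag <- substr(qseq, fstart, fstart + flen - 1L)
                w1 <- max(1L, tr$start[i] - pad)
                w2 <- min(nchar(sseq), tr$end[i] + pad)
                window <- substr(sseq, w1, w2)
                pa <- Biostrings::pairwiseAlignment(
                    pattern = chartr("Uu", "Tt", frag),
                    subject = chartr("Uu", "Tt", window),
                    type = "local", substitutionMatrix = submat,
                    gapOpening = 2, gapExtension = 1)
                sc <- Biostrings::score(pa)
                if (sc < min_score) next
                qa <- chartr("Tt", "Uu", as.character(Biostrings::alignedPattern(pa)))
                sa <- chartr("Tt", "Uu", as.character(Biostrings::alignedSubject(pa)))
                qs <- fstart - 1L + Biostrings::start(Biostrings::pattern(pa))
                qe <- fstart - 1L + Biostrings::end(Biostrings::pattern(pa))
                ss <- w1 - 1L + Biostrings::start(Biostrings::subject(pa))
                se <- w1 - 1L + Biostrings::end(Biostrings::subject(pa))
                ev <- max(1e-300, sum(nchar(db$subjects)) * 2^(-sc))
                hsps[[length(hsps) + 1L]] <- hsp(qs, qe, ss, se, "plus", qa, sa,
                                                 bit_score = sc, e_value = signif(ev, 3))
                rows[[length(rows) + 1L]] <- tibble::tibble(
                    query_id = qname, subject_id = sid, hsp = length(hsps),
                    family_id = fam, member = tr$member[i], is_decoy = tr$is_decoy[i],
                    true_start = tr$start[i], true_end = tr$end[i], bit_score = sc)
            }
            hits <- if (length(hsps)) list(blast_hit(sid, nchar(sseq), hsps)) else list()
            results[[length(results) + 1L]] <- search_result(qname, L, hits)
            if (length(rows)) link[[length(link) + 1L]] <- do.call(rbind, rows)
        }
    })
    list(results = results,
         hsp_truth = if (length(link)) do.call(rbind, link) else NULL)
}

#' Total extension error in nucleotides
#'
#' Number of nucleotides missing or in excess at the two ends of the
#' predicted full-length interval relative to the planted truth:
#' `|pred_start - true_start| + |pred_end - true_end|`.
#'
#' @param predicted an `"extended_match"` or list with `subject_id`,
#'   `start`, `end`.
#' @param truth a truth record (list or one-row data frame with
#'   `subject_id`, `start`, `end`).
#' @return non-negative integer.
#' @export
total_error <- function(predicted, truth) {
    ps <- predicted$subject_id; ts <- truth$subject_id
    if (!is.null(ps) && !is.null(ts) && !is.na(ps) && !is.na(ts) && ps != ts)
        stop_input("predicted and truth intervals are on different subjects ('%s' vs '%s')",
                   ps, ts)
    abs(predicted$start - truth$start) + abs(predicted$end - truth$end)
}

#' Quality tertile binning of HSPs
#'
#' Thresholds are bit-score tertiles over the truth-matched HSPs (group
#' sizes equal up to 1, the remainder going to the higher-quality bins);
#' all HSPs are then assigned by those thresholds, ties going to the
#' higher bin. A degenerate flag is raised when all truth scores are
#' equal (a single bin absorbs everything).
#'
#' @param bit_scores numeric vector of HSP bit scores.
#' @param is_truth logical vector marking truth-matched HSPs (>= 3
#'   required).
#' @return list with `bin` (factor `high`/`moderate`/`low` per HSP),
#'   `thresholds` (named numeric: minimum score of the high and moderate
#'   bins) and `degenerate`.
#' @export
bin_by_quality <- function(bit_scores, is_truth = rep(TRUE, length(bit_scores))) {
    ts <- sort(bit_scores[is_truth], decreasing = TRUE)
    n <- length(ts)
    if (n < 3) stop_input("at least 3 truth-matched HSPs are required for binning")
    base <- n %/% 3L
    r <- n %% 3L
    sizes <- base + c(r >= 1L, r >= 2L, 0L)
    t_high <- ts[sizes[1]]
    t_mod <- ts[sizes[1] + sizes[2]]
    degenerate <- length(unique(ts)) == 1L
    if (degenerate)
        warning("all truth-matched HSP scores are equal; binning is degenerate")
    bin <- ifelse(bit_scores >= t_high, "high",
                  ifelse(bit_scores >= t_mod, "moderate", "low"))
    list(bin = factor(bin, levels = c("high", "moderate", "low")),
         thresholds = c(high = t_high, moderate = t_mod),
         degenerate = degenerate)
}

#' Split search results into three BLAST files by HSP quality
#'
#' Writes the high/moderate/low HSPs into three separate BLAST pairwise
#' text files using the thresholds from [bin_by_quality()].
#'
#' @param results list of [search_result()] objects.
#' @param thresholds named numeric from [bin_by_quality()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the three file paths.
#' @export
write_quality_bins <- function(results, thresholds, dir, prefix = "quality") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pick <- function(lo, hi) {
        lapply(results, function(res) {
            hits <- lapply(res$hits, function(h) {
                keep <- vapply(h$hsps, function(p)
                    p$bit_score >= lo && p$bit_score < hi, logical(1))
                if (!any(keep)) return(NULL)
                blast_hit(h$subject_id, h$subject_length, h$hsps[keep], h$subject_def)
            })
            search_result(res$query_id, res$query_length,
                          Filter(Negate(is.null), hits))
        })
    }
    paths <- c(high = file.path(dir, sprintf("%s_high.txt", prefix)),
               moderate = file.path(dir, sprintf("%s_moderate.txt", prefix)),
               low = file.path(dir, sprintf("%s_low.txt", prefix)))
    write_blast_text(pick(thresholds[["high"]], Inf), paths[["high"]])
    write_blast_text(pick(thresholds[["moderate"]], thresholds[["high"]]), paths[["moderate"]])
    write_blast_text(pick(-Inf, thresholds[["moderate"]]), paths[["low"]])
    paths
}

boot_ci <- function(x, n_boot, seed) {
    est <- mean(x)
    if (n_boot <= 1L || length(x) < 2L) return(c(lower = est, upper = est))
    withr::with_seed(seed, {
        means <- vapply(seq_len(n_boot), function(i)
            mean(sample(x, replace = TRUE)), numeric(1))
        q <- quantile(means, c(0.025, 0.975), names = FALSE)
        c(lower = q[1], upper = q[2])
    })
}

#' Extension accuracy benchmark
#'
#' Builds the artificial database, fabricates partial-match HSPs into the
#' planted (non-decoy) intervals, extends each HSP with every requested
#' method and scores the total error against the planted truth.
#'
#' @param families list of [family_spec()] objects.
#' @param methods extension methods to compare.
#' @param flank_len,flank_mode protocol overrides applied to every
#'   family (defaults: 1000 nt natural-stub flanks).
#' @param seed integer seed for fabrication.
#' @param config an [extension_config()].
#' @param frac,jitter fragment parameters passed to [fabricate_search()].
#' @return list with `records` (tibble: one row per HSP x method),
#'   `summary` (per-method median/quartiles/mean) and `by_family`
#'   (per family x method medians).
#' @export
run_extension_benchmark <- function(families,
                                    methods = c("simple", "locarna", "meta"),
                                    flank_len = 1000L,
                                    flank_mode = "natural_stub",
                                    seed = 1L, config = extension_config(),
                                    frac = 0.6, jitter = 0.2) {
    if (inherits(families, "family_spec")) families <- list(families)
    families <- lapply(families, function(f) {
        f$flank_len <- as.integer(flank_len)
        f$flank_mode <- flank_mode
        f
    })
    db <- build_artificial_database(families)
    fab <- fabricate_search(db, frac = frac, jitter = jitter,
                            include_decoys = FALSE, seed = seed)
    if (is.null(fab$hsp_truth)) stop_input("no fabricated HSPs survived filtering")
    scorers <- lapply(db$queries, function(q) model_scorer(query_model(q)))
    rows <- list()
    ht <- fab$hsp_truth
    for (i in seq_len(nrow(ht))) {
        res <- fab$results[[match(ht$query_id[i], vapply(fab$results, `[[`, "", "query_id"))]]
        p <- res$hits[[1]]$hsps[[ht$hsp[i]]]
        qseq <- db$queries[[ht$query_id[i]]]
        sseq <- db$subjects[[ht$subject_id[i]]]
        truth <- ht[i, ]
        for (m in methods) {
            em <- switch(m,
                simple = simple_extend(p, nchar(qseq), nchar(sseq),
                                       subject_id = ht$subject_id[i]),
                locarna = locarna_extend(p, qseq, sseq, config, ht$subject_id[i]),
                meta = meta_extend(p, qseq, sseq, scorers[[ht$query_id[i]]],
                                   config, ht$subject_id[i]),
                stop_input("unknown extension method '%s'", m))
            err <- total_error(em, list(subject_id = truth$subject_id,
                                        start = truth$true_start,
                                        end = truth$true_end))
            rows[[length(rows) + 1L]] <- tibble::tibble(
                family_id = truth$family_id, query_id = truth$query_id,
                member = truth$member, method = m,
                pred_start = em$start, pred_end = em$end,
                true_start = truth$true_start, true_end = truth$true_end,
                bit_score = truth$bit_score, total_error = err)
        }
    }
    records <- do.call(rbind, rows)
    agg <- function(df) tibble::tibble(
        n = nrow(df), median = median(df$total_error),
        q1 = quantile(df$total_error, 0.25, names = FALSE),
        q3 = quantile(df$total_error, 0.75, names = FALSE),
        mean = mean(df$total_error))
    summary <- do.call(rbind, lapply(split(records, records$method), function(df)
        cbind(tibble::tibble(method = df$method[1]), agg(df))))
    by_family <- do.call(rbind, lapply(
        split(records, list(records$family_id, records$method), drop = TRUE),
        function(df) cbind(tibble::tibble(family_id = df$family_id[1],
                                          method = df$method[1]), agg(df))))
    list(records = records, summary = summary, by_family = by_family)
}

#' Structure prediction quality benchmark
#'
#' Builds the artificial database with shuffled flanking regions,
#' fabricates HSPs into planted members and decoys, bins the HSPs into
#' quality tertiles per query, runs the full characterization (anchored
#' extension, homology calls, reference selection, structure prediction)
#' and measures the tree edit distance of every predicted structure to
#' the family template, normalized by the query length. Reports the mean
#' per method and quality bin with percentile bootstrap intervals, plus
#' the decoy baseline (same pipeline on decoy intervals, all bins
#' pooled). Queries with fewer than 3 truth-matched HSPs are excluded
#' (recorded in `excluded_queries`).
#'
#' @param families list of [family_spec()] objects.
#' @param methods prediction method names (see [prediction_methods()]).
#' @param flank_len,flank_mode protocol overrides (defaults: shuffled
#'   500 nt flanks).
#' @param n_boot bootstrap iterations for the 95 percent intervals
#'   (default 100).
#' @param seed integer seed.
#' @param config an [extension_config()].
#' @param frac,jitter fragment parameters passed to [fabricate_search()].
#' @return list with `records`, `summary` (method x bin), `decoy_baseline`
#'   (per method), `by_family` and `excluded_queries`.
#' @export
run_structure_benchmark <- function(families, methods = "C-A-r-Rc",
                                    flank_len = 500L, flank_mode = "shuffled",
                                    n_boot = 100L, seed = 1L,
                                    config = extension_config(),
                                    frac = 0.6, jitter = 0.2) {
    if (inherits(families, "family_spec")) families <- list(families)
    families <- lapply(families, function(f) {
        f$flank_len <- as.integer(flank_len)
        f$flank_mode <- flank_mode
        f
    })
    db <- build_artificial_database(families)
    fab <- fabricate_search(db, frac = frac, jitter = jitter,
                            include_decoys = TRUE, seed = seed)
    if (is.null(fab$hsp_truth)) stop_input("no fabricated HSPs survived filtering")
    templates <- setNames(
        lapply(families, function(f) secondary_structure(f$template_seq,
                                                         f$template_structure)),
        vapply(families, `[[`, "", "family_id"))
    rows <- list()
    excluded <- character(0)
    for (qi in seq_along(fab$results)) {
        res <- fab$results[[qi]]
        ht <- fab$hsp_truth[fab$hsp_truth$query_id == res$query_id, , drop = FALSE]
        if (!nrow(ht)) next
        qseq <- db$queries[[res$query_id]]
        bins <- tryCatch(bin_by_quality(ht$bit_score, !ht$is_decoy),
                         error = function(e) e)
        if (inherits(bins, "error")) {
            excluded <- c(excluded, res$query_id)
            next
        }
        sseq <- db$subjects[[ht$subject_id[1]]]
        matches <- lapply(seq_len(nrow(ht)), function(i) {
            p <- res$hits[[1]]$hsps[[ht$hsp[i]]]
            locarna_extend(p, qseq, sseq, config, ht$subject_id[i])
        })
        model <- query_model(qseq)
        calls <- score_and_classify(matches, model)
        refs <- select_reference_sequences(matches, calls, qseq, config = config)
        context <- predict_context(
            qseq, references = refs,
            all_match_seqs = vapply(matches, `[[`, "", "sequence"),
            extension = config)
        fam <- ht$family_id[1]
        for (i in seq_len(nrow(ht))) {
            for (m in methods) {
                st <- predict_structure(m, matches[[i]], context)
                absent <- inherits(st, "structure_absence")
                d <- if (absent) NA_real_ else
                    tree_edit_distance(st, templates[[fam]]) / nchar(qseq)
                rows[[length(rows) + 1L]] <- tibble::tibble(
                    family_id = fam, query_id = res$query_id,
                    member = ht$member[i], is_decoy = ht$is_decoy[i],
                    bin = as.character(bins$bin[i]), method = m,
                    dist = d,
                    absent_reason = if (absent) st$reason else NA_character_)
            }
        }
    }
    if (!length(rows)) stop_input("no benchmark records were produced")
    records <- do.call(rbind, rows)
    ok <- records[!is.na(records$dist), , drop = FALSE]
    homolog <- ok[!ok$is_decoy, , drop = FALSE]
    summarize <- function(df, keys) {
        do.call(rbind, lapply(split(df, df[keys], drop = TRUE), function(g) {
            ci <- boot_ci(g$dist, n_boot, seed)
            cbind(tibble::as_tibble(g[1, keys, drop = FALSE]),
                  tibble::tibble(n = nrow(g), mean = mean(g$dist),
                                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]]))
        }))
    }
    summary <- summarize(homolog, c("method", "bin"))
    decoy <- ok[ok$is_decoy, , drop = FALSE]
    decoy_baseline <- if (nrow(decoy)) summarize(decoy, "method") else NULL
    by_family <- summarize(homolog, c("family_id", "bin"))
    list(records = records, summary = summary, decoy_baseline = decoy_baseline,
         by_family = by_family, excluded_queries = excluded)
}
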