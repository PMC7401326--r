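test_that("simple extension adds the unmatched query stretches to both ends", {
    # partial match q 14-24 / s 21-31 of a 31-nt query
    h <- hsp(14, 24, 21, 31, "plus", bit_score = 22.3, e_value = 1e-5)
    em <- simple_extend(h, 31, 60)
    expect_equal(c(em$start, em$end), c(8L, 38L))
    expect_false(em$truncated_5p || em$truncated_3p)

    # full-coverage HSP extends by nothing
    h2 <- hsp(1, 20, 31, 50, "plus")
    em2 <- simple_extend(h2, 20, 100)
    expect_equal(c(em2$start, em2$end), c(31L, 50L))

    # clamping at the subject 5' boundary sets the truncation flag
    h3 <- hsp(40, 49, 5, 14, "plus")
    em3 <- simple_extend(h3, 50, 60)
    expect_equal(c(em3$start, em3$end), c(1L, 15L))
    expect_true(em3$truncated_5p)
    expect_false(em3$truncated_3p)
})

test_that("simple extension matches an independent one-line oracle on random HSPs", {
    for (seed in 1:20) {
        h <- withr::with_seed(seed, rand_hsp(40L, 200L))
        em <- simple_extend(h, 40L, 200L)
        up <- h$q_start - 1L
        down <- 40L - h$q_end
        if (h$strand == "plus") {
            expect_equal(em$start, max(1L, h$s_start - up))
            expect_equal(em$end, min(200L, h$s_end + down))
        } else {
            expect_equal(em$start, max(1L, h$s_start - down))
            expect_equal(em$end, min(200L, h$s_end + up))
        }
        expect_lte(em$start, em$end) # clamping never empties the interval
    }
})

test_that("anchor extraction finds maximal gap-free runs", {
    h <- hsp(14, 24, 21, 31, "plus", "GGGAAACCCAU", "GGGAAACCCAU")
    a <- extract_anchors(h)
    expect_equal(nrow(a), 1L)
    expect_equal(a$length, 11L)
    expect_equal(c(a$q_start, a$s_start), c(14L, 21L))

    h2 <- hsp(1, 4, 1, 5, "plus", "AC-GU", "ACAGU")
    a2 <- extract_anchors(h2)
    expect_equal(a2$length, c(2L, 2L))
    expect_equal(a2$q_start, c(1L, 3L))
    expect_equal(a2$s_start, c(1L, 4L))

    # without aligned strings: one run spanning the start of the match
    h3 <- hsp(5, 14, 11, 22)
    a3 <- extract_anchors(h3)
    expect_equal(nrow(a3), 1L)
    expect_equal(a3$length, 10L)
})

test_that("anchor extraction equals a column-scanning oracle on random alignments", {
    for (seed in 1:25) {
        h <- withr::with_seed(seed, rand_hsp())
        a <- extract_anchors(h, min_anchor_run = 1L)
        # oracle: scan columns one by one
        qc <- strsplit(h$q_aln, "")[[1]]
        sc <- strsplit(h$s_aln, "")[[1]]
        runs <- list()
        qpos <- h$q_start - 1L
        spos_qo <- 0L
        cur <- NULL
        for (k in seq_along(qc)) {
            if (qc[k] != "-") qpos <- qpos + 1L
            if (sc[k] != "-") spos_qo <- spos_qo + 1L
            if (qc[k] != "-" && sc[k] != "-") {
                if (is.null(cur)) cur <- c(qpos, spos_qo, 0L)
                cur[3] <- cur[3] + 1L
            } else if (!is.null(cur)) {
                runs[[length(runs) + 1L]] <- cur
                cur <- NULL
            }
        }
        if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
        expect_equal(nrow(a), length(runs))
        for (r in seq_along(runs)) {
            expect_equal(a$q_start[r], runs[[r]][1])
            expect_equal(a$length[r], runs[[r]][3])
            s_plus <- if (h$strand == "plus") h$s_start - 1L + runs[[r]][2]
                      else h$s_end - (runs[[r]][2] + runs[[r]][3] - 1L) + 1L
            expect_equal(a$s_start[r], s_plus)
        }
    }
})

test_that("anchored alignment: identity, free end gaps and anchor constraints", {
    al <- anchored_align("ACGU", "ACGU")
    expect_equal(al$score, 4)
    expect_equal(al$q_aln, "ACGU")

    # window overhangs are free
    al2 <- anchored_align("ACGU", "UUACGUUU")
    expect_equal(al2$score, 4)
    expect_equal(gsub("-", "", al2$q_aln), "ACGU")

    # anchored score never exceeds the unconstrained score
    for (seed in 1:10) {
        withr::with_seed(seed, {
            q <- rand_seq(sample(6:10, 1))
            w <- rand_seq(sample(8:14, 1))
            qa <- sample.int(nchar(q) - 2L, 1)
            wa <- sample.int(nchar(w) - 2L, 1)
            anch <- data.frame(q_start = qa, w_start = wa, length = 2L)
            free <- anchored_align(q, w)
            con <- anchored_align(q, w, anch)
            expect_lte(con$score, free$score)
        })
    }
})

test_that("anchored alignment equals the brute-force matching oracle", {
    # the worked instance with one fixed anchor
    q <- "ACGUACGU"; w <- "UUACGAACGUUU"
    anch <- data.frame(q_start = 5L, w_start = 7L, length = 4L)
    al <- anchored_align(q, w, anch)
    expect_equal(al$score, oracle_align_score(q, w, anch))

    for (seed in 1:12) {
        withr::with_seed(seed, {
            q <- rand_seq(sample(3:8, 1))
            w <- rand_seq(sample(3:9, 1))
            al <- anchored_align(q, w)
            expect_equal(al$score, oracle_align_score(q, w))
        })
    }
})

test_that("anchors violating co-linearity are rejected", {
    bad <- data.frame(q_start = c(1L, 3L), w_start = c(5L, 2L), length = c(2L, 2L))
    expect_error(anchored_align("ACGUACGU", "ACGUACGU", bad), "co-linearity")
})

test_that("anchored extension recovers an exactly embedded query copy", {
    q <- "GGGAAACCCUUUGGGAAACCCAUGCAUGCAU"
    subj <- paste0("ACGUACGUACGUACGUACGU", q, "ACGUACGUACGUACG")
    h <- hsp(14, 24, 34, 44, "plus", substr(q, 14, 24), substr(q, 14, 24),
             22.3, 1e-5)
    for (o_loc in c(0L, 10L, 30L)) {
        em <- locarna_extend(h, q, subj, extension_config(o_loc = o_loc))
        expect_equal(c(em$start, em$end), c(21L, 51L))
        expect_equal(em$sequence, q)
        expect_equal(em$method, "locarna")
    }
})

test_that("anchored extension absorbs a deletion the simple method misses", {
    q <- withr::with_seed(99, rand_seq(40))
    # homolog: query with a 2-nt deletion at positions 5-6 (5' of the HSP)
    hom <- paste0(substr(q, 1, 4), substr(q, 7, 40))
    subj <- paste0(withr::with_seed(7, rand_seq(20)), hom,
                   withr::with_seed(8, rand_seq(20)))
    truth <- c(21L, 20L + nchar(hom))
    # HSP: exact match of query 15-34 (subject coordinates shifted by -2)
    h <- hsp(15, 34, 21 + 14 - 2, 21 + 33 - 2, "plus",
             substr(q, 15, 34), substr(q, 15, 34), 20, 1e-4)
    s <- simple_extend(h, nchar(q), nchar(subj), subj)
    l <- locarna_extend(h, q, subj)
    err_simple <- abs(s$start - truth[1]) + abs(s$end - truth[2])
    err_loc <- abs(l$start - truth[1]) + abs(l$end - truth[2])
    expect_equal(err_loc, 0L)
    expect_equal(abs(s$start - truth[1]), 2L) # misses by the deletion at 5'
    expect_gt(err_simple, err_loc)
    # the realignment score matches the brute-force oracle on the window
    w1 <- max(1L, s$start - 30L); w2 <- min(nchar(subj), s$end + 30L)
    window <- substr(subj, w1, w2)
    anch <- extract_anchors(h)
    anch <- data.frame(q_start = anch$q_start, w_start = anch$s_start - w1 + 1L,
                       length = anch$length)
    al <- anchored_align(q, window, anch)
    expect_equal(al$score, oracle_align_score(q, window, anch))
})

test_that("anchored columns keep identical coordinates through extension", {
    q <- "GGGAAACCCUUUGGGAAACCCAUGCAUGCAU"
    subj <- paste0("ACGUACGUACGUACGUACGU", q, "ACGUACGUACGUACG")
    h <- hsp(14, 24, 34, 44, "plus", substr(q, 14, 24), substr(q, 14, 24), 22, 1e-5)
    em <- locarna_extend(h, q, subj)
    # anchor columns: query i aligned to subject position 20 + i
    expect_equal(substr(em$sequence, 14, 24), substr(q, 14, 24))
    expect_equal(em$start + 13L, h$s_start)
})

test_that("minus-strand HSPs extend on the query-oriented reverse complement", {
    q <- "GGGAAACCCUUUGGGAAACCCAUGCAUGCAU"
    L <- nchar(q)
    x <- 18L
    subj <- paste0(withr::with_seed(3, rand_seq(x)), revcomp(q),
                   withr::with_seed(4, rand_seq(12)))
    a <- 14L; b <- 24L
    s1 <- x + L - b + 1L; s2 <- x + L - a + 1L
    h <- hsp(a, b, s1, s2, "minus", substr(q, a, b), substr(q, a, b), 22, 1e-5)
    em_s <- simple_extend(h, L, nchar(subj), subj)
    expect_equal(c(em_s$start, em_s$end), c(x + 1L, x + L))
    expect_equal(em_s$sequence, q)
    em_l <- locarna_extend(h, q, subj)
    expect_equal(c(em_l$start, em_l$end), c(x + 1L, x + L))
    expect_equal(em_l$sequence, q)
    expect_equal(em_l$strand, "minus")
})

test_that("meta extension picks the higher-scoring candidate, ties to locarna", {
    q <- "GGGAAACCCUUUGGGAAACCCAUGCAUGCAU"
    subj <- paste0("ACGUACGUACGUACGUACGU", q, "ACGUACGUACGUACG")
    h <- hsp(14, 24, 34, 44, "plus", substr(q, 14, 24), substr(q, 14, 24), 22, 1e-5)
    # identical candidates -> tie -> the anchored-method label is kept
    em <- meta_extend(h, q, subj, scorer = function(s) 12)
    expect_equal(em$method, "locarna")
    expect_equal(em$model_score, 12)

    # a fixture where the two candidates differ: homolog with a deletion
    model <- query_model(q)
    sc <- attr(meta_extend(h, q, subj, model_scorer(model)), "candidate_scores")
    expect_named(sc, c("simple", "locarna"))
    q2 <- withr::with_seed(99, rand_seq(40))
    hom <- paste0(substr(q2, 1, 4), substr(q2, 7, 40))
    subj2 <- paste0(withr::with_seed(7, rand_seq(20)), hom,
                    withr::with_seed(8, rand_seq(20)))
    h2 <- hsp(15, 34, 21 + 14 - 2, 21 + 33 - 2, "plus",
              substr(q2, 15, 34), substr(q2, 15, 34), 20, 1e-4)
    cand_simple <- simple_extend(h2, nchar(q2), nchar(subj2), subj2)$sequence
    cand_loc <- locarna_extend(h2, q2, subj2)$sequence
    expect_false(identical(cand_simple, cand_loc))
    # the scorer decides: rig it for each candidate in turn
    pick_simple <- meta_extend(h2, q2, subj2,
                               function(s) if (identical(s, cand_simple)) 15.5 else 12)
    expect_equal(pick_simple$method, "simple")
    expect_equal(pick_simple$model_score, 15.5)
    pick_loc <- meta_extend(h2, q2, subj2,
                            function(s) if (identical(s, cand_loc)) 15.5 else 12)
    expect_equal(pick_loc$method, "locarna")
    expect_equal(pick_loc$model_score, 15.5)
    # the model scorer agrees with the truth-matching candidate here
    em_model <- meta_extend(h2, q2, subj2, model_scorer(query_model(q2)))
    expect_equal(em_model$method, "locarna")
})

test_that("scorer failures in meta extension carry both candidates", {
    q <- "GGGAAACCCUUUGGGAAACCCAUGCAUGCAU"
    subj <- paste0("ACGUACGUACGUACGUACGU", q, "ACGUACGUACGUACG")
    h <- hsp(14, 24, 34, 44, "plus", substr(q, 14, 24), substr(q, 14, 24), 22, 1e-5)
    err <- tryCatch(meta_extend(h, q, subj, function(s) stop("boom")),
                    rnaxtender_scorer_error = function(e) e)
    expect_s3_class(err, "rnaxtender_scorer_error")
    expect_named(err$candidates, c("simple", "locarna"))
    expect_equal(err$candidates$locarna$sequence, q)
})

test_that("extension configuration validates its invariants", {
    expect_equal(extension_config()$o_loc, 30L)
    expect_error(extension_config(o_loc = -1), "o_loc")
    expect_error(extension_config(gap_open = 1), "gap costs")
})
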