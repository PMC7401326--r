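test_that("dinucleotide shuffle preserves composition and dinucleotide counts", {
    x <- "GGGAAACCCUUUGGGAAACCCAUGCAUGCAU"
    for (seed in 1:10) {
        y <- dinucleotide_shuffle(x, seed = seed)
        expect_equal(nchar(y), nchar(x))
        expect_equal(sort(strsplit(y, "")[[1]]), sort(strsplit(x, "")[[1]]))
        cx <- dinuc_counts(x); cy <- dinuc_counts(y)
        expect_equal(sort(names(cx)), sort(names(cy)))
        expect_equal(as.integer(cy[names(cx)]), as.integer(cx))
    }
    expect_identical(dinucleotide_shuffle(x, seed = 7),
                     dinucleotide_shuffle(x, seed = 7))
    ys <- vapply(1:20, function(s) dinucleotide_shuffle(x, seed = s), character(1))
    expect_gt(length(unique(ys)), 1) # different seeds generally differ
    expect_equal(dinucleotide_shuffle("AC", seed = 1), "AC")
})

test_that("synthetic family generation respects rates and the template", {
    f0 <- generate_synthetic_family(FIXTURE_STRUCT, n = 5, sub_rate = 0,
                                    indel_rate = 0, seed = 3, family_id = "f0",
                                    n_queries_held_out = 1)
    expect_s3_class(f0, "family_spec")
    expect_length(unique(f0$member_seqs), 1) # sub_rate 0 -> identical members
    expect_equal(f0$member_seqs[1], f0$template_seq)

    # compensatory fraction of paired-site substitutions is near the target
    comp_p <- 0.8
    f <- generate_synthetic_family(FIXTURE_STRUCT, n = 60, sub_rate = 0.3,
                                   indel_rate = 0, seed = 4, family_id = "f",
                                   compensatory_prob = comp_p,
                                   n_queries_held_out = 1)
    pr <- secondary_structure(f$template_seq, f$template_structure)$pairs
    tc <- strsplit(f$template_seq, "")[[1]]
    canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
    n_canon <- 0L; n_mut <- 0L
    for (m in f$member_seqs) {
        mc <- strsplit(m, "")[[1]]
        for (k in seq_len(nrow(pr))) {
            i <- pr$i[k]; j <- pr$j[k]
            if (mc[i] != tc[i] || mc[j] != tc[j]) {
                n_mut <- n_mut + 1L
                if (paste0(mc[i], mc[j]) %in% canonical) n_canon <- n_canon + 1L
            }
        }
    }
    frac <- n_canon / n_mut
    se <- sqrt(comp_p * (1 - comp_p) / n_mut)
    # non-compensatory events can stay canonical by chance (< 1/3 of them)
    expect_gte(frac, comp_p - 3 * se)
    expect_lte(frac, comp_p + (1 - comp_p) / 3 + 3 * se)

    # at the default substitution rate, members stay fold-compatible with
    # at least 80 percent of the template pairs
    fd <- generate_synthetic_family(FIXTURE_STRUCT, n = 20, sub_rate = 0.1,
                                    indel_rate = 0, seed = 5, family_id = "fd",
                                    n_queries_held_out = 1)
    prd <- secondary_structure(fd$template_seq, fd$template_structure)$pairs
    for (m in fd$member_seqs) {
        mc <- strsplit(m, "")[[1]]
        ok <- mean(can_pair_chr(mc[prd$i], mc[prd$j]))
        expect_gte(ok, 0.8)
    }
    expect_error(generate_synthetic_family(FIXTURE_STRUCT, n = 3, sub_rate = 1),
                 "rates")
})

test_that("artificial database construction plants members, decoys and truth", {
    f <- generate_synthetic_family(FIXTURE_STRUCT, n = 5, sub_rate = 0.05,
                                   indel_rate = 0, seed = 10, family_id = "famA",
                                   n_queries_held_out = 3, n_decoys_per_seq = 10,
                                   flank_len = 50)
    db <- build_artificial_database(f)
    expect_length(db$queries, 3)
    expect_length(db$subjects, 1)
    expect_equal(sum(!db$truth$is_decoy), 2)  # 5 members - 3 held out
    expect_equal(sum(db$truth$is_decoy), 20)  # 10 decoys per planted member
    # every truth interval recovers the planted sequence
    for (i in seq_len(nrow(db$truth))) {
        sub <- substr(db$subjects[[db$truth$subject_id[i]]],
                      db$truth$start[i], db$truth$end[i])
        expect_equal(nchar(sub), db$truth$end[i] - db$truth$start[i] + 1L)
        expect_true(grepl("^[ACGU]+$", sub))
    }
    planted <- db$truth[!db$truth$is_decoy, ]
    held_out <- names(db$queries)
    for (i in seq_len(nrow(planted))) {
        sub <- substr(db$subjects[[planted$subject_id[i]]],
                      planted$start[i], planted$end[i])
        expect_true(sub %in% f$member_seqs)
    }

    # zero flanks, one member, no decoys: the subject is the member itself
    f2 <- family_spec("tiny", c("GGGAAACCCUUU", "GGGAAACCCUUA"), "(((...)))...",
                      n_queries_held_out = 1, flank_len = 0, n_decoys_per_seq = 0,
                      seed = 2)
    db2 <- build_artificial_database(f2)
    expect_equal(nrow(db2$truth), 1)
    planted_seq <- substr(db2$subjects[[1]], db2$truth$start, db2$truth$end)
    expect_equal(planted_seq, db2$subjects[[1]])
    expect_error(family_spec("x", "ACGU", "....", n_queries_held_out = 3),
                 "at least")
})

test_that("total error is the sum of absolute end offsets", {
    t <- list(subject_id = "s", start = 100L, end = 160L)
    expect_equal(total_error(list(subject_id = "s", start = 100L, end = 160L), t), 0L)
    # 3 nt missing at 5', 2 nt excess at 3'
    expect_equal(total_error(list(subject_id = "s", start = 103L, end = 162L), t), 5L)
    expect_error(total_error(list(subject_id = "other", start = 1L, end = 2L), t),
                 "different subjects")
    # symmetric under a coordinate flip (reverse-complement view of length L)
    withr::with_seed(31, {
        for (i in 1:10) {
            L <- 500L
            ts <- sample.int(300, 1); te <- ts + sample.int(80, 1)
            ps <- ts + sample(-5:5, 1); pe <- te + sample(-5:5, 1)
            fwd <- total_error(list(start = ps, end = pe), list(start = ts, end = te))
            rev <- total_error(list(start = L - pe + 1L, end = L - ps + 1L),
                               list(start = L - te + 1L, end = L - ts + 1L))
            expect_equal(fwd, rev)
        }
    })
})

test_that("quality binning computes tertile thresholds with ties upward", {
    b9 <- bin_by_quality(9:1)
    expect_equal(as.integer(table(b9$bin)), c(3L, 3L, 3L))
    b10 <- bin_by_quality(10:1)
    expect_equal(as.integer(table(b10$bin)), c(4L, 3L, 3L))
    # all HSPs assigned by the truth thresholds, ties to the higher bin
    scores <- c(10, 8, 8, 5, 5, 2)
    b <- bin_by_quality(scores, is_truth = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
    expect_equal(as.character(b$bin[2]), as.character(b$bin[3]))
    expect_error(bin_by_quality(c(1, 2)), "at least 3")
    expect_warning(bdeg <- bin_by_quality(rep(5, 6)), "degenerate")
    expect_true(bdeg$degenerate)
    expect_equal(as.character(unique(bdeg$bin)), "high")
})

test_that("quality bins are written as three parseable BLAST files", {
    hsps <- withr::with_seed(77, lapply(1:6, function(i) rand_hsp(40L, 120L)))
    res <- list(search_result("q1", 40L, list(blast_hit("s1", 120L, hsps[1:3]))),
                search_result("q2", 40L, list(blast_hit("s2", 120L, hsps[4:6]))))
    scores <- vapply(hsps, `[[`, numeric(1), "bit_score")
    b <- bin_by_quality(scores)
    dir <- tempfile()
    paths <- write_quality_bins(res, b$thresholds, dir)
    expect_length(paths, 3)
    n_by_bin <- vapply(paths, function(p) {
        parsed <- parse_blast_text(p)
        sum(unlist(lapply(parsed, function(r) lapply(r$hits, function(h)
            length(h$hsps)))), 0L)
    }, integer(1))
    expect_equal(sum(n_by_bin), length(scores)) # partition: nothing lost
    high <- parse_blast_text(paths[["high"]])
    for (r in high) for (h in r$hits) for (p in h$hsps)
        expect_gte(p$bit_score, b$thresholds[["high"]])
})

test_that("ungapped planted copies are recovered with zero error by all methods", {
    fam <- generate_synthetic_family(FIXTURE_STRUCT, n = 5, sub_rate = 0,
                                     indel_rate = 0, seed = 60, family_id = "exact",
                                     n_decoys_per_seq = 2)
    bx <- run_extension_benchmark(list(fam), flank_len = 80, seed = 61)
    expect_true(all(bx$records$total_error[bx$records$method == "locarna"] == 0))
    expect_true(all(bx$records$total_error[bx$records$method == "meta"] == 0))
    expect_true(all(bx$records$total_error[bx$records$method == "simple"] == 0))
})

test_that("extension benchmark reproduces the method ordering on indel families", {
    fams <- fixture_families(5, seed0 = 300, n = 6, sub_rate = 0.08,
                             indel_rate = 0.04)
    bx <- run_extension_benchmark(fams, flank_len = 120, seed = 19)
    med <- setNames(bx$summary$median, bx$summary$method)
    expect_lte(med[["locarna"]], med[["simple"]])
    # meta picks one of the two component intervals for every single HSP
    rec <- bx$records
    key <- function(df) paste(df$family_id, df$query_id, df$member)
    for (m in c("meta")) {
        dm <- rec[rec$method == "meta", ]
        ds <- rec[rec$method == "simple", ]
        dl <- rec[rec$method == "locarna", ]
        stopifnot(identical(key(dm), key(ds)), identical(key(dm), key(dl)))
        same_simple <- dm$pred_start == ds$pred_start & dm$pred_end == ds$pred_end
        same_loc <- dm$pred_start == dl$pred_start & dm$pred_end == dl$pred_end
        expect_true(all(same_simple | same_loc))
    }
    # summary medians match recomputation from the record table
    for (m in unique(bx$records$method)) {
        expect_equal(med[[m]],
                     median(bx$records$total_error[bx$records$method == m]))
    }
})

test_that("structure benchmark aggregates per bin with bootstrap intervals", {
    fams <- fixture_families(2, seed0 = 400, n = 7, sub_rate = 0.08,
                             indel_rate = 0.02, n_decoys_per_seq = 2)
    bs <- run_structure_benchmark(fams, flank_len = 150, n_boot = 25, seed = 20)
    expect_true(all(c("method", "bin", "n", "mean", "ci_lower", "ci_upper") %in%
                    names(bs$summary)))
    # means match recomputation from the raw records
    ok <- bs$records[!is.na(bs$records$dist) & !bs$records$is_decoy, ]
    for (r in seq_len(nrow(bs$summary))) {
        g <- ok[ok$method == bs$summary$method[r] & ok$bin == bs$summary$bin[r], ]
        expect_equal(bs$summary$mean[r], mean(g$dist))
        expect_equal(bs$summary$n[r], nrow(g))
    }
    # only observed bins appear; none has zero records
    expect_true(all(bs$summary$n > 0))
    expect_true(all(bs$summary$ci_lower <= bs$summary$mean + 1e-12))
    expect_true(all(bs$summary$ci_upper >= bs$summary$mean - 1e-12))
    # the decoy baseline sits above the homolog distances
    expect_gt(bs$decoy_baseline$mean[1], mean(ok$dist))

    # n_boot = 1 collapses the interval to the point estimate
    bs1 <- run_structure_benchmark(fams[1], flank_len = 150, n_boot = 1, seed = 20)
    expect_equal(bs1$summary$ci_lower, bs1$summary$mean)
    expect_equal(bs1$summary$ci_upper, bs1$summary$mean)
})
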