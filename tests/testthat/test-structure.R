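test_that("secondary structure construction validates its invariants", {
    s <- secondary_structure("GGGAAACCC", "(((...)))")
    expect_equal(nrow(s$pairs), 3)
    expect_equal(s$pairs$i, 1:3)
    expect_equal(s$pairs$j, 9:7)
    expect_error(secondary_structure("ACGUA", "(((."), "length")
    expect_error(secondary_structure("ACGUA", "(()))"), "ill-nested")
    expect_error(secondary_structure("ACGUA", "((.))"), "hairpin")
})

test_that("maximum-pairing fold matches exhaustive enumeration", {
    expect_equal(fold("GGGAAACCC")$dotbracket, "(((...)))")
    expect_equal(fold("AAAAAA")$dotbracket, "......")
    for (seed in 1:15) {
        s <- withr::with_seed(seed, rand_seq(sample(5:9, 1)))
        got <- fold(s)
        expect_equal(nrow(got$pairs), oracle_max_pairs(s))
        # returned structure is itself valid and canonical
        for (k in seq_len(nrow(got$pairs))) {
            a <- substr(canon_rna(s), got$pairs$i[k], got$pairs$i[k])
            b <- substr(canon_rna(s), got$pairs$j[k], got$pairs$j[k])
            expect_true(can_pair <- paste0(a, b) %in%
                        c("AU", "UA", "GC", "CG", "GU", "UG"))
            expect_gt(got$pairs$j[k] - got$pairs$i[k], 3)
        }
    }
})

test_that("constrained folds honor constraints and stay optimal", {
    # forcing position 1 unpaired costs exactly one pair here
    f <- fold("GGGAAACCC", constraints = list(unpaired = 1L))
    expect_equal(nrow(f$pairs), 2)
    expect_equal(nrow(f$pairs), oracle_max_pairs("GGGAAACCC", unpaired = 1L))
    # random constrained instances against the enumeration oracle
    for (seed in 16:25) {
        withr::with_seed(seed, {
            s <- rand_seq(sample(6:9, 1))
            u <- sample.int(nchar(s), 2)
            got <- fold(s, constraints = list(unpaired = u))
            expect_equal(nrow(got$pairs), oracle_max_pairs(s, unpaired = u))
            expect_false(any(c(got$pairs$i, got$pairs$j) %in% u))
        })
    }
    # constraint monotonicity: constraints never increase the pair count
    for (seed in 26:35) {
        withr::with_seed(seed, {
            s <- rand_seq(12)
            u <- sample.int(12, 3)
            expect_gte(nrow(fold(s)$pairs),
                       nrow(fold(s, constraints = list(unpaired = u))$pairs))
        })
    }
})

test_that("forced pairs are kept and contradictions raise errors", {
    f <- fold("GGGAAACCC", constraints = list(pairs = cbind(2L, 8L)))
    expect_true(any(f$pairs$i == 2 & f$pairs$j == 8))
    expect_error(fold("GGGAAACCC", constraints = list(unpaired = 2L,
                                                      pairs = cbind(2L, 8L))),
                 "contradictory")
    expect_error(fold("GGGAAACCC", constraints = list(pairs = cbind(1L, 3L))),
                 "contradictory") # violates the minimum loop
    expect_error(fold("AAGAAACAA", constraints = list(pairs = cbind(1L, 9L))),
                 "contradictory") # A-A cannot pair
})

test_that("suboptimal structures come in exact non-increasing pair-count order", {
    s1 <- suboptimal("GGGAAACCC", 1)
    expect_length(s1, 1)
    expect_equal(s1[[1]]$dotbracket, fold("GGGAAACCC")$dotbracket)

    s3 <- suboptimal("GGGAAACCC", 3)
    counts <- vapply(s3, function(x) nrow(x$pairs), integer(1))
    expect_equal(counts, c(3L, 2L, 2L))
    # against the enumeration oracle: the k-th best count matches
    all_counts <- sort(vapply(oracle_all_structures("GGGAAACCC"), nrow, integer(1)),
                       decreasing = TRUE)
    expect_equal(counts, all_counts[1:3])
    # structures are distinct and valid
    expect_equal(anyDuplicated(vapply(s3, `[[`, "", "dotbracket")), 0L)

    for (seed in 40:45) {
        s <- withr::with_seed(seed, rand_seq(8))
        k <- 4
        subs <- suboptimal(s, k)
        counts <- vapply(subs, function(x) nrow(x$pairs), integer(1))
        oc <- sort(vapply(oracle_all_structures(s), nrow, integer(1)),
                   decreasing = TRUE)
        expect_equal(counts, oc[seq_along(counts)])
        expect_equal(anyDuplicated(vapply(subs, `[[`, "", "dotbracket")), 0L)
        expect_lte(length(subs), k)
    }
})

test_that("query-anchored MSA merges pairwise alignments on query columns", {
    refs <- c(r1 = "GGGAAACCC", r2 = "GGGAAACCC")
    msa <- query_anchored_msa("GGGAAACCC", refs)
    expect_equal(unname(nchar(msa$rows)), rep(9L, 3))
    expect_false(any(grepl("-", msa$rows)))

    # one reference with one insertion opens exactly one insertion column
    refs2 <- c(r1 = "GGGAAAACCC")
    msa2 <- query_anchored_msa("GGGAAACCC", refs2)
    expect_equal(unname(nchar(msa2$rows[1])), 10L)
    expect_equal(sum(is.na(msa2$query_pos)), 1L)
    expect_error(query_anchored_msa("GGGAAACCC", character(0)), "at least one")
})

test_that("MSA column count equals the independent merge of pairwise alignments", {
    for (seed in 1:8) {
        withr::with_seed(seed, {
            q <- rand_seq(15)
            refs <- vapply(1:3, function(i) rand_seq(sample(12:18, 1)), character(1))
            names(refs) <- paste0("r", 1:3)
            msa <- query_anchored_msa(q, refs)
            cfg <- extension_config()
            # oracle: per-slot maximum insertion length over the pairwise
            # alignments, recomputed directly from the alignment operations
            ins <- matrix(0L, length(refs), nchar(q) + 1L)
            for (r in seq_along(refs)) {
                res <- rnaxtender:::cpp_affine_align(
                    canon_rna(q), canon_rna(refs[[r]]), 1, -1, -2, -1,
                    FALSE, FALSE, TRUE, TRUE)
                ops <- strsplit(res$ops, "")[[1]]
                qi <- cumsum(ops != "W")
                for (k in seq_along(ops)) if (ops[k] == "W")
                    ins[r, qi[k] + 1L] <- ins[r, qi[k] + 1L] + 1L
            }
            expected_cols <- nchar(q) + sum(apply(ins, 2, max))
            expect_equal(unname(nchar(msa$rows[1])), expected_cols)
        })
    }
})

test_that("consensus structure reduces to the single-sequence fold on identical rows", {
    rows <- rep("GGGAAACCC", 3)
    cons <- consensus_structure(rows)
    expect_equal(cons$structure$dotbracket, fold("GGGAAACCC")$dotbracket)
    expect_equal(cons$structure$sequence, "GGGAAACCC")
})

test_that("covariation earns consensus pairs a bonus", {
    # compensatory GC -> AU at columns 2/8; both rows pair, two pair types
    rows <- c("AGGAAACCA", "AAGAAACUA")
    cfg <- consensus_config(min_support_frac = 0.5, covariation_bonus = 1)
    cons <- consensus_structure(rows, cfg)
    expect_true(any(cons$structure$pairs$i == 2 & cons$structure$pairs$j == 8))
    # direct score audit: support 2 + bonus 1
    k <- which(cons$structure$pairs$i == 2)
    expect_equal(cons$support[k], 2L)
})

test_that("rows with no common pairs give an empty consensus", {
    rows <- c("GGGGAAAAAA", "AAAAAAGGGG")
    cons <- consensus_structure(rows)
    expect_equal(nrow(cons$structure$pairs), 0)
    expect_error(consensus_structure("GGGAAACCC"), "at least 2")
    expect_error(consensus_structure(c("ACGU", "ACGUA")), "unequal")
})

test_that("structure selection minimizes tree edit distance with stable ties", {
    cands <- list(secondary_structure("GGGAAACCC", "(((...)))"),
                  secondary_structure("GGGAAACCC", ".((...))."),
                  secondary_structure("GGGAAACCC", "........."))
    ref <- secondary_structure("GGGAAACCC", ".((...)).")
    sel <- select_by_reference(cands, ref)
    expect_equal(attr(sel, "index"), 2L)
    expect_equal(attr(sel, "distance"), 0)
    # argmin verified against the full distance table
    d <- vapply(cands, tree_edit_distance, numeric(1), b = ref)
    expect_equal(attr(sel, "index"), which.min(d))
    # single candidate returns itself
    one <- select_by_reference(cands[1], ref)
    expect_equal(attr(one, "index"), 1L)
})

test_that("reference selection keeps dissimilar homologs ordered by score", {
    q <- "GGGGGAAAACCCCCAAAAGGGGAAAACCCC"
    mk <- function(seq, id) structure(
        list(subject_id = id, sequence = seq, method = "locarna"),
        class = "extended_match")
    near_q <- q
    div1 <- paste0("AU", substr(q, 3, 28), "AU")
    div2 <- paste0("UA", substr(q, 3, 28), "GC")
    matches <- list(mk(near_q, "ident"), mk(div1, "div1"), mk(div2, "div2"),
                    mk(div1, "unc1"), mk(div2, "unc2"))
    calls <- tibble::tibble(s = c(60, 40, 50, 10, 5), l = 30,
                            label = c("homologous", "homologous", "homologous",
                                      "uncertain", "uncertain"),
                            error = NA_character_)
    refs <- select_reference_sequences(matches, calls, q)
    # the identical sequence and the non-homologous calls are excluded
    expect_false("ident" %in% names(refs))
    expect_equal(names(refs), c("div2", "div1")) # descending score
    # identity oracle recount: every kept reference is below the threshold
    for (r in refs) expect_lte(identity_fraction(r, q), 0.98)
    # all matches identical to the query -> empty selection
    same <- list(mk(q, "a"), mk(q, "b"))
    calls2 <- tibble::tibble(s = c(60, 60), l = 30,
                             label = "homologous", error = NA_character_)
    expect_length(select_reference_sequences(same, calls2, q), 0)
})

test_that("identity_fraction equals a direct alignment recount", {
    for (seed in 1:6) {
        withr::with_seed(seed, {
            a <- rand_seq(12); b <- rand_seq(10)
            cfg <- extension_config()
            res <- rnaxtender:::cpp_affine_align(canon_rna(a), canon_rna(b),
                                                 1, -1, -2, -1,
                                                 FALSE, FALSE, FALSE, FALSE)
            ops <- strsplit(res$ops, "")[[1]]
            ac <- strsplit(canon_rna(a), "")[[1]]
            bc <- strsplit(canon_rna(b), "")[[1]]
            ai <- cumsum(ops != "W"); bi <- cumsum(ops != "Q")
            matches <- sum(ops == "M" & ac[pmax(ai, 1)] == bc[pmax(bi, 1)])
            expect_equal(identity_fraction(a, b), matches / length(ops))
        })
    }
    expect_equal(identity_fraction("ACGU", "ACGU"), 1)
})

test_that("every registered method yields a structure or a typed absence", {
    reg <- prediction_methods()
    expect_equal(nrow(reg), 15)
    expect_setequal(reg$category, c(1L, 2L))
    q <- "GGGAAACCCUUUGGGAAACCC"
    refs <- c(r1 = "GGCAAAGCCUUUGGGAAACCC", r2 = "GGGAAACCCUUAGGGAAACCC")
    ctx_full <- predict_context(q, references = refs, all_match_seqs = unname(refs),
                                cm_structure = fold(q))
    ctx_bare <- predict_context(q)
    for (m in reg$name) {
        for (ctx in list(ctx_full, ctx_bare)) {
            out <- predict_structure(m, "GGGAAACCCUUUGGGAAACCC", ctx)
            expect_true(inherits(out, "secondary_structure") ||
                        inherits(out, "structure_absence"),
                        label = sprintf("method %s returned %s", m, class(out)[1]))
            if (inherits(out, "structure_absence"))
                expect_match(out$reason, "model|engine|reference")
        }
    }
    expect_error(predict_structure("nope", "ACGU", ctx_bare), "registered")
})

test_that("recipe dispatch follows the registry semantics", {
    q <- "GGGAAACCC"
    ctx <- predict_context(q)
    expect_equal(predict_structure("rnafold", "GGGAAACCC", ctx)$dotbracket,
                 "(((...)))")
    # no covariance model -> typed absence
    ab <- predict_structure("rfam-Rc", "GGGAAACCC", ctx)
    expect_s3_class(ab, "structure_absence")
    expect_match(ab$reason, "covariance model")
    # fq-sub: the query's fold is among the suboptimals -> distance 0
    out <- predict_structure("fq-sub", "GGGAAACCC", ctx)
    expect_equal(out$dotbracket, "(((...)))")
    # an engine adapter is used when configured
    ctx_eng <- predict_context(q, engines = list(
        turbofold = function(seq, refs) strrep(".", nchar(seq))),
        all_match_seqs = "GGGAAACCC")
    te <- predict_structure("Turbo-fast", "GGGAAACCC", ctx_eng)
    expect_equal(te$dotbracket, ".........")
})

test_that("tree edit distance is a metric matching brute force on small trees", {
    expect_equal(tree_edit_distance("(((...)))", "(((...)))"), 0)
    expect_equal(tree_edit_distance("(((...)))", "........."), 9)
    expect_error(tree_edit_distance("(()", ".."), "ill-nested")

    dbs <- unlist(lapply(4:7, oracle_all_dotbrackets))
    dbs <- c("", ".", "..", dbs)
    set <- withr::with_seed(11, sample(dbs, min(18, length(dbs))))
    for (a in set) for (b in set) {
        expect_equal(tree_edit_distance(a, b), oracle_tree_dist(a, b),
                     label = sprintf("ted('%s','%s')", a, b))
    }
    # symmetry and triangle inequality on random triples
    withr::with_seed(12, {
        for (i in 1:15) {
            tri <- sample(dbs, 3)
            dab <- tree_edit_distance(tri[1], tri[2])
            dba <- tree_edit_distance(tri[2], tri[1])
            dbc <- tree_edit_distance(tri[2], tri[3])
            dac <- tree_edit_distance(tri[1], tri[3])
            expect_equal(dab, dba)
            expect_lte(dac, dab + dbc)
        }
    })
})

test_that("base-pair distance is the symmetric difference of pair sets", {
    expect_equal(basepair_distance("(((...)))", "(((...)))"), 0)
    expect_equal(basepair_distance("(((...)))", "........."), 3)
    expect_error(basepair_distance("((...))", "........."), "unequal")
    withr::with_seed(13, {
        for (i in 1:10) {
            s <- rand_seq(9)
            a <- fold(s)$dotbracket
            b <- sample(oracle_all_dotbrackets(9), 1)
            expect_equal(basepair_distance(a, b) == 0, identical(a, b))
        }
    })
})
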