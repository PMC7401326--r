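# Secondary structure prediction and comparison.
#
# The built-in folder maximizes the number of canonical base pairs
# (Watson-Crick + GU) subject to a minimum hairpin loop and optional hard
# constraints; it is a deliberately simple combinatorial engine — all
# thermodynamic engines are external command adapters behind the same
# method registry. The registry implements the recipe logic: consensus
# structures from query-anchored alignments feeding constrained folds,
# selection among suboptimal structures by tree edit distance to a
# reference, and covariance-model consensus constraints.

#' Construct a secondary structure
#'
#' @param sequence nucleotide string.
#' @param dotbracket dot-bracket string of the same length; only nested
#'   structures are supported (no pseudoknot bracket layers).
#' @param min_loop minimum hairpin loop size enforced on the pairs.
#' @return object of class `"secondary_structure"` with fields
#'   `sequence`, `dotbracket` and `pairs` (data frame `i < j`, 1-based).
#' @export
secondary_structure <- function(sequence, dotbracket, min_loop = 3L) {
    if (nchar(sequence) != nchar(dotbracket))
        stop_input("sequence and structure lengths differ (%d vs %d)",
                   nchar(sequence), nchar(dotbracket))
    if (!grepl("^[().]*$", dotbracket))
        stop_input("structure contains characters other than '(', ')' and '.'")
    pairs <- db_to_pairs(dotbracket)
    if (nrow(pairs) && any(pairs$j - pairs$i <= min_loop))
        stop_input("structure violates the minimum hairpin loop of %d", min_loop)
    structure(list(sequence = sequence, dotbracket = dotbracket, pairs = pairs),
              class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
    cat(sprintf("<secondary_structure> %d nt, %d pair(s)\n%s\n%s\n",
                nchar(x$sequence), nrow(x$pairs), x$sequence, x$dotbracket))
    invisible(x)
}

# dot-bracket -> data.frame(i, j); errors on ill-nesting
db_to_pairs <- function(db) {
    ch <- str_chars(db)
    stack <- integer(0)
    i <- integer(0); j <- integer(0)
    for (k in seq_along(ch)) {
        if (ch[k] == "(") {
            stack <- c(stack, k)
        } else if (ch[k] == ")") {
            if (!length(stack)) stop_input("ill-nested structure: unmatched ')' at %d", k)
            i <- c(i, stack[length(stack)])
            j <- c(j, k)
            stack <- stack[-length(stack)]
        }
    }
    if (length(stack)) stop_input("ill-nested structure: unmatched '(' at %d", stack[1])
    o <- order(i)
    data.frame(i = as.integer(i[o]), j = as.integer(j[o]))
}

pairs_to_db <- function(n, pair_i, pair_j) {
    ch <- rep(".", n)
    ch[pair_i] <- "("
    ch[pair_j] <- ")"
    paste(ch, collapse = "")
}

#' Folding configuration
#'
#' @param min_loop minimum hairpin loop size (unpaired bases enclosed by
#'   a pair); default 3.
#' @return list of class `"fold_config"`.
#' @export
fold_config <- function(min_loop = 3L) {
    structure(list(min_loop = as.integer(min_loop)), class = "fold_config")
}

normalize_constraints <- function(constraints, n) {
    unpaired <- integer(0)
    pairs <- matrix(integer(0), ncol = 2)
    if (!is.null(constraints)) {
        if (!is.null(constraints$unpaired)) unpaired <- as.integer(constraints$unpaired)
        if (!is.null(constraints$pairs)) {
            p <- constraints$pairs
            if (is.data.frame(p)) p <- as.matrix(p[, 1:2])
            pairs <- matrix(as.integer(p), ncol = 2)
        }
    }
    if (length(unpaired) && (min(unpaired) < 1 || max(unpaired) > n))
        stop_input("unpaired constraint out of range")
    if (nrow(pairs)) {
        if (min(pairs) < 1 || max(pairs) > n) stop_input("pair constraint out of range")
        bad <- intersect(unpaired, as.vector(pairs))
        if (length(bad))
            stop_input("contradictory constraints: position %d both paired and unpaired", bad[1])
    }
    list(unpaired = unpaired, pairs = pairs)
}

#' Fold a sequence by constrained maximum base pairing
#'
#' Returns the structure with the maximum number of canonical pairs
#' (Watson-Crick + GU, T treated as U) honoring the constraints.
#' Traceback is deterministic (the 3'-most base pairs with its 5'-most
#' admissible partner; pairing preferred over leaving unpaired).
#'
#' @param seq nucleotide string.
#' @param constraints optional list with `unpaired` (integer positions
#'   forced unpaired) and `pairs` (two-column matrix of forced pairs).
#' @param config a [fold_config()].
#' @return a [secondary_structure()].
#' @export
fold <- function(seq, constraints = NULL, config = fold_config()) {
    n <- nchar(seq)
    if (!is_nucleotide_string(seq)) stop_input("sequence contains non-IUPAC characters")
    cn <- normalize_constraints(constraints, n)
    unp <- rep(FALSE, n)
    unp[cn$unpaired] <- TRUE
    res <- cpp_fold(canon_rna(seq), config$min_loop, unp,
                    as.integer(cn$pairs[, 1]), as.integer(cn$pairs[, 2]),
                    integer(0), integer(0))
    if (!isTRUE(res$feasible))
        stop_input("contradictory folding constraints")
    secondary_structure(seq, pairs_to_db(n, res$pair_i, res$pair_j), config$min_loop)
}

# constrained fold returning NULL on infeasibility (internal, used by the
# k-best search where infeasible branches are simply pruned)
fold_or_null <- function(cseq, min_loop, forced, banned) {
    res <- cpp_fold(cseq, min_loop, rep(FALSE, nchar(cseq)),
                    forced[, 1], forced[, 2], banned[, 1], banned[, 2])
    if (!isTRUE(res$feasible)) return(NULL)
    list(pair_i = res$pair_i, pair_j = res$pair_j, n_pairs = res$n_pairs)
}

#' Best and suboptimal structures by pair count
#'
#' Enumerates the k best distinct structures in non-increasing pair-count
#' order, exactly at any length, by a Lawler-style partition search: each
#' subproblem fixes some pairs of an already-emitted structure and bans
#' one, and is solved by the constrained folding kernel. Deterministic.
#' Fewer than `k` structures are returned when the structure space is
#' exhausted.
#'
#' @param seq nucleotide string.
#' @param k number of structures (>= 1).
#' @param config a [fold_config()].
#' @return list of [secondary_structure()], non-increasing pair counts,
#'   first element equal to [fold()].
#' @export
suboptimal <- function(seq, k, config = fold_config()) {
    if (k < 1) stop_input("k must be >= 1")
    n <- nchar(seq)
    cseq <- canon_rna(seq)
    empty <- matrix(integer(0), ncol = 2)
    root <- fold_or_null(cseq, config$min_loop, empty, empty)
    out <- list()
    nodes <- list(list(forced = empty, banned = empty, sol = root, id = 1L))
    next_id <- 2L
    while (length(out) < k && length(nodes)) {
        np <- vapply(nodes, function(nd) nd$sol$n_pairs, integer(1))
        ids <- vapply(nodes, function(nd) nd$id, integer(1))
        pick <- order(-np, ids)[1]
        nd <- nodes[[pick]]
        nodes <- nodes[-pick]
        out[[length(out) + 1L]] <- secondary_structure(
            seq, pairs_to_db(n, nd$sol$pair_i, nd$sol$pair_j), config$min_loop)
        sol_pairs <- cbind(nd$sol$pair_i, nd$sol$pair_j)
        if (nrow(nd$forced)) {
            fixed_key <- paste(nd$forced[, 1], nd$forced[, 2])
            free <- !(paste(sol_pairs[, 1], sol_pairs[, 2]) %in% fixed_key)
        } else free <- rep(TRUE, nrow(sol_pairs))
        free_pairs <- sol_pairs[free, , drop = FALSE]
        if (nrow(free_pairs)) {
            o <- order(free_pairs[, 1], free_pairs[, 2])
            free_pairs <- free_pairs[o, , drop = FALSE]
        }
        for (t in seq_len(nrow(free_pairs))) {
            forced <- rbind(nd$forced, free_pairs[seq_len(t - 1L), , drop = FALSE])
            banned <- rbind(nd$banned, free_pairs[t, , drop = FALSE])
            sol <- fold_or_null(cseq, config$min_loop, forced, banned)
            if (!is.null(sol)) {
                nodes[[length(nodes) + 1L]] <- list(forced = forced, banned = banned,
                                                    sol = sol, id = next_id)
                next_id <- next_id + 1L
            }
        }
    }
    out
}

# ---------------------------------------------------------------------------
# Query-anchored multiple alignment and consensus structure

#' Query-anchored multiple sequence alignment
#'
#' Each reference is pairwise-aligned to the query (free end gaps on the
#' reference) and the pairwise alignments are merged on the query
#' coordinates: every query position is one column, and the longest
#' insertion observed between two query positions opens that many
#' insertion columns (insertions are left-justified).
#'
#' @param query_seq query sequence (the anchor row).
#' @param reference_seqs named character vector of reference sequences
#'   (>= 1).
#' @param config an [extension_config()] supplying alignment scores.
#' @return object of class `"query_msa"`: `rows` (named character vector,
#'   query first) and `query_pos` (per column: query position or `NA`
#'   for insertion columns).
#' @export
query_anchored_msa <- function(query_seq, reference_seqs, config = extension_config()) {
    if (!length(reference_seqs)) stop_input("at least one reference sequence is required")
    L <- nchar(query_seq)
    nms <- names(reference_seqs)
    if (is.null(nms)) nms <- paste0("ref", seq_along(reference_seqs))

    # per reference: residues aligned to each query position (NA = gap) and
    # insertion strings in the L+1 slots between/around query positions
    placed <- lapply(reference_seqs, function(ref) {
        res <- cpp_affine_align(canon_rna(query_seq), canon_rna(ref),
                                config$match_reward, config$mismatch_penalty,
                                config$gap_open, config$gap_extend,
                                FALSE, FALSE, TRUE, TRUE)
        ops <- str_chars(res$ops)
        rc <- str_chars(toupper(ref))
        qi <- cumsum(ops != "W") # query pos consumed (for M/Q)
        ri <- cumsum(ops != "Q") # ref pos consumed (for M/W)
        at <- rep(NA_character_, L)
        ins <- vector("list", L + 1L)
        for (col in seq_along(ops)) {
            if (ops[col] == "M") at[qi[col]] <- rc[ri[col]]
            else if (ops[col] == "W") {
                slot <- qi[col] + 1L # insertion before query position slot
                ins[[slot]] <- c(ins[[slot]], rc[ri[col]])
            }
        }
        list(at = at, ins = vapply(ins, function(x) paste(x, collapse = ""), character(1)))
    })
    ins_len <- vapply(seq_len(L + 1L), function(s)
        max(c(0L, vapply(placed, function(p) nchar(p$ins[s]), integer(1)))), integer(1))

    build_row <- function(at, ins) {
        parts <- character(0)
        for (s in seq_len(L + 1L)) {
            pad <- ins_len[s] - nchar(ins[s])
            parts <- c(parts, paste0(ins[s], strrep("-", pad)))
            if (s <= L) parts <- c(parts, if (is.na(at[s])) "-" else at[s])
        }
        paste(parts, collapse = "")
    }
    qrow <- build_row(str_chars(toupper(query_seq)), rep("", L + 1L))
    rows <- c(query = qrow,
              setNames(vapply(placed, function(p) build_row(p$at, p$ins), character(1)), nms))
    qpos <- integer(0)
    for (s in seq_len(L + 1L)) {
        qpos <- c(qpos, rep(NA_integer_, ins_len[s]), if (s <= L) s else integer(0))
    }
    structure(list(rows = rows, query_pos = qpos), class = "query_msa")
}

#' Consensus structure configuration
#'
#' @param min_support_frac minimum fraction of rows that must be able to
#'   pair at a column pair for it to enter the consensus (at least two
#'   rows are always required).
#' @param covariation_bonus score bonus for a column pair supported by at
#'   least two distinct pair types (covariation evidence).
#' @param min_loop minimum hairpin loop on column indices.
#' @return list of class `"consensus_config"`.
#' @export
consensus_config <- function(min_support_frac = 0.5, covariation_bonus = 1,
                             min_loop = 3L) {
    if (min_support_frac <= 0 || min_support_frac > 1)
        stop_input("min_support_frac must be in (0, 1]")
    structure(list(min_support_frac = min_support_frac,
                   covariation_bonus = covariation_bonus,
                   min_loop = as.integer(min_loop)),
              class = "consensus_config")
}

#' Consensus secondary structure of an alignment
#'
#' Scores each column pair by the number of rows whose residues can pair
#' (plus a covariation bonus when at least two distinct pair types
#' occur), drops pairs supported by fewer than `max(2,
#' ceiling(min_support_frac * nrows))` rows, and reports the
#' maximum-score nested structure over columns together with the
#' conserved-unpaired columns (unpaired in the consensus, modal residue
#' in at least `min_support_frac` of the rows).
#'
#' @param alignment a `"query_msa"` or character vector of >= 2
#'   equal-length aligned rows.
#' @param config a [consensus_config()].
#' @return object of class `"consensus_structure"`: `structure` (a
#'   [secondary_structure()] over columns), `support` (rows supporting
#'   each consensus pair), `conserved_unpaired` (column indices) and
#'   `query_pos` (column -> query position map when available).
#' @export
consensus_structure <- function(alignment, config = consensus_config()) {
    query_pos <- NULL
    rows <- if (inherits(alignment, "query_msa")) {
        query_pos <- alignment$query_pos
        alignment$rows
    } else alignment
    if (length(rows) < 2) stop_input("consensus requires at least 2 alignment rows")
    widths <- nchar(rows)
    if (length(unique(widths)) != 1) stop_input("alignment rows of unequal length")
    C <- widths[1]
    R <- length(rows)
    mat <- do.call(rbind, strsplit(canon_rna(rows), "", fixed = TRUE))

    need <- max(2L, ceiling(config$min_support_frac * R))
    W <- matrix(0, C, C)
    for (a in seq_len(C)) {
        bmax <- C
        bs <- seq_len(C)
        bs <- bs[bs > a + config$min_loop]
        if (!length(bs)) next
        xa <- mat[, a]
        for (b in bs) {
            ok <- can_pair_chr(xa, mat[, b])
            cnt <- sum(ok)
            if (cnt < need) next
            types <- unique(paste0(xa[ok], mat[ok, b]))
            W[a, b] <- cnt + if (length(types) >= 2) config$covariation_bonus else 0
        }
    }
    res <- cpp_fold_weighted(W, config$min_loop)
    pair_i <- res$pair_i; pair_j <- res$pair_j

    # consensus sequence: modal non-gap residue per column ('N' if all gaps)
    cons_seq <- vapply(seq_len(C), function(cc) {
        x <- mat[, cc]
        x <- x[x != "-"]
        if (!length(x)) return("N")
        tab <- sort(table(x), decreasing = TRUE)
        names(tab)[1]
    }, character(1))
    db <- pairs_to_db(C, pair_i, pair_j)
    ss <- secondary_structure(paste(cons_seq, collapse = ""), db, config$min_loop)

    support <- if (length(pair_i))
        vapply(seq_along(pair_i), function(k)
            sum(can_pair_chr(mat[, pair_i[k]], mat[, pair_j[k]])), integer(1))
    else integer(0)

    paired_cols <- c(pair_i, pair_j)
    conserved <- vapply(seq_len(C), function(cc) {
        x <- mat[, cc]
        nx <- x[x != "-"]
        length(nx) > 0 && max(table(nx)) >= config$min_support_frac * R
    }, logical(1))
    conserved_unpaired <- setdiff(which(conserved), paired_cols)

    structure(list(structure = ss, support = support,
                   conserved_unpaired = as.integer(conserved_unpaired),
                   query_pos = query_pos),
              class = "consensus_structure")
}

# ---------------------------------------------------------------------------
# Reference selection and structure selection

#' Reference sequence selection rules
#'
#' @param max_identity_to_query matches over alignment columns above
#'   which a sequence is considered (nearly) identical to the query and
#'   excluded (such sequences distort consensus prediction).
#' @param max_mutual_identity pairwise dereplication threshold among the
#'   selected references.
#' @return list of class `"reference_selection"`.
#' @export
reference_selection <- function(max_identity_to_query = 0.98,
                                max_mutual_identity = 0.99) {
    if (max_identity_to_query <= 0 || max_identity_to_query > 1 ||
        max_mutual_identity <= 0 || max_mutual_identity > 1)
        stop_input("identity thresholds must be in (0, 1]")
    structure(list(max_identity_to_query = max_identity_to_query,
                   max_mutual_identity = max_mutual_identity),
              class = "reference_selection")
}

#' Pairwise identity as matches over alignment columns
#'
#' Global alignment (no free end gaps) under the default scores; identity
#' is the number of identical aligned residue columns divided by the
#' total number of alignment columns.
#'
#' @param a,b nucleotide strings.
#' @param config an [extension_config()].
#' @return fraction in `[0, 1]`.
#' @export
identity_fraction <- function(a, b, config = extension_config()) {
    res <- cpp_affine_align(canon_rna(a), canon_rna(b),
                            config$match_reward, config$mismatch_penalty,
                            config$gap_open, config$gap_extend,
                            FALSE, FALSE, FALSE, FALSE)
    ops <- str_chars(res$ops)
    ai <- cumsum(ops != "W"); bi <- cumsum(ops != "Q")
    ac <- str_chars(canon_rna(a)); bc <- str_chars(canon_rna(b))
    matches <- sum(ops == "M" & ac[pmax(ai, 1)] == bc[pmax(bi, 1)])
    matches / length(ops)
}

#' Select reference sequences for category-1 prediction methods
#'
#' Keeps homologous-labeled matches whose identity to the query does not
#' exceed the threshold, orders them by descending model score, and
#' dereplicates nearly identical sequences.
#'
#' @param matches list of `"extended_match"` objects.
#' @param calls the matching rows of [score_and_classify()] (1:1 with
#'   `matches`).
#' @param query_seq query sequence.
#' @param selection a [reference_selection()].
#' @param config an [extension_config()] for the identity alignments.
#' @return named character vector of reference sequences (possibly
#'   empty), names from subject ids.
#' @export
select_reference_sequences <- function(matches, calls, query_seq,
                                       selection = reference_selection(),
                                       config = extension_config()) {
    if (length(matches) != nrow(calls))
        stop_input("matches and calls are not aligned 1:1")
    keep <- which(!is.na(calls$label) & calls$label == "homologous")
    if (!length(keep)) return(setNames(character(0), character(0)))
    seqs <- vapply(matches[keep], function(m) m$sequence, character(1))
    ids <- vapply(matches[keep], function(m)
        if (is.na(m$subject_id)) "match" else m$subject_id, character(1))
    scores <- calls$s[keep]
    idq <- vapply(seqs, identity_fraction, numeric(1), b = query_seq, config = config)
    ok <- idq <= selection$max_identity_to_query
    seqs <- seqs[ok]; ids <- ids[ok]; scores <- scores[ok]
    if (!length(seqs)) return(setNames(character(0), character(0)))
    o <- order(-scores, ids)
    seqs <- seqs[o]; ids <- ids[o]
    sel <- integer(0)
    for (i in seq_along(seqs)) {
        dup <- any(vapply(sel, function(j)
            identity_fraction(seqs[i], seqs[j], config) > selection$max_mutual_identity,
            logical(1)))
        if (!dup) sel <- c(sel, i)
    }
    setNames(seqs[sel], ids[sel])
}

#' Select the candidate structure closest to a reference
#'
#' @param candidates list of [secondary_structure()] (>= 1).
#' @param reference_structure a [secondary_structure()] (its sequence may
#'   differ from the candidates').
#' @return the candidate minimizing [tree_edit_distance()] to the
#'   reference (ties to the earlier candidate), with the distance in
#'   `attr(, "distance")` and its index in `attr(, "index")`.
#' @export
select_by_reference <- function(candidates, reference_structure) {
    if (!length(candidates)) stop_input("at least one candidate is required")
    d <- vapply(candidates, tree_edit_distance, numeric(1), b = reference_structure)
    k <- which.min(d)
    out <- candidates[[k]]
    attr(out, "distance") <- d[k]
    attr(out, "index") <- k
    out
}

#' Base-pair distance between two structures of equal length
#'
#' Size of the symmetric difference of the two base-pair sets.
#'
#' @param a,b [secondary_structure()] objects or dot-bracket strings of
#'   equal length.
#' @return non-negative integer count.
#' @export
basepair_distance <- function(a, b) {
    pa <- if (inherits(a, "secondary_structure")) a else secondary_structure(strrep("N", nchar(a)), a)
    pb <- if (inherits(b, "secondary_structure")) b else secondary_structure(strrep("N", nchar(b)), b)
    if (nchar(pa$dotbracket) != nchar(pb$dotbracket))
        stop_input("structures of unequal length")
    ka <- paste(pa$pairs$i, pa$pairs$j)
    kb <- paste(pb$pairs$i, pb$pairs$j)
    length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# ---------------------------------------------------------------------------
# Method registry and dispatch

#' Registry of secondary structure prediction methods
#'
#' Category 1 methods pool reference sequences from the search output;
#' category 2 methods use only the match itself (plus, for the rfam-*
#' recipes, a covariance-model consensus structure). Methods backed by
#' external engines return a typed absence when no engine adapter is
#' configured. The C-* and M-* name pairs denote the two multiple-aligner
#' back-ends; with the built-in aligner they map to the same recipe but
#' stay distinct registry entries.
#'
#' @return tibble with columns `name`, `category`,
#'   `needs_reference_seqs`, `needs_cm`, `needs_external`, `description`.
#' @export
prediction_methods <- function() {
    tibble::tribble(
        ~name, ~category, ~needs_reference_seqs, ~needs_cm, ~needs_external, ~description,
        "rnafold",       2L, FALSE, FALSE, FALSE, "de novo fold of the extended match",
        "C-A-r-Rc",      1L, TRUE,  FALSE, FALSE, "consensus pairs from reference MSA constrain the fold",
        "M-A-r-Rc",      1L, TRUE,  FALSE, FALSE, "consensus pairs from reference MSA constrain the fold",
        "C-A-U-r-Rc",    1L, TRUE,  FALSE, FALSE, "consensus pairs plus conserved-unpaired constraints",
        "M-A-U-r-Rc",    1L, TRUE,  FALSE, FALSE, "consensus pairs plus conserved-unpaired constraints",
        "rfam-Rc",       2L, FALSE, TRUE,  FALSE, "covariance-model consensus structure constrains the fold",
        "rfam-centroid", 2L, FALSE, TRUE,  TRUE,  "model consensus sequence feeds an external homology folder",
        "C-A-sub",       1L, TRUE,  FALSE, FALSE, "consensus structure selects the best suboptimal structure",
        "M-A-sub",       1L, TRUE,  FALSE, FALSE, "consensus structure selects the best suboptimal structure",
        "rfam-sub",      2L, FALSE, TRUE,  FALSE, "model consensus selects the best suboptimal structure",
        "fq-sub",        2L, FALSE, FALSE, FALSE, "query fold selects the best suboptimal structure",
        "centroid",      1L, TRUE,  FALSE, TRUE,  "external homology folder on selected references",
        "centroid-fast", 1L, FALSE, FALSE, TRUE,  "external homology folder on the first few matches",
        "TurboFold",     1L, TRUE,  FALSE, TRUE,  "external joint folder on selected references",
        "Turbo-fast",    1L, FALSE, FALSE, TRUE,  "external joint folder on the first few matches")
}

#' Typed absence of a predicted structure
#'
#' @param method method name.
#' @param reason human-readable reason the method produced no structure.
#' @return object of class `"structure_absence"`.
#' @export
structure_absence <- function(method, reason) {
    structure(list(method = method, reason = reason), class = "structure_absence")
}

#' @export
print.structure_absence <- function(x, ...) {
    cat(sprintf("<structure_absence> %s: %s\n", x$method, x$reason))
    invisible(x)
}

#' Prediction context shared by the method recipes
#'
#' @param query_seq query sequence.
#' @param query_struct optional query dot-bracket; folded when `NULL`.
#' @param references named character vector of selected reference
#'   sequences (category-1 methods; see
#'   [select_reference_sequences()]).
#' @param all_match_seqs character vector of all extended match
#'   sequences in input order (used by the `*-fast` methods).
#' @param cm_structure a [secondary_structure()] carrying the covariance
#'   model's consensus sequence and structure, or `NULL` when no model
#'   is available.
#' @param engines named list of external engine adapters; each is a
#'   function `(seq, references)` returning a dot-bracket string.
#'   Recognized names: `rnafold`, `centroid`, `turbofold`, `unafold`.
#' @param n_suboptimal suboptimal structures generated for `*-sub`
#'   recipes.
#' @param n_fast number of leading matches used by `*-fast` methods.
#' @param extension an [extension_config()] for the mapping alignments.
#' @param consensus a [consensus_config()].
#' @param fold_cfg a [fold_config()].
#' @return list of class `"predict_context"`.
#' @export
predict_context <- function(query_seq, query_struct = NULL, references = NULL,
                            all_match_seqs = NULL, cm_structure = NULL,
                            engines = list(), n_suboptimal = 10L, n_fast = 3L,
                            extension = extension_config(),
                            consensus = consensus_config(),
                            fold_cfg = fold_config()) {
    structure(list(query_seq = query_seq, query_struct = query_struct,
                   references = references, all_match_seqs = all_match_seqs,
                   cm_structure = cm_structure, engines = engines,
                   n_suboptimal = as.integer(n_suboptimal), n_fast = as.integer(n_fast),
                   extension = extension, consensus = consensus, fold_cfg = fold_cfg,
                   cache = new.env(parent = emptyenv())),
              class = "predict_context")
}

# map pairs (and unpaired positions) given on `source_seq` onto
# `target_seq` through a free-end-gap pairwise alignment; pairs whose
# mapped target bases cannot pair are dropped (soft constraints)
map_structure_constraints <- function(target_seq, source_seq, source_pairs,
                                      source_unpaired = integer(0),
                                      config = extension_config()) {
    res <- cpp_affine_align(canon_rna(target_seq), canon_rna(source_seq),
                            config$match_reward, config$mismatch_penalty,
                            config$gap_open, config$gap_extend,
                            TRUE, TRUE, TRUE, TRUE)
    ops <- str_chars(res$ops)
    ti <- cumsum(ops != "W"); si <- cumsum(ops != "Q")
    target_at <- rep(NA_integer_, nchar(source_seq))
    m <- ops == "M"
    target_at[si[m]] <- ti[m]
    tc <- str_chars(canon_rna(target_seq))
    pairs <- matrix(integer(0), ncol = 2)
    if (nrow(source_pairs)) {
        a <- target_at[source_pairs$i]
        b <- target_at[source_pairs$j]
        ok <- !is.na(a) & !is.na(b) & (b - a > 3) & can_pair_chr(tc[pmax(a, 1)], tc[pmax(b, 1)])
        pairs <- cbind(a[ok], b[ok])
    }
    unpaired <- target_at[source_unpaired]
    unpaired <- unpaired[!is.na(unpaired)]
    unpaired <- setdiff(unpaired, as.vector(pairs))
    list(pairs = pairs, unpaired = as.integer(unpaired))
}

# consensus over the context references, projected onto query positions;
# the reference MSA and consensus are computed once per context
context_consensus <- function(match_seq, context, use_unpaired = FALSE) {
    refs <- context$references
    if (is.null(refs) || !length(refs))
        return(NULL)
    cons <- if (!is.null(context$cache$consensus)) context$cache$consensus else {
        msa <- query_anchored_msa(context$query_seq, refs, context$extension)
        cc <- consensus_structure(msa, context$consensus)
        if (!is.null(context$cache)) context$cache$consensus <- cc
        cc
    }
    # project consensus pairs to query coordinates (both ends on query columns)
    qp <- cons$query_pos
    pr <- cons$structure$pairs
    if (nrow(pr)) {
        a <- qp[pr$i]; b <- qp[pr$j]
        # keep pairs whose ends both sit on query columns and still respect
        # the minimum loop after insertion columns are removed
        ok <- !is.na(a) & !is.na(b) & (b - a > 3)
        pr <- data.frame(i = a[ok], j = b[ok])
    }
    unp <- integer(0)
    if (use_unpaired) {
        unp <- qp[cons$conserved_unpaired]
        unp <- unp[!is.na(unp)]
    }
    map <- map_structure_constraints(match_seq, context$query_seq, pr, unp,
                                     context$extension)
    qdb <- rep(".", nchar(context$query_seq))
    if (nrow(pr)) { qdb[pr$i] <- "("; qdb[pr$j] <- ")" }
    list(constraints = map,
         query_structure = secondary_structure(context$query_seq,
                                               paste(qdb, collapse = "")))
}

query_fold <- function(context) {
    if (!is.null(context$query_struct))
        secondary_structure(context$query_seq, context$query_struct)
    else fold(context$query_seq, config = context$fold_cfg)
}

run_engine <- function(name, method, seq, refs, context) {
    eng <- context$engines[[name]]
    if (is.null(eng))
        return(structure_absence(method, "external engine unavailable"))
    db <- tryCatch(eng(seq, refs), error = function(e)
        structure_absence(method, sprintf("external engine failed: %s", conditionMessage(e))))
    if (inherits(db, "structure_absence")) return(db)
    if (inherits(db, "secondary_structure")) return(db)
    secondary_structure(seq, db)
}

#' Predict a secondary structure for an extended match
#'
#' Dispatches the recipe registered under `method_name` (see
#' [prediction_methods()]). Always returns either a valid
#' [secondary_structure()] or a [structure_absence()] stating why the
#' method cannot run (no covariance model, no external engine, not
#' enough reference sequences) — never silently nothing.
#'
#' @param method_name a registered method name.
#' @param match an `"extended_match"` or a plain sequence string.
#' @param context a [predict_context()].
#' @return a [secondary_structure()] or [structure_absence()].
#' @export
predict_structure <- function(method_name, match, context) {
    reg <- prediction_methods()
    if (!method_name %in% reg$name)
        stop_input("unknown prediction method '%s'; registered: %s",
                   method_name, paste(reg$name, collapse = ", "))
    seq <- if (inherits(match, "extended_match")) match$sequence else match

    if (method_name == "rnafold") {
        if (!is.null(context$engines$rnafold))
            return(run_engine("rnafold", method_name, seq, NULL, context))
        return(fold(seq, config = context$fold_cfg))
    }
    if (method_name %in% c("C-A-r-Rc", "M-A-r-Rc", "C-A-U-r-Rc", "M-A-U-r-Rc")) {
        cons <- context_consensus(seq, context,
                                  use_unpaired = grepl("-U-", method_name, fixed = TRUE))
        if (is.null(cons))
            return(structure_absence(method_name, "not enough reference sequences"))
        return(fold(seq, constraints = cons$constraints, config = context$fold_cfg))
    }
    if (method_name == "rfam-Rc") {
        if (is.null(context$cm_structure))
            return(structure_absence(method_name, "covariance model not available"))
        map <- map_structure_constraints(seq, context$cm_structure$sequence,
                                         context$cm_structure$pairs,
                                         config = context$extension)
        return(fold(seq, constraints = map, config = context$fold_cfg))
    }
    if (method_name == "rfam-centroid") {
        if (is.null(context$cm_structure))
            return(structure_absence(method_name, "covariance model not available"))
        return(run_engine("centroid", method_name, seq,
                          context$cm_structure$sequence, context))
    }
    if (method_name %in% c("C-A-sub", "M-A-sub", "rfam-sub", "fq-sub")) {
        reference <- if (method_name == "fq-sub") {
            query_fold(context)
        } else if (method_name == "rfam-sub") {
            if (is.null(context$cm_structure))
                return(structure_absence(method_name, "covariance model not available"))
            context$cm_structure
        } else {
            cons <- context_consensus(seq, context)
            if (is.null(cons))
                return(structure_absence(method_name, "not enough reference sequences"))
            cons$query_structure
        }
        subs <- if (!is.null(context$engines$unafold)) {
            out <- run_engine("unafold", method_name, seq, NULL, context)
            if (inherits(out, "structure_absence")) return(out)
            if (inherits(out, "secondary_structure")) list(out) else out
        } else suboptimal(seq, context$n_suboptimal, context$fold_cfg)
        return(select_by_reference(subs, reference))
    }
    if (method_name %in% c("centroid", "centroid-fast", "TurboFold", "Turbo-fast")) {
        fast <- method_name %in% c("centroid-fast", "Turbo-fast")
        refs <- if (fast) head(context$all_match_seqs, context$n_fast) else context$references
        if (!fast && (is.null(refs) || !length(refs)))
            return(structure_absence(method_name, "not enough reference sequences"))
        eng <- if (grepl("^centroid", method_name)) "centroid" else "turbofold"
        return(run_engine(eng, method_name, seq, refs, context))
    }
    stop_input("unhandled method '%s'", method_name) # unreachable
}
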