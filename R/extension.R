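# Extension of partial HSP matches to predicted full-length subject
# intervals. Three methods: "simple" (pure coordinate arithmetic),
# "locarna" (anchored free-end-gap realignment of a padded subject window
# against the query; the built-in aligner is sequence-only, an external
# sequence-structure aligner can be plugged in behind the same interface)
# and "meta" (the better of the two by model score).

#' Extension configuration
#'
#' @param o_loc extra padding (nt) added to each side of the simple
#'   extension window before realignment; default 30.
#' @param match_reward,mismatch_penalty,gap_open,gap_extend alignment
#'   scores; defaults mirror the blastn search scoring (+1/-1, gap
#'   existence 2, extension 1). A gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param min_anchor_run minimum length of a gap-free HSP run used as an
#'   alignment anchor.
#' @return a list of class `"extension_config"`.
#' @export
extension_config <- function(o_loc = 30L, match_reward = 1, mismatch_penalty = -1,
                             gap_open = -2, gap_extend = -1, min_anchor_run = 1L) {
    if (o_loc < 0) stop_input("o_loc must be >= 0")
    if (gap_open > 0 || gap_extend > 0) stop_input("gap costs must be <= 0")
    structure(list(o_loc = as.integer(o_loc), match_reward = match_reward,
                   mismatch_penalty = mismatch_penalty, gap_open = gap_open,
                   gap_extend = gap_extend, min_anchor_run = as.integer(min_anchor_run)),
              class = "extension_config")
}

new_extended_match <- function(subject_id, start, end, strand, sequence, method,
                               truncated_5p = FALSE, truncated_3p = FALSE,
                               model_score = NA_real_) {
    structure(list(subject_id = subject_id, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   sequence = sequence, method = method,
                   truncated_5p = truncated_5p, truncated_3p = truncated_3p,
                   model_score = model_score),
              class = "extended_match")
}

#' @export
print.extended_match <- function(x, ...) {
    cat(sprintf("<extended_match> %s:%d-%d (%s) by '%s'%s%s\n",
                x$subject_id, x$start, x$end, x$strand, x$method,
                if (x$truncated_5p) " [5' truncated]" else "",
                if (x$truncated_3p) " [3' truncated]" else ""))
    invisible(x)
}

#' Simple extension of an HSP to the query length
#'
#' Adds the unmatched 5' and 3' stretches of the query to both ends of
#' the subject match: in 1-based plus-strand terms, for a plus-strand
#' HSP the interval becomes `[s_start - (q_start - 1), s_end +
#' (query_length - q_end)]` (mirrored for minus-strand HSPs, where the
#' query 5' end faces the high subject coordinate). The interval is
#' clamped to `[1, subject_length]` with truncation flags set on the
#' query-oriented side where clamping occurred.
#'
#' @param hsp an [hsp()] object.
#' @param query_length full query length (>= `hsp$q_end`).
#' @param subject_length full subject sequence length.
#' @param subject_seq optional subject sequence; when given, the
#'   query-oriented extended sequence is filled in.
#' @param subject_id subject identifier carried into the result.
#' @return an `"extended_match"` with the predicted full-length interval.
#' @export
simple_extend <- function(hsp, query_length, subject_length,
                          subject_seq = NULL, subject_id = NA_character_) {
    if (query_length < hsp$q_end)
        stop_input("query_length (%d) smaller than HSP q_end (%d)", query_length, hsp$q_end)
    if (subject_length < hsp$s_end)
        stop_input("subject_length (%d) smaller than HSP s_end (%d)", subject_length, hsp$s_end)
    up <- hsp$q_start - 1L                 # unmatched query 5' stretch
    down <- query_length - hsp$q_end       # unmatched query 3' stretch
    if (hsp$strand == "plus") {
        start <- hsp$s_start - up
        end <- hsp$s_end + down
    } else {
        start <- hsp$s_start - down
        end <- hsp$s_end + up
    }
    cl_start <- max(1L, start)
    cl_end <- min(as.integer(subject_length), end)
    low_trunc <- cl_start > start
    high_trunc <- cl_end < end
    t5 <- if (hsp$strand == "plus") low_trunc else high_trunc
    t3 <- if (hsp$strand == "plus") high_trunc else low_trunc
    seq <- if (!is.null(subject_seq)) {
        s <- substr(subject_seq, cl_start, cl_end)
        if (hsp$strand == "minus") revcomp(s) else s
    } else NA_character_
    new_extended_match(subject_id, cl_start, cl_end, hsp$strand, seq, "simple",
                       truncated_5p = t5, truncated_3p = t3)
}

#' Extract alignment anchors from an HSP
#'
#' Anchors are the maximal runs of alignment columns in which neither
#' aligned string has a gap; runs shorter than `min_anchor_run` are
#' dropped. When the HSP carries no aligned strings (tabular input) a
#' single anchor spanning the start of the match is returned, with length
#' `min(query span, subject span)`.
#'
#' @param hsp an [hsp()] object.
#' @param min_anchor_run minimum run length (default 1).
#' @return data frame with columns `q_start` (query coordinate of the run
#'   start), `s_start` (plus-strand subject coordinate of the run's
#'   lowest position) and `length`.
#' @export
extract_anchors <- function(hsp, min_anchor_run = 1L) {
    if (is.na(hsp$q_aln)) {
        len <- min(hsp$q_end - hsp$q_start + 1L, hsp$s_end - hsp$s_start + 1L)
        return(data.frame(q_start = hsp$q_start, s_start = hsp$s_start, length = len))
    }
    qc <- str_chars(hsp$q_aln)
    sc <- str_chars(hsp$s_aln)
    if (length(qc) != length(sc))
        stop_input("aligned strings of unequal length")
    solid <- qc != "-" & sc != "-"
    # cumulative residue counts give the coordinate of each column
    qpos <- hsp$q_start - 1L + cumsum(qc != "-")
    spos_qo <- cumsum(sc != "-") # query-oriented subject offset (1..)
    runs <- rle(solid)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= min_anchor_run
    if (!any(keep)) {
        return(data.frame(q_start = integer(0), s_start = integer(0), length = integer(0)))
    }
    cs <- starts[keep]; ce <- ends[keep]; lens <- runs$lengths[keep]
    q_start <- qpos[cs]
    s_start <- if (hsp$strand == "plus") {
        hsp$s_start - 1L + spos_qo[cs]
    } else {
        # query-oriented offset o maps to plus-strand coordinate s_end - o + 1;
        # the run's lowest plus-strand coordinate is at its last column
        hsp$s_end - spos_qo[ce] + 1L
    }
    data.frame(q_start = as.integer(q_start), s_start = as.integer(s_start),
               length = as.integer(lens))
}

# score of one aligned column under the config
column_score <- function(a, b, config) {
    ifelse(canon_rna(a) == canon_rna(b), config$match_reward, config$mismatch_penalty)
}

align_segment <- function(q, w, config, free_start, free_end) {
    # terminal gap runs of the window (its overhangs beyond the query) are
    # free; the query itself is aligned globally so that its end residues
    # are assigned window positions rather than dropped as free end gaps
    res <- cpp_affine_align(canon_rna(q), canon_rna(w),
                            config$match_reward, config$mismatch_penalty,
                            config$gap_open, config$gap_extend,
                            FALSE, FALSE, free_start, free_end)
    ops <- str_chars(res$ops)
    qc <- str_chars(q); wc <- str_chars(w)
    qi <- cumsum(ops != "W"); wi <- cumsum(ops != "Q")
    q_aln <- rep("-", length(ops))
    q_aln[ops != "W"] <- qc[qi[ops != "W"]]
    w_aln <- rep("-", length(ops))
    w_aln[ops != "Q"] <- wc[wi[ops != "Q"]]
    list(q_aln = q_aln, w_aln = w_aln, score = res$score)
}

#' Anchored pairwise alignment with free window end gaps
#'
#' Alignment of `query` against `window` in which every anchored column
#' is fixed, terminal overhangs of the window at either end are free
#' (zero gap cost), the query is aligned globally, and the stretches
#' between consecutive anchors are solved as independent global
#' alignments. Tie-breaking is deterministic (aligned column preferred
#' over a gap, gap in the query row preferred over a gap in the window
#' row).
#'
#' @param query,window nucleotide strings.
#' @param anchors data frame with `q_start`, `w_start`, `length`
#'   (1-based positions in `query` and `window`); must be co-linear and
#'   non-overlapping in both sequences. `NULL` or zero rows means an
#'   unconstrained free-end-gap alignment.
#' @param config an [extension_config()].
#' @return list with `q_aln`, `w_aln` (gapped strings) and `score`.
#' @export
anchored_align <- function(query, window, anchors = NULL, config = extension_config()) {
    n <- nchar(query); m <- nchar(window)
    if (is.null(anchors)) anchors <- data.frame(q_start = integer(0),
                                                w_start = integer(0),
                                                length = integer(0))
    if (nrow(anchors) > 1) {
        o <- order(anchors$q_start)
        anchors <- anchors[o, , drop = FALSE]
    }
    if (nrow(anchors)) {
        q_end <- anchors$q_start + anchors$length - 1L
        w_end <- anchors$w_start + anchors$length - 1L
        ok <- all(anchors$q_start >= 1) && all(q_end <= n) &&
            all(anchors$w_start >= 1) && all(w_end <= m) &&
            (nrow(anchors) < 2 ||
             (all(diff(anchors$q_start) > 0) && all(diff(anchors$w_start) > 0) &&
              all(anchors$q_start[-1] > q_end[-nrow(anchors)]) &&
              all(anchors$w_start[-1] > w_end[-nrow(anchors)])))
        if (!ok) stop_input("anchors violate co-linearity or range")
    }
    qc <- str_chars(query); wc <- str_chars(window)
    pieces_q <- character(0); pieces_w <- character(0)
    total <- 0
    prev_q <- 0L; prev_w <- 0L
    k <- nrow(anchors)
    for (a in seq_len(k + 1L)) {
        seg_q_end <- if (a <= k) anchors$q_start[a] - 1L else n
        seg_w_end <- if (a <= k) anchors$w_start[a] - 1L else m
        sq <- if (seg_q_end >= prev_q + 1L) substr(query, prev_q + 1L, seg_q_end) else ""
        sw <- if (seg_w_end >= prev_w + 1L) substr(window, prev_w + 1L, seg_w_end) else ""
        seg <- align_segment(sq, sw, config, free_start = (a == 1L), free_end = (a == k + 1L))
        pieces_q <- c(pieces_q, seg$q_aln)
        pieces_w <- c(pieces_w, seg$w_aln)
        total <- total + seg$score
        if (a <= k) {
            idx_q <- anchors$q_start[a]:(anchors$q_start[a] + anchors$length[a] - 1L)
            idx_w <- anchors$w_start[a]:(anchors$w_start[a] + anchors$length[a] - 1L)
            pieces_q <- c(pieces_q, qc[idx_q])
            pieces_w <- c(pieces_w, wc[idx_w])
            total <- total + sum(column_score(qc[idx_q], wc[idx_w], config))
            prev_q <- idx_q[length(idx_q)]
            prev_w <- idx_w[length(idx_w)]
        }
    }
    list(q_aln = paste(pieces_q, collapse = ""),
         w_aln = paste(pieces_w, collapse = ""),
         score = total)
}

#' Extend an HSP by anchored realignment ("locarna" method)
#'
#' The simple extension interval is padded by `o_loc` nucleotides on each
#' side (clamped to the subject), the padded window is aligned to the
#' full query with the HSP's gap-free runs as anchors and free end gaps,
#' and the returned interval is the span of window positions between the
#' first and last alignment column in which a query residue is aligned
#' to a window residue — window overhangs aligned to end gaps are
#' trimmed away.
#'
#' @param hsp an [hsp()] object.
#' @param query_seq full query sequence.
#' @param subject_seq full database sequence of the hit.
#' @param config an [extension_config()].
#' @param subject_id subject identifier carried into the result.
#' @return an `"extended_match"`.
#' @export
locarna_extend <- function(hsp, query_seq, subject_seq, config = extension_config(),
                           subject_id = NA_character_) {
    qlen <- nchar(query_seq)
    slen <- nchar(subject_seq)
    simple <- simple_extend(hsp, qlen, slen, subject_id = subject_id)
    w1 <- max(1L, simple$start - config$o_loc)
    w2 <- min(slen, simple$end + config$o_loc)
    if (w2 < w1) stop_input("empty window after clamping")
    window_plus <- substr(subject_seq, w1, w2)
    window <- if (hsp$strand == "minus") revcomp(window_plus) else window_plus

    anchors <- extract_anchors(hsp, config$min_anchor_run)
    # map anchors into the query-oriented window frame
    if (nrow(anchors)) {
        w_start <- if (hsp$strand == "plus") {
            anchors$s_start - w1 + 1L
        } else {
            # plus-strand run [p, p+len-1] maps to window-frame start w2-(p+len-1)+1
            w2 - (anchors$s_start + anchors$length - 1L) + 1L
        }
        anchors <- data.frame(q_start = anchors$q_start, w_start = as.integer(w_start),
                              length = anchors$length)
    } else {
        anchors <- data.frame(q_start = integer(0), w_start = integer(0), length = integer(0))
    }

    aln <- anchored_align(query_seq, window, anchors, config)
    qa <- str_chars(aln$q_aln); wa <- str_chars(aln$w_aln)
    matched <- qa != "-" & wa != "-"
    if (!any(matched)) stop_input("alignment contains no matched column")
    wpos <- cumsum(wa != "-")
    first <- min(which(matched)); last <- max(which(matched))
    wa1 <- wpos[first]; wa2 <- wpos[last] # window-frame interval
    if (hsp$strand == "plus") {
        start <- w1 + wa1 - 1L; end <- w1 + wa2 - 1L
    } else {
        start <- w2 - wa2 + 1L; end <- w2 - wa1 + 1L
    }
    seqm <- substr(window, wa1, wa2)
    new_extended_match(subject_id, start, end, hsp$strand, seqm, "locarna",
                       truncated_5p = simple$truncated_5p && wa1 == 1L,
                       truncated_3p = simple$truncated_3p && wa2 == nchar(window))
}

#' Extend an HSP by the "meta" method
#'
#' Runs both the simple and the anchored ("locarna") extension and
#' returns whichever candidate scores higher against the query model;
#' ties go to the anchored candidate. Both scores are kept in the
#' `"candidate_scores"` attribute for diagnostics.
#'
#' @param hsp an [hsp()] object.
#' @param query_seq full query sequence.
#' @param subject_seq full database sequence of the hit.
#' @param scorer a function mapping a sequence to a bit score, e.g.
#'   [model_scorer()] on a [query_model()].
#' @param config an [extension_config()].
#' @param subject_id subject identifier carried into the result.
#' @return an `"extended_match"` with `method` recording the winner and
#'   `model_score` its score.
#' @export
meta_extend <- function(hsp, query_seq, subject_seq, scorer,
                        config = extension_config(), subject_id = NA_character_) {
    qlen <- nchar(query_seq); slen <- nchar(subject_seq)
    cand_simple <- simple_extend(hsp, qlen, slen, subject_seq, subject_id)
    cand_loc <- locarna_extend(hsp, query_seq, subject_seq, config, subject_id)
    scores <- tryCatch(
        c(simple = as.numeric(scorer(cand_simple$sequence)),
          locarna = as.numeric(scorer(cand_loc$sequence))),
        error = function(e) {
            cond <- structure(class = c("rnaxtender_scorer_error", "error", "condition"),
                              list(message = sprintf("model scorer failed: %s", conditionMessage(e)),
                                   call = sys.call(-1),
                                   candidates = list(simple = cand_simple, locarna = cand_loc)))
            stop(cond)
        })
    win <- if (scores[["locarna"]] >= scores[["simple"]]) cand_loc else cand_simple
    win$model_score <- max(scores)
    attr(win, "candidate_scores") <- scores
    win
}

#' Extend every HSP of a search result set
#'
#' Batch driver used by the pipeline, the CLI and the benchmark: applies
#' one extension method to every HSP of every hit of every query.
#'
#' @param results list of [search_result()] objects.
#' @param query_seqs named character vector of query sequences.
#' @param db named character vector of database (subject) sequences.
#' @param method `"simple"`, `"locarna"` or `"meta"`.
#' @param config an [extension_config()].
#' @param scorer required for `method = "meta"`; see [meta_extend()].
#' @return a list with `matches` (list of `"extended_match"`) and `table`
#'   (tibble with one row per HSP: ids, intervals, flags, scores).
#' @export
extend_matches <- function(results, query_seqs, db, method = c("locarna", "simple", "meta"),
                           config = extension_config(), scorer = NULL) {
    method <- match.arg(method)
    if (method == "meta" && is.null(scorer))
        stop_input("method 'meta' requires a scorer")
    rows <- list(); matches <- list()
    for (res in results) {
        if (!res$query_id %in% names(query_seqs))
            stop_input("query '%s' not found in query sequences", res$query_id)
        qseq <- query_seqs[[res$query_id]]
        for (h in res$hits) {
            sseq <- if (h$subject_id %in% names(db)) db[[h$subject_id]] else NULL
            for (k in seq_along(h$hsps)) {
                p <- h$hsps[[k]]
                em <- tryCatch({
                    if (is.null(sseq)) stop_input("subject '%s' not found in database", h$subject_id)
                    switch(method,
                           simple = simple_extend(p, res$query_length, h$subject_length,
                                                  sseq, h$subject_id),
                           locarna = locarna_extend(p, qseq, sseq, config, h$subject_id),
                           meta = meta_extend(p, qseq, sseq, scorer, config, h$subject_id))
                }, error = function(e) e)
                failed <- inherits(em, "error")
                rows[[length(rows) + 1L]] <- tibble::tibble(
                    query_id = res$query_id, subject_id = h$subject_id, hsp = k,
                    q_start = p$q_start, q_end = p$q_end,
                    s_start = p$s_start, s_end = p$s_end,
                    strand = p$strand, bit_score = p$bit_score, e_value = p$e_value,
                    start = if (failed) NA_integer_ else em$start,
                    end = if (failed) NA_integer_ else em$end,
                    method = if (failed) method else em$method,
                    truncated_5p = if (failed) NA else em$truncated_5p,
                    truncated_3p = if (failed) NA else em$truncated_3p,
                    error = if (failed) conditionMessage(em) else NA_character_)
                matches <- append(matches, list(if (failed) NULL else em))
            }
        }
    }
    list(matches = matches, table = do.call(rbind, rows))
}
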