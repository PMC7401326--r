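# BLAST output parsing and writing, FASTA and dot-bracket I/O.
#
# Coordinates: the BLAST-facing layer and the whole internal model use
# 1-based inclusive coordinates (the Biostrings/IRanges convention).
# Minus-strand HSPs are normalized so that s_start <= s_end on the plus
# strand of the subject, with strand = "minus" recorded; their aligned
# strings stay query-oriented exactly as BLAST prints them (the subject
# string is the reverse complement of the plus-strand segment).

#' Construct one high-scoring pair (HSP)
#'
#' @param q_start,q_end 1-based inclusive query coordinates.
#' @param s_start,s_end 1-based inclusive plus-strand subject coordinates
#'   (`s_start <= s_end` even for minus-strand HSPs).
#' @param strand `"plus"` or `"minus"`.
#' @param q_aln,s_aln gapped aligned strings of equal length (gap `-`),
#'   query-oriented; `NA` when the source format carries no alignment.
#' @param bit_score bit score of the HSP.
#' @param e_value expectation value.
#' @param raw_score optional raw alignment score.
#' @return an object of class `"hsp"`.
#' @export
hsp <- function(q_start, q_end, s_start, s_end, strand = c("plus", "minus"),
                q_aln = NA_character_, s_aln = NA_character_,
                bit_score = NA_real_, e_value = NA_real_, raw_score = NA_real_) {
    strand <- match.arg(strand)
    x <- structure(list(q_start = as.integer(q_start), q_end = as.integer(q_end),
                        s_start = as.integer(s_start), s_end = as.integer(s_end),
                        strand = strand,
                        q_aln = as.character(q_aln), s_aln = as.character(s_aln),
                        bit_score = as.numeric(bit_score),
                        e_value = as.numeric(e_value),
                        raw_score = as.numeric(raw_score)),
                   class = "hsp")
    validate_hsp(x)
    x
}

validate_hsp <- function(x, line = NA_integer_) {
    where <- if (is.na(line)) "" else sprintf(" (HSP ending at line %d)", line)
    if (x$q_start > x$q_end)
        stop_input("invalid HSP%s: q_start > q_end", where)
    if (x$s_start > x$s_end)
        stop_input("invalid HSP%s: s_start > s_end", where)
    if (!is.na(x$q_aln)) {
        if (is.na(x$s_aln) || nchar(x$q_aln) != nchar(x$s_aln))
            stop_input("invalid HSP%s: aligned strings of unequal length", where)
        if (!is_nucleotide_string(x$q_aln, allow_gap = TRUE) ||
            !is_nucleotide_string(x$s_aln, allow_gap = TRUE))
            stop_input("invalid HSP%s: aligned strings contain non-IUPAC characters", where)
        if (ungapped_length(x$q_aln) != x$q_end - x$q_start + 1L)
            stop_input("invalid HSP%s: query alignment length does not match coordinates", where)
        if (ungapped_length(x$s_aln) != x$s_end - x$s_start + 1L)
            stop_input("invalid HSP%s: subject alignment length does not match coordinates", where)
    }
    invisible(x)
}

#' Construct a hit (one subject sequence with its HSPs)
#'
#' @param subject_id subject identifier (first token of the definition line).
#' @param subject_length subject sequence length in nucleotides.
#' @param hsps list of [hsp()] objects, input order preserved.
#' @param subject_def optional full definition line.
#' @return an object of class `"blast_hit"`.
#' @export
blast_hit <- function(subject_id, subject_length, hsps = list(), subject_def = subject_id) {
    if (subject_length < 1) stop_input("subject_length must be >= 1")
    structure(list(subject_id = subject_id, subject_def = subject_def,
                   subject_length = as.integer(subject_length), hsps = hsps),
              class = "blast_hit")
}

#' Construct a search result (one query with its hits)
#'
#' @param query_id query identifier.
#' @param query_length query length in nucleotides (>= 1).
#' @param hits list of [blast_hit()] objects, input order preserved.
#' @return an object of class `"search_result"`.
#' @export
search_result <- function(query_id, query_length, hits = list()) {
    if (query_length < 1) stop_input("query_length must be >= 1")
    structure(list(query_id = query_id, query_length = as.integer(query_length),
                   hits = hits),
              class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
    n_hsp <- sum(vapply(x$hits, function(h) length(h$hsps), integer(1)))
    cat(sprintf("<search_result> query '%s' (%d nt): %d hit(s), %d HSP(s)\n",
                x$query_id, x$query_length, length(x$hits), n_hsp))
    invisible(x)
}

#' @export
print.hsp <- function(x, ...) {
    cat(sprintf("<hsp> q %d-%d / s %d-%d (%s), %.1f bits, E = %g\n",
                x$q_start, x$q_end, x$s_start, x$s_end, x$strand,
                x$bit_score, x$e_value))
    invisible(x)
}

# ---------------------------------------------------------------------------
# BLAST pairwise text (modern blastn dialect)

#' Parse BLAST pairwise text output
#'
#' Reads the classic pairwise text report of modern `blastn` (one or more
#' queries). Multi-line HSP blocks are concatenated; minus-strand HSPs are
#' normalized to plus-strand subject coordinates with the strand recorded.
#' Other text dialects (older programs, protein reports) are not targeted.
#'
#' @param input path to a file, or a character vector of lines.
#' @return list of [search_result()] objects, one per query (possibly empty).
#' @export
parse_blast_text <- function(input) {
    lines <- as_lines(input)

    results <- list()
    query <- NULL          # pending search_result fields
    hit <- NULL            # pending hit fields
    pend <- NULL           # pending HSP accumulator
    in_query_def <- FALSE
    in_subject_def <- FALSE
    footer <- FALSE        # inside the Lambda/statistics footer

    finalize_hsp <- function(ln) {
        if (is.null(pend)) return(invisible(NULL))
        if (is.null(pend$q_first) || is.null(pend$s_first))
            stop_input("malformed HSP block ending at line %d: missing alignment lines", ln)
        minus <- identical(pend$strand, "minus")
        h <- structure(list(q_start = as.integer(pend$q_first),
                            q_end = as.integer(pend$q_last),
                            s_start = as.integer(if (minus) pend$s_last else pend$s_first),
                            s_end = as.integer(if (minus) pend$s_first else pend$s_last),
                            strand = if (minus) "minus" else "plus",
                            q_aln = pend$q_aln, s_aln = pend$s_aln,
                            bit_score = pend$bit_score, e_value = pend$e_value,
                            raw_score = pend$raw_score),
                       class = "hsp")
        validate_hsp(h, line = ln)
        hit$hsps[[length(hit$hsps) + 1L]] <<- h
        pend <<- NULL
        invisible(NULL)
    }
    finalize_hit <- function(ln) {
        if (is.null(hit)) return(invisible(NULL))
        finalize_hsp(ln)
        query$hits[[length(query$hits) + 1L]] <<-
            blast_hit(hit$subject_id, hit$subject_length, hit$hsps, hit$subject_def)
        hit <<- NULL
        invisible(NULL)
    }
    finalize_query <- function(ln) {
        if (is.null(query)) return(invisible(NULL))
        finalize_hit(ln)
        results[[length(results) + 1L]] <<-
            search_result(query$query_id, query$query_length, query$hits)
        query <<- NULL
        invisible(NULL)
    }

    for (ln in seq_along(lines)) {
        line <- lines[[ln]]

        if (grepl("^Query=", line)) {
            finalize_query(ln)
            footer <- FALSE
            def <- sub("^Query=\\s*", "", line)
            query <- list(query_def = def, query_id = NA_character_,
                          query_length = NA_integer_, hits = list())
            in_query_def <- TRUE
            next
        }
        if (grepl("^Lambda", line)) { # statistics footer; '>' cannot follow for this query
            finalize_hit(ln)
            footer <- TRUE
            next
        }
        if (footer) next
        if (is.null(query)) next

        if (in_query_def) {
            m <- regmatches(line, regexec("^Length=(\\d+)\\s*$", line))[[1]]
            if (length(m)) {
                query$query_length <- as.integer(m[2])
                query$query_id <- strsplit(trimws(query$query_def), "\\s+")[[1]][1]
                in_query_def <- FALSE
            } else if (nzchar(trimws(line))) {
                query$query_def <- paste0(query$query_def, " ", trimws(line))
            }
            next
        }

        if (grepl("^>", line)) {
            finalize_hit(ln)
            hit <- list(subject_def = trimws(sub("^>", "", line)),
                        subject_id = NA_character_, subject_length = NA_integer_,
                        hsps = list())
            in_subject_def <- TRUE
            next
        }
        if (in_subject_def) {
            m <- regmatches(line, regexec("^Length=(\\d+)\\s*$", line))[[1]]
            if (length(m)) {
                hit$subject_length <- as.integer(m[2])
                hit$subject_id <- strsplit(hit$subject_def, "\\s+")[[1]][1]
                in_subject_def <- FALSE
            } else if (nzchar(trimws(line))) {
                hit$subject_def <- paste(hit$subject_def, trimws(line))
            }
            next
        }
        if (is.null(hit)) next

        m <- regmatches(line, regexec(
            "^\\s*Score\\s*=\\s*([0-9.eE+-]+)\\s*bits\\s*\\(([0-9.]+)\\),\\s*Expect\\s*=\\s*([^,\\s]+)", line))[[1]]
        if (length(m)) {
            finalize_hsp(ln)
            pend <- list(bit_score = as.numeric(m[2]), raw_score = as.numeric(m[3]),
                         e_value = as.numeric(m[4]), strand = "plus",
                         q_aln = "", s_aln = "",
                         q_first = NULL, q_last = NULL, s_first = NULL, s_last = NULL)
            if (is.na(pend$bit_score) || is.na(pend$e_value))
                stop_input("malformed score line at line %d: '%s'", ln, line)
            next
        }
        if (is.null(pend)) next

        m <- regmatches(line, regexec("^\\s*Strand=(Plus|Minus)/(Plus|Minus)", line))[[1]]
        if (length(m)) {
            pend$strand <- if (m[3] == "Minus") "minus" else "plus"
            next
        }
        m <- regmatches(line, regexec("^(Query|Sbjct)\\s+(\\d+)\\s+([A-Za-z-]+)\\s+(\\d+)\\s*$", line))[[1]]
        if (length(m)) {
            a <- as.integer(m[3]); b <- as.integer(m[5]); s <- m[4]
            if (ungapped_length(s) != abs(b - a) + 1L)
                stop_input("malformed coordinate line at line %d: '%s'", ln, line)
            if (m[2] == "Query") {
                if (is.null(pend$q_first)) pend$q_first <- a
                pend$q_last <- b
                pend$q_aln <- paste0(pend$q_aln, s)
            } else {
                if (is.null(pend$s_first)) pend$s_first <- a
                pend$s_last <- b
                pend$s_aln <- paste0(pend$s_aln, s)
            }
            next
        }
        if (grepl("^(Query|Sbjct)\\s", line))
            stop_input("malformed coordinate line at line %d: '%s'", ln, line)
    }
    finalize_query(length(lines))
    results
}

#' Write search results as BLAST pairwise text
#'
#' Emits the modern `blastn` pairwise dialect; the output re-parses with
#' [parse_blast_text()] to the same field values (round trip).
#'
#' @param results list of [search_result()] objects.
#' @param path optional file path; when `NULL` the text is returned.
#' @param line_width alignment block width (columns per Query/Sbjct line).
#' @return invisibly, the text as a single string.
#' @export
write_blast_text <- function(results, path = NULL, line_width = 60L) {
    out <- c("BLASTN 2.17.0+", "", "")
    for (res in results) {
        out <- c(out, sprintf("Query= %s", res$query_id), "",
                 sprintf("Length=%d", res$query_length), "")
        if (length(res$hits) == 0) {
            out <- c(out, "", "***** No hits found *****", "", "")
        }
        for (h in res$hits) {
            out <- c(out, "", sprintf(">%s", h$subject_def),
                     sprintf("Length=%d", h$subject_length), "")
            for (p in h$hsps) {
                raw <- if (is.na(p$raw_score)) 0 else p$raw_score
                out <- c(out, sprintf(" Score = %s bits (%s),  Expect = %s",
                                      format(p$bit_score, digits = 10),
                                      format(raw, digits = 10),
                                      format(p$e_value, digits = 10)))
                qa <- p$q_aln; sa <- p$s_aln
                if (is.na(qa)) { # reconstruct a coordinate-only stub
                    qa <- paste(rep("N", p$q_end - p$q_start + 1L), collapse = "")
                    sa <- paste(rep("N", p$s_end - p$s_start + 1L), collapse = "")
                    w <- max(nchar(qa), nchar(sa))
                    qa <- formatC(qa, width = -w, flag = "-")
                    qa <- gsub(" ", "-", qa)
                    sa <- gsub(" ", "-", formatC(sa, width = -w, flag = "-"))
                }
                qc <- str_chars(qa); sc <- str_chars(sa)
                ident <- sum(canon_rna(qc) == canon_rna(sc) & qc != "-")
                gaps <- sum(qc == "-" | sc == "-")
                len <- nchar(qa)
                out <- c(out, sprintf(" Identities = %d/%d (%d%%), Gaps = %d/%d (%d%%)",
                                      ident, len, round(100 * ident / len),
                                      gaps, len, round(100 * gaps / len)),
                         sprintf(" Strand=Plus/%s", if (p$strand == "minus") "Minus" else "Plus"),
                         "")
                qpos <- p$q_start
                spos <- if (p$strand == "minus") p$s_end else p$s_start
                sdir <- if (p$strand == "minus") -1L else 1L
                for (off in seq(1L, len, by = line_width)) {
                    idx <- off:min(off + line_width - 1L, len)
                    qchunk <- paste(qc[idx], collapse = "")
                    schunk <- paste(sc[idx], collapse = "")
                    nq <- ungapped_length(qchunk)
                    ns <- ungapped_length(schunk)
                    qend <- qpos + nq - 1L
                    send <- spos + sdir * (ns - 1L)
                    marks <- ifelse(canon_rna(qc[idx]) == canon_rna(sc[idx]) &
                                    qc[idx] != "-", "|", " ")
                    num_w <- max(nchar(c(qpos, spos, qend, send)))
                    out <- c(out,
                             sprintf("Query  %-*d  %s  %d", num_w, qpos, qchunk, qend),
                             sprintf("       %*s  %s", num_w, "", paste(marks, collapse = "")),
                             sprintf("Sbjct  %-*d  %s  %d", num_w, spos, schunk, send),
                             "")
                    qpos <- qend + 1L
                    spos <- send + sdir
                }
                out <- c(out, "")
            }
        }
        out <- c(out, "", "Lambda      K        H",
                 "    1.10    0.333    0.549 ", "")
    }
    txt <- paste(out, collapse = "\n")
    if (!is.null(path)) writeLines(txt, path)
    invisible(txt)
}

# ---------------------------------------------------------------------------
# BLAST tabular (outfmt 6/7)

#' Default BLAST tabular column names (outfmt 6)
#' @return character vector of the 12 standard column names.
#' @export
blast_tabular_columns <- function() {
    c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
      "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

#' Parse BLAST tabular output (outfmt 6/7)
#'
#' Comment lines (`#`, outfmt 7) are ignored. Rows with `sstart > send`
#' are minus-strand HSPs and are normalized (coordinates swapped, strand
#' recorded). Aligned strings are absent in this format; downstream
#' anchoring falls back to a single full-match run. Query and subject
#' lengths are taken from `qlen`/`slen` columns when present, otherwise
#' inferred as the maximum observed end coordinate.
#'
#' @param input path to a file, or a character vector of lines.
#' @param columns column names in file order; must include `qstart`,
#'   `qend`, `sstart`, `send`, `bitscore` and `evalue`.
#' @return list of [search_result()] objects, one per query.
#' @export
parse_blast_tabular <- function(input, columns = blast_tabular_columns()) {
    needed <- c("qstart", "qend", "sstart", "send", "bitscore", "evalue")
    missing_cols <- setdiff(needed, columns)
    if (length(missing_cols))
        stop_input("tabular configuration error: missing mandatory column(s): %s",
                   paste(missing_cols, collapse = ", "))
    lines <- as_lines(input)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (!length(lines)) return(list())
    df <- read.table(text = lines, stringsAsFactors = FALSE)
    if (ncol(df) < length(columns))
        stop_input("tabular configuration error: %d columns declared, %d found",
                   length(columns), ncol(df))
    names(df)[seq_along(columns)] <- columns
    if (!"qseqid" %in% columns) df$qseqid <- "query"
    if (!"sseqid" %in% columns) df$sseqid <- "subject"

    results <- list()
    for (q in unique(df$qseqid)) {
        dq <- df[df$qseqid == q, , drop = FALSE]
        qlen <- if ("qlen" %in% names(dq)) max(dq$qlen) else max(dq$qend)
        hits <- list()
        for (s in unique(dq$sseqid)) {
            ds <- dq[dq$sseqid == s, , drop = FALSE]
            slen <- if ("slen" %in% names(ds)) max(ds$slen) else max(ds$sstart, ds$send)
            hsps <- lapply(seq_len(nrow(ds)), function(i) {
                minus <- ds$sstart[i] > ds$send[i]
                hsp(q_start = ds$qstart[i], q_end = ds$qend[i],
                    s_start = if (minus) ds$send[i] else ds$sstart[i],
                    s_end = if (minus) ds$sstart[i] else ds$send[i],
                    strand = if (minus) "minus" else "plus",
                    bit_score = ds$bitscore[i], e_value = ds$evalue[i])
            })
            hits[[length(hits) + 1L]] <- blast_hit(s, slen, hsps)
        }
        results[[length(results) + 1L]] <- search_result(q, qlen, hits)
    }
    results
}

# ---------------------------------------------------------------------------
# FASTA (via Biostrings) and dot-bracket files

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector of upper-case sequences; names are the
#'   first token of each definition line, full deflines kept in
#'   `attr(, "deflines")`.
#' @export
read_fasta <- function(path) {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
    defs <- names(seqs)
    ids <- vapply(strsplit(defs, "\\s+"), `[`, character(1), 1)
    names(seqs) <- ids
    attr(seqs, "deflines") <- defs
    seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @param width line width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
    set <- Biostrings::BStringSet(unlist(as.list(seqs)))
    Biostrings::writeXStringSet(set, path, width = width)
    invisible(path)
}

#' Read a Vienna-style dot-bracket file
#'
#' Records are `>name`, a sequence line, and a structure line (a trailing
#' parenthesized energy, if present, is stripped).
#'
#' @param path file path or character vector of lines.
#' @return list of [secondary_structure()] objects, named by record.
#' @export
read_dotbracket <- function(path) {
    lines <- as_lines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    i <- 1L
    while (i <= length(lines)) {
        if (!grepl("^>", lines[i]))
            stop_input("dot-bracket parse error at record starting '%s'", lines[i])
        nm <- trimws(sub("^>", "", lines[i]))
        if (i + 2L > length(lines))
            stop_input("dot-bracket record '%s' is truncated", nm)
        seq <- trimws(lines[i + 1L])
        db <- trimws(sub("\\s*\\(-?[0-9.]+\\)\\s*$", "", lines[i + 2L]))
        out[[nm]] <- secondary_structure(seq, db)
        i <- i + 3L
    }
    out
}

#' Write secondary structures to a Vienna-style dot-bracket file
#'
#' @param structures named list of [secondary_structure()] objects.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_dotbracket <- function(structures, path) {
    nms <- names(structures)
    if (is.null(nms)) nms <- paste0("structure_", seq_along(structures))
    txt <- unlist(lapply(seq_along(structures), function(i) {
        s <- structures[[i]]
        c(paste0(">", nms[i]), s$sequence, s$dotbracket)
    }))
    writeLines(txt, path)
    invisible(path)
}
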