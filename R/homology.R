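# Homology classification of extended matches against a query model.
#
# The classification rule operates on a bit score s and the query length
# l: a subject is homologous when s/l >= 0.5 and s >= 20, not homologous
# when s < 0, and uncertain otherwise. The per-nucleotide term guards
# against fragments with locally concentrated similarity.

#' Classify a model bit score into a homology label
#'
#' @param s bit score(s) of the extended match against the query model.
#' @param l query length(s) in nucleotides (> 0).
#' @return character vector over `{"homologous", "uncertain",
#'   "not_homologous"}`.
#' @export
classify_homology <- function(s, l) {
    if (any(l <= 0)) stop_input("query length l must be positive")
    out <- rep("uncertain", length(s))
    out[s / l >= 0.5 & s >= 20] <- "homologous"
    out[s < 0] <- "not_homologous"
    out
}

#' Build a query model for homology scoring
#'
#' The model couples the query sequence with a secondary structure
#' (user-supplied or folded with the built-in predictor) and the scoring
#' parameters of the built-in covariance-model stand-in. The stand-in is
#' a documented replacement for profile covariance-model scoring: it
#' makes no claim of equivalence to any external tool's bit scores, but
#' is calibrated so that the classification thresholds behave sensibly
#' (an identical full-length match of length l scores `l * match +
#' n_pairs * pair_bonus` bits).
#'
#' @param query_seq query sequence.
#' @param query_struct optional dot-bracket structure of the query; when
#'   `NULL` the built-in folder is used.
#' @param pair_bonus bits added for each query base pair whose aligned
#'   candidate nucleotides can pair (WC/GU), subtracted otherwise.
#' @param match,mismatch log-odds nucleotide matrix (bits).
#' @param gap_open,gap_extend affine gap costs (bits, <= 0).
#' @return an object of class `"query_model"`.
#' @export
query_model <- function(query_seq, query_struct = NULL, pair_bonus = 2,
                        match = 1, mismatch = -1, gap_open = -2, gap_extend = -1) {
    if (!is_nucleotide_string(query_seq) || nchar(query_seq) < 1)
        stop_input("query_seq must be a non-empty IUPAC nucleotide string")
    if (is.null(query_struct))
        query_struct <- fold(query_seq)$dotbracket
    if (nchar(query_struct) != nchar(query_seq))
        stop_input("query structure and sequence lengths differ")
    ss <- secondary_structure(query_seq, query_struct)
    structure(list(query_seq = canon_rna(query_seq), query_struct = query_struct,
                   pairs = ss$pairs, query_length = nchar(query_seq),
                   pair_bonus = pair_bonus, match = match, mismatch = mismatch,
                   gap_open = gap_open, gap_extend = gap_extend,
                   scorer_kind = "builtin"),
              class = "query_model")
}

#' Score a candidate sequence against a query model (built-in stand-in)
#'
#' Globally aligns the candidate to the query with free end gaps on the
#' candidate under the model's log-odds matrix, then adds `pair_bonus`
#' bits for every query base pair whose aligned candidate nucleotides
#' can pair (Watson-Crick or GU) and subtracts it otherwise (a pair
#' partner aligned to a gap counts as broken). Deterministic and
#' invariant under T/U relabeling.
#'
#' @param candidate_seq candidate nucleotide sequence (non-empty).
#' @param model a [query_model()].
#' @return bit score (numeric scalar).
#' @export
builtin_model_score <- function(candidate_seq, model) {
    if (is.na(candidate_seq) || nchar(candidate_seq) < 1)
        stop_input("candidate sequence is empty")
    if (!is_nucleotide_string(candidate_seq))
        stop_input("candidate sequence contains non-IUPAC characters")
    cand <- canon_rna(candidate_seq)
    res <- cpp_affine_align(cand, model$query_seq,
                            model$match, model$mismatch,
                            model$gap_open, model$gap_extend,
                            TRUE, TRUE, FALSE, FALSE)
    ops <- str_chars(res$ops)
    ci <- cumsum(ops != "W")     # candidate position per column
    qi <- cumsum(ops != "Q")     # query position per column
    # candidate residue aligned to each query position (NA when gapped)
    cand_at <- rep(NA_integer_, model$query_length)
    matched <- ops == "M"
    cand_at[qi[matched]] <- ci[matched]
    score <- res$score
    if (nrow(model$pairs)) {
        cc <- str_chars(cand)
        a <- cand_at[model$pairs$i]
        b <- cand_at[model$pairs$j]
        ok <- !is.na(a) & !is.na(b) & can_pair_chr(cc[pmax(a, 1)], cc[pmax(b, 1)])
        score <- score + model$pair_bonus * (sum(ok) - sum(!ok))
    }
    score
}

#' Scorer function for a query model
#'
#' @param model a [query_model()].
#' @return a function mapping a candidate sequence to a bit score.
#' @export
model_scorer <- function(model) {
    force(model)
    function(seq) builtin_model_score(seq, model)
}

#' External scorer adapter (covariance-model command contract)
#'
#' Wraps a command-line scorer: the template's `{fasta}` placeholder is
#' replaced by a temporary FASTA file with the candidate, and the
#' command must print the total bit score of the candidate against the
#' model (the contract matched by covariance-model aligners that report
#' a total bit score) as the last numeric token on its last non-empty
#' output line. The user's model file path can be baked into the
#' template verbatim.
#'
#' @param cmd_template command template containing `{fasta}`.
#' @return a function mapping a candidate sequence to a bit score.
#' @export
command_scorer <- function(cmd_template) {
    if (!grepl("{fasta}", cmd_template, fixed = TRUE))
        stop_input("command template must contain the {fasta} placeholder")
    function(seq) {
        fa <- tempfile(fileext = ".fa")
        on.exit(unlink(fa), add = TRUE)
        writeLines(c(">candidate", seq), fa)
        cmd <- gsub("{fasta}", fa, cmd_template, fixed = TRUE)
        out <- system(cmd, intern = TRUE)
        out <- out[nzchar(trimws(out))]
        if (!length(out)) stop_input("external scorer produced no output")
        toks <- strsplit(trimws(out[length(out)]), "\\s+")[[1]]
        val <- suppressWarnings(as.numeric(toks))
        val <- val[!is.na(val)]
        if (!length(val)) stop_input("external scorer output carries no numeric score")
        val[length(val)]
    }
}

#' Score and classify a batch of extended matches
#'
#' One homology call per match; per-match scorer errors are recorded in
#' the `error` column without aborting the batch.
#'
#' @param extended_matches list of `"extended_match"` objects (or a
#'   character vector of sequences).
#' @param model a [query_model()].
#' @param scorer optional scorer function overriding the built-in one
#'   (e.g. [command_scorer()]).
#' @return tibble with columns `subject_id`, `method`, `s`, `l`, `label`,
#'   `error`.
#' @export
score_and_classify <- function(extended_matches, model, scorer = NULL) {
    if (is.null(scorer)) scorer <- model_scorer(model)
    if (is.character(extended_matches))
        extended_matches <- lapply(extended_matches, function(s)
            new_extended_match(NA_character_, 1L, nchar(s), "plus", s, "simple"))
    n <- length(extended_matches)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        m <- extended_matches[[i]]
        res <- tryCatch(as.numeric(scorer(m$sequence)), error = function(e) e)
        failed <- inherits(res, "error")
        s_val <- if (failed) NA_real_ else res
        rows[[i]] <- tibble::tibble(
            subject_id = m$subject_id,
            method = m$method,
            s = s_val,
            l = model$query_length,
            label = if (failed) NA_character_
                    else classify_homology(s_val, model$query_length),
            error = if (failed) conditionMessage(res) else NA_character_)
    }
    if (!n) return(tibble::tibble(subject_id = character(0), method = character(0),
                                  s = numeric(0), l = integer(0),
                                  label = character(0), error = character(0)))
    do.call(rbind, rows)
}
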