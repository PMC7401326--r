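# End-to-end orchestration: parse -> extend -> classify -> predict ->
# report. Deterministic given inputs, config and seeds; outputs carry the
# configuration (no timestamps) so re-runs are byte-identical.

#' Pipeline run configuration
#'
#' @param extension_method HSP extension method (default `"locarna"`).
#' @param prediction_methods structure prediction methods to run
#'   (default `rnafold`, `TurboFold`, `rfam-Rc`). Methods requiring an
#'   external engine without a configured adapter are substituted by the
#'   built-in consensus-constrained fold and the substitution is noted
#'   in the report.
#' @param o_loc window padding for the anchored extension (nt).
#' @param query_struct optional query dot-bracket for the homology model.
#' @param scorer `"builtin"` or `"command"`.
#' @param scorer_command command template for [command_scorer()] when
#'   `scorer = "command"`; a user model file path may be baked in
#'   verbatim.
#' @param cm_file optional dot-bracket file with the covariance-model
#'   consensus (sequence + structure) used by the `rfam-*` methods.
#' @param engines named list of external engine adapters (see
#'   [predict_context()]).
#' @param n_suboptimal,n_fast structure-recipe parameters.
#' @param pair_bonus,match,mismatch homology stand-in scoring parameters.
#' @param seed integer seed recorded in the output metadata and used for
#'   any randomized step.
#' @param out_dir default output directory for [run_pipeline()].
#' @return list of class `"run_config"`.
#' @export
run_config <- function(extension_method = c("locarna", "simple", "meta"),
                       prediction_methods = c("rnafold", "TurboFold", "rfam-Rc"),
                       o_loc = 30L, query_struct = NULL,
                       scorer = c("builtin", "command"), scorer_command = NULL,
                       cm_file = NULL, engines = list(),
                       n_suboptimal = 10L, n_fast = 3L,
                       pair_bonus = 2, match = 1, mismatch = -1,
                       seed = 1L, out_dir = NULL) {
    extension_method <- match.arg(extension_method)
    scorer <- match.arg(scorer)
    unknown <- setdiff(prediction_methods, prediction_methods()$name)
    if (length(unknown))
        stop_input("unknown prediction method(s): %s (registered: %s)",
                   paste(unknown, collapse = ", "),
                   paste(prediction_methods()$name, collapse = ", "))
    if (scorer == "command" && is.null(scorer_command))
        stop_input("scorer = 'command' requires scorer_command")
    structure(list(extension_method = extension_method,
                   prediction_methods = prediction_methods,
                   extension = extension_config(o_loc = o_loc),
                   query_struct = query_struct,
                   scorer = scorer, scorer_command = scorer_command,
                   cm_file = cm_file, engines = engines,
                   n_suboptimal = as.integer(n_suboptimal),
                   n_fast = as.integer(n_fast),
                   pair_bonus = pair_bonus, match = match, mismatch = mismatch,
                   seed = as.integer(seed), out_dir = out_dir),
              class = "run_config")
}

# methods whose external engine is missing fall back to the built-in
# consensus-constrained fold; returns list(method -> note or NA)
resolve_methods <- function(config) {
    reg <- prediction_methods()
    out <- list()
    for (m in config$prediction_methods) {
        row <- reg[reg$name == m, ]
        eng <- if (grepl("^centroid|^rfam-centroid", m)) "centroid"
               else if (grepl("^Turbo", m)) "turbofold" else NULL
        if (row$needs_external && !is.null(eng) && is.null(config$engines[[eng]])) {
            out[[m]] <- "substituted: built-in consensus-constrained fold (external engine unavailable)"
        } else {
            out[[m]] <- NA_character_
        }
    }
    out
}

#' Run the full characterization pipeline
#'
#' Parses the search output, extends every HSP to a predicted full-length
#' match, classifies its homology to the query, predicts secondary
#' structures with the configured methods and writes machine-readable
#' reports. Every HSP of the input appears exactly once in the output,
#' including failed ones (with the error recorded).
#'
#' @param blast_file BLAST output file (pairwise text or tabular).
#' @param query_fasta FASTA file with the query sequence(s).
#' @param db_fasta FASTA file with the database searched (subject ids
#'   must resolve here; unresolvable subjects are recorded per hit).
#' @param config a [run_config()].
#' @param out_dir output directory; `NULL` (and no `config$out_dir`)
#'   skips file output.
#' @param format `"text"` or `"tabular"`.
#' @return (invisibly) list with `reports` (one entry per HSP), `table`
#'   (flat tibble) and `files` (written paths).
#' @export
run_pipeline <- function(blast_file, query_fasta, db_fasta,
                         config = run_config(), out_dir = config$out_dir,
                         format = c("text", "tabular")) {
    format <- match.arg(format)
    results <- if (format == "text") parse_blast_text(blast_file)
               else parse_blast_tabular(blast_file)
    queries <- read_fasta(query_fasta)
    db <- read_fasta(db_fasta)
    cm_structure <- if (!is.null(config$cm_file)) read_dotbracket(config$cm_file)[[1]]
                    else NULL
    method_notes <- resolve_methods(config)

    reports <- list()
    rows <- list()
    struct_files <- list()
    for (res in results) {
        if (!res$query_id %in% names(queries))
            stop_input("query '%s' not found in %s", res$query_id, query_fasta)
        qseq <- queries[[res$query_id]]
        model <- query_model(qseq, config$query_struct, pair_bonus = config$pair_bonus,
                             match = config$match, mismatch = config$mismatch)
        scorer <- if (config$scorer == "command") command_scorer(config$scorer_command)
                  else model_scorer(model)
        ext <- extend_matches(list(res), queries, db,
                              method = config$extension_method,
                              config = config$extension,
                              scorer = if (config$extension_method == "meta") scorer else NULL)
        calls <- score_and_classify(
            lapply(ext$matches, function(m) if (is.null(m))
                new_extended_match(NA_character_, 1L, 1L, "plus", NA_character_, "failed")
                else m),
            model, scorer)
        okm <- !vapply(ext$matches, is.null, logical(1))
        refs <- select_reference_sequences(ext$matches[okm], calls[okm, , drop = FALSE],
                                           qseq, config = config$extension)
        context <- predict_context(
            qseq, query_struct = config$query_struct, references = refs,
            all_match_seqs = vapply(ext$matches[okm], `[[`, "", "sequence"),
            cm_structure = cm_structure, engines = config$engines,
            n_suboptimal = config$n_suboptimal, n_fast = config$n_fast,
            extension = config$extension)

        for (k in seq_len(nrow(ext$table))) {
            m <- ext$matches[[k]]
            failed <- is.null(m)
            structures <- list()
            if (!failed) {
                for (pm in config$prediction_methods) {
                    note <- method_notes[[pm]]
                    st <- if (!is.na(note)) {
                        predict_structure(if (length(refs)) "C-A-r-Rc" else "rnafold",
                                          m, context)
                    } else predict_structure(pm, m, context)
                    absent <- inherits(st, "structure_absence")
                    structures[[pm]] <- list(
                        dotbracket = if (absent) NA_character_ else st$dotbracket,
                        sequence = if (absent) NA_character_ else st$sequence,
                        reason = if (absent) st$reason else NA_character_,
                        note = note)
                    if (!absent) {
                        key <- pm
                        nm <- sprintf("%s|%s|hsp%d", ext$table$query_id[k],
                                      ext$table$subject_id[k], ext$table$hsp[k])
                        struct_files[[key]] <- c(struct_files[[key]],
                                                 setNames(list(st), nm))
                    }
                }
            }
            reports[[length(reports) + 1L]] <- list(
                query_id = ext$table$query_id[k],
                subject_id = ext$table$subject_id[k],
                hsp = list(index = ext$table$hsp[k],
                           q_start = ext$table$q_start[k], q_end = ext$table$q_end[k],
                           s_start = ext$table$s_start[k], s_end = ext$table$s_end[k],
                           strand = ext$table$strand[k],
                           bit_score = ext$table$bit_score[k],
                           e_value = ext$table$e_value[k]),
                extended = if (failed) NULL else list(
                    start = m$start, end = m$end, strand = m$strand,
                    method = m$method, truncated_5p = m$truncated_5p,
                    truncated_3p = m$truncated_3p, sequence = m$sequence),
                homology = list(s = calls$s[k], l = calls$l[k], label = calls$label[k]),
                structures = structures,
                error = ext$table$error[k])
            rows[[length(rows) + 1L]] <- cbind(
                ext$table[k, ],
                tibble::tibble(s = calls$s[k], label = calls$label[k]))
        }
    }
    table <- if (length(rows)) do.call(rbind, rows) else NULL

    files <- character(0)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        cfg_plain <- lapply(unclass(config)[setdiff(names(config), "engines")],
                            function(x) if (is.object(x)) unclass(x) else x)
        meta <- list(package = "rnaxtender",
                     config = cfg_plain,
                     n_queries = length(results),
                     n_reports = length(reports))
        out <- list(metadata = meta, reports = reports)
        json_path <- file.path(out_dir, "reports.json")
        jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE)
        files <- c(files, json_path)
        if (!is.null(table)) {
            tsv_path <- file.path(out_dir, "reports.tsv")
            utils::write.table(table, tsv_path, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            files <- c(files, tsv_path)
            ok <- !is.na(table$start)
            if (any(ok)) {
                fa_path <- file.path(out_dir, "extended.fasta")
                seqs <- vapply(reports[ok], function(r) r$extended$sequence, character(1))
                names(seqs) <- sprintf("%s|%s|hsp%d %d-%d(%s)",
                                       table$query_id[ok], table$subject_id[ok],
                                       table$hsp[ok], table$start[ok], table$end[ok],
                                       table$strand[ok])
                write_fasta(seqs, fa_path)
                files <- c(files, fa_path)
            }
        }
        if (length(struct_files)) {
            sdir <- file.path(out_dir, "structures")
            dir.create(sdir, showWarnings = FALSE)
            for (pm in names(struct_files)) {
                p <- file.path(sdir, paste0(gsub("[^A-Za-z0-9_-]", "_", pm), ".db"))
                write_dotbracket(struct_files[[pm]], p)
                files <- c(files, p)
            }
        }
        html_path <- file.path(out_dir, "summary.html")
        writeLines(render_summary_html(reports), html_path)
        files <- c(files, html_path)
    }
    invisible(list(reports = reports, table = table, files = files))
}

# minimal static HTML summary (reduced analog of the original interactive
# report: one row per HSP with homology call and predicted structures)
render_summary_html <- function(reports) {
    esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        gsub(">", "&gt;", x, fixed = TRUE)
    }
    rows <- vapply(reports, function(r) {
        structs <- vapply(names(r$structures), function(nm) {
            s <- r$structures[[nm]]
            if (!is.na(s$reason)) sprintf("<li>%s: <em>%s</em></li>", esc(nm), esc(s$reason))
            else sprintf("<li>%s: <code>%s</code></li>", esc(nm), esc(s$dotbracket))
        }, character(1))
        ext <- if (is.null(r$extended)) "<em>extension failed</em>" else
            sprintf("%d-%d (%s), method %s", r$extended$start, r$extended$end,
                    r$extended$strand, r$extended$method)
        sprintf(paste0("<tr><td>%s</td><td>%s</td><td>q %d-%d / s %d-%d (%s), %.1f bits",
                       "</td><td>%s</td><td>%s (s = %.1f)</td><td><ul>%s</ul></td></tr>"),
                esc(r$query_id), esc(r$subject_id),
                r$hsp$q_start, r$hsp$q_end, r$hsp$s_start, r$hsp$s_end,
                r$hsp$strand, r$hsp$bit_score, ext,
                esc(ifelse(is.na(r$homology$label), "NA", r$homology$label)),
                ifelse(is.na(r$homology$s), NA_real_, r$homology$s),
                paste(structs, collapse = ""))
    }, character(1))
    c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
      "<title>Search characterization summary</title></head><body>",
      "<h1>Characterized HSPs</h1>",
      "<table border='1' cellpadding='4'>",
      "<tr><th>Query</th><th>Subject</th><th>HSP</th><th>Extended match</th><th>Homology</th><th>Structures</th></tr>",
      rows, "</table></body></html>")
}
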