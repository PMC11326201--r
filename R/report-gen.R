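# Case-wide reporting: metric collection, range summaries across structures
# and isoforms, precomputed-score merging, digenic pair enumeration, and
# deterministic HTML/CSV rendering.

#' Collect per-job metric rows from a case directory
#'
#' One row per numeric metric in each complete structural job's result
#' record; incomplete jobs contribute nothing but are listed as pending.
#' Malformed result records are skipped with a warning. The digenic job is
#' collected separately (see [read_digenic_result()]).
#'
#' @param root case root.
#' @param full_id case full id.
#' @param gene_map optional named character vector transcript -> gene, used
#'   to label variants `"<gene>:<mutation>"`; otherwise the mutation string
#'   alone is the variant label.
#' @return list: `rows` (data frame `variant`, `transcript`,
#'   `structure_id`, `calc_type`, `metric`, `value`), `pending` (jobs not
#'   complete).
#' @export
collect_results <- function(root, full_id, gene_map = NULL) {
  st <- aggregate_status(root, full_id)
  jobs <- st$jobs
  structural <- jobs[jobs$calc_type != "digenic", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(structural))) {
    if (structural$state[i] != "complete") next
    f <- file.path(root, structural$workdir[i], "result.json")
    rec <- tryCatch(jsonlite::fromJSON(f), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$metrics)) {
      vu_warn("malformed result record for job %s; skipped", structural$job_id[i])
      next
    }
    variant <- structural$mutation[i]
    if (!is.null(gene_map) && structural$transcript[i] %in% names(gene_map))
      variant <- paste0(gene_map[[structural$transcript[i]]], ":", variant)
    for (m in names(rec$metrics)) {
      v <- rec$metrics[[m]]
      if (!is.numeric(v) || !is.finite(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant, transcript = structural$transcript[i],
        structure_id = structural$structure_id[i],
        calc_type = structural$calc_type[i], metric = m, value = v,
        stringsAsFactors = FALSE)
    }
  }
  rows <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(variant = character(0), transcript = character(0),
               structure_id = character(0), calc_type = character(0),
               metric = character(0), value = numeric(0))
  pending <- structural[structural$state != "complete", , drop = FALSE]
  list(rows = rows, pending = pending)
}

#' Read the case's digenic result record
#'
#' @inheritParams collect_results
#' @return data frame of scored gene pairs, or `NULL` when the digenic job
#'   has not completed.
#' @export
read_digenic_result <- function(root, full_id) {
  plan <- read_workplan(file.path(root, "VUStruct", full_id, "workplan.csv"))
  dg <- plan[plan$calc_type == "digenic", , drop = FALSE]
  if (nrow(dg) == 0) return(NULL)
  f <- file.path(root, dg$workdir[1], "result.json")
  if (!file.exists(f)) return(NULL)
  jsonlite::fromJSON(f)
}

#' Summarize metric ranges per variant
#'
#' For each (variant, metric), the (min, max) over all structures and
#' transcript isoforms that contributed rows. Ranges arise because several
#' structures and isoforms are analysed per variant; a single contributing
#' row gives `min == max`. Output order and content are invariant to input
#' row order.
#'
#' @param rows metric rows from [collect_results()].
#' @param variants optional character vector of variant labels to force
#'   into the output (with `NA` ranges when they contributed no rows).
#' @return data frame `variant`, `metric`, `min`, `max`, `n`.
#' @export
summarize_ranges <- function(rows, variants = NULL) {
  if (nrow(rows) > 0) {
    agg <- aggregate(value ~ variant + metric, data = rows,
                     FUN = function(v) c(min = min(v), max = max(v), n = length(v)))
    out <- data.frame(variant = agg$variant, metric = agg$metric,
                      min = agg$value[, "min"], max = agg$value[, "max"],
                      n = as.integer(agg$value[, "n"]), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(variant = character(0), metric = character(0),
                      min = numeric(0), max = numeric(0), n = integer(0))
  }
  extra <- setdiff(variants, out$variant)
  if (length(extra) > 0) {
    out <- rbind(out, data.frame(variant = extra, metric = NA_character_,
                                 min = NA_real_, max = NA_real_, n = 0L))
  }
  out[order(out$variant, out$metric), , drop = FALSE]
}

#' Read a precomputed score table (TSV)
#'
#' Per-variant sources (AlphaMissense-like) are keyed by
#' (`unp`, `pos`, `alt_aa`); per-site sources (ConSurf-/COSMIS-like) by
#' (`unp`, `pos`) and carry no `alt_aa` column.
#'
#' @param path TSV with columns `unp`, `pos`, (`alt_aa`,) `value`.
#' @return list with `data` and `per_site` flag, for
#'   [attach_precomputed()].
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  per_site <- !"alt_aa" %in% names(df)
  list(data = df, per_site = per_site)
}

#' Attach precomputed scores to a variant summary
#'
#' Exact-key lookup only: per-variant tables on (`unp`, `pos`, `alt_aa`),
#' per-site tables on (`unp`, `pos`). Missing keys yield `NA` (rendered as
#' an em dash); values are never interpolated.
#'
#' @param summary data frame with columns `unp`, `pos`, `alt_aa` (one row
#'   per variant), e.g. from [case_summary()].
#' @param tables named list of [read_score_table()] results; one summary
#'   column is added per table name.
#' @return `summary` with the score columns appended.
#' @export
attach_precomputed <- function(summary, tables) {
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    df <- tab$data
    keys <- if (tab$per_site) paste(df$unp, df$pos) else
      paste(df$unp, df$pos, df$alt_aa)
    if (anyDuplicated(keys))
      vu_stop("vustruct_table_error", "duplicate keys in score table '%s'", nm)
    want <- if (tab$per_site) paste(summary$unp, summary$pos) else
      paste(summary$unp, summary$pos, summary$alt_aa)
    summary[[nm]] <- df$value[match(want, keys)]
  }
  summary
}

#' Deterministic digenic predictor stub
#'
#' A symmetric, hash-based score in `[0, 1]` standing in for trained
#' digenic-disease predictors (the plug-in contract is the in-scope
#' artifact; trained weights are not).
#'
#' @param gene_a,gene_b gene symbols (order-insensitive).
#' @return numeric score in `[0, 1]`.
#' @export
digenic_stub <- function(gene_a, gene_b) {
  vu_hash01(sort(c(gene_a, gene_b)))
}

#' Enumerate and score digenic candidate gene pairs
#'
#' Scores all `C(n, 2)` unordered pairs of the case's genes with a
#' symmetric predictor and returns pairs at or above the threshold, sorted
#' by descending score (ties broken lexicographically). The predictor
#' contract — symmetry and range `[0, 1]` — is asserted for every pair.
#'
#' @param genes character vector of gene symbols.
#' @param predictor `function(gene_a, gene_b) -> score`; default the
#'   deterministic stub.
#' @param threshold minimum reported score.
#' @return data frame `gene_a`, `gene_b` (lexicographic within pair),
#'   `score`, `predictor`.
#' @export
digenic_candidates <- function(genes, predictor = digenic_stub,
                               threshold = 0.5) {
  genes <- unique(genes)
  pred_name <- deparse(substitute(predictor))
  if (length(genes) < 2)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), predictor = character(0)))
  pairs <- combn(sort(genes), 2)
  score <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    s <- predictor(a, b)
    if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1)
      vu_stop("vustruct_contract_error",
              "predictor returned an out-of-range score for (%s, %s)", a, b)
    if (abs(s - predictor(b, a)) > 1e-12)
      vu_stop("vustruct_contract_error",
              "predictor is not symmetric for (%s, %s)", a, b)
    score[i] <- s
  }
  out <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ], score = score,
                    predictor = pred_name, stringsAsFactors = FALSE)
  out <- out[out$score >= threshold, , drop = FALSE]
  out[order(-out$score, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Build the per-variant case summary table
#'
#' One row per missense variant: identity, inheritance, and per-metric
#' (min, max) columns spread wide from [summarize_ranges()].
#'
#' @param records the case's variant records ([parse_vustruct_csv()] frame)
#'   with a `variant` label column (`"<gene>:<mutation>"`).
#' @param ranges output of [summarize_ranges()].
#' @return data frame, one row per variant, with `<metric>_min` /
#'   `<metric>_max` columns.
#' @export
case_summary <- function(records, ranges) {
  out <- data.frame(variant = records$variant, gene = records$gene,
                    transcript = records$transcript, unp = records$unp,
                    pos = records$pos, ref_aa = records$ref_aa,
                    alt_aa = records$alt_aa,
                    inheritance = records$inheritance,
                    stringsAsFactors = FALSE)
  metrics <- sort(unique(ranges$metric[!is.na(ranges$metric)]))
  for (m in metrics) {
    sub <- ranges[!is.na(ranges$metric) & ranges$metric == m, ]
    idx <- match(out$variant, sub$variant)
    out[[paste0(m, "_min")]] <- sub$min[idx]
    out[[paste0(m, "_max")]] <- sub$max[idx]
  }
  out
}

# ---- rendering -----------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_cell <- function(v) {
  if (is.null(v) || length(v) == 0 || is.na(v)) return("&mdash;")
  if (is.numeric(v)) return(formatC(v, format = "g", digits = 4))
  html_escape(as.character(v))
}

html_table <- function(df, id = NULL) {
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(seq_along(df), function(j) fmt_cell(df[[j]][i]), character(1))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0("<table", if (!is.null(id)) sprintf(" id='%s'", id), ">\n",
         head, "\n", paste(body, collapse = "\n"), "\n</table>")
}

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset='utf-8'><title>",
         html_escape(title), "</title>\n",
         "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
         "td,th{border:1px solid #999;padding:2px 8px}</style></head>\n<body>\n",
         "<h1>", html_escape(title), "</h1>\n", body, "\n</body></html>\n")
}

#' Render the case report
#'
#' Writes a landing page (`index.html`) with one summary row per variant
#' and expandable isoform sub-rows (canonical first), one page per
#' transcript with its structure summary table, and the clinician-facing
#' summary spreadsheet (`summary.csv`, one row per missense variant).
#' Rendering is a pure function of its inputs: identical inputs give
#' byte-identical output, and generation time is kept in a separate
#' metadata file (`render_meta.json`), never in the report content.
#'
#' @param summary per-variant table from [case_summary()] (after
#'   [attach_precomputed()]), optionally with a `digenic_flag` column.
#' @param metric_rows rows from [collect_results()].
#' @param digenic scored pair table ([digenic_candidates()] output or
#'   `NULL`).
#' @param isoforms data frame `variant`, `transcript`, `canonical`, `unp`
#'   — one sub-row per impacted isoform.
#' @param out_dir output directory (created).
#' @param case_title page title.
#' @return `out_dir`, invisibly.
#' @export
render_case <- function(summary, metric_rows, digenic, isoforms, out_dir,
                        case_title = "VUStruct case report") {
  dir.create(file.path(out_dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  tx_ids <- sort(unique(c(isoforms$transcript, metric_rows$transcript)))
  tx_page <- function(id) file.path("transcripts", paste0(id, ".html"))

  parts <- character(0)
  parts <- c(parts, "<h2>Variant summary</h2>")
  for (i in seq_len(nrow(summary))) {
    v <- summary$variant[i]
    cols <- setdiff(names(summary), "variant")
    row_tab <- html_table(summary[i, cols, drop = FALSE])
    sub <- isoforms[isoforms$variant == v, , drop = FALSE]
    sub <- sub[order(!sub$canonical, sub$transcript), , drop = FALSE]
    sub_html <- if (nrow(sub) > 0) {
      links <- sprintf("<li>%s%s &mdash; <a href='%s'>report</a></li>",
                       html_escape(sub$transcript),
                       ifelse(sub$canonical, " (canonical)", ""),
                       tx_page(sub$transcript))
      paste0("<ul>\n", paste(links, collapse = "\n"), "\n</ul>")
    } else ""
    parts <- c(parts, sprintf(
      "<details open><summary><b>%s</b></summary>\n%s\n%s</details>",
      html_escape(v), row_tab, sub_html))
  }
  if (!is.null(digenic) && nrow(digenic) > 0) {
    parts <- c(parts, "<h2>Digenic candidate pairs</h2>", html_table(digenic))
  }
  writeLines(html_page(case_title, paste(parts, collapse = "\n")),
             file.path(out_dir, "index.html"))

  for (id in tx_ids) {
    rows <- metric_rows[metric_rows$transcript == id, , drop = FALSE]
    body <- c(sprintf("<p><a href='../index.html'>&larr; case report</a></p>"),
              "<h2>Structure summary</h2>",
              if (nrow(rows) > 0) html_table(rows) else "<p>No completed calculations.</p>")
    for (sid in sort(unique(rows$structure_id))) {
      srows <- rows[rows$structure_id == sid, c("calc_type", "metric", "value")]
      body <- c(body, sprintf("<h3>Structure %s</h3>", html_escape(sid)),
                html_table(srows))
    }
    writeLines(html_page(paste("Transcript", id), paste(body, collapse = "\n")),
               file.path(out_dir, tx_page(id)))
  }

  csv <- summary
  write.csv(csv, file.path(out_dir, "summary.csv"), row.names = FALSE, na = "")
  jsonlite::write_json(list(generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       file.path(out_dir, "render_meta.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
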