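# Case work planning: GUID-suffixed case directories, workplan.csv,
# status-directory protocol, ddG relax-cache, and deterministic stub
# executors standing in for the licensed external calculators.

CALC_TYPES <- c("ddg_monomer", "ddg_cartesian", "pathprox", "ppi_disruption",
                "ptm_proximity", "digenic")
STRUCTURAL_CALCS <- setdiff(CALC_TYPES, "digenic")
JOB_STATES <- c("planned", "queued", "running", "complete", "failed")
WORKPLAN_COLUMNS <- c("job_id", "calc_type", "transcript", "structure_id",
                      "mutation", "params_json", "workdir")

#' Case identifier with GUID
#'
#' Appends an RFC-4122 v4 GUID to the user-supplied case id so that
#' concurrent runs of the same case never share a directory.
#'
#' @param user_case_id user-facing case name.
#' @param guid optionally a fixed GUID (for reproducible runs); by default
#'   a fresh random v4 GUID is generated.
#' @return list of class `case_identifier`: `user_case_id`, `guid`,
#'   `full_id` (`"<user_case_id>_<guid>"`).
#' @export
new_case_id <- function(user_case_id, guid = NULL) {
  if (is.null(guid)) guid <- uuid_v4()
  structure(list(user_case_id = user_case_id, guid = guid,
                 full_id = paste(user_case_id, guid, sep = "_")),
            class = "case_identifier")
}

#' Generate an RFC-4122 version-4 UUID
#'
#' Random hex with the version nibble set to 4 and the variant bits to 10.
#' Draws from the session RNG, so a seeded caller gets reproducible ids.
#'
#' @return a UUID string.
#' @export
uuid_v4 <- function() {
  b <- sample.int(256L, 16L, replace = TRUE) - 1L
  b[7] <- bitwOr(bitwAnd(b[7], 0x0FL), 0x40L)   # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 0x3FL), 0x80L)   # variant 10
  h <- sprintf("%02x", b)
  paste0(paste0(h[1:4], collapse = ""), "-", paste0(h[5:6], collapse = ""),
         "-", paste0(h[7:8], collapse = ""), "-", paste0(h[9:10], collapse = ""),
         "-", paste0(h[11:16], collapse = ""))
}

# directory schema: VUStruct/<full_id>/<transcript>/<source_and_id>/<calc>/work
job_workdir <- function(full_id, transcript, source, structure_id, calc) {
  file.path("VUStruct", full_id, transcript,
            paste(source, structure_id, sep = "_"), calc, "work")
}

#' Regular expression for the case directory schema
#'
#' Every work and status directory created by the planner matches this
#' pattern (paths relative to the case root).
#'
#' @return a single regex string.
#' @export
path_schema_regex <- function() {
  "^VUStruct/[^/]+/[^/]+/[^/]+/(ddg_monomer|ddg_cartesian|pathprox|ppi_disruption|ptm_proximity|digenic)/(work|status)$"
}

#' Plan the case's calculation jobs
#'
#' One job per (variant x chosen structure x registered structural
#' calculator), plus one digenic job per non-empty case. Ordering is
#' deterministic: variant order, then structure selection order, then
#' calculator name. Planning writes nothing scheduler-specific. ddG jobs
#' carry a `needs_relax` parameter: the first job touching a given
#' (structure content, chain, protocol) triple — consulting the optional
#' relax cache — performs the relax step, later ones reuse it.
#'
#' @param case a [new_case_id()].
#' @param variants list of per-variant entries: `gene`, `transcript_id`,
#'   `mutation` (string), `selection` (a `selection_result` or list of
#'   candidates), optional `calc_params` (named by calc_type, merged into
#'   each job's params).
#' @param calcs structural calculators to register (subset of
#'   `ddg_monomer`, `ddg_cartesian`, `pathprox`, `ppi_disruption`,
#'   `ptm_proximity`).
#' @param ddg_cache_dir optional relax-cache directory (see
#'   [ddg_cache_lookup()]).
#' @param digenic include the case-level digenic job?
#' @return data frame of class `vustruct_workplan` with the workplan.csv
#'   columns; attribute `case` holds the case identifier, attribute
#'   `flagged` the mutations planned without structures.
#' @export
plan_case <- function(case, variants, calcs = c("ddg_cartesian", "pathprox"),
                      ddg_cache_dir = NULL, digenic = TRUE) {
  calcs <- sort(match.arg(calcs, STRUCTURAL_CALCS, several.ok = TRUE))
  rows <- list(); flagged <- character(0)
  relax_seen <- character(0)
  genes <- character(0)
  for (v in variants) {
    genes <- union(genes, v$gene)
    chosen <- if (inherits(v$selection, "selection_result"))
      v$selection$chosen else v$selection
    if (length(chosen) == 0) {
      flagged <- c(flagged, v$mutation)
      next
    }
    for (cand in chosen) {
      for (calc in calcs) {
        spec <- v$calc_params[[calc]]
        if (!is.null(spec) && !is.null(spec$by_structure))
          spec <- spec$by_structure[[cand$structure_id]]
        if (calc == "pathprox" && is.null(spec) &&
            "pathprox" %in% names(v$calc_params)) {
          # labels could not be mapped onto this structure; omit the job
          flagged <- c(flagged, paste0(v$mutation, "@", cand$structure_id,
                                       ":pathprox"))
          next
        }
        params <- c(list(coord_path = cand$coord_path), spec)
        if (calc %in% c("ddg_monomer", "ddg_cartesian")) {
          protocol <- sub("^ddg_", "", calc)
          key <- ddg_cache_key(cand$coord_path, cand$chain_ids[1], protocol)
          hit <- key %in% relax_seen ||
            (!is.null(ddg_cache_dir) && ddg_cache_lookup(key, ddg_cache_dir))
          relax_seen <- union(relax_seen, key)
          params$chain <- cand$chain_ids[1]
          params$protocol <- protocol
          params$needs_relax <- !hit
        }
        rows[[length(rows) + 1L]] <- data.frame(
          job_id = "", calc_type = calc, transcript = v$transcript_id,
          structure_id = cand$structure_id, mutation = v$mutation,
          params_json = as.character(
            jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)),
          workdir = job_workdir(case$full_id, v$transcript_id, cand$source,
                                cand$structure_id, calc),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (digenic && length(variants) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      job_id = "", calc_type = "digenic", transcript = "case",
      structure_id = "all", mutation = "",
      params_json = as.character(
        jsonlite::toJSON(list(genes = sort(genes)), digits = NA)),
      workdir = file.path("VUStruct", case$full_id, "case", "all",
                          "digenic", "work"),
      stringsAsFactors = FALSE)
  }
  plan <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(job_id = character(0), calc_type = character(0),
               transcript = character(0), structure_id = character(0),
               mutation = character(0), params_json = character(0),
               workdir = character(0), stringsAsFactors = FALSE)
  plan$job_id <- sprintf("J%04d", seq_len(nrow(plan)))
  attr(plan, "case") <- case
  attr(plan, "flagged") <- flagged
  class(plan) <- c("vustruct_workplan", "data.frame")
  plan
}

statusdir_of <- function(workdir) file.path(dirname(workdir), "status")

#' Write / read workplan.csv
#'
#' The committed workplan.csv dialect:
#' `job_id,calc_type,transcript,structure_id,mutation,params_json,workdir`.
#' A write/read cycle reproduces the planned job table exactly.
#'
#' @param plan a [plan_case()] data frame.
#' @param path file path.
#' @export
write_workplan <- function(plan, path) {
  df <- as.data.frame(plan)[, WORKPLAN_COLUMNS]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_workplan
#' @export
read_workplan <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), WORKPLAN_COLUMNS))
    vu_stop("vustruct_format_error", "not a workplan.csv: columns %s",
            paste(names(df), collapse = ","))
  df
}

#' Materialize the case directory tree
#'
#' Creates every work and sibling status directory under `root`, writes the
#' `planned` status marker for each job and workplan.csv at the case root.
#'
#' @param plan a [plan_case()] result.
#' @param root filesystem root under which `VUStruct/<full_id>/...` is laid
#'   out.
#' @return the case directory path, invisibly.
#' @export
materialize_case <- function(plan, root) {
  case <- attr(plan, "case")
  for (i in seq_len(nrow(plan))) {
    wd <- file.path(root, plan$workdir[i])
    sd <- file.path(root, statusdir_of(plan$workdir[i]))
    dir.create(wd, recursive = TRUE, showWarnings = FALSE)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    write_status(sd, "planned", "job planned")
  }
  case_dir <- file.path(root, "VUStruct", case$full_id)
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  write_workplan(plan, file.path(case_dir, "workplan.csv"))
  flagged <- attr(plan, "flagged")
  if (length(flagged) > 0)
    writeLines(flagged, file.path(case_dir, "flagged_variants.txt"))
  invisible(case_dir)
}

# ---- status protocol: one flat file per state transition -----------------

STATE_FILES <- c(planned = "01_planned", queued = "02_queued",
                 running = "03_running", complete = "04_complete",
                 failed = "04_failed")

#' Record a job state transition
#'
#' States advance `planned -> queued -> running -> complete|failed`; a
#' transition whose predecessor marker is missing, or any transition out of
#' a terminal state, is illegal.
#'
#' @param statusdir the job's status directory.
#' @param state one of `planned`, `queued`, `running`, `complete`, `failed`.
#' @param note free-text progress note stored in the marker file.
#' @export
write_status <- function(statusdir, state, note = "") {
  state <- match.arg(state, JOB_STATES)
  have <- names(STATE_FILES)[file.exists(file.path(statusdir, STATE_FILES))]
  if (any(c("complete", "failed") %in% have))
    vu_stop("vustruct_status_error", "job already in a terminal state")
  pred <- switch(state, planned = NULL, queued = "planned",
                 running = "queued", complete = "running", failed = "running")
  if (!is.null(pred) && !pred %in% have)
    vu_stop("vustruct_status_error",
            "illegal transition to %s without %s marker", state, pred)
  writeLines(paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), note),
             file.path(statusdir, STATE_FILES[[state]]))
  invisible(state)
}

#' Current state of a job's status directory
#'
#' @param statusdir the job's status directory.
#' @return the most advanced recorded state, or `"unknown"` when the
#'   directory is missing or holds no legible marker.
#' @export
read_status <- function(statusdir) {
  if (!dir.exists(statusdir)) return("unknown")
  have <- names(STATE_FILES)[file.exists(file.path(statusdir, STATE_FILES))]
  if (length(have) == 0) return("unknown")
  have[which.max(match(have, JOB_STATES))]
}

# ---- ddG relax cache -----------------------------------------------------

#' ddG relax-cache key
#'
#' Content hash of the coordinate file plus chain and protocol: equal keys
#' mean identical relax inputs, so the relax stage can be reused.
#'
#' @param coord_path coordinate file.
#' @param chain chain id.
#' @param protocol `"monomer"` or `"cartesian"`.
#' @return a key string.
#' @export
ddg_cache_key <- function(coord_path, chain, protocol) {
  protocol <- match.arg(protocol, c("monomer", "cartesian"))
  content <- paste(readLines(coord_path, warn = FALSE), collapse = "\n")
  paste(vu_hash(content), chain, protocol, sep = "_")
}

#' ddG relax-cache operations
#'
#' The cache is a flat directory with one marker file per key; a marker
#' whose content does not match its key is treated as corrupt (miss, with a
#' warning).
#'
#' @param key a [ddg_cache_key()].
#' @param repo cache directory.
#' @return `ddg_cache_lookup` returns `TRUE` (hit) or `FALSE` (miss).
#' @export
ddg_cache_lookup <- function(key, repo) {
  f <- file.path(repo, key)
  if (!file.exists(f)) return(FALSE)
  content <- tryCatch(readLines(f, warn = FALSE)[1], error = function(e) NA)
  if (is.na(content) || content != key) {
    vu_warn("corrupt relax-cache entry %s; treated as miss", key)
    return(FALSE)
  }
  TRUE
}

#' @rdname ddg_cache_lookup
#' @export
ddg_cache_put <- function(key, repo) {
  dir.create(repo, recursive = TRUE, showWarnings = FALSE)
  writeLines(key, file.path(repo, key))
  invisible(key)
}

# ---- stub executors ------------------------------------------------------

# deterministic stub metric in [lo, hi)
stub_metric <- function(parts, lo, hi) {
  lo + (hi - lo) * vu_hash01(parts)
}

#' Execute one planned job with the stub calculator contract
#'
#' Drives the status protocol (`queued -> running -> complete|failed`) and,
#' on success, writes a deterministic result record (`result.json`) in the
#' job's work directory. ddG / PPI-disruption / PTM-proximity metrics are
#' derived from a keyed hash of (structure id, mutation, calc type, stub
#' seed) — deterministic stand-ins for the licensed external calculators.
#' `pathprox` jobs run the real spatial computation
#' ([permutation_pvalue()]) from the residue keys recorded in the job's
#' parameters; `digenic` jobs score all gene pairs with the registered
#' predictor stub.
#'
#' @param job one workplan row (list or one-row data frame).
#' @param root case root (the directory holding `VUStruct/`).
#' @param stub_seed integer mixed into the stub hash.
#' @param fail inject a failure (final state `failed`, reason file, no
#'   result record).
#' @return final state string, invisibly.
#' @export
run_stub <- function(job, root, stub_seed = 0L, fail = FALSE) {
  job <- as.list(job)
  wd <- file.path(root, job$workdir)
  sd <- file.path(root, statusdir_of(job$workdir))
  if (!dir.exists(wd) || !dir.exists(sd))
    vu_stop("vustruct_input_error", "work/status directory missing for %s",
            job$job_id)
  params <- jsonlite::fromJSON(job$params_json)
  write_status(sd, "queued", "submitted")
  write_status(sd, "running", job$calc_type)
  if (fail || isTRUE(params$inject_failure)) {
    write_status(sd, "failed", "injected failure")
    writeLines("injected failure", file.path(wd, "failure_reason.txt"))
    return(invisible("failed"))
  }
  metrics <- switch(job$calc_type,
    ddg_monomer = ,
    ddg_cartesian = list(ddg_reu = round(stub_metric(
      c(job$structure_id, job$mutation, job$calc_type, stub_seed), -3, 9), 3)),
    ppi_disruption = list(ppi_disruption_prob = round(stub_metric(
      c(job$structure_id, job$mutation, job$calc_type, stub_seed), 0, 1), 4)),
    ptm_proximity = list(ptm_min_dist = round(stub_metric(
      c(job$structure_id, job$mutation, job$calc_type, stub_seed), 2, 30), 2)),
    pathprox = {
      cp <- params$coord_path
      if (!grepl("^/", cp)) cp <- file.path(root, cp)
      coords <- read_residue_coords(cp)
      res <- permutation_pvalue(unlist(params$query_keys),
                                unlist(params$p_keys), unlist(params$b_keys),
                                coords, n_perm = params$n_perm %||% 999,
                                seed = params$seed %||% 1)
      list(pathprox_score = res$score, pathprox_pvalue = res$p_value)
    },
    digenic = NULL)
  if (identical(job$calc_type, "digenic")) {
    pairs <- digenic_candidates(unlist(params$genes), threshold = 0)
    jsonlite::write_json(pairs, file.path(wd, "result.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    rec <- list(job_id = job$job_id, calc_type = job$calc_type,
                transcript = job$transcript, structure_id = job$structure_id,
                mutation = job$mutation, metrics = metrics)
    jsonlite::write_json(rec, file.path(wd, "result.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_status(sd, "complete", "result written")
  invisible("complete")
}

#' Run every job in a plan
#'
#' @param plan a [plan_case()] result (or workplan data frame).
#' @param root case root.
#' @param stub_seed stub hash seed.
#' @param fail_jobs job ids to fail (failure injection).
#' @return named character vector of final states.
#' @export
run_all_stubs <- function(plan, root, stub_seed = 0L, fail_jobs = character(0)) {
  states <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    states[i] <- run_stub(plan[i, ], root, stub_seed = stub_seed,
                          fail = plan$job_id[i] %in% fail_jobs)
  }
  setNames(states, plan$job_id)
}

#' Aggregate case progress
#'
#' Reads workplan.csv under the case directory and every job's status
#' directory. Counts always sum to the number of planned jobs (unreadable
#' status directories count as `unknown`); the per-variant rollup marks a
#' variant complete iff all of its jobs are complete.
#'
#' @param root case root.
#' @param full_id the case's `full_id` (see [new_case_id()]).
#' @return list of class `case_status`: `counts` (named integer), `jobs`
#'   (workplan plus `state`), `variants` (rollup with `all_complete`,
#'   `any_failed`).
#' @export
aggregate_status <- function(root, full_id) {
  case_dir <- file.path(root, "VUStruct", full_id)
  if (!dir.exists(case_dir))
    vu_stop("vustruct_input_error", "case directory %s does not exist", case_dir)
  plan <- read_workplan(file.path(case_dir, "workplan.csv"))
  plan$state <- vapply(plan$workdir, function(wd)
    read_status(file.path(root, statusdir_of(wd))), character(1))
  counts <- table(factor(plan$state, levels = c(JOB_STATES, "unknown")))
  key <- paste(plan$transcript, plan$mutation, sep = "|")
  structural <- plan$calc_type != "digenic"
  variants <- do.call(rbind, lapply(unique(key[structural]), function(kk) {
    st <- plan$state[structural & key == kk]
    parts <- strsplit(kk, "|", fixed = TRUE)[[1]]
    data.frame(transcript = parts[1], mutation = parts[2],
               n_jobs = length(st),
               all_complete = all(st == "complete"),
               any_failed = any(st == "failed"), stringsAsFactors = FALSE)
  }))
  structure(list(counts = c(counts), jobs = plan, variants = variants),
            class = "case_status")
}

#' @export
print.case_status <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("<case status>", paste(sprintf("%s: %d", names(nz), nz), collapse = ", "), "\n")
  done <- sum(x$variants$all_complete)
  cat(sprintf("  variants complete: %d / %d\n", done, nrow(x$variants)))
  invisible(x)
}

#' Refresh the case status summary, optionally on an interval
#'
#' One call aggregates and returns the status; with `watch = TRUE` the
#' aggregation repeats every `interval` seconds (default 30 minutes, the
#' report-refresh cadence) until all jobs reach a terminal state.
#'
#' @inheritParams aggregate_status
#' @param watch repeat until done?
#' @param interval seconds between refreshes.
#' @return the last `case_status`.
#' @export
refresh_status <- function(root, full_id, watch = FALSE, interval = 1800) {
  repeat {
    st <- aggregate_status(root, full_id)
    active <- sum(st$counts[c("planned", "queued", "running", "unknown")])
    if (!watch || active == 0) return(st)
    Sys.sleep(interval)
  }
}
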