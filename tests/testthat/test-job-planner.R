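# shared toy planning setup: 1 variant x 2 structures, coordinate files on
# disk so the ddG cache can hash them
planner_fixture <- function(root, calcs = c("ddg_cartesian", "pathprox")) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  seq20 <- "MKVLQASDFGHIKLMNPQRS"
  make_toy_structure(seq20, "line", file.path(root, "s1.pdb"))
  make_toy_structure(substr(seq20, 3, 18), "helix", file.path(root, "s2.pdb"))
  c1 <- toy_candidate("s1", 1:20, coord_path = file.path(root, "s1.pdb"))
  c2 <- toy_candidate("s2", 3:18, method = "EM", resolution = 3.2,
                      coord_path = file.path(root, "s2.pdb"))
  case <- new_case_id("toy", guid = "00000000-0000-4000-8000-000000000001")
  variants <- list(list(gene = "G1", transcript_id = "TX1", mutation = "K2R",
                        selection = list(c1, c2)))
  list(case = case, variants = variants,
       plan = plan_case(case, variants, calcs = calcs))
}

test_that("generated GUIDs are well-formed v4 and case ids compose", {
  withr::with_seed(2, {
    ids <- replicate(20, uuid_v4())
    expect_true(all(grepl(
      "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$",
      ids)))
    expect_equal(length(unique(ids)), 20)
  })
  case <- new_case_id("UDN123", guid = "00000000-0000-4000-8000-000000000099")
  expect_equal(case$full_id, "UDN123_00000000-0000-4000-8000-000000000099")
})

test_that("planning produces the variant x structure x calc product plus one digenic job", {
  root <- withr::local_tempdir()
  fx <- planner_fixture(root)
  plan <- fx$plan
  expect_equal(nrow(plan), 1 * 2 * 2 + 1)
  expect_equal(sum(plan$calc_type == "digenic"), 1)
  # deterministic ordering: structure order then calc name
  expect_equal(plan$calc_type[1:4],
               c("ddg_cartesian", "pathprox", "ddg_cartesian", "pathprox"))
  expect_equal(plan$structure_id[1:4], c("s1", "s1", "s2", "s2"))
  # no scheduler-specific content anywhere
  expect_false(any(grepl("slurm|sbatch|bsub|lsf", unlist(plan),
                         ignore.case = TRUE)))

  # empty variant list: no jobs at all, not even digenic
  empty <- plan_case(fx$case, list())
  expect_equal(nrow(empty), 0)

  # variant with empty selection is flagged, not planned
  novar <- plan_case(fx$case, list(list(gene = "G", transcript_id = "T",
                                        mutation = "A1V", selection = list())))
  expect_equal(sum(novar$calc_type != "digenic"), 0)
  expect_equal(attr(novar, "flagged"), "A1V")
})

test_that("work directories follow the case path schema with the GUID root", {
  root <- withr::local_tempdir()
  fx <- planner_fixture(root)
  materialize_case(fx$plan, root)
  rel_dirs <- c(fx$plan$workdir,
                file.path(dirname(fx$plan$workdir), "status"))
  expect_true(all(grepl(path_schema_regex(), rel_dirs)))
  expect_true(all(dir.exists(file.path(root, rel_dirs))))
  expect_true(all(startsWith(fx$plan$workdir,
                             file.path("VUStruct", fx$case$full_id))))

  # same case replanned under a different GUID: identical relative paths
  # below the full_id root
  case2 <- new_case_id("toy", guid = "00000000-0000-4000-8000-000000000002")
  plan2 <- plan_case(case2, fx$variants)
  strip <- function(p, id) sub(paste0("^VUStruct/", id, "/"), "", p)
  expect_equal(strip(plan2$workdir, case2$full_id),
               strip(fx$plan$workdir, fx$case$full_id))
})

test_that("workplan.csv round-trips exactly", {
  root <- withr::local_tempdir()
  fx <- planner_fixture(root)
  f <- file.path(root, "workplan.csv")
  write_workplan(fx$plan, f)
  back <- read_workplan(f)
  expect_equal(back, as.data.frame(fx$plan)[, vustruct:::WORKPLAN_COLUMNS],
               ignore_attr = TRUE)
  expect_error(read_workplan(withr::local_tempfile(lines = "a,b\n1,2")),
               class = "vustruct_format_error")
})

test_that("the relax cache deduplicates ddG jobs by structure content", {
  root <- withr::local_tempdir()
  seqA <- "MKVLQASDFG"
  make_toy_structure(seqA, "line", file.path(root, "a.pdb"))
  cand <- function(id) toy_candidate(id, 1:10,
                                     coord_path = file.path(root, "a.pdb"))
  case <- new_case_id("c", guid = "00000000-0000-4000-8000-00000000000a")
  # two variants on one structure: exactly one relax-bearing ddg job
  vars <- list(list(gene = "G", transcript_id = "T", mutation = "K2R",
                    selection = list(cand("s"))),
               list(gene = "G", transcript_id = "T", mutation = "V3A",
                    selection = list(cand("s"))))
  plan <- plan_case(case, vars, calcs = "ddg_cartesian")
  needs <- vapply(plan$params_json[plan$calc_type == "ddg_cartesian"],
                  function(j) jsonlite::fromJSON(j)$needs_relax, logical(1))
  expect_equal(sum(needs), 1L)

  # cache primitives: put-then-lookup hits, empty repo misses, corrupt
  # entries degrade to a miss with a warning
  repo <- withr::local_tempdir()
  key <- ddg_cache_key(file.path(root, "a.pdb"), "A", "cartesian")
  expect_false(ddg_cache_lookup(key, repo))
  ddg_cache_put(key, repo)
  expect_true(ddg_cache_lookup(key, repo))
  writeLines("garbage", file.path(repo, key))
  expect_warning(miss <- ddg_cache_lookup(key, repo), "corrupt")
  expect_false(miss)

  # one changed coordinate changes the key
  make_toy_structure(seqA, "helix", file.path(root, "b.pdb"))
  key2 <- ddg_cache_key(file.path(root, "b.pdb"), "A", "cartesian")
  expect_false(key == key2)
  # a pre-warmed repo suppresses the relax step at planning time
  ddg_cache_put(key, repo)
  plan2 <- plan_case(case, vars[1], calcs = "ddg_cartesian",
                     ddg_cache_dir = repo)
  needs2 <- jsonlite::fromJSON(
    plan2$params_json[plan2$calc_type == "ddg_cartesian"])$needs_relax
  expect_false(needs2)
})

test_that("status protocol enforces legal lifecycle transitions", {
  sd <- withr::local_tempdir()
  expect_equal(read_status(sd), "unknown")
  expect_error(write_status(sd, "running"), class = "vustruct_status_error")
  write_status(sd, "planned")
  expect_error(write_status(sd, "complete"), class = "vustruct_status_error")
  write_status(sd, "queued"); write_status(sd, "running")
  expect_equal(read_status(sd), "running")
  write_status(sd, "complete")
  expect_equal(read_status(sd), "complete")
  expect_error(write_status(sd, "running"), class = "vustruct_status_error")
})

test_that("stub runs are deterministic, injectable, and drive real spatial jobs", {
  root <- withr::local_tempdir()
  fx <- planner_fixture(root, calcs = "ddg_cartesian")
  materialize_case(fx$plan, root)
  job <- fx$plan[1, ]
  run_stub(job, root)
  f <- file.path(root, job$workdir, "result.json")
  first <- readLines(f)
  # re-run the same job from scratch: byte-identical result record
  unlink(file.path(root, vustruct:::statusdir_of(job$workdir)),
         recursive = TRUE)
  dir.create(file.path(root, vustruct:::statusdir_of(job$workdir)))
  write_status(file.path(root, vustruct:::statusdir_of(job$workdir)), "planned")
  run_stub(job, root)
  expect_identical(readLines(f), first)
  rec <- jsonlite::fromJSON(f)
  expect_true(is.numeric(rec$metrics$ddg_reu))

  # failure injection: failed status, reason file, no result record
  job2 <- fx$plan[2, ]
  expect_equal(run_stub(job2, root, fail = TRUE), "failed")
  expect_equal(read_status(file.path(root,
                                     vustruct:::statusdir_of(job2$workdir))),
               "failed")
  expect_true(file.exists(file.path(root, job2$workdir, "failure_reason.txt")))
  expect_false(file.exists(file.path(root, job2$workdir, "result.json")))

  # pathprox jobs delegate to the real spatial computation
  pvars <- list(list(
    gene = "G1", transcript_id = "TX1", mutation = "K2R",
    selection = list(toy_candidate("s1", 1:20,
                                   coord_path = file.path(root, "s1.pdb"))),
    calc_params = list(pathprox = list(
      query_keys = "A:2", p_keys = paste0("A:", 3:6),
      b_keys = paste0("A:", 12:18), n_perm = 200, seed = 4))))
  pcase <- new_case_id("pp", guid = "00000000-0000-4000-8000-00000000000b")
  pplan <- plan_case(pcase, pvars, calcs = "pathprox", digenic = FALSE)
  materialize_case(pplan, root)
  run_all_stubs(pplan, root)
  prec <- jsonlite::fromJSON(file.path(root, pplan$workdir[1], "result.json"))
  co <- read_residue_coords(file.path(root, "s1.pdb"))
  want <- permutation_pvalue("A:2", paste0("A:", 3:6), paste0("A:", 12:18),
                             co, n_perm = 200, seed = 4)
  expect_equal(prec$metrics$pathprox_score, want$score)
  expect_equal(prec$metrics$pathprox_pvalue, want$p_value)
})

test_that("status aggregation counts every job and rolls up variants", {
  root <- withr::local_tempdir()
  fx <- planner_fixture(root)
  # give pathprox jobs usable label keys so all jobs can run
  vars <- fx$variants
  vars[[1]]$calc_params <- list(pathprox = list(by_structure = list(
    s1 = list(query_keys = "A:2", p_keys = paste0("A:", 3:5),
              b_keys = paste0("A:", 10:14), n_perm = 50, seed = 1),
    s2 = list(query_keys = "A:1", p_keys = paste0("A:", 2:4),
              b_keys = paste0("A:", 8:12), n_perm = 50, seed = 1))))
  plan <- plan_case(fx$case, vars)
  materialize_case(plan, root)
  st0 <- aggregate_status(root, fx$case$full_id)
  expect_equal(unname(st0$counts["planned"]), nrow(plan))
  expect_equal(sum(st0$counts), nrow(plan))

  states <- run_all_stubs(plan, root, fail_jobs = plan$job_id[3])
  st <- aggregate_status(root, fx$case$full_id)
  expect_equal(unname(st$counts["complete"]), nrow(plan) - 1L)
  expect_equal(unname(st$counts["failed"]), 1L)
  expect_equal(sum(st$counts), nrow(plan))
  expect_true(any(st$variants$any_failed))
  # refresh without watch returns the same snapshot
  expect_equal(refresh_status(root, fx$case$full_id)$counts, st$counts)

  # unreadable status directory counts as unknown
  unlink(file.path(root, vustruct:::statusdir_of(plan$workdir[1])),
         recursive = TRUE)
  st2 <- aggregate_status(root, fx$case$full_id)
  expect_equal(unname(st2$counts["unknown"]), 1L)
  expect_equal(sum(st2$counts), nrow(plan))
})
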