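test_that("drug libraries apply the affinity filter and collapse duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\ta\t5", "d1\ta\t5", "d1\tb\t50"), path)
  lib <- load_drug_library(path)
  expect_equal(lib[["d1"]], "a")
  expect_equal(attr(lib, "n_filtered"), 1L)
  # without an affinity column everything is retained
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\ta", "d1\tb", "d2\tc"), path2)
  lib2 <- load_drug_library(path2)
  expect_setequal(lib2[["d1"]], c("a", "b"))
  blank <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), blank)
  expect_error(load_drug_library(blank), "empty|no lines")
})

test_that("a 20-drug library round-trips through write and load", {
  fx <- study_fixture()
  lib <- fx$library[1:20]
  class(lib) <- "drug_target_library"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_drug_library(lib, path)
  lib2 <- load_drug_library(path)
  expect_equal(lapply(lib2, sort)[names(lib)], lapply(lib, sort))
})

test_that("screen applies the printed AND rule and never aborts on bad drugs", {
  fx <- study_fixture()
  small <- fx$library[c("D001", "D004", "D005")]
  small[["DX"]] <- c("not_in_graph_1", "not_in_graph_2")
  class(small) <- "drug_target_library"
  mod <- extract_module(
    setNames(seq_along(fx$planted), fx$planted) / sum(seq_along(fx$planted)),
    k = length(fx$planted))
  rep <- run_screen(fx$graph, mod, small, fx$dag, fx$annot,
                    n_perm = 50, rng_seed = 3)
  r <- rep$report
  expect_equal(nrow(r), 4)
  expect_equal(r$skip_reason[r$drug == "DX"], "no target in interactome")
  executed <- r[r$drug != "DX", ]
  expect_equal(executed$final_candidate,
               executed$pass_np & executed$pass_fs & executed$pass_rwr)
  # a planted drug passes, decoys fail, and an empty intersection is legal
  expect_true(r$final_candidate[r$drug == "D001"])
  expect_false(any(r$final_candidate[r$drug %in% c("D004", "D005")]))
  decoys_only <- run_screen(fx$graph, mod,
                            structure(fx$library["D004"],
                                      class = "drug_target_library"),
                            n_perm = 20, rng_seed = 3)
  expect_equal(length(candidate_sets(decoys_only)$all_three), 0)
})

test_that("per-drug child seeds isolate drugs from library composition", {
  fx <- study_fixture()
  mod <- extract_module(
    setNames(rev(seq_along(fx$planted)), fx$planted), k = 10)
  lib2 <- structure(fx$library[c("D001", "D004")],
                    class = "drug_target_library")
  lib3 <- structure(fx$library[c("D001", "D004", "D020")],
                    class = "drug_target_library")
  r2 <- run_screen(fx$graph, mod, lib2, n_perm = 30, rng_seed = 17)
  r3 <- run_screen(fx$graph, mod, lib3, n_perm = 30, rng_seed = 17)
  cols <- c("d", "z_np", "p_np", "cor", "z_rwr", "p_rwr")
  expect_equal(r2$report[r2$report$drug == "D001", cols],
               r3$report[r3$report$drug == "D001", cols],
               ignore_attr = TRUE)
})

test_that("per-method results equal standalone reruns with the child seed", {
  fx <- study_fixture()
  mod <- extract_module(
    setNames(rev(seq_along(fx$planted)), fx$planted), k = 10)
  lib <- structure(fx$library["D002"], class = "drug_target_library")
  rep <- run_screen(fx$graph, mod, lib, n_perm = 40, rng_seed = 23)
  standalone <- proximity_screen(
    fx$graph, intersect(fx$library[["D002"]], igraph::V(fx$graph)$name),
    mod, n_perm = 40, rng_seed = derive_seed(23, "np:D002"),
    bins = fx$bins, D = fx$D)
  expect_equal(rep$report$d[1], standalone$d_obs)
  expect_equal(rep$report$z_np[1], standalone$z_np)
  expect_equal(rep$report$p_np[1], standalone$p)
})

test_that("candidate sets are monotone under threshold loosening", {
  fx <- study_fixture()
  small <- structure(fx$library[c("D001", "D002", "D004", "D010")],
                     class = "drug_target_library")
  mod <- extract_module(
    setNames(seq_along(fx$planted), fx$planted), k = length(fx$planted))
  strict <- run_screen(fx$graph, mod, small, fx$dag, fx$annot,
                       n_perm = 50, rng_seed = 5)
  loose <- run_screen(fx$graph, mod, small, fx$dag, fx$annot,
                      n_perm = 50, rng_seed = 5,
                      thresholds = screen_thresholds(
                        z_np = -2, p_np = 0.1, fs = 0.5, p_fs = 0.1,
                        z_rwr = 2, p_rwr = 0.1))
  expect_true(all(candidate_sets(strict)$all_three %in%
                  candidate_sets(loose)$all_three))
})

test_that("reports serialize deterministically with a manifest", {
  fx <- study_fixture()
  lib <- structure(fx$library[c("D001", "D004")],
                   class = "drug_target_library")
  mod <- extract_module(setNames(seq_along(fx$planted), fx$planted), k = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_screen_report(run_screen(fx$graph, mod, lib, n_perm = 25,
                                 rng_seed = 9), d1)
  write_screen_report(run_screen(fx$graph, mod, lib, n_perm = 25,
                                 rng_seed = 9), d2)
  f1 <- file.path(d1, "screen_report.tsv")
  f2 <- file.path(d2, "screen_report.tsv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(file.exists(file.path(d1, "run_manifest.json")))
})
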