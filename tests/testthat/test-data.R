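write_demo_csv <- function(path, rows) {
  writeLines(c("id,smiles,label_a,label_b", rows), path)
}

test_that("dataset loading drops record rows without id/SMILES and validates the rest", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_demo_csv(path, c("d1,CCO,1,0", "d2,,0,1", "d3,CCN,1,1",
                         "d4,CCC,0,0", "d5,CO,1,0"))
  recs <- load_drug_dataset(path)
  expect_length(recs, 4)
  expect_equal(attr(recs, "dropped"), 1)
  expect_equal(attr(recs, "label_names"), c("label_a", "label_b"))
  expect_equal(recs[[1]]$labels, c(label_a = 1L, label_b = 0L))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,smiles,label_a,label_b", empty)
  expect_error(load_drug_dataset(empty), class = "moladr_validation_error")

  dup <- withr::local_tempfile(fileext = ".csv")
  write_demo_csv(dup, c("d1,CCO,1,0", "d1,CCN,0,1"))
  err <- expect_error(load_drug_dataset(dup), class = "moladr_validation_error")
  expect_match(conditionMessage(err), "d1")

  nonbin <- withr::local_tempfile(fileext = ".csv")
  write_demo_csv(nonbin, c("d1,CCO,1,0", "d2,CCN,2,1"))
  err2 <- expect_error(load_drug_dataset(nonbin), class = "moladr_validation_error")
  expect_match(conditionMessage(err2), "row 2")

  expect_error(load_drug_dataset(tempfile()), class = "moladr_io_error")
})

test_that("datasets round-trip through the CSV dialect", {
  recs <- tiny_records(n = 5, n_labels = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_drug_dataset(recs, path)
  back <- load_drug_dataset(path)
  expect_equal(label_matrix(back), label_matrix(recs))
  expect_equal(vapply(back, `[[`, character(1), "smiles"),
               vapply(recs, `[[`, character(1), "smiles"))
})

test_that("label statistics obey density = cardinality / N_l", {
  # the ADReCS-SOC setting: cardinality 16.5 over 27 labels -> 0.6111
  Y <- rbind(c(rep(1, 16), rep(0, 11)), c(rep(1, 17), rep(0, 10)))
  st <- label_stats(Y)
  expect_equal(st$cardinality, 16.5)
  expect_equal(round(st$density, 4), 0.6111)

  ones <- matrix(1, 5, 4)
  expect_equal(label_stats(ones)$cardinality, 4)
  expect_equal(label_stats(ones)$density, 1.0)
  zeros <- matrix(0, 5, 4)
  expect_equal(label_stats(zeros)$cardinality, 0)
  expect_equal(label_stats(zeros)$density, 0)

  set.seed(3)
  Yr <- matrix(rbinom(60, 1, 0.4), 15, 4)
  str_ <- label_stats(Yr)
  expect_equal(str_$density, str_$cardinality / 4)
  expect_equal(unname(diag(str_$co_occurrence)), unname(colSums(Yr)))
  expect_true(isSymmetric(str_$co_occurrence))
  expect_error(label_stats(matrix(0, 0, 3)), class = "moladr_validation_error")
})

test_that("holdout split uses the floor rule and is a seeded partition", {
  recs <- lapply(seq_len(2248), function(i)
    list(id = paste0("d", i), smiles = "C", labels = c(l = 1L)))
  sp <- split_train_test(recs, 0.9, seed = 1)
  expect_length(sp$train, 2023)
  expect_length(sp$test, 225)
  ids <- c(vapply(sp$train, `[[`, character(1), "id"),
           vapply(sp$test, `[[`, character(1), "id"))
  expect_setequal(ids, paste0("d", 1:2248))
  expect_length(intersect(vapply(sp$train, `[[`, character(1), "id"),
                          vapply(sp$test, `[[`, character(1), "id")), 0)

  sp2 <- split_train_test(recs, 0.9, seed = 1)
  expect_identical(vapply(sp$train, `[[`, character(1), "id"),
                   vapply(sp2$train, `[[`, character(1), "id"))

  small <- recs[1:10]
  sp3 <- split_train_test(small, 0.9, seed = 2)
  expect_length(sp3$train, 9)
  expect_length(sp3$test, 1)
  expect_error(split_train_test(recs[1], 0.9), class = "moladr_validation_error")
})

test_that("k-fold validation folds partition the records with near-equal sizes", {
  recs <- lapply(seq_len(90), function(i)
    list(id = paste0("d", i), smiles = "C", labels = c(l = 0L)))
  folds <- kfold_split(recs, k = 5, seed = 3)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) length(f$validation), integer(1))
  expect_equal(sizes, rep(18L, 5))
  all_val <- unlist(lapply(folds, function(f)
    vapply(f$validation, `[[`, character(1), "id")))
  expect_setequal(all_val, paste0("d", 1:90))
  expect_equal(length(all_val), 90)          # pairwise disjoint
  for (f in folds) {
    expect_length(intersect(vapply(f$train, `[[`, character(1), "id"),
                            vapply(f$validation, `[[`, character(1), "id")), 0)
  }
  # uneven N: sizes differ by at most one
  folds2 <- kfold_split(recs[1:47], k = 5, seed = 3)
  sizes2 <- vapply(folds2, function(f) length(f$validation), integer(1))
  expect_lte(max(sizes2) - min(sizes2), 1)
  expect_identical(kfold_split(recs, 5, seed = 9), kfold_split(recs, 5, seed = 9))
  expect_error(kfold_split(recs[1:3], k = 5), class = "moladr_validation_error")
})

test_that("jackknife yields one leave-one-out pair per record", {
  recs <- lapply(seq_len(171), function(i)
    list(id = paste0("d", i), smiles = "C", labels = c(l = 1L)))
  pairs <- jackknife_split(recs)
  expect_length(pairs, 171)
  expect_true(all(vapply(pairs, function(p) length(p$train), integer(1)) == 170))
  held <- vapply(pairs, function(p) p$test[[1]]$id, character(1))
  expect_setequal(held, paste0("d", 1:171))
  expect_equal(length(unique(held)), 171)

  p3 <- jackknife_split(recs[1:3])
  expect_length(p3, 3)
  expect_true(all(vapply(p3, function(p) length(p$train), integer(1)) == 2))
  expect_error(jackknife_split(recs[1]), class = "moladr_validation_error")
})

test_that("the synthetic generator is seeded, parseable, and rule-faithful at zero noise", {
  spec <- synthetic_spec(30, 4, label_noise = 0, seed = 11)
  recs <- generate_synthetic(spec)
  recs2 <- generate_synthetic(spec)
  expect_identical(recs, recs2)
  expect_length(recs, 30)

  # every SMILES parses and labels are binary
  for (r in recs) {
    expect_s3_class(smiles_to_graph(r$smiles), "molecular_graph")
    expect_true(all(r$labels %in% c(0L, 1L)))
  }

  # noise-free labels are exactly recoverable by substructure matching
  found <- match_markers(recs, spec$markers)
  expect_equal(unname(label_matrix(recs)), found)

  # label noise perturbs labels away from the clean assignment
  noisy <- generate_synthetic(synthetic_spec(60, 4, label_noise = 0.3, seed = 11))
  expect_gt(sum(label_matrix(noisy) != attr(noisy, "clean_labels")), 0)
})

test_that("planted-label prevalence stays inside a 99% binomial interval", {
  prev <- 0.35
  spec <- synthetic_spec(500, 4, label_noise = 0, marker_prevalence = prev,
                         seed = 23)
  recs <- generate_synthetic(spec)
  counts <- colSums(label_matrix(recs))
  ci <- qbinom(c(0.005, 0.995), 500, prev)
  for (j in 1:4) {
    expect_gte(counts[j], ci[1])
    expect_lte(counts[j], ci[2])
  }
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec(10, 99), class = "moladr_validation_error")
  expect_error(synthetic_spec(10, 2, label_noise = 2),
               class = "moladr_validation_error")
  expect_error(synthetic_spec(10, 1, markers = "C(((("),
               class = "moladr_validation_error")
})
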