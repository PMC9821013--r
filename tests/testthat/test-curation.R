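test_that("pIC50 conversion inverts -log10 of a molar IC50", {
  expect_equal(to_pic50(1e-6), 6)
  expect_equal(to_pic50(1e-9), 9)
  # sotorasib's experimental potency: 30.2 nM is pIC50 7.52
  expect_equal(to_pic50(3.02e-8), 7.52, tolerance = 0.005 / 7.52)
  # round trip across the assay-relevant range
  p <- seq(3, 12, by = 0.25)
  expect_equal(to_pic50(10^(-p)), p, tolerance = 1e-9)
  expect_error(to_pic50(0), "positive")
  expect_error(to_pic50(-1e-9), "positive")
  expect_error(to_pic50(NA_real_), "missing")

  expect_equal(ic50_to_molar(30.2, "nM"), 3.02e-8)
  expect_equal(ic50_to_molar(c(1, 1), c("uM", "mM")), c(1e-6, 1e-3))
  expect_error(ic50_to_molar(1, "furlongs"), "unknown")
})

test_that("activity labelling uses an inclusive threshold at pIC50 6", {
  expect_equal(label_activity(c(6, 5.99, 7.43)),
               c("active", "inactive", "active"))
  expect_equal(label_activity(5, threshold = 5), "active")
  expect_error(label_activity(Inf), "finite")
})

test_that("deduplication keeps the most potent record per structure", {
  rec <- data.frame(compound_id = c("a1", "a2", "b1"),
                    pic50 = c(8, 7, 6.5), # 10 nM, 100 nM, ~316 nM
                    stringsAsFactors = FALSE)
  out <- deduplicate_compounds(rec, key = c("A", "A", "B"))
  expect_equal(out$records$compound_id, c("a1", "b1"))
  expect_equal(out$n_removed, 1)

  # singleton input unchanged
  one <- deduplicate_compounds(rec[3, ], key = "B")
  expect_equal(one$records$compound_id, "b1")
  expect_equal(one$n_removed, 0)

  # exact ties keep the first record in input order
  tie <- data.frame(compound_id = c("x1", "x2"), pic50 = c(8, 8))
  expect_equal(deduplicate_compounds(tie, key = c("A", "A"))$records$compound_id,
               "x1")

  # unparseable structures are routed to rejects, not dropped silently
  out <- deduplicate_compounds(rec, key = c("A", NA, "B"))
  expect_equal(out$rejects$compound_id, "a2")
  expect_equal(nrow(out$records), 2)

  # idempotence
  once <- deduplicate_compounds(rec, key = c("A", "A", "B"))$records
  once$structure_key <- c("A", "B")
  twice <- deduplicate_compounds(once)$records
  expect_equal(twice$compound_id, once$compound_id)

  # surviving records preserve input order
  set.seed(4)
  n <- 50
  big <- data.frame(compound_id = sprintf("c%02d", 1:n),
                    pic50 = round(runif(n, 4, 9), 2))
  keys <- sample(LETTERS[1:12], n, replace = TRUE)
  out <- deduplicate_compounds(big, key = keys)
  expect_false(is.unsorted(match(out$records$compound_id, big$compound_id)))
})

test_that("molecular-weight filter removes strictly-heavier compounds", {
  rec <- data.frame(compound_id = c("a", "b", "c"),
                    molecular_weight = c(999, 1000.0, 1000.5))
  out <- filter_molecular_weight(rec)
  expect_equal(out$records$compound_id, c("a", "b")) # 1000.0 retained
  expect_equal(out$n_removed, 1)
  empty <- filter_molecular_weight(rec[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$n_removed, 0)
})

test_that("Lipinski violation counting follows the rule of five", {
  expect_equal(lipinski_violations(600, 6, 0, 2), 2)
  expect_equal(lipinski_violations(300, 2, 6, 2), 1) # donors alone
  expect_equal(lipinski_violations(300, 2, 1, 2), 0)
  expect_equal(lipinski_violations(501, 5.1, 6, 11), 4)
  # boundary values do not violate
  expect_equal(lipinski_violations(500, 5, 5, 10), 0)
})

test_that("descriptors and drug-likeness come from the structure toolkit", {
  prof <- lipinski_profile(c("CCO", "not-a-smiles"))
  expect_true(prof$available[1])
  expect_false(prof$available[2])
  expect_match(prof$reason[2], "parse")
  # ethanol: one donor, one acceptor, no violations
  expect_equal(prof$h_bond_donors[1], 1)
  expect_equal(prof$h_bond_acceptors[1], 1)
  expect_equal(prof$violations[1], 0)
  expect_equal(prof$molecular_weight[1], 46.07, tolerance = 1e-3)

  mols <- fixture_smiles()
  desc <- molecular_descriptors(mols$smiles)
  expect_true(all(desc$available))
  # afatinib (MW 485.9) stays under the curation cutoff and under 500 Da
  afat <- desc[mols$name == "afatinib", ]
  expect_equal(afat$molecular_weight, 485.94, tolerance = 1e-3)
  expect_equal(afat$h_bond_donors, 2)
})

test_that("canonical structure keys collapse equivalent SMILES", {
  keys <- canonical_key(c("CCO", "OCC", "c1ccccc1", "C1=CC=CC=C1",
                          "not-a-smiles"))
  expect_equal(keys[1], keys[2])
  expect_equal(keys[3], keys[4])
  expect_false(keys[1] == keys[3])
  expect_true(is.na(keys[5]))
  # the two key backends agree on what is equivalent
  cans <- canonical_key(c("CCO", "OCC"), method = "cansmiles")
  expect_equal(cans[1], cans[2])
})

test_that("the curation pipeline applies its rules in order and logs counts", {
  raw <- data.frame(
    compound_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    smiles = c("CCO", "OCC", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
               "CCN", "bad(((smiles"),
    ic50 = c(100, 10, 2000, 50, 10, 10), # nM; c2 is the more potent ethanol
    ic50_units = "nM",
    molecular_weight = c(46.07, 46.07, 78.11, 180.16, 1200, 45.08),
    stringsAsFactors = FALSE)
  cur <- curate_dataset(raw)
  # ethanol deduplicated (keep c2), heavy c5 removed, bad SMILES rejected
  expect_equal(cur$records$compound_id, c("c2", "c3", "c4"))
  expect_equal(nrow(cur$rejects), 1)
  expect_equal(cur$rejects$compound_id, "c6")
  expect_equal(cur$records$activity,
               c("active", "inactive", "active")) # 10 nM -> 8, 2 uM -> 5.7
  expect_equal(cur$records$pic50[1], 8)
  # conservation: kept + removed + rejects == input
  total <- nrow(cur$records) + sum(cur$log$removed)
  expect_equal(total, nrow(raw))
  # the log tracks each rule
  expect_equal(cur$log$remaining[nrow(cur$log)], nrow(cur$records))

  out_csv <- tempfile(fileext = ".csv")
  out_log <- tempfile(fileext = ".json")
  write_curated(cur, out_csv, out_log)
  back <- read.csv(out_csv, stringsAsFactors = FALSE)
  expect_equal(back$compound_id, cur$records$compound_id)
  log <- jsonlite::read_json(out_log, simplifyVector = TRUE)
  expect_equal(log$removed, cur$log$removed)
})

test_that("train/test splitting is stratified, sized, and reproducible", {
  rec <- data.frame(compound_id = sprintf("c%04d", 1:1255),
                    pic50 = c(rep(7, 800), rep(5, 455)))
  rec$activity <- label_activity(rec$pic50)
  out <- split_train_test(rec, train_fraction = 0.7, seed = 99)
  expect_equal(sum(out$split == "train"), 878)
  expect_equal(sum(out$split == "test"), 377)
  # stratification: class balance preserved within ~1%
  tr_frac <- mean(out$activity[out$split == "train"] == "active")
  expect_equal(tr_frac, 800 / 1255, tolerance = 0.01)
  # determinism
  expect_identical(split_train_test(rec, 0.7, seed = 99)$split, out$split)
  expect_false(identical(split_train_test(rec, 0.7, seed = 100)$split,
                         out$split))

  # n = 10 at 50% -> 5/5
  ten <- data.frame(pic50 = rnorm(10, 6), activity = "active")
  expect_equal(unname(table(split_train_test(ten, 0.5, seed = 1)$split)),
               c(5L, 5L), ignore_attr = TRUE)

  # pre-assigned labels are preserved verbatim
  rec$split <- rep(c("train", "test"), length.out = 1255)
  kept <- split_train_test(rec, 0.7, seed = 1)
  expect_identical(kept$split, rec$split)

  expect_error(split_train_test(rec, 1.2, seed = 1), "between 0 and 1")
  expect_error(split_train_test(rec[0, ], 0.7, seed = 1), "empty")
})

test_that("activity tables round-trip through the reader", {
  tbl <- data.frame(compound_id = c("a", "b"), smiles = c("CCO", "CCN"),
                    ic50 = c(100, 10), ic50_units = "nM")
  path <- tempfile(fileext = ".csv")
  write.csv(tbl, path, row.names = FALSE)
  back <- read_activity_table(path)
  expect_equal(back$compound_id, tbl$compound_id)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = "CCO"), bad, row.names = FALSE)
  expect_error(read_activity_table(bad), "missing columns")
  nolabel <- tempfile(fileext = ".csv")
  write.csv(data.frame(compound_id = "a", smiles = "CCO"), nolabel,
            row.names = FALSE)
  expect_error(read_activity_table(nolabel), "pic50 or an ic50")
})
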