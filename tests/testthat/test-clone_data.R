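test_that("records are assigned to the expected clone categories", {
  records <- rbind(
    rec(1, r1 = 2, r2a = 1),                 # ECs only
    rec(2, r2a = 1, fsc = 2, fc = "I"),      # ECs, FSCs and FCs
    rec(3, fsc = 3),                         # FSCs alone
    rec(4, fc = "E3;E4"),                    # FCs alone
    rec(5, r1 = 1, fc = "E4"),               # discontinuous ECs + FCs
    rec(6)                                   # unlabeled
  )
  cat <- clonecensus:::classify_records(ovariole_records(records))
  expect_equal(as.character(cat),
               c("EC_only", "EC_FSC", "FSC_only", "FC_only", "EC_plus_FC", NA))
})

test_that("ingest reproduces the 0 hr APF MARCM category table", {
  table <- ingest_records(marcm_0h_like_records())
  expect_equal(table$n_scored, 207)
  expect_equal(table$n_marked, 98)
  expect_equal(table$n_unlabeled, 109)
  n <- setNames(table$categories$n, table$categories$category)
  expect_equal(unname(n[c("EC_only", "EC_FSC", "FSC_only", "FC_only",
                          "EC_plus_FC")]), c(46, 24, 3, 9, 16))
  # printed category shares, percent, to the published rounding
  expect_near(100 * unname(n[c("EC_only", "EC_FSC", "FSC_only",
                               "EC_plus_FC")]) / 98,
              c(46.9, 24.5, 3.1, 16.3), 0.05)
  # totals reconcile with per-row counts
  expect_equal(table$total_ec, 46 * 3 + 24 * 4 + 16 * 3)
  expect_equal(table$total_fsc, 24 * 4 + 3 * 4)
})

test_that("category assignment is a partition and order-invariant", {
  set.seed(11)
  for (i in 1:5) {
    n <- 60
    records <- do.call(rbind, lapply(seq_len(n), function(j) {
      rec(j, r1 = rpois(1, 0.8), r2a = rpois(1, 0.5), fsc = rpois(1, 0.6),
          fc = sample(c("", "I", "E4", "I;G;E1", "E2;E3"), 1))
    }))
    table <- ingest_records(records)
    expect_equal(sum(table$categories$n) + table$n_unlabeled, n)
    shuffled <- records[sample(n), ]
    f1 <- aggregate_frequencies(table)
    f2 <- aggregate_frequencies(ingest_records(shuffled))
    expect_equal(f1[c("f_ec", "f_fc", "f_fsc", "f_ecfc")],
                 f2[c("f_ec", "f_fc", "f_fsc", "f_ecfc")])
  }
})

test_that("day-2 adult reclassification follows the young-egg-chamber rule", {
  # FCs in the two youngest egg chambers imply a lost FSC: FSC count stays 0
  r1 <- reclassify_day2_adult(rec(1, r1 = 1, fc = "E1", age = "adult_day2"))
  expect_true(r1$fsc_inferred)
  expect_equal(r1$n_fsc, 0)
  expect_equal(as.character(clonecensus:::classify_records(r1)), "EC_FSC")
  # FCs only in mature chambers do not fire the rule
  r2 <- reclassify_day2_adult(rec(2, fc = "E4", age = "adult_day2"))
  expect_false(r2$fsc_inferred)
  expect_equal(as.character(clonecensus:::classify_records(r2)), "FC_only")
  # FSCs present: identity
  r3 <- reclassify_day2_adult(rec(3, r1 = 2, fsc = 3, age = "adult_day2"))
  expect_equal(r3$n_fsc, 3)
  expect_equal(as.character(clonecensus:::classify_records(r3)), "EC_FSC")
  # idempotent
  expect_identical(reclassify_day2_adult(r1), r1)
  # usage error on day-0 records
  expect_error(reclassify_day2_adult(rec(4, r1 = 1)), "adult day 2")
})

test_that("aggregation applies the shared EC+FC counting convention", {
  obs0 <- aggregate_frequencies(load_experiment("marcm_0h"))
  expect_near(obs0$f_ec, 0.63, 0.01)
  expect_near(obs0$f_fc, 0.25, 0.01)
  expect_near(obs0$f_fsc, 0.03, 0.01)
  obs36 <- aggregate_frequencies(load_experiment("marcm_36h"))
  expect_near(obs36$f_ec, 0.645, 0.001)
  expect_near(obs36$f_fc, 0.529, 0.001)
  # a table of only EC-only ovarioles
  records <- do.call(rbind, lapply(1:5, function(i) rec(i, r1 = 1)))
  obs <- aggregate_frequencies(ingest_records(records))
  expect_equal(c(obs$f_ec, obs$f_fc, obs$f_fsc, obs$f_ecfc), c(1, 0, 0, 0))
})

test_that("readers round-trip records and aggregated tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(marcm_0h_like_records(), path, row.names = FALSE)
  records <- read_ovariole_records(path)
  expect_equal(nrow(records), 207)
  expect_equal(ingest_records(records)$n_marked, 98)

  table <- load_experiment("marcm_0h")
  expect_s3_class(table, "clone_category_table")
  expect_equal(table$total_ec, 253)
  expect_equal(table$total_fsc, 111)
  expect_equal(table$categories$mean_fsc[table$categories$category == "FSC_only"],
               14 / 3, tolerance = 1e-6)
})

test_that("malformed inputs are rejected", {
  expect_error(ovariole_records(rec(1, r1 = -1)), "non-negative")
  expect_error(ovariole_records(rec(1, fc = "E9")), "unknown FC location")
  expect_error(ovariole_records(data.frame(ovariole_id = 1)), "missing record")
  empty <- ingest_records(rec(1))
  expect_error(aggregate_frequencies(empty), "no marked ovarioles")
  expect_error(clone_category_table(
    data.frame(category = c("a", "b", "c", "d", "e"),
               n = 1:5, mean_ec = NA, mean_fsc = NA), 15, 0),
    "one row per clone category")
  # basal-stalk imaging keeps its third state
  r <- ovariole_records(rec(1, fc = "E4", stalk = "not_imaged"))
  expect_equal(r$basal_stalk, "not_imaged")
})
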