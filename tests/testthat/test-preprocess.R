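# Preprocessing: MITS encoding, plurality rule, EAVA two-spike construction,
# imputation, site exclusion, grouping and raw CSMF aggregation.

test_that("encode_mits implements the {1, 0.5, 0} scheme", {
  x <- encode_mits("beta", "alpha", cl3)
  expect_equal(unname(x), c(0.5, 0.5, 0))
  expect_equal(unname(encode_mits("gamma", "gamma", cl3)), c(0, 0, 1))
  expect_equal(unname(encode_mits("gamma", NA, cl3)), c(0, 0, 1))
  expect_error(encode_mits("nope", NA, cl3), "unknown")
})

test_that("plurality rule picks the max, breaking ties to the lowest index", {
  expect_equal(plurality_rule(c(0.2, 0.2, 0.6)), 3)
  expect_equal(plurality_rule(c(0.5, 0.5, 0)), 1)
  expect_equal(plurality_rule(c(0, 1, 0)), 2)
})

test_that("eava_multicause builds the w / (1 - w) two-spike composition", {
  cl <- cause_list("children")
  y <- eava_multicause("pneumonia", "diarrhea", 0.75, cl)
  expect_equal(unname(y[c("pneumonia", "diarrhea")]), c(0.75, 0.25))
  expect_equal(sum(y), 1)
  y2 <- eava_multicause("malaria", "HIV", 0.6, cl)
  expect_equal(unname(y2[c("malaria", "HIV")]), c(0.6, 0.4))
  y3 <- eava_multicause("malaria", "HIV", 1, cl)
  expect_equal(unname(y3["malaria"]), 1)
  expect_error(eava_multicause("malaria", "malaria", 0.75, cl), "differ")
  expect_error(eava_multicause("malaria", "HIV", 0.5, cl), "0.5")
  # plurality of the two-spike output is the first cause for any w > 0.5
  for (w in c(0.51, 0.6, 0.75, 0.9, 1)) {
    yw <- eava_multicause("diarrhea", "malaria", w, cl)
    expect_equal(plurality_rule(yw), 3)  # diarrhea is cause 3
  }
})

test_that("survey imputation fills inconclusive records with the conclusive mean", {
  y <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(NA, NA, NA))
  sv <- survey_from_matrix(y, cl3, "eava")
  sv$eava_inconclusive <- c(FALSE, FALSE, TRUE)
  out <- impute_survey_inconclusive(sv, "eava", cl3)
  expect_equal(unname(va_matrix(out, "eava", cl3)[3, ]), c(0.75, 0.25, 0))
  # conclusive rows untouched, count preserved, flag retained
  expect_equal(va_matrix(out, "eava", cl3)[1:2, ], va_matrix(sv, "eava", cl3)[1:2, ])
  expect_equal(nrow(out), 3)
  expect_equal(out$eava_imputed, c(FALSE, FALSE, TRUE))

  # all conclusive -> identity; single conclusive record -> its own values
  expect_identical(impute_survey_inconclusive(sv[1:2, ], "eava", cl3),
                   sv[1:2, ])
  sv2 <- survey_from_matrix(rbind(c(0, 1, 0), c(NA, NA, NA)), cl3, "eava")
  sv2$eava_inconclusive <- c(FALSE, TRUE)
  expect_equal(unname(va_matrix(impute_survey_inconclusive(sv2, "eava", cl3),
                                "eava", cl3)[2, ]), c(0, 1, 0))
  sv3 <- sv2; sv3$eava_inconclusive <- c(TRUE, TRUE)
  expect_error(impute_survey_inconclusive(sv3, "eava", cl3), "no conclusive")
})

test_that("paired imputation uses the single-cause matrix row of the underlying cause", {
  x <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  y <- rbind(c(0.6, 0.3, 0.1), c(0.8, 0.1, 0.1), c(0, 1, 0), c(0, 0, 1),
             c(NA, NA, NA))
  pd <- paired_from_matrices(x, y, cl3, "eava")
  pd$eava_inconclusive <- c(rep(FALSE, 4), TRUE)
  out <- impute_paired_inconclusive(pd, "eava", cl3)
  # mean conclusive y among underlying == alpha records: (0.7, 0.2, 0.1)
  expect_equal(unname(va_matrix(out, "eava", cl3)[5, ]), c(0.7, 0.2, 0.1))
  expect_equal(out$eava_imputed, c(rep(FALSE, 4), TRUE))
  # no inconclusive records -> no-op
  expect_identical(impute_paired_inconclusive(out, "eava", cl3), out)
  # underlying cause with no conclusive data is an error naming the cause
  pd2 <- pd[3:5, ]
  pd2$eava_inconclusive <- c(FALSE, FALSE, TRUE)
  expect_error(impute_paired_inconclusive(pd2, "eava", cl3), "alpha")
})

test_that("site exclusion mirrors the neonate South-Africa adjustment", {
  # 614 records, 274 flagged -> 340 remain
  n <- 614
  pd <- tibble::tibble(id = as.character(seq_len(n)),
                       site = rep(c("South Africa", "other"), c(274, 340)))
  expect_message(out <- exclude_sites(pd, "South Africa"), "274")
  expect_equal(nrow(out), 340)
  expect_equal(nrow(exclude_sites(pd, character())), n)
  expect_equal(nrow(exclude_sites(pd, c("South Africa", "other"))), 0)
})

test_that("raw_csmf aggregates scores and normalizes by record count", {
  y <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.75, 0.25, 0))
  sv <- survey_from_matrix(y, cl3, "algo")
  out <- raw_csmf(sv, "algo", cl3)
  expect_equal(out$aggregate, c(2.25, 0.75, 0))
  expect_equal(out$csmf, c(0.75, 0.25, 0))
  expect_equal(sum(out$aggregate), nrow(sv))
  expect_equal(sum(out$csmf), 1)
  expect_error(raw_csmf(sv[0, ], "algo", cl3), "no records")
})

test_that("raw CSMF percentages recompute from the published aggregates", {
  # both columns are independently rounded to one decimal in print, so the
  # recomputed percentage can differ from the printed one by up to ~0.1
  for (tab in c("table1", "table2")) {
    t <- load_fixture(tab)
    n <- attr(t, "n")
    expect_true(all(abs(100 * t$score / n - t$pct) <= 0.1 + 1e-9))
  }
})

test_that("contingency tables expand to per-death records with correct encodings", {
  ne <- cause_list("neonates")
  t4 <- load_fixture("table4")
  pd <- contingency_to_paired(t4, ne)
  expect_equal(nrow(pd), 340)
  # cell (infection, prematurity) = 26 records at 0.5/0.5
  sel <- pd$underlying == "infection" & pd$immediate == "prematurity"
  expect_equal(sum(sel), 26)
  x <- mits_matrix(pd[sel, ], ne)
  expect_true(all(x[, "infection"] == 0.5 & x[, "prematurity"] == 0.5))
  # table 3: malaria underlying row covers 51 records
  t3 <- load_fixture("table3")
  pd3 <- contingency_to_paired(t3, cause_list("children"))
  expect_equal(sum(pd3$underlying == "malaria"), 51)
  expect_equal(nrow(pd3), 426)
  # encodings are valid x compositions
  x3 <- mits_matrix(pd3, cause_list("children"))
  expect_true(all(x3 %in% c(0, 0.5, 1)) && all(rowSums(x3) == 1))
})

test_that("cause grouping sums scores within groups and preserves mass", {
  fine <- c("malaria", "meningitis", "typhoid", "pneumonia")
  grouped <- cause_list("custom", c("malaria", "pneumonia", "other infections"),
                        grouping = c(malaria = "malaria",
                                     meningitis = "other infections",
                                     typhoid = "other infections",
                                     pneumonia = "pneumonia"))
  data <- tibble::tibble(
    id = "d1", underlying = "meningitis", immediate = "malaria",
    algo_malaria = 0.4, algo_meningitis = 0.3, algo_typhoid = 0.2,
    algo_pneumonia = 0.1)
  out <- group_causes(data, grouped, algorithms = "algo")
  expect_equal(out$algo_other_infections, 0.5)
  expect_equal(out$algo_malaria, 0.4)
  expect_equal(out$underlying, "other infections")
  expect_equal(out$immediate, "malaria")
  y <- va_matrix(out, "algo", grouped)
  expect_equal(sum(y), 1)
})
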