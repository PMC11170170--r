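test_that("P score sums the 2+ and 3+ percentages", {
  rec <- data.frame(sample_id = c("a", "b", "c"), patient_id = c("a", "b", "c"),
                    pct0 = c(0, 0, 70), pct1 = c(3, 100, 0),
                    pct2 = c(60, 0, 30), pct3 = c(37, 0, 0))
  expect_equal(p_score(rec), c(97, 0, 30))
})

test_that("P score is invariant to the 0 / 1+ split", {
  base <- make_staining(40)
  shifted <- base
  shifted$pct0 <- base$pct0 - 20
  shifted$pct1 <- base$pct1 + 20
  expect_equal(p_score(base), p_score(shifted))
})

test_that("staining validation rejects broken records", {
  bad_sum <- make_staining(50); bad_sum$pct0 <- bad_sum$pct0 + 5
  expect_error(p_score(bad_sum), "sum to 100")
  neg <- data.frame(sample_id = "s", patient_id = "p",
                    pct0 = 71, pct1 = -1, pct2 = 18, pct3 = 12)
  expect_error(p_score(neg), "non-negative")
  missing_col <- make_staining(50); missing_col$pct3 <- NULL
  expect_error(p_score(missing_col), "lack column")
  neg_arch <- make_staining(50, archival_years = -1)
  expect_error(validate_staining(neg_arch), "archival_years")
})

test_that("positivity boundary is inclusive at the cutoff", {
  rec <- make_staining(c(30, 29.5, 76))
  expect_equal(is_positive(rec), c(TRUE, FALSE, TRUE))
  # cutoff degenerate ends
  any2p <- make_staining(c(0.5, 0))
  expect_equal(is_positive(any2p, positivity_cutoff(min_pscore = 0)), c(TRUE, TRUE))
  expect_equal(sum(is_positive(make_staining(c(100, 50)),
                               positivity_cutoff(min_pscore = 100))), 1)
})

test_that("the legacy >=1+ 10% preset scores 1+ staining", {
  rec <- data.frame(sample_id = "s", patient_id = "p",
                    pct0 = 80, pct1 = 15, pct2 = 5, pct3 = 0)
  expect_false(is_positive(rec))                 # P score 5 < 30
  expect_true(is_positive(rec, legacy_cutoff())) # 20% at >=1+
})

test_that("positivity is monotone when mass moves up the intensity scale", {
  set.seed(3)
  for (i in 1:25) {
    p <- runif(1, 0, 80)
    rec <- make_staining(p)
    up <- rec
    shift <- min(rec$pct0, runif(1, 0, 30))
    up$pct0 <- rec$pct0 - shift
    up$pct2 <- rec$pct2 + shift
    if (is_positive(rec)) expect_true(is_positive(up))
  }
})

test_that("prevalence reproduces printed per-indication arithmetic", {
  rec <- rbind(make_prevalence_group(201, 140, "SyS", "S"),
               make_prevalence_group(70, 6, "gastric", "G"))
  tab <- prevalence_by(rec, "tumor_type")
  sys <- tab[tab$group == "SyS", ]
  gas <- tab[tab$group == "gastric", ]
  expect_equal(sys$positive, 140); expect_equal(sys$rate_pct, 70)
  expect_equal(gas$positive, 6); expect_equal(gas$rate_pct, 9)
  # all-negative group: rate 0, median over all its samples
  neg <- make_prevalence_group(10, 0, "melanoma", "M")
  tab2 <- prevalence_by(rbind(rec, neg), "tumor_type")
  expect_equal(tab2$rate_pct[tab2$group == "melanoma"], 0)
  expect_equal(tab2$median_pscore[tab2$group == "melanoma"], 0)
})

test_that("prevalence is conserved under group refinement", {
  rec <- make_prevalence_group(60, 25, "NSCLC", "N")
  rec$histology <- rep(c("AC", "SCC"), 30)
  whole <- prevalence_by(rec, "tumor_type")
  parts <- prevalence_by(rec, "histology")
  expect_equal(sum(parts$positive), whole$positive)
  expect_equal(sum(parts$n), whole$n)
})

test_that("multi-sample patients count once, any positive sample qualifying", {
  rec <- make_staining(c(0, 60, 10),
                       patient_id = c("P1", "P1", "P2"),
                       sample_id = c("P1-S1", "P1-S2", "P2-S1"))
  by_patient <- prevalence_by(rec, "tumor_type")
  expect_equal(by_patient$n, 2)
  expect_equal(by_patient$positive, 1)
  by_sample <- prevalence_by(rec, "tumor_type", unit = "sample")
  expect_equal(by_sample$n, 3)
  expect_equal(by_sample$positive, 1)
})

test_that("paired-location agreement matches hand-built fixtures", {
  # 16 dual-location patients, 13 agreeing by construction
  agree_pos <- make_staining(rep(c(60, 70), 8),
                             patient_id = rep(sprintf("D%02d", 1:8), each = 2),
                             sample_id = sprintf("A%02d", 1:16),
                             tissue_location = rep(c("primary", "metastatic"), 8))
  agree_neg <- make_staining(rep(c(5, 0), 5),
                             patient_id = rep(sprintf("E%02d", 1:5), each = 2),
                             sample_id = sprintf("B%02d", 1:10),
                             tissue_location = rep(c("primary", "metastatic"), 5))
  disagree <- make_staining(rep(c(80, 0), 3),
                            patient_id = rep(sprintf("F%02d", 1:3), each = 2),
                            sample_id = sprintf("C%02d", 1:6),
                            tissue_location = rep(c("primary", "metastatic"), 3))
  # plus a patient lacking a metastatic sample: excluded, reported
  lone <- make_staining(50, patient_id = "L1", sample_id = "L1-S1")
  res <- pairwise_location_agreement(rbind(agree_pos, agree_neg, disagree, lone))
  expect_equal(res$n_dual, 16)
  expect_equal(res$agreeing, 13)
  expect_equal(res$pct, 81)
  expect_equal(res$excluded, 1)

  both_pos <- make_staining(c(50, 55), patient_id = c("X", "X"),
                            sample_id = c("X1", "X2"),
                            tissue_location = c("primary", "metastatic"))
  expect_equal(pairwise_location_agreement(both_pos)$fraction, 1)

  split <- make_staining(c(50, 5), patient_id = c("Y", "Y"),
                         sample_id = c("Y1", "Y2"),
                         tissue_location = c("primary", "metastatic"))
  expect_equal(pairwise_location_agreement(split)$agreeing, 0)

  # per-location maximum decides when a location has several samples
  multi <- make_staining(c(0, 60, 55), patient_id = c("Z", "Z", "Z"),
                         sample_id = c("Z1", "Z2", "Z3"),
                         tissue_location = c("primary", "primary", "metastatic"))
  expect_equal(pairwise_location_agreement(multi)$agreeing, 1)
})

test_that("archival strata partition records into half-open bins", {
  rec <- make_staining(c(50, 50, 0, 0, 50),
                       archival_years = c(0, 0.99, 1.0, 4.9, 7))
  tab <- archival_strata(rec, breaks = c(0, 1, 5))
  expect_equal(tab$group, c("[0,1)", "[1,5)", "[5,Inf)"))
  expect_equal(sum(tab$n), nrow(rec))
  # boundary record at exactly 1.0 lands in the second bin
  expect_equal(tab$n[tab$group == "[1,5)"], 2)
  expect_error(archival_strata(rec, breaks = c(5, 1)), "strictly increasing")
})

test_that("archival prevalence is flat under a constant-positivity simulation", {
  cfg <- ihc_model_config(intercepts = c(SyS = 0), mix = c(SyS = 1))
  cohort <- data.frame(patient_id = sprintf("P%05d", 1:4000))
  rec <- simulate_ihc(cfg, cohort, seed = 99)
  tab <- archival_strata(rec, breaks = c(0, 1, 5))
  se <- sqrt(0.5 * 0.5 / tab$n)
  expect_true(all(abs(tab$rate - 0.5) < 3 * se))
})

test_that("reader concordance scores pairwise percent agreement", {
  calls <- rep(c(TRUE, FALSE), 5)
  same <- reader_concordance(list(r1 = calls, r2 = calls))
  expect_equal(same$pairs$agreement_pct, 100)
  at_floor <- reader_concordance(list(r1 = calls, r2 = c(calls[1:8], !calls[9:10])))
  expect_equal(at_floor$pairs$agreement_pct, 80)
  expect_false(at_floor$pairs$below_floor)  # >= 80 acceptance floor
  # three readers, hand-enumerated: r1/r2 agree 4/5, r1/r3 2/5, r2/r3 3/5
  r1 <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  r2 <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  r3 <- c(FALSE, TRUE, TRUE, FALSE, FALSE)
  three <- reader_concordance(list(r1 = r1, r2 = r2, r3 = r3))
  expect_equal(three$pairs$agreement_pct, c(80, 40, 60))
  expect_true(any(three$pairs$below_floor))
  expect_equal(three$overall_pct, mean(c(80, 40, 60)))
  expect_error(reader_concordance(list(r1 = r1, r2 = r2[1:3])), "mismatched")
  expect_error(reader_concordance(list(r1 = r1)), "two readers")
})
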