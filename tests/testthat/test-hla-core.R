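test_that("allele parsing handles canonical, deep and suffixed names", {
  a <- parse_allele("A*02:01")
  expect_equal(a$locus, "A")
  expect_equal(a$fields, c("02", "01"))
  expect_true(is.na(a$suffix))

  b <- parse_allele("A*02:135")
  expect_equal(b$fields, c("02", "135"))

  d <- parse_allele("A*02:01:01:02N")
  expect_equal(d$fields, c("02", "01", "01", "02"))
  expect_equal(d$suffix, "N")
  expect_equal(two_field(d), "A*02:01")

  expect_equal(format(parse_allele("HLA-A*02:01")), "A*02:01")
})

test_that("allele parsing round-trips through formatting", {
  fixtures <- c("A*02:01", "A*02:135", "A*02:01:01:02N", "A*68:01:02",
                "A*24:02:01:02L", "B*07:02", "A*02:05:01:01")
  for (s in fixtures) expect_equal(format(parse_allele(s)), s)
})

test_that("malformed allele strings name the offence", {
  expect_error(parse_allele("A*02"), "fewer than two fields")
  expect_error(parse_allele("A*02:01X"), "malformed")
  expect_error(parse_allele("02:01"), "malformed")
  expect_error(parse_allele("A*02:01:01:02:03"), "more than four")
  expect_error(parse_allele(""), "non-empty")
})

test_that("genotype-list parsing tracks candidates and ambiguity", {
  g1 <- parse_genotype("A*02:01+A*03:01")
  expect_length(g1$candidates, 1L)
  expect_false(g1$ambiguous)

  g2 <- parse_genotype("A*02:01+A*68:01|A*02:135+A*69:02")
  expect_length(g2$candidates, 2L)
  expect_true(g2$ambiguous)
  expect_equal(format(g2$candidates[[2L]][[1L]]), "A*02:135")

  g3 <- parse_genotype("A*02:01+A*02:01")
  expect_false(g3$ambiguous)
  expect_equal(format(g3$candidates[[1L]][[1L]]),
               format(g3$candidates[[1L]][[2L]]))

  expect_error(parse_genotype("A*02:01"), "exactly two alleles")
  expect_error(parse_genotype("A*02:01+A*03:01+A*11:01"), "exactly two")
  expect_error(parse_genotype("A*02:01+B*07:02"), "mixes loci")
  expect_error(parse_genotype(""), "empty")
})

test_that("P-group resolution maps members and falls back to singletons", {
  expect_equal(p_group(parse_allele("A*02:09"), PG), "02:01P")
  expect_equal(p_group(parse_allele("A*02:642"), PG), "02:01P")
  expect_equal(p_group(parse_allele("A*02:01:01:01"), PG), "02:01P")
  expect_equal(p_group(parse_allele("A*97:99"), PG), "97:99P")
  # two-field projection never changes the group for listed alleles
  for (s in c("A*02:01:01:01", "A*02:02:01:02", "A*02:05:01:01", "A*68:01:02")) {
    deep <- parse_allele(s)
    expect_equal(p_group(parse_allele(two_field(deep)), PG), p_group(deep, PG))
  }
})

test_that("the IMGT dialect reader skips comments and handles empty groups", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# comment line",
    "A*;02:01:01:01/02:09;02:01P",
    "A*;02:135;",
    "",
    "A*;99:01/99:02;99:01P"
  ), path)
  tbl <- read_pgroup_table(path)
  expect_equal(p_group(parse_allele("A*02:09"), tbl), "02:01P")
  expect_equal(p_group(parse_allele("A*02:135"), tbl), "02:135P")
  expect_equal(p_group(parse_allele("A*99:02"), tbl), "99:01P")
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("garbage-without-semicolons", p2)
  expect_error(read_pgroup_table(p2), "malformed")
})

test_that("candidate assessment follows the inclusion/no-exclusion rule", {
  expect_equal(assess_candidate(pair("A*02:01", "A*01:01"), RULES, PG), "eligible")
  expect_equal(assess_candidate(pair("A*02:01", "A*02:05"), RULES, PG), "ineligible")
  expect_equal(assess_candidate(pair("A*01:01", "A*03:01"), RULES, PG), "ineligible")
  # P-group members carry the same status as their group representative
  expect_equal(assess_candidate(pair("A*02:09", "A*01:01"), RULES, PG), "eligible")
})

test_that("exclusion dominates inclusion over a randomized allele pool", {
  pool <- c("A*02:01", "A*02:02", "A*02:03", "A*02:06", "A*02:09", "A*02:07",
            "A*01:01", "A*03:01", "A*24:02", "A*68:01", "A*11:01")
  set.seed(42)
  for (i in 1:50) {
    p <- pair(sample(pool, 1), sample(pool, 1))
    # replacing either allele with the exclusion allele never yields eligible
    expect_equal(assess_candidate(list(p[[1L]], parse_allele("A*02:05")), RULES, PG),
                 "ineligible")
    # adding an inclusion allele to an eligible pair never makes it ineligible
    if (assess_candidate(p, RULES, PG) == "eligible") {
      expect_equal(assess_candidate(list(p[[1L]], parse_allele("A*02:01")), RULES, PG),
                   "eligible")
    }
  }
})

test_that("null alleles confer neither inclusion nor exclusion by default", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A*;02:99N;02:01P", "A*;02:98N;02:05P",
               "A*;02:01:01:01;02:01P", "A*;01:01:01:01;01:01P"), path)
  tbl <- read_pgroup_table(path)
  null_inc <- pair("A*02:99N", "A*01:01")
  null_exc <- pair("A*02:01", "A*02:98N")
  expect_equal(assess_candidate(null_inc, default_rules(), tbl), "ineligible")
  expect_equal(assess_candidate(null_exc, default_rules(), tbl), "eligible")
  counted <- default_rules(count_null_alleles = TRUE)
  expect_equal(assess_candidate(null_inc, counted, tbl), "eligible")
  expect_equal(assess_candidate(null_exc, counted, tbl), "ineligible")
})

test_that("genotype assessment is unanimous-or-indeterminate", {
  # single candidate equals the candidate assessment
  pool <- c("A*02:01", "A*02:05", "A*01:01", "A*02:03", "A*24:02")
  set.seed(7)
  for (i in 1:20) {
    a <- sample(pool, 1); b <- sample(pool, 1)
    g <- parse_genotype(paste0(a, "+", b))
    expect_equal(assess_genotype(g, RULES, PG)$status,
                 assess_candidate(pair(a, b), RULES, PG))
  }
  # discordant candidates -> indeterminate, reason names them
  g <- parse_genotype("A*02:01+A*68:01|A*02:135+A*69:02")
  res <- assess_genotype(g, RULES, PG)
  expect_equal(res$status, "indeterminate")
  expect_match(res$reason, "02:135")
  expect_equal(res$contribution_category, "none")
  # all candidates ineligible -> ineligible
  g2 <- parse_genotype("A*01:01+A*03:01|A*11:01+A*24:02")
  expect_equal(assess_genotype(g2, RULES, PG)$status, "ineligible")
})

test_that("contribution categories follow the 02:01P-first rule", {
  expect_equal(contribution_category(pair("A*02:01", "A*02:06"), RULES, PG), "A0201P")
  expect_equal(contribution_category(pair("A*02:09", "A*01:01"), RULES, PG), "A0201P")
  expect_equal(contribution_category(pair("A*02:03", "A*02:06"), RULES, PG),
               "A0203_and_0206_exclusive")
  expect_equal(contribution_category(pair("A*02:02", "A*01:01"), RULES, PG),
               "A0202_exclusive")
  expect_equal(contribution_category(pair("A*02:03", "A*02:03"), RULES, PG),
               "A0203_exclusive")
  expect_equal(contribution_category(pair("A*02:06", "A*24:02"), RULES, PG),
               "A0206_exclusive")
  expect_equal(contribution_category(pair("A*02:02", "A*02:03"), RULES, PG),
               "other_mixed")
  expect_error(contribution_category(pair("A*01:01", "A*03:01"), RULES, PG),
               "eligible")
})

test_that("cohort summaries report rates and partition eligible counts", {
  # hand-enumerated 10-patient cohort, 3 eligible by construction
  cohort <- data.frame(
    patient_id = sprintf("P%02d", 1:10),
    genotype = c("A*02:01+A*01:01", "A*02:03+A*02:06", "A*02:09+A*02:09",
                 rep("A*01:01+A*03:01", 5), "A*02:01+A*02:05",
                 "A*02:01+A*68:01|A*02:135+A*69:02"),
    population = rep(c("g1", "g2"), 5),
    stringsAsFactors = FALSE
  )
  s <- summarize_eligibility(cohort, RULES, PG, group_keys = "population")
  overall <- s[s$group == "Overall", ]
  expect_equal(overall$screened, 10)
  expect_equal(overall$eligible, 3)
  expect_equal(overall$rate_pct, 30.0)
  expect_equal(overall$indeterminate, 1)
  # partition: category counts sum to the eligible count, per group and overall
  cat_cols <- c("A0201P", "A0202_exclusive", "A0203_exclusive",
                "A0206_exclusive", "A0203_and_0206_exclusive", "other_mixed")
  for (i in seq_len(nrow(s)))
    expect_equal(sum(unlist(s[i, cat_cols])), s$eligible[i])

  # single eligible patient -> 100%
  one <- summarize_eligibility(
    data.frame(patient_id = "P1", genotype = "A*02:01+A*01:01"), RULES, PG)
  expect_equal(one$rate_pct, 100)

  # missing demographics grouped as Not recorded
  cohort$population[1] <- NA
  s2 <- summarize_eligibility(cohort, RULES, PG, group_keys = "population")
  expect_true("Not recorded" %in% s2$group)

  expect_error(summarize_eligibility(cohort[0, ], RULES, PG), "non-empty")
})

test_that("exclusive non-02:01P share isolates the added inclusion alleles", {
  cohort <- data.frame(
    patient_id = sprintf("P%02d", 1:8),
    genotype = c(rep("A*02:01+A*01:01", 4), "A*02:02+A*01:01",
                 "A*02:03+A*02:06", "A*02:06+A*24:02", "A*01:01+A*03:01"),
    stringsAsFactors = FALSE
  )
  s <- summarize_eligibility(cohort, RULES, PG)
  expect_equal(s$eligible, 7)
  expect_equal(s$exclusive_non0201_share, 3 / 7)
})
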