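dflags <- function(co, reach = "descending_visualized") {
  fscreen:::.participant_flags(co, reach)
}

one_lesion_cohort <- function(site, histology, size = NA, hgd = FALSE,
                              sex = "male", age = 60L) {
  fs_cohort(tibble::tibble(id = "q", sex = sex, age_years = age),
            lesion_row("q", site, histology, size, hgd))
}

test_that("the built-in list covers the twelve published rules", {
  s <- builtin_strategies()
  expect_length(s, 12)
  expect_equal(names(s)[1], "no_referral")
  expect_setequal(names(s), c(
    "no_referral", "uk", "score", "norccap", "plco", "ge2_neoplasms_ge1_an",
    "ge2_neoplasms", "histology_an", "an_ge_10mm", "any_an", "any_neoplasm",
    "any_neoplasm_or_hpp"))
  # baseline never refers, even facing distal CRC
  co <- one_lesion_cohort("sigmoid", "crc", 30)
  expect_false(decide_referral(s$no_referral, co))
})

test_that("PLCO score components match the published mapping", {
  sc <- plco_score(62, "male", lesion_row("q", "sigmoid", "adenoma_tubular",
                                          6))
  expect_equal(sc$total, 5)  # 2 + 1 + 2
  expect_true(sc$refer)
  sc <- plco_score(57, "female", NULL)
  expect_equal(sc$total, 1)  # 1 + 0 + 0
  expect_false(sc$refer)
  sc <- plco_score(55, "female", lesion_row("q", "rectum", "hyperplastic",
                                            3))
  expect_equal(sc$total, 2)  # 1 + 0 + 1
  expect_false(sc$refer)
  # ages above the published bands keep the maximal 3 points
  expect_equal(plco_score(74, "female", NULL)$age_points, 3L)
  expect_error(plco_score(45, "male", NULL), "not defined below age 50")
})

test_that("referral decisions reproduce the published rule wordings", {
  s <- builtin_strategies()
  aa12 <- one_lesion_cohort("sigmoid", "adenoma_tubular", 12)
  expect_true(decide_referral(s$an_ge_10mm, aa12))   # large adenoma
  expect_false(decide_referral(s$ge2_neoplasms, aa12))  # only one lesion
  expect_true(decide_referral(s$any_an, aa12))

  hpp2 <- one_lesion_cohort("sigmoid", "hyperplastic", 2)
  expect_true(decide_referral(s$any_neoplasm_or_hpp, hpp2))
  expect_false(decide_referral(s$any_neoplasm, hpp2))

  tv4 <- one_lesion_cohort("rectum", "adenoma_tubulovillous", 4)
  expect_true(decide_referral(s$histology_an, tv4))   # villous components
  expect_false(decide_referral(s$an_ge_10mm, tv4))    # but small

  # NORCCAP refers any adenoma; SCORE needs > 5 mm for plain polyps
  tiny_adenoma <- one_lesion_cohort("rectum", "adenoma_tubular", 3)
  expect_true(decide_referral(s$norccap, tiny_adenoma))
  expect_false(decide_referral(s$score, tiny_adenoma))
  expect_true(decide_referral(
    s$score, one_lesion_cohort("rectum", "hyperplastic", 6)))
  expect_false(decide_referral(
    s$score, one_lesion_cohort("rectum", "hyperplastic", 5)))

  # two small adenomas: >= 2 neoplasms refers, the AN-requiring variant not
  two_small <- fs_cohort(
    tibble::tibble(id = "q", sex = "male", age_years = 60L),
    dplyr::bind_rows(lesion_row("q", "rectum", "adenoma_tubular", 4),
                     lesion_row("q", "sigmoid", "adenoma_tubular", 5)))
  expect_true(decide_referral(s$ge2_neoplasms, two_small))
  expect_false(decide_referral(s$ge2_neoplasms_ge1_an, two_small))

  # CRC alone satisfies both count-based rules
  crc <- one_lesion_cohort("rectum", "crc", 25)
  expect_true(decide_referral(s$ge2_neoplasms_ge1_an, crc))
  expect_true(decide_referral(s$ge2_neoplasms, crc))
})

test_that("the UK hyperplastic-polyposis clause counts distal non-rectal polyps", {
  s <- builtin_strategies()
  mk <- function(n_sigmoid, n_rectum = 0) {
    les <- dplyr::bind_rows(
      if (n_sigmoid > 0) dplyr::bind_rows(lapply(seq_len(n_sigmoid), function(i)
        lesion_row("q", "sigmoid", "hyperplastic", 3))),
      if (n_rectum > 0) dplyr::bind_rows(lapply(seq_len(n_rectum), function(i)
        lesion_row("q", "rectum", "hyperplastic", 3))))
    fs_cohort(tibble::tibble(id = "q", sex = "male", age_years = 60L), les)
  }
  expect_true(decide_referral(s$uk, mk(20)))
  expect_false(decide_referral(s$uk, mk(19)))
  expect_false(decide_referral(s$uk, mk(0, 25)))  # rectal polyps do not count
})

test_that("UK size clause strictness is configurable", {
  ten <- one_lesion_cohort("rectum", "hyperplastic", 10)
  expect_true(decide_referral(builtin_strategies()$uk, ten))
  expect_false(decide_referral(
    builtin_strategies(uk_size_strict = TRUE)$uk, ten))
})

test_that("strategy nesting holds on random synthetic cohorts", {
  chains <- list(
    c("ge2_neoplasms_ge1_an", "ge2_neoplasms"),
    c("histology_an", "any_an", "any_neoplasm", "any_neoplasm_or_hpp"),
    c("an_ge_10mm", "any_an"))
  s <- builtin_strategies()
  for (seed in c(3, 14, 15)) {
    co <- generate_cohort(seed = seed, n = 3000)
    flags <- dflags(co)
    dec <- lapply(s, function(x) decide_referral(x, flags))
    for (ch in chains) {
      for (i in seq_len(length(ch) - 1)) {
        expect_true(all(dec[[ch[i + 1]]] | !dec[[ch[i]]]),
                    info = paste(ch[i], "subset of", ch[i + 1], "seed", seed))
      }
    }
  }
})

test_that("decisions are blind to proximal lesions and to lesion order", {
  set.seed(101)
  co <- generate_cohort(seed = 5, n = 2000)
  flags <- dflags(co)
  distal <- is_distal(co$lesions$site, "descending_visualized")
  # strip all proximal lesions
  co_stripped <- fs_cohort(co$participants, co$lesions[distal, ])
  # shuffle lesion order
  co_shuffled <- fs_cohort(co$participants,
                           co$lesions[sample.int(nrow(co$lesions)), ])
  f_str <- dflags(co_stripped)
  f_shuf <- dflags(co_shuffled)
  for (st in builtin_strategies()) {
    base <- decide_referral(st, flags)
    expect_equal(decide_referral(st, f_str), base, info = st$id)
    expect_equal(decide_referral(st, f_shuf), base, info = st$id)
  }
})

test_that("PLCO always refers distal CRC at screening ages", {
  s <- builtin_strategies()$plco
  for (sex in c("male", "female")) {
    for (age in c(55L, 64L, 79L)) {
      co <- one_lesion_cohort("rectum", "crc", 20, sex = sex, age = age)
      expect_true(decide_referral(s, co), info = paste(sex, age))
    }
  }
})

test_that("custom strategies can be written as formulas over the distal summary", {
  st <- fs_strategy("big_or_many", "Adenoma >= 15 mm or >= 4 adenomas",
                    ~ (!is.na(max_adenoma_size) & max_adenoma_size >= 15) |
                      n_adenoma >= 4)
  expect_true(decide_referral(st, one_lesion_cohort("rectum",
                                                    "adenoma_tubular", 18)))
  expect_false(decide_referral(st, one_lesion_cohort("rectum",
                                                     "adenoma_tubular", 12)))
})
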