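test_that("rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -2.5)),
               c(1, 2, 3, -1, -3))
  expect_equal(round_half_up(c(8.16, 8.14, 11.75), 1), c(8.2, 8.1, 11.8))
  expect_equal(round_half_up(84.5), 85)
})

test_that("Clopper-Pearson intervals match the exact binomial test", {
  for (n in c(1L, 10L, 37L, 140L)) {
    for (x in unique(c(0L, 1L, n %/% 2, n))) {
      for (conf in c(0.9, 0.95)) {
        got <- clopper_pearson(x, n, conf)
        want <- stats::binom.test(x, n, conf.level = conf)$conf.int
        expect_equal(got$ci_low, want[1], tolerance = 1e-12,
                     info = paste(x, n, conf))
        expect_equal(got$ci_high, want[2], tolerance = 1e-12,
                     info = paste(x, n, conf))
      }
    }
  }
})

test_that("Clopper-Pearson boundaries take their closed forms", {
  expect_equal(clopper_pearson(0, 10)$ci_low, 0)
  up <- clopper_pearson(10, 10)
  expect_equal(up$ci_high, 1)
  expect_equal(up$ci_low, 0.025^(1 / 10), tolerance = 1e-12)
  # zero denominator propagates missing, no error
  z <- clopper_pearson(0, 0)
  expect_true(is.na(z$proportion) && is.na(z$ci_low))
})

test_that("interval coverage is conservative across the parameter grid", {
  # exact coverage by enumeration over the binomial support (the limit of
  # infinitely many simulated draws) must be >= nominal at every grid point
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(20L, 100L)) {
      ci <- clopper_pearson(0:n, n)
      covered <- ci$ci_low <= p & p <= ci$ci_high
      expect_gte(sum(stats::dbinom(0:n, n, p)[covered]), 0.95)
    }
  }
})

test_that("NCN and incremental NCN follow their ratio definitions", {
  expect_equal(round_half_up(ncn(547, 67), 1), 8.2)
  expect_equal(round_half_up(ncn(1874, 74), 1), 25.3)
  expect_true(is.na(ncn(0, 0)))
  expect_equal(round_half_up(incremental_ncn(1276, 129, 547, 67), 1), 11.8)
  expect_equal(round_half_up(incremental_ncn(3127, 212, 547, 67), 1), 17.8)
  expect_true(is.na(incremental_ncn(547, 67, 547, 67)))  # zero increment
})

test_that("NPV counts non-referred participants without the proximal finding", {
  referred <- c(rep(FALSE, 10), rep(TRUE, 5))
  prox <- c(rep(FALSE, 9), TRUE, rep(TRUE, 5))
  expect_equal(npv(referred, prox)$proportion, 0.9)
  expect_true(is.na(npv(rep(TRUE, 4), rep(FALSE, 4))$proportion))
  expect_equal(npv(rep(FALSE, 8), rep(FALSE, 8))$proportion, 1)
})

test_that("adherence-adjusted gain is linear in adherence", {
  expect_equal(adherence_adjusted_gain(68, 92, 0.75), 18)
  expect_equal(adherence_adjusted_gain(60, 80, 1), 20)
  expect_equal(adherence_adjusted_gain(70, 70, 0.3), 0)
})

test_that("evaluation of the toy cohort matches hand-derived outcomes", {
  mt <- evaluate_strategies(
    toy_cohort(),
    strategies = c("no_referral", "ge2_neoplasms_ge1_an", "ge2_neoplasms",
                   "any_an"))
  b <- mt$burden
  g <- function(st, str) b[b$strategy == st & b$stratum == str, ]
  # any AN: men p1 (distal CRC) and p2 (distal AA) referred; p3's AA is
  # proximal and invisible
  expect_equal(g("any_an", "men")$n_referred, 2L)
  expect_equal(g("any_an", "men")$prox_an_total, 2L)      # p1, p3
  expect_equal(g("any_an", "men")$prox_an_detected, 1)    # p1 only
  expect_equal(g("any_an", "men")$ncn, 2)
  expect_equal(g("any_an", "women")$n_referred, 0L)
  # >= 2 neoplasms: p6 (two distal small adenomas) now also referred
  expect_equal(g("ge2_neoplasms", "women")$n_referred, 1L)
  expect_equal(g("ge2_neoplasms", "men")$n_referred, 1L)  # p1 via CRC
  # no referral detects nothing proximal
  expect_equal(g("no_referral", "both")$prox_an_detected, 0)
  expect_true(is.na(g("no_referral", "both")$ncn))

  s <- mt$sensitivity
  gs <- function(st, str, e) s[s$strategy == st & s$stratum == str &
                                 s$endpoint == e, ]
  expect_equal(gs("any_an", "men", "crc")$n_detected, 1)
  expect_equal(gs("any_an", "men", "crc")$n_total, 1L)
  expect_equal(gs("any_an", "men", "aa")$n_total, 2L)     # p2, p3 (not p1)
  expect_equal(gs("any_an", "men", "aa")$n_detected, 1)
  expect_equal(gs("any_an", "men", "any_an")$n_detected, 2)
  expect_equal(gs("any_an", "men", "any_an")$n_total, 3L)
  # NPV: among men only p3 is not referred, and he has a proximal AA
  expect_equal(gs("any_an", "men", "any_an")$npv, 0)
  expect_equal(gs("any_an", "men", "crc")$npv, 1)
  expect_equal(gs("any_an", "both", "any_an")$npv, 0.75)
  expect_equal(gs("any_an", "women", "any_an")$npv, 1)
})

test_that("sex strata add up to the combined stratum at full adherence", {
  co <- generate_cohort(seed = 21, n = 4000)
  mt <- evaluate_strategies(co)
  b <- mt$burden
  s <- mt$sensitivity
  for (st in unique(b$strategy)) {
    men <- b[b$strategy == st & b$stratum == "men", ]
    women <- b[b$strategy == st & b$stratum == "women", ]
    both <- b[b$strategy == st & b$stratum == "both", ]
    expect_equal(men$n_referred + women$n_referred, both$n_referred)
    expect_equal(men$prox_an_detected + women$prox_an_detected,
                 both$prox_an_detected)
    for (e in c("crc", "aa", "any_an")) {
      rows <- s[s$strategy == st & s$endpoint == e, ]
      expect_equal(sum(rows$n_detected[rows$stratum != "both"]),
                   rows$n_detected[rows$stratum == "both"])
      expect_equal(sum(rows$n_total[rows$stratum != "both"]),
                   rows$n_total[rows$stratum == "both"])
    }
  }
})

test_that("aggregated metrics equal re-aggregation of per-participant outcomes", {
  co <- generate_cohort(seed = 33, n = 3000)
  strategies <- builtin_strategies()
  mt <- evaluate_strategies(co)
  for (id in c("uk", "plco", "any_neoplasm")) {
    out <- screening_outcomes(co, strategies[[id]])
    for (str in c("men", "women", "both")) {
      g <- if (str == "both") rep(TRUE, nrow(out)) else
        out$sex == c(men = "male", women = "female")[[str]]
      b <- mt$burden[mt$burden$strategy == id & mt$burden$stratum == str, ]
      expect_equal(b$n_referred, sum(out$referred[g]))
      expect_equal(b$prox_an_detected, sum(out$prox_an_detected[g]))
      s <- mt$sensitivity[mt$sensitivity$strategy == id &
                            mt$sensitivity$stratum == str, ]
      expect_equal(s$n_detected[s$endpoint == "any_an"], sum(out$det_an[g]))
      expect_equal(s$n_total[s$endpoint == "aa"], sum(out$has_aa[g]))
    }
  }
})

test_that("partial adherence scales the expected referral-dependent yield linearly", {
  co <- generate_cohort(seed = 55, n = 5000)
  full <- evaluate_strategies(co, strategies = c("ge2_neoplasms_ge1_an",
                                                 "any_an"))
  half <- evaluate_strategies(co, strategies = c("ge2_neoplasms_ge1_an",
                                                 "any_an"),
                              adherence = 0.5, seed = 1, n_reps = 50)
  fb <- full$burden[full$burden$strategy == "any_an" &
                      full$burden$stratum == "both", ]
  hb <- half$burden[half$burden$strategy == "any_an" &
                      half$burden$stratum == "both", ]
  expect_equal(hb$n_colonoscopies, 0.5 * fb$n_colonoscopies)
  expect_equal(hb$prox_an_detected, 0.5 * fb$prox_an_detected)
  # expected detections interpolate linearly between no attendance and full
  none <- evaluate_strategies(co, strategies = c("ge2_neoplasms_ge1_an",
                                                 "any_an"),
                              adherence = 0, n_reps = 0)
  fs_ <- full$sensitivity; hs <- half$sensitivity; ns <- none$sensitivity
  for (e in c("crc", "aa", "any_an")) {
    pick <- function(tab) tab$n_detected[tab$strategy == "any_an" &
                                           tab$stratum == "both" &
                                           tab$endpoint == e]
    expect_equal(pick(hs), (pick(fs_) + pick(ns)) / 2, tolerance = 1e-9)
  }
  # Monte-Carlo means track the closed form
  expect_lt(abs(hb$mc_colonoscopies - hb$n_colonoscopies),
            0.05 * max(hb$n_colonoscopies, 1))
  expect_lt(abs(hb$mc_prox_an_detected - hb$prox_an_detected),
            0.15 * max(hb$prox_an_detected, 1))
  # stochastic draws are reproducible under the same seed
  half2 <- evaluate_strategies(co, strategies = c("ge2_neoplasms_ge1_an",
                                                  "any_an"),
                               adherence = 0.5, seed = 1, n_reps = 50)
  expect_equal(half2$burden$mc_colonoscopies, half$burden$mc_colonoscopies)
})

test_that("counts-only evaluation reproduces participant-level evaluation", {
  co <- generate_cohort(seed = 77, n = 4000)
  mt <- evaluate_strategies(co)
  # rebuild the aggregate counts table from the participant-level run
  b <- mt$burden; s <- mt$sensitivity
  wide <- function(e, col) {
    v <- s[s$endpoint == e, c("strategy", "stratum", col)]
    names(v)[3] <- paste0(sub("any_an", "an", e), "_", sub("n_", "", col))
    v
  }
  counts <- Reduce(function(a, bb) dplyr::left_join(a, bb,
                                                    by = c("strategy",
                                                           "stratum")),
                   c(list(b[, c("strategy", "stratum", "n", "prox_an_total",
                                "n_colonoscopies", "prox_an_detected")]),
                     lapply(c("crc", "aa", "any_an"), wide, "n_detected"),
                     lapply(c("crc", "aa", "any_an"), wide, "n_total")))
  names(counts)[names(counts) == "n_colonoscopies"] <- "colonoscopies"
  mt2 <- evaluate_counts(counts)
  expect_equal(mt2$burden$ncn, b$ncn)
  expect_equal(mt2$burden$delta_ncn, b$delta_ncn)
  s2 <- mt2$sensitivity
  expect_equal(s2$sensitivity, s$sensitivity)
  expect_equal(s2$ci_low, s$ci_low)
  # NPV from aggregate counts agrees for the any-AN endpoint
  expect_equal(s2$npv[s2$endpoint == "any_an"],
               s$npv[s$endpoint == "any_an"])
})
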