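# Synthetic screening cohort ---------------------------------------------------
#
# A seeded stand-in for an undeposited screening-colonoscopy cohort. The
# calibration targets (sex ratio, age bands, per-sex prevalence of the most
# advanced finding, distal shares of CRC/AA, proximal-AN carrier rates) come
# from published marginals of the KolosSal screening population; multiplicity
# and size/histology mixes within each class are not published and are
# invented, documented synthetic shapes.

#' Default synthetic-cohort parameters
#'
#' Returns the calibrated parameter set of the generator. Probabilities are
#' exact count ratios from the published cohort tables: 49.0% male; per-sex
#' age-band shares over 55-59/60-64/65-69/70-74/75-79; per-sex probabilities
#' of the most advanced finding (CRC, advanced adenoma, non-advanced adenoma,
#' hyperplastic polyp, other polyp, none); distal shares of 118/140 (men) and
#' 51/73 (women) for CRC and 646/971 / 345/544 for AA under the
#' descending-colon reach; and the rate at which distal-CRC carriers harbour
#' a synchronous proximal AA (12/118 men, 1/51 women), which closes the
#' proximal-AN carrier accounting at 359/7323 men and 222/7624 women.
#'
#' Shape parameters without a published counterpart (synchronous lesion
#' multiplicities, within-class size mixes, distal site weights) are invented
#' and documented in the methods vignette; `prox_an_association` is an odds
#' multiplier on the synchronous proximal-AA rate (default 1 = calibrated
#' value).
#'
#' @param n Number of participants to generate (default: the published
#'   cohort size, 14,947).
#' @return A list of class `fs_cohort_params`; validated so that every
#'   probability vector sums to one.
#' @export
default_cohort_params <- function(n = 14947) {
  p <- list(
    n = n,
    male_fraction = 0.490,
    age_band_breaks = c(55, 60, 65, 70, 75, 80),  # [55,60), ..., [75,80)
    age_band_probs = list(
      male = c(2680, 1608, 1527, 1045, 463) / 7323,
      female = c(2992, 1655, 1522, 1032, 423) / 7624
    ),
    finding_probs = list(
      male = c(crc = 140, advanced_adenoma = 985, nonadvanced_adenoma = 1721,
               hyperplastic_polyp = 796, other_polyp = 192,
               none = 3489) / 7323,
      female = c(crc = 73, advanced_adenoma = 554, nonadvanced_adenoma = 1267,
                 hyperplastic_polyp = 772, other_polyp = 170,
                 none = 4788) / 7624
    ),
    distal_crc = c(male = 118 / 140, female = 51 / 73),
    distal_aa = c(male = 646 / 971, female = 345 / 544),
    prox_aa_given_distal_crc = c(male = 12 / 118, female = 1 / 51),
    prox_an_association = 1,
    # --- invented synthetic shapes (no published counterpart) ---
    aa_second_lesion_prob = 0.15,
    aa_large_prob = 0.6,     # AA advanced via size >= 10 mm
    aa_hgd_prob = 0.15,
    nonadv_count_probs = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
    hpp_count_support = c(1, 2, 3, 4, 5, 22),
    hpp_count_probs = c(0.55, 0.25, 0.12, 0.05, 0.028, 0.002),
    sync_nonadv_rate = 0.25, # Poisson mean, CRC/AA carriers
    sync_hpp_rate = 0.15,    # Poisson mean, adenoma-or-worse carriers
    lesser_distal_prob = 0.6,
    distal_site_probs = c(rectum = 0.35, sigmoid = 0.45, descending = 0.20),
    proximal_site_probs = c(splenic_flexure = 0.08, transverse = 0.27,
                            hepatic_flexure = 0.10, ascending = 0.33,
                            cecum = 0.22)
  )
  class(p) <- "fs_cohort_params"
  validate_cohort_params(p)
  p
}

#' @rdname default_cohort_params
#' @param params Parameter list to validate.
#' @export
validate_cohort_params <- function(params) {
  stopifnot(inherits(params, "fs_cohort_params"))
  chk1 <- function(v, what) {
    if (abs(sum(v) - 1) > 1e-9) {
      stop(what, " probabilities do not sum to 1", call. = FALSE)
    }
    if (any(v < 0 | v > 1)) stop(what, " probabilities outside [0,1]",
                                 call. = FALSE)
  }
  for (sx in c("male", "female")) {
    chk1(params$age_band_probs[[sx]], paste(sx, "age band"))
    chk1(params$finding_probs[[sx]], paste(sx, "finding"))
  }
  chk1(params$nonadv_count_probs, "nonadvanced multiplicity")
  chk1(params$hpp_count_probs, "hyperplastic multiplicity")
  chk1(params$distal_site_probs, "distal site")
  chk1(params$proximal_site_probs, "proximal site")
  frac <- c(params$male_fraction, params$distal_crc, params$distal_aa,
            params$prox_aa_given_distal_crc, params$aa_second_lesion_prob,
            params$aa_large_prob, params$aa_hgd_prob,
            params$lesser_distal_prob)
  if (any(frac < 0 | frac > 1)) stop("fraction outside [0,1]", call. = FALSE)
  if (params$n < 1) stop("n_participants must be positive", call. = FALSE)
  invisible(params)
}

# odds-multiplier helper for the proximal association knob
.apply_odds <- function(p, mult) {
  o <- p / (1 - p) * mult
  o / (1 + o)
}

#' Generate a synthetic screening cohort
#'
#' Samples, per participant: sex, an age band and a uniform integer age
#' within it, and the most advanced finding category. The index lesion(s) of
#' that category are placed distal or proximal so that the *share of carriers
#' with all index-class lesions distal* equals the calibrated per-sex distal
#' fraction; distal-CRC carriers additionally receive a synchronous proximal
#' advanced adenoma at the calibrated rate, reproducing the published
#' proximal-AN carrier accounting. Synchronous lesions of strictly lower
#' class (non-advanced adenomas, hyperplastic polyps) are added with small
#' invented multiplicities; hyperplastic-polyp carriers occasionally carry a
#' distal hyperplastic-polyposis pattern (>= 20 sigmoid polyps) so that the
#' UK trial's polyposis clause is exercisable. Every generated advanced
#' adenoma carries at least one advanced feature by construction.
#'
#' @param params An `fs_cohort_params`, see [default_cohort_params()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param n Override `params$n`.
#' @return An [fs_cohort()] with the seed recorded in `provenance`.
#' @export
generate_cohort <- function(params = default_cohort_params(), seed = NULL,
                            n = params$n) {
  validate_cohort_params(params)
  if (n < 1) stop("n_participants must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  sex <- ifelse(runif(n) < params$male_fraction, "male", "female")
  age <- integer(n)
  cat_lv <- names(params$finding_probs$male)
  category <- character(n)
  brk <- params$age_band_breaks
  for (sx in c("male", "female")) {
    i <- which(sex == sx)
    band <- sample.int(length(params$age_band_probs[[sx]]), length(i),
                       replace = TRUE, prob = params$age_band_probs[[sx]])
    age[i] <- brk[band] + floor(runif(length(i)) * (brk[band + 1] - brk[band]))
    category[i] <- sample(cat_lv, length(i), replace = TRUE,
                          prob = params$finding_probs[[sx]])
  }
  ids <- sprintf("S%07d", seq_len(n))

  dsite <- function(k) sample(names(params$distal_site_probs), k,
                              replace = TRUE, prob = params$distal_site_probs)
  psite <- function(k) sample(names(params$proximal_site_probs), k,
                              replace = TRUE,
                              prob = params$proximal_site_probs)
  site_for <- function(distal) {  # elementwise placement -> site token
    out <- character(length(distal))
    out[distal] <- dsite(sum(distal))
    out[!distal] <- psite(sum(!distal))
    out
  }
  les <- list()
  add <- function(pid, distal, size, histology, hgd) {
    les[[length(les) + 1]] <<- data.table::data.table(
      participant_id = pid, site = site_for(distal),
      size_mm = as.integer(size), histology = histology, hgd = hgd)
  }
  # AA feature sampler: guarantees >= 1 advanced feature per lesion
  aa_lesion <- function(k) {
    large <- runif(k) < params$aa_large_prob
    size <- integer(k)
    size[large] <- sample(10:25, sum(large), replace = TRUE)
    size[!large] <- sample(4:9, sum(!large), replace = TRUE)
    hist <- character(k)
    hist[large] <- sample(c("adenoma_tubular", "adenoma_tubulovillous"),
                          sum(large), replace = TRUE, prob = c(0.7, 0.3))
    hist[!large] <- sample(c("adenoma_tubulovillous", "adenoma_villous"),
                           sum(!large), replace = TRUE, prob = c(0.6, 0.4))
    list(size = size, histology = hist,
         hgd = runif(k) < params$aa_hgd_prob)
  }

  # --- CRC carriers ---
  i_crc <- which(category == "crc")
  if (length(i_crc)) {
    f <- params$distal_crc[sex[i_crc]]
    d <- runif(length(i_crc)) < f
    add(ids[i_crc], d, sample(15:60, length(i_crc), replace = TRUE),
        rep("crc", length(i_crc)), rep(FALSE, length(i_crc)))
    # synchronous proximal AA among distal-CRC carriers
    p_mix <- .apply_odds(params$prox_aa_given_distal_crc[sex[i_crc]],
                         params$prox_an_association)
    mix <- d & (runif(length(i_crc)) < p_mix)
    if (any(mix)) {
      ft <- aa_lesion(sum(mix))
      add(ids[i_crc][mix], rep(FALSE, sum(mix)), ft$size, ft$histology,
          ft$hgd)
    }
  }
  # --- AA carriers ---
  i_aa <- which(category == "advanced_adenoma")
  if (length(i_aa)) {
    k <- length(i_aa)
    all_distal <- runif(k) < params$distal_aa[sex[i_aa]]
    two <- runif(k) < params$aa_second_lesion_prob
    ft <- aa_lesion(k)
    # first index lesion: distal iff the all-distal coin came up
    add(ids[i_aa], all_distal, ft$size, ft$histology, ft$hgd)
    if (any(two)) {
      ft2 <- aa_lesion(sum(two))
      # second lesion distal when all-distal, else 50/50
      d2 <- ifelse(all_distal[two], TRUE, runif(sum(two)) < 0.5)
      add(ids[i_aa][two], d2, ft2$size, ft2$histology, ft2$hgd)
    }
  }
  # --- non-advanced adenoma carriers ---
  i_na <- which(category == "nonadvanced_adenoma")
  if (length(i_na)) {
    cnt <- sample(as.integer(names(params$nonadv_count_probs)),
                  length(i_na), replace = TRUE,
                  prob = params$nonadv_count_probs)
    pid <- rep(ids[i_na], cnt)
    m <- length(pid)
    add(pid, runif(m) < params$lesser_distal_prob,
        sample(2:9, m, replace = TRUE), rep("adenoma_tubular", m),
        rep(FALSE, m))
  }
  # --- hyperplastic polyp carriers ---
  i_hp <- which(category == "hyperplastic_polyp")
  if (length(i_hp)) {
    cnt <- sample(params$hpp_count_support, length(i_hp), replace = TRUE,
                  prob = params$hpp_count_probs)
    polyposis <- cnt >= 20
    pid <- rep(ids[i_hp], cnt)
    m <- length(pid)
    d <- runif(m) < params$lesser_distal_prob
    site <- site_for(d)
    # distal hyperplastic-polyposis phenotype: all polyps sigmoid
    pp <- rep(polyposis, cnt)
    site[pp] <- "sigmoid"
    les[[length(les) + 1]] <- data.table::data.table(
      participant_id = pid, site = site,
      size_mm = as.integer(sample(1:8, m, replace = TRUE)),
      histology = "hyperplastic", hgd = FALSE)
  }
  # --- other polyp carriers ---
  i_ot <- which(category == "other_polyp")
  if (length(i_ot)) {
    m <- length(i_ot)
    add(ids[i_ot], runif(m) < params$lesser_distal_prob,
        sample(2:6, m, replace = TRUE), rep("other_polyp", m),
        rep(FALSE, m))
  }
  # --- synchronous lesser lesions (never change the most advanced class) ---
  i_anc <- c(i_crc, i_aa)  # AN carriers may carry non-advanced adenomas
  if (length(i_anc)) {
    extra <- pmin(rpois(length(i_anc), params$sync_nonadv_rate), 3L)
    pid <- rep(ids[i_anc], extra)
    m <- length(pid)
    if (m) add(pid, runif(m) < params$lesser_distal_prob,
               sample(2:9, m, replace = TRUE), rep("adenoma_tubular", m),
               rep(FALSE, m))
  }
  i_adc <- c(i_crc, i_aa, i_na)  # adenoma-or-worse carriers may carry HPPs
  if (length(i_adc)) {
    extra <- pmin(rpois(length(i_adc), params$sync_hpp_rate), 3L)
    pid <- rep(ids[i_adc], extra)
    m <- length(pid)
    if (m) add(pid, runif(m) < params$lesser_distal_prob,
               sample(1:8, m, replace = TRUE), rep("hyperplastic", m),
               rep(FALSE, m))
  }

  lesions <- if (length(les)) {
    as_tibble(data.table::rbindlist(les))
  } else {
    tibble(participant_id = character(), site = character(),
           size_mm = integer(), histology = character(), hgd = logical())
  }
  fs_cohort(
    participants = tibble(id = ids, sex = sex, age_years = age),
    lesions = lesions,
    provenance = paste0("synthetic cohort (fscreen generator), n=", n,
                        if (!is.null(seed)) paste0(", seed=", seed) else "")
  )
}

#' Calibration report for a generated cohort
#'
#' Compares every calibrated marginal of the generator against its realised
#' value in a cohort: sex ratio, the twelve per-sex most-advanced-finding
#' prevalences, per-sex distal shares of CRC and AA (share of carriers with
#' *all* index-class lesions distal, under the descending-colon reach), and
#' per-sex proximal-AN carrier rates. Expected values are the param-implied
#' expectations; deviations beyond `flag_se` binomial standard errors are
#' flagged.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param params The parameters it was generated with.
#' @param flag_se Flagging threshold in standard-error units (default 4).
#' @return Tibble with columns `target`, `expected`, `realized`, `n`, `se`,
#'   `z`, `flag`.
#' @export
calibration_report <- function(cohort, params = default_cohort_params(),
                               flag_se = 4) {
  stopifnot(inherits(cohort, "fs_cohort"))
  pt <- cohort$participants
  flags <- .participant_flags(cohort, "descending_visualized")
  maf <- most_advanced_finding(cohort)
  stopifnot(identical(maf$id, pt$id))
  rows <- list()
  rec <- function(target, expected, num, den) {
    realized <- if (den > 0) num / den else NA_real_
    se <- if (den > 0) sqrt(expected * (1 - expected) / den) else NA_real_
    z <- if (den > 0 && se > 0) (realized - expected) / se else NA_real_
    rows[[length(rows) + 1]] <<- tibble(
      target = target, expected = expected, realized = realized,
      n = den, se = se, z = z, flag = !is.na(z) && abs(z) > flag_se)
  }
  n <- nrow(pt)
  rec("male_fraction", params$male_fraction, sum(pt$sex == "male"), n)
  for (sx in c("male", "female")) {
    g <- pt$sex == sx
    fp <- params$finding_probs[[sx]]
    for (cl in names(fp)) {
      rec(paste0(sx, "_prev_", cl), unname(fp[cl]),
          sum(g & maf$most_advanced == cl), sum(g))
    }
    # distal shares among carriers of the index class
    crc_g <- g & flags$has_crc
    rec(paste0(sx, "_crc_all_distal"), unname(params$distal_crc[sx]),
        sum(crc_g & flags$crc_all_distal), sum(crc_g))
    aa_g <- g & maf$most_advanced == "advanced_adenoma"
    rec(paste0(sx, "_aa_all_distal"), unname(params$distal_aa[sx]),
        sum(aa_g & flags$aa_all_distal), sum(aa_g))
    # param-implied proximal-AN carrier rate
    p_mix <- .apply_odds(params$prox_aa_given_distal_crc[[sx]],
                         params$prox_an_association)
    e_prox <- unname(
      params$finding_probs[[sx]]["crc"] *
        ((1 - params$distal_crc[[sx]]) + params$distal_crc[[sx]] * p_mix) +
        params$finding_probs[[sx]]["advanced_adenoma"] *
        (1 - params$distal_aa[[sx]]))
    rec(paste0(sx, "_prox_an_carrier"), e_prox, sum(g & flags$prox_an),
        sum(g))
  }
  dplyr::bind_rows(rows)
}
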