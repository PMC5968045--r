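# Referral strategies ----------------------------------------------------------
#
# A strategy is a named predicate over a participant's FS-visible (distal)
# findings, plus age and sex for the PLCO score. Predicates receive the distal
# summary table (one row per participant) and must be vectorised and blind to
# proximal lesions.

#' Construct a referral strategy
#'
#' A strategy predicate is a function of the per-participant distal summary
#' table and returns a logical referral decision per row. The summary columns
#' available to predicates are:
#'
#' * `age_years`, `sex` — demographics (`"male"`/`"female"`)
#' * `n_distal`, `n_adenoma`, `n_neoplasm`, `n_aa`, `n_an`, `n_hpp`,
#'   `n_hpp_above_rectum` — distal lesion counts (a neoplasm is an adenoma or
#'   CRC; AN additionally requires advanced features)
#' * `any_crc`, `any_villous`, `any_hgd`, `any_hpp` — distal feature flags
#'   (`any_hgd` counts high-grade dysplasia on adenomatous lesions)
#' * `max_adenoma_size`, `max_polyp_size` — largest distal adenoma / non-CRC
#'   polyp in mm (`NA` when none, or sizes unrecorded)
#' * `most_advanced_distal` — ordered factor over [neoplasia_classes()]
#'
#' `predicate` may be a function, or a one-sided formula / quoted expression
#' over those columns, e.g. `~ n_adenoma >= 3 | any_crc`.
#'
#' @param id Machine-readable strategy id (snake_case).
#' @param label Display label as used in rendered tables.
#' @param predicate Function of the summary table, or formula/expression.
#' @param auto_refers_any_distal_an Does the rule automatically refer every
#'   participant with any distal advanced neoplasm? (Rules that do not are
#'   conventionally set in italics in published tables; here it is metadata
#'   only — distal lesions are detected by FS itself either way.)
#' @param trial Optional trial name the rule originates from.
#' @return An object of class `fs_strategy`.
#' @export
fs_strategy <- function(id, label, predicate,
                        auto_refers_any_distal_an = NA, trial = NULL) {
  if (inherits(predicate, "formula")) {
    expr <- predicate[[2]]
    predicate <- function(flags) {
      rlang::eval_tidy(expr, data = as.data.frame(flags))
    }
  } else if (is.language(predicate)) {
    expr <- predicate
    predicate <- function(flags) {
      rlang::eval_tidy(expr, data = as.data.frame(flags))
    }
  }
  stopifnot(is.function(predicate))
  structure(list(id = id, label = label, predicate = predicate,
                 auto_refers_any_distal_an = auto_refers_any_distal_an,
                 trial = trial),
            class = "fs_strategy")
}

#' @export
print.fs_strategy <- function(x, ...) {
  cat("<fs_strategy> ", x$id, " (", x$label, ")\n", sep = "")
  invisible(x)
}

#' US PLCO trial referral score
#'
#' Additive score: age band (50-54: 0, 55-59: 1, 60-64: 2, 65-70: 3) + sex
#' (female 0, male 1) + most advanced distal finding (no polyps 0,
#' hyperplasia 1, tubular adenoma < 10 mm 2, advanced lesion — adenoma
#' >= 10 mm, villous histology, high-grade dysplasia or CRC — 3). Referral at
#' a total of 4 or more.
#'
#' The published age mapping stops at 70; since screening cohorts extend
#' beyond that age, ages above 70 keep the maximal 3 points (monotone
#' extension — the score has no published band above 70).
#'
#' @param age_years Integer age (>= 50; younger ages are outside the score's
#'   definition and raise an error).
#' @param sex `"male"` or `"female"`.
#' @param lesions Data frame of the participant's *distal* lesions (cohort
#'   lesion columns); may have zero rows.
#' @return List with `age_points`, `sex_points`, `finding_points`, `total`
#'   and `refer` (`total >= 4`).
#' @examples
#' plco_score(62, "male",
#'            data.frame(participant_id = "a", site = "sigmoid", size_mm = 6,
#'                       histology = "adenoma_tubular", hgd = FALSE))
#' @export
plco_score <- function(age_years, sex, lesions = NULL) {
  stopifnot(length(age_years) == 1, sex %in% c("male", "female"))
  if (age_years < 50) {
    stop("PLCO score is not defined below age 50", call. = FALSE)
  }
  age_points <- .plco_age_points(age_years)
  sex_points <- if (sex == "male") 1L else 0L
  if (is.null(lesions) || nrow(lesions) == 0) {
    finding_points <- 0L
  } else {
    cls <- .lesion_class(lesions$histology, lesions$size_mm, lesions$hgd)
    finding_points <-
      if (any(cls %in% c("crc", "advanced_adenoma"))) 3L
      else if (any(cls == "nonadvanced_adenoma")) 2L
      else if (any(cls == "hyperplastic_polyp")) 1L
      else 0L
  }
  total <- age_points + sex_points + finding_points
  list(age_points = age_points, sex_points = sex_points,
       finding_points = finding_points, total = total, refer = total >= 4)
}

.plco_age_points <- function(age_years) {
  ifelse(age_years < 55, 0L,
         ifelse(age_years < 60, 1L, ifelse(age_years < 65, 2L, 3L)))
}

# vectorised PLCO over the flags table
.plco_refer <- function(flags) {
  if (any(flags$age_years < 50)) {
    stop("PLCO score is not defined below age 50", call. = FALSE)
  }
  finding <- ifelse(flags$n_an >= 1, 3L,
             ifelse(flags$n_adenoma >= 1, 2L,
             ifelse(flags$any_hpp, 1L, 0L)))
  total <- .plco_age_points(flags$age_years) +
    ifelse(flags$sex == "male", 1L, 0L) + finding
  total >= 4
}

#' The twelve built-in referral strategies
#'
#' Returns, in the conventional published order, the no-referral baseline,
#' the four FS trial criteria (UK, SCORE, NORCCAP, US/PLCO) and seven further
#' recommended or conceivable rules over distal findings:
#'
#' | id | rule |
#' |----|------|
#' | `no_referral` | never refer |
#' | `uk` | CRC, polyp or adenoma >= 10 mm, (tubulo-)villous histology, HGD, >= 3 adenomas, or >= 20 hyperplastic polyps above the rectum |
#' | `score` | CRC, polyp > 5 mm, (tubulo-)villous histology, HGD, or >= 3 adenomas |
#' | `norccap` | CRC, polyp >= 10 mm, or any adenoma |
#' | `plco` | PLCO score >= 4 (see [plco_score()]) |
#' | `ge2_neoplasms_ge1_an` | >= 2 adenomas of which >= 1 advanced, or CRC |
#' | `ge2_neoplasms` | >= 2 adenomas, or CRC |
#' | `histology_an` | (tubulo-)villous adenoma, HGD or CRC |
#' | `an_ge_10mm` | adenoma >= 10 mm or CRC |
#' | `any_an` | any advanced neoplasm |
#' | `any_neoplasm` | any adenoma or CRC (guideline-recommended rule) |
#' | `any_neoplasm_or_hpp` | any adenoma, CRC or hyperplastic polyp |
#'
#' "Polyp" clauses (UK, SCORE, NORCCAP) include hyperplastic and other
#' polyps; "adenoma"/"neoplasm" clauses exclude them. Count thresholds count
#' distal lesions (one lesion row each). The UK trial published its size
#' clause as "> 1 cm"; following the >= 1 cm convention used by the other
#' trials it is implemented as `>= 10 mm` by default — set
#' `uk_size_strict = TRUE` for a strict `> 10 mm` reading. The SCORE "> 5 mm"
#' clause is strict.
#'
#' @param uk_size_strict Logical; see above.
#' @return Named list of [fs_strategy()] objects, length 12.
#' @export
builtin_strategies <- function(uk_size_strict = FALSE) {
  ge <- function(x, k) !is.na(x) & x >= k
  gt <- function(x, k) !is.na(x) & x > k
  uk_large <- if (uk_size_strict) function(x) gt(x, 10) else
    function(x) ge(x, 10)
  s <- list(
    fs_strategy("no_referral", "No referral",
                function(f) rep(FALSE, nrow(f)),
                auto_refers_any_distal_an = FALSE),
    fs_strategy("uk", "UK FS screening trial",
                function(f) f$any_crc | uk_large(f$max_polyp_size) |
                  f$any_villous | f$any_hgd | f$n_adenoma >= 3 |
                  f$n_hpp_above_rectum >= 20,
                auto_refers_any_distal_an = TRUE, trial = "UK"),
    fs_strategy("score", "SCORE",
                function(f) f$any_crc | gt(f$max_polyp_size, 5) |
                  f$any_villous | f$any_hgd | f$n_adenoma >= 3,
                auto_refers_any_distal_an = TRUE, trial = "SCORE"),
    fs_strategy("norccap", "NORCCAP",
                function(f) f$any_crc | ge(f$max_polyp_size, 10) |
                  f$n_adenoma >= 1,
                auto_refers_any_distal_an = TRUE, trial = "NORCCAP"),
    fs_strategy("plco", "US (PLCO)", .plco_refer,
                auto_refers_any_distal_an = FALSE, trial = "US PLCO"),
    fs_strategy("ge2_neoplasms_ge1_an", "\u22652 neoplasms, \u22651 AN",
                function(f) f$any_crc | (f$n_adenoma >= 2 & f$n_aa >= 1),
                auto_refers_any_distal_an = FALSE),
    fs_strategy("ge2_neoplasms", "\u22652 neoplasms",
                function(f) f$any_crc | f$n_adenoma >= 2,
                auto_refers_any_distal_an = FALSE),
    fs_strategy("histology_an", "Histology-defined AN",
                function(f) f$any_crc | f$any_villous | f$any_hgd,
                auto_refers_any_distal_an = FALSE),
    fs_strategy("an_ge_10mm", "AN \u22651 cm",
                function(f) f$any_crc | ge(f$max_adenoma_size, 10),
                auto_refers_any_distal_an = FALSE),
    fs_strategy("any_an", "Any AN",
                function(f) f$n_an >= 1,
                auto_refers_any_distal_an = TRUE),
    fs_strategy("any_neoplasm", "Any neoplasm",
                function(f) f$n_neoplasm >= 1,
                auto_refers_any_distal_an = TRUE),
    fs_strategy("any_neoplasm_or_hpp", "Any neoplasm or HPP",
                function(f) f$n_neoplasm >= 1 | f$any_hpp,
                auto_refers_any_distal_an = TRUE)
  )
  setNames(s, vapply(s, `[[`, "", "id"))
}

#' Apply a referral strategy
#'
#' Computes the referral decision for every participant from distal findings
#' (plus demographics for PLCO). Accepts either an `fs_cohort` (the distal
#' summary is computed under `reach`) or a precomputed summary table.
#'
#' @param strategy An `fs_strategy`.
#' @param x An `fs_cohort` or a distal summary table.
#' @inheritParams distal_sites
#' @return Logical vector, one decision per participant.
#' @export
decide_referral <- function(strategy, x, reach = "descending_visualized") {
  stopifnot(inherits(strategy, "fs_strategy"))
  flags <- if (inherits(x, "fs_cohort")) .participant_flags(x, reach) else x
  out <- strategy$predicate(flags)
  stopifnot(is.logical(out), length(out) == nrow(flags))
  out & !is.na(out)
}

# resolve strategy selection by id from the built-ins (plus user strategies)
.resolve_strategies <- function(strategies, uk_size_strict = FALSE) {
  if (is.null(strategies)) return(builtin_strategies(uk_size_strict))
  if (inherits(strategies, "fs_strategy")) strategies <- list(strategies)
  if (is.character(strategies)) {
    all <- builtin_strategies(uk_size_strict)
    unknown <- setdiff(strategies, names(all))
    if (length(unknown)) {
      stop("unknown strategy id(s): ", paste(unknown, collapse = ", "),
           "\nvalid ids: ", paste(names(all), collapse = ", "),
           call. = FALSE)
    }
    return(all[strategies])
  }
  stopifnot(all(vapply(strategies, inherits, TRUE, "fs_strategy")))
  setNames(strategies, vapply(strategies, `[[`, "", "id"))
}
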