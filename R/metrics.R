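# Outcome measures -------------------------------------------------------------

#' Round half away from zero
#'
#' Rendered screening tables conventionally round 0.5 upward (84.5% -> 85%),
#' unlike R's round-half-even. Internal computations keep full precision;
#' only display values pass through this.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval: the lower bound is the
#' `alpha/2` quantile of `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper
#' bound the `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x = n`).
#'
#' @param x Successes (vectorised).
#' @param n Trials.
#' @param conf Confidence level, default 0.95.
#' @return Tibble with `x`, `n`, `proportion`, `ci_low`, `ci_high`,
#'   `conf_level`. A zero denominator propagates `NA` rather than erroring.
#' @examples
#' clopper_pearson(118, 140)  # 0.843 (0.772, 0.899)
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(all(x >= 0 & x <= n, na.rm = TRUE), conf > 0, conf < 1)
  alpha <- 1 - conf
  k <- pmax(length(x), length(n))
  x <- rep_len(x, k); n <- rep_len(n, k)
  prop <- ifelse(n > 0, x / n, NA_real_)
  lo <- ifelse(n == 0, NA_real_,
               ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1)))
  hi <- ifelse(n == 0, NA_real_,
               ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x)))
  tibble(x = x, n = n, proportion = prop, ci_low = lo, ci_high = hi,
         conf_level = conf)
}

#' Sensitivity with exact confidence interval
#'
#' The share of endpoint carriers detected by FS itself or through
#' colonoscopy referral, among all carriers found at screening colonoscopy.
#'
#' @param detected Number detected.
#' @param total Number of endpoint carriers (the denominator).
#' @inheritParams clopper_pearson
#' @return Tibble as in [clopper_pearson()].
#' @export
sensitivity_estimate <- function(detected, total, conf = 0.95) {
  stopifnot(all(detected <= total, na.rm = TRUE))
  clopper_pearson(detected, total, conf)
}

#' Number of colonoscopies needed per proximal advanced neoplasm detected
#'
#' `NCN = colonoscopies performed / participants in whom a proximal AN is
#' detected`. Undefined (NA) when nothing is detected — notably the
#' no-referral baseline.
#'
#' @param n_colonoscopies Follow-up colonoscopies performed (referred and
#'   attended participants).
#' @param prox_an_detected Participants with a proximal AN detected at
#'   follow-up.
#' @return Numeric ratio (full precision; render with
#'   [round_half_up()] to one decimal).
#' @examples
#' ncn(547, 67)   # 8.16... -> printed 8.2
#' @export
ncn <- function(n_colonoscopies, prox_an_detected) {
  stopifnot(all(n_colonoscopies >= 0), all(prox_an_detected >= 0))
  ifelse(prox_an_detected > 0, n_colonoscopies / prox_an_detected, NA_real_)
}

#' Incremental NCN between two referral strategies
#'
#' Additional colonoscopies per additional proximal AN detected when
#' relaxing the reference rule: `(colonoscopies - ref colonoscopies) /
#' (detected - ref detected)`. Undefined when no additional AN is detected.
#'
#' @param n_colonoscopies,prox_an_detected Counts under the more extensive
#'   strategy.
#' @param ref_colonoscopies,ref_detected Counts under the reference strategy.
#' @return Numeric ratio, `NA` when the detection increment is <= 0.
#' @examples
#' incremental_ncn(1276, 129, 547, 67)  # 729/62 = 11.76 -> printed 11.8
#' @export
incremental_ncn <- function(n_colonoscopies, prox_an_detected,
                            ref_colonoscopies, ref_detected) {
  d_col <- n_colonoscopies - ref_colonoscopies
  d_det <- prox_an_detected - ref_detected
  ifelse(d_det > 0, d_col / d_det, NA_real_)
}

#' Negative predictive value from per-participant flags
#'
#' The probability that a participant who is *not* referred to colonoscopy
#' harbours no proximal lesion of the endpoint class: `#(not referred & no
#' proximal endpoint lesion) / #(not referred)`.
#'
#' @param referred Logical vector of referral decisions.
#' @param has_proximal Logical vector: proximal endpoint lesion present.
#' @inheritParams clopper_pearson
#' @return Tibble as in [clopper_pearson()]; `NA` when everyone is referred.
#' @export
npv <- function(referred, has_proximal, conf = 0.95) {
  stopifnot(length(referred) == length(has_proximal))
  n <- sum(!referred)
  clopper_pearson(sum(!referred & !has_proximal), n, conf)
}

#' Expected sensitivity gain under partial follow-up adherence
#'
#' With independent per-participant attendance at probability `adherence`,
#' the expected sensitivity gain of a referral strategy over the no-referral
#' baseline shrinks linearly: `adherence * (sens_full - sens_no_referral)`.
#' This is the closed-form counterpart of the stochastic attendance mechanism
#' in [evaluate_strategies()].
#'
#' @param sens_no_referral,sens_full Sensitivities (any common scale, e.g.
#'   percent) without referral and with full-adherence referral.
#' @param adherence Attendance probability in `[0, 1]`.
#' @return Expected gain on the same scale as the inputs.
#' @examples
#' adherence_adjusted_gain(68, 92, 0.75)  # 18 percentage points
#' @export
adherence_adjusted_gain <- function(sens_no_referral, sens_full, adherence) {
  stopifnot(all(adherence >= 0 & adherence <= 1))
  adherence * (sens_full - sens_no_referral)
}

# Full evaluation ---------------------------------------------------------------

.endpoints <- c("crc", "aa", "any_an")

#' Evaluate referral strategies on a cohort
#'
#' Computes the full strategy-by-stratum metric grid: referral counts and
#' rates, proximal-AN yield, NCN, incremental NCN against a reference
#' strategy, and per-endpoint sensitivity (with exact confidence intervals)
#' and negative predictive value, for men, women and both sexes combined.
#'
#' With `adherence < 1`, attendance at follow-up colonoscopy is an
#' independent per-participant coin. The primary columns then carry the
#' closed-form expected counts (linear in adherence); confidence intervals,
#' which require integer counts, are reported only at full adherence. Set
#' `n_reps > 0` to additionally report seeded Monte-Carlo means
#' (`mc_` columns) over replicated attendance draws.
#'
#' @param cohort An `fs_cohort`.
#' @param strategies `NULL` for all built-ins, a character vector of built-in
#'   ids, or a list of [fs_strategy()] objects.
#' @inheritParams distal_sites
#' @param mode Detection semantics, see [endpoint_status()].
#' @param adherence Probability that a referred participant attends follow-up
#'   colonoscopy (default 1).
#' @param reference Strategy id used as the incremental-NCN reference
#'   (default the most restrictive rule, `"ge2_neoplasms_ge1_an"`).
#' @param conf Confidence level for intervals.
#' @param seed Seed for the stochastic attendance draws (ignored at full
#'   adherence).
#' @param n_reps Monte-Carlo replicates when `adherence < 1`.
#' @param uk_size_strict Passed to [builtin_strategies()].
#' @return An object of class `fs_metric_table`: a list with tibbles
#'   `burden` (strategy x stratum), `sensitivity` (strategy x stratum x
#'   endpoint) and a `meta` list recording the run configuration.
#' @export
evaluate_strategies <- function(cohort, strategies = NULL,
                                reach = c("descending_visualized",
                                          "sigmoid_only"),
                                mode = c("all_lesions", "any_lesion"),
                                adherence = 1,
                                reference = "ge2_neoplasms_ge1_an",
                                conf = 0.95, seed = NULL, n_reps = 200,
                                uk_size_strict = FALSE) {
  stopifnot(inherits(cohort, "fs_cohort"),
            adherence >= 0, adherence <= 1)
  reach <- match.arg(reach)
  mode <- match.arg(mode)
  strategies <- .resolve_strategies(strategies, uk_size_strict)
  flags <- .participant_flags(cohort, reach)
  n_pt <- nrow(flags)

  strata <- list(men = flags$sex == "male",
                 women = flags$sex == "female",
                 both = rep(TRUE, n_pt))
  strata <- strata[vapply(strata, any, TRUE)]
  if (length(strata) < 3) {
    warning("empty sex stratum omitted", call. = FALSE)
  }

  referral <- vapply(strategies, function(s) decide_referral(s, flags),
                     logical(n_pt))
  if (is.null(dim(referral))) referral <- matrix(referral, nrow = n_pt)

  ep_has <- cbind(crc = flags$has_crc_endpoint, aa = flags$has_aa_endpoint,
                  any_an = flags$has_an_endpoint)
  ep_all <- cbind(crc = flags$crc_all_distal, aa = flags$aa_all_distal,
                  any_an = flags$an_all_distal)
  ep_any <- cbind(crc = flags$crc_any_distal, aa = flags$aa_any_distal,
                  any_an = flags$an_any_distal)
  ep_prox <- cbind(crc = flags$prox_crc, aa = flags$prox_aa,
                   any_an = flags$prox_an)
  base_det <- if (mode == "all_lesions") ep_has & ep_all else ep_has & ep_any

  mc <- NULL
  if (adherence < 1 && n_reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    mc <- matrix(0, nrow = length(strategies) * length(strata), ncol = 5)
  }

  burden <- list(); sens <- list(); row_i <- 0
  for (si in seq_along(strategies)) {
    st <- strategies[[si]]
    ref_vec <- referral[, si]
    for (gi in seq_along(strata)) {
      g <- strata[[gi]]
      row_i <- row_i + 1
      n_g <- sum(g)
      n_ref <- sum(ref_vec & g)
      # closed-form expectations, exact at adherence = 1
      e_col <- adherence * n_ref
      e_prox_det <- adherence * sum(ref_vec & g & flags$prox_an)
      det_cnt <- unname(vapply(.endpoints, function(e) {
        sum(base_det[g, e]) +
          adherence * sum(ep_has[g, e] & !base_det[g, e] & ref_vec[g])
      }, 0))
      tot_cnt <- unname(colSums(ep_has[g, , drop = FALSE]))
      burden[[row_i]] <- tibble(
        strategy = st$id, label = st$label, stratum = names(strata)[gi],
        n = n_g, n_referred = n_ref, referral_rate = n_ref / n_g,
        n_colonoscopies = e_col,
        prox_an_total = sum(flags$prox_an[g]),
        prox_an_detected = e_prox_det,
        ncn = ncn(e_col, e_prox_det)
      )
      exact <- adherence == 1
      ci <- clopper_pearson(ifelse(rep(exact, 3), det_cnt, NA_real_),
                            tot_cnt, conf)
      npvs <- unname(vapply(.endpoints, function(e) {
        nr <- sum(g & !ref_vec)
        if (nr == 0) NA_real_ else sum(g & !ref_vec & !ep_prox[, e]) / nr
      }, 0))
      sens[[row_i]] <- tibble(
        strategy = st$id, label = st$label, stratum = names(strata)[gi],
        endpoint = .endpoints,
        n_total = as.integer(tot_cnt), n_detected = det_cnt,
        sensitivity = ifelse(tot_cnt > 0, det_cnt / tot_cnt, NA_real_),
        ci_low = ci$ci_low, ci_high = ci$ci_high,
        npv = npvs
      )
      if (!is.null(mc)) {
        acc <- numeric(5)
        for (r in seq_len(n_reps)) {
          att <- ref_vec & (runif(n_pt) < adherence)
          det_r <- base_det | (ep_has & att)
          acc <- acc + c(sum(att & g), sum(att & g & flags$prox_an),
                         colSums(det_r[g, , drop = FALSE]))
        }
        mc[row_i, ] <- acc / n_reps
      }
    }
  }
  burden <- dplyr::bind_rows(burden)
  sens <- dplyr::bind_rows(sens)
  if (!is.null(mc)) {
    burden$mc_colonoscopies <- mc[, 1]
    burden$mc_prox_an_detected <- mc[, 2]
    mc_det <- as.data.frame(mc[, 3:5])
    names(mc_det) <- paste0("mc_detected_", .endpoints)
    burden <- dplyr::bind_cols(burden, mc_det)
  }

  # incremental NCN against the reference strategy, within stratum; when the
  # reference is not part of the run the column is left undefined
  if (!reference %in% burden$strategy) {
    burden$delta_ncn <- NA_real_
    return(structure(list(
      burden = burden, sensitivity = sens,
      meta = list(reach = reach, mode = mode, adherence = adherence,
                  reference = NA_character_, conf = conf, seed = seed,
                  n_participants = n_pt, source = "participant_level",
                  strategies = names(strategies))
    ), class = "fs_metric_table"))
  }
  ref_rows <- burden[burden$strategy == reference,
                     c("stratum", "n_colonoscopies", "prox_an_detected")]
  names(ref_rows)[2:3] <- c("ref_col", "ref_det")
  burden <- dplyr::left_join(burden, ref_rows, by = "stratum")
  burden$delta_ncn <- ifelse(
    burden$strategy == reference, NA_real_,
    incremental_ncn(burden$n_colonoscopies, burden$prox_an_detected,
                    burden$ref_col, burden$ref_det))
  burden$ref_col <- NULL; burden$ref_det <- NULL

  structure(list(
    burden = burden, sensitivity = sens,
    meta = list(reach = reach, mode = mode, adherence = adherence,
                reference = reference, conf = conf, seed = seed,
                n_participants = n_pt, source = "participant_level",
                strategies = names(strategies))
  ), class = "fs_metric_table")
}

#' Evaluate strategies from published aggregate counts
#'
#' Recomputes every derived metric — referral rates, sensitivities with exact
#' confidence intervals, NCN, incremental NCN, the no-referral negative
#' predictive value — from a strategy-level counts table, so published
#' results can be reproduced without participant-level data. See
#' [kolossal_counts()] for the expected columns and a bundled example.
#'
#' @param counts Data frame with columns `strategy`, `label` (optional),
#'   `stratum`, `n`, `prox_an_total`, `colonoscopies`, `prox_an_detected`,
#'   and `<endpoint>_detected` / `<endpoint>_total` for endpoints `crc`,
#'   `aa`, `an`.
#' @inheritParams evaluate_strategies
#' @return An `fs_metric_table` (see [evaluate_strategies()]); the NPV column
#'   is derived from proximal-AN counts and therefore only filled for the
#'   `any_an` endpoint.
#' @export
evaluate_counts <- function(counts, reference = "ge2_neoplasms_ge1_an",
                            conf = 0.95) {
  counts <- as_tibble(counts)
  req <- c("strategy", "stratum", "n", "prox_an_total", "colonoscopies",
           "prox_an_detected", "crc_detected", "crc_total", "aa_detected",
           "aa_total", "an_detected", "an_total")
  miss <- setdiff(req, names(counts))
  if (length(miss)) {
    stop("counts table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(counts)) counts$label <- counts$strategy
  burden <- tibble(
    strategy = counts$strategy, label = counts$label,
    stratum = counts$stratum, n = counts$n,
    n_referred = counts$colonoscopies,
    referral_rate = counts$colonoscopies / counts$n,
    n_colonoscopies = counts$colonoscopies,
    prox_an_total = counts$prox_an_total,
    prox_an_detected = counts$prox_an_detected,
    ncn = ncn(counts$colonoscopies, counts$prox_an_detected)
  )
  if (!reference %in% burden$strategy) {
    stop("reference strategy '", reference, "' is not in the counts table",
         call. = FALSE)
  }
  ref_rows <- burden[burden$strategy == reference,
                     c("stratum", "n_colonoscopies", "prox_an_detected")]
  names(ref_rows)[2:3] <- c("ref_col", "ref_det")
  burden <- dplyr::left_join(burden, ref_rows, by = "stratum")
  burden$delta_ncn <- ifelse(
    burden$strategy == reference, NA_real_,
    incremental_ncn(burden$n_colonoscopies, burden$prox_an_detected,
                    burden$ref_col, burden$ref_det))
  burden$ref_col <- NULL; burden$ref_det <- NULL

  ep_map <- c(crc = "crc", aa = "aa", any_an = "an")
  sens <- dplyr::bind_rows(lapply(names(ep_map), function(e) {
    det <- counts[[paste0(ep_map[[e]], "_detected")]]
    tot <- counts[[paste0(ep_map[[e]], "_total")]]
    ci <- clopper_pearson(det, tot, conf)
    # NPV derivable from aggregate counts only for the proximal-AN endpoint
    npv_val <- if (e == "any_an") {
      nr <- counts$n - counts$colonoscopies
      ifelse(nr > 0,
             (nr - (counts$prox_an_total - counts$prox_an_detected)) / nr,
             NA_real_)
    } else NA_real_
    tibble(strategy = counts$strategy, label = counts$label,
           stratum = counts$stratum, endpoint = e,
           n_total = tot, n_detected = det,
           sensitivity = ci$proportion, ci_low = ci$ci_low,
           ci_high = ci$ci_high, npv = npv_val)
  }))
  # endpoint varies fastest within each strategy x stratum row
  sens <- sens[order(rep(seq_len(nrow(counts)), times = 3)), ]
  structure(list(
    burden = burden, sensitivity = sens,
    meta = list(reach = NA_character_, mode = NA_character_, adherence = 1,
                reference = reference, conf = conf, seed = NULL,
                n_participants = NA_integer_, source = "aggregate_counts",
                strategies = unique(counts$strategy))
  ), class = "fs_metric_table")
}

#' @export
print.fs_metric_table <- function(x, ...) {
  cat("<fs_metric_table> ", length(unique(x$burden$strategy)),
      " strategies x ", length(unique(x$burden$stratum)), " strata (",
      x$meta$source, ")\n", sep = "")
  cat("  reach=", x$meta$reach, " mode=", x$meta$mode,
      " adherence=", x$meta$adherence, "\n", sep = "")
  print(head(x$burden, 6))
  invisible(x)
}
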