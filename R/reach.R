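# FS reach assumptions and detection semantics --------------------------------

.reach_levels <- c("descending_visualized", "sigmoid_only")

#' Distal segments under an FS reach assumption
#'
#' In the main analysis mode FS is assumed to reach and visualize the
#' descending colon (`"descending_visualized"`), so rectum, sigmoid and
#' descending colon are distal and everything from the splenic flexure upward
#' is proximal. The sensitivity-analysis mode `"sigmoid_only"` restricts reach
#' to rectum and sigmoid.
#'
#' @param reach `"descending_visualized"` (default) or `"sigmoid_only"`.
#' @return Character vector of distal site tokens.
#' @export
distal_sites <- function(reach = c("descending_visualized", "sigmoid_only")) {
  reach <- match.arg(reach)
  switch(reach,
         descending_visualized = c("rectum", "sigmoid", "descending"),
         sigmoid_only = c("rectum", "sigmoid"))
}

#' Is a lesion site within FS reach?
#'
#' @param site Character vector of site tokens (see [fs_sites()]); a
#'   `"missing"` site is an error — unlocalised lesions must be handled at
#'   load time.
#' @inheritParams distal_sites
#' @return Logical vector.
#' @examples
#' is_distal("descending", "descending_visualized")  # TRUE
#' is_distal("descending", "sigmoid_only")           # FALSE
#' @export
is_distal <- function(site, reach = c("descending_visualized",
                                      "sigmoid_only")) {
  reach <- match.arg(reach)
  if (any(is.na(site) | site == "missing")) {
    stop("lesion with missing site: location must be resolved or dropped ",
         "before reach classification", call. = FALSE)
  }
  bad <- !site %in% fs_sites()
  if (any(bad)) {
    stop("unknown site token(s): ", paste(unique(site[bad]), collapse = ", "),
         call. = FALSE)
  }
  site %in% distal_sites(reach)
}

#' Screening outcome for a single participant
#'
#' FS is assumed to detect, within its reach, the same lesions as colonoscopy
#' would. Proximal lesions are detected only if the participant is referred
#' and attends the follow-up colonoscopy, which is assumed complete.
#'
#' @param lesions Data frame of the participant's lesions (cohort lesion
#'   columns).
#' @param referred Logical referral decision, computed from distal findings
#'   only.
#' @param attends Logical: does the referred participant attend follow-up
#'   colonoscopy? Ignored when `referred` is `FALSE`.
#' @inheritParams distal_sites
#' @return A list of class `fs_detection` with elements `referred`,
#'   `attended_colonoscopy`, `distal_detected` and `proximal_detected`
#'   (lesion-row subsets).
#' @export
apply_screening <- function(lesions, referred, reach = "descending_visualized",
                            attends = TRUE) {
  d <- is_distal(lesions$site, reach)
  attended <- isTRUE(referred) && isTRUE(attends)
  structure(list(
    referred = isTRUE(referred),
    attended_colonoscopy = attended,
    distal_detected = lesions[d, , drop = FALSE],
    proximal_detected = if (attended) lesions[!d, , drop = FALSE]
                        else lesions[0, , drop = FALSE]
  ), class = "fs_detection")
}

#' Endpoint membership and detection for one participant
#'
#' Endpoints follow the participant-level convention of screening studies:
#' `"crc"` — at least one carcinoma; `"aa"` — advanced adenoma as the *most
#' advanced* finding (CRC carriers are excluded from the AA denominator);
#' `"any_an"` — at least one advanced neoplasm (CRC or AA).
#'
#' Under `mode = "all_lesions"` (default) the endpoint counts as detected only
#' if *every* lesion of the endpoint's class set is detected. This is why a
#' participant with a distal CRC and an undetected proximal AA counts as
#' detected for the CRC endpoint but not for the any-AN endpoint.
#' `mode = "any_lesion"` requires at least one detected lesion of the set.
#'
#' @param lesions The participant's lesion rows.
#' @param detection An `fs_detection` from [apply_screening()].
#' @param endpoint `"crc"`, `"aa"` or `"any_an"`.
#' @param mode `"all_lesions"` or `"any_lesion"`.
#' @return Named logical vector `c(has_endpoint, detected)`.
#' @export
endpoint_status <- function(lesions, detection,
                            endpoint = c("any_an", "crc", "aa"),
                            mode = c("all_lesions", "any_lesion")) {
  endpoint <- match.arg(endpoint)
  mode <- match.arg(mode)
  cls <- .lesion_class(lesions$histology, lesions$size_mm, lesions$hgd)
  in_set <- switch(endpoint,
                   crc = cls == "crc",
                   aa = cls == "advanced_adenoma",
                   any_an = cls %in% c("crc", "advanced_adenoma"))
  has <- switch(endpoint,
                crc = any(in_set),
                any_an = any(in_set),
                aa = length(cls) > 0 && any(in_set) && !any(cls == "crc"))
  if (!has) {
    return(c(has_endpoint = FALSE, detected = FALSE))
  }
  det_rows <- rbind(detection$distal_detected, detection$proximal_detected)
  det_cls <- .lesion_class(det_rows$histology, det_rows$size_mm, det_rows$hgd)
  det_in_set <- switch(endpoint,
                       crc = sum(det_cls == "crc"),
                       aa = sum(det_cls == "advanced_adenoma"),
                       any_an = sum(det_cls %in% c("crc", "advanced_adenoma")))
  detected <- if (mode == "all_lesions") det_in_set == sum(in_set)
              else det_in_set >= 1
  c(has_endpoint = TRUE, detected = detected)
}

# Vectorised participant flags --------------------------------------------------
#
# One row per participant; computed once per (cohort, reach) and shared by the
# strategy predicates, the detection logic and the metrics. Columns prefixed
# with nothing are the documented distal summary available to custom strategy
# predicates.
.participant_flags <- function(cohort, reach = "descending_visualized") {
  pt <- cohort$participants
  les <- cohort$lesions
  lv <- neoplasia_classes()

  if (nrow(les) > 0) {
    cls <- .lesion_class(les$histology, les$size_mm, les$hgd)
    dt <- data.table::data.table(
      participant_id = les$participant_id,
      site = les$site,
      size_mm = as.numeric(les$size_mm),
      histology = les$histology,
      hgd = les$hgd,
      class_int = as.integer(cls),
      distal = is_distal(les$site, reach)
    )
    i_crc <- match("crc", lv)
    i_aa <- match("advanced_adenoma", lv)
    i_hpp <- match("hyperplastic_polyp", lv)
    agg <- dt[, {
      adeno <- histology %in% .adenoma_histologies
      an <- class_int >= i_aa
      is_crc <- class_int == i_crc
      is_aa <- class_int == i_aa
      is_hpp <- class_int == i_hpp
      ad_sz <- size_mm[distal & adeno]
      pol_sz <- size_mm[distal & !is_crc]
      list(
        n_distal = sum(distal),
        n_adenoma = sum(distal & adeno),
        n_neoplasm = sum(distal & (adeno | is_crc)),
        n_aa = sum(distal & is_aa),
        n_an = sum(distal & an),
        n_hpp = sum(distal & is_hpp),
        n_hpp_above_rectum = sum(distal & is_hpp & site != "rectum"),
        any_crc = any(distal & is_crc),
        any_villous = any(distal & histology %in% .villous_histologies),
        any_hgd = any(distal & adeno & hgd),
        any_hpp = any(distal & is_hpp),
        max_adenoma_size = if (any(!is.na(ad_sz))) max(ad_sz, na.rm = TRUE)
                           else NA_real_,
        max_polyp_size = if (any(!is.na(pol_sz))) max(pol_sz, na.rm = TRUE)
                         else NA_real_,
        most_advanced_int = max(class_int),
        most_advanced_distal_int = max(c(1L, class_int[distal])),
        has_crc = any(is_crc),
        crc_all_distal = all(distal[is_crc]),
        crc_any_distal = any(distal & is_crc),
        has_aa_lesion = any(is_aa),
        aa_all_distal = all(distal[is_aa]),
        aa_any_distal = any(distal & is_aa),
        has_an = any(an),
        an_all_distal = all(distal[an]),
        an_any_distal = any(distal & an),
        prox_crc = any(is_crc & !distal),
        prox_aa = any(is_aa & !distal),
        prox_an = any(an & !distal)
      )
    }, by = "participant_id"]
    idx <- match(pt$id, agg$participant_id)
  } else {
    agg <- NULL
    idx <- rep(NA_integer_, nrow(pt))
  }

  out <- data.table::data.table(
    id = pt$id, sex = pt$sex, age_years = pt$age_years
  )
  num0 <- function(col, default) {
    v <- if (is.null(agg)) rep(default, nrow(pt)) else agg[[col]][idx]
    v[is.na(idx)] <- default
    v
  }
  for (col in c("n_distal", "n_adenoma", "n_neoplasm", "n_aa", "n_an",
                "n_hpp", "n_hpp_above_rectum")) {
    out[[col]] <- as.integer(num0(col, 0L))
  }
  for (col in c("any_crc", "any_villous", "any_hgd", "any_hpp", "has_crc",
                "crc_any_distal", "has_aa_lesion", "aa_any_distal", "has_an",
                "an_any_distal", "prox_crc", "prox_aa", "prox_an")) {
    out[[col]] <- as.logical(num0(col, FALSE))
  }
  for (col in c("crc_all_distal", "aa_all_distal", "an_all_distal")) {
    out[[col]] <- as.logical(num0(col, TRUE))
  }
  out$max_adenoma_size <- num0("max_adenoma_size", NA_real_)
  out$max_polyp_size <- num0("max_polyp_size", NA_real_)
  out$most_advanced_int <- as.integer(num0("most_advanced_int", 1L))
  out$most_advanced_distal_int <-
    as.integer(num0("most_advanced_distal_int", 1L))
  lvf <- factor(lv, levels = lv, ordered = TRUE)
  out$most_advanced <- lvf[out$most_advanced_int]
  out$most_advanced_distal <- lvf[out$most_advanced_distal_int]
  # endpoint membership
  out$has_crc_endpoint <- out$has_crc
  out$has_aa_endpoint <- out$most_advanced == "advanced_adenoma"
  out$has_an_endpoint <- out$has_an
  out
}

#' Per-participant screening outcomes under a strategy
#'
#' The participant-level detail behind [evaluate_strategies()]: one row per
#' participant with the referral decision, endpoint membership and detection
#' flags. Useful for auditing and for recomputing aggregate metrics
#' independently.
#'
#' @param cohort An `fs_cohort`.
#' @param strategy An `fs_strategy` (see [builtin_strategies()]).
#' @inheritParams distal_sites
#' @param mode Detection semantics, see [endpoint_status()].
#' @param attends Logical vector (recycled) of follow-up attendance among
#'   referred participants.
#' @return Tibble with columns `id`, `sex`, `referred`, `attended`,
#'   `has_<endpoint>`, `det_<endpoint>` for the three endpoints, and
#'   `prox_an`, `prox_an_detected`.
#' @export
screening_outcomes <- function(cohort, strategy,
                               reach = "descending_visualized",
                               mode = c("all_lesions", "any_lesion"),
                               attends = TRUE) {
  mode <- match.arg(mode)
  flags <- .participant_flags(cohort, reach)
  referred <- decide_referral(strategy, flags)
  .outcomes_from_flags(flags, referred, mode, attends)
}

.outcomes_from_flags <- function(flags, referred, mode, attends) {
  attended <- referred & rep_len(attends, length(referred))
  det <- function(has, all_d, any_d) {
    if (mode == "all_lesions") has & (all_d | attended)
    else has & (any_d | attended)
  }
  tibble(
    id = flags$id, sex = flags$sex,
    referred = referred, attended = attended,
    has_crc = flags$has_crc_endpoint,
    det_crc = det(flags$has_crc_endpoint, flags$crc_all_distal,
                  flags$crc_any_distal),
    has_aa = flags$has_aa_endpoint,
    det_aa = det(flags$has_aa_endpoint, flags$aa_all_distal,
                 flags$aa_any_distal),
    has_an = flags$has_an_endpoint,
    det_an = det(flags$has_an_endpoint, flags$an_all_distal,
                 flags$an_any_distal),
    prox_crc = flags$prox_crc,
    prox_aa = flags$prox_aa,
    prox_an = flags$prox_an,
    prox_an_detected = flags$prox_an & attended
  )
}
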