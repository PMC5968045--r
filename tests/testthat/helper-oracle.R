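# Independent brute-force re-derivation of screening outcomes, written as
# plain per-participant loops against the clinical definitions. Used to
# cross-check the vectorised package path on small cohorts.

oracle_class <- function(histology, size, hgd) {
  if (histology == "crc") return("crc")
  if (histology %in% c("adenoma_tubular", "adenoma_tubulovillous",
                       "adenoma_villous")) {
    adv <- (!is.na(size) && size >= 10) ||
      histology %in% c("adenoma_tubulovillous", "adenoma_villous") ||
      isTRUE(hgd)
    return(if (adv) "aa" else "na")
  }
  if (histology == "hyperplastic") return("hpp")
  "other"
}

oracle_outcomes <- function(cohort, refer_fun, reach = "descending_visualized",
                            mode = "all_lesions") {
  dsites <- if (reach == "sigmoid_only") c("rectum", "sigmoid")
            else c("rectum", "sigmoid", "descending")
  pt <- cohort$participants
  out <- list()
  for (i in seq_len(nrow(pt))) {
    les <- cohort$lesions[cohort$lesions$participant_id == pt$id[i], ]
    cls <- character(nrow(les))
    for (j in seq_len(nrow(les))) {
      cls[j] <- oracle_class(les$histology[j], les$size_mm[j], les$hgd[j])
    }
    distal <- les$site %in% dsites
    referred <- isTRUE(refer_fun(les[distal, , drop = FALSE],
                                 cls[distal], pt$age_years[i], pt$sex[i]))
    detected <- distal | referred  # follow-up colonoscopy sees everything
    ep <- function(set) {
      has <- any(cls %in% set)
      det <- if (!has) FALSE
             else if (mode == "all_lesions") all(detected[cls %in% set])
             else any(detected[cls %in% set])
      c(has, det)
    }
    crc <- ep("crc")
    an <- ep(c("crc", "aa"))
    aa <- ep("aa")
    if (any(cls == "crc")) aa <- c(FALSE, FALSE)  # AA = most advanced finding
    out[[i]] <- data.frame(
      id = pt$id[i], sex = pt$sex[i], referred = referred,
      has_crc = crc[1], det_crc = crc[2],
      has_aa = aa[1], det_aa = aa[2],
      has_an = an[1], det_an = an[2],
      prox_an = any(cls %in% c("crc", "aa") & !distal),
      prox_an_detected = referred && any(cls %in% c("crc", "aa") & !distal)
    )
  }
  do.call(rbind, out)
}

# independent statements of three referral rules for the oracle
oracle_refer_any_an <- function(dles, dcls, age, sex) any(dcls %in% c("crc", "aa"))
oracle_refer_ge2 <- function(dles, dcls, age, sex) {
  any(dcls == "crc") || sum(dcls %in% c("aa", "na")) >= 2
}
oracle_refer_norccap <- function(dles, dcls, age, sex) {
  any(dcls == "crc") ||
    any(!is.na(dles$size_mm) & dles$size_mm >= 10 & dcls != "crc") ||
    any(dcls %in% c("aa", "na"))
}
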