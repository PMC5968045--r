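# Builders for small in-code cohorts.

lesion_row <- function(pid, site, histology, size = NA_integer_,
                       hgd = FALSE) {
  tibble::tibble(participant_id = pid, site = site,
                 size_mm = as.integer(size), histology = histology,
                 hgd = hgd)
}

empty_lesions <- function() {
  tibble::tibble(participant_id = character(), site = character(),
                 size_mm = integer(), histology = character(),
                 hgd = logical())
}

# Six-participant cohort with hand-checkable outcomes: distal/proximal AN in
# men, a lesion-free woman, a multi-adenoma woman.
toy_cohort <- function() {
  participants <- tibble::tibble(
    id = paste0("p", 1:6),
    sex = c("male", "male", "male", "female", "female", "female"),
    age_years = c(60L, 65L, 58L, 62L, 70L, 57L)
  )
  lesions <- dplyr::bind_rows(
    lesion_row("p1", "sigmoid", "crc", 30),
    lesion_row("p1", "ascending", "adenoma_tubular", 12),      # proximal AA
    lesion_row("p2", "rectum", "adenoma_tubular", 12),         # distal AA
    lesion_row("p3", "cecum", "adenoma_villous", 5),           # proximal AA
    lesion_row("p3", "sigmoid", "adenoma_tubular", 4),
    lesion_row("p4", "sigmoid", "hyperplastic", 3),
    lesion_row("p6", "rectum", "adenoma_tubular", 6),
    lesion_row("p6", "sigmoid", "adenoma_tubular", 4),
    lesion_row("p6", "transverse", "adenoma_tubular", 5)
  )
  fs_cohort(participants, lesions, provenance = "toy fixture")
}

# Random small cohort over the full token space, for property tests.
random_cohort <- function(n, max_lesions = 4, p_lesion = 0.7) {
  participants <- tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_years = sample(55:79, n, replace = TRUE)
  )
  les <- list()
  for (i in seq_len(n)) {
    if (runif(1) > p_lesion) next
    k <- sample.int(max_lesions, 1)
    les[[length(les) + 1]] <- tibble::tibble(
      participant_id = participants$id[i],
      site = sample(fs_sites(), k, replace = TRUE),
      size_mm = as.integer(sample(1:30, k, replace = TRUE)),
      histology = sample(fs_histologies(), k, replace = TRUE,
                         prob = c(0.05, 0.1, 0.1, 0.4, 0.25, 0.1)),
      hgd = runif(k) < 0.1
    )
  }
  lesions <- if (length(les)) dplyr::bind_rows(les) else empty_lesions()
  fs_cohort(participants, lesions, provenance = "random fixture")
}
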