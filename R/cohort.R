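# Domain vocabulary -----------------------------------------------------------

#' Anatomical segments, histology tokens and the neoplasia hierarchy
#'
#' `fs_sites()` returns the recognised colonic segments ordered from the anus
#' upward; `"missing"` marks an unrecorded location. `fs_histologies()` returns
#' the recognised lesion histology tokens. `neoplasia_classes()` returns the
#' neoplasia hierarchy in increasing order of clinical relevance; participant
#' summaries use the maximum of this order over all lesions.
#'
#' "Neoplasm" means adenoma or colorectal cancer (CRC); "advanced neoplasia"
#' (AN) means CRC or advanced adenoma (AA). Hyperplastic and other polyps are
#' non-neoplastic for the purposes of referral rules.
#'
#' @return Character vector of tokens.
#' @export
fs_sites <- function() {
  c("rectum", "sigmoid", "descending", "splenic_flexure", "transverse",
    "hepatic_flexure", "ascending", "cecum")
}

#' @rdname fs_sites
#' @export
fs_histologies <- function() {
  c("crc", "adenoma_villous", "adenoma_tubulovillous", "adenoma_tubular",
    "hyperplastic", "other_polyp")
}

#' @rdname fs_sites
#' @export
neoplasia_classes <- function() {
  c("none", "other_polyp", "hyperplastic_polyp", "nonadvanced_adenoma",
    "advanced_adenoma", "crc")
}

.adenoma_histologies <- c("adenoma_tubular", "adenoma_tubulovillous",
                          "adenoma_villous")
.villous_histologies <- c("adenoma_tubulovillous", "adenoma_villous")

# Lesion classification -------------------------------------------------------

#' Classify lesions into the neoplasia hierarchy
#'
#' An adenoma is *advanced* (AA) if it has at least one of the standard
#' advanced features: size >= 10 mm, (tubulo-)villous components, or
#' high-grade dysplasia. Carcinomas classify as `crc` regardless of size or
#' dysplasia. Hyperplastic and other polyps pass through unchanged.
#'
#' An adenoma with missing size and no other advanced feature cannot be
#' asserted advanced and is classified `nonadvanced_adenoma`; a warning
#' reports how many lesions this audit rule affected.
#'
#' @param histology Character vector of histology tokens (see
#'   [fs_histologies()]).
#' @param size_mm Integer lesion size in millimetres; `NA` if unrecorded.
#' @param hgd Logical: high-grade dysplasia present. Only honoured on
#'   adenomatous lesions.
#' @return Ordered factor with levels [neoplasia_classes()].
#' @examples
#' classify_lesion("adenoma_tubular", 12, FALSE)   # advanced_adenoma
#' classify_lesion("adenoma_villous", 4, FALSE)    # advanced_adenoma
#' classify_lesion("adenoma_tubular", 5, FALSE)    # nonadvanced_adenoma
#' @export
classify_lesion <- function(histology, size_mm = NA_integer_, hgd = FALSE) {
  n_audit <- sum(histology == "adenoma_tubular" & is.na(size_mm) & !hgd)
  if (n_audit > 0) {
    warning(sprintf(paste0(
      "%d adenoma(s) with missing size and no other advanced feature ",
      "classified as nonadvanced"), n_audit), call. = FALSE)
  }
  .lesion_class(histology, size_mm, hgd)
}

# vectorised core, no audit warning (callers that need the audit count it)
.lesion_class <- function(histology, size_mm, hgd) {
  bad <- !histology %in% fs_histologies()
  if (any(bad)) {
    stop("unknown histology token(s): ",
         paste(unique(histology[bad]), collapse = ", "), call. = FALSE)
  }
  adeno <- histology %in% .adenoma_histologies
  advanced <- adeno & ((!is.na(size_mm) & size_mm >= 10) |
                         histology %in% .villous_histologies |
                         (!is.na(hgd) & hgd))
  out <- character(length(histology))
  out[histology == "crc"] <- "crc"
  out[advanced] <- "advanced_adenoma"
  out[adeno & !advanced] <- "nonadvanced_adenoma"
  out[histology == "hyperplastic"] <- "hyperplastic_polyp"
  out[histology == "other_polyp"] <- "other_polyp"
  factor(out, levels = neoplasia_classes(), ordered = TRUE)
}

#' Most advanced finding per participant
#'
#' Returns the maximum of [classify_lesion()] over each participant's lesions
#' under the neoplasia hierarchy; participants without lesions are `none`.
#'
#' @param cohort An `fs_cohort` (see [load_cohort()], [generate_cohort()]).
#' @return Tibble with columns `id`, `most_advanced` (ordered factor).
#' @export
most_advanced_finding <- function(cohort) {
  stopifnot(inherits(cohort, "fs_cohort"))
  les <- cohort$lesions
  lv <- neoplasia_classes()
  if (nrow(les) > 0) {
    cls <- as.integer(.lesion_class(les$histology, les$size_mm, les$hgd))
    dt <- data.table::data.table(participant_id = les$participant_id, c = cls)
    agg <- dt[, list(m = max(c)), by = "participant_id"]
  } else {
    agg <- data.table::data.table(participant_id = character(), m = integer())
  }
  idx <- match(cohort$participants$id, agg$participant_id)
  m <- agg$m[idx]
  m[is.na(m)] <- 1L  # none
  tibble(id = cohort$participants$id,
         most_advanced = factor(lv[m], levels = lv, ordered = TRUE))
}

# Cohort container -------------------------------------------------------------

#' Construct a screening cohort
#'
#' A cohort couples a participant table (`id`, `sex`, `age_years`) with a
#' lesion table (`participant_id`, `site`, `size_mm`, `histology`, `hgd`).
#' Validation enforces unique participant ids, known site and histology
#' tokens, non-negative sizes and lesion rows that reference an existing
#' participant. Most users will obtain cohorts via [load_cohort()] or
#' [generate_cohort()].
#'
#' @param participants Data frame with columns `id` (character), `sex`
#'   (`"male"`/`"female"`), `age_years` (integer).
#' @param lesions Data frame with columns `participant_id`, `site`, `size_mm`,
#'   `histology`, `hgd` (logical). May have zero rows.
#' @param provenance Free-text label recording where the cohort came from.
#' @param exclusion_log Named integer vector of records dropped per rule.
#' @return An object of class `fs_cohort`.
#' @export
fs_cohort <- function(participants, lesions, provenance = "",
                      exclusion_log = integer()) {
  participants <- as_tibble(participants)
  lesions <- as_tibble(lesions)
  stopifnot(all(c("id", "sex", "age_years") %in% names(participants)),
            all(c("participant_id", "site", "size_mm", "histology", "hgd")
                %in% names(lesions)))
  participants$id <- as.character(participants$id)
  if (anyDuplicated(participants$id)) {
    stop("duplicate participant id(s): ",
         paste(head(unique(participants$id[duplicated(participants$id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (!all(participants$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  lesions$participant_id <- as.character(lesions$participant_id)
  if (nrow(lesions) > 0) {
    bad_site <- !lesions$site %in% c(fs_sites(), "missing")
    if (any(bad_site)) {
      stop("unknown site token(s) in lesion rows ",
           paste(head(which(bad_site), 5), collapse = ", "), ": ",
           paste(unique(lesions$site[bad_site]), collapse = ", "),
           call. = FALSE)
    }
    bad_hist <- !lesions$histology %in% fs_histologies()
    if (any(bad_hist)) {
      stop("unknown histology token(s) in lesion rows ",
           paste(head(which(bad_hist), 5), collapse = ", "), ": ",
           paste(unique(lesions$histology[bad_hist]), collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.na(lesions$size_mm) & lesions$size_mm < 0)) {
      stop("negative lesion size", call. = FALSE)
    }
    orphan <- !lesions$participant_id %in% participants$id
    if (any(orphan)) {
      stop("lesion rows reference unknown participant id(s): ",
           paste(head(unique(lesions$participant_id[orphan]), 5),
                 collapse = ", "), call. = FALSE)
    }
    lesions$hgd <- as.logical(lesions$hgd)
  }
  structure(list(participants = participants, lesions = lesions,
                 provenance = provenance,
                 exclusion_log = exclusion_log),
            class = "fs_cohort")
}

#' @export
print.fs_cohort <- function(x, ...) {
  cat("<fs_cohort> ", nrow(x$participants), " participants (",
      sum(x$participants$sex == "male"), " men), ",
      nrow(x$lesions), " lesions\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  if (length(x$exclusion_log)) {
    cat("  exclusions:",
        paste(names(x$exclusion_log), x$exclusion_log, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Ingestion --------------------------------------------------------------------

#' Load a cohort from delimited files
#'
#' Reads a participant CSV (`id,sex,age`, sex coded `M`/`F`) and a lesion CSV
#' (`participant_id,site,size_mm,histology,hgd`), applies the eligibility age
#' window (55-79 by default, mirroring a screening programme open to ages
#' 55 to 79), and handles lesions with unrecorded location. Any additional
#' participant columns whose names start with `excl_` are treated as upstream
#' exclusion flags (0/1): flagged participants are dropped and counted.
#'
#' @param participants_file,lesions_file Paths to the two CSV files.
#'   `lesions_file = NULL` yields a lesion-free cohort.
#' @param min_age,max_age Inclusive eligibility window in years.
#' @param missing_location One of `"drop_participant"` (default: a participant
#'   with any unlocalised lesion is removed from analyses entirely),
#'   `"drop_lesion"` (only the unlocalised lesion rows are removed) or
#'   `"keep"`.
#' @return An [fs_cohort()]; `exclusion_log` holds per-rule counts and the
#'   invariant `retained + participant-level exclusions = input rows` always
#'   holds.
#' @export
load_cohort <- function(participants_file, lesions_file = NULL,
                        min_age = 55, max_age = 79,
                        missing_location = c("drop_participant", "drop_lesion",
                                             "keep")) {
  missing_location <- match.arg(missing_location)
  pt <- readr::read_csv(participants_file, show_col_types = FALSE,
                        progress = FALSE)
  req <- c("id", "sex", "age")
  if (!all(req %in% names(pt))) {
    stop("participants file must have columns id, sex, age", call. = FALSE)
  }
  pt$id <- as.character(pt$id)
  if (anyDuplicated(pt$id)) {
    stop("duplicate participant id(s): ",
         paste(head(unique(pt$id[duplicated(pt$id)]), 5), collapse = ", "),
         call. = FALSE)
  }
  sex_map <- c(M = "male", F = "female", male = "male", female = "female")
  if (!all(pt$sex %in% names(sex_map))) {
    stop("unknown sex token(s): ",
         paste(unique(pt$sex[!pt$sex %in% names(sex_map)]), collapse = ", "),
         call. = FALSE)
  }
  pt$sex <- unname(sex_map[pt$sex])
  input_ids <- pt$id

  log <- c()
  # upstream exclusion flags (bowel prep, prior colonoscopy, ...)
  for (col in grep("^excl_", names(pt), value = TRUE)) {
    flagged <- !is.na(pt[[col]]) & pt[[col]] == 1
    log[sub("^excl_", "", col)] <- sum(flagged)
    pt <- pt[!flagged, ]
  }
  in_age <- pt$age >= min_age & pt$age <= max_age
  log["age"] <- sum(!in_age)
  pt <- pt[in_age, ]

  if (is.null(lesions_file)) {
    les <- tibble(participant_id = character(), site = character(),
                  size_mm = integer(), histology = character(),
                  hgd = logical())
  } else {
    les <- readr::read_csv(lesions_file, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             participant_id = readr::col_character(),
                             site = readr::col_character(),
                             size_mm = readr::col_integer(),
                             histology = readr::col_character(),
                             hgd = readr::col_integer()))
    les$hgd <- !is.na(les$hgd) & les$hgd == 1
    orphan <- !les$participant_id %in% input_ids
    if (any(orphan)) {
      stop("lesion rows ", paste(head(which(orphan), 5), collapse = ", "),
           " reference participant id(s) absent from the participants file",
           call. = FALSE)
    }
  }

  if (missing_location != "keep" && nrow(les) > 0) {
    miss <- les$site == "missing"
    if (missing_location == "drop_participant") {
      drop_ids <- unique(les$participant_id[miss])
      drop_ids <- drop_ids[drop_ids %in% pt$id]
      log["missing_location"] <- length(drop_ids)
      pt <- pt[!pt$id %in% drop_ids, ]
      les <- les[!les$participant_id %in% drop_ids, ]
    } else {
      log["missing_location_lesions"] <- sum(miss)
      les <- les[!miss, ]
    }
  }
  # lesions belonging to excluded participants simply leave the analysis set;
  # a lesion that never matched any input participant is a data error
  if (nrow(les) > 0) {
    known <- les$participant_id %in% pt$id
    les <- les[known, ]
  }
  n_audit <- sum(les$histology == "adenoma_tubular" & is.na(les$size_mm) &
                   !les$hgd)
  if (n_audit > 0) {
    warning(sprintf(paste0(
      "%d adenoma(s) with missing size and no other advanced feature will ",
      "classify as nonadvanced"), n_audit), call. = FALSE)
  }
  fs_cohort(
    participants = tibble(id = pt$id, sex = pt$sex,
                          age_years = as.integer(pt$age)),
    lesions = les,
    provenance = paste0("loaded from ", participants_file),
    exclusion_log = log
  )
}

#' Write a cohort in the package CSV dialect
#'
#' Writes `participants.csv` (`id,sex,age`, sex coded `M`/`F`) and
#' `lesions.csv` (`participant_id,site,size_mm,histology,hgd`) into `dir`.
#'
#' @param cohort An `fs_cohort`.
#' @param dir Output directory; created if absent.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fs_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pf <- file.path(dir, "participants.csv")
  lf <- file.path(dir, "lesions.csv")
  pt <- cohort$participants
  readr::write_csv(tibble(id = pt$id,
                          sex = ifelse(pt$sex == "male", "M", "F"),
                          age = pt$age_years), pf, progress = FALSE)
  les <- cohort$lesions
  readr::write_csv(tibble(participant_id = les$participant_id,
                          site = les$site, size_mm = les$size_mm,
                          histology = les$histology,
                          hgd = as.integer(les$hgd)), lf, progress = FALSE)
  invisible(c(participants = pf, lesions = lf))
}
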