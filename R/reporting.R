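# Rendering and file-level pipeline --------------------------------------------

.fmt_pct <- function(x) ifelse(is.na(x), "--",
                               sprintf("%d", round_half_up(100 * x)))
.fmt_ratio <- function(x) ifelse(is.na(x), "--",
                                 sprintf("%.1f", round_half_up(x, 1)))
# sprintf("%-28s", ...) pads by bytes; pad by character count so that labels
# containing multi-byte glyphs stay aligned
.pad <- function(s, width) {
  paste0(s, strrep(" ", pmax(0, width - nchar(s, type = "chars"))))
}

#' Published aggregate strategy-level counts (KolosSal cohort)
#'
#' Strategy-by-stratum counts published for the KolosSal screening-colonoscopy
#' cohort (14,947 participants; descending-colon reach, full adherence):
#' follow-up colonoscopies, proximal advanced neoplasms detected, and
#' detected/total participants per endpoint (CRC; AA as most advanced
#' finding; any AN). This is the input for the counts-only evaluation mode,
#' [evaluate_counts()], from which every published sensitivity, NCN and
#' incremental-NCN value can be recomputed.
#'
#' @return Tibble with one row per strategy and stratum.
#' @examples
#' mt <- evaluate_counts(kolossal_counts())
#' subset(mt$burden, stratum == "both" & strategy == "any_an")
#' @export
kolossal_counts <- function() {
  path <- system.file("extdata", "kolossal_counts.csv", package = "fscreen",
                      mustWork = TRUE)
  counts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labels <- vapply(builtin_strategies(), `[[`, "", "label")
  counts$label <- unname(labels[counts$strategy])
  counts
}

#' Render the sensitivity table
#'
#' Fixed-width text table, one block per stratum, strategies sorted by the
#' number of colonoscopies (the no-referral baseline leads): per endpoint the
#' number detected and the sensitivity in percent with its exact confidence
#' interval. Percentages round half-up to whole percent.
#'
#' @param mt An `fs_metric_table`.
#' @return Character vector of lines (class `fs_rendered`), printable with
#'   `cat(x, sep = "\n")`.
#' @export
render_sensitivity_table <- function(mt) {
  stopifnot(inherits(mt, "fs_metric_table"))
  out <- character()
  wide <- mt$sensitivity
  for (str in unique(mt$burden$stratum)) {
    b <- mt$burden[mt$burden$stratum == str, ]
    b <- b[order(b$n_colonoscopies), ]
    hdr <- vapply(.endpoints, function(e) {
      tot <- wide$n_total[wide$stratum == str & wide$endpoint == e][1]
      sprintf("%s (N=%d)", toupper(sub("any_an", "Any AN", e)), tot)
    }, "")
    out <- c(out, sprintf("== %s ==", str),
             sprintf("%s %8s  %-22s %-22s %-22s",
                     .pad("Referral criterion", 28),
                     "Colons.", hdr[1], hdr[2], hdr[3]))
    for (i in seq_len(nrow(b))) {
      cells <- vapply(.endpoints, function(e) {
        r <- wide[wide$stratum == str & wide$endpoint == e &
                    wide$strategy == b$strategy[i], ]
        if (is.na(r$sensitivity)) return("--")
        sprintf("%4d  %s (%s-%s)", as.integer(round(r$n_detected)),
                .fmt_pct(r$sensitivity), .fmt_pct(r$ci_low),
                .fmt_pct(r$ci_high))
      }, "")
      out <- c(out, sprintf("%s %8d  %-22s %-22s %-22s",
                            .pad(b$label[i], 28),
                            as.integer(round(b$n_colonoscopies[i])),
                            cells[1], cells[2], cells[3]))
    }
    out <- c(out, "")
  }
  structure(out, class = "fs_rendered")
}

#' Render the colonoscopy-burden table
#'
#' Fixed-width text table per stratum, strategies sorted by the number of
#' colonoscopies: referrals (and % of screenees), proximal AN detected (and
#' % of carriers), NCN and incremental NCN against the reference strategy
#' (`Ref.` marks the reference row; `--` marks undefined ratios). Ratios
#' round half-up to one decimal.
#'
#' @inheritParams render_sensitivity_table
#' @return Character vector of lines (class `fs_rendered`).
#' @export
render_burden_table <- function(mt) {
  stopifnot(inherits(mt, "fs_metric_table"))
  out <- character()
  for (str in unique(mt$burden$stratum)) {
    b <- mt$burden[mt$burden$stratum == str, ]
    b <- b[order(b$n_colonoscopies), ]
    out <- c(out,
             sprintf("== %s (N=%d, incl. %d with prox. AN) ==", str,
                     b$n[1], b$prox_an_total[1]),
             sprintf("%s %14s %18s %6s %6s",
                     .pad("Referral criterion", 28),
                     "Colonoscopies", "Prox. AN detected", "NCN",
                     "dNCN"))
    for (i in seq_len(nrow(b))) {
      dn <- if (b$strategy[i] == mt$meta$reference) "Ref."
            else .fmt_ratio(b$delta_ncn[i])
      out <- c(out, sprintf(
        "%s %8d (%s%%) %12d (%s%%) %6s %6s", .pad(b$label[i], 28),
        as.integer(round(b$n_colonoscopies[i])),
        .fmt_pct(b$referral_rate[i]),
        as.integer(round(b$prox_an_detected[i])),
        .fmt_pct(ifelse(b$prox_an_total[i] > 0,
                        b$prox_an_detected[i] / b$prox_an_total[i], NA)),
        .fmt_ratio(b$ncn[i]), dn))
    }
    out <- c(out, "")
  }
  structure(out, class = "fs_rendered")
}

#' @export
print.fs_rendered <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}

#' Sex-specific mixed referral policies
#'
#' Evaluates a policy applying one referral rule to men and another to women:
#' combined colonoscopies, combined proximal AN detected, per-sex and
#' combined NCN. Applying the same rule to both sexes reproduces the
#' both-sexes row of that rule.
#'
#' @param mt An `fs_metric_table` with `men` and `women` strata.
#' @param men_strategy,women_strategy Strategy ids.
#' @return One-row tibble.
#' @export
mixed_policy_summary <- function(mt, men_strategy, women_strategy) {
  stopifnot(inherits(mt, "fs_metric_table"))
  pick <- function(strategy, stratum) {
    r <- mt$burden[mt$burden$strategy == strategy &
                     mt$burden$stratum == stratum, ]
    if (nrow(r) != 1) {
      stop("strategy '", strategy, "' not found for stratum '", stratum,
           "'", call. = FALSE)
    }
    r
  }
  m <- pick(men_strategy, "men")
  w <- pick(women_strategy, "women")
  tibble(
    men_strategy = men_strategy, women_strategy = women_strategy,
    n_colonoscopies = m$n_colonoscopies + w$n_colonoscopies,
    prox_an_detected = m$prox_an_detected + w$prox_an_detected,
    ncn_men = m$ncn, ncn_women = w$ncn,
    ncn_combined = ncn(m$n_colonoscopies + w$n_colonoscopies,
                       m$prox_an_detected + w$prox_an_detected)
  )
}

#' Write a metric table to files
#'
#' Writes `burden.csv` and `sensitivity.csv` (tidy, full precision), the two
#' rendered text tables, and `meta.json` (run configuration, including a
#' digest of the configuration for idempotence checks).
#'
#' @param mt An `fs_metric_table`.
#' @param dir Output directory; created if absent.
#' @return Invisibly, the written paths.
#' @export
write_metric_table <- function(mt, dir) {
  stopifnot(inherits(mt, "fs_metric_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(burden = file.path(dir, "burden.csv"),
             sensitivity = file.path(dir, "sensitivity.csv"),
             sensitivity_table = file.path(dir, "sensitivity_table.txt"),
             burden_table = file.path(dir, "burden_table.txt"),
             meta = file.path(dir, "meta.json"))
  readr::write_csv(mt$burden, paths["burden"], progress = FALSE)
  readr::write_csv(mt$sensitivity, paths["sensitivity"], progress = FALSE)
  writeLines(render_sensitivity_table(mt), paths["sensitivity_table"])
  writeLines(render_burden_table(mt), paths["burden_table"])
  meta <- mt$meta
  meta$config_hash <- rlang::hash(meta)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, null = "null")
  invisible(paths)
}

# File-level pipeline -----------------------------------------------------------

#' Simulate a cohort to files
#'
#' Generates a synthetic cohort, writes it in the package CSV dialect
#' together with a calibration report and a provenance record.
#'
#' @param out_dir Output directory; created if absent.
#' @param params [default_cohort_params()] by default.
#' @param seed Integer seed (recorded in the provenance file).
#' @param n Override the participant count.
#' @return Invisibly, a named vector of written paths.
#' @export
fs_simulate <- function(out_dir, params = default_cohort_params(), seed = 1,
                        n = params$n) {
  cohort <- generate_cohort(params, seed = seed, n = n)
  paths <- write_cohort(cohort, out_dir)
  cal <- calibration_report(cohort, params)
  cal_path <- file.path(out_dir, "calibration_report.csv")
  readr::write_csv(cal, cal_path, progress = FALSE)
  prov <- list(generator = "fscreen", n = n, seed = seed,
               provenance = cohort$provenance,
               config_hash = rlang::hash(list(params = unclass(params),
                                              seed = seed, n = n)))
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE)
  invisible(c(paths, calibration = cal_path, provenance = prov_path))
}

#' Evaluate a cohort (or counts table) to files
#'
#' Runs [evaluate_strategies()] on a cohort read from CSV files (or given
#' directly), or [evaluate_counts()] on an aggregate counts CSV, and writes
#' the tidy and rendered outputs via [write_metric_table()].
#'
#' @param out_dir Output directory.
#' @param cohort An `fs_cohort`, or `NULL` when using file input.
#' @param participants_file,lesions_file Cohort CSVs (ignored when `cohort`
#'   or `counts_file` is given).
#' @param counts_file Aggregate counts CSV for the counts-only mode.
#' @inheritParams evaluate_strategies
#' @return The `fs_metric_table`, invisibly; files as side effect.
#' @export
fs_evaluate <- function(out_dir, cohort = NULL, participants_file = NULL,
                        lesions_file = NULL, counts_file = NULL,
                        strategies = NULL,
                        reach = "descending_visualized",
                        mode = "all_lesions", adherence = 1,
                        reference = "ge2_neoplasms_ge1_an", conf = 0.95,
                        seed = NULL) {
  if (!is.null(counts_file)) {
    counts <- readr::read_csv(counts_file, show_col_types = FALSE,
                              progress = FALSE)
    mt <- evaluate_counts(counts, reference = reference, conf = conf)
  } else {
    if (is.null(cohort)) {
      if (is.null(participants_file)) {
        stop("supply a cohort, cohort files, or a counts file",
             call. = FALSE)
      }
      cohort <- load_cohort(participants_file, lesions_file)
    }
    mt <- evaluate_strategies(cohort, strategies = strategies, reach = reach,
                              mode = mode, adherence = adherence,
                              reference = reference, conf = conf,
                              seed = seed)
  }
  write_metric_table(mt, out_dir)
  invisible(mt)
}

#' Mixed-policy comparison report
#'
#' Renders [mixed_policy_summary()] rows for a set of (men-strategy,
#' women-strategy) pairs.
#'
#' @param mt An `fs_metric_table`.
#' @param pairs List of length-2 character vectors
#'   `c(men_strategy, women_strategy)`.
#' @param out_file Optional CSV path.
#' @return Tibble with one row per pair.
#' @export
fs_report <- function(mt, pairs, out_file = NULL) {
  res <- dplyr::bind_rows(lapply(pairs, function(p) {
    mixed_policy_summary(mt, p[[1]], p[[2]])
  }))
  if (!is.null(out_file)) readr::write_csv(res, out_file, progress = FALSE)
  res
}
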