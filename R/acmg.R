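#' Valid ACMG evidence tags
#'
#' The 28 evidence codes of the ACMG/AMP sequence-variant interpretation
#' guideline (Richards et al. 2015): one very-strong (PVS1), four strong
#' (PS1-PS4), six moderate (PM1-PM6) and five supporting (PP1-PP5)
#' pathogenic codes; one stand-alone (BA1), four strong (BS1-BS4) and seven
#' supporting (BP1-BP7) benign codes.
#'
#' @return Character vector of tag names.
#' @export
acmg_tags <- function() {
  c("PVS1",
    paste0("PS", 1:4),
    paste0("PM", 1:6),
    paste0("PP", 1:5),
    "BA1",
    paste0("BS", 1:4),
    paste0("BP", 1:7))
}

#' Stand-alone benign rule from population allele frequency
#'
#' BA1 applies when a variant's maximum allele frequency across the supplied
#' population cohorts is strictly greater than `threshold` (default 5%):
#' common polymorphisms are benign on frequency alone.
#'
#' @param pop_af_max Numeric vector of maximum population allele frequencies
#'   in `[0, 1]`.
#' @param threshold Frequency cutoff, strict (default 0.05).
#' @return Logical vector.
#' @export
apply_ba1 <- function(pop_af_max, threshold = 0.05) {
  if (any(pop_af_max < 0 | pop_af_max > 1, na.rm = TRUE)) {
    stopf("pop_af_max must lie in [0, 1]")
  }
  !is.na(pop_af_max) & pop_af_max > threshold
}

# tag category counts for one evidence set
acmg_counts <- function(tags) {
  list(pvs = sum(tags == "PVS1"),
       ps = sum(grepl("^PS[1-4]$", tags)),
       pm = sum(grepl("^PM[1-6]$", tags)),
       pp = sum(grepl("^PP[1-5]$", tags)),
       ba1 = any(tags == "BA1"),
       bs = sum(grepl("^BS[1-4]$", tags)),
       bp = sum(grepl("^BP[1-7]$", tags)))
}

#' Combine ACMG evidence into a 5-class call
#'
#' Implements the published ACMG/AMP evidence-combining table as an explicit
#' rule set, mapped to the five numeric classes used in clinical reporting:
#' pathogenic (5), likely pathogenic (4), VUS (3), likely benign (2), benign
#' (1). BA1 alone is sufficient for benign. When both a
#' pathogenic-qualifying and a benign-qualifying combination are satisfied,
#' the evidence is contradictory and the call falls back to VUS with
#' `conflict = TRUE`.
#'
#' @param tags Character vector of evidence tags (see [acmg_tags()]); an
#'   empty vector yields VUS.
#' @return One-row tibble: `class_number`, `label`, `conflict`.
#' @export
combine_evidence <- function(tags) {
  tags <- unique(as.character(tags))
  tags <- tags[nzchar(tags)]
  unknown <- setdiff(tags, acmg_tags())
  if (length(unknown)) stopf("unknown ACMG tag(s): %s", paste(unknown, collapse = ", "))
  k <- acmg_counts(tags)
  pathogenic <-
    (k$pvs >= 1 && (k$ps >= 1 || k$pm >= 2 || (k$pm >= 1 && k$pp >= 1) || k$pp >= 2)) ||
    k$ps >= 2 ||
    (k$ps >= 1 && (k$pm >= 3 || (k$pm >= 2 && k$pp >= 2) || (k$pm >= 1 && k$pp >= 4)))
  likely_path <-
    (k$pvs >= 1 && k$pm >= 1) ||
    (k$ps >= 1 && k$pm >= 1) ||
    (k$ps >= 1 && k$pp >= 2) ||
    k$pm >= 3 ||
    (k$pm >= 2 && k$pp >= 2) ||
    (k$pm >= 1 && k$pp >= 4)
  benign <- k$ba1 || k$bs >= 2
  likely_benign <- (k$bs >= 1 && k$bp >= 1) || k$bp >= 2
  path_side <- pathogenic || likely_path
  benign_side <- benign || likely_benign
  if (path_side && benign_side) {
    return(tibble(class_number = 3L, label = "VUS", conflict = TRUE))
  }
  cls <- if (pathogenic) 5L else if (likely_path) 4L else if (benign) 1L else if (likely_benign) 2L else 3L
  labels <- c("benign", "likely_benign", "VUS", "likely_pathogenic", "pathogenic")
  tibble(class_number = cls, label = labels[cls], conflict = FALSE)
}

#' Classify a filtered call set
#'
#' Joins each passing call to its evidence tags and population allele
#' frequencies (by normalized variant key), forces BA1 when the maximum
#' population frequency exceeds `ba1_threshold`, combines evidence with
#' [combine_evidence()], and summarises counts in the reporting groups
#' Class_1_2 (benign / likely benign), Class_3 (VUS) and Class_4_5
#' (likely pathogenic / pathogenic). Calls without an evidence row get an
#' empty evidence set (VUS unless BA1 applies).
#'
#' @param calls Filtered call tibble with `key` and `filter_status`; only
#'   passing calls are classified.
#' @param evidence Optional tibble `key`, `tags` (semicolon-joined).
#' @param pop_af Optional tibble `key`, `cohort`, `af`.
#' @param ba1_threshold BA1 population-frequency cutoff (default 0.05).
#' @return Object of class `acmg_classification`: list with `variants` (per
#'   call: `class_number`, `label`, `conflict`, `pop_af_max`, `class_group`)
#'   and `summary` (group counts).
#' @export
classify_callset <- function(calls, evidence = NULL, pop_af = NULL,
                             ba1_threshold = 0.05) {
  passing <- calls
  if ("filter_status" %in% names(passing)) {
    passing <- passing |> filter(.data$filter_status == "pass")
  }
  if (!nrow(passing)) {
    variants <- passing |>
      mutate(pop_af_max = double(), tags = character(),
             class_number = integer(), label = character(),
             conflict = logical(), class_group = character())
    summary <- tibble(class_group = c("Class_1_2", "Class_3", "Class_4_5"),
                      n = c(0L, 0L, 0L))
    return(structure(list(variants = variants, summary = summary),
                     class = "acmg_classification"))
  }
  af_max <- if (!is.null(pop_af) && nrow(pop_af)) {
    pop_af |>
      group_by(.data$key) |>
      summarise(pop_af_max = max(.data$af), .groups = "drop")
  } else {
    tibble(key = character(), pop_af_max = double())
  }
  ev <- if (!is.null(evidence) && nrow(evidence)) {
    evidence |> select("key", "tags")
  } else {
    tibble(key = character(), tags = character())
  }
  x <- passing |>
    left_join(af_max, by = "key") |>
    left_join(ev, by = "key") |>
    mutate(pop_af_max = dplyr::coalesce(.data$pop_af_max, 0),
           tags = dplyr::coalesce(.data$tags, ""))
  cls <- purrr::map2_dfr(x$tags, x$pop_af_max, function(tg, af) {
    tag_vec <- strsplit(tg, ";", fixed = TRUE)[[1]]
    tag_vec <- trimws(tag_vec[nzchar(trimws(tag_vec))])
    if (apply_ba1(af, ba1_threshold)) tag_vec <- union(tag_vec, "BA1")
    combine_evidence(tag_vec)
  })
  variants <- dplyr::bind_cols(x, cls) |>
    mutate(class_group = case_when(
      .data$class_number <= 2L ~ "Class_1_2",
      .data$class_number == 3L ~ "Class_3",
      TRUE ~ "Class_4_5"
    ))
  summary <- tibble(class_group = c("Class_1_2", "Class_3", "Class_4_5")) |>
    left_join(variants |> count(.data$class_group), by = "class_group") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(list(variants = variants, summary = summary),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("<acmg_classification> %d classified variant(s)\n", nrow(x$variants)))
  print(x$summary)
  invisible(x)
}

#' @rdname classify_callset
#' @param x An `acmg_classification` object.
#' @param ... Unused.
#' @method tidy acmg_classification
#' @export
tidy.acmg_classification <- function(x, ...) {
  as_tibble(x$variants)
}

#' @rdname classify_callset
#' @method glance acmg_classification
#' @export
glance.acmg_classification <- function(x, ...) {
  x$summary |> tidyr::pivot_wider(names_from = "class_group", values_from = "n")
}

#' Read evidence / population-AF tables
#'
#' Evidence TSV columns: `key`, `tags` (semicolon-joined ACMG codes).
#' Population TSV columns: `key`, `cohort`, `af`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_evidence_tsv <- function(path) {
  read_tsv_hash(path) |> mutate(tags = dplyr::coalesce(as.character(.data$tags), ""))
}

#' @rdname read_evidence_tsv
#' @export
read_pop_af_tsv <- function(path) {
  read_tsv_hash(path) |> mutate(af = as.numeric(.data$af))
}
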