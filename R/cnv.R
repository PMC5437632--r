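#' Library-size normalization of a depth matrix
#'
#' The depth matrix is a long tibble with one row per (sample, exon):
#' columns `sample_id`, `gene`, `exon_index`, `depth` (mean read depth over
#' the exon) and `role` (`test` or `reference_normal`). Normalization divides
#' each sample's exon depths by that sample's mean over the retained exons,
#' so a diploid sample centers at 1.0 and calls are invariant to sequencing
#' yield. Exons failing coverage QC should be removed before normalization.
#'
#' @param depths Long depth tibble (see above).
#' @return The tibble with a `norm` column added.
#' @export
normalize_depth_matrix <- function(depths) {
  check_depth_matrix(depths)
  out <- depths |>
    group_by(.data$sample_id) |>
    mutate(norm = .data$depth / mean(.data$depth)) |>
    ungroup()
  if (any(!is.finite(out$norm))) {
    bad <- unique(out$sample_id[!is.finite(out$norm)])
    stopf("sample '%s' has zero total depth; cannot normalize", bad[1])
  }
  out
}

check_depth_matrix <- function(depths) {
  needed <- c("sample_id", "gene", "exon_index", "depth", "role")
  missing_cols <- setdiff(needed, names(depths))
  if (length(missing_cols)) {
    stopf("depth matrix missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (any(depths$depth < 0)) stopf("negative depths in matrix")
  if (!all(depths$role %in% c("test", "reference_normal"))) {
    stopf("role must be 'test' or 'reference_normal'")
  }
  invisible(depths)
}

#' Per-exon coverage ratios against the reference-normal pool
#'
#' For a test sample, each exon's normalized coverage is ratioed against the
#' mean normalized coverage of the reference diploid normals, giving 1.0 for
#' a diploid exon, ~0.5 for a single-copy (heterozygous) loss and ~1.5 for a
#' single-copy gain. Significance comes from a two-sided one-sample z test of
#' the test sample's log2 value against the reference pool's per-exon log2
#' mean and standard deviation, with a floor of `sd_floor` on the standard
#' deviation to keep near-constant exons from producing vanishing p-values.
#' The signed fold change is `ratio` for ratios of at least 1 and `-1/ratio`
#' below 1, so a heterozygous deletion sits near -2.
#'
#' Exons where any reference normal has zero coverage are uncallable and
#' excluded (returned in the `"uncallable"` attribute).
#'
#' @param depths Long depth tibble; must contain at least 2 reference
#'   normals (a warning is given below 10).
#' @param test_sample Sample id with `role = "test"`.
#' @param sd_floor Minimum log2-scale standard deviation (default 0.05).
#' @return Tibble with `gene`, `exon_index`, `ratio`, `log2_ratio`,
#'   `fold_change`, `p_value`, ordered by gene and exon.
#' @export
exon_ratios <- function(depths, test_sample, sd_floor = 0.05) {
  if (!"norm" %in% names(depths)) depths <- normalize_depth_matrix(depths)
  refs <- depths |> filter(.data$role == "reference_normal")
  n_ref <- length(unique(refs$sample_id))
  if (n_ref < 2L) stopf("at least 2 reference normals are required (got %d)", n_ref)
  if (n_ref < 10L) {
    warn(sprintf("only %d reference normals: per-exon variability is poorly estimated", n_ref))
  }
  test <- depths |> filter(.data$sample_id == !!test_sample)
  if (!nrow(test)) stopf("test sample '%s' not found in depth matrix", test_sample)

  ref_stats <- refs |>
    group_by(.data$gene, .data$exon_index) |>
    summarise(ref_mean = mean(.data$norm),
              any_zero = any(.data$norm <= 0),
              log2_mu = mean(log2(pmax(.data$norm, .Machine$double.xmin))),
              log2_sd = sd(log2(pmax(.data$norm, .Machine$double.xmin))),
              .groups = "drop")
  joined <- inner_join(test |> select("gene", "exon_index", "norm"),
                       ref_stats, by = c("gene", "exon_index"))
  uncallable <- joined |> filter(.data$any_zero | .data$ref_mean <= 0)
  callable <- joined |> filter(!(.data$any_zero | .data$ref_mean <= 0))

  z_cap <- 38 # keeps p strictly positive at double precision
  out <- callable |>
    mutate(
      ratio = .data$norm / .data$ref_mean,
      log2_ratio = log2(pmax(.data$ratio, .Machine$double.xmin)),
      fold_change = if_else(.data$ratio >= 1, .data$ratio, -1 / .data$ratio),
      sd_used = pmax(.data$log2_sd, sd_floor),
      z = pmax(pmin((log2(pmax(.data$norm, .Machine$double.xmin)) - .data$log2_mu) /
                      .data$sd_used, z_cap), -z_cap),
      p_value = 2 * pnorm(-abs(.data$z))
    ) |>
    arrange(.data$gene, .data$exon_index) |>
    select("gene", "exon_index", "ratio", "log2_ratio", "fold_change", "p_value")
  attr(out, "uncallable") <- uncallable |> select("gene", "exon_index")
  attr(out, "test_sample") <- test_sample
  out
}

#' Segment significant exons into CNV calls
#'
#' An exon is individually significant for gain when `fold_change > gain_fc`
#' with `p_value < alpha`, and for loss when `fold_change < loss_fc` with
#' `p_value < alpha` (defaults 1.3, -1.7, 0.05: a single-copy gain in a
#' diploid expects +1.5, a single-copy loss -2.0). Maximal runs of
#' consecutive same-direction significant exons within one gene become
#' segments; a single intervening non-significant callable exon splits a
#' run. A segment covering every callable exon of its gene is `whole_gene`,
#' otherwise `intragenic`. Member p-values are combined by Fisher's method
#' (reported for ranking; calling uses the per-exon thresholds exactly).
#'
#' @param ratios Output of [exon_ratios()].
#' @param gain_fc Gain fold-change threshold, exclusive (default 1.3).
#' @param loss_fc Loss fold-change threshold, exclusive (default -1.7).
#' @param alpha Per-exon significance level, exclusive (default 0.05).
#' @return Tibble of segments: `gene`, `first_exon`, `last_exon`, `n_exons`,
#'   `direction`, `scope`, `mean_fold_change`, `combined_p`.
#' @export
call_segments <- function(ratios, gain_fc = 1.3, loss_fc = -1.7, alpha = 0.05) {
  empty <- tibble(gene = character(), first_exon = integer(),
                  last_exon = integer(), n_exons = integer(),
                  direction = character(), scope = character(),
                  mean_fold_change = double(), combined_p = double())
  if (!nrow(ratios)) return(empty)
  x <- ratios |>
    arrange(.data$gene, .data$exon_index) |>
    mutate(direction = case_when(
      .data$fold_change > gain_fc & .data$p_value < alpha ~ "gain",
      .data$fold_change < loss_fc & .data$p_value < alpha ~ "loss",
      TRUE ~ "none"
    ))
  x <- x |>
    group_by(.data$gene) |>
    mutate(run_id = cumsum(.data$direction != lag(.data$direction, default = "<start>"))) |>
    ungroup()
  if (!any(x$direction != "none")) return(empty)
  segs <- x |>
    filter(.data$direction != "none") |>
    group_by(.data$gene, .data$run_id, .data$direction) |>
    summarise(first_exon = min(.data$exon_index),
              last_exon = max(.data$exon_index),
              n_exons = n(),
              mean_fold_change = mean(.data$fold_change),
              combined_p = fisher_combine(.data$p_value),
              .groups = "drop")
  if (!nrow(segs)) return(empty)
  gene_sizes <- x |> count(.data$gene, name = "n_callable")
  segs |>
    left_join(gene_sizes, by = "gene") |>
    mutate(scope = if_else(.data$n_exons == .data$n_callable, "whole_gene", "intragenic")) |>
    arrange(.data$gene, .data$first_exon) |>
    select("gene", "first_exon", "last_exon", "n_exons", "direction",
           "scope", "mean_fold_change", "combined_p")
}

fisher_combine <- function(p) {
  p <- pmax(p, .Machine$double.xmin)
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Call germline CNVs for one test sample
#'
#' Convenience wrapper chaining exclusion of QC-failing exons,
#' [normalize_depth_matrix()], [exon_ratios()] and [call_segments()] into a
#' fitted-object interface with [tidy()], [glance()] and [autoplot()]
#' methods.
#'
#' @param depths Long depth tibble (`sample_id`, `gene`, `exon_index`,
#'   `depth`, `role`).
#' @param test_sample Test sample id.
#' @param exclude Optional tibble of `(gene, exon_index)` to drop before
#'   normalization (e.g. from [consistently_failing_exons()]).
#' @param gain_fc,loss_fc,alpha,sd_floor Calling parameters, see
#'   [call_segments()] and [exon_ratios()].
#' @return An object of class `cnv_call` with elements `ratios`, `segments`,
#'   `test_sample`, `params`.
#' @export
call_cnv <- function(depths, test_sample, exclude = NULL,
                     gain_fc = 1.3, loss_fc = -1.7, alpha = 0.05,
                     sd_floor = 0.05) {
  check_depth_matrix(depths)
  if (!is.null(exclude) && nrow(exclude)) {
    depths <- anti_join(depths, exclude |> select("gene", "exon_index"),
                        by = c("gene", "exon_index"))
  }
  depths <- normalize_depth_matrix(depths)
  ratios <- exon_ratios(depths, test_sample, sd_floor = sd_floor)
  segments <- call_segments(ratios, gain_fc = gain_fc, loss_fc = loss_fc,
                            alpha = alpha)
  structure(list(ratios = ratios, segments = segments,
                 test_sample = test_sample,
                 params = list(gain_fc = gain_fc, loss_fc = loss_fc,
                               alpha = alpha, sd_floor = sd_floor)),
            class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat(sprintf("<cnv_call> sample %s: %d callable exon(s), %d segment(s)\n",
              x$test_sample, nrow(x$ratios), nrow(x$segments)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

#' @rdname call_cnv
#' @param x A `cnv_call` object.
#' @param ... Unused.
#' @method tidy cnv_call
#' @export
tidy.cnv_call <- function(x, ...) {
  x$segments |> mutate(sample_id = x$test_sample, .before = 1L)
}

#' @rdname call_cnv
#' @method glance cnv_call
#' @export
glance.cnv_call <- function(x, ...) {
  tibble(sample_id = x$test_sample,
         n_exons_callable = nrow(x$ratios),
         n_segments = nrow(x$segments),
         n_gain = sum(x$segments$direction == "gain"),
         n_loss = sum(x$segments$direction == "loss"),
         min_combined_p = if (nrow(x$segments)) min(x$segments$combined_p) else NA_real_)
}

#' Read / write a depth matrix TSV
#'
#' On-disk layout: rows are `GENE_exonN` regions, columns samples; the first
#' header line (`#region<TAB>...`) names the samples and the second
#' (`#role<TAB>...`) gives each sample's role (`test` or
#' `reference_normal`).
#'
#' @param path File path.
#' @return Long depth tibble.
#' @export
read_depth_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], "#") || !startsWith(lines[2], "#")) {
    stopf("depth matrix file %s lacks the two '#' header lines", path)
  }
  h1 <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  h2 <- strsplit(sub("^#", "", lines[2]), "\t", fixed = TRUE)[[1]]
  samples <- h1[-1]
  roles <- h2[-1]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  purrr::map_dfr(body, function(p) {
    m <- regmatches(p[1], regexec("^(.+)_exon([0-9]+)$", p[1]))[[1]]
    if (length(m) != 3L) stopf("bad region label '%s' in depth matrix", p[1])
    tibble(sample_id = samples, gene = m[2], exon_index = as.integer(m[3]),
           depth = as.numeric(p[-1]), role = roles)
  }) |>
    arrange(.data$sample_id, .data$gene, .data$exon_index)
}

#' @rdname read_depth_matrix
#' @param depths Long depth tibble to write.
#' @export
write_depth_matrix <- function(depths, path) {
  check_depth_matrix(depths)
  roles <- depths |> distinct(.data$sample_id, .data$role) |> arrange(.data$sample_id)
  wide <- depths |>
    mutate(region = paste0(.data$gene, "_exon", .data$exon_index)) |>
    select("region", "sample_id", "depth") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "depth") |>
    arrange(.data$region)
  wide <- wide[, c("region", roles$sample_id)]
  h1 <- paste0("#", paste(c("region", roles$sample_id), collapse = "\t"))
  h2 <- paste0("#", paste(c("role", roles$role), collapse = "\t"))
  body <- do.call(paste, c(lapply(wide, format_tsv_col), list(sep = "\t")))
  writeLines(c(h1, h2, body), path, sep = "\n")
  invisible(path)
}
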