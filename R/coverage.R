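#' Per-exon coverage statistics
#'
#' Computes, for one sample, the mean and minimum read depth over every
#' nucleotide position of each panel exon. Panel positions absent from the
#' depth table count as depth 0, which is the conservative choice for the
#' minimum rule: an exon passes QC only if its *lowest* covered position —
#' not its average — reaches `min_depth` reads.
#'
#' @param depths Data frame of per-position depths with columns `sample_id`,
#'   `chrom`, `pos` (0-based), `depth`.
#' @param panel A [gene_panel()].
#' @param sample_id Sample to evaluate.
#' @param min_depth Minimum per-position depth an exon must reach everywhere
#'   to pass (default 50 reads).
#' @return Tibble with one row per exon: `gene`, `exon_index`, `width`,
#'   `mean_depth`, `min_depth`, `passes_min`.
#' @export
exon_coverage <- function(depths, panel, sample_id, min_depth = 50) {
  stopifnot(inherits(panel, "gene_panel"))
  d <- depths |> filter(.data$sample_id == !!sample_id)
  if (!nrow(d)) stopf("no depth records for sample '%s'", sample_id)
  if (any(d$depth < 0)) stopf("negative depth values in input")
  if (anyDuplicated(d[, c("chrom", "pos")])) {
    stopf("duplicate (chrom, pos) depth rows for sample '%s': ambiguous input", sample_id)
  }
  lookup <- split(setNames(d$depth, d$pos), d$chrom)
  per_exon <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    positions <- seq.int(panel$start[i], panel$end[i] - 1L)
    vals <- lookup[[panel$chrom[i]]][as.character(positions)]
    vals[is.na(vals)] <- 0
    tibble(gene = panel$gene[i], exon_index = panel$exon_index[i],
           width = length(positions),
           mean_depth = mean(vals), min_depth = as.integer(min(vals)))
  })
  per_exon |> mutate(passes_min = .data$min_depth >= !!min_depth)
}

#' Flag exons failing the minimum-coverage rule
#'
#' @param stats Output of [exon_coverage()].
#' @param min_depth Threshold in reads (default 50).
#' @return Tibble of failing `(gene, exon_index)` pairs.
#' @export
flag_failing_exons <- function(stats, min_depth = 50) {
  if (!nrow(stats)) stopf("empty coverage statistics")
  stats |>
    filter(.data$min_depth < !!min_depth) |>
    select("gene", "exon_index")
}

#' Exons that fail consistently across a cohort
#'
#' An exon is consistently poor when it fails the minimum rule in more than
#' `fraction` of the supplied samples; such exons are excluded from CNV
#' calling.
#'
#' @param depths Per-position depth table covering several samples.
#' @param panel A [gene_panel()].
#' @param sample_ids Samples to evaluate (default: all in `depths`).
#' @param min_depth Per-position threshold (default 50).
#' @param fraction Failure fraction above which an exon is excluded
#'   (default 0.5).
#' @return Tibble of `(gene, exon_index)` to exclude.
#' @export
consistently_failing_exons <- function(depths, panel, sample_ids = NULL,
                                       min_depth = 50, fraction = 0.5) {
  sample_ids <- sample_ids %||% unique(depths$sample_id)
  fails <- purrr::map_dfr(sample_ids, function(s) {
    exon_coverage(depths, panel, s, min_depth = min_depth) |>
      mutate(sample_id = s)
  })
  fails |>
    group_by(.data$gene, .data$exon_index) |>
    summarise(fail_frac = mean(!.data$passes_min), .groups = "drop") |>
    filter(.data$fail_frac > fraction) |>
    select("gene", "exon_index")
}

#' Coverage profile by distance into the flanking introns
#'
#' For each distance d = 1..`max_flank` outside an exon boundary, reports the
#' mean depth over all positions exactly d bp outside an exon, and the
#' fraction of flank regions of size d (two per exon, one per side) whose
#' minimum depth is at least `min_depth`. Capture coverage decays with
#' distance from the exon-intron boundary, so the fraction is non-increasing
#' in d. Distances here are raw (not truncated at intron midpoints): the
#' profile describes the capture chemistry, not the calling convention.
#'
#' @inheritParams exon_coverage
#' @param max_flank Largest distance (bp) to profile (default 200).
#' @return Tibble with `distance`, `mean_depth`, `fraction_ge_min`.
#' @export
flank_coverage_profile <- function(depths, panel, sample_id,
                                   max_flank = 200, min_depth = 50) {
  stopifnot(inherits(panel, "gene_panel"), max_flank >= 1)
  d <- depths |> filter(.data$sample_id == !!sample_id)
  if (!nrow(d)) stopf("no depth records for sample '%s'", sample_id)
  lookup <- split(setNames(d$depth, d$pos), d$chrom)
  dist <- seq_len(max_flank)
  grid <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    bind_rows(
      tibble(region = paste0(panel$gene[i], ":", panel$exon_index[i], ":L"),
             chrom = panel$chrom[i], distance = dist,
             pos = panel$start[i] - dist),
      tibble(region = paste0(panel$gene[i], ":", panel$exon_index[i], ":R"),
             chrom = panel$chrom[i], distance = dist,
             pos = panel$end[i] - 1L + dist)
    )
  })
  grid$depth <- purrr::map2_dbl(grid$chrom, grid$pos, function(ch, p) {
    v <- lookup[[ch]][as.character(p)]
    if (is.null(v) || is.na(v)) 0 else v
  })
  grid <- grid |>
    group_by(.data$region) |>
    arrange(.data$distance, .by_group = TRUE) |>
    mutate(run_min = cummin(.data$depth)) |>
    ungroup()
  grid |>
    group_by(.data$distance) |>
    summarise(mean_depth = mean(.data$depth),
              fraction_ge_min = mean(.data$run_min >= min_depth),
              .groups = "drop")
}

#' Read / write per-position depth TSV
#'
#' The on-disk dialect is a four-column TSV (`sample_id`, `chrom`, `pos`,
#' `depth`) with a `#`-prefixed header, as emitted by standard depth tools
#' after light reshaping.
#'
#' @param path File path.
#' @return A tibble of per-position depths.
#' @export
read_depths_tsv <- function(path) {
  out <- read_tsv_hash(path)
  out |> mutate(pos = as.integer(.data$pos), depth = as.integer(.data$depth),
                sample_id = as.character(.data$sample_id),
                chrom = as.character(.data$chrom))
}

#' @rdname read_depths_tsv
#' @param depths Depth tibble to write.
#' @export
write_depths_tsv <- function(depths, path) {
  write_tsv_hash(depths[, c("sample_id", "chrom", "pos", "depth")], path)
}
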