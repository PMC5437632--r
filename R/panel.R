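#' Gene panel representation
#'
#' A gene panel is a tibble of exon target regions with one row per exon:
#' `chrom`, `start` (0-based inclusive), `end` (0-based exclusive), `gene`,
#' `exon_index` (1-based within the gene's canonical transcript), `strand`,
#' plus the effective flank extents `lflank`/`rflank` (bp of intronic flank
#' assigned to the left/right of each exon after midpoint truncation in short
#' introns). Coordinates are BED-native half-open throughout; 1-based
#' coordinates appear only in variant records (VCF-native).
#'
#' @param regions A data frame with columns `chrom`, `start`, `end`, `gene`,
#'   `exon_index`, and optionally `strand` (defaults to `"+"`).
#' @param flank_bp Non-negative integer: nominal intronic flank captured
#'   around each exon (default 50 bp, the width routinely analysed for
#'   splice-region variants on capture panels).
#' @return A `gene_panel` tibble sorted by (chrom, start).
#' @export
gene_panel <- function(regions, flank_bp = 50) {
  stopifnot(is.data.frame(regions))
  needed <- c("chrom", "start", "end", "gene", "exon_index")
  missing_cols <- setdiff(needed, names(regions))
  if (length(missing_cols)) {
    stopf("panel regions missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(flank_bp) || length(flank_bp) != 1L || is.na(flank_bp) || flank_bp < 0) {
    stopf("flank_bp must be a single non-negative number")
  }
  x <- as_tibble(regions)
  if (!"strand" %in% names(x)) x$strand <- "+"
  x <- x |>
    mutate(
      chrom = as.character(.data$chrom),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      gene = as.character(.data$gene),
      exon_index = as.integer(.data$exon_index),
      strand = as.character(.data$strand)
    )
  validate_panel_regions(x)
  x <- arrange(x, .data$chrom, .data$start)
  x <- compute_flanks(x, as.integer(flank_bp))
  structure(x, class = c("gene_panel", class(tibble())),
            flank_bp = as.integer(flank_bp))
}

validate_panel_regions <- function(x) {
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stopf("invalid region (end <= start) for %s exon %d",
          x$gene[bad[1]], x$exon_index[bad[1]])
  }
  if (any(x$exon_index < 1L)) stopf("exon_index must be >= 1")
  dup <- x |> count(.data$gene, .data$exon_index) |> filter(n > 1L)
  if (nrow(dup)) {
    stopf("duplicate (gene, exon_index): %s exon %d", dup$gene[1], dup$exon_index[1])
  }
  multi_strand <- x |>
    group_by(.data$gene) |>
    summarise(k = dplyr::n_distinct(.data$strand), .groups = "drop") |>
    filter(.data$k > 1L)
  if (nrow(multi_strand)) {
    stopf("gene %s has exons on more than one strand", multi_strand$gene[1])
  }
  # within-gene exon intervals must be disjoint
  ov <- x |>
    arrange(.data$gene, .data$chrom, .data$start) |>
    group_by(.data$gene, .data$chrom) |>
    mutate(prev_end = lag(.data$end)) |>
    ungroup() |>
    filter(!is.na(.data$prev_end) & .data$start < .data$prev_end)
  if (nrow(ov)) {
    stopf("overlapping exons within gene %s", ov$gene[1])
  }
  invisible(x)
}

# Flank extents: nominal flank_bp on each side, truncated at the midpoint of
# short introns so every intronic position maps to at most one exon's flank.
compute_flanks <- function(x, flank_bp) {
  x <- x |>
    arrange(.data$gene, .data$chrom, .data$start) |>
    group_by(.data$gene, .data$chrom) |>
    mutate(
      gap_right = lead(.data$start) - .data$end,
      gap_left = .data$start - lag(.data$end)
    ) |>
    ungroup() |>
    mutate(
      rflank = pmin(flank_bp, if_else(is.na(.data$gap_right),
                                      Inf, as.numeric(.data$gap_right %/% 2L))),
      lflank = pmin(flank_bp, if_else(is.na(.data$gap_left),
                                      Inf, as.numeric(.data$gap_left - .data$gap_left %/% 2L)))
    ) |>
    mutate(rflank = as.integer(.data$rflank), lflank = as.integer(.data$lflank)) |>
    select(-"gap_right", -"gap_left") |>
    arrange(.data$chrom, .data$start)
  x
}

#' Load a gene panel from BED
#'
#' Reads a 4+ column BED file whose name field encodes gene and exon as
#' `GENE_exonN`, and returns a [gene_panel()]. Column 6, when present, is
#' taken as the strand.
#'
#' @param bed_path Path to a BED file.
#' @param flank_bp Nominal intronic flank in bp (default 50).
#' @return A `gene_panel` tibble.
#' @export
load_panel <- function(bed_path, flank_bp = 50) {
  if (!file.exists(bed_path)) stopf("BED file not found: %s", bed_path)
  lines <- readLines(bed_path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) stopf("BED file %s contains no records", bed_path)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  parse_one <- function(i) {
    p <- parts[[i]]
    ln <- rows[i]
    if (length(p) < 4L) stopf("malformed BED line %d: fewer than 4 columns", ln)
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end)) {
      stopf("malformed BED line %d: non-numeric coordinates", ln)
    }
    if (end <= start) stopf("malformed BED line %d: end <= start", ln)
    m <- regmatches(p[4], regexec("^(.+)_exon([0-9]+)$", p[4]))[[1]]
    if (length(m) != 3L) {
      stopf("malformed BED line %d: name '%s' is not GENE_exonN", ln, p[4])
    }
    tibble(chrom = p[1], start = start, end = end,
           gene = m[2], exon_index = as.integer(m[3]),
           strand = if (length(p) >= 6L && p[6] %in% c("+", "-")) p[6] else "+")
  }
  regions <- purrr::map_dfr(seq_along(rows), parse_one)
  gene_panel(regions, flank_bp = flank_bp)
}

#' Write a gene panel back to BED
#'
#' Emits 6-column BED with the `GENE_exonN` name dialect; [load_panel()] on
#' the result round-trips the region list exactly.
#'
#' @param panel A `gene_panel`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  lines <- sprintf("%s\t%d\t%d\t%s_exon%d\t0\t%s",
                   panel$chrom, panel$start, panel$end,
                   panel$gene, panel$exon_index, panel$strand)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Summarise a panel by gene
#'
#' @param panel A `gene_panel`.
#' @return A tibble with `gene`, `n_exons`, `total_bp`.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "gene_panel"))
  panel |>
    as_tibble() |>
    group_by(.data$gene) |>
    summarise(n_exons = n(), total_bp = sum(.data$end - .data$start),
              .groups = "drop")
}

#' Classify genomic positions against a panel
#'
#' Every position is `exonic` (inside an exon interval), `noncoding_flank`
#' (inside an exon's effective intronic flank, see [gene_panel()]), or
#' `off_target`. Exonic status wins over any other exon's flank. Positions on
#' chromosomes absent from the panel are `off_target` (reported once via a
#' message, not an error).
#'
#' @param panel A `gene_panel`.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions (same length as `chrom`, or
#'   one of the two may have length 1).
#' @return Character vector in `c("exonic", "noncoding_flank", "off_target")`.
#' @export
classify_position <- function(panel, chrom, pos) {
  stopifnot(inherits(panel, "gene_panel"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- rep("off_target", n)
  unknown <- setdiff(unique(chrom), unique(panel$chrom))
  unknown <- setdiff(unknown, .germpanel_state$warned_chroms)
  if (length(unknown)) {
    inform(sprintf("classify_position: chromosome(s) not in panel treated as off_target: %s",
                   paste(unknown, collapse = ", ")))
    .germpanel_state$warned_chroms <- c(.germpanel_state$warned_chroms, unknown)
  }
  exonic <- rep(FALSE, n)
  flank <- rep(FALSE, n)
  for (i in seq_len(nrow(panel))) {
    on_chrom <- chrom == panel$chrom[i]
    if (!any(on_chrom)) next
    s <- panel$start[i]; e <- panel$end[i]
    exonic <- exonic | (on_chrom & pos >= s & pos < e)
    flank <- flank | (on_chrom & ((pos >= s - panel$lflank[i] & pos < s) |
                                    (pos >= e & pos < e + panel$rflank[i])))
  }
  out[flank] <- "noncoding_flank"
  out[exonic] <- "exonic"
  out
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d exons across %d gene(s), flank_bp = %d\n",
              nrow(x), length(unique(x$gene)), attr(x, "flank_bp")))
  NextMethod()
}
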