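#' Refine CNV segment boundaries with structural-variant evidence
#'
#' Coverage-derived CNV segments have exon-level resolution; split-read /
#' read-pair SV records carry base-level breakpoints. Each segment is matched
#' to the SV record of the same direction (DEL to loss, DUP to gain) that
#' maximizes reciprocal overlap with the segment's genomic interval (first
#' exon start to last exon end), provided the reciprocal overlap reaches
#' `min_reciprocal` and the SV has at least `min_support` supporting reads.
#' Matched segments gain `refined_start`/`refined_end` from the SV and a
#' `boundary_note` locating each breakpoint relative to exon anatomy (e.g. a
#' deletion called over exons 11-18 whose SV starts mid-exon-10 is noted as
#' starting within exon 10 and ending 5' of exon 18). Unmatched segments
#' pass through with `NA` refinement. Refinement never alters the base
#' segment's direction, scope, fold change or p-value.
#'
#' Ties in reciprocal overlap are broken by higher support, then smaller SV
#' interval, then leftmost start, making the result independent of input
#' order.
#'
#' @param segments Segment tibble from [call_segments()] (needs `gene`,
#'   `first_exon`, `last_exon`, `direction`).
#' @param svs SV tibble: `chrom`, `start` (0-based), `end` (exclusive),
#'   `sv_type` (`DEL`/`DUP`), `support`.
#' @param panel A [gene_panel()] supplying exon coordinates.
#' @param min_support Minimum supporting read count (default 3).
#' @param min_reciprocal Minimum reciprocal overlap (default 0.5).
#' @return `segments` with `seg_start`, `seg_end`, `refined_start`,
#'   `refined_end`, `sv_support`, `boundary_note` added.
#' @export
reconcile <- function(segments, svs, panel, min_support = 3, min_reciprocal = 0.5) {
  stopifnot(inherits(panel, "gene_panel"))
  if (!nrow(segments)) {
    return(segments |> mutate(seg_start = integer(), seg_end = integer(),
                              refined_start = integer(), refined_end = integer(),
                              sv_support = integer(), boundary_note = character()))
  }
  svs <- as_tibble(svs)
  if (nrow(svs)) {
    if (!all(svs$sv_type %in% c("DEL", "DUP"))) {
      stopf("sv_type must be DEL or DUP (translocations/inversions are out of scope)")
    }
    if (any(svs$end <= svs$start)) stopf("SV record with end <= start")
    svs <- svs |> filter(.data$support >= min_support)
  }
  seg_coords <- segments |>
    mutate(.seg_id = row_number()) |>
    left_join(
      as_tibble(panel) |> select("chrom", "start", "end", "gene", "exon_index"),
      by = "gene", relationship = "many-to-many"
    ) |>
    filter(.data$exon_index >= .data$first_exon,
           .data$exon_index <= .data$last_exon) |>
    group_by(.data$.seg_id) |>
    summarise(chrom = first(.data$chrom), seg_start = min(.data$start),
              seg_end = max(.data$end), .groups = "drop")
  out <- segments |>
    mutate(.seg_id = row_number()) |>
    left_join(seg_coords, by = ".seg_id")

  match_one <- function(i) {
    dir_type <- if (out$direction[i] == "loss") "DEL" else "DUP"
    cand <- svs |> filter(.data$sv_type == dir_type, .data$chrom == out$chrom[i])
    if (!nrow(cand)) return(NULL)
    s1 <- out$seg_start[i]; e1 <- out$seg_end[i]
    ov <- pmax(0, pmin(e1, cand$end) - pmax(s1, cand$start))
    ro <- pmin(ov / (e1 - s1), ov / (cand$end - cand$start))
    cand <- cand |> mutate(ro = ro) |> filter(.data$ro >= min_reciprocal)
    if (!nrow(cand)) return(NULL)
    cand |>
      arrange(dplyr::desc(.data$ro), dplyr::desc(.data$support),
              .data$end - .data$start, .data$start) |>
      dplyr::slice(1L)
  }
  notes <- purrr::map(seq_len(nrow(out)), function(i) {
    best <- match_one(i)
    if (is.null(best)) {
      return(list(refined_start = NA_integer_, refined_end = NA_integer_,
                  sv_support = NA_integer_, boundary_note = NA_character_))
    }
    note <- paste0(
      "starts ", describe_breakpoint(panel, out$gene[i], best$start), "; ",
      "ends ", describe_breakpoint(panel, out$gene[i], best$end - 1L)
    )
    list(refined_start = as.integer(best$start), refined_end = as.integer(best$end),
         sv_support = as.integer(best$support), boundary_note = note)
  })
  out |>
    mutate(refined_start = purrr::map_int(notes, "refined_start"),
           refined_end = purrr::map_int(notes, "refined_end"),
           sv_support = purrr::map_int(notes, "sv_support"),
           boundary_note = purrr::map_chr(notes, "boundary_note")) |>
    select(-".seg_id")
}

# Locate a genomic position relative to a gene's exon anatomy, in transcript
# orientation: inside exon k -> "within exon k"; in the intron between two
# exons -> named by its flanking exons with the downstream (5'-of) exon
# called out, which is how breakpoints are described in review.
describe_breakpoint <- function(panel, gene, pos) {
  g <- as_tibble(panel) |> filter(.data$gene == !!gene) |> arrange(.data$start)
  if (!nrow(g)) return(sprintf("at position %d (gene not in panel)", pos))
  strand <- g$strand[1]
  inside <- which(pos >= g$start & pos < g$end)
  if (length(inside)) {
    e <- g$exon_index[inside[1]]
    w <- g$end[inside[1]] - g$start[inside[1]]
    mid <- pos > g$start[inside[1]] + 0.25 * w && pos < g$end[inside[1]] - 0.25 * w
    return(sprintf(if (mid) "in the middle of exon %d" else "within exon %d", e))
  }
  if (pos < g$start[1]) {
    side <- if (strand == "+") "upstream of" else "downstream of"
    return(sprintf("%s exon %d", side, g$exon_index[1]))
  }
  if (pos >= g$end[nrow(g)]) {
    side <- if (strand == "+") "downstream of" else "upstream of"
    return(sprintf("%s exon %d", side, g$exon_index[nrow(g)]))
  }
  left <- max(which(g$end <= pos))
  right <- left + 1L
  five_prime_of <- if (strand == "+") g$exon_index[right] else g$exon_index[left]
  sprintf("in the intron between exons %d and %d, 5' of exon %d",
          g$exon_index[left], g$exon_index[right], five_prime_of)
}

#' Read SV records
#'
#' Accepts the TSV dialect (`chrom`, `start`, `end`, `sv_type`, `support`)
#' or an uncompressed VCF with `SVTYPE` and `END` INFO keys (via vcfR);
#' supporting-read counts are taken from the `PE`/`SR` INFO fields when
#' present.
#'
#' @param path File path.
#' @return SV tibble with 0-based half-open coordinates.
#' @export
read_sv_records <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stopf("reading SV VCF requires the vcfR package; supply the TSV dialect instead")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
    info_get <- function(key) {
      m <- regmatches(fix$INFO, regexec(paste0("(?:^|;)", key, "=([^;]+)"), fix$INFO))
      purrr::map_chr(m, function(x) if (length(x) == 2L) x[2] else NA_character_)
    }
    pe <- suppressWarnings(as.integer(info_get("PE")))
    sr <- suppressWarnings(as.integer(info_get("SR")))
    support <- dplyr::coalesce(pe, 0L) + dplyr::coalesce(sr, 0L)
    return(tibble(chrom = fix$CHROM,
                  start = as.integer(fix$POS) - 1L,
                  end = as.integer(info_get("END")),
                  sv_type = info_get("SVTYPE"),
                  support = support))
  }
  out <- read_tsv_hash(path)
  out |> mutate(start = as.integer(.data$start), end = as.integer(.data$end),
                support = as.integer(.data$support), chrom = as.character(.data$chrom))
}
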