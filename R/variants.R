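#' Normalize variant representations
#'
#' Reduces each (pos, ref, alt) to a canonical minimal representation so that
#' different callers' padded encodings of the same indel unify: the shared
#' allele suffix is trimmed first, then the shared prefix (always keeping at
#' least one base of each allele), with `pos` advanced by the number of
#' prefix bases removed. Positions are 1-based (VCF-native).
#'
#' @param chrom,pos,ref,alt Parallel vectors describing variants.
#' @return Tibble with normalized `chrom`, `pos`, `ref`, `alt` and a `key`
#'   string `chrom:pos:ref>alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  bad <- ref == alt
  if (any(bad)) stopf("ref and alt are identical at %s:%d", chrom[which(bad)[1]], pos[which(bad)[1]])
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    stopf("alleles must be non-empty strings over A/C/G/T")
  }
  trim_one <- function(p, r, a) {
    rb <- strsplit(r, "", fixed = TRUE)[[1]]
    ab <- strsplit(a, "", fixed = TRUE)[[1]]
    # shared suffix first
    while (length(rb) > 1L && length(ab) > 1L && rb[length(rb)] == ab[length(ab)]) {
      rb <- rb[-length(rb)]; ab <- ab[-length(ab)]
    }
    # then shared prefix, advancing pos
    while (length(rb) > 1L && length(ab) > 1L && rb[1] == ab[1]) {
      rb <- rb[-1]; ab <- ab[-1]; p <- p + 1L
    }
    list(pos = p, ref = paste(rb, collapse = ""), alt = paste(ab, collapse = ""))
  }
  out <- purrr::pmap(list(pos, ref, alt), trim_one)
  tibble(
    chrom = chrom,
    pos = purrr::map_int(out, "pos"),
    ref = purrr::map_chr(out, "ref"),
    alt = purrr::map_chr(out, "alt")
  ) |>
    mutate(key = paste0(.data$chrom, ":", .data$pos, ":", .data$ref, ">", .data$alt))
}

#' Merge two callers' variant sets by union
#'
#' Call sets from the two callers are unified on normalized variant keys; a
#' variant reported by both keeps a single record with `callers = "A;B"`.
#' When both callers report, DP and VF are taken from caller A (declared
#' precedence); VF disagreements greater than `vf_discrepancy` are reported
#' via a message. Indels of 30 bp or longer are routed out of the SNV/indel
#' path (they belong to CNV/SV calling) and dropped with a message.
#'
#' @param calls_a,calls_b Data frames with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `DP`, `VF`.
#' @param vf_discrepancy VF difference (fraction) above which a shared call's
#'   caller disagreement is reported (default 0.10).
#' @param max_indel_bp Indel length at and above which records are rejected
#'   to the CNV/SV path (default 30).
#' @return Tibble of merged calls with `callers`, `DP`, `VF`, `variant_type`,
#'   and normalized coordinates plus `key`.
#' @export
union_merge <- function(calls_a, calls_b, vf_discrepancy = 0.10, max_indel_bp = 30) {
  prep <- function(calls, label) {
    if (is.null(calls) || !nrow(calls)) {
      return(tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), key = character(), DP = integer(),
                    VF = double(), caller = character()))
    }
    norm <- normalize_variant(calls$chrom, calls$pos, calls$ref, calls$alt)
    out <- norm |> mutate(DP = as.integer(calls$DP), VF = as.numeric(calls$VF),
                          caller = label)
    if (anyDuplicated(out$key)) {
      stopf("caller %s call set contains duplicate normalized variants", label)
    }
    out
  }
  a <- prep(calls_a, "A")
  b <- prep(calls_b, "B")
  both <- bind_rows(a, b)
  if (!nrow(both)) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), key = character(), callers = character(),
                  DP = integer(), VF = double(), variant_type = character()))
  }
  conflict <- both |>
    distinct(.data$chrom, .data$pos, .data$alt, .data$ref) |>
    count(.data$chrom, .data$pos, .data$alt) |>
    filter(n > 1L)
  if (nrow(conflict)) {
    stopf("inconsistent normalization: conflicting ref alleles at %s:%d",
          conflict$chrom[1], conflict$pos[1])
  }
  shared <- intersect(a$key, b$key)
  if (length(shared)) {
    cmp <- inner_join(a |> select("key", vf_a = "VF"),
                      b |> select("key", vf_b = "VF"), by = "key") |>
      filter(abs(.data$vf_a - .data$vf_b) > vf_discrepancy)
    if (nrow(cmp)) {
      inform(sprintf("union_merge: %d shared call(s) with VF discrepancy > %.0f percentage points",
                     nrow(cmp), 100 * vf_discrepancy))
    }
  }
  merged <- both |>
    group_by(.data$key) |>
    arrange(.data$caller, .by_group = TRUE) |>
    summarise(chrom = first(.data$chrom), pos = first(.data$pos),
              ref = first(.data$ref), alt = first(.data$alt),
              callers = paste(sort(unique(.data$caller)), collapse = ";"),
              DP = first(.data$DP), VF = first(.data$VF),
              .groups = "drop") |>
    mutate(variant_type = if_else(nchar(.data$ref) == nchar(.data$alt), "SNV", "indel")) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    select("chrom", "pos", "ref", "alt", "key", "callers", "DP", "VF", "variant_type")
  long <- abs(nchar(merged$ref) - nchar(merged$alt)) >= max_indel_bp &
    merged$variant_type == "indel"
  if (any(long)) {
    inform(sprintf("union_merge: %d indel(s) of >= %d bp routed to the CNV/SV path and dropped",
                   sum(long), max_indel_bp))
    merged <- merged[!long, ]
  }
  merged
}

#' Apply region-class-dependent DP/VF filters
#'
#' A call passes only if it lies on target (exonic or in an exon's intronic
#' flank), its total depth reaches `dp_min`, and its alt-allele fraction
#' reaches the class threshold: `vf_exonic` for exonic SNVs/indels,
#' `vf_noncoding` for everything else. All thresholds are inclusive. Failure
#' reasons are assigned in order depth, VF, region.
#'
#' @param calls Merged call tibble (see [union_merge()]) with 1-based `pos`.
#' @param panel A [gene_panel()] used to assign `region_class`.
#' @param dp_min Minimum total depth in reads (default 50).
#' @param vf_exonic Minimum VF for exonic calls (default 0.20).
#' @param vf_noncoding Minimum VF for non-exonic calls (default 0.25).
#' @return `calls` with `region_class`, `vf_threshold`, `filter_status`
#'   (`pass`, `fail_depth`, `fail_vf`, `fail_region`) added.
#' @export
apply_filters <- function(calls, panel, dp_min = 50, vf_exonic = 0.20,
                          vf_noncoding = 0.25) {
  stopifnot(inherits(panel, "gene_panel"))
  if (any(calls$VF < 0 | calls$VF > 1, na.rm = TRUE)) stopf("VF outside [0, 1]")
  if (!nrow(calls)) {
    return(calls |> mutate(region_class = character(), vf_threshold = double(),
                           filter_status = character()))
  }
  calls |>
    mutate(
      region_class = classify_position(panel, .data$chrom, .data$pos - 1L),
      vf_threshold = if_else(.data$region_class == "exonic", vf_exonic, vf_noncoding),
      filter_status = case_when(
        .data$DP < dp_min ~ "fail_depth",
        .data$VF < .data$vf_threshold ~ "fail_vf",
        .data$region_class == "off_target" ~ "fail_region",
        TRUE ~ "pass"
      )
    )
}

#' Assign zygosity from the alt-allele fraction
#'
#' Germline heterozygotes are expected at VF between 0.40 and 0.60 and
#' homozygotes at VF of at least 0.90; anything between the bands is
#' reported as ambiguous rather than auto-resolved.
#'
#' @param calls Call tibble with a `VF` column.
#' @return `calls` with a `zygosity` column.
#' @export
assign_zygosity <- function(calls) {
  calls |>
    mutate(zygosity = case_when(
      .data$VF >= 0.40 & .data$VF <= 0.60 ~ "heterozygous",
      .data$VF >= 0.90 ~ "homozygous",
      TRUE ~ "ambiguous"
    ))
}

#' Flag borderline passing calls
#'
#' A passing call is borderline when it barely clears the filter: DP within
#' `dp_margin` reads above `dp_min`, or VF within `vf_margin` above its
#' region-class threshold. Borderline calls explain most replicate-to-
#' replicate discordance in the noncoding flanks.
#'
#' @param calls Filtered call tibble (needs `DP`, `VF`, `vf_threshold`,
#'   `filter_status`).
#' @param dp_min Depth filter the calls were passed through (default 50).
#' @param dp_margin Reads above `dp_min` still considered borderline
#'   (default 10).
#' @param vf_margin VF above the class threshold still considered borderline
#'   (default 0.03).
#' @return `calls` with a logical `borderline` column (`NA` for non-passing
#'   calls).
#' @export
flag_borderline <- function(calls, dp_min = 50, dp_margin = 10, vf_margin = 0.03) {
  calls |>
    mutate(borderline = if_else(
      .data$filter_status == "pass",
      .data$DP < dp_min + dp_margin | .data$VF < .data$vf_threshold + vf_margin,
      NA
    ))
}

#' Read caller output as a call tibble
#'
#' Accepts either the TSV dialect (`chrom`, `pos`, `ref`, `alt`, `DP`, `VF`,
#' optional `caller`) or an uncompressed VCF 4.2 file (extension `.vcf`),
#' whose DP is taken from FORMAT `DP` (or INFO `DP`) and VF from FORMAT `AD`
#' (alt reads / total) or a `VF`/`AF` field. VCF parsing uses the vcfR
#' package.
#'
#' @param path Path to a TSV or VCF file.
#' @return Tibble of calls with 1-based `pos`.
#' @export
read_caller_calls <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    return(read_caller_vcf(path))
  }
  out <- read_tsv_hash(path)
  out |> mutate(pos = as.integer(.data$pos), DP = as.integer(.data$DP),
                VF = as.numeric(.data$VF), chrom = as.character(.data$chrom))
}

read_caller_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the vcfR package; supply the TSV dialect instead")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- suppressWarnings(vcfR::extract.gt(v, element = "AD"))
  n <- nrow(fix)
  DP <- rep(NA_integer_, n); VF <- rep(NA_real_, n)
  if (!is.null(dp) && ncol(dp) >= 1L) DP <- as.integer(dp[, 1L])
  if (!is.null(ad) && ncol(ad) >= 1L) {
    parts <- strsplit(ad[, 1L], ",", fixed = TRUE)
    alt_reads <- purrr::map_dbl(parts, function(p) {
      if (length(p) < 2L || anyNA(p)) NA_real_ else as.numeric(p[2])
    })
    tot <- purrr::map_dbl(parts, function(p) {
      if (length(p) < 2L || anyNA(p)) NA_real_ else sum(as.numeric(p))
    })
    VF <- alt_reads / tot
    DP <- if_else(is.na(DP), as.integer(round(tot)), DP)
  }
  tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
         ref = fix$REF, alt = fix$ALT,
         DP = unname(DP), VF = unname(VF))
}

#' Write a filtered call table
#'
#' @param calls Call tibble.
#' @param path Output TSV path (header line begins with `#`).
#' @export
write_calls_tsv <- function(calls, path) {
  write_tsv_hash(calls, path)
}
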