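mk_calls <- function(...) tibble::tribble(...)

test_that("allele normalization trims suffix then prefix and adjusts pos", {
  out <- normalize_variant("chr1", 100L, "AT", "AG")
  expect_equal(out$pos, 101L)
  expect_equal(out$ref, "T")
  expect_equal(out$alt, "G")
  expect_error(normalize_variant("chr1", 100L, "A", "A"), "identical")
  expect_error(normalize_variant("chr1", 100L, "AN", "A"), "A/C/G/T")

  # random padded representations of one indel all reduce to the same key
  set.seed(21)
  base <- list(pos = 500L, ref = "GAC", alt = "G") # 2 bp deletion
  for (i in 1:50) {
    left <- paste(sample(c("A", "C", "G", "T"), sample(0:3, 1), replace = TRUE),
                  collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), sample(0:3, 1), replace = TRUE),
                   collapse = "")
    padded_ref <- paste0(left, base$ref, right)
    padded_alt <- paste0(left, base$alt, right)
    padded_pos <- base$pos - nchar(left)
    got <- normalize_variant("chr1", padded_pos, padded_ref, padded_alt)
    orc <- oracle_normalize(padded_pos, padded_ref, padded_alt)
    expect_equal(got$pos, orc$pos)
    expect_equal(got$ref, orc$ref)
    expect_equal(got$alt, orc$alt)
    expect_equal(got$key, paste0("chr1:", base$pos, ":", base$ref, ">", base$alt))
  }
})

test_that("union merge is an idempotent, commutative set union on keys", {
  a <- mk_calls(
    ~chrom, ~pos, ~ref, ~alt, ~DP, ~VF,
    "chr1", 100L, "A", "G", 120L, 0.48,
    "chr1", 200L, "C", "T", 90L, 0.52,
    "chr1", 300L, "G", "A", 80L, 0.55
  )
  b <- mk_calls(
    ~chrom, ~pos, ~ref, ~alt, ~DP, ~VF,
    "chr1", 100L, "A", "G", 110L, 0.50,
    "chr1", 400L, "T", "C", 70L, 0.45
  )
  m <- union_merge(a, b)
  expect_equal(nrow(m), 4L)
  expect_equal(m$callers[m$pos == 100L], "A;B")
  expect_equal(m$DP[m$pos == 100L], 120L) # caller A precedence
  expect_equal(sort(m$callers), sort(c("A;B", "A", "A", "B")))
  # commutative up to provenance labels
  m2 <- union_merge(b, a)
  expect_equal(m$key, m2$key)
  # disjoint sets of sizes 3 and 2 give 5 records
  expect_equal(nrow(union_merge(a, mk_calls(
    ~chrom, ~pos, ~ref, ~alt, ~DP, ~VF,
    "chr1", 500L, "A", "C", 60L, 0.5,
    "chr1", 600L, "G", "T", 60L, 0.5
  ))), 5L)
  # idempotent: merging a set with itself is the set
  expect_equal(nrow(union_merge(a, a)), nrow(a))
})

test_that("union merge matches a brute-force set union on random call sets", {
  set.seed(31)
  universe <- tibble::tibble(
    chrom = "chr1", pos = sample(1000:9999, 60),
    ref = sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  )
  universe$alt <- vapply(universe$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  for (trial in 1:10) {
    ia <- sample(60, sample(5:30, 1))
    ib <- sample(60, sample(5:30, 1))
    a <- universe[ia, ] |> dplyr::mutate(DP = 100L, VF = 0.5)
    b <- universe[ib, ] |> dplyr::mutate(DP = 100L, VF = 0.5)
    m <- union_merge(a, b)
    expect_equal(nrow(m), length(union(ia, ib)))
    expect_equal(sum(m$callers == "A;B"), length(intersect(ia, ib)))
  }
})

test_that("conflicting ref alleles at one site are a normalization error", {
  a <- mk_calls(~chrom, ~pos, ~ref, ~alt, ~DP, ~VF, "chr1", 100L, "A", "G", 50L, 0.5)
  b <- mk_calls(~chrom, ~pos, ~ref, ~alt, ~DP, ~VF, "chr1", 100L, "C", "G", 50L, 0.5)
  expect_error(union_merge(a, b), "inconsistent normalization")
})

test_that("long indels are routed out of the SNV/indel path", {
  ins <- paste(rep("A", 35), collapse = "")
  a <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "G",
                      alt = paste0("G", ins), DP = 80L, VF = 0.5)
  expect_message(m <- union_merge(a, NULL), "CNV/SV path")
  expect_equal(nrow(m), 0L)
})

test_that("DP/VF filters apply inclusive thresholds by region class", {
  panel <- toy_panel(flank_bp = 50)
  # exon1 spans 0-based [1000,1200); VCF pos is 1-based
  calls <- tibble::tibble(
    chrom = "chr1",
    pos = c(1001L, 1225L, 1001L, 1001L, 5000L),
    ref = "A", alt = "G",
    key = paste0("k", 1:5),
    DP = c(50L, 100L, 49L, 100L, 500L),
    VF = c(0.20, 0.22, 0.60, 0.19, 0.50),
    variant_type = "SNV"
  )
  f <- apply_filters(calls, panel)
  expect_equal(f$region_class,
               c("exonic", "noncoding_flank", "exonic", "exonic", "off_target"))
  expect_equal(f$filter_status,
               c("pass", "fail_vf", "fail_depth", "fail_vf", "fail_region"))
  # noncoding boundary is inclusive at 0.25
  f2 <- apply_filters(dplyr::mutate(calls[2, ], VF = 0.25), panel)
  expect_equal(f2$filter_status, "pass")
})

test_that("raising any filter threshold never grows the pass set", {
  set.seed(41)
  panel <- toy_panel()
  calls <- tibble::tibble(
    chrom = "chr1",
    pos = sample(900:3400, 300, replace = FALSE),
    ref = "A", alt = "G", key = paste0("k", 1:300),
    DP = sample(10:300, 300, replace = TRUE),
    VF = runif(300), variant_type = "SNV"
  )
  base <- apply_filters(calls, panel)
  for (tweak in list(c(60, 0.20, 0.25), c(50, 0.30, 0.25), c(50, 0.20, 0.35))) {
    harder <- apply_filters(calls, panel, dp_min = tweak[1],
                            vf_exonic = tweak[2], vf_noncoding = tweak[3])
    expect_true(all(harder$key[harder$filter_status == "pass"] %in%
                      base$key[base$filter_status == "pass"]))
  }
  expect_false(any(base$region_class == "off_target" &
                     base$filter_status == "pass"))
})

test_that("zygosity bands follow the heterozygous 40-60% convention", {
  calls <- tibble::tibble(VF = c(0.50, 1.00, 0.75, 0.40, 0.60, 0.90, 0.89))
  z <- assign_zygosity(calls)
  expect_equal(z$zygosity, c("heterozygous", "homozygous", "ambiguous",
                             "heterozygous", "heterozygous", "homozygous",
                             "ambiguous"))
})

test_that("borderline flags match a direct margin predicate on a DP/VF grid", {
  grid <- tidyr::expand_grid(DP = seq(50L, 80L, by = 2L),
                             VF = seq(0.25, 0.35, by = 0.01)) |>
    dplyr::mutate(vf_threshold = 0.25, filter_status = "pass")
  out <- flag_borderline(grid)
  expect_equal(out$borderline, grid$DP < 60 | grid$VF < 0.28)
  # the worked noncoding example: DP 51, VF 0.26 barely passes
  one <- flag_borderline(tibble::tibble(DP = 51L, VF = 0.26,
                                        vf_threshold = 0.25,
                                        filter_status = "pass"))
  expect_true(one$borderline)
  solid <- flag_borderline(tibble::tibble(DP = 500L, VF = 0.50,
                                          vf_threshold = 0.20,
                                          filter_status = "pass"))
  expect_false(solid$borderline)
})
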