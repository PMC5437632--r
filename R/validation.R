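#' Exact binomial detection power
#'
#' Probability that a variant present at true allele fraction `true_vf` is
#' detected at sequencing depth `depth` under the rule "the observed allele
#' fraction clears the filter threshold": with alt-read count
#' X ~ Binomial(depth, true_vf), power = P(X >= ceiling(vf_threshold *
#' depth)). The tail is computed exactly (no normal approximation — the
#' depths of interest are small). At 17 reads and a heterozygous fraction of
#' 0.5 against a 20% threshold the power is 0.9936, i.e. 99% sensitivity.
#'
#' Note the ceiling makes power non-monotone in depth (sawtooth): see
#' [min_depth_for_power()].
#'
#' @param depth Integer vector of read depths (>= 1).
#' @param true_vf True allele fraction(s) in (0, 1].
#' @param vf_threshold Calling threshold(s) on the observed fraction.
#' @return Numeric vector of sensitivities in `[0, 1]`.
#' @export
detection_power <- function(depth, true_vf, vf_threshold) {
  n <- max(length(depth), length(true_vf), length(vf_threshold))
  depth <- rep_len(as.integer(depth), n)
  true_vf <- rep_len(as.numeric(true_vf), n)
  vf_threshold <- rep_len(as.numeric(vf_threshold), n)
  if (any(depth < 1L)) stopf("depth must be >= 1")
  if (any(true_vf <= 0 | true_vf > 1)) stopf("true_vf must lie in (0, 1]")
  k <- as.integer(ceiling(vf_threshold * depth))
  over <- k > depth
  if (any(over)) {
    warn("vf_threshold * depth exceeds depth: sensitivity is 0")
  }
  out <- ifelse(k <= 0L, 1, pbinom(pmax(k, 1L) - 1L, depth, true_vf, lower.tail = FALSE))
  out[over] <- 0
  out
}

#' Minimum depth achieving a sensitivity target
#'
#' Because the detection rule uses `ceiling(vf_threshold * depth)` alt
#' reads, power oscillates as depth grows (isolated lower depths can
#' transiently exceed the target before dipping back under it). The
#' operationally meaningful answer is the smallest depth from which the
#' target is met at that depth *and every greater depth*; for a heterozygous
#' variant (VF 0.5) against a 20% threshold at 99% sensitivity that depth is
#' 17.
#'
#' @param true_vf True allele fraction; must exceed `vf_threshold` or power
#'   never converges to 1.
#' @param vf_threshold Calling threshold on the observed fraction.
#' @param target Sensitivity target in (0, 1) (default 0.99).
#' @param max_depth Search horizon (default 100000).
#' @return Smallest stable depth (integer).
#' @export
min_depth_for_power <- function(true_vf, vf_threshold, target = 0.99,
                                max_depth = 100000L) {
  if (target <= 0 || target >= 1) stopf("target must lie in (0, 1)")
  if (true_vf <= vf_threshold) {
    stopf("true_vf (%.3f) must exceed vf_threshold (%.3f): power does not converge to 1",
          true_vf, vf_threshold)
  }
  # scan until the power has stayed above target long enough that the
  # binomial concentration bound rules out any later dip
  horizon <- 1L
  repeat {
    horizon <- min(horizon * 32L, max_depth)
    p <- detection_power(seq_len(horizon), true_vf, vf_threshold)
    # Chernoff bound on the miss probability at depth d
    kl <- vf_threshold * log(vf_threshold / true_vf) +
      (1 - vf_threshold) * log((1 - vf_threshold) / (1 - true_vf))
    bound_ok <- exp(-horizon * kl) < (1 - target) / 10
    fails <- which(p < target)
    if (!length(fails)) return(1L)
    if (bound_ok || horizon == max_depth) {
      d <- max(fails) + 1L
      if (d > horizon) stopf("no stable depth found below max_depth = %d", max_depth)
      return(d)
    }
  }
}

#' Tabulate detection power over a grid
#'
#' @param depths Integer vector of depths.
#' @param true_vfs Numeric vector of true allele fractions.
#' @param vf_threshold Calling threshold (single value, default 0.20).
#' @return Tibble `depth`, `true_vf`, `vf_threshold`, `sensitivity`.
#' @export
power_table <- function(depths, true_vfs, vf_threshold = 0.20) {
  grid <- tidyr::expand_grid(depth = as.integer(depths), true_vf = true_vfs)
  grid |>
    mutate(vf_threshold = vf_threshold,
           sensitivity = detection_power(.data$depth, .data$true_vf, vf_threshold))
}

#' Characterize false-positive noise from control replicates
#'
#' Pre-filter call sets from replicated control samples are reduced to one
#' row per (control, variant); a call is *reproducible* when its normalized
#' key appears in every replicate of its control, and a noise artifact
#' otherwise. For each candidate threshold pair the surviving count is the
#' number of non-reproducible calls that would still pass DP/VF filtering in
#' at least one replicate — the operative question being whether the
#' production thresholds (DP 50, VF 0.20 exonic / 0.25 noncoding) eliminate
#' all of them. Controls with a single replicate are excluded with a
#' warning.
#'
#' @param calls Tibble of pre-filter calls with columns `control_id`,
#'   `replicate_id`, `key`, `DP`, `VF`, `region_class`.
#' @param dp_min,vf_exonic,vf_noncoding Production thresholds
#'   (defaults 50, 0.20, 0.25).
#' @param threshold_grid Optional tibble of candidate thresholds with
#'   columns `dp_min`, `vf_exonic`, `vf_noncoding`; the production pair is
#'   always included.
#' @return Object of class `noise_profile`: list with `calls` (per-variant
#'   table with `reproducible`), `surviving` (per threshold pair), and
#'   `thresholds_ok` (TRUE when the production pair leaves zero surviving
#'   noise calls).
#' @export
characterize_noise <- function(calls, dp_min = 50, vf_exonic = 0.20,
                               vf_noncoding = 0.25, threshold_grid = NULL) {
  needed <- c("control_id", "replicate_id", "key", "DP", "VF", "region_class")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols)) {
    stopf("noise call table missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  rep_counts <- calls |>
    distinct(.data$control_id, .data$replicate_id) |>
    count(.data$control_id, name = "n_reps")
  single <- rep_counts |> filter(.data$n_reps < 2L)
  if (nrow(single)) {
    warn(sprintf("excluding %d control(s) with a single replicate", nrow(single)))
    calls <- calls |> anti_join(single |> select("control_id"), by = "control_id")
    rep_counts <- rep_counts |> filter(.data$n_reps >= 2L)
  }
  if (!nrow(calls)) stopf("no controls with >= 2 replicates")
  per_variant <- calls |>
    group_by(.data$control_id, .data$key) |>
    summarise(region_class = first(.data$region_class),
              n_seen = dplyr::n_distinct(.data$replicate_id),
              DP = max(.data$DP), VF = max(.data$VF),
              .groups = "drop") |>
    left_join(rep_counts, by = "control_id") |>
    mutate(reproducible = .data$n_seen == .data$n_reps)
  # occurrence-level pass check for the surviving counts
  occ <- calls |>
    left_join(per_variant |> select("control_id", "key", "reproducible"),
              by = c("control_id", "key"))
  grid <- tibble(dp_min = dp_min, vf_exonic = vf_exonic, vf_noncoding = vf_noncoding)
  if (!is.null(threshold_grid)) grid <- distinct(bind_rows(grid, threshold_grid))
  surviving <- purrr::pmap_dfr(grid, function(dp_min, vf_exonic, vf_noncoding) {
    surv <- occ |>
      filter(!.data$reproducible,
             .data$DP >= dp_min,
             .data$VF >= if_else(.data$region_class == "exonic", vf_exonic, vf_noncoding)) |>
      distinct(.data$control_id, .data$key)
    tibble(dp_min = dp_min, vf_exonic = vf_exonic, vf_noncoding = vf_noncoding,
           n_surviving = nrow(surv))
  })
  thresholds_ok <- surviving$n_surviving[1] == 0L
  structure(list(calls = per_variant, surviving = surviving,
                 thresholds_ok = thresholds_ok),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> %d variant(s), %d non-reproducible; production thresholds eliminate all noise: %s\n",
              nrow(x$calls), sum(!x$calls$reproducible), x$thresholds_ok))
  invisible(x)
}

#' @rdname characterize_noise
#' @param x A `noise_profile` object.
#' @param ... Unused.
#' @method tidy noise_profile
#' @export
tidy.noise_profile <- function(x, ...) as_tibble(x$calls)

#' @rdname characterize_noise
#' @method glance noise_profile
#' @export
glance.noise_profile <- function(x, ...) {
  tibble(n_variants = nrow(x$calls),
         n_noise = sum(!x$calls$reproducible),
         n_surviving_production = x$surviving$n_surviving[1],
         thresholds_ok = x$thresholds_ok)
}

#' Replicate concordance of filtered call sets
#'
#' Given filtered calls from replicates of one sample (intra-run or
#' inter-run), computes per-region-class call counts per replicate, all
#' pairwise Jaccard indices on normalized keys, whether the exonic call
#' sets are identical across replicates, and the fraction of discordant
#' variants (present in some but not all replicates) that are flagged
#' borderline — the expected explanation for noncoding discordance.
#'
#' @param calls Tibble with `replicate_id`, `key`, `region_class`,
#'   `borderline` (logical), and optionally `run`, `barcode` (carried
#'   through to the counts table).
#' @param design `"intra_run"` or `"inter_run"` (label only; recorded in
#'   the result).
#' @return Object of class `concordance`: list with `counts`, `jaccard`,
#'   `all_identical_exonic`, `borderline_explained`, `design`.
#' @export
replicate_concordance <- function(calls, design = c("intra_run", "inter_run")) {
  design <- match.arg(design)
  reps <- sort(unique(calls$replicate_id))
  if (length(reps) < 2L) stopf("need >= 2 replicates")
  carry <- intersect(c("run", "barcode"), names(calls))
  counts <- calls |>
    group_by(across(dplyr::all_of(c("replicate_id", carry))), .data$region_class) |>
    summarise(n = n(), .groups = "drop") |>
    tidyr::complete(replicate_id = reps,
                    region_class = unique(calls$region_class),
                    fill = list(n = 0L))
  key_sets <- function(class_filter) {
    lapply(setNames(reps, reps), function(r) {
      calls$key[calls$replicate_id == r & calls$region_class == class_filter]
    })
  }
  jaccard <- purrr::map_dfr(unique(calls$region_class), function(cl) {
    sets <- key_sets(cl)
    pairs <- utils::combn(reps, 2L, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      a <- sets[[as.character(pr[1])]]; b <- sets[[as.character(pr[2])]]
      u <- length(union(a, b))
      tibble(region_class = cl, rep_a = pr[1], rep_b = pr[2],
             jaccard = if (u == 0L) 1 else length(intersect(a, b)) / u)
    })
  })
  exonic_sets <- key_sets("exonic")
  all_identical_exonic <- all(vapply(
    exonic_sets, function(s) setequal(s, exonic_sets[[1]]), logical(1)))
  presence <- calls |>
    distinct(.data$key, .data$replicate_id) |>
    count(.data$key, name = "n_seen")
  discordant_keys <- presence$key[presence$n_seen < length(reps)]
  borderline_explained <- if (!length(discordant_keys)) {
    NA_real_
  } else {
    flagged <- calls |>
      filter(.data$key %in% discordant_keys) |>
      group_by(.data$key) |>
      summarise(b = any(.data$borderline %in% TRUE), .groups = "drop")
    mean(flagged$b)
  }
  structure(list(counts = counts, jaccard = jaccard,
                 all_identical_exonic = all_identical_exonic,
                 borderline_explained = borderline_explained,
                 design = design),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %s: exonic identical = %s; mean Jaccard by class:\n",
              x$design, x$all_identical_exonic))
  print(x$jaccard |> group_by(.data$region_class) |>
          summarise(mean_jaccard = mean(.data$jaccard), .groups = "drop"))
  if (!is.na(x$borderline_explained)) {
    cat(sprintf("borderline explains %.0f%% of discordant variants\n",
                100 * x$borderline_explained))
  }
  invisible(x)
}

#' @rdname replicate_concordance
#' @param x A `concordance` object.
#' @param ... Unused.
#' @method tidy concordance
#' @export
tidy.concordance <- function(x, ...) as_tibble(x$jaccard)

#' @rdname replicate_concordance
#' @method glance concordance
#' @export
glance.concordance <- function(x, ...) {
  jc <- x$jaccard |> group_by(.data$region_class) |>
    summarise(mean_jaccard = mean(.data$jaccard), .groups = "drop")
  tibble(design = x$design,
         all_identical_exonic = x$all_identical_exonic,
         mean_jaccard_exonic = jc$mean_jaccard[jc$region_class == "exonic"][1],
         mean_jaccard_noncoding = jc$mean_jaccard[jc$region_class == "noncoding_flank"][1],
         borderline_explained = x$borderline_explained)
}

#' Seeded CNV parameter-recovery study
#'
#' Simulates replicate cohorts of 20 reference diploid normals (10% per-exon
#' depth CV) plus three test samples — a whole-gene heterozygous deletion
#' (copy ratio 0.5), a single-exon duplication (copy ratio 1.5) and an
#' unspiked null — and measures, at the production calling thresholds, the
#' recovery sensitivity of each planted event and the false segment rate per
#' gene on the null sample. Single-exon duplications count as recovered only
#' when the called segment is exactly the spiked exon.
#'
#' @param n_replicates Number of simulated cohorts (default 100).
#' @param seed Base seed; replicate i uses `seed + i`.
#' @param n_genes Genes per simulated panel (default 4).
#' @param gain_fc,loss_fc,alpha Calling thresholds (production defaults).
#' @return One-row tibble: `whole_gene_loss_sensitivity`,
#'   `single_exon_dup_sensitivity`, `false_segment_rate_per_gene`,
#'   `n_replicates`.
#' @export
cnv_recovery_study <- function(n_replicates = 100, seed = 1, n_genes = 4,
                               gain_fc = 1.3, loss_fc = -1.7, alpha = 0.05) {
  whole_hits <- 0L
  single_hits <- 0L
  false_segments <- 0L
  null_gene_draws <- 0L
  for (i in seq_len(n_replicates)) {
    cfg <- sim_config(
      seed = seed + i, n_genes = n_genes,
      spikes = tibble(
        sample_id = c("T_LOSS", "T_DUP"),
        gene = c("GENE01", "GENE02"),
        first_exon = c(NA_integer_, 2L),
        last_exon = c(NA_integer_, 2L),
        copy_ratio = c(0.5, 1.5)
      ),
      n_null_test_samples = 1
    )
    panel <- sim_panel(cfg)
    dm <- sim_depths(cfg, panel)
    segs_loss <- call_segments(exon_ratios(dm$depths, "T_LOSS"),
                               gain_fc = gain_fc, loss_fc = loss_fc, alpha = alpha)
    whole_hits <- whole_hits +
      any(segs_loss$gene == "GENE01" & segs_loss$direction == "loss")
    segs_dup <- call_segments(exon_ratios(dm$depths, "T_DUP"),
                              gain_fc = gain_fc, loss_fc = loss_fc, alpha = alpha)
    single_hits <- single_hits +
      any(segs_dup$gene == "GENE02" & segs_dup$direction == "gain" &
            segs_dup$first_exon == 2L & segs_dup$last_exon == 2L)
    segs_null <- call_segments(exon_ratios(dm$depths, "NULL01"),
                               gain_fc = gain_fc, loss_fc = loss_fc, alpha = alpha)
    false_segments <- false_segments + nrow(segs_null)
    null_gene_draws <- null_gene_draws + n_genes
  }
  tibble(
    whole_gene_loss_sensitivity = whole_hits / n_replicates,
    single_exon_dup_sensitivity = single_hits / n_replicates,
    false_segment_rate_per_gene = false_segments / null_gene_draws,
    n_replicates = as.integer(n_replicates)
  )
}
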