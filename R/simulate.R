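#' Simulation configuration
#'
#' Bundles the parameters of the synthetic panel study. Defaults describe a
#' compact capture panel sequenced at clinical depth: 8 genes of 4-12 exons
#' (spanning single-exon CNV challenge cases through mid-size
#' cancer-predisposition genes), a pool of 20 reference diploid normals,
#' mean exonic depth 800 reads with 10% per-exon coefficient of variation
#' (negative-binomial noise), 50 bp captured intronic flanks, 3 replicates
#' and 13 control samples for the noise study.
#'
#' @param seed Mandatory integer seed; every simulated artifact is a
#'   deterministic function of it.
#' @param n_genes Number of panel genes (>= 1).
#' @param exons_per_gene Length-2 integer range of exons per gene.
#' @param n_reference_normals Size of the reference diploid pool.
#' @param mean_exon_depth Mean exonic read depth.
#' @param depth_cv Per-exon coefficient of variation of depth.
#' @param flank_bp Captured intronic flank (bp).
#' @param spikes Tibble of planted CNVs: `sample_id`, `gene`, `first_exon`,
#'   `last_exon` (`NA` = whole gene), `copy_ratio` (0.5 het loss, 1.5 het
#'   gain, 0 hom loss, 2 hom gain).
#' @param n_null_test_samples Unspiked test samples (false-call surface).
#' @param variant_spikes Tibble of planted variants per sample:
#'   `region_class`, `n`, `DP`, `true_vf`, `is_noise`.
#' @param n_replicates Replicates per sample for call-set simulation.
#' @param n_runs Distinct run labels the replicates are spread across.
#' @param n_controls Control samples for the noise study.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 8,
                       exons_per_gene = c(4L, 12L),
                       n_reference_normals = 20,
                       mean_exon_depth = 800,
                       depth_cv = 0.10,
                       flank_bp = 50,
                       spikes = NULL,
                       n_null_test_samples = 1,
                       variant_spikes = default_variant_spikes(),
                       n_replicates = 3,
                       n_runs = 1,
                       n_controls = 13) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed is mandatory and must be a single integer")
  }
  if (n_genes < 1) stopf("n_genes must be >= 1")
  stopifnot(length(exons_per_gene) == 2L, exons_per_gene[1] >= 1,
            exons_per_gene[2] >= exons_per_gene[1],
            n_reference_normals >= 2, depth_cv > 0, mean_exon_depth > 0)
  if (!is.null(spikes)) {
    spikes <- as_tibble(spikes)
    stopifnot(all(c("sample_id", "gene", "copy_ratio") %in% names(spikes)))
    if (!"first_exon" %in% names(spikes)) spikes$first_exon <- NA_integer_
    if (!"last_exon" %in% names(spikes)) spikes$last_exon <- NA_integer_
    if (!all(spikes$copy_ratio %in% c(0, 0.5, 1.5, 2))) {
      stopf("copy_ratio must be one of 0, 0.5, 1.5, 2 (integer copy states in a diploid)")
    }
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 n_reference_normals = as.integer(n_reference_normals),
                 mean_exon_depth = mean_exon_depth, depth_cv = depth_cv,
                 flank_bp = as.integer(flank_bp), spikes = spikes,
                 n_null_test_samples = as.integer(n_null_test_samples),
                 variant_spikes = as_tibble(variant_spikes),
                 n_replicates = as.integer(n_replicates),
                 n_runs = as.integer(n_runs),
                 n_controls = as.integer(n_controls)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_variant_spikes <- function() {
  tibble(
    region_class = c("exonic", "noncoding_flank", "exonic", "noncoding_flank"),
    n = c(8L, 8L, 3L, 3L),
    DP = c(800, 300, 200, 120),
    true_vf = c(0.5, 0.5, 0.5, 0.5),
    is_noise = c(FALSE, FALSE, TRUE, TRUE)
  )
}

# negative-binomial draw with mean mu and target CV; falls back to Poisson
# when mu is too small for the CV to be attainable
rnb_cv <- function(n, mu, cv) {
  excess <- cv^2 - 1 / mu
  size <- ifelse(excess > 1e-8, 1 / excess, Inf)
  out <- numeric(n)
  fin <- is.finite(size)
  out[fin] <- rnbinom(sum(fin), mu = mu[fin], size = size[fin])
  out[!fin] <- rpois(sum(!fin), lambda = mu[!fin])
  out
}

#' Simulate a gene panel
#'
#' Deterministic under the config seed: exon lengths 80-300 bp, introns
#' 200-2000 bp, genes laid out sequentially on one chromosome with 10 kb
#' intergenic gaps, all on the + strand.
#'
#' @param config A [sim_config()].
#' @return A [gene_panel()].
#' @export
sim_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cursor <- 10000L
  rows <- list()
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
    lens <- sample(80:300, n_ex, replace = TRUE)
    introns <- sample(200:2000, max(n_ex - 1L, 1L), replace = TRUE)
    starts <- integer(n_ex)
    s <- cursor
    for (i in seq_len(n_ex)) {
      starts[i] <- s
      s <- s + lens[i] + if (i < n_ex) introns[i] else 0L
    }
    rows[[g]] <- tibble(chrom = "chr1", start = starts, end = starts + lens,
                        gene = sprintf("GENE%02d", g), exon_index = seq_len(n_ex),
                        strand = "+")
    cursor <- s + 10000L
  }
  gene_panel(bind_rows(rows), flank_bp = config$flank_bp)
}

#' Simulate a depth matrix with planted CNVs
#'
#' Reference normals are drawn diploid; each spiked test sample's exons in
#' the spiked span have their expected depth multiplied by `copy_ratio`
#' before negative-binomial noise. Per-exon capture efficiency (log-normal,
#' shared across samples) emulates bait-to-bait variability and cancels in
#' the reference ratio. Returns the long depth tibble plus a machine-
#' readable truth table of planted segments.
#'
#' @param config A [sim_config()] (its `spikes` define the planted truth).
#' @param panel Panel from [sim_panel()] (or any [gene_panel()]).
#' @return List with `depths` (long tibble: `sample_id`, `gene`,
#'   `exon_index`, `depth`, `role`) and `truth` (planted segments with
#'   `direction`).
#' @export
sim_depths <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "gene_panel"))
  set.seed(config$seed + 1L)
  exons <- as_tibble(panel) |> select("gene", "exon_index")
  spikes <- config$spikes
  if (!is.null(spikes) && nrow(spikes)) {
    unknown <- setdiff(spikes$gene, exons$gene)
    if (length(unknown)) stopf("spike references unknown gene: %s", unknown[1])
    n_ex <- exons |> count(.data$gene, name = "n_exons")
    spikes <- spikes |>
      left_join(n_ex, by = "gene") |>
      mutate(first_exon = if_else(is.na(.data$first_exon), 1L, as.integer(.data$first_exon)),
             last_exon = if_else(is.na(.data$last_exon), .data$n_exons,
                                 as.integer(.data$last_exon))) |>
      select(-"n_exons")
    if (any(spikes$first_exon > spikes$last_exon)) stopf("spike with first_exon > last_exon")
  } else {
    spikes <- tibble(sample_id = character(), gene = character(),
                     first_exon = integer(), last_exon = integer(),
                     copy_ratio = double())
  }
  efficiency <- exp(rnorm(nrow(exons), mean = 0, sd = 0.3))
  efficiency <- pmin(pmax(efficiency, 0.3), 3)
  exons$mu0 <- config$mean_exon_depth * efficiency

  ref_ids <- sprintf("NORM%02d", seq_len(config$n_reference_normals))
  test_ids <- unique(c(spikes$sample_id,
                       if (config$n_null_test_samples > 0)
                         sprintf("NULL%02d", seq_len(config$n_null_test_samples))))
  all_samples <- tibble(
    sample_id = c(ref_ids, test_ids),
    role = c(rep("reference_normal", length(ref_ids)), rep("test", length(test_ids)))
  )
  grid <- tidyr::expand_grid(all_samples, exons)
  grid <- grid |>
    left_join(spikes |> select("sample_id", "gene", "first_exon", "last_exon",
                               "copy_ratio"),
              by = c("sample_id", "gene"), relationship = "many-to-many") |>
    mutate(in_span = !is.na(.data$copy_ratio) &
             .data$exon_index >= .data$first_exon &
             .data$exon_index <= .data$last_exon,
           cr = if_else(.data$in_span, .data$copy_ratio, 1)) |>
    group_by(.data$sample_id, .data$gene, .data$exon_index) |>
    summarise(role = first(.data$role), mu0 = first(.data$mu0),
              cr = prod(.data$cr), .groups = "drop")
  grid <- grid |>
    mutate(mu = .data$mu0 * .data$cr,
           depth = ifelse(.data$mu <= 0, 0,
                          rnb_cv(n(), pmax(.data$mu, 1e-9), config$depth_cv)))
  truth <- spikes |>
    mutate(direction = if_else(.data$copy_ratio < 1, "loss", "gain"))
  list(
    depths = grid |>
      select("sample_id", "gene", "exon_index", "depth", "role") |>
      arrange(.data$sample_id, .data$gene, .data$exon_index),
    truth = truth
  )
}

#' Simulate replicated two-caller call sets with planted truth
#'
#' For one sample, plants `variant_spikes` at random panel positions
#' (exonic spikes inside exons, noncoding spikes inside effective flanks).
#' True variants appear in every replicate with depth drawn around the spike
#' DP and alt reads drawn Binomial(DP, true_vf) — the same model the power
#' analysis assumes — and are seen by both callers with probability 0.85
#' (one random caller otherwise). Noise calls appear in a random strict
#' subset of replicates, with DP or VF below the production thresholds by
#' construction, and are usually caller-private.
#'
#' @param config A [sim_config()].
#' @param panel A [gene_panel()].
#' @param sample_id Label for the simulated sample.
#' @param seed_offset Added to the config seed (lets multiple samples share
#'   one config deterministically).
#' @return List with `calls` (tibble: `sample_id`, `replicate_id`, `run`,
#'   `barcode`, `caller`, `chrom`, `pos` 1-based, `ref`, `alt`, `DP`, `VF`,
#'   `region_class`, `is_noise`) and `truth` (planted variant table).
#' @export
sim_callsets <- function(config, panel, sample_id = "S1", seed_offset = 2L) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "gene_panel"))
  set.seed(config$seed + seed_offset)
  vs <- config$variant_spikes
  stopifnot(all(c("region_class", "n", "DP", "true_vf", "is_noise") %in% names(vs)))
  p <- as_tibble(panel)
  bases <- c("A", "C", "G", "T")
  draw_position <- function(class) {
    i <- sample(nrow(p), 1L)
    if (class == "exonic") {
      pos0 <- sample(seq(p$start[i], p$end[i] - 1L), 1L)
    } else {
      cand <- c(
        if (p$lflank[i] > 0) seq(p$start[i] - p$lflank[i], p$start[i] - 1L),
        if (p$rflank[i] > 0) seq(p$end[i], p$end[i] + p$rflank[i] - 1L)
      )
      if (is.null(cand)) return(draw_position(class))
      pos0 <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    list(chrom = p$chrom[i], pos0 = pos0)
  }
  planted <- purrr::pmap_dfr(vs, function(region_class, n, DP, true_vf, is_noise) {
    purrr::map_dfr(seq_len(n), function(j) {
      loc <- draw_position(region_class)
      ref <- sample(bases, 1L)
      alt <- sample(setdiff(bases, ref), 1L)
      tibble(region_class = region_class, chrom = loc$chrom,
             pos = loc$pos0 + 1L, ref = ref, alt = alt,
             DP_target = DP, true_vf = true_vf, is_noise = is_noise)
    })
  })
  planted <- planted |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    mutate(key = paste0(.data$chrom, ":", .data$pos, ":", .data$ref, ">", .data$alt))

  reps <- seq_len(config$n_replicates)
  run_of <- ((reps - 1L) %% config$n_runs) + 1L
  barcodes <- sprintf("BC%02d", sample(90, config$n_replicates))
  vf_thr <- function(class) if (class == "exonic") 0.20 else 0.25

  rows <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
    v <- planted[i, ]
    if (!v$is_noise) {
      present <- rep(TRUE, length(reps))
    } else {
      present <- runif(length(reps)) < 0.5
      if (all(present)) present[sample(length(reps), 1L)] <- FALSE
      if (!any(present)) present[sample(length(reps), 1L)] <- TRUE
    }
    purrr::map_dfr(which(present), function(r) {
      if (!v$is_noise) {
        DP <- max(1L, as.integer(round(rnb_cv(1L, v$DP_target, config$depth_cv))))
        alt_reads <- rbinom(1L, DP, v$true_vf)
        if (alt_reads == 0L) alt_reads <- 1L # a call record implies >= 1 alt read
        both <- runif(1) < 0.85
        callers <- if (both) c("A", "B") else sample(c("A", "B"), 1L)
      } else {
        # noise sits below the production thresholds: low depth or low VF
        if (runif(1) < 0.5) {
          DP <- sample(10:49, 1L)
          alt_reads <- max(1L, rbinom(1L, DP, runif(1, 0.10, 0.45)))
        } else {
          DP <- sample(50:400, 1L)
          thr <- vf_thr(v$region_class)
          alt_reads <- max(1L, as.integer(floor(DP * runif(1, 0.03, thr - 0.02))))
        }
        callers <- sample(c("A", "B"), 1L)
      }
      VF <- alt_reads / DP
      tibble(sample_id = sample_id, replicate_id = r, run = run_of[r],
             barcode = barcodes[r], caller = callers,
             chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             DP = DP, VF = VF, region_class = v$region_class,
             is_noise = v$is_noise, key = v$key)
    })
  })
  list(calls = rows, truth = planted |> mutate(sample_id = sample_id))
}

#' Simulate the replicated-control noise study
#'
#' Runs [sim_callsets()] for `n_controls` control samples (2-3 replicates
#' each) and stacks the pre-filter calls in the shape
#' [characterize_noise()] consumes.
#'
#' @param config A [sim_config()].
#' @param panel A [gene_panel()].
#' @return List with `calls` (columns `control_id`, `replicate_id`, `key`,
#'   `DP`, `VF`, `region_class`, `is_noise`) and `truth`.
#' @export
sim_noise_study <- function(config, panel) {
  out <- purrr::map(seq_len(config$n_controls), function(ci) {
    cfg_i <- config
    cfg_i$n_replicates <- max(2L, config$n_replicates)
    sim_callsets(cfg_i, panel, sample_id = sprintf("CTRL%02d", ci),
                 seed_offset = 100L + ci)
  })
  calls <- purrr::map_dfr(out, "calls") |>
    distinct(.data$sample_id, .data$replicate_id, .data$key, .keep_all = TRUE) |>
    rename(control_id = "sample_id") |>
    select("control_id", "replicate_id", "key", "DP", "VF",
           "region_class", "is_noise")
  truth <- purrr::map_dfr(out, "truth") |> rename(control_id = "sample_id")
  list(calls = calls, truth = truth)
}

#' Simulate SV records matching planted CNVs
#'
#' For each planted CNV segment, emits a DEL/DUP record whose breakpoints
#' jitter into the flanking introns (or the neighbouring exon), emulating
#' the base-resolution evidence a split-read caller provides on top of the
#' exon-resolution coverage signal.
#'
#' @param config A [sim_config()].
#' @param panel A [gene_panel()].
#' @param truth Planted segment table from [sim_depths()].
#' @return SV tibble (`chrom`, `start`, `end`, `sv_type`, `support`).
#' @export
sim_svs <- function(config, panel, truth) {
  set.seed(config$seed + 3L)
  if (!nrow(truth)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  sv_type = character(), support = integer()))
  }
  p <- as_tibble(panel)
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    g <- p |> filter(.data$gene == tr$gene)
    first <- g |> filter(.data$exon_index == tr$first_exon)
    last <- g |> filter(.data$exon_index == tr$last_exon)
    tibble(chrom = first$chrom,
           start = as.integer(first$start - sample(10:120, 1L)),
           end = as.integer(last$end + sample(10:120, 1L)),
           sv_type = if (tr$direction == "loss") "DEL" else "DUP",
           support = sample(5:30, 1L))
  })
}

#' Write a complete synthetic input bundle
#'
#' Emits, under `dir`: `panel.bed`, `depth_matrix.tsv`, per-replicate caller
#' call TSVs (`calls_<sample>_rep<k>_<caller>.tsv`), `svs.tsv`,
#' `evidence.tsv`, `population_af.tsv` and `truth.json`. Byte-identical
#' across repeated invocations with the same config.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the simulated objects.
#' @export
sim_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- sim_panel(config)
  write_panel_bed(panel, file.path(dir, "panel.bed"))
  dm <- sim_depths(config, panel)
  write_depth_matrix(dm$depths, file.path(dir, "depth_matrix.tsv"))
  svs <- sim_svs(config, panel, dm$truth)
  write_tsv_hash(svs, file.path(dir, "svs.tsv"))

  samples <- unique(dm$depths$sample_id[dm$depths$role == "test"])
  if (!length(samples)) samples <- "S1"
  cs <- purrr::map(seq_along(samples), function(si) {
    sim_callsets(config, panel, sample_id = samples[si], seed_offset = 10L + si)
  })
  for (one in cs) {
    for (r in unique(one$calls$replicate_id)) {
      for (cl in c("A", "B")) {
        sub <- one$calls |>
          filter(.data$replicate_id == r, .data$caller == cl) |>
          select("chrom", "pos", "ref", "alt", "DP", "VF")
        write_tsv_hash(sub, file.path(dir, sprintf("calls_%s_rep%d_%s.tsv",
                                                   one$calls$sample_id[1], r, cl)))
      }
    }
  }
  vt <- purrr::map_dfr(cs, "truth")
  ev_pop <- sim_evidence(config, vt)
  write_tsv_hash(ev_pop$evidence, file.path(dir, "evidence.tsv"))
  write_tsv_hash(ev_pop$pop_af, file.path(dir, "population_af.tsv"))
  truth <- list(cnv = dm$truth, variants = vt |> select(-"DP_target"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(list(panel = panel, depths = dm$depths, cnv_truth = dm$truth,
                 callsets = cs, svs = svs, evidence = ev_pop$evidence,
                 pop_af = ev_pop$pop_af))
}

#' Simulate evidence tags and population allele frequencies
#'
#' Emulates the annotation profile of germline panel calls: the majority of
#' true variants are common polymorphisms (maximum population AF above 5%,
#' hence BA1 benign), a minority carry pathogenic evidence (PVS1 + PM2), and
#' the remainder are rare untagged variants (VUS).
#'
#' @param config A [sim_config()].
#' @param variant_truth Truth table from [sim_callsets()].
#' @param frac_common,frac_pathogenic Mixture fractions
#'   (defaults 0.70, 0.10).
#' @return List with `evidence` and `pop_af` tibbles keyed by variant.
#' @export
sim_evidence <- function(config, variant_truth, frac_common = 0.70,
                         frac_pathogenic = 0.10) {
  set.seed(config$seed + 4L)
  keys <- unique(variant_truth$key[!variant_truth$is_noise])
  n <- length(keys)
  if (!n) {
    return(list(evidence = tibble(key = character(), tags = character()),
                pop_af = tibble(key = character(), cohort = character(),
                                af = double())))
  }
  cls <- sample(c("common", "pathogenic", "rare"), n, replace = TRUE,
                prob = c(frac_common, frac_pathogenic, 1 - frac_common - frac_pathogenic))
  cohorts <- c("1000G", "ExAC", "ESP")
  pop_af <- purrr::map_dfr(seq_len(n), function(i) {
    peak <- switch(cls[i],
                   common = runif(1, 0.06, 0.45),
                   pathogenic = runif(1, 0, 1e-4),
                   rare = runif(1, 0, 0.04))
    af <- pmin(1, peak * runif(3, 0.5, 1))
    af[sample.int(3, 1L)] <- peak # one cohort attains the intended maximum
    tibble(key = keys[i], cohort = cohorts, af = af)
  })
  evidence <- tibble(key = keys,
                     tags = if_else(cls == "pathogenic", "PVS1;PM2", ""))
  list(evidence = evidence, pop_af = pop_af)
}
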