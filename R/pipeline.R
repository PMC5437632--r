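#' Build and validate a pipeline run configuration
#'
#' All thresholds default to the production values: DP 50, VF 0.20 exonic /
#' 0.25 noncoding, CNV fold change +1.3 / -1.7 at p < 0.05, BA1 at 5%
#' population frequency. Any can be overridden. The configuration may also
#' be read from a flat YAML file with [read_run_config()].
#'
#' @param panel_bed Path to the panel BED.
#' @param calls_a,calls_b Paths to the two callers' call files (TSV or VCF).
#' @param sample_id Sample label for reports (default "SAMPLE").
#' @param depth_matrix Optional path to a depth-matrix TSV (enables CNV
#'   calling).
#' @param test_samples Optional character vector of test samples to call
#'   CNVs for (default: every `test`-role sample in the matrix).
#' @param svs Optional path to an SV TSV/VCF (enables breakpoint
#'   refinement).
#' @param evidence,pop_af Optional paths to evidence / population-AF TSVs.
#' @param out_dir Output directory.
#' @param flank_bp,dp_min,vf_exonic,vf_noncoding,gain_fc,loss_fc,alpha,
#'   ba1_threshold,dp_margin,vf_margin,min_support,min_reciprocal Thresholds
#'   (see module functions).
#' @return A validated `run_config` list.
#' @export
run_config <- function(panel_bed, calls_a = NULL, calls_b = NULL,
                       sample_id = "SAMPLE",
                       depth_matrix = NULL, test_samples = NULL, svs = NULL,
                       evidence = NULL, pop_af = NULL,
                       out_dir = "germpanel_out",
                       flank_bp = 50, dp_min = 50, vf_exonic = 0.20,
                       vf_noncoding = 0.25, gain_fc = 1.3, loss_fc = -1.7,
                       alpha = 0.05, ba1_threshold = 0.05,
                       dp_margin = 10, vf_margin = 0.03,
                       min_support = 3, min_reciprocal = 0.5) {
  cfg <- list(panel_bed = panel_bed, calls_a = calls_a, calls_b = calls_b,
              sample_id = sample_id, depth_matrix = depth_matrix,
              test_samples = test_samples, svs = svs, evidence = evidence,
              pop_af = pop_af, out_dir = out_dir, flank_bp = flank_bp,
              dp_min = dp_min, vf_exonic = vf_exonic,
              vf_noncoding = vf_noncoding, gain_fc = gain_fc,
              loss_fc = loss_fc, alpha = alpha,
              ba1_threshold = ba1_threshold, dp_margin = dp_margin,
              vf_margin = vf_margin, min_support = min_support,
              min_reciprocal = min_reciprocal)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  for (nm in c("vf_exonic", "vf_noncoding", "alpha", "ba1_threshold",
               "min_reciprocal", "vf_margin")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stopf("config: %s must be a single number in [0, 1] (got %s)", nm,
            paste(v, collapse = ","))
    }
  }
  for (nm in c("dp_min", "flank_bp", "dp_margin", "min_support")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stopf("config: %s must be a single non-negative number", nm)
    }
  }
  if (cfg$gain_fc <= 1) stopf("config: gain_fc must exceed 1")
  if (cfg$loss_fc >= -1) stopf("config: loss_fc must be below -1")
  for (nm in c("panel_bed", "calls_a", "calls_b", "depth_matrix", "svs",
               "evidence", "pop_af")) {
    v <- cfg[[nm]]
    if (!is.null(v) && !file.exists(v)) stopf("config: %s file not found: %s", nm, v)
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path Path to a flat YAML file of config fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the germline analysis end to end
#'
#' Orchestrates filter -> classify -> CNV -> SV refinement and writes the
#' report bundle to `config$out_dir`: `variants.tsv` (merged, filtered,
#' zygosity- and borderline-annotated, ACMG-classified calls),
#' `cnv_segments.tsv`, `cnv_refined.tsv`, a per-sample `summary.json`
#' (counts of exonic/noncoding calls by class group) and an echo of the
#' effective configuration (`config_used.yaml`). Re-running on identical
#' inputs produces byte-identical reports. Per-stage record counts are
#' logged to standard error.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with `variants`, `classification`, `segments`,
#'   `refined`, `summary`.
#' @export
run_germline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[germpanel] ", fmt), ...))

  panel <- load_panel(config$panel_bed, flank_bp = config$flank_bp)
  log_stage("panel: %d exons, %d genes", nrow(panel), length(unique(panel$gene)))

  calls_a <- if (!is.null(config$calls_a)) read_caller_calls(config$calls_a) else NULL
  calls_b <- if (!is.null(config$calls_b)) read_caller_calls(config$calls_b) else NULL
  merged <- union_merge(calls_a, calls_b)
  filtered <- apply_filters(merged, panel, dp_min = config$dp_min,
                            vf_exonic = config$vf_exonic,
                            vf_noncoding = config$vf_noncoding) |>
    assign_zygosity() |>
    flag_borderline(dp_min = config$dp_min, dp_margin = config$dp_margin,
                    vf_margin = config$vf_margin)
  log_stage("variants: %d merged, %d pass, %d fail_depth, %d fail_vf, %d fail_region",
            nrow(filtered), sum(filtered$filter_status == "pass"),
            sum(filtered$filter_status == "fail_depth"),
            sum(filtered$filter_status == "fail_vf"),
            sum(filtered$filter_status == "fail_region"))

  evidence <- if (!is.null(config$evidence)) read_evidence_tsv(config$evidence) else NULL
  pop_af <- if (!is.null(config$pop_af)) read_pop_af_tsv(config$pop_af) else NULL
  classification <- classify_callset(filtered, evidence = evidence,
                                     pop_af = pop_af,
                                     ba1_threshold = config$ba1_threshold)
  classified <- filtered |>
    left_join(classification$variants |>
                select("key", "class_number", "label", "conflict", "class_group"),
              by = "key")
  write_tsv_hash(classified, file.path(config$out_dir, "variants.tsv"))

  segments <- tibble(gene = character(), first_exon = integer(),
                     last_exon = integer(), n_exons = integer(),
                     direction = character(), scope = character(),
                     mean_fold_change = double(), combined_p = double(),
                     sample_id = character())
  if (!is.null(config$depth_matrix)) {
    depths <- read_depth_matrix(config$depth_matrix)
    tests <- config$test_samples %||%
      unique(depths$sample_id[depths$role == "test"])
    segments <- purrr::map_dfr(tests, function(s) {
      tidy(call_cnv(depths, s, gain_fc = config$gain_fc,
                    loss_fc = config$loss_fc, alpha = config$alpha))
    })
    log_stage("cnv: %d segment(s) across %d test sample(s)", nrow(segments),
              length(tests))
  }
  write_tsv_hash(segments, file.path(config$out_dir, "cnv_segments.tsv"))

  refined <- segments
  if (nrow(segments) && !is.null(config$svs)) {
    svs <- read_sv_records(config$svs)
    refined <- purrr::map_dfr(unique(segments$sample_id), function(s) {
      reconcile(segments |> filter(.data$sample_id == s), svs, panel,
                min_support = config$min_support,
                min_reciprocal = config$min_reciprocal)
    })
    log_stage("sv: %d of %d segment(s) refined",
              sum(!is.na(refined$refined_start)), nrow(refined))
  }
  write_tsv_hash(refined, file.path(config$out_dir, "cnv_refined.tsv"))

  grp_counts <- function(cls) {
    pass <- classified |> filter(.data$filter_status == "pass",
                                 .data$region_class == cls)
    as.list(table(factor(pass$class_group,
                         levels = c("Class_1_2", "Class_3", "Class_4_5"))))
  }
  summary <- list(
    sample_id = config$sample_id,
    n_merged = nrow(filtered),
    n_pass = sum(filtered$filter_status == "pass"),
    exonic = grp_counts("exonic"),
    noncoding = grp_counts("noncoding_flank"),
    n_cnv_segments = nrow(segments),
    n_cnv_refined = if (nrow(refined)) sum(!is.na(refined$refined_start %||% NA)) else 0L
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_echo <- unclass(config)
  cfg_echo <- cfg_echo[!vapply(cfg_echo, is.null, logical(1))]
  yaml::write_yaml(cfg_echo, file.path(config$out_dir, "config_used.yaml"))
  invisible(list(variants = classified, classification = classification,
                 segments = segments, refined = refined, summary = summary))
}
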