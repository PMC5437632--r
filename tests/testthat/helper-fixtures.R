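# Builders and independent oracles shared across tests.

toy_panel <- function(flank_bp = 50) {
  gene_panel(tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 2000L, 3000L),
    end = c(1200L, 2150L, 3300L),
    gene = "BRCA9",
    exon_index = 1:3,
    strand = "+"
  ), flank_bp = flank_bp)
}

write_toy_bed <- function(path, lines = NULL) {
  lines <- lines %||% c(
    "chr1\t1000\t1200\tBRCA9_exon1\t0\t+",
    "chr1\t2000\t2150\tBRCA9_exon2\t0\t+",
    "chr1\t3000\t3300\tBRCA9_exon3\t0\t+"
  )
  writeLines(lines, path)
  path
}

# brute-force position classifier: scans every region and its raw flanks
oracle_classify <- function(panel, chrom, pos) {
  p <- as.data.frame(panel)
  vapply(seq_along(pos), function(i) {
    ex <- any(p$chrom == chrom[i] & pos[i] >= p$start & pos[i] < p$end)
    if (ex) return("exonic")
    fl <- any(p$chrom == chrom[i] &
                ((pos[i] >= p$start - p$lflank & pos[i] < p$start) |
                   (pos[i] >= p$end & pos[i] < p$end + p$rflank)))
    if (fl) "noncoding_flank" else "off_target"
  }, character(1))
}

# per-position loop oracle for exon coverage stats
oracle_exon_coverage <- function(depths, panel, sid) {
  p <- as.data.frame(panel)
  d <- depths[depths$sample_id == sid, ]
  out <- lapply(seq_len(nrow(p)), function(i) {
    vals <- vapply(seq(p$start[i], p$end[i] - 1L), function(pp) {
      hit <- d$depth[d$chrom == p$chrom[i] & d$pos == pp]
      if (length(hit)) hit[1] else 0L
    }, numeric(1))
    data.frame(gene = p$gene[i], exon_index = p$exon_index[i],
               mean_depth = mean(vals), min_depth = min(vals))
  })
  do.call(rbind, out)
}

# exhaustive allele-trim oracle: tries every shared-suffix/prefix reduction
oracle_normalize <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# data-driven ACMG oracle: minimal qualifying combinations as count vectors
oracle_acmg <- function(tags) {
  cnt <- c(pvs = sum(tags == "PVS1"),
           ps = sum(tags %in% paste0("PS", 1:4)),
           pm = sum(tags %in% paste0("PM", 1:6)),
           pp = sum(tags %in% paste0("PP", 1:5)),
           ba1 = as.integer("BA1" %in% tags),
           bs = sum(tags %in% paste0("BS", 1:4)),
           bp = sum(tags %in% paste0("BP", 1:7)))
  meets <- function(combos) {
    any(vapply(combos, function(cb) all(cnt[names(cb)] >= cb), logical(1)))
  }
  path_combos <- list(
    c(pvs = 1, ps = 1), c(pvs = 1, pm = 2), c(pvs = 1, pm = 1, pp = 1),
    c(pvs = 1, pp = 2), c(ps = 2), c(ps = 1, pm = 3),
    c(ps = 1, pm = 2, pp = 2), c(ps = 1, pm = 1, pp = 4)
  )
  lp_combos <- list(
    c(pvs = 1, pm = 1), c(ps = 1, pm = 1), c(ps = 1, pp = 2),
    c(pm = 3), c(pm = 2, pp = 2), c(pm = 1, pp = 4)
  )
  ben_combos <- list(c(ba1 = 1), c(bs = 2))
  lb_combos <- list(c(bs = 1, bp = 1), c(bp = 2))
  p_side <- meets(path_combos) || meets(lp_combos)
  b_side <- meets(ben_combos) || meets(lb_combos)
  if (p_side && b_side) return(list(class_number = 3L, conflict = TRUE))
  cls <- if (meets(path_combos)) 5L else if (meets(lp_combos)) 4L
  else if (meets(ben_combos)) 1L else if (meets(lb_combos)) 2L else 3L
  list(class_number = cls, conflict = FALSE)
}

jaccard_oracle <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 1 else length(intersect(a, b)) / u
}

# depth matrix with a known diploid structure, optionally spiked
make_depth_matrix <- function(n_ref = 20, n_exons_per_gene = c(A = 8, B = 6),
                              mean_depth = 800, cv = 0.10,
                              test_spikes = NULL, seed = 42) {
  set.seed(seed)
  exons <- do.call(rbind, lapply(names(n_exons_per_gene), function(g) {
    data.frame(gene = g, exon_index = seq_len(n_exons_per_gene[[g]]))
  }))
  exons$mu <- mean_depth * exp(rnorm(nrow(exons), 0, 0.2))
  samples <- c(sprintf("N%02d", seq_len(n_ref)), "TEST")
  roles <- c(rep("reference_normal", n_ref), "test")
  rows <- lapply(seq_along(samples), function(si) {
    cr <- rep(1, nrow(exons))
    if (samples[si] == "TEST" && !is.null(test_spikes)) {
      for (k in seq_len(nrow(test_spikes))) {
        sel <- exons$gene == test_spikes$gene[k] &
          exons$exon_index >= test_spikes$first_exon[k] &
          exons$exon_index <= test_spikes$last_exon[k]
        cr[sel] <- test_spikes$copy_ratio[k]
      }
    }
    mu <- exons$mu * cr
    excess <- cv^2 - 1 / pmax(mu, 1e-9)
    depth <- numeric(nrow(exons))
    nb <- mu > 0 & excess > 1e-8
    po <- mu > 0 & !nb
    depth[nb] <- rnbinom(sum(nb), mu = mu[nb], size = 1 / excess[nb])
    depth[po] <- rpois(sum(po), lambda = mu[po])
    data.frame(sample_id = samples[si], gene = exons$gene,
               exon_index = exons$exon_index,
               depth = depth,
               role = roles[si])
  })
  tibble::as_tibble(do.call(rbind, rows))
}
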