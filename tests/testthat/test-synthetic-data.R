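test_that("genome generation is seed-deterministic down to the FASTA bytes", {
  spec <- genome_spec(n_genes = 100, gene_len_mean = 450,
                      true_pseudo_fraction = 0.05, seed = 1)
  g1 <- make_genome(spec)
  g2 <- make_genome(spec)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(g1$features, g2$features)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  g1f <- tempfile(fileext = ".gff3"); g2f <- tempfile(fileext = ".gff3")
  write_assembly(g1, f1, g1f)
  write_assembly(g2, f2, g2f)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # exactly round(n * fraction) true pseudogenes
  expect_equal(sum(g1$features$status == "pseudogene"), 5L)
})

test_that("with no true pseudogenes every feature classifies as a gene", {
  g <- make_genome(genome_spec(n_genes = 40, gene_len_mean = 450,
                               true_pseudo_fraction = 0, seed = 5))
  expect_true(all(g$features$status == "gene"))
  verdicts <- vapply(g$features$nt_sequence, function(s) {
    classify_vs_reference(s, s)$status
  }, character(1))
  expect_true(all(verdicts == "gene"))
})

test_that("true pseudogenes carry their stated causes and classify accordingly", {
  g <- make_genome(genome_spec(n_genes = 120, gene_len_mean = 600,
                               true_pseudo_fraction = 0.2, cause_mix = 0.5,
                               seed = 7))
  pg <- which(g$features$status == "pseudogene")
  expect_equal(length(pg), 24L)
  causes <- unlist(g$features$causes[pg])
  expect_setequal(unique(causes), c("internal_stop", "frameshift"))
})

test_that("intergenic GC tracks the requested composition", {
  spec <- genome_spec(n_genes = 150, gene_len_mean = 450, gc = 0.7,
                      intergenic_mean = 200, seed = 9)
  g <- make_genome(spec)
  ft <- g$features
  contig <- g$contigs[[1]]
  mask <- rep(TRUE, nchar(contig))
  for (i in seq_len(nrow(ft))) mask[ft$start[i]:ft$end[i]] <- FALSE
  inter <- paste(strsplit(contig, "")[[1]][mask], collapse = "")
  gc_frac <- sum(strsplit(inter, "")[[1]] %in% c("G", "C")) / nchar(inter)
  expect_equal(gc_frac, 0.7, tolerance = 0.02 / 0.7)
})

test_that("feature-level corruption conserves the feature ledger", {
  g <- make_genome(genome_spec(n_genes = 200, gene_len_mean = 450,
                               true_pseudo_fraction = 0.05, seed = 11))
  st <- corrupt(g, coverage = 5, quality = 20, seed = 13)
  n_true_pg <- sum(g$features$status == "pseudogene")
  n_spurious <- nrow(st$event_log)
  n_intact <- sum(st$corrupted$features$status == "gene")
  expect_identical(n_intact + n_true_pg + n_spurious, 200L)
  # event log is complete: every status flip has an event
  flipped <- g$features$status == "gene" &
    st$corrupted$features$status == "pseudogene"
  expect_setequal(st$event_log$feature_id, g$features$feature_id[flipped])
})

test_that("corruption draws follow the configured binomial rate", {
  # constant pi = 0.01 regardless of coverage
  model <- corruption_model(beta0 = qlogis(0.01), beta_cov = 0, beta_q = 0)
  g <- make_genome(genome_spec(n_genes = 4000, gene_len_mean = 300,
                               true_pseudo_fraction = 0, seed = 15))
  counts <- vapply(1:50, function(s) {
    nrow(corrupt(g, 50, 35, model, seed = s)$event_log)
  }, numeric(1))
  expect_equal(mean(counts), 40, tolerance = 3 * sqrt(40 * 0.99 / 50) / 40)
})

test_that("corruption at extreme coverage is the identity", {
  g <- make_genome(genome_spec(n_genes = 30, gene_len_mean = 450,
                               true_pseudo_fraction = 0.1, seed = 17))
  st <- corrupt(g, coverage = 1e12, quality = 40, seed = 19)
  expect_identical(st$corrupted$contigs, g$contigs)
  expect_equal(nrow(st$event_log), 0L)
  st_b <- corrupt(g, 1e12, 40,
                  corruption_model(mode = "base_level"), seed = 19)
  expect_equal(nrow(st_b$event_log), 0L)
})

test_that("the coupled flip stream makes counts monotone in coverage", {
  g <- make_genome(genome_spec(n_genes = 300, gene_len_mean = 300,
                               true_pseudo_fraction = 0, seed = 21))
  for (seed in 1:3) {
    counts <- vapply(c(5, 10, 25, 50, 100, 250, 500), function(cv) {
      nrow(corrupt(g, cv, 35, seed = seed)$event_log)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("base-level in-frame indels leave features classified as genes", {
  model <- corruption_model(mode = "base_level", sub_rate0 = 0,
                            indel_rate0 = 5e-4,
                            indel_len_prob = c(0, 0, 1))
  g <- make_genome(genome_spec(n_genes = 60, gene_len_mean = 450,
                               true_pseudo_fraction = 0, seed = 23))
  st <- corrupt(g, 50, 35, model, seed = 25)
  ev <- st$event_log
  expect_true(all(abs(ev$length) == 3))
  touched <- table(ev$feature_id)
  single <- names(touched)[touched == 1]
  expect_gt(length(single), 3)
  for (fid in single) {
    i <- match(fid, g$features$feature_id)
    expect_equal(st$corrupted$features$status[[i]], "gene")
    v <- classify_vs_reference(g$features$nt_sequence[[i]],
                               st$corrupted$features$nt_sequence[[i]])
    expect_false("frameshift" %in% v$causes)
  }
})

test_that("fragmentation drops short contigs and spanning features", {
  g <- make_genome(genome_spec(n_genes = 50, gene_len_mean = 450,
                               intergenic_mean = 60, seed = 27))
  expect_identical(fragment_assembly(g, 0), g)
  fr <- fragment_assembly(g, n_breaks = 8, min_contig_len = 200, seed = 29)
  expect_true(all(nchar(fr$contigs) >= 200))
  ev <- attr(fr, "fragment_events")
  dropped_features <- ev$id[ev$what == "truncated_feature"]
  expect_true(all(!dropped_features %in% fr$features$feature_id))
  # every input feature is either retained or logged as truncated
  expect_setequal(c(fr$features$feature_id, dropped_features),
                  g$features$feature_id)
  # with no length cutoff, sequence is conserved exactly
  fr_all <- fragment_assembly(g, n_breaks = 5, min_contig_len = 1, seed = 31)
  expect_identical(paste(fr_all$contigs, collapse = ""), g$contigs[[1]])
  # retained features still carry their original sequences
  keep <- fr$features
  reex <- extract_feature_seqs(fr)
  expect_identical(reex$features$nt_sequence, keep$nt_sequence)
})

test_that("simulate_experiment emits the full factorial observation table", {
  spec <- genome_spec(n_genes = 40, gene_len_mean = 300,
                      true_pseudo_fraction = 0.05, seed = 33)
  res <- simulate_experiment(
    spec, coverages = c(5, 10, 25, 50, 100, 250, 500), qualities = 35,
    replicates = 3, seed = 35, method = "truth"
  )
  obs <- res$observations
  expect_equal(nrow(obs), 7 * 3 * 2) # 21 observations x 2 causes
  expect_equal(sort(unique(obs$coverage)), c(5, 10, 25, 50, 100, 250, 500))
  res2 <- simulate_experiment(
    spec, coverages = c(5, 10, 25, 50, 100, 250, 500), qualities = 35,
    replicates = 3, seed = 35, method = "truth"
  )
  expect_identical(obs, res2$observations)
  expect_error(simulate_experiment(spec, coverages = numeric()), "empty")
})

test_that("the full pipeline recovers the coverage needed for 1 spurious pseudogene per Mbp", {
  spec <- genome_spec(n_genes = 1000, true_pseudo_fraction = 0.02, seed = 37)
  model <- corruption_model()
  # two qualities so both model coefficients are identified from the
  # observation table, not extrapolated
  ratios <- vapply(1:3, function(ms) {
    res <- simulate_experiment(
      spec, coverages = c(5, 10, 25, 50, 100, 250, 500),
      qualities = c(20, 35),
      replicates = 2, model = model, seed = 40 + ms, method = "classifier"
    )
    obs <- res$observations
    glen <- obs$genome_length[[1]]
    n_cds <- obs$n[[1]]
    # pool causes: total spurious pseudogenes per condition
    agg <- stats::aggregate(k ~ coverage + quality + replicate, obs, sum)
    agg$n <- n_cds
    fit <- fit_binomial(agg)
    got <- coverage_for_density(fit, 1.0, 35, n_cds, glen)$coverage
    # analytic oracle from the generator parameters
    f <- function(cv) {
      pi_spurious(model, cv, 35) * n_cds * 1e6 / glen - 1
    }
    truth_cov <- uniroot(f, c(1, 1e5))$root
    got / truth_cov
  }, numeric(1))
  expect_true(all(ratios > 1 / 1.5 & ratios < 1.5))
})
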