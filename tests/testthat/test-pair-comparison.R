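test_that("ANI of a genome with itself is exactly 100", {
  set.seed(5)
  g <- c(chr = random_dna(12000))
  r <- ani(g, g)
  expect_identical(r$ani, 100)
  expect_identical(r$aligned_fraction, 1)
  expect_equal(r$n_fragments, 24L)
})

test_that("ANI under i.i.d. substitutions tracks the substitution rate", {
  set.seed(9)
  a <- random_dna(100000)
  b <- mutate_dna(a, 0.02)
  r <- ani(c(chr = a), c(chr = b))
  expect_gt(r$ani, 97.6)
  expect_lt(r$ani, 98.4)
  # per-fragment Hamming oracle: mean identity of 1-kb windows
  idents <- vapply(seq(1, 99001, by = 1000), function(s) {
    fa <- substr(a, s, s + 999)
    fb <- substr(b, s, s + 999)
    mean(strsplit(fa, "")[[1]] == strsplit(fb, "")[[1]])
  }, numeric(1))
  expect_equal(r$ani, mean(idents) * 100, tolerance = 0.01)
})

test_that("ANI is undefined when no fragment aligns", {
  set.seed(10)
  a <- c(chr = random_dna(3000))
  b <- c(chr = random_dna(3000))
  r <- ani(a, b)
  expect_true(is.na(r$ani))
})

test_that("ANI decreases monotonically in the substitution rate", {
  rates <- c(0, 0.005, 0.01, 0.02)
  means <- vapply(rates, function(rate) {
    vals <- vapply(1:3, function(rep) {
      set.seed(100 + rep)
      a <- random_dna(100000)
      b <- if (rate > 0) mutate_dna(a, rate) else a
      ani(c(chr = a), c(chr = b))$ani
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("nearest_neighbor picks the argmax with lexicographic ties", {
  m <- matrix(c(NA, 99.9, 98, 99.9, NA, 97, 98, 97, NA), 3, 3,
              dimnames = list(c("a1", "a2", "a3"), c("a1", "a2", "a3")))
  nn <- nearest_neighbor(m)
  expect_equal(nn$partner_id[nn$assembly_id == "a1"], "a2")
  expect_equal(nn$partner_id[nn$assembly_id == "a2"], "a1")
  # tie
  m2 <- matrix(c(NA, 99, 99, 99, NA, 95, 99, 95, NA), 3, 3,
               dimnames = list(c("b", "c", "a"), c("b", "c", "a")))
  nn2 <- nearest_neighbor(m2)
  expect_equal(nn2$partner_id[nn2$assembly_id == "b"], "a")
  # brute force over random matrices
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    ids <- paste0("g", sample(letters, n))
    m3 <- matrix(runif(n * n, 90, 100), n, n, dimnames = list(ids, ids))
    m3 <- (m3 + t(m3)) / 2
    nn3 <- nearest_neighbor(m3)
    for (r in seq_len(nrow(nn3))) {
      i <- match(nn3$assembly_id[r], ids)
      vals <- m3[i, ]; vals[i] <- NA
      expect_equal(nn3$ani[r], max(vals, na.rm = TRUE))
      best <- sort(ids[which(vals == max(vals, na.rm = TRUE))])[1]
      expect_equal(nn3$partner_id[r], best)
    }
  }
})

test_that("match_cds pairs identical annotation sets one-to-one", {
  set.seed(19)
  seqs <- vapply(1:8, function(i) random_dna(300), "")
  fa <- toy_features("A", seqs, "gene")
  fb <- toy_features("B", seqs, "gene")
  clusters <- match_cds(fa, fb)
  expect_length(clusters, 8L)
  for (cl in clusters) {
    expect_equal(nrow(cl$members), 2L)
    expect_setequal(cl$members$assembly_id, c("A", "B"))
    expect_false(cl$excluded_paralog)
  }
})

test_that("clusters of more than two members are flagged as paralogous", {
  set.seed(21)
  base <- random_dna(400)
  copy <- mutate_dna(base, 0.05) # ~95% identical paralog
  fa <- toy_features("A", c(base, copy), "gene")
  fb <- toy_features("B", base, "gene")
  clusters <- match_cds(fa, fb)
  expect_length(clusters, 1L)
  expect_equal(nrow(clusters[[1]]$members), 3L)
  expect_true(clusters[[1]]$excluded_paralog)
})

test_that("match_cds equals brute-force all-pairs thresholding", {
  set.seed(25)
  seqs_a <- character(20); seqs_b <- character(20)
  for (i in 1:20) {
    s <- random_dna(250)
    seqs_a[i] <- s
    seqs_b[i] <- mutate_dna(s, runif(1, 0, 0.20))
  }
  fa <- toy_features("A", seqs_a, "gene")
  fb <- toy_features("B", seqs_b, "gene")
  clusters <- match_cds(fa, fb, method = "kmer")
  # oracle: all-pairs identity thresholding + transitive closure
  all_seq <- c(seqs_a, seqs_b)
  n <- length(all_seq)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <- percent_identity(all_seq[i], all_seq[j]) >= 0.90
  }
  reach <- adj | diag(n)
  for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ])
  oracle_comp <- apply(reach, 1, function(r) min(which(r)))
  ids <- c(fa$feature_id, fb$feature_id)
  oracle_parts <- unname(split(ids, oracle_comp))
  got_parts <- lapply(clusters, function(cl) cl$members$feature_id)
  key <- function(parts) sort(vapply(parts, function(p)
    paste(sort(p), collapse = "|"), ""))
  expect_equal(key(got_parts), key(oracle_parts))
})

test_that("match_cds is order-invariant and prefilter-invariant", {
  set.seed(27)
  seqs <- vapply(1:10, function(i) random_dna(200), "")
  fa <- toy_features("A", seqs, "gene")
  fb <- toy_features("B", vapply(seqs, mutate_dna, "", rate = 0.05), "gene")
  ref <- match_cds(fa, fb, method = "allpairs")
  perm <- match_cds(fa[sample(nrow(fa)), ], fb[sample(nrow(fb)), ],
                    method = "allpairs")
  expect_equal(perm, ref)
  expect_equal(match_cds(fa, fb, method = "kmer"), ref)
})

test_that("congruence fractions match hand counts and handle empties", {
  # 8 congruent internal-stop pairs + 2 incongruent
  mk <- function(i, sA, cA, sB, cB) {
    members <- data.frame(
      assembly_id = c("A", "B"),
      feature_id = sprintf("p%02d_%s", i, c("a", "b")),
      status = c(sA, sB), stringsAsFactors = FALSE
    )
    members$causes <- list(cA, cB)
    members$nt_sequence <- strrep("A", 30)
    list(members = members, excluded_paralog = FALSE)
  }
  clusters <- c(
    lapply(1:8, function(i) mk(i, "pseudogene", "internal_stop",
                               "pseudogene", "internal_stop")),
    lapply(9:10, function(i) mk(i, "pseudogene", "internal_stop",
                                "gene", character()))
  )
  cs <- congruence_summary(clusters)
  expect_equal(cs$internal_stop$n_congruent, 8L)
  expect_equal(cs$internal_stop$n_incongruent, 2L)
  expect_equal(cs$internal_stop$fraction_incongruent, 0.2)
  expect_equal(cs$internal_stop$weight, 10L)
  expect_true(is.na(cs$frameshift$fraction_incongruent))
  expect_equal(cs$frameshift$weight, 0L)

  # adding a congruent pair never increases the incongruent fraction
  more <- c(clusters, list(mk(11, "pseudogene", "internal_stop",
                              "pseudogene", "internal_stop")))
  cs2 <- congruence_summary(more)
  expect_lte(cs2$internal_stop$fraction_incongruent,
             cs$internal_stop$fraction_incongruent)
})

test_that("congruence_summary rejects clusters from more than two assemblies", {
  members <- data.frame(
    assembly_id = c("A", "B", "C"), feature_id = c("x", "y", "z"),
    status = "gene", stringsAsFactors = FALSE
  )
  members$causes <- list(character(), character(), character())
  members$nt_sequence <- "AAA"
  expect_error(
    congruence_summary(list(list(members = members, excluded_paralog = TRUE))),
    "exactly two"
  )
})

test_that("spurious_counts is zero for an assembly against itself", {
  g <- make_genome(genome_spec(n_genes = 30, gene_len_mean = 450,
                               true_pseudo_fraction = 0.1, seed = 41))
  clone <- g
  clone$assembly_id <- "clone"
  sc <- spurious_counts(clone, g)
  expect_identical(sc$count$frameshift, 0L)
  expect_identical(sc$count$internal_stop, 0L)
})

test_that("a reassembly copy with a 1-nt deletion yields one spurious frameshift", {
  g <- make_genome(genome_spec(n_genes = 25, gene_len_mean = 450,
                               true_pseudo_fraction = 0, seed = 43))
  re <- g
  re$assembly_id <- "re"
  i <- 7L
  re$features$nt_sequence[[i]] <- delete_at(re$features$nt_sequence[[i]],
                                            200, 1)
  re <- annotate_with_classifier(re, g)
  expect_equal(re$features$causes[[i]], "frameshift")
  sc <- spurious_counts(re, g)
  expect_identical(sc$count$frameshift, 1L)
  expect_identical(sc$count$internal_stop, 0L)
  expect_equal(sc$rate$frameshift, 1 / 25)
  expect_equal(sc$density$frameshift, 1e6 / re$genome_length)
})

test_that("only the nearest pair in a paralogous cluster contributes", {
  set.seed(47)
  base <- random_dna(400)
  paralog <- mutate_dna(base, 0.06)
  ref_ft <- toy_features("ref", c(base, paralog), "gene")
  re_ft <- toy_features("re", base, "pseudogene",
                        causes = list("internal_stop"))
  ref <- assembly_annotation("ref", c(chr = strrep("A", 1000)),
                             cds_features("d", "chr", 1L, 10L, "+", "gene",
                                          nt_sequence = "ACGTACGTAC"))
  # build proper assembly objects carrying the toy features
  ref$features <- ref_ft
  re <- ref
  re$assembly_id <- "re"
  re$features <- re_ft
  sc <- spurious_counts(re, ref)
  expect_identical(sc$count$internal_stop, 1L)
  # the retained pair is (re pseudogene, identical ref gene); a second
  # pairing with the paralog must not be counted
  expect_identical(sc$n_cds, 1L)
})

test_that("overlap membership reproduces planted sharing patterns", {
  set.seed(49)
  shared_all <- vapply(1:5, function(i) random_dna(300), "")
  shared_ab <- vapply(1:2, function(i) random_dna(300), "")
  private_a <- random_dna(300)
  genes_everywhere <- vapply(1:4, function(i) random_dna(300), "")
  mk_asm <- function(id, pseudo_seqs, gene_seqs) {
    ft <- rbind(
      toy_features(id, c(pseudo_seqs, gene_seqs),
                   status = c(rep("pseudogene", length(pseudo_seqs)),
                              rep("gene", length(gene_seqs))),
                   causes = c(rep(list("internal_stop"), length(pseudo_seqs)),
                              rep(list(character()), length(gene_seqs))))
    )
    asm <- assembly_annotation(id, c(chr = strrep("A", 10)),
                               cds_features(character(), character(),
                                            integer(), integer(),
                                            character(), character()))
    asm$features <- ft
    asm
  }
  a <- mk_asm("A", c(shared_all, shared_ab, private_a), genes_everywhere)
  b <- mk_asm("B", c(shared_all, shared_ab), genes_everywhere)
  c3 <- mk_asm("C", shared_all, genes_everywhere)
  mem <- overlap_membership(list(a, b, c3))
  counts <- overlap_region_counts(mem)
  expect_equal(unname(counts[["A+B+C"]]), 5L)
  expect_equal(unname(counts[["A+B"]]), 2L)
  expect_equal(unname(counts[["A"]]), 1L)
  # four identical assemblies: every pseudogene cluster spans all four
  asms <- lapply(c("w", "x", "y", "z"), mk_asm,
                 pseudo_seqs = shared_all, gene_seqs = genes_everywhere)
  mem4 <- overlap_membership(asms)
  expect_true(all(vapply(mem4, length, integer(1)) == 4L))
  expect_error(overlap_membership(list(a)), "at least two")
})

test_that("assembly-length and subsample filters use the stated bounds", {
  expect_true(pair_run_filter(100, 100))
  expect_false(pair_run_filter(94, 100))
  expect_true(pair_run_filter(105, 100)) # inclusive bound
  expect_true(pair_run_filter(95, 100))
  expect_false(pair_run_filter(106, 100))

  expect_true(subsample_filter(1e6, 1e6, 50, 50, 0.9))
  expect_false(subsample_filter(0.79e6, 1e6, 50, 50, 0.9))
  expect_true(subsample_filter(0.80e6, 1e6, 50, 50, 0.9)) # inclusive
  expect_false(subsample_filter(1e6, 1e6, 39, 50, 0.9))
  expect_true(subsample_filter(1e6, 1e6, 60, 50, 0.9))
  expect_false(subsample_filter(1e6, 1e6, 50, 50, 0.80)) # strict
  expect_true(subsample_filter(1e6, 1e6, 50, 50, 0.801))
})

test_that("incongruence vanishes as the corruption rate goes to zero", {
  g <- make_genome(genome_spec(n_genes = 40, gene_len_mean = 450,
                               true_pseudo_fraction = 0.1, seed = 51))
  # same logit model, coverage sweep acts as the corruption-rate dial
  fracs <- vapply(c(5, 50, 5000), function(cv) {
    st1 <- corrupt(g, cv, 20, seed = 61)
    st2 <- corrupt(g, cv, 20, seed = 62)
    a <- annotate_with_classifier(st1$corrupted, g)
    a$assembly_id <- "copy1"
    b <- annotate_with_classifier(st2$corrupted, g)
    b$assembly_id <- "copy2"
    cs <- congruence_summary(match_cds(a, b))
    vals <- c(cs$frameshift$fraction_incongruent,
              cs$internal_stop$fraction_incongruent)
    w <- c(cs$frameshift$weight, cs$internal_stop$weight)
    sum(vals * w, na.rm = TRUE) / sum(w)
  }, numeric(1))
  expect_true(fracs[1] > fracs[3])
  expect_equal(fracs[3], 0)
})
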