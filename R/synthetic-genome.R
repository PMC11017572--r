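# Synthetic bacterial genomes with ground-truth annotation. A genome is a
# single contig (circular convention; features do not wrap the origin) of
# protein-coding ORFs separated by intergenic spacers. A chosen fraction
# of features are true pseudogenes, broken by a stop-introducing
# substitution or an out-of-frame indel, mirroring the two pseudogene
# causes the analysis tracks.

#' Specification of a synthetic genome
#'
#' @param n_genes number of coding features (>= 1).
#' @param gene_len_mean,gene_len_sd ORF length distribution in bp
#'   (normal, rounded to whole codons, minimum 150 bp).
#' @param intergenic_mean mean intergenic spacer length in bp
#'   (exponential, minimum 20 bp).
#' @param gc GC fraction of intergenic sequence and codon composition.
#' @param true_pseudo_fraction fraction of features that are genuine
#'   pseudogenes (`round(n_genes * fraction)` features, exactly).
#' @param cause_mix fraction of true pseudogenes caused by an internal
#'   stop (the rest are frameshifts).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 1000L, gene_len_mean = 900, gene_len_sd = 200,
                        intergenic_mean = 120, gc = 0.5,
                        true_pseudo_fraction = 0.02, cause_mix = 0.5,
                        seed = 1L) {
  stopifnot(n_genes >= 1L, gene_len_mean >= 150, gc > 0, gc < 1,
            true_pseudo_fraction >= 0, true_pseudo_fraction <= 1,
            cause_mix >= 0, cause_mix <= 1)
  structure(list(
    n_genes = as.integer(n_genes), gene_len_mean = gene_len_mean,
    gene_len_sd = gene_len_sd, intergenic_mean = intergenic_mean, gc = gc,
    true_pseudo_fraction = true_pseudo_fraction, cause_mix = cause_mix,
    seed = as.integer(seed)
  ), class = "genome_spec")
}

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# n random sense codons (no stops), GC-biased.
sample_sense_codons <- function(n, gc, stops) {
  if (n == 0L) return(character())
  codons <- paste0(sample_bases(n, gc), sample_bases(n, gc),
                   sample_bases(n, gc))
  bad <- codons %in% stops
  while (any(bad)) {
    nb <- sum(bad)
    codons[bad] <- paste0(sample_bases(nb, gc), sample_bases(nb, gc),
                          sample_bases(nb, gc))
    bad <- codons %in% stops
  }
  codons
}

# Replace an interior sense codon by a stop codon (codon index in
# [2, m - 2] so the classifier agrees the stop is internal).
introduce_internal_stop <- function(orf, codon_u, stop_u, stops) {
  m <- nchar(orf) %/% 3L
  j <- 2L + floor(codon_u * (m - 3L))
  stop_codon <- stops[1L + floor(stop_u * length(stops))]
  p <- (j - 1L) * 3L + 1L
  list(seq = paste0(substr(orf, 1L, p - 1L), stop_codon,
                    substr(orf, p + 3L, nchar(orf))),
       position = p)
}

# Insert or delete `len` bases at an interior position, clear of the
# start codon and of the terminal 10% (so the classifier's 5% terminal
# guard never masks a planted frameshift).
apply_indel <- function(seq, len, insert, pos_u, base_u) {
  L <- nchar(seq)
  lo <- 4L
  hi <- max(lo, floor(0.9 * L))
  p <- lo + floor(pos_u * (hi - lo + 1L))
  if (insert) {
    # inserted bases derived deterministically from base_u
    bases <- c("A", "C", "G", "T")
    ins <- paste(bases[1L + (floor(base_u * 4^(seq_len(len))) %% 4)],
                 collapse = "")
    list(seq = paste0(substr(seq, 1L, p - 1L), ins, substr(seq, p, L)),
         position = p, net = len)
  } else {
    list(seq = paste0(substr(seq, 1L, p - 1L), substr(seq, p + len, L)),
         position = p, net = -len)
  }
}

#' Generate a ground-truth synthetic genome
#'
#' @param spec a [genome_spec()].
#' @return An [assembly_annotation()] whose feature table records the true
#'   gene/pseudogene statuses and causes; `nt_sequence` holds each
#'   feature's coding-orientation sequence. Rerunning with the same spec
#'   reproduces the genome byte-for-byte.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  stops <- stop_codons("11")
  with_seed(derive_seed(spec$seed, 101L), {
    n <- spec$n_genes
    n_codons <- pmax(50L, round(stats::rnorm(n, spec$gene_len_mean / 3,
                                             spec$gene_len_sd / 3)))
    orfs <- vapply(n_codons, function(m) {
      paste0("ATG",
             paste(sample_sense_codons(m - 2L, spec$gc, stops), collapse = ""),
             stops[sample.int(length(stops), 1L)])
    }, character(1))
    spacer_len <- pmax(20L, round(stats::rexp(n + 1L,
                                              1 / spec$intergenic_mean)))
    spacers <- vapply(spacer_len, function(L) {
      paste(sample_bases(L, spec$gc), collapse = "")
    }, character(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    status <- rep("gene", n)
    causes <- rep(list(character()), n)
    n_pseudo <- round(n * spec$true_pseudo_fraction)
    if (n_pseudo > 0L) {
      pseudo_idx <- sort(sample.int(n, n_pseudo))
      for (i in pseudo_idx) {
        status[[i]] <- "pseudogene"
        if (stats::runif(1) < spec$cause_mix) {
          causes[[i]] <- "internal_stop"
          orfs[[i]] <- introduce_internal_stop(
            orfs[[i]], stats::runif(1), stats::runif(1), stops
          )$seq
        } else {
          causes[[i]] <- "frameshift"
          orfs[[i]] <- apply_indel(
            orfs[[i]], len = sample(1:2, 1L), insert = stats::runif(1) < 0.5,
            pos_u = stats::runif(1), base_u = stats::runif(1)
          )$seq
        }
      }
    }
    placed <- ifelse(strand == "-", reverse_complement(orfs), orfs)
    segments <- character(2L * n + 1L)
    segments[seq(1L, 2L * n + 1L, by = 2L)] <- spacers
    segments[seq(2L, 2L * n, by = 2L)] <- placed
    contig <- paste(segments, collapse = "")
    ends <- cumsum(nchar(segments))
    feat_seg <- seq(2L, 2L * n, by = 2L)
    start <- ends[feat_seg - 1L] + 1L
    end <- ends[feat_seg]
    features <- cds_features(
      feature_id = sprintf("gene_%05d", seq_len(n)),
      contig_id = "chr_1", start = start, end = end, strand = strand,
      status = status, causes = causes, nt_sequence = orfs
    )
    assembly_annotation(
      assembly_id = sprintf("synthetic_%d", spec$seed),
      contigs = c(chr_1 = contig), features = features
    )
  })
}
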