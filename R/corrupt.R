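# Coverage- and quality-dependent error injection into a ground-truth
# genome. This stands in for the full read-simulation + assembly +
# annotation chain: errors are injected directly at the assembly level.
# In `feature_level` mode each intact gene independently becomes a
# spurious pseudogene with probability
# plogis(beta0 + beta_cov * log10(coverage) + beta_q * quality), exactly
# the model family the analysis fits, making parameter recovery a sharp
# end-to-end test. In `base_level` mode substitutions and indels are
# scattered genome-wide at per-bp rates with the same covariate
# dependence, exercising the ORF classifier on realistic mutation
# patterns.

#' Assembly-level corruption model
#'
#' @param mode `"feature_level"` or `"base_level"`.
#' @param beta0,beta_cov,beta_q logit-scale coefficients of the per-CDS
#'   spurious-pseudogenization probability (defaults 2, -3, -0.1: at
#'   Q35 roughly 1 spurious pseudogene per Mbp at ~60-fold coverage,
#'   decaying to essentially none above 200-fold).
#' @param sub_rate0,indel_rate0 per-bp substitution/indel rates at the
#'   reference condition (`ref_coverage`, `ref_quality`), scaled across
#'   conditions by the same logit-linear factor (base_level mode).
#' @param indel_len_prob probabilities of indel lengths 1, 2, 3.
#' @param ref_coverage,ref_quality reference condition anchoring the
#'   base-level rates.
#' @return An object of class `corruption_model`.
#' @export
corruption_model <- function(mode = c("feature_level", "base_level"),
                             beta0 = 2, beta_cov = -3, beta_q = -0.1,
                             sub_rate0 = 2e-4, indel_rate0 = 4e-5,
                             indel_len_prob = c(0.5, 0.3, 0.2),
                             ref_coverage = 50, ref_quality = 35) {
  mode <- match.arg(mode)
  stopifnot(length(indel_len_prob) == 3L, all(indel_len_prob >= 0),
            abs(sum(indel_len_prob) - 1) < 1e-9, ref_coverage > 0)
  structure(list(
    mode = mode, beta0 = beta0, beta_cov = beta_cov, beta_q = beta_q,
    sub_rate0 = sub_rate0, indel_rate0 = indel_rate0,
    indel_len_prob = indel_len_prob,
    ref_coverage = ref_coverage, ref_quality = ref_quality
  ), class = "corruption_model")
}

#' Per-CDS spurious-pseudogenization probability of a corruption model
#'
#' @param model a [corruption_model()].
#' @param coverage fold coverage (> 0).
#' @param quality mean base Q-score.
#' @return Probability in (0, 1).
#' @export
pi_spurious <- function(model, coverage, quality) {
  stopifnot(coverage > 0)
  stats::plogis(model$beta0 + model$beta_cov * log10(coverage) +
                  model$beta_q * quality)
}

# Rebuild a single-contig assembly from (possibly edited) feature
# sequences, preserving intergenic spacers and recomputing coordinates.
rebuild_assembly <- function(truth, new_seqs, new_status, new_causes,
                             assembly_id, coverage, quality) {
  ft <- truth$features
  ord <- order(ft$start)
  stopifnot(length(truth$contig_lengths) == 1L)
  contig <- truth$contigs[[1L]]
  placed <- new_seqs
  minus <- ft$strand == "-"
  if (any(minus)) placed[minus] <- reverse_complement(new_seqs[minus])
  pieces <- character(2L * nrow(ft) + 1L)
  prev_end <- 0L
  for (r in seq_along(ord)) {
    i <- ord[[r]]
    pieces[[2L * r - 1L]] <- substr(contig, prev_end + 1L, ft$start[[i]] - 1L)
    pieces[[2L * r]] <- placed[[i]]
    prev_end <- ft$end[[i]]
  }
  pieces[[2L * nrow(ft) + 1L]] <- substr(contig, prev_end + 1L, nchar(contig))
  new_contig <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  start <- integer(nrow(ft)); end <- integer(nrow(ft))
  for (r in seq_along(ord)) {
    i <- ord[[r]]
    start[[i]] <- ends[[2L * r - 1L]] + 1L
    end[[i]] <- ends[[2L * r]]
  }
  features <- cds_features(
    feature_id = ft$feature_id, contig_id = names(truth$contig_lengths),
    start = start, end = end, strand = ft$strand,
    status = new_status, causes = new_causes, nt_sequence = new_seqs
  )
  assembly_annotation(
    assembly_id = assembly_id,
    contigs = stats::setNames(new_contig, names(truth$contig_lengths)),
    features = features, coverage = coverage, quality = quality,
    platform = "synthetic", assembler = "synthetic"
  )
}

new_event <- function(feature_id, event, length, position) {
  data.frame(feature_id = feature_id, event = event,
             length = as.integer(length), position = as.integer(position),
             stringsAsFactors = FALSE)
}

empty_event_log <- function() {
  new_event(character(), character(), integer(), integer())
}

corrupt_feature_level <- function(truth, coverage, quality, model, seed) {
  stops <- stop_codons("11")
  ft <- truth$features
  n <- nrow(ft)
  p <- pi_spurious(model, coverage, quality)
  # the flip draw per feature comes from a stream keyed only by `seed`,
  # so for a fixed seed the set of flipped features is monotone in the
  # flip probability: higher coverage can only remove flips, never add
  # them (common-random-numbers coupling across conditions).
  u_flip <- with_seed(derive_seed(seed, 1L), stats::runif(n))
  detail <- with_seed(derive_seed(seed, 2L),
                      matrix(stats::runif(5L * n), ncol = 5L))
  intact <- ft$status == "gene"
  flip <- intact & (u_flip < p)
  new_seqs <- ft$nt_sequence
  new_status <- ft$status
  new_causes <- ft$causes
  events <- list()
  for (i in which(flip)) {
    if (detail[i, 1L] < attr(model, "cause_mix_effective")) {
      res <- introduce_internal_stop(new_seqs[[i]], detail[i, 2L],
                                     detail[i, 3L], stops)
      new_seqs[[i]] <- res$seq
      new_status[[i]] <- "pseudogene"
      new_causes[[i]] <- "internal_stop"
      events[[length(events) + 1L]] <-
        new_event(ft$feature_id[[i]], "stop_substitution", 0L, res$position)
    } else {
      len <- if (detail[i, 2L] < 0.5) 1L else 2L
      res <- apply_indel(new_seqs[[i]], len, insert = detail[i, 3L] < 0.5,
                         pos_u = detail[i, 4L], base_u = detail[i, 5L])
      new_seqs[[i]] <- res$seq
      new_status[[i]] <- "pseudogene"
      new_causes[[i]] <- "frameshift"
      events[[length(events) + 1L]] <-
        new_event(ft$feature_id[[i]], "indel", res$net, res$position)
    }
  }
  list(seqs = new_seqs, status = new_status, causes = new_causes,
       events = if (length(events)) do.call(rbind, events) else
         empty_event_log())
}

mutate_bases <- function(seq, positions, u_bases) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (t in seq_along(positions)) {
    p <- positions[[t]]
    alt <- setdiff(bases, ch[[p]])
    ch[[p]] <- alt[[1L + floor(u_bases[[t]] * length(alt))]]
  }
  paste(ch, collapse = "")
}

corrupt_base_level <- function(truth, coverage, quality, model, seed) {
  stops <- stop_codons("11")
  scale <- pi_spurious(model, coverage, quality) /
    pi_spurious(model, model$ref_coverage, model$ref_quality)
  sub_rate <- min(model$sub_rate0 * scale, 0.2)
  indel_rate <- min(model$indel_rate0 * scale, 0.05)
  ft <- truth$features
  new_seqs <- ft$nt_sequence
  new_status <- ft$status
  new_causes <- ft$causes
  events <- list()
  with_seed(derive_seed(seed, 3L), {
    for (i in seq_len(nrow(ft))) {
      s <- new_seqs[[i]]
      L <- nchar(s)
      m <- L %/% 3L
      feat_causes <- new_causes[[i]]
      # substitutions, evaluated in the original reading frame
      n_sub <- stats::rbinom(1L, L, sub_rate)
      if (n_sub > 0L) {
        pos <- sort(sample.int(L, n_sub))
        ub <- stats::runif(n_sub)
        before <- s
        s <- mutate_bases(s, pos, ub)
        for (t in seq_along(pos)) {
          j <- (pos[[t]] - 1L) %/% 3L + 1L
          cs <- substr(s, (j - 1L) * 3L + 1L, j * 3L)
          was <- substr(before, (j - 1L) * 3L + 1L, j * 3L)
          made_stop <- j <= m - 2L && cs %in% stops && !(was %in% stops)
          ev <- if (made_stop) "stop_substitution" else "silent"
          if (made_stop) feat_causes <- union(feat_causes, "internal_stop")
          events[[length(events) + 1L]] <-
            new_event(ft$feature_id[[i]], ev, 0L, pos[[t]])
        }
      }
      # indels; net length mod 3 decides the frameshift label
      n_ind <- stats::rbinom(1L, L, indel_rate)
      net <- 0L
      if (n_ind > 0L) {
        for (t in seq_len(n_ind)) {
          len <- sample(1:3, 1L, prob = model$indel_len_prob)
          res <- apply_indel(s, len, insert = stats::runif(1) < 0.5,
                             pos_u = stats::runif(1),
                             base_u = stats::runif(1))
          s <- res$seq
          net <- net + res$net
          events[[length(events) + 1L]] <-
            new_event(ft$feature_id[[i]], "indel", res$net, res$position)
        }
        if (net %% 3L != 0L) feat_causes <- union(feat_causes, "frameshift")
      }
      new_seqs[[i]] <- s
      new_causes[[i]] <- feat_causes
      if (length(feat_causes)) new_status[[i]] <- "pseudogene"
    }
  })
  list(seqs = new_seqs, status = new_status, causes = new_causes,
       events = if (length(events)) do.call(rbind, events) else
         empty_event_log())
}

#' Corrupt a ground-truth genome at a given coverage and quality
#'
#' @param truth a single-contig [assembly_annotation()] from
#'   [make_genome()].
#' @param coverage,quality nominal fold coverage and mean base quality of
#'   the emulated sequencing experiment.
#' @param model a [corruption_model()].
#' @param seed integer seed. In feature-level mode the per-feature flip
#'   draws depend only on the seed (not on the condition), so runs at the
#'   same seed across a coverage grid are coupled: the realized spurious
#'   count is non-increasing in coverage by construction.
#' @param cause_mix fraction of spurious pseudogenes assigned the
#'   internal-stop cause in feature-level mode (default 0.5).
#' @return An object of class `synthetic_truth`: `genome` (the input
#'   truth), `corrupted` (an [assembly_annotation()] whose statuses are
#'   the ground-truth labels after corruption), `event_log` (data.frame
#'   with `feature_id`, `event` in stop_substitution/indel/silent,
#'   `length`, `position`), plus `coverage`, `quality`, `pi`, `mode`.
#' @export
corrupt <- function(truth, coverage, quality, model = corruption_model(),
                    seed = 1L, cause_mix = 0.5) {
  stopifnot(inherits(truth, "assembly_annotation"),
            inherits(model, "corruption_model"))
  if (any(is.na(truth$features$nt_sequence))) {
    stop("truth features must carry sequences")
  }
  p <- pi_spurious(model, coverage, quality)
  if (!is.finite(p) || p >= 1) stop("misconfigured model: pi >= 1")
  attr(model, "cause_mix_effective") <- cause_mix
  res <- if (model$mode == "feature_level") {
    corrupt_feature_level(truth, coverage, quality, model, seed)
  } else {
    corrupt_base_level(truth, coverage, quality, model, seed)
  }
  corrupted <- rebuild_assembly(
    truth, res$seqs, res$status, res$causes,
    assembly_id = paste0(truth$assembly_id, "_reassembly"),
    coverage = coverage, quality = quality
  )
  structure(list(
    genome = truth, corrupted = corrupted, event_log = res$events,
    coverage = coverage, quality = quality, pi = p, mode = model$mode
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %s at %g-fold, Q%g (pi = %.3g): %d corruption events\n",
    x$genome$assembly_id, x$coverage, x$quality, x$pi, nrow(x$event_log)
  ))
  invisible(x)
}

#' Fragment an assembly into contigs
#'
#' Splits contigs at uniformly random positions. Contigs shorter than
#' `min_contig_len` are dropped before "annotation"; features spanning a
#' break are absent from the output and recorded as truncation events
#' (they are not counted as frameshift or internal-stop pseudogenes).
#'
#' @param assembly an [assembly_annotation()] with sequences.
#' @param n_breaks number of random break points (>= 0).
#' @param min_contig_len minimum retained contig length (default 200 bp).
#' @param seed integer seed.
#' @return A fragmented [assembly_annotation()]; the attribute
#'   `"fragment_events"` lists dropped features and contigs.
#' @export
fragment_assembly <- function(assembly, n_breaks, min_contig_len = 200L,
                              seed = 1L) {
  stopifnot(n_breaks >= 0L)
  if (n_breaks == 0L) return(assembly)
  contigs <- assembly$contigs
  ft <- assembly$features
  offsets <- cumsum(c(0L, utils::head(nchar(contigs), -1L)))
  names(offsets) <- names(contigs)
  total <- sum(nchar(contigs))
  breaks_global <- with_seed(derive_seed(seed, 7L),
                             sort(sample.int(total - 1L, n_breaks)))
  events <- list()
  new_contigs <- character()
  keep_rows <- list()
  for (ci in names(contigs)) {
    L <- nchar(contigs[[ci]])
    local_breaks <- breaks_global[breaks_global > offsets[[ci]] &
                                    breaks_global <= offsets[[ci]] + L - 1L] -
      offsets[[ci]]
    bounds <- c(0L, local_breaks, L)
    for (s in seq_len(length(bounds) - 1L)) {
      seg_start <- bounds[[s]] + 1L
      seg_end <- bounds[[s + 1L]]
      seg_len <- seg_end - seg_start + 1L
      seg_id <- sprintf("%s_part%02d", ci, s)
      seg_features <- which(ft$contig_id == ci &
                              ft$start >= seg_start & ft$end <= seg_end)
      spanning <- which(ft$contig_id == ci &
                          ((ft$start < seg_start & ft$end >= seg_start) |
                             (ft$start <= seg_end & ft$end > seg_end)))
      for (i in spanning) {
        events[[length(events) + 1L]] <- data.frame(
          what = "truncated_feature", id = ft$feature_id[[i]],
          stringsAsFactors = FALSE
        )
      }
      if (seg_len < min_contig_len) {
        events[[length(events) + 1L]] <- data.frame(
          what = "dropped_contig", id = seg_id, stringsAsFactors = FALSE
        )
        next
      }
      new_contigs[[seg_id]] <- substr(contigs[[ci]], seg_start, seg_end)
      if (length(seg_features)) {
        sub <- ft[seg_features, , drop = FALSE]
        sub$contig_id <- seg_id
        sub$start <- sub$start - seg_start + 1L
        sub$end <- sub$end - seg_start + 1L
        keep_rows[[length(keep_rows) + 1L]] <- sub
      }
    }
  }
  new_ft <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    ft[integer(), , drop = FALSE]
  rownames(new_ft) <- NULL
  out <- assembly_annotation(
    assembly_id = assembly$assembly_id, contigs = new_contigs,
    features = new_ft, coverage = assembly$coverage,
    quality = assembly$quality, platform = assembly$platform,
    assembler = assembly$assembler
  )
  # spanning events deduplicated: a feature may straddle several segments
  ev <- if (length(events)) unique(do.call(rbind, events)) else
    data.frame(what = character(), id = character(), stringsAsFactors = FALSE)
  attr(out, "fragment_events") <- ev
  out
}

#' Run a full factorial corruption experiment
#'
#' Corrupts a ground-truth genome over a coverage x quality grid with
#' replicates, annotates each corrupted copy (by reference-based
#' classification or by the generator's own labels), counts spurious
#' pseudogenes against the truth genome via [spurious_counts()], and
#' returns the observation table that [fit_binomial()] consumes.
#'
#' @param spec a [genome_spec()] (the truth genome is generated from it).
#' @param coverages,qualities nonempty grids; defaults mirror the usual
#'   subsampling series 5, 10, 25, 50, 100, 250, 500-fold and Q 20/30/35.
#' @param replicates replicates per condition (default 3).
#' @param model a [corruption_model()].
#' @param seed master seed; per-replicate streams are derived from it, so
#'   the same master seed reproduces the observation table exactly.
#' @param method `"classifier"` (annotate corrupted features with
#'   [classify_vs_reference()], the full pipeline) or `"truth"` (use the
#'   generator's ground-truth labels; faster).
#' @param min_similarity clustering threshold for spurious counting.
#' @return A list with `observations` (data.frame: coverage, quality,
#'   replicate, cause, k, n, genome_length, density) and `truth` (the
#'   generated genome).
#' @export
simulate_experiment <- function(spec,
                                coverages = c(5, 10, 25, 50, 100, 250, 500),
                                qualities = c(20, 30, 35),
                                replicates = 3L,
                                model = corruption_model(),
                                seed = 1L,
                                method = c("classifier", "truth"),
                                min_similarity = 0.90) {
  method <- match.arg(method)
  if (!length(coverages) || !length(qualities)) stop("empty condition grid")
  truth <- make_genome(spec)
  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- derive_seed(seed, 11L, r)
    for (q in qualities) {
      for (cv in coverages) {
        st <- corrupt(truth, cv, q, model, seed = rep_seed)
        obs_asm <- if (method == "classifier") {
          annotate_with_classifier(st$corrupted, truth)
        } else {
          st$corrupted
        }
        sc <- spurious_counts(obs_asm, truth, min_similarity = min_similarity)
        for (cause in c("frameshift", "internal_stop")) {
          rows[[length(rows) + 1L]] <- data.frame(
            coverage = cv, quality = q, replicate = r, cause = cause,
            k = sc$count[[cause]], n = sc$n_cds,
            genome_length = sc$genome_length,
            density = sc$density[[cause]], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(observations = do.call(rbind, rows), truth = truth)
}
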