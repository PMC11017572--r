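# Cross-assembly coding-sequence matching and pseudogene congruence
# statistics. Features from two (or more) assemblies are single-linkage
# clustered under the relation percent_identity >= min_similarity;
# clusters of more than two members suggest paralogous copies and are
# excluded from congruence statistics.

as_feature_table <- function(x, default_id) {
  if (inherits(x, "assembly_annotation")) {
    ft <- x$features
    ft$assembly_id <- x$assembly_id
  } else {
    ft <- x
    if (is.null(ft$assembly_id)) ft$assembly_id <- default_id
  }
  if (any(is.na(ft$nt_sequence))) {
    stop("features missing nt_sequence; run extract_feature_seqs() first")
  }
  ft[, c("assembly_id", "feature_id", "status", "causes", "nt_sequence")]
}

#' Cluster coding sequences across assemblies
#'
#' Single-linkage clustering of features under the relation
#' `percent_identity >= min_similarity` (default 0.90). Candidate pairs
#' are found either by exhaustive all-pairs comparison or through an exact
#' k-mer prefilter (sequences sharing no 21-mer cannot reach 90% identity
#' over the minimum CDS length in practice); the prefilter does not change
#' the result, only the cost. Clusters of more than two members are
#' flagged `excluded_paralog`; singleton clusters are retained but carry
#' no pair information.
#'
#' @param ... two or more [assembly_annotation()] objects (or feature
#'   tables with an `assembly_id` column), or a single list of them.
#' @param min_similarity nucleotide identity threshold (default 0.90).
#' @param method `"auto"` (all-pairs below 65 unique sequences, k-mer
#'   prefilter above), `"allpairs"`, or `"kmer"`.
#' @param k k-mer length for the prefilter.
#' @return A list of clusters, each a list with `members` (data.frame with
#'   `assembly_id`, `feature_id`, `status`, `causes`, `nt_sequence`) and
#'   `excluded_paralog` (TRUE iff more than two members). Cluster order
#'   and member order are canonical (sorted by assembly then feature id),
#'   so the output is invariant to input permutation.
#' @export
match_cds <- function(..., min_similarity = 0.90,
                      method = c("auto", "allpairs", "kmer"), k = 21L) {
  method <- match.arg(method)
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1]]) &&
      !inherits(inputs[[1]], "assembly_annotation") &&
      is.null(inputs[[1]]$features) && is.null(inputs[[1]]$feature_id)) {
    inputs <- inputs[[1]]
  }
  if (length(inputs) < 2L) stop("need at least two assemblies")
  tabs <- lapply(seq_along(inputs), function(i) {
    as_feature_table(inputs[[i]], default_id = paste0("assembly_", i))
  })
  ft <- do.call(rbind, tabs)
  if (nrow(ft) == 0L) return(list())
  ft <- ft[order(ft$assembly_id, ft$feature_id), , drop = FALSE]
  rownames(ft) <- NULL
  useq <- unique(ft$nt_sequence)
  umap <- match(ft$nt_sequence, useq)
  nu <- length(useq)
  # the k-mer prefilter needs k-mers to exist; exhaustive comparison is
  # reserved for tiny or very short inputs
  if (method == "auto") {
    method <- if (nu <= 16L || any(nchar(useq) < k + 4L)) "allpairs" else
      "kmer"
  }
  cand <- if (method == "allpairs") {
    if (nu >= 2L) {
      cp <- utils::combn(nu, 2L)
      data.table::data.table(a = cp[1L, ], b = cp[2L, ])
    } else data.table::data.table(a = integer(), b = integer())
  } else {
    kmer_candidate_pairs(useq, k = k)
  }
  if (nrow(cand) > 0L) {
    ident <- mapply(function(i, j) percent_identity(useq[[i]], useq[[j]]),
                    cand$a, cand$b)
    cand <- cand[ident >= min_similarity]
  }
  memb <- edge_components(nu, cand)
  cluster_of <- memb[umap]
  clusters <- lapply(split(seq_len(nrow(ft)), cluster_of), function(rows) {
    members <- ft[rows, , drop = FALSE]
    rownames(members) <- NULL
    list(members = members, excluded_paralog = nrow(members) > 2L)
  })
  first_key <- vapply(clusters, function(cl) {
    paste(cl$members$assembly_id[[1]], cl$members$feature_id[[1]])
  }, character(1))
  clusters <- clusters[order(first_key)]
  names(clusters) <- NULL
  clusters
}

cluster_assemblies <- function(clusters) {
  unique(unlist(lapply(clusters, function(cl) cl$members$assembly_id)))
}

member_has_cause <- function(members, i, cause) {
  cause %in% members$causes[[i]]
}

#' Pseudogene congruence statistics for a pair of assemblies
#'
#' Counts, per cause (frameshift and internal stop), how many
#' cross-assembly CDS pairs are congruent (both members pseudogenes, at
#' least one carrying the cause) versus incongruent (exactly one member a
#' pseudogene, carrying the cause). Only non-paralog clusters of exactly
#' two members, one from each assembly, contribute. The incongruent
#' fraction is `n_incongruent / (n_congruent + n_incongruent)`, undefined
#' (`NA`) when the denominator is zero.
#'
#' @param clusters output of [match_cds()] over exactly two assemblies.
#' @return An object of class `congruence_summary`: per cause, a list with
#'   `n_congruent`, `n_incongruent`, `fraction_incongruent`, `weight`.
#' @export
congruence_summary <- function(clusters) {
  ids <- cluster_assemblies(clusters)
  if (length(ids) != 2L) {
    stop("congruence_summary requires clusters drawn from exactly two assemblies")
  }
  counts <- list(
    frameshift = c(congruent = 0L, incongruent = 0L),
    internal_stop = c(congruent = 0L, incongruent = 0L)
  )
  for (cl in clusters) {
    mb <- cl$members
    if (cl$excluded_paralog || nrow(mb) != 2L) next
    if (length(unique(mb$assembly_id)) != 2L) next # same-assembly pair
    pg <- mb$status == "pseudogene"
    if (!any(pg)) next
    for (cause in names(counts)) {
      carried <- vapply(seq_len(2L), member_has_cause,
                        logical(1), members = mb, cause = cause)
      if (all(pg)) {
        if (any(carried)) {
          counts[[cause]][["congruent"]] <- counts[[cause]][["congruent"]] + 1L
        }
      } else if (carried[pg]) {
        counts[[cause]][["incongruent"]] <-
          counts[[cause]][["incongruent"]] + 1L
      }
    }
  }
  out <- lapply(counts, function(ct) {
    w <- sum(ct)
    list(
      n_congruent = unname(ct[["congruent"]]),
      n_incongruent = unname(ct[["incongruent"]]),
      fraction_incongruent = if (w > 0L) unname(ct[["incongruent"]]) / w else
        NA_real_,
      weight = unname(w)
    )
  })
  structure(out, class = "congruence_summary", assemblies = ids)
}

#' @export
print.congruence_summary <- function(x, ...) {
  cat("<congruence_summary>", paste(attr(x, "assemblies"), collapse = " vs "),
      "\n")
  for (cause in names(x)) {
    s <- x[[cause]]
    cat(sprintf("  %-13s congruent %d, incongruent %d, fraction %s\n",
                cause, s$n_congruent, s$n_incongruent,
                if (is.na(s$fraction_incongruent)) "NA" else
                  sprintf("%.4f", s$fraction_incongruent)))
  }
  invisible(x)
}

#' @export
as.data.frame.congruence_summary <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(cause) {
    s <- x[[cause]]
    data.frame(cause = cause, n_congruent = s$n_congruent,
               n_incongruent = s$n_incongruent,
               fraction_incongruent = s$fraction_incongruent,
               weight = s$weight, stringsAsFactors = FALSE)
  }))
}

#' Spurious-pseudogene counts of a reassembly against a reference
#'
#' A spurious pseudogene is a pseudogene in the reassembly that clusters
#' with a gene in the reference. Within each multi-member cluster, only
#' the single highest-identity cross-assembly pair is retained (ties
#' broken lexicographically on feature ids) so paralogous copies do not
#' inflate counts. Counts are normalized by the reassembly's total number
#' of coding sequences (rate) and by its length (per-Mbp density).
#'
#' @param reassembly,reference annotated [assembly_annotation()] objects
#'   with feature sequences.
#' @param min_similarity clustering threshold (default 0.90).
#' @param clusters optional precomputed [match_cds()] output for the two
#'   assemblies (to avoid re-clustering).
#' @return An object of class `spurious_counts` with per-cause `count`,
#'   `rate` (count / n_cds), `density` (per Mbp), plus `n_cds` and
#'   `genome_length`.
#' @export
spurious_counts <- function(reassembly, reference, min_similarity = 0.90,
                            clusters = NULL) {
  if (nrow(reference$features) == 0L) stop("reference has no features")
  if (is.null(clusters)) {
    clusters <- match_cds(reassembly, reference,
                          min_similarity = min_similarity)
  }
  re_id <- reassembly$assembly_id
  ref_id <- reference$assembly_id
  counts <- c(frameshift = 0L, internal_stop = 0L)
  for (cl in clusters) {
    mb <- cl$members
    re_rows <- which(mb$assembly_id == re_id)
    ref_rows <- which(mb$assembly_id == ref_id)
    if (!length(re_rows) || !length(ref_rows)) next
    # retain the single nearest cross-assembly pair in the cluster
    pairs <- expand.grid(i = re_rows, j = ref_rows)
    pairs$ident <- mapply(function(i, j) {
      percent_identity(mb$nt_sequence[[i]], mb$nt_sequence[[j]])
    }, pairs$i, pairs$j)
    pairs <- pairs[order(-pairs$ident, mb$feature_id[pairs$i],
                         mb$feature_id[pairs$j]), , drop = FALSE]
    i <- pairs$i[[1L]]; j <- pairs$j[[1L]]
    if (mb$status[[i]] == "pseudogene" && mb$status[[j]] == "gene") {
      for (cause in names(counts)) {
        if (member_has_cause(mb, i, cause)) {
          counts[[cause]] <- counts[[cause]] + 1L
        }
      }
    }
  }
  n_cds <- nrow(reassembly$features)
  gl <- reassembly$genome_length
  structure(list(
    count = as.list(counts),
    rate = lapply(counts, function(x) if (n_cds > 0L) x / n_cds else NA_real_),
    density = lapply(counts, function(x) x * 1e6 / gl),
    n_cds = n_cds, genome_length = gl,
    reassembly_id = re_id, reference_id = ref_id
  ), class = "spurious_counts")
}

#' @export
print.spurious_counts <- function(x, ...) {
  cat(sprintf("<spurious_counts> %s vs reference %s (%d CDS)\n",
              x$reassembly_id, x$reference_id, x$n_cds))
  for (cause in names(x$count)) {
    cat(sprintf("  %-13s count %d, rate %.3g, density %.3g /Mbp\n",
                cause, x$count[[cause]], x$rate[[cause]], x$density[[cause]]))
  }
  invisible(x)
}

#' Pseudogene cluster membership across several assemblies of one sample
#'
#' Clusters all coding sequences across the assemblies and, for each
#' cluster containing at least one pseudogene, records the set of
#' assemblies contributing a pseudogene member — the membership sets
#' behind a Venn-style overlap of pseudogene calls.
#'
#' @param assemblies list of two or more [assembly_annotation()] objects
#'   of the same sample.
#' @param min_similarity clustering threshold (default 0.90).
#' @return Named list mapping a cluster label (the lexicographically first
#'   member's `assembly_id:feature_id`) to the sorted character vector of
#'   assembly ids with a pseudogene member in that cluster.
#' @export
overlap_membership <- function(assemblies, min_similarity = 0.90) {
  if (length(assemblies) < 2L) stop("need at least two assemblies")
  clusters <- match_cds(assemblies, min_similarity = min_similarity)
  out <- list()
  for (cl in clusters) {
    mb <- cl$members
    pg <- mb$status == "pseudogene"
    if (!any(pg)) next
    label <- paste0(mb$assembly_id[[1]], ":", mb$feature_id[[1]])
    out[[label]] <- sort(unique(mb$assembly_id[pg]))
  }
  out
}

#' Region counts of an overlap membership map
#'
#' @param membership output of [overlap_membership()].
#' @return Table of counts keyed by the sorted, `"+"`-joined assembly-id
#'   combination (one Venn region per distinct combination).
#' @export
overlap_region_counts <- function(membership) {
  keys <- vapply(membership, paste, character(1), collapse = "+")
  table(keys)
}

#' Assembly-length sanity filter for paired sequencing runs
#'
#' Keep a reassembly only when its length is between 95% and 105%
#' (inclusive) of the reference assembly's length.
#'
#' @param assembly_len,reference_len assembly lengths in bp (> 0).
#' @return Logical: keep?
#' @export
pair_run_filter <- function(assembly_len, reference_len) {
  stopifnot(all(assembly_len > 0), all(reference_len > 0))
  ratio <- assembly_len / reference_len
  ratio >= 0.95 & ratio <= 1.05
}

#' Inclusion filter for subsampled-coverage reassemblies
#'
#' Keep a reassembly only when (i) its total size is between 80% and 120%
#' of the source assembly size (inclusive), (ii) its observed coverage is
#' between 80% and 120% of the target coverage (inclusive), and (iii) its
#' alignment fraction (shared gene content) with the source assembly is
#' strictly greater than 0.80.
#'
#' @param total_len,source_len assembly sizes in bp.
#' @param observed_cov,target_cov fold coverages.
#' @param alignment_fraction shared gene content fraction in `[0, 1]`.
#' @return Logical: keep?
#' @export
subsample_filter <- function(total_len, source_len, observed_cov, target_cov,
                             alignment_fraction) {
  stopifnot(all(total_len > 0), all(source_len > 0), all(observed_cov > 0),
            all(target_cov > 0))
  size_ratio <- total_len / source_len
  cov_ratio <- observed_cov / target_cov
  size_ratio >= 0.80 & size_ratio <= 1.20 &
    cov_ratio >= 0.80 & cov_ratio <= 1.20 &
    alignment_fraction > 0.80
}
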