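# Fragment-based average nucleotide identity between two genomes,
# following the usual gANI-style conventions: the query is cut into
# non-overlapping 1-kb fragments, each fragment is placed on its best
# matching locus in the subject by exact-seed voting, and fragments
# aligning at >= 70% identity over >= 70% of their length contribute to
# the mean identity. The result is averaged over both directions.

as_contigs <- function(x) {
  if (inherits(x, "assembly_annotation")) {
    if (is.null(x$contigs)) stop("assembly has no contig sequences")
    return(x$contigs)
  }
  if (methods::is(x, "DNAStringSet")) {
    return(stats::setNames(as.character(x), names(x)))
  }
  stopifnot(is.character(x))
  x
}

# One direction: fragments of `query` against `subject`.
ani_one_direction <- function(query, subject, fragment_len, k,
                              min_identity, min_cov) {
  frags <- list()
  for (cs in query) {
    L <- nchar(cs)
    nfrag <- L %/% fragment_len
    if (nfrag == 0L) next
    starts <- (seq_len(nfrag) - 1L) * fragment_len + 1L
    frags <- c(frags, as.list(substring(cs, starts, starts + fragment_len - 1L)))
  }
  frags <- unlist(frags, use.names = FALSE)
  if (length(frags) == 0L) {
    return(list(identities = numeric(), n_fragments = 0L))
  }
  # three exact seeds per fragment vote on the target diagonal
  offsets <- c(1L, fragment_len %/% 2L, fragment_len - k + 1L)
  seed_seq <- unlist(lapply(frags, substring, offsets, offsets + k - 1L))
  seed_frag <- rep(seq_along(frags), each = length(offsets))
  seed_off <- rep(offsets, times = length(frags))
  clean <- !grepl("[^ACGT]", seed_seq)
  hits_frag <- integer(); hits_contig <- integer(); hits_diag <- integer()
  if (any(clean)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq[clean]))
    cfrag <- seed_frag[clean]; coff <- seed_off[clean]
    for (ci in seq_along(subject)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject[[ci]]))
      st <- Biostrings::startIndex(m)
      counts <- lengths(st)
      take <- counts > 0L & counts <= 50L # skip hyper-repetitive seeds
      if (!any(take)) next
      pos <- unlist(st[take], use.names = FALSE)
      rep_idx <- rep(which(take), counts[take])
      hits_frag <- c(hits_frag, cfrag[rep_idx])
      hits_contig <- c(hits_contig, rep(ci, length(pos)))
      hits_diag <- c(hits_diag, pos - coff[rep_idx] + 1L)
    }
  }
  identities <- rep(NA_real_, length(frags))
  if (length(hits_frag)) {
    hit_dt <- data.table::data.table(
      frag = hits_frag, contig = hits_contig, diag = hits_diag
    )
    frag <- contig <- diag <- votes <- NULL
    agg <- hit_dt[, list(votes = .N), by = list(frag, contig, diag)]
    data.table::setorder(agg, frag, -votes, contig, diag)
    best <- agg[!duplicated(agg$frag)]
    for (r in seq_len(nrow(best))) {
      fi <- best$frag[[r]]
      f <- frags[[fi]]
      subj <- subject[[best$contig[[r]]]]
      d <- best$diag[[r]]
      ident <- NA_real_
      if (best$votes[[r]] >= 2L && d >= 1L &&
          d + fragment_len - 1L <= nchar(subj)) {
        # seeds agree on one diagonal: substitution-only placement,
        # identity from direct base comparison
        win <- substr(subj, d, d + fragment_len - 1L)
        ident <- 1 - hamming_mismatches(f, win) / fragment_len
      }
      if (is.na(ident) || ident < min_identity) {
        slack <- max(30L, fragment_len %/% 10L)
        ws <- max(1L, d - slack)
        we <- min(nchar(subj), d + fragment_len - 1L + slack)
        if (we - ws + 1L >= min_cov * fragment_len) {
          aln <- raw_alignment(f, substr(subj, ws, we), type = "global-local")
          # identity over the pattern-spanned columns
          ident <- Biostrings::nmatch(aln) /
            nchar(as.character(Biostrings::pattern(aln)))
        }
      }
      identities[[fi]] <- ident
    }
  }
  pass <- !is.na(identities) & identities >= min_identity
  list(identities = identities[pass], n_fragments = length(frags))
}

#' Average nucleotide identity between two genomes
#'
#' @param genomeA,genomeB [assembly_annotation()] objects, `DNAStringSet`s,
#'   or named character vectors of contig sequences.
#' @param fragment_len fragment length in bp (default 1000).
#' @param min_identity,min_cov fragment acceptance cutoffs (defaults 0.70
#'   identity over 0.70 of the fragment length).
#' @param k exact-seed length used to place fragments (default 21).
#' @return An object of class `ani_result`: `ani` (percent in `[0, 100]`,
#'   `NA` when no fragment passes the cutoffs in either direction),
#'   `aligned_fraction`, `n_fragments`. `ani(A, A)` is exactly 100.
#' @export
ani <- function(genomeA, genomeB, fragment_len = 1000L, min_identity = 0.70,
                min_cov = 0.70, k = 21L) {
  A <- as_contigs(genomeA); B <- as_contigs(genomeB)
  if (length(A) == 0L || length(B) == 0L) stop("empty genome")
  d1 <- ani_one_direction(A, B, fragment_len, k, min_identity, min_cov)
  d2 <- ani_one_direction(B, A, fragment_len, k, min_identity, min_cov)
  ids <- list(d1$identities, d2$identities)
  dir_means <- vapply(ids, function(v) {
    if (length(v)) mean(v) * 100 else NA_real_
  }, numeric(1))
  n_frag <- d1$n_fragments + d2$n_fragments
  n_pass <- length(d1$identities) + length(d2$identities)
  ani_val <- if (all(is.na(dir_means))) NA_real_ else
    mean(dir_means, na.rm = TRUE)
  structure(list(
    ani = ani_val,
    aligned_fraction = if (n_frag > 0L) n_pass / n_frag else NA_real_,
    n_fragments = n_frag
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> ANI %s%% over %d fragments (aligned fraction %.3f)\n",
              if (is.na(x$ani)) "NA" else sprintf("%.4f", x$ani),
              x$n_fragments, x$aligned_fraction))
  invisible(x)
}

#' Nearest neighbor of each assembly by ANI
#'
#' @param ani_matrix square numeric matrix of ANI percents with assembly
#'   ids as dimnames; `NA` entries mean undefined ANI.
#' @return A `data.frame` with columns `assembly_id`, `partner_id`, `ani`;
#'   one row per assembly with at least one defined ANI. The partner is
#'   the distinct assembly with maximal ANI, ties broken by lexicographic
#'   assembly id.
#' @export
nearest_neighbor <- function(ani_matrix) {
  stopifnot(is.matrix(ani_matrix), nrow(ani_matrix) >= 2L,
            nrow(ani_matrix) == ncol(ani_matrix),
            !is.null(rownames(ani_matrix)))
  ids <- rownames(ani_matrix)
  out <- list()
  for (i in seq_along(ids)) {
    vals <- ani_matrix[i, ]
    vals[i] <- NA
    if (all(is.na(vals))) next
    best <- max(vals, na.rm = TRUE)
    cand <- sort(ids[which(!is.na(vals) & vals == best)])
    out[[length(out) + 1L]] <- data.frame(
      assembly_id = ids[[i]], partner_id = cand[[1L]], ani = best,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(assembly_id = character(), partner_id = character(),
                      ani = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
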