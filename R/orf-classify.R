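# Reference-based classification of observed coding sequences as intact
# genes or frameshift / internal-stop pseudogenes. This is a desk-scale
# stand-in for homology-based pseudogene calling in large annotation
# pipelines: the observed sequence is globally aligned to its reference
# ORF, the reading frame is tracked along the alignment, and verdicts are
# derived from indel bookkeeping and in-frame translation.

stop_codons <- function(code_table = "11") {
  code <- Biostrings::getGeneticCode(as.character(code_table))
  names(code)[code == "*"]
}

START_CODONS <- c("ATG", "GTG", "TTG")

#' Nucleotide percent identity of two sequences
#'
#' Identity of the global alignment under the package's fixed scoring
#' (match 1, mismatch -1, affine gaps costing 2 + length): matches divided
#' by aligned columns, gap columns counting in the denominator. Symmetric,
#' in `[0, 1]`, and exactly 1 iff the sequences are identical.
#'
#' @param a,b nonempty nucleotide strings.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("percent_identity: empty input")
  if (a == b) return(1.0)
  aln <- raw_alignment(a, b, type = "global")
  pairs <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  # columns = non-gap chars of both sequences minus doubly-counted
  # aligned pairs; end-gap columns are included
  Biostrings::nmatch(aln) / (nchar(a) + nchar(b) - pairs)
}

# Walk an alignment (pattern = observed, subject = reference) and report:
#  - gap runs with their reference start positions and net indel lengths,
#  - in-frame premature stops in the observed sequence, where the frame is
#    inherited from the reference through the alignment.
walk_alignment <- function(obs_aln, ref_aln, stops, ref_len) {
  oc <- strsplit(obs_aln, "", fixed = TRUE)[[1]]
  rc <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  ncols <- length(oc)
  m <- ref_len %/% 3L # reference codons, codon m is the terminal stop
  runs <- list() # each: list(ref_start, net)
  n_matches <- 0L
  offset <- 0L # insertions minus deletions so far
  refpos <- 0L
  in_run <- FALSE
  run_start_ref <- NA_integer_
  run_net <- 0L
  # per-reference-position record of the observed base and frame state
  obs_at_ref <- character(ref_len)
  inframe_at_ref <- logical(ref_len)
  for (i in seq_len(ncols)) {
    o <- oc[[i]]; r <- rc[[i]]
    if (o == "-" || r == "-") {
      if (!in_run) {
        in_run <- TRUE
        run_start_ref <- refpos + 1L
        run_net <- 0L
      }
      if (r == "-") { # insertion in observed
        offset <- offset + 1L
        run_net <- run_net + 1L
      } else { # deletion from observed
        offset <- offset - 1L
        refpos <- refpos + 1L
        run_net <- run_net - 1L
        if (refpos <= ref_len) {
          obs_at_ref[[refpos]] <- "-"
          inframe_at_ref[[refpos]] <- FALSE
        }
      }
    } else {
      if (in_run) {
        runs[[length(runs) + 1L]] <-
          list(ref_start = run_start_ref, net = run_net)
        in_run <- FALSE
      }
      refpos <- refpos + 1L
      if (o == r) n_matches <- n_matches + 1L
      if (refpos <= ref_len) {
        obs_at_ref[[refpos]] <- o
        inframe_at_ref[[refpos]] <- (offset %% 3L == 0L)
      }
    }
  }
  if (in_run) {
    runs[[length(runs) + 1L]] <- list(ref_start = run_start_ref, net = run_net)
  }
  # premature stops: reference codons fully covered, in frame, no gaps,
  # whose observed triplet is a stop. Codons m (terminal stop) and m-1
  # (last complete codon before the stop) are not "internal".
  n_stops <- 0L
  if (m >= 3L) {
    for (j in seq_len(m - 2L)) {
      p <- (j - 1L) * 3L + 1L
      trip <- obs_at_ref[p:(p + 2L)]
      if (all(inframe_at_ref[p:(p + 2L)]) && !any(trip == "-") &&
          paste(trip, collapse = "") %in% stops) {
        n_stops <- n_stops + 1L
      }
    }
  }
  list(runs = runs, n_matches = n_matches, ncols = ncols, n_stops = n_stops)
}

#' Classify an observed sequence against its reference ORF
#'
#' Globally aligns `obs` to `ref_orf` and tracks the reading frame along
#' the alignment. A frameshift is reported when the net indel length over
#' any prefix of the (frame-relevant) indel runs is not a multiple of 3 —
#' i.e., some aligned segment is out of frame — ignoring indels within the
#' final 5% of the reference length (alignment end gaps are unreliable).
#' An internal stop is reported when the in-frame translation of `obs`
#' (frame inherited from the reference through the alignment) contains a
#' stop codon strictly before the reference's terminal stop; a stop in the
#' last complete codon before the reference stop does not count, since it
#' terminates where the gene terminates. Out-of-frame regions are not
#' translated, so a frameshift does not cascade into spurious internal
#' stop calls.
#'
#' @param ref_orf reference ORF: starts with a start codon (ATG/GTG/TTG),
#'   ends with a stop codon, length divisible by 3.
#' @param obs putative homolog, 5'->3'.
#' @param code_table genetic code id (default "11", bacterial).
#' @param terminal_guard fraction of the reference 3' end inside which
#'   indels are not called as frameshifts (default 0.05).
#' @return An object of class `orf_verdict`: `status` ("gene",
#'   "pseudogene", or "unclassifiable" when `obs` exceeds 10% ambiguous
#'   bases), `causes` (subset of frameshift/internal_stop),
#'   `n_premature_stops`, `net_indel_mod3`, `identity`.
#' @export
classify_vs_reference <- function(ref_orf, obs, code_table = "11",
                                  terminal_guard = 0.05) {
  if (!nzchar(ref_orf) || !nzchar(obs)) stop("empty sequence")
  ref_orf <- toupper(ref_orf); obs <- toupper(obs)
  L <- nchar(ref_orf)
  stops <- stop_codons(code_table)
  if (L %% 3L != 0L) stop("reference ORF length not divisible by 3")
  if (!substr(ref_orf, 1L, 3L) %in% START_CODONS) {
    stop("reference ORF does not start with a start codon")
  }
  if (!substr(ref_orf, L - 2L, L) %in% stops) {
    stop("reference ORF does not end with a stop codon")
  }
  n_amb <- nchar(obs) - sum(charToRaw(obs) %in% charToRaw("ACGT"))
  if (n_amb / nchar(obs) > 0.10) {
    return(structure(list(
      status = "unclassifiable", causes = character(),
      n_premature_stops = NA_integer_, net_indel_mod3 = NA_integer_,
      identity = NA_real_
    ), class = "orf_verdict"))
  }
  aln <- align_pair(obs, ref_orf, type = "global")
  w <- walk_alignment(aln$pattern, aln$subject, stops, L)
  guard_start <- floor((1 - terminal_guard) * L)
  qualifying <- Filter(function(r) r$ref_start <= guard_start, w$runs)
  nets <- vapply(qualifying, `[[`, integer(1), "net")
  framebroken <- length(nets) > 0L && any(cumsum(nets) %% 3L != 0L)
  net_mod3 <- if (length(nets)) as.integer(sum(nets) %% 3L) else 0L
  causes <- character()
  if (framebroken) causes <- c(causes, "frameshift")
  if (w$n_stops >= 1L) causes <- c(causes, "internal_stop")
  structure(list(
    status = if (length(causes)) "pseudogene" else "gene",
    causes = causes,
    n_premature_stops = w$n_stops,
    net_indel_mod3 = net_mod3,
    identity = w$n_matches / w$ncols
  ), class = "orf_verdict")
}

#' @export
print.orf_verdict <- function(x, ...) {
  cat(sprintf(
    "<orf_verdict> %s%s; premature stops %s; net indel mod 3 = %s; identity %.4f\n",
    x$status,
    if (length(x$causes)) paste0(" [", paste(x$causes, collapse = ", "), "]") else "",
    x$n_premature_stops, x$net_indel_mod3,
    if (is.na(x$identity)) NA else x$identity
  ))
  invisible(x)
}
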