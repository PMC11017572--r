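# Internal helpers shared across modules.

#' @importFrom data.table data.table setkey setorder
.datatable.aware <- TRUE

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with an arbitrary sequence of integer indices into a
#' new seed below 2^31, so that independent random streams (one per
#' condition, replicate, or stage) can be derived deterministically from a
#' single master seed.
#'
#' @param master integer master seed.
#' @param ... further integer indices identifying the stream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(as.numeric(master), as.numeric(unlist(list(...))))
  h <- 0
  # multiplier kept small so h * mult stays exact in double precision
  for (v in idx) h <- (h * 69069 + abs(v) + 1) %% 2147483629
  as.integer(h)
}

# Run an expression with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming mismatch count between two equal-length strings (fast byte path).
hamming_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

.pkg_cache <- new.env(parent = emptyenv())

scoring_matrix <- function() {
  if (is.null(.pkg_cache$submat)) {
    .pkg_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE
    )
  }
  .pkg_cache$submat
}

raw_alignment <- function(a, b, type = "global") {
  Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = scoring_matrix(),
    gapOpening = 2, gapExtension = 1, type = type
  )
}

# Global alignment with the package's fixed scoring (match 1, mismatch
# -1, gap of length L costs 2 + L), returning the full aligned strings.
# The fast pattern()/subject() accessors clip terminal one-sided columns,
# which are reconstructed here from the aligned ranges.
align_pair <- function(a, b, type = "global") {
  aln <- raw_alignment(a, b, type = type)
  p0 <- as.character(Biostrings::pattern(aln))
  s0 <- as.character(Biostrings::subject(aln))
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  head_p <- ps - 1L; tail_p <- nchar(a) - pe
  head_s <- ss - 1L; tail_s <- nchar(b) - se
  if (type != "global") { # keep local subject clipping
    head_s <- 0L; tail_s <- 0L
  }
  pattern <- paste0(
    substr(a, 1L, head_p), strrep("-", head_s), p0,
    strrep("-", tail_s), substr(a, pe + 1L, nchar(a))
  )
  subject <- paste0(
    strrep("-", head_p), substr(b, 1L, head_s * (type == "global")), s0,
    substr(b, se + 1L, (se + tail_s) * (type == "global")),
    strrep("-", tail_p)
  )
  list(pattern = pattern, subject = subject,
       score = Biostrings::score(aln))
}

# Identity of an alignment: matches / aligned columns (gap columns count
# in the denominator).
alignment_identity <- function(pattern, subject) {
  pa <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sa <- strsplit(subject, "", fixed = TRUE)[[1]]
  sum(pa == sa & pa != "-") / length(pa)
}

# Exact numeric codes of all k-mers of one sequence (NA across non-ACGT
# characters). 4^k fits exactly in a double for k <= 26.
kmer_codes <- function(seq, k) {
  u <- utf8ToInt(seq)
  digs <- rep(NA_real_, length(u))
  digs[u == 65L] <- 0 # A
  digs[u == 67L] <- 1 # C
  digs[u == 71L] <- 2 # G
  digs[u == 84L] <- 3 # T
  if (length(u) < k) return(numeric())
  v <- stats::filter(digs, 4^(0:(k - 1)), sides = 1)
  as.numeric(v[k:length(u)])
}

# Candidate pairs of sequences sharing at least one exact k-mer.
# Used as a prefilter before alignment; at >= 90% identity over >= 150 bp
# the probability of sharing no 21-mer is negligible, while unrelated
# random sequences essentially never share one.
kmer_candidate_pairs <- function(seqs, k = 21L) {
  n <- length(seqs)
  if (n < 2L) return(data.table::data.table(a = integer(), b = integer()))
  codes <- lapply(seqs, kmer_codes, k = k)
  nk <- lengths(codes)
  dt <- data.table::data.table(
    code = unlist(codes, use.names = FALSE),
    id = rep.int(seq_len(n), nk)
  )
  code <- id <- i.id <- a <- b <- NULL # NSE notes
  dt <- dt[!is.na(code)]
  dt <- unique(dt)
  # only codes shared by more than one sequence can produce a pair
  shared <- dt$code[duplicated(dt$code)]
  if (!length(shared)) {
    return(data.table::data.table(a = integer(), b = integer()))
  }
  sub <- dt[code %in% shared]
  j <- sub[sub, on = "code", allow.cartesian = TRUE]
  pairs <- j[id < i.id, list(a = id, b = i.id)]
  unique(pairs)
}

# Connected components over n nodes given an edge table (single linkage).
edge_components <- function(n, edges) {
  if (n == 0L) return(integer())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  }
  igraph::components(g)$membership
}
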