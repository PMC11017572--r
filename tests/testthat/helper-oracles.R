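# Independent oracles used by the tests. These deliberately reimplement
# the checked quantities by brute force (quadratic DP, exhaustive
# enumeration, direct summation, iterated grid search) and never call the
# code paths they verify.

# Needleman-Wunsch global alignment identity with affine gaps
# (match 1, mismatch -1, gap of length L costs gap_open + L * gap_ext),
# matches / aligned columns. Quadratic DP with full traceback.
nw_identity_oracle <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 2, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b: consuming A
  Y <- matrix(NEG, n + 1, m + 1) # gap in a: consuming B
  pM <- matrix(0L, n + 1, m + 1)
  pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
    pX[i, 1] <- if (i == 2) 1L else 2L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -(gap_open + (j - 1) * gap_ext)
    pY[1, j] <- if (j == 2) 1L else 2L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + s; pM[i, j] <- k
      candX <- c(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      kx <- which.max(candX)
      X[i, j] <- candX[kx]; pX[i, j] <- kx
      candY <- c(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      ky <- which.max(candY)
      Y[i, j] <- candY[ky]; pY[i, j] <- ky
    }
  }
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  matches <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1L) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1L
      state <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      nxt <- if (pX[i, j] == 1L) 1L else 2L
      i <- i - 1; state <- nxt
    } else {
      nxt <- if (pY[i, j] == 1L) 1L else 3L
      j <- j - 1; state <- nxt
    }
  }
  matches / cols
}

# Exhaustive pair-enumeration congruence oracle over a cluster list.
congruence_oracle <- function(clusters) {
  out <- list(frameshift = c(0L, 0L), internal_stop = c(0L, 0L))
  for (cl in clusters) {
    mb <- cl$members
    if (nrow(mb) != 2L) next
    if (length(unique(mb$assembly_id)) != 2L) next
    pg <- mb$status == "pseudogene"
    if (sum(pg) == 0L) next
    for (cause in names(out)) {
      c1 <- cause %in% mb$causes[[1]]
      c2 <- cause %in% mb$causes[[2]]
      if (sum(pg) == 2L && (c1 || c2)) {
        out[[cause]][1] <- out[[cause]][1] + 1L
      } else if (sum(pg) == 1L) {
        carrier <- if (pg[1]) c1 else c2
        if (carrier) out[[cause]][2] <- out[[cause]][2] + 1L
      }
    }
  }
  lapply(out, function(v) {
    w <- sum(v)
    list(n_congruent = v[1], n_incongruent = v[2],
         fraction_incongruent = if (w > 0) v[2] / w else NA_real_,
         weight = w)
  })
}

# Binomial CDF by direct summation of the probability mass.
binom_cdf_oracle <- function(t, n, p) {
  i <- 0:t
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# One-covariate binomial MLE (logit(p) = b0 + b1 * log10(cov)) by
# iterated grid search refinement.
grid_mle_oracle <- function(k, n, coverage, b0_range = c(-10, 10),
                            b1_range = c(-10, 10), rounds = 8L,
                            grid_n = 21L) {
  l <- log10(coverage)
  ll <- function(b0, b1) {
    mu <- plogis(b0 + b1 * l)
    sum(dbinom(k, n, pmin(pmax(mu, 1e-15), 1 - 1e-15), log = TRUE))
  }
  for (r in seq_len(rounds)) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = grid_n)
    b1s <- seq(b1_range[1], b1_range[2], length.out = grid_n)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    b0 <- b0s[best[1]]; b1 <- b1s[best[2]]
    span0 <- diff(b0_range) / (grid_n - 1)
    span1 <- diff(b1_range) / (grid_n - 1)
    b0_range <- c(b0 - span0, b0 + span0)
    b1_range <- c(b1 - span1, b1 + span1)
  }
  c(b0 = b0, b1 = b1)
}

# ---- shared fixture builders -------------------------------------------

# An ORF whose interior codons contain no T, so no point substitution or
# indel junction in the interior can create a stop codon by accident.
fixture_orf <- function(n_codons = 60) {
  safe <- c("GCA", "GGC", "CAG", "AAC", "GAA", "CCG", "GCG", "AGC")
  paste0("ATG",
         paste(rep_len(safe, n_codons - 2), collapse = ""),
         "TAA")
}

delete_at <- function(seq, pos, len) {
  paste0(substr(seq, 1, pos - 1), substr(seq, pos + len, nchar(seq)))
}

insert_at <- function(seq, pos, what) {
  paste0(substr(seq, 1, pos - 1), what, substr(seq, pos, nchar(seq)))
}

replace_codon <- function(orf, codon_idx, codon) {
  p <- (codon_idx - 1) * 3 + 1
  paste0(substr(orf, 1, p - 1), codon, substr(orf, p + 3, nchar(orf)))
}

# Feature table for toy clustering tests.
toy_features <- function(id, seqs, status, causes = NULL) {
  ft <- cds_features(
    feature_id = sprintf("%s_f%02d", id, seq_along(seqs)),
    contig_id = "chr", start = rep(1L, length(seqs)), end = nchar(seqs),
    strand = "+",
    status = status, causes = causes, nt_sequence = seqs
  )
  ft$assembly_id <- id
  ft
}

# Random toy cluster list for congruence tests.
random_clusters <- function(n_clusters, seed) {
  set.seed(seed)
  all_causes <- list(character(), "frameshift", "internal_stop",
                     c("frameshift", "internal_stop"))
  lapply(seq_len(n_clusters), function(i) {
    size <- sample(1:3, 1, prob = c(0.2, 0.6, 0.2))
    ids <- if (size == 1) sample(c("A", "B"), 1) else
      if (size == 2) sample(c("A", "B"), 2, replace = sample(c(TRUE, FALSE), 1)) else
        sample(c("A", "B"), 3, replace = TRUE)
    status <- sample(c("gene", "pseudogene"), size, replace = TRUE)
    causes <- lapply(seq_len(size), function(j) {
      if (status[j] == "gene") character() else
        all_causes[[sample(2:4, 1)]]
    })
    members <- data.frame(
      assembly_id = ids,
      feature_id = sprintf("c%03d_m%d", i, seq_len(size)),
      status = status, stringsAsFactors = FALSE
    )
    members$causes <- causes
    members$nt_sequence <- strrep("A", 30)
    list(members = members, excluded_paralog = size > 2)
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(ch)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in idx) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  paste(ch, collapse = "")
}
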