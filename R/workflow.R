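# Workflow drivers: annotate a reassembly with the reference-based
# classifier, survey pseudogene congruence across a set of assemblies,
# screen assemblies with the nearest-neighbor binomial filter, and run
# the coverage-model experiment end to end.

#' Annotate an assembly by classification against a reference
#'
#' For each feature whose reference counterpart (matched by feature id)
#' is an intact gene, the observed sequence is classified with
#' [classify_vs_reference()] and the verdict's status and causes replace
#' the feature's annotation. Features whose reference counterpart is
#' itself a pseudogene inherit the reference's status and causes (the
#' ancestral defect), since an intact reference ORF to classify against
#' does not exist.
#'
#' @param assembly the assembly to annotate (features with sequences).
#' @param reference the reference [assembly_annotation()].
#' @return The assembly with re-annotated `status`/`causes`.
#' @export
annotate_with_classifier <- function(assembly, reference) {
  ft <- assembly$features
  ref_ft <- reference$features
  idx <- match(ft$feature_id, ref_ft$feature_id)
  for (i in seq_len(nrow(ft))) {
    j <- idx[[i]]
    if (is.na(j)) next
    if (ref_ft$status[[j]] == "gene") {
      if (ft$nt_sequence[[i]] == ref_ft$nt_sequence[[j]]) {
        ft$status[[i]] <- "gene"
        ft$causes[[i]] <- character()
      } else {
        v <- classify_vs_reference(ref_ft$nt_sequence[[j]],
                                   ft$nt_sequence[[i]])
        if (v$status != "unclassifiable") {
          ft$status[[i]] <- v$status
          ft$causes[[i]] <- v$causes
        }
      }
    } else {
      ft$status[[i]] <- ref_ft$status[[j]]
      ft$causes[[i]] <- ref_ft$causes[[j]]
    }
  }
  assembly$features <- ft
  assembly
}

# Weighted median of values with nonnegative weights.
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[[which(cw >= 0.5)[1L]]]
}

#' Weighted moving median trend
#'
#' Sorts points by `x` and reports, at each point, the weighted median of
#' `y` within a centered window — the trend summary used for
#' incongruence-vs-ANI curves (each point weighted by its pseudogene pair
#' count).
#'
#' @param x,y coordinates.
#' @param w nonnegative weights.
#' @param window odd window size (default 5).
#' @return data.frame with `x`, `y`, `w`, `trend`, sorted by `x`.
#' @export
weighted_moving_median <- function(x, y, w, window = 5L) {
  stopifnot(length(x) == length(y), length(x) == length(w), window >= 1L)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; w <- w[ord]
  half <- window %/% 2L
  n <- length(x)
  trend <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sel <- lo:hi
    if (sum(w[sel]) == 0) return(NA_real_)
    weighted_median(y[sel], w[sel])
  }, numeric(1))
  data.frame(x = x, y = y, w = w, trend = trend)
}

#' Pairwise ANI matrix over a set of assemblies
#'
#' @param assemblies named list of [assembly_annotation()] objects (or
#'   contig sets).
#' @param ... passed to [ani()].
#' @return Symmetric matrix of ANI percents with 100 on the diagonal.
#' @export
ani_matrix <- function(assemblies, ...) {
  ids <- names(assemblies)
  if (is.null(ids)) {
    ids <- vapply(assemblies, function(a) a$assembly_id, character(1))
  }
  n <- length(assemblies)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- ani(assemblies[[i]], assemblies[[j]], ...)
      m[i, j] <- m[j, i] <- r$ani
    }
  }
  m
}

#' Pseudogene congruence survey across a set of assemblies
#'
#' Computes all-pairs ANI, picks each assembly's nearest neighbor,
#' clusters coding sequences per pair at the similarity threshold, and
#' tabulates congruent/incongruent pseudogene pairs per cause, together
#' with a weighted moving-median trend of the incongruent fraction
#' against ANI.
#'
#' @param assemblies named list of at least two annotated assemblies with
#'   feature sequences.
#' @param min_similarity CDS clustering threshold (default 0.90).
#' @param trend_window window of the weighted moving median (default 5).
#' @param ... passed to [ani()] (e.g. `fragment_len`).
#' @return A list with `pairs` (one row per assembly with a defined
#'   neighbor and per cause: counts, fraction, weight), `trend` (per
#'   cause), and `ani_matrix`.
#' @export
run_congruence_survey <- function(assemblies, min_similarity = 0.90,
                                  trend_window = 5L, ...) {
  if (length(assemblies) < 2L) stop("need at least two assemblies")
  if (is.null(names(assemblies))) {
    names(assemblies) <- vapply(assemblies, function(a) a$assembly_id,
                                character(1))
  }
  am <- ani_matrix(assemblies, ...)
  nn <- nearest_neighbor(am)
  rows <- list()
  for (r in seq_len(nrow(nn))) {
    a <- assemblies[[nn$assembly_id[[r]]]]
    b <- assemblies[[nn$partner_id[[r]]]]
    clusters <- match_cds(a, b, min_similarity = min_similarity)
    cs <- congruence_summary(clusters)
    for (cause in names(cs)) {
      s <- cs[[cause]]
      rows[[length(rows) + 1L]] <- data.frame(
        assembly_id = nn$assembly_id[[r]], partner_id = nn$partner_id[[r]],
        ani = nn$ani[[r]], cause = cause,
        n_congruent = s$n_congruent, n_incongruent = s$n_incongruent,
        fraction_incongruent = s$fraction_incongruent, weight = s$weight,
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, rows)
  trend <- lapply(split(pairs, pairs$cause), function(df) {
    ok <- !is.na(df$fraction_incongruent)
    if (sum(ok) == 0L) return(NULL)
    weighted_moving_median(df$ani[ok], df$fraction_incongruent[ok],
                           df$weight[ok], window = trend_window)
  })
  list(pairs = pairs, trend = trend, ani_matrix = am)
}

#' Screen assemblies with the nearest-neighbor binomial filter
#'
#' @param stats data.frame with columns `assembly_id`, `n_stops`,
#'   `n_cds` (internal-stop pseudogene and CDS counts per assembly).
#' @param neighbors data.frame with columns `assembly_id`, `partner_id`,
#'   `ani` (e.g. from [nearest_neighbor()]).
#' @param ani_gate,quantile passed to [binomial_filter()].
#' @return A list with `verdicts` (one row per assembly: evaluated,
#'   threshold, reject, ...) and `summary` (`n_total`, `n_evaluated`,
#'   `n_rejected`, `fraction_rejected` among evaluated; `NA` when none
#'   evaluated).
#' @export
run_filter_screen <- function(stats, neighbors, ani_gate = 99.9,
                              quantile = 0.99) {
  stopifnot(all(c("assembly_id", "n_stops", "n_cds") %in% names(stats)))
  if (is.null(neighbors) ||
      !all(c("assembly_id", "partner_id", "ani") %in% names(neighbors))) {
    stop("missing or malformed neighbor table")
  }
  rows <- list()
  for (i in seq_len(nrow(stats))) {
    id <- stats$assembly_id[[i]]
    j <- match(id, neighbors$assembly_id)
    if (is.na(j)) {
      rows[[length(rows) + 1L]] <- data.frame(
        assembly_id = id, partner_id = NA_character_, neighbor_ani = NA_real_,
        evaluated = FALSE, n_stops = stats$n_stops[[i]],
        n_cds = stats$n_cds[[i]], neighbor_rate = NA_real_,
        threshold = NA_integer_, reject = NA, stringsAsFactors = FALSE
      )
      next
    }
    partner <- neighbors$partner_id[[j]]
    pk <- match(partner, stats$assembly_id)
    if (is.na(pk)) stop("neighbor ", partner, " missing from stats table")
    v <- binomial_filter(
      n_stops = stats$n_stops[[i]], n_cds = stats$n_cds[[i]],
      neighbor_stops = stats$n_stops[[pk]],
      neighbor_n_cds = stats$n_cds[[pk]],
      neighbor_ani = neighbors$ani[[j]],
      ani_gate = ani_gate, quantile = quantile
    )
    rows[[length(rows) + 1L]] <- data.frame(
      assembly_id = id, partner_id = partner, neighbor_ani = v$neighbor_ani,
      evaluated = v$evaluated, n_stops = v$n_stops, n_cds = v$n_cds,
      neighbor_rate = v$neighbor_rate, threshold = v$threshold,
      reject = v$reject, stringsAsFactors = FALSE
    )
  }
  verdicts <- do.call(rbind, rows)
  n_eval <- sum(verdicts$evaluated)
  n_rej <- sum(verdicts$reject[verdicts$evaluated])
  list(
    verdicts = verdicts,
    summary = list(
      n_total = nrow(verdicts), n_evaluated = n_eval, n_rejected = n_rej,
      fraction_rejected = if (n_eval > 0L) n_rej / n_eval else NA_real_
    )
  )
}

#' Fit the coverage model and derive its two predictions
#'
#' Fits [fit_binomial()] per cause on an observation table (e.g. from
#' [simulate_experiment()]) and reports, per cause, the expected
#' spurious-pseudogene density at a reporting coverage (default 50-fold)
#' and the coverage required to reach a target density (default 1 per
#' Mbp).
#'
#' @param observations data.frame with columns `cause`, `k`, `n`,
#'   `coverage`, `quality`, `genome_length`.
#' @param report_coverage coverage at which to report the expected
#'   density (default 50).
#' @param target_density density defining the required coverage (default
#'   1 per Mbp).
#' @param quality quality at which predictions are evaluated (default:
#'   the maximum quality present, i.e. the most favorable condition).
#' @return A list with `fits` (per cause) and `predictions` (data.frame
#'   per cause: density at `report_coverage`, coverage for
#'   `target_density`, flags).
#' @export
run_coverage_experiment <- function(observations, report_coverage = 50,
                                    target_density = 1.0, quality = NULL) {
  stopifnot(all(c("cause", "k", "n", "coverage", "quality",
                  "genome_length") %in% names(observations)))
  if (is.null(quality)) quality <- max(observations$quality)
  fits <- list()
  rows <- list()
  for (cause in unique(observations$cause)) {
    obs <- observations[observations$cause == cause, , drop = FALSE]
    fit <- fit_binomial(obs)
    fits[[cause]] <- fit
    n_cds <- round(mean(obs$n))
    glen <- mean(obs$genome_length)
    if ("boundary" %in% fit$flags) {
      rows[[length(rows) + 1L]] <- data.frame(
        cause = cause, density_at_report = NA_real_,
        coverage_for_target = NA_real_, flag = "boundary",
        stringsAsFactors = FALSE
      )
      next
    }
    dens <- predict_density(fit, report_coverage, quality, n_cds, glen)
    cov <- coverage_for_density(fit, target_density, quality, n_cds, glen)
    rows[[length(rows) + 1L]] <- data.frame(
      cause = cause, density_at_report = dens,
      coverage_for_target = cov$coverage, flag = cov$flag,
      stringsAsFactors = FALSE
    )
  }
  list(fits = fits, predictions = do.call(rbind, rows))
}
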