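# Reading/writing annotated assemblies and pseudogene density summaries.

PSEUDO_CAUSES <- c("frameshift", "internal_stop", "partial")

#' Build a coding-feature table
#'
#' Constructs the feature table used throughout the package: one row per
#' CDS-bearing locus with 1-based inclusive coordinates, gene/pseudogene
#' status and the set of pseudogene causes.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param contig_id contig each feature lies on.
#' @param start,end 1-based inclusive coordinates (`start <= end`).
#' @param strand `"+"` or `"-"`.
#' @param status `"gene"` or `"pseudogene"`.
#' @param causes list of character vectors, each a subset of
#'   `c("frameshift", "internal_stop", "partial")`. A gene must have an
#'   empty cause set; a pseudogene may have an empty cause set only when
#'   no recognized cause is available.
#' @param nt_sequence optional spliced, strand-corrected (5'->3')
#'   nucleotide sequence per feature.
#' @return A `data.frame` with one row per feature and a `causes` list
#'   column.
#' @export
cds_features <- function(feature_id, contig_id, start, end, strand, status,
                         causes = NULL, nt_sequence = NA_character_) {
  n <- length(feature_id)
  if (is.null(causes)) causes <- rep(list(character()), n)
  contig_id <- rep_len(contig_id, n)
  strand <- rep_len(strand, n)
  status <- rep_len(status, n)
  stopifnot(
    length(contig_id) == n, length(start) == n, length(end) == n,
    length(strand) == n, length(status) == n, length(causes) == n,
    all(strand %in% c("+", "-")), all(status %in% c("gene", "pseudogene")),
    !anyDuplicated(feature_id)
  )
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < start)) {
    stop("invalid coordinates: need 1 <= start <= end")
  }
  bad <- vapply(causes, function(cs) !all(cs %in% PSEUDO_CAUSES), logical(1))
  if (any(bad)) stop("unknown cause labels in `causes`")
  gene_with_cause <- status == "gene" &
    vapply(causes, length, integer(1)) > 0L
  if (any(gene_with_cause)) stop("a feature with status 'gene' cannot carry causes")
  df <- data.frame(
    feature_id = as.character(feature_id),
    contig_id = as.character(contig_id),
    start = start, end = end,
    strand = as.character(strand),
    status = as.character(status),
    nt_sequence = rep_len(as.character(nt_sequence), n),
    stringsAsFactors = FALSE
  )
  df$causes <- causes
  df
}

#' Assemble an annotated-genome object
#'
#' Bundles contig sequences, coding features, and acquisition metadata
#' (fold coverage, mean base quality, platform, assembler) into a single
#' object.
#'
#' @param assembly_id assembly identifier.
#' @param contigs named character vector (or `DNAStringSet`) of contig
#'   sequences; may alternatively be a named integer vector of contig
#'   lengths when only coordinates are needed.
#' @param features feature table from [cds_features()] (may have 0 rows).
#' @param coverage,quality,platform,assembler optional metadata.
#' @return An object of class `assembly_annotation` with elements
#'   `assembly_id`, `contigs`, `contig_lengths`, `genome_length`,
#'   `features`, `coverage`, `quality`, `platform`, `assembler`.
#' @export
assembly_annotation <- function(assembly_id, contigs, features,
                                coverage = NA_real_, quality = NA_real_,
                                platform = NA_character_,
                                assembler = NA_character_) {
  if (methods::is(contigs, "DNAStringSet")) {
    contigs <- stats::setNames(as.character(contigs), names(contigs))
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must be uniquely named")
  }
  if (is.character(contigs)) {
    contig_lengths <- stats::setNames(nchar(contigs), names(contigs))
  } else {
    contig_lengths <- stats::setNames(as.integer(contigs), names(contigs))
    contigs <- NULL
  }
  if (nrow(features) > 0L) {
    unknown <- setdiff(features$contig_id, names(contig_lengths))
    if (length(unknown)) {
      stop("features reference unknown contigs: ",
           paste(unknown, collapse = ", "))
    }
    if (any(features$end > contig_lengths[features$contig_id])) {
      stop("feature coordinates exceed contig length")
    }
  }
  structure(list(
    assembly_id = as.character(assembly_id),
    contigs = contigs,
    contig_lengths = contig_lengths,
    genome_length = sum(as.numeric(contig_lengths)),
    features = features,
    coverage = coverage, quality = quality,
    platform = platform, assembler = assembler
  ), class = "assembly_annotation")
}

#' @export
print.assembly_annotation <- function(x, ...) {
  np <- sum(x$features$status == "pseudogene")
  cat(sprintf(
    "<assembly_annotation> %s: %d contig(s), %s bp, %d CDS (%d pseudogene)\n",
    x$assembly_id, length(x$contig_lengths),
    format(x$genome_length, big.mark = ","), nrow(x$features), np
  ))
  invisible(x)
}

#' Extract strand-corrected feature sequences
#'
#' Fills the `nt_sequence` column of an assembly's feature table from its
#' contig sequences, reverse-complementing minus-strand features so every
#' sequence reads 5'->3' in the coding orientation.
#'
#' @param assembly an [assembly_annotation()] with contig sequences.
#' @return The assembly with `features$nt_sequence` populated.
#' @export
extract_feature_seqs <- function(assembly) {
  if (is.null(assembly$contigs)) stop("assembly has no contig sequences")
  ft <- assembly$features
  if (nrow(ft) == 0L) return(assembly)
  seqs <- substring(assembly$contigs[ft$contig_id], ft$start, ft$end)
  minus <- ft$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  assembly$features$nt_sequence <- unname(seqs)
  assembly
}

#' Read a FASTA file
#'
#' @param path FASTA file path (multi-record, wrapped or unwrapped).
#' @return Named character vector of uppercase sequences; record IDs are
#'   the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate record IDs in FASTA: ", path)
  stats::setNames(toupper(as.character(set)), ids)
}

# Map free-text pseudogene qualifiers to the package's cause labels
# (case-insensitive substring matching).
parse_causes <- function(text) {
  if (length(text) == 0L || all(is.na(text))) return(character())
  txt <- tolower(paste(text[!is.na(text)], collapse = " "))
  causes <- character()
  if (grepl("frameshift", txt, fixed = TRUE)) {
    causes <- c(causes, "frameshift")
  }
  if (grepl("internal stop", txt, fixed = TRUE) ||
      grepl("internal_stop", txt, fixed = TRUE)) {
    causes <- c(causes, "internal_stop")
  }
  if (grepl("incomplete", txt, fixed = TRUE) ||
      grepl("partial", txt, fixed = TRUE)) {
    causes <- c(causes, "partial")
  }
  causes
}

#' Read CDS features from a GFF3 file
#'
#' Parses CDS-bearing loci with their pseudogene status and causes. A
#' feature is recognized as a pseudogene when it carries `pseudo=true`, or
#' `gene_biotype=pseudogene`, or is of type `pseudogene` (annotation
#' pipelines vary in which convention they emit; the union is accepted).
#' Causes are extracted by case-insensitive substring match in the `Note`
#' and `pseudogene` qualifiers: "frameshift" -> frameshift,
#' "internal stop" -> internal_stop, "incomplete"/"partial" -> partial.
#' A pseudogene whose qualifiers match no recognized cause is kept with an
#' empty cause set and a warning.
#'
#' @param path GFF3 file path.
#' @return A feature table as from [cds_features()]; coordinates are the
#'   GFF3 native 1-based inclusive ones.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  in_fasta <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "##FASTA")) in_fasta <- TRUE
    if (in_fasta || ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9L) {
      stop(sprintf("malformed GFF line at line %d of %s (%d fields, expected 9)",
                   i, path, nf))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  keep <- as.character(md$type) %in% c("CDS", "pseudogene")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    return(cds_features(character(), character(), integer(), integer(),
                        character(), character()))
  }
  get_chr <- function(col) {
    if (col %in% colnames(md)) as.character(md[[col]]) else
      rep(NA_character_, length(gr))
  }
  ids <- get_chr("ID")
  if (anyNA(ids)) {
    ids[is.na(ids)] <- sprintf("feature_%05d", which(is.na(ids)))
  }
  # collapse duplicate CDS segments of the same locus (multi-line CDS)
  first <- !duplicated(ids)
  pseudo_attr <- tolower(get_chr("pseudo"))
  biotype <- tolower(get_chr("gene_biotype"))
  is_pseudo <- (as.character(md$type) == "pseudogene") |
    (!is.na(pseudo_attr) & pseudo_attr == "true") |
    (!is.na(biotype) & biotype == "pseudogene")
  notes <- if ("Note" %in% colnames(md)) {
    vapply(as.list(md$Note), function(v) paste(v, collapse = " "), character(1))
  } else rep(NA_character_, length(gr))
  pg_qual <- if ("pseudogene" %in% colnames(md)) get_chr("pseudogene") else
    rep(NA_character_, length(gr))
  causes <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    if (!is_pseudo[[i]]) {
      causes[[i]] <- character()
      next
    }
    causes[[i]] <- parse_causes(c(notes[[i]], pg_qual[[i]]))
    has_text <- (!is.na(notes[[i]]) && nzchar(notes[[i]])) ||
      (!is.na(pg_qual[[i]]) && nzchar(pg_qual[[i]]))
    if (length(causes[[i]]) == 0L && has_text) {
      warning(sprintf("pseudogene %s: unrecognized cause string; cause set left empty",
                      ids[[i]]), call. = FALSE)
    }
  }
  cds_features(
    feature_id = ids[first],
    contig_id = as.character(GenomicRanges::seqnames(gr))[first],
    start = GenomicRanges::start(gr)[first],
    end = GenomicRanges::end(gr)[first],
    strand = ifelse(as.character(GenomicRanges::strand(gr))[first] == "-", "-", "+"),
    status = ifelse(is_pseudo[first], "pseudogene", "gene"),
    causes = causes[first]
  )
}

cause_note <- function(causes) {
  if (length(causes) == 0L) return(NA_character_)
  lab <- c(frameshift = "frameshifted", internal_stop = "internal stop",
           partial = "incomplete")
  paste(lab[causes], collapse = " and ")
}

#' Write an assembly as FASTA + GFF3
#'
#' Writes contig sequences and the feature table so that
#' `read_gff3()`/`read_fasta()` reproduce the features, statuses, causes,
#' and sequences exactly.
#'
#' @param assembly an [assembly_annotation()] with contig sequences.
#' @param fasta_path,gff_path output paths.
#' @export
write_assembly <- function(assembly, fasta_path, gff_path) {
  if (is.null(assembly$contigs)) stop("assembly has no contig sequences")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(assembly$contigs), fasta_path
  )
  ft <- assembly$features
  if (nrow(ft) == 0L) {
    writeLines("##gff-version 3", gff_path)
    return(invisible(NULL))
  }
  gr <- GenomicRanges::GRanges(
    ft$contig_id,
    IRanges::IRanges(ft$start, ft$end),
    strand = ft$strand
  )
  is_pg <- ft$status == "pseudogene"
  S4Vectors::mcols(gr)$source <- "pseudocheck"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- ft$feature_id
  S4Vectors::mcols(gr)$pseudo <- ifelse(is_pg, "true", NA_character_)
  S4Vectors::mcols(gr)$Note <- vapply(ft$causes, cause_note, character(1))
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(NULL)
}

#' Read an assembly (FASTA + GFF3) into one object
#'
#' @param assembly_id identifier for the returned object.
#' @param fasta_path,gff_path input paths.
#' @inheritParams assembly_annotation
#' @return An [assembly_annotation()] with `nt_sequence` populated.
#' @export
read_assembly <- function(assembly_id, fasta_path, gff_path,
                          coverage = NA_real_, quality = NA_real_,
                          platform = NA_character_,
                          assembler = NA_character_) {
  contigs <- read_fasta(fasta_path)
  features <- read_gff3(gff_path)
  extract_feature_seqs(assembly_annotation(
    assembly_id, contigs, features,
    coverage = coverage, quality = quality,
    platform = platform, assembler = assembler
  ))
}

#' Read an assembly metadata table
#'
#' Delimited text with a header and columns `assembly_id`, `coverage`,
#' `quality`, `platform`, `assembler`; missing values are propagated as
#' `NA`.
#'
#' @param path TSV path.
#' @param sep field separator.
#' @return A `data.frame`.
#' @export
read_metadata <- function(path, sep = "\t") {
  md <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("assembly_id", "coverage", "quality", "platform", "assembler")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stop("metadata table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  md$coverage <- as.numeric(md$coverage)
  md$quality <- as.numeric(md$quality)
  md
}

#' Per-Mbp pseudogene density of an assembly
#'
#' Counts pseudogenes by cause and normalizes by genome length. A
#' pseudogene carrying several causes counts once in each cause-specific
#' tally: `density_x = n_x * 1e6 / genome_length` exactly.
#'
#' @param assembly an [assembly_annotation()] with `genome_length > 0`.
#' @return An object of class `pseudogene_density` with counts
#'   (`n_frameshift`, `n_internal_stop`, `n_partial`, `n_cds_total`) and
#'   densities (`density_frameshift`, `density_internal_stop`,
#'   `density_partial`), plus `genome_length`.
#' @export
pseudogene_density <- function(assembly) {
  if (!is.finite(assembly$genome_length) || assembly$genome_length <= 0) {
    stop("genome_length must be positive")
  }
  ft <- assembly$features
  is_pg <- ft$status == "pseudogene"
  has_cause <- function(c) {
    sum(is_pg & vapply(ft$causes, function(cs) c %in% cs, logical(1)))
  }
  n_fs <- has_cause("frameshift")
  n_is <- has_cause("internal_stop")
  n_pa <- has_cause("partial")
  gl <- assembly$genome_length
  structure(list(
    n_frameshift = n_fs, n_internal_stop = n_is, n_partial = n_pa,
    n_cds_total = nrow(ft),
    density_frameshift = n_fs * 1e6 / gl,
    density_internal_stop = n_is * 1e6 / gl,
    density_partial = n_pa * 1e6 / gl,
    genome_length = gl
  ), class = "pseudogene_density")
}

#' @export
print.pseudogene_density <- function(x, ...) {
  cat(sprintf(
    "<pseudogene_density> %d CDS on %s bp: frameshift %d (%.3f /Mbp), internal stop %d (%.3f /Mbp), partial %d\n",
    x$n_cds_total, format(x$genome_length, big.mark = ","),
    x$n_frameshift, x$density_frameshift,
    x$n_internal_stop, x$density_internal_stop, x$n_partial
  ))
  invisible(x)
}
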