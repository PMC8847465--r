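#' Region annotation for one locus
#'
#' Records, in alignment coordinates (1-based inclusive), the 5' regulatory
#' span, the exon and intron spans of the genomic coding region, the codon
#' phase of the first exon column and the genome whose ungapped sequence
#' defines the reading frame.
#'
#' @param locus_id Locus identifier.
#' @param chromosome Chromosome label.
#' @param five_prime_span Length-2 vector or NULL.
#' @param exon_spans,intron_spans 2-column matrices (or list of length-2
#'   vectors) of 1-based inclusive spans, ordered.
#' @param frame_offset Codon phase (0-2) of the first exon column.
#' @param reference_role Role tag (default `"Or"`) or genome name whose
#'   ungapped sequence defines the reading frame.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(locus_id, chromosome = NA_character_,
                              five_prime_span = NULL,
                              exon_spans = NULL, intron_spans = NULL,
                              frame_offset = 0L, reference_role = "Or") {
  exon_spans <- as_span_matrix(exon_spans)
  intron_spans <- as_span_matrix(intron_spans)
  if (nrow(exon_spans) > 0L) {
    if (any(exon_spans[, "end"] < exon_spans[, "start"])) {
      ggm_stop("empty or inverted exon span", "ggm_annotation_error")
    }
    if (is.unsorted(exon_spans[, "start"], strictly = TRUE)) {
      ggm_stop("exon spans must be ordered by start", "ggm_annotation_error")
    }
    if (nrow(exon_spans) > 1L &&
        any(exon_spans[-1L, "start"] <= exon_spans[-nrow(exon_spans), "end"])) {
      ggm_stop("exon spans overlap", "ggm_annotation_error")
    }
  }
  if (!frame_offset %in% 0:2) {
    ggm_stop("frame_offset must be 0, 1 or 2", "ggm_frame_error")
  }
  if (!is.null(five_prime_span)) {
    five_prime_span <- as.integer(five_prime_span)
    stopifnot(length(five_prime_span) == 2L)
  }
  structure(
    list(locus_id = locus_id, chromosome = chromosome,
         five_prime_span = five_prime_span,
         exon_spans = exon_spans, intron_spans = intron_spans,
         frame_offset = as.integer(frame_offset),
         reference_role = reference_role),
    class = "region_annotation"
  )
}

#' Check an annotation against the alignment it describes
#'
#' Enforces that the ungapped reference coding length, after dropping the
#' `frame_offset` leading bases, is a positive multiple of 3.
#'
#' @param ann A [region_annotation()].
#' @param coding_set The `coding_genomic` [ortholog_set()] for the locus.
#' @return `ann`, invisibly.
#' @export
validate_annotation <- function(ann, coding_set) {
  len <- ungapped_length(coding_set, ann$reference_role, ann$exon_spans)
  len <- len - ann$frame_offset
  if (len <= 0L || len %% 3L != 0L) {
    ggm_stop(sprintf(
      "locus %s: ungapped reference coding length %d (after frame offset) is not a positive multiple of 3",
      ann$locus_id, len), "ggm_frame_error")
  }
  invisible(ann)
}

#' Read region annotations from GFF3 or BED
#'
#' GFF3 dialect: feature types `five_prime_region`, `exon`, `intron` and one
#' `coding_region` carrying `frame_offset` and `reference_role` attributes;
#' every feature has a `locus_id` attribute and a `chromosome` attribute may
#' ride on `coding_region`. BED dialect (6 columns): the name field is
#' `<locus_id>|<feature>` with the same feature vocabulary; BED intervals are
#' converted from 0-based half-open to 1-based inclusive.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.
#' @param locus_id Locus whose features to extract.
#' @return A [region_annotation()].
#' @export
load_annotation <- function(path, locus_id) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- S4Vectors::mcols(gr)
    keep <- !is.na(meta$locus_id) & meta$locus_id == locus_id
    gr <- gr[keep]
    meta <- S4Vectors::mcols(gr)
    if (length(gr) == 0L) {
      ggm_stop(sprintf("no features for locus '%s' in %s", locus_id, path),
               "ggm_annotation_error")
    }
    feat <- as.character(meta$type)
    st <- GenomicRanges::start(gr)
    en <- GenomicRanges::end(gr)
    frame_offset <- 0L
    reference_role <- "Or"
    chromosome <- NA_character_
    cr <- which(feat == "coding_region")
    if (length(cr) > 0L) {
      if (!is.null(meta$frame_offset)) {
        fo <- meta$frame_offset[cr[1L]]
        if (!is.na(fo)) frame_offset <- as.integer(fo)
      }
      if (!is.null(meta$reference_role)) {
        rr <- meta$reference_role[cr[1L]]
        if (!is.na(rr)) reference_role <- as.character(rr)
      }
      if (!is.null(meta$chromosome)) {
        ch <- meta$chromosome[cr[1L]]
        if (!is.na(ch)) chromosome <- as.character(ch)
      }
    }
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- S4Vectors::mcols(gr)$name
    parts <- strsplit(nm, "|", fixed = TRUE)
    lid <- vapply(parts, `[`, "", 1L)
    feat_all <- vapply(parts, `[`, "", 2L)
    keep <- lid == locus_id
    if (!any(keep)) {
      ggm_stop(sprintf("no features for locus '%s' in %s", locus_id, path),
               "ggm_annotation_error")
    }
    feat <- feat_all[keep]
    st <- GenomicRanges::start(gr)[keep]
    en <- GenomicRanges::end(gr)[keep]
    frame_offset <- 0L
    reference_role <- "Or"
    chromosome <- NA_character_
  } else {
    ggm_stop(paste0("unsupported annotation format: ", ext),
             "ggm_annotation_error")
  }
  pick <- function(what) {
    i <- which(feat == what)
    if (length(i) == 0L) return(NULL)
    m <- cbind(start = st[i], end = en[i])
    m[order(m[, "start"]), , drop = FALSE]
  }
  fp <- pick("five_prime_region")
  region_annotation(
    locus_id = locus_id, chromosome = chromosome,
    five_prime_span = if (!is.null(fp)) c(fp[1L, "start"], fp[1L, "end"]),
    exon_spans = pick("exon"), intron_spans = pick("intron"),
    frame_offset = frame_offset, reference_role = reference_role
  )
}

#' Write one locus annotation as GFF3
#' @param ann A [region_annotation()].
#' @param path Output path.
#' @param seqid Sequence identifier to write (defaults to the locus id).
#' @return `path`, invisibly.
#' @export
write_annotation_gff <- function(ann, path, seqid = ann$locus_id) {
  spans <- list()
  types <- character(0)
  if (!is.null(ann$five_prime_span)) {
    spans <- c(spans, list(ann$five_prime_span))
    types <- c(types, "five_prime_region")
  }
  add <- function(m, ty) {
    for (i in seq_len(nrow(m))) {
      spans[[length(spans) + 1L]] <<- m[i, ]
      types <<- c(types, ty)
    }
  }
  add(ann$exon_spans, "exon")
  add(ann$intron_spans, "intron")
  if (nrow(ann$exon_spans) > 0L) {
    spans <- c(spans, list(c(min(ann$exon_spans), max(ann$exon_spans))))
    types <- c(types, "coding_region")
  }
  m <- do.call(rbind, spans)
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = m[, 1L], end = m[, 2L])
  )
  S4Vectors::mcols(gr)$type <- types
  S4Vectors::mcols(gr)$locus_id <- ann$locus_id
  S4Vectors::mcols(gr)$frame_offset <-
    ifelse(types == "coding_region", ann$frame_offset, NA_integer_)
  S4Vectors::mcols(gr)$reference_role <-
    ifelse(types == "coding_region", ann$reference_role, NA_character_)
  S4Vectors::mcols(gr)$chromosome <-
    ifelse(types == "coding_region", ann$chromosome, NA_character_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Subregion of each alignment column for a region set: "five_prime", "exon",
# "intron" or NA (unannotated).
subregion_of_columns <- function(set, ann) {
  out <- rep(NA_character_, set$alignment_length)
  if (set$region_kind == "five_prime") {
    sp <- ann$five_prime_span %||% c(1L, set$alignment_length)
    out[seq.int(sp[1L], sp[2L])] <- "five_prime"
  } else {
    out[cols_in_spans(ann$exon_spans)] <- "exon"
    out[cols_in_spans(ann$intron_spans)] <- "intron"
  }
  out
}
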