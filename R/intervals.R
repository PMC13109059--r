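#' Construct a table of genomic intervals
#'
#' Intervals are the atom of all overlap logic in loopbridge. They use the
#' BED convention throughout: 0-based starts, half-open `[start, end)` spans.
#' Inputs in 1-based coordinates are the caller's responsibility to convert;
#' no auto-detection is attempted.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer-like vector, 0-based inclusive start positions.
#' @param end Integer-like vector, 0-based exclusive end positions
#'   (`end > start`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the loopbridge interval invariants: `chrom` non-empty,
#' `start >= 0`, `end > start`, no missing values.
#'
#' @param x A data.frame with columns `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_intervals <- function(x, what = "interval table") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must be a data.frame with columns chrom, start, end")
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$chrom) || anyNA(x$start) || anyNA(x$end))
    stop(what, ": missing values in chrom/start/end")
  if (any(!nzchar(x$chrom)))
    stop(what, ": empty chromosome name")
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad))
    stop(what, ": invalid span at row ", bad[1],
         " (need start >= 0 and end > start)")
  invisible(x)
}

# 0-based half-open data.frame -> 1-based closed GRanges (internal boundary).
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> 0-based half-open data.frame, sorted by (chrom, start, end).
granges_to_df0 <- function(gr) {
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
}

#' Pairwise interval overlap test
#'
#' Vectorised over rows of `a` and `b` (recycled); `TRUE` where the two spans
#' lie on the same chromosome and their intersection is at least
#' `min_overlap` bp. Half-open spans mean book-ended intervals
#' (`[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param a,b Interval tables (see [genomic_intervals()]); rows are paired.
#' @param min_overlap Minimum intersection length in bp (>= 1).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b, min_overlap = 1) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  n <- max(nrow(a), nrow(b))
  if (n == 0) return(logical(0))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  a$chrom[ai] == b$chrom[bi] & ov >= min_overlap
}

#' Merge intervals into a minimal disjoint cover
#'
#' Returns the smallest sorted set of disjoint intervals covering the union
#' of the input. Overlapping and book-ended intervals (`[a,b)` + `[b,c)`)
#' are fused, matching the common bed-merge default. Idempotent and
#' invariant to input order.
#'
#' @param x Interval table.
#' @return Sorted interval table of disjoint spans.
#' @examples
#' merge_intervals(genomic_intervals(c("chr1", "chr1"), c(0, 10), c(10, 20)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(genomic_intervals())
  granges_to_df0(GenomicRanges::reduce(as_granges0(x)))
}

#' Co-localization of two peak sets
#'
#' The merged pairwise intersections of intervals in `setA` with intervals in
#' `setB`, keeping only intersections of at least `min_overlap` bp. This is
#' the operation behind co-bound regulatory sites: active enhancers as
#' H3K27ac co-localized with Med1, insulators as CTCF co-localized with the
#' cohesin subunit Rad21.
#'
#' @param a,b Interval tables.
#' @param min_overlap Minimum per-pair intersection length in bp.
#' @return Sorted, merged interval table of co-localized spans.
#' @export
colocalize <- function(a, b, min_overlap = 1) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (nrow(a) == 0 || nrow(b) == 0) return(genomic_intervals())
  ga <- as_granges0(a); gb <- as_granges0(b)
  # disjoint seqlevels are a legitimate no-overlap case, not a user error
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap))
  if (length(hits) == 0) return(genomic_intervals())
  pieces <- IRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                gb[S4Vectors::subjectHits(hits)])
  granges_to_df0(GenomicRanges::reduce(pieces))
}

#' Symmetric promoter windows around TSSs
#'
#' One window per gene, `[max(0, tss - flank), tss + flank)`, clamped at the
#' chromosome origin. Strand is deliberately ignored: windows are symmetric.
#'
#' @param tss_records Data.frame with at least `gene_id`, `chrom`, `tss`
#'   (see [read_gene_table()]).
#' @param flank Flank size in bp on each side of the TSS (> 0); default
#'   2000 bp, the conventional promoter-proximal window.
#' @return Interval table with a `gene_id` column, input gene order preserved.
#' @export
promoter_windows <- function(tss_records, flank = 2000) {
  if (!all(c("gene_id", "chrom", "tss") %in% names(tss_records)))
    stop("tss_records must have columns gene_id, chrom, tss")
  if (flank <= 0) stop("flank must be > 0")
  out <- data.frame(
    gene_id = as.character(tss_records$gene_id),
    chrom = as.character(tss_records$chrom),
    start = pmax(0, tss_records$tss - flank),
    end = tss_records$tss + flank,
    stringsAsFactors = FALSE
  )
  validate_intervals(out, "promoter windows")
  out
}

#' Membership query against an interval set
#'
#' For each query interval, does it overlap (by at least `min_overlap` bp)
#' any interval of `subject`?
#'
#' @param query,subject Interval tables.
#' @param min_overlap Minimum overlap in bp.
#' @return Logical vector, one element per query row.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1) {
  validate_intervals(query, "query"); validate_intervals(subject, "subject")
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges0(query), as_granges0(subject),
                                 minoverlap = min_overlap)) > 0
}
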