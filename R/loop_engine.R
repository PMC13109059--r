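#' CPM-normalize an interaction set
#'
#' Replaces each raw read count by `count / library_size * 1e6` (counts per
#' million), so interaction strengths are comparable between conditions with
#' different sequencing depth. The label is preserved and the resulting
#' library size is exactly 1e6 (up to floating point). Relative ratios
#' between interactions are conserved.
#'
#' @param iset An [interaction_set()] with raw counts.
#' @return A CPM-normalized `interaction_set`.
#' @export
cpm_normalize <- function(iset) {
  if (n_interactions(iset) == 0 || iset$library_size <= 0)
    stop("cannot CPM-normalize an empty set or zero library")
  df <- iset$interactions
  df$count <- df$count / iset$library_size * 1e6
  interaction_set(df, iset$label)
}

#' Filter interactions to high-confidence cis loops
#'
#' Retains interactions with confidence score strictly greater than
#' `min_score` (the CHiCAGO-style "score > 5" convention) and, when
#' `cis_only`, with both anchors on the same chromosome (inter-chromosomal
#' loops removed). `library_size` is recomputed from the survivors.
#'
#' @param iset An `interaction_set`.
#' @param min_score Score cutoff; strict inequality. Default 5.
#' @param cis_only Drop inter-chromosomal interactions? Default `TRUE`.
#' @return Filtered `interaction_set`.
#' @export
filter_confident <- function(iset, min_score = 5, cis_only = TRUE) {
  df <- iset$interactions
  keep <- df$score > min_score
  if (cis_only) keep <- keep & df$chrom1 == df$chrom2
  interaction_set(df[keep, , drop = FALSE], iset$label)
}

#' Collapse duplicate interactions
#'
#' Interactions with identical bait and other-end coordinates (e.g. the same
#' loop observed in merged biological replicates) are fused: counts summed,
#' score taken as the maximum, bait gene from the first occurrence. Output
#' keeps first-occurrence order.
#'
#' @param iset An `interaction_set`.
#' @return Deduplicated `interaction_set`.
#' @export
collapse_duplicates <- function(iset) {
  df <- iset$interactions
  if (nrow(df) == 0) return(iset)
  key <- paste(df$chrom1, df$start1, df$end1,
               df$chrom2, df$start2, df$end2, sep = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  out <- df[first, , drop = FALSE]
  out$count <- as.numeric(tapply(df$count, idx, sum)[as.character(seq_len(nrow(out)))])
  out$score <- as.numeric(tapply(df$score, idx, max)[as.character(seq_len(nrow(out)))])
  rownames(out) <- NULL
  interaction_set(out, iset$label)
}

#' Genomic span of each loop
#'
#' Distance between the two anchor midpoints, `|mid(bait) - mid(other end)|`
#' with `mid = floor((start + end) / 2)`. `NA` for trans (inter-chromosomal)
#' pairs, for which linear distance is undefined.
#'
#' @param iset An `interaction_set`.
#' @return Numeric vector of distances in bp, one per interaction.
#' @export
loop_distance <- function(iset) {
  df <- iset$interactions
  m1 <- floor((df$start1 + df$end1) / 2)
  m2 <- floor((df$start2 + df$end2) / 2)
  d <- abs(m1 - m2)
  d[df$chrom1 != df$chrom2] <- NA_real_
  d
}

parse_region <- function(region) {
  if (is.character(region) && length(region) == 1) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("cannot parse region string '", region, "'")
    region <- data.frame(chrom = m[2], start = as.numeric(m[3]),
                         end = as.numeric(m[4]), stringsAsFactors = FALSE)
  }
  if (is.list(region) && !is.data.frame(region))
    region <- as.data.frame(region, stringsAsFactors = FALSE)
  validate_intervals(region, "region")
  if (nrow(region) != 1) stop("region must be a single interval")
  region
}

#' Virtual 4C viewpoint track
#'
#' Projects all interactions of one viewpoint gene onto a linear track: the
#' display region is tiled left-to-right with half-open bins of `bin_size`
#' bp (the last bin clipped at the region edge), and each interaction whose
#' `gene` equals the viewpoint gene adds its count to the bin containing its
#' other-end midpoint. Midpoints on a bin boundary fall in the bin starting
#' there; midpoints outside the region are dropped. Intended for
#' CPM-normalized sets so tracks are comparable across conditions.
#'
#' @param iset An `interaction_set` (typically after [cpm_normalize()]).
#' @param viewpoint_gene Gene id of the viewpoint promoter.
#' @param region Display window: a one-row interval table, a list with
#'   `chrom`/`start`/`end`, or a string `"chr1:0-9000"`.
#' @param bin_size Bin width in bp; default 1500, the working resolution of
#'   4-cutter promoter-capture maps.
#' @return Data.frame `chrom, start, end, signal` (bedGraph-like, loadable
#'   as a track), with attributes `viewpoint_gene` and `bin_size`.
#' @export
virtual_4c <- function(iset, viewpoint_gene, region, bin_size = 1500) {
  region <- parse_region(region)
  if (bin_size <= 0) stop("bin_size must be > 0")
  starts <- seq(region$start, region$end - 1, by = bin_size)
  ends <- pmin(starts + bin_size, region$end)
  signal <- numeric(length(starts))
  df <- iset$interactions
  df <- df[df$gene == viewpoint_gene & df$chrom2 == region$chrom, ,
           drop = FALSE]
  if (nrow(df) > 0) {
    mid <- floor((df$start2 + df$end2) / 2)
    inside <- mid >= region$start & mid < region$end
    if (any(inside)) {
      bin <- floor((mid[inside] - region$start) / bin_size) + 1
      agg <- tapply(df$count[inside], bin, sum)
      signal[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  out <- data.frame(chrom = region$chrom, start = starts, end = ends,
                    signal = signal, stringsAsFactors = FALSE)
  attr(out, "viewpoint_gene") <- viewpoint_gene
  attr(out, "bin_size") <- bin_size
  out
}

#' Write a virtual 4C track as 4-column TSV
#'
#' `chrom start end signal`, no header: a bedGraph-compatible text track.
#'
#' @param track Output of [virtual_4c()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_v4c_track <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%.10g", track$chrom,
                     as.integer(track$start), as.integer(track$end),
                     track$signal), path)
  invisible(path)
}
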