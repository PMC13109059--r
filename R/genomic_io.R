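#' Construct an interaction set
#'
#' The pcHiC loop container: a labelled collection of bait/other-end anchor
#' pairs with raw (or CPM-normalized) read counts and a CHiCAGO-like
#' confidence score. The bait is the probe-captured promoter fragment;
#' columns 1-3 of the interaction table are always the bait side.
#'
#' @param interactions Data.frame with columns `chrom1,start1,end1`
#'   (bait), `chrom2,start2,end2` (other end), `count` (>= 0),
#'   `score` (>= 0) and optionally `gene` (bait gene id, `""` when unknown).
#' @param label Condition name (non-empty string).
#' @return An object of class `interaction_set`: a list with elements
#'   `label`, `interactions` and `library_size` (the sum of counts).
#' @export
interaction_set <- function(interactions, label) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label))
    stop("label must be a non-empty string")
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "count", "score")
  if (!is.data.frame(interactions) || !all(req %in% names(interactions)))
    stop("interactions must have columns ", paste(req, collapse = ", "))
  if (!"gene" %in% names(interactions))
    interactions$gene <- rep("", nrow(interactions))
  interactions <- interactions[, c(req, "gene")]
  interactions$gene <- as.character(interactions$gene)
  validate_intervals(
    data.frame(chrom = interactions$chrom1, start = interactions$start1,
               end = interactions$end1), "bait anchors")
  validate_intervals(
    data.frame(chrom = interactions$chrom2, start = interactions$start2,
               end = interactions$end2), "other-end anchors")
  if (nrow(interactions) > 0) {
    if (anyNA(interactions$count) || any(interactions$count < 0))
      stop("counts must be non-negative")
    if (anyNA(interactions$score) || any(interactions$score < 0))
      stop("scores must be non-negative")
  }
  structure(
    list(label = label, interactions = interactions,
         library_size = sum(interactions$count)),
    class = "interaction_set"
  )
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("interaction_set '", x$label, "': ", nrow(x$interactions),
      " interactions, library size ", format(x$library_size), "\n", sep = "")
  invisible(x)
}

#' Number of interactions in a set
#' @param x An `interaction_set`.
#' @return Integer count of loop records.
#' @export
n_interactions <- function(x) nrow(x$interactions)

# Bait / other-end anchors of an interaction set as interval tables.
#' Extract anchor intervals from an interaction set
#' @param x An `interaction_set`.
#' @param side `"bait"`, `"other_end"`, or `"both"` (rbind of the two).
#' @return Interval table (chrom, start, end).
#' @export
anchors <- function(x, side = c("both", "bait", "other_end")) {
  side <- match.arg(side)
  b <- data.frame(chrom = x$interactions$chrom1,
                  start = x$interactions$start1,
                  end = x$interactions$end1, stringsAsFactors = FALSE)
  o <- data.frame(chrom = x$interactions$chrom2,
                  start = x$interactions$start2,
                  end = x$interactions$end2, stringsAsFactors = FALSE)
  switch(side, bait = b, other_end = o, both = rbind(b, o))
}

strip_bed_lines <- function(lines) {
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

parse_num <- function(x, lineno, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad))
    stop("parse error in ", path, " line ", lineno[bad[1]],
         ": non-numeric ", what, " '", x[bad[1]], "'")
  v
}

#' Read a BED file of intervals
#'
#' Reads BED3+ (columns beyond the first three ignored); `track`, `browser`
#' and `#` comment lines are skipped. Coordinates are kept as in the file
#' (BED is natively 0-based half-open). Malformed records raise an error
#' naming the offending line.
#'
#' @param path Path to a BED file.
#' @return Interval table in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- strip_bed_lines(readLines(path))
  if (length(raw$lines) == 0) return(genomic_intervals())
  fields <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("parse error in ", path, " line ", raw$lineno[which(nf < 3)[1]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_num(vapply(fields, `[[`, "", 2L), raw$lineno, "start", path)
  end <- parse_num(vapply(fields, `[[`, "", 3L), raw$lineno, "end", path)
  bad <- which(start < 0 | end <= start | !nzchar(chrom) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("parse error in ", path, " line ", raw$lineno[bad[1]],
         ": invalid interval (need integer 0 <= start < end)")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED3
#'
#' One tab-separated line per interval, coordinates written as stored
#' (0-based half-open), no header; round-trips losslessly through
#' [read_bed()]. An empty collection yields an empty file.
#'
#' @param intervals Interval table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(intervals, path) {
  validate_intervals(intervals)
  lines <- if (nrow(intervals) == 0) character(0) else
    sprintf("%s\t%d\t%d", intervals$chrom,
            as.integer(intervals$start), as.integer(intervals$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BEDPE-dialect interaction file
#'
#' The loopbridge interaction dialect is BEDPE-derived: tab-separated
#' `chrom1 start1 end1 chrom2 start2 end2 count score [gene]`, with columns
#' 1-3 the bait (captured promoter) anchor. The name/strand columns of
#' canonical BEDPE are dropped because pcHiC loops carry exactly a read
#' count and a confidence score. The optional 9th column is the bait gene id.
#'
#' @param path Path to the interaction file.
#' @param label Condition name for the resulting set.
#' @return An [interaction_set()] whose `library_size` is the sum of counts.
#' @export
read_bedpe_interactions <- function(path, label) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- strip_bed_lines(readLines(path))
  if (length(raw$lines) == 0)
    return(interaction_set(empty_interaction_df(), label))
  fields <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8))
    stop("parse error in ", path, " line ", raw$lineno[which(nf < 8)[1]],
         ": fewer than 8 fields")
  getf <- function(i) vapply(fields, `[[`, "", i)
  df <- data.frame(
    chrom1 = getf(1L),
    start1 = parse_num(getf(2L), raw$lineno, "start1", path),
    end1 = parse_num(getf(3L), raw$lineno, "end1", path),
    chrom2 = getf(4L),
    start2 = parse_num(getf(5L), raw$lineno, "start2", path),
    end2 = parse_num(getf(6L), raw$lineno, "end2", path),
    count = parse_num(getf(7L), raw$lineno, "count", path),
    score = parse_num(getf(8L), raw$lineno, "score", path),
    gene = vapply(seq_along(fields), function(i)
      if (nf[i] >= 9) fields[[i]][[9L]] else "", ""),
    stringsAsFactors = FALSE
  )
  for (side in 1:2) {
    s <- df[[paste0("start", side)]]; e <- df[[paste0("end", side)]]
    bad <- which(s < 0 | e <= s)
    if (length(bad))
      stop("parse error in ", path, " line ", raw$lineno[bad[1]],
           ": invalid anchor", side, " coordinates")
  }
  bad <- which(df$count < 0 | df$score < 0)
  if (length(bad))
    stop("parse error in ", path, " line ", raw$lineno[bad[1]],
         ": negative count or score")
  interaction_set(df, label)
}

empty_interaction_df <- function() {
  data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             chrom2 = character(), start2 = numeric(), end2 = numeric(),
             count = numeric(), score = numeric(), gene = character(),
             stringsAsFactors = FALSE)
}

#' Write an interaction set in the BEDPE dialect
#'
#' Inverse of [read_bedpe_interactions()]; numeric counts/scores are written
#' with full precision so the round trip is lossless.
#'
#' @param iset An `interaction_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(iset, path) {
  df <- iset$interactions
  lines <- if (nrow(df) == 0) character(0) else
    paste(df$chrom1, format_coord(df$start1), format_coord(df$end1),
          df$chrom2, format_coord(df$start2), format_coord(df$end2),
          format_num(df$count), format_num(df$score), df$gene, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) sprintf("%d", as.integer(x))
format_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 2^31, sprintf("%d", as.integer(x)),
         sprintf("%.15g", x))
}

DE_STATUS_LEVELS <- c("up", "down", "ns")

#' Read a TSS / gene annotation table
#'
#' Tab-separated with a header row naming (at least) `gene_id`, `chrom`,
#' `tss`, `strand`, `is_oncogene`, `de_status`. `tss` is a 0-based position;
#' `de_status` is normalized case-insensitively to `up`/`down`/`ns`;
#' `is_oncogene` is coerced to logical. Duplicate gene ids are an error.
#'
#' @param path Path to the TSV.
#' @return Data.frame of validated TSS records in file order.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand", "is_oncogene", "de_status")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("gene table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in ", path, ": ", dup[1])
  if (anyNA(df$tss) || any(df$tss < 0))
    stop("gene table ", path, ": tss must be >= 0")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene table ", path, ": strand must be '+' or '-'")
  df$de_status <- tolower(as.character(df$de_status))
  if (!all(df$de_status %in% DE_STATUS_LEVELS))
    stop("gene table ", path, ": de_status must be one of ",
         paste(DE_STATUS_LEVELS, collapse = "/"), " (case-insensitive)")
  df$is_oncogene <- as.logical(df$is_oncogene)
  if (anyNA(df$is_oncogene))
    stop("gene table ", path, ": is_oncogene must be logical (TRUE/FALSE)")
  df[, req]
}

#' Write a TSS / gene annotation table
#' @param genes Data.frame as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' Tab-separated; first column holds unique gene ids, remaining columns one
#' sample each. Values must be numeric and non-missing.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression matrix ", path, " needs >= 2 columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in expression matrix ", path)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#' @param m Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical cohort table
#'
#' Tab-separated with header columns `sample_id`, `survival_time` (days,
#' > 0) and `event` (1 = death observed, 0 = right-censored). Extra columns
#' are preserved.
#'
#' @param path Path to the TSV.
#' @return Data.frame of validated cohort records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "survival_time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  validate_cohort(df)
  df
}

validate_cohort <- function(df) {
  if (anyNA(df$survival_time) || any(df$survival_time <= 0))
    stop("survival_time must be positive")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death observed)")
  invisible(df)
}

#' Write a clinical cohort table
#' @param cohort Data.frame with `sample_id`, `survival_time`, `event`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
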