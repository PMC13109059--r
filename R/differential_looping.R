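#' Promoter-enhancer loops of one gene
#'
#' Interactions baited at `gene_id` whose other end overlaps an active
#' enhancer (the catalog's H3K27ac/Med1 co-localized set). Expects a set
#' that has already been confidence-filtered and CPM-normalized. An unknown
#' gene yields an empty collection, not an error.
#'
#' @param iset Filtered, normalized `interaction_set`.
#' @param gene_id Bait gene id.
#' @param catalog An `element_catalog` with enhancers built from
#'   H3K27ac/Med1 co-localization.
#' @param min_overlap Minimum overlap in bp.
#' @return Data.frame of qualifying interaction records.
#' @export
gene_pe_loops <- function(iset, gene_id, catalog, min_overlap = 1) {
  df <- iset$interactions[iset$interactions$gene == gene_id, , drop = FALSE]
  if (nrow(df) == 0) return(df)
  oe <- data.frame(chrom = df$chrom2, start = df$start2, end = df$end2,
                   stringsAsFactors = FALSE)
  df[overlaps_any(oe, catalog$enhancers, min_overlap), , drop = FALSE]
}

#' Mean normalized count over a gene's PE loops
#'
#' Arithmetic mean of the (CPM-normalized) counts; `NA` on empty input,
#' meaning the gene has no qualifying promoter-enhancer loop in that
#' condition.
#'
#' @param loops Data.frame of interactions sharing one bait gene.
#' @return Numeric scalar, or `NA` if empty.
#' @export
mean_pe_count <- function(loops) {
  if (nrow(loops) == 0) return(NA_real_)
  mean(loops$count)
}

#' Differential looping record for one gene
#'
#' Per-gene mean promoter-enhancer interaction strength in each condition
#' and their difference, `delta = mean_count_a - mean_count_b` (condition A
#' minus condition B). Direction is `increased` when `delta > threshold`,
#' `not_increased` otherwise, and `not_evaluable` when either condition
#' lacks a qualifying PE loop (delta undefined).
#'
#' @param gene_id Gene id.
#' @param iset_a,iset_b Filtered, CPM-normalized interaction sets for the
#'   two conditions.
#' @param catalog An `element_catalog`.
#' @param threshold Minimum delta to call an increase; default 0 (any
#'   positive difference).
#' @param min_overlap Minimum enhancer overlap in bp.
#' @return One-row data.frame with `gene_id`, `n_pe_loops_a`,
#'   `n_pe_loops_b`, `mean_count_a`, `mean_count_b`, `delta`, `direction`.
#' @export
delta_record <- function(gene_id, iset_a, iset_b, catalog, threshold = 0,
                         min_overlap = 1) {
  la <- gene_pe_loops(iset_a, gene_id, catalog, min_overlap)
  lb <- gene_pe_loops(iset_b, gene_id, catalog, min_overlap)
  ma <- mean_pe_count(la); mb <- mean_pe_count(lb)
  delta <- if (is.na(ma) || is.na(mb)) NA_real_ else ma - mb
  direction <- if (is.na(delta)) "not_evaluable" else
    if (delta > threshold) "increased" else "not_increased"
  data.frame(gene_id = gene_id, n_pe_loops_a = nrow(la),
             n_pe_loops_b = nrow(lb), mean_count_a = ma, mean_count_b = mb,
             delta = delta, direction = direction,
             stringsAsFactors = FALSE)
}

#' Per-gene promoter-enhancer loop strength
#'
#' Mean (CPM-normalized) count over each bait gene's enhancer-overlapping
#' loops, for every gene in the set at once (one overlap pass). This is the
#' per-promoter loop-strength table correlated against expression.
#'
#' @param iset Filtered, normalized `interaction_set`.
#' @param catalog An `element_catalog`.
#' @param min_overlap Minimum enhancer overlap in bp.
#' @return Data.frame `gene_id`, `n` (qualifying loops), `mean_count`.
#' @export
gene_pe_means <- function(iset, catalog, min_overlap = 1) {
  df <- iset$interactions
  if (nrow(df) == 0)
    return(data.frame(gene_id = character(), n = integer(),
                      mean_count = numeric(), stringsAsFactors = FALSE))
  oe <- data.frame(chrom = df$chrom2, start = df$start2, end = df$end2,
                   stringsAsFactors = FALSE)
  df <- df[overlaps_any(oe, catalog$enhancers, min_overlap) &
             nzchar(df$gene), , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(gene_id = character(), n = integer(),
                      mean_count = numeric(), stringsAsFactors = FALSE))
  agg_n <- tapply(df$count, df$gene, length)
  agg_m <- tapply(df$count, df$gene, mean)
  data.frame(gene_id = names(agg_m), n = as.integer(agg_n),
             mean_count = as.numeric(agg_m), stringsAsFactors = FALSE)
}

#' Cohort-level promoter-enhancer remodeling summary
#'
#' Applies the per-gene delta procedure across a gene list. A gene is
#' evaluable when it has at least one qualifying (confidence-filtered,
#' enhancer-overlapping) PE loop in *both* conditions;
#' `fraction_increased = n_increased / n_evaluable` (NA when nothing is
#' evaluable).
#'
#' @param gene_ids Character vector of genes to evaluate.
#' @param iset_a,iset_b Filtered, CPM-normalized interaction sets.
#' @param catalog An `element_catalog`.
#' @param threshold Delta threshold for calling an increase.
#' @param min_overlap Minimum enhancer overlap in bp.
#' @return List with `n_evaluable`, `n_increased`, `fraction_increased`,
#'   and `records` (one [delta_record()] row per gene).
#' @export
remodeling_summary <- function(gene_ids, iset_a, iset_b, catalog,
                               threshold = 0, min_overlap = 1) {
  if (length(gene_ids) == 0) stop("gene_ids must be non-empty")
  gene_ids <- as.character(gene_ids)
  ma <- gene_pe_means(iset_a, catalog, min_overlap)
  mb <- gene_pe_means(iset_b, catalog, min_overlap)
  ia <- match(gene_ids, ma$gene_id); ib <- match(gene_ids, mb$gene_id)
  n_a <- ifelse(is.na(ia), 0L, ma$n[ia])
  n_b <- ifelse(is.na(ib), 0L, mb$n[ib])
  mean_a <- ifelse(is.na(ia), NA_real_, ma$mean_count[ia])
  mean_b <- ifelse(is.na(ib), NA_real_, mb$mean_count[ib])
  delta <- mean_a - mean_b
  direction <- ifelse(is.na(delta), "not_evaluable",
                      ifelse(delta > threshold, "increased", "not_increased"))
  records <- data.frame(gene_id = gene_ids, n_pe_loops_a = n_a,
                        n_pe_loops_b = n_b, mean_count_a = mean_a,
                        mean_count_b = mean_b, delta = delta,
                        direction = direction, stringsAsFactors = FALSE)
  n_eval <- sum(direction != "not_evaluable")
  n_inc <- sum(direction == "increased")
  list(n_evaluable = n_eval, n_increased = n_inc,
       fraction_increased = if (n_eval > 0) n_inc / n_eval else NA_real_,
       records = records)
}
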