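LOOP_CLASSES <- c("PP", "PE", "P_INS", "P_OTHER")
ELEMENT_CLASSES <- c("promoter", "enhancer", "insulator", "other")

#' Build a regulatory element catalog
#'
#' Assembles the three merged interval indexes used for anchor
#' classification:
#' * enhancers — H3K27ac peaks co-localized with Med1 (active-enhancer
#'   hallmarks);
#' * insulators — CTCF peaks co-localized with the cohesin subunit Rad21;
#' * promoters — either symmetric TSS windows (`tss_window` mode, default)
#'   or Pol II peaks co-localized with H3K4me3 (`hallmark` mode).
#'
#' @param peaks_by_mark Named list of interval tables. Required names:
#'   `H3K27ac`, `Med1`, `CTCF`, `Rad21`; plus `PolII` and `H3K4me3` for
#'   `promoter_mode = "hallmark"`.
#' @param tss_records Gene table (see [read_gene_table()]); required for
#'   `tss_window` mode.
#' @param promoter_mode How promoters are defined.
#' @param flank Promoter window flank in bp (`tss_window` mode).
#' @param min_overlap Minimum co-localization overlap in bp.
#' @return An object of class `element_catalog`: list with merged interval
#'   tables `promoters`, `enhancers`, `insulators`.
#' @export
build_catalog <- function(peaks_by_mark, tss_records = NULL,
                          promoter_mode = c("tss_window", "hallmark"),
                          flank = 2000, min_overlap = 1) {
  promoter_mode <- match.arg(promoter_mode)
  need <- c("H3K27ac", "Med1", "CTCF", "Rad21")
  if (promoter_mode == "hallmark") need <- c(need, "PolII", "H3K4me3")
  miss <- setdiff(need, names(peaks_by_mark))
  if (length(miss))
    stop("missing required peak set(s): ", paste(miss, collapse = ", "))
  enh <- colocalize(peaks_by_mark$H3K27ac, peaks_by_mark$Med1,
                    min_overlap = min_overlap)
  ins <- colocalize(peaks_by_mark$CTCF, peaks_by_mark$Rad21,
                    min_overlap = min_overlap)
  prom <- if (promoter_mode == "tss_window") {
    if (is.null(tss_records))
      stop("tss_window promoter mode requires tss_records")
    merge_intervals(promoter_windows(tss_records, flank)[,
                      c("chrom", "start", "end")])
  } else {
    colocalize(peaks_by_mark$PolII, peaks_by_mark$H3K4me3,
               min_overlap = min_overlap)
  }
  structure(list(promoters = prom, enhancers = merge_intervals(enh),
                 insulators = merge_intervals(ins)),
            class = "element_catalog")
}

#' @export
print.element_catalog <- function(x, ...) {
  cat("element_catalog: ", nrow(x$promoters), " promoter, ",
      nrow(x$enhancers), " enhancer, ", nrow(x$insulators),
      " insulator intervals\n", sep = "")
  invisible(x)
}

#' Classify anchors into regulatory element classes
#'
#' Each anchor gets exactly one class with fixed precedence
#' promoter > enhancer > insulator > other: an anchor overlapping both a
#' promoter and an enhancer is called promoter (capture design biases
#' anchors promoter-ward, and the precedence makes class fractions
#' disjoint).
#'
#' @param anchor_df Interval table of anchors.
#' @param catalog An [build_catalog()] result.
#' @param min_overlap Minimum overlap in bp to count as membership.
#' @return Factor with levels promoter/enhancer/insulator/other.
#' @export
classify_anchors <- function(anchor_df, catalog, min_overlap = 1) {
  cls <- rep("other", nrow(anchor_df))
  cls[overlaps_any(anchor_df, catalog$insulators, min_overlap)] <- "insulator"
  cls[overlaps_any(anchor_df, catalog$enhancers, min_overlap)] <- "enhancer"
  cls[overlaps_any(anchor_df, catalog$promoters, min_overlap)] <- "promoter"
  factor(cls, levels = ELEMENT_CLASSES)
}

#' Classify loops by their other-end element
#'
#' For bait-anchored capture interactions the bait is a promoter by design,
#' so the loop type is the other-end's element class: PP
#' (promoter-promoter), PE (promoter-enhancer), P_INS (promoter-insulator)
#' or P_OTHER.
#'
#' @param iset An `interaction_set`.
#' @param catalog An `element_catalog`.
#' @param min_overlap Minimum overlap in bp.
#' @return Factor with levels PP/PE/P_INS/P_OTHER, one per interaction.
#' @export
classify_loops <- function(iset, catalog, min_overlap = 1) {
  oe <- anchors(iset, "other_end")
  cls <- classify_anchors(oe, catalog, min_overlap)
  factor(LOOP_CLASSES[as.integer(cls)], levels = LOOP_CLASSES)
}

#' Select loops anchored at TF peaks
#'
#' Subsets to interactions anchored at transcription-factor binding sites
#' (e.g. AP-1 ChIP-seq peaks): by default a loop is kept when either anchor
#' overlaps a TF peak; `other_end_only` requires the distal anchor.
#'
#' @param iset An `interaction_set`.
#' @param tf_peaks Interval table of TF peaks.
#' @param mode Anchor rule.
#' @param min_overlap Minimum overlap in bp.
#' @return Filtered `interaction_set`.
#' @export
select_tf_anchored <- function(iset, tf_peaks,
                               mode = c("either_anchor", "other_end_only"),
                               min_overlap = 1) {
  mode <- match.arg(mode)
  hit_oe <- overlaps_any(anchors(iset, "other_end"), tf_peaks, min_overlap)
  keep <- if (mode == "either_anchor") {
    hit_oe | overlaps_any(anchors(iset, "bait"), tf_peaks, min_overlap)
  } else hit_oe
  interaction_set(iset$interactions[keep, , drop = FALSE], iset$label)
}

#' Loop-type tally
#'
#' Fraction of loops in each of the four classes; fractions cover all
#' classes (zeros included) and sum to 1. The pie-chart summary used for
#' TF-anchored loop-type distributions.
#'
#' @param iset A non-empty `interaction_set`.
#' @param catalog An `element_catalog`.
#' @param min_overlap Minimum overlap in bp.
#' @return Named numeric vector over PP/PE/P_INS/P_OTHER.
#' @export
tally_loop_types <- function(iset, catalog, min_overlap = 1) {
  if (n_interactions(iset) == 0)
    stop("cannot tally loop types of an empty interaction set")
  cls <- classify_loops(iset, catalog, min_overlap)
  tab <- table(cls)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Build motif-analysis region sets
#'
#' Constructs the merged genomic regions handed to external motif-enrichment
#' software, by staged interval algebra over oncogene loops:
#' 1. merge the anchor spans of the (oncogene-restricted) interaction set
#'    with open-chromatin (ATAC) peaks;
#' 2. keep merged intervals associated with a differentially expressed
#'    oncogene, i.e. overlapping a promoter window around a DE-oncogene TSS;
#' 3. for the `promoter_enhancer` variant keep intervals overlapping
#'    H3K27ac (acetylation) peaks; for the `insulator` variant keep
#'    intervals overlapping CTCF/Rad21 co-localized sites.
#'
#' Stages 2-3 filter whole stage-1 intervals by association (default) rather
#' than trimming to the intersection; set `restrict = "intersect"` to trim.
#' An empty result after any stage produces an empty output with one warning
#' per empty stage.
#'
#' @param iset Interaction set already restricted to oncogene baits.
#' @param atac_peaks Interval table of open-chromatin peaks.
#' @param de_tss Gene table filtered to differentially expressed oncogenes.
#' @param acetyl_peaks H3K27ac peaks (`promoter_enhancer` variant).
#' @param insulator_sites CTCF/Rad21 co-localized intervals (`insulator`
#'   variant).
#' @param variant Which region set to build.
#' @param flank Promoter-window flank for DE TSS association, bp.
#' @param restrict `"keep"` (whole intervals) or `"intersect"` (trim).
#' @param min_overlap Minimum overlap in bp for association.
#' @return Sorted merged interval table, ready to write with
#'   [write_regions()].
#' @export
build_motif_regions <- function(iset, atac_peaks, de_tss,
                                acetyl_peaks = NULL, insulator_sites = NULL,
                                variant = c("promoter_enhancer", "insulator"),
                                flank = 2000,
                                restrict = c("keep", "intersect"),
                                min_overlap = 1) {
  variant <- match.arg(variant)
  restrict <- match.arg(restrict)
  stage1 <- merge_intervals(rbind(anchors(iset, "both"), atac_peaks))
  if (nrow(stage1) == 0) {
    warning("motif regions: empty after stage 1 (loops + ATAC)")
    return(genomic_intervals())
  }
  if (variant == "promoter_enhancer" && nrow(de_tss) == 0)
    stop("promoter_enhancer variant requires non-empty de_tss")
  win <- promoter_windows(de_tss, flank)[, c("chrom", "start", "end")]
  stage2 <- restrict_regions(stage1, win, restrict, min_overlap)
  if (nrow(stage2) == 0) {
    warning("motif regions: empty after stage 2 (DE-oncogene TSS association)")
    return(genomic_intervals())
  }
  filt <- if (variant == "promoter_enhancer") {
    if (is.null(acetyl_peaks))
      stop("promoter_enhancer variant requires acetyl_peaks")
    acetyl_peaks
  } else {
    if (is.null(insulator_sites))
      stop("insulator variant requires insulator_sites")
    insulator_sites
  }
  stage3 <- restrict_regions(stage2, filt, restrict, min_overlap)
  if (nrow(stage3) == 0) {
    warning("motif regions: empty after stage 3 (", variant, " filter)")
    return(genomic_intervals())
  }
  merge_intervals(stage3)
}

restrict_regions <- function(x, by, restrict, min_overlap) {
  if (restrict == "keep") {
    x[overlaps_any(x, by, min_overlap), , drop = FALSE]
  } else {
    colocalize(x, by, min_overlap)
  }
}
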