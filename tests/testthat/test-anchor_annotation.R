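toy_catalog <- function() {
  peaks <- list(
    H3K27ac = genomic_intervals("chr1", c(0, 5000), c(100, 5400)),
    Med1 = genomic_intervals("chr1", c(50, 5200), c(150, 5600)),
    CTCF = genomic_intervals("chr1", 8000, 8400),
    Rad21 = genomic_intervals("chr1", 8100, 8500))
  tss <- data.frame(gene_id = "g1", chrom = "chr1", tss = 20000,
                    strand = "+", is_oncogene = TRUE, de_status = "up",
                    stringsAsFactors = FALSE)
  build_catalog(peaks, tss, promoter_mode = "tss_window", flank = 2000)
}

test_that("catalog assembles hallmark co-localizations per element class", {
  cat <- toy_catalog()
  expect_equal(cat$enhancers,
               genomic_intervals("chr1", c(50, 5200), c(100, 5400)))
  expect_equal(cat$insulators, genomic_intervals("chr1", 8100, 8400))
  expect_equal(cat$promoters, genomic_intervals("chr1", 18000, 22000))

  # disjoint hallmark pair -> empty insulator set
  peaks <- list(H3K27ac = genomic_intervals("chr1", 0, 100),
                Med1 = genomic_intervals("chr1", 50, 150),
                CTCF = genomic_intervals("chr1", 0, 100),
                Rad21 = genomic_intervals("chr1", 500, 600))
  tss <- data.frame(gene_id = "g1", chrom = "chr1", tss = 5000,
                    stringsAsFactors = FALSE)
  cat2 <- build_catalog(peaks, tss)
  expect_equal(nrow(cat2$insulators), 0)
  expect_equal(cat2$promoters, genomic_intervals("chr1", 3000, 7000))

  expect_error(build_catalog(peaks[c("H3K27ac", "Med1")], tss), "CTCF")
  expect_error(build_catalog(peaks, tss, promoter_mode = "hallmark"),
               "PolII")
})

test_that("anchor classification applies promoter>enhancer>insulator>other", {
  cat <- toy_catalog()
  # spans promoter AND enhancer territory -> promoter wins
  both <- rbind(genomic_intervals("chr1", 19000, 21000),   # promoter only
                genomic_intervals("chr1", 40, 120),        # enhancer
                genomic_intervals("chr1", 8000, 8200),     # insulator
                genomic_intervals("chr1", 30000, 30100))   # nothing
  expect_equal(as.character(classify_anchors(both, cat)),
               c("promoter", "enhancer", "insulator", "other"))
  # an anchor overlapping enhancer and promoter is called promoter
  cat2 <- cat; cat2$promoters <- genomic_intervals("chr1", 0, 60)
  expect_equal(as.character(classify_anchors(
    genomic_intervals("chr1", 40, 120), cat2)), "promoter")
})

test_that("loop classes derive from the other end; oracle equivalence", {
  cat <- toy_catalog()
  iset <- make_iset(
    list("chr1", 19000, 20500, "chr1", 5200, 5400, 1, 6),  # PE
    list("chr1", 19000, 20500, "chr1", 18500, 19500, 1, 6),# PP
    list("chr1", 19000, 20500, "chr1", 8100, 8300, 1, 6),  # P_INS
    list("chr1", 19000, 20500, "chr1", 30000, 30100, 1, 6))# P_OTHER
  expect_equal(as.character(classify_loops(iset, cat)),
               c("PE", "PP", "P_INS", "P_OTHER"))
  set.seed(41)
  anchors_rand <- random_intervals(200, chroms = "chr1", limit = 40000)
  got <- classify_anchors(anchors_rand, cat)
  expect_equal(as.character(got), oracle_classify(anchors_rand, cat))
})

test_that("classification ignores catalog intervals that touch no anchor", {
  cat <- toy_catalog()
  iset <- make_iset(list("chr1", 19000, 20500, "chr1", 5200, 5400, 1, 6))
  before <- classify_loops(iset, cat)
  cat$enhancers <- rbind(cat$enhancers,
                         genomic_intervals("chr9", 0, 1000))
  cat$insulators <- rbind(cat$insulators,
                          genomic_intervals("chr1", 900000, 900100))
  expect_equal(classify_loops(iset, cat), before)
})

test_that("TF-anchored selection honours either-anchor and other-end modes", {
  tf <- genomic_intervals("chr1", 19500, 19600)
  iset <- make_iset(
    list("chr1", 19000, 20500, "chr1", 5200, 5400, 1, 6),    # TF at bait
    list("chr1", 50000, 51500, "chr1", 19550, 19650, 1, 6),  # TF at other end
    list("chr1", 50000, 51500, "chr1", 70000, 71500, 1, 6))  # TF nowhere
  either <- select_tf_anchored(iset, tf)
  expect_equal(n_interactions(either), 2)
  oe_only <- select_tf_anchored(iset, tf, mode = "other_end_only")
  expect_equal(n_interactions(oe_only), 1)
  expect_equal(oe_only$interactions$start2, 19550)
})

test_that("loop-type tally covers all classes and sums to one", {
  cat <- toy_catalog()
  iset <- make_iset(
    list("chr1", 19000, 20500, "chr1", 5200, 5400, 1, 6),
    list("chr1", 19000, 20500, "chr1", 5200, 5400, 1, 6),
    list("chr1", 19000, 20500, "chr1", 18500, 19500, 1, 6),
    list("chr1", 19000, 20500, "chr1", 18500, 19500, 1, 6))
  frac <- tally_loop_types(iset, cat)
  expect_equal(frac, c(PP = 0.5, PE = 0.5, P_INS = 0, P_OTHER = 0))
  expect_equal(sum(frac), 1, tolerance = 1e-9)
  solo <- make_iset(list("chr1", 19000, 20500, "chr1", 30000, 30100, 1, 6))
  expect_equal(tally_loop_types(solo, cat)[["P_OTHER"]], 1)
  expect_error(tally_loop_types(interaction_set(
    solo$interactions[0, ], "x"), cat), "empty")
})

test_that("tally recovers planted class proportions on a simulated set", {
  cfg <- simulation_config(seed = 17, n_genes = 500, coloc_prob = 1,
                           enhancers_per_gene = 2, insulators_per_gene = 1,
                           pp_loop_prob = 0)
  genome <- simulate_genome(cfg)
  peaks <- simulate_peaks(cfg, genome)
  sim <- simulate_interactions(cfg, genome, peaks)
  cat <- build_catalog(peaks, genome$genes, flank = 2000)
  frac <- tally_loop_types(sim$a, cat)
  # generative truth: one loop per wired distal site, so the planted class
  # proportions are the kept-site type shares
  sites <- attr(peaks, "sites")
  wired <- table(sites$type[sites$type != "promoter"])
  expect_lt(abs(frac[["PE"]] - wired[["enhancer"]] / sum(wired)), 0.03)
  expect_lt(abs(frac[["P_INS"]] - wired[["insulator"]] / sum(wired)), 0.03)
  expect_equal(sum(frac), 1, tolerance = 1e-9)
})

test_that("motif region construction follows the staged set algebra", {
  # toy scenario: 3 genes, peaks and loops with known algebra
  tss <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                    tss = c(10000, 50000, 90000), strand = "+",
                    is_oncogene = TRUE,
                    de_status = c("up", "up", "ns"),
                    stringsAsFactors = FALSE)
  de_tss <- tss[tss$de_status == "up", ]
  iset <- make_iset(
    list("chr1", 9250, 10750, "chr1", 8000, 9500, 5, 6, "g1"),
    list("chr1", 49250, 50750, "chr1", 60000, 61500, 5, 6, "g2"),
    list("chr1", 89250, 90750, "chr1", 95000, 96500, 5, 6, "g3"),
    list("chr1", 9250, 10750, "chr1", 30000, 31500, 5, 6, "g1"))
  atac <- genomic_intervals("chr1", c(9000, 60500), c(10000, 61000))
  acetyl <- genomic_intervals("chr1", c(8100, 60200), c(8200, 60400))

  # stage 1 merge: loop end [8000,9500) + ATAC [9000,10000) fuse
  stage1 <- merge_intervals(rbind(anchors(iset, "both"), atac))
  expect_true(any(stage1$start == 8000 & stage1$end == 10750))

  got <- build_motif_regions(iset, atac, de_tss, acetyl_peaks = acetyl)
  # hand-computed set algebra:
  #   stage 2 keeps [8000,10750) (g1 window) and [49250,50750) (g2 window);
  #   the distal anchors at 30000/60000 and all g3 regions fall outside the
  #   DE promoter windows; stage 3 keeps only the acetyl-marked [8000,10750)
  expect_equal(got, genomic_intervals("chr1", 8000, 10750))

  # insulator variant filters stage 2 by the insulator catalog instead
  ins <- genomic_intervals("chr1", 50000, 50400)
  got_ins <- build_motif_regions(iset, atac, de_tss,
                                 insulator_sites = ins,
                                 variant = "insulator")
  expect_equal(got_ins, genomic_intervals("chr1", 49250, 50750))

  # emptiness at a stage warns and returns empty
  far_tss <- data.frame(gene_id = "gx", chrom = "chr9", tss = 5000,
                        strand = "+", is_oncogene = TRUE, de_status = "up",
                        stringsAsFactors = FALSE)
  expect_warning(out <- build_motif_regions(iset, atac, far_tss,
                                            acetyl_peaks = acetyl),
                 "stage 2")
  expect_equal(nrow(out), 0)
})

test_that("motif regions stay inside the merged loop+ATAC point set", {
  cfg <- simulation_config(seed = 19, n_genes = 80)
  genome <- simulate_genome(cfg)
  peaks <- simulate_peaks(cfg, genome)
  sim <- simulate_interactions(cfg, genome, peaks)
  de <- genome$genes[genome$genes$de_status == "up" &
                       genome$genes$is_oncogene, ]
  got <- build_motif_regions(sim$a, peaks$ATAC, de,
                             acetyl_peaks = peaks$H3K27ac)
  hull <- merge_intervals(rbind(anchors(sim$a, "both"), peaks$ATAC))
  inside <- vapply(seq_len(nrow(got)), function(i)
    any(hull$chrom == got$chrom[i] & hull$start <= got$start[i] &
          hull$end >= got$end[i]), logical(1))
  expect_true(all(inside))
})
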