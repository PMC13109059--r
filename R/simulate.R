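#' The seven major AP-1 subunit genes
#'
#' Jun-family (JUN, JUNB, JUND) and Fos-family (FOS, FOSB, FOSL1, FOSL2)
#' members, the default gene set for composite TF-activity scoring.
#' @export
AP1_SUBUNITS <- c("JUN", "JUNB", "JUND", "FOS", "FOSB", "FOSL1", "FOSL2")

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator, with planted effects whose
#' recovery is the package's validation surface. Defaults encode the study
#' conditions the pipeline is exercised under: 300 captured genes, a
#' promoter-enhancer base mean of 50 reads per loop, a planted remodeling
#' fraction of 0.30 at 2-fold effect size, a planted loop-expression
#' Spearman correlation of 0.3, and a survival cohort of 400 patients with
#' hazard ratio 2 for the high-activity group.
#'
#' @param seed Master seed; every generator stream derives a fixed
#'   substream from it, so the same seed reproduces every artifact
#'   byte-for-byte.
#' @param n_chroms,chrom_length Genome shape: chromosomes `chr1..chrN` of
#'   `chrom_length` bp.
#' @param n_genes Number of captured genes; placed with >=
#'   `gene_spacing` bp between TSSs.
#' @param gene_spacing Minimum TSS spacing in bp (default 20 kb).
#' @param oncogene_fraction Fraction of genes flagged as oncogenes
#'   (default 0.56, the share of oncogene baits on a mixed
#'   oncogene/highly-expressed capture panel).
#' @param de_fraction Fraction of genes differentially expressed (half up,
#'   half down in condition A).
#' @param n_samples_per_condition Expression samples per condition.
#' @param enhancers_per_gene,insulators_per_gene Regulatory sites wired to
#'   each gene.
#' @param pp_loop_prob Probability a gene also loops to its neighbouring
#'   promoter (promoter-promoter contact).
#' @param count_mean Mean of the per-gene base Poisson loop-count rate;
#'   gene-level rates are Gamma-distributed around it
#'   (`shape = count_shape`), so loop strength varies continuously across
#'   genes.
#' @param count_shape Gamma shape of the gene-level rate distribution.
#' @param score_pass_prob Probability a loop's confidence score clears the
#'   score-5 cutoff.
#' @param fraction_increased Fraction of genes whose PE loops are planted
#'   as increased in condition A; the complement is planted decreased, so
#'   every gene has a well-defined direction.
#' @param fold_change PE mean-count ratio for planted increases (> 0).
#' @param rho Planted Spearman correlation between PE loop strength and
#'   expression (Gaussian copula; the latent Pearson correlation is
#'   converted so the rank correlation is exact).
#' @param de_lfc Planted log2 fold change of DE genes in condition A.
#' @param expression_noise_sd Per-sample log2 expression noise SD.
#' @param tf_anchor_enrichment Probability a promoter/enhancer site carries
#'   a TF peak.
#' @param coloc_prob Probability the two hallmark marks of an
#'   enhancer/insulator site are co-placed (site "active").
#' @param n_cohort Survival cohort size.
#' @param hazard_ratio Hazard multiplier for samples with above-median
#'   latent TF activity (> 0).
#' @param censoring_rate Target fraction of censored subjects.
#' @param subunit_noise_sd SD of subunit-level noise around the latent
#'   activity.
#' @param bait_width Anchor fragment width in bp (default 1500, the
#'   4-cutter capture resolution).
#' @param peak_width ChIP/ATAC peak width in bp.
#' @param promoter_flank Promoter window flank in bp.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 4, chrom_length = 5e6,
                              n_genes = 300, gene_spacing = 20000,
                              oncogene_fraction = 0.56,
                              de_fraction = 0.4,
                              n_samples_per_condition = 3,
                              enhancers_per_gene = 3,
                              insulators_per_gene = 1,
                              pp_loop_prob = 0.25,
                              count_mean = 50,
                              count_shape = 10,
                              score_pass_prob = 0.9,
                              fraction_increased = 0.30,
                              fold_change = 2,
                              rho = 0.3,
                              de_lfc = 2,
                              expression_noise_sd = 0.1,
                              tf_anchor_enrichment = 0.6,
                              coloc_prob = 0.9,
                              n_cohort = 400,
                              hazard_ratio = 2,
                              censoring_rate = 0.2,
                              subunit_noise_sd = 0.5,
                              bait_width = 1500,
                              peak_width = 1000,
                              promoter_flank = 2000) {
  cfg <- as.list(environment())
  fracs <- c("oncogene_fraction", "de_fraction", "score_pass_prob",
             "fraction_increased", "tf_anchor_enrichment", "coloc_prob",
             "censoring_rate", "pp_loop_prob")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be in [0, 1]")
  if (abs(cfg$rho) > 1) stop("rho must be in [-1, 1]")
  if (cfg$fold_change <= 0) stop("fold_change must be > 0")
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (cfg$count_mean <= 0 || cfg$count_shape <= 0)
    stop("count_mean and count_shape must be > 0")
  if (cfg$n_genes < 1 || cfg$n_chroms < 1) stop("need >= 1 gene/chromosome")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "simulation_config")
}

# Fixed per-stream substreams of the master seed: adding a stream never
# perturbs existing ones. Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  offsets <- c(genome = 101L, peaks = 202L, interactions = 303L,
               expression = 404L, cohort = 505L)
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]] * 104729) %%
               2147483629)
}

#' Simulate a gene annotation over a toy genome
#'
#' Places `n_genes` TSSs uniformly at random with at least `gene_spacing`
#' bp between neighbours (per chromosome), then draws oncogene and
#' differential-expression flags at the configured fractions.
#' Deterministic per seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genes` (a gene table as in [read_gene_table()]) and
#'   `chrom_sizes` (named vector).
#' @export
simulate_genome <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "genome"))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  if (any(per * cfg$gene_spacing > cfg$chrom_length))
    stop("genes do not fit: ", max(per), " genes x ", cfg$gene_spacing,
         " bp spacing exceeds chromosome length ", cfg$chrom_length)
  tss <- integer(0); chrom <- character(0)
  for (i in seq_len(cfg$n_chroms)) {
    g <- per[i]
    if (g == 0) next
    slack <- cfg$chrom_length - g * cfg$gene_spacing
    u <- sort(sample.int(slack + 1, g, replace = TRUE) - 1)
    tss <- c(tss, u + cfg$gene_spacing * (seq_len(g) - 1) +
               floor(cfg$gene_spacing / 2))
    chrom <- c(chrom, rep(chroms[i], g))
  }
  n <- length(tss)
  de <- sample(c("up", "down", "ns"), n, replace = TRUE,
               prob = c(cfg$de_fraction / 2, cfg$de_fraction / 2,
                        1 - cfg$de_fraction))
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chrom,
    tss = tss,
    strand = sample(c("+", "-"), n, replace = TRUE),
    is_oncogene = stats::runif(n) < cfg$oncogene_fraction,
    de_status = de,
    stringsAsFactors = FALSE
  )
  list(genes = genes, chrom_sizes = chrom_sizes)
}

clamp_center <- function(center, half, L) pmin(pmax(center, half), L - half)

# Minimum distance from each (chrom, center) point to a reference point set;
# Inf when the chromosome has no reference points.
min_dist_to <- function(chrom, center, ref_chrom, ref_center) {
  out <- rep(Inf, length(center))
  for (ch in unique(chrom)) {
    refs <- sort(ref_center[ref_chrom == ch])
    if (length(refs) == 0) next
    idx <- which(chrom == ch)
    pos <- findInterval(center[idx], refs)
    d_lo <- ifelse(pos >= 1, center[idx] - refs[pmax(pos, 1)], Inf)
    d_hi <- ifelse(pos < length(refs),
                   refs[pmin(pos + 1, length(refs))] - center[idx], Inf)
    out[idx] <- pmin(abs(d_lo), abs(d_hi))
  }
  out
}

# Greedy same-type thinning: drop sites closer than min_gap to an
# already-kept site on the same chromosome (placement order preserved).
thin_sites <- function(df, min_gap) {
  keep <- logical(nrow(df))
  kept <- split(numeric(0), character(0))
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    prev <- kept[[ch]]
    if (is.null(prev) || all(abs(prev - df$center[i]) >= min_gap)) {
      keep[i] <- TRUE
      kept[[ch]] <- c(prev, df$center[i])
    }
  }
  df[keep, , drop = FALSE]
}

#' Simulate hallmark peak sets
#'
#' Places ChIP/ATAC peaks around the simulated genes: promoter hallmarks
#' (Pol II, H3K4me3) centered on every TSS; enhancer hallmarks (H3K27ac,
#' Med1) at designated enhancer sites 5-50 kb from their gene's TSS,
#' co-placed with probability `coloc_prob` (otherwise only one of the pair
#' is placed, so the site is not called active); insulator hallmarks
#' (CTCF, Rad21) likewise at 10-60 kb; ATAC peaks at all promoter and
#' enhancer sites; TF peaks at promoter/enhancer sites with probability
#' `tf_anchor_enrichment`.
#'
#' @param cfg A [simulation_config()].
#' @param genome A [simulate_genome()] result.
#' @return Named list of interval tables for marks `ATAC`, `PolII`,
#'   `H3K4me3`, `H3K27ac`, `Med1`, `CTCF`, `Rad21`, `TF`, with the site
#'   wiring table in `attr(, "sites")`.
#' @export
simulate_peaks <- function(cfg, genome) {
  set.seed(substream_seed(cfg$seed, "peaks"))
  g <- genome$genes
  half <- cfg$peak_width / 2
  L <- cfg$chrom_length
  expand_sites <- function(type, per_gene, d_min, d_max) {
    if (per_gene <= 0)
      return(data.frame(gene_id = character(), type = character(),
                        chrom = character(), center = numeric(),
                        stringsAsFactors = FALSE))
    gi <- rep(seq_len(nrow(g)), each = per_gene)
    n <- length(gi)
    off <- sample(c(-1, 1), n, replace = TRUE) *
      round(stats::runif(n, d_min, d_max))
    data.frame(gene_id = g$gene_id[gi], type = type, chrom = g$chrom[gi],
               center = clamp_center(g$tss[gi] + off, half, L),
               stringsAsFactors = FALSE)
  }
  prom <- data.frame(gene_id = g$gene_id, type = "promoter",
                     chrom = g$chrom, center = g$tss,
                     stringsAsFactors = FALSE)
  enh <- expand_sites("enhancer", cfg$enhancers_per_gene, 5000, 50000)
  ins <- expand_sites("insulator", cfg$insulators_per_gene, 10000, 60000)
  # Keep element territories mutually exclusive so each designated site
  # classifies as its own type: distal sites stay clear of every promoter
  # window (any gene), insulators stay clear of enhancer sites, and
  # same-type sites do not overlap each other.
  clear_of_tss <- cfg$promoter_flank + cfg$bait_width / 2 + half
  enh <- enh[min_dist_to(enh$chrom, enh$center, g$chrom, g$tss) >=
               clear_of_tss, , drop = FALSE]
  enh <- thin_sites(enh, cfg$peak_width)
  ins <- ins[min_dist_to(ins$chrom, ins$center, g$chrom, g$tss) >=
               clear_of_tss &
               min_dist_to(ins$chrom, ins$center, enh$chrom, enh$center) >=
                 cfg$bait_width / 2 + cfg$peak_width, , drop = FALSE]
  ins <- thin_sites(ins, cfg$peak_width)
  sites <- rbind(prom, enh, ins)
  sites$start <- sites$center - half
  sites$end <- sites$center + half
  sites$site_id <- sprintf("s%05d", seq_len(nrow(sites)))
  # Pair placement: both marks with prob coloc_prob, else one at random.
  pairfate <- function(n) {
    both <- stats::runif(n) < cfg$coloc_prob
    first <- stats::runif(n) < 0.5
    cbind(m1 = both | first, m2 = both | !first, active = both)
  }
  is_enh <- sites$type == "enhancer"
  is_ins <- sites$type == "insulator"
  is_prom <- sites$type == "promoter"
  fe <- pairfate(sum(is_enh)); fi <- pairfate(sum(is_ins))
  sites$active <- FALSE
  sites$active[is_prom] <- TRUE
  sites$active[is_enh] <- fe[, "active"]
  sites$active[is_ins] <- fi[, "active"]
  sites$has_tf <- FALSE
  sites$has_tf[is_prom | is_enh] <-
    stats::runif(sum(is_prom | is_enh)) < cfg$tf_anchor_enrichment
  iv <- function(idx) {
    s <- sites[idx, , drop = FALSE]
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               stringsAsFactors = FALSE)
  }
  peaks <- list(
    ATAC = iv(is_prom | is_enh),
    PolII = iv(is_prom),
    H3K4me3 = iv(is_prom),
    # H3K27ac additionally marks active promoters; Med1 co-localization is
    # what restricts the enhancer catalog to enhancer sites
    H3K27ac = iv(is_prom | seq_len(nrow(sites)) %in%
                   which(is_enh)[fe[, "m1"]]),
    Med1 = iv(which(is_enh)[fe[, "m2"]]),
    CTCF = iv(which(is_ins)[fi[, "m1"]]),
    Rad21 = iv(which(is_ins)[fi[, "m2"]]),
    TF = iv(sites$has_tf)
  )
  attr(peaks, "sites") <- sites
  peaks
}

#' Simulate two-condition pcHiC interaction sets with planted remodeling
#'
#' For each gene, loops run from its promoter bait (a `bait_width` fragment
#' centered on the TSS) to its enhancer and insulator sites, plus an
#' occasional promoter-promoter loop to the neighbouring gene. Counts are
#' Poisson with a Gamma-distributed gene-level base rate (mean
#' `count_mean`). A `fraction_increased` subset of genes has its
#' promoter-enhancer loop rates multiplied by `fold_change` in condition A;
#' the remaining genes are planted decreased (divided by `fold_change`) so
#' every gene carries a recoverable direction. Confidence scores clear the
#' score-5 cutoff with probability `score_pass_prob`. Deterministic per
#' seed.
#'
#' @param cfg A [simulation_config()].
#' @param genome A [simulate_genome()] result.
#' @param peaks A [simulate_peaks()] result.
#' @return List with interaction sets `a` and `b` (raw counts) and `truth`,
#'   a per-gene table of the planted direction and PE-loop rates.
#' @export
simulate_interactions <- function(cfg, genome, peaks) {
  set.seed(substream_seed(cfg$seed, "interactions"))
  g <- genome$genes
  sites <- attr(peaks, "sites")
  bw2 <- floor(cfg$bait_width / 2)
  base_rate <- stats::rgamma(nrow(g), shape = cfg$count_shape,
                             rate = cfg$count_shape / cfg$count_mean)
  increased <- stats::runif(nrow(g)) < cfg$fraction_increased
  lam_a <- ifelse(increased, base_rate * cfg$fold_change,
                  base_rate / cfg$fold_change)
  lam_b <- base_rate
  bait_start <- pmax(0, g$tss - bw2)
  # distal loops: one per non-promoter site of each gene
  ds <- sites[sites$type != "promoter", , drop = FALSE]
  dgi <- match(ds$gene_id, g$gene_id)
  oth_start <- pmax(0, ds$center - bw2)
  loops <- data.frame(
    chrom1 = g$chrom[dgi], start1 = bait_start[dgi],
    end1 = bait_start[dgi] + cfg$bait_width,
    chrom2 = ds$chrom, start2 = oth_start,
    end2 = oth_start + cfg$bait_width,
    type = ds$type, gene = ds$gene_id, stringsAsFactors = FALSE)
  # occasional promoter-promoter loop to the next gene on the chromosome
  if (nrow(g) > 1) {
    i <- seq_len(nrow(g) - 1)
    pp <- i[g$chrom[i] == g$chrom[i + 1] &
              stats::runif(length(i)) < cfg$pp_loop_prob]
    if (length(pp)) {
      loops <- rbind(loops, data.frame(
        chrom1 = g$chrom[pp], start1 = bait_start[pp],
        end1 = bait_start[pp] + cfg$bait_width,
        chrom2 = g$chrom[pp + 1], start2 = bait_start[pp + 1],
        end2 = bait_start[pp + 1] + cfg$bait_width,
        type = "promoter", gene = g$gene_id[pp],
        stringsAsFactors = FALSE))
    }
  }
  gi <- match(loops$gene, g$gene_id)
  is_pe <- loops$type == "enhancer"
  mk_condition <- function(lam_pe, label) {
    lam <- ifelse(is_pe, lam_pe[gi],
                  ifelse(loops$type == "insulator", base_rate[gi],
                         base_rate[gi] * 0.8))
    count <- stats::rpois(nrow(loops), lam)
    pass <- stats::runif(nrow(loops)) < cfg$score_pass_prob
    score <- ifelse(pass, stats::runif(nrow(loops), 5.5, 12),
                    stats::runif(nrow(loops), 0.5, 4.5))
    interaction_set(
      data.frame(loops[, c("chrom1", "start1", "end1",
                           "chrom2", "start2", "end2")],
                 count = count, score = score, gene = loops$gene,
                 stringsAsFactors = FALSE),
      label)
  }
  iset_a <- mk_condition(lam_a, "condition_a")
  iset_b <- mk_condition(lam_b, "condition_b")
  n_pe <- table(factor(ds$gene_id[ds$type == "enhancer"],
                       levels = g$gene_id))
  truth <- data.frame(
    gene_id = g$gene_id,
    direction = ifelse(increased, "increased", "not_increased"),
    lambda_pe_a = lam_a, lambda_pe_b = lam_b,
    n_pe_sites = as.integer(n_pe),
    stringsAsFactors = FALSE
  )
  list(a = iset_a, b = iset_b, truth = truth)
}

# Spearman target -> latent bivariate-normal Pearson correlation.
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Simulate expression with a planted loop-strength association
#'
#' Per-gene log2 expression follows a Gaussian copula against the gene's
#' planted PE loop rate, calibrated so the *Spearman* correlation equals
#' `rho`. The gene-level residual is shared between conditions (a gene's
#' baseline identity), DE genes additionally receive `de_lfc` log2 units
#' (up) or `-de_lfc` (down) in condition A, and each sample adds
#' independent log2 noise of SD `expression_noise_sd`. Because the DE
#' shift perturbs condition A only, condition B carries the planted copula
#' exactly.
#'
#' @param cfg A [simulation_config()].
#' @param genome A [simulate_genome()] result.
#' @param truth Truth table from [simulate_interactions()] (per-gene PE
#'   rates).
#' @return List with matrices `a` and `b` (genes x samples, linear scale).
#' @export
simulate_expression <- function(cfg, genome, truth) {
  set.seed(substream_seed(cfg$seed, "expression"))
  g <- genome$genes
  n <- nrow(g)
  idx <- match(g$gene_id, truth$gene_id)
  if (anyNA(idx)) stop("truth table is missing genes")
  r <- spearman_to_pearson(cfg$rho)
  eps <- stats::rnorm(n)  # gene baseline, shared across conditions
  zs <- function(strength)
    stats::qnorm(rank(strength, ties.method = "average") / (n + 1))
  shift_a <- ifelse(g$de_status == "up", cfg$de_lfc,
                    ifelse(g$de_status == "down", -cfg$de_lfc, 0))
  mu_a <- 5 + r * zs(truth$lambda_pe_a[idx]) + sqrt(1 - r^2) * eps + shift_a
  mu_b <- 5 + r * zs(truth$lambda_pe_b[idx]) + sqrt(1 - r^2) * eps
  draw <- function(mu, prefix) {
    m <- 2^(matrix(mu, n, cfg$n_samples_per_condition) +
              matrix(stats::rnorm(n * cfg$n_samples_per_condition,
                                  sd = cfg$expression_noise_sd),
                     n, cfg$n_samples_per_condition))
    dimnames(m) <- list(g$gene_id,
                        sprintf("%s%02d", prefix,
                                seq_len(cfg$n_samples_per_condition)))
    m
  }
  list(a = draw(mu_a, "a"), b = draw(mu_b, "b"))
}

#' Simulate a survival cohort with a planted activity-score hazard
#'
#' Each sample draws a standard-normal latent TF activity; subunit
#' expressions are monotone in the latent plus independent noise, and
#' survival is exponential with the hazard multiplied by `hazard_ratio`
#' for samples whose latent activity is above the cohort median.
#' Censoring is independent exponential, tuned to the configured rate.
#'
#' @param cfg A [simulation_config()].
#' @return List with `expression` (subunits x samples matrix, linear
#'   scale), `clinical` (sample_id, survival_time, event) and `latent`
#'   (the per-sample latent activity, for truth checks).
#' @export
simulate_cohort <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "cohort"))
  n <- cfg$n_cohort
  ids <- sprintf("p%04d", seq_len(n))
  latent <- stats::rnorm(n)
  base <- stats::runif(length(AP1_SUBUNITS), 6, 10)  # subunit baselines
  expr <- 2^(outer(base, rep(1, n)) +
               outer(rep(1, length(AP1_SUBUNITS)), latent) +
               matrix(stats::rnorm(length(AP1_SUBUNITS) * n,
                                   sd = cfg$subunit_noise_sd),
                      length(AP1_SUBUNITS), n))
  dimnames(expr) <- list(AP1_SUBUNITS, ids)
  base_hazard <- 1 / 1000  # median baseline survival ~ 693 days
  high <- latent > stats::median(latent)
  rate <- base_hazard * ifelse(high, cfg$hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  cens_rate <- if (cfg$censoring_rate > 0)
    base_hazard * cfg$censoring_rate / (1 - cfg$censoring_rate) else 0
  t_cens <- if (cens_rate > 0) stats::rexp(n, cens_rate) else rep(Inf, n)
  clinical <- data.frame(
    sample_id = ids,
    survival_time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
  list(expression = expr, clinical = clinical,
       latent = stats::setNames(latent, ids))
}
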