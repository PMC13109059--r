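# Independent brute-force oracles used to cross-check the interval algebra
# and the binned/grouped computations. All deliberately O(n*m) or based on
# explicit 0/1 coverage vectors over a small coordinate space, so they share
# no code path with the implementations they check.

# Merge oracle: paint a 0/1 coverage vector over [0, limit) and read off
# maximal covered runs. Book-ended intervals fuse naturally.
oracle_merge <- function(x, limit = NULL) {
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, , drop = FALSE]
    lim <- if (is.null(limit)) max(xi$end) else limit
    cov <- logical(lim)
    for (i in seq_len(nrow(xi)))
      cov[(xi$start[i] + 1):xi$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Co-localization oracle: all-pairs intersections, then the merge oracle.
oracle_colocalize <- function(a, b, min_overlap = 1) {
  pieces <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (e - s >= min_overlap)
      pieces[[length(pieces) + 1]] <- data.frame(
        chrom = a$chrom[i], start = s, end = e, stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  oracle_merge(do.call(rbind, pieces))
}

# Linear-scan anchor classifier with explicit precedence.
oracle_classify <- function(anchors_df, catalog, min_overlap = 1) {
  hit <- function(a_row, set) {
    if (nrow(set) == 0) return(FALSE)
    any(set$chrom == a_row$chrom &
          pmin(set$end, a_row$end) - pmax(set$start, a_row$start) >=
            min_overlap)
  }
  vapply(seq_len(nrow(anchors_df)), function(i) {
    a <- anchors_df[i, ]
    if (hit(a, catalog$promoters)) "promoter"
    else if (hit(a, catalog$enhancers)) "enhancer"
    else if (hit(a, catalog$insulators)) "insulator"
    else "other"
  }, character(1))
}

# Loop-by-loop virtual 4C assignment oracle.
oracle_v4c <- function(iset, gene, region, bin_size) {
  starts <- seq(region$start, region$end - 1, by = bin_size)
  signal <- numeric(length(starts))
  df <- iset$interactions
  for (i in seq_len(nrow(df))) {
    if (df$gene[i] != gene || df$chrom2[i] != region$chrom) next
    mid <- floor((df$start2[i] + df$end2[i]) / 2)
    if (mid < region$start || mid >= region$end) next
    bin <- floor((mid - region$start) / bin_size) + 1
    signal[bin] <- signal[bin] + df$count[i]
  }
  signal
}

# Hand-rolled two-group log-rank O/E/V accumulation over event times.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  grp_a <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp_a)
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Random valid interval tables over a small coordinate space.
random_intervals <- function(n, chroms = c("chr1", "chr2"), limit = 20000,
                             max_width = 400) {
  start <- sample.int(limit - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# Small interaction-set fixture with explicit fields.
make_iset <- function(..., label = "test") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom1 = r[[1]], start1 = as.numeric(r[[2]]),
               end1 = as.numeric(r[[3]]), chrom2 = r[[4]],
               start2 = as.numeric(r[[5]]), end2 = as.numeric(r[[6]]),
               count = as.numeric(r[[7]]), score = as.numeric(r[[8]]),
               gene = if (length(r) >= 9) r[[9]] else "",
               stringsAsFactors = FALSE)))
  interaction_set(df, label)
}
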