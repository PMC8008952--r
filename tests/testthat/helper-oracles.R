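# Independent brute-force oracles used to verify the implementation on
# small inputs. These deliberately avoid the code paths they check.

oracle_scan_gatc <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- integer(0)
  if (n >= 4) {
    for (p in 1:(n - 3)) {
      if (substr(seq, p, p + 3) == "GATC") out <- c(out, p - 1L)
    }
  }
  out
}

# per-read, per-fragment interval-intersection tally (straddle double-counts)
oracle_fragment_counts <- function(reads, frags) {
  counts <- numeric(nrow(frags))
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(frags))) {
      if (reads$chrom[i] == frags$chrom[j] &&
          reads$start[i] < frags$end[j] &&
          reads$end[i] > frags$start[j]) {
        counts[j] <- counts[j] + 1
      }
    }
  }
  counts
}

# exhaustive single-changepoint search with the pooled two-sample t statistic
oracle_best_split <- function(x) {
  m <- length(x)
  best <- -Inf
  bi <- 0L
  for (i in 1:(m - 1)) {
    l <- x[1:i]
    r <- x[(i + 1):m]
    ss <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    sp2 <- ss / max(1, m - 2)
    tt <- if (sp2 == 0) {
      if (mean(l) != mean(r)) Inf else 0
    } else {
      abs(mean(l) - mean(r)) / sqrt(sp2 * (1 / i + 1 / (m - i)))
    }
    if (tt > best) {
      best <- tt
      bi <- i
    }
  }
  bi
}

# per-base membership masks on a toy chromosome of length L (single chrom)
oracle_base_overlap <- function(A, B, L) {
  mask <- function(iv) {
    m <- logical(L)
    for (i in seq_len(nrow(iv))) {
      if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1):iv$end[i]] <- TRUE
    }
    m
  }
  ma <- mask(A)
  mb <- mask(B)
  shared <- sum(ma & mb)
  list(pct_A_in_B = 100 * shared / sum(ma),
       pct_B_in_A = 100 * shared / sum(mb),
       shared_bp = shared)
}

oracle_peaks_within <- function(peaks, regions) {
  n <- 0L
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    inside <- any(regions$chrom == peaks$chrom[i] &
                    regions$start <= mid & mid < regions$end)
    if (inside) n <- n + 1L
  }
  n
}

# per-base value lookup of a piecewise track; NA where uncovered
oracle_window_mean <- function(track, chrom, lo, hi) {
  vals <- c()
  for (b in lo:(hi - 1)) {
    row <- which(track$chrom == chrom & track$start <= b & b < track$end &
                   !is.na(track$score))
    if (length(row)) vals <- c(vals, track$score[row[1]])
  }
  if (length(vals)) mean(vals) else NA_real_
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build a single-chromosome score track with uniform fragment width
make_score_track <- function(scores, width = 10L, chrom = "chr1") {
  n <- length(scores)
  tibble::tibble(
    chrom = chrom,
    start = (seq_len(n) - 1L) * width,
    end = seq_len(n) * width,
    frag = seq_len(n),
    score = scores
  )
}

random_intervals <- function(n, L, max_w = 500L) {
  starts <- sort(sample.int(L - max_w, n))
  widths <- sample.int(max_w, n, replace = TRUE)
  tibble::tibble(chrom = "toy", start = starts,
                 end = pmin(starts + widths, L))
}
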