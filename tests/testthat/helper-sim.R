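# shared fixture builders -----------------------------------------------

# a bare signal track on one chromosome
make_track <- function(score, chrom = "chr1") {
  n <- length(score)
  tibble::tibble(tile_id = seq_len(n), chrom = chrom,
                 start = seq(1L, by = 100L, length.out = n),
                 end = seq(1L, by = 100L, length.out = n) + 59L,
                 score = score)
}

# track drawn from a 2-state Gaussian HMM (for parameter recovery)
make_hmm_track <- function(n, mu = c(0, 2), sd = c(0.5, 0.5),
                           p_stay = c(0.99, 0.9), seed = 1) {
  set.seed(seed)
  A <- matrix(c(p_stay[1], 1 - p_stay[1], 1 - p_stay[2], p_stay[2]),
              2, byrow = TRUE)
  states <- integer(n)
  s <- 1L
  for (i in seq_len(n)) {
    states[i] <- s
    s <- sample(1:2, 1, prob = A[s, ])
  }
  list(track = make_track(stats::rnorm(n, mu[states], sd[states])),
       states = states)
}

# noise + one planted flat segment
make_segment_track <- function(n = 500, seg = 201:210, snr = 3,
                               noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n, 0, noise_sd)
  x[seg] <- x[seg] + snr
  make_track(x)
}

# long-format chip scores for two conditions with given per-tile means
make_chip <- function(mean_a, mean_b, noise_sd = 0, n_rep = 2, seed = 1,
                      conds = c("A", "B")) {
  set.seed(seed)
  n <- length(mean_a)
  base <- make_track(numeric(n))[, c("tile_id", "chrom", "start", "end")]
  out <- list()
  for (ci in 1:2) {
    mu <- list(mean_a, mean_b)[[ci]]
    for (r in seq_len(n_rep)) {
      tr <- base
      tr$condition <- conds[ci]
      tr$replicate <- r
      tr$score <- mu + stats::rnorm(n, 0, noise_sd)
      out[[length(out) + 1]] <- tr
    }
  }
  dplyr::bind_rows(out)
}

# independent brute-force per-base oracle for the central-40% marking rule
brute_force_marked <- function(gene, domains, crit) {
  L <- gene$end - gene$start + 1L
  f <- crit$central_fraction
  lo <- gene$start + floor(L * (0.5 - f / 2))          # 1-based first bp
  hi <- gene$start - 1L + ceiling(L * (0.5 + f / 2))   # 1-based last bp
  seg <- lo:hi
  covered <- rep(FALSE, length(seg))
  for (i in seq_len(nrow(domains))) {
    if (domains$chrom[i] != gene$chrom) next
    covered <- covered | (seg >= domains$start[i] & seg <= domains$end[i])
  }
  ov <- sum(covered)
  ov >= crit$min_overlap_bp &&
    (ov / length(seg)) >= crit$min_covered_fraction
}

tiny_cfg <- function(...) {
  sim_config(n_chromosomes = 1, chrom_length_bp = 3e5, n_genes = 60, ...)
}
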