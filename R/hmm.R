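#' Parameters of the two-state segmentation HMM
#'
#' Background and enriched states with Gaussian emissions. State identity is
#' fixed by the constraint `mu_enr > mu_bg`; EM relabels if it swaps them.
#'
#' @param mu_bg,mu_enr emission means (standardized log2 units)
#' @param sd_bg,sd_enr emission standard deviations (> 0)
#' @param p_stay_bg,p_stay_enr self-transition probabilities in (0, 1)
#' @param posterior_threshold posterior probability cutoff for calling a
#'   tile enriched, in \[0.5, 1); the default 0.95 is the stringent setting
#' @param min_run_tiles minimum number of tiles in a domain
#' @param max_gap_tiles maximum sub-threshold gap (tiles) merged between
#'   candidate runs
#' @return list of class `hmm_params`
#' @export
hmm_params <- function(mu_bg = 0, mu_enr = 2, sd_bg = 1, sd_enr = 1,
                       p_stay_bg = 0.99, p_stay_enr = 0.9,
                       posterior_threshold = 0.95,
                       min_run_tiles = 3L, max_gap_tiles = 1L) {
  p <- list(mu_bg = mu_bg, mu_enr = mu_enr, sd_bg = sd_bg, sd_enr = sd_enr,
            p_stay_bg = p_stay_bg, p_stay_enr = p_stay_enr,
            posterior_threshold = posterior_threshold,
            min_run_tiles = as.integer(min_run_tiles),
            max_gap_tiles = as.integer(max_gap_tiles),
            converged = NA, loglik = NA_real_)
  validate_hmm_params(p)
  structure(p, class = "hmm_params")
}

validate_hmm_params <- function(p) {
  if (!(p$mu_enr > p$mu_bg)) stop("mu_enr must be > mu_bg")
  if (p$sd_bg <= 0 || p$sd_enr <= 0) stop("emission sds must be > 0")
  if (p$p_stay_bg <= 0 || p$p_stay_bg >= 1 ||
      p$p_stay_enr <= 0 || p$p_stay_enr >= 1) {
    stop("self-transition probabilities must be in (0, 1)")
  }
  if (p$posterior_threshold < 0.5 || p$posterior_threshold >= 1) {
    stop("posterior_threshold must be in [0.5, 1)")
  }
  invisible(p)
}

hmm_matrices <- function(p) {
  list(
    mu = c(p$mu_bg, p$mu_enr),
    sd = c(p$sd_bg, p$sd_enr),
    trans = matrix(c(p$p_stay_bg, 1 - p$p_stay_bg,
                     1 - p$p_stay_enr, p$p_stay_enr),
                   nrow = 2, byrow = TRUE),
    init = c(0.95, 0.05)
  )
}

track_segments <- function(track) {
  r <- rle(as.character(track$chrom))
  as.integer(r$lengths)
}

#' Fit the two-state HMM by expectation-maximization
#'
#' Emission means/sds, transition probabilities and the initial distribution
#' are re-estimated on the chromosome-concatenated track (transitions reset
#' at chromosome boundaries). Initialization comes from quantiles of the
#' track (background mean at the median, enriched mean at the 90th
#' percentile) unless `init` is supplied. Convergence: log-likelihood
#' improvement < 1e-4, at most 200 iterations; non-convergence returns the
#' best-so-far parameters with `converged = FALSE` and a warning.
#'
#' @param track standardized signal track (tibble with chrom, score)
#' @param init optional [hmm_params()] starting point
#' @param max_iter,tol EM controls
#' @param fix_background optional c(mean, sd): hold the background
#'   emission fixed (semi-supervised fit of the enriched state only);
#'   used for one-sided differential decoding
#' @return fitted [hmm_params()] with `loglik` and `converged` filled in
#' @export
fit_hmm <- function(track, init = NULL, max_iter = 200L, tol = 1e-4,
                    fix_background = NULL) {
  x <- track$score
  if (length(x) < 100) stop("track must have >= 100 tiles")
  seg <- track_segments(track)
  if (is.null(init)) {
    s0 <- max(stats::mad(x), stats::sd(x) / 2, 0.05)
    if (!is.null(fix_background)) {
      init <- hmm_params(
        mu_bg = fix_background[1],
        mu_enr = max(stats::quantile(x, 0.95),
                     fix_background[1] + 2 * fix_background[2]),
        sd_bg = max(fix_background[2], 1e-3), sd_enr = s0)
    } else {
      init <- hmm_params(
        mu_bg = stats::median(x),
        mu_enr = max(stats::quantile(x, 0.9), stats::median(x) + 0.1),
        sd_bg = s0, sd_enr = s0)
    }
  }
  p <- init
  m <- hmm_matrices(p)
  init_prob <- m$init
  prev_ll <- -Inf
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    fb <- hmm_forward_backward(x, seg, m$mu, m$sd, m$trans, init_prob)
    g <- fb$gamma
    wk <- colSums(g)
    mu_new <- c(sum(g[, 1] * x), sum(g[, 2] * x)) / wk
    sd_new <- sqrt(pmax(
      c(sum(g[, 1] * (x - mu_new[1])^2),
        sum(g[, 2] * (x - mu_new[2])^2)) / wk, 1e-6))
    sd_new <- pmax(sd_new, 1e-3)
    if (!is.null(fix_background)) {
      mu_new[1] <- fix_background[1]
      sd_new[1] <- max(fix_background[2], 1e-3)
      # keep the free state above the anchored background
      mu_new[2] <- max(mu_new[2], mu_new[1] + 1e-6)
    }
    xi <- fb$xi
    trans_new <- xi / rowSums(xi)
    trans_new <- pmin(pmax(trans_new, 1e-6), 1 - 1e-6)
    trans_new <- trans_new / rowSums(trans_new)
    init_new <- fb$init_post / sum(fb$init_post)
    init_new <- pmin(pmax(init_new, 1e-6), 1 - 1e-6)
    # enforce state identity: state 2 is the enriched (higher-mean) state
    if (mu_new[2] < mu_new[1]) {
      mu_new <- rev(mu_new); sd_new <- rev(sd_new)
      trans_new <- trans_new[2:1, 2:1]; init_new <- rev(init_new)
    }
    m$mu <- mu_new; m$sd <- sd_new; m$trans <- trans_new
    init_prob <- init_new / sum(init_new)
    if (is.finite(prev_ll) && fb$loglik - prev_ll < tol) {
      converged <- TRUE
      prev_ll <- fb$loglik
      break
    }
    prev_ll <- fb$loglik
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter,
            " iterations; returning best-so-far parameters")
  }
  out <- p
  out$mu_bg <- m$mu[1]; out$mu_enr <- max(m$mu[2], m$mu[1] + 1e-9)
  out$sd_bg <- m$sd[1]; out$sd_enr <- m$sd[2]
  out$p_stay_bg <- m$trans[1, 1]; out$p_stay_enr <- m$trans[2, 2]
  out$loglik <- prev_ll
  out$converged <- converged
  out$n_iter <- n_iter
  structure(out, class = "hmm_params")
}

#' Posterior probability of the enriched state per tile
#'
#' @param track signal track (chrom, score)
#' @param params [hmm_params()]
#' @return numeric vector of posterior P(enriched) per tile
#' @export
posterior_enriched <- function(track, params) {
  m <- hmm_matrices(params)
  fb <- hmm_forward_backward(track$score, track_segments(track),
                             m$mu, m$sd, m$trans, m$init)
  fb$gamma[, 2]
}

# EM on a signal-free track collapses the two emission states; a posterior
# decoded from near-identical states is meaningless, so segmentation then
# reports no enrichment.
states_collapsed <- function(params) {
  pooled_sd <- sqrt((params$sd_bg^2 + params$sd_enr^2) / 2)
  (params$mu_enr - params$mu_bg) < 0.25 * pooled_sd
}

#' Call enriched domains from a signal track
#'
#' Tiles with posterior P(enriched) >= `posterior_threshold` form candidate
#' runs (ties at the threshold are included); runs separated by at most
#' `max_gap_tiles` sub-threshold tiles are merged; merged runs spanning
#' fewer than `min_run_tiles` tiles are discarded. The domain spans the
#' first tile start to the last tile end.
#'
#' @param track standardized signal track (tile_id, chrom, start, end,
#'   score)
#' @param params fitted [hmm_params()]
#' @param label condition label recorded on the output
#' @return tibble: chrom, start, end, condition, n_tiles, mean_score,
#'   mean_posterior
#' @export
call_domains <- function(track, params, label = NA_character_) {
  validate_hmm_params(params)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  condition = character(), n_tiles = integer(),
                  mean_score = numeric(), mean_posterior = numeric())
  if (states_collapsed(params)) return(empty)
  post <- posterior_enriched(track, params)
  domains_from_posterior(track, post, params, label, empty)
}

domains_from_posterior <- function(track, post, params, label, empty) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    sel <- which(track$chrom == chrom)
    runs <- find_runs(post[sel] >= params$posterior_threshold,
                      max_gap = params$max_gap_tiles,
                      min_run = params$min_run_tiles)
    if (nrow(runs) == 0) next
    out[[chrom]] <- tibble(
      chrom = chrom,
      start = track$start[sel][runs$start],
      end = track$end[sel][runs$end],
      condition = label,
      n_tiles = runs$end - runs$start + 1L,
      mean_score = vapply(seq_len(nrow(runs)), function(i) {
        mean(track$score[sel][runs$start[i]:runs$end[i]])
      }, numeric(1)),
      mean_posterior = vapply(seq_len(nrow(runs)), function(i) {
        mean(post[sel][runs$start[i]:runs$end[i]])
      }, numeric(1))
    )
  }
  if (length(out) == 0) empty else bind_rows(out)
}

#' Moderated per-tile differential statistic between two conditions
#'
#' A moderated t-like statistic per tile: the difference of condition means
#' divided by `sqrt(s_tile^2 + s0^2)`, where `s_tile^2` pools the replicate
#' variances of both conditions (variance of the difference of means) and
#' `s0` is the median of `s_tile` over all tiles (variance shrinkage; keeps
#' zero-replicate-variance tiles finite). The statistic is then smoothed by
#' a centered moving average of `window_tiles` (odd) within chromosomes.
#'
#' @param chip long tile-score tibble with replicate scores
#' @param cond_a,cond_b condition labels; the statistic is positive where
#'   `cond_b` exceeds `cond_a`
#' @param window_tiles moving-average window (odd number of tiles)
#' @return tibble: tile_id, chrom, start, end, stat (smoothed), stat_raw
#' @export
differential_score <- function(chip, cond_a, cond_b, window_tiles = 5L) {
  if (window_tiles %% 2 == 0) stop("window_tiles must be odd")
  per_cond <- function(cond) {
    sub <- chip[chip$condition == cond, ]
    if (nrow(sub) == 0) stop("condition '", cond, "' absent from input")
    sub %>%
      group_by(.data$tile_id, .data$chrom, .data$start, .data$end) %>%
      summarise(m = mean(.data$score, na.rm = TRUE),
                v = stats::var(.data$score, na.rm = TRUE),
                nrep = sum(!is.na(.data$score)), .groups = "drop") %>%
      arrange(.data$chrom, .data$start)
  }
  a <- per_cond(cond_a)
  b <- per_cond(cond_b)
  if (!identical(a$tile_id, b$tile_id)) {
    stop("conditions '", cond_a, "' and '", cond_b,
         "' have different tile layouts")
  }
  v_a <- ifelse(is.na(a$v), 0, a$v)
  v_b <- ifelse(is.na(b$v), 0, b$v)
  s_tile <- sqrt(v_a / pmax(a$nrep, 1) + v_b / pmax(b$nrep, 1))
  s0 <- stats::median(s_tile)
  denom <- sqrt(s_tile^2 + s0^2)
  denom[denom == 0] <- 1   # all-identical degenerate input
  raw <- (b$m - a$m) / denom
  smooth <- numeric(length(raw))
  for (chrom in unique(a$chrom)) {
    sel <- a$chrom == chrom
    smooth[sel] <- moving_average(raw[sel], window_tiles)
  }
  tibble(tile_id = a$tile_id, chrom = a$chrom, start = a$start,
         end = a$end, stat = smooth, stat_raw = raw)
}

#' Call differentially enriched domains from a differential statistic track
#'
#' Decodes the (possibly negated) smoothed statistic with the same
#' two-state HMM machinery as [call_domains()]: EM fit on the statistic
#' track, posterior thresholding, gap merging, minimum-run filtering.
#' `direction = "loss"` negates the statistic before decoding, so gain
#' domains of A-vs-B equal loss domains of B-vs-A.
#'
#' Because the moving average autocorrelates the statistic, EM on a
#' signal-free track can split the smoothed noise into two shallow
#' "states"; the fitted enrichment is therefore additionally required to
#' stand out against the raw (pre-smoothing) noise scale of the
#' statistic: when the fitted state separation is below `min_separation`
#' times the MAD of the raw statistic, no domains are called.
#'
#' @param stat_track output of [differential_score()]
#' @param direction `"gain"` or `"loss"`
#' @param comparison label recorded on the output (e.g. `"1h_vs_D"`)
#' @param params optional [hmm_params()]; fitted by EM when `NULL`
#' @param min_separation minimum fitted state separation, in units of the
#'   raw statistic's MAD
#' @return tibble: chrom, start, end, comparison, direction, n_tiles,
#'   mean_score, mean_posterior
#' @export
call_differential_domains <- function(stat_track, direction,
                                      comparison = NA_character_,
                                      params = NULL,
                                      min_separation = 1.0) {
  direction <- match.arg(direction, c("gain", "loss"))
  track <- stat_track
  oriented <- if (direction == "loss") -track$stat else track$stat
  # one-sided decoding: the background emission is anchored at the
  # track's robust location/scale and the statistic is floored there, so
  # opposite-direction signal can neither capture a state of its own nor
  # drag the free (enriched) state onto the negative side
  anchor <- stats::median(oriented)
  scale <- max(stats::mad(oriented), 1e-6)
  track$score <- pmax(oriented, anchor)
  if (is.null(params)) {
    params <- fit_hmm(track, fix_background = c(anchor, scale))
  }
  raw_scale <- stats::mad(stat_track$stat_raw, na.rm = TRUE)
  if ((params$mu_enr - params$mu_bg) < min_separation * raw_scale) {
    doms <- call_domains(track, params, label = comparison)[0, ]
  } else {
    doms <- call_domains(track, params, label = comparison)
  }
  doms$comparison <- doms$condition
  doms$direction <- rep(direction, nrow(doms))
  doms$condition <- NULL
  doms
}
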