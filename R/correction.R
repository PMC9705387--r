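# Minimal quantitative model of consensus long-read correction
# chimerising two subgenomes. A long read from subgenome A is corrected
# by majority vote over short reads recruited by window identity; when
# the subgenome divergence d is below the recruitment allowance (long
# read error e plus margin m), short reads from subgenome B are
# recruited and can out-vote the A allele at a diagnostic site.
#
# Model (shared by the Monte-Carlo and exact modes):
#  * a diagnostic site is a position where A and B differ; its
#    recruitment window of w bp contains the site plus w-1 positions,
#    each divergent independently with probability d (the divergent
#    count is shared by all reads at that site);
#  * short-read errors occur at e/10 per base; window identity is
#    computed from divergence and short-read errors (the long read's
#    own errors set the allowance 1 - e - m, not the observed
#    mismatches);
#  * per window position, a same-subgenome read mismatches the long
#    read with probability e/10, and a B read mismatches with
#    probability 1 - (e/10)/3 at divergent positions (a short-read
#    error re-creates the A base one third of the time under the
#    uniform-alternative substitution model) and e/10 elsewhere;
#  * a read is recruited iff its mismatch count is at most
#    floor(w * (e + m));
#  * each recruited read votes its own allele at the site, flipped by
#    its own sequencing error (a flip hits the opposite allele one
#    third of the time, otherwise the vote is discarded);
#  * the corrected allele is the majority vote; ties (including zero
#    recruits) retain the long read's base, which is the B allele with
#    probability e/3.
# The chimerisation rate is the probability that the corrected allele
# is the B allele.

# joint vote-count distribution: P[va+1, vb+1] for n reads voting
# "own" allele w.p. p_own and the opposite w.p. p_opp
.vote_dist <- function(n, p_own, p_opp) {
  P <- matrix(0, n + 1, n + 1)
  P[1, 1] <- 1
  if (n == 0) return(P)
  p_none <- 1 - p_own - p_opp
  for (r in seq_len(n)) {
    Q <- matrix(0, n + 1, n + 1)
    for (i in 0:(r - 1)) for (j in 0:(r - 1 - i)) {
      p <- P[i + 1, j + 1]
      if (p == 0) next
      Q[i + 2, j + 1] <- Q[i + 2, j + 1] + p * p_own
      Q[i + 1, j + 2] <- Q[i + 1, j + 2] + p * p_opp
      Q[i + 1, j + 1] <- Q[i + 1, j + 1] + p * p_none
    }
    P <- Q
  }
  P
}

# P(corrected = B | a recruited A reads, b recruited B reads)
.p_corr_b <- function(a, b, e_s, p_long_b) {
  PA <- .vote_dist(a, 1 - e_s, e_s / 3)   # (VA, VB) from A reads
  PB <- .vote_dist(b, 1 - e_s, e_s / 3)   # (VB, VA) from B reads
  p_b <- 0
  for (i in 0:a) for (j in 0:a) {
    pa <- PA[i + 1, j + 1]
    if (pa == 0) next
    for (k in 0:b) for (l in 0:b) {
      pb <- PB[k + 1, l + 1]
      if (pb == 0) next
      va <- i + l; vb <- j + k
      p_b <- p_b + pa * pb *
        (if (vb > va) 1 else if (vb == va) p_long_b else 0)
    }
  }
  p_b
}

#' Simulate consensus-correction chimerisation of a diagnostic site
#'
#' Quantifies the hypothesised failure mode of consensus long-read
#' correction in a hybrid whose subgenomes are more similar than the
#' long-read error rate: short reads from the wrong subgenome pass the
#' identity recruitment filter and the majority vote replaces the true
#' allele. Returns the fraction of diagnostic sites whose corrected
#' allele is the other subgenome's allele, either by seeded Monte-Carlo
#' simulation or by exact enumeration over the window composition
#' (practical for windows up to a few tens of bp).
#'
#' At \code{error_rate = 0} and \code{margin = 0} wrong-subgenome reads
#' are never recruited and the rate is 0. At \code{d = 0} the
#' subgenomes are identical, there are no distinguishing sites, and the
#' rate is reported as 0 by convention (with a message). The rate is
#' non-increasing in \code{d}: more divergence means fewer recruited
#' wrong-subgenome reads.
#'
#' @param model A \code{\linkS4class{CorrectionModel}}.
#' @param d Subgenome divergence (substitution fraction) in [0, 1).
#' @param n_sites Number of diagnostic sites to simulate (Monte-Carlo
#'   mode; must be >= 1).
#' @param method \code{"montecarlo"} or \code{"exact"}.
#' @return A list with \code{rate} (chimerisation rate in [0, 1]),
#'   \code{method}, \code{n_sites} (\code{NA} for exact mode) and
#'   \code{se} (Monte-Carlo standard error, \code{NA} for exact mode).
#' @examples
#' m <- correctionModel(seed = 7)
#' simulateConsensusCorrection(m, d = 0.057, n_sites = 2000)$rate
#' @export
simulateConsensusCorrection <- function(model, d, n_sites = 10000,
                                        method = c("montecarlo",
                                                   "exact")) {
  method <- match.arg(method)
  stopifnot(is(model, "CorrectionModel"))
  stopifnot_scalar_number(d, "d", 0, 1, strict_upper = TRUE)
  if (method == "montecarlo" && (is.na(n_sites) || n_sites < 1))
    stop("n_sites must be >= 1")
  if (d == 0) {
    message("d = 0: subgenomes identical, no distinguishing sites; ",
            "chimerisation rate reported as 0 by convention")
    return(list(rate = 0, method = method, n_sites = NA_real_,
                se = NA_real_))
  }
  e <- model@error_rate
  e_s <- e / 10
  w <- as.integer(model@window_bp)
  t <- floor(w * (e + model@margin))
  ca <- as.integer(model@coverage_a)
  cb <- as.integer(model@coverage_b)
  p_long_b <- e / 3

  if (method == "exact") {
    # P(mismatches <= t) for a B read, given kd divergent positions
    r_b_given <- vapply(1:w, function(kd) {
      x <- 0:min(kd, t)
      sum(stats::dbinom(x, kd, 1 - e_s / 3) *
            stats::pbinom(t - x, w - kd, e_s))
    }, numeric(1))
    r_a <- stats::pbinom(t, w, e_s)
    pcorr <- outer(0:ca, 0:cb,
                   Vectorize(function(a, b)
                     .p_corr_b(a, b, e_s, p_long_b)))
    wa <- stats::dbinom(0:ca, ca, r_a)
    pk <- stats::dbinom(0:(w - 1), w - 1, d)
    rate <- 0
    for (kd in 1:w) {
      wb <- stats::dbinom(0:cb, cb, r_b_given[kd])
      rate <- rate + pk[kd] * as.numeric(t(wa) %*% pcorr %*% wb)
    }
    return(list(rate = rate, method = "exact", n_sites = NA_real_,
                se = NA_real_))
  }

  with_seed(model@seed, {
    n <- as.integer(n_sites)
    kd <- 1L + stats::rbinom(n, w - 1L, d)
    # recruited same-subgenome reads
    k_a <- stats::rbinom(n, ca, stats::pbinom(t, w, e_s))
    # B reads: mismatch count depends on the shared divergent count
    k_b <- integer(n)
    if (cb > 0) {
      mm <- matrix(stats::rbinom(n * cb, rep(kd, cb), 1 - e_s / 3) +
                     stats::rbinom(n * cb, rep(w - kd, cb), e_s),
                   nrow = n)
      k_b <- rowSums(mm <= t)
    }
    # votes
    va1 <- stats::rbinom(n, k_a, 1 - e_s)
    vb1 <- stats::rbinom(n, k_a - va1, 1 / 3)
    vb2 <- stats::rbinom(n, k_b, 1 - e_s)
    va2 <- stats::rbinom(n, k_b - vb2, 1 / 3)
    va <- va1 + va2; vb <- vb1 + vb2
    tie_b <- stats::runif(n) < p_long_b
    corr_b <- vb > va | (vb == va & tie_b)
    p_hat <- mean(corr_b)
    list(rate = p_hat, method = "montecarlo", n_sites = n,
         se = sqrt(p_hat * (1 - p_hat) / n))
  })
}
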