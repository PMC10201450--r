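# Kolmogorov-Waring fitting of per-gene motif counts, and diagnostic
# accuracy of model predictions against experimental G4-formation calls.
#
# The Kolmogorov-Waring distribution is the stationary law of a
# birth-death process; it is defined here through the recurrence
#   p_{k+1} = p_k * theta * (k + alpha) / (k + 1 + beta),  k >= 0,
# with p_0 fixed by normalization.  Its zero class has the closed form
# p_0 = 1 - alpha/beta (for alpha < beta), which is how the fraction of
# genes with no observed motif ("non-observed events") is estimated.

#' Kolmogorov-Waring probability mass function
#'
#' Evaluates the PMF on 0..k_max via the birth-death recurrence, with p_0
#' set by normalization. `k_max` is auto-extended until the truncated tail
#' mass is below 1e-9.
#'
#' @param theta ratio of birth to death intensity, in \\[0, 1\\].
#' @param alpha,beta positive shape parameters.
#' @param k_max minimum truncation point (auto-extended).
#' @return numeric vector p\\[k+1\\] = P(K = k), k = 0..k_max', summing to 1.
#' @export
kw_pmf <- function(theta, alpha, beta, k_max = 255) {
  stopifnot(theta >= 0, theta <= 1, alpha > 0, beta > 0)
  if (theta == 1 && (beta - alpha) <= 1)
    stop("non-convergent tail: theta = 1 requires beta - alpha > 1")
  if (theta == 0) return(1)
  k_max <- max(k_max, 8)
  repeat {
    k <- 0:(k_max - 1)
    ratios <- theta * (k + alpha) / (k + 1 + beta)
    q <- cumprod(c(1, ratios))  # unnormalized, q[1] = p_0 weight
    tot <- sum(q)
    r_end <- theta * (k_max + alpha) / (k_max + 1 + beta)
    tail_est <- if (r_end < 1) q[k_max + 1] * r_end / (1 - r_end) else Inf
    if (tail_est / (tot + tail_est) < 1e-9) return(q / tot)
    if (k_max >= 2^22)
      stop("non-convergent tail at theta = ", theta)
    k_max <- k_max * 4
  }
}

#' Closed-form zero-class probability
#'
#' @param alpha,beta parameters with 0 < alpha < beta.
#' @return 1 - alpha/beta.
#' @export
p0_closed_form <- function(alpha, beta) {
  if (!(alpha > 0 && alpha < beta))
    stop("p0 closed form requires 0 < alpha < beta")
  1 - alpha / beta
}

#' Draw from a Kolmogorov-Waring distribution
#'
#' @param n number of draws.
#' @param theta,alpha,beta distribution parameters.
#' @param seed integer seed.
#' @return integer vector of counts.
#' @export
rkw <- function(n, theta, alpha, beta, seed = 1) {
  p <- kw_pmf(theta, alpha, beta)
  with_seed(seed, sample.int(length(p), n, replace = TRUE, prob = p) - 1L)
}

kw_nll <- function(par, tab, ks, zero_truncated) {
  theta <- stats::plogis(par[1])
  alpha <- exp(par[2])
  beta <- alpha + exp(par[3])
  p <- tryCatch(kw_pmf(theta, alpha, beta, k_max = max(ks, 8)),
                error = function(e) NULL)
  if (is.null(p) || length(p) <= max(ks)) return(1e12)
  ll <- sum(tab * log(p[ks + 1]))
  if (zero_truncated) ll <- ll - sum(tab) * log1p(-p[1])
  if (!is.finite(ll)) return(1e12)
  -ll
}

#' Fit a Kolmogorov-Waring distribution by maximum likelihood
#'
#' Multi-start bounded optimization: theta initialized over
#' \\{0.5, 0.9, 0.99\\} and the alpha/beta ratio over the same grid (the
#' alpha scale starts at the sample mean). With `zero_truncated` the
#' likelihood conditions on k >= 1 (for samples where zero counts are
#' unobservable). The fit is deterministic for given data.
#'
#' @param counts nonnegative integer vector (>= 50 observations).
#' @param zero_truncated condition the likelihood on k >= 1.
#' @param seed accepted for interface symmetry; the optimizer itself is
#'   deterministic.
#' @return object of class "kw_fit": theta, alpha, beta, p0_closed,
#'   p0_pmf, loglik, k_max, pmf.
#' @export
fit_kw <- function(counts, zero_truncated = FALSE, seed = 1) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (length(counts) < 50)
    stop("fit_kw needs at least 50 observations")
  if (length(unique(counts)) < 2)
    stop("degenerate data: all counts equal")
  if (zero_truncated && any(counts == 0))
    stop("zero counts present in a zero-truncated fit")
  tabf <- table(counts)
  ks <- as.integer(names(tabf))
  tab <- as.numeric(tabf)
  m <- mean(counts)
  best <- NULL
  for (theta0 in c(0.5, 0.9, 0.99)) for (ratio0 in c(0.5, 0.9, 0.99)) {
    alpha0 <- max(m, 0.5)
    beta0 <- alpha0 / ratio0 + 1e-3
    par0 <- c(stats::qlogis(theta0), log(alpha0), log(beta0 - alpha0))
    opt <- stats::optim(par0, kw_nll, tab = tab, ks = ks,
                        zero_truncated = zero_truncated,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- stats::plogis(best$par[1])
  alpha <- exp(best$par[2])
  beta <- alpha + exp(best$par[3])
  pmf <- kw_pmf(theta, alpha, beta, k_max = max(counts, 8))
  structure(list(
    theta = theta, alpha = alpha, beta = beta,
    p0_closed = 1 - alpha / beta, p0_pmf = pmf[1],
    loglik = -best$value, k_max = length(pmf) - 1L, pmf = pmf,
    zero_truncated = zero_truncated, n = length(counts)
  ), class = "kw_fit")
}

#' @export
print.kw_fit <- function(x, ...) {
  cat(sprintf(
    "Kolmogorov-Waring fit (n = %d%s)\n  theta = %.4f  alpha = %.3f  beta = %.3f\n  p0 (closed form 1 - alpha/beta) = %.4f   p0 (normalized PMF) = %.4f\n  log-likelihood = %.2f\n",
    x$n, if (x$zero_truncated) ", zero-truncated" else "",
    x$theta, x$alpha, x$beta, x$p0_closed, x$p0_pmf, x$loglik))
  invisible(x)
}

#' Total variation distance between two discrete distributions
#'
#' @param p,q probability vectors (padded with zeros to a common length).
#' @return TV distance in \\[0, 1\\].
#' @export
tv_distance <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, numeric(n - length(p)))
  q <- c(q, numeric(n - length(q)))
  sum(abs(p - q)) / 2
}

#' Diagnostic accuracy statistics from a confusion table
#'
#' Accuracy, sensitivity and specificity as percentages; LR+ (positive
#' likelihood ratio) = sensitivity / (1 - specificity) on the proportion
#' scale; Cohen's kappa with a large-sample 95% CI (on a 2x2 table the
#' weighted and unweighted kappa coincide).
#'
#' @param tp,fp,tn,fn nonnegative counts, total > 0.
#' @return list with counts, accuracy, sensitivity, specificity (percent),
#'   lr_pos, kappa, kappa_ci (length-2), n.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion table")
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  lr_pos <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
       accuracy = 100 * acc, sensitivity = 100 * sens,
       specificity = 100 * spec, lr_pos = lr_pos,
       kappa = kappa,
       kappa_ci = kappa + c(-1, 1) * stats::qnorm(0.975) * se)
}

EXPERIMENTAL_CALLS <- c(
  positive = "single_major", positive = "major_minor",
  positive = "multiple",
  negative = "weak", negative = "duplex_plus_g4", negative = "two_layer",
  negative = "duplex", negative = "non_g4"
)

#' Evaluate scanner predictions against experimental G4 calls
#'
#' Prediction is positive when the bulged scanner accepts the sequence
#' under any of the three models. The experimental call is positive for
#' single-major, major+minor or multiple G4 conformations; weak G4,
#' duplex + G4, two-layer G4, duplex and non-G4 calls are negative.
#' Sequences matched only by the canonical scanner are flagged
#' canonical_only and excluded from the bulged-model confusion table.
#'
#' @param sequence_table data.frame with columns `sequence` and
#'   `experimental_call` (and optionally `id`).
#' @return list(metrics = [confusion_metrics()] result, table = per-row
#'   annotation with predicted/experimental/category columns).
#' @export
evaluate_predictions <- function(sequence_table) {
  stopifnot(all(c("sequence", "experimental_call") %in%
                  names(sequence_table)))
  call <- sequence_table$experimental_call
  bad <- setdiff(unique(call), unname(EXPERIMENTAL_CALLS))
  if (length(bad))
    stop("unknown experimental call label(s): ", paste(bad, collapse = ", "))
  exp_pos <- call %in% EXPERIMENTAL_CALLS[names(EXPERIMENTAL_CALLS) ==
                                            "positive"]
  pred_bs <- vapply(sequence_table$sequence,
                    function(s) nrow(scan_bulged(s)) > 0, logical(1))
  pred_cs <- vapply(sequence_table$sequence,
                    function(s) nrow(scan_canonical(s)) > 0, logical(1))
  canonical_only <- pred_cs & !pred_bs
  cat4 <- ifelse(canonical_only, "canonical_only",
          ifelse(pred_bs & exp_pos, "TP",
          ifelse(pred_bs & !exp_pos, "FP",
          ifelse(!pred_bs & exp_pos, "FN", "TN"))))
  tab <- cbind(sequence_table,
               predicted = pred_bs, experimental_positive = exp_pos,
               category = cat4)
  kept <- cat4[cat4 != "canonical_only"]
  list(metrics = confusion_metrics(tp = sum(kept == "TP"),
                                   fp = sum(kept == "FP"),
                                   tn = sum(kept == "TN"),
                                   fn = sum(kept == "FN")),
       table = tab)
}

#' Worked-example validated bulged-G4 sequences
#'
#' Four experimentally characterized promoter/intron sequences (E2F8,
#' EGR1, CACNA2D2 and ACTN4 loci), printed with their flanking
#' dinucleotides, together with their published per-sequence annotation:
#' number of intact G-stems, number of bulges, inserted nucleotides,
#' model, and the NMR-based experimental call.
#'
#' @return data.frame (id, locus, sequence, n_intact_stems, n_bulges,
#'   bulges, model, experimental_call).
#' @export
bulged_g4_examples <- function() {
  data.frame(
    id = c("BS33", "BS15", "BS40", "BS31"),
    locus = c("E2F8 promoter", "EGR1 promoter", "CACNA2D2 promoter",
              "ACTN4 intron 1"),
    sequence = c("TAGAGGCGGGAGTGGAGGGCG",
                 "CTGAGGTGGGCGGGCGGGCC",
                 "AAGAGAGAGGGAGGGAGGGAG",
                 "GAGATCGGTGGGAGGGAGGGTG"),
    n_intact_stems = c(2L, 3L, 3L, 3L),
    n_bulges = c(2L, 1L, 2L, 1L),
    bulges = c("A,T", "A", "A,A", "ATC"),
    model = c("G2B2", "G3B1", "G3B2", "G3B1"),
    experimental_call = c("major_minor", "single_major", "single_major",
                          "single_major"),
    stringsAsFactors = FALSE
  )
}
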