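#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm runif rnorm coef glm predict binomial cor sd
#'   p.adjust phyper chisq.test fisher.test setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler: uniforms are drawn on the CDF interval of the
#' truncation bounds and mapped back through `qnorm()`. Used for
#' progression-free survival draws whose class definitions impose hard
#' truncation (resistant below 12 months, sensitive above 22 months).
#'
#' @param n number of draws
#' @param mean,sd normal location and scale (months, for PFS use)
#' @param lower,upper truncation bounds (open interval in the continuous sense)
#' @return numeric vector of length `n` inside `(lower, upper)`
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Rank-based ROC AUC (Mann-Whitney, ties get 0.5 credit)
#'
#' @param scores numeric predictor (higher = more likely positive)
#' @param positive logical vector, TRUE for positive-class samples
#' @return AUC in \[0, 1\]
#' @export
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)                      # midranks give ties 0.5 credit
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# canonical unordered-pair key, vectorized
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1
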