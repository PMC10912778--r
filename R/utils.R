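# Internal helpers shared across modules.

# Deterministic per-stage child seed derived from one pipeline seed, so a stage
# can be rerun in isolation with the same stream it saw inside the pipeline.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
.stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

.is_prop <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# Chi-squared test of independence without continuity correction, plus
# Pearson residuals (O - E) / sqrt(E). Shared by the inter-subnetwork analysis
# and the regulon-status cross-table. Cells with E < 1 are flagged; the test is
# still reported (with a warning) as the downstream consumer expects.
.chisq_residuals <- function(tab) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  .assert(total > 0, "contingency table is empty")
  expected <- outer(rowSums(tab), colSums(tab)) / total
  ok <- expected > 0
  residuals <- matrix(0, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  residuals[ok] <- (tab[ok] - expected[ok]) / sqrt(expected[ok])
  chi2 <- sum(residuals^2)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  flagged <- which(expected < 1 & ok, arr.ind = TRUE)
  if (nrow(flagged) > 0)
    warning("chi-squared approximation doubtful: ", nrow(flagged),
            " cell(s) with expected count < 1")
  list(observed = tab, expected = expected, residuals = residuals,
       statistic = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       flagged = flagged)
}

#' Chi-squared independence test with Pearson residuals
#'
#' The contingency-table test shared by the inter-subnetwork connection
#' analysis and the regulon-status cross-table: chi-squared without
#' continuity correction, expected counts from the independence model, and
#' Pearson residuals (O - E) / sqrt(E) whose squares sum to the statistic.
#'
#' @param tab a contingency table or matrix of counts.
#' @return list: observed, expected, residuals, statistic, df, p, flagged
#'   (cells with expected count < 1).
#' @export
chisq_residual_test <- function(tab) .chisq_residuals(tab)

# Roman-numeral community labels ordered by size rank (cosmetic convention).
.roman_labels <- function(n) as.character(utils::as.roman(seq_len(n)))
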