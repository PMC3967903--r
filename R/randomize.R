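# Permutation null models for spatial concentration and feeder dominance.

.perm_result <- function(observed, null_values, statistic) {
  n_rep <- length(null_values)
  structure(list(
    statistic = statistic, observed = observed, null_values = null_values,
    null_mean = mean(null_values), null_sd = stats::sd(null_values),
    p_value = (1 + sum(null_values >= observed)) / (n_rep + 1),
    n_rep = n_rep), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(paste0("Permutation null test: %s\n",
                     "  observed = %.4f, null = %.4f +/- %.4f (%d replicates)",
                     ", P = %.4g\n"),
              x$statistic, x$observed, x$null_mean, x$null_sd, x$n_rep,
              x$p_value))
  invisible(x)
}

# shared machinery over an aggregated (group, cell, n) count table:
# observed mean of per-group maxima, and replicate maxima under independent
# uniform reassignment of each group's items among its cells
.null_max <- function(group, n, n_rep, seed, share = FALSE) {
  groups <- unique(group)
  gi <- match(group, groups)
  G <- length(groups)
  k <- tabulate(gi, nbins = G)          # cells (options) per group
  N <- as.numeric(rowsum(n, gi))        # items per group
  obs_max <- as.numeric(tapply(n, gi, max))
  observed <- if (share) mean(obs_max / N) else mean(obs_max)
  gl <- rep(gi, n)                      # item-level group index
  K <- max(k)
  null_values <- withr_seed(seed, vapply(seq_len(n_rep), function(r) {
    u <- floor(stats::runif(length(gl)) * k[gl]) + 1L
    counts <- tabulate((u - 1L) * G + gl, nbins = G * K)
    mx <- .row_max(counts, G, K)
    if (share) mean(mx / N) else mean(mx)
  }, numeric(1)))
  .perm_result(observed, null_values,
               if (share) "mean max daily concentration"
               else "mean visits by the top individual")
}

#' Null model for daily spatial concentration
#'
#' Tests whether individuals concentrate their daily visits on particular
#' feeders more than expected at random. The observed statistic is the mean,
#' over all bird-days, of the concentration at the bird-day's most-visited
#' feeder. Each replicate reassigns every visit of each bird-day
#' independently and uniformly among the feeders that bird visited that day
#' (conserving its visit total) and recomputes the mean. The p-value is
#' one-sided for observed > null with the add-one convention
#' `(1 + b) / (n_rep + 1)`.
#'
#' @param visits Visit table (or [count_visits()] output).
#' @param n_rep Number of replicates (default 100).
#' @param seed Integer seed.
#' @return An object of class `perm_test`: `observed`, `null_values`,
#'   `null_mean`, `null_sd`, `p_value`, `n_rep`.
#' @export
null_concentration <- function(visits, n_rep = 100L, seed = 1L) {
  if (n_rep < 1) stop("invalid config: n_rep must be >= 1", call. = FALSE)
  cnt <- if ("n" %in% names(visits)) visits else count_visits(visits)
  if (!nrow(cnt)) stop("visits is empty", call. = FALSE)
  .null_max(.key(cnt$tag_id, as.character(cnt$date)), cnt$n,
            n_rep, seed, share = TRUE)
}

#' Null model for feeder dominance
#'
#' Tests whether single individuals dominate feeders in visit counts. The
#' observed statistic is the mean, over all feeder-days, of the visit count
#' of the individual that visited most; each replicate reassigns every
#' visit of each feeder-day independently and uniformly among the
#' individuals that visited it that day. Same p-value convention as
#' [null_concentration()].
#'
#' @inheritParams null_concentration
#' @return A `perm_test` object.
#' @export
null_dominance <- function(visits, n_rep = 100L, seed = 1L) {
  if (n_rep < 1) stop("invalid config: n_rep must be >= 1", call. = FALSE)
  cnt <- if ("n" %in% names(visits)) visits else count_visits(visits)
  if (!nrow(cnt)) stop("visits is empty", call. = FALSE)
  .null_max(.key(cnt$feeder_id, as.character(cnt$date)), cnt$n,
            n_rep, seed, share = FALSE)
}
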