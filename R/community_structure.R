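#' Mean nearest taxon distance (MNTD) of a sample
#'
#' The mean, over the taxa of a sample, of the patristic distance from each
#' taxon to its nearest co-occurring relative. Incidence-only: abundances are
#' ignored.
#'
#' @param sample Character vector of tip labels (>= 2), a subset of
#'   `rownames(d)`.
#' @param d Patristic distance matrix from [patristic_matrix()].
#' @return MNTD in the units of `d` (Ma for a dated tree).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' mntd(c("A", "B", "C"), patristic_matrix(tr))  # (2 + 2 + 4) / 3
mntd <- function(sample, d) {
  idx <- mntd_check(sample, d)
  cpp_mntd(d, idx)
}

mntd_check <- function(sample, d) {
  if (is.null(rownames(d))) stop("distance matrix needs dimnames", call. = FALSE)
  idx <- match(sample, rownames(d))
  if (anyNA(idx)) {
    stop("sample taxa absent from the distance matrix: ",
         paste(sample[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(idx) < 2L) {
    stop("MNTD needs at least 2 taxa in the sample", call. = FALSE)
  }
  idx
}

#' Nearest taxon index (NTI) against a richness null
#'
#' \deqn{NTI = -1 \times (MNTD_{obs} - \overline{MNTD_{null}}) /
#'   SD(MNTD_{null}).}
#' The null draws the observed number of taxa uniformly from the pool
#' (default: all taxa in the phylogeny) `n_reps` times. Positive NTI indicates
#' phylogenetic clustering, negative overdispersion; significance is judged by
#' the two-tailed permutation rank p at `alpha`, with the +/-1.96 shortcut
#' available through the reported index itself. The null SD is the population
#' (divide-by-n) SD by default. A degenerate null (SD = 0, e.g. sample =
#' pool) yields NTI 0 and classification `"degenerate"`.
#'
#' @inheritParams mntd
#' @param pool Character vector of pool tip labels; default all of
#'   `rownames(d)`. Must contain the sample.
#' @param n_reps Monte-Carlo draws (default 999).
#' @param seed Optional integer seed (scoped to this call).
#' @param mode `"montecarlo"` or `"exhaustive"` over all C(pool, k) subsets.
#' @param exhaustive_cap Cap on the number of exhaustively enumerated subsets.
#' @param alpha Two-tailed significance level for the classification.
#' @param sd_type `"population"` (default) or `"sample"` null SD.
#' @param site Optional site label carried into the result.
#' @return One-row data frame: `site`, `n_taxa`, `mntd_observed`, `null_mean`,
#'   `null_sd`, `nti`, `rank_p`, `n_reps`, `classification`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
#' nti(c("A", "B"), patristic_matrix(tr), mode = "exhaustive")$nti  # ~ +1.789
nti <- function(sample, d, pool = rownames(d), n_reps = 999, seed = NULL,
                mode = c("montecarlo", "exhaustive"), exhaustive_cap = 1e5,
                alpha = 0.05, sd_type = c("population", "sample"),
                site = NA_character_) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  idx <- mntd_check(sample, d)
  pool_idx <- match(pool, rownames(d))
  if (anyNA(pool_idx)) {
    stop("pool taxa absent from the distance matrix: ",
         paste(pool[is.na(pool_idx)], collapse = ", "), call. = FALSE)
  }
  if (!all(idx %in% pool_idx)) {
    stop("sample must be a subset of the pool", call. = FALSE)
  }
  k <- length(idx)
  np <- length(pool_idx)
  observed <- cpp_mntd(d, idx)

  if (mode == "exhaustive") {
    if (choose(np, k) > exhaustive_cap) {
      stop("choose(", np, ", ", k, ") exceeds exhaustive_cap", call. = FALSE)
    }
    draws <- combn(pool_idx, k)
  } else {
    n_reps <- assert_scalar_count(n_reps, "n_reps")
    draws <- with_seed_(seed,
      replicate(n_reps, pool_idx[sample.int(np, k)]))
    draws <- matrix(draws, nrow = k)
  }
  null_mntd <- cpp_mntd_many(d, draws)

  res <- finish_ses(site, observed, null_mntd, null_sd_fun(sd_type),
                    classify = function(z) "nonsignificant")
  out <- data.frame(site = res$site, n_taxa = k,
                    mntd_observed = res$observed, null_mean = res$null_mean,
                    null_sd = res$null_sd, nti = -res$ses,
                    rank_p = res$rank_p, n_reps = res$n_reps,
                    classification = res$classification,
                    stringsAsFactors = FALSE)
  if (out$classification != "degenerate") {
    out$classification <- classify_structure(out, alpha)
  }
  out
}

#' Classify community phylogenetic structure from an NTI result
#'
#' `"clustered"` when NTI > 0 with rank p < `alpha`; `"dispersed"` when
#' NTI < 0 with rank p < `alpha`; otherwise `"nonsignificant"`. Degenerate
#' results pass through.
#'
#' @param r Data frame from [nti()] (columns `nti`, `rank_p`, and optionally
#'   `classification`).
#' @param alpha Significance level, in (0, 1); default 0.05.
#' @return Character vector of labels.
#' @export
classify_structure <- function(r, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  out <- ifelse(r$rank_p < alpha & r$nti > 0, "clustered",
                ifelse(r$rank_p < alpha & r$nti < 0, "dispersed",
                       "nonsignificant"))
  if (!is.null(r$classification)) out[r$classification == "degenerate"] <- "degenerate"
  out
}
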