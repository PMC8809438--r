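#' Construct and validate a genus-level clade-age table
#'
#' One row per clade (genus), carrying the crown age of the clade in Ma, the
#' number of species the genus contributes to the sample or pool, a
#' geographical-origin label (or `"Unknown"`), and the genus class within the
#' regional vegetation (`dominant`, `common`, `occasional`, `endemic`).
#'
#' @param genus Character vector of unique genus labels.
#' @param age_ma Positive finite crown ages, Ma.
#' @param species_count Integer species counts, >= 1.
#' @param origin Origin labels; defaults to `"Unknown"`.
#' @param genus_class One of dominant/common/occasional/endemic; defaults to
#'   `"occasional"`.
#' @return A data frame of class `"clade_age_table"`.
#' @export
#' @examples
#' clade_age_table(c("Saxifraga", "Potentilla"), age_ma = c(20, 10),
#'                 species_count = c(2, 6))
clade_age_table <- function(genus, age_ma, species_count,
                            origin = "Unknown", genus_class = "occasional") {
  df <- data.frame(genus = as.character(genus), age_ma = as.numeric(age_ma),
                   species_count = species_count,
                   origin = as.character(origin),
                   genus_class = as.character(genus_class),
                   stringsAsFactors = FALSE)
  validate_clade_table(df)
}

validate_clade_table <- function(df) {
  req <- c("genus", "age_ma", "species_count")
  if (!all(req %in% names(df))) {
    stop("clade table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("clade table is empty", call. = FALSE)
  if (anyDuplicated(df$genus)) {
    stop("duplicate genus labels: ",
         paste(unique(df$genus[duplicated(df$genus)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$age_ma) || any(!is.finite(df$age_ma)) || any(df$age_ma <= 0)) {
    stop("clade ages must be finite and positive (Ma)", call. = FALSE)
  }
  sc <- df$species_count
  if (anyNA(sc) || any(sc < 1) || any(sc != floor(sc))) {
    stop("species_count must be integer >= 1", call. = FALSE)
  }
  df$species_count <- as.integer(sc)
  if (is.null(df$origin)) df$origin <- "Unknown"
  if (is.null(df$genus_class)) df$genus_class <- "occasional"
  bad <- setdiff(unique(df$genus_class),
                 c("dominant", "common", "occasional", "endemic"))
  if (length(bad)) stop("unknown genus_class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(df) <- c("clade_age_table", "data.frame")
  df
}

#' Read a clade-age table CSV
#'
#' Columns: `genus`, `age_ma`, `species_count`, optionally `origin` and
#' `genus_class`.
#'
#' @param path CSV path.
#' @return A `"clade_age_table"` data frame.
#' @export
read_clade_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(df$origin)) df$origin <- "Unknown"
  if (is.null(df$genus_class)) df$genus_class <- "occasional"
  validate_clade_table(df)
}

#' Mean divergence time (MDT) of an assemblage
#'
#' The species-count-weighted mean of genus crown ages,
#' \deqn{MDT = \sum_i AGE_i S_i / \sum_i S_i,}
#' where \eqn{AGE_i} is the crown age of genus \eqn{i} and \eqn{S_i} its
#' species count in the sample. Also reports the median clade age —
#' unweighted by default, species-weighted when `weighted_median = TRUE`.
#'
#' @param clades A `"clade_age_table"` restricted to one assemblage.
#' @param weighted_median Use the species-count-weighted median age?
#' @return A one-row data frame: `mdt`, `median_age` (both Ma), `n_clades`,
#'   `n_species`.
#' @export
#' @examples
#' tab <- clade_age_table(c("A", "B"), age_ma = c(20, 10), species_count = c(2, 6))
#' mdt(tab)$mdt  # (20*2 + 10*6) / 8 = 12.5
mdt <- function(clades, weighted_median = FALSE) {
  clades <- validate_clade_table(as.data.frame(clades))
  w <- clades$species_count
  med <- if (weighted_median) weighted_median_(clades$age_ma, w) else median(clades$age_ma)
  data.frame(mdt = sum(clades$age_ma * w) / sum(w),
             median_age = med,
             n_clades = nrow(clades),
             n_species = sum(w))
}

# Weighted median: smallest age whose cumulative weight reaches half the
# total; midpoint of the two straddling ages at an exact half split.
weighted_median_ <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' Standardized effect size of MDT against a richness-preserving null
#'
#' The null holds the number of genera in the sample fixed and draws that many
#' genera uniformly without replacement from the pool, each drawn genus
#' carrying its pool-level species count; MDT is recomputed per draw.
#' \deqn{SES = (MDT_{obs} - \overline{MDT_{null}}) / SD(MDT_{null}).}
#' Values above +1.96 flag a significantly ancient flora, below -1.96 a
#' significantly young one. A two-tailed permutation rank p (ties split
#' evenly) is reported alongside. A degenerate null (SD = 0, e.g. sample =
#' pool) yields SES 0 and classification `"degenerate"`.
#'
#' @param sample Clade-age table for the assemblage under test.
#' @param pool Clade-age table for the sampling pool (>= sample's genera).
#' @param n_reps Number of Monte-Carlo draws (default 999).
#' @param seed Optional integer seed (scoped to this call).
#' @param mode `"montecarlo"` or `"exhaustive"` (all C(pool, k) subsets;
#'   only when that count is <= `exhaustive_cap`).
#' @param exhaustive_cap Maximum number of subsets enumerated exhaustively.
#' @param sd_type Null SD convention: `"population"` (default) or `"sample"`.
#' @param site Optional site label carried into the result.
#' @return One-row data frame: `site`, `observed`, `null_mean`, `null_sd`,
#'   `ses`, `rank_p`, `n_reps`, `classification`.
#' @export
#' @examples
#' pool <- clade_age_table(paste0("g", 1:4), c(10, 10, 10, 30), rep(1L, 4))
#' ses_mdt(pool[4, ], pool, mode = "exhaustive")$ses  # 15/sqrt(75) = 1.732
ses_mdt <- function(sample, pool, n_reps = 999, seed = NULL,
                    mode = c("montecarlo", "exhaustive"),
                    exhaustive_cap = 1e5, sd_type = c("population", "sample"),
                    site = NA_character_) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  sample <- validate_clade_table(as.data.frame(sample))
  pool <- validate_clade_table(as.data.frame(pool))
  k <- nrow(sample)
  np <- nrow(pool)
  if (k > np) stop("sample has more genera than the pool", call. = FALSE)

  observed <- mdt(sample)$mdt
  num <- pool$age_ma * pool$species_count  # per-genus age * count
  den <- as.numeric(pool$species_count)

  if (mode == "exhaustive") {
    if (choose(np, k) > exhaustive_cap) {
      stop("choose(", np, ", ", k, ") exceeds exhaustive_cap", call. = FALSE)
    }
    draws <- combn(np, k)
  } else {
    n_reps <- assert_scalar_count(n_reps, "n_reps")
    draws <- with_seed_(seed, replicate(n_reps, sample.int(np, k)))
    draws <- matrix(draws, nrow = k)
  }
  null_mdt <- colSums(matrix(num[draws], nrow = k)) /
    colSums(matrix(den[draws], nrow = k))

  finish_ses(site, observed, null_mdt, null_sd_fun(sd_type),
             classify = function(z) classify_flora(z))
}

# Shared SES/rank-p bookkeeping for ses_mdt and nti.
finish_ses <- function(site, observed, null_vals, sdfun, classify) {
  null_mean <- mean(null_vals)
  null_sd <- sdfun(null_vals)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  ses <- if (degenerate) 0 else (observed - null_mean) / null_sd
  data.frame(site = site, observed = observed, null_mean = null_mean,
             null_sd = if (degenerate) 0 else null_sd, ses = ses,
             rank_p = two_tailed_rank_p(observed, null_vals),
             n_reps = length(null_vals),
             classification = if (degenerate) "degenerate" else classify(ses),
             stringsAsFactors = FALSE)
}

#' Classify a flora from its SES-MDT
#'
#' Strictly above +1.96: `"ancient"`; strictly below -1.96: `"young"`;
#' otherwise `"nonsignificant"`. A data frame from [ses_mdt()] passes a
#' `"degenerate"` classification through unchanged.
#'
#' @param ses Numeric SES values, or a [ses_mdt()] result data frame.
#' @param threshold Two-sided significance threshold (default 1.96).
#' @return Character vector of labels.
#' @export
classify_flora <- function(ses, threshold = 1.96) {
  if (is.data.frame(ses)) {
    out <- classify_flora(ses$ses, threshold)
    out[ses$classification == "degenerate"] <- "degenerate"
    return(out)
  }
  ifelse(ses > threshold, "ancient",
         ifelse(ses < -threshold, "young", "nonsignificant"))
}
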