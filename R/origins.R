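#' Load a category-to-supergroup origin mapping
#'
#' Reads a YAML file whose top-level keys are supergroups (e.g. Laurasian,
#' Gondwanan, Unknown) and values the origin categories they contain. The
#' packaged default groups East Asian, Tethyan and other Northern-Hemisphere
#' categories under Laurasian, and African / Southern-Hemisphere categories
#' under Gondwanan.
#'
#' @param path YAML path; default the mapping shipped with the package.
#' @return Named character vector: `names` are categories, values supergroups.
#' @export
origin_supergroup_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "origin_supergroups.yaml",
                                package = "floraphylo")
  spec <- yaml::read_yaml(path)
  out <- unlist(lapply(names(spec), function(sg) {
    stats::setNames(rep(sg, length(spec[[sg]])), spec[[sg]])
  }))
  if (anyDuplicated(names(out))) {
    stop("origin category mapped to more than one supergroup", call. = FALSE)
  }
  out
}

#' Tabulate clade counts by geographical origin
#'
#' Counts clades per origin category and per supergroup. Every non-`"Unknown"`
#' label in the table must appear in the mapping.
#'
#' @param clades A `"clade_age_table"` (or data frame with `origin`).
#' @param mapping Category -> supergroup map, see [origin_supergroup_map()].
#' @return A list of class `"origin_summary"`: `categories` (data frame
#'   `category`, `supergroup`, `n`), `supergroups` (data frame `supergroup`,
#'   `n`), `total`.
#' @export
tabulate_origins <- function(clades, mapping = origin_supergroup_map()) {
  origin <- if (nrow(as.data.frame(clades)) == 0L) character(0) else {
    o <- as.data.frame(clades)$origin
    if (is.null(o)) stop("clade table lacks an origin column", call. = FALSE)
    as.character(o)
  }
  if (!"Unknown" %in% names(mapping)) mapping <- c(mapping, Unknown = "Unknown")
  unmapped <- setdiff(unique(origin), names(mapping))
  if (length(unmapped)) {
    stop("origin label(s) not in the mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  cats <- names(mapping)
  n_cat <- as.integer(table(factor(origin, levels = cats)))
  categories <- data.frame(category = cats,
                           supergroup = unname(mapping),
                           n = n_cat, stringsAsFactors = FALSE)
  sgs <- unique(unname(mapping))
  supergroups <- data.frame(
    supergroup = sgs,
    n = vapply(sgs, function(s) sum(n_cat[categories$supergroup == s]), 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(categories = categories, supergroups = supergroups,
                 total = length(origin)),
            class = "origin_summary")
}

#' @export
print.origin_summary <- function(x, ...) {
  cat("origin_summary:", x$total, "clades\n")
  print(x$supergroups, row.names = FALSE)
  invisible(x)
}

#' Count clades strictly older than an age threshold
#'
#' @param clades A `"clade_age_table"`.
#' @param threshold_ma Positive age threshold in Ma; the comparison is strict
#'   (`age > threshold`), so a clade exactly at the threshold is not counted.
#' @return List with `count` and `proportion` (count / total clades).
#' @export
#' @examples
#' tab <- clade_age_table(c("a", "b", "c"), c(2, 6, 10), c(1, 1, 1))
#' count_older_than(tab, 5.3)  # 2 of 3
count_older_than <- function(clades, threshold_ma) {
  clades <- validate_clade_table(as.data.frame(clades))
  stopifnot(is.numeric(threshold_ma), length(threshold_ma) == 1L,
            threshold_ma > 0)
  n <- sum(clades$age_ma > threshold_ma)
  list(count = n, proportion = n / nrow(clades))
}

#' Representativeness of a clade table against vegetation genera
#'
#' Fraction of the region's dominant and common genera (those defining the
#' vegetation types) that are present in the clade-age table — a check that
#' the dated clades speak for the flora.
#'
#' @param clades A `"clade_age_table"`.
#' @param dominant,common Non-empty character vectors of genus names.
#' @return Named numeric vector `c(dominant = , common = )` of proportions.
#' @export
representativeness <- function(clades, dominant, common) {
  stopifnot(length(dominant) > 0L, length(common) > 0L)
  genera <- as.data.frame(clades)$genus
  c(dominant = mean(dominant %in% genera),
    common = mean(common %in% genera))
}
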