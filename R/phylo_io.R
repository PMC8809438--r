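#' Read and validate a dated phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream statistics
#' require: the tree must be rooted, tip labels unique, and every branch must
#' carry a nonnegative length (in Ma for a dated tree). Missing branch lengths
#' are rejected rather than silently zero-filled. Polytomies are accepted
#' verbatim.
#'
#' @param path Path to a Newick file (branch lengths mandatory).
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' patristic_matrix(tr)["A", "C"]
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) stop("malformed Newick in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick in '", path, "': no tree could be parsed",
         call. = FALSE)
  }
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Validate the invariants a dated input tree must satisfy
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths; every edge must carry a length",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  invisible(tree)
}

#' Patristic distance matrix of a dated tree
#'
#' Pairwise tip-to-tip distances, each the sum of branch lengths along the
#' unique path between two tips (units Ma on a dated tree). This matrix is the
#' substrate for [mntd()] and [nti()].
#'
#' @param tree A rooted `"phylo"` object with >= 2 tips and branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, dimnames the tip
#'   labels.
#' @export
patristic_matrix <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2L) {
    stop("patristic distances need at least 2 tips", call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Export a labelled distance matrix as CSV
#'
#' @param d Symmetric matrix with dimnames, e.g. from [patristic_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}

GROWTH_FORMS <- c("tree", "shrub", "liana", "annual herb", "perennial herb",
                  "herbaceous climber")

#' Construct a site-by-species occurrence matrix
#'
#' The container for checklist data: a binary sites x species incidence
#' matrix plus per-species metadata (genus, optional family, growth form,
#' China-endemic flag). Species occurring in no site are dropped.
#'
#' @param incidence Binary matrix, rows sites, columns species, with dimnames.
#' @param species_meta Data frame with columns `species`, `genus`,
#'   `growth_form` (one of tree, shrub, liana, annual herb, perennial herb,
#'   herbaceous climber), `endemic` (logical), optionally `family`.
#' @return An object of class `"occurrence_matrix"`: a list with elements
#'   `incidence` and `species_meta`.
#' @export
occurrence_matrix <- function(incidence, species_meta) {
  if (is.null(rownames(incidence)) || is.null(colnames(incidence))) {
    stop("incidence must have site rownames and species colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(incidence))) stop("site IDs must be unique", call. = FALSE)
  if (anyDuplicated(colnames(incidence))) stop("species IDs must be unique", call. = FALSE)
  storage.mode(incidence) <- "integer"
  if (!all(incidence %in% c(0L, 1L))) {
    stop("incidence must be strictly 0/1", call. = FALSE)
  }
  keep <- colSums(incidence) > 0L
  incidence <- incidence[, keep, drop = FALSE]
  req <- c("species", "genus", "growth_form", "endemic")
  if (!all(req %in% names(species_meta))) {
    stop("species_meta needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  species_meta <- species_meta[match(colnames(incidence), species_meta$species), , drop = FALSE]
  if (anyNA(species_meta$species)) {
    stop("species_meta is missing rows for some incidence species", call. = FALSE)
  }
  bad <- setdiff(unique(species_meta$growth_form), GROWTH_FORMS)
  if (length(bad)) {
    stop("unknown growth form(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  species_meta$endemic <- as.logical(species_meta$endemic)
  if (anyNA(species_meta$endemic)) stop("endemic flag must be TRUE/FALSE", call. = FALSE)
  rownames(species_meta) <- NULL
  structure(list(incidence = incidence, species_meta = species_meta),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("occurrence_matrix:", nrow(x$incidence), "sites x",
      ncol(x$incidence), "species\n")
  invisible(x)
}

#' Read a long-format occurrence checklist CSV
#'
#' Expects UTF-8 CSV with header columns `site`, `species`, `genus`,
#' `growth_form`, `endemic` (optionally `family`). Duplicate (site, species)
#' rows are collapsed with a warning. A species mapped to two genera is a
#' validation error. Rows may arrive in any order.
#'
#' @param path CSV path.
#' @return An [occurrence_matrix()].
#' @export
read_occurrence <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("site", "species", "genus", "growth_form", "endemic")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("occurrence CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("occurrence CSV has no data rows", call. = FALSE)
  # endemic accepts logical, 0/1, yes/no
  df$endemic <- parse_flag(df$endemic)

  gmap <- unique(df[, c("species", "genus")])
  offenders <- unique(gmap$species[duplicated(gmap$species)])
  if (length(offenders)) {
    stop("species mapped to more than one genus: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }

  ndup <- sum(duplicated(df[, c("site", "species")]))
  if (ndup > 0L) {
    warning(ndup, " duplicate (site, species) row(s) collapsed", call. = FALSE)
    df <- df[!duplicated(df[, c("site", "species")]), , drop = FALSE]
  }

  sites <- sort(unique(df$site))
  species <- sort(unique(df$species))
  inc <- matrix(0L, length(sites), length(species),
                dimnames = list(sites, species))
  inc[cbind(match(df$site, sites), match(df$species, species))] <- 1L

  meta_cols <- intersect(c("species", "genus", "family", "growth_form", "endemic"),
                         names(df))
  meta <- unique(df[, meta_cols, drop = FALSE])
  meta <- meta[!duplicated(meta$species), , drop = FALSE]
  occurrence_matrix(inc, meta)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  low <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(low))
  out[low %in% c("true", "yes", "1", "t", "y")] <- TRUE
  out[low %in% c("false", "no", "0", "f", "n")] <- FALSE
  if (anyNA(out)) stop("endemic column must be logical/yes-no/0-1", call. = FALSE)
  out
}

#' Write an occurrence matrix as a long-format checklist CSV
#'
#' Inverse of [read_occurrence()] up to row order.
#'
#' @param occ An [occurrence_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrence <- function(occ, path) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  idx <- which(occ$incidence == 1L, arr.ind = TRUE)
  long <- data.frame(site = rownames(occ$incidence)[idx[, 1]],
                     species = colnames(occ$incidence)[idx[, 2]],
                     stringsAsFactors = FALSE)
  long <- merge(long, occ$species_meta, by = "species", sort = FALSE)
  front <- c("site", "species", "genus")
  long <- long[order(long$site, long$species),
               c(front, setdiff(names(long), front))]
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
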