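#' Assemble a run configuration for the end-to-end pipeline
#'
#' Inputs may be given as file paths (Newick / CSV, read through the
#' package's readers) or as in-memory objects. Defaults mirror the method's
#' conventions: 999 permutations, alpha 0.05, +/-1.96 SES thresholds,
#' whole-study sampling pool, unweighted median age.
#'
#' @param tree `"phylo"` object or Newick path.
#' @param clades `"clade_age_table"` or CSV path.
#' @param occurrence [occurrence_matrix()] or long-format CSV path.
#' @param regions Optional data frame (`site`, `region`) or CSV path.
#' @param out_dir Output directory for the report bundle.
#' @param n_reps Permutation replicates (default 999).
#' @param seed Integer seed for the whole run.
#' @param alpha Significance level for NTI classification.
#' @param pool `"study"` (all taxa in the phylogeny, the default) or
#'   `"occurrence"` (tips present in the checklist).
#' @param weighted_median Species-weighted median age?
#' @return A `"run_config"` list.
#' @export
run_config <- function(tree, clades, occurrence, regions = NULL,
                       out_dir = tempfile("floraphylo_run_"),
                       n_reps = 999, seed = 1, alpha = 0.05,
                       pool = c("study", "occurrence"),
                       weighted_median = FALSE) {
  pool <- match.arg(pool)
  n_reps <- assert_scalar_count(n_reps, "n_reps")
  seed <- assert_scalar_count(seed, "seed", min = 0L)
  stopifnot(alpha > 0, alpha < 1)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(clades)) clades <- read_clade_table(clades)
  if (is.character(occurrence)) occurrence <- read_occurrence(occurrence)
  if (is.character(regions)) {
    regions <- read.csv(regions, stringsAsFactors = FALSE, comment.char = "#")
  }
  validate_phylogeny(tree)
  clades <- validate_clade_table(as.data.frame(clades))
  stopifnot(inherits(occurrence, "occurrence_matrix"))
  structure(list(tree = tree, clades = clades, occurrence = occurrence,
                 regions = regions, out_dir = out_dir, n_reps = n_reps,
                 seed = seed, alpha = alpha, pool = pool,
                 weighted_median = weighted_median),
            class = "run_config")
}

#' Dry-run cross-checks of a configuration
#'
#' Returns findings rather than raising: tree coverage of the checklist
#' species, genera in the checklist absent from the clade table, empty
#' inputs, and site-ID agreement with the region map. A `"fatal"` finding
#' makes [run_pipeline()] refuse to run.
#'
#' @param config A [run_config()].
#' @return Data frame with columns `level` (`info`/`warning`/`fatal`) and
#'   `message`.
#' @export
validate_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- list()
  add <- function(level, msg) findings[[length(findings) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)

  inc <- config$occurrence$incidence
  if (ncol(inc) == 0L || sum(inc) == 0L) {
    add("fatal", "occurrence matrix is empty")
  } else {
    sp <- colnames(inc)
    on_tree <- sp %in% config$tree$tip.label
    add(if (sum(on_tree) >= 2L) "info" else "fatal",
        sprintf("tree covers %d/%d checklist species (%.1f%%)%s",
                sum(on_tree), length(sp), 100 * mean(on_tree),
                if (all(on_tree)) "" else paste0("; absent: ",
                  paste(utils::head(sp[!on_tree], 10L), collapse = ", "),
                  if (sum(!on_tree) > 10L) ", ..." else "")))
    gmiss <- setdiff(unique(config$occurrence$species_meta$genus),
                     config$clades$genus)
    if (length(gmiss)) {
      add("warning", paste0("checklist genera absent from the clade table: ",
                            paste(gmiss, collapse = ", ")))
    }
  }
  if (!is.null(config$regions)) {
    miss <- setdiff(rownames(inc), config$regions$site)
    if (length(miss)) {
      add("fatal", paste0("sites missing from the region map: ",
                          paste(miss, collapse = ", ")))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(level = character(0), message = character(0))
}

#' Run the full flora-age / community-structure pipeline
#'
#' One seeded pass over the inputs: per-site (and per-region and study-wide)
#' MDT with SES-MDT for sites, per-site NTI, geographical-origin tabulation,
#' and the richness summary, written as CSV plus a run-metadata JSON. Each
#' CSV starts with a `#`-comment header carrying the configuration hash;
#' identical configuration and seed give byte-identical outputs. Partial
#' outputs are removed if the run fails.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the computed tables plus `files` and
#'   `metadata`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- validate_run(config)
  if (any(findings$level == "fatal")) {
    stop("validation failed:\n  ",
         paste(findings$message[findings$level == "fatal"], collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(config$out_dir,
                     c(mdt = "mdt_ses.csv", nti = "nti.csv",
                       origins = "origins.csv", richness = "richness.csv",
                       metadata = "run_metadata.json"))
  names(files) <- c("mdt", "nti", "origins", "richness", "metadata")
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)

  t0 <- Sys.time()
  hash <- config_hash(config)
  set.seed(config$seed)

  inc <- config$occurrence$incidence
  meta <- config$occurrence$species_meta

  # --- MDT / SES-MDT -------------------------------------------------------
  # Per-site samples use county-specific species counts per genus; the null
  # pool carries the clade table's own (study-wide) counts.
  site_tables <- lapply(rownames(inc), function(s) {
    sp <- colnames(inc)[inc[s, ] == 1L]
    g <- meta$genus[match(sp, meta$species)]
    cnt <- table(g)
    keep <- names(cnt)[names(cnt) %in% config$clades$genus]
    if (!length(keep)) return(NULL)
    tab <- config$clades[match(keep, config$clades$genus), , drop = FALSE]
    tab$species_count <- as.integer(cnt[keep])
    tab
  })
  names(site_tables) <- rownames(inc)

  mdt_rows <- list()
  for (s in rownames(inc)) {
    tab <- site_tables[[s]]
    if (is.null(tab)) next
    m <- mdt(tab, weighted_median = config$weighted_median)
    ses <- ses_mdt(tab, config$clades, n_reps = config$n_reps, site = s)
    mdt_rows[[s]] <- cbind(data.frame(unit = s, unit_type = "site"), m,
                           ses[, c("null_mean", "null_sd", "ses", "rank_p",
                                   "classification")])
  }
  unit_mdt <- function(unit, unit_type, sp) {
    g <- meta$genus[match(sp, meta$species)]
    cnt <- table(g)
    keep <- names(cnt)[names(cnt) %in% config$clades$genus]
    tab <- config$clades[match(keep, config$clades$genus), , drop = FALSE]
    tab$species_count <- as.integer(cnt[keep])
    cbind(data.frame(unit = unit, unit_type = unit_type),
          mdt(tab, weighted_median = config$weighted_median),
          data.frame(null_mean = NA_real_, null_sd = NA_real_, ses = NA_real_,
                     rank_p = NA_real_, classification = NA_character_))
  }
  if (!is.null(config$regions)) {
    for (rg in unique(config$regions$region)) {
      members <- intersect(config$regions$site[config$regions$region == rg],
                           rownames(inc))
      sp <- colnames(inc)[colSums(inc[members, , drop = FALSE]) > 0L]
      mdt_rows[[paste0("region:", rg)]] <- unit_mdt(rg, "region", sp)
    }
  }
  mdt_rows[["all"]] <- unit_mdt("all", "study", colnames(inc))
  mdt_tab <- do.call(rbind, mdt_rows)
  rownames(mdt_tab) <- NULL

  # --- NTI -----------------------------------------------------------------
  d <- patristic_matrix(config$tree)
  covered <- intersect(colnames(inc), config$tree$tip.label)
  dropped <- ncol(inc) - length(covered)
  if (dropped > 0L) {
    message(dropped, " checklist species absent from the phylogeny ",
            "dropped from phylogenetic statistics")
  }
  pool <- if (config$pool == "study") config$tree$tip.label else covered
  nti_rows <- lapply(rownames(inc), function(s) {
    sp <- intersect(colnames(inc)[inc[s, ] == 1L], covered)
    if (length(sp) < 2L) {
      return(data.frame(site = s, n_taxa = length(sp),
                        mntd_observed = NA_real_, null_mean = NA_real_,
                        null_sd = NA_real_, nti = NA_real_, rank_p = NA_real_,
                        n_reps = 0L, classification = "degenerate",
                        stringsAsFactors = FALSE))
    }
    nti(sp, d, pool = pool, n_reps = config$n_reps, alpha = config$alpha,
        site = s)
  })
  nti_tab <- do.call(rbind, nti_rows)

  # --- origins & richness --------------------------------------------------
  org <- tabulate_origins(config$clades)
  org_tab <- org$categories
  org_tab$scope <- "category"
  sg <- data.frame(category = org$supergroups$supergroup,
                   supergroup = org$supergroups$supergroup,
                   n = org$supergroups$n, scope = "supergroup",
                   stringsAsFactors = FALSE)
  org_tab <- rbind(org_tab, sg)

  rich <- summarize_checklist(config$occurrence, config$regions)

  # --- write bundle --------------------------------------------------------
  write_with_hash <- function(df, path) {
    con <- file(path, "w")
    writeLines(paste0("# config_hash: ", hash), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_with_hash(mdt_tab, files[["mdt"]])
  write_with_hash(nti_tab, files[["nti"]])
  write_with_hash(org_tab, files[["origins"]])
  write_with_hash(rich$units, files[["richness"]])

  metadata <- list(
    package = "floraphylo",
    version = as.character(utils::packageVersion("floraphylo")),
    seed = config$seed, n_reps = config$n_reps, alpha = config$alpha,
    pool = config$pool, weighted_median = config$weighted_median,
    config_hash = hash,
    n_sites = nrow(inc), n_species = ncol(inc),
    n_species_on_tree = length(covered),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(metadata, files[["metadata"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(list(mdt = mdt_tab, nti = nti_tab, origins = org_tab,
                 richness = rich, findings = findings,
                 files = files, metadata = metadata))
}

# Hash of the scientific content of a configuration (inputs + parameters),
# independent of the output directory.
config_hash <- function(config) {
  key <- list(tree = ape::write.tree(config$tree),
              clades = config$clades,
              incidence = config$occurrence$incidence,
              species_meta = config$occurrence$species_meta,
              regions = config$regions,
              n_reps = config$n_reps, seed = config$seed,
              alpha = config$alpha, pool = config$pool,
              weighted_median = config$weighted_median)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(key, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
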