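#' Richness, endemism and growth-form summaries of a checklist
#'
#' Descriptive tabulations per site, per region and for the whole study area:
#' species / genus (/ family, when the metadata carries it) counts, endemic
#' species and endemic genus counts, growth-form breakdowns, monotypic genera,
#' and the endemic percentage. Regional counts use union semantics — a
#' species shared by two member counties is counted once — never sums of
#' county counts. A genus is endemic when every one of its checklist species
#' is endemic, and monotypic when it holds exactly one checklist species;
#' both are defined within the checklist at hand. Percentages are rounded
#' half-up to 2 decimals.
#'
#' @param occ An [occurrence_matrix()].
#' @param regions Data frame with columns `site`, `region` covering every
#'   site in `occ`. Optional (`NULL`): only site and study-wide rows then.
#' @return A list of class `"richness_summary"`: `units` (one row per site,
#'   per region, and a study-wide `"all"` row, with `unit`, `unit_type`,
#'   `n_species`, `n_genera`, `n_families` (NA without family metadata),
#'   `n_endemic_species`, `n_endemic_genera`, `n_monotypic_genera`,
#'   `endemic_pct`, one count column per growth form) and `growth_forms`
#'   (study-wide species counts per growth form).
#' @export
summarize_checklist <- function(occ, regions = NULL) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  inc <- occ$incidence
  meta <- occ$species_meta

  if (!is.null(regions)) {
    stopifnot(all(c("site", "region") %in% names(regions)))
    unmapped <- setdiff(rownames(inc), regions$site)
    if (length(unmapped)) {
      stop("site(s) missing from the region map: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
  }

  unit_row <- function(unit, unit_type, species) {
    m <- meta[meta$species %in% species, , drop = FALSE]
    gsz <- table(m$genus)
    end_by_genus <- tapply(m$endemic, m$genus, all)
    forms <- as.integer(table(factor(m$growth_form, levels = GROWTH_FORMS)))
    names(forms) <- gsub(" ", "_", GROWTH_FORMS)
    cbind(
      data.frame(unit = unit, unit_type = unit_type,
                 n_species = nrow(m),
                 n_genera = length(gsz),
                 n_families = if ("family" %in% names(m))
                   length(unique(m$family)) else NA_integer_,
                 n_endemic_species = sum(m$endemic),
                 n_endemic_genera = sum(end_by_genus),
                 n_monotypic_genera = sum(gsz == 1L),
                 endemic_pct = if (nrow(m))
                   round_half_up(100 * sum(m$endemic) / nrow(m)) else NA_real_,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(forms)))
  }

  site_species <- lapply(rownames(inc), function(s)
    colnames(inc)[inc[s, ] == 1L])
  names(site_species) <- rownames(inc)

  rows <- lapply(rownames(inc), function(s)
    unit_row(s, "site", site_species[[s]]))

  if (!is.null(regions)) {
    for (rg in unique(regions$region)) {
      members <- intersect(regions$site[regions$region == rg], rownames(inc))
      sp <- unique(unlist(site_species[members]))  # union, not sum
      rows <- c(rows, list(unit_row(rg, "region", sp)))
    }
  }
  rows <- c(rows, list(unit_row("all", "study", colnames(inc))))
  units <- do.call(rbind, rows)

  gf <- data.frame(growth_form = GROWTH_FORMS,
                   n_species = as.integer(table(factor(meta$growth_form,
                                                       levels = GROWTH_FORMS))),
                   stringsAsFactors = FALSE)
  structure(list(units = units, growth_forms = gf),
            class = "richness_summary")
}

#' @export
print.richness_summary <- function(x, ...) {
  all_row <- x$units[x$units$unit_type == "study", ]
  cat("richness_summary:", all_row$n_species, "species,",
      all_row$n_genera, "genera;", all_row$endemic_pct, "% endemic\n")
  invisible(x)
}
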