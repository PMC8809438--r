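#' Simulate a dated ultrametric phylogeny
#'
#' Yule trees are simulated forward from a crown pair: starting with two
#' lineages at the root, each of the k extant lineages speciates at rate
#' `birth`, and the present is taken immediately before the speciation event
#' that would create tip n+1, so the expected tree depth is
#' \eqn{\sum_{k=2}^{n} 1/(\lambda k)}. Birth-death trees (`death > 0`) are
#' delegated to [ape::rphylo()], conditioned on `n_tips` extant species.
#'
#' @param n_tips Number of tips, >= 2.
#' @param model `"yule"` or `"birth-death"`.
#' @param birth Speciation rate (> death).
#' @param death Extinction rate (>= 0; forced 0 for `"yule"`).
#' @param seed Optional integer seed (scoped to this call).
#' @return A rooted ultrametric `"phylo"` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "birth-death"),
                          birth = 1, death = 0, seed = NULL) {
  model <- match.arg(model)
  n_tips <- assert_scalar_count(n_tips, "n_tips", min = 2L)
  if (model == "yule") death <- 0
  if (!is.numeric(birth) || !is.numeric(death) || death < 0 || birth <= death) {
    stop("need birth > death >= 0", call. = FALSE)
  }
  tree <- with_seed_(seed, {
    if (model == "yule") sim_yule_(n_tips, birth)
    else ape::rphylo(n_tips, birth = birth, death = death)
  })
  tree$tip.label <- paste0("t", seq_len(n_tips))
  validate_phylogeny(tree)
  tree
}

# Forward pure-birth simulation. Lineage bookkeeping: each lineage id records
# its birth time; a split closes the lineage and opens two children.
sim_yule_ <- function(n, lambda) {
  birth_t <- c(0, 0)            # crown start: two lineages at the root
  split_t <- rep(NA_real_, 2)
  children <- vector("list", 2)
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + rexp(1, lambda * k)
    who <- active[sample.int(k, 1L)]
    id1 <- length(birth_t) + 1L
    id2 <- id1 + 1L
    birth_t <- c(birth_t, t, t)
    split_t <- c(split_t, NA_real_, NA_real_)
    children[[who]] <- c(id1, id2)
    children[c(id1, id2)] <- list(NULL, NULL)
    split_t[who] <- t
    active <- c(setdiff(active, who), id1, id2)
  }
  present <- t + rexp(1, lambda * n)  # stop just before the next speciation
  tip_no <- 0L
  build <- function(id) {
    len <- (if (is.null(children[[id]])) present else split_t[id]) - birth_t[id]
    if (is.null(children[[id]])) {
      tip_no <<- tip_no + 1L
      sprintf("t%d:%.12g", tip_no, len)
    } else {
      sprintf("(%s,%s):%.12g", build(children[[id]][1]),
              build(children[[id]][2]), len)
    }
  }
  txt <- sprintf("(%s,%s);", build(1L), build(2L))
  ape::read.tree(text = txt)
}

#' Distribution specification for the clade-table simulator
#'
#' @param dist One of `"constant"`, `"uniform"`, `"lognormal"`,
#'   `"exponential"` (ages) or `"constant"`, `"geometric"`, `"poisson"`
#'   (counts).
#' @param ... Parameters: `value` (constant), `min`/`max` (uniform),
#'   `meanlog`/`sdlog` (lognormal), `rate` (exponential), `mean` (geometric /
#'   poisson; both are shifted by one so counts are >= 1).
#' @return A `"dist_spec"` list.
#' @export
dist_spec <- function(dist, ...) {
  structure(list(dist = dist, params = list(...)), class = "dist_spec")
}

draw_dist <- function(spec, n, what = c("age", "count")) {
  what <- match.arg(what)
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  x <- switch(spec$dist,
    constant = rep(p$value, n),
    uniform = runif(n, p$min, p$max),
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    exponential = rexp(n, p$rate),
    geometric = 1 + rgeom(n, prob = 1 / p$mean),   # mean = p$mean per shift
    poisson = 1 + rpois(n, p$mean - 1),
    stop("unknown distribution: ", spec$dist, call. = FALSE))
  if (what == "age" && any(x <= 0)) stop("age distribution produced a nonpositive age",
                                         call. = FALSE)
  if (what == "count") x <- as.integer(round(x))
  x
}

dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$dist,
    constant = p$value,
    uniform = (p$min + p$max) / 2,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    exponential = 1 / p$rate,
    geometric = p$mean,
    poisson = p$mean)
}

# Defaults emulate the studied flora: lognormal ages matched to a 19.4 Ma
# mean and 13.75 Ma median; heavy-tailed species counts averaging ~4.8 per
# genus (1911 species over 397 genera); origin frequencies from the published
# 126-clade tabulation.
default_age_dist <- function() {
  dist_spec("lognormal", meanlog = log(13.75),
            sdlog = sqrt(2 * log(19.40 / 13.75)))
}
default_count_dist <- function() dist_spec("geometric", mean = 4.8)
default_origin_probs <- function() {
  c("Eastern Asia" = 40, "Tethyan" = 18, "Northern Hemisphere unknown" = 28,
    "North America" = 3, "Central Asia" = 3, "Southwest Asia" = 2,
    "Eurasia" = 1, "Southwest China" = 1, "Northwest China" = 1,
    "Qinghai-Tibet plateau" = 1, "Eastern Asia or Western North America" = 1,
    "Central Asia or the Qinghai-Tibet plateau" = 1, "Africa" = 2,
    "Southern Hemisphere unknown" = 1, "Unknown" = 23) / 126
}
default_class_probs <- function() {
  c(dominant = 11, common = 45, occasional = 63, endemic = 7) / 126
}

#' Simulate a genus-level clade-age table
#'
#' Crown ages, species counts, origin labels and genus classes are drawn
#' independently per clade from the given specifications. Defaults emulate a
#' temperate mountain flora: lognormal ages (mean 19.4 Ma, median 13.75 Ma),
#' geometric species counts (mean 4.8), and origin frequencies dominated by
#' East Asian and Tethyan categories.
#'
#' @param n_clades Number of clades (default 126).
#' @param age_dist,count_dist [dist_spec()] objects for crown ages (Ma) and
#'   species counts.
#' @param origin_probs Named probability vector over origin categories
#'   (must sum to 1).
#' @param class_probs Named probability vector over genus classes.
#' @param seed Optional integer seed (scoped to this call).
#' @return A `"clade_age_table"` with genera `G001..`.
#' @export
simulate_clade_table <- function(n_clades = 126,
                                 age_dist = default_age_dist(),
                                 count_dist = default_count_dist(),
                                 origin_probs = default_origin_probs(),
                                 class_probs = default_class_probs(),
                                 seed = NULL) {
  n_clades <- assert_scalar_count(n_clades, "n_clades")
  for (pv in list(origin_probs, class_probs)) {
    if (is.null(names(pv)) || any(pv < 0) || abs(sum(pv) - 1) > 1e-8) {
      stop("probabilities must be named, nonnegative and sum to 1", call. = FALSE)
    }
  }
  with_seed_(seed, {
    clade_age_table(
      genus = sprintf("G%03d", seq_len(n_clades)),
      age_ma = draw_dist(age_dist, n_clades, "age"),
      species_count = draw_dist(count_dist, n_clades, "count"),
      origin = sample(names(origin_probs), n_clades, replace = TRUE,
                      prob = origin_probs),
      genus_class = sample(names(class_probs), n_clades, replace = TRUE,
                           prob = class_probs))
  })
}

#' Describe a community-assembly scenario
#'
#' @param regime `"neutral"`, `"filtering"` or `"repulsion"`. At
#'   `strength = 0` every regime reduces to neutral (uniform) sampling.
#' @param strength Nonnegative effect strength.
#' @param n_sites Number of sites to assemble.
#' @param richness Species richness per site: a single value or a
#'   `c(min, max)` range sampled uniformly per site.
#' @param seed Optional integer seed.
#' @param endemic_rate Bernoulli rate for the per-species endemic flag.
#' @return An `"assembly_scenario"` list.
#' @export
assembly_scenario <- function(regime = c("neutral", "filtering", "repulsion"),
                              strength = 0, n_sites = 10, richness = 10,
                              seed = NULL, endemic_rate = 0.3) {
  regime <- match.arg(regime)
  stopifnot(is.numeric(strength), length(strength) == 1L, strength >= 0,
            length(richness) %in% 1:2, all(richness >= 2))
  structure(list(regime = regime, strength = strength,
                 n_sites = assert_scalar_count(n_sites, "n_sites"),
                 richness = as.integer(richness), seed = seed,
                 endemic_rate = endemic_rate),
            class = "assembly_scenario")
}

# Species proportions per growth form from a temperate-mountain checklist
# (22/197/7/224/1452/9 of 1911).
growth_form_probs <- function() {
  stats::setNames(c(22, 197, 7, 224, 1452, 9) / 1911, GROWTH_FORMS)
}

#' Assemble site-by-species communities on a phylogeny
#'
#' Draws `n_sites` communities from the tips of `tree` under the scenario's
#' regime. Neutral: uniform subsets of the tips. Filtering: a focal tip is
#' chosen uniformly per site and tips are sampled without replacement with
#' weight `exp(-strength * d(tip, focal))`, concentrating each community
#' around one point of the tree. Repulsion: tips are added sequentially with
#' weight `(min distance to the tips already chosen)^strength`, pushing
#' communities apart on the tree. Species metadata (genus from the tip-label
#' prefix before `"_"`, growth form, endemic flag) is drawn alongside.
#'
#' @param tree A dated `"phylo"`.
#' @param scenario An [assembly_scenario()].
#' @return An [occurrence_matrix()] over the sampled tips, sites
#'   `site01..`.
#' @export
simulate_communities <- function(tree, scenario) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  validate_phylogeny(tree)
  tips <- tree$tip.label
  n <- length(tips)
  rmax <- max(scenario$richness)
  if (rmax > n) stop("richness exceeds the number of tips", call. = FALSE)
  d <- patristic_matrix(tree)

  with_seed_(scenario$seed, {
    inc <- matrix(0L, scenario$n_sites, n,
                  dimnames = list(sprintf("site%02d", seq_len(scenario$n_sites)),
                                  tips))
    for (s in seq_len(scenario$n_sites)) {
      r <- if (length(scenario$richness) == 2L)
        sample(seq(scenario$richness[1], scenario$richness[2]), 1L)
      else scenario$richness
      picked <- draw_community(d, n, r, scenario$regime, scenario$strength)
      inc[s, picked] <- 1L
    }
    meta <- data.frame(
      species = tips,
      genus = ifelse(grepl("_", tips), sub("_.*$", "", tips), tips),
      growth_form = sample(GROWTH_FORMS, n, replace = TRUE,
                           prob = growth_form_probs()),
      endemic = runif(n) < scenario$endemic_rate,
      stringsAsFactors = FALSE)
    occurrence_matrix(inc, meta)
  })
}

draw_community <- function(d, n, r, regime, strength) {
  if (regime == "neutral" || strength == 0) return(sample.int(n, r))
  if (regime == "filtering") {
    focal <- sample.int(n, 1L)
    w <- exp(-strength * d[, focal])
    return(sample.int(n, r, prob = w))
  }
  # repulsion: sequential, weight = (min distance to chosen)^strength
  picked <- sample.int(n, 1L)
  while (length(picked) < r) {
    mind <- apply(d[, picked, drop = FALSE], 1, min)
    w <- mind^strength
    w[picked] <- 0
    picked <- c(picked, sample.int(n, 1L, prob = w))
  }
  picked
}

#' Deterministic small fixture for integration tests and examples
#'
#' The `"kunlun-mini"` profile is a scaled-down analogue of a
#' county-partitioned mountain flora: a 60-tip dated Yule tree whose tips are
#' species grouped into 20 genera, a 20-clade age table whose species counts
#' match the checklist, 8 sites in 4 regions assembled under mild habitat
#' filtering, and an endemic fraction of 0.30 set exactly by construction.
#' The fixture is rebuilt from a fixed internal seed, so it is identical on
#' every call.
#'
#' @param profile Fixture name; only `"kunlun-mini"` is defined.
#' @return List with elements `tree`, `clades`, `occurrence`, `regions`.
#' @export
make_fixture <- function(profile = "kunlun-mini") {
  if (!identical(profile, "kunlun-mini")) {
    stop("unknown fixture profile: ", profile, call. = FALSE)
  }
  withr::with_seed(4271, {
    n_genera <- 20L
    n_species <- 60L
    sizes <- as.vector(rmultinom(1, n_species - n_genera,
                                 rep(1 / n_genera, n_genera))) + 1L
    species <- unlist(lapply(seq_len(n_genera), function(g)
      sprintf("G%02d_s%d", g, seq_len(sizes[g]))))

    tree <- simulate_tree(n_species, "yule", birth = 0.15)
    tree$tip.label <- sample(species)

    clades <- simulate_clade_table(n_genera)
    clades$genus <- sprintf("G%02d", seq_len(n_genera))
    clades$species_count <- sizes

    occ <- simulate_communities(
      tree,
      assembly_scenario("filtering", strength = 0.5, n_sites = 8L,
                        richness = c(18L, 30L)))
    # endemic fraction 0.30 exactly, by construction
    nsp <- nrow(occ$species_meta)
    flag <- rep(FALSE, nsp)
    flag[sample.int(nsp, round(0.3 * nsp))] <- TRUE
    occ$species_meta$endemic <- flag

    regions <- data.frame(
      site = rownames(occ$incidence),
      region = rep(c("east", "west", "central-north", "central-south"),
                   each = 2),
      stringsAsFactors = FALSE)
    list(tree = tree, clades = clades, occurrence = occ, regions = regions)
  })
}
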